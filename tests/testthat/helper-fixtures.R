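# Fixture builders and independent oracles shared across the suite.

# assemble an ivs_receptor directly from an atom table (bypasses PDB I/O
# for geometric fixtures)
make_receptor <- function(atoms, pdb_id = "FIX", ligand = NULL) {
  defaults <- list(alt = NA_character_, o = 1, is_hetero = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  structure(list(pdb_id = pdb_id, atoms = tibble::as_tibble(atoms),
                 removed = NULL, ligand = ligand),
            class = "ivs_receptor")
}

# fixed-width PDB ATOM/HETATM line
pdb_line <- function(type, serial, name, resn, chain, resi, x, y, z,
                     occ = 1.00, alt = " ", element = NULL) {
  element <- element %||% substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resi, x, y, z, occ, 0, element)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a small protein-plus-clutter PDB fixture; returns the path
write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# ten-residue glycine-ish backbone to keep cleaned structures non-empty
protein_lines <- function(chain = "A", z = 0) {
  unlist(lapply(1:10, function(i) {
    c(pdb_line("ATOM", i * 4 - 3, " N  ", "GLY", chain, i, i * 3.0, 0, z),
      pdb_line("ATOM", i * 4 - 2, " CA ", "GLY", chain, i, i * 3.0 + 1, 0.5, z),
      pdb_line("ATOM", i * 4 - 1, " C  ", "GLY", chain, i, i * 3.0 + 2, 0, z),
      pdb_line("ATOM", i * 4, " O  ", "GLY", chain, i, i * 3.0 + 2, 1.2, z))
  }))
}

# planar hexagonal carbon ring (benzene-like) as pose atom tibble,
# centred at `center`, normal along `normal`
hex_ring <- function(center = c(0, 0, 0), normal = c(0, 0, 1), radius = 1.4) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  ang <- 2 * pi * (0:5) / 6
  tibble::tibble(
    element = "C",
    x = center[1] + radius * (cos(ang) * u[1] + sin(ang) * v[1]),
    y = center[2] + radius * (cos(ang) * u[2] + sin(ang) * v[2]),
    z = center[3] + radius * (cos(ang) * u[3] + sin(ang) * v[3])
  )
}

# receptor with one aromatic-residue ring built from hex_ring coordinates
ring_receptor <- function(resid = "TYR", center = c(0, 0, 0),
                          normal = c(0, 0, 1), chain = "A", resno = 119L) {
  ring <- hex_ring(center, normal)
  names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  make_receptor(tibble::tibble(
    eleno = seq_len(6), elety = names, resid = resid, chain = chain,
    resno = resno, x = ring$x, y = ring$y, z = ring$z, elesy = "C"
  ), pdb_id = "RING")
}

# random rigid rotation matrix (seeded by caller)
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent brute-force consensus oracle: plain loops, no grouping
# machinery shared with the implementation
brute_force_consensus <- function(hits, mapping, compounds) {
  passed <- hits[hits$passed, , drop = FALSE]
  u_of <- stats::setNames(mapping$uniprot_id, mapping$pdb_id)
  passed <- passed[passed$pdb_id %in% names(u_of), , drop = FALSE]
  passed$uniprot_id <- unname(u_of[passed$pdb_id])
  out <- list()
  for (u in sort(unique(passed$uniprot_id))) {
    sub <- passed[passed$uniprot_id == u, , drop = FALSE]
    if (!all(compounds %in% sub$compound_id)) next
    best <- sapply(compounds, function(cid) {
      min(sub$V0[sub$compound_id == cid])
    })
    out[[u]] <- list(uniprot_id = u, retrieval_count = nrow(sub),
                     best = best)
  }
  out
}

# random passed-hit table for oracle comparisons
random_hit_table <- function(n_targets, n_compounds = 3, n_uniprot = NULL) {
  n_uniprot <- n_uniprot %||% max(2, ceiling(n_targets / 3))
  pdb <- sprintf("P%03d", seq_len(n_targets))
  mapping <- tibble::tibble(
    pdb_id = pdb,
    uniprot_id = sprintf("U%03d", sample.int(n_uniprot, n_targets,
                                             replace = TRUE))
  )
  hits <- expand.grid(compound_id = sprintf("Q%d", seq_len(n_compounds)),
                      pdb_id = pdb, stringsAsFactors = FALSE)
  hits <- tibble::as_tibble(hits)
  hits$V0 <- round(stats::runif(nrow(hits), -11, -5), 2)
  hits$V <- hits$V0 / -6.5
  hits$passed <- stats::runif(nrow(hits)) < 0.35
  list(hits = hits, mapping = mapping,
       compounds = sprintf("Q%d", seq_len(n_compounds)))
}
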