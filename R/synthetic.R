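# Synthetic inputs with known ground truth: recorded affinity matrices
# with planted true targets, toy receptor/ligand structure files, and
# decoy candidate libraries. These emulate the statistical structure the
# screen assumes -- true targets bind the query better than decoys and
# background -- so every stage is testable offline; they do not simulate
# real docking energetics.

#' Specification of a synthetic screening panel
#'
#' Affinities are drawn from normal distributions: non-binder query
#' affinities ~ N(`base_mean`, `base_sd`), with `planted_shift` (negative)
#' added on planted true (compound, target) pairs, and decoy affinities ~
#' N(`decoy_mean`, `decoy_sd`). The defaults straddle the -7.5 kcal/mol
#' retention threshold so both filter branches are exercised.
#'
#' @param n_targets Number of panel structures.
#' @param n_planted Number of true targets (planted for every compound).
#' @param base_mean,base_sd Background query affinity, kcal/mol.
#' @param planted_shift Added to planted pairs, kcal/mol (negative).
#' @param decoy_mean,decoy_sd Decoy affinity distribution, kcal/mol.
#' @param n_compounds Number of query compounds.
#' @param n_decoys Decoys per query (default 10).
#' @param seed RNG seed; generation is deterministic per seed.
#' @return Validated list of class `ivs_synth_spec`.
#' @export
synthetic_panel_spec <- function(n_targets = 50, n_planted = 2,
                                 base_mean = -6.0, base_sd = 0.8,
                                 planted_shift = -3.0,
                                 decoy_mean = -6.5, decoy_sd = 0.8,
                                 n_compounds = 3, n_decoys = 10,
                                 seed = 1) {
  if (n_planted > n_targets) {
    abort("n_planted must not exceed n_targets",
          class = "ivs_parameter_error")
  }
  if (base_sd < 0 || decoy_sd < 0) {
    abort("standard deviations must be >= 0", class = "ivs_parameter_error")
  }
  if (n_planted > 0 && planted_shift >= 0) {
    abort("planted_shift must be negative (stronger binding)",
          class = "ivs_parameter_error")
  }
  structure(as.list(environment()), class = "ivs_synth_spec")
}

#' Generate a recorded affinity table with planted true targets
#'
#' Emits everything a replay screen needs plus the ground-truth key:
#' query and decoy affinity tables, the decoy map, a synthetic
#' PDB-to-UniProt mapping (one accession per structure), and the planted
#' (compound, target) pairs.
#'
#' @param spec An [synthetic_panel_spec()].
#' @return List with `affinities`, `decoy_affinities`, `decoy_map`,
#'   `panel`, `compounds` and `truth` tibbles.
#' @export
generate_affinity_table <- function(spec = synthetic_panel_spec()) {
  stopifnot(inherits(spec, "ivs_synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  pdb_ids <- sprintf("T%03d", seq_len(spec$n_targets))
  compound_ids <- sprintf("Q%d", seq_len(spec$n_compounds))
  decoy_ids <- sprintf("D%02d", seq_len(spec$n_decoys))
  planted <- pdb_ids[seq_len(spec$n_planted)]

  aff <- tidyr::crossing(compound_id = compound_ids, pdb_id = pdb_ids) |>
    mutate(
      planted = .data$pdb_id %in% planted,
      affinity_kcal_mol = rnorm(n(), spec$base_mean, spec$base_sd) +
        ifelse(.data$planted, spec$planted_shift, 0)
    )
  decoy_aff <- tidyr::crossing(compound_id = decoy_ids, pdb_id = pdb_ids) |>
    mutate(affinity_kcal_mol = rnorm(n(), spec$decoy_mean, spec$decoy_sd))

  list(
    affinities = select(aff, "compound_id", "pdb_id", "affinity_kcal_mol"),
    decoy_affinities = decoy_aff,
    decoy_map = tidyr::crossing(query_id = compound_ids,
                                decoy_id = decoy_ids),
    panel = tibble(pdb_id = pdb_ids,
                   uniprot_id = sprintf("U%05d", seq_len(spec$n_targets)),
                   molecule_name = sprintf("synthetic target %d",
                                           seq_len(spec$n_targets))),
    compounds = tibble(id = compound_ids),
    truth = filter(aff, .data$planted)[c("compound_id", "pdb_id")]
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a toy receptor/ligand complex
#'
#' Writes a pseudo-protein built from carbon pseudo-atoms on a regular
#' lattice filling a sphere, with a pocket of known centre carved out
#' (a spherical cavity one cavity-radius below the surface, opened by a
#' narrow channel), plus a small rigid ligand that fits the cavity.
#' Geometry-only: it tests plumbing and pocket detection, not chemistry.
#' Output files are byte-identical for a fixed spec.
#'
#' @param cavity_radius Cavity radius, A.
#' @param shell_thickness Protein shell around the cavity, A.
#' @param ligand_size Ligand heavy-atom count (>= 3).
#' @param lattice Pseudo-atom lattice spacing, A.
#' @param carve_cavity Set `FALSE` to emit a convex solid ball (a
#'   no-pocket negative control).
#' @param dir Output directory.
#' @return List with `receptor` and `ligand` file paths, the true
#'   `cavity_center`, and the spec fields.
#' @export
generate_toy_complex <- function(cavity_radius = 5, shell_thickness = 6,
                                 ligand_size = 5, lattice = 2.0,
                                 carve_cavity = TRUE, dir = tempdir()) {
  stopifnot(cavity_radius > 0, shell_thickness > 0, ligand_size >= 3)
  r_out <- cavity_radius + shell_thickness
  ax <- seq(-r_out, r_out, by = lattice)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- rowSums(pts^2) <= r_out^2
  center <- c(0, 0, r_out - cavity_radius)
  if (carve_cavity) {
    d2cav <- rowSums(sweep(pts, 2, center)^2)
    in_channel <- pts[, 1]^2 + pts[, 2]^2 <= 2^2 & pts[, 3] > center[3]
    keep <- keep & d2cav > cavity_radius^2 & !in_channel
  }
  pts <- pts[keep, , drop = FALSE]

  # rigid ligand: ring of carbons of radius ~1.4 A around the cavity centre
  ang <- 2 * pi * (seq_len(ligand_size) - 1) / ligand_size
  lig <- cbind(center[1] + 1.4 * cos(ang), center[2] + 1.4 * sin(ang),
               center[3] + 0)
  rog <- sqrt(mean(rowSums(sweep(lig, 2, colMeans(lig))^2)))
  if (carve_cavity && rog >= cavity_radius) {
    warn(paste0("ligand radius of gyration (", round(rog, 2),
                " A) is not smaller than the cavity radius (",
                cavity_radius, " A); it will not fit"))
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  receptor_path <- file.path(dir, "toy_receptor.pdb")
  ligand_path <- file.path(dir, "toy_ligand.sdf")
  bio3d::write.pdb(
    file = receptor_path, type = rep("ATOM", nrow(pts)),
    eleno = seq_len(nrow(pts)), elety = rep("C", nrow(pts)),
    resid = rep("PSE", nrow(pts)), chain = rep("A", nrow(pts)),
    resno = seq_len(nrow(pts)), xyz = as.numeric(t(pts)),
    o = rep(1, nrow(pts)), b = rep(0, nrow(pts)),
    elesy = rep("C", nrow(pts))
  )
  writeLines(.sdf_v2000("toy_ligand", lig,
                        cbind(seq_len(ligand_size),
                              c(seq_len(ligand_size)[-1], 1L), 1L)),
             ligand_path)
  list(receptor = receptor_path, ligand = ligand_path,
       cavity_center = center, cavity_radius = cavity_radius,
       shell_thickness = shell_thickness, ligand_size = ligand_size,
       carve_cavity = carve_cavity)
}

# minimal V2000 writer for generated carbon skeletons
.sdf_v2000 <- function(title, coords, bonds, elements = "C") {
  n <- nrow(coords)
  elements <- rep(elements, length.out = n)
  c(
    title, "  ivscreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], elements),
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3]),
    "M  END", "$$$$"
  )
}

#' Generate a decoy candidate library around target properties
#'
#' Emits acyclic polyol/polyether carbon chains spanning the MW/HBD/HBA
#' matching windows of a query: hydroxyl count sets HBD, total oxygen
#' count sets HBA, chain length tunes MW. At least `n_guaranteed`
#' candidates are constructed inside all windows (chains are structurally
#' dissimilar from ring-bearing queries by construction); the remainder
#' spread over and beyond the windows so selection is non-trivial.
#'
#' @param query_props One-row tibble with `mw`, `hbd`, `hba` (e.g. from
#'   [compound_properties()]).
#' @param n_candidates Library size.
#' @param seed RNG seed; the library is deterministic per seed.
#' @param n_guaranteed Candidates forced inside the matching windows.
#' @return Compound tibble (`id`, `name`, `structure`, `formula`,
#'   `role = "decoy"`) with properties appended.
#' @export
generate_decoy_library <- function(query_props, n_candidates = 50, seed = 1,
                                   n_guaranteed = 12) {
  stopifnot(is.data.frame(query_props), nrow(query_props) == 1,
            all(c("mw", "hbd", "hba") %in% names(query_props)),
            n_candidates >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  qmw <- query_props$mw
  qhbd <- query_props$hbd
  qhba <- query_props$hba
  smiles <- character(n_candidates)
  for (i in seq_len(n_candidates)) {
    inside <- i <= n_guaranteed
    hbd_i <- max(0L, qhbd + sample(-1:1, 1))
    hba_i <- max(hbd_i, qhba + sample(-1:1, 1))
    if (abs(hba_i - qhba) > 1) hba_i <- qhba + 1L   # clamp back into window
    jitter <- if (inside) stats::runif(1, -10, 10) else
      stats::runif(1, -45, 45)
    nc <- max(hbd_i + 2L,
              round((qmw + jitter - 2.016 - 15.999 * hba_i) / 14.027))
    smiles[i] <- .chain_smiles(nc, hbd_i, hba_i - hbd_i)
  }
  lib <- tibble(
    id = sprintf("D%03d", seq_len(n_candidates)),
    name = sprintf("decoy candidate %d", seq_len(n_candidates)),
    structure = smiles, role = "decoy"
  )
  compound_properties(lib)
}

# linear carbon chain with n_oh hydroxyl substituents and n_ether backbone
# oxygens at seeded random positions
.chain_smiles <- function(nc, n_oh, n_ether) {
  interior <- 2:(nc - 1)
  oh_pos <- sort(sample(interior, min(n_oh, length(interior))))
  gaps <- setdiff(2:(nc - 2), c(oh_pos, oh_pos - 1))
  eth_pos <- sort(sample(gaps, min(n_ether, length(gaps))))
  toks <- character(nc)
  for (j in seq_len(nc)) {
    toks[j] <- if (j %in% oh_pos) "C(O)" else "C"
    if (j %in% eth_pos) toks[j] <- paste0(toks[j], "O")
  }
  paste0(toks, collapse = "")
}
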