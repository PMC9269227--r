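# Compound registry: structures, formulas, Lipinski-style properties,
# ESI-MS identity checks.

# Integer nominal masses of the most abundant isotope; unit-resolution
# positive-mode ESI-MS reports [M+H]+ = nominal mass + 1.
.NOMINAL_MASS <- c(
  H = 1L, B = 11L, C = 12L, N = 14L, O = 16L, F = 19L, Na = 23L, Mg = 24L,
  Si = 28L, P = 31L, S = 32L, Cl = 35L, K = 39L, Ca = 40L, Br = 79L, I = 127L
)

# IUPAC 2021 standard atomic weights (abridged), Da.
.ATOMIC_WEIGHT <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

# Usual organic valences used to infer implicit hydrogens on SDF heavy atoms.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Query compounds of the hemp-leaf screen
#'
#' The three phytocannabinoids screened by the package's worked examples:
#' compound 1 (2alpha-hydroxy-delta-3,7-cannabitriol, a hydroxylated
#' cannabitriol assigned the 1R,2R,6R configuration; the SMILES is encoded
#' from the assigned name and verified against its C21H30O3 formula),
#' cannabidiol (CBD) and cannabidiolic acid (CBDA) with their standard
#' stereochemistry.
#'
#' @return A tibble with columns `id`, `name`, `structure` (SMILES),
#'   `formula` (Hill notation) and `role` (`"query"`).
#' @export
#' @examples
#' hemp_compounds()
hemp_compounds <- function() {
  tibble(
    id = c("1", "2", "3"),
    name = c("2a-hydroxy-3,7-cannabitriol", "cannabidiol", "cannabidiolic acid"),
    structure = c(
      "CCCCCc1cc(O)c([C@H]2[C@H](O)C(=C)CC[C@H]2C(C)=C)c(O)c1",
      "CCCCCc1cc(O)c([C@@H]2C=C(C)CC[C@H]2C(=C)C)c(O)c1",
      "CCCCCc1cc(O)c([C@@H]2C=C(C)CC[C@H]2C(=C)C)c(O)c1C(=O)O"
    ),
    formula = c("C21H30O3", "C21H30O2", "C22H30O4"),
    role = "query"
  )
}

#' Read compounds from a SMILES or SDF file
#'
#' SMILES files (`.smi`) hold one record per line: structure, whitespace, id.
#' SDF molecule titles become ids. Unnamed records get `M1`, `M2`, ...
#'
#' @param path File path ending in `.smi`/`.smiles` or `.sdf`.
#' @param role Role assigned to all records, `"query"` or `"decoy"`.
#' @return Tibble with columns `id`, `name`, `structure`, `formula`, `role`.
#' @export
read_compounds <- function(path, role = c("query", "decoy")) {
  role <- match.arg(role)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles", "txt")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    structure <- map_chr(parts, 1)
    id <- map_chr(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("M", i)
    })
  } else if (ext == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    structure <- unname(ChemmineOB::propOB(sdf)$cansmi)
    id <- unname(ChemmineR::sdfid(sdf))
    blank <- !nzchar(id)
    id[blank] <- paste0("M", which(blank))
  } else {
    abort(paste0("unsupported compound file extension: '", ext, "'"),
          class = "ivs_format_error")
  }
  if (anyDuplicated(id)) {
    abort("duplicate compound ids in input", class = "ivs_format_error")
  }
  out <- tibble(id = id, name = id, structure = structure, role = role)
  out$formula <- map_chr(out$structure, function(s) .parse_mol(s)$formula)
  select(out, "id", "name", "structure", "formula", "role")
}

# Parse one SMILES into an atom/bond graph via Open Babel, with implicit
# hydrogens inferred from default valences (SDF output is kekulised).
# Single-heavy-atom molblocks defeat ChemmineR's reader, so those atom lines
# are taken from the fixed-width V2000 block directly.
.parse_mol <- function(structure, id = "query") {
  if (!nzchar(structure)) {
    abort(paste0("empty structure for compound '", id, "'"),
          class = "ivs_structure_error")
  }
  sdf_txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(structure, " ", id, "\n")),
    error = function(e) "")
  lines <- unlist(strsplit(sdf_txt, "\n", fixed = TRUE))
  if (length(lines) < 4) {
    abort(paste0("structure for compound '", id, "' could not be parsed: '",
                 structure, "'"), class = "ivs_structure_error")
  }
  natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(natoms) || natoms < 1) {
    abort(paste0("structure for compound '", id, "' could not be parsed: '",
                 structure, "'"), class = "ivs_structure_error")
  }
  atom_lines <- lines[5:(4 + natoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge <- dplyr::case_match(chg_code, 1 ~ 3, 2 ~ 2, 3 ~ 1, 5 ~ -1,
                              6 ~ -2, 7 ~ -3, .default = 0)
  bonds <- if (!is.na(nbonds) && nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    tibble(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  # "M  CHG" property lines override the atom-block charge column
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    f <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) {
      charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  deg_order <- rep(0, natoms)
  heavy_deg <- rep(0L, natoms)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]; o <- bonds$order[i]
    deg_order[a] <- deg_order[a] + o
    deg_order[b] <- deg_order[b] + o
    heavy_deg[a] <- heavy_deg[a] + 1L
    heavy_deg[b] <- heavy_deg[b] + 1L
  }
  val <- unname(.DEFAULT_VALENCE[element])
  val[is.na(val)] <- deg_order[is.na(val)]
  n_h <- pmax(0, val + charge - deg_order)
  n_h[element == "N" & charge > 0] <- pmax(0, 4 - deg_order)[element == "N" & charge > 0]
  atoms <- tibble(
    idx = seq_len(natoms), element = element, charge = charge,
    n_h = as.integer(round(n_h)), heavy_degree = heavy_deg
  )
  list(atoms = atoms, bonds = bonds, formula = .hill_formula(atoms))
}

.hill_formula <- function(atoms) {
  counts <- table(atoms$element)
  counts["H"] <- sum(atoms$n_h) + ifelse("H" %in% names(counts), counts[["H"]], 0)
  counts <- counts[counts > 0]
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(map_chr(ord, function(e) {
    paste0(e, ifelse(counts[[e]] > 1, counts[[e]], ""))
  }), collapse = "")
}

.parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  els <- sub("[0-9]*$", "", toks)
  ns <- as.integer(sub("^[A-Z][a-z]?", "", paste0(toks, "")))
  ns[is.na(ns)] <- 1L
  bad <- setdiff(els, names(.NOMINAL_MASS))
  if (length(bad)) {
    abort(paste0("unknown element(s) in formula '", formula, "': ",
                 paste(bad, collapse = ", ")), class = "ivs_structure_error")
  }
  setNames(ns, els)
}

#' Nominal mass of a molecular formula
#'
#' Integer sum of most-abundant-isotope nominal masses (C = 12, H = 1,
#' O = 16, ...), the mass scale of unit-resolution ESI-MS.
#'
#' @param formula Character vector of Hill-notation formulas.
#' @return Integer vector of nominal masses in Da.
#' @export
#' @examples
#' nominal_mass(c("C21H30O2", "H2O"))
nominal_mass <- function(formula) {
  map_int(formula, function(f) {
    counts <- .parse_formula(f)
    as.integer(sum(.NOMINAL_MASS[names(counts)] * counts))
  })
}

.average_mw <- function(formula) {
  map_dbl(formula, function(f) {
    counts <- .parse_formula(f)
    sum(.ATOMIC_WEIGHT[names(counts)] * counts)
  })
}

#' Compute molecular properties for a compound table
#'
#' Adds average molecular weight, nominal mass, the protonated nominal m/z
#' (`nominal_mass + 1`, matching unit-resolution positive-mode ESI-MS),
#' Lipinski-style hydrogen-bond donor (O/N bearing at least one H) and
#' acceptor (any N or O) counts, and the number of rotatable bonds
#' (acyclic single bonds between non-terminal heavy atoms).
#'
#' @param compounds Tibble with at least `id` and `structure` (SMILES)
#'   columns, e.g. from [hemp_compounds()] or [read_compounds()].
#' @return The input tibble with columns `formula`, `mw`, `nominal_mass`,
#'   `mz_protonated`, `hbd`, `hba`, `n_rot` appended (existing property
#'   columns are recomputed).
#' @export
#' @examples
#' compound_properties(hemp_compounds())
compound_properties <- function(compounds) {
  stopifnot(is.data.frame(compounds), all(c("id", "structure") %in% names(compounds)))
  props <- pmap(list(compounds$structure, compounds$id), function(s, id) {
    mol <- .parse_mol(s, id)
    don <- with(mol$atoms, element %in% c("N", "O") & n_h > 0)
    acc <- mol$atoms$element %in% c("N", "O")
    tibble(
      formula = mol$formula,
      mw = .average_mw(mol$formula),
      nominal_mass = nominal_mass(mol$formula),
      hbd = sum(don),
      hba = sum(acc),
      n_rot = .count_rotatable(mol)
    )
  })
  props <- bind_rows(props)
  out <- compounds[setdiff(names(compounds), names(props))]
  out <- as_tibble(cbind(out, props))
  out$mz_protonated <- out$nominal_mass + 1L
  out
}

# Rotatable: acyclic (bridge) single bonds whose endpoints both carry
# another heavy neighbour. Bridges found with igraph; ring bonds are the
# non-bridges.
.count_rotatable <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(0L)
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("a1", "a2")]), directed = FALSE)
  bridge_idx <- igraph::bridges(g)
  is_bridge <- seq_len(nrow(b)) %in% as.integer(bridge_idx)
  hd <- mol$atoms$heavy_degree
  sum(is_bridge & b$order == 1L & hd[b$a1] > 1L & hd[b$a2] > 1L)
}

#' Check a compound identity against an observed ESI-MS m/z
#'
#' Compares the computed nominal `[M+H]+` m/z with the observed
#' unit-resolution value.
#'
#' @param compounds Compound tibble (see [compound_properties()]).
#' @param expected_mz Integer vector of observed `[M+H]+` values, recycled
#'   to the number of compounds if length one.
#' @return The compound tibble with `expected_mz`, `mz_protonated` and
#'   logical `identity_ok` columns.
#' @export
#' @examples
#' validate_identity(hemp_compounds(), c(331, 315, 359))
validate_identity <- function(compounds, expected_mz) {
  props <- compound_properties(compounds)
  expected_mz <- as.integer(expected_mz)
  if (length(expected_mz) == 1) expected_mz <- rep(expected_mz, nrow(props))
  stopifnot(length(expected_mz) == nrow(props))
  props$expected_mz <- expected_mz
  props$identity_ok <- props$mz_protonated == expected_mz
  props
}

#' Write a compound property table as TSV
#'
#' @param props Output of [compound_properties()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(props, path) {
  cols <- c("id", "name", "formula", "mw", "nominal_mass", "mz_protonated",
            "hbd", "hba", "n_rot")
  readr::write_tsv(props[intersect(cols, names(props))], path)
  invisible(path)
}
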