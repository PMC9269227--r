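# Receptor ingestion and cleaning. PDB I/O goes through bio3d; this module
# removes crystallographic clutter (waters, ions, buffer components),
# resolves altlocs and multi-model files, and extracts the co-crystallised
# ligand when one is present.

#' Default exclusion list for structure cleaning
#'
#' Residue names of waters, common monoatomic ions and frequent
#' crystallisation additives that are stripped from receptor structures.
#' User-extensible: pass `c(default_exclusion_list(), "XYZ")` to
#' [clean_structure()].
#'
#' @return Character vector of PDB residue names.
#' @export
default_exclusion_list <- function() {
  c(
    # waters
    "HOH", "WAT", "DOD", "H2O",
    # ions
    "NA", "K", "CL", "BR", "IOD", "MG", "CA", "ZN", "MN", "FE", "NI",
    "CU", "CO", "CD", "HG", "SR", "CS", "LI", "F",
    # buffers / cryoprotectants / additives
    "SO4", "PO4", "NO3", "ACT", "FMT", "GOL", "EDO", "PEG", "PGE", "PG4",
    "MPD", "DMS", "TRS", "MES", "EPE", "BME", "IMD", "ACE", "CIT", "TLA",
    "SCN", "AZI", "BCT", "CO3", "NH4", "OXL", "MLI"
  )
}

#' Clean a receptor structure
#'
#' Reads a PDB entry (or re-cleans an existing `ivs_receptor`), keeps the
#' first model of multi-model files, resolves alternate locations to the
#' highest-occupancy conformer (ties to the alphabetically first altloc),
#' removes excluded residues (waters, ions, buffer components) into a
#' removal log, and extracts the largest remaining hetero group as the
#' co-crystallised ligand (ties broken by lower chain id, then residue
#' number). Cleaning is idempotent.
#'
#' @param x Path to a PDB file, a `bio3d` `pdb` object, or an
#'   `ivs_receptor`.
#' @param exclusion Character vector of residue names to remove,
#'   default [default_exclusion_list()].
#' @param pdb_id Identifier recorded on the result; defaults to the file
#'   base name.
#' @return An object of class `ivs_receptor`: a list with `pdb_id`,
#'   `atoms` (tibble: `eleno`, `elety`, `resid`, `chain`, `resno`, `x`,
#'   `y`, `z`, `o`, `elesy`, `is_hetero`), `removed` (tibble log with one
#'   row per removed residue instance) and `ligand` (atom tibble or
#'   `NULL`).
#' @export
clean_structure <- function(x, exclusion = default_exclusion_list(),
                            pdb_id = NULL) {
  if (inherits(x, "ivs_receptor")) {
    atoms <- x$atoms
    pdb_id <- pdb_id %||% x$pdb_id
    prior_removed <- x$removed
    prior_ligand <- x$ligand
  } else {
    if (is.character(x)) {
      pdb_id <- pdb_id %||% toupper(tools::file_path_sans_ext(basename(x)))
      x <- bio3d::read.pdb(x, multi = FALSE, verbose = FALSE)
    }
    stopifnot(inherits(x, "pdb"))
    pdb_id <- pdb_id %||% "UNKNOWN"
    atoms <- as_tibble(x$atom[, c("type", "eleno", "elety", "alt", "resid",
                                  "chain", "resno", "x", "y", "z", "o",
                                  "elesy")])
    # bio3d parses model 1 into $atom for multi-model files (multi = FALSE)
    atoms$is_hetero <- atoms$type == "HETATM"
    atoms$type <- NULL
    prior_removed <- NULL
    prior_ligand <- NULL
  }
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$o[is.na(atoms$o)] <- 1

  # altloc resolution: within each residue keep the altloc whose mean
  # occupancy is highest; blank altloc atoms are always kept
  has_alt <- !is.na(atoms$alt) & nzchar(trimws(as.character(atoms$alt)))
  if (any(has_alt)) {
    alt_atoms <- atoms[has_alt, ]
    keep_alt <- alt_atoms |>
      group_by(.data$chain, .data$resno, .data$resid, .data$alt) |>
      summarise(occ = mean(.data$o), .groups = "drop_last") |>
      arrange(dplyr::desc(.data$occ), .data$alt) |>
      slice(1) |>
      ungroup()
    alt_keep_key <- paste(keep_alt$chain, keep_alt$resno, keep_alt$resid,
                          keep_alt$alt)
    drop <- has_alt & !(paste(atoms$chain, atoms$resno, atoms$resid,
                              atoms$alt) %in% alt_keep_key)
    atoms <- atoms[!drop, ]
  }
  atoms$alt <- NA_character_

  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort(paste0(pdb_id, ": non-finite atom coordinates"),
          class = "ivs_format_error")
  }

  excluded <- atoms$resid %in% exclusion
  removed <- atoms[excluded, ] |>
    group_by(.data$resid, .data$chain, .data$resno) |>
    summarise(n_atoms = n(), .groups = "drop") |>
    mutate(category = dplyr::if_else(.data$resid %in%
                                       c("HOH", "WAT", "DOD", "H2O"),
                                     "water", "ion_or_buffer"))
  atoms <- atoms[!excluded, ]

  protein <- atoms[!atoms$is_hetero, ]
  if (nrow(protein) == 0) {
    abort(paste0(pdb_id, ": no protein atoms remain after cleaning"),
          class = "ivs_degenerate_structure")
  }

  het <- atoms[atoms$is_hetero, ]
  ligand <- prior_ligand
  if (nrow(het) > 0) {
    groups <- het |>
      group_by(.data$chain, .data$resno, .data$resid) |>
      summarise(n_heavy = sum(.data$elesy != "H", na.rm = TRUE),
                .groups = "drop") |>
      arrange(dplyr::desc(.data$n_heavy), .data$chain, .data$resno)
    g <- groups[1, ]
    ligand <- het |>
      filter(.data$chain == g$chain, .data$resno == g$resno,
             .data$resid == g$resid)
    atoms <- atoms |>
      filter(!(.data$is_hetero & .data$chain == g$chain &
                 .data$resno == g$resno & .data$resid == g$resid))
  }

  removed_all <- bind_rows(prior_removed, removed)
  structure(
    list(pdb_id = pdb_id, atoms = atoms, removed = removed_all,
         ligand = ligand),
    class = "ivs_receptor"
  )
}

#' @export
print.ivs_receptor <- function(x, ...) {
  cat("<ivs_receptor> ", x$pdb_id, ": ", nrow(x$atoms), " atoms",
      if (!is.null(x$ligand)) {
        paste0(", ligand ", x$ligand$resid[1], " (", nrow(x$ligand),
               " atoms)")
      } else {
        ", no co-crystallised ligand"
      },
      ", ", nrow(x$removed) %||% 0L, " residues removed\n", sep = "")
  invisible(x)
}

#' Write a cleaned receptor back to PDB format
#'
#' @param receptor An `ivs_receptor`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_receptor <- function(receptor, path) {
  stopifnot(inherits(receptor, "ivs_receptor"))
  a <- receptor$atoms
  bio3d::write.pdb(
    file = path,
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    eleno = a$eleno, elety = a$elety, resid = a$resid, chain = a$chain,
    resno = a$resno, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    o = a$o, elesy = a$elesy
  )
  invisible(path)
}

# protein heavy-atom coordinate matrix
.receptor_coords <- function(receptor, hetero = FALSE) {
  a <- receptor$atoms
  if (!hetero) a <- a[!a$is_hetero, ]
  a <- a[is.na(a$elesy) | a$elesy != "H", ]
  as.matrix(a[, c("x", "y", "z")])
}
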