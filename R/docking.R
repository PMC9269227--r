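# Docking engine contract. Two backends: an AutoDock-Vina-compatible
# subprocess adapter (PDBQT preparation through Open Babel, centre/size/
# exhaustiveness/seed flags, pose affinities parsed from the output file),
# and a deterministic replay backend that serves a recorded affinity table
# so every downstream stage runs with no engine installed.

#' Read / write recorded affinity tables
#'
#' TSV with header `compound_id`, `pdb_id`, `affinity_kcal_mol`.
#'
#' @param path File path.
#' @return Tibble with those three columns.
#' @export
read_affinity_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("compound_id", "pdb_id", "affinity_kcal_mol")
  if (!all(need %in% names(tab))) {
    abort(paste0("affinity table must have columns: ",
                 paste(need, collapse = ", ")), class = "ivs_format_error")
  }
  tab$compound_id <- as.character(tab$compound_id)
  as_tibble(tab[need])
}

#' @rdname read_affinity_table
#' @param table Affinity tibble.
#' @export
write_affinity_table <- function(table, path) {
  readr::write_tsv(table[c("compound_id", "pdb_id", "affinity_kcal_mol")], path)
  invisible(path)
}

#' Replay docking backend
#'
#' Serves best affinities from a recorded table. Bit-reproducible: the
#' entire downstream pipeline on the same table yields identical reports
#' across runs and platforms.
#'
#' @param table Recorded affinity tibble (or path to its TSV) with columns
#'   `compound_id`, `pdb_id`, `affinity_kcal_mol`.
#' @return Backend object of class `c("replay_backend", "ivs_backend")`.
#' @export
replay_backend <- function(table) {
  if (is.character(table)) table <- read_affinity_table(table)
  stopifnot(all(c("compound_id", "pdb_id", "affinity_kcal_mol") %in%
                  names(table)))
  structure(list(table = as_tibble(table),
                 meta = list(engine = "replay", version = "recorded-table")),
            class = c("replay_backend", "ivs_backend"))
}

#' AutoDock-Vina-compatible subprocess backend
#'
#' Invokes an external Vina-convention executable per job with
#' `--center_x/y/z`, `--size_x/y/z`, `--exhaustiveness` and `--seed`;
#' pose affinities are parsed from `REMARK VINA RESULT` records of the
#' output PDBQT. Receptors and ligands must be prepared PDBQT files (see
#' [prepare_pdbqt()]).
#'
#' @param exec Path to the engine executable.
#' @param workdir Scratch directory for per-job output files.
#' @return Backend object of class `c("vina_backend", "ivs_backend")`.
#' @export
vina_backend <- function(exec = "vina", workdir = tempdir()) {
  structure(list(exec = exec, workdir = workdir,
                 meta = list(engine = "vina-compatible", exec = exec)),
            class = c("vina_backend", "ivs_backend"))
}

#' Prepare a ligand or receptor as PDBQT
#'
#' Converts through Open Babel: hydrogens appropriate for pH 7.4,
#' Gasteiger partial charges, and (for ligands) rotatable-bond typing with
#' all open-chain single bonds treated as active torsions — the engine
#' input convention. Receptors are written rigid (`-xr`).
#'
#' @param infile Input structure (PDB, SDF, MOL, SMILES...).
#' @param outfile Output PDBQT path; default swaps the extension.
#' @param rigid Prepare as rigid receptor rather than flexible ligand.
#' @return `outfile`, invisibly.
#' @export
prepare_pdbqt <- function(infile, outfile = NULL, rigid = FALSE) {
  outfile <- outfile %||% paste0(tools::file_path_sans_ext(infile), ".pdbqt")
  if (Sys.which("obabel") == "") {
    abort("Open Babel ('obabel') not found on PATH",
          class = "ivs_engine_error")
  }
  args <- c(infile, "-opdbqt", "-O", outfile, "-p", "7.4",
            "--partialcharge", "gasteiger", if (rigid) "-xr")
  status <- suppressWarnings(
    system2("obabel", args, stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(outfile)) {
    abort(paste0("PDBQT preparation failed for ", infile),
          class = "ivs_engine_error")
  }
  invisible(outfile)
}

#' Dock one job
#'
#' @param backend A backend from [replay_backend()] or [vina_backend()].
#' @param job One-row tibble (or list) with `compound_id` and `pdb_id`;
#'   for the Vina backend also `ligand_file`, `receptor_file` and the box
#'   columns `center_x/y/z`, `size_x/y/z` (see [build_box()]).
#' @param exhaustiveness Search effort (default 64).
#' @param seed Engine random seed; fixed by default so repeated runs on
#'   identical inputs agree.
#' @param ... Unused.
#' @return One-row tibble: `compound_id`, `pdb_id`, `best_affinity`
#'   (kcal/mol, the V0 used downstream), `n_poses`, `engine`, `seed`, and
#'   a `poses` list-column (pose rank/affinity tibble, empty for replay).
#' @export
dock <- function(backend, job, exhaustiveness = 64L, seed = 20220624L, ...) {
  UseMethod("dock")
}

.dock_record <- function(compound_id, pdb_id, best, poses, engine, seed) {
  tibble(compound_id = as.character(compound_id), pdb_id = pdb_id,
         best_affinity = best, n_poses = nrow(poses),
         engine = engine, seed = as.integer(seed), poses = list(poses))
}

#' @export
dock.replay_backend <- function(backend, job, exhaustiveness = 64L,
                                seed = 20220624L, ...) {
  hit <- backend$table |>
    filter(.data$compound_id == as.character(job$compound_id),
           .data$pdb_id == job$pdb_id)
  if (nrow(hit) == 0) {
    abort(paste0("no recorded affinity for (", job$compound_id, ", ",
                 job$pdb_id, ")"), class = "ivs_engine_error",
          compound_id = job$compound_id, pdb_id = job$pdb_id)
  }
  v0 <- min(hit$affinity_kcal_mol)
  poses <- tibble(rank = 1L, affinity = v0)
  .dock_record(job$compound_id, job$pdb_id, v0, poses, "replay", seed)
}

#' @export
dock.vina_backend <- function(backend, job, exhaustiveness = 64L,
                              seed = 20220624L, ...) {
  stopifnot(exhaustiveness >= 1)
  for (f in c("ligand_file", "receptor_file")) {
    if (is.null(job[[f]]) || !file.exists(job[[f]])) {
      abort(paste0("missing ", f, " for job (", job$compound_id, ", ",
                   job$pdb_id, ")"), class = "ivs_engine_error")
    }
  }
  if (Sys.which(backend$exec) == "") {
    abort(paste0("docking engine '", backend$exec, "' not found on PATH"),
          class = "ivs_engine_error")
  }
  out <- file.path(backend$workdir,
                   paste0(job$compound_id, "_", job$pdb_id, "_out.pdbqt"))
  args <- c("--receptor", job$receptor_file, "--ligand", job$ligand_file,
            "--center_x", job$center_x, "--center_y", job$center_y,
            "--center_z", job$center_z,
            "--size_x", job$size_x, "--size_y", job$size_y,
            "--size_z", job$size_z,
            "--exhaustiveness", exhaustiveness, "--seed", seed,
            "--out", out)
  res <- suppressWarnings(
    system2(backend$exec, as.character(args), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(out)) {
    abort(paste0("engine failure for job (", job$compound_id, ", ",
                 job$pdb_id, "): ",
                 paste(utils::tail(res, 3), collapse = " | ")),
          class = "ivs_engine_error")
  }
  lines <- grep("^REMARK VINA RESULT:", readLines(out, warn = FALSE),
                value = TRUE)
  aff <- as.numeric(map_chr(strsplit(trimws(sub("^REMARK VINA RESULT:", "",
                                                lines)), "\\s+"), 1))
  if (length(aff) == 0 || any(!is.finite(aff))) {
    abort(paste0("no poses parsed for job (", job$compound_id, ", ",
                 job$pdb_id, ")"), class = "ivs_engine_error")
  }
  poses <- tibble(rank = seq_along(aff), affinity = sort(aff))
  .dock_record(job$compound_id, job$pdb_id, min(aff), poses,
               backend$meta$engine, seed)
}

#' Dock a batch of jobs
#'
#' Runs every job, collecting per-job failures instead of aborting: a
#' corrupt receptor or a missing table entry is logged and the batch
#' continues. Results are independent of job order.
#'
#' @param jobs Tibble of jobs (see [dock()]).
#' @param backend Docking backend.
#' @inheritParams dock
#' @return Tibble of docking records; failed jobs are attached as the
#'   `failures` attribute (tibble: `compound_id`, `pdb_id`, `error`).
#'   Aborts with class `ivs_batch_error` when every job fails.
#' @export
dock_batch <- function(jobs, backend, exhaustiveness = 64L,
                       seed = 20220624L, ...) {
  stopifnot(is.data.frame(jobs), nrow(jobs) >= 1)
  recs <- vector("list", nrow(jobs))
  fails <- list()
  for (i in seq_len(nrow(jobs))) {
    job <- jobs[i, ]
    recs[[i]] <- tryCatch(
      dock(backend, job, exhaustiveness = exhaustiveness, seed = seed, ...),
      ivs_engine_error = function(e) {
        fails[[length(fails) + 1L]] <<- tibble(
          compound_id = as.character(job$compound_id), pdb_id = job$pdb_id,
          error = conditionMessage(e))
        NULL
      })
  }
  out <- bind_rows(recs)
  failures <- if (length(fails)) bind_rows(fails) else
    tibble(compound_id = character(), pdb_id = character(),
           error = character())
  if (nrow(out) == 0) {
    abort("all docking jobs failed", class = "ivs_batch_error",
          failures = failures)
  }
  if (nrow(failures) > 0) {
    warn(paste0(nrow(failures), " of ", nrow(jobs),
                " docking jobs failed and were logged"))
  }
  attr(out, "failures") <- failures
  out
}
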