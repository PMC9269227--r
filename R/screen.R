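# Decoy normalisation, retention filtering and ranking. The screen's
# statistic is the dimensionless V = V0 / VR, where V0 is the query's best
# docking affinity on a structure and VR the mean best affinity of its ten
# decoys there. V discounts promiscuous targets that bind anything
# drug-like. Retention keeps structures with V0 below -7.5 kcal/mol AND
# V above 0.75, both read as strict inequalities.

#' Normalise one affinity against decoy affinities
#'
#' `VR` is the arithmetic mean of the decoys' best affinities (no
#' trimming); `V = V0 / VR`.
#'
#' @param v0 Best affinity of the query on one structure, kcal/mol.
#' @param decoy_affinities Numeric vector of the decoys' best affinities
#'   on the same structure, kcal/mol.
#' @return One-row tibble with `VR` and `V`.
#' @export
#' @examples
#' normalize_affinity(-10.1, rep(-8, 10))  # V = 1.2625
normalize_affinity <- function(v0, decoy_affinities) {
  if (length(decoy_affinities) == 0 || !all(is.finite(decoy_affinities))) {
    abort("decoy affinities must be a nonempty finite vector",
          class = "ivs_normalization_error")
  }
  vr <- mean(decoy_affinities)
  if (vr >= 0) {
    abort(paste0("mean decoy affinity is non-negative (", round(vr, 3),
                 " kcal/mol); V is undefined"),
          class = "ivs_normalization_error")
  }
  tibble(VR = vr, V = v0 / vr)
}

#' Normalise a table of docking records
#'
#' Joins each query (compound, structure) record with its decoys' records
#' on the same structure and computes `VR` and `V` per pair. Pairs whose
#' decoy mean is zero/positive or that have no decoy affinities are
#' excluded with a warning (logged in the `dropped` attribute).
#'
#' @param records Query docking records (`compound_id`, `pdb_id`,
#'   `best_affinity`), e.g. from [dock_batch()].
#' @param decoy_records Docking records of the decoy molecules.
#' @param decoy_map Tibble mapping `query_id` to `decoy_id` (ten rows per
#'   query in the standard design).
#' @return Tibble of normalised hits: `compound_id`, `pdb_id`, `V0`,
#'   `VR`, `V`, `n_decoys`.
#' @export
normalize_affinities <- function(records, decoy_records, decoy_map) {
  stopifnot(all(c("compound_id", "pdb_id", "best_affinity") %in% names(records)),
            all(c("query_id", "decoy_id") %in% names(decoy_map)))
  dm <- decoy_map |>
    mutate(query_id = as.character(.data$query_id),
           decoy_id = as.character(.data$decoy_id))
  dec <- decoy_records |>
    select(decoy_id = "compound_id", "pdb_id",
           decoy_affinity = "best_affinity") |>
    inner_join(dm, by = "decoy_id", relationship = "many-to-many")
  vr_tab <- dec |>
    group_by(.data$query_id, .data$pdb_id) |>
    summarise(VR = mean(.data$decoy_affinity),
              n_decoys = n(), .groups = "drop")
  hits <- records |>
    select("compound_id", "pdb_id", V0 = "best_affinity") |>
    left_join(vr_tab, by = c(compound_id = "query_id", pdb_id = "pdb_id"))
  bad <- is.na(hits$VR) | hits$VR >= 0
  if (any(bad)) {
    warn(paste0(sum(bad), " hit(s) excluded from normalisation ",
                "(no decoy affinities or non-negative decoy mean)"))
  }
  dropped <- hits[bad, ]
  hits <- hits[!bad, ]
  hits$V <- hits$V0 / hits$VR
  out <- select(hits, "compound_id", "pdb_id", "V0", "VR", "V", "n_decoys")
  attr(out, "dropped") <- dropped
  out
}

#' Retention filter of the screen
#'
#' @param e_max Affinity threshold, kcal/mol: hits are kept only when
#'   `V0 < e_max` (strictly "below"). Default -7.5. Must be negative.
#' @param v_min V threshold: kept only when `V > v_min` (strictly
#'   "above"). Default 0.75. Must be positive.
#' @return List of class `ivs_filter`.
#' @export
screen_filter <- function(e_max = -7.5, v_min = 0.75) {
  if (!is.numeric(e_max) || !(e_max < 0)) {
    abort("e_max must be a negative affinity in kcal/mol",
          class = "ivs_parameter_error")
  }
  if (!is.numeric(v_min) || !(v_min > 0)) {
    abort("v_min must be positive", class = "ivs_parameter_error")
  }
  structure(list(e_max = e_max, v_min = v_min), class = "ivs_filter")
}

#' Apply the retention filter to normalised hits
#'
#' Marks each hit as passed iff `V0 < e_max` and `V > v_min`, both strict.
#' Non-binding scores (`V0 >= 0`) always fail. Row order is preserved.
#'
#' @param hits Normalised hit tibble from [normalize_affinities()].
#' @param filter An [screen_filter()].
#' @return `hits` with a logical `passed` column.
#' @export
apply_screen_filter <- function(hits, filter = screen_filter()) {
  stopifnot(inherits(filter, "ivs_filter"),
            all(c("V0", "V") %in% names(hits)))
  hits$passed <- hits$V0 < filter$e_max & hits$V > filter$v_min &
    hits$V0 < 0
  attr(hits, "filter") <- filter
  hits
}

#' Per-compound top-scoring targets
#'
#' For each compound, the extremum over its passed hits: minimum `V0`
#' (`by = "affinity"`) or maximum `V` (`by = "V"`). Ties are broken by
#' lower `V0`, then lexicographic `pdb_id`, and flagged in the `tied`
#' column. Compounds with no passed hit are omitted with a warning.
#'
#' @param hits Filtered hits (with `passed`), see [apply_screen_filter()].
#' @param by Ranking criterion.
#' @param mapping Optional `pdb_id` to `uniprot_id`/`molecule_name`
#'   mapping tibble, merged into the result.
#' @return Tibble: `compound_id`, `criterion`, `pdb_id`, `value`, `tied`
#'   (+ mapping columns when supplied).
#' @export
top_scores <- function(hits, by = c("affinity", "V"), mapping = NULL) {
  by <- match.arg(by)
  stopifnot("passed" %in% names(hits))
  ph <- filter(hits, .data$passed)
  all_ids <- unique(as.character(hits$compound_id))
  missing <- setdiff(all_ids, unique(as.character(ph$compound_id)))
  if (length(missing)) {
    warn(paste0("no passed hits for compound(s): ",
                paste(missing, collapse = ", "), "; omitted"))
  }
  if (nrow(ph) == 0) {
    out <- tibble(compound_id = character(), criterion = character(),
                  pdb_id = character(), value = numeric(), tied = logical())
    return(out)
  }
  picked <- ph |>
    group_by(.data$compound_id) |>
    mutate(.key = if (by == "affinity") .data$V0 else -.data$V) |>
    mutate(tied = sum(.data$.key == min(.data$.key)) > 1) |>
    arrange(.data$.key, .data$V0, .data$pdb_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  out <- tibble(
    compound_id = picked$compound_id,
    criterion = by,
    pdb_id = picked$pdb_id,
    value = if (by == "affinity") picked$V0 else picked$V,
    tied = picked$tied
  )
  if (!is.null(mapping)) {
    out <- left_join(out, .norm_mapping(mapping), by = "pdb_id")
  }
  out
}

.norm_mapping <- function(mapping) {
  stopifnot(all(c("pdb_id", "uniprot_id") %in% names(mapping)))
  m <- as_tibble(mapping)
  if (!"molecule_name" %in% names(m)) m$molecule_name <- NA_character_
  distinct(m[c("pdb_id", "uniprot_id", "molecule_name")])
}

#' Consensus targets shared by all query compounds
#'
#' Groups passed hits by UniProt accession and keeps only accessions with
#' at least one passed hit for every query compound. `retrieval_count` is
#' the total number of passed (compound, structure) hits in the group;
#' `best_affinity` per compound is the minimum `V0` over that compound's
#' passed hits on the accession (with the structure achieving it).
#' Sorted by descending retrieval count, ties by best overall affinity.
#'
#' @param hits Filtered hits (with `passed`).
#' @param mapping `pdb_id` to `uniprot_id` (+ optional `molecule_name`)
#'   tibble. Hits whose structure is unmapped are excluded from the
#'   consensus only, with a warning.
#' @param compounds Compound ids that must all be covered; defaults to
#'   every compound appearing in `hits`.
#' @return Long tibble: one row per (accession, compound) with
#'   `uniprot_id`, `molecule_name`, `retrieval_count`, `compound_id`,
#'   `best_affinity`, `best_pdb_id`.
#' @export
consensus_targets <- function(hits, mapping, compounds = NULL) {
  stopifnot("passed" %in% names(hits))
  compounds <- as.character(compounds %||% unique(hits$compound_id))
  m <- .norm_mapping(mapping)
  ph <- filter(hits, .data$passed)
  unmapped <- setdiff(unique(ph$pdb_id), m$pdb_id)
  if (length(unmapped)) {
    warn(paste0("structures without UniProt mapping excluded from ",
                "consensus: ", paste(unmapped, collapse = ", ")))
  }
  ph <- inner_join(ph, m, by = "pdb_id")
  if (nrow(ph) == 0) return(.empty_consensus())
  shared <- ph |>
    group_by(.data$uniprot_id) |>
    summarise(covered = length(unique(.data$compound_id)),
              retrieval_count = n(),
              overall_best = min(.data$V0), .groups = "drop") |>
    filter(.data$covered == length(compounds))
  if (nrow(shared) == 0) return(.empty_consensus())
  per_best <- ph |>
    filter(.data$uniprot_id %in% shared$uniprot_id) |>
    group_by(.data$uniprot_id, .data$compound_id) |>
    arrange(.data$V0, .data$pdb_id, .by_group = TRUE) |>
    summarise(best_affinity = first(.data$V0),
              best_pdb_id = first(.data$pdb_id),
              molecule_name = first(.data$molecule_name),
              .groups = "drop")
  out <- per_best |>
    inner_join(shared[c("uniprot_id", "retrieval_count", "overall_best")],
               by = "uniprot_id") |>
    arrange(dplyr::desc(.data$retrieval_count), .data$overall_best,
            .data$uniprot_id, .data$compound_id) |>
    select("uniprot_id", "molecule_name", "retrieval_count",
           "compound_id", "best_affinity", "best_pdb_id")
  out
}

.empty_consensus <- function() {
  tibble(uniprot_id = character(), molecule_name = character(),
         retrieval_count = integer(), compound_id = character(),
         best_affinity = numeric(), best_pdb_id = character())
}

#' Pivot a consensus table to one row per target
#'
#' Wide shape with one `affinity (pdb)` column pair per compound.
#'
#' @param consensus Output of [consensus_targets()].
#' @return Wide tibble, one row per UniProt accession.
#' @export
consensus_table <- function(consensus) {
  consensus |>
    mutate(cell = sprintf("%.1f (%s)", .data$best_affinity,
                          .data$best_pdb_id)) |>
    select("uniprot_id", "molecule_name", "retrieval_count",
           "compound_id", "cell") |>
    tidyr::pivot_wider(names_from = "compound_id", values_from = "cell",
                       names_prefix = "compound_")
}

#' Run an inverse virtual screen end to end
#'
#' Orchestrates the three steps of the screen: (1) dock every query
#' compound and every decoy against the panel, (2) normalise each best
#' affinity by the mean decoy affinity into V, (3) filter and rank —
#' per-compound top targets under both criteria and the cross-compound
#' consensus grouped by UniProt.
#'
#' @param compounds Query compound tibble (`id` required; `ligand_file`
#'   used by live backends).
#' @param panel Panel tibble: `pdb_id`, `uniprot_id`, optional
#'   `molecule_name`, and (for live backends) `receptor_file` plus box
#'   columns `center_x/y/z`, `size_x/y/z`.
#' @param decoy_map Tibble mapping `query_id` to `decoy_id` (and
#'   `ligand_file` for live backends).
#' @param backend Docking backend ([replay_backend()] / [vina_backend()]).
#' @param filter Retention thresholds, see [screen_filter()].
#' @param exhaustiveness,seed Passed to the engine.
#' @return Object of class `ivs_screen`: list with `hits` (all normalised
#'   hits with `passed`), `top_affinity`, `top_v`, `consensus`, `filter`,
#'   `params` and `failures`. Supports [print()], [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
run_screen <- function(compounds, panel, decoy_map, backend,
                       filter = screen_filter(), exhaustiveness = 64L,
                       seed = 20220624L) {
  stopifnot(is.data.frame(compounds), "id" %in% names(compounds),
            is.data.frame(panel), "pdb_id" %in% names(panel))
  panel <- distinct(as_tibble(panel))
  query_ids <- as.character(compounds$id)
  decoy_ids <- unique(as.character(decoy_map$decoy_id))

  make_jobs <- function(ids, files = NULL) {
    jobs <- tidyr::crossing(compound_id = ids, panel["pdb_id"])
    extra <- intersect(c("receptor_file", "center_x", "center_y", "center_z",
                         "size_x", "size_y", "size_z"), names(panel))
    if (length(extra)) {
      jobs <- left_join(jobs, panel[c("pdb_id", extra)], by = "pdb_id")
    }
    if (!is.null(files)) jobs <- left_join(jobs, files, by = "compound_id")
    jobs
  }
  qfiles <- if ("ligand_file" %in% names(compounds)) {
    tibble(compound_id = query_ids, ligand_file = compounds$ligand_file)
  }
  dfiles <- if ("ligand_file" %in% names(decoy_map)) {
    distinct(tibble(compound_id = as.character(decoy_map$decoy_id),
                    ligand_file = decoy_map$ligand_file))
  }
  q_records <- dock_batch(make_jobs(query_ids, qfiles), backend,
                          exhaustiveness = exhaustiveness, seed = seed)
  d_records <- dock_batch(make_jobs(decoy_ids, dfiles), backend,
                          exhaustiveness = exhaustiveness, seed = seed)

  hits <- normalize_affinities(q_records, d_records, decoy_map)
  hits <- apply_screen_filter(hits, filter)
  mapping <- .norm_mapping(panel)
  top_affinity <- top_scores(hits, "affinity", mapping)
  top_v <- top_scores(hits, "V", mapping)
  consensus <- consensus_targets(hits, mapping, compounds = query_ids)

  structure(
    list(
      hits = hits, top_affinity = top_affinity, top_v = top_v,
      consensus = consensus, filter = filter,
      params = list(exhaustiveness = exhaustiveness, seed = seed,
                    engine = backend$meta, n_decoys_per_query =
                      nrow(decoy_map) / max(1, length(query_ids))),
      failures = bind_rows(attr(q_records, "failures"),
                           attr(d_records, "failures"))
    ),
    class = "ivs_screen"
  )
}

#' @export
print.ivs_screen <- function(x, ...) {
  cat("<ivs_screen>\n")
  cat("  hits:", nrow(x$hits), "normalised,", sum(x$hits$passed),
      "passed (V0 <", x$filter$e_max, "kcal/mol, V >", x$filter$v_min,
      ")\n")
  cat("  consensus targets:", length(unique(x$consensus$uniprot_id)), "\n")
  if (nrow(x$top_affinity)) {
    cat("  top targets by affinity:\n")
    print(as.data.frame(x$top_affinity), row.names = FALSE)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-hit table of a screen
#'
#' @param x An `ivs_screen`.
#' @param ... Unused.
#' @return The normalised hit tibble with filter status.
#' @method tidy ivs_screen
#' @export
tidy.ivs_screen <- function(x, ...) as_tibble(x$hits)

#' One-row summary of a screen
#'
#' @param x An `ivs_screen`.
#' @param ... Unused.
#' @return One-row tibble with hit counts, thresholds and engine name.
#' @method glance ivs_screen
#' @export
glance.ivs_screen <- function(x, ...) {
  tibble(
    n_hits = nrow(x$hits), n_passed = sum(x$hits$passed),
    n_compounds = length(unique(x$hits$compound_id)),
    n_structures = length(unique(x$hits$pdb_id)),
    n_consensus = length(unique(x$consensus$uniprot_id)),
    e_max = x$filter$e_max, v_min = x$filter$v_min,
    engine = x$params$engine$engine %||% NA_character_,
    n_failures = nrow(x$failures)
  )
}

#' Affinity-versus-V plot of a screen
#'
#' Scatter of V against V0 with the two retention thresholds drawn; the
#' kept region is the lower-right quadrant past both lines.
#'
#' @param object An `ivs_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ivs_screen
#' @export
autoplot.ivs_screen <- function(object, ...) {
  ggplot2::ggplot(object$hits,
                  ggplot2::aes(x = .data$V0, y = .data$V,
                               colour = .data$passed,
                               shape = .data$compound_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$filter$e_max,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$filter$v_min,
                        linetype = "dashed") +
    ggplot2::labs(x = "best affinity V0 (kcal/mol)",
                  y = "V = V0 / VR (dimensionless)",
                  colour = "retained", shape = "compound") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a screen report to disk
#'
#' Emits `screen_report.json` (hits, rankings, thresholds, engine
#' provenance), `top_scores.tsv` and `consensus_targets.tsv`.
#'
#' @param x An `ivs_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(x, dir) {
  stopifnot(inherits(x, "ivs_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- bind_rows(x$top_affinity, x$top_v)
  readr::write_tsv(top, file.path(dir, "top_scores.tsv"))
  readr::write_tsv(x$consensus, file.path(dir, "consensus_targets.tsv"))
  report <- list(
    version = as.character(utils::packageVersion("ivscreen")),
    filter = unclass(x$filter),
    params = x$params,
    retrieval_count_definition =
      "total passed (compound, structure) hits per UniProt accession",
    glance = glance(x),
    hits = x$hits,
    top_scores = top,
    consensus = x$consensus,
    failures = x$failures
  )
  jsonlite::write_json(report, file.path(dir, "screen_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
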