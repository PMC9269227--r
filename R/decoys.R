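# Property-matched, structurally dissimilar decoy selection. Decoys
# calibrate non-specific binding: they resemble the query in MW/HBD/HBA but
# differ in structure, so their mean affinity VR estimates what "anything
# drug-like" scores on a target.

#' Decoy matching windows
#'
#' Tolerances used to decide whether a candidate "resembles" the query:
#' molecular weight within `mw` Da, donor and acceptor counts within
#' `hbd`/`hba`, and 2D FP2-fingerprint Tanimoto similarity strictly below
#' `max_similarity` (so decoys are property-matched but structurally
#' different; the query itself, at similarity 1, is always excluded).
#'
#' @param mw MW half-window in Da.
#' @param hbd,hba Count half-windows.
#' @param max_similarity Exclusive upper bound on Tanimoto similarity.
#' @return A named list of class `ivs_windows`.
#' @export
decoy_windows <- function(mw = 25, hbd = 1, hba = 1, max_similarity = 0.4) {
  stopifnot(mw > 0, hbd >= 0, hba >= 0,
            max_similarity > 0, max_similarity <= 1)
  structure(list(mw = mw, hbd = hbd, hba = hba,
                 max_similarity = max_similarity),
            class = "ivs_windows")
}

.fp2_similarity <- function(query_smiles, candidate_smiles) {
  smi <- paste0(c(query_smiles, candidate_smiles), " S",
                seq_len(1 + length(candidate_smiles)), collapse = "\n")
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
  sdf <- suppressWarnings(ChemmineR::read.SDFset(
    unlist(strsplit(sdf_txt, "\n", fixed = TRUE))))
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  sims <- ChemmineR::fpSim(fp[1], fp, method = "Tanimoto", sorted = FALSE)
  unname(sims[-1])
}

#' Select property-matched decoys for a query compound
#'
#' Candidates are eligible when all three property windows hold and the
#' FP2 Tanimoto similarity to the query is strictly below the threshold.
#' Among eligible candidates, the `n` with the smallest absolute MW
#' difference are kept (ties broken by id), making the selection
#' deterministic and invariant under permutation of the candidate list.
#'
#' @param candidates Tibble of candidate compounds (`id`, `structure`, ...).
#' @param query One-row tibble with the query compound.
#' @param n Number of decoys required (default 10).
#' @param windows Matching tolerances, see [decoy_windows()].
#' @return A tibble of `n` decoys with property, `delta_mw` and
#'   `similarity` columns; the windows, query id and threshold are attached
#'   as attributes (`windows`, `query_id`).
#' @export
#' @examples
#' query <- compound_properties(hemp_compounds()[2, ])
#' lib <- generate_decoy_library(query, n_candidates = 40, seed = 7)
#' select_decoys(lib, query)
select_decoys <- function(candidates, query, n = 10, windows = decoy_windows()) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1,
            is.data.frame(query), nrow(query) == 1, n >= 1)
  if (!inherits(windows, "ivs_windows")) windows <- do.call(decoy_windows, windows)
  qp <- if (all(c("mw", "hbd", "hba") %in% names(query))) query else
    compound_properties(query)
  cp <- if (all(c("mw", "hbd", "hba") %in% names(candidates))) candidates else
    compound_properties(candidates)
  cp$similarity <- .fp2_similarity(qp$structure, cp$structure)
  cp$delta_mw <- abs(cp$mw - qp$mw)
  eligible <- cp$delta_mw <= windows$mw &
    abs(cp$hbd - qp$hbd) <= windows$hbd &
    abs(cp$hba - qp$hba) <= windows$hba &
    cp$similarity < windows$max_similarity
  pool <- cp[eligible, , drop = FALSE]
  if (nrow(pool) < n) {
    abort(
      paste0("insufficient decoys for query '", qp$id, "': ", nrow(pool),
             " eligible of ", nrow(cp), " candidates, ", n, " required (short by ",
             n - nrow(pool), ")"),
      class = "ivs_insufficient_decoys",
      n_eligible = nrow(pool), n_required = n
    )
  }
  pool <- pool[order(pool$delta_mw, pool$id), , drop = FALSE]
  out <- as_tibble(pool[seq_len(n), , drop = FALSE])
  out$role <- "decoy"
  attr(out, "windows") <- windows
  attr(out, "query_id") <- qp$id
  out
}

#' Re-verify a decoy set against its own constraints
#'
#' Audits that every decoy still satisfies the matching windows and the
#' dissimilarity threshold recorded when the set was built. Selection
#' followed by verification is idempotent: a returned decoy set always
#' passes.
#'
#' @param decoys Output of [select_decoys()].
#' @param query The query compound (one-row tibble).
#' @return `TRUE` invisibly; aborts with class `ivs_decoy_audit_error`
#'   describing the first violated constraint otherwise.
#' @export
verify_decoy_set <- function(decoys, query) {
  windows <- attr(decoys, "windows") %||% decoy_windows()
  qp <- if (all(c("mw", "hbd", "hba") %in% names(query))) query else
    compound_properties(query)
  cp <- compound_properties(decoys)
  cp$similarity <- .fp2_similarity(qp$structure, cp$structure)
  ok_mw <- abs(cp$mw - qp$mw) <= windows$mw
  ok_hbd <- abs(cp$hbd - qp$hbd) <= windows$hbd
  ok_hba <- abs(cp$hba - qp$hba) <= windows$hba
  ok_sim <- cp$similarity < windows$max_similarity
  bad <- !(ok_mw & ok_hbd & ok_hba & ok_sim)
  if (any(bad)) {
    abort(paste0("decoy set fails audit for: ",
                 paste(cp$id[bad], collapse = ", ")),
          class = "ivs_decoy_audit_error")
  }
  invisible(TRUE)
}
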