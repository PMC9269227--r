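# Normalisation, retention filtering, ranking and the end-to-end screen.

test_that("V normalisation follows the defining ratio", {
  # identical decoys force V = 1
  r <- normalize_affinity(-9.0, rep(-9.0, 10))
  expect_equal(r$VR, -9.0)
  expect_equal(r$V, 1.0)
  # direct substitution: -10.1 / -8.0
  r2 <- normalize_affinity(-10.1, rep(-8.0, 10))
  expect_equal(r2$V, 1.2625)
  expect_error(normalize_affinity(-9, numeric()),
               class = "ivs_normalization_error")
  expect_error(normalize_affinity(-9, rep(0.5, 10)),
               class = "ivs_normalization_error")
})

test_that("table normalisation matches per-pair hand computation", {
  records <- tibble::tibble(compound_id = c("q1", "q1", "q2"),
                            pdb_id = c("A", "B", "A"),
                            best_affinity = c(-9, -8, -7))
  decoy_records <- tidyr::crossing(compound_id = c("d1", "d2"),
                                   pdb_id = c("A", "B")) |>
    dplyr::mutate(best_affinity = c(-6, -8, -7, -9))
  decoy_map <- tidyr::crossing(query_id = c("q1", "q2"),
                               decoy_id = c("d1", "d2"))
  hits <- normalize_affinities(records, decoy_records, decoy_map)
  # VR on A = mean(-6, -7) = -6.5; on B = mean(-8, -9) = -8.5
  expect_equal(hits$VR, c(-6.5, -8.5, -6.5))
  expect_equal(hits$V, c(-9 / -6.5, -8 / -8.5, -7 / -6.5))
  expect_equal(hits$n_decoys, c(2L, 2L, 2L))
})

test_that("hits with no decoys or non-negative decoy means are excluded with a warning", {
  records <- tibble::tibble(compound_id = c("q1", "q1"),
                            pdb_id = c("A", "B"),
                            best_affinity = c(-9, -8))
  decoy_records <- tibble::tibble(compound_id = "d1", pdb_id = "A",
                                  best_affinity = -6)
  decoy_map <- tibble::tibble(query_id = "q1", decoy_id = "d1")
  expect_warning(
    hits <- normalize_affinities(records, decoy_records, decoy_map),
    "excluded")
  expect_equal(hits$pdb_id, "A")
  expect_equal(attr(hits, "dropped")$pdb_id, "B")
})

test_that("both retention thresholds are strict inequalities", {
  hits <- tibble::tibble(
    compound_id = "q", pdb_id = c("A", "B", "C", "D", "E"),
    V0 = c(-7.4, -8.0, -7.6, -7.5, -8.2),
    VR = -10, V = c(0.9, 0.75, 0.80, 0.80, 0.75 + 1e-9), n_decoys = 10L)
  out <- apply_screen_filter(hits)
  # -7.4 fails "below -7.5"; V = 0.75 fails "above 0.75";
  # V0 = -7.5 exactly fails the strict bound
  expect_equal(out$passed, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$pdb_id, hits$pdb_id)  # order preserved
})

test_that("non-binding (V0 >= 0) hits always fail", {
  hits <- tibble::tibble(compound_id = "q", pdb_id = "A", V0 = 0.3,
                         VR = -8, V = 0.3 / -8, n_decoys = 10L)
  # even a permissive filter cannot pass a positive affinity
  out <- apply_screen_filter(hits, screen_filter(e_max = -0.001,
                                                 v_min = 1e-6))
  expect_false(out$passed)
})

test_that("relaxing either threshold never shrinks the kept set", {
  set.seed(7)
  hits <- tibble::tibble(
    compound_id = "q", pdb_id = sprintf("P%02d", 1:60),
    V0 = stats::runif(60, -11, -5), VR = stats::runif(60, -9, -5))
  hits$V <- hits$V0 / hits$VR
  hits$n_decoys <- 10L
  kept <- function(e, v) {
    which(apply_screen_filter(hits, screen_filter(e, v))$passed)
  }
  base <- kept(-7.5, 0.75)
  for (e in c(-7.0, -6.5, -6.0)) expect_true(all(base %in% kept(e, 0.75)))
  for (v in c(0.6, 0.5, 0.2)) expect_true(all(base %in% kept(-7.5, v)))
})

test_that("top scores pick the extremum per compound with deterministic tie-breaks", {
  hits <- tibble::tibble(
    compound_id = c("1", "1", "1", "2", "2"),
    pdb_id = c("BBB", "AAA", "CCC", "ZZZ", "YYY"),
    V0 = c(-9.5, -9.5, -8.0, -8.8, -8.8),
    VR = -8, n_decoys = 10L)
  hits$V <- hits$V0 / hits$VR
  hits <- apply_screen_filter(hits)
  top <- top_scores(hits, by = "affinity")
  # identical V0: lexicographic pdb_id breaks the tie, flagged
  expect_equal(top$pdb_id[top$compound_id == "1"], "AAA")
  expect_true(top$tied[top$compound_id == "1"])
  expect_equal(top$pdb_id[top$compound_id == "2"], "YYY")
  topv <- top_scores(hits, by = "V")
  expect_equal(topv$value[topv$compound_id == "1"], -9.5 / -8)

  # a compound with no passed hits is omitted with a warning
  hits2 <- hits
  hits2$passed[hits2$compound_id == "2"] <- FALSE
  expect_warning(t2 <- top_scores(hits2, by = "affinity"), "omitted")
  expect_equal(t2$compound_id, "1")
})

test_that("consensus keeps only targets covered by every compound", {
  mapping <- tibble::tibble(pdb_id = c("A1", "A2", "B1"),
                            uniprot_id = c("U1", "U1", "U2"))
  hits <- tibble::tibble(
    compound_id = c("1", "2", "3", "1", "2"),
    pdb_id = c("A1", "A2", "A1", "B1", "B1"),
    V0 = c(-8, -9, -8.5, -10, -10),
    VR = -8, n_decoys = 10L)
  hits$V <- hits$V0 / hits$VR
  hits$passed <- TRUE
  cons <- consensus_targets(hits, mapping, compounds = c("1", "2", "3"))
  # U2 lacks compound 3 and is excluded despite stronger affinities
  expect_equal(unique(cons$uniprot_id), "U1")
  expect_equal(cons$retrieval_count, rep(3L, 3))
  expect_equal(cons$best_affinity[cons$compound_id == "2"], -9)
})

test_that("unmapped structures are excluded from consensus with a warning", {
  mapping <- tibble::tibble(pdb_id = "A1", uniprot_id = "U1")
  hits <- tibble::tibble(compound_id = c("1", "1"),
                         pdb_id = c("A1", "QQQ"), V0 = -9, VR = -8,
                         V = 9 / 8, n_decoys = 10L, passed = TRUE)
  expect_warning(cons <- consensus_targets(hits, mapping, compounds = "1"),
                 "QQQ")
  expect_equal(unique(cons$uniprot_id), "U1")
})

test_that("consensus agrees with the brute-force oracle on random tables", {
  set.seed(2024)
  for (i in 1:25) {
    inst <- random_hit_table(n_targets = sample(5:50, 1))
    oracle <- brute_force_consensus(inst$hits, inst$mapping, inst$compounds)
    got <- consensus_targets(inst$hits, inst$mapping,
                             compounds = inst$compounds)
    expect_equal(sort(unique(got$uniprot_id)),
                 sort(as.character(names(oracle))))
    for (u in names(oracle)) {
      sub <- got[got$uniprot_id == u, ]
      expect_equal(unique(sub$retrieval_count), oracle[[u]]$retrieval_count)
      expect_equal(
        stats::setNames(sub$best_affinity, sub$compound_id)[inst$compounds],
        oracle[[u]]$best)
    }
  }
})

test_that("the replayed screen is reproducible bit for bit", {
  ex <- hemp_screen_example()
  backend <- replay_backend(dplyr::bind_rows(ex$affinities,
                                             ex$decoy_affinities))
  # the recorded table covers only retained pairs; missing jobs are
  # logged failures
  s1 <- suppressWarnings(run_screen(ex$compounds, ex$panel, ex$decoy_map,
                                    backend))
  s2 <- suppressWarnings(run_screen(ex$compounds, ex$panel, ex$decoy_map,
                                    backend))
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$consensus, s2$consensus)
})

test_that("an extreme filter empties the report sections with warnings", {
  ex <- hemp_screen_example()
  backend <- replay_backend(dplyr::bind_rows(ex$affinities,
                                             ex$decoy_affinities))
  ws <- testthat::capture_warnings(
    scr <- run_screen(ex$compounds, ex$panel, ex$decoy_map, backend,
                      filter = screen_filter(e_max = -1e6)))
  expect_true(any(grepl("omitted|no passed", ws)))
  expect_equal(nrow(scr$top_affinity), 0)
  expect_equal(nrow(scr$consensus), 0)
  expect_equal(sum(scr$hits$passed), 0)
})

test_that("screen objects support tidy, glance, autoplot and report writing", {
  ex <- hemp_screen_example()
  backend <- replay_backend(dplyr::bind_rows(ex$affinities,
                                             ex$decoy_affinities))
  scr <- suppressWarnings(run_screen(ex$compounds, ex$panel, ex$decoy_map,
                                     backend))
  td <- generics::tidy(scr)
  expect_true(all(c("V0", "VR", "V", "passed") %in% names(td)))
  gl <- generics::glance(scr)
  expect_equal(gl$n_passed, 9L)
  expect_equal(gl$e_max, -7.5)
  p <- ggplot2::autoplot(scr)
  expect_s3_class(p, "ggplot")

  dir <- tempfile()
  write_screen_report(scr, dir)
  expect_true(file.exists(file.path(dir, "screen_report.json")))
  rep <- jsonlite::read_json(file.path(dir, "screen_report.json"))
  expect_equal(rep$filter$e_max, -7.5)
  top <- readr::read_tsv(file.path(dir, "top_scores.tsv"),
                         show_col_types = FALSE)
  expect_true(all(c("affinity", "V") %in% top$criterion))
})
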