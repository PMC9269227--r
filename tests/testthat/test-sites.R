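# Binding-site definition and docking-box construction.

test_that("ligand-derived site is the heavy-atom centroid and bounds", {
  lig <- tibble::tibble(
    eleno = 1:3, elety = c("C1", "C2", "C3"), alt = NA_character_,
    resid = "LIG", chain = "A", resno = 1L,
    x = c(0, 2, 4), y = 0, z = 0, o = 1, elesy = "C", is_hetero = TRUE)
  rec <- make_receptor(
    tibble::tibble(eleno = 4, elety = "CA", resid = "GLY", chain = "A",
                   resno = 2L, x = 10, y = 0, z = 0, elesy = "C"),
    ligand = lig)
  site <- site_from_ligand(rec)
  expect_equal(c(site$center_x, site$center_y, site$center_z), c(2, 0, 0))
  expect_equal(site$max_x - site$min_x, 4)
  expect_equal(site$provenance, "ligand_derived")
})

test_that("the larger of two hetero groups is extracted as the ligand", {
  lines <- c(
    protein_lines(),
    pdb_line("HETATM", 101, " C1 ", "AAA", "B", 301, 5, 5, 5),
    pdb_line("HETATM", 102, " C2 ", "AAA", "B", 301, 6, 5, 5),
    pdb_line("HETATM", 103, " C1 ", "BBB", "A", 302, 8, 8, 8),
    pdb_line("HETATM", 104, " C2 ", "BBB", "A", 302, 9, 8, 8),
    pdb_line("HETATM", 105, " C3 ", "BBB", "A", 302, 10, 8, 8)
  )
  rec <- clean_structure(write_fixture_pdb(lines))
  expect_equal(unique(rec$ligand$resid), "BBB")

  # equal sizes: tie broken by lower chain id
  lines_tie <- c(
    protein_lines(),
    pdb_line("HETATM", 101, " C1 ", "AAA", "B", 301, 5, 5, 5),
    pdb_line("HETATM", 102, " C2 ", "AAA", "B", 301, 6, 5, 5),
    pdb_line("HETATM", 103, " C1 ", "BBB", "A", 302, 8, 8, 8),
    pdb_line("HETATM", 104, " C2 ", "BBB", "A", 302, 9, 8, 8)
  )
  rec_tie <- clean_structure(write_fixture_pdb(lines_tie))
  expect_equal(unique(rec_tie$ligand$chain), "A")
})

test_that("a retained single-atom hetero group is a degenerate ligand", {
  lines <- c(protein_lines(),
             pdb_line("HETATM", 101, " X  ", "UNX", "A", 301, 5, 5, 5))
  rec <- clean_structure(write_fixture_pdb(lines))
  expect_error(site_from_ligand(rec), class = "ivs_degenerate_ligand")
})

test_that("docking-box arithmetic: extent plus twice the buffer per axis", {
  site <- ivscreen:::.site_tibble(c(5, 5, 5), c(0, 0, 0), c(10, 10, 10),
                                  1, "ligand_derived")
  box <- build_box(site)
  expect_equal(c(box$center_x, box$center_y, box$center_z), c(5, 5, 5))
  expect_equal(c(box$size_x, box$size_y, box$size_z), c(30, 30, 30))
  expect_equal(box$spacing, 1.0)

  point <- ivscreen:::.site_tibble(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3),
                                   1, "detected")
  expect_equal(unlist(build_box(point)[c("size_x", "size_y", "size_z")],
                      use.names = FALSE), c(20, 20, 20))

  aniso <- ivscreen:::.site_tibble(c(2, 4, 6), c(0, 0, 0), c(4, 8, 12),
                                   1, "detected")
  expect_equal(unlist(build_box(aniso)[c("size_x", "size_y", "size_z")],
                      use.names = FALSE), c(24, 28, 32))

  expect_error(build_box(site, buffer = 0), class = "ivs_parameter_error")
})

test_that("the box always contains the site with at least the buffer margin", {
  set.seed(101)
  for (i in 1:20) {
    lo <- stats::runif(3, -30, 30)
    hi <- lo + stats::runif(3, 0, 25)
    site <- ivscreen:::.site_tibble((lo + hi) / 2, lo, hi, 1, "detected")
    buffer <- stats::runif(1, 1, 15)
    box <- build_box(site, buffer = buffer)
    bmin <- c(box$center_x, box$center_y, box$center_z) -
      c(box$size_x, box$size_y, box$size_z) / 2
    bmax <- c(box$center_x, box$center_y, box$center_z) +
      c(box$size_x, box$size_y, box$size_z) / 2
    expect_true(all(lo - bmin >= buffer - 1e-9))
    expect_true(all(bmax - hi >= buffer - 1e-9))
  }
})

test_that("the pocket scan recovers a carved cavity and rejects a convex shape", {
  tc <- generate_toy_complex(dir = tempfile())
  rec <- clean_structure(tc$receptor)
  sites <- detect_binding_sites(rec)
  expect_gte(nrow(sites), 1)
  err <- sqrt(sum((c(sites$center_x[1], sites$center_y[1],
                     sites$center_z[1]) - tc$cavity_center)^2))
  expect_lt(err, 2)
  # scores ranked descending
  expect_true(all(diff(sites$score) <= 0))

  convex <- generate_toy_complex(carve_cavity = FALSE, dir = tempfile())
  expect_equal(nrow(detect_binding_sites(clean_structure(convex$receptor))), 0)
})

test_that("pocket detection is invariant under rigid translation", {
  tc <- generate_toy_complex(dir = tempfile())
  rec <- clean_structure(tc$receptor)
  s1 <- detect_binding_sites(rec)
  shift <- c(7.3, -4.1, 2.9)
  rec2 <- rec
  rec2$atoms$x <- rec2$atoms$x + shift[1]
  rec2$atoms$y <- rec2$atoms$y + shift[2]
  rec2$atoms$z <- rec2$atoms$z + shift[3]
  s2 <- detect_binding_sites(rec2)
  expect_equal(s2$score, s1$score)
  expect_equal(s2$center_x, s1$center_x + shift[1], tolerance = 1e-8)
  expect_equal(s2$center_y, s1$center_y + shift[2], tolerance = 1e-8)
  expect_equal(s2$center_z, s1$center_z + shift[3], tolerance = 1e-8)
})

test_that("site dispatch prefers the co-crystallised ligand", {
  lig <- tibble::tibble(
    eleno = 1:3, elety = c("C1", "C2", "C3"), alt = NA_character_,
    resid = "LIG", chain = "A", resno = 1L,
    x = c(0, 2, 4), y = 0, z = 0, o = 1, elesy = "C", is_hetero = TRUE)
  rec <- make_receptor(
    tibble::tibble(eleno = 4:5, elety = "CA", resid = "GLY", chain = "A",
                   resno = 2:3, x = c(10, 12), y = 0, z = 0, elesy = "C"),
    ligand = lig)
  site <- binding_site(rec)
  expect_equal(site$provenance, "ligand_derived")
})
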