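# Geometric pose audit: hydrogen bonds, pi-pi stacking, salt bridges.

ser_receptor <- function() {
  make_receptor(tibble::tibble(
    eleno = 1:6,
    elety = c("N", "CA", "C", "O", "CB", "OG"),
    resid = "SER", chain = "B", resno = 195L,
    x = c(-4, -3.2, -4, -5, -1.5, 0), y = c(2, 1, 0, 0, 1, 0), z = 0,
    elesy = c("N", "C", "C", "O", "C", "O")), pdb_id = "SERF")
}

test_that("a textbook O-H...O geometry is detected and labelled; long contacts are not", {
  rec <- ser_receptor()
  # ligand hydroxyl: O 2.9 A from Ser OG with the H roughly on the O-O axis
  pose <- as_pose(
    tibble::tibble(element = c("O", "H", "C"),
                   x = c(2.9, 2.0, 3.5), y = c(0, 0.08, 1), z = 0),
    bonds = tibble::tibble(a1 = c(1, 1), a2 = c(2, 3), order = 1L))
  hb <- detect_hbonds(pose, rec)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$residue, "B:Ser195")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_gt(hb$angle, 160)

  far <- as_pose(
    tibble::tibble(element = c("O", "H", "C"),
                   x = c(4.2, 3.3, 4.8), y = c(0, 0.08, 1), z = 0),
    bonds = tibble::tibble(a1 = c(1, 1), a2 = c(2, 3), order = 1L))
  expect_equal(nrow(detect_hbonds(far, rec)), 0)
})

test_that("a bad D-H...A angle rejects an otherwise close contact", {
  rec <- ser_receptor()
  # H pointing away from the acceptor: angle near 0. The ligand oxygen is
  # flagged donor-only so the receptor-donor reading of the pair (which
  # is legitimate chemistry) does not mask the angle rejection.
  pose <- as_pose(
    tibble::tibble(element = c("O", "H"), x = c(2.9, 3.86), y = 0, z = 0,
                   is_donor = c(TRUE, FALSE),
                   is_acceptor = FALSE),
    bonds = tibble::tibble(a1 = 1, a2 = 2, order = 1L))
  expect_equal(nrow(detect_hbonds(pose, rec)), 0)
  # without hydrogens the same heavy-atom geometry is reported,
  # distance-only
  heavy <- as_pose(tibble::tibble(element = "O", x = 2.9, y = 0, z = 0))
  hb <- detect_hbonds(heavy, rec)
  expect_equal(nrow(hb), 1)
  expect_true(is.na(hb$angle))
})

test_that("pi stacking classifies parallel and T-shaped windows and respects the cutoff", {
  rec <- ring_receptor()
  par <- as_pose(hex_ring(center = c(0, 0, 3.8)), rings = list(1:6))
  got <- detect_pistacks(par, rec)
  expect_equal(got$geometry, "parallel")
  expect_equal(got$centroid_distance, 3.8, tolerance = 1e-6)
  expect_equal(got$residue, "A:Tyr119")

  none <- as_pose(hex_ring(center = c(0, 0, 7.0)), rings = list(1:6))
  expect_equal(nrow(detect_pistacks(none, rec)), 0)

  perp <- as_pose(hex_ring(center = c(0, 0, 5.0), normal = c(1, 0, 0)),
                  rings = list(1:6))
  gp <- detect_pistacks(perp, rec)
  expect_equal(gp$geometry, "t_shaped")
  expect_equal(gp$interplanar_angle, 90, tolerance = 1e-6)

  # intermediate tilt (45 degrees) is excluded
  tilt <- as_pose(hex_ring(center = c(0, 0, 4), normal = c(1, 0, 1)),
                  rings = list(1:6))
  expect_equal(nrow(detect_pistacks(tilt, rec)), 0)
})

test_that("ring-pair geometry is symmetric under swapping the two rings", {
  set.seed(5)
  for (i in 1:10) {
    a <- as.matrix(hex_ring(stats::runif(3, -3, 3), stats::rnorm(3))[, c("x", "y", "z")])
    b <- as.matrix(hex_ring(stats::runif(3, -3, 3), stats::rnorm(3))[, c("x", "y", "z")])
    g1 <- pi_stack_geometry(a, b)
    g2 <- pi_stack_geometry(b, a)
    expect_equal(g1$centroid_distance, g2$centroid_distance)
    expect_equal(g1$interplanar_angle, g2$interplanar_angle,
                 tolerance = 1e-8)
    expect_equal(g1$geometry, g2$geometry)
  }
})

test_that("carboxylate-guanidinium pairs are reported as salt bridges", {
  rec <- make_receptor(tibble::tibble(
    eleno = 1:3, elety = c("NE", "NH1", "NH2"), resid = "ARG",
    chain = "A", resno = 288L,
    x = c(3.5, 4.2, 4.2), y = c(0, 0.8, -0.8), z = 0, elesy = "N"),
    pdb_id = "ARGF")
  # ligand carboxylate: C bonded to O (double) and O (single)
  pose <- as_pose(
    tibble::tibble(element = c("C", "O", "O", "C"),
                   x = c(1, 0.4, 0.4, 2.4), y = c(0, 1, -1, 0), z = 0),
    bonds = tibble::tibble(a1 = c(1, 1, 1), a2 = c(2, 3, 4),
                           order = c(2L, 1L, 1L)))
  sb <- detect_salt_bridges(pose, rec)
  expect_gte(nrow(sb), 1)
  expect_equal(unique(sb$residue), "A:Arg288")
  expect_equal(unique(sb$ligand_role), "anionic")
  expect_true(all(sb$distance <= 4.0))
})

test_that("contacts are invariant under a joint rigid rototranslation", {
  rec <- ser_receptor()
  pose <- as_pose(
    tibble::tibble(element = c("O", "H", "C"),
                   x = c(2.9, 2.0, 3.5), y = c(0, 0.08, 1), z = 0),
    bonds = tibble::tibble(a1 = c(1, 1), a2 = c(2, 3), order = 1L))
  before <- interaction_report(pose, rec)
  set.seed(31)
  R <- random_rotation()
  t <- c(5, -3, 11)
  xf <- function(m) sweep(as.matrix(m) %*% t(R), 2, t, "+")
  rec2 <- rec
  rec2$atoms[, c("x", "y", "z")] <- xf(rec$atoms[, c("x", "y", "z")])
  pose2 <- pose
  pose2$atoms[, c("x", "y", "z")] <- xf(pose$atoms[, c("x", "y", "z")])
  after <- interaction_report(pose2, rec2)
  expect_equal(after$hbonds$residue, before$hbonds$residue)
  expect_equal(after$hbonds$distance, before$hbonds$distance,
               tolerance = 1e-8)
  expect_equal(after$hbonds$angle, before$hbonds$angle, tolerance = 1e-6)
})

test_that("every reported contact satisfies its own recorded cutoffs", {
  rec <- make_receptor(dplyr::bind_rows(
    ser_receptor()$atoms,
    dplyr::mutate(ring_receptor(center = c(2, 3, 2))$atoms, eleno = 10:15)),
    pdb_id = "MIX")
  set.seed(8)
  atoms <- tibble::tibble(
    element = sample(c("C", "O", "N"), 30, replace = TRUE),
    x = stats::runif(30, -2, 6), y = stats::runif(30, -2, 6),
    z = stats::runif(30, -2, 4))
  pose <- as_pose(atoms)
  rep <- interaction_report(pose, rec)
  expect_true(all(rep$hbonds$distance <= 3.5))
  expect_true(all(rep$saltbridges$distance <= 4.0))
  expect_true(all(rep$pistacks$centroid_distance <= 5.5))
  expect_true(all(rep$pistacks$geometry %in% c("parallel", "t_shaped")))
})

test_that("known-site scoring intersects contacts with the reference list", {
  contacts <- tibble::tibble(residue = c("B:Ser60", "B:Leu120"))
  expect_setequal(
    score_known_site(contacts, c("Ser60", "Leu120", "Gly121")),
    c("Ser60", "Leu120"))
  expect_length(score_known_site(tibble::tibble(residue = character()),
                                 c("Ser60")), 0)
  # chain-qualified references match only their chain
  expect_setequal(score_known_site(contacts, c("B:Ser60", "A:Leu120")),
                  "B:Ser60")
})
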