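# Geometric audit of docking poses: hydrogen bonds, pi-pi stacking and
# salt bridges between a ligand pose and receptor residues, reported with
# chain:ResnameNumber labels. Default cutoffs are the widely used
# geometric criteria (H-bond donor-acceptor <= 3.5 A with D-H...A >= 120
# degrees when hydrogens exist; ring centroids <= 5.5 A, parallel when the
# interplanar angle is <= 30 degrees, T-shaped at 60-90 degrees; charged
# group distance <= 4.0 A), all configurable.

#' Build a ligand pose object
#'
#' @param atoms Data frame with `element`, `x`, `y`, `z` and optionally
#'   `charge`, `is_donor`, `is_acceptor` (donor/acceptor default to
#'   O/N-based typing; donors additionally need a bonded or implicit
#'   hydrogen when bonds are supplied).
#' @param bonds Optional data frame with `a1`, `a2`, `order`.
#' @param rings Optional list of integer vectors: aromatic ring atom
#'   indices.
#' @return Object of class `ivs_pose`.
#' @export
as_pose <- function(atoms, bonds = NULL, rings = list()) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$idx <- seq_len(nrow(atoms))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (is.null(bonds)) bonds <- tibble(a1 = integer(), a2 = integer(),
                                      order = integer())
  heavy_nbrs <- function(i) {
    c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
  }
  if (!"is_acceptor" %in% names(atoms)) {
    atoms$is_acceptor <- atoms$element %in% c("N", "O")
  }
  if (!"is_donor" %in% names(atoms)) {
    has_h <- map_lgl(atoms$idx, function(i) {
      nb <- heavy_nbrs(i)
      length(nb) == 0 || any(atoms$element[nb] == "H")
    })
    atoms$is_donor <- atoms$element %in% c("N", "O") & has_h
  }
  structure(list(atoms = atoms, bonds = as_tibble(bonds), rings = rings),
            class = "ivs_pose")
}

#' Read a ligand pose from an SDF (or convertible) file
#'
#' SDF is read directly; other formats Open Babel understands (e.g.
#' PDBQT) are converted first. Aromatic rings are perceived for pi-pi
#' detection; donors/acceptors are typed from the molecular graph.
#'
#' @param path Pose file.
#' @return An `ivs_pose`.
#' @export
read_pose <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "sdf") {
    sdf_txt <- ChemmineOB::convertFormat(toupper(ext), "SDF",
                                         paste(readLines(path, warn = FALSE),
                                               collapse = "\n"))
    tmp <- tempfile(fileext = ".sdf")
    writeLines(sdf_txt, tmp)
    path <- tmp
  }
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- tibble(
    element = sub("_.*$", "", rownames(ab)),
    x = ab[, 1], y = ab[, 2], z = ab[, 3]
  )
  bonds <- tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  rings <- tryCatch({
    rr <- ChemmineR::rings(sdf, upper = 6, type = "all", arom = TRUE)
    arom <- rr$RINGS[unlist(rr$AROMATIC)]
    lapply(arom, function(r) as.integer(sub("^.*_", "", r)))
  }, error = function(e) list())
  as_pose(atoms, bonds, rings)
}

.residue_label <- function(chain, resid, resno) {
  resname <- paste0(toupper(substr(resid, 1, 1)),
                    tolower(substr(resid, 2, nchar(resid))))
  paste0(chain, ":", resname, resno)
}

# receptor polar/charged/aromatic atom typing by residue and atom name
.BACKBONE_DONOR <- "N"
.BACKBONE_ACCEPTOR <- c("O", "OXT")
.SIDECHAIN_DONOR <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG"
)
.SIDECHAIN_ACCEPTOR <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)
.AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)
.CATIONIC <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("ND1", "NE2"))
.ANIONIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.receptor_typed <- function(receptor, roles) {
  a <- receptor$atoms
  a <- a[!a$is_hetero & (is.na(a$elesy) | a$elesy != "H"), ]
  a$elety <- trimws(a$elety)
  pick <- function(table, backbone = character()) {
    sel <- a$elety %in% backbone & a$resid != "PRO" |
      map_lgl(seq_len(nrow(a)), function(i) {
        ent <- table[[a$resid[i]]]
        !is.null(ent) && a$elety[i] %in% ent
      })
    out <- a[sel, ]
    out$residue <- .residue_label(out$chain, out$resid, out$resno)
    out
  }
  switch(roles,
    donor = pick(.SIDECHAIN_DONOR, .BACKBONE_DONOR),
    acceptor = pick(.SIDECHAIN_ACCEPTOR, .BACKBONE_ACCEPTOR),
    cationic = pick(.CATIONIC),
    anionic = pick(.ANIONIC)
  )
}

.pairwise_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.pose_xyz <- function(pose, sel = TRUE) {
  as.matrix(pose$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

#' Detect hydrogen bonds between a pose and receptor residues
#'
#' All donor-acceptor pairs (in both directions) whose heavy-atom
#' distance is within the cutoff. When the pose carries explicit
#' hydrogens on a donor, the best D-H...A angle must also reach
#' `min_angle`; with no hydrogens available the criterion is
#' distance-only and the angle is reported as `NA` (receptor structures
#' rarely carry hydrogens).
#'
#' @param pose An `ivs_pose`.
#' @param receptor An `ivs_receptor`.
#' @param max_dist Donor-acceptor heavy-atom cutoff, A (default 3.5).
#' @param min_angle Minimum D-H...A angle, degrees (default 120).
#' @return Tibble sorted by distance: `class`, `donor_owner`,
#'   `ligand_atom`, `residue`, `distance`, `angle`.
#' @export
detect_hbonds <- function(pose, receptor, max_dist = 3.5, min_angle = 120) {
  stopifnot(inherits(pose, "ivs_pose"), inherits(receptor, "ivs_receptor"))
  la <- pose$atoms
  if (is.null(la$is_donor) || is.null(la$is_acceptor)) {
    abort("pose atoms are not typed (donor/acceptor flags missing)",
          class = "ivs_typing_error")
  }
  h_idx <- which(la$element == "H")
  h_of <- function(i) {
    b <- pose$bonds
    c(b$a2[b$a1 == i & b$a2 %in% h_idx], b$a1[b$a2 == i & b$a1 %in% h_idx])
  }
  one_side <- function(lig_sel, rec, lig_is_donor) {
    lig <- la[lig_sel, ]
    if (nrow(lig) == 0 || nrow(rec) == 0) return(NULL)
    D <- .pairwise_dist(.pose_xyz(pose, lig_sel),
                        as.matrix(rec[, c("x", "y", "z")]))
    hits <- which(D <= max_dist, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    out <- tibble(
      class = "hbond",
      donor_owner = if (lig_is_donor) "ligand" else "receptor",
      ligand_atom = paste0(lig$element[hits[, 1]], lig$idx[hits[, 1]]),
      residue = rec$residue[hits[, 2]],
      distance = D[hits],
      angle = NA_real_
    )
    if (lig_is_donor && length(h_idx) > 0) {
      for (r in seq_len(nrow(hits))) {
        di <- lig$idx[hits[r, 1]]
        hs <- h_of(di)
        if (length(hs) == 0) next
        acc <- as.numeric(rec[hits[r, 2], c("x", "y", "z")])
        don <- as.numeric(la[di, c("x", "y", "z")])
        angs <- map_dbl(hs, function(h) {
          hv <- as.numeric(la[h, c("x", "y", "z")])
          v1 <- don - hv; v2 <- acc - hv
          acos(pmin(1, pmax(-1, sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        })
        out$angle[r] <- max(angs)
      }
      out <- out[is.na(out$angle) | out$angle >= min_angle, ]
    }
    out
  }
  res <- bind_rows(
    one_side(which(la$is_donor & la$element != "H"),
             .receptor_typed(receptor, "acceptor"), TRUE),
    one_side(which(la$is_acceptor & la$element != "H"),
             .receptor_typed(receptor, "donor"), FALSE)
  )
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(class = character(), donor_owner = character(),
                  ligand_atom = character(), residue = character(),
                  distance = numeric(), angle = numeric()))
  }
  # one contact per heavy-atom pair: a ligand-donor assignment (which can
  # carry angle evidence) wins over the receptor-donor reading of the
  # same pair
  res <- res |>
    group_by(.data$ligand_atom, .data$residue, .data$distance) |>
    arrange(.data$donor_owner, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  arrange(res, .data$distance)
}

# centroid and unit normal of a ring given its coordinate matrix
.ring_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Geometry of one ring pair
#'
#' Centroid distance, interplanar angle (folded to 0-90 degrees) and the
#' stacking class: `parallel` when the angle is at most `parallel_max`,
#' `t_shaped` within `[t_min, 90]`, otherwise `none`. Symmetric in its
#' two arguments.
#'
#' @param ring_a,ring_b Coordinate matrices (>= 3 rows) of the two rings.
#' @param max_dist Centroid distance cutoff, A.
#' @param parallel_max,t_min Interplanar angle windows, degrees.
#' @return One-row tibble: `centroid_distance`, `interplanar_angle`,
#'   `geometry`.
#' @export
pi_stack_geometry <- function(ring_a, ring_b, max_dist = 5.5,
                              parallel_max = 30, t_min = 60) {
  pa <- .ring_plane(as.matrix(ring_a))
  pb <- .ring_plane(as.matrix(ring_b))
  d <- sqrt(sum((pa$centroid - pb$centroid)^2))
  ang <- acos(pmin(1, abs(sum(pa$normal * pb$normal)))) * 180 / pi
  geometry <- if (d > max_dist) "none"
  else if (ang <= parallel_max) "parallel"
  else if (ang >= t_min) "t_shaped"
  else "none"
  tibble(centroid_distance = d, interplanar_angle = ang,
         geometry = geometry)
}

#' Detect pi-pi stacking between pose rings and aromatic residues
#'
#' Receptor rings considered: His, Phe, Tyr and Trp side chains. Ring
#' pairs within the centroid cutoff are classified parallel or T-shaped
#' by interplanar angle; intermediate geometries are excluded.
#'
#' @inheritParams detect_hbonds
#' @inheritParams pi_stack_geometry
#' @return Tibble: `class`, `ligand_ring`, `residue`,
#'   `centroid_distance`, `interplanar_angle`, `geometry`.
#' @export
detect_pistacks <- function(pose, receptor, max_dist = 5.5,
                            parallel_max = 30, t_min = 60) {
  stopifnot(inherits(pose, "ivs_pose"), inherits(receptor, "ivs_receptor"))
  a <- receptor$atoms
  a <- a[!a$is_hetero, ]
  a$elety <- trimws(a$elety)
  rec_rings <- list()
  res_tab <- distinct(a[a$resid %in% names(.AROMATIC_RINGS),
                        c("chain", "resno", "resid")])
  for (i in seq_len(nrow(res_tab))) {
    r <- res_tab[i, ]
    for (atom_set in .AROMATIC_RINGS[[r$resid]]) {
      sel <- a$chain == r$chain & a$resno == r$resno & a$resid == r$resid &
        a$elety %in% atom_set
      if (sum(sel) == length(atom_set)) {
        rec_rings[[length(rec_rings) + 1L]] <- list(
          xyz = as.matrix(a[sel, c("x", "y", "z")]),
          residue = .residue_label(r$chain, r$resid, r$resno))
      }
    }
  }
  out <- list()
  for (li in seq_along(pose$rings)) {
    lr <- pose$rings[[li]]
    if (length(lr) < 3) next
    lxyz <- .pose_xyz(pose, lr)
    for (rr in rec_rings) {
      g <- pi_stack_geometry(lxyz, rr$xyz, max_dist = max_dist,
                             parallel_max = parallel_max, t_min = t_min)
      if (g$geometry != "none") {
        out[[length(out) + 1L]] <- mutate(
          g, class = "pistack",
          ligand_ring = paste(lr, collapse = "+"),
          residue = rr$residue, .before = 1)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(class = character(), ligand_ring = character(),
                  residue = character(), centroid_distance = numeric(),
                  interplanar_angle = numeric(), geometry = character()))
  }
  arrange(bind_rows(out), .data$centroid_distance)
}

#' Detect salt bridges between pose and receptor charged groups
#'
#' Ligand anionic atoms (carboxylate oxygens or explicit negative formal
#' charge) against Arg/Lys/His cationic nitrogens, and ligand cationic
#' atoms (explicit positive charge or quaternary nitrogen) against
#' Asp/Glu carboxylate oxygens; contact when within `max_dist`.
#'
#' @inheritParams detect_hbonds
#' @param max_dist Charged-group distance cutoff, A (default 4.0).
#' @return Tibble: `class`, `ligand_atom`, `residue`, `distance`,
#'   `ligand_role`.
#' @export
detect_salt_bridges <- function(pose, receptor, max_dist = 4.0) {
  stopifnot(inherits(pose, "ivs_pose"), inherits(receptor, "ivs_receptor"))
  la <- pose$atoms
  b <- pose$bonds
  carboxylate_o <- function() {
    cand <- which(la$element == "O")
    keep(cand, function(o) {
      nb <- c(b$a2[b$a1 == o], b$a1[b$a2 == o])
      any(map_lgl(nb, function(cc) {
        if (la$element[cc] != "C") return(FALSE)
        onb <- c(b$a2[b$a1 == cc], b$a1[b$a2 == cc])
        os <- onb[la$element[onb] == "O"]
        dbl <- b$order[(b$a1 == cc & b$a2 %in% os) |
                         (b$a2 == cc & b$a1 %in% os)]
        length(os) >= 2 && any(dbl == 2)
      }))
    })
  }
  anionic <- union(which(la$charge < 0), carboxylate_o())
  quat_n <- which(la$element == "N" &
                    map_int(la$idx, function(i) {
                      sum(b$a1 == i | b$a2 == i)
                    }) >= 4)
  cationic <- union(which(la$charge > 0), quat_n)
  one <- function(lig_sel, rec, role) {
    if (length(lig_sel) == 0 || nrow(rec) == 0) return(NULL)
    D <- .pairwise_dist(.pose_xyz(pose, lig_sel),
                        as.matrix(rec[, c("x", "y", "z")]))
    hits <- which(D <= max_dist, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    tibble(class = "saltbridge",
           ligand_atom = paste0(la$element[lig_sel[hits[, 1]]],
                                lig_sel[hits[, 1]]),
           residue = rec$residue[hits[, 2]],
           distance = D[hits], ligand_role = role)
  }
  res <- bind_rows(
    one(anionic, .receptor_typed(receptor, "cationic"), "anionic"),
    one(cationic, .receptor_typed(receptor, "anionic"), "cationic")
  )
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(class = character(), ligand_atom = character(),
                  residue = character(), distance = numeric(),
                  ligand_role = character()))
  }
  arrange(distinct(res), .data$distance)
}

#' Full interaction report for one pose
#'
#' Runs hydrogen-bond, pi-pi and salt-bridge detection and, when a
#' reference residue list for the known binding site is supplied, scores
#' how many of those residues the pose actually contacts.
#'
#' @inheritParams detect_hbonds
#' @param compound_id,pdb_id,pose_rank Provenance recorded on the report.
#' @param reference_residues Optional character vector of known
#'   binding-site residues (`"Ser60"` or `"B:Ser60"` forms).
#' @param ... Cutoff overrides passed to the detectors.
#' @return Object of class `ivs_contacts`: list with `hbonds`,
#'   `pistacks`, `saltbridges`, `known_site_hits` and provenance fields.
#' @export
interaction_report <- function(pose, receptor, compound_id = "ligand",
                               pdb_id = receptor$pdb_id, pose_rank = 1L,
                               reference_residues = NULL, ...) {
  rep <- structure(list(
    compound_id = compound_id, pdb_id = pdb_id, pose_rank = pose_rank,
    hbonds = detect_hbonds(pose, receptor, ...),
    pistacks = detect_pistacks(pose, receptor),
    saltbridges = detect_salt_bridges(pose, receptor)
  ), class = "ivs_contacts")
  rep$known_site_hits <- if (!is.null(reference_residues)) {
    score_known_site(rep, reference_residues)
  } else {
    character()
  }
  rep
}

#' @export
print.ivs_contacts <- function(x, ...) {
  cat("<ivs_contacts> ", x$compound_id, " vs ", x$pdb_id, " (pose ",
      x$pose_rank, "): ", nrow(x$hbonds), " H-bond(s), ",
      nrow(x$pistacks), " pi-stack(s), ", nrow(x$saltbridges),
      " salt bridge(s)\n", sep = "")
  if (length(x$known_site_hits)) {
    cat("  known-site residues contacted:",
        paste(x$known_site_hits, collapse = ", "), "\n")
  }
  invisible(x)
}

#' All contacts of a report as one tibble
#'
#' @param x An `ivs_contacts`.
#' @return Tibble with a `class` column distinguishing contact types.
#' @export
contacts_table <- function(x) {
  stopifnot(inherits(x, "ivs_contacts"))
  bind_rows(x$hbonds, x$pistacks, x$saltbridges)
}

#' Score contacts against a known binding-site residue list
#'
#' Returns the reference residues found among the contacted residues.
#' Reference labels may carry a chain prefix (`"B:Ser60"`) or not
#' (`"Ser60"`); chain-less references are matched ignoring the contact's
#' chain (label normalisation).
#'
#' @param x An `ivs_contacts` or any tibble with a `residue` column.
#' @param reference_residues Character vector of residue labels.
#' @return Character vector: the subset of `reference_residues`
#'   contacted.
#' @export
score_known_site <- function(x, reference_residues) {
  contacts <- if (inherits(x, "ivs_contacts")) contacts_table(x) else x
  stopifnot("residue" %in% names(contacts))
  hit <- unique(contacts$residue)
  hit_nochain <- sub("^[^:]*:", "", hit)
  ok <- map_lgl(reference_residues, function(r) {
    if (grepl(":", r, fixed = TRUE)) r %in% hit else r %in% hit_nochain
  })
  reference_residues[ok]
}
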