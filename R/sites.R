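# Binding-site definition and docking-box construction. When a structure
# carries a co-crystallised ligand its coordinates map the cavity; otherwise
# a deterministic grid buriedness scan proposes up to five pockets and the
# top-scoring one is used. The docking box adds a 10 A buffer per direction
# around the site at 1.0 A grid spacing (recorded as metadata).

.site_tibble <- function(center, bmin, bmax, score, provenance) {
  center <- unname(center); bmin <- unname(bmin); bmax <- unname(bmax)
  tibble(
    center_x = center[1], center_y = center[2], center_z = center[3],
    min_x = bmin[1], min_y = bmin[2], min_z = bmin[3],
    max_x = bmax[1], max_y = bmax[2], max_z = bmax[3],
    score = score, provenance = provenance
  )
}

#' Binding site from the co-crystallised ligand
#'
#' Centre is the ligand heavy-atom centroid; the bounding box is the
#' ligand's axis-aligned heavy-atom extent.
#'
#' @param receptor An `ivs_receptor` whose `ligand` is present.
#' @return One-row site tibble (`center_*`, `min_*`, `max_*`, `score`,
#'   `provenance = "ligand_derived"`).
#' @export
site_from_ligand <- function(receptor) {
  stopifnot(inherits(receptor, "ivs_receptor"))
  lig <- receptor$ligand
  if (is.null(lig) || nrow(lig) == 0) {
    abort(paste0(receptor$pdb_id, ": no co-crystallised ligand present"),
          class = "ivs_no_ligand_error")
  }
  heavy <- lig[is.na(lig$elesy) | lig$elesy != "H", ]
  if (nrow(heavy) < 3) {
    abort(paste0(receptor$pdb_id, ": retained hetero group has fewer than ",
                 "3 heavy atoms; not a usable ligand"),
          class = "ivs_degenerate_ligand")
  }
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  .site_tibble(colMeans(xyz), apply(xyz, 2, min), apply(xyz, 2, max),
               score = nrow(heavy), provenance = "ligand_derived")
}

#' Detect binding pockets by a grid buriedness scan
#'
#' Scans a regular grid over the protein bounding box. A grid point is
#' buried when (a) it lies at least `clearance` A from every protein atom
#' and (b) protein atoms occlude at least `min_occluded` of 7 scan
#' directions (+/-x, +/-y, +/-z and the (1,1,1) diagonal) within
#' `probe_max` A — a strict majority of directions by default, so points
#' outside a convex surface, where up to four directions can graze the
#' protein, are never buried. Buried points are clustered by 26-connectivity; each
#' cluster is a candidate pocket scored by its point count. Up to
#' `max_sites` clusters with at least `min_points` points are returned,
#' ranked by score. Fully deterministic; the grid is anchored at the
#' protein bounding box, so results translate rigidly with the receptor.
#'
#' @param receptor An `ivs_receptor`.
#' @param spacing Grid spacing in A.
#' @param probe_max Occlusion search length per direction, A.
#' @param min_occluded Minimum occluded directions (of 7) for burial.
#' @param clearance Minimum distance to any protein atom, A.
#' @param occlusion_radius Perpendicular capture radius of an occluding
#'   atom along a scan ray, A.
#' @param min_points Pocket reporting threshold (cluster size).
#' @param max_sites Maximum number of pockets returned.
#' @return Site tibble with up to `max_sites` rows ranked by descending
#'   score (`provenance = "detected"`); zero rows when no pocket reaches
#'   the threshold.
#' @export
detect_binding_sites <- function(receptor, spacing = 1.0, probe_max = 8.0,
                                 min_occluded = 5L, clearance = 2.0,
                                 occlusion_radius = 1.5,
                                 min_points = 10L, max_sites = 5L) {
  stopifnot(inherits(receptor, "ivs_receptor"), spacing > 0)
  A <- .receptor_coords(receptor)
  if (nrow(A) == 0) {
    abort(paste0(receptor$pdb_id, ": no protein atoms"),
          class = "ivs_degenerate_structure")
  }
  lo <- apply(A, 2, min)
  hi <- apply(A, 2, max)
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid_idx <- as.matrix(expand.grid(ix = seq_along(gx), iy = seq_along(gy),
                                    iz = seq_along(gz)))
  G <- cbind(gx[grid_idx[, 1]], gy[grid_idx[, 2]], gz[grid_idx[, 3]])

  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1), c(1, 1, 1) / sqrt(3))
  # tiny tolerance so boundary-exact distances (common when atoms sit on
  # a lattice commensurate with the grid) classify identically after a
  # rigid translation despite floating-point noise
  eps <- 1e-6
  occl_r2 <- occlusion_radius^2 + eps
  clear2 <- clearance^2 - eps
  reach2 <- (probe_max + occlusion_radius)^2 + eps

  buried <- logical(nrow(G))
  chunk <- 4000L
  starts <- seq(1L, nrow(G), by = chunk)
  Ad <- A %*% t(dirs)                      # atom projections per direction
  for (s in starts) {
    e <- min(s + chunk - 1L, nrow(G))
    Gc <- G[s:e, , drop = FALSE]
    D2 <- outer(rowSums(Gc^2), rowSums(A^2), "+") - 2 * (Gc %*% t(A))
    near <- D2 <= reach2
    clear_ok <- .rowMins(D2) >= clear2
    n_occ <- integer(nrow(Gc))
    Gd <- Gc %*% t(dirs)
    for (d in seq_len(nrow(dirs))) {
      # t = projection of (atom - point) on direction d; perp^2 = |v|^2 - t^2
      Tm <- matrix(Ad[, d], nrow(Gc), nrow(A), byrow = TRUE) - Gd[, d]
      occ <- near & Tm > eps & Tm <= probe_max + eps & (D2 - Tm^2) <= occl_r2
      n_occ <- n_occ + as.integer(.rowAnys(occ))
    }
    buried[s:e] <- clear_ok & n_occ >= min_occluded
  }
  if (!any(buried)) return(.site_tibble(NA, NA, NA, NA, "detected")[0, ])

  idx <- grid_idx[buried, , drop = FALSE]
  pts <- G[buried, , drop = FALSE]
  comp <- .cluster26(idx)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_points)
  if (length(keep) == 0) return(.site_tibble(NA, NA, NA, NA, "detected")[0, ])
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- head(keep, max_sites)
  bind_rows(lapply(keep, function(k) {
    p <- pts[comp == k, , drop = FALSE]
    .site_tibble(colMeans(p), apply(p, 2, min), apply(p, 2, max),
                 score = nrow(p), provenance = "detected")
  }))
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))
.rowAnys <- function(m) rowSums(m) > 0

# connected components of integer lattice points under 26-connectivity
.cluster26 <- function(idx) {
  M <- max(idx) + 2L
  key <- idx[, 1] + M * (idx[, 2] + M * idx[, 3])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[seq_len(nrow(offs) / 2), , drop = FALSE]  # half-shell
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nk <- (idx[, 1] + offs[r, 1]) + M * ((idx[, 2] + offs[r, 2]) +
                                           M * (idx[, 3] + offs[r, 3]))
    j <- match(nk, key)
    hit <- !is.na(j)
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(which(hit), j[hit])
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  igraph::components(g)$membership
}

#' Define the binding site of a receptor
#'
#' Dispatch rule: when a co-crystallised ligand was retained its
#' coordinates map the cavity ([site_from_ligand()]); otherwise the
#' highest-scoring detected pocket is used ([detect_binding_sites()]).
#'
#' @param receptor An `ivs_receptor`.
#' @param ... Passed to [detect_binding_sites()] when detection is needed.
#' @return One-row site tibble.
#' @export
binding_site <- function(receptor, ...) {
  if (!is.null(receptor$ligand) && nrow(receptor$ligand) > 0) {
    return(site_from_ligand(receptor))
  }
  sites <- detect_binding_sites(receptor, ...)
  if (nrow(sites) == 0) {
    abort(paste0(receptor$pdb_id, ": no binding pocket found"),
          class = "ivs_no_site_error")
  }
  sites[1, ]
}

#' Build the docking box around a binding site
#'
#' Per-axis box size is the site extent plus twice the buffer; the centre
#' is the site bounding-box centre. The grid spacing is engine metadata
#' (Vina-style engines take centre/size only) and is recorded verbatim.
#'
#' @param site One-row site tibble (from [binding_site()] or friends).
#' @param buffer Distance buffer per direction in A (default 10).
#' @param spacing Grid spacing in A, recorded as metadata (default 1.0).
#' @return One-row tibble: `center_x/y/z`, `size_x/y/z`, `buffer`,
#'   `spacing`.
#' @export
#' @examples
#' site <- tibble::tibble(
#'   center_x = 5, center_y = 5, center_z = 5,
#'   min_x = 0, min_y = 0, min_z = 0, max_x = 10, max_y = 10, max_z = 10,
#'   score = 1, provenance = "ligand_derived"
#' )
#' build_box(site)  # size 30 x 30 x 30
build_box <- function(site, buffer = 10, spacing = 1.0) {
  stopifnot(is.data.frame(site), nrow(site) == 1)
  if (!is.numeric(buffer) || buffer <= 0) {
    abort("docking-box buffer must be a positive distance in Angstrom",
          class = "ivs_parameter_error")
  }
  bmin <- c(site$min_x, site$min_y, site$min_z)
  bmax <- c(site$max_x, site$max_y, site$max_z)
  size <- (bmax - bmin) + 2 * buffer
  ctr <- (bmax + bmin) / 2
  tibble(
    center_x = ctr[1], center_y = ctr[2], center_z = ctr[3],
    size_x = size[1], size_y = size[2], size_z = size[3],
    buffer = buffer, spacing = spacing
  )
}
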