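#' Local radius map from the thickness segmentation
#'
#' Anisotropy-aware Euclidean distance transform of the binary thickness
#' volume: each foreground voxel holds the distance in mm to the nearest
#' background voxel centre; background voxels hold 0. Sampled at skeleton
#' points this gives the local branch radius.
#'
#' @param b binary [volume] (the thickness-measurement segmentation).
#' @return A grayscale [volume] of radii in mm.
#' @export
radius_map <- function(b) {
  stopifnot_volume(b, binary = TRUE)
  d <- dim(b$data)
  r <- edt_cpp(as.logical(b$data), d, b$spacing)
  r[!is.finite(r)] <- max(d * b$spacing[1:3])   # all-foreground volume
  out <- array(r, dim = d)
  structure(list(data = out, spacing = b$spacing), class = "volume")
}

#' A branch: ordered polyline with per-point diameters
#'
#' @param id integer id.
#' @param pts n x 3 mm coordinate matrix.
#' @param diameters per-point diameters, mm (optional until assigned).
#' @param provenance fragment ids this branch was reassembled from.
#' @return A `nest_branch` list with arc `length` (staircase-corrected) and
#'   `median_thickness`.
#' @export
nest_branch <- function(id, pts, diameters = NULL, provenance = integer(0)) {
  if (!is.matrix(pts) || ncol(pts) != 3 || nrow(pts) < 2)
    stop("branch needs an n x 3 coordinate matrix with n >= 2 points")
  structure(list(id = id, pts = pts, diameters = diameters,
                 provenance = provenance,
                 length = polyline_length_smooth(pts),
                 median_thickness = if (is.null(diameters)) NA_real_
                                    else median(diameters)),
            class = "nest_branch")
}

#' Convert reconnected edges to branches
#'
#' @param edges an [edge_set] (after linking and short-edge removal).
#' @return List of [nest_branch] objects, ids renumbered 1..n.
#' @export
edges_to_branches <- function(edges) {
  out <- vector("list", length(edges$edges))
  for (i in seq_along(edges$edges)) {
    e <- edges$edges[[i]]
    out[[i]] <- nest_branch(i, e$pts, provenance = e$provenance)
  }
  out
}

#' Assign per-point thickness to a branch
#'
#' Nearest-voxel lookup of twice the radius map at every polyline point
#' (voxel-level superposition of skeleton and thickness segmentation; no
#' trilinear interpolation). Points falling on background, or outside the
#' volume, get diameter 0 (out-of-bounds points additionally warn).
#'
#' @param branch a [nest_branch].
#' @param rmap radius [volume] from [radius_map()].
#' @return The branch with `diameters` and `median_thickness` filled.
#' @export
assign_thickness <- function(branch, rmap) {
  dims <- dim(rmap$data)
  sp <- rmap$spacing
  upper <- c((dims[3] - 1) * sp[3], (dims[2] - 1) * sp[2], (dims[1] - 1) * sp[1])
  oob <- branch$pts[, 1] < -sp[3] / 2 | branch$pts[, 1] > upper[1] + sp[3] / 2 |
         branch$pts[, 2] < -sp[2] / 2 | branch$pts[, 2] > upper[2] + sp[2] / 2 |
         branch$pts[, 3] < -sp[1] / 2 | branch$pts[, 3] > upper[3] + sp[1] / 2
  if (any(oob))
    warning(sprintf("branch %d: %d points outside the volume get diameter 0",
                    branch$id, sum(oob)))
  kji <- mm_to_voxel(branch$pts, sp, dims)
  dia <- 2 * rmap$data[cbind(kji[, 1], kji[, 2], kji[, 3])]
  dia[oob] <- 0
  branch$diameters <- dia
  branch$median_thickness <- median(dia)
  branch
}

#' Remove branches dominated by zero-thickness points
#'
#' Branches whose fraction of zero-diameter points strictly exceeds
#' `max_zero_frac` are removed (thin branches can vanish from the thickness
#' segmentation; their diameters are unrecoverable). Exactly at the
#' boundary the branch is kept. The removal count is recorded in the
#' `removed_zero` attribute.
#'
#' @param branches list of [nest_branch] with diameters assigned.
#' @param max_zero_frac maximum tolerated zero fraction (default 0.10).
#' @return The filtered branch list.
#' @export
clean_zero_thickness <- function(branches, max_zero_frac = 0.10) {
  zf <- vapply(branches, function(b) mean(b$diameters == 0), numeric(1))
  out <- branches[zf <= max_zero_frac]
  attr(out, "removed_zero") <- sum(zf > max_zero_frac)
  out
}

#' Interpolate zero-thickness points along a branch
#'
#' Iterative nearest-neighbour propagation along the polyline: in each pass
#' every zero-diameter point adjacent to a positive one takes that value
#' (the mean of the two sides if both are positive), until no zeros remain.
#' Positive diameters are never modified.
#'
#' @param branch a [nest_branch] with diameters assigned, not all zero.
#' @return The branch with strictly positive diameters.
#' @export
interpolate_zero <- function(branch) {
  d <- branch$diameters
  if (all(d == 0)) stop("cannot interpolate an all-zero branch")
  n <- length(d)
  while (any(d == 0)) {
    left <- c(0, d[-n])
    right <- c(d[-1], 0)
    fill <- d == 0 & (left > 0 | right > 0)
    val <- ifelse(left > 0 & right > 0, (left + right) / 2,
                  pmax(left, right))
    d[fill] <- val[fill]
  }
  branch$diameters <- d
  branch$median_thickness <- median(d)
  branch
}

#' Detect contact points between branches
#'
#' For every cross-branch pair of skeleton sample points the surface gap is
#' the centre distance minus the two local radii; point pairs with gap at
#' most `tol_mm` qualify (negative gaps mean interpenetration of the voxel
#' data and are allowed). Runs of qualifying point pairs lying within
#' `merge_arc_mm` of arc length of each other on both branches collapse
#' into one contact, reported at the minimal-gap pair with its location at
#' the midpoint between the two skeleton points.
#'
#' @param branches list of [nest_branch] with diameters assigned.
#' @param tol_mm contact tolerance in mm (default 0.5, one in-plane voxel).
#' @param merge_arc_mm merge radius along the branches (default 2).
#' @return data.frame `branch_a, branch_b, x, y, z, gap` with one row per
#'   touching region, ordered by branch pair.
#' @export
detect_contacts <- function(branches, tol_mm = 0.5, merge_arc_mm = 2) {
  empty <- data.frame(branch_a = integer(0), branch_b = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      gap = numeric(0))
  if (length(branches) < 2) return(empty)
  pts <- do.call(rbind, lapply(branches, `[[`, "pts"))
  rad <- unlist(lapply(branches, function(b) b$diameters / 2))
  ids <- rep(vapply(branches, `[[`, 0L, "id"),
             vapply(branches, function(b) nrow(b$pts), 0L))
  arc <- unlist(lapply(branches, function(b) {
    seg <- sqrt(rowSums((b$pts[-1, , drop = FALSE] -
                         b$pts[-nrow(b$pts), , drop = FALSE])^2))
    c(0, cumsum(seg))
  }))
  cand <- contact_candidates_cpp(pts, rad, ids, tol_mm)
  if (nrow(cand) == 0) return(empty)
  gap <- cand$dist - rad[cand$ia] - rad[cand$ib]
  ok <- gap <= tol_mm
  if (!any(ok)) return(empty)
  cand <- cand[ok, , drop = FALSE]
  gap <- gap[ok]
  a <- pmin(ids[cand$ia], ids[cand$ib])
  b <- pmax(ids[cand$ia], ids[cand$ib])
  arc_a <- ifelse(ids[cand$ia] <= ids[cand$ib], arc[cand$ia], arc[cand$ib])
  arc_b <- ifelse(ids[cand$ia] <= ids[cand$ib], arc[cand$ib], arc[cand$ia])
  out <- list()
  for (key in unique(paste(a, b))) {
    sel <- which(paste(a, b) == key)
    sel <- sel[order(arc_a[sel], arc_b[sel])]
    # single-linkage clustering of qualifying pairs along both arcs
    cluster <- integer(length(sel))
    cid <- 0L
    for (t in seq_along(sel)) {
      assigned <- FALSE
      if (t > 1) {
        prev <- sel[seq_len(t - 1)]
        near <- abs(arc_a[prev] - arc_a[sel[t]]) <= merge_arc_mm &
                abs(arc_b[prev] - arc_b[sel[t]]) <= merge_arc_mm
        if (any(near)) {
          cluster[t] <- cluster[which(near)[1]]
          assigned <- TRUE
        }
      }
      if (!assigned) { cid <- cid + 1L; cluster[t] <- cid }
    }
    for (cl in unique(cluster)) {
      grp <- sel[cluster == cl]
      bestpos <- grp[which.min(gap[grp])]
      mid <- (pts[cand$ia[bestpos], ] + pts[cand$ib[bestpos], ]) / 2
      out[[length(out) + 1L]] <- data.frame(
        branch_a = a[bestpos], branch_b = b[bestpos],
        x = mid[1], y = mid[2], z = mid[3], gap = gap[bestpos])
    }
  }
  res <- do.call(rbind, out)
  res[order(res$branch_a, res$branch_b, res$z, res$y, res$x), , drop = FALSE]
}

#' Horizontal angle of a branch
#'
#' Elevation, in degrees within `[0, 90]`, of the branch's end-to-end vector
#' from the plane perpendicular to gravity.
#'
#' @param branch a [nest_branch].
#' @param gravity unit gravity vector (default `c(0, 0, -1)`).
#' @return Angle in degrees.
#' @export
horizontal_angle <- function(branch, gravity = c(0, 0, -1)) {
  u <- branch$pts[nrow(branch$pts), ] - branch$pts[1, ]
  nu <- vec_norm(u)
  if (nu == 0) return(0)
  g <- gravity / vec_norm(gravity)
  asin(min(abs(sum(u * g)) / nu, 1)) * 180 / pi
}

#' Morphometric summary of a digitized nest
#'
#' Builds the per-branch table (length, median thickness, connectivity =
#' number of contact regions, normalized connectivity = contacts per mm of
#' branch length, horizontal angle) and global statistics: means with
#' standard deviations and the fraction of branches steeper than 45 degrees.
#'
#' @param branches list of [nest_branch].
#' @param contacts contact data.frame from [detect_contacts()].
#' @param gravity unit gravity vector (default `c(0, 0, -1)`).
#' @param scaffold_ids branch ids flagged as scaffold (default none).
#' @return A `nest_summary`: list with `branch_table` (a valid branch table,
#'   see [validate_branch_table()], plus `normalized_connectivity`) and
#'   `global` statistics.
#' @export
summarize_nest <- function(branches, contacts, gravity = c(0, 0, -1),
                           scaffold_ids = integer(0)) {
  if (length(branches) == 0) stop("no branches to summarize")
  ids <- vapply(branches, `[[`, 0L, "id")
  ncont <- vapply(ids, function(i)
    sum(contacts$branch_a == i) + sum(contacts$branch_b == i), 0L)
  tab <- data.frame(
    branch_id = ids,
    length_mm = vapply(branches, `[[`, 0, "length"),
    median_thickness_mm = vapply(branches, function(b)
      ifelse(is.na(b$median_thickness), 0, b$median_thickness), 0),
    n_points = vapply(branches, function(b) nrow(b$pts), 0L),
    n_contacts = ncont,
    horizontal_angle_deg = vapply(branches, horizontal_angle, 0,
                                  gravity = gravity),
    scaffold_flag = ids %in% scaffold_ids)
  tab$normalized_connectivity <- tab$n_contacts / tab$length_mm
  glob <- list(
    n_branches = nrow(tab),
    n_contacts = nrow(contacts),
    mean_length_mm = mean(tab$length_mm),
    sd_length_mm = sd(tab$length_mm),
    mean_thickness_mm = mean(tab$median_thickness_mm),
    sd_thickness_mm = sd(tab$median_thickness_mm),
    mean_connectivity = mean(tab$n_contacts),
    sd_connectivity = sd(tab$n_contacts),
    frac_angle_gt_45 = mean(tab$horizontal_angle_deg > 45))
  structure(list(branch_table = tab, global = glob), class = "nest_summary")
}

#' @export
print.nest_summary <- function(x, ...) {
  g <- x$global
  cat(sprintf(
    paste0("<nest_summary> %d branches, %d contacts\n",
           "  length    %.1f +/- %.1f mm\n",
           "  thickness %.2f +/- %.2f mm\n",
           "  contacts  %.1f +/- %.1f per branch\n",
           "  %.0f%% of branches steeper than 45 degrees\n"),
    g$n_branches, g$n_contacts, g$mean_length_mm, g$sd_length_mm,
    g$mean_thickness_mm, g$sd_thickness_mm, g$mean_connectivity,
    g$sd_connectivity, 100 * g$frac_angle_gt_45))
  invisible(x)
}

#' Histograms of branch length, thickness and connectivity
#'
#' Writes a four-panel PNG mirroring the standard morphometric panels:
#' branch length, median thickness, connectivity, and normalized
#' connectivity distributions.
#'
#' @param summary a `nest_summary`.
#' @param path output PNG path.
#' @export
plot_summary <- function(summary, path) {
  tab <- summary$branch_table
  grDevices::png(path, width = 900, height = 700)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::hist(tab$length_mm, main = "Branch length", xlab = "mm",
                 col = "grey80", border = "white")
  graphics::hist(tab$median_thickness_mm, main = "Branch thickness",
                 xlab = "mm", col = "grey80", border = "white")
  graphics::hist(tab$n_contacts, main = "Connectivity",
                 xlab = "contacts per branch", col = "grey80", border = "white")
  graphics::hist(tab$normalized_connectivity, main = "Normalized connectivity",
                 xlab = "contacts per mm", col = "grey80", border = "white")
  invisible(path)
}
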