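#' Specification of a synthetic nest phantom
#'
#' Defines the study conditions the generator emulates: a tangle of
#' interlocked curved twigs at the scale of a sparrow nest, reduced in
#' extent so a desk run finishes in minutes. Branch diameters span the
#' range observed in real nests (1.2-8.8 mm): ordinary branches follow a
#' lognormal centred on 2.3 mm, while a couple of scaffold branches (the
#' anchors that would originate from the host tree) are markedly thicker.
#' Two thirds of the ordinary branches are steeper than 45 degrees,
#' mirroring the predominantly upright insertion observed in domed nests.
#' Foreground/background intensities emulate the modest soft-tissue-to-air
#' contrast of an 8-bit nest CT for which the default segmentation cutoffs
#' (28 and 24) are the calibrated optima.
#'
#' @param n_branches total number of branches including the scaffold.
#' @param box domain box (x, y, z) in mm.
#' @param length_mean,length_sd branch length distribution, mm.
#' @param arc_deg_range arc angle range in degrees; 36 degrees keeps the
#'   radius of curvature above 5/pi times the branch length, so the medial
#'   axis assumption of thinning holds.
#' @param diam_meanlog,diam_sdlog lognormal parameters of ordinary branch
#'   diameters (mm scale).
#' @param diam_range admissible diameter range, mm (values are clamped).
#' @param n_scaffold number of scaffold branches.
#' @param scaffold_diam_range scaffold diameter range, mm.
#' @param frac_steep fraction of ordinary branches with elevation > 45 deg.
#' @param p_connector probability that an ordinary branch is placed as a
#'   straight connector grazing two existing branches (raises network
#'   connectivity and closes loops, as interlocking does in real nests).
#' @param contact_overlap_mm surface interpenetration at built contacts, mm
#'   (touching branches merge slightly in a real segmentation).
#' @param min_angle_deg minimum crossing angle at a contact; near-parallel
#'   overlaps are rejected because neither a real scan nor the pipeline can
#'   separate them.
#' @param min_contact_sep_mm minimum arc separation between built
#'   attachment points along any one branch. Interlocked twigs cross at
#'   spread locations; junction zones packed closer than the junction-trim
#'   scale would leave only fragments no reconstruction can recover, which
#'   is outside the method's stated operating envelope.
#' @param tip_clearance_mm contact zones must stay this far from every
#'   branch tip. A tip-to-tip abutment is indistinguishable from a
#'   continuation by any endpoint-matching score (a documented limitation),
#'   and twigs in an interlocked nest bear on each other mid-shaft.
#' @param spacing voxel spacing (dz, dy, dx), mm.
#' @param fg,bg foreground/background intensities (8-bit).
#' @param noise_sd additive Gaussian noise sd (grayscale units).
#' @param min_contacts required number of true surface contacts (NULL =
#'   whatever the construction produces, at least n_branches - 1 built-in
#'   attachments).
#' @param seed RNG seed; every generator run is deterministic given it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_branches = 30, box = c(100, 100, 100),
                         length_mean = 60, length_sd = 10,
                         arc_deg_range = c(5, 36),
                         diam_meanlog = log(2.3), diam_sdlog = 0.15,
                         diam_range = c(1.2, 8.8),
                         n_scaffold = 2, scaffold_diam_range = c(6, 8.8),
                         frac_steep = 0.66, p_connector = 0.5,
                         contact_overlap_mm = 0.3, min_angle_deg = 25,
                         min_contact_sep_mm = 12, tip_clearance_mm = 8,
                         spacing = c(0.1, 0.5, 0.5),
                         fg = 37, bg = 19, noise_sd = 5,
                         min_contacts = NULL, seed = 1L) {
  p <- as.list(environment())
  if (p$n_branches < 1) stop("need at least one branch")
  if (any(p$box <= 0) || any(p$spacing <= 0)) stop("box and spacing must be positive")
  if (p$fg < 0 || p$fg > 255 || p$bg < 0 || p$bg > 255)
    stop("intensities must lie in [0, 255]")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  p$n_scaffold <- min(p$n_scaffold, p$n_branches)
  structure(p, class = "phantom_spec")
}

random_unit_perp <- function(u) {
  repeat {
    r <- rnorm(3)
    w <- r - sum(r * u) * u
    nw <- vec_norm(w)
    if (nw > 1e-6) return(w / nw)
  }
}

direction_from_angles <- function(elev_deg, azim_deg) {
  e <- elev_deg * pi / 180
  a <- azim_deg * pi / 180
  c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
}

# circular-arc polyline of length L, arc angle phi (radians), sampled every
# step_mm; tangent at arc position s0 equals u; point at s0 sits at origin
arc_polyline <- function(L, phi, u, curve_dir, s0, step_mm = 1) {
  s <- unique(c(seq(0, L, by = step_mm), L))
  if (phi < 1e-6) {
    pts <- outer(s - s0, u)
  } else {
    R <- L / phi
    pts <- outer(R * sin((s - s0) / R), u) +
           outer(R * (1 - cos((s - s0) / R)), curve_dir)
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

inside_box <- function(pts, box, margin) {
  all(pts[, 1] >= margin & pts[, 1] <= box[1] - margin &
      pts[, 2] >= margin & pts[, 2] <= box[2] - margin &
      pts[, 3] >= margin & pts[, 3] <= box[3] - margin)
}

cross_distance_matrix <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# distances from each point of A to the nearest point of B
min_cross_distances <- function(A, B) {
  apply(cross_distance_matrix(A, B), 1, min)
}

placement_ok <- function(pts, r_new, branches, allow_overlap, max_graze_mm,
                         tip_clear = 0) {
  for (b in branches) {
    dm <- cross_distance_matrix(pts, b$pts)
    dmin <- apply(dm, 1, min)
    lim <- r_new + b$diameter / 2
    if (any(dmin < lim - allow_overlap)) return(FALSE)   # deep interpenetration
    graze <- dmin <= lim + 0.3
    if (sum(graze) > 1 && diff(range(which(graze))) > max_graze_mm)
      return(FALSE)                                      # long parallel overlap
    if (tip_clear > 0 && any(graze)) {
      # contact zones must not touch either branch's tips (1 mm sampling)
      gi <- which(graze)
      if (min(gi) <= tip_clear || max(gi) > nrow(pts) - tip_clear)
        return(FALSE)
      gj <- which(apply(dm[gi, , drop = FALSE] <= lim + 0.3, 2, any))
      if (min(gj) <= tip_clear || max(gj) > nrow(b$pts) - tip_clear)
        return(FALSE)
    }
  }
  TRUE
}

#' Generate a ground-truth synthetic nest
#'
#' Places `n_branches` smooth twigs (gentle circular arcs and straight
#' connectors) in the domain box: the scaffold first, spanning the box
#' interior at shallow elevations, then ordinary branches each attached to
#' the existing structure with a controlled surface overlap, so the
#' structure is connected by construction. All ground truth (polylines at
#' 1 mm sampling, constant per-branch diameters, scaffold ids, true surface
#' contacts) is recorded. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return A `ground_truth_nest`: list with `branches` (list of
#'   `id, pts, diameter`), `scaffold_ids`, `contacts` (data.frame
#'   `branch_a, branch_b, x, y, z, gap`), and the originating `spec`.
#' @export
make_nest <- function(spec) {
  set.seed(spec$seed)
  box <- spec$box
  branches <- list()
  draw_diam <- function(scaffold) {
    if (scaffold) runif(1, spec$scaffold_diam_range[1], spec$scaffold_diam_range[2])
    else min(max(exp(rnorm(1, spec$diam_meanlog, spec$diam_sdlog)),
                 spec$diam_range[1]), spec$diam_range[2])
  }
  draw_elev <- function(scaffold) {
    if (scaffold) runif(1, 0, 25)
    else if (runif(1) < spec$frac_steep) runif(1, 46, 85) else runif(1, 5, 44)
  }
  tangent_at <- function(pts, i) {
    i2 <- min(i + 1, nrow(pts)); i1 <- max(i - 1, 1)
    u <- pts[i2, ] - pts[i1, ]
    u / vec_norm(u)
  }
  att_arcs <- list()   # arc positions (mm ~ index) of attachments per branch
  sep_ok <- function(branch_idx, arc_pos) {
    length(att_arcs) < branch_idx || is.null(att_arcs[[branch_idx]]) ||
      all(abs(att_arcs[[branch_idx]] - arc_pos) >= spec$min_contact_sep_mm)
  }
  note_att <- function(branch_idx, arc_pos) {
    if (length(att_arcs) < branch_idx) att_arcs[[branch_idx]] <<- numeric(0)
    if (is.null(att_arcs[[branch_idx]])) att_arcs[[branch_idx]] <<- numeric(0)
    att_arcs[[branch_idx]] <<- c(att_arcs[[branch_idx]], arc_pos)
  }

  for (bi in seq_len(spec$n_branches)) {
    scaffold <- bi <= spec$n_scaffold
    placed <- FALSE
    for (attempt in seq_len(800)) {
      # progressive relaxation so a crowded but feasible box still fills:
      # first drop the attachment-spacing constraint, then tip clearance
      # and the graze cap, finally admit shorter twigs
      relax_sep <- attempt > 400
      relax_tip <- attempt > 550
      tip_clear <- if (relax_tip) 0 else spec$tip_clearance_mm
      graze_cap <- if (relax_tip) 25 else 12
      diam <- draw_diam(scaffold)
      r <- diam / 2
      L <- max(rnorm(1, spec$length_mean, spec$length_sd), 15)
      if (attempt > 700) L <- L * 0.7
      if (scaffold) L <- min(L * 1.3, 0.8 * min(box))
      connector <- !scaffold && bi > 2 && runif(1) < spec$p_connector
      phi <- runif(1, spec$arc_deg_range[1], spec$arc_deg_range[2]) * pi / 180

      if (bi == 1) {
        u <- direction_from_angles(draw_elev(TRUE), runif(1, 0, 360))
        center <- box / 2 + runif(3, -8, 8)
        pts <- sweep(arc_polyline(L, phi, u, random_unit_perp(u), L / 2), 2,
                     center, `+`)
        others <- branches
      } else if (connector) {
        ia <- sample(length(branches), 1)
        ib <- sample(setdiff(seq_along(branches), ia), 1)
        A <- branches[[ia]]; B <- branches[[ib]]
        pa_i <- sample(nrow(A$pts), 1); pb_i <- sample(nrow(B$pts), 1)
        if (!relax_sep && (!sep_ok(ia, pa_i) || !sep_ok(ib, pb_i))) next
        pa <- A$pts[pa_i, ]; pb <- B$pts[pb_i, ]
        d0 <- vec_norm(pb - pa)
        if (d0 < 0.3 * L || d0 > 0.85 * L) next
        u <- (pb - pa) / d0
        angA <- min(angle_deg(u, tangent_at(A$pts, pa_i)),
                    180 - angle_deg(u, tangent_at(A$pts, pa_i)))
        angB <- min(angle_deg(u, tangent_at(B$pts, pb_i)),
                    180 - angle_deg(u, tangent_at(B$pts, pb_i)))
        if (angA < spec$min_angle_deg || angB < spec$min_angle_deg) next
        dA <- A$diameter / 2 + r - spec$contact_overlap_mm
        dB <- B$diameter / 2 + r - spec$contact_overlap_mm
        if (abs(dA - dB) > 0.5) next
        o <- random_unit_perp(u) * dA
        start <- pa + o - u * (L - d0) / 2
        s <- unique(c(seq(0, L, by = 1), L))
        pts <- sweep(outer(s, u), 2, start, `+`)
        colnames(pts) <- c("x", "y", "z")
        others <- branches[-c(ia, ib)]
        # the grazed partners still must not be deeply penetrated
        if (!placement_ok(pts, r, branches[c(ia, ib)],
                          allow_overlap = spec$contact_overlap_mm + 0.4,
                          max_graze_mm = graze_cap,
                          tip_clear = tip_clear)) next
      } else {
        ia <- sample(length(branches), 1)
        A <- branches[[ia]]
        rng <- seq(ceiling(nrow(A$pts) * 0.1), floor(nrow(A$pts) * 0.9))
        pa_i <- rng[sample.int(length(rng), 1)]
        if (!relax_sep && !sep_ok(ia, pa_i)) next
        pa <- A$pts[pa_i, ]
        u <- direction_from_angles(draw_elev(scaffold), runif(1, 0, 360))
        angA <- min(angle_deg(u, tangent_at(A$pts, pa_i)),
                    180 - angle_deg(u, tangent_at(A$pts, pa_i)))
        if (angA < spec$min_angle_deg) next
        dA <- A$diameter / 2 + r - spec$contact_overlap_mm
        o <- random_unit_perp(u) * dA
        s0 <- runif(1, 0.2, 0.8) * L
        pts <- sweep(arc_polyline(L, phi, u, random_unit_perp(u), s0), 2,
                     pa + o, `+`)
        others <- branches[-ia]
        if (!placement_ok(pts, r, branches[ia],
                          allow_overlap = spec$contact_overlap_mm + 0.4,
                          max_graze_mm = graze_cap,
                          tip_clear = tip_clear)) next
      }
      if (!inside_box(pts, box, margin = r + 1)) next
      if (length(others) &&
          !placement_ok(pts, r, others, allow_overlap = 0.4,
                        max_graze_mm = graze_cap,
                        tip_clear = tip_clear)) next
      branches[[bi]] <- list(id = bi, pts = pts, diameter = diam)
      if (bi > 1) {
        if (connector) {
          note_att(ia, pa_i); note_att(ib, pb_i)
          note_att(bi, (L - d0) / 2); note_att(bi, (L - d0) / 2 + d0)
        } else {
          note_att(ia, pa_i); note_att(bi, s0)
        }
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place branch %d in the box after 800 attempts; the spec is infeasible", bi))
  }

  contacts <- true_contacts(branches)
  if (!is.null(spec$min_contacts) && nrow(contacts) < spec$min_contacts)
    stop(sprintf("phantom produced %d contacts, fewer than the requested %d",
                 nrow(contacts), spec$min_contacts))
  structure(list(branches = branches,
                 scaffold_ids = seq_len(spec$n_scaffold),
                 contacts = contacts, spec = spec),
            class = "ground_truth_nest")
}

# brute-force true contact regions: cross-branch point pairs with surface
# gap <= 0 (touching in the continuous geometry), clustered along both arcs
true_contacts <- function(branches, gap_tol = 0, merge_arc_mm = 4) {
  out <- list()
  nb <- length(branches)
  if (nb < 2) return(data.frame(branch_a = integer(0), branch_b = integer(0),
                                x = numeric(0), y = numeric(0), z = numeric(0),
                                gap = numeric(0)))
  for (a in seq_len(nb - 1)) {
    for (b in (a + 1):nb) {
      A <- branches[[a]]; B <- branches[[b]]
      lim <- A$diameter / 2 + B$diameter / 2
      d2 <- outer(rowSums(A$pts^2), rep(1, nrow(B$pts))) +
            outer(rep(1, nrow(A$pts)), rowSums(B$pts^2)) -
            2 * A$pts %*% t(B$pts)
      d <- sqrt(pmax(d2, 0))
      hit <- which(d <= lim + gap_tol, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      # single-linkage clustering of touching point pairs along both arcs
      # (1 mm sampling: index differences approximate arc mm)
      o <- order(hit[, 1], hit[, 2])
      hit <- hit[o, , drop = FALSE]
      grp <- integer(nrow(hit))
      cid <- 0L
      for (t in seq_len(nrow(hit))) {
        near <- if (t > 1)
          which(abs(hit[seq_len(t - 1), 1] - hit[t, 1]) <= merge_arc_mm &
                abs(hit[seq_len(t - 1), 2] - hit[t, 2]) <= merge_arc_mm)
        else integer(0)
        if (length(near)) grp[t] <- grp[near[1]]
        else { cid <- cid + 1L; grp[t] <- cid }
      }
      for (g in unique(grp)) {
        rows <- hit[grp == g, , drop = FALSE]
        gaps <- d[rows] - lim
        best <- which.min(gaps)
        pa <- A$pts[rows[best, 1], ]; pb <- B$pts[rows[best, 2], ]
        mid <- (pa + pb) / 2
        out[[length(out) + 1L]] <- data.frame(
          branch_a = A$id, branch_b = B$id,
          x = mid[1], y = mid[2], z = mid[3], gap = gaps[best])
      }
    }
  }
  if (!length(out)) return(data.frame(branch_a = integer(0), branch_b = integer(0),
                                      x = numeric(0), y = numeric(0), z = numeric(0),
                                      gap = numeric(0)))
  do.call(rbind, out)
}

#' Voxelize a ground-truth nest into a grayscale stack
#'
#' Renders every branch as a tube of its diameter (a voxel is foreground
#' iff its centre lies within the radius of the polyline), assigns
#' foreground/background intensities, and adds optional Gaussian noise with
#' a recorded seed. The volume dimensions derive from the spec's box and
#' spacing.
#'
#' @param nest a `ground_truth_nest`.
#' @param spacing voxel spacing (dz, dy, dx), mm; defaults to the spec's.
#' @param fg,bg foreground/background intensities; defaults from the spec
#'   when called on a spec-built nest, else 200/10.
#' @param noise_sd Gaussian noise sd; default from the spec.
#' @param seed noise seed; default the spec seed + 1.
#' @return A grayscale [volume].
#' @export
voxelize <- function(nest, spacing = NULL, fg = NULL, bg = NULL,
                     noise_sd = NULL, seed = NULL) {
  sp <- nest$spec
  if (is.null(spacing)) spacing <- if (!is.null(sp)) sp$spacing else c(0.1, 0.5, 0.5)
  if (is.null(fg)) fg <- if (!is.null(sp)) sp$fg else 200
  if (is.null(bg)) bg <- if (!is.null(sp)) sp$bg else 10
  if (is.null(noise_sd)) noise_sd <- if (!is.null(sp)) sp$noise_sd else 0
  if (is.null(seed)) seed <- if (!is.null(sp)) sp$seed + 1L else 1L
  box <- if (!is.null(sp)) sp$box else {
    mx <- do.call(rbind, lapply(nest$branches, `[[`, "pts"))
    apply(mx, 2, max) + 5
  }
  dims <- c(floor(box[3] / spacing[1]) + 1,
            floor(box[2] / spacing[2]) + 1,
            floor(box[1] / spacing[3]) + 1)
  for (b in nest$branches) {
    hi <- apply(b$pts, 2, max) + b$diameter / 2
    if (any(hi > box)) stop("nest exceeds the volume bounds")
  }
  mask <- voxelize_cpp(lapply(nest$branches, `[[`, "pts"),
                       vapply(nest$branches, `[[`, 0, "diameter"),
                       as.integer(dims), spacing)
  arr <- array(ifelse(mask, fg, bg), dim = dims)
  if (noise_sd > 0) {
    set.seed(seed)
    arr <- arr + array(rnorm(length(arr), 0, noise_sd), dim = dims)
    arr <- pmin(pmax(round(arr), 0), 255)
  }
  volume(array(as.numeric(arr), dim = dims), spacing)
}

#' Break a ground-truth branch into fragments with a known gap
#'
#' Splits the branch at its arc midpoint, removing `gap_mm` of arc length
#' around the cut (as junction elimination would), and returns the
#' fragments together with the true adjacency map. With a `crossing`
#' branch, both branches are split where they pass closest to each other,
#' which yields the classic X scenario: 4 fragments, 2 true adjacencies,
#' and 4 false candidate pairings. A zero gap returns the branch unbroken.
#'
#' @param branch a `list(id, pts, diameter)` ground-truth branch.
#' @param gap_mm arc length removed around each cut.
#' @param crossing optional second ground-truth branch.
#' @return List with `edges` (an [edge_set] of fragments, each carrying the
#'   originating branch id in `truth_branch`), `truth_pairs` (data.frame
#'   `frag_i, frag_j` of true adjacencies), and `diameters` (per-fragment).
#' @export
make_fragmentation_fixture <- function(branch, gap_mm, crossing = NULL) {
  frags <- list()
  truth <- list()
  dia <- numeric(0)
  split_one <- function(pts, s_cut, gap) {
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    if (gap >= s[length(s)]) stop("gap larger than the branch")
    left <- pts[s <= s_cut - gap / 2, , drop = FALSE]
    right <- pts[s >= s_cut + gap / 2, , drop = FALSE]
    if (nrow(left) < 2 || nrow(right) < 2) stop("gap leaves a degenerate fragment")
    list(left, right)
  }
  add_branch <- function(pts, diameter, s_cut, gap) {
    if (gap <= 0) {
      frags[[length(frags) + 1L]] <<- pts
      dia <<- c(dia, diameter)
      return(length(frags))
    }
    halves <- split_one(pts, s_cut, gap)
    i1 <- length(frags) + 1L
    frags[[i1]] <<- halves[[1]]
    frags[[i1 + 1L]] <<- halves[[2]]
    dia <<- c(dia, diameter, diameter)
    truth[[length(truth) + 1L]] <<- data.frame(frag_i = i1, frag_j = i1 + 1L)
    c(i1, i1 + 1L)
  }
  if (is.null(crossing)) {
    seg <- sqrt(rowSums((branch$pts[-1, , drop = FALSE] -
                         branch$pts[-nrow(branch$pts), , drop = FALSE])^2))
    total <- sum(seg)
    idx_a <- add_branch(branch$pts, branch$diameter, total / 2, gap_mm)
    ids_branch <- rep(branch$id, length(idx_a))
  } else {
    d2 <- outer(rowSums(branch$pts^2), rep(1, nrow(crossing$pts))) +
          outer(rep(1, nrow(branch$pts)), rowSums(crossing$pts^2)) -
          2 * branch$pts %*% t(crossing$pts)
    w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    arc_at <- function(pts, i) {
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      c(0, cumsum(seg))[i]
    }
    idx_a <- add_branch(branch$pts, branch$diameter,
                        arc_at(branch$pts, w[1]), gap_mm)
    idx_b <- add_branch(crossing$pts, crossing$diameter,
                        arc_at(crossing$pts, w[2]), gap_mm)
    ids_branch <- c(rep(branch$id, length(idx_a)),
                    rep(crossing$id, length(idx_b)))
  }
  edges <- lapply(seq_along(frags), function(i)
    list(id = i, pts = frags[[i]], provenance = i, truth_branch = ids_branch[i]))
  list(edges = structure(list(edges = edges, spacing = c(1, 1, 1), dropped = 0L),
                         class = "edge_set"),
       truth_pairs = if (length(truth)) do.call(rbind, truth) else
         data.frame(frag_i = integer(0), frag_j = integer(0)),
       diameters = dia)
}

#' Compare a recovered digitization against ground truth
#'
#' Maps every recovered branch to the ground-truth branch owning the
#' majority of its sample points (nearest-polyline assignment), then
#' reports: recovered vs true branch counts, the number of spurious merges
#' (recovered branches mixing two true branches, each holding more than 20
#' percent of points), per-true-branch relative length error and absolute
#' median-diameter error, and the fraction of true contacts recovered
#' (a recovered contact between the mapped pair within `contact_match_mm`
#' of the true location).
#'
#' @param nest the `ground_truth_nest`.
#' @param branches recovered branches (list of [nest_branch]).
#' @param contacts recovered contact data.frame.
#' @param contact_match_mm match radius for contact locations, mm.
#' @return A list of recovery metrics.
#' @export
evaluate_recovery <- function(nest, branches, contacts,
                              contact_match_mm = 6) {
  true_pts <- lapply(nest$branches, `[[`, "pts")
  assign_true <- function(pts) {
    sam <- resample_polyline(pts, 2)
    dmat <- vapply(true_pts, function(tp) min_cross_distances(sam, tp),
                   numeric(nrow(sam)))
    if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1)
    apply(dmat, 1, which.min)
  }
  maps <- lapply(branches, function(b) assign_true(b$pts))
  majority <- vapply(maps, function(m) {
    tab <- sort(table(m), decreasing = TRUE)
    as.integer(names(tab)[1])
  }, 0L)
  mixed <- vapply(maps, function(m) {
    tab <- table(m) / length(m)
    sum(tab > 0.2) >= 2
  }, logical(1))

  per_true <- data.frame(true_id = as.integer(vapply(nest$branches, function(b) b$id, 0)))
  per_true$true_length <- vapply(nest$branches, function(b)
    polyline_length(b$pts), 0)
  per_true$true_diameter <- vapply(nest$branches, `[[`, 0, "diameter")
  per_true$recovered_length <- vapply(per_true$true_id, function(i)
    sum(vapply(branches[majority == i], `[[`, 0, "length")), 0)
  per_true$n_recovered <- vapply(per_true$true_id, function(i)
    sum(majority == i), 0L)
  per_true$recovered_diameter <- vapply(per_true$true_id, function(i) {
    sel <- which(majority == i)
    if (!length(sel)) return(NA_real_)
    stats::weighted.mean(
      vapply(branches[sel], `[[`, 0, "median_thickness"),
      vapply(branches[sel], `[[`, 0, "length"))
  }, 0)

  tc <- nest$contacts
  found <- logical(nrow(tc))
  if (nrow(tc) && nrow(contacts)) {
    rec_ids <- as.integer(vapply(branches, function(b) b$id, 0))
    rec_a <- majority[match(contacts$branch_a, rec_ids)]
    rec_b <- majority[match(contacts$branch_b, rec_ids)]
    for (r in seq_len(nrow(tc))) {
      pairmatch <- (rec_a == tc$branch_a[r] & rec_b == tc$branch_b[r]) |
                   (rec_a == tc$branch_b[r] & rec_b == tc$branch_a[r])
      if (!any(pairmatch)) next
      dd <- sqrt((contacts$x[pairmatch] - tc$x[r])^2 +
                 (contacts$y[pairmatch] - tc$y[r])^2 +
                 (contacts$z[pairmatch] - tc$z[r])^2)
      found[r] <- any(dd <= contact_match_mm)
    }
  }
  list(n_true = length(nest$branches),
       n_recovered = length(branches),
       spurious_merges = sum(mixed),
       majority = majority,
       per_true = per_true,
       length_rel_err = with(per_true[per_true$n_recovered > 0, ],
                             abs(recovered_length - true_length) / true_length),
       diameter_abs_err = with(per_true[per_true$n_recovered > 0, ],
                               abs(recovered_diameter - true_diameter)),
       contact_recovery = if (nrow(tc)) mean(found) else NA_real_,
       n_true_contacts = nrow(tc),
       n_recovered_contacts = nrow(contacts))
}
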