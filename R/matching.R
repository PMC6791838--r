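#' Parameters of the endpoint friendship score and fragment linking
#'
#' The score multiplies the endpoint distance `D`, the orientation mismatch
#' `A`, the larger of the two line-to-point distances `d1, d2`, the larger
#' of the two bearing mismatches `a1, a2`, and the thickness-ratio term
#' raised to `exponent_T`. Components below their floors are replaced by the
#' floor before multiplication: 1.0 mm for `D`, 0.5 mm for `d`, 0.1 for the
#' raw thickness ratio, and (in symmetric mode) 1 degree for the angle terms
#' so a single zero factor cannot collapse the product for geometrically
#' distant pairs. Lower scores mean better matches.
#'
#' `mode = "symmetric"` (default) uses the order-independent thickness ratio
#' `max(t1,t2)/min(t1,t2)` and the angle floors; `mode = "literal"` uses the
#' raw ratio `t2/t1` with its 0.1 floor, raw bearing angles, and no angle
#' floors.
#'
#' @param floor_D floor of the endpoint distance, mm.
#' @param floor_d floor of the line-to-point distances, mm.
#' @param floor_ratio floor of the thickness-ratio term.
#' @param exponent_T exponent of the thickness-ratio term.
#' @param floor_angle_deg floor of the angle terms, degrees (symmetric mode).
#' @param search_radius_mm only endpoint pairs closer than this are scored.
#' @param link_threshold largest score still accepted as a link; the default
#'   was calibrated on the synthetic fragmentation suite as the largest
#'   value producing zero false merges across seeds, with a safety margin.
#' @param L_dir_mm arc length over which the endpoint direction vector is
#'   measured.
#' @param stub_len_mm fragments shorter than this are treated as stubs:
#'   their own line-distance and bearing terms are unreliable (the whole
#'   fragment sits in the curled contact zone), so the score falls back to
#'   the opposite, well-oriented side's terms when that side is long.
#' @param endpoint_thickness_samples number of samples for the endpoint
#'   thickness median.
#' @param mode `"symmetric"` or `"literal"`.
#' @return A `score_params` list.
#' @export
score_params <- function(floor_D = 1.0, floor_d = 0.5, floor_ratio = 0.1,
                         exponent_T = 3, floor_angle_deg = 1.0,
                         search_radius_mm = 10, link_threshold = 2000,
                         L_dir_mm = 12, endpoint_thickness_samples = 10L,
                         stub_len_mm = 12,
                         mode = c("symmetric", "literal")) {
  mode <- match.arg(mode)
  p <- list(floor_D = floor_D, floor_d = floor_d, floor_ratio = floor_ratio,
            exponent_T = exponent_T, floor_angle_deg = floor_angle_deg,
            search_radius_mm = search_radius_mm,
            link_threshold = link_threshold, L_dir_mm = L_dir_mm,
            endpoint_thickness_samples = as.integer(endpoint_thickness_samples),
            stub_len_mm = stub_len_mm, mode = mode)
  if (any(c(p$floor_D, p$floor_d, p$floor_ratio, p$floor_angle_deg) < 0))
    stop("floors must be >= 0")
  if (p$exponent_T <= 0) stop("exponent_T must be > 0")
  if (p$search_radius_mm <= 0) stop("search_radius_mm must be > 0")
  if (p$L_dir_mm <= 0) stop("L_dir_mm must be > 0")
  structure(p, class = "score_params")
}

vec_norm <- function(v) sqrt(sum(v^2))

angle_deg <- function(u, v) {
  d <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

point_line_distance <- function(q, p, v) {
  w <- q - p
  proj <- sum(w * v)
  vec_norm(w - proj * v)
}

#' Describe one endpoint of an edge
#'
#' Returns the terminal position `p`, the unit direction `v` pointing from
#' the endpoint into the branch (towards the point at arc length `L_dir_mm`
#' along the polyline; for shorter edges, towards the far endpoint), and the
#' local thickness `t`: the median diameter over a fixed number of sample
#' points nearest the endpoint, looked up in the thickness radius map.
#' Zero-diameter samples (skeleton points falling outside the thickness
#' segmentation) are excluded from the median; when no positive sample
#' exists `t` is `NA` and the thickness term of the score becomes neutral.
#'
#' @param edge an edge entry (`list(id, pts, ...)` with mm coordinates).
#' @param side `"first"` or `"last"`.
#' @param radius_map optional radius [volume] from [radius_map()].
#' @param params a [score_params] object.
#' @return A list `p`, `v`, `t` (class `endpoint_descriptor`).
#' @export
endpoint_descriptor <- function(edge, side = c("first", "last"),
                                radius_map = NULL, params = score_params()) {
  side <- match.arg(side)
  pts <- edge$pts
  if (!is.matrix(pts) || nrow(pts) < 2) stop("degenerate edge: need >= 2 points")
  if (side == "last") pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  p <- pts[1, ]
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  ti <- which(s >= params$L_dir_mm)[1]
  if (is.na(ti)) ti <- nrow(pts)
  v <- pts[ti, ] - p
  nv <- vec_norm(v)
  if (nv == 0) { v <- pts[nrow(pts), ] - p; nv <- vec_norm(v) }
  v <- v / nv
  t_med <- NA_real_
  if (!is.null(radius_map)) {
    ns <- min(params$endpoint_thickness_samples, nrow(pts))
    samp <- pts[seq_len(ns), , drop = FALSE]
    kji <- mm_to_voxel(samp, radius_map$spacing, dim(radius_map$data))
    dia <- 2 * radius_map$data[cbind(kji[, 1], kji[, 2], kji[, 3])]
    dia <- dia[dia > 0]
    if (length(dia)) t_med <- median(dia)
  }
  structure(list(p = p, v = v, t = t_med, arc_len = s[length(s)]),
            class = "endpoint_descriptor")
}

#' Combine friendship-score components with floor enforcement
#'
#' Applies the floors and evaluates
#' `C = D * A * max(d1, d2) * max(a1, a2) * ratio^T`. Exposed separately so
#' component-level behaviour (floors, exponent) can be exercised directly.
#'
#' @param D endpoint distance, mm.
#' @param A orientation mismatch, degrees (0 = perfect).
#' @param d1,d2 line-to-point distances, mm.
#' @param a1,a2 bearing mismatches, degrees (0 = perfect).
#' @param ratio thickness-ratio term.
#' @param params a [score_params] object.
#' @param floors if `FALSE`, skip all floor enforcement.
#' @return The score `C` (lower = better).
#' @export
friendship_combine <- function(D, A, d1, d2, a1, a2, ratio,
                               params = score_params(), floors = TRUE) {
  if (floors) {
    D <- max(D, params$floor_D)
    d1 <- max(d1, params$floor_d)
    d2 <- max(d2, params$floor_d)
    ratio <- max(ratio, params$floor_ratio)
    if (params$mode == "symmetric") {
      A <- max(A, params$floor_angle_deg)
      a1 <- max(a1, params$floor_angle_deg)
      a2 <- max(a2, params$floor_angle_deg)
    }
  }
  D * A * max(d1, d2) * max(a1, a2) * ratio^params$exponent_T
}

#' Friendship score between two endpoint descriptors
#'
#' Computes the geometric components between endpoints `p1`, `p2` with
#' inward unit directions `v1`, `v2`:
#' `D = |p1 - p2|`; `A = 180 - angle(v1, v2)` so collinear continuation
#' (inward vectors anti-parallel) scores 0; `d_i` is the perpendicular
#' distance from the opposite endpoint to the infinite line through `p_i`
#' along `v_i`; the bearings are `a_i = 180 - angle(p_i -> p_j, v_i)` in
#' symmetric mode (0 = perfect) or the raw angle in literal mode; the
#' thickness term is `max(t1,t2)/min(t1,t2)` (symmetric) or `t2/t1`
#' (literal). Floors are enforced before multiplication.
#'
#' @param e1,e2 [endpoint_descriptor] objects.
#' @param params a [score_params] object.
#' @param floors set `FALSE` to disable floor enforcement.
#' @return A `pair_score` list with all components and the combined `C`;
#'   `C` is `NA` when the literal thickness ratio is undefined (both
#'   thicknesses zero), in which case the pair must be skipped.
#' @export
friendship_score <- function(e1, e2, params = score_params(), floors = TRUE) {
  p1 <- e1$p; p2 <- e2$p; v1 <- e1$v; v2 <- e2$v
  D <- vec_norm(p1 - p2)
  A <- 180 - angle_deg(v1, v2)
  d1 <- point_line_distance(p2, p1, v1)
  d2 <- point_line_distance(p1, p2, v2)
  if (D > 0) {
    u12 <- (p2 - p1) / D
    raw1 <- angle_deg(u12, v1)
    raw2 <- angle_deg(-u12, v2)
  } else raw1 <- raw2 <- 180
  if (params$mode == "symmetric") {
    a1 <- 180 - raw1; a2 <- 180 - raw2
  } else {
    a1 <- raw1; a2 <- raw2
  }
  t1 <- e1$t; t2 <- e2$t
  undefined <- FALSE
  if (params$mode == "symmetric") {
    if (is.na(t1) || is.na(t2) || (t1 == 0 && t2 == 0)) ratio <- 1
    else if (min(t1, t2) == 0) ratio <- Inf
    else ratio <- max(t1, t2) / min(t1, t2)
  } else {
    if (is.na(t1) || is.na(t2)) ratio <- 1
    else if (t1 == 0) { ratio <- NA_real_; undefined <- t2 == 0 }
    else ratio <- t2 / t1
    if (!undefined && is.na(ratio)) ratio <- Inf
  }
  # stub fallback: a fragment lying entirely inside the curled contact
  # zone cannot define its own line or bearing; defer to the long side
  stub_len <- if (is.null(params$stub_len_mm)) 0 else params$stub_len_mm
  len1 <- if (is.null(e1$arc_len)) Inf else e1$arc_len
  len2 <- if (is.null(e2$arc_len)) Inf else e2$arc_len
  d1e <- d1; d2e <- d2; a1e <- a1; a2e <- a2
  if (len1 < stub_len && len2 >= stub_len) { d1e <- d2; a1e <- a2 }
  if (len2 < stub_len && len1 >= stub_len) { d2e <- d1; a2e <- a1 }
  C <- if (undefined) NA_real_ else
    friendship_combine(D, A, d1e, d2e, a1e, a2e, ratio, params, floors)
  structure(list(D = D, A = A, d1 = d1, d2 = d2, a1 = a1, a2 = a2,
                 ratio = ratio, C = C), class = "pair_score")
}

edge_endpoints_table <- function(es) {
  rows <- list()
  for (e in es$edges) {
    n <- nrow(e$pts)
    rows[[length(rows) + 1L]] <- data.frame(
      edge = e$id, side = "first",
      x = e$pts[1, 1], y = e$pts[1, 2], z = e$pts[1, 3])
    rows[[length(rows) + 1L]] <- data.frame(
      edge = e$id, side = "last",
      x = e$pts[n, 1], y = e$pts[n, 2], z = e$pts[n, 3])
  }
  do.call(rbind, rows)
}

#' Enumerate candidate endpoint pairs within the search radius
#'
#' All cross-edge endpoint pairs whose distance is at most
#' `search_radius_mm`; the two endpoints of one edge are never paired.
#'
#' @param edges an [edge_set].
#' @param params a [score_params] object.
#' @return data.frame with columns `edge_i, side_i, edge_j, side_j, D`.
#' @export
candidate_pairs <- function(edges, params = score_params()) {
  ep <- edge_endpoints_table(edges)
  out <- data.frame(edge_i = integer(0), side_i = character(0),
                    edge_j = integer(0), side_j = character(0), D = numeric(0))
  if (is.null(ep) || nrow(ep) < 2) return(out)
  dm <- as.matrix(stats::dist(ep[, c("x", "y", "z")]))
  idx <- which(upper.tri(dm) & dm <= params$search_radius_mm, arr.ind = TRUE)
  if (nrow(idx)) {
    keep <- ep$edge[idx[, 1]] != ep$edge[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
  }
  if (nrow(idx) == 0) return(out)
  data.frame(edge_i = ep$edge[idx[, 1]], side_i = ep$side[idx[, 1]],
             edge_j = ep$edge[idx[, 2]], side_j = ep$side[idx[, 2]],
             D = dm[idx])
}

score_all_pairs <- function(es, radius_map, params) {
  cand <- candidate_pairs(es, params)
  if (nrow(cand) == 0) return(cbind(cand, C = numeric(0)))
  desc <- list()
  for (e in es$edges) {
    desc[[paste(e$id, "first")]] <-
      endpoint_descriptor(e, "first", radius_map, params)
    desc[[paste(e$id, "last")]] <-
      endpoint_descriptor(e, "last", radius_map, params)
  }
  comp <- lapply(seq_len(nrow(cand)), function(r) {
    friendship_score(desc[[paste(cand$edge_i[r], cand$side_i[r])]],
                     desc[[paste(cand$edge_j[r], cand$side_j[r])]],
                     params)
  })
  cand$A <- vapply(comp, `[[`, 0, "A")
  cand$d1 <- vapply(comp, `[[`, 0, "d1")
  cand$d2 <- vapply(comp, `[[`, 0, "d2")
  cand$a1 <- vapply(comp, `[[`, 0, "a1")
  cand$a2 <- vapply(comp, `[[`, 0, "a2")
  cand$ratio <- vapply(comp, `[[`, 0, "ratio")
  cand$C <- vapply(comp, `[[`, 0, "C")
  cand
}

bridge_points <- function(a, b, step_mm) {
  gap <- vec_norm(b - a)
  n <- max(0L, as.integer(floor(gap / step_mm)) - 1L)
  if (n == 0) return(NULL)
  w <- seq_len(n) / (n + 1)
  out <- outer(1 - w, a) + outer(w, b)
  colnames(out) <- names(a)
  out
}

merge_edge_pair <- function(e_i, side_i, e_j, side_j) {
  pts_i <- e_i$pts
  pts_j <- e_j$pts
  if (side_i == "first") pts_i <- pts_i[rev(seq_len(nrow(pts_i))), , drop = FALSE]
  if (side_j == "last") pts_j <- pts_j[rev(seq_len(nrow(pts_j))), , drop = FALSE]
  # bridge the junction gap so the reconstructed branch is a continuous
  # polyline again (the junction trim removed the points in between)
  step_i <- polyline_length(pts_i) / max(nrow(pts_i) - 1, 1)
  step_j <- polyline_length(pts_j) / max(nrow(pts_j) - 1, 1)
  bridge <- bridge_points(pts_i[nrow(pts_i), ], pts_j[1, ],
                          max(min(step_i, step_j), 0.05))
  list(id = min(e_i$id, e_j$id),
       pts = rbind(pts_i, bridge, pts_j),
       provenance = sort(unique(c(e_i$provenance, e_j$provenance))))
}

#' Link fragment edges that originate from the same physical branch
#'
#' Iterative greedy matching: in each round all candidate endpoint pairs
#' among the current edges are scored, and the globally best (lowest score)
#' pair at or below `link_threshold` is merged into a single edge, with the
#' junction gap bridged by interpolated points and fragment provenance
#' retained. Descriptors of merged edges are recomputed before the next
#' round; the process stops when no pair qualifies, after at most
#' (number of fragments - 1) merges. Equal scores are broken towards the
#' lexicographically smallest (edge id, side) pair, so runs are
#' deterministic.
#'
#' @param edges an [edge_set] of fragments.
#' @param radius_map optional radius [volume] for the thickness term.
#' @param params a [score_params] object.
#' @return An [edge_set] of reconnected branches; the merge history (pair
#'   ids and scores) is attached as attribute `"merges"`, and the full
#'   last-round score audit as attribute `"audit"`.
#' @export
link_edges <- function(edges, radius_map = NULL, params = score_params()) {
  es <- edges
  merges <- list()
  audit <- NULL
  repeat {
    scored <- score_all_pairs(es, radius_map, params)
    audit <- scored
    ok <- which(is.finite(scored$C) & scored$C <= params$link_threshold)
    if (length(ok) == 0) break
    sc <- scored[ok, , drop = FALSE]
    side_rank <- function(s) ifelse(s == "first", 0L, 1L)
    o <- order(sc$C, pmin(sc$edge_i, sc$edge_j), pmax(sc$edge_i, sc$edge_j),
               side_rank(sc$side_i), side_rank(sc$side_j))
    best <- sc[o[1], ]
    ei <- which(vapply(es$edges, `[[`, 0L, "id") == best$edge_i)
    ej <- which(vapply(es$edges, `[[`, 0L, "id") == best$edge_j)
    merged <- merge_edge_pair(es$edges[[ei]], best$side_i,
                              es$edges[[ej]], best$side_j)
    es$edges[[ei]] <- merged
    es$edges[[ej]] <- NULL
    merges[[length(merges) + 1L]] <- data.frame(
      edge_i = best$edge_i, side_i = best$side_i,
      edge_j = best$edge_j, side_j = best$side_j, C = best$C)
  }
  attr(es, "merges") <- if (length(merges)) do.call(rbind, merges) else
    data.frame(edge_i = integer(0), side_i = character(0),
               edge_j = integer(0), side_j = character(0), C = numeric(0))
  attr(es, "audit") <- audit
  es
}

#' Remove residual short edges
#'
#' Edges with arc length below `min_len_mm` (leftover stubs from junction
#' contact regions) are dropped; the number removed is recorded in the
#' `dropped_short` attribute.
#'
#' @param edges an [edge_set].
#' @param min_len_mm removal threshold, mm (default 5).
#' @return The filtered [edge_set].
#' @export
drop_short <- function(edges, min_len_mm = 5) {
  lens <- vapply(edges$edges, function(e) polyline_length(e$pts), numeric(1))
  keep <- lens >= min_len_mm
  out <- edges
  out$edges <- edges$edges[keep]
  attr(out, "dropped_short") <- sum(!keep)
  attr(out, "merges") <- attr(edges, "merges")
  out
}
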