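# Voxel phantoms and brute-force oracles used across the test files.
# All phantoms are built in code at test time; nothing is stored on disk.

# straight polyline of length L along unit direction dirv, centred at center
line_pts <- function(dirv, center, L, step = 1) {
  s <- seq(-L / 2, L / 2, by = step)
  pts <- outer(s, dirv) + matrix(center, length(s), 3, byrow = TRUE)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# solid cylinder mask: axis along x, radius r_mm, in a (z, y, x) array
cylinder_volume <- function(r_mm = 2, len_vox = 40, spacing = c(0.1, 0.5, 0.5),
                            pad_mm = 4) {
  cy <- r_mm + pad_mm
  cz <- r_mm + pad_mm
  dims <- c(round(2 * cz / spacing[1]) + 1,
            round(2 * cy / spacing[2]) + 1, len_vox)
  arr <- array(FALSE, dims)
  z <- ((seq_len(dims[1])) - 1) * spacing[1]
  y <- ((seq_len(dims[2])) - 1) * spacing[2]
  disc <- outer((z - cz)^2, (y - cy)^2, `+`) <= r_mm^2
  for (i in seq_len(dims[3])) arr[, , i][disc] <- TRUE
  volume(arr, spacing)
}

torus_volume <- function(R0 = 10, r0 = 2.2, spacing = c(0.5, 0.5, 0.5)) {
  n <- ceiling(2 * (R0 + r0 + 2) / spacing[2]) + 1
  nz <- ceiling(2 * (r0 + 2) / spacing[1]) + 1
  arr <- array(FALSE, c(nz, n, n))
  c0 <- c((nz - 1) / 2, (n - 1) / 2, (n - 1) / 2)
  for (k in seq_len(nz)) for (j in seq_len(n)) for (i in seq_len(n)) {
    z <- (k - 1 - c0[1]) * spacing[1]
    y <- (j - 1 - c0[2]) * spacing[2]
    x <- (i - 1 - c0[3]) * spacing[3]
    rho <- sqrt(x^2 + y^2)
    if ((rho - R0)^2 + z^2 <= r0^2) arr[k, j, i] <- TRUE
  }
  volume(arr, spacing)
}

# voxel chain mask from mm polylines: 3D digital-differential-analyzer
# rasterization, giving 1-voxel-wide 26-connected chains
chain_volume <- function(polylines, dims, spacing) {
  arr <- array(FALSE, dims)
  for (pts in polylines) {
    kji <- nestweave:::mm_to_voxel(pts, spacing, dims)
    for (s in seq_len(nrow(kji) - 1)) {
      a <- kji[s, ]; b <- kji[s + 1, ]
      n <- max(abs(b - a), 1)
      for (t in 0:n) {
        v <- round(a + (b - a) * t / n)
        arr[v[1], v[2], v[3]] <- TRUE
      }
    }
  }
  volume(arr, spacing)
}

resample_dense <- function(pts, step) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  t <- seq(0, s[length(s)], by = step)
  out <- matrix(0, length(t), 3)
  for (u in seq_along(t)) {
    i <- findInterval(t[u], s, all.inside = TRUE)
    w <- (t[u] - s[i]) / max(s[i + 1] - s[i], 1e-12)
    out[u, ] <- (1 - w) * pts[i, ] + w * pts[i + 1, ]
  }
  colnames(out) <- c("x", "y", "z")
  out
}

# brute-force 3D flood fill oracle for fill_holes (6-connectivity), pure R
r_fill_holes <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  queue <- which(!mask & !outside)
  border <- arrayInd(queue, d)
  on_border <- border[, 1] %in% c(1, d[1]) | border[, 2] %in% c(1, d[2]) |
               border[, 3] %in% c(1, d[3])
  stack <- queue[on_border]
  outside[stack] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (length(stack)) {
    idx <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kji <- arrayInd(idx, d)
    for (r in seq_len(6)) {
      q <- kji + offs[r, , drop = FALSE]
      if (any(q < 1) || any(q > d)) next
      lin <- q[1] + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1))
      if (!mask[lin] && !outside[lin]) {
        outside[lin] <- TRUE
        stack <- c(stack, lin)
      }
    }
  }
  mask | !outside
}

# brute-force anisotropic EDT oracle (tiny volumes only); voxels beyond
# the volume count as background at their would-be centres
r_edt <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask)
  out <- array(0, d)
  if (length(fg) == 0) return(out)
  bg <- which(!mask)
  bgi <- arrayInd(bg, d)
  bg_mm <- cbind(bgi[, 1] * spacing[1], bgi[, 2] * spacing[2],
                 bgi[, 3] * spacing[3])
  fgi <- arrayInd(fg, d)
  for (t in seq_along(fg)) {
    kji <- fgi[t, ]
    edge <- min(kji[1] * spacing[1], (d[1] + 1 - kji[1]) * spacing[1],
                kji[2] * spacing[2], (d[2] + 1 - kji[2]) * spacing[2],
                kji[3] * spacing[3], (d[3] + 1 - kji[3]) * spacing[3])
    inner <- if (length(bg)) {
      fg_mm <- kji * spacing
      min(sqrt(colSums((t(bg_mm) - fg_mm)^2)))
    } else Inf
    out[fg[t]] <- min(inner, edge)
  }
  out
}

# component count via igraph over the voxel adjacency (independent of the
# package's labeling kernel)
igraph_components <- function(mask, dims) {
  vox <- which(mask)
  if (length(vox) == 0) return(0)
  adj <- nestweave:::voxel_adjacency_cpp(as.integer(vox), as.integer(dims))
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (nrow(adj)) g <- igraph::add_edges(g, t(adj))
  igraph::components(g)$no
}

graph_cycle_rank <- function(g) {
  ig <- skeleton_igraph(g)
  igraph::ecount(ig) - igraph::vcount(ig) + igraph::components(ig)$no
}

# random gentle-arc ground-truth branch for matching fixtures
random_arc_branch <- function(seed, scenario = c("straight", "curved")) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  L <- runif(1, 70, 110)
  phi <- if (scenario == "straight") runif(1, 1, 5) else runif(1, 20, 36)
  u <- nestweave:::direction_from_angles(runif(1, 0, 80), runif(1, 0, 360))
  w <- nestweave:::random_unit_perp(u)
  pts <- nestweave:::arc_polyline(L, phi * pi / 180, u, w, L / 2)
  list(id = 1L, pts = sweep(pts, 2, c(100, 100, 100), `+`),
       diameter = exp(rnorm(1, log(2.3), 0.3)))
}

crossing_branch_for <- function(branch, seed) {
  set.seed(seed + 1000)
  mid <- branch$pts[ceiling(nrow(branch$pts) / 2), ]
  u2 <- nestweave:::direction_from_angles(runif(1, 0, 80), runif(1, 0, 360))
  w2 <- nestweave:::random_unit_perp(u2)
  L2 <- runif(1, 70, 110)
  pts2 <- sweep(nestweave:::arc_polyline(L2, runif(1, 3, 20) * pi / 180,
                                         u2, w2, L2 / 2),
                2, mid + runif(3, -1, 1), `+`)
  list(id = 2L, pts = pts2, diameter = exp(rnorm(1, log(2.3), 0.3)))
}

# two-branch ground-truth nest at a grazing contact, for mini pipeline runs
two_branch_nest <- function(noise_sd = 5, seed = 7) {
  sp <- c(0.1, 0.5, 0.5)
  b1 <- list(id = 1L, pts = line_pts(c(1, 0, 0), c(40, 40, 20), 60), diameter = 3)
  b2 <- list(id = 2L,
             pts = line_pts(c(cos(pi / 3), sin(pi / 3), 0), c(40, 40, 22.7), 60),
             diameter = 3)
  structure(list(branches = list(b1, b2), scaffold_ids = 1L,
                 contacts = nestweave:::true_contacts(list(b1, b2)),
                 spec = list(box = c(80, 80, 45), spacing = sp, fg = 37,
                             bg = 19, noise_sd = noise_sd, seed = seed)),
            class = "ground_truth_nest")
}

# synthetic voxel-chain structure with 4 junctions, 6 endpoints, 9 edges:
# junction backbone J1-J2-J3-J4 plus 2+1+1+2 free tails
four_junction_graph <- function() {
  sp <- c(0.5, 0.5, 0.5)
  J <- list(c(20, 40, 20), c(40, 40, 20), c(60, 40, 20), c(80, 40, 20))
  seg <- function(a, b) rbind(a, b)
  polys <- list(
    seg(J[[1]], J[[2]]), seg(J[[2]], J[[3]]), seg(J[[3]], J[[4]]),
    seg(J[[1]], J[[1]] + c(-12, 12, 6)), seg(J[[1]], J[[1]] + c(-12, -12, -6)),
    seg(J[[2]], J[[2]] + c(0, 18, 8)), seg(J[[3]], J[[3]] + c(0, -18, -8)),
    seg(J[[4]], J[[4]] + c(12, 12, 6)), seg(J[[4]], J[[4]] + c(12, -12, -6)))
  polys <- lapply(polys, function(m) {
    colnames(m) <- c("x", "y", "z"); m
  })
  chain_volume(polys, c(80, 120, 200), sp)
}

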