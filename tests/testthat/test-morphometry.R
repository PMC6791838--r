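test_that("radius_map matches the analytic cylinder radius and an EDT oracle", {
  cyl <- cylinder_volume(r_mm = 2, len_vox = 30)
  rmap <- radius_map(cyl)
  # cylinder_volume centres the axis at (r + pad) mm in z and y
  axis_vals <- rmap$data[6 / 0.1 + 1, 6 / 0.5 + 1, 8:22]
  expect_true(all(abs(axis_vals - 2) <= max(cyl$spacing) / 2))
  expect_true(all(rmap$data[!cyl$data] == 0))

  # single foreground voxel: radius is the smallest spacing
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  r1 <- radius_map(volume(one, c(0.1, 0.5, 0.5)))
  expect_equal(r1$data[3, 3, 3], 0.1)

  # all-foreground volume: distances grow monotonically from the border
  allfg <- radius_map(volume(array(TRUE, c(9, 9, 9)), c(1, 1, 1)))
  expect_equal(allfg$data[1:5, 5, 5], 1:5)

  # brute-force anisotropic EDT oracle on a random small volume
  set.seed(23)
  arr <- array(runif(6 * 7 * 8) > 0.4, c(6, 7, 8))
  sp <- c(0.2, 0.7, 0.4)
  expect_equal(radius_map(volume(arr, sp))$data, r_edt(arr, sp),
               tolerance = 1e-9)
})

test_that("assign_thickness samples diameters at the nearest voxel", {
  cyl <- cylinder_volume(r_mm = 2, len_vox = 30)
  rmap <- radius_map(cyl)
  cy <- 6; cz <- 6   # axis position used by cylinder_volume (r + pad), mm
  axis <- cbind(x = seq(2, 12, by = 0.5), y = cy, z = cz)
  br <- nest_branch(1L, axis)
  br <- assign_thickness(br, rmap)
  expect_true(all(abs(br$diameters - 4) <= 1))
  expect_equal(br$median_thickness, median(br$diameters))

  # a polyline in the background gets zero diameters
  bgline <- cbind(x = seq(2, 8), y = 0.5, z = 0.5)
  bz <- assign_thickness(nest_branch(2L, bgline), rmap)
  expect_true(all(bz$diameters == 0))

  # out-of-bounds points get zero plus a warning
  oob <- cbind(x = c(2, 4, 1e4), y = cy, z = cz)
  expect_warning(bo <- assign_thickness(nest_branch(3L, oob), rmap),
                 "outside the volume")
  expect_equal(bo$diameters[3], 0)
})

test_that("zero-thickness cleanup applies the strictly-greater 10% rule", {
  mk <- function(frac_zero, n = 20) {
    b <- nest_branch(1L, cbind(x = seq_len(n), y = 0, z = 0))
    b$diameters <- rep(2, n)
    b$diameters[seq_len(round(frac_zero * n))] <- 0
    b
  }
  expect_length(clean_zero_thickness(list(mk(0)), 0.10), 1)
  expect_length(clean_zero_thickness(list(mk(0.5)), 0.10), 0)
  expect_length(clean_zero_thickness(list(mk(0.10)), 0.10), 1)  # boundary kept
  out <- clean_zero_thickness(list(mk(0), mk(0.5), mk(0.10)), 0.10)
  expect_equal(attr(out, "removed_zero"), 1L)
})

test_that("interpolate_zero propagates nearest positive values", {
  mk <- function(d) {
    b <- nest_branch(1L, cbind(x = seq_along(d), y = 0, z = 0))
    b$diameters <- d
    b
  }
  expect_equal(interpolate_zero(mk(c(4, 0, 4)))$diameters, c(4, 4, 4))
  expect_equal(interpolate_zero(mk(c(4, 0, 0, 6)))$diameters, c(4, 4, 6, 6))
  expect_equal(interpolate_zero(mk(c(3, 2, 5)))$diameters, c(3, 2, 5))
  # positive values never change; zeros always resolve
  set.seed(31)
  for (rep in 1:10) {
    d <- runif(15, 1, 6)
    zeros <- sample(15, 5)
    d[zeros] <- 0
    out <- interpolate_zero(mk(d))$diameters
    expect_true(all(out > 0))
    expect_equal(out[-zeros], d[-zeros])
  }
  expect_error(interpolate_zero(mk(c(0, 0))), "all-zero")
})

test_that("detect_contacts finds touching regions and matches a brute-force scan", {
  mkbr <- function(id, p0, dirv, L, diam, n = 60) {
    w <- seq(0, 1, length.out = n)
    pts <- outer(1 - w, p0) + outer(w, p0 + dirv * L)
    colnames(pts) <- c("x", "y", "z")
    b <- nest_branch(id, pts)
    b$diameters <- rep(diam, n)
    b$median_thickness <- diam
    b
  }
  # two parallel 4 mm branches with 4.2 mm axis separation: gap 0.2
  b1 <- mkbr(1L, c(0, 10, 10), c(1, 0, 0), 50, 4)
  b2 <- mkbr(2L, c(0, 10, 14.2), c(1, 0, 0), 50, 4)
  ct <- detect_contacts(list(b1, b2), tol_mm = 0.5)
  expect_equal(unique(ct[, c("branch_a", "branch_b")]),
               data.frame(branch_a = 1L, branch_b = 2L), ignore_attr = TRUE)
  expect_true(all(abs(ct$gap - 0.2) < 1e-9))

  # far-apart branches: nothing
  b3 <- mkbr(3L, c(0, 60, 60), c(0, 1, 0), 40, 4)
  expect_equal(nrow(detect_contacts(list(b1, b3))), 0)

  # random 10-branch set against an O(n^2) point-pair oracle
  set.seed(37)
  brs <- lapply(1:10, function(i)
    mkbr(i, runif(3, 0, 60), nestweave:::direction_from_angles(runif(1, 0, 90),
                                                               runif(1, 0, 360)),
         runif(1, 30, 60), runif(1, 1.5, 5)))
  ct <- detect_contacts(brs, tol_mm = 0.5)
  # oracle: for each branch pair, does any point pair qualify?
  touching_oracle <- function(a, b) {
    d <- nestweave:::cross_distance_matrix(a$pts, b$pts)
    any(d - a$diameters[1] / 2 - b$diameters[1] / 2 <= 0.5)
  }
  for (i in 1:9) for (j in (i + 1):10) {
    expected <- touching_oracle(brs[[i]], brs[[j]])
    found <- any(ct$branch_a == i & ct$branch_b == j)
    expect_equal(found, expected, info = sprintf("pair %d-%d", i, j))
  }
  # symmetry under branch relabeling: reverse the list
  ct_rev <- detect_contacts(rev(brs), tol_mm = 0.5)
  expect_equal(nrow(ct_rev), nrow(ct))
})

test_that("horizontal angles and the nest summary follow their definitions", {
  vert <- nest_branch(1L, cbind(x = c(0, 0), y = c(0, 0), z = c(0, 30)))
  expect_equal(horizontal_angle(vert), 90)
  hor <- nest_branch(2L, cbind(x = c(0, 30), y = c(0, 0), z = c(0, 0)))
  expect_equal(horizontal_angle(hor), 0)

  mk <- function(id, pts, diam) {
    b <- nest_branch(id, pts)
    b$diameters <- rep(diam, nrow(pts))
    b$median_thickness <- diam
    b
  }
  brs <- list(mk(1L, cbind(x = seq(0, 50, 5), y = 0, z = 0), 2),
              mk(2L, cbind(x = 0, y = seq(0, 40, 5), z = seq(0, 40, 5) * 2), 3))
  contacts <- data.frame(branch_a = 1L, branch_b = 2L, x = 0, y = 0, z = 0,
                         gap = -0.1)
  sm <- summarize_nest(brs, contacts, scaffold_ids = 2L)
  tab <- sm$branch_table
  expect_equal(tab$n_contacts, c(1L, 1L))
  expect_equal(tab$normalized_connectivity, tab$n_contacts / tab$length_mm)
  expect_equal(tab$scaffold_flag, c(FALSE, TRUE))
  expect_equal(sm$global$frac_angle_gt_45, 0.5)
  expect_equal(sm$global$n_branches, 2)
  validate_branch_table(tab[, nestweave:::branch_table_columns])
  expect_error(summarize_nest(list(), contacts), "no branches")
})
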