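# small hand-built networks: branches as vertical/horizontal rods with
# explicit centres, thicknesses and contact locations
toy_branch <- function(id, center, diam, L = 50) {
  pts <- cbind(x = center[1] + c(-L / 2, L / 2), y = center[2], z = center[3])
  b <- nest_branch(id, pts)
  b$diameters <- rep(diam, 2)
  b$median_thickness <- diam
  b
}

toy_contact <- function(a, b, loc, gap = -0.1) {
  data.frame(branch_a = min(a, b), branch_b = max(a, b),
             x = loc[1], y = loc[2], z = loc[3], gap = gap)
}

test_that("the cylinder mass model gives the closed-form value and scaling", {
  b <- toy_branch(1L, c(0, 0, 0), diam = 2, L = 100)
  b$length <- 100
  expect_equal(branch_mass(b, 0.7), 0.7 * pi * 0.1^2 * 10, tolerance = 1e-12)
  b4 <- b; b4$median_thickness <- 4
  expect_equal(branch_mass(b4), 4 * branch_mass(b), tolerance = 1e-12)
  bad <- b; bad$length <- 0
  expect_error(branch_mass(bad), "positive")
})

test_that("build_network validates contacts and attaches masses", {
  brs <- list(toy_branch(1L, c(0, 0, 10), 3), toy_branch(2L, c(0, 10, 20), 2),
              toy_branch(3L, c(0, 20, 30), 2))
  ct <- rbind(toy_contact(1, 2, c(0, 5, 15)), toy_contact(2, 3, c(0, 15, 25)))
  net <- build_network(brs, ct)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$nodes$mass > 0))
  empty <- build_network(brs, ct[0, ])
  expect_equal(nrow(empty$edges), 0)
  bad <- rbind(ct, toy_contact(3, 9, c(0, 0, 0)))
  expect_error(build_network(brs, bad), "does not exist")
})

test_that("scaffold identification follows percentile, component and override", {
  brs <- c(lapply(1:8, function(i) toy_branch(i, c(0, 10 * i, 10), 2)),
           list(toy_branch(9L, c(0, 25, 5), 6), toy_branch(10L, c(0, 45, 5), 6.2)))
  ct <- rbind(toy_contact(9, 10, c(0, 35, 5)),
              do.call(rbind, lapply(1:7, function(i)
                toy_contact(i, i + 1, c(0, 10 * i + 5, 10)))),
              toy_contact(2, 9, c(0, 22, 7)))
  net <- build_network(brs, ct)
  expect_equal(identify_scaffold(net, 80), c(9L, 10L))
  expect_equal(identify_scaffold(net, override = 7L), 7L)
  # uniform thickness: deterministic single pick, lowest id among maxima
  uni <- build_network(lapply(1:4, function(i) toy_branch(i, c(0, 10 * i, 5), 2)),
                       toy_contact(1, 2, c(0, 15, 5)))
  expect_equal(identify_scaffold(uni, 95), 1L)
})

test_that("support scores sum gravity-aligned partner thickness", {
  # candidate 2 sits above branch 1; the single contact is straight below
  brs <- list(toy_branch(1L, c(0, 0, 10), 3), toy_branch(2L, c(0, 0, 14), 2))
  ct <- toy_contact(1, 2, c(0, 0, 12))
  net <- build_network(brs, ct)
  expect_equal(support_score(2L, 1L, net), 3)     # t_partner * (g . u = 1)
  expect_equal(support_score(2L, integer(0), net), 0)
  # contact straight above the candidate contributes nothing
  ct_up <- toy_contact(1, 2, c(0, 0, 16))
  expect_equal(support_score(2L, 1L, build_network(brs, ct_up)), 0)

  # multiple contacts: equals the hand-computed sum on a 4-branch network
  brs4 <- list(toy_branch(1L, c(0, 0, 10), 3), toy_branch(2L, c(0, 10, 10), 2.5),
               toy_branch(3L, c(0, 20, 10), 2), toy_branch(4L, c(0, 10, 14), 1.5))
  ct4 <- rbind(toy_contact(1, 4, c(0, 6, 12)),    # below and to the side
               toy_contact(2, 4, c(0, 10, 12)),   # straight below
               toy_contact(3, 4, c(0, 14, 16)))   # above: no support
  net4 <- build_network(brs4, ct4)
  # hand sum: 3 * (2 / sqrt(20)) from the oblique contact below,
  # 2.5 * 1 from the contact straight below, 0 from the contact above
  expect_equal(support_score(4L, c(1L, 2L, 3L), net4),
               3 * (2 / sqrt(20)) + 2.5, tolerance = 1e-12)
})

test_that("greedy placement is scaffold-first, support-maximal and verifiable", {
  # star: scaffold hub below five branches of distinct thickness
  hub <- toy_branch(1L, c(0, 0, 5), 6, L = 80)
  arms <- lapply(2:6, function(i) toy_branch(i, c(0, 10 * (i - 2) - 20, 9), 1 + 0.5 * i))
  ct <- do.call(rbind, lapply(2:6, function(i)
    toy_contact(1, i, c(0, 10 * (i - 2) - 20, 7))))
  net <- build_network(c(list(hub), arms), ct)
  seq_g <- simulate_greedy(net, scaffold_ids = 1L)
  expect_equal(seq_g$branch_id[1], 1L)
  # all arms have equal support geometry, so ties resolve by thickness
  expect_equal(seq_g$branch_id[-1], c(6L, 5L, 4L, 3L, 2L))

  # invariants: permutation, strictly increasing cumulative mass
  expect_setequal(seq_g$branch_id, net$nodes$id)
  expect_true(all(diff(seq_g$cumulative_mass) > 0))

  # post-hoc greedy property: every placed branch had maximal support
  for (k in 2:nrow(seq_g)) {
    placed <- seq_g$branch_id[seq_len(k - 1)]
    remaining <- setdiff(net$nodes$id, placed)
    scores <- vapply(remaining, support_score, 0, placed = placed, network = net)
    expect_equal(support_score(seq_g$branch_id[k], placed, net), max(scores))
  }
})

test_that("gradual placement builds the load-bearing skeleton first", {
  # chain 1-2-3-4 supported from below, plus branch 5 attached only through
  # a horizontal (zero-alignment) contact: 5 must fall to phase 2
  brs <- list(toy_branch(1L, c(0, 0, 4), 5), toy_branch(2L, c(0, 12, 8), 3),
              toy_branch(3L, c(0, 24, 12), 2.5), toy_branch(4L, c(0, 36, 16), 2),
              toy_branch(5L, c(0, 18, 8), 1.5))
  ct <- rbind(toy_contact(1, 2, c(0, 6, 5)),
              toy_contact(2, 3, c(0, 18, 9)),
              toy_contact(3, 4, c(0, 30, 13)),
              toy_contact(2, 5, c(0, 15, 8)),   # exactly level: no support
              toy_contact(3, 5, c(0, 21, 12)))  # level with branch 5 centre? above
  net <- build_network(brs, ct)
  seq_gr <- simulate_gradual(net, scaffold_ids = 1L)
  phase1 <- attr(seq_gr, "phase1")
  expect_false(5L %in% phase1)
  expect_setequal(phase1, 1:4)
  expect_equal(seq_gr$branch_id[5], 5L)
  expect_setequal(seq_gr$branch_id, 1:5)
  expect_true(all(diff(seq_gr$cumulative_mass) > 0))

  # phase 1 is a spanning tree over the load-bearing contacts
  tree <- nestweave:::max_support_tree(net, c(0, 0, -1))
  sub <- igraph::induced_subgraph(tree, match(as.character(phase1),
                                              igraph::V(tree)$name))
  expect_equal(igraph::ecount(sub), length(phase1) - 1)
  expect_true(igraph::is_tree(sub))

  # a pure tree-shaped supported network has an empty phase 2
  net_tree <- build_network(brs[1:4], ct[1:3, ])
  seq_t <- simulate_gradual(net_tree, scaffold_ids = 1L)
  expect_setequal(attr(seq_t, "phase1"), 1:4)
})

test_that("both strategies conserve mass and agree on the total", {
  set.seed(41)
  brs <- lapply(1:8, function(i)
    toy_branch(i, c(runif(1, -20, 20), runif(1, 0, 60), runif(1, 0, 40)),
               runif(1, 1.5, 6)))
  ct <- do.call(rbind, lapply(1:7, function(i)
    toy_contact(i, i + 1, c(0, 8 * i, runif(1, 0, 40)))))
  net <- build_network(brs, ct)
  sg <- simulate_greedy(net)
  sr <- simulate_gradual(net)
  expect_setequal(sg$branch_id, net$nodes$id)
  expect_setequal(sr$branch_id, net$nodes$id)
  expect_equal(sg$cumulative_mass[8], sum(net$nodes$mass))
  expect_equal(sr$cumulative_mass[8], sg$cumulative_mass[8])
  expect_equal(mass_curve(sg)$cumulative_mass, cumsum(mass_curve(sg)$mass))
  # determinism
  expect_identical(simulate_greedy(net), sg)
  expect_identical(simulate_gradual(net), sr)
})

test_that("mass curves accumulate stepwise", {
  brs <- lapply(1:3, function(i) {
    b <- toy_branch(i, c(0, 10 * i, 5), 2)
    b
  })
  net <- build_network(brs, toy_contact(1, 2, c(0, 15, 5)))
  net$nodes$mass <- c(1, 2, 3)
  sq <- nestweave:::seq_result(c(1L, 2L, 3L), net, "manual")
  expect_equal(sq$cumulative_mass, c(1, 3, 6))
  one <- nestweave:::seq_result(2L, net, "manual")
  expect_equal(one$cumulative_mass, 2)
})
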