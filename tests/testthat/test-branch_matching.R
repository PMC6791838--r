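straight_edge <- function(from, to, n = 40) {
  w <- seq(0, 1, length.out = n)
  pts <- outer(1 - w, from) + outer(w, to)
  colnames(pts) <- c("x", "y", "z")
  list(id = 1L, pts = pts, provenance = 1L)
}

test_that("endpoint descriptors point into the branch over the chord length", {
  e <- straight_edge(c(0, 0, 0), c(30, 0, 0))
  d1 <- endpoint_descriptor(e, "first")
  expect_equal(d1$v, c(x = 1, y = 0, z = 0), tolerance = 1e-12)
  expect_equal(d1$p, c(x = 0, y = 0, z = 0))
  d2 <- endpoint_descriptor(e, "last")
  expect_equal(d2$v, c(x = -1, y = 0, z = 0), tolerance = 1e-12)

  # edge shorter than the chord length: direction spans the whole edge
  short <- straight_edge(c(0, 0, 0), c(3, 0, 0), n = 5)
  expect_equal(endpoint_descriptor(short, "first")$v, c(x = 1, y = 0, z = 0),
               tolerance = 1e-12)

  expect_error(endpoint_descriptor(list(pts = matrix(0, 1, 3)), "first"),
               "degenerate")
})

test_that("the direction over a circular arc equals the closed-form chord", {
  # quarter circle of radius 20 in the xy plane, sampled finely
  theta <- seq(0, pi / 2, length.out = 400)
  pts <- cbind(x = 20 * cos(theta), y = 20 * sin(theta), z = 0)
  e <- list(id = 1L, pts = pts)
  L <- 5
  d <- endpoint_descriptor(e, "first", params = score_params(L_dir_mm = L))
  # chord from arc position 0 to arc position L on a radius-20 circle
  phi <- L / 20
  chord <- c(20 * cos(phi) - 20, 20 * sin(phi), 0)
  chord <- chord / sqrt(sum(chord^2))
  expect_equal(unname(d$v), chord, tolerance = 1e-3)
})

test_that("friendship components reproduce the printed floors and hand value", {
  p <- score_params(mode = "literal")
  # components below their floors are replaced before multiplication
  expect_equal(friendship_combine(D = 0.4, A = 10, d1 = 0.2, d2 = 0.2,
                                  a1 = 5, a2 = 8, ratio = 0.05, params = p),
               1.0 * 10 * 0.5 * 8 * 0.1^3)
  # the hand-evaluated example: C = 1.0 * 10 * 0.5 * 8 * (0.1)^3 = 0.04
  expect_equal(friendship_combine(D = 1.0, A = 10, d1 = 0.5, d2 = 0.3,
                                  a1 = 5, a2 = 8, ratio = 0.1, params = p),
               0.04)
})

test_that("perfect collinear continuation scores zero with floors disabled", {
  e1 <- straight_edge(c(-30, 0, 0), c(0, 0, 0))
  e2 <- straight_edge(c(2, 0, 0), c(32, 0, 0))
  d1 <- endpoint_descriptor(e1, "last")
  d2 <- endpoint_descriptor(e2, "first")
  s <- friendship_score(d1, d2, score_params(), floors = FALSE)
  expect_equal(s$A, 0, tolerance = 1e-9)
  expect_equal(s$C, 0, tolerance = 1e-9)
})

test_that("the score is symmetric and monotone in symmetric mode", {
  set.seed(8)
  p <- score_params()
  for (rep in 1:20) {
    mk <- function() structure(list(p = runif(3, 0, 50),
                                    v = nestweave:::random_unit_perp(c(1, 0, 0)),
                                    t = runif(1, 1, 6), arc_len = 50),
                               class = "endpoint_descriptor")
    a <- mk(); b <- mk()
    expect_equal(friendship_score(a, b, p)$C, friendship_score(b, a, p)$C,
                 tolerance = 1e-9)
  }
  # monotone nondecreasing in each component above its floor
  base <- friendship_combine(2, 10, 1, 1, 5, 5, 1.2, p)
  expect_gte(friendship_combine(3, 10, 1, 1, 5, 5, 1.2, p), base)
  expect_gte(friendship_combine(2, 20, 1, 1, 5, 5, 1.2, p), base)
  expect_gte(friendship_combine(2, 10, 2, 1, 5, 5, 1.2, p), base)
  expect_gte(friendship_combine(2, 10, 1, 1, 9, 5, 1.2, p), base)
  expect_gte(friendship_combine(2, 10, 1, 1, 5, 5, 2.0, p), base)
})

test_that("the literal thickness ratio signals undefined zero-over-zero pairs", {
  mkd <- function(t) structure(list(p = c(0, 0, 0), v = c(1, 0, 0), t = t,
                                    arc_len = 50),
                               class = "endpoint_descriptor")
  mkd2 <- function(t) structure(list(p = c(5, 0, 0), v = c(-1, 0, 0), t = t,
                                     arc_len = 50),
                                class = "endpoint_descriptor")
  p <- score_params(mode = "literal")
  expect_true(is.na(friendship_score(mkd(0), mkd2(0), p)$C))
  expect_false(is.na(friendship_score(mkd(2), mkd2(2), p)$C))
})

test_that("candidate pairs match brute-force enumeration within the radius", {
  far <- edge_set(list(straight_edge(c(0, 0, 0), c(30, 0, 0)),
                       list(id = 2L, pts = straight_edge(c(80, 0, 0), c(110, 0, 0))$pts,
                            provenance = 2L)))
  expect_equal(nrow(candidate_pairs(far, score_params(search_radius_mm = 10))), 0)

  near <- edge_set(list(straight_edge(c(0, 0, 0), c(30, 0, 0)),
                        list(id = 2L, pts = straight_edge(c(33, 0, 0), c(63, 0, 0))$pts,
                             provenance = 2L)))
  cp <- candidate_pairs(near, score_params(search_radius_mm = 10))
  expect_equal(nrow(cp), 1)
  expect_equal(cp$D, 3)

  # k mutually close edges: count equals O(n^2) enumeration
  set.seed(13)
  edges <- lapply(1:6, function(i) {
    a <- runif(3, 0, 15)
    list(id = i, pts = straight_edge(a, a + c(20, 0, 0))$pts, provenance = i)
  })
  es <- edge_set(edges)
  cp <- candidate_pairs(es, score_params(search_radius_mm = 12))
  ep <- nestweave:::edge_endpoints_table(es)
  brute <- 0
  for (i in seq_len(nrow(ep) - 1)) for (j in (i + 1):nrow(ep)) {
    if (ep$edge[i] == ep$edge[j]) next
    d <- sqrt(sum((ep[i, c("x", "y", "z")] - ep[j, c("x", "y", "z")])^2))
    if (d <= 12) brute <- brute + 1
  }
  expect_equal(nrow(cp), brute)
})

test_that("link_edges restores broken branches and never merges across an X", {
  # straight 100 mm branch broken with a 4 mm gap
  b <- list(id = 1L, pts = straight_edge(c(0, 10, 10), c(100, 10, 10), n = 101)$pts,
            diameter = 2.5)
  fx <- make_fragmentation_fixture(b, gap_mm = 4)
  linked <- link_edges(fx$edges, NULL, score_params())
  expect_equal(length(linked), 1)
  expect_equal(nestweave:::polyline_length(linked$edges[[1]]$pts), 100,
               tolerance = 1)
  expect_equal(nrow(attr(linked, "merges")), 1)

  # X crossing: 4 fragments, the 2 true branches restored; the continuation
  # pairs outscore the crossing pairs under brute-force evaluation
  b1 <- list(id = 1L, pts = straight_edge(c(0, 0, 20), c(80, 80, 28), n = 120)$pts,
             diameter = 2.5)
  b2 <- list(id = 2L, pts = straight_edge(c(0, 80, 22), c(80, 0, 30), n = 120)$pts,
             diameter = 2.5)
  fx2 <- make_fragmentation_fixture(b1, gap_mm = 4, crossing = b2)
  expect_equal(length(fx2$edges), 4)
  expect_equal(nrow(fx2$truth_pairs), 2)
  scored <- nestweave:::score_all_pairs(fx2$edges, NULL, score_params())
  truth <- fx2$truth_pairs
  is_true <- mapply(function(i, j)
    any((truth$frag_i == i & truth$frag_j == j) |
        (truth$frag_i == j & truth$frag_j == i)),
    scored$edge_i, scored$edge_j)
  # the best score for each true pairing beats every false pairing
  best_true <- max(vapply(seq_len(nrow(truth)), function(k) {
    rows <- is_true & ((scored$edge_i == truth$frag_i[k] &
                        scored$edge_j == truth$frag_j[k]) |
                       (scored$edge_i == truth$frag_j[k] &
                        scored$edge_j == truth$frag_i[k]))
    min(scored$C[rows])
  }, 0))
  expect_lt(best_true, min(scored$C[!is_true]))
  linked2 <- link_edges(fx2$edges, NULL, score_params())
  expect_equal(length(linked2), 2)
  tb <- vapply(fx2$edges$edges, function(e) e$truth_branch, 0L)
  for (e in linked2$edges) expect_length(unique(tb[e$provenance]), 1)

  # edges beyond the search radius: identity, and fixed point respects n - 1
  far <- edge_set(list(straight_edge(c(0, 0, 0), c(30, 0, 0)),
                       list(id = 2L, pts = straight_edge(c(80, 0, 0), c(110, 0, 0))$pts,
                            provenance = 2L)))
  lf <- link_edges(far, NULL, score_params())
  expect_equal(length(lf), 2)
  expect_equal(nrow(attr(lf, "merges")), 0)
})

test_that("drop_short removes exactly the edges below the threshold", {
  set.seed(17)
  edges <- lapply(1:10, function(i) {
    L <- runif(1, 1, 40)
    a <- runif(3, 0, 100)
    list(id = i, pts = straight_edge(a, a + c(L, 0, 0), n = 10)$pts,
         provenance = i)
  })
  es <- edge_set(edges)
  out <- drop_short(es, 5)
  lens <- vapply(edges, function(e) nestweave:::polyline_length(e$pts), 0)
  expect_equal(length(out), sum(lens >= 5))
  expect_equal(attr(out, "dropped_short"), sum(lens < 5))
  all_long <- edge_set(edges[lens >= 5])
  expect_equal(length(drop_short(all_long, 5)), length(all_long))
})
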