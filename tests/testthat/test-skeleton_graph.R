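test_that("thinning reduces a solid cylinder to a single full-length chain", {
  cyl <- cylinder_volume(r_mm = 2, len_vox = 40)
  sk <- thin(cyl)
  expect_true(all(cyl$data[sk$data]))       # skeleton inside the foreground
  g <- build_graph(sk)
  types <- vapply(g$nodes, `[[`, "", "type")
  expect_equal(sum(types == "endpoint"), 2)
  expect_equal(length(g$edges), 1)
  true_len <- (40 - 1) * 0.5
  expect_equal(g$edges[[1]]$length_mm, true_len, tolerance = 0.15 * true_len)
  expect_false(any(thin(volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)))$data))
})

test_that("thinning preserves component count and cycle rank on phantoms", {
  # cylinder: one component, no cycle
  cyl <- cylinder_volume(r_mm = 1.5, len_vox = 24)
  g_c <- build_graph(thin(cyl))
  expect_equal(igraph_components(thin(cyl)$data, dim(cyl$data)), 1)
  expect_equal(graph_cycle_rank(g_c), 0)

  # torus: one component, exactly one cycle
  tor <- torus_volume()
  skt <- thin(tor)
  expect_equal(igraph_components(skt$data, dim(tor$data)), 1)
  expect_equal(graph_cycle_rank(build_graph(skt)), 1)

  # X of two crossing solid tubes: one component, no cycle
  sp <- c(0.25, 0.5, 0.5)
  dims <- c(41, 61, 61)
  arr <- array(FALSE, dims)
  for (k in seq_len(dims[1])) for (j in seq_len(dims[2])) for (i in seq_len(dims[3])) {
    z <- (k - 21) * sp[1]; y <- (j - 31) * sp[2]; x <- (i - 31) * sp[3]
    if (y^2 + z^2 <= 1.44 || (x - y)^2 / 2 + z^2 <= 1.44) arr[k, j, i] <- TRUE
  }
  xv <- volume(arr, sp)
  skx <- thin(xv)
  expect_equal(igraph_components(skx$data, dims), 1)
  expect_equal(graph_cycle_rank(build_graph(skx)), 0)
})

test_that("build_graph classifies chains, Y forks and the 4-junction figure", {
  sp <- c(0.5, 0.5, 0.5)
  # straight 50-voxel chain
  chain <- chain_volume(list(line_pts(c(1, 0, 0), c(15, 5, 5), 24.5, 0.5)),
                        c(20, 20, 70), sp)
  g <- build_graph(chain)
  types <- vapply(g$nodes, `[[`, "", "type")
  expect_equal(sum(types == "endpoint"), 2)
  expect_equal(length(g$edges), 1)
  # faithful cover: edge + node voxels = skeleton voxels
  covered <- sort(unique(c(unlist(lapply(g$edges, `[[`, "path")),
                           unlist(lapply(g$nodes, `[[`, "voxels")))))
  expect_equal(covered, seq_along(g$vox))

  # Y shape: 1 junction, 3 endpoints, 3 edges
  c0 <- c(15, 15, 10)
  ypolys <- list(rbind(c0, c0 + c(10, 0, 0)),
                 rbind(c0, c0 + c(-7, 7, 0)),
                 rbind(c0, c0 + c(-7, -7, 0)))
  ypolys <- lapply(ypolys, function(m) { colnames(m) <- c("x", "y", "z"); m })
  gy <- build_graph(chain_volume(ypolys, c(40, 60, 60), sp))
  ty <- vapply(gy$nodes, `[[`, "", "type")
  expect_equal(sum(ty == "junction"), 1)
  expect_equal(sum(ty == "endpoint"), 3)
  expect_equal(length(gy$edges), 3)

  # 4 junctions and 6 end vertices give 9 edges
  gf <- build_graph(four_junction_graph())
  tf <- vapply(gf$nodes, `[[`, "", "type")
  expect_equal(sum(tf == "junction"), 4)
  expect_equal(sum(tf == "endpoint"), 6)
  expect_equal(length(gf$edges), 9)

  # a solid 2x2x2 block is not a thin skeleton
  solid <- array(FALSE, c(6, 6, 6)); solid[2:3, 2:3, 2:3] <- TRUE
  expect_error(build_graph(volume(solid, sp)), "not a thin skeleton")
})

test_that("prune_tails removes short spurs iteratively and is idempotent", {
  sp <- c(0.5, 0.5, 0.5)
  main <- line_pts(c(1, 0, 0), c(55, 20, 10), 100, 0.5)
  spur <- rbind(c(55, 20, 10), c(55, 23, 10))
  colnames(spur) <- c("x", "y", "z")
  g <- build_graph(chain_volume(list(main, spur), c(40, 80, 240), sp))
  expect_equal(length(g$edges), 3)   # spur splits the chain
  pruned <- prune_tails(g, 5)
  expect_equal(length(pruned$edges), 1)
  expect_equal(pruned$edges[[1]]$length_mm, 100, tolerance = 2)
  # fixed point: pruning again changes nothing
  again <- prune_tails(pruned, 5)
  expect_equal(length(again$edges), 1)
  expect_equal(sort(again$vox), sort(pruned$vox))

  # nothing shorter than the threshold: identity
  clean <- build_graph(chain_volume(list(main), c(40, 80, 240), sp))
  expect_equal(sort(prune_tails(clean, 5)$vox), sort(clean$vox))

  # cascade: a spur whose removal exposes a second short tail
  hook <- rbind(c(100, 20, 10), c(103, 20, 10), c(103, 23, 10))
  colnames(hook) <- c("x", "y", "z")
  g2 <- build_graph(chain_volume(list(main, hook), c(40, 80, 240), sp))
  p2 <- prune_tails(g2, 5)
  expect_equal(length(p2$edges), 1)
  expect_equal(p2$edges[[1]]$length_mm, 100, tolerance = 2)
})

test_that("break_junctions yields simple end-to-end edges with the 2 mm trim", {
  # the 4-junction figure decomposes into exactly its 9 end-to-end edges
  gf <- prune_tails(build_graph(four_junction_graph()), 5)
  es <- break_junctions(gf, 2)
  expect_s3_class(es, "edge_set")
  expect_equal(length(es), 9)

  # a single chain passes through unchanged
  sp <- c(0.5, 0.5, 0.5)
  chain <- build_graph(chain_volume(list(line_pts(c(1, 0, 0), c(25, 10, 5), 40, 0.5)),
                                    c(25, 45, 110), sp))
  es1 <- break_junctions(chain, 2)
  expect_equal(length(es1), 1)
  expect_equal(nestweave:::polyline_length(es1$edges[[1]]$pts), 40, tolerance = 0.8)

  # X crossing of two 60 mm chains: 4 edges of about 30 - 2 mm
  c0 <- c(45, 45, 10)
  xp <- list(line_pts(c(1, 0, 0), c0, 60, 0.5),
             line_pts(c(0, 1, 0), c0, 60, 0.5))
  gx <- build_graph(chain_volume(xp, c(25, 180, 180), sp))
  esx <- break_junctions(gx, 2)
  expect_equal(length(esx), 4)
  lens <- vapply(esx$edges, function(e) nestweave:::polyline_length(e$pts), 0)
  expect_true(all(abs(lens - 28) < 1.5))

  # no polyline retains a former junction voxel
  jun_mm <- do.call(rbind, lapply(gx$nodes[vapply(gx$nodes, `[[`, "", "type") == "junction"],
                                  function(n) gx$mm[n$voxels, , drop = FALSE]))
  for (e in esx$edges) {
    dd <- nestweave:::min_cross_distances(e$pts, jun_mm)
    expect_gt(min(dd), 1.9)
  }
})
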