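test_that("decay calibration solves exp(-k d*) = p* exactly", {
  expect_equal(calibrate_decay(300, 0.05), -log(0.05) / 300)
  expect_equal(calibrate_decay(300, 0.05), 0.009986, tolerance = 1e-4)
  expect_equal(calibrate_decay(500, 0.05), 0.005991, tolerance = 1e-4)
  for (d in c(50, 150, 987)) {
    k <- calibrate_decay(d, 0.05)
    expect_equal(exp(-k * d), 0.05)
  }
  expect_error(dispersal_model(-10))
  expect_error(dispersal_model(100, 1))
  expect_error(dispersal_model(100, 0))
})

test_that("corridor least-cost distance matches the hand count", {
  s <- corridor_surface(n_corridor = 10, corridor_cost = 10, res = 2)
  p <- extract_patches(s)
  d <- least_cost_distances(s, p)$d
  expect_equal(d[1, 2], 10 * 2 * 10)   # 10 cells x 2 m x cost 10
  # cost-1 corridor: plain metric distance between patch borders
  s1 <- corridor_surface(n_corridor = 10, corridor_cost = 1, res = 2)
  p1 <- extract_patches(s1)
  expect_equal(least_cost_distances(s1, p1)$d[1, 2], 10 * 2)
})

test_that("least-cost routes detour around high-cost walls", {
  # wall of cost 1000 forces a detour; oracle = exhaustive path enumeration
  g <- matrix(2L, 5, 5)
  g[1, 1] <- 1L
  g[1, 5] <- 1L
  g[1:4, 3] <- 3L
  ct <- cost_table(1:3, c(1, 10, 1000))
  s <- assign_costs(land_use_raster(g, resolution = 2), ct)
  p <- extract_patches(s)
  d <- least_cost_distances(s, p)$d
  cost <- s$cost
  zero <- c(p$cells[[1]], p$cells[[2]])
  oracle <- oracle_least_cost(cost, 2, p$cells[[1]], p$cells[[2]],
                              zero_cells = zero)
  expect_equal(d[1, 2], oracle, tolerance = 1e-12)
  # the detour is strictly longer than the straight-line lower bound
  expect_gt(d[1, 2], 8 * 2 * 10)
})

test_that("least-cost distances equal exhaustive enumeration on random grids", {
  for (seed in 1:6) {
    set.seed(seed)
    g <- matrix(sample(2:4, 25, replace = TRUE, prob = c(0.6, 0.3, 0.1)), 5, 5)
    g[1, 1] <- 1L
    g[5, 5] <- 1L
    ct <- cost_table(1:4, c(1, 10, 100, 1000))
    s <- assign_costs(land_use_raster(g, resolution = 2), ct)
    p <- extract_patches(s)
    if (nrow(p$patches) != 2L) next
    d <- least_cost_distances(s, p)$d
    oracle <- oracle_least_cost(s$cost, 2, p$cells[[1]], p$cells[[2]],
                                zero_cells = unlist(p$cells))
    expect_equal(d[1, 2], oracle, tolerance = 1e-12)
  }
})

test_that("fully ringed nodata isolates a patch with +Inf distance", {
  g <- matrix(2L, 7, 7)
  g[4, 4] <- 1L
  g[3, 3:5] <- -9999L
  g[5, 3:5] <- -9999L
  g[4, 3] <- -9999L
  g[4, 5] <- -9999L
  g[1, 1] <- 1L
  s <- assign_costs(land_use_raster(g), cost_table(1:2, c(1, 10)))
  p <- extract_patches(s)
  expect_equal(nrow(p$patches), 2L)
  led <- least_cost_edge_distances(s, p, cbind(1, 2))
  expect_false(led$reachable)
  expect_equal(led$distance, Inf)
})

test_that("planar graph has Voronoi-adjacency edges, not the complete graph", {
  # three collinear patches: ends joined only through the middle
  g <- matrix(2L, 3, 31)
  g[2, 1:3] <- 1L
  g[2, 15:17] <- 1L
  g[2, 29:31] <- 1L
  s <- assign_costs(land_use_raster(g), cost_table(1:2, c(1, 10)))
  p <- extract_patches(s)
  gr <- build_patch_graph(s, p)
  expect_equal(nrow(gr$edges), 2L)
  expect_false(any(gr$edges$from == 1 & gr$edges$to == 3))

  # effective distance end-to-end = sum of the two edges
  expect_equal(gr$d[1, 3], gr$d[1, 2] + gr$d[2, 3])

  # four patches at square corners: 4 or 5 edges, never the full 6
  g2 <- matrix(2L, 21, 21)
  for (rc in list(c(2, 2), c(2, 20), c(20, 2), c(20, 20)))
    g2[rc[1] + (-1:1), rc[2] + (-1:1)] <- 1L
  s2 <- assign_costs(land_use_raster(g2), cost_table(1:2, c(1, 10)))
  p2 <- extract_patches(s2)
  gr2 <- build_patch_graph(s2, p2)
  expect_gte(nrow(gr2$edges), 4L)
  expect_lte(nrow(gr2$edges), 5L)

  # single patch: no edges
  g3 <- matrix(2L, 5, 5)
  g3[3, 3] <- 1L
  s3 <- assign_costs(land_use_raster(g3), cost_table(1:2, c(1, 10)))
  gr3 <- build_patch_graph(s3, extract_patches(s3))
  expect_equal(nrow(gr3$edges), 0L)
})

test_that("effective distances equal Floyd-Warshall on the edge list", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    m <- sample(seq_len(nrow(all_pairs)), max(n - 1, sample(n:nrow(all_pairs), 1)))
    edges <- data.frame(from = all_pairs[m, 1], to = all_pairs[m, 2],
                        distance = stats::runif(length(m), 10, 500))
    expect_equal(effective_distances(edges, n), oracle_fw(edges, n),
                 tolerance = 1e-12)
  }
  # chain additivity and triangle shortcut
  ch <- data.frame(from = c(1, 2), to = c(2, 3), distance = c(100, 200))
  expect_equal(effective_distances(ch, 3)[1, 3], 300)
  tri <- data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                    distance = c(100, 100, 250))
  expect_equal(effective_distances(tri, 3)[1, 3], 200)
})

test_that("PC matches the brute-force double sum on a 3-patch chain", {
  a <- c(100, 200, 300)
  A <- 1e4
  k <- log(20) / 300
  edges <- data.frame(from = c(1, 2), to = c(2, 3), distance = c(100, 100))
  d <- effective_distances(edges, 3)
  graph <- structure(list(
    nodes = data.frame(id = 1:3, area_m2 = a), edges = edges, d = d, A = A,
    resolution = 2, mode = "planar"), class = "patch_graph")
  model <- structure(list(d_star = 300, p_star = 0.05, k = k),
                     class = "dispersal_model")
  expect_equal(probability_of_connectivity(graph, model),
               oracle_pc(a, d, A, k), tolerance = 1e-12)
  dpc <- delta_pc(graph, model)
  expect_equal(dpc$dPC, oracle_dpc(graph, k), tolerance = 1e-9)
  expect_true(all(dpc$dPC >= 0))
})

test_that("PC limit cases: single full patch gives 1; k -> Inf leaves self terms", {
  g1 <- structure(list(nodes = data.frame(id = 1, area_m2 = 400),
                       edges = data.frame(from = integer(0), to = integer(0),
                                          distance = numeric(0)),
                       d = matrix(0, 1, 1), A = 400, resolution = 2,
                       mode = "planar"), class = "patch_graph")
  m <- dispersal_model(100)
  expect_equal(probability_of_connectivity(g1, m), 1)
  expect_equal(delta_pc(g1, m)$dPC, 100)

  a <- c(100, 300)
  d <- matrix(c(0, 200, 200, 0), 2)
  g2 <- structure(list(nodes = data.frame(id = 1:2, area_m2 = a),
                       edges = data.frame(from = 1, to = 2, distance = 200),
                       d = d, A = 1e4, resolution = 2, mode = "planar"),
                  class = "patch_graph")
  huge_k <- structure(list(d_star = 1, p_star = 1e-300, k = 690),
                      class = "dispersal_model")
  expect_equal(probability_of_connectivity(g2, huge_k), sum(a^2) / 1e8,
               tolerance = 1e-9)
})

test_that("duplicate-symmetric patches get equal dPC", {
  g <- matrix(2L, 11, 21)
  g[5:7, 2:4] <- 1L
  g[5:7, 18:20] <- 1L
  s <- assign_costs(land_use_raster(g), cost_table(1:2, c(1, 10)))
  p <- extract_patches(s)
  gr <- build_patch_graph(s, p)
  dpc <- delta_pc(gr, dispersal_model(100))
  expect_equal(dpc$dPC[1], dpc$dPC[2], tolerance = 1e-9)
})

test_that("PC is monotone: non-increasing in k, non-decreasing in area", {
  set.seed(21)
  rb <- random_blob_surface(21)
  gr <- build_patch_graph(rb$surface, rb$patches)
  ks <- c(0.001, 0.005, 0.02, 0.1)
  pcs <- vapply(ks, function(k) {
    m <- structure(list(d_star = 1, p_star = exp(-k), k = k),
                   class = "dispersal_model")
    probability_of_connectivity(gr, m)
  }, numeric(1))
  expect_true(all(diff(pcs) <= 1e-15))
  expect_true(all(pcs >= 0 & pcs <= 1))
  # growing one patch area increases PC (A fixed)
  gr2 <- gr
  gr2$nodes$area_m2[1] <- gr2$nodes$area_m2[1] * 2
  m <- dispersal_model(100)
  expect_gt(probability_of_connectivity(gr2, m),
            probability_of_connectivity(gr, m))
  # shrinking a distance increases PC
  gr3 <- gr
  gr3$d <- gr$d * 0.5
  expect_gte(probability_of_connectivity(gr3, m),
             probability_of_connectivity(gr, m))
})

test_that("sites inherit the dPC of their containing patch, with snapping", {
  g <- matrix(2L, 9, 21)
  g[2:4, 2:6] <- 1L
  g[6:8, 14:19] <- 1L
  s <- assign_costs(land_use_raster(g, resolution = 2),
                    cost_table(1:2, c(1, 10)))
  p <- extract_patches(s)
  gr <- build_patch_graph(s, p)
  dpc <- delta_pc(gr, dispersal_model(100))
  sites <- data.frame(site = 1:4,
                      x = c(6, 9, 33, 39),
                      y = c(13, 13, 5, 9))
  # sites 1 and 2 in patch 1, site 3 in patch 2, site 4 just outside patch 2
  sc <- site_connectivity(sites, p, dpc, snap_cells = 0)
  expect_equal(sc$patch_id[1:3], c(1L, 1L, 2L))
  expect_equal(sc$dPC[1], sc$dPC[2])
  expect_true(is.na(sc$dPC[4]))
  # within the snap tolerance, site 4 attaches to its nearest patch
  sc2 <- site_connectivity(sites, p, dpc, snap_cells = 2)
  expect_equal(sc2$patch_id[4], 2L)
})
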