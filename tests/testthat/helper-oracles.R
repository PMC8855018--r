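# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's code paths (double sums, Floyd-Warshall, DFS path
# enumeration) so that agreement is informative.

# explicit double-sum PC
oracle_pc <- function(areas, d, A, k) {
  n <- length(areas)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- if (i == j) 1 else if (is.finite(d[i, j])) exp(-k * d[i, j]) else 0
    acc <- acc + areas[i] * areas[j] * p
  }
  acc / A^2
}

# Floyd-Warshall all-pairs shortest paths from an edge list
oracle_fw <- function(edges, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges$from[e]; j <- edges$to[e]; w <- edges$distance[e]
    if (is.finite(w)) {
      d[i, j] <- min(d[i, j], w)
      d[j, i] <- min(d[j, i], w)
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# per-patch dPC by explicit removal + FW + double sum
oracle_dpc <- function(graph, k) {
  n <- nrow(graph$nodes)
  a <- graph$nodes$area_m2
  d <- oracle_fw(graph$edges, n)
  pc <- oracle_pc(a, d, graph$A, k)
  vapply(seq_len(n), function(i) {
    keep <- setdiff(seq_len(n), i)
    if (length(keep) == 0L) return(100)
    e <- graph$edges
    e <- e[e$from != i & e$to != i, , drop = FALSE]
    e$from <- match(e$from, keep)
    e$to <- match(e$to, keep)
    d2 <- oracle_fw(e, length(keep))
    100 * (pc - oracle_pc(a[keep], d2, graph$A, k)) / pc
  }, numeric(1))
}

# exhaustive simple-path enumeration (branch and bound) for the least-cost
# distance between two cell sets on a small grid, using the same step-weight
# convention (mean cell cost x step length, patch cells cost 0) but a fully
# independent implementation
oracle_least_cost <- function(cost, res, cells_a, cells_b, zero_cells = NULL) {
  nr <- nrow(cost); nc <- ncol(cost)
  cst <- cost
  if (!is.null(zero_cells)) cst[zero_cells] <- 0
  best <- Inf
  target <- rep(FALSE, nr * nc); target[cells_b] <- TRUE
  visited <- rep(FALSE, nr * nc)
  dfs <- function(cell, acc) {
    if (acc >= best) return()
    if (target[cell]) { best <<- min(best, acc); return() }
    r <- ((cell - 1) %% nr) + 1; c <- ((cell - 1) %/% nr) + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      nb <- (c2 - 1) * nr + r2
      if (visited[nb] || is.na(cst[nb])) next
      w <- (cst[cell] + cst[nb]) / 2 * res *
        (if (dr != 0 && dc != 0) sqrt(2) else 1)
      visited[nb] <<- TRUE
      dfs(nb, acc + w)
      visited[nb] <<- FALSE
    }
  }
  for (s in cells_a) {
    visited[] <- FALSE
    visited[s] <- TRUE
    dfs(s, 0)
  }
  best
}

# build n x p data whose sample correlation matrix equals `sigma` exactly:
# orthonormalize centred Gaussian columns, then colour with chol(sigma)
make_exact_correlated <- function(n, sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(sigma)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))
  Y <- Q %*% chol(sigma) * sqrt(n - 1)
  as.data.frame(Y)
}

# small two-patch surface: single-cell habitat patches at the two ends of a
# corridor of given cost
corridor_surface <- function(n_corridor = 10, corridor_cost = 10, res = 2) {
  g <- matrix(2L, 1, n_corridor + 2L)
  g[1, 1] <- 1L
  g[1, n_corridor + 2L] <- 1L
  ct <- cost_table(1:2, c(1, corridor_cost),
                   is_habitat = c(TRUE, FALSE), strict = FALSE)
  assign_costs(land_use_raster(g, resolution = res), ct)
}

# random small landscape with a controlled number of habitat blobs; returns
# surface + patches (blob count may collapse if blobs merge)
random_blob_surface <- function(seed, dims = c(30L, 30L), n_blobs = 4L,
                                res = 2) {
  set.seed(seed)
  nr <- dims[1]; nc <- dims[2]
  g <- matrix(2L, nr, nc)
  if (stats::runif(1) < 0.5) g[sample.int(nr, 1), ] <- 3L  # a barrier line
  for (b in seq_len(n_blobs)) {
    r0 <- sample(3:(nr - 2), 1); c0 <- sample(3:(nc - 2), 1)
    h <- sample(1:3, 1); w <- sample(1:3, 1)
    g[max(1, r0 - h):min(nr, r0 + h), max(1, c0 - w):min(nc, c0 + w)] <- 1L
  }
  ct <- cost_table(1:3, c(1, 10, 1000))
  surface <- assign_costs(land_use_raster(g, resolution = res), ct)
  list(surface = surface, patches = extract_patches(surface))
}

# default-size synthetic study, generated once per test run (shared by the
# pipeline and acceptance tests)
.study_cache <- new.env()
cached_default_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- generate_study(synthetic_config(seed = 20260928L))
  .study_cache$study
}

# moderate-size config for tests that need a full but quick study
small_config <- function(seed = 42L) {
  synthetic_config(seed = seed, dims = c(350L, 350L), n_sites = 12L,
                   site_area_range = c(400, 2000), n_filler = 10L,
                   filler_area_range = c(100, 400), n_forest_strips = 3L,
                   n_roads = 2L, n_buildings = 5L, n_shrub_blobs = 8L,
                   fields_nx = 8L, fields_ny = 8L)
}
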