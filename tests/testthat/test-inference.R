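test_that("z-scoring centres, scales and preserves missing values", {
  expect_equal(zscore_scale(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(4, NA, 8, 12)
  z <- zscore_scale(x)
  expect_true(is.na(z[2]))
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_equal(stats::sd(z, na.rm = TRUE), 1)
  # idempotent on already-scaled input
  expect_equal(zscore_scale(z), z, tolerance = 1e-12)
  expect_error(zscore_scale(rep(3, 5), "flat"), "flat")
})

test_that("collinearity screen never co-selects pairs above the threshold", {
  set.seed(14)
  for (i in 1:20) {
    n <- 40
    d <- data.frame(h1 = stats::rnorm(n), h2 = stats::rnorm(n),
                    c1 = stats::rnorm(n), c2 = stats::rnorm(n),
                    l1 = stats::rnorm(n))
    # inject correlation between some candidates
    d$h2 <- d$h1 * 0.8 + d$h2 * 0.3
    d$c2 <- d$c1 * stats::runif(1, 0, 1) + d$c2 * 0.5
    sc <- tryCatch(
      collinearity_screen(d, list(herb = c("h1", "h2"), conn = c("c1", "c2"),
                                  local = "l1")),
      error = function(e) NULL)
    if (is.null(sc)) next
    r <- stats::cor(d[sc$selected])
    expect_lte(max(abs(r[upper.tri(r)])), 0.3)
    expect_equal(sc$max_abs_r, max(abs(r[upper.tri(r)])), tolerance = 1e-12)
  }
})

test_that("screen reproduces the expected retained/excluded split on a
           structured fixture", {
  # correlation structure shaped like the study's candidate table: the two
  # buffer radii strongly correlated, the two dispersal distances strongly
  # correlated, the 100-m buffer too correlated with connectivity, and the
  # retained triple mutually near-independent
  vars <- c("tfi_100", "tfi_300", "dpc_150", "dpc_500", "local")
  sigma <- diag(5)
  dimnames(sigma) <- list(vars, vars)
  sigma["tfi_100", "tfi_300"] <- sigma["tfi_300", "tfi_100"] <- 0.85
  sigma["dpc_150", "dpc_500"] <- sigma["dpc_500", "dpc_150"] <- 0.90
  sigma["tfi_100", "dpc_150"] <- sigma["dpc_150", "tfi_100"] <- 0.45
  sigma["tfi_100", "dpc_500"] <- sigma["dpc_500", "tfi_100"] <- 0.40
  sigma["tfi_300", "dpc_150"] <- sigma["dpc_150", "tfi_300"] <- 0.35
  sigma["tfi_300", "dpc_500"] <- sigma["dpc_500", "tfi_300"] <- 0.20
  sigma["local", vars[1:4]] <- sigma[vars[1:4], "local"] <- 0.10
  d <- make_exact_correlated(35, sigma, seed = 3)
  names(d) <- vars
  sc <- collinearity_screen(
    d, list(herbicide = c("tfi_100", "tfi_300"),
            connectivity = c("dpc_150", "dpc_500"), local = "local"))
  expect_equal(unname(sc$selected),
               c("tfi_300", "dpc_500", "local"))
  excl_pairs <- paste(sc$exclusions$var1, sc$exclusions$var2)
  expect_true("tfi_100 tfi_300" %in% excl_pairs)
  expect_true("dpc_150 dpc_500" %in% excl_pairs)
  expect_lte(sc$max_abs_r, 0.3)
})

test_that("screen edge cases: duplicates, r just over threshold, independence", {
  d <- make_exact_correlated(30, diag(3), seed = 6)
  names(d) <- c("a", "b", "l")
  d$a_dup <- d$a
  sc <- collinearity_screen(d, list(g1 = c("a", "a_dup"), g2 = "b", g3 = "l"))
  expect_length(sc$selected, 3)  # only one of the duplicated pair retained
  expect_true(any(sc$exclusions$r == 1))

  # exact r = 0.31 pair cannot be co-selected; 0.29 can
  s2 <- diag(3)
  s2[1, 2] <- s2[2, 1] <- 0.31
  d2 <- make_exact_correlated(35, s2, seed = 5)
  names(d2) <- c("x", "y", "l")
  expect_error(collinearity_screen(d2, list(g1 = "x", g2 = "y", g3 = "l")),
               "0.3")
  s3 <- diag(3)
  s3[1, 2] <- s3[2, 1] <- 0.29
  d3 <- make_exact_correlated(35, s3, seed = 5)
  names(d3) <- c("x", "y", "l")
  sc3 <- collinearity_screen(d3, list(g1 = "x", g2 = "y", g3 = "l"))
  expect_equal(unname(sc3$selected), c("x", "y", "l"))
})

test_that("OLS fit equals the normal-equation oracle, with sandy-vs-clay coding", {
  set.seed(31)
  n <- 30
  d <- data.frame(
    herb = stats::rnorm(n), conn = stats::rnorm(n),
    soil = sample(c("clay", "sandy"), n, replace = TRUE))
  d$y <- 5 - 2 * scale(d$herb)[, 1] + 3 * scale(d$conn)[, 1] +
    4 * (d$soil == "sandy") + stats::rnorm(n, 0, 0.5)
  fit <- fit_gaussian_lm(d, "y", "herb", "conn", "soil")
  X <- cbind(1, scale(d$herb)[, 1], scale(d$conn)[, 1],
             as.numeric(d$soil == "sandy"))
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$coefficients$beta, as.numeric(beta_hat), tolerance = 1e-10)
  # SEs from the classical covariance formula
  res <- d$y - X %*% beta_hat
  s2 <- sum(res^2) / (n - 4)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit$coefficients$se, as.numeric(se), tolerance = 1e-10)
  # contrast direction is sandy minus clay
  expect_match(fit$coefficients$term[4], "sandy")
  expect_gt(fit$coefficients$beta[4], 0)
})

test_that("perfect linear data give exact coefficients and zero residuals", {
  d <- data.frame(x = 1:10, z = stats::rnorm(10), w = stats::rnorm(10))
  d$y <- 2 * d$x
  fit <- suppressWarnings(  # lm warns on an essentially perfect fit
    fit_gaussian_lm(d, "y", "x", "z", "w", scale_predictors = FALSE))
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "x"], 2,
               tolerance = 1e-10)
  expect_equal(unname(fit$residuals), rep(0, 10), tolerance = 1e-10)
})

test_that("complete-case handling records n and drops missing rows", {
  set.seed(12)
  d <- data.frame(y = stats::rnorm(20), h = stats::rnorm(20),
                  c = stats::rnorm(20), l = stats::rnorm(20))
  d$h[c(3, 7)] <- NA
  fit <- fit_gaussian_lm(d, "y", "h", "c", "l")
  expect_equal(fit$n, 18)
  expect_error(fit_gaussian_lm(d[1:6, ], "y", "h", "c", "l"), "complete cases")
  d$dup <- d$c
  expect_error(fit_gaussian_lm(d, "y", "c", "dup", "l"), "rank")
})

test_that("OLS slope scales inversely with predictor scaling", {
  set.seed(44)
  d <- data.frame(y = stats::rnorm(25), h = stats::rnorm(25),
                  c = stats::rnorm(25), l = stats::rnorm(25))
  f1 <- fit_gaussian_lm(d, "y", "h", "c", "l", scale_predictors = FALSE)
  d2 <- d; d2$h <- d2$h * 10
  f2 <- fit_gaussian_lm(d2, "y", "h", "c", "l", scale_predictors = FALSE)
  expect_equal(f2$coefficients$beta[2], f1$coefficients$beta[2] / 10,
               tolerance = 1e-10)
  # with z-scoring, scaling the raw predictor changes nothing
  f3 <- fit_gaussian_lm(d, "y", "h", "c", "l")
  f4 <- fit_gaussian_lm(d2, "y", "h", "c", "l")
  expect_equal(f4$coefficients$beta, f3$coefficients$beta, tolerance = 1e-10)
})

test_that("pearson matrix is symmetric, unit-diagonal, with exact t-test flags", {
  d <- data.frame(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  pm <- pearson_matrix(d)
  expect_equal(pm$r["a", "b"], 0.6, tolerance = 1e-12)
  expect_equal(pm$r, t(pm$r))
  expect_equal(unname(diag(pm$r)), c(1, 1))
  d2 <- data.frame(x = stats::rnorm(20))
  d2$y <- -d2$x
  d2$z <- d2$x
  pm2 <- pearson_matrix(d2)
  expect_equal(pm2$r["x", "y"], -1, tolerance = 1e-12)
  expect_equal(pm2$r["x", "z"], 1, tolerance = 1e-12)
  expect_true(pm2$significant["x", "y"])
  # p values match cor.test directly
  set.seed(10)
  d3 <- data.frame(u = stats::rnorm(15), v = stats::rnorm(15))
  d3$v[1:3] <- NA
  pm3 <- pearson_matrix(d3)
  ct <- stats::cor.test(d3$u[-(1:3)], d3$v[-(1:3)])
  expect_equal(pm3$p["u", "v"], ct$p.value, tolerance = 1e-12)
  expect_equal(pm3$n["u", "v"], 12)
})

test_that("Moran's I matches the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(17)
  n <- 25
  coords <- cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
  x <- stats::rnorm(n)
  w <- 1 / as.matrix(stats::dist(coords))
  diag(w) <- 0
  # ape row-standardizes the weights internally; feed the standardized
  # matrix to our statistic so both compute the same quantity
  wst <- w / rowSums(w)
  ref <- ape::Moran.I(x, w)
  expect_equal(moran_i(x, wst), ref$observed, tolerance = 1e-10)
})

test_that("diagnostics flag influence and heteroscedasticity, Moran p is calibrated", {
  set.seed(23)
  n <- 30
  d <- data.frame(h = stats::rnorm(n), c = stats::rnorm(n),
                  l = stats::rnorm(n))
  d$y <- 1 + d$h + stats::rnorm(n)
  coords <- data.frame(x = stats::runif(n, 0, 1000),
                       y = stats::runif(n, 0, 1000))
  fit <- fit_gaussian_lm(d, "y", "h", "c", "l")
  dg <- model_diagnostics(fit, coords, n_perm = 99, seed = 1)
  expect_equal(nrow(dg$cooks), n)
  expect_true(dg$moran$p_perm > 0 && dg$moran$p_perm <= 1)

  # duplicating one extreme site raises its influence
  d2 <- d
  d2$y[1] <- d2$y[1] + 15
  fit2 <- fit_gaussian_lm(d2, "y", "h", "c", "l")
  dg2 <- model_diagnostics(fit2, coords, n_perm = 9, seed = 1)
  expect_gt(dg2$cooks$cooks[1], dg$cooks$cooks[1])
  expect_true(dg2$cooks$flag[1])

  # heteroscedastic data: |residual| grows with fitted -> positive slope,
  # small p
  set.seed(29)
  n2 <- 120
  dh <- data.frame(h = stats::rnorm(n2), c = stats::rnorm(n2),
                   l = stats::rnorm(n2))
  dh$y <- 5 + 3 * dh$h + stats::rnorm(n2, 0, 0.2 + 1.5 * pmax(dh$h + 2, 0))
  fith <- fit_gaussian_lm(dh, "y", "h", "c", "l")
  dgh <- model_diagnostics(fith, cbind(stats::runif(n2), stats::runif(n2)),
                           n_perm = 9, seed = 2)
  expect_gt(dgh$spread_slope, 0)
  expect_lt(dgh$spread_p, 0.05)

  # i.i.d. residuals: permutation p shows no systematic rejection at 5%
  set.seed(37)
  rej <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    di <- data.frame(h = stats::rnorm(25), c = stats::rnorm(25),
                     l = stats::rnorm(25))
    di$y <- stats::rnorm(25)
    fi <- fit_gaussian_lm(di, "y", "h", "c", "l")
    dgi <- model_diagnostics(fi, cbind(stats::runif(25), stats::runif(25)),
                             n_perm = 99)
    if (dgi$moran$p_perm < 0.05) rej <- rej + 1
  }
  expect_lt(rej / reps, 0.15)
})
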