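#' z-score scaling
#'
#' Centre and scale to unit sample standard deviation (n - 1 denominator)
#' over the non-missing entries; missing values are preserved. Continuous
#' explanatory variables are scaled this way before model fitting so that
#' coefficients are comparable across predictors.
#'
#' @param x numeric vector.
#' @param name variable name used in error messages.
#' @return scaled vector.
#' @export
zscore_scale <- function(x, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  if (sum(ok) < 2L)
    stop("cannot scale `", name, "`: fewer than 2 non-missing values")
  s <- stats::sd(x[ok])
  if (s == 0) stop("cannot scale `", name, "`: zero spread")
  (x - mean(x[ok])) / s
}

#' Collinearity screen: one variable per category
#'
#' Candidate explanatory variables come grouped into categories (herbicide
#' pressure, connectivity, local conditions). The screen selects exactly one
#' variable per category such that every pairwise Pearson correlation among
#' the selected set satisfies |r| <= threshold; variables correlated above
#' the threshold are never co-selected. When several feasible sets exist the
#' set minimizing the maximum pairwise |r| wins, with ties broken by category
#' order then name order. Every rejected pair is logged with its correlation.
#'
#' @param data data.frame holding all candidate variables.
#' @param groups named list: category -> character vector of column names,
#'   in priority order.
#' @param threshold maximum tolerated |r| (default 0.3).
#' @param relax when no set passes the threshold: `FALSE` (default) raises an
#'   error listing the offending correlations; `TRUE` returns the minimax set
#'   anyway, flagged `feasible = FALSE` (used by the pipeline so a run on
#'   unluckily correlated data still completes, with the violation logged).
#' @return list `selected` (named character, one per category), `max_abs_r`,
#'   `feasible`, `exclusions` (data.frame `var1`, `var2`, `r` of
#'   over-threshold pairs), `candidates_r` (full candidate correlation
#'   matrix), `dropped` (unusable candidates).
#' @export
collinearity_screen <- function(data, groups, threshold = 0.3,
                                relax = FALSE) {
  vars <- unlist(groups, use.names = FALSE)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("screen candidates not in data: ", paste(miss, collapse = ", "))
  # candidates without usable data (all missing or constant) cannot enter
  usable <- vapply(vars, function(v) {
    x <- data[[v]]
    sum(!is.na(x)) >= 3L && stats::sd(x, na.rm = TRUE) > 0
  }, TRUE)
  dropped <- vars[!usable]
  groups <- lapply(groups, function(g) setdiff(g, dropped))
  empty <- names(groups)[vapply(groups, length, 1L) == 0L]
  if (length(empty))
    stop("no usable screen candidate left in category: ",
         paste(empty, collapse = ", "))
  vars <- unlist(groups, use.names = FALSE)
  suppressWarnings(
    r <- stats::cor(data[vars], use = "pairwise.complete.obs"))
  ij <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  exclusions <- data.frame(var1 = vars[ij[, 1]], var2 = vars[ij[, 2]],
                           r = r[ij])
  combos <- expand.grid(rev(lapply(groups, seq_along)),
                        KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(groups)),
                                                drop = FALSE]
  names(combos) <- names(groups)
  best <- NULL; best_max <- Inf
  fallback <- NULL; fallback_max <- Inf
  for (i in seq_len(nrow(combos))) {
    sel <- mapply(function(g, k) g[k], groups, unlist(combos[i, ]))
    pair_r <- r[sel, sel, drop = FALSE]
    m <- if (length(sel) > 1L) max(abs(pair_r[upper.tri(pair_r)])) else 0
    if (is.na(m)) next  # a pair with no overlapping observations
    if (m <= threshold && m < best_max - 1e-15) {
      best <- sel; best_max <- m
    }
    if (m < fallback_max - 1e-15) {
      fallback <- sel; fallback_max <- m
    }
  }
  if (is.null(best) && !(relax && !is.null(fallback)))
    stop("no feasible variable set with all pairwise |r| <= ", threshold,
         "; offending correlations:\n",
         paste(sprintf("  %s ~ %s: r = %.3f", exclusions$var1,
                       exclusions$var2, exclusions$r), collapse = "\n"))
  feasible <- !is.null(best)
  if (!feasible) { best <- fallback; best_max <- fallback_max }
  list(selected = best, max_abs_r = best_max, feasible = feasible,
       exclusions = exclusions, candidates_r = r, dropped = dropped)
}

#' Fixed three-predictor Gaussian linear model
#'
#' Ordinary least squares fit of
#' `response ~ herbicide + connectivity + local`, the fixed structure used
#' for every community response (one landscape herbicide variable, one
#' landscape connectivity variable, one local variable; no more, to avoid
#' overfitting at n ~ 35). Continuous predictors are z-scored; a categorical
#' local variable (soil) is coded with `"clay"` as the reference level so the
#' reported contrast reads "sandy versus clay". Rows with any missing input
#' are dropped (complete cases) and the n used is recorded.
#'
#' @param data site table.
#' @param response response column name.
#' @param herbicide,connectivity,local predictor column names.
#' @param scale_predictors z-score continuous predictors (default TRUE).
#' @return object of class `model_fit`: `coefficients` (data.frame `term`,
#'   `beta`, `se`, `t`, `p`), `n`, `residuals`, `fitted`, `lm` (the underlying
#'   [stats::lm] object), `spec`.
#' @export
fit_gaussian_lm <- function(data, response, herbicide, connectivity, local,
                            scale_predictors = TRUE) {
  vars <- c(response, herbicide, connectivity, local)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("model variables not in data: ",
                         paste(miss, collapse = ", "))
  d <- data[vars]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) <= 5L)
    stop("too few complete cases (", nrow(d), ") to fit 3 slopes + intercept")
  for (v in c(herbicide, connectivity, local)) {
    if (is.numeric(d[[v]])) {
      if (scale_predictors) d[[v]] <- zscore_scale(d[[v]], v)
    } else {
      d[[v]] <- factor(d[[v]])
      if ("clay" %in% levels(d[[v]]))
        d[[v]] <- stats::relevel(d[[v]], ref = "clay")
    }
  }
  f <- stats::as.formula(paste(response, "~",
                               paste(c(herbicide, connectivity, local),
                                     collapse = " + ")))
  fit <- stats::lm(f, data = d)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design matrix")
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(sm), beta = sm[, 1],
                              se = sm[, 2], t = sm[, 3], p = sm[, 4],
                              row.names = NULL),
    n = nrow(d), residuals = stats::residuals(fit),
    fitted = stats::fitted(fit), lm = fit,
    spec = list(response = response, herbicide = herbicide,
                connectivity = connectivity, local = local,
                rows_used = which(keep))),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %s ~ %s + %s + %s  (n = %d)\n", x$spec$response,
              x$spec$herbicide, x$spec$connectivity, x$spec$local, x$n))
  print(format(x$coefficients, digits = 3))
  invisible(x)
}

#' Pairwise Pearson correlation report
#'
#' Pairwise-complete Pearson correlations across a set of community metrics,
#' with per-pair n and a significance flag from the exact t transform
#' (`t = r sqrt((n-2)/(1-r^2))`, df = n - 2, two-sided) at the given level.
#'
#' @param metrics data.frame of numeric columns (one row per site).
#' @param level significance level for the flag (default 0.01).
#' @return object of class `correlation_report`: matrices `r`, `n`, `p`,
#'   logical `significant`, plus `level`.
#' @export
pearson_matrix <- function(metrics, level = 0.01) {
  metrics <- metrics[vapply(metrics, is.numeric, TRUE)]
  m <- ncol(metrics)
  r <- diag(1, m); n <- matrix(NA_real_, m, m); p <- matrix(NA_real_, m, m)
  dimnames(r) <- dimnames(n) <- dimnames(p) <-
    list(names(metrics), names(metrics))
  diag(n) <- colSums(!is.na(metrics))
  diag(p) <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ok <- !is.na(metrics[[i]]) & !is.na(metrics[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L || stats::sd(metrics[[i]][ok]) == 0 ||
        stats::sd(metrics[[j]][ok]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(metrics[[i]][ok], metrics[[j]][ok],
                          method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, n = n, p = p, significant = !is.na(p) & p < level,
                 level = level),
            class = "correlation_report")
}

#' Regression diagnostics
#'
#' Numeric counterparts of the usual graphical model checks: residual vs
#' fitted table with a spread-vs-fitted slope statistic (|residual| regressed
#' on fitted values, flagging heteroscedasticity), Cook's distances (flagged
#' above 4/n), and Moran's I of the residuals under inverse-distance weights
#' with a permutation p value (spatial autocorrelation check).
#'
#' @param fit a `model_fit`.
#' @param coords data.frame or matrix of site coordinates (`x`, `y`), one row
#'   per row of the data used to fit (rows dropped as incomplete are ignored
#'   automatically when `coords` covers the full table).
#' @param n_perm number of residual permutations (default 199).
#' @param seed optional seed for the permutation draw.
#' @return list `residual_table`, `spread_slope`, `spread_p`, `cooks`
#'   (data.frame with flags), `moran` (list `I`, `p_perm`).
#' @export
model_diagnostics <- function(fit, coords, n_perm = 199L, seed = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  coords <- as.matrix(coords)
  if (nrow(coords) != fit$n) {
    if (nrow(coords) >= max(fit$spec$rows_used))
      coords <- coords[fit$spec$rows_used, , drop = FALSE]
    else stop("coords rows do not match the fitted data")
  }
  res <- unname(fit$residuals); fitted <- unname(fit$fitted)
  sl <- stats::lm(abs(res) ~ fitted)
  sp <- summary(sl)$coefficients
  cooks <- stats::cooks.distance(fit$lm)
  w <- 1 / as.matrix(stats::dist(coords))
  diag(w) <- 0
  w[!is.finite(w)] <- 0
  if (!is.null(seed)) set.seed(seed)
  obs <- moran_i(res, w)
  perm <- replicate(n_perm, moran_i(sample(res), w))
  list(residual_table = data.frame(fitted = fitted, residual = res),
       spread_slope = sp[2, 1], spread_p = sp[2, 4],
       cooks = data.frame(row = fit$spec$rows_used, cooks = unname(cooks),
                          flag = unname(cooks) > 4 / fit$n),
       moran = list(I = obs,
                    p_perm = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)))
}

#' Moran's I statistic
#'
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `W` the total weight. Used on model residuals with
#' inverse-distance weights.
#'
#' @param x numeric vector.
#' @param w weight matrix (zero diagonal).
#' @return Moran's I.
#' @export
moran_i <- function(x, w) {
  z <- x - mean(x)
  n <- length(z)
  (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
}
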