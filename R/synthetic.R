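#' Configuration for the synthetic study generator
#'
#' Defaults are sized to the study design the package targets: 35 small
#' semi-natural sites (0.1-1 ha) regularly scattered in an agricultural
#' matrix mapped at 2-m resolution, field polygons carrying herbicide
#' treatment-frequency indices in [0, 2.09], plant abundances as
#' quadrat-occupancy counts (0-10 of 10 quadrats), insect abundances as
#' transect counts, and trait tables with realistic missingness. Effect
#' sizes `beta = (intercept, herbicide, connectivity, local)` and noise
#' standard deviations are the study-scale values (see the methods
#' vignette for their derivation); they define the ground truth embedded in
#' every generated community.
#'
#' @param seed integer seed; fixes all randomness end to end.
#' @param dims raster dimensions (rows, cols).
#' @param resolution cell size in metres.
#' @param n_sites number of study sites (each inside its own habitat patch).
#' @param site_area_range habitat patch area range for sites, m2.
#' @param n_filler,filler_area_range additional site-free habitat patches
#'   (they dilute per-patch importance, as in a real landscape).
#' @param n_forest_strips,n_roads,n_buildings,n_shrub_blobs counts of
#'   barrier / matrix features.
#' @param tfi_range uniform range of field herbicide TFI values.
#' @param tfi_na_rate fraction of fields with unknown TFI (beyond parcels
#'   dropped for overlapping habitat).
#' @param fields_nx,fields_ny field tiling granularity.
#' @param p_sandy probability a site sits on sandy (vs clay) soil.
#' @param responses list per taxon of response truths (`beta`, `sigma`).
#' @param cwm_targets list per taxon of trait CWM gradients.
#' @param pools species pool sizes per taxon.
#' @param rank_abundance_sd lognormal sd of the rank-abundance shape
#'   (0 = equal expected abundances).
#' @param evenness optional target evenness; `1` forces equal within-site
#'   abundances (construction check).
#' @param genus_rate,unident_rate per-taxon probability that a record is
#'   only genus-level / unidentified.
#' @param trait_missing per-taxon named missingness rates for species trait
#'   values.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    dims = c(500L, 500L),
    resolution = 2,
    n_sites = 35L,
    site_area_range = c(1000, 10000),
    n_filler = 40L,
    filler_area_range = c(100, 800),
    n_forest_strips = 5L,
    n_roads = 4L,
    n_buildings = 12L,
    n_shrub_blobs = 20L,
    tfi_range = c(0, 2.09),
    tfi_na_rate = 0.12,
    fields_nx = 12L,
    fields_ny = 12L,
    p_sandy = 20 / 32,
    responses = NULL,
    cwm_targets = NULL,
    pools = c(plants = 147L, rhopalocera = 32L, orthoptera = 17L),
    rank_abundance_sd = 1,
    evenness = NULL,
    genus_rate = c(plants = 0.05, rhopalocera = 0.05, orthoptera = 0.12),
    unident_rate = c(plants = 0, rhopalocera = 0.01, orthoptera = 0.16),
    trait_missing = list(
      plants = c(dispersal = 5 / 147, specialization = 12 / 147,
                 pollination = 1 / 147),
      rhopalocera = c(dispersal = 0, specialization = 0),
      orthoptera = c(dispersal = 0, specialization = 0))) {
  if (is.null(responses)) responses <- default_truth()
  if (is.null(cwm_targets)) cwm_targets <- default_cwm_targets()
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Ground-truth effect sizes embedded by the generator
#'
#' One entry per taxon and response: `beta` is
#' `(intercept, herbicide, connectivity, local)` on the scale of z-scored
#' continuous predictors (the soil contrast is the unscaled sandy-vs-clay
#' indicator), `sigma` the Gaussian noise sd of the site-level expectation.
#'
#' @return nested list, `truth[[taxon]][[response]]`.
#' @export
default_truth <- function() {
  list(
    plants = list(
      richness  = list(beta = c(16.57, -2.08, 1.77, 6.30), sigma = 5.6),
      abundance = list(beta = c(92.35, -15.04, 15.13, 33.72), sigma = 30)),
    rhopalocera = list(
      richness  = list(beta = c(6.36, -0.58, -0.08, 0.50), sigma = 2.7),
      abundance = list(beta = c(27.20, -8.84, 9.27, 2.67), sigma = 19)),
    orthoptera = list(
      richness  = list(beta = c(4.54, 0.92, -0.38, -0.18), sigma = 1.7),
      abundance = list(beta = c(20.21, -0.53, -3.10, 0.63), sigma = 12)))
}

#' @rdname default_truth
#' @export
default_cwm_targets <- function() {
  list(
    plants = list(
      dispersal      = c(1.01, 0.08, -0.09, -0.09),
      specialization = c(18.13, 0.26, 0.12, 0.05),
      pollination    = c(45.48, -4.46, 0.30, 2.05)),
    rhopalocera = list(
      dispersal      = c(2.74, -0.07, -0.02, 0.05),
      specialization = c(1.13, -0.03, 0.04, 0.02)),
    orthoptera = list(
      specialization = c(0.18, -0.01, 0.08, 0.16)))
}

# grow a connected blob of `n_cells` cells around (r0, c0), staying inside
# the box [rmin,rmax]x[cmin,cmax]; returns linear (column-major) indices
.grow_blob <- function(r0, c0, n_cells, nr, nc, rmin = 1L, rmax = nr,
                       cmin = 1L, cmax = nc) {
  bnr <- rmax - rmin + 1L; bnc <- cmax - cmin + 1L
  mem <- matrix(FALSE, bnr, bnc)
  start <- (c0 - cmin) * bnr + (r0 - rmin + 1L)
  mem[start] <- TRUE
  cells <- integer(n_cells)
  cells[1] <- start; ncur <- 1L
  frontier <- start
  while (ncur < n_cells && length(frontier) > 0L) {
    i <- sample.int(length(frontier), 1L)
    f <- frontier[i]
    fr <- ((f - 1L) %% bnr) + 1L; fc <- ((f - 1L) %/% bnr) + 1L
    nr_ <- fr + c(-1L, 1L, 0L, 0L); nc_ <- fc + c(0L, 0L, -1L, 1L)
    ok <- nr_ >= 1L & nr_ <= bnr & nc_ >= 1L & nc_ <= bnc
    cand <- (nc_[ok] - 1L) * bnr + nr_[ok]
    cand <- cand[!mem[cand]]
    if (length(cand) == 0L) {
      frontier <- frontier[-i]
      next
    }
    new <- cand[sample.int(length(cand), 1L)]
    mem[new] <- TRUE
    ncur <- ncur + 1L
    cells[ncur] <- new
    frontier <- c(frontier, new)
  }
  cells <- cells[seq_len(ncur)]
  gr <- ((cells - 1L) %% bnr) + rmin
  gc <- ((cells - 1L) %/% bnr) + cmin
  (gc - 1L) * nr + gr
}

#' Generate a synthetic agricultural landscape
#'
#' Builds a categorical land-use raster (grassland habitat blobs in a crop
#' matrix, with forest strips, roads, buildings and shrub patches), places
#' one site inside each of `n_sites` habitat patches laid out on a jittered
#' regular grid, and tiles the extent with rectangular field polygons
#' carrying herbicide TFI draws (fields overlapping habitat, plus a random
#' fraction, have unknown TFI). Deterministic for a given seed.
#'
#' @param config a [synthetic_config()].
#' @param seed optional override of `config$seed`.
#' @return list `raster` ([land_use_raster()]), `sites` (data.frame `site`,
#'   `x`, `y`), `fields` ([field_set()]), `site_cells` (seed cell per site).
#' @export
generate_landscape <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  nr <- config$dims[1]; nc <- config$dims[2]; res <- config$resolution
  g <- matrix(2L, nr, nc)                       # crop matrix

  for (i in seq_len(config$n_forest_strips)) {  # forest barriers
    wdt <- sample(2:4, 1)
    if (stats::runif(1) < 0.5) {
      r0 <- sample.int(nr - wdt, 1)
      g[r0:(r0 + wdt - 1L), ] <- 3L
    } else {
      c0 <- sample.int(nc - wdt, 1)
      g[, c0:(c0 + wdt - 1L)] <- 3L
    }
  }
  for (i in seq_len(config$n_roads)) {
    if (stats::runif(1) < 0.5) g[sample.int(nr, 1), ] <- 5L
    else g[, sample.int(nc, 1)] <- 5L
  }
  for (i in seq_len(config$n_buildings)) {
    r0 <- sample.int(nr - 4L, 1); c0 <- sample.int(nc - 4L, 1)
    g[r0:(r0 + sample(2:4, 1)), c0:(c0 + sample(2:4, 1))] <- 4L
  }
  for (i in seq_len(config$n_shrub_blobs)) {
    idx <- .grow_blob(sample.int(nr, 1), sample.int(nc, 1),
                      sample(20:80, 1), nr, nc)
    g[idx] <- 6L
  }

  # jittered regular grid of site patch seeds
  n_tot <- config$n_sites
  kx <- ceiling(sqrt(n_tot * nc / nr))
  ky <- ceiling(n_tot / kx)
  if (kx * ky < n_tot) stop("infeasible site placement")
  sx <- nc / kx; sy <- nr / ky
  max_cells <- floor(max(config$site_area_range) / res^2)
  half_box <- floor(min(sx, sy) / 2) - 1L
  if (half_box^2 * 4 < max_cells * 1.2)
    stop("too many sites for the habitat available: shrink site areas or grid")
  centres <- expand.grid(ix = seq_len(kx), iy = seq_len(ky))
  centres <- centres[seq_len(n_tot), , drop = FALSE]
  site_cells <- integer(n_tot)
  site_patch_cells <- vector("list", n_tot)
  for (s in seq_len(n_tot)) {
    c0 <- round((centres$ix[s] - 0.5) * sx + stats::runif(1, -0.15, 0.15) * sx)
    r0 <- round((centres$iy[s] - 0.5) * sy + stats::runif(1, -0.15, 0.15) * sy)
    r0 <- min(max(r0, half_box + 1L), nr - half_box)
    c0 <- min(max(c0, half_box + 1L), nc - half_box)
    area <- stats::runif(1, config$site_area_range[1], config$site_area_range[2])
    idx <- .grow_blob(r0, c0, round(area / res^2), nr, nc,
                      rmin = r0 - half_box, rmax = r0 + half_box,
                      cmin = c0 - half_box, cmax = c0 + half_box)
    g[idx] <- 1L
    site_cells[s] <- (c0 - 1L) * nr + r0
    site_patch_cells[[s]] <- idx
  }
  for (i in seq_len(config$n_filler)) {        # site-free habitat
    r0 <- sample.int(nr, 1); c0 <- sample.int(nc, 1)
    area <- stats::runif(1, config$filler_area_range[1],
                         config$filler_area_range[2])
    idx <- .grow_blob(r0, c0, round(area / res^2), nr, nc)
    g[idx] <- 1L
  }

  raster <- land_use_raster(g, resolution = res, origin = c(0, 0))
  rows <- ((site_cells - 1L) %% nr) + 1L
  cols <- ((site_cells - 1L) %/% nr) + 1L
  sites <- data.frame(site = seq_len(n_tot),
                      x = (cols - 0.5) * res,
                      y = (nr - rows + 0.5) * res)

  # rectangular field tiling with TFI draws
  xb <- sort(c(0, stats::runif(config$fields_nx - 1L, 0.05, 0.95), 1)) * nc * res
  polys <- list(); tfi <- numeric(0)
  for (i in seq_len(config$fields_nx)) {
    yb <- sort(c(0, stats::runif(config$fields_ny - 1L, 0.05, 0.95), 1)) * nr * res
    for (j in seq_len(config$fields_ny)) {
      p <- cbind(c(xb[i], xb[i + 1], xb[i + 1], xb[i]),
                 c(yb[j], yb[j], yb[j + 1], yb[j + 1]))
      polys[[length(polys) + 1L]] <- p
      # habitat fraction inside the rectangle (from the raster)
      c1 <- max(1L, floor(xb[i] / res) + 1L); c2 <- min(nc, ceiling(xb[i + 1] / res))
      r2 <- min(nr, nr - floor(yb[j] / res)); r1 <- max(1L, nr - ceiling(yb[j + 1] / res) + 1L)
      hfrac <- mean(g[r1:r2, c1:c2] == 1L)
      tfi <- c(tfi, if (hfrac > 0.3 || stats::runif(1) < config$tfi_na_rate)
        NA_real_ else stats::runif(1, config$tfi_range[1], config$tfi_range[2]))
    }
  }
  list(raster = raster, sites = sites, fields = field_set(polys, tfi),
       site_cells = site_cells)
}

#' Generate local site covariates
#'
#' Soil type (sandy vs clay), moisture class (1-3), four per-visit flowering
#' covers, and the three herbaceous height-class covers, drawn around the
#' descriptive statistics of the emulated study design.
#'
#' @param config a [synthetic_config()].
#' @param seed optional override (`config$seed + 1` by default so the draws
#'   do not overlap the landscape stream).
#' @return data.frame one row per site.
#' @export
generate_local_covariates <- function(config, seed = config$seed + 1L) {
  set.seed(seed)
  n <- config$n_sites
  soil <- sample(c("sandy", "clay"), n, replace = TRUE,
                 prob = c(config$p_sandy, 1 - config$p_sandy))
  moisture <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
  fl_mean <- pmin(pmax(stats::rnorm(n, 12.89, 8.80), 0), 60)
  visits <- t(vapply(fl_mean, function(m)
    pmin(pmax(stats::rnorm(4, m, 3), 0), 100), numeric(4)))
  low <- pmin(pmax(stats::rnorm(n, 12.06, 16.63), 0), 70)
  high <- pmin(pmax(stats::rnorm(n, 58.71, 26.88), 0), 95)
  medium <- pmin(pmax(stats::rnorm(n, 20, 8), 0), pmax(100 - low - high, 0))
  data.frame(site = seq_len(n), soil = soil, moisture = moisture,
             floral_v1 = visits[, 1], floral_v2 = visits[, 2],
             floral_v3 = visits[, 3], floral_v4 = visits[, 4],
             floral = rowMeans(visits),
             cover_low = low, cover_medium = medium, cover_high = high)
}

# z-score with NA -> 0 (mean): the generative model uses the available
# exposure information; sites with unknown exposure sit at the average.
.gen_z <- function(x) {
  z <- rep(0, length(x))
  ok <- !is.na(x)
  if (sum(ok) >= 2L && stats::sd(x[ok]) > 0)
    z[ok] <- (x[ok] - mean(x[ok])) / stats::sd(x[ok])
  z
}

# synthetic species pool with names, genera and traits for one taxon
.make_pool <- function(taxon, config) {
  n <- config$pools[[taxon]]
  n_gen <- max(2L, round(n / 2.5))
  genus <- sprintf("%sGenus%02d", toupper(substr(taxon, 1, 1)),
                   sample.int(n_gen, n, replace = TRUE))
  name <- sprintf("%s species%03d", genus, seq_len(n))
  if (taxon == "plants") {
    traits <- data.frame(
      taxon = name,
      dispersal = pmin(pmax(stats::rlnorm(n, log(0.8), 0.9), 0.1), 25),
      specialization = stats::runif(n, 8.3, 24.3),
      pollination = stats::runif(n, 0, 100))
  } else if (taxon == "rhopalocera") {
    traits <- data.frame(
      taxon = name,
      dispersal = sample(1:3, n, replace = TRUE, prob = c(0.05, 0.25, 0.7)),
      specialization = sample(1:4, n, replace = TRUE,
                              prob = c(0.6, 0.3, 0.08, 0.02)))
  } else {
    traits <- data.frame(
      taxon = name,
      dispersal = sample(1:3, n, replace = TRUE, prob = c(0.1, 0.3, 0.6)),
      specialization = sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2)))
  }
  mr <- config$trait_missing[[taxon]]
  for (tc in names(mr)) if (mr[[tc]] > 0)
    traits[[tc]][stats::runif(n) < mr[[tc]]] <- NA
  traits
}

#' Generate site communities and trait tables for one taxon
#'
#' Site-level expected richness and abundance follow the embedded linear
#' model `mu = b0 + b_herb z(TFI) + b_conn z(dPC) + b_local local` with
#' Gaussian noise; species identities and abundances are then drawn to
#' realize those totals under a lognormal rank-abundance shape, with
#' species-selection and allocation weights tilted toward the site's target
#' community-weighted mean traits (so CWM responses carry their own
#' gradients). Plant abundances are capped at quadrat semantics (0-10);
#' records are degraded to genus-level or unidentified at the configured
#' rates. Negative or sub-richness site totals are truncated and logged.
#'
#' @param config a [synthetic_config()].
#' @param covariates data.frame with one row per site holding `tfi`, `dpc`
#'   and `local` columns for this taxon (see [generate_study()]).
#' @param taxon `"plants"`, `"rhopalocera"` or `"orthoptera"`.
#' @param seed seed for this taxon's stream.
#' @return list `records` (long community data.frame), `traits`, `truth`
#'   (beta/sigma used), `expected` (site-level latent expectations and
#'   realized targets), `log` (character vector of truncation events).
#' @export
generate_communities <- function(config, covariates, taxon, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  taxa <- c("plants", "rhopalocera", "orthoptera")
  taxon <- match.arg(taxon, taxa)
  if (is.null(seed)) seed <- config$seed + 10L + match(taxon, taxa)
  set.seed(seed)

  truth <- config$responses[[taxon]]
  n <- nrow(covariates)
  zt <- .gen_z(covariates$tfi)
  zd <- .gen_z(covariates$dpc)
  loc <- covariates$local
  if (is.character(loc) || is.factor(loc)) loc <- as.numeric(loc == "sandy")
  else if (taxon != "plants") loc <- .gen_z(loc)

  lp <- function(beta) beta[1] + beta[2] * zt + beta[3] * zd + beta[4] * loc
  pool <- .make_pool(taxon, config)
  S <- nrow(pool)
  logmsg <- character(0)

  mu_r <- lp(truth$richness$beta)
  mu_a <- lp(truth$abundance$beta)
  lat_r <- mu_r + stats::rnorm(n, 0, truth$richness$sigma)
  lat_a <- mu_a + stats::rnorm(n, 0, truth$abundance$sigma)
  R <- pmin(pmax(round(lat_r), 1L), S)
  if (taxon == "plants") R <- pmin(R, S)      # plants: occupancy-capped below
  A <- round(lat_a)
  low <- A < R
  if (any(low)) {
    logmsg <- c(logmsg, sprintf(
      "site %d: latent abundance %.1f below richness %d; truncated",
      covariates$site[low], lat_a[low], R[low]))
    A[low] <- R[low]
  }

  # rank-abundance base weights
  base_w <- if (config$rank_abundance_sd > 0)
    exp(config$rank_abundance_sd * stats::qnorm((S - seq_len(S) + 0.5) / S))
  else rep(1, S)

  # CWM target kernels per site
  cwm <- config$cwm_targets[[taxon]]
  kernel <- matrix(1, n, S)
  if (!is.null(cwm) && is.null(config$evenness)) {
    for (tc in names(cwm)) {
      tv <- pool[[tc]]
      tau <- stats::sd(tv, na.rm = TRUE)
      if (!is.finite(tau) || tau == 0) next
      target <- lp(cwm[[tc]])
      k_tc <- exp(-outer(target, tv, `-`)^2 / (2 * tau^2))
      k_tc[, is.na(tv)] <- 1
      kernel <- kernel * k_tc
    }
  }

  records <- vector("list", n)
  for (s in seq_len(n)) {
    w <- base_w * kernel[s, ]
    sel <- sample.int(S, R[s], prob = w)
    if (!is.null(config$evenness) && config$evenness == 1) {
      per <- max(1L, round(A[s] / R[s]))
      counts <- rep(per, R[s])
    } else {
      extra <- A[s] - R[s]
      counts <- rep(1L, R[s])
      if (extra > 0)
        counts <- counts + stats::rmultinom(1, extra, prob = w[sel])[, 1]
    }
    if (taxon == "plants") {                  # quadrat occupancy cap
      over <- counts > 10L
      while (any(over)) {
        excess <- sum(counts[over] - 10L)
        counts[over] <- 10L
        free <- which(counts < 10L)
        if (length(free) == 0L || excess == 0L) {
          if (excess > 0L)
            logmsg <- c(logmsg, sprintf(
              "site %d: dropped %d quadrat counts (all species saturated)",
              covariates$site[s], excess))
          break
        }
        add <- stats::rmultinom(1, excess, prob = w[sel][free])[, 1]
        counts[free] <- counts[free] + add
        over <- counts > 10L
      }
    }
    records[[s]] <- data.frame(site = covariates$site[s],
                               taxon = pool$taxon[sel],
                               resolution = "species",
                               abundance = as.numeric(counts))
  }
  records <- do.call(rbind, records)

  # degrade identification: genus-level and unidentified records
  gr <- config$genus_rate[[taxon]]; ur <- config$unident_rate[[taxon]]
  u <- stats::runif(nrow(records))
  to_gen <- u < gr
  to_uni <- u >= gr & u < gr + ur
  records$taxon[to_gen] <- paste(genus_of(records$taxon[to_gen]), "sp.")
  records$resolution[to_gen] <- "genus"
  records$taxon[to_uni] <- "unidentified"
  records$resolution[to_uni] <- "unidentified"
  # merge duplicates created by degradation
  records <- stats::aggregate(abundance ~ site + taxon + resolution,
                              data = records, FUN = sum)
  if (taxon == "plants") records$abundance <- pmin(records$abundance, 10)
  records <- records[order(records$site, records$taxon), ]
  rownames(records) <- NULL

  genus_taxa <- unique(records$taxon[records$resolution == "genus"])
  traits <- propagate_genus_traits(pool, genus_taxa)

  list(records = records, traits = traits, truth = truth,
       expected = data.frame(site = covariates$site, mu_richness = mu_r,
                             mu_abundance = mu_a, richness = R, abundance = A),
       log = logmsg)
}

#' Generate a complete synthetic study
#'
#' Chains the full design: landscape raster, habitat patches and planar
#' connectivity graphs for the flora and insect cost schemes, per-site dPC
#' at the preset dispersal distances, buffer-averaged TFI at 100 and 300 m,
#' local covariates, and one community + trait table per taxon with the
#' configured ground-truth effects. Everything is deterministic in
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list `landscape`, `covariates` (site table with all explanatory
#'   variables), `connectivity` (per cost scheme: graph, PC, dPC),
#'   `communities` (per taxon), `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  land <- generate_landscape(config)
  covs <- generate_local_covariates(config)

  conn <- list()
  site_dpc <- data.frame(site = land$sites$site)
  schemes <- list(flora = "flora", insects = "insects")
  for (sc in names(schemes)) {
    surface <- assign_costs(land$raster, cost_preset(sc))
    patches <- extract_patches(surface)
    graph <- build_patch_graph(surface, patches)
    dists <- dispersal_preset(if (sc == "flora") "flora" else "insects")
    per_k <- list()
    for (dn in names(dists)) {
      model <- dispersal_model(dists[[dn]])
      rep_ <- connectivity_ranking(graph, model)
      per_k[[dn]] <- rep_
      sc_col <- sprintf("dpc_%s_%d", sc, as.integer(dists[[dn]]))
      site_dpc[[sc_col]] <-
        site_connectivity(land$sites, patches, rep_$dPC)$dPC
    }
    conn[[sc]] <- list(patches = patches, graph = graph, results = per_k)
  }

  tfi100 <- tfi300 <- numeric(nrow(land$sites))
  for (i in seq_len(nrow(land$sites))) {
    xy <- c(land$sites$x[i], land$sites$y[i])
    tfi100[i] <- tfi_buffer_mean(xy, land$fields, 100)$tfi
    tfi300[i] <- tfi_buffer_mean(xy, land$fields, 300)$tfi
  }

  covariates <- cbind(land$sites, covs[setdiff(names(covs), "site")],
                      tfi_100 = tfi100, tfi_300 = tfi300,
                      site_dpc[setdiff(names(site_dpc), "site")])

  comm_inputs <- list(
    plants = data.frame(site = covariates$site, tfi = covariates$tfi_300,
                        dpc = covariates$dpc_flora_500,
                        local = covariates$soil),
    rhopalocera = data.frame(site = covariates$site, tfi = covariates$tfi_300,
                             dpc = covariates$dpc_insects_300,
                             local = covariates$floral),
    orthoptera = data.frame(site = covariates$site, tfi = covariates$tfi_100,
                            dpc = covariates$dpc_insects_300,
                            local = covariates$cover_low))
  communities <- lapply(names(comm_inputs), function(tx)
    generate_communities(config, comm_inputs[[tx]], tx))
  names(communities) <- names(comm_inputs)

  list(landscape = land, covariates = covariates, connectivity = conn,
       communities = communities, config = config)
}
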