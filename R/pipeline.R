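#' Run the full analysis pipeline
#'
#' Orchestrates the complete chain on a study bundle (normally produced by
#' [generate_study()] or assembled from files with [read_study()]):
#' descriptive statistics of the candidate explanatory variables, the
#' collinearity screen (one herbicide, one connectivity, one local variable
#' per taxon, all pairwise |r| <= 0.3), the fixed three-predictor Gaussian
#' linear models for every community response, the cross-taxon Pearson
#' correlation matrix of community metrics, and the connectivity report.
#' A run log records the seed, screen exclusions, dropped sites and NA
#' propagation.
#'
#' @param study a study bundle as returned by [generate_study()].
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV plus a plain-text run log.
#' @param screen_threshold collinearity threshold (default 0.3).
#' @return list `descriptives`, `screen` (per taxon), `models` (coefficient
#'   table, one row per taxon x response x term), `fits` (the underlying
#'   `model_fit` objects), `correlations`, `connectivity`, `metrics`
#'   (per-taxon site metric tables), `log`.
#' @export
run_pipeline <- function(study, out_dir = NULL, screen_threshold = 0.3) {
  covs <- study$covariates
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("pipeline run: seed = %s, %d sites",
      deparse(study$config$seed), nrow(covs))

  ## per-site community metrics
  metrics <- lapply(study$communities, function(cm)
    site_metrics(cm$records, cm$traits))
  for (tx in names(metrics)) {
    m <- metrics[[tx]]
    bad <- setdiff(m$site, covs$site)
    if (length(bad))
      stop("stage metrics: community has unknown site id(s): ",
           paste(bad, collapse = ", "))
  }

  ## candidate variable groups per taxon
  groups <- list(
    plants = list(
      herbicide = c("tfi_300", "tfi_100"),
      connectivity = c("dpc_flora_500", "dpc_flora_150"),
      local = "soil_sandy"),
    rhopalocera = list(
      herbicide = c("tfi_300", "tfi_100"),
      connectivity = c("dpc_insects_300", "dpc_insects_100"),
      local = "floral"),
    orthoptera = list(
      herbicide = c("tfi_100", "tfi_300"),
      connectivity = c("dpc_insects_300", "dpc_insects_100"),
      local = "cover_low"))
  covs$soil_sandy <- as.numeric(covs$soil == "sandy")

  ## descriptive table of the candidate explanatory variables
  cand <- unique(unlist(groups))
  cand_num <- setdiff(cand, "soil_sandy")
  descriptives <- data.frame(
    variable = cand_num,
    mean = vapply(covs[cand_num], mean, numeric(1), na.rm = TRUE),
    sd = vapply(covs[cand_num], stats::sd, numeric(1), na.rm = TRUE),
    min = vapply(covs[cand_num], min, numeric(1), na.rm = TRUE),
    max = vapply(covs[cand_num], max, numeric(1), na.rm = TRUE),
    n = vapply(covs[cand_num], function(x) sum(!is.na(x)), numeric(1)),
    row.names = NULL)

  ## collinearity screen per taxon
  screens <- lapply(names(groups), function(tx) {
    sc <- collinearity_screen(covs, groups[[tx]],
                              threshold = screen_threshold, relax = TRUE)
    for (v in sc$dropped)
      say("screen [%s]: candidate %s dropped (all missing or constant)", tx, v)
    for (i in seq_len(nrow(sc$exclusions)))
      say("screen [%s]: %s ~ %s excluded from co-selection (r = %.3f)", tx,
          sc$exclusions$var1[i], sc$exclusions$var2[i], sc$exclusions$r[i])
    say("screen [%s]: selected %s (max |r| = %.3f%s)", tx,
        paste(sc$selected, collapse = " + "), sc$max_abs_r,
        if (sc$feasible) "" else "; NO feasible set, minimax retained")
    sc
  })
  names(screens) <- names(groups)

  ## fixed-structure models per taxon x response
  fits <- list(); rows <- list()
  for (tx in names(groups)) {
    sel <- screens[[tx]]$selected
    site_tab <- merge(covs, metrics[[tx]], by = "site")
    if (tx == "plants" && sel[["local"]] == "soil_sandy")
      site_tab$soil_sandy <- site_tab$soil    # factor coding, clay reference
    responses <- intersect(
      c("richness", "abundance", "evenness",
        grep("^cwm_", names(metrics[[tx]]), value = TRUE)),
      names(site_tab))
    for (resp in responses) {
      fit <- tryCatch(
        fit_gaussian_lm(site_tab, resp, sel[["herbicide"]],
                        sel[["connectivity"]], sel[["local"]]),
        error = function(e)
          stop("stage models [", tx, " ", resp, "]: ", conditionMessage(e)))
      dropped <- nrow(site_tab) - fit$n
      if (dropped > 0)
        say("models [%s %s]: %d site(s) dropped as incomplete", tx, resp,
            dropped)
      fits[[paste(tx, resp, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(taxon = tx, response = resp, n = fit$n),
        fit$coefficients)
    }
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL

  ## cross-taxon correlation matrix of community metrics
  met_all <- covs["site"]
  for (tx in names(metrics)) {
    m <- metrics[[tx]]
    names(m)[-1] <- paste(tx, names(m)[-1], sep = ".")
    met_all <- merge(met_all, m, by = "site", all.x = TRUE)
  }
  correlations <- pearson_matrix(met_all[-1], level = 0.01)

  ## connectivity report
  conn_report <- do.call(rbind, lapply(names(study$connectivity), function(sc) {
    res <- study$connectivity[[sc]]$results
    do.call(rbind, lapply(names(res), function(dn) {
      data.frame(scheme = sc, dispersal = dn, PC = res[[dn]]$PC,
                 patch_id = res[[dn]]$dPC$id, dPC = res[[dn]]$dPC$dPC)
    }))
  }))

  for (cm in study$communities)
    for (l in cm$log) say("generator: %s", l)

  out <- list(descriptives = descriptives, screen = screens, models = models,
              fits = fits, correlations = correlations,
              connectivity = conn_report, metrics = metrics, log = logline)
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

#' Write pipeline results to a directory
#'
#' @param results output of [run_pipeline()].
#' @param out_dir directory (created if needed).
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$descriptives,
                   file.path(out_dir, "explanatory_descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(results$models, file.path(out_dir, "model_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(results$correlations$r),
                   file.path(out_dir, "metric_correlations.csv"))
  utils::write.csv(results$connectivity,
                   file.path(out_dir, "connectivity_report.csv"),
                   row.names = FALSE)
  for (tx in names(results$metrics))
    utils::write.csv(results$metrics[[tx]],
                     file.path(out_dir, paste0("metrics_", tx, ".csv")),
                     row.names = FALSE)
  writeLines(results$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read / write long-format community CSV
#'
#' Columns `site`, `taxon`, `resolution`, `abundance`; strict validation
#' with row-numbered errors.
#'
#' @param path CSV path.
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "taxon", "resolution", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("community CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!df$resolution %in% c("species", "genus", "unidentified"))
  if (length(bad))
    stop("community CSV row ", bad[1] + 1L, ": bad resolution flag '",
         df$resolution[bad[1]], "'")
  bad <- which(is.na(df$abundance) | df$abundance < 0)
  if (length(bad))
    stop("community CSV row ", bad[1] + 1L, ": invalid abundance")
  df
}

#' @param records community records.
#' @rdname read_community_csv
#' @export
write_community_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read site and field tables
#'
#' Sites: CSV with `site`, `x`, `y`. Fields: long CSV with `field_id`,
#' `vertex`, `x`, `y` plus a per-field `tfi` column (repeated along
#' vertices, NA allowed).
#'
#' @param path CSV path.
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("site", "x", "y"), names(df))
  if (length(miss)) stop("sites CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_sites_csv
#' @export
read_fields_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("field_id", "vertex", "x", "y", "tfi"), names(df))
  if (length(miss)) stop("fields CSV missing columns: ",
                         paste(miss, collapse = ", "))
  ids <- unique(df$field_id)
  polys <- lapply(ids, function(i) {
    d <- df[df$field_id == i, ]
    as.matrix(d[order(d$vertex), c("x", "y")])
  })
  tfi <- vapply(ids, function(i) df$tfi[df$field_id == i][1], numeric(1))
  field_set(polys, tfi)
}

#' @param fields a [field_set()].
#' @rdname read_sites_csv
#' @export
write_fields_csv <- function(fields, path) {
  rows <- lapply(seq_along(fields$polygons), function(i) {
    p <- fields$polygons[[i]]
    data.frame(field_id = i, vertex = seq_len(nrow(p)), x = p[, 1],
               y = p[, 2], tfi = fields$tfi[i])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
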