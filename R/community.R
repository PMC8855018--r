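#' Community records
#'
#' Community data are handled as long-format records: one row per site x
#' taxon with columns `site`, `taxon`, `resolution` (one of `"species"`,
#' `"genus"`, `"unidentified"`) and `abundance`. For plants, abundance is the
#' number of 1-m2 quadrats (of 10) occupied; for insects it is the number of
#' individuals counted on transects. `genus_of()` extracts the genus (first
#' word of the taxon name), which drives the congeneric-collapse rule and
#' genus-level trait propagation.
#'
#' @param taxon character vector of taxon names.
#' @return character vector of genus names.
#' @export
genus_of <- function(taxon) sub("\\s.*$", "", taxon)

.check_community <- function(records) {
  need <- c("site", "taxon", "resolution", "abundance")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("community records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$abundance < 0)) stop("abundances must be non-negative")
  bad <- setdiff(unique(records$resolution),
                 c("species", "genus", "unidentified"))
  if (length(bad))
    stop("unknown taxon resolution flag(s): ", paste(bad, collapse = ", "))
  invisible(records)
}

# Records that carry a taxonomic identity at a site, with genus-level records
# collapsed onto congeneric species-level records when those exist (a
# "Chorthippus sp." adds nothing when a Chorthippus species is already
# recorded there). Unidentified records never carry identity.
.identified_rows <- function(rows) {
  rows <- rows[rows$abundance > 0, , drop = FALSE]
  sp <- rows$resolution == "species"
  gen <- rows$resolution == "genus"
  sp_genera <- unique(genus_of(rows$taxon[sp]))
  keep_gen <- gen & !(genus_of(rows$taxon) %in% sp_genera)
  rows[sp | keep_gen, , drop = FALSE]
}

#' Site species richness
#'
#' Number of distinct taxa with positive abundance. A genus-level record
#' counts as one taxon only when no congeneric species-level record is
#' present at the site; unidentified records never count.
#'
#' @param records long-format community records (may span several sites).
#' @return named integer vector of richness per site.
#' @export
richness <- function(records) {
  .check_community(records)
  sites <- unique(records$site)
  out <- vapply(sites, function(s) {
    nrow(.identified_rows(records[records$site == s, , drop = FALSE]))
  }, integer(1))
  stats::setNames(out, sites)
}

#' Site total abundance
#'
#' Sum of abundances over all records, including genus-level and
#' unidentified ones (an individual counts whether or not it was named).
#'
#' @inheritParams richness
#' @return named numeric vector per site.
#' @export
total_abundance <- function(records) {
  .check_community(records)
  tot <- tapply(records$abundance, records$site, sum)
  tot[as.character(unique(records$site))]
}

#' Pielou's evenness index
#'
#' `J = H / ln(S)` where `H` is the Shannon entropy of abundance shares over
#' the identified taxa of the site and `S` their number. Undefined (missing)
#' when fewer than two identified taxa are present. Natural logarithms
#' throughout; Shannon entropy is delegated to [vegan::diversity()].
#'
#' @inheritParams richness
#' @return named numeric vector per site (NA where S < 2).
#' @export
pielou_evenness <- function(records) {
  .check_community(records)
  sites <- unique(records$site)
  out <- vapply(sites, function(s) {
    rows <- .identified_rows(records[records$site == s, , drop = FALSE])
    if (nrow(rows) < 2L) return(NA_real_)
    h <- vegan::diversity(rows$abundance, index = "shannon")
    h / log(nrow(rows))
  }, numeric(1))
  stats::setNames(out, sites)
}

#' Community-weighted mean trait value
#'
#' Abundance-weighted mean of a trait over the taxa of a community. Taxa with
#' unknown trait are removed before weighting, and the weights are
#' renormalized over the trait-known taxa. Missing when no trait-known taxon
#' is present.
#'
#' @param abundance abundances (one community).
#' @param trait trait values aligned with `abundance`; NA = unknown.
#' @return the CWM, or NA.
#' @export
community_weighted_mean <- function(abundance, trait) {
  if (length(abundance) != length(trait))
    stop("`abundance` and `trait` lengths differ")
  ok <- !is.na(trait) & abundance > 0
  if (!any(ok)) return(NA_real_)
  sum(abundance[ok] * trait[ok]) / sum(abundance[ok])
}

#' Species specialization index from co-occurrence
#'
#' For a focal species, `theta = gamma / mu(alpha)` where `gamma` is the
#' cumulative number of distinct species over all plots containing the focal
#' species and `mu(alpha)` the mean richness of those plots. `theta >= 1`
#' always; large values indicate co-occurrence with many different species
#' across plots, i.e. a generalist (the index decreases with specialization).
#' `mu_alpha = "all"` averages richness over every plot of the reference
#' database instead (an alternative reading; plot-containing is the default).
#'
#' @param occurrence logical or 0/1 matrix, plots x species.
#' @param focal species (column) name or index.
#' @param mu_alpha `"containing"` (default) or `"all"`.
#' @return theta (>= 1 under the default mode).
#' @export
theta_wb <- function(occurrence, focal, mu_alpha = c("containing", "all")) {
  mu_alpha <- match.arg(mu_alpha)
  occurrence <- occurrence > 0
  if (is.character(focal)) focal <- match(focal, colnames(occurrence))
  if (is.na(focal) || focal < 1 || focal > ncol(occurrence))
    stop("unknown focal species")
  plots <- which(occurrence[, focal])
  if (length(plots) == 0L) stop("focal species absent from every plot")
  gamma <- sum(colSums(occurrence[plots, , drop = FALSE]) > 0)
  alpha <- if (mu_alpha == "containing")
    mean(rowSums(occurrence[plots, , drop = FALSE]))
  else mean(rowSums(occurrence))
  gamma / alpha
}

#' Dependence on insect pollination
#'
#' Percentage of reference databases that list insects as a pollen vector for
#' the species, among databases holding any pollen-vector information for it.
#'
#' @param insect_vector logical vector, one entry per database: `TRUE` if
#'   insects are listed, `FALSE` if not, `NA` if the database has no
#'   information for the species.
#' @return percentage in [0, 100], or NA when no database is informative.
#' @export
pollination_dependence <- function(insect_vector) {
  ok <- !is.na(insect_vector)
  if (!any(ok)) return(NA_real_)
  100 * sum(insect_vector[ok]) / sum(ok)
}

#' Propagate species traits to genus-level taxa
#'
#' A genus-level record receives a trait value only if all congeneric
#' species with a known value share the same value; otherwise it stays
#' missing. Applied per trait column.
#'
#' @param traits data.frame with column `taxon` plus trait columns.
#' @param genus_taxa character vector of genus-level taxon names (e.g.
#'   `"Chorthippus sp."`); genus extracted via [genus_of()].
#' @param trait_cols trait columns to propagate (default: all non-`taxon`
#'   numeric columns).
#' @return `traits` with one appended row per genus-level taxon.
#' @export
propagate_genus_traits <- function(traits, genus_taxa, trait_cols = NULL) {
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          "taxon")
  genera <- genus_of(traits$taxon)
  add <- lapply(genus_taxa, function(gt) {
    g <- genus_of(gt)
    row <- stats::setNames(as.list(rep(NA_real_, length(trait_cols))),
                           trait_cols)
    for (tc in trait_cols) {
      vals <- traits[[tc]][genera == g]
      vals <- vals[!is.na(vals)]
      if (length(vals) >= 1L && length(unique(vals)) == 1L)
        row[[tc]] <- vals[1]
    }
    cbind(data.frame(taxon = gt), as.data.frame(row))
  })
  out <- rbind(traits[, c("taxon", trait_cols), drop = FALSE],
               do.call(rbind, add))
  rownames(out) <- NULL
  out
}

#' Per-site structural and functional community metrics
#'
#' Computes richness, total abundance, Pielou evenness and the
#' community-weighted mean of each trait column for every site. CWMs use
#' identified taxa only (after congeneric collapse) and renormalize over
#' trait-known taxa; trait values for genus-level records should be prepared
#' with [propagate_genus_traits()] beforehand.
#'
#' @param records long-format community records.
#' @param traits data.frame with `taxon` plus numeric trait columns.
#' @return data.frame, one row per site: `site`, `richness`, `abundance`,
#'   `evenness`, and one `cwm_<trait>` column per trait.
#' @export
site_metrics <- function(records, traits = NULL) {
  .check_community(records)
  sites <- unique(records$site)
  out <- data.frame(site = sites,
                    richness = as.integer(richness(records)[as.character(sites)]),
                    abundance = as.numeric(total_abundance(records)[as.character(sites)]),
                    evenness = as.numeric(pielou_evenness(records)[as.character(sites)]))
  if (!is.null(traits)) {
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          "taxon")
    for (tc in trait_cols) {
      out[[paste0("cwm_", tc)]] <- vapply(sites, function(s) {
        rows <- .identified_rows(records[records$site == s, , drop = FALSE])
        tv <- traits[[tc]][match(rows$taxon, traits$taxon)]
        community_weighted_mean(rows$abundance, tv)
      }, numeric(1))
    }
  }
  rownames(out) <- NULL
  out
}
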