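#' Categorical land-use raster
#'
#' Construct a land-use raster from an integer matrix of class codes. The grid
#' is stored row-major with row 1 at the top; cell centres are at
#' `x = origin[1] + (col - 0.5) * resolution`,
#' `y = origin[2] + (nrow - row + 0.5) * resolution`, i.e. `origin` is the
#' lower-left corner of the grid (the ESRI ASCII `xllcorner`/`yllcorner`
#' convention).
#'
#' @param grid integer matrix of land-use class codes.
#' @param resolution cell edge length in metres (default 2, the working
#'   resolution used throughout: fine enough to resolve linear features such
#'   as roads and hedges that condition movement).
#' @param origin numeric length-2, planar coordinates of the lower-left corner.
#' @param nodata reserved code for cells with no data (`NA` entries in `grid`
#'   are also treated as nodata).
#' @return object of class `land_use_raster`.
#' @export
land_use_raster <- function(grid, resolution = 2, origin = c(0, 0),
                            nodata = -9999L) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number")
  storage.mode(grid) <- "integer"
  grid[!is.na(grid) & grid == nodata] <- NA_integer_
  structure(
    list(grid = grid, resolution = as.numeric(resolution),
         origin = as.numeric(origin), nodata = as.integer(nodata)),
    class = "land_use_raster")
}

#' @export
print.land_use_raster <- function(x, ...) {
  codes <- sort(unique(as.vector(x$grid)))
  cat(sprintf("land_use_raster: %d x %d cells @ %g m (%d classes, %d nodata cells)\n",
              nrow(x$grid), ncol(x$grid), x$resolution,
              length(codes), sum(is.na(x$grid))))
  invisible(x)
}

#' Read / write an ESRI ASCII grid
#'
#' Minimal reader and writer for the plain-text ESRI ASCII grid format
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`
#' header followed by rows top to bottom).
#'
#' @param path file path.
#' @return `read_asc()` returns a [land_use_raster()].
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing field: ", k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid: expected %d values, found %d", nr * nc,
                 length(vals)))
  grid <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) -9999L else as.integer(hdr$nodata_value)
  land_use_raster(grid, resolution = hdr$cellsize,
                  origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0),
                  nodata = nodata)
}

#' @param raster a [land_use_raster()].
#' @rdname read_asc
#' @export
write_asc <- function(raster, path) {
  stopifnot(inherits(raster, "land_use_raster"))
  g <- raster$grid
  g[is.na(g)] <- raster$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$resolution),
    sprintf("NODATA_value %d", raster$nodata))
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cost (resistance) table
#'
#' Map land-use class codes to movement resistance. Habitat classes are those
#' with cost 1 unless `is_habitat` is given explicitly. The canonical tiers
#' are 1 (habitat), 10 (favourable), 100 (unfavourable), 1000 (barrier);
#' arbitrary positive costs are allowed when `strict = FALSE`.
#'
#' @param class_code integer class codes.
#' @param cost positive resistance per metre traversed.
#' @param label optional class labels.
#' @param is_habitat logical; defaults to `cost == 1`.
#' @param strict if `TRUE`, require costs in \{1, 10, 100, 1000\}.
#' @return data.frame of class `cost_table`.
#' @export
cost_table <- function(class_code, cost, label = NULL, is_habitat = NULL,
                       strict = TRUE) {
  class_code <- as.integer(class_code)
  cost <- as.numeric(cost)
  if (anyDuplicated(class_code)) stop("duplicated class codes in cost table")
  if (any(!is.finite(cost)) || any(cost <= 0))
    stop("all costs must be positive and finite")
  if (strict && !all(cost %in% c(1, 10, 100, 1000)))
    stop("strict mode: costs must lie in {1, 10, 100, 1000}")
  if (is.null(is_habitat)) is_habitat <- cost == 1
  if (!any(is_habitat)) stop("cost table must contain at least one habitat class")
  out <- data.frame(class_code = class_code,
                    label = if (is.null(label)) paste0("class_", class_code) else as.character(label),
                    cost = cost, is_habitat = as.logical(is_habitat))
  class(out) <- c("cost_table", "data.frame")
  out
}

#' Read a cost table from CSV
#'
#' Expects columns `class_code`, `cost` and optionally `label`, `is_habitat`.
#' @inheritParams read_asc
#' @param strict see [cost_table()].
#' @export
read_cost_table <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_code", "cost")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cost table CSV missing columns: ", paste(miss, collapse = ", "))
  cost_table(df$class_code, df$cost, label = df$label,
             is_habitat = if ("is_habitat" %in% names(df)) df$is_habitat else NULL,
             strict = strict)
}

#' Per-taxon cost presets for the synthetic land-use catalogue
#'
#' The synthetic catalogue uses codes 1 grassland, 2 crop, 3 forest,
#' 4 building, 5 road, 6 shrub. Insects (butterflies and orthopterans of
#' herbaceous environments) treat grassland as habitat (1), shrub as
#' favourable (10), crops and roads as unfavourable (100), and forests and
#' tall buildings as barriers (1000). For flora, wind-driven dispersal makes
#' most of the matrix weakly resistant: only forests and tall buildings are
#' barriers (1000), herbaceous cover is habitat (1), and everything else is
#' cost 10.
#'
#' @param taxon `"insects"` or `"flora"`.
#' @return a [cost_table()].
#' @export
cost_preset <- function(taxon = c("insects", "flora")) {
  taxon <- match.arg(taxon)
  labels <- c("grassland", "crop", "forest", "building", "road", "shrub")
  if (taxon == "insects")
    cost_table(1:6, c(1, 100, 1000, 1000, 100, 10), label = labels)
  else
    cost_table(1:6, c(1, 10, 1000, 1000, 10, 10), label = labels)
}

#' Assign movement costs to a land-use raster
#'
#' Cell-wise lookup of the cost table over the class grid. Nodata cells are
#' impassable: they take cost `NA` and are excluded from the movement graph.
#'
#' @param raster a [land_use_raster()].
#' @param costs a [cost_table()].
#' @return object of class `cost_surface` with fields `cost` (numeric matrix),
#'   `habitat` (logical matrix), `resolution`, `origin`.
#' @export
assign_costs <- function(raster, costs) {
  stopifnot(inherits(raster, "land_use_raster"), inherits(costs, "cost_table"))
  g <- raster$grid
  codes <- sort(unique(g[!is.na(g)]))
  unmapped <- setdiff(codes, costs$class_code)
  if (length(unmapped))
    stop("unmapped land-use class code(s): ", paste(unmapped, collapse = ", "))
  idx <- match(g, costs$class_code)
  cost <- matrix(costs$cost[idx], nrow = nrow(g))
  habitat <- matrix(costs$is_habitat[idx], nrow = nrow(g))
  habitat[is.na(habitat)] <- FALSE
  structure(list(cost = cost, habitat = habitat,
                 resolution = raster$resolution, origin = raster$origin),
            class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf("cost_surface: %d x %d cells @ %g m, %d habitat cells (%.1f%%)\n",
              nrow(x$cost), ncol(x$cost), x$resolution, sum(x$habitat),
              100 * mean(x$habitat)))
  invisible(x)
}

#' Pool a habitat mosaic into a single class
#'
#' Small habitat mosaics (fine-grained mixtures of several classes) are pooled
#' into one composite habitat whose cost is the arithmetic mean of the pooled
#' classes. Class codes keep their identity in the raster (no cells are
#' reassigned); the pooled classes simply share one label and one cost, so
#' total class coverage is preserved.
#'
#' @param costs a [cost_table()].
#' @param mosaic_classes class codes to pool (all must be present).
#' @param label label for the pooled composite class.
#' @return a [cost_table()] with the pooled classes sharing the mean cost.
#' @export
pool_mosaic <- function(costs, mosaic_classes, label = "mosaic") {
  stopifnot(inherits(costs, "cost_table"))
  mosaic_classes <- as.integer(mosaic_classes)
  if (length(mosaic_classes) == 0L) stop("`mosaic_classes` must be non-empty")
  miss <- setdiff(mosaic_classes, costs$class_code)
  if (length(miss))
    stop("mosaic class code(s) not in cost table: ", paste(miss, collapse = ", "))
  i <- costs$class_code %in% mosaic_classes
  pooled_cost <- mean(costs$cost[i])
  costs$cost[i] <- pooled_cost
  costs$label[i] <- label
  costs$is_habitat[i] <- pooled_cost == 1
  if (!any(costs$is_habitat))
    costs$is_habitat[i] <- TRUE  # pooled composite treated as the habitat
  attr(costs, "pooled") <- list(classes = mosaic_classes, cost = pooled_cost)
  costs
}

# row-major linear index helpers (cell 1 = top-left, advancing along rows)
cell_index <- function(row, col, nr) (col - 1L) * nr + row   # R column-major
# We store matrices in R's native column-major order but define deterministic
# "row-major order of first cell" for patch ids explicitly where needed.

#' Extract habitat patches from a cost surface
#'
#' Habitat patches are the 8-neighbourhood connected components of the habitat
#' mask. Components smaller than `min_cells` are discarded. Patch ids are
#' assigned in row-major order (reading the grid left to right, top to bottom)
#' of each component's first cell, which makes them stable and deterministic.
#'
#' @param surface a `cost_surface`.
#' @param min_cells minimum component size in cells (default 1).
#' @return object of class `patch_set`: a list with `patches` (data.frame
#'   `id`, `n_cells`, `area_m2`, `centroid_x`, `centroid_y`), `cells` (list of
#'   cell linear indices, column-major), `label` (integer matrix of patch ids,
#'   NA outside patches), plus grid metadata.
#' @export
extract_patches <- function(surface, min_cells = 1L) {
  stopifnot(inherits(surface, "cost_surface"))
  hab <- surface$habitat
  nr <- nrow(hab); nc <- ncol(hab)
  idx <- which(hab)                       # column-major linear indices
  label <- matrix(NA_integer_, nr, nc)
  empty <- list(
    patches = data.frame(id = integer(), n_cells = integer(),
                         area_m2 = numeric(), centroid_x = numeric(),
                         centroid_y = numeric()),
    cells = list(), label = label, resolution = surface$resolution,
    origin = surface$origin, dim = c(nr, nc))
  class(empty) <- "patch_set"
  if (length(idx) == 0L) return(empty)

  comp <- .label_components(hab)
  # order components by row-major position of their first cell
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  rowmajor <- (rows - 1L) * nc + cols
  first_pos <- tapply(rowmajor, comp[idx], min)
  ord <- order(first_pos)
  sizes <- tabulate(comp[idx])
  keep <- which(sizes[ord] >= min_cells)
  if (length(keep) == 0L) return(empty)

  old_ids <- as.integer(names(first_pos))[ord][keep]
  new_id <- integer(max(comp[idx]))
  new_id[old_ids] <- seq_along(old_ids)

  cells <- vector("list", length(old_ids))
  res <- surface$resolution
  out <- data.frame(id = seq_along(old_ids), n_cells = 0L, area_m2 = 0,
                    centroid_x = 0, centroid_y = 0)
  for (j in seq_along(old_ids)) {
    ci <- idx[comp[idx] == old_ids[j]]
    cells[[j]] <- ci
    label[ci] <- j
    r <- ((ci - 1L) %% nr) + 1L
    cc <- ((ci - 1L) %/% nr) + 1L
    out$n_cells[j] <- length(ci)
    out$area_m2[j] <- length(ci) * res^2
    out$centroid_x[j] <- surface$origin[1] + mean(cc - 0.5) * res
    out$centroid_y[j] <- surface$origin[2] + mean(nr - r + 0.5) * res
  }
  structure(list(patches = out, cells = cells, label = label,
                 resolution = res, origin = surface$origin, dim = c(nr, nc)),
            class = "patch_set")
}

# 8-connected component labelling of a logical matrix via igraph.
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  id_of <- integer(nr * nc)
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- sh[1]; dc <- sh[2]
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[nb]
    edges <- c(edges, rbind(id_of[idx[ok][ok2]], id_of[nb[ok2]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp <- integer(nr * nc)
  comp[idx] <- memb
  comp
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches, %d habitat cells, areas %s m2\n",
              nrow(x$patches), sum(x$patches$n_cells),
              if (nrow(x$patches)) paste0(min(x$patches$area_m2), "-",
                                          max(x$patches$area_m2)) else "-"))
  invisible(x)
}

#' Export patches to CSV / labelled raster
#'
#' @param patches a `patch_set`.
#' @param csv optional path for the patch attribute table.
#' @param raster_path optional path for the labelled-patch ASCII grid
#'   (patch id per cell, nodata outside patches).
#' @export
write_patches <- function(patches, csv = NULL, raster_path = NULL) {
  stopifnot(inherits(patches, "patch_set"))
  if (!is.null(csv))
    utils::write.csv(patches$patches, csv, row.names = FALSE)
  if (!is.null(raster_path)) {
    lab <- land_use_raster(patches$label, resolution = patches$resolution,
                           origin = patches$origin)
    write_asc(lab, raster_path)
  }
  invisible(patches)
}
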