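#' Planar polygon helpers
#'
#' Small planar-geometry toolkit used by the buffer covariates: shoelace
#' area, Sutherland-Hodgman clipping of a polygon against a convex clip
#' polygon, and circle-polygon intersection area (the circle is represented
#' as a regular 720-gon, giving relative area errors below 1e-5 at the
#' buffer radii used here).
#'
#' @param poly two-column matrix of vertex coordinates (closed implicitly).
#' @return `polygon_area()` returns the absolute area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @param subject polygon to clip (matrix).
#' @param clip convex clip polygon (matrix, counter-clockwise).
#' @rdname polygon_area
#' @export
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (is.null(out) || nrow(out) < 3L) return(matrix(numeric(0), ncol = 2))
    a <- clip[i, ]; b <- clip[if (i == n) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    px <- out[, 1]; py <- out[, 2]
    m <- length(px)
    side <- ex * (py - a[2]) - ey * (px - a[1])   # >= 0 means inside (CCW clip)
    qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
    qside <- c(side[-1], side[1])
    crossed <- (side >= 0) != (qside >= 0)
    tt <- side / (side - qside)                   # valid where crossed
    ix <- px + tt * (qx - px); iy <- py + tt * (qy - py)
    # q-vertices kept at key j+1, crossing intersections at key j+0.5
    keep <- qside >= 0
    keys <- c(seq_len(m)[keep] + 1, seq_len(m)[crossed] + 0.5)
    allx <- c(qx[keep], ix[crossed]); ally <- c(qy[keep], iy[crossed])
    o <- order(keys)
    out <- cbind(allx[o], ally[o])
  }
  out
}

# convex and counter-clockwise test (used to pick the cheap clipping order)
.is_convex_ccw <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ex <- xn - x; ey <- yn - y
  cr <- ex * c(ey[-1], ey[1]) - ey * c(ex[-1], ex[1])
  all(cr >= 0)
}

#' @param centre circle centre, length-2 numeric.
#' @param radius circle radius.
#' @param n_seg number of segments approximating the circle.
#' @rdname polygon_area
#' @export
circle_polygon <- function(centre, radius, n_seg = 720L) {
  th <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

#' Field polygons with herbicide treatment indices
#'
#' @param polygons list of two-column coordinate matrices (one per field).
#' @param tfi herbicide treatment frequency index per field; `NA` marks a
#'   field (or non-agricultural parcel) with no information.
#' @return object of class `field_set`.
#' @export
field_set <- function(polygons, tfi) {
  if (length(polygons) != length(tfi))
    stop("`polygons` and `tfi` lengths differ")
  if (any(tfi < 0, na.rm = TRUE)) stop("TFI values must be non-negative")
  areas <- vapply(polygons, polygon_area, numeric(1))
  if (any(areas <= 0)) stop("degenerate field polygon (zero area)")
  structure(list(polygons = polygons, tfi = as.numeric(tfi), area = areas),
            class = "field_set")
}

#' Buffer-averaged herbicide treatment frequency index
#'
#' Area-weighted mean TFI over the intersections of field polygons with a
#' circular buffer around the site. When the informative area (fields with a
#' known TFI) covers less than `min_informative` of the buffer disc, the
#' value is missing: too little of the surrounding land is documented to
#' characterize it. The site's own untreated footprint is simply land without
#' TFI information, so it counts against the informative fraction.
#'
#' @param site_xy site centre, length-2 numeric.
#' @param fields a [field_set()].
#' @param radius buffer radius in metres (100 and 300 in the standard
#'   analysis; any positive radius is accepted).
#' @param min_informative minimum informative area fraction (default 0.5).
#' @param n_seg circle discretization (see [circle_polygon()]).
#' @return list `tfi` (NA when under-informed), `informative_fraction`.
#' @export
tfi_buffer_mean <- function(site_xy, fields, radius, min_informative = 0.5,
                            n_seg = 720L) {
  stopifnot(inherits(fields, "field_set"), radius > 0)
  disc <- circle_polygon(site_xy, radius, n_seg)
  buffer_area <- polygon_area(disc)
  w <- numeric(length(fields$polygons))
  for (i in seq_along(fields$polygons)) {
    # fast reject by bounding box
    p <- fields$polygons[[i]]
    if (min(p[, 1]) > site_xy[1] + radius || max(p[, 1]) < site_xy[1] - radius ||
        min(p[, 2]) > site_xy[2] + radius || max(p[, 2]) < site_xy[2] - radius)
      next
    # clipping the (many-vertex) disc against a convex field is much cheaper
    cl <- if (.is_convex_ccw(p)) clip_polygon_convex(disc, p)
    else clip_polygon_convex(p, disc)
    if (nrow(cl) >= 3L) w[i] <- polygon_area(cl)
  }
  informative <- !is.na(fields$tfi) & w > 0
  info_area <- sum(w[informative])
  frac <- info_area / buffer_area
  tfi <- if (info_area == 0 || frac < min_informative) NA_real_
  else sum(w[informative] * fields$tfi[informative]) / info_area
  list(tfi = tfi, informative_fraction = frac)
}

#' Mean floral availability over visits
#'
#' Arithmetic mean of the flowering-plant cover (%) noted at each of up to
#' four site visits; missing when no visit was recorded.
#'
#' @param covers numeric vector of per-visit covers, `NA` for unrecorded
#'   visits.
#' @return mean cover (%), or NA.
#' @export
floral_availability <- function(covers) {
  covers <- covers[!is.na(covers)]
  if (length(covers) == 0L) return(NA_real_)
  if (any(covers < 0 | covers > 100)) stop("covers must lie in [0, 100]")
  mean(covers)
}

#' Validate herbaceous vegetation cover classes
#'
#' Covers (%) of the three height classes: low (< 20 cm), medium (20-40 cm)
#' and high (> 40 cm). Values outside [0, 100] are an error; rows whose
#' classes sum to more than 100 are passed through but flagged.
#'
#' @param low,medium,high numeric vectors of covers (%).
#' @return data.frame `low`, `medium`, `high`, `flag_sum_gt_100`.
#' @export
validate_cover_classes <- function(low, medium, high) {
  v <- cbind(low = low, medium = medium, high = high)
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("cover classes must lie in [0, 100]")
  data.frame(low = low, medium = medium, high = high,
             flag_sum_gt_100 = rowSums(v) > 100)
}
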