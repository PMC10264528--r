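# The twelve quantitative CT features of a segmented nodule cross-section:
# Feret diameter (mean of max and min), perimeter, area, mean/median/modal
# attenuation, SD of attenuation, linear mass density, histogram skewness
# and excess kurtosis, circularity and solidity.
#
# Conventions (fixed, documented in the methods vignette):
#  * perimeter from the marching-squares 0.5-level contour, lightly smoothed
#    (circular moving average) so that circularity of a digital disk
#    approaches 1; the raw polyline and a pixel-edge count are available
#    behind `method`;
#  * Feret geometry on the convex hull of pixel *corner* points, so a
#    one-pixel object has a nonzero diameter;
#  * skewness/kurtosis use population (1/N) moments, SD the sample (n-1)
#    denominator; kurtosis is excess (Gaussian -> 0);
#  * modal attenuation on integer-HU bins, ties broken toward the lowest HU.

mask_spacing <- function(mask, spacing = NULL) {
  sp <- spacing %||% attr(mask, "pixel_spacing")
  if (is.null(sp)) stop("no pixel spacing available for this mask", call. = FALSE)
  sp <- as.numeric(sp)
  if (length(sp) == 1) sp <- rep(sp, 2)
  sp
}

#' Area of a nodule mask
#'
#' @param mask A [nodule_mask] or logical matrix.
#' @param spacing Optional (row, col) pixel spacing in mm; defaults to the
#'   spacing carried by the mask.
#' @return Area in mm^2: pixel count times row spacing times column spacing.
#' @export
measure_area <- function(mask, spacing = NULL) {
  sp <- mask_spacing(mask, spacing)
  n <- sum(mask)
  if (n == 0) stop("mask is empty", call. = FALSE)
  n * sp[1] * sp[2]
}

#' Trace the outer boundary contour of a mask
#'
#' Marching-squares contour at the 0.5 level between foreground and
#' background (via [grDevices::contourLines()]), vertices in physical mm.
#' With several loops (should not occur for a single-component hole-filled
#' mask) the loop enclosing the largest area is returned.
#'
#' @param mask A [nodule_mask] or logical matrix (single component).
#' @param spacing Optional (row, col) spacing in mm.
#' @param smoothing Odd integer window of the circular moving average
#'   applied to contour vertices; 0 or 1 disables smoothing and yields the
#'   raw marching-squares polyline. Contours with fewer vertices than the
#'   window are returned unsmoothed.
#' @return An `nsn_contour`: matrix with columns (row_mm, col_mm) of closed
#'   polygon vertices (first vertex not repeated), `closed` attribute TRUE.
#' @export
trace_boundary <- function(mask, spacing = NULL, smoothing = 0) {
  sp <- mask_spacing(mask, spacing)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- as.numeric(mask)
  cl <- grDevices::contourLines(x = seq(-1, nr), y = seq(-1, nc), z = z,
                                levels = 0.5)
  if (length(cl) == 0) stop("no contour found", call. = FALSE)
  polys <- lapply(cl, function(l) {
    v <- cbind(row = l$x, col = l$y)
    # contourLines closes loops by repeating the first vertex; drop it
    if (nrow(v) > 1 && all(abs(v[1, ] - v[nrow(v), ]) < 1e-12))
      v <- v[-nrow(v), , drop = FALSE]
    v
  })
  outer <- polys[[which.max(vapply(polys, polygon_area, numeric(1)))]]
  if (smoothing > 1) outer <- smooth_closed_polyline(outer, smoothing)
  v_mm <- cbind(row_mm = outer[, 1] * sp[1], col_mm = outer[, 2] * sp[2])
  structure(v_mm, closed = TRUE, class = c("nsn_contour", "matrix", "array"))
}

# circular boxcar average of closed polygon vertices
smooth_closed_polyline <- function(v, window) {
  n <- nrow(v)
  window <- as.integer(window)
  if (window %% 2 == 0) window <- window + 1L
  if (n <= window) return(v)
  h <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, k) ((i + k - 1L) %% n) + 1L)
  cbind(rowMeans(matrix(v[idx, 1], n)), rowMeans(matrix(v[idx, 2], n)))
}

#' Perimeter of a nodule
#'
#' Euclidean length of the closed outer contour.  `method = "contour"`
#' (default) measures the smoothed marching-squares contour; `"raw_contour"`
#' the unsmoothed polyline; `"pixel_edge"` counts exposed pixel faces (the
#' classical over-estimating convention, kept for comparison).
#'
#' @param x An `nsn_contour` (from [trace_boundary()]) or a [nodule_mask].
#' @param spacing Optional spacing (masks only).
#' @param method Perimeter convention, see above (masks only; a supplied
#'   contour is measured as-is).
#' @param smoothing Smoothing window forwarded to [trace_boundary()] when
#'   `method = "contour"`.
#' @return Perimeter in mm.
#' @export
measure_perimeter <- function(x, spacing = NULL,
                              method = c("contour", "raw_contour", "pixel_edge"),
                              smoothing = 5) {
  method <- match.arg(method)
  if (inherits(x, "nsn_contour") || (is.matrix(x) && is.numeric(x) && ncol(x) == 2)) {
    closed <- isTRUE(attr(x, "closed"))
    if (!inherits(x, "nsn_contour")) {
      # bare vertex matrix: accept if explicitly closed by repetition
      if (nrow(x) > 2 && all(abs(x[1, ] - x[nrow(x), ]) < 1e-12)) {
        x <- x[-nrow(x), , drop = FALSE]
        closed <- TRUE
      }
    }
    if (!closed) stop("contour is not closed", call. = FALSE)
    return(polyline_length_closed(x))
  }
  sp <- mask_spacing(x, spacing)
  if (method == "pixel_edge") {
    m <- matrix(FALSE, nrow(x) + 2, ncol(x) + 2)
    m[2:(nrow(x) + 1), 2:(ncol(x) + 1)] <- x
    nr <- nrow(m)
    idx <- which(m)
    expo <- function(off, len) sum(!m[idx + off]) * len
    return(expo(-1L, sp[2]) + expo(1L, sp[2]) + expo(-nr, sp[1]) + expo(nr, sp[1]))
  }
  win <- if (method == "raw_contour") 0 else smoothing
  polyline_length_closed(trace_boundary(x, spacing = sp, smoothing = win))
}

# corner points (in mm) of all boundary pixels of a mask; boundary pixels
# suffice for any convex-hull quantity
mask_corner_points <- function(mask, spacing = NULL) {
  sp <- mask_spacing(mask, spacing)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  bdry <- which(mask & !inner)
  r <- ((bdry - 1L) %% nr)       # 0-based pixel rows
  c <- ((bdry - 1L) %/% nr)
  corners <- cbind(row = c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
                   col = c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
  corners <- unique(corners)
  cbind(row_mm = corners[, 1] * sp[1], col_mm = corners[, 2] * sp[2])
}

# convex hull (vertices in counter-clockwise order) of the pixel corners
corner_hull <- function(mask, spacing = NULL) {
  pts <- mask_corner_points(mask, spacing)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # (x = col, y = row)
  pts[rev(h), , drop = FALSE]
}

#' Feret (caliper) diameters of a nodule
#'
#' Computed on the convex hull of the corner points of all mask pixels.
#' The maximum Feret diameter is the largest distance between two hull
#' vertices; the minimum is the smallest width over directions normal to
#' hull edges (rotating-calipers result).  The reported summary diameter is
#' the mean of the maximum and minimum.
#'
#' @param mask A [nodule_mask] or logical matrix.
#' @param spacing Optional (row, col) spacing in mm.
#' @return Named numeric vector `c(max, min, mean)` in mm.
#' @export
feret_diameters <- function(mask, spacing = NULL) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  hull <- corner_hull(mask, spacing)
  n <- nrow(hull)
  # max: largest pairwise distance between hull vertices
  d2max <- 0
  for (i in seq_len(n - 1)) {
    d2 <- (hull[(i + 1):n, 1] - hull[i, 1])^2 + (hull[(i + 1):n, 2] - hull[i, 2])^2
    d2max <- max(d2max, d2)
  }
  # min: smallest hull width across hull-edge normals
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- hull[, 1] * nrm[1] + hull[, 2] * nrm[2]
    wmin <- min(wmin, max(proj) - min(proj))
  }
  fmax <- sqrt(d2max)
  c(max = fmax, min = wmin, mean = (fmax + wmin) / 2)
}

#' Attenuation statistics inside a mask
#'
#' @param image An [hu_image] (or numeric matrix).
#' @param mask Logical matrix congruent with `image`.
#' @return List with `mean`, `median` (midpoint-interpolated for even
#'   counts), `mode` (most frequent integer-HU bin, ties toward the lowest
#'   HU), `sd` (sample, n-1 denominator; `NA` with `sd_defined = FALSE` for
#'   a single pixel) and `n`.
#' @export
intensity_stats <- function(image, mask) {
  vals <- as.numeric(unclass(image)[mask])
  if (length(vals) == 0) stop("mask is empty", call. = FALSE)
  bins <- round(vals)
  tab <- table(bins)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  list(mean = mean(vals),
       median = stats::median(vals),
       mode = min(modes),
       sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_,
       sd_defined = length(vals) >= 2,
       n = length(vals))
}

#' Histogram skewness and excess kurtosis inside a mask
#'
#' Population-moment estimators: skewness \eqn{m_3 / m_2^{3/2}} and excess
#' kurtosis \eqn{m_4 / m_2^2 - 3} with \eqn{m_k = \frac{1}{N}\sum (x_i -
#' \bar x)^k}; a Gaussian histogram gives skewness 0 and kurtosis 0.
#'
#' @inheritParams intensity_stats
#' @return List with `skewness`, `kurtosis`, `defined` (FALSE when the
#'   region has zero variance or fewer than 3 pixels, in which case both
#'   moments are `NA` rather than NaN).
#' @export
histogram_moments <- function(image, mask) {
  vals <- as.numeric(unclass(image)[mask])
  m2 <- central_moment(vals, 2)
  if (length(vals) < 3 || m2 == 0)
    return(list(skewness = NA_real_, kurtosis = NA_real_, defined = FALSE))
  list(skewness = central_moment(vals, 3) / m2^1.5,
       kurtosis = central_moment(vals, 4) / m2^2 - 3,
       defined = TRUE)
}

#' Linear mass density of a nodule cross-section
#'
#' Mass per unit length of the nodule slice, the 2D analogue of nodule
#' mass: \deqn{LMD = area \times (mean\ HU + 1000) / 1000} in mg/mm, taking
#' water-equivalent density 1 mg/mm^3 and air at -1000 HU (zero mass).
#'
#' @param area Cross-sectional area in mm^2.
#' @param mean_hu Mean attenuation of the segmented region in HU; must be
#'   >= -1000.
#' @return LMD in mg/mm.
#' @examples
#' linear_mass_density(47.90, -600)  # 19.16 mg/mm
#' @export
linear_mass_density <- function(area, mean_hu) {
  if (any(area <= 0)) stop("`area` must be positive", call. = FALSE)
  if (any(mean_hu < -1000))
    stop("`mean_hu` below -1000 HU is outside the physical domain",
         call. = FALSE)
  area * (mean_hu + 1000) / 1000
}

#' Circularity and solidity shape descriptors
#'
#' Circularity is \eqn{4\pi \cdot area / perimeter^2} (1 for a perfect
#' circle); raw values slightly above 1 from contour smoothing are clamped
#' to 1 with a message.  Solidity is the mask area divided by the area of
#' the convex hull of its pixel corners (1 for a convex, indentation-free
#' shape).
#'
#' @param area Area in mm^2.
#' @param perimeter Perimeter in mm (> 0).
#' @param mask The mask (for the convex hull); with `spacing` as elsewhere.
#' @param spacing Optional (row, col) spacing in mm.
#' @return Named numeric vector `c(circularity, solidity)`.
#' @export
shape_descriptors <- function(area, perimeter, mask, spacing = NULL) {
  if (perimeter <= 0) stop("`perimeter` must be positive", call. = FALSE)
  circ <- 4 * pi * area / perimeter^2
  if (circ > 1) {
    message(sprintf("raw circularity %.4f > 1 clamped to 1 (digitization)", circ))
    circ <- 1
  }
  hull <- corner_hull(mask, spacing)
  sol <- area / polygon_area(hull)
  c(circularity = circ, solidity = min(sol, 1))
}

#' Extract the full quantitative feature vector of a nodule
#'
#' Composes the individual measurements into the twelve-feature vector used
#' throughout the package (the three Feret quantities are reported
#' separately but the summary feature is their mean).  The internal
#' consistency `lmd = area * (mean_hu + 1000) / 1000` holds exactly by
#' construction.
#'
#' @param image An [hu_image].
#' @param mask A [nodule_mask] (or logical matrix) congruent with `image`.
#' @param spacing Optional (row, col) spacing in mm.
#' @param perimeter_method Convention passed to [measure_perimeter()].
#' @param smoothing Contour smoothing window for the default convention.
#' @return An `nsn_features` named numeric vector with elements
#'   `feret_mean`, `feret_max`, `feret_min`, `perimeter`, `area`,
#'   `mean_hu`, `median_hu`, `mode_hu`, `sd_hu`, `lmd`, `skewness`,
#'   `kurtosis`, `circularity`, `solidity`.
#' @export
extract_features <- function(image, mask, spacing = NULL,
                             perimeter_method = "contour", smoothing = 5) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  sp <- mask_spacing(mask, spacing %||% attr(image, "pixel_spacing"))
  area <- measure_area(mask, sp)
  perim <- measure_perimeter(mask, sp, method = perimeter_method,
                             smoothing = smoothing)
  fer <- feret_diameters(mask, sp)
  ints <- intensity_stats(image, mask)
  mom <- histogram_moments(image, mask)
  shp <- shape_descriptors(area, perim, mask, sp)
  nsn_features(c(
    feret_mean = unname(fer["mean"]), feret_max = unname(fer["max"]),
    feret_min = unname(fer["min"]),
    perimeter = perim, area = area,
    mean_hu = ints$mean, median_hu = ints$median, mode_hu = ints$mode,
    sd_hu = ints$sd,
    lmd = linear_mass_density(area, ints$mean),
    skewness = mom$skewness, kurtosis = mom$kurtosis,
    circularity = unname(shp["circularity"]),
    solidity = unname(shp["solidity"])))
}

feature_names <- c("feret_mean", "feret_max", "feret_min", "perimeter",
                   "area", "mean_hu", "median_hu", "mode_hu", "sd_hu",
                   "lmd", "skewness", "kurtosis", "circularity", "solidity")

# the twelve features reported in cohort tables (Feret summary only)
reported_feature_names <- c("feret_mean", "perimeter", "area", "mean_hu",
                            "median_hu", "mode_hu", "sd_hu", "lmd",
                            "skewness", "kurtosis", "circularity", "solidity")

#' Feature vector constructor
#'
#' @param x Named numeric vector covering all feature names (see
#'   [extract_features()]).
#' @return An `nsn_features` object.
#' @export
nsn_features <- function(x) {
  if (!is.numeric(x) || !all(feature_names %in% names(x)))
    stop("feature vector must contain: ",
         paste(feature_names, collapse = ", "), call. = FALSE)
  structure(as.numeric(x[feature_names]), names = feature_names,
            class = "nsn_features")
}

#' @export
print.nsn_features <- function(x, ...) {
  cat("<nsn_features>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Average two repeated measurements of the same nodule
#'
#' Reliability practice: the analysis is repeated after an interval and the
#' element-wise mean of the two feature vectors is used downstream.
#'
#' @param a,b `nsn_features` vectors of the same nodule.
#' @return The element-wise mean, an `nsn_features` vector.
#' @export
average_repeats <- function(a, b) {
  stopifnot(inherits(a, "nsn_features"), inherits(b, "nsn_features"))
  nsn_features((unclass(a) + unclass(b)[names(a)]) / 2)
}
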