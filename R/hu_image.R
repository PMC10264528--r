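# Calibrated 2D CT attenuation grid.
#
# Coordinate convention (used everywhere in the package): 0-based (row, col),
# pixel centers at integer coordinates, so pixel (i, j) occupies the square
# [i - 0.5, i + 0.5] x [j - 0.5, j + 0.5] in pixel units.  Physical positions
# are pixel coordinates multiplied by the per-axis spacing in mm.

#' Construct a calibrated HU image
#'
#' An `hu_image` is a numeric matrix of CT attenuation values in Hounsfield
#' units (HU; air = -1000, water = 0) together with its physical pixel
#' spacing.  All segmentation and feature operations in the package consume
#' this container.
#'
#' @param values Numeric matrix of attenuation values (HU). All values must
#'   be finite.
#' @param pixel_spacing Numeric vector of length 1 or 2: physical size of one
#'   pixel in mm as (row spacing, column spacing). A single value is used for
#'   both axes.
#' @return An object of class `hu_image`: the matrix with a `pixel_spacing`
#'   attribute and an origin-convention tag.
#' @examples
#' img <- hu_image(matrix(-900, 10, 10), pixel_spacing = 0.7)
#' pixel_spacing(img)
#' @export
hu_image <- function(values, pixel_spacing = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite everywhere", call. = FALSE)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop("`pixel_spacing` must be one or two positive finite values (mm)",
         call. = FALSE)
  structure(values,
            pixel_spacing = pixel_spacing,
            origin = "0-based (row, col), pixel centers at integers",
            class = c("hu_image", "matrix", "array"))
}

#' @rdname hu_image
#' @param x An `hu_image`.
#' @export
pixel_spacing <- function(x) {
  sp <- attr(x, "pixel_spacing")
  if (is.null(sp)) stop("object has no pixel spacing", call. = FALSE)
  sp
}

#' @export
print.hu_image <- function(x, ...) {
  sp <- pixel_spacing(x)
  cat(sprintf("<hu_image> %d x %d pixels, spacing %.4g x %.4g mm, HU range [%.1f, %.1f]\n",
              nrow(x), ncol(x), sp[1], sp[2], min(x), max(x)))
  invisible(x)
}

is_hu_image <- function(x) inherits(x, "hu_image")

# strip class/attributes, keep plain matrix
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "pixel_spacing") <- NULL
  attr(y, "origin") <- NULL
  y
}
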