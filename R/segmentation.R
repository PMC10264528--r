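# Threshold segmentation of nonsolid nodules inside a hand-drawn polygonal
# ROI.  The workflow mirrors standard 2D densitometry practice: outline the
# nodule with a polygon, keep pixels at or above a fixed attenuation
# threshold (default -800 HU), retain the largest 8-connected component and
# fill interior holes.

#' Polygonal region of interest
#'
#' Vertices are given in pixel coordinates as (row, col) pairs, 0-based,
#' with pixel centers at integer coordinates.  The polygon must be simple
#' (non-self-intersecting) and have at least three vertices; it is treated
#' as closed (last vertex joins the first).
#'
#' @param vertices Numeric matrix (n x 2) or data.frame with columns
#'   (row, col).
#' @return An object of class `roi_polygon`.
#' @examples
#' roi_polygon(cbind(row = c(1, 1, 8, 8), col = c(1, 8, 8, 1)))
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3 || any(!is.finite(v)))
    stop("ROI polygon needs >= 3 finite (row, col) vertices", call. = FALSE)
  colnames(v) <- c("row", "col")
  # drop a duplicated closing vertex
  if (nrow(v) > 3 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (polygon_self_intersects(v))
    stop("ROI polygon is self-intersecting; a simple polygon is required",
         call. = FALSE)
  structure(list(vertices = v, closed = TRUE), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %d vertices, row range [%.4g, %.4g], col range [%.4g, %.4g]\n",
              nrow(x$vertices), min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2])))
  invisible(x)
}

# segment intersection test for simplicity check (proper crossings and
# mid-segment touches count; shared endpoints of adjacent edges do not)
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r)
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
  (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Rasterize a polygonal ROI onto an image grid
#'
#' A pixel belongs to the rasterized ROI iff its center lies inside the
#' polygon under the even-odd rule; pixel centers falling exactly on the
#' polygon boundary are included.
#'
#' @param polygon An [roi_polygon] (or a vertex matrix coercible to one).
#' @param image_shape Integer vector (n_rows, n_cols) or a matrix/`hu_image`
#'   whose dimensions are used.
#' @return Logical matrix of the requested shape.
#' @examples
#' sq <- roi_polygon(cbind(c(0.5, 0.5, 3.5, 3.5), c(0.5, 3.5, 3.5, 0.5)))
#' sum(rasterize_roi(sq, c(6, 6)))  # 9 pixel centers inside
#' @export
rasterize_roi <- function(polygon, image_shape) {
  if (!inherits(polygon, "roi_polygon")) polygon <- roi_polygon(polygon)
  shape <- if (is.matrix(image_shape)) dim(image_shape) else as.integer(image_shape)
  if (length(shape) != 2 || any(shape < 1))
    stop("`image_shape` must be two positive integers", call. = FALSE)
  v <- polygon$vertices
  if (min(v[, 1]) < -0.5 || max(v[, 1]) > shape[1] - 0.5 ||
      min(v[, 2]) < -0.5 || max(v[, 2]) > shape[2] - 0.5)
    stop("ROI polygon extends outside the image bounds", call. = FALSE)
  # restrict the point-in-polygon sweep to the bounding box
  r0 <- max(0L, floor(min(v[, 1])));  r1 <- min(shape[1] - 1L, ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2])));  c1 <- min(shape[2] - 1L, ceiling(max(v[, 2])))
  out <- matrix(FALSE, shape[1], shape[2])
  if (r1 < r0 || c1 < c0) return(out)
  pr <- rep(r0:r1, times = c1 - c0 + 1)
  pc <- rep(c0:c1, each = r1 - r0 + 1)
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  n <- nrow(v)
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    r_i <- v[i, 1]; c_i <- v[i, 2]; r_j <- v[j, 1]; c_j <- v[j, 2]
    # even-odd crossing test on the (col as x, row as y) plane
    crosses <- ((c_i > pc) != (c_j > pc)) &
      (pr < (r_j - r_i) * (pc - c_i) / (c_j - c_i) + r_i)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # boundary tie -> inclusion: point within eps of the segment
    dr <- r_j - r_i; dc <- c_j - c_i
    len2 <- dr * dr + dc * dc
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((pr - r_i) * dr + (pc - c_i) * dc) / len2))
      d2 <- (pr - (r_i + t * dr))^2 + (pc - (c_i + t * dc))^2
    } else {
      d2 <- (pr - r_i)^2 + (pc - c_i)^2
    }
    on_edge <- on_edge | d2 < eps
  }
  keep <- inside | on_edge
  out[cbind(pr[keep] + 1L, pc[keep] + 1L)] <- TRUE
  out
}

#' Binary nodule mask with segmentation provenance
#'
#' Created by [threshold_segment()]; a logical grid congruent with the
#' source image, carrying the threshold used, the connectivity convention
#' and the pixel spacing.
#'
#' @param grid Logical matrix.
#' @param pixel_spacing (row, col) spacing in mm.
#' @param threshold_used HU threshold recorded for provenance.
#' @param connectivity Foreground connectivity used for component labelling.
#' @return An object of class `nodule_mask`.
#' @export
nodule_mask <- function(grid, pixel_spacing = 1, threshold_used = NA_real_,
                        connectivity = 8) {
  if (!is.matrix(grid) || !is.logical(grid))
    stop("`grid` must be a logical matrix", call. = FALSE)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  structure(grid,
            pixel_spacing = pixel_spacing,
            threshold_used = threshold_used,
            connectivity = connectivity,
            class = c("nodule_mask", "matrix", "array"))
}

#' @export
print.nodule_mask <- function(x, ...) {
  sp <- attr(x, "pixel_spacing")
  cat(sprintf("<nodule_mask> %d x %d grid, %d foreground pixels, threshold %s HU, spacing %.4g x %.4g mm\n",
              nrow(x), ncol(x), sum(x),
              format(attr(x, "threshold_used")), sp[1], sp[2]))
  invisible(x)
}

#' Label connected components of a binary grid
#'
#' Components of the foreground under 8- (default) or 4-connectivity.
#' Used internally by [threshold_segment()] and exported because the
#' labelling convention is part of the segmentation contract.
#'
#' @param grid Logical matrix.
#' @param connectivity 8 or 4.
#' @return Integer matrix; 0 is background, components are numbered from 1
#'   in order of their first pixel in column-major order.
#' @details Uses the run-based two-pass algorithm: maximal vertical runs of
#'   foreground are extracted per column and merged across adjacent columns
#'   with union-find, so cost scales with the number of runs rather than
#'   pixels.
#' @export
label_components <- function(grid, connectivity = 8) {
  stopifnot(is.matrix(grid))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  if (!any(grid)) return(lab)
  # maximal TRUE-runs per column
  run_col <- integer(0); run_s <- integer(0); run_e <- integer(0)
  col_first <- integer(nc + 1)  # index of first run of each column in the vectors
  for (j in seq_len(nc)) {
    col_first[j] <- length(run_s) + 1L
    cj <- grid[, j]
    if (any(cj)) {
      r <- rle(cj)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      run_col <- c(run_col, rep.int(j, sum(keep)))
      run_s <- c(run_s, starts[keep])
      run_e <- c(run_e, ends[keep])
    }
  }
  col_first[nc + 1] <- length(run_s) + 1L
  nruns <- length(run_s)
  parent <- seq_len(nruns)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == "8") 1L else 0L
  for (j in seq_len(nc - 1L)) {
    a0 <- col_first[j]; a1 <- col_first[j + 1] - 1L
    b0 <- col_first[j + 1]; b1 <- col_first[j + 2] - 1L
    if (a1 < a0 || b1 < b0) next
    for (a in a0:a1) {
      for (b in b0:b1) {
        if (run_s[a] <= run_e[b] + slack && run_s[b] <= run_e[a] + slack) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  root <- vapply(seq_len(nruns), find, integer(1))
  # number components by their first pixel in column-major order
  first_px <- (run_col - 1L) * nr + run_s
  comp_first <- tapply(first_px, root, min)
  ordered_roots <- as.integer(names(sort(comp_first)))
  comp_id <- integer(nruns)
  comp_id[ordered_roots] <- seq_along(ordered_roots)
  for (k in seq_len(nruns))
    lab[run_s[k]:run_e[k], run_col[k]] <- comp_id[root[k]]
  lab
}

#' Fill interior holes of a binary mask
#'
#' Background pixels not reachable from the image border through 4-connected
#' background are interior holes and are set to foreground.
#'
#' @param grid Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  # pad with one background ring so all outside background is one component
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- grid
  bg <- label_components(!pad, connectivity = 4)
  outside_label <- bg[1, 1]
  filled <- pad | (bg != outside_label)
  filled[2:(nr + 1), 2:(nc + 1)]
}

#' Segment a nodule by fixed attenuation threshold inside an ROI
#'
#' Keeps ROI pixels with attenuation at or above `threshold` (inclusive,
#' default -800 HU), labels 8-connected components, retains the largest
#' (ties broken toward the component appearing first in column-major
#' order), and fills interior holes (4-connected background).
#'
#' @param image An [hu_image].
#' @param roi Logical matrix congruent with `image`, or an [roi_polygon]
#'   which is rasterized first.
#' @param threshold Attenuation threshold in HU; pixels with `HU >=
#'   threshold` are candidate foreground.
#' @param connectivity Foreground connectivity (8 or 4).
#' @param fill_holes Fill interior holes after component selection.
#' @return A [nodule_mask].
#' @examples
#' img <- hu_image(matrix(-900, 12, 12), 0.7)
#' img[4:9, 4:9] <- -600
#' roi <- matrix(TRUE, 12, 12)
#' m <- threshold_segment(img, roi)
#' sum(m)  # 36
#' @export
threshold_segment <- function(image, roi, threshold = -800,
                              connectivity = 8, fill_holes = TRUE) {
  if (!is_hu_image(image)) stop("`image` must be an hu_image", call. = FALSE)
  if (inherits(roi, "roi_polygon")) roi <- rasterize_roi(roi, dim(image))
  if (!is.matrix(roi) || !is.logical(roi) || !all(dim(roi) == dim(image)))
    stop("`roi` must be a logical matrix congruent with the image",
         call. = FALSE)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  vals <- as_plain_matrix(image)
  cand <- roi & (vals >= threshold)
  if (!any(cand))
    stopf("no nodule at threshold %g HU: ROI attenuation range is [%g, %g] HU",
          threshold, min(vals[roi]), max(vals[roi]))
  lab <- label_components(cand, connectivity = connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)  # ties -> lowest label (first in column-major order)
  m <- lab == keep
  if (fill_holes) {
    m <- fill_holes(m)
    m <- m & roi  # hole filling cannot escape the ROI
  }
  nodule_mask(m, pixel_spacing = pixel_spacing(image),
              threshold_used = threshold, connectivity = connectivity)
}

#' Select the slice with the largest segmented cross-section
#'
#' Quantification is performed on the largest cross-sectional area of the
#' nodule; given candidate slices (each an image plus its ROI), segments
#' each and returns the index of the largest post-segmentation area in mm^2.
#'
#' @param slices List, each element a list with components `image`
#'   ([hu_image]) and `roi` (logical matrix or [roi_polygon]).
#' @param threshold HU threshold passed to [threshold_segment()].
#' @param ... Further arguments for [threshold_segment()].
#' @return Integer index (1-based) of the selected slice, with attributes
#'   `areas` (mm^2 per slice, NA where segmentation failed) and `tie`
#'   (TRUE when the maximum was not unique; the lowest index is returned).
#' @export
select_largest_slice <- function(slices, threshold = -800, ...) {
  if (!is.list(slices) || length(slices) < 1)
    stop("`slices` must be a non-empty list", call. = FALSE)
  areas <- vapply(slices, function(s) {
    m <- tryCatch(threshold_segment(s$image, s$roi, threshold = threshold, ...),
                  error = function(e) NULL)
    if (is.null(m)) NA_real_ else measure_area(m)
  }, numeric(1))
  if (all(is.na(areas)))
    stop("no slice could be segmented at the requested threshold",
         call. = FALSE)
  best <- which(areas == max(areas, na.rm = TRUE))
  if (length(best) > 1)
    message("largest-slice tie between slices ", paste(best, collapse = ", "),
            "; taking the lowest index")
  structure(best[1], areas = areas, tie = length(best) > 1)
}
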