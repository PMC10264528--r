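# Synthetic CT generator: single ground-glass-nodule slices, baseline /
# follow-up pairs with a known LMD growth factor, and whole cohorts with
# known group structure.  Everything is seeded and reproducible; ground
# truth is returned alongside every image so downstream stages can be
# tested without patient data.

#' Specification of one synthetic ground-glass nodule
#'
#' @param shape_type `"ellipse"` or `"fourier_blob"` (ellipse with random
#'   low-order radial harmonics controlled by `boundary_irregularity`).
#' @param equivalent_diameter Diameter in mm of the circle with the
#'   nodule's area. The default validation range is 6-30 mm, the axial
#'   size band of nonsolid nodules the pipeline targets.
#' @param aspect_ratio Major/minor axis ratio, >= 1.
#' @param boundary_irregularity In [0, 1]; 0 is a smooth ellipse.
#' @param attenuation_mean Mean interior attenuation in HU; must lie in
#'   (-800, -200) so the interior sits above the segmentation threshold but
#'   below solid-tissue density.
#' @param attenuation_sd Interior attenuation SD in HU (>= 0).
#' @param attenuation_skewness Target skewness of the interior histogram;
#'   positive values use a shifted-gamma law, 0 a symmetric Gaussian.
#' @param seed Integer seed driving all randomness for this nodule.
#' @param validate Enforce the diameter and attenuation ranges.
#' @return A `nodule_spec` list.
#' @export
nodule_spec <- function(shape_type = c("ellipse", "fourier_blob"),
                        equivalent_diameter = 10,
                        aspect_ratio = 1,
                        boundary_irregularity = 0,
                        attenuation_mean = -620,
                        attenuation_sd = 130,
                        attenuation_skewness = 0.8,
                        seed = 1L,
                        validate = TRUE) {
  shape_type <- match.arg(shape_type)
  if (validate) {
    if (attenuation_mean <= -800 || attenuation_mean >= -200)
      stopf("attenuation_mean %g HU outside (-800, -200): interior must be above the segmentation threshold and below solid density",
            attenuation_mean)
    if (equivalent_diameter < 6 || equivalent_diameter > 30)
      stopf("equivalent_diameter %g mm outside the 6-30 mm nodule range (use validate = FALSE to override)",
            equivalent_diameter)
  }
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1", call. = FALSE)
  if (boundary_irregularity < 0 || boundary_irregularity > 1)
    stop("boundary_irregularity must lie in [0, 1]", call. = FALSE)
  if (attenuation_sd < 0) stop("attenuation_sd must be >= 0", call. = FALSE)
  structure(list(shape_type = shape_type,
                 equivalent_diameter = equivalent_diameter,
                 aspect_ratio = aspect_ratio,
                 boundary_irregularity = boundary_irregularity,
                 attenuation_mean = attenuation_mean,
                 attenuation_sd = attenuation_sd,
                 attenuation_skewness = attenuation_skewness,
                 seed = as.integer(seed)),
            class = "nodule_spec")
}

# Sample n interior attenuations with the requested (mean, sd, skewness).
# Positive skewness: shifted gamma with shape 4/skew^2, scale sd*skew/2,
# location mean - shape*scale (closed-form moment match).  skewness == 0:
# Gaussian fallback (the gamma law cannot represent it).  Negative
# skewness is rejected.
sample_attenuation_law <- function(n, mean, sd, skewness,
                                   law = c("auto", "gamma", "gaussian"),
                                   moment_match = TRUE) {
  law <- match.arg(law)
  if (sd == 0) return(rep(mean, n))
  if (law == "auto") law <- if (skewness == 0) "gaussian" else "gamma"
  if (law == "gamma") {
    if (skewness <= 0)
      stopf("the shifted-gamma attenuation law requires skewness > 0 (got %g); request skewness 0 with the gaussian law instead",
            skewness)
    shape <- 4 / skewness^2
    scale <- sd * skewness / 2
    x <- stats::rgamma(n, shape = shape, scale = scale) + (mean - shape * scale)
  } else {
    if (skewness != 0)
      stopf("the gaussian attenuation law is symmetric; skewness %g is unattainable", skewness)
    x <- stats::rnorm(n, mean, sd)
  }
  if (moment_match && n >= 2 && stats::sd(x) > 0) {
    # pin the sample mean and SD exactly; an affine map with positive slope
    # leaves skewness and kurtosis untouched
    x <- (x - mean(x)) / stats::sd(x) * sd + mean
  }
  x
}

# radius of the nodule outline at polar angles theta (pixel-free, in mm)
outline_radius <- function(spec, theta) {
  r_eq <- spec$equivalent_diameter / 2
  a <- r_eq * sqrt(spec$aspect_ratio)
  b <- r_eq / sqrt(spec$aspect_ratio)
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (spec$shape_type == "fourier_blob" && spec$boundary_irregularity > 0) {
    harm <- with_seed(spec$seed + 17L, {
      k <- 2:6
      amp <- stats::runif(length(k), 0, 1) * spec$boundary_irregularity / length(k) * 2
      phase <- stats::runif(length(k), 0, 2 * pi)
      list(k = k, amp = amp, phase = phase)
    })
    mod <- rep(0, length(theta))
    for (i in seq_along(harm$k))
      mod <- mod + harm$amp[i] * cos(harm$k[i] * theta + harm$phase[i])
    r <- r * (1 + mod)
  }
  r
}

#' Render a synthetic nodule on a parenchyma background
#'
#' Produces a calibrated HU slice: Gaussian parenchyma background (default
#' -900 +/- 50 HU), a nodule whose interior attenuations follow the
#' shifted-gamma / Gaussian law of the spec, composited by per-pixel
#' maximum so the nodule is separable at the -800 HU threshold, and an
#' optional one-pixel linear partial-volume blend band at the boundary.
#'
#' @param spec A [nodule_spec].
#' @param background_mean,background_sd Parenchyma attenuation law (HU).
#' @param pixel_spacing Pixel size in mm (scalar or (row, col)).
#' @param margin_mm Background margin around the nodule (>= 5 mm).
#' @param edge_blend Apply the one-pixel partial-volume blend band.
#' @param law Attenuation law selection (see details in [nodule_spec()]).
#' @param moment_match Pin the sample mean/SD of the interior draw exactly
#'   to the spec values (affine correction; leaves skewness untouched).
#' @param orientation Rotation of the nodule outline in radians.
#' @return A `synthetic_nodule` list: `image` ([hu_image]), `true_mask`
#'   ([nodule_mask] of pixel centers inside the outline), `ground_truth`
#'   (area/diameter plus moments of the rendered interior pixels, and the
#'   implied LMD), `spec`, and the render parameters (needed to render a
#'   follow-up).
#' @export
render_nodule <- function(spec, background_mean = -900, background_sd = 50,
                          pixel_spacing = 0.7, margin_mm = 5,
                          edge_blend = TRUE, law = "auto",
                          moment_match = TRUE, orientation = 0) {
  stopifnot(inherits(spec, "nodule_spec"))
  sp <- as.numeric(pixel_spacing)
  if (length(sp) == 1) sp <- rep(sp, 2)
  if (any(sp <= 0)) stop("pixel_spacing must be positive", call. = FALSE)
  if (margin_mm < 5) stop("margin_mm must be >= 5 mm", call. = FALSE)
  # fail early on unsatisfiable moment triples
  if (spec$attenuation_sd > 0) {
    if (spec$attenuation_skewness < 0)
      stopf("attenuation_skewness %g < 0 is unattainable: the shifted-gamma law has positive skew and the gaussian fallback is symmetric",
            spec$attenuation_skewness)
    if (law == "gamma" && spec$attenuation_skewness <= 0)
      stopf("the shifted-gamma attenuation law requires skewness > 0 (got %g)",
            spec$attenuation_skewness)
  }
  r_max <- spec$equivalent_diameter / 2 * sqrt(spec$aspect_ratio) *
    (1 + spec$boundary_irregularity)
  half_mm <- r_max + margin_mm
  nr <- 2L * ceiling(half_mm / sp[1]) + 1L
  nc <- 2L * ceiling(half_mm / sp[2]) + 1L
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)          # pixel coords of the center
  rows <- (matrix(0:(nr - 1), nr, nc) - ctr[1]) * sp[1]
  cols <- (matrix(0:(nc - 1), nr, nc, byrow = TRUE) - ctr[2]) * sp[2]
  rho <- sqrt(rows^2 + cols^2)
  theta <- atan2(cols, rows) - orientation
  r_out <- matrix(outline_radius(spec, as.numeric(theta)), nr, nc)
  px <- sqrt(sp[1] * sp[2])
  coverage <- if (edge_blend)
    pmin(1, pmax(0, 0.5 + (r_out - rho) / px))
  else
    as.numeric(rho <= r_out)
  mask <- rho <= r_out
  img <- with_seed(spec$seed, {
    bg <- matrix(stats::rnorm(nr * nc, background_mean, background_sd), nr, nc)
    touched <- which(coverage > 0)
    nod_vals <- sample_attenuation_law(length(touched), spec$attenuation_mean,
                                       spec$attenuation_sd,
                                       spec$attenuation_skewness,
                                       law = law, moment_match = moment_match)
    nod <- bg
    # per-pixel max guarantees the nodule is never darker than parenchyma
    nod[touched] <- pmax(bg[touched],
                         coverage[touched] * nod_vals +
                           (1 - coverage[touched]) * bg[touched])
    nod
  })
  image <- hu_image(img, pixel_spacing = sp)
  tmask <- nodule_mask(mask, pixel_spacing = sp, threshold_used = NA_real_,
                       connectivity = 8)
  inside <- img[mask]
  m2 <- central_moment(inside, 2)
  area <- sum(mask) * sp[1] * sp[2]
  gt <- list(area = area,
             equivalent_diameter = spec$equivalent_diameter,
             mean_hu = mean(inside),
             sd_hu = if (length(inside) >= 2) stats::sd(inside) else NA_real_,
             skewness = if (m2 > 0) central_moment(inside, 3) / m2^1.5 else NA_real_,
             kurtosis = if (m2 > 0) central_moment(inside, 4) / m2^2 - 3 else NA_real_,
             moments_defined = m2 > 0,
             lmd = area * (mean(inside) + 1000) / 1000)
  structure(list(image = image, true_mask = tmask, ground_truth = gt,
                 spec = spec,
                 render_params = list(background_mean = background_mean,
                                      background_sd = background_sd,
                                      pixel_spacing = sp,
                                      margin_mm = margin_mm,
                                      edge_blend = edge_blend, law = law,
                                      moment_match = moment_match,
                                      orientation = orientation)),
            class = "synthetic_nodule")
}

#' @export
print.synthetic_nodule <- function(x, ...) {
  cat(sprintf("<synthetic_nodule> %s, d = %g mm; image %d x %d px; true area %.2f mm^2, LMD %.2f mg/mm\n",
              x$spec$shape_type, x$spec$equivalent_diameter,
              nrow(x$image), ncol(x$image),
              x$ground_truth$area, x$ground_truth$lmd))
  invisible(x)
}

#' Growth scenario connecting two scans
#'
#' @param true_doubling_time Doubling time in days (positive, `Inf` for a
#'   stable nodule).
#' @param scan_interval Days between baseline and follow-up (> 0).
#' @param lmd_change_sign `"+"` (growth), `"0"` (stable up to noise) or
#'   `"-"` (shrinkage with `true_doubling_time` read as a halving time).
#' @return A `growth_scenario` list; its implied LMD ratio is
#'   `2^(scan_interval / true_doubling_time)` for `"+"`.
#' @export
growth_scenario <- function(true_doubling_time, scan_interval,
                            lmd_change_sign = c("+", "0", "-")) {
  lmd_change_sign <- match.arg(lmd_change_sign)
  if (!is.finite(scan_interval) || scan_interval <= 0)
    stop("scan_interval must be positive and finite", call. = FALSE)
  if (is.na(true_doubling_time) || true_doubling_time <= 0)
    stop("true_doubling_time must be positive (or Inf)", call. = FALSE)
  if (lmd_change_sign %in% c("+", "-") && !is.finite(true_doubling_time))
    stopf("lmd_change_sign '%s' requires a finite doubling time", lmd_change_sign)
  structure(list(true_doubling_time = true_doubling_time,
                 scan_interval = scan_interval,
                 lmd_change_sign = lmd_change_sign),
            class = "growth_scenario")
}

#' Render the follow-up scan of a synthetic nodule
#'
#' The follow-up nodule's true LMD equals the baseline LMD times
#' `2^(scan_interval / DT)` (growth) — realized by splitting the LMD factor
#' geometrically between the area and the mass-per-area channel
#' (`mean + 1000`), since growth of a real nodule couples size and density.
#'
#' @param baseline A `synthetic_nodule` from [render_nodule()].
#' @param scenario A [growth_scenario].
#' @param split Fraction of the LMD factor (in log space) assigned to
#'   area; the remainder scales `mean + 1000`. Default 0.5.
#' @param seed Seed for the follow-up rendering; defaults to the baseline
#'   seed + 1.
#' @return List with `nodule` (the follow-up `synthetic_nodule`) and
#'   `true_lmd_ratio` (the exact configured factor).
#' @export
render_followup <- function(baseline, scenario, split = 0.5, seed = NULL) {
  stopifnot(inherits(baseline, "synthetic_nodule"),
            inherits(scenario, "growth_scenario"))
  if (split < 0 || split > 1) stop("split must lie in [0, 1]", call. = FALSE)
  ratio <- switch(scenario$lmd_change_sign,
                  "+" = 2^(scenario$scan_interval / scenario$true_doubling_time),
                  "0" = 1,
                  "-" = 2^(-scenario$scan_interval / scenario$true_doubling_time))
  spec <- baseline$spec
  area_factor <- ratio^split
  dens_factor <- ratio^(1 - split)
  new_mean <- (spec$attenuation_mean + 1000) * dens_factor - 1000
  if (new_mean >= -200)
    stopf("requested LMD ratio %.3f would raise mean attenuation to %.1f HU (>= -200 HU): the nodule would no longer be nonsolid",
          ratio, new_mean)
  if (new_mean <= -800)
    stopf("requested LMD ratio %.3f would lower mean attenuation to %.1f HU (<= -800 HU): the nodule would fall below the segmentation threshold",
          ratio, new_mean)
  new_spec <- nodule_spec(shape_type = spec$shape_type,
                          equivalent_diameter = spec$equivalent_diameter * sqrt(area_factor),
                          aspect_ratio = spec$aspect_ratio,
                          boundary_irregularity = spec$boundary_irregularity,
                          attenuation_mean = new_mean,
                          attenuation_sd = spec$attenuation_sd,
                          attenuation_skewness = spec$attenuation_skewness,
                          seed = seed %||% (spec$seed + 1L),
                          validate = FALSE)
  rp <- baseline$render_params
  fu <- render_nodule(new_spec,
                      background_mean = rp$background_mean,
                      background_sd = rp$background_sd,
                      pixel_spacing = rp$pixel_spacing,
                      margin_mm = rp$margin_mm,
                      edge_blend = rp$edge_blend, law = rp$law,
                      moment_match = rp$moment_match,
                      orientation = rp$orientation)
  list(nodule = fu, true_lmd_ratio = ratio)
}

#' Add simulated repeat-measurement (rater) noise to cohort features
#'
#' Emulates the second reading of the baseline images: each feature column
#' receives independent Gaussian noise whose variance is chosen so the
#' expected single-measurement agreement ICC equals `icc_target`
#' (noise variance = between-nodule variance x (1 - ICC) / ICC).
#'
#' @param features Numeric matrix or data.frame (nodules x features).
#' @param icc_target Target ICC in (0, 1].
#' @param seed Integer seed.
#' @return List of two matrices `set1`, `set2` (independent noisy reads).
#' @export
simulate_repeat_measurement <- function(features, icc_target = 0.88, seed = 1L) {
  x <- as.matrix(features)
  if (icc_target <= 0 || icc_target > 1)
    stop("icc_target must lie in (0, 1]", call. = FALSE)
  with_seed(seed, {
    noisy <- function() {
      y <- x
      for (j in seq_len(ncol(x))) {
        vb <- stats::var(x[, j])
        ve <- vb * (1 - icc_target) / icc_target
        y[, j] <- x[, j] + stats::rnorm(nrow(x), 0, sqrt(ve))
      }
      y
    }
    list(set1 = noisy(), set2 = noisy())
  })
}
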