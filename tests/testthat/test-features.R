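# The twelve quantitative features, checked against hand computations and
# brute-force oracles.

test_that("area is pixel count times pixel area", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  expect_equal(measure_area(m, 0.5), 0.25)
  sq <- matrix(FALSE, 25, 25); sq[3:22, 3:22] <- TRUE
  expect_equal(measure_area(sq, 0.7), 196)
  # rasterized disk r = 10 mm at 0.5 mm: within a one-pixel boundary band
  d <- disk_mask(20)
  expect_lt(abs(measure_area(d, 0.5) - pi * 100), 2 * pi * 10 * 0.5)
  expect_error(measure_area(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("boundary tracing follows the marching-squares 0.5-level convention", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  ct <- trace_boundary(m, spacing = 1)
  expect_equal(nrow(ct), 4)  # closed diamond
  expect_equal(measure_perimeter(ct), 2 * sqrt(2))
  # 2 x 2 block: hand-derived marching squares gives 4 sides + 4 corner cuts
  m2 <- matrix(FALSE, 6, 6); m2[3:4, 3:4] <- TRUE
  expect_equal(measure_perimeter(m2, 1, method = "raw_contour"), 4 + 2 * sqrt(2))
  # disk r = 20 px: default contour length within 2% of the circumference
  d <- disk_mask(20)
  p <- measure_perimeter(d, 1)
  expect_lt(abs(p - 2 * pi * 20) / (2 * pi * 20), 0.02)
  # open contour is refused
  open_v <- cbind(c(0, 0, 10), c(0, 10, 10))
  expect_error(measure_perimeter(open_v), "not closed")
})

test_that("perimeter of explicit contours is the exact polyline length", {
  sq <- cbind(c(0, 0, 10, 10, 0), c(0, 10, 10, 0, 0))  # closed square, side 10
  expect_equal(measure_perimeter(sq), 40)
  # random blob: returned length equals an independent segment sum
  b <- random_blob_mask(11)
  ct <- trace_boundary(b, spacing = 1)
  v <- rbind(ct, ct[1, ])
  oracle <- sum(sqrt(rowSums((v[-1, ] - v[-nrow(v), ])^2)))
  expect_equal(measure_perimeter(ct), oracle)
})

test_that("Feret diameters match unit-square geometry and brute force", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  f <- feret_diameters(m1, 1)
  expect_equal(unname(f), c(sqrt(2), 1, (sqrt(2) + 1) / 2))
  # 10 x 2 pixel bar at 1 mm
  bar <- matrix(FALSE, 8, 16); bar[4:5, 4:13] <- TRUE
  fb <- feret_diameters(bar, 1)
  expect_equal(unname(fb["max"]), sqrt(10^2 + 2^2))
  expect_equal(unname(fb["min"]), 2)
  # digital disk d = 15 mm: the corner hull inflates the diameter by
  # exactly one pixel, so both calipers sit in [d, d + 2 px]
  dm <- disk_mask(15)  # r = 15 px at 0.5 mm -> d = 15 mm
  fd <- feret_diameters(dm, 0.5)
  expect_lt(abs(fd["max"] - 15.5), 0.5)
  expect_lt(abs(fd["min"] - 15.5), 0.5)
})

test_that("Feret max/min equal brute-force corner oracles on random blobs", {
  for (seed in 1:50) {
    b <- random_blob_mask(seed)
    f <- feret_diameters(b, 1)
    expect_equal(unname(f["max"]), feret_max_oracle(b))
    grid_min <- feret_min_oracle(b)
    # the grid oracle can only overestimate the true minimal width; the
    # width function has kink minima, so the discretization error is
    # first order: at most diam * (pi / n_angles) / 2
    tol <- unname(f["max"]) * (pi / 1800) / 2
    expect_lte(unname(f["min"]), grid_min + 1e-9)
    expect_gte(unname(f["min"]), grid_min - tol - 1e-9)
  }
})

test_that("intensity statistics follow the documented conventions", {
  img <- hu_image(matrix(c(-700, -600, -600, -900), 2, 2), 1)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  s <- intensity_stats(img, mask)
  expect_equal(s$mean, -1900 / 3)
  expect_equal(s$median, -600)
  expect_equal(s$mode, -600)
  expect_equal(s$sd, sd(c(-700, -600, -600)))
  # constant region
  imgc <- hu_image(matrix(-611.59, 3, 3), 1)
  sc <- intensity_stats(imgc, matrix(TRUE, 3, 3))
  expect_equal(sc$mean, -611.59)
  expect_equal(sc$median, -611.59)
  expect_equal(sc$mode, -612)  # integer-HU binning
  expect_equal(sc$sd, 0)
  # mode tie resolves to the lowest HU
  vals <- c(-700, -700, -700, -650, -650, -650, -600)
  imgt <- hu_image(matrix(c(vals, rep(0, 2)), 3, 3), 1)
  st <- intensity_stats(imgt, matrix(c(rep(TRUE, 7), FALSE, FALSE), 3, 3))
  expect_equal(st$mode, -700)
  # single pixel: sd undefined-flagged
  s1 <- intensity_stats(img, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_false(s1$sd_defined)
  expect_true(is.na(s1$sd))
})

test_that("histogram moments use population estimators, excess kurtosis", {
  sym <- hu_image(matrix(c(-700, -650, -600, 0), 2, 2), 1)
  msk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  hm <- histogram_moments(sym, msk)
  expect_equal(hm$skewness, 0)
  # {0,0,0,1}: hand-derived skew 2/sqrt(3), excess kurtosis -2/3
  img <- hu_image(matrix(c(0, 0, 0, 1), 2, 2), 1)
  hm2 <- histogram_moments(img, matrix(TRUE, 2, 2))
  expect_equal(hm2$skewness, 2 / sqrt(3))
  expect_equal(hm2$kurtosis, 7 / 3 - 3)
  # zero variance: flagged NA, not NaN
  hz <- histogram_moments(hu_image(matrix(-500, 3, 3), 1), matrix(TRUE, 3, 3))
  expect_false(hz$defined)
  expect_true(is.na(hz$skewness) && !is.nan(hz$skewness))
  # estimator recovers the skewness of a gamma sample within 3 MC SE
  set.seed(8)
  x <- rgamma(101 * 101, shape = 4 / 1.12^2, scale = 50)
  imgg <- hu_image(matrix(x - 1000, 101, 101), 1)
  hg <- histogram_moments(imgg, matrix(TRUE, 101, 101))
  expect_lt(abs(hg$skewness - 1.12), 0.13)
})

test_that("moments match the direct-summation oracle to 1e-10", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(50:900, 1)
    vals <- round(rnorm(n, -620, 140))
    side <- ceiling(sqrt(n))
    img <- matrix(-1000, side, side)
    msk <- matrix(FALSE, side, side)
    msk[seq_len(n)] <- TRUE
    img[seq_len(n)] <- vals
    hm <- histogram_moments(hu_image(img, 1), msk)
    o <- moments_oracle(vals)
    expect_equal(hm$skewness, unname(o["skewness"]), tolerance = 1e-10)
    expect_equal(hm$kurtosis, unname(o["kurtosis"]), tolerance = 1e-10)
  }
})

test_that("linear mass density is the exact area-density product", {
  expect_equal(linear_mass_density(47.90, -600), 19.16)
  expect_equal(linear_mass_density(123.4, -1000), 0)   # air: zero mass
  expect_equal(linear_mass_density(38.74, -611.59), 38.74 * 388.41 / 1000)
  expect_error(linear_mass_density(10, -1001), "-1000")
  expect_error(linear_mass_density(0, -500), "positive")
})

test_that("shape descriptors behave like circularity and solidity should", {
  # ideal square, analytic inputs: circularity pi/4
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  sh <- shape_descriptors(100, 40, sq, 1)
  expect_equal(unname(sh["circularity"]), pi / 4)
  expect_equal(unname(sh["solidity"]), 1)  # corner hull of a square is itself
  # plus-shaped mask: hand-derived octagon hull area 700, mask area 500
  plus <- matrix(FALSE, 30, 30)
  plus[11:20, ] <- TRUE; plus[, 11:20] <- TRUE
  shp <- shape_descriptors(measure_area(plus, 1),
                           measure_perimeter(plus, 1), plus, 1)
  expect_equal(unname(shp["solidity"]), 500 / 700)
  # large convex masks: solidity within quantization of 1
  expect_gte(extract_features(uniform_image(disk_mask(60)),
                              nodule_mask(disk_mask(60), 1))["solidity"], 0.98)
  # raw circularity > 1 is clamped with a message
  expect_message(sh2 <- shape_descriptors(100, 2, sq, 1), "clamped")
  expect_equal(unname(sh2["circularity"]), 1)
})

test_that("extract_features composes consistently", {
  for (seed in c(3, 14, 27)) {
    spec <- nodule_spec(equivalent_diameter = 11, attenuation_skewness = 1,
                        seed = seed)
    nod <- render_nodule(spec)
    img <- nod$image; mask <- nod$true_mask
    f <- extract_features(img, mask)
    expect_equal(unname(f["area"]), measure_area(mask))
    expect_equal(unname(f["perimeter"]), measure_perimeter(mask))
    expect_equal(unname(f["feret_mean"]),
                 unname(feret_diameters(mask)["mean"]))
    st <- intensity_stats(img, mask)
    expect_equal(unname(f["mean_hu"]), st$mean)
    expect_equal(unname(f["mode_hu"]), st$mode)
    # internal consistency invariant: lmd = area (mean + 1000) / 1000 exactly
    expect_identical(unname(f["lmd"]),
                     unname(f["area"]) * (unname(f["mean_hu"]) + 1000) / 1000)
  }
})

test_that("repeat-measurement averaging is the element-wise mean", {
  spec <- nodule_spec(seed = 5)
  nod <- render_nodule(spec)
  f <- extract_features(nod$image, nod$true_mask)
  expect_equal(average_repeats(f, f), f)
  g <- f
  g["mode_hu"] <- -746.5; f["mode_hu"] <- -746
  expect_equal(unname(average_repeats(f, g)["mode_hu"]), -746.25)
  g["skewness"] <- 1.2; f["skewness"] <- 1.0
  expect_equal(unname(average_repeats(f, g)["skewness"]), 1.1)
})

test_that("features are scale-equivariant and rotation-robust", {
  b <- random_blob_mask(21)
  f1 <- extract_features(uniform_image(b, spacing = 1), nodule_mask(b, 1))
  f2 <- extract_features(uniform_image(b, spacing = 2), nodule_mask(b, 2))
  expect_equal(unname(f2["area"]), 4 * unname(f1["area"]))
  expect_equal(unname(f2["perimeter"]), 2 * unname(f1["perimeter"]))
  expect_equal(unname(f2[c("feret_mean", "feret_max", "feret_min")]),
               2 * unname(f1[c("feret_mean", "feret_max", "feret_min")]))
  same <- c("mean_hu", "median_hu", "mode_hu", "sd_hu", "skewness",
            "kurtosis", "circularity", "solidity")
  expect_equal(unclass(f2[same]), unclass(f1[same]))
  # rasterized ellipse at 0 / 30 / 90 degrees: geometry agrees within 3%
  fs <- sapply(c(0, pi / 6, pi / 2), function(a) {
    m <- ellipse_mask(40, 25, ang = a)
    extract_features(uniform_image(m), nodule_mask(m, 1))[
      c("feret_mean", "perimeter", "area", "circularity", "solidity")]
  })
  spread <- apply(fs, 1, function(x) diff(range(x)) / mean(x))
  expect_true(all(spread < 0.03))
})

test_that("digital disks approach circularity 1 and irregularity lowers it", {
  circ <- sapply(c(20, 60, 100), function(r) {
    m <- disk_mask(r)
    suppressMessages(extract_features(uniform_image(m), nodule_mask(m, 1))["circularity"])
  })
  expect_true(all(circ >= 0.95 & circ <= 1))
  expect_gte(circ[3], 0.99)
  # growing boundary irregularity decreases circularity and solidity
  f_smooth <- extract_features_of_blob(0)
  f_rough <- extract_features_of_blob(0.5)
  expect_gt(unname(f_smooth["circularity"]), unname(f_rough["circularity"]))
  expect_gt(unname(f_smooth["solidity"]), unname(f_rough["solidity"]))
})
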