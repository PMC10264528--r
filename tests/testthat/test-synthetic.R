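# Synthetic CT generator: attenuation law, growth realization, cohorts.

test_that("unsatisfiable moment triples are rejected with a clear reason", {
  expect_error(nodule_spec(attenuation_skewness = -0.4, seed = 1) |>
                 render_nodule(), "unattainable")
  spec0 <- nodule_spec(attenuation_skewness = 0, seed = 1)
  expect_error(render_nodule(spec0, law = "gamma"), "skewness > 0")
  # the symmetric fallback handles skewness 0
  nod <- render_nodule(spec0, pixel_spacing = 0.4, edge_blend = FALSE)
  expect_lt(abs(nod$ground_truth$skewness), 0.3)
})

test_that("a zero-SD spec renders a constant interior, flagged moments", {
  spec <- nodule_spec(equivalent_diameter = 10, attenuation_mean = -600,
                      attenuation_sd = 0, seed = 2)
  nod <- render_nodule(spec, edge_blend = FALSE)
  inside <- nod$image[nod$true_mask]
  expect_true(all(inside == -600))
  expect_equal(nod$ground_truth$sd_hu, 0)
  expect_false(nod$ground_truth$moments_defined)
  expect_true(is.na(nod$ground_truth$skewness))
})

test_that("rendered area matches the analytic ellipse area", {
  spec <- nodule_spec(equivalent_diameter = 20, aspect_ratio = 1, seed = 3,
                      attenuation_skewness = 1)
  nod <- render_nodule(spec, pixel_spacing = 0.7)
  # within one pixel-perimeter band of pi * 10^2
  expect_lt(abs(nod$ground_truth$area - pi * 100), 2 * pi * 10 * 0.7)
  # the ground-truth area is exactly the pixel-count oracle
  expect_equal(nod$ground_truth$area, sum(nod$true_mask) * 0.49)
})

test_that("interior moments recover the spec within 3 MC errors", {
  # nodule large enough for ~1e4 interior pixels; spec placed so the
  # parenchyma floor (per-pixel max compositing) never censors the gamma tail
  spec <- nodule_spec(equivalent_diameter = 30, attenuation_mean = -500,
                      attenuation_sd = 100, attenuation_skewness = 1, seed = 7)
  nod <- render_nodule(spec, pixel_spacing = 0.25, edge_blend = FALSE)
  gt <- nod$ground_truth
  expect_gte(sum(nod$true_mask), 1e4)
  # mean and SD are pinned exactly by moment matching
  expect_equal(gt$mean_hu, -500, tolerance = 1e-10)
  expect_equal(gt$sd_hu, 100, tolerance = 1e-10)
  # skewness: 3 x MC SE of the estimator at n ~ 1.1e4 (measured SE ~ 0.038)
  expect_lt(abs(gt$skewness - 1), 0.12)
})

test_that("follow-up rendering realizes the configured LMD factor", {
  spec <- nodule_spec(equivalent_diameter = 12, attenuation_mean = -600,
                      attenuation_sd = 150, attenuation_skewness = 1.12,
                      seed = 11)
  base <- render_nodule(spec, pixel_spacing = 0.35)
  # one doubling
  fu <- render_followup(base, growth_scenario(1000, 1000, "+"))
  expect_equal(fu$true_lmd_ratio, 2)
  measured <- fu$nodule$ground_truth$lmd / base$ground_truth$lmd
  expect_lt(abs(measured - 2) / 2, 0.02)   # rendering quantization only
  # stable scan: ratio 1, a fresh noise realization of the same nodule
  fu0 <- render_followup(base, growth_scenario(Inf, 1000, "0"))
  expect_equal(fu0$true_lmd_ratio, 1)
  expect_equal(dim(fu0$nodule$image), dim(base$image))
  expect_false(identical(unclass(fu0$nodule$image), unclass(base$image)))
  # growth over 1,020 days at DT 586 days
  fu2 <- render_followup(base, growth_scenario(586, 1020, "+"))
  expect_equal(fu2$true_lmd_ratio, 2^(1020 / 586))
  measured2 <- fu2$nodule$ground_truth$lmd / base$ground_truth$lmd
  expect_lt(abs(measured2 - fu2$true_lmd_ratio) / fu2$true_lmd_ratio, 0.02)
})

test_that("follow-ups that would leave the nonsolid regime are refused", {
  spec <- nodule_spec(equivalent_diameter = 10, attenuation_mean = -350,
                      attenuation_skewness = 1, seed = 4)
  base <- render_nodule(spec)
  # huge growth: density channel would exceed -200 HU
  expect_error(render_followup(base, growth_scenario(100, 1500, "+"), split = 0),
               "no longer be nonsolid")
  # deep shrinkage of a faint nodule: would fall below the threshold
  faint <- render_nodule(nodule_spec(attenuation_mean = -780,
                                     attenuation_skewness = 1, seed = 5))
  expect_error(render_followup(faint, growth_scenario(300, 3000, "-"), split = 0),
               "below the segmentation threshold")
  # inconsistent scenario: growth sign with infinite DT
  expect_error(growth_scenario(Inf, 1000, "+"), "finite doubling time")
})

test_that("rendering and cohort simulation are seed-deterministic", {
  spec <- nodule_spec(seed = 9)
  a <- render_nodule(spec); b <- render_nodule(spec)
  expect_identical(unclass(a$image), unclass(b$image))
  ca <- simulate_cohort(cohort_config(n_nodules = 40, seed = 13))
  cb <- simulate_cohort(cohort_config(n_nodules = 40, seed = 13))
  expect_identical(ca$truth_table, cb$truth_table)
  cc <- simulate_cohort(cohort_config(n_nodules = 40, seed = 14))
  expect_false(identical(ca$truth_table, cc$truth_table))
})

test_that("cohort group structure and feature medians hit their targets", {
  # degenerate growing fraction: every DT at or above the cutoff
  c0 <- simulate_cohort(cohort_config(n_nodules = 30, growing_fraction = 0,
                                      seed = 2))
  expect_true(all(c0$truth_table$dt_days >= DT_CUTOFF_DAYS))
  expect_true(all(c0$truth_table$group == "nongrowing"))
  # large cohort: growing-group median skewness within MC error of 1.12
  cfg <- cohort_config(n_nodules = 5000, seed = 21)
  co <- simulate_cohort(cfg)
  tt <- co$truth_table
  g <- tt$group == "growing"
  expect_lt(abs(median(tt$skewness[g]) - 1.12), 0.03)
  expect_lt(abs(median(tt$lmd[g]) - 26.63) / 26.63, 0.06)
  expect_lt(abs(median(tt$area[!g]) - 32.17) / 32.17, 0.06)
  # labels are consistent with the assigned doubling times
  expect_true(all((tt$dt_days < cfg$dt_cutoff) == g))
})

test_that("repeat-measurement noise lands the target ICC", {
  co <- simulate_cohort(cohort_config(n_nodules = 400, seed = 31))
  feats <- co$truth_table[, c("feret_mean", "perimeter", "area", "mean_hu",
                              "median_hu", "mode_hu", "sd_hu", "lmd",
                              "skewness", "kurtosis", "circularity",
                              "solidity")]
  rm <- simulate_repeat_measurement(feats, icc_target = 0.88, seed = 5)
  icc <- icc_reliability(rm$set1, rm$set2)
  expect_lt(abs(median(icc) - 0.88), 0.04)
})

test_that("image-backed cohorts carry renderable records", {
  co <- simulate_cohort(cohort_config(n_nodules = 3, seed = 17),
                        include_images = TRUE)
  expect_length(co$records, 3)
  ok <- !vapply(co$records, function(r) is.null(r$baseline), logical(1))
  expect_true(all(ok))
  r <- co$records[[1]]
  if (!is.null(r$followup)) {
    m <- r$followup$ground_truth$lmd / r$baseline$ground_truth$lmd
    expect_lt(abs(m - r$true_lmd_ratio) / r$true_lmd_ratio, 0.12)
  }
})
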