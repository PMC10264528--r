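# End-to-end pipeline: per-nodule processing (segment both timepoints,
# extract features, score growth, flag risk) and cohort-level reporting
# (correlation, group-contrast, logistic and ROC tables).

#' Pipeline run configuration
#'
#' Defaults are the operating points of the published workflow: -800 HU
#' segmentation threshold, 1,556-day doubling-time cutoff, and the
#' baseline risk cutoffs skewness 0.90 and LMD 19.16 mg/mm.
#'
#' @param threshold Segmentation threshold (HU).
#' @param dt_cutoff Doubling-time cutoff (days) for the growing label.
#' @param skewness_cutoff Baseline skewness above which a nodule is
#'   flagged high risk.
#' @param lmd_cutoff Baseline LMD (mg/mm) above which a high-risk nodule
#'   escalates to highest risk.
#' @param p_enter,p_remove Stepwise logistic thresholds.
#' @param icc_form ICC form for reliability analysis.
#' @param perimeter_method,smoothing Perimeter convention (see
#'   [measure_perimeter()]).
#' @param seed Seed for any simulation launched from this config.
#' @return A `run_config` list.
#' @export
run_config <- function(threshold = -800, dt_cutoff = 1556,
                       skewness_cutoff = 0.90, lmd_cutoff = 19.16,
                       p_enter = 0.05, p_remove = 0.10, icc_form = "A1",
                       perimeter_method = "contour", smoothing = 5,
                       seed = 1L) {
  vals <- c(threshold, dt_cutoff, skewness_cutoff, lmd_cutoff)
  if (any(!is.finite(vals))) stop("all cutoffs must be finite", call. = FALSE)
  structure(list(threshold = threshold, dt_cutoff = dt_cutoff,
                 skewness_cutoff = skewness_cutoff, lmd_cutoff = lmd_cutoff,
                 p_enter = p_enter, p_remove = p_remove, icc_form = icc_form,
                 perimeter_method = perimeter_method, smoothing = smoothing,
                 seed = as.integer(seed)),
            class = "run_config")
}

as_image <- function(x) if (is_hu_image(x)) x else read_ct(x)
as_roi <- function(x, shape) {
  if (is.character(x)) x <- read_roi(x)
  if (inherits(x, "roi_polygon")) x <- rasterize_roi(x, shape)
  x
}

#' Process one nodule end to end
#'
#' Segments baseline and follow-up, extracts the feature vectors, computes
#' the doubling time on LMD, and assigns the baseline risk flag: `"high"`
#' when baseline skewness exceeds the skewness cutoff, escalating to
#' `"highest"` when baseline LMD also exceeds the LMD cutoff, `"none"`
#' otherwise.  A segmentation failure yields a structured failure record
#' (status + diagnostic), not an error.
#'
#' @param baseline,followup [hu_image]s or image file paths.
#' @param roi_baseline,roi_followup ROI per timepoint: [roi_polygon],
#'   logical matrix, or vertex file path.
#' @param interval_days Days between the scans.
#' @param config A [run_config].
#' @return A `nodule_record` list: `status` (`"ok"` or
#'   `"segmentation_failure"`), per-timepoint `features`, `growth`
#'   ([doubling_time()] result), `risk_flag`, and provenance.
#' @export
run_nodule <- function(baseline, followup, roi_baseline, roi_followup,
                       interval_days, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  img1 <- as_image(baseline); img2 <- as_image(followup)
  one <- function(img, roi) {
    roi <- as_roi(roi, dim(img))
    mask <- threshold_segment(img, roi, threshold = config$threshold)
    extract_features(img, mask, perimeter_method = config$perimeter_method,
                     smoothing = config$smoothing)
  }
  f1 <- tryCatch(one(img1, roi_baseline), error = function(e) e)
  f2 <- tryCatch(one(img2, roi_followup), error = function(e) e)
  if (inherits(f1, "error") || inherits(f2, "error")) {
    msgs <- c(if (inherits(f1, "error")) paste("baseline:", conditionMessage(f1)),
              if (inherits(f2, "error")) paste("follow-up:", conditionMessage(f2)))
    return(structure(list(status = "segmentation_failure",
                          message = paste(msgs, collapse = "; "),
                          config = config),
                     class = "nodule_record"))
  }
  growth <- doubling_time(unname(f1["lmd"]), unname(f2["lmd"]),
                          interval_days, cutoff = config$dt_cutoff)
  risk <- "none"
  if (f1["skewness"] > config$skewness_cutoff) {
    risk <- if (f1["lmd"] > config$lmd_cutoff) "highest" else "high"
  }
  structure(list(status = "ok",
                 baseline_features = f1, followup_features = f2,
                 growth = growth, risk_flag = risk, config = config),
            class = "nodule_record")
}

#' @export
print.nodule_record <- function(x, ...) {
  if (x$status != "ok") {
    cat("<nodule_record> SEGMENTATION FAILURE:", x$message, "\n")
  } else {
    cat(sprintf("<nodule_record> DT %s d (%s), baseline skewness %.2f, LMD %.2f mg/mm, risk flag: %s\n",
                if (is.finite(x$growth$doubling_time))
                  sprintf("%.0f", x$growth$doubling_time) else "Inf",
                x$growth$label, x$baseline_features["skewness"],
                x$baseline_features["lmd"], x$risk_flag))
  }
  invisible(x)
}

fmt_med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}

#' Cohort-level statistical analysis
#'
#' Runs the full statistics chain on a cohort table: per-feature Spearman
#' correlation with doubling time, growing-vs-nongrowing contrasts
#' (median/IQR + Mann-Whitney), univariate and backward-stepwise logistic
#' regression of growth on the twelve features and the covariates, and ROC
#' analyses for skewness, LMD and the fitted multivariable model.
#'
#' @param cohort An `nsn_cohort` from [simulate_cohort()], or a data.frame
#'   with the twelve feature columns, covariate columns (`age`, `male`,
#'   `smoker`, `cancer_history`, `emphysema`, `upper_lobe`) and either a
#'   `group` column or `dt_days` (grouped at the config cutoff).
#' @param config A [run_config].
#' @param out_dir Optional directory; when given, CSV tables, ROC point
#'   files and a markdown report are written there (deterministic bytes
#'   for a given cohort and config).
#' @return A `cohort_report` list: `correlation`, `group_contrast`,
#'   `univariate`, `stepwise`, `roc` (list of [roc_analysis()] results),
#'   `n`, `files` (paths written, or NULL).
#' @export
run_cohort <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  tab <- if (inherits(cohort, "nsn_cohort")) cohort$truth_table else as.data.frame(cohort)
  feats <- intersect(reported_feature_names, names(tab))
  if (!all(c("lmd", "skewness") %in% feats))
    stop("cohort table must contain at least the lmd and skewness columns",
         call. = FALSE)
  if (is.null(tab$group)) {
    if (is.null(tab$dt_days))
      stop("cohort table needs a `group` or `dt_days` column", call. = FALSE)
    tab$group <- ifelse(tab$dt_days < config$dt_cutoff, "growing", "nongrowing")
  }
  grow <- tab$group == "growing"
  # correlation of each feature with DT (rank-based, so infinite DTs of
  # stable nodules are handled as top ties)
  correlation <- NULL
  if (!is.null(tab$dt_days)) {
    correlation <- do.call(rbind, lapply(feats, function(f) {
      s <- spearman(tab[[f]], tab$dt_days)
      data.frame(feature = f, median_iqr = fmt_med_iqr(tab[[f]]),
                 rho = s$rho, p = s$p, stringsAsFactors = FALSE)
    }))
  }
  group_contrast <- do.call(rbind, lapply(feats, function(f) {
    mw <- mann_whitney(tab[[f]][grow], tab[[f]][!grow])
    data.frame(feature = f,
               growing = fmt_med_iqr(tab[[f]][grow]),
               nongrowing = fmt_med_iqr(tab[[f]][!grow]),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }))
  covars <- intersect(c("age", "male", "smoker", "cancer_history",
                        "emphysema", "upper_lobe"), names(tab))
  design <- tab[c(feats, covars)]
  design[covars] <- lapply(design[covars], as.numeric)
  step <- backward_stepwise(design, grow, p_enter = config$p_enter,
                            p_remove = config$p_remove)
  roc <- list(skewness = roc_analysis(tab$skewness, grow),
              lmd = roc_analysis(tab$lmd, grow))
  model_fit <- logistic_fit(tab[c("skewness", "lmd")], grow)
  roc$model <- roc_analysis(attr(model_fit, "fitted"), grow)
  report <- structure(list(correlation = correlation,
                           group_contrast = group_contrast,
                           univariate = step$univariate,
                           stepwise = step,
                           skewness_lmd_model = model_fit,
                           roc = roc,
                           n = nrow(tab), n_growing = sum(grow),
                           config = config, files = NULL),
                      class = "cohort_report")
  if (!is.null(out_dir)) report <- write_cohort_report(report, out_dir)
  report
}

# deterministic CSV + markdown serialization of a cohort report
write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 6, trim = TRUE), p, row.names = FALSE,
                     quote = TRUE)
    files <<- c(files, p)
  }
  if (!is.null(report$correlation)) wcsv(report$correlation, "correlation.csv")
  wcsv(report$group_contrast, "group_contrast.csv")
  wcsv(report$univariate, "univariate_logistic.csv")
  if (!is.null(report$stepwise$model))
    wcsv(as.data.frame(report$stepwise$model), "multivariable_logistic.csv")
  for (nm in names(report$roc))
    wcsv(report$roc[[nm]]$curve, paste0("roc_", nm, ".csv"))
  md <- file.path(out_dir, "report.md")
  cfg <- report$config
  lines <- c(
    "# Nonsolid nodule cohort analysis",
    "",
    sprintf("Nodules: %d (%d growing, %d nongrowing)", report$n,
            report$n_growing, report$n - report$n_growing),
    "",
    "## Provenance",
    sprintf("- segmentation threshold: %g HU (inclusive)", cfg$threshold),
    sprintf("- doubling-time cutoff: %g days (growing iff DT < cutoff)", cfg$dt_cutoff),
    sprintf("- risk cutoffs: skewness > %g, LMD > %g mg/mm",
            cfg$skewness_cutoff, cfg$lmd_cutoff),
    sprintf("- perimeter convention: %s (smoothing window %d); Feret on pixel-corner hull",
            cfg$perimeter_method, cfg$smoothing),
    sprintf("- stepwise logistic: enter p < %g, remove p > %g", cfg$p_enter, cfg$p_remove),
    sprintf("- seed: %d", cfg$seed),
    "",
    "## Selected predictors (backward stepwise)",
    if (length(report$stepwise$selected))
      paste("-", report$stepwise$selected)
    else "- (none retained)",
    "",
    "## ROC summaries",
    vapply(names(report$roc), function(nm)
      sprintf("- %s: AUC %.3f, Youden cutoff %.4g (J = %.3f)", nm,
              report$roc[[nm]]$auc, report$roc[[nm]]$optimal_cutoff,
              report$roc[[nm]]$youden_j), character(1)),
    "")
  writeLines(lines, md)
  files <- c(files, md)
  report$files <- files
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d nodules (%d growing)\n", x$n, x$n_growing))
  cat("selected predictors:",
      if (length(x$stepwise$selected)) paste(x$stepwise$selected, collapse = ", ")
      else "(none)", "\n")
  for (nm in names(x$roc))
    cat(sprintf("  ROC %-9s AUC %.3f, Youden cutoff %.4g\n", nm,
                x$roc[[nm]]$auc, x$roc[[nm]]$optimal_cutoff))
  invisible(x)
}
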