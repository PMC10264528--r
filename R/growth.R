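# Growth scoring: mass doubling time on linear mass density, and the
# growing / nongrowing dichotomy at the 1,556-day cutoff.

#' Default doubling-time cutoff separating growing from nongrowing nodules
#' (days).
#' @export
DT_CUTOFF_DAYS <- 1556

#' Mass doubling time from two timepoints' linear mass density
#'
#' Exponential-growth (Schwartz) model applied to LMD:
#' \deqn{DT = \Delta t \cdot \ln 2 / \ln(LMD_2 / LMD_1)}
#' A nonpositive LMD change gives an infinite doubling time (no positive
#' variation), never a negative one.
#'
#' @param baseline,followup Either `nsn_features` vectors (their `lmd`
#'   element is used) or single positive LMD values in mg/mm.
#' @param interval_days Time between the two scans in days (> 0). May be
#'   omitted when `baseline`/`followup` are timepoint lists with
#'   `scan_date` (class Date) and `features`.
#' @param cutoff Doubling-time cutoff in days for the growth label.
#' @return A `growth_result` list: `interval` (days), `lmd_ratio`,
#'   `doubling_time` (days, possibly `Inf`), `label` (`"growing"` or
#'   `"nongrowing"`), `cutoff_used`.
#' @examples
#' doubling_time(10, 20, 1000)$doubling_time   # 1000 days
#' doubling_time(10, 40, 3112)$doubling_time   # 1556 days
#' @export
doubling_time <- function(baseline, followup, interval_days = NULL,
                          cutoff = DT_CUTOFF_DAYS) {
  get_lmd <- function(x) {
    if (is.list(x) && !is.null(x$features)) unname(x$features["lmd"])
    else if (inherits(x, "nsn_features")) unname(x["lmd"])
    else as.numeric(x)
  }
  if (is.null(interval_days)) {
    if (!is.list(baseline) || is.null(baseline$scan_date) ||
        !is.list(followup) || is.null(followup$scan_date))
      stop("`interval_days` is required unless both arguments are ",
           "timepoints with scan dates", call. = FALSE)
    interval_days <- as.numeric(difftime(followup$scan_date,
                                         baseline$scan_date, units = "days"))
  }
  lmd1 <- get_lmd(baseline); lmd2 <- get_lmd(followup)
  if (!is.finite(interval_days) || interval_days <= 0)
    stop("scan interval must be positive", call. = FALSE)
  if (!is.finite(lmd1) || !is.finite(lmd2) || lmd1 <= 0 || lmd2 <= 0)
    stop("both LMD values must be positive and finite", call. = FALSE)
  ratio <- lmd2 / lmd1
  dt <- if (ratio <= 1) Inf else interval_days * log(2) / log(ratio)
  structure(list(interval = interval_days,
                 lmd_ratio = ratio,
                 doubling_time = dt,
                 label = classify_growth(dt, cutoff),
                 cutoff_used = cutoff),
            class = "growth_result")
}

#' Classify a doubling time as growing or nongrowing
#'
#' Growing iff the doubling time is strictly below the cutoff; a nodule
#' with DT equal to the cutoff, or infinite (stable/shrinking), is
#' nongrowing.
#'
#' @param dt Doubling time in days (positive or `Inf`).
#' @param cutoff Cutoff in days (default 1556).
#' @return `"growing"` or `"nongrowing"`.
#' @export
classify_growth <- function(dt, cutoff = DT_CUTOFF_DAYS) {
  if (any(!is.na(dt) & dt <= 0)) stop("doubling time must be positive", call. = FALSE)
  ifelse(dt < cutoff, "growing", "nongrowing")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf("<growth_result> interval %.0f d, LMD ratio %.4f, DT %s d -> %s (cutoff %.0f d)\n",
              x$interval, x$lmd_ratio,
              if (is.finite(x$doubling_time)) sprintf("%.1f", x$doubling_time) else "Inf",
              x$label, x$cutoff_used))
  invisible(x)
}
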