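# The statistical chain applied to a nodule cohort: measurement
# reliability (ICC), rank correlation with doubling time, growing-vs-
# nongrowing contrasts (Mann-Whitney), univariate and backward-stepwise
# multivariable logistic regression, and ROC analysis with Youden-optimal
# cutoffs.

#' Intraclass correlation between two measurement sets
#'
#' Single-measurement two-way ICC per feature, default the absolute-
#' agreement, mixed-effects form ICC(A,1):
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with subject (`MS_R`), rater (`MS_C`) and residual (`MS_E`) mean squares,
#' n subjects and k = 2 raters.  `form = "C1"` gives the consistency form
#' without the rater term.
#'
#' @param set1,set2 Numeric matrices or data.frames (nodules x features)
#'   holding the two measurement sets in the same feature order.
#' @param form `"A1"` (absolute agreement, default) or `"C1"` (consistency).
#' @return Named numeric vector of per-feature ICCs; features with zero
#'   between-nodule variance are `NA` and listed in the `degenerate`
#'   attribute.
#' @export
icc_reliability <- function(set1, set2, form = c("A1", "C1")) {
  form <- match.arg(form)
  a <- as.matrix(set1); b <- as.matrix(set2)
  if (!all(dim(a) == dim(b)))
    stop("the two measurement sets must have identical dimensions", call. = FALSE)
  n <- nrow(a)
  if (n < 5) stop("ICC needs at least 5 nodules", call. = FALSE)
  k <- 2
  out <- numeric(ncol(a))
  names(out) <- colnames(a) %||% paste0("f", seq_len(ncol(a)))
  degenerate <- character(0)
  for (j in seq_len(ncol(a))) {
    x <- cbind(a[, j], b[, j])
    gm <- mean(x)
    row_m <- rowMeans(x); col_m <- colMeans(x)
    ssr <- k * sum((row_m - gm)^2)
    ssc <- n * sum((col_m - gm)^2)
    sst <- sum((x - gm)^2)
    sse <- sst - ssr - ssc
    msr <- ssr / (n - 1)
    msc <- ssc / (k - 1)
    mse <- sse / ((n - 1) * (k - 1))
    denom <- if (form == "A1")
      msr + (k - 1) * mse + k / n * (msc - mse)
    else
      msr + (k - 1) * mse
    if (msr <= 0 || denom <= 0) {
      out[j] <- NA_real_
      degenerate <- c(degenerate, names(out)[j])
    } else {
      out[j] <- (msr - mse) / denom
    }
  }
  structure(out, form = form, degenerate = degenerate)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks for ties; `rho` is the Pearson correlation of the ranks
#' and the two-sided p value uses the t approximation on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3). Pairs with missing
#'   values are dropped.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman needs at least 3 complete pairs", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Mann-Whitney U test
#'
#' U from rank sums with average ranks for ties.  For small samples
#' (n_a + n_b <= `exact_limit`) the two-sided p value is computed by exact
#' enumeration of all group assignments of the pooled sample (valid under
#' ties); otherwise by normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric vectors (the two groups).
#' @param exact_limit Largest pooled size for exact enumeration.
#' @return List with `U` (statistic of group `a`), `U_other`, `p`,
#'   `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 12) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  if (n1 + n2 <= exact_limit) {
    # enumerate all ways to assign n1 of the pooled ranks to group a
    combs <- utils::combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    ustats <- apply(combs, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(ustats - mu) >= abs(u1 - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u1 - n1 * n2 / 2)
      z <- (abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    p <- min(p, 1)
    method <- "normal approximation with tie and continuity correction"
  }
  list(U = u1, U_other = u2, p = p, method = method)
}

as_binary_outcome <- function(outcome) {
  if (is.character(outcome)) outcome <- outcome == "growing"
  if (is.factor(outcome)) outcome <- outcome == levels(outcome)[2]
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  y
}

#' Logistic regression with Wald statistics and separation diagnostics
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) with
#' per-predictor odds ratios, coefficients and two-sided Wald p values.
#' Complete or quasi-complete separation is detected (fitted probabilities
#' numerically 0/1, or a vanishing deviance) and flagged rather than
#' reported as silently huge odds ratios.
#'
#' @param design Data frame or matrix of predictors (no intercept column).
#' @param outcome Binary outcome (0/1, logical, factor, or
#'   `"growing"`/`"nongrowing"` labels; `"growing"` is the event).
#' @return A `logistic_model`: data.frame with `term`, `beta`, `or`, `se`,
#'   `z`, `p`, plus attributes `converged`, `separated`, `n`, `fitted`,
#'   `fit` (the underlying glm).
#' @export
logistic_fit <- function(design, outcome) {
  y <- as_binary_outcome(outcome)
  X <- as.data.frame(design)
  if (any(vapply(X, function(col) length(unique(col)) < 2, logical(1))))
    stop("design contains a constant column", call. = FALSE)
  dat <- cbind(.y = y, X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separated <- sep_warn || fit$deviance < 1e-6
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm),
                    beta = sm[, 1],
                    or = exp(sm[, 1]),
                    se = sm[, 2],
                    z = sm[, 3],
                    p = sm[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab, class = c("logistic_model", "data.frame"),
            converged = fit$converged, separated = separated,
            n = length(y), fitted = as.numeric(stats::fitted(fit)), fit = fit)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> n = %d%s%s\n", attr(x, "n"),
              if (isTRUE(attr(x, "separated"))) ", SEPARATION DETECTED (estimates unreliable)" else "",
              if (!isTRUE(attr(x, "converged"))) ", did not converge" else ""))
  print.data.frame(cbind(x[1], round(x[-1], 4)))
  invisible(x)
}

#' Backward-stepwise multivariable logistic regression
#'
#' Candidates significant in univariate screening (single-predictor Wald
#' p < `p_enter`) start the multivariable model; the predictor with the
#' largest Wald p is dropped while that p exceeds `p_remove`, refitting
#' until stable.  The full elimination trace is retained.
#'
#' @param design Data frame of candidate predictors.
#' @param outcome Binary outcome as in [logistic_fit()].
#' @param p_enter Univariate screening threshold (default 0.05).
#' @param p_remove Removal threshold during elimination (default 0.10).
#' @return List with `model` (final [logistic_fit()] result, or NULL when
#'   nothing survives screening), `selected` (character vector of retained
#'   predictors), `univariate` (screening table), `trace` (elimination
#'   steps).
#' @export
backward_stepwise <- function(design, outcome, p_enter = 0.05, p_remove = 0.10) {
  y <- as_binary_outcome(outcome)
  X <- as.data.frame(design)
  uni <- do.call(rbind, lapply(names(X), function(v) {
    m <- logistic_fit(X[v], y)
    data.frame(term = v, beta = m$beta[2], or = m$or[2], p = m$p[2],
               separated = attr(m, "separated"), stringsAsFactors = FALSE)
  }))
  current <- uni$term[!is.na(uni$p) & uni$p < p_enter]
  trace <- list()
  model <- NULL
  while (length(current) > 0) {
    model <- logistic_fit(X[current], y)
    ptab <- model[model$term != "(Intercept)", ]
    worst <- which.max(ptab$p)
    trace[[length(trace) + 1]] <- data.frame(
      step = length(trace) + 1L,
      predictors = paste(current, collapse = "+"),
      worst_term = ptab$term[worst], worst_p = ptab$p[worst],
      stringsAsFactors = FALSE)
    if (ptab$p[worst] > p_remove) {
      current <- setdiff(current, ptab$term[worst])
      model <- NULL
    } else break
  }
  if (is.null(model) && length(current) > 0) model <- logistic_fit(X[current], y)
  list(model = model,
       selected = if (length(current)) current else character(0),
       univariate = uni,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' The ROC curve over all distinct score thresholds; the AUC equals the
#' tie-corrected Mann-Whitney statistic divided by n1*n0 (computed from
#' ranks, so the AUC-U equivalence holds exactly, ties included).
#' Candidate cutoffs are midpoints between consecutive distinct scores
#' (plus the extremes); a case is called positive when its score exceeds
#' the cutoff.  The optimal cutoff maximizes the Youden index
#' J = sensitivity + specificity - 1, ties broken toward the lower cutoff.
#'
#' @param score Numeric predictor (higher = more likely positive).
#' @param outcome Binary outcome as in [logistic_fit()].
#' @return A `roc_result` list: `curve` (data.frame of cutoff, sensitivity,
#'   specificity), `auc`, `optimal_cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(score, outcome) {
  y <- as_binary_outcome(outcome)
  ok <- is.finite(score)
  score <- score[ok]; y <- y[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(score)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  s <- sort(unique(score))
  cuts <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  sens <- vapply(cuts, function(c) mean(score[y == 1] > c), numeric(1))
  spec <- vapply(cuts, function(c) mean(score[y == 0] <= c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]   # ties -> lower cutoff (cuts are increasing)
  structure(list(curve = data.frame(cutoff = cuts, sensitivity = sens,
                                    specificity = spec, youden = j),
                 auc = auc,
                 optimal_cutoff = cuts[best],
                 youden_j = j[best],
                 sensitivity = sens[best],
                 specificity = spec[best],
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (n+ = %d, n- = %d); Youden cutoff %.4g (J = %.3f, sens %.3f, spec %.3f)\n",
              x$auc, x$n_pos, x$n_neg, x$optimal_cutoff, x$youden_j,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x A `roc_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  o <- order(1 - x$curve$specificity, x$curve$sensitivity)
  graphics::plot(1 - x$curve$specificity[o], x$curve$sensitivity[o],
                 type = "s", xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
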