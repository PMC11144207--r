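#' Empirical ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance: the probability that a random
#' event subject scores higher than a random non-event subject, ties
#' counting one half. This equals the trapezoidal area under the empirical
#' ROC curve. Operating points list (threshold, sensitivity,
#' 1-specificity) for every distinct score, using the >= threshold
#' decision rule.
#'
#' @param scores numeric risk scores, one per subject.
#' @param labels binary outcomes (0/1), both classes present.
#' @param alpha confidence level complement for the attached DeLong
#'   interval (see \code{\link{delong_ci}}); set NULL to skip.
#' @return a \code{roc_result}: operating points (sorted by threshold),
#'   \code{auc}, \code{ci_low}, \code{ci_high}, \code{alpha}.
#' @export
roc_auc <- function(scores, labels, alpha = 0.05) {
  check_two_classes(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)                       # average ranks: ties count 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  op <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels == 1] >= t),
                         numeric(1)),
    one_minus_specificity = vapply(thr, function(t)
      mean(scores[labels == 0] >= t), numeric(1)))
  ci <- c(NA_real_, NA_real_)
  if (!is.null(alpha)) ci <- delong_ci(scores, labels, alpha)
  structure(list(operating_points = op, auc = auc,
                 ci_low = ci[1], ci_high = ci[2],
                 alpha = if (is.null(alpha)) NA_real_ else alpha),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f", x$auc))
  if (!is.na(x$ci_low))
    cat(sprintf(", %d%% CI %.4f-%.4f", round(100 * (1 - x$alpha)),
                x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance from the DeLong placement values: for each event
#' subject the fraction of non-events it outscores (ties half), and vice
#' versa; \eqn{\widehat{var} = S_{10}/n_1 + S_{01}/n_0}. The interval is
#' the normal approximation truncated to [0, 1]. Degenerate data with AUC
#' exactly 0 or 1 give zero variance and a point interval, with a warning.
#'
#' @inheritParams roc_auc
#' @param alpha two-sided miscoverage; 0.05 gives a 95\% interval.
#' @return numeric \code{c(ci_low, ci_high)}.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  check_two_classes(labels)
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  if (length(xs) < 2L || length(ys) < 2L)
    stop("DeLong variance needs at least 2 subjects in each class")
  # placement values via outer comparison (cohort-scale n, so affordable)
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)   # per-event placements
  v01 <- colMeans(cmp)   # per-non-event placements
  auc <- mean(cmp)
  var_auc <- stats::var(v10) / length(xs) + stats::var(v01) / length(ys)
  if (auc %in% c(0, 1) || var_auc == 0) {
    warning("degenerate AUC (no score overlap): returning point interval")
    return(c(auc, auc))
  }
  z <- stats::qnorm(1 - alpha / 2)
  lo <- max(0, auc - z * sqrt(var_auc))
  hi <- min(1, auc + z * sqrt(var_auc))
  c(lo, hi)
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  invisible(TRUE)
}

#' Optimism-bootstrap calibration of a logistic model
#'
#' Refits the model on the full cohort and smooths observed outcome
#' against predicted probability (the apparent curve) on a fixed grid of
#' predicted probabilities. Each bootstrap replicate refits on a resample,
#' and its optimism is the difference between the replicate model's
#' calibration on the resample and on the original data; the
#' bias-corrected curve subtracts the mean optimism from the apparent
#' curve. The calibration slope and intercept are the coefficients of the
#' logistic recalibration fit outcome ~ linear predictor; their reported
#' values are optimism-corrected the same way (apparent slope is 1 and
#' intercept 0 by construction on the training data). Resamples containing
#' a single outcome class are redrawn.
#'
#' @param table a \code{cohort_table}.
#' @param covariates covariates of the model being assessed.
#' @param n_boot bootstrap replicates; 0 gives the apparent curve only.
#' @param seed RNG seed.
#' @param grid_size number of predicted-probability grid points.
#' @return a \code{calibration_result}: \code{grid}, \code{apparent},
#'   \code{bias_corrected} (NULL when \code{n_boot} = 0), \code{slope},
#'   \code{intercept}, \code{n_boot}.
#' @export
calibrate_bootstrap <- function(table, covariates, n_boot = 1000,
                                seed = 20240601, grid_size = 50) {
  if (n_boot < 0) stop("n_boot must be >= 0")
  df <- as.data.frame(table)
  y <- df$rp_grade2plus
  full <- fit_logistic(table, covariates)
  p_full <- predict_risk(full, df)$probability
  grid <- seq(min(p_full), max(p_full), length.out = grid_size)
  apparent <- smooth_calibration(p_full, y, grid)
  res <- list(grid = grid, apparent = apparent, bias_corrected = NULL,
              slope = 1, intercept = 0, n_boot = n_boot)
  if (n_boot > 0) {
    opt_curve <- matrix(NA_real_, n_boot, grid_size)
    slope_test <- numeric(n_boot)
    int_test <- numeric(n_boot)
    n_redraw <- 0L
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        repeat {
          idx <- sample.int(nrow(df), replace = TRUE)
          if (length(unique(y[idx])) == 2L) break
          n_redraw <- n_redraw + 1L
        }
        boot_tab <- as_cohort_table(df[idx, , drop = FALSE])
        mb <- try(fit_logistic(boot_tab, covariates), silent = TRUE)
        if (inherits(mb, "try-error")) {
          opt_curve[b, ] <- 0; slope_test[b] <- NA; int_test[b] <- NA
          next
        }
        p_boot <- predict_risk(mb, df[idx, , drop = FALSE])$probability
        p_orig <- predict_risk(mb, df)$probability
        cb <- smooth_calibration(p_boot, y[idx], grid)
        co <- smooth_calibration(p_orig, y, grid)
        opt_curve[b, ] <- cb - co
        lp_orig <- predict_risk(mb, df)$linear_predictor
        rec <- suppressWarnings(stats::glm(y ~ lp_orig, family = stats::binomial()))
        slope_test[b] <- stats::coef(rec)[2]
        int_test[b] <- stats::coef(rec)[1]
      }
    })
    if (n_redraw > 0L)
      message(n_redraw, " single-class bootstrap resample(s) redrawn")
    res$bias_corrected <- apparent - colMeans(opt_curve, na.rm = TRUE)
    # corrected index = apparent index - mean optimism; apparent slope is 1,
    # optimism of the slope is (1 - slope on original), so the corrected
    # slope is the mean test slope (likewise for the intercept about 0)
    res$slope <- mean(slope_test, na.rm = TRUE)
    res$intercept <- mean(int_test, na.rm = TRUE)
  }
  structure(res, class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %d boot; corrected slope %.3f, intercept %.3f\n",
    x$n_boot, x$slope, x$intercept))
  invisible(x)
}

# Locally smoothed observed frequency as a function of predicted
# probability, evaluated on `grid`; constant extrapolation outside the
# observed range. Saturated/grouped predictions (few distinct values)
# fall back to exact per-group frequencies.
smooth_calibration <- function(p, y, grid) {
  ux <- sort(unique(p))
  if (length(ux) <= 10L) {
    freq <- vapply(ux, function(v) mean(y[p == v]), numeric(1))
    if (length(ux) == 1L) return(rep(freq, length(grid)))
    return(stats::approx(ux, freq, xout = grid, rule = 2)$y)
  }
  lo <- stats::lowess(p, y, f = 2 / 3, iter = 0)
  stats::approx(lo$x, lo$y, xout = grid, rule = 2, ties = "ordered")$y
}

#' Nomogram point scales for a logistic model
#'
#' Converts a fitted model into the familiar points scheme: each
#' covariate's score is \eqn{100 |\beta_j| (x_j - ref_j) / \max_k |\beta_k|
#' (max_k - min_k)}, where the reference \eqn{ref_j} is the end of the
#' covariate's range that minimises \eqn{\beta_j x_j} (so points are
#' non-negative), and the covariate with the largest \eqn{|\beta| \cdot
#' range} spans exactly 0-100 points. Total points map back to predicted
#' probability through the linear predictor.
#'
#' @param model a \code{logistic_model}.
#' @param ranges named list of \code{c(min, max)} per model covariate.
#' @param n_scale_points points per per-variable scale table.
#' @return a \code{nomogram_spec}: per-variable scale tables, the
#'   points-per-logit conversion, and a total-points-to-probability table.
#' @export
nomogram_points <- function(model, ranges, n_scale_points = 11) {
  stopifnot(inherits(model, "logistic_model"))
  beta <- model$coefficients
  need <- names(beta)
  if (!all(need %in% names(ranges)))
    stop("ranges must cover every model covariate")
  ranges <- ranges[need]
  for (nm in need) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] >= r[2])
      stop("invalid or zero-width range for covariate ", nm)
  }
  span <- vapply(need, function(nm) abs(beta[[nm]]) * diff(ranges[[nm]]),
                 numeric(1))
  max_span <- max(span)
  if (max_span == 0) stop("all coefficients are zero: no points to assign")
  scales <- lapply(need, function(nm) {
    r <- ranges[[nm]]
    ref <- if (beta[[nm]] >= 0) r[1] else r[2]
    vals <- seq(r[1], r[2], length.out = n_scale_points)
    data.frame(value = vals,
               points = 100 * abs(beta[[nm]]) * abs(vals - ref) / max_span)
  })
  names(scales) <- need
  ref_values <- vapply(need, function(nm)
    if (beta[[nm]] >= 0) ranges[[nm]][1] else ranges[[nm]][2], numeric(1))
  lp_ref <- model$intercept + sum(beta * ref_values)
  lp_per_point <- max_span / 100
  total_max <- sum(vapply(scales, function(s) max(s$points), numeric(1)))
  totals <- seq(0, total_max, length.out = 101)
  prob_map <- data.frame(
    total_points = totals,
    probability = stats::plogis(lp_ref + totals * lp_per_point))
  structure(list(scales = scales, ref_values = ref_values,
                 lp_reference = lp_ref, lp_per_point = lp_per_point,
                 total_to_probability = prob_map,
                 top_variable = need[which.max(span)]),
            class = "nomogram_spec")
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat(sprintf("<nomogram_spec> %d variables; '%s' spans 100 points\n",
              length(x$scales), x$top_variable))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic \eqn{\sum (O - E)^2 / E} with expected counts from
#' the margin products, no continuity correction, and the chi-square upper
#' tail on \eqn{(r-1)(c-1)} degrees of freedom — the convention that
#' reproduces the cohort-characteristics comparisons this pipeline
#' re-derives from printed counts.
#'
#' @param counts r x c matrix of non-negative counts with positive margins.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all row and column margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}
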