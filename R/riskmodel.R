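#' Logistic risk model on the logit scale
#'
#' Holds an intercept and named covariate coefficients of a binomial
#' regression for grade->=2 radiation pneumonitis. Coefficients act on
#' functional dose-volume covariates expressed in percent (0-100); the
#' linear predictor is a logit and must be passed through the sigmoid to
#' obtain a probability.
#'
#' @param intercept numeric, logit units.
#' @param coefficients named numeric vector, logit per percent; names must
#'   be a subset of \code{V5}...\code{V60}.
#' @param covariate_scale declared unit of the covariates.
#' @param method optional label of the selection strategy that produced the
#'   model.
#' @return a \code{logistic_model}.
#' @export
logistic_model <- function(intercept, coefficients = numeric(0),
                           covariate_scale = "percent", method = NULL) {
  coefficients <- unlist(coefficients)
  if (!is.finite(intercept) || any(!is.finite(coefficients)))
    stop("model parameters must be finite")
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named")
  unknown <- setdiff(names(coefficients), fv_names())
  if (length(unknown))
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 covariate_scale = covariate_scale, method = method),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model%s> logit = %.5g",
              if (is.null(x$method)) "" else paste0(" [", x$method, "]"),
              x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf(" %+.5g*%s", x$coefficients[[nm]], nm))
  cat("\n")
  invisible(x)
}

#' The published risk models
#'
#' \code{published_stepwise_model()} is the final model selected by both
#' bidirectional stepwise AIC and exhaustive best-subset search in the
#' source study: logit = 0.23656 - 0.13784 V35 + 0.37445 V30 - 0.38317 V25
#' + 0.21341 V20 - 0.10209 V15 + 0.03815 V10, with covariates in percent.
#' \code{published_lasso_model()} is that study's lasso-selected
#' (penalised) model. Both ship as reference constants: their coefficients
#' cannot be re-estimated without the original cohort, but they can be
#' evaluated, scored and turned into nomograms.
#'
#' @return a \code{logistic_model}.
#' @export
published_stepwise_model <- function() {
  logistic_model(
    intercept = 0.23656,
    coefficients = c(V35 = -0.13784, V30 = 0.37445, V25 = -0.38317,
                     V20 = 0.21341, V15 = -0.10209, V10 = 0.03815),
    method = "stepwise")
}

#' @rdname published_stepwise_model
#' @export
published_lasso_model <- function() {
  logistic_model(
    intercept = -1.052542,
    coefficients = c(V60 = -1.109038e-01, V50 = 3.400737e-02,
                     V35 = -4.149203e-02, V30 = 1.388844e-01,
                     V15 = -1.720682e-01, V10 = 1.125483e-01,
                     V5 = -5.982490e-06),
    method = "lasso")
}

#' Evaluate a logistic risk model
#'
#' @param model a \code{logistic_model}.
#' @param fv a named numeric vector (one patient), an \code{fv_vector}, or
#'   a data frame with one column per covariate (one row per patient). All
#'   covariates named in the model must be present.
#' @return list with \code{linear_predictor} (logit) and
#'   \code{probability}, each of length \code{nrow(fv)} (or 1).
#' @examples
#' predict_risk(published_stepwise_model(),
#'              c(V35 = 0, V30 = 0, V25 = 0, V20 = 0, V15 = 0, V10 = 0))
#' @export
predict_risk <- function(model, fv) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.data.frame(fv)) {
    X <- fv
  } else {
    X <- as.data.frame(as.list(unclass(fv)))
  }
  need <- names(model$coefficients)
  missing_cov <- setdiff(need, names(X))
  if (length(missing_cov))
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  eta <- rep(model$intercept, nrow(X))
  for (nm in need) eta <- eta + model$coefficients[[nm]] * X[[nm]]
  list(linear_predictor = as.numeric(eta),
       probability = stats::plogis(as.numeric(eta)))
}

#' Maximum-likelihood logistic fit
#'
#' Fits outcome ~ covariates by binomial IRLS (via \code{stats::glm}) and
#' verifies the score equations at the returned solution. Quasi-complete
#' separation — diagnosed as any coefficient exceeding 15 on the
#' standardised covariate scale — raises an error naming the covariate, as
#' does a singular design.
#'
#' @param table a \code{cohort_table}.
#' @param covariates character vector of covariate names (columns of
#'   \code{table}); empty for the intercept-only model.
#' @param max_iter IRLS iteration cap.
#' @param tol score-equation tolerance: at convergence
#'   \eqn{\max_j |X^T (y - p)|_j < tol \cdot n}.
#' @return a \code{logistic_model} with attributes \code{se} (standard
#'   errors), \code{loglik}, \code{aic} and \code{n}.
#' @export
fit_logistic <- function(table, covariates = character(0), max_iter = 100,
                         tol = 1e-8) {
  df <- as.data.frame(table)
  y <- df$rp_grade2plus
  check_fit_preconditions(y, length(covariates))
  X <- fit_design(df, covariates)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = max_iter)))
  beta <- fit$coefficients
  if (anyNA(beta)) {
    bad <- names(beta)[is.na(beta)]
    stop("singular design: coefficient(s) not estimable for ",
         paste(bad, collapse = ", "))
  }
  if (length(covariates)) {
    sds <- vapply(covariates, function(v) stats::sd(df[[v]]), numeric(1))
    std_beta <- abs(beta[covariates] * sds)
    if (any(std_beta > 15))
      stop("perfect or quasi-complete separation on covariate(s): ",
           paste(covariates[std_beta > 15], collapse = ", "))
  }
  p <- as.numeric(stats::plogis(X %*% beta))
  score <- as.numeric(crossprod(X, y - p))
  if (max(abs(score)) >= tol * length(y))
    warning(sprintf("score equations not met to tolerance (max |score| = %.3g)",
                    max(abs(score))))
  W <- p * (1 - p)
  info <- crossprod(X * sqrt(W))
  se <- sqrt(diag(solve(info)))
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  m <- logistic_model(beta[["(Intercept)"]], beta[covariates],
                      method = "glm")
  attr(m, "se") <- stats::setNames(se, colnames(X))
  attr(m, "loglik") <- ll
  attr(m, "aic") <- -2 * ll + 2 * length(beta)
  attr(m, "n") <- length(y)
  m
}

check_fit_preconditions <- function(y, p) {
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present to fit")
  if (length(y) <= p + 1L)
    stop("more parameters than observations")
  invisible(TRUE)
}

fit_design <- function(df, covariates) {
  X <- cbind(`(Intercept)` = rep(1, nrow(df)),
             as.matrix(df[, covariates, drop = FALSE]))
  colnames(X) <- c("(Intercept)", covariates)
  X
}

# AIC of a subset fit, via glm.fit; returns NA when IRLS does not converge.
subset_aic <- function(X, y, cols) {
  Xs <- X[, c(1L, cols + 1L), drop = FALSE]
  fit <- suppressWarnings(stats::glm.fit(
    Xs, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  if (!fit$converged || anyNA(fit$coefficients)) return(NA_real_)
  fit$aic
}

#' Selection result container
#'
#' @param method one of \code{"stepwise"}, \code{"best_subset"},
#'   \code{"lasso"}, \code{"ensemble_importance"}.
#' @param selected ordered character vector of selected covariate names.
#' @param criterion_trace data frame of per-step / per-lambda / per-variable
#'   criterion values.
#' @param final_model fitted \code{logistic_model}, or NULL for pure
#'   importance rankings.
#' @param extras optional list of method-specific details.
#' @return a \code{selection_result}.
#' @export
selection_result <- function(method, selected, criterion_trace,
                             final_model = NULL, extras = list()) {
  if (nrow(as.data.frame(criterion_trace)) == 0L)
    stop("criterion trace must be non-empty")
  structure(list(method = method, selected = selected,
                 criterion_trace = criterion_trace,
                 final_model = final_model, extras = extras),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result [%s]> selected: %s\n", x$method,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  if (!is.null(x$final_model)) print(x$final_model)
  invisible(x)
}

#' Bidirectional stepwise selection under AIC
#'
#' Starts from the full candidate model and repeatedly applies the single
#' variable addition or removal that most reduces AIC
#' (\eqn{-2 \log L + 2k}), stopping when no move reduces it. Ties are
#' broken toward fewer variables, then by covariate order
#' V5 < V10 < ... < V60. The result is a local optimum: no single-variable
#' move improves its AIC.
#'
#' @param table a \code{cohort_table}.
#' @param candidates candidate covariate names.
#' @return a \code{selection_result} with a per-step trace.
#' @export
stepwise_select <- function(table, candidates = fv_names()) {
  df <- as.data.frame(table)
  y <- df$rp_grade2plus
  check_fit_preconditions(y, length(candidates))
  candidates <- candidates[order(match(candidates, fv_names()))]
  X <- fit_design(df, candidates)
  p <- length(candidates)
  cur <- seq_len(p)
  cur_aic <- subset_aic(X, y, cur)
  if (is.na(cur_aic)) stop("full candidate model did not converge")
  trace <- data.frame(step = 0L, action = "start",
                      variable = NA_character_, aic = cur_aic,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    moves <- list()
    for (j in cur)
      moves[[length(moves) + 1L]] <- list(action = "drop", var = j,
                                          set = setdiff(cur, j))
    for (j in setdiff(seq_len(p), cur))
      moves[[length(moves) + 1L]] <- list(action = "add", var = j,
                                          set = sort(c(cur, j)))
    if (!length(moves)) break
    aics <- vapply(moves, function(m) subset_aic(X, y, m$set), numeric(1))
    sizes <- vapply(moves, function(m) length(m$set), integer(1))
    vars <- vapply(moves, function(m) m$var, integer(1))
    ok <- !is.na(aics)
    if (!any(ok)) break
    ord <- order(aics, sizes, vars)
    ord <- ord[ok[ord]]
    best <- ord[1]
    if (aics[best] >= cur_aic - 1e-10) break
    cur <- moves[[best]]$set
    cur_aic <- aics[best]
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, action = moves[[best]]$action,
      variable = candidates[moves[[best]]$var], aic = cur_aic,
      stringsAsFactors = FALSE))
  }
  sel <- candidates[cur]
  selection_result("stepwise", sel, trace,
                   final_model = fit_logistic(table, sel))
}

#' Exhaustive best-subset selection under AIC
#'
#' Fits all \eqn{2^p} covariate subsets (including the empty model) and
#' returns the AIC-minimal one; ties are broken toward fewer variables,
#' then lexicographically in covariate order. Subsets whose IRLS does not
#' converge are skipped with a warning and can never be chosen.
#'
#' @inheritParams stepwise_select
#' @return a \code{selection_result}; the trace holds one row per subset.
#' @export
best_subset_select <- function(table, candidates = fv_names()) {
  df <- as.data.frame(table)
  y <- df$rp_grade2plus
  p <- length(candidates)
  if (p > 20L) stop("exhaustive enumeration limited to 20 candidates")
  check_fit_preconditions(y, 0L)
  candidates <- candidates[order(match(candidates, fv_names()))]
  X <- fit_design(df, candidates)
  n_sub <- 2L^p
  aics <- numeric(n_sub)
  sizes <- integer(n_sub)
  members <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    bits <- which(bitwAnd(s - 1L, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    members[[s]] <- bits
    sizes[s] <- length(bits)
    aics[s] <- subset_aic(X, y, bits)
  }
  n_skip <- sum(is.na(aics))
  if (n_skip > 0L)
    warning(n_skip, " subset(s) skipped: IRLS did not converge")
  lex <- vapply(members, function(b) paste(b, collapse = ","), character(1))
  ord <- order(aics, sizes, lex, na.last = TRUE)
  best <- ord[1]
  sel <- candidates[members[[best]]]
  trace <- data.frame(subset = lex, size = sizes, aic = aics,
                      stringsAsFactors = FALSE)
  selection_result("best_subset", sel, trace,
                   final_model = fit_logistic(table, sel),
                   extras = list(best_aic = aics[best]))
}

# ---- lasso: coordinate-descent penalised binomial regression ----

#' L1-penalised logistic regression path
#'
#' Coordinate-descent lasso for the binomial model, minimising
#' \eqn{-\frac{1}{n}\ell(\beta_0, \beta) + \lambda \|\beta\|_1} over
#' standardised covariates (unpenalised intercept). The path is log-spaced
#' from \eqn{\lambda_{max}} — the smallest \eqn{\lambda} at which every
#' coefficient is zero, \eqn{\max_j |x_j^T (y - \bar y)| / n} — down to
#' \code{lambda_min_ratio} times it. The outer loop is IRLS; the inner
#' loop is cyclic coordinate descent on the weighted least-squares
#' surrogate, warm-started along the path. Karush-Kuhn-Tucker residuals of
#' the exact binomial objective are returned for every path point.
#'
#' @param X numeric matrix of covariates (n x p), original scale.
#' @param y binary response vector.
#' @param lambda optional decreasing vector of penalties; computed from
#'   \code{n_lambda} and \code{lambda_min_ratio} when NULL.
#' @param n_lambda path length.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param tol coordinate-descent convergence tolerance.
#' @param max_outer IRLS iteration cap per path point.
#' @return list with \code{lambda}, \code{beta0} (intercepts),
#'   \code{beta} (p x n_lambda, original covariate scale),
#'   \code{beta_std} (standardised scale), \code{kkt_max} (max KKT residual
#'   per path point), \code{center}, \code{scale}.
#' @export
lasso_path <- function(X, y, lambda = NULL, n_lambda = 100,
                       lambda_min_ratio = 1e-4, tol = 1e-12,
                       max_outer = 250) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(X^2) - ctr^2)
  if (any(scl == 0)) scl[scl == 0] <- 1   # constant column: stays at zero
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ybar <- mean(y)
  lambda_max <- max(abs(crossprod(Xs, y - ybar))) / n
  if (lambda_max <= 0)
    stop("degenerate response: penalty path is undefined")
  if (is.null(lambda))
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = n_lambda))
  nl <- length(lambda)
  null_dev <- -2 * sum(y * log(max(ybar, 1e-12)) +
                         (1 - y) * log(max(1 - ybar, 1e-12)))
  B <- matrix(0, p, nl)
  b0s <- numeric(nl)
  kkt <- numeric(nl)
  beta <- rep(0, p)
  b0_null <- stats::qlogis(min(max(ybar, 1e-12), 1 - 1e-12))
  b0 <- b0_null
  n_done <- nl
  for (l in seq_len(nl)) {
    lam <- lambda[l]
    if (lam >= lambda_max * (1 - 1e-12)) {
      # analytic threshold: at or above lambda_max the penalised solution is
      # the intercept-only model with every coefficient exactly zero
      beta <- rep(0, p)
      b0 <- b0_null
      B[, l] <- beta
      b0s[l] <- b0
      grad <- as.numeric(crossprod(Xs, ybar - y)) / n
      kkt[l] <- max(pmax(abs(grad) - lam, 0))
      next
    }
    for (outer in seq_len(max_outer)) {
      eta <- as.numeric(b0 + Xs %*% beta)
      pr <- stats::plogis(eta)
      w <- pmax(pr * (1 - pr), 1e-6)
      z <- eta + (y - pr) / w
      wx2 <- colSums(w * Xs^2) / n      # fixed within the inner solve
      sw <- sum(w)
      # cyclic coordinate descent on the weighted LS surrogate
      r <- z - b0 - as.numeric(Xs %*% beta)
      for (cycle in seq_len(500L)) {
        delta <- 0
        b0_new <- b0 + sum(w * r) / sw
        delta <- max(delta, abs(b0_new - b0))
        r <- r - (b0_new - b0)
        b0 <- b0_new
        for (j in seq_len(p)) {
          rho <- sum(w * Xs[, j] * r) / n + wx2[j] * beta[j]
          bj <- if (rho > lam) (rho - lam) / wx2[j]
                else if (rho < -lam) (rho + lam) / wx2[j] else 0
          if (bj != beta[j]) {
            r <- r - Xs[, j] * (bj - beta[j])
            delta <- max(delta, abs(bj - beta[j]))
            beta[j] <- bj
          }
        }
        if (delta < max(tol * 100, 1e-9 * max(1, max(abs(beta))))) break
      }
      eta_new <- as.numeric(b0 + Xs %*% beta)
      if (max(abs(eta_new - eta)) < 1e-8 * max(1, max(abs(eta_new)))) break
    }
    pr <- stats::plogis(as.numeric(b0 + Xs %*% beta))
    grad <- as.numeric(crossprod(Xs, pr - y)) / n
    kkt[l] <- max(ifelse(beta == 0, pmax(abs(grad) - lam, 0),
                         abs(grad + lam * sign(beta))))
    B[, l] <- beta
    b0s[l] <- b0
    dev <- -2 * sum(y * log(pmax(pr, 1e-300)) +
                      (1 - y) * log(pmax(1 - pr, 1e-300)))
    # stop the path once the fit saturates or coefficients diverge: smaller
    # lambdas only chase the (possibly nonexistent) unpenalised optimum
    if (l < nl && (max(abs(beta)) > 15 || dev < 0.001 * null_dev)) {
      n_done <- l
      break
    }
  }
  keep <- seq_len(n_done)
  B <- B[, keep, drop = FALSE]
  b0s <- b0s[keep]
  beta_orig <- B / scl
  b0_orig <- b0s - colSums(B * (ctr / scl))
  rownames(beta_orig) <- rownames(B) <- colnames(X)
  list(lambda = lambda[keep], beta0 = b0_orig, beta = beta_orig,
       beta_std = B, beta0_std = b0s, kkt_max = kkt[keep], center = ctr,
       scale = scl, lambda_max = lambda_max, n_requested = nl)
}

soft_threshold <- function(x, lam) sign(x) * pmax(abs(x) - lam, 0)

#' Lasso variable selection with cross-validated lambda
#'
#' Runs \code{\link{lasso_path}} on the 12 functional dose-volume
#' covariates, selects lambda by K-fold cross-validated binomial deviance,
#' and reports the covariates with nonzero coefficients at that lambda.
#' The returned final model carries the penalised coefficients at the
#' selected lambda (shrunken, as in the published lasso formula), not a
#' refitted unpenalised model.
#'
#' @inheritParams stepwise_select
#' @param n_lambda path length.
#' @param cv_folds number of cross-validation folds.
#' @param seed RNG seed for the fold assignment.
#' @return a \code{selection_result}; the trace holds lambda, mean CV
#'   deviance and nonzero count per path point; extras hold the full path
#'   and KKT residuals.
#' @export
lasso_select <- function(table, candidates = fv_names(), n_lambda = 100,
                         cv_folds = 10, seed = 20240601) {
  df <- as.data.frame(table)
  y <- df$rp_grade2plus
  check_fit_preconditions(y, 0L)
  candidates <- candidates[order(match(candidates, fv_names()))]
  X <- as.matrix(df[candidates])
  n <- nrow(X)
  path <- lasso_path(X, y, n_lambda = n_lambda)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  dev <- matrix(NA_real_, cv_folds, length(path$lambda))
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2L) next
    pk <- lasso_path(X[tr, , drop = FALSE], y[tr], lambda = path$lambda)
    mk <- length(pk$lambda)    # fold path may stop earlier (separation guard)
    eta <- sweep(X[!tr, , drop = FALSE] %*% pk$beta, 2, pk$beta0, "+")
    pr <- stats::plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    dev[k, seq_len(mk)] <-
      colMeans(-2 * (y[!tr] * log(pr) + (1 - y[!tr]) * log(1 - pr)))
  }
  cv_dev <- colMeans(dev, na.rm = TRUE)
  best <- which.min(cv_dev)
  nz <- which(path$beta[, best] != 0)
  sel <- candidates[nz]
  model <- logistic_model(path$beta0[best], path$beta[nz, best],
                          method = "lasso")
  trace <- data.frame(lambda = path$lambda, cv_deviance = cv_dev,
                      n_nonzero = colSums(path$beta != 0))
  selection_result("lasso", sel, trace, final_model = model,
                   extras = list(path = path, lambda_selected = path$lambda[best]))
}

#' Random-forest importance ranking
#'
#' Bagged classification trees (CART with Gini splitting, bootstrap
#' resampling, random feature subsets of size sqrt(p)) via the
#' randomForest package, reporting both out-of-bag permutation importance
#' (mean decrease in accuracy) and total Gini decrease, each ranked in
#' descending order. Intended as a screening companion to the regression
#' selectors; no logistic model is attached.
#'
#' @inheritParams stepwise_select
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @return a \code{selection_result}; \code{selected} is the permutation-
#'   importance ranking, \code{criterion_trace} holds both measures,
#'   extras hold the Gini ranking and the importance standard deviations.
#' @export
ensemble_importance <- function(table, candidates = fv_names(),
                                n_trees = 500, seed = 20240601) {
  df <- as.data.frame(table)
  y <- df$rp_grade2plus
  if (nrow(df) < 10L) stop("at least 10 subjects needed for out-of-bag importance")
  check_fit_preconditions(y, 0L)
  candidates <- candidates[order(match(candidates, fv_names()))]
  rf <- with_seed(seed, randomForest::randomForest(
    x = df[candidates], y = factor(y, levels = c(0, 1)),
    ntree = n_trees, importance = TRUE))
  imp <- randomForest::importance(rf, scale = FALSE)
  acc <- imp[, "MeanDecreaseAccuracy"]
  gini <- imp[, "MeanDecreaseGini"]
  acc_sd <- rf$importanceSD[, "MeanDecreaseAccuracy"]
  trace <- data.frame(variable = candidates,
                      mean_decrease_accuracy = acc[candidates],
                      mean_decrease_gini = gini[candidates],
                      row.names = NULL)
  selection_result(
    "ensemble_importance",
    selected = candidates[order(acc[candidates], decreasing = TRUE)],
    criterion_trace = trace,
    extras = list(
      gini_ranking = candidates[order(gini[candidates], decreasing = TRUE)],
      importance_sd = acc_sd, oob_error = rf$err.rate[n_trees, "OOB"]))
}
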