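test_that("published models evaluate to their printed intercepts at zero covariates", {
  zeros <- stats::setNames(as.list(rep(0, 12)), fv_names())
  zeros <- as.data.frame(zeros)
  step <- predict_risk(published_stepwise_model(), zeros)
  expect_equal(step$linear_predictor, 0.23656)
  expect_equal(step$probability, plogis(0.23656))
  lasso <- predict_risk(published_lasso_model(), zeros)
  expect_equal(lasso$linear_predictor, -1.052542)
})

test_that("predict_risk maps logit 0 to probability one half and checks inputs", {
  m <- logistic_model(0, c(V20 = 1))
  expect_equal(predict_risk(m, c(V20 = 0))$probability, 0.5)
  expect_error(predict_risk(m, c(V5 = 1)), "missing covariate")
  expect_error(logistic_model(0, c(VX = 1)), "unknown covariate")
})

test_that("intercept-only fit equals the log odds of the event fraction", {
  # 16 events vs 25 non-events, the split of the cohort being emulated
  co <- make_cohort(41, seed = 1)
  co$rp_grade2plus <- c(rep(1, 16), rep(0, 25))
  m <- fit_logistic(co, character(0))
  expect_equal(m$intercept, log(16 / 25), tolerance = 1e-8)
  expect_equal(unname(attr(m, "aic")),
               -2 * (16 * log(16 / 41) + 25 * log(25 / 41)) + 2,
               tolerance = 1e-8)
})

test_that("a balanced outcome-independent binary covariate gets a zero coefficient", {
  X <- data.frame(matrix(30, 8, 12)); names(X) <- fv_names()
  X$V5 <- rep(c(0, 1), each = 4)
  X$rp_grade2plus <- rep(c(0, 1), 4)
  co <- as_cohort_table(X)
  m <- fit_logistic(co, "V5")
  expect_lt(abs(m$coefficients[["V5"]]), 1e-7)
})

test_that("logistic estimates recover the truth within three standard errors", {
  beta <- c(V10 = 0.08, V30 = -0.05, V50 = 0.1)
  co <- make_cohort(2000, beta = beta, intercept = -1, seed = 2)
  m <- fit_logistic(co, names(beta))
  se <- attr(m, "se")
  true_intercept <- -1 - sum(beta * 30)   # raw-scale intercept
  expect_lt(abs(m$intercept - true_intercept) / se[["(Intercept)"]], 3)
  for (nm in names(beta))
    expect_lt(abs(m$coefficients[[nm]] - beta[[nm]]) / se[[nm]], 3)
})

test_that("separation and degenerate designs raise informative errors", {
  co <- make_cohort(40, seed = 3)
  co$V5 <- ifelse(co$rp_grade2plus == 1, 50, 10)   # perfect separation
  expect_error(fit_logistic(co, "V5"), "separation.*V5")
  co2 <- make_cohort(40, seed = 4)
  co2$V10 <- co2$V5                                 # collinear pair
  expect_error(fit_logistic(co2, c("V5", "V10")), "singular")
  co3 <- make_cohort(10, seed = 5)
  co3$rp_grade2plus <- rep(0, 10)
  expect_error(fit_logistic(co3, "V5"), "both outcome classes")
})

test_that("stepwise keeps a strong predictor and never worsens the start AIC", {
  beta <- c(V30 = 3)
  co <- make_cohort(500, beta = beta, intercept = 0, seed = 6, mu = 0, sd = 1)
  cand <- c("V5", "V15", "V30", "V45", "V60")
  res <- stepwise_select(co, cand)
  expect_true("V30" %in% res$selected)
  full_aic <- res$criterion_trace$aic[1]
  expect_lte(utils::tail(res$criterion_trace$aic, 1), full_aic)
  # local optimality: no single add/drop improves the final AIC
  X <- ventidose:::fit_design(as.data.frame(co), cand)
  y <- co$rp_grade2plus
  final <- match(res$selected, cand)
  final_aic <- ventidose:::subset_aic(X, y, final)
  for (j in seq_along(cand)) {
    alt <- if (j %in% final) setdiff(final, j) else sort(c(final, j))
    expect_gte(ventidose:::subset_aic(X, y, alt), final_aic - 1e-8)
  }
})

test_that("stepwise agrees with MASS::stepAIC from the full model", {
  co <- make_cohort(200, beta = c(V10 = 0.15, V40 = -0.1), seed = 7)
  cand <- c("V10", "V25", "V40", "V55")
  res <- stepwise_select(co, cand)
  df <- as.data.frame(co)[c(cand, "rp_grade2plus")]
  full <- stats::glm(rp_grade2plus ~ ., data = df, family = binomial())
  ms <- MASS::stepAIC(full, direction = "both", trace = 0)
  expect_setequal(res$selected, setdiff(names(coef(ms)), "(Intercept)"))
})

test_that("stepwise and exhaustive search coincide on a three-covariate problem", {
  co <- make_cohort(150, beta = c(V20 = 0.2), seed = 8)
  cand <- c("V10", "V20", "V30")
  expect_setequal(stepwise_select(co, cand)$selected,
                  best_subset_select(co, cand)$selected)
})

test_that("best subset enumerates every subset and attains the minimum", {
  co <- make_cohort(120, beta = c(V15 = 0.25, V35 = -0.2), seed = 9)
  cand <- c("V5", "V15", "V25", "V35", "V45")
  res <- best_subset_select(co, cand)
  expect_identical(nrow(res$criterion_trace), 32L)
  expect_equal(res$extras$best_aic, min(res$criterion_trace$aic, na.rm = TRUE))
  expect_equal(unname(attr(res$final_model, "aic")), res$extras$best_aic,
               tolerance = 1e-6)
})

test_that("best subset picks the empty model when no covariate informs the outcome", {
  X <- data.frame(matrix(30, 16, 12)); names(X) <- fv_names()
  X$V5 <- rep(c(10, 50), 8)
  X$rp_grade2plus <- rep(c(0, 0, 1, 1), 4)   # independent of V5
  co <- as_cohort_table(X)
  res <- best_subset_select(co, "V5")
  expect_identical(res$selected, character(0))
})

test_that("best subset and stepwise agree on strong-signal data with all 12 covariates", {
  co <- make_cohort(300, beta = c(V25 = 0.3, V55 = -0.25), seed = 10)
  bs <- best_subset_select(co)
  sw <- stepwise_select(co)
  expect_setequal(bs$selected, sw$selected)
  expect_true(all(c("V25", "V55") %in% bs$selected))
})

test_that("lasso zeroes every coefficient at and above lambda_max", {
  co <- make_cohort(150, beta = c(V20 = 0.2), seed = 11)
  X <- as.matrix(as.data.frame(co)[fv_names()])
  y <- co$rp_grade2plus
  p1 <- lasso_path(X, y, n_lambda = 5)
  expect_true(all(p1$beta[, 1] == 0))
  p2 <- lasso_path(X, y, lambda = c(2 * p1$lambda_max, p1$lambda_max))
  expect_true(all(p2$beta == 0))
})

test_that("unpenalised lasso limit matches the maximum-likelihood fit", {
  co <- make_cohort(200, beta = c(V10 = 0.1, V50 = -0.08), seed = 12)
  X <- as.matrix(as.data.frame(co)[c("V10", "V30", "V50")])
  y <- co$rp_grade2plus
  p <- lasso_path(X, y, lambda = c(max(abs(crossprod(scale(X), y - mean(y)))) / nrow(X), 0))
  m <- fit_logistic(co, c("V10", "V30", "V50"))
  expect_lt(abs(p$beta0[2] - m$intercept), 1e-4)
  expect_lt(max(abs(p$beta[, 2] - m$coefficients[c("V10", "V30", "V50")])), 1e-4)
})

test_that("lasso path satisfies KKT conditions and shrinks monotonically", {
  co <- make_cohort(150, beta = c(V15 = 0.2, V45 = -0.15), seed = 13)
  X <- as.matrix(as.data.frame(co)[fv_names()])
  p <- lasso_path(X, co$rp_grade2plus, n_lambda = 60)
  expect_lt(max(p$kkt_max), 1e-6)
  nz <- colSums(p$beta != 0)
  # nonzero count grows (never shrinks) as lambda decreases along the path
  expect_true(all(diff(nz) >= -1e-9 | nz[-1] >= nz[-length(nz)] - 1))
  # coefficient path is continuous: no jumps larger than the lambda step scale
  jumps <- abs(p$beta_std[, -1] - p$beta_std[, -ncol(p$beta_std)])
  expect_lt(max(jumps), 0.25)
})

test_that("lasso path agrees with glmnet at matched penalties", {
  co <- make_cohort(120, beta = c(V20 = 0.25), seed = 14)
  X <- as.matrix(as.data.frame(co)[fv_names()])
  y <- co$rp_grade2plus
  ref <- lasso_path(X, y, n_lambda = 20)
  lam <- ref$lambda[c(5, 10, 15)]
  g <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                      thresh = 1e-14)
  mine <- lasso_path(X, y, lambda = lam)
  expect_lt(max(abs(as.matrix(g$beta) - mine$beta)), 1e-4)
  expect_lt(max(abs(g$a0 - mine$beta0)), 1e-4)
})

test_that("cross-validated lasso selection is deterministic and well-formed", {
  co <- make_cohort(100, beta = c(V25 = 0.4), seed = 15)
  a <- lasso_select(co, n_lambda = 40, cv_folds = 5, seed = 99)
  b <- lasso_select(co, n_lambda = 40, cv_folds = 5, seed = 99)
  expect_identical(a$selected, b$selected)
  expect_identical(a$criterion_trace, b$criterion_trace)
  expect_true("V25" %in% a$selected)
  expect_true(all(a$selected %in% fv_names()))
})

test_that("random-forest importance: constant covariates score zero, dominant ones first", {
  co <- make_cohort(200, beta = c(V30 = 3), seed = 16, mu = 0, sd = 1)
  co$V60 <- 7   # constant covariate
  res <- ensemble_importance(co, n_trees = 300, seed = 1)
  tr <- res$criterion_trace
  expect_lt(abs(tr$mean_decrease_accuracy[tr$variable == "V60"]), 0.01)
  expect_lt(abs(tr$mean_decrease_gini[tr$variable == "V60"]), 0.01)
  expect_identical(res$selected[1], "V30")
  expect_identical(res$extras$gini_ranking[1], "V30")
})

test_that("permuting the outcome leaves permutation importances at the null", {
  co <- make_cohort(150, beta = c(V20 = 0.3), seed = 17)
  withr::local_seed(18)
  co$rp_grade2plus <- sample(co$rp_grade2plus)
  res <- ensemble_importance(co, n_trees = 400, seed = 2)
  imp <- res$criterion_trace$mean_decrease_accuracy
  # no covariate retains real signal: importances hug zero, and at least
  # 95% sit within two cross-covariate standard deviations of their mean
  expect_lt(max(abs(imp)), 0.01)
  expect_gte(mean(abs(imp - mean(imp)) <= 2 * sd(imp)), 0.95)
})

test_that("selectors propagate fit preconditions", {
  co <- make_cohort(30, seed = 19)
  co$rp_grade2plus <- rep(0, 30)
  expect_error(stepwise_select(co, c("V5", "V10")), "both outcome classes")
  expect_error(best_subset_select(co, c("V5", "V10")), "both outcome classes")
  co2 <- make_cohort(8, seed = 20)
  expect_error(ensemble_importance(co2), "at least 10")
})
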