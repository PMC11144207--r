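test_that("AUC handles perfect separation, ties and a worked example", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), alpha = NULL)$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0), alpha = NULL)$auc, 0.5)
  # 1 concordant of 4 event/non-event pairs
  expect_equal(roc_auc(c(3, 2, 1, 4), c(1, 0, 1, 0), alpha = NULL)$auc, 0.25)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("AUC equals brute-force pairwise concordance on random instances", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq_len(12), n, replace = TRUE)   # many ties
    expect_identical(roc_auc(scores, labels, alpha = NULL)$auc,
                     brute_force_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::local_seed(32)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4); labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels, alpha = NULL)$auc
  expect_equal(roc_auc(exp(scores), labels, alpha = NULL)$auc, a)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels, alpha = NULL)$auc, a,
               tolerance = 1e-12)
})

test_that("operating points trace the empirical ROC", {
  withr::local_seed(33)
  scores <- round(rnorm(25), 1)
  labels <- rbinom(25, 1, 0.5); labels[1:2] <- c(0, 1)
  r <- roc_auc(scores, labels, alpha = NULL)
  op <- r$operating_points
  expect_true(!is.unsorted(op$threshold))
  expect_true(all(op$sensitivity >= 0 & op$sensitivity <= 1))
  i <- which.min(abs(op$threshold - stats::median(scores)))
  t0 <- op$threshold[i]
  expect_equal(op$sensitivity[i], mean(scores[labels == 1] >= t0))
})

test_that("DeLong interval contains the AUC and matches pROC", {
  withr::local_seed(34)
  scores <- c(rnorm(30), rnorm(30, 1))
  labels <- rep(c(0, 1), each = 30)
  r <- roc_auc(scores, labels)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(labels, scores,
                                                 direction = "<", quiet = TRUE),
                                       method = "delong"))
  expect_equal(c(r$ci_low, r$ci_high), as.numeric(ref)[c(1, 3)],
               tolerance = 1e-9)
})

test_that("degenerate separation collapses the DeLong interval with a warning", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_warning(ci <- delong_ci(scores, labels), "degenerate")
  expect_equal(ci, c(1, 1))
})

test_that("apparent calibration of grouped predictions recovers group frequencies", {
  # two prediction groups with known event rates
  X <- data.frame(matrix(30, 40, 12)); names(X) <- fv_names()
  X$V20 <- rep(c(10, 50), each = 20)
  X$rp_grade2plus <- c(rep(c(0, 1), c(15, 5)), rep(c(0, 1), c(5, 15)))
  co <- as_cohort_table(X)
  cal <- calibrate_bootstrap(co, "V20", n_boot = 0)
  expect_null(cal$bias_corrected)
  m <- fit_logistic(co, "V20")
  p <- sort(unique(predict_risk(m, X)$probability))
  # saturated two-group model: smoothed curve passes through 0.25 and 0.75
  lo <- cal$apparent[which.min(abs(cal$grid - p[1]))]
  hi <- cal$apparent[which.min(abs(cal$grid - p[2]))]
  expect_equal(lo, 0.25, tolerance = 1e-6)
  expect_equal(hi, 0.75, tolerance = 1e-6)
})

test_that("a well-specified model has bias-corrected calibration slope near one", {
  beta <- c(V15 = 0.12, V35 = -0.1)
  co <- make_cohort(500, beta = beta, intercept = 0.3, seed = 35)
  cal <- calibrate_bootstrap(co, names(beta), n_boot = 200, seed = 36)
  expect_gte(cal$slope, 0.85)
  expect_lte(cal$slope, 1.15)
  expect_true(all(cal$bias_corrected >= -0.05 & cal$bias_corrected <= 1.05))
})

test_that("a grossly overfit model shows positive optimism", {
  co <- make_cohort(41, seed = 37)   # 12 noise covariates, n = 41
  cal <- calibrate_bootstrap(co, fv_names(), n_boot = 100, seed = 38)
  # optimism shrinks the corrected slope below the apparent slope of 1
  expect_lt(cal$slope, 1)
  mean_optimism <- mean(cal$apparent - cal$bias_corrected)
  expect_gt(mean_optimism, 0)
})

test_that("calibration rejects negative bootstrap counts", {
  co <- make_cohort(50, seed = 39)
  expect_error(calibrate_bootstrap(co, "V5", n_boot = -1), "n_boot")
})

test_that("nomogram normalisation: spans, references and probability map", {
  m <- logistic_model(-2, c(V10 = 0.05, V30 = -0.02, V50 = 0))
  rng <- list(V10 = c(0, 100), V30 = c(0, 100), V50 = c(0, 100))
  nom <- nomogram_points(m, rng)
  # V10 has the largest |beta|*range: spans exactly 0-100
  expect_identical(nom$top_variable, "V10")
  expect_equal(range(nom$scales$V10$points), c(0, 100))
  # zero coefficient: flat zero scale
  expect_true(all(nom$scales$V50$points == 0))
  # negative coefficient: reference at the range maximum, points decrease in x
  expect_equal(nom$scales$V30$points[1], 100 * 0.02 * 100 / (0.05 * 100))
  expect_equal(utils::tail(nom$scales$V30$points, 1), 0)
  # total points reproduce the linear predictor through the probability map
  x <- c(V10 = 60, V30 = 40, V50 = 10)
  pts <- sum(vapply(names(x), function(nm) {
    s <- nom$scales[[nm]]
    stats::approx(s$value, s$points, xout = x[[nm]])$y
  }, numeric(1)))
  lp <- -2 + 0.05 * 60 - 0.02 * 40
  expect_equal(plogis(lp),
               stats::approx(nom$total_to_probability$total_points,
                             nom$total_to_probability$probability,
                             xout = pts)$y, tolerance = 1e-6)
  # single-covariate model spans 0-100 by construction
  nom1 <- nomogram_points(logistic_model(0, c(V20 = -0.3)),
                          list(V20 = c(10, 60)))
  expect_equal(range(nom1$scales$V20$points), c(0, 100))
  expect_error(nomogram_points(m, list(V10 = c(0, 0), V30 = c(0, 1),
                                       V50 = c(0, 1))), "zero-width|invalid")
})

test_that("the published model with equal ranges is dominated by V25", {
  nom <- nomogram_points(published_stepwise_model(),
                         stats::setNames(rep(list(c(0, 100)), 6),
                                         names(published_stepwise_model()$coefficients)))
  expect_identical(nom$top_variable, "V25")
})

test_that("Pearson chi-square matches the 2x2 closed form and independence limit", {
  withr::local_seed(40)
  for (rep in 1:10) {
    t2 <- matrix(sample(1:30, 4, replace = TRUE), 2, 2)
    a <- t2[1, 1]; b <- t2[1, 2]; c2 <- t2[2, 1]; d <- t2[2, 2]
    n <- sum(t2)
    closed <- n * (a * d - b * c2)^2 /
      ((a + b) * (c2 + d) * (a + c2) * (b + d))
    expect_equal(pearson_chi2(t2)$statistic, closed, tolerance = 1e-12)
  }
  ident <- rbind(c(12, 18, 6), c(4, 6, 2))   # identical row distributions
  res <- pearson_chi2(ident)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "margins")
})
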