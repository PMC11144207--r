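# Shared fixtures and independent oracles, built in code at test time.

# Small cohort with independent N(mu, sd) covariates (columns V5..V60) and
# outcomes from a chosen linear predictor over mean-centred covariates, so
# `intercept` is the population logit. The raw-scale true intercept is
# intercept - sum(beta * mu).
make_cohort <- function(n, beta = c(), intercept = 0, seed = 1,
                        mu = 30, sd = 10) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * 12, mu, sd), n, 12)
  colnames(X) <- fv_names()
  eta <- rep(intercept, n)
  for (nm in names(beta)) eta <- eta + beta[[nm]] * (X[, nm] - mu)
  y <- rbinom(n, 1, plogis(eta))
  as_cohort_table(data.frame(X, rp_grade2plus = y, check.names = FALSE))
}

# Independent brute-force AUC: explicit loop over every (event, non-event)
# pair, ties counting one half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Independent voxel-by-voxel Jacobian oracle: finite-differences the
# deformation map phi(x) = x + u(x) with explicit loops and a textbook
# 3x3 determinant. Central differences inside, one-sided at borders.
brute_force_jacobian <- function(field) {
  u <- field$vectors
  sp <- field$spacing
  n <- dim(u)[1:3]
  J <- array(NA_real_, n)
  d1 <- function(vals, idx, axis) {
    i <- idx
    h <- sp[axis]
    lo <- idx; hi <- idx
    if (idx[axis] == 1) { hi[axis] <- 2; return((vals[t(hi)] - vals[t(lo)]) / h) }
    if (idx[axis] == n[axis]) { lo[axis] <- n[axis] - 1; return((vals[t(hi)] - vals[t(lo)]) / h) }
    lo[axis] <- idx[axis] - 1; hi[axis] <- idx[axis] + 1
    (vals[t(hi)] - vals[t(lo)]) / (2 * h)
  }
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    idx <- c(i, j, k)
    A <- matrix(0, 3, 3)
    for (comp in 1:3) for (axis in 1:3) {
      # derivative of phi_comp = x_comp + u_comp
      A[comp, axis] <- (comp == axis) + d1(u[, , , comp], idx, axis)
    }
    J[i, j, k] <- A[1, 1] * (A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2]) -
      A[1, 2] * (A[2, 1] * A[3, 3] - A[2, 3] * A[3, 1]) +
      A[1, 3] * (A[2, 1] * A[3, 2] - A[2, 2] * A[3, 1])
  }
  J
}

# Smooth random displacement field: filtered white noise, periodic-free.
random_smooth_field <- function(n = c(8, 8, 8), spacing = c(2, 2, 2),
                                amplitude = 1.5, seed = 1) {
  withr::local_seed(seed)
  u <- array(0, c(n, 3))
  for (k in 1:3) {
    raw <- array(rnorm(prod(n)), n)
    sm <- ventidose:::gaussian_smooth3(raw, c(1.5, 1.5, 1.5))
    u[, , , k] <- amplitude * sm / max(abs(sm))
  }
  displacement_field(u, spacing)
}
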