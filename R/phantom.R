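#' Specification of a synthetic breathing phantom
#'
#' The phantom emulates a thorax over one breathing excursion: a smooth
#' CT-like intensity pattern, two ellipsoidal lungs, and an analytic
#' craniocaudal displacement field whose Jacobian determinant is known in
#' closed form. It exists so that registration, ventilation mapping and
#' dosimetry can be validated without patient data.
#'
#' The breathing field is \eqn{u = (0, 0, u_z)} with
#' \deqn{u_z(x,y,z) = A \, \tau(t_x) \tau(t_y) \, g(s) / g_{max},}
#' where \eqn{t_x, t_y, s} are coordinates normalised to the grid extent,
#' \eqn{\tau(t) = \sin^2(\pi t)} tapers the field to zero (with zero slope)
#' at the lateral borders, and \eqn{g(s) = \sin(\pi s) e^{-\lambda s}} is a
#' spatial sinusoid decaying toward the lung apex (\eqn{s = 1}) at rate
#' \eqn{\lambda} (\code{motion_decay}). Because only \eqn{\partial u_z /
#' \partial z} enters the determinant, \eqn{J = 1 + \partial u_z/\partial z}
#' exactly, available from \code{\link{phantom_true_jacobian}}.
#'
#' \code{field_mode = "affine"} replaces the breathing field with the linear
#' field \eqn{u(x) = a (x - x_c)} about the grid centre, for which
#' \eqn{J = (1 + a)^3} at every voxel — the standard closed-form check.
#'
#' @param grid_shape integer length-3 voxel counts, all >= 8.
#' @param spacing mm per voxel, length 3.
#' @param lung_geometry list of two lists, each with \code{center} (mm) and
#'   \code{semi_axes} (mm) of a lung ellipsoid; \code{NULL} scales a default
#'   two-lung layout to the grid extent.
#' @param motion_amplitude peak craniocaudal displacement, mm (>= 0).
#' @param motion_decay dimensionless decay rate of motion toward the apex.
#' @param noise_sd standard deviation of additive HU-like intensity noise.
#' @param seed integer RNG seed for the noise.
#' @param field_mode \code{"breathing"} (default) or \code{"affine"}.
#' @param affine_scale the coefficient \eqn{a} of the affine test field.
#' @return A \code{phantom_spec} object.
#' @examples
#' spec <- phantom_spec(grid_shape = c(16, 16, 16), motion_amplitude = 5)
#' ph <- generate_phantom_pair(spec)
#' ph$lung
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         spacing = c(4, 4, 4),
                         lung_geometry = NULL,
                         motion_amplitude = 10,
                         motion_decay = 1.5,
                         noise_sd = 0,
                         seed = 20240601,
                         field_mode = c("breathing", "affine"),
                         affine_scale = 0.1) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  field_mode <- match.arg(field_mode)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three counts, all >= 8")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  if (motion_amplitude < 0) stop("motion_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  extent <- (grid_shape - 1) * spacing
  if (is.null(lung_geometry)) {
    lung_geometry <- list(
      list(center = c(0.31, 0.5, 0.5) * extent,
           semi_axes = c(0.17, 0.22, 0.38) * extent),
      list(center = c(0.69, 0.5, 0.5) * extent,
           semi_axes = c(0.17, 0.22, 0.38) * extent))
  }
  for (ell in lung_geometry) {
    if (any(ell$center - ell$semi_axes < 0) ||
        any(ell$center + ell$semi_axes > extent))
      stop("degenerate geometry: lung ellipsoid extends beyond the grid ",
           "(centre ", paste(signif(ell$center, 4), collapse = ","),
           " mm, semi-axes ", paste(signif(ell$semi_axes, 4), collapse = ","),
           " mm, grid extent ", paste(signif(extent, 4), collapse = ","), " mm)")
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 lung_geometry = lung_geometry,
                 motion_amplitude = motion_amplitude,
                 motion_decay = motion_decay, noise_sd = noise_sd,
                 seed = as.integer(seed), field_mode = field_mode,
                 affine_scale = affine_scale),
            class = "phantom_spec")
}

# Evaluate the analytic displacement components at world coordinates
# (3D arrays x, y, z). Returns list(ux, uy, uz).
phantom_field_components <- function(spec, w) {
  n <- spec$grid_shape
  extent <- (n - 1) * spec$spacing
  if (spec$field_mode == "affine") {
    ctr <- extent / 2
    a <- spec$affine_scale
    return(list(ux = a * (w$x - ctr[1]), uy = a * (w$y - ctr[2]),
                uz = a * (w$z - ctr[3])))
  }
  A <- spec$motion_amplitude
  lam <- spec$motion_decay
  tx <- w$x / extent[1]; ty <- w$y / extent[2]; s <- w$z / extent[3]
  gmax <- phantom_g_max(lam)
  g <- sin(pi * s) * exp(-lam * s)
  uz <- A * sin(pi * tx)^2 * sin(pi * ty)^2 * g / gmax
  list(ux = array(0, n), uy = array(0, n), uz = uz)
}

# Peak of g(s) = sin(pi s) exp(-lambda s) on [0, 1]; the stationary point
# solves tan(pi s) = pi / lambda.
phantom_g_max <- function(lam) {
  if (lam == 0) return(1)
  s_star <- atan(pi / lam) / pi
  sin(pi * s_star) * exp(-lam * s_star)
}

#' Closed-form Jacobian of the phantom deformation
#'
#' For the breathing field only the \eqn{\partial u_z/\partial z} term
#' enters the determinant, so \eqn{J = 1 + \partial u_z/\partial z} exactly;
#' for the affine mode \eqn{J = (1 + a)^3} at every voxel. Used as the
#' independent oracle for \code{\link{jacobian_determinant}}.
#'
#' @param spec a \code{phantom_spec}.
#' @return A \code{ventilation_map} holding the analytic Jacobian.
#' @export
phantom_true_jacobian <- function(spec) {
  n <- spec$grid_shape
  g0 <- image_grid(array(0, n), spec$spacing)
  if (spec$field_mode == "affine") {
    J <- array((1 + spec$affine_scale)^3, n)
    return(ventilation_map(J, spec$spacing))
  }
  w <- world_coordinate_arrays(g0)
  extent <- (n - 1) * spec$spacing
  A <- spec$motion_amplitude; lam <- spec$motion_decay
  tx <- w$x / extent[1]; ty <- w$y / extent[2]; s <- w$z / extent[3]
  gmax <- phantom_g_max(lam)
  dg_ds <- exp(-lam * s) * (pi * cos(pi * s) - lam * sin(pi * s))
  duz_dz <- A * sin(pi * tx)^2 * sin(pi * ty)^2 * dg_ds / (gmax * extent[3])
  ventilation_map(1 + duz_dz, spec$spacing)
}

#' Generate a synthetic exhale/inhale pair with known deformation
#'
#' Builds the exhale volume from a smooth analytic intensity model (soft
#' tissue body, air-filled lungs with low-frequency internal texture),
#' evaluates the analytic displacement field on the grid, and produces the
#' inhale volume by resampling exhale through that field with trilinear
#' interpolation. Optional Gaussian intensity noise is added independently
#' to both volumes after warping.
#'
#' @param spec a \code{phantom_spec}.
#' @return list with elements \code{exhale}, \code{inhale} (image_grid),
#'   \code{truth} (displacement_field mapping fixed = inhale grid points to
#'   their exhale locations), and \code{lung} (structure_mask).
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape
  g0 <- image_grid(array(0, n), spec$spacing)
  w <- world_coordinate_arrays(g0)
  extent <- (n - 1) * spec$spacing

  # smooth body envelope: product of border tapers, superelliptic falloff
  tx <- w$x / extent[1]; ty <- w$y / extent[2]; tz <- w$z / extent[3]
  body <- (sin(pi * tx) * sin(pi * ty))^0.5 * (0.25 + 0.75 * sin(pi * tz)^0.5)

  lung_soft <- array(0, n)
  inside <- array(FALSE, n)
  for (ell in spec$lung_geometry) {
    r2 <- ((w$x - ell$center[1]) / ell$semi_axes[1])^2 +
          ((w$y - ell$center[2]) / ell$semi_axes[2])^2 +
          ((w$z - ell$center[3]) / ell$semi_axes[3])^2
    lung_soft <- pmax(lung_soft, exp(-r2^2))
    inside <- inside | (r2 <= 1)
  }
  texture <- sin(2 * pi * w$x / 29) * sin(2 * pi * w$y / 23) *
    sin(2 * pi * w$z / 37)
  intens <- -1000 + 1000 * body - 750 * lung_soft + 140 * texture * lung_soft

  exhale_vals <- intens
  u <- phantom_field_components(spec, w)
  vectors <- array(0, c(n, 3))
  vectors[, , , 1] <- u$ux; vectors[, , , 2] <- u$uy; vectors[, , , 3] <- u$uz
  truth <- displacement_field(vectors, spec$spacing)
  exhale <- image_grid(exhale_vals, spec$spacing)
  inhale <- warp_image(exhale, truth)
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      exhale$values <- exhale$values + array(stats::rnorm(prod(n), 0, spec$noise_sd), n)
      inhale$values <- inhale$values + array(stats::rnorm(prod(n), 0, spec$noise_sd), n)
    })
  }
  lung <- structure_mask(inside, spec$spacing, name = "lung")
  list(exhale = exhale, inhale = inhale, truth = truth, lung = lung)
}

#' Synthetic dose distribution with Gaussian falloff
#'
#' Dose equals \code{prescription} at \code{target_center} and decays as
#' \eqn{D(r) = D_0 \exp(-r^2 / (2 \sigma^2))} with \eqn{\sigma =}
#' \code{falloff_mm}. The voxel sum times the voxel volume approaches the
#' closed-form integral \eqn{D_0 (2\pi)^{3/2} \sigma^3} on grids that
#' contain the bulk of the falloff.
#'
#' @param spec a \code{phantom_spec} providing the grid.
#' @param target_center mm 3-vector; must lie inside the grid extent.
#' @param prescription peak dose in Gy (> 0).
#' @param falloff_mm Gaussian sigma of the dose falloff in mm (> 0).
#' @return a \code{dose_grid}.
#' @export
generate_dose_grid <- function(spec, target_center, prescription = 60,
                               falloff_mm = 30) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (prescription <= 0) stop("prescription must be > 0")
  if (falloff_mm <= 0) stop("falloff_mm must be > 0")
  target_center <- as.numeric(target_center)
  extent <- (spec$grid_shape - 1) * spec$spacing
  if (length(target_center) != 3L || any(target_center < 0) ||
      any(target_center > extent))
    stop("target_center lies outside the grid extent")
  g0 <- image_grid(array(0, spec$grid_shape), spec$spacing)
  w <- world_coordinate_arrays(g0)
  r2 <- (w$x - target_center[1])^2 + (w$y - target_center[2])^2 +
    (w$z - target_center[3])^2
  dose_grid(prescription * exp(-r2 / (2 * falloff_mm^2)), spec$spacing)
}

#' Specification of a simulated patient cohort
#'
#' Defines the joint distribution of the 12 functional dose-volume
#' covariates V5...V60 and the logistic outcome model that generates
#' grade->=2 radiation-pneumonitis labels. Covariates are drawn from a
#' multivariate normal with the given mean and covariance, sorted in
#' decreasing order across the 12 dose levels so every draw is a valid
#' cumulative DVH (V5 >= V10 >= ... >= V60), and clipped to [0, 100].
#'
#' The defaults reproduce the study conditions the pipeline targets: 41
#' patients, outcomes generated from the published stepwise risk model, and
#' a strongly autocorrelated covariance so that neighbouring dose levels
#' carry nearly collinear information — the regime in which different
#' variable selectors genuinely disagree.
#'
#' @param n_patients cohort size.
#' @param true_model a \code{logistic_model} generating the outcome.
#' @param covariate_mean length-12 mean vector of V5...V60, in percent.
#' @param covariate_covariance 12x12 symmetric positive semi-definite
#'   covariance (percent^2).
#' @param seed integer RNG seed.
#' @return a \code{cohort_sim_spec}.
#' @export
cohort_sim_spec <- function(n_patients = 41,
                            true_model = default_true_model(),
                            covariate_mean = default_covariate_mean(),
                            covariate_covariance = default_covariate_covariance(),
                            seed = 20240601) {
  covariate_mean <- as.numeric(covariate_mean)
  covariate_covariance <- as.matrix(covariate_covariance)
  if (length(covariate_mean) != 12L)
    stop("covariate_mean must have 12 entries (V5...V60)")
  if (!identical(dim(covariate_covariance), c(12L, 12L)))
    stop("covariate_covariance must be 12x12")
  if (max(abs(covariate_covariance - t(covariate_covariance))) > 1e-8)
    stop("covariate_covariance must be symmetric")
  ev <- eigen(covariate_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("covariate_covariance is not positive semi-definite")
  structure(list(n_patients = as.integer(n_patients), true_model = true_model,
                 covariate_mean = covariate_mean,
                 covariate_covariance = covariate_covariance,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' @rdname cohort_sim_spec
#' @export
default_true_model <- function() {
  # published stepwise coefficients as the generating mechanism, with the
  # simulation intercept calibrated once so the expected event rate at the
  # default covariate distribution equals the 16/41 rate of the cohort the
  # pipeline emulates
  m <- published_stepwise_model()
  logistic_model(-0.898, m$coefficients, method = "simulation-truth")
}

#' @rdname cohort_sim_spec
#' @export
default_covariate_mean <- function() {
  # plausible decreasing fLung DVH profile (percent receiving >= 5..60 Gy)
  c(V5 = 62, V10 = 52, V15 = 43, V20 = 36, V25 = 30, V30 = 25,
    V35 = 20, V40 = 16, V45 = 12, V50 = 9, V55 = 6, V60 = 4)
}

#' @rdname cohort_sim_spec
#' @export
default_covariate_covariance <- function() {
  # AR(1)-correlated cumulative percentages: adjacent dose levels are nearly
  # collinear (rho = 0.92), per-level sd 9 percent
  rho <- 0.92
  sd <- 9
  R <- rho^abs(outer(1:12, 1:12, "-"))
  sd^2 * R
}

#' Names of the 12 functional dose-volume covariates, V5 through V60
#' @export
fv_names <- function() paste0("V", seq(5, 60, by = 5))

#' Simulate a cohort of functional dose-volume covariates and RP outcomes
#'
#' @param spec a \code{cohort_sim_spec}.
#' @return a \code{cohort_table}: a data frame with columns
#'   \code{patient_id}, \code{V5}...\code{V60} (percent) and
#'   \code{rp_grade2plus} (0/1).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    ee <- eigen(spec$covariate_covariance, symmetric = TRUE)
    lam <- pmax(ee$values, 0)
    L <- ee$vectors %*% diag(sqrt(lam))
    Z <- matrix(stats::rnorm(n * 12), nrow = 12)
    X <- t(spec$covariate_mean + L %*% Z)
    # sort each patient's 12 values in decreasing order: valid cumulative DVH
    X <- t(apply(X, 1, sort, decreasing = TRUE))
    X <- pmin(pmax(X, 0), 100)
    colnames(X) <- fv_names()
    eta <- predict_risk(spec$true_model, as.data.frame(X))$linear_predictor
    y <- stats::rbinom(n, 1, stats::plogis(eta))
  })
  df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), X,
                   rp_grade2plus = y, check.names = FALSE)
  as_cohort_table(df)
}

#' Validate and tag a cohort data frame
#'
#' @param df data frame with columns \code{V5}...\code{V60} and
#'   \code{rp_grade2plus}; a \code{patient_id} column is added if missing.
#' @return the validated \code{cohort_table}.
#' @export
as_cohort_table <- function(df) {
  df <- as.data.frame(df)
  need <- c(fv_names(), "rp_grade2plus")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(df$rp_grade2plus %in% c(0, 1)))
    stop("rp_grade2plus must be binary 0/1")
  if (anyNA(df[need])) stop("cohort table must not contain missing values")
  if (is.null(df$patient_id))
    df$patient_id <- sprintf("P%03d", seq_len(nrow(df)))
  class(df) <- c("cohort_table", "data.frame")
  df
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
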