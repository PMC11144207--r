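#' Warp an image through a displacement field
#'
#' Samples \code{moving} at the displaced positions \eqn{x + u(x)} of every
#' voxel centre \eqn{x} of the field's grid, with trilinear interpolation;
#' sample positions outside the moving grid take the nearest-edge value.
#'
#' @param moving an \code{image_grid}.
#' @param field a \code{displacement_field} on a grid with the same shape,
#'   spacing and origin as \code{moving}.
#' @return an \code{image_grid} on the field's grid.
#' @export
warp_image <- function(moving, field) {
  stopifnot(inherits(moving, "image_grid"), inherits(field, "displacement_field"))
  if (!same_grid(moving, field))
    stop("moving image and displacement field must share shape, spacing and origin")
  w <- world_coordinate_arrays(field)
  pts <- cbind(as.vector(w$x) + as.vector(field$vectors[, , , 1]),
               as.vector(w$y) + as.vector(field$vectors[, , , 2]),
               as.vector(w$z) + as.vector(field$vectors[, , , 3]))
  vals <- trilinear_sample_world(moving, pts)
  image_grid(array(vals, grid_shape(field)), field$spacing, field$origin)
}

# Spacing-aware gradient of a 3D array: central differences in the
# interior, one-sided at the borders. Returns list(gx, gy, gz) in
# units of value per mm.
gradient3 <- function(v, spacing) {
  n <- dim(v)
  g <- vector("list", 3)
  for (axis in 1:3) {
    h <- spacing[axis]
    nd <- n[axis]
    fwd <- shift_axis(v, axis, 1L)
    bwd <- shift_axis(v, axis, -1L)
    gr <- (fwd - bwd) / (2 * h)
    # one-sided at the two border slabs
    idx_first <- slab_index(n, axis, 1L)
    idx_last <- slab_index(n, axis, nd)
    gr[idx_first] <- (v[slab_index(n, axis, 2L)] - v[idx_first]) / h
    gr[idx_last] <- (v[idx_last] - v[slab_index(n, axis, nd - 1L)]) / h
    g[[axis]] <- gr
  }
  names(g) <- c("gx", "gy", "gz")
  g
}

# Shift a 3D array by `by` voxels along `axis` (replicating the edge),
# so that result[i] = v[i + by] with clamping.
shift_axis <- function(v, axis, by) {
  n <- dim(v)
  idx <- pmin(pmax(seq_len(n[axis]) + by, 1L), n[axis])
  switch(axis, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}

# Logical index matrix selecting one slab perpendicular to `axis`.
slab_index <- function(n, axis, at) {
  out <- as.matrix(expand.grid(
    x = if (axis == 1L) at else seq_len(n[1]),
    y = if (axis == 2L) at else seq_len(n[2]),
    z = if (axis == 3L) at else seq_len(n[3])))
  colnames(out) <- NULL
  out
}

#' Multi-resolution diffusive demons registration
#'
#' Estimates the displacement field mapping each fixed-grid point to its
#' corresponding moving-image location, by Thirion-style demons forces with
#' Gaussian field regularisation, run coarse to fine. The commercial
#' deformable-registration step it replaces is treated as pluggable: any
#' smooth field source (including precomputed fields read with
#' \code{\link{read_volume}}) can feed the downstream ventilation analysis.
#'
#' Each iteration warps \code{moving} through the current field, computes
#' the demons force \eqn{v = (F - M_w)\nabla M_w / (|\nabla M_w|^2 + (F -
#' M_w)^2 / s^2)} (with \eqn{s} the mean voxel spacing), adds it to the
#' field and smooths every component with a Gaussian of standard deviation
#' \code{smoothing_sigma_mm}. Iteration counts are fixed (no convergence
#' test) so results are deterministic. If the final field fails to improve
#' the mean squared intensity difference over the zero field, the zero
#' field is returned with a warning.
#'
#' @param fixed,moving \code{image_grid}s on identical grids (resample
#'   first otherwise).
#' @param levels number of resolution levels (coarsest is downsampled by
#'   \code{2^(levels-1)}).
#' @param iterations_per_level demons iterations at each level.
#' @param smoothing_sigma_mm Gaussian regularisation sigma in mm.
#' @return a \code{displacement_field} on the fixed grid.
#' @export
register_demons <- function(fixed, moving, levels = 3,
                            iterations_per_level = 50,
                            smoothing_sigma_mm = 2) {
  stopifnot(inherits(fixed, "image_grid"), inherits(moving, "image_grid"))
  if (!same_grid(fixed, moving))
    stop("fixed and moving must share shape, spacing and origin; resample first")
  rng_f <- diff(range(fixed$values))
  rng_m <- diff(range(moving$values))
  if (rng_f == 0 || rng_m == 0) {
    warning("constant-intensity input: registration problem has no gradient; ",
            "returning zero field")
    return(displacement_field(array(0, c(grid_shape(fixed), 3)),
                              fixed$spacing, fixed$origin))
  }
  mse0 <- mean((fixed$values - moving$values)^2)

  field <- NULL
  for (lev in seq_len(levels)) {
    factor <- 2L^(levels - lev)
    f_l <- downsample_grid(fixed, factor)
    m_l <- downsample_grid(moving, factor)
    if (is.null(field)) {
      u <- array(0, c(grid_shape(f_l), 3))
      field <- displacement_field(u, f_l$spacing, f_l$origin)
    } else {
      field <- resample_field(field, f_l)
    }
    field <- demons_iterate(f_l, m_l, field, iterations_per_level,
                            smoothing_sigma_mm)
  }
  if (!same_grid(field, fixed)) field <- resample_field(field, fixed)
  mse1 <- mean((fixed$values - warp_image(moving, field)$values)^2)
  if (mse1 > mse0) {
    warning("demons registration did not improve the intensity match; ",
            "returning zero field")
    return(displacement_field(array(0, c(grid_shape(fixed), 3)),
                              fixed$spacing, fixed$origin))
  }
  field
}

demons_iterate <- function(fixed, moving, field, iters, sigma_mm) {
  s2 <- mean(fixed$spacing)^2
  sigma_vox <- sigma_mm / fixed$spacing
  u <- field$vectors
  for (it in seq_len(iters)) {
    fld <- displacement_field(u, fixed$spacing, fixed$origin)
    mw <- warp_image(moving, fld)$values
    diffv <- fixed$values - mw
    g <- gradient3(mw, fixed$spacing)
    denom <- g$gx^2 + g$gy^2 + g$gz^2 + diffv^2 / s2
    denom[denom < 1e-9] <- Inf
    scale <- diffv / denom
    u[, , , 1] <- gaussian_smooth3(u[, , , 1] + scale * g$gx, sigma_vox)
    u[, , , 2] <- gaussian_smooth3(u[, , , 2] + scale * g$gy, sigma_vox)
    u[, , , 3] <- gaussian_smooth3(u[, , , 3] + scale * g$gz, sigma_vox)
  }
  displacement_field(u, fixed$spacing, fixed$origin)
}

# Smooth-then-subsample by an integer factor; spacing scales accordingly.
downsample_grid <- function(g, factor) {
  if (factor <= 1L) return(g)
  v <- gaussian_smooth3(g$values, rep(factor / 2, 3))
  n <- grid_shape(g)
  ix <- seq(1L, n[1], by = factor)
  iy <- seq(1L, n[2], by = factor)
  iz <- seq(1L, n[3], by = factor)
  image_grid(v[ix, iy, iz, drop = FALSE], g$spacing * factor, g$origin)
}

# Trilinearly resample a displacement field onto a target grid (vectors
# stay world-mm, so no value rescaling is needed).
resample_field <- function(field, target) {
  w <- world_coordinate_arrays(target)
  pts <- cbind(as.vector(w$x), as.vector(w$y), as.vector(w$z))
  n <- grid_shape(target)
  out <- array(0, c(n, 3))
  for (k in 1:3) {
    comp <- image_grid(field$vectors[, , , k], field$spacing, field$origin)
    out[, , , k] <- array(trilinear_sample_world(comp, pts), n)
  }
  displacement_field(out, target$spacing, target$origin)
}
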