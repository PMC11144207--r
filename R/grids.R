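#' Voxel grid containers
#'
#' The pipeline moves scalar images, dose distributions, boolean structure
#' masks and displacement vector fields between stages. All four share the
#' same geometry model: a regular voxel lattice with per-axis spacing (mm)
#' and a world-space origin (mm) at the centre of voxel (1,1,1), axes
#' world-aligned, x varying fastest in storage.
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @return An object of class \code{image_grid} (a list with elements
#'   \code{values}, \code{spacing}, \code{origin}).
#' @examples
#' g <- image_grid(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
#' grid_shape(g)
#' @export
image_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' Dose distribution on a voxel grid
#'
#' @param dose numeric 3D array of absorbed dose per voxel, in Gy;
#'   non-negative and finite.
#' @inheritParams image_grid
#' @return An object of class \code{c("dose_grid", "image_grid")}; the dose
#'   array is stored in \code{$values}.
#' @export
dose_grid <- function(dose, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  g <- image_grid(dose, spacing, origin)
  if (any(!is.finite(g$values))) stop("dose must be finite everywhere")
  if (any(g$values < 0)) stop("dose must be non-negative")
  class(g) <- c("dose_grid", "image_grid")
  g
}

#' Boolean structure mask on a voxel grid
#'
#' @param inside logical 3D array, TRUE for voxels inside the structure.
#' @param name label for the structure (e.g. \code{"lung"}, \code{"fLung"}).
#' @inheritParams image_grid
#' @return An object of class \code{structure_mask}.
#' @export
structure_mask <- function(inside, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           name = "structure") {
  inside <- as.array(inside)
  if (length(dim(inside)) != 3L) stop("`inside` must be a 3D array")
  storage.mode(inside) <- "logical"
  if (anyNA(inside)) stop("mask must not contain NA")
  g <- image_grid(array(0, dim(inside)), spacing, origin)
  structure(list(inside = inside, spacing = g$spacing, origin = g$origin,
                 name = as.character(name)[1]),
            class = "structure_mask")
}

#' Displacement vector field on a voxel grid
#'
#' Vectors are world-axis displacements in mm, defined at the voxel centres
#' of the fixed grid; a voxel at world position x corresponds to position
#' x + u(x) in the moving image.
#'
#' @param vectors numeric 4D array with dim \code{c(nx, ny, nz, 3)}; finite.
#' @inheritParams image_grid
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("`vectors` must be a 4D array with last dim 3")
  if (any(!is.finite(vectors))) {
    bad <- which(!is.finite(vectors), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite displacement component at voxel (%d,%d,%d)",
                 bad[1], bad[2], bad[3]))
  }
  g <- image_grid(array(0, d[1:3]), spacing, origin)
  structure(list(vectors = vectors, spacing = g$spacing, origin = g$origin),
            class = "displacement_field")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(grid_shape(x), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask '%s'> %s voxels, %d inside (%.1f%%)\n",
              x$name, paste(grid_shape(x), collapse = "x"),
              sum(x$inside), 100 * mean(x$inside)))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<displacement_field> %s voxels, |u| mean %.3f mm, max %.3f mm\n",
              paste(grid_shape(x), collapse = "x"), mean(m), max(m)))
  invisible(x)
}

#' Voxel counts of a grid object
#'
#' @param x an \code{image_grid}, \code{dose_grid}, \code{structure_mask} or
#'   \code{displacement_field}.
#' @return integer length-3 vector of voxel counts along (x, y, z).
#' @export
grid_shape <- function(x) {
  if (!is.null(x$values)) return(dim(x$values))
  if (!is.null(x$inside)) return(dim(x$inside))
  dim(x$vectors)[1:3]
}

#' World coordinates of voxel centres along each axis
#'
#' @param x a grid object.
#' @return list of three numeric vectors (mm) for the x, y, z axes.
#' @export
grid_axes <- function(x) {
  n <- grid_shape(x)
  lapply(1:3, function(i) x$origin[i] + (seq_len(n[i]) - 1) * x$spacing[i])
}

# TRUE when two grid objects share shape, spacing and origin (tolerance in mm).
#' @rdname grid_shape
#' @param y a second grid object.
#' @param tol geometric tolerance in mm.
#' @export
same_grid <- function(x, y, tol = 1e-6) {
  identical(as.integer(grid_shape(x)), as.integer(grid_shape(y))) &&
    all(abs(x$spacing - y$spacing) < tol) &&
    all(abs(x$origin - y$origin) < tol)
}

# Trilinear sampling of a 3D array at continuous voxel indices (1-based).
# Out-of-grid queries clamp to the nearest edge value. ix/iy/iz are equal
# length vectors; returns a vector of samples.
trilinear_sample_index <- function(values, ix, iy, iz) {
  n <- dim(values)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  ix <- clamp(ix, 1, n[1]); iy <- clamp(iy, 1, n[2]); iz <- clamp(iz, 1, n[3])
  x0 <- clamp(floor(ix), 1, n[1] - 1L); fx <- ix - x0
  y0 <- clamp(floor(iy), 1, n[2] - 1L); fy <- iy - y0
  z0 <- clamp(floor(iz), 1, n[3] - 1L); fz <- iz - z0
  if (n[1] == 1L) { x0 <- rep(1, length(ix)); fx <- 0 }
  if (n[2] == 1L) { y0 <- rep(1, length(iy)); fy <- 0 }
  if (n[3] == 1L) { z0 <- rep(1, length(iz)); fz <- 0 }
  idx <- function(i, j, k) ((k - 1) * n[2] + (j - 1)) * n[1] + i
  v <- as.vector(values)
  x1 <- pmin(x0 + 1L, n[1]); y1 <- pmin(y0 + 1L, n[2]); z1 <- pmin(z0 + 1L, n[3])
  v000 <- v[idx(x0, y0, z0)]; v100 <- v[idx(x1, y0, z0)]
  v010 <- v[idx(x0, y1, z0)]; v110 <- v[idx(x1, y1, z0)]
  v001 <- v[idx(x0, y0, z1)]; v101 <- v[idx(x1, y0, z1)]
  v011 <- v[idx(x0, y1, z1)]; v111 <- v[idx(x1, y1, z1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Sample a grid at world-space points (n x 3 matrix, mm).
trilinear_sample_world <- function(grid, pts) {
  ix <- (pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1
  iy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1
  iz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1
  trilinear_sample_index(grid$values, ix, iy, iz)
}

# World coordinate arrays (each a 3D array matching the grid shape).
world_coordinate_arrays <- function(x) {
  n <- grid_shape(x)
  ax <- grid_axes(x)
  list(x = array(rep(ax[[1]], times = n[2] * n[3]), n),
       y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), n),
       z = array(rep(ax[[3]], each = n[1] * n[2]), n))
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
# Edge handling: replicate padding. sigma of 0 along an axis skips it.
gaussian_smooth3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    a <- convolve_axis(a, k, axis)
  }
  a
}

# 1D convolution of a 3D array along one axis with replicate padding.
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(k) - 1L) %/% 2L
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + dp[1] - 1L), , drop = FALSE]
  res <- array(out, dp)
  aperm(res, order(perm))
}
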