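#' Cumulative dose-volume histogram of a structure
#'
#' Voxel-counting DVH with uniform voxel volume: at each dose edge \eqn{d},
#' the curve holds \eqn{100 \cdot |\{v \in mask : D(v) \ge d\}| / |mask|}.
#' The curve starts at 100\% at 0 Gy and is non-increasing; the last edge
#' exceeds the maximum dose so the curve ends at 0\%. If the dose grid does
#' not share the mask's grid it is resampled to it with trilinear
#' interpolation (the mask's topology is never resampled).
#'
#' @param dose a \code{dose_grid}.
#' @param mask a nonempty \code{structure_mask}.
#' @param bin_width histogram resolution in Gy.
#' @return a \code{dvh_curve}: list with \code{bin_edges} (Gy) and
#'   \code{cumulative_percent}.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.1) {
  d <- structure_dose_values(dose, mask)
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  cp <- 100 * vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(bin_edges = edges, cumulative_percent = cp,
                 structure = mask$name, bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve '%s'> %d bins of %.3g Gy, max dose < %.3g Gy\n",
              x$structure, length(x$bin_edges), x$bin_width,
              max(x$bin_edges)))
  invisible(x)
}

#' Volume receiving at least a dose level (Vx)
#'
#' \eqn{V_x} is the percent of the structure's voxels with dose >= x Gy
#' (inclusive).
#'
#' @inheritParams cumulative_dvh
#' @param level dose level x, Gy.
#' @return percent of structure volume, in [0, 100].
#' @export
volume_at_dose <- function(dose, mask, level) {
  d <- structure_dose_values(dose, mask)
  100 * mean(d >= level)
}

#' Functional dose-volume vector V5...V60 for fLung
#'
#' Applies \code{\link{volume_at_dose}} at 5-Gy steps from 5 to 60 Gy to
#' the high-function lung mask, producing the 12 covariates of the risk
#' models. By clinical convention the values are percent of the structure's
#' own volume; absolute volumes in cc are available via
#' \code{absolute = TRUE}.
#'
#' @param dose a \code{dose_grid}.
#' @param flung the fLung \code{structure_mask}.
#' @param levels dose levels in Gy, default \code{seq(5, 60, by = 5)}.
#' @param absolute if TRUE, return absolute volumes in cc instead of
#'   percent.
#' @return named numeric vector of class \code{fv_vector}
#'   (\code{V5}...\code{V60}), non-increasing in dose level.
#' @export
extract_fv_vector <- function(dose, flung, levels = seq(5, 60, by = 5),
                              absolute = FALSE) {
  d <- structure_dose_values(dose, flung)
  frac <- vapply(levels, function(x) mean(d >= x), numeric(1))
  out <- if (absolute) {
    voxel_cc <- prod(flung$spacing) / 1000
    frac * length(d) * voxel_cc
  } else 100 * frac
  names(out) <- paste0("V", levels)
  class(out) <- "fv_vector"
  out
}

#' @export
print.fv_vector <- function(x, ...) {
  print(round(unclass(x), 2))
  invisible(x)
}

# Dose values over the mask voxels, resampling the dose to the mask grid
# if their geometries differ.
structure_dose_values <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (sum(mask$inside) == 0L) stop("empty structure mask")
  if (same_grid(dose, mask)) {
    dose$values[mask$inside]
  } else {
    w <- world_coordinate_arrays(mask)
    pts <- cbind(as.vector(w$x)[as.vector(mask$inside)],
                 as.vector(w$y)[as.vector(mask$inside)],
                 as.vector(w$z)[as.vector(mask$inside)])
    trilinear_sample_world(dose, pts)
  }
}
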