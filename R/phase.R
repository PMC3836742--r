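#' Field map container
#'
#' A 3D volume of magnetic field perturbation expressed in ppm of B0,
#' tagged with its provenance in the decomposition
#' total field = background field + local (tissue) field.
#'
#' @param values real 3D array (ppm), finite.
#' @param grid a [grid_geometry()].
#' @param provenance one of "total", "background", "local".
#' @export
field_map <- function(values, grid, provenance = c("total", "background",
                                                   "local")) {
  provenance <- match.arg(provenance)
  check_dims(values, grid)
  if (any(!is.finite(values))) stop("field map values must be finite")
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "qsm_field_map")
}

#' @export
print.qsm_field_map <- function(x, ...) {
  cat(sprintf("QSM field map (%s): %d x %d x %d, range [%.4g, %.4g] ppm\n",
              x$provenance, dim(x$values)[1], dim(x$values)[2],
              dim(x$values)[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Wrapped GRE phase volume
#'
#' @param values phase in radians, all within (-pi, pi].
#' @param acq [acquisition_params()].
#' @param grid [grid_geometry()].
#' @export
wrapped_phase_volume <- function(values, acq, grid) {
  check_dims(values, grid)
  stopifnot(inherits(acq, "qsm_acq"))
  if (any(values <= -pi - 1e-12) || any(values > pi + 1e-12))
    stop("wrapped phase must lie in (-pi, pi]")
  structure(list(values = values, acq = acq, grid = grid),
            class = "qsm_wrapped_phase")
}

#' Wrap phase into (-pi, pi]
#'
#' @param phase numeric array or vector of phase values in radians.
#' @return values congruent to the input modulo 2*pi, in (-pi, pi].
#' @examples
#' wrap_phase(3 * pi / 2)  # -pi/2
#' @export
wrap_phase <- function(phase) {
  if (any(!is.finite(phase))) stop("phase must be finite")
  phase - 2 * pi * ceiling((phase - pi) / (2 * pi))
}

#' Laplacian-based phase unwrapping
#'
#' Exploits the trigonometric identity
#' `lap(phi) = cos(phi) * lap(sin(phi)) - sin(phi) * lap(cos(phi))`,
#' which is invariant under 2*pi wraps: the right-hand side computed from
#' wrapped phase equals the Laplacian of the true phase. Applying the
#' inverse Laplacian yields an unwrapped estimate directly. Because the
#' inverse annihilates harmonic components, this step also removes part of
#' the slowly varying background phase along with the global offset (the
#' output is zero-mean).
#'
#' @param wp a [wrapped_phase_volume()] (or plain array with `grid`).
#' @param grid required when `wp` is a plain array.
#' @return unwrapped phase volume (radians, zero mean), plain array.
#' @export
unwrap_laplacian <- function(wp, grid = NULL) {
  if (inherits(wp, "qsm_wrapped_phase")) {
    grid <- wp$grid
    phi <- wp$values
  } else {
    if (is.null(grid)) stop("'grid' is required for a plain phase array")
    phi <- wp
  }
  check_dims(phi, grid)
  s <- sin(phi); cphi <- cos(phi)
  rhs <- cphi * fourier_laplacian(s, grid) - s * fourier_laplacian(cphi, grid)
  inverse_laplacian(rhs, grid)
}

#' Convert phase to field shift in ppm of B0
#'
#' The GRE phase accrued at echo time te in a field offset dB is
#' `phi = phase_sign * gamma * B0 * dB * te` (dB in absolute units);
#' inverting and scaling gives ppm.
#'
#' @param phase phase volume in radians (unwrapped).
#' @param acq [acquisition_params()].
#' @param grid [grid_geometry()].
#' @param provenance provenance tag of the resulting field map.
#' @return a [field_map()] in ppm of B0.
#' @export
phase_to_field <- function(phase, acq, grid, provenance = "total") {
  stopifnot(inherits(acq, "qsm_acq"))
  ppm <- acq$phase_sign * phase /
    (acq$gamma_rad_per_t_s * acq$b0_tesla * acq$te_s) * 1e6
  field_map(ppm, grid, provenance)
}
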