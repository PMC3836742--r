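#' Grid geometry for a 3D acquisition volume
#'
#' Bundles the array dimensions, voxel size and main-field (B0) direction
#' that every Fourier-domain operator in the package needs. Slices are
#' assumed perpendicular to the main field by default, so `b0_dir` defaults
#' to the +z axis.
#'
#' @param dims integer vector of length 3; voxels per axis. Each dimension
#'   must be even and at least 8 (spectral operators assume an even grid).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param b0_dir numeric vector of length 3, direction of the static field
#'   in world axes; normalised internally and must have non-zero length.
#' @return an object of class `qsm_grid` with elements `dims`, `voxel_size`
#'   and `b0_dir` (unit norm).
#' @examples
#' g <- grid_geometry(c(16, 16, 16), c(1, 1, 1))
#' g$b0_dir
#' @export
grid_geometry <- function(dims, voxel_size = c(1, 1, 1), b0_dir = c(0, 0, 1)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)))
    stop("'dims' must be three integers")
  if (any(dims < 8L) || any(dims %% 2L != 0L))
    stop("all grid dimensions must be even and >= 8")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("invalid geometry: voxel sizes must be positive and finite")
  b0_dir <- as.numeric(b0_dir)
  nb <- sqrt(sum(b0_dir^2))
  if (length(b0_dir) != 3L || !is.finite(nb) || nb < 1e-12)
    stop("'b0_dir' must be a non-zero 3-vector")
  structure(list(dims = dims, voxel_size = voxel_size, b0_dir = b0_dir / nb),
            class = "qsm_grid")
}

#' @export
print.qsm_grid <- function(x, ...) {
  cat(sprintf("QSM grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, B0 = (%.3g, %.3g, %.3g)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$b0_dir[1], x$b0_dir[2], x$b0_dir[3]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_dims <- function(volume, grid) {
  if (!identical(dim(volume), as.integer(grid$dims)))
    stop("volume dimensions do not match the grid")
  invisible(TRUE)
}

# DFT sample frequencies in cycles/mm, numpy-fftfreq ordering.
fft_freqs <- function(n, d) {
  m <- c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  m / (n * d)
}

# Expand per-axis vectors fx, fy, fz to full 3D arrays on `dims`.
axis_array <- function(v, dims, axis) {
  if (axis == 1L) array(v, dims)
  else if (axis == 2L) array(rep(v, each = dims[1]), dims)
  else array(rep(v, each = dims[1] * dims[2]), dims)
}

ifft_real <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

#' Fourier-domain unit dipole kernel
#'
#' Builds the k-space kernel D(k) = 1/3 - (k.b0)^2 / |k|^2 that maps a
#' susceptibility distribution (ppm) to the field perturbation it induces
#' (ppm of B0), under the Lorentz-sphere convention. The kernel is singular
#' at the origin of k-space, which makes the induced-field offset -- and
#' hence absolute susceptibility -- undetermined; the DC bin is therefore
#' imposed (`dc_value`, default 0), making all derived maps relative to a
#' reference.
#'
#' @param grid a [grid_geometry()] object.
#' @param dc_value value assigned to the k = 0 bin (default 0).
#' @return an object of class `qsm_dipole_kernel` with elements `grid`,
#'   `values` (real 3D array over DFT frequencies) and `dc_value`.
#' @seealso [apply_dipole()]
#' @export
build_dipole_kernel <- function(grid, dc_value = 0) {
  stopifnot(inherits(grid, "qsm_grid"))
  d <- grid$dims
  kx <- axis_array(fft_freqs(d[1], grid$voxel_size[1]), d, 1L)
  ky <- axis_array(fft_freqs(d[2], grid$voxel_size[2]), d, 2L)
  kz <- axis_array(fft_freqs(d[3], grid$voxel_size[3]), d, 3L)
  b <- grid$b0_dir
  k2 <- kx^2 + ky^2 + kz^2
  kb <- kx * b[1] + ky * b[2] + kz * b[3]
  k2[1, 1, 1] <- 1  # avoid 0/0 at DC; overwritten below
  values <- 1 / 3 - kb^2 / k2
  values[1, 1, 1] <- dc_value
  structure(list(grid = grid, values = values, dc_value = dc_value),
            class = "qsm_dipole_kernel")
}

#' Apply the dipole operator to a volume
#'
#' Computes the field perturbation induced by a susceptibility volume as a
#' circular convolution: inverse-FFT of the dipole kernel times the FFT of
#' the volume. The operator is linear and self-adjoint (the kernel is real
#' and even under k -> -k).
#'
#' @param kernel a [build_dipole_kernel()] result.
#' @param volume real 3D array with the kernel grid's dimensions.
#' @return real 3D array, same dimensions.
#' @export
apply_dipole <- function(kernel, volume) {
  stopifnot(inherits(kernel, "qsm_dipole_kernel"))
  check_dims(volume, kernel$grid)
  ifft_real(kernel$values * stats::fft(volume))
}

# Spectrum of the 7-point finite-difference Laplacian (periodic boundary).
laplacian_spectrum <- function(grid) {
  d <- grid$dims
  h <- grid$voxel_size
  sx <- (2 * cos(2 * pi * (0:(d[1] - 1)) / d[1]) - 2) / h[1]^2
  sy <- (2 * cos(2 * pi * (0:(d[2] - 1)) / d[2]) - 2) / h[2]^2
  sz <- (2 * cos(2 * pi * (0:(d[3] - 1)) / d[3]) - 2) / h[3]^2
  axis_array(sx, d, 1L) + axis_array(sy, d, 2L) + axis_array(sz, d, 3L)
}

#' Discrete Laplacian and its inverse via the FFT
#'
#' `fourier_laplacian()` applies the 7-point finite-difference Laplacian as
#' a spectral multiplication (periodic boundary); `inverse_laplacian()`
#' divides by the same spectrum with the DC bin zeroed, so its output has
#' exactly zero mean and `inverse_laplacian(fourier_laplacian(v))`
#' reproduces `v - mean(v)`.
#'
#' @param volume real 3D array.
#' @param grid a [grid_geometry()] object matching `volume`.
#' @return real 3D array of the same dimensions.
#' @export
fourier_laplacian <- function(volume, grid) {
  check_dims(volume, grid)
  ifft_real(laplacian_spectrum(grid) * stats::fft(volume))
}

#' @rdname fourier_laplacian
#' @export
inverse_laplacian <- function(volume, grid) {
  check_dims(volume, grid)
  spec <- laplacian_spectrum(grid)
  X <- stats::fft(volume)
  spec[1, 1, 1] <- Inf  # zero the DC mode: output is mean-free
  ifft_real(X / spec)
}

# Shift an array by one voxel along `axis`; `forward` pulls the next voxel
# with replicate (Neumann) boundary at the far face.
shift_replicate <- function(x, axis, forward = TRUE) {
  d <- dim(x)
  idx <- if (forward) c(2:d[axis], d[axis]) else c(1, 1:(d[axis] - 1))
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Forward-difference gradient and its negative adjoint
#'
#' `gradient_field()` returns forward differences along x, y and z with a
#' replicate (Neumann) boundary, as a list of three co-registered volumes.
#' `divergence()` is defined as the negative adjoint of the gradient, so
#' that `sum(gradient_field(u)$x * g$x + ...) == -sum(u * divergence(g))`
#' holds exactly; this is the discrete integration-by-parts identity the
#' regularised solvers rely on.
#'
#' @param volume real 3D array.
#' @param gf a gradient field as returned by `gradient_field()`.
#' @return `gradient_field()`: list with components `x`, `y`, `z` (class
#'   `qsm_gradient_field`); `divergence()`: a real 3D array.
#' @export
gradient_field <- function(volume) {
  stopifnot(length(dim(volume)) == 3L)
  structure(list(
    x = shift_replicate(volume, 1L) - volume,
    y = shift_replicate(volume, 2L) - volume,
    z = shift_replicate(volume, 3L) - volume
  ), class = "qsm_gradient_field")
}

# negative adjoint of one forward-difference axis
div_axis <- function(g, axis) {
  d <- dim(g)
  n <- d[axis]
  prev <- shift_replicate(g, axis, forward = FALSE)
  out <- g - prev
  # boundary rows of the adjoint: first voxel has no predecessor, last
  # voxel's own difference never contributed
  switch(axis,
         { out[1, , ] <- g[1, , ]; out[n, , ] <- -prev[n, , ] },
         { out[, 1, ] <- g[, 1, ]; out[, n, ] <- -prev[, n, ] },
         { out[, , 1] <- g[, , 1]; out[, , n] <- -prev[, , n] })
  out
}

#' @rdname gradient_field
#' @export
divergence <- function(gf) {
  stopifnot(inherits(gf, "qsm_gradient_field"))
  div_axis(gf$x, 1L) + div_axis(gf$y, 2L) + div_axis(gf$z, 3L)
}
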