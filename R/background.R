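#' PDF solver configuration
#'
#' @param rel_tol relative residual tolerance for the conjugate-gradient
#'   stopping rule: iterate until the CG (normal-equation) residual norm
#'   falls below `rel_tol` times its starting value, i.e. a thousandth by
#'   default.
#' @param max_iter iteration cap; hitting it flags the fit as
#'   non-converged rather than failing silently.
#' @export
pdf_config <- function(rel_tol = 1e-3, max_iter = 500L) {
  if (rel_tol <= 0 || rel_tol >= 1) stop("'rel_tol' must be in (0, 1)")
  structure(list(rel_tol = rel_tol, max_iter = as.integer(max_iter)),
            class = "qsm_pdf_config")
}

#' Background-field removal by projection onto dipole fields (PDF)
#'
#' Fits a magnetic dipole distribution supported in the extra-cerebral
#' space whose induced field matches the measured field inside the brain:
#' minimises `|| W o (b_meas - D(Mc o chi_ext)) ||_2` over `chi_ext`, where
#' `Mc` is the brain-mask complement and W the magnitude-derived noise
#' weighting (zero outside the brain). Solved by conjugate gradient on the
#' normal equations (CGLS, with the adjoint operator applied explicitly);
#' the least-squares residual history it produces is monotone
#' non-increasing.
#'
#' @param b_meas measured total field, a [field_map()].
#' @param brain_mask 0/1 array delimiting the dipole-free region: exobrain
#'   sources are allowed only in its complement, so pass the full
#'   anatomical brain mask here (sources must not hug the tissue whose
#'   field is being fitted).
#' @param w weighting volume carrying the brain-only data term, zero
#'   outside the (typically eroded, see [erode_mask()]) brain mask.
#' @param kernel dipole kernel on the acquisition grid.
#' @param cfg a [pdf_config()].
#' @return list of class `qsm_pdf_fit`: `chi_ext` (exobrain dipole
#'   distribution, zero inside the brain), `b_bg` (background
#'   [field_map()]), `iterations`, `residual_history` (weighted
#'   least-squares residual norms), `cg_relative_residual` (final
#'   normal-equation residual over its starting value), `converged`.
#' @export
pdf_fit <- function(b_meas, brain_mask, w, kernel, cfg = pdf_config()) {
  stopifnot(inherits(b_meas, "qsm_field_map"),
            inherits(kernel, "qsm_dipole_kernel"),
            inherits(cfg, "qsm_pdf_config"))
  grid <- kernel$grid
  check_dims(b_meas$values, grid)
  check_dims(brain_mask, grid)
  check_dims(w, grid)
  mc <- 1 - (brain_mask > 0)
  if (!any(mc > 0)) stop("empty exobrain region: brain mask covers the grid")
  w <- w * (brain_mask > 0)  # W carries brain-only information

  A  <- function(x) w * apply_dipole(kernel, mc * x)
  At <- function(y) mc * apply_dipole(kernel, w * y)

  b <- w * b_meas$values
  x <- array(0, grid$dims)
  r <- b                      # least-squares residual W(b - D Mc x)
  s <- At(r)                  # normal-equation (CG) residual
  gam <- sum(s^2)
  s0 <- sqrt(gam)
  hist <- sqrt(sum(r^2))
  iter <- 0L
  converged <- TRUE
  if (s0 > 0) {
    p <- s
    converged <- FALSE
    while (iter < cfg$max_iter) {
      q <- A(p)
      qq <- sum(q^2)
      if (qq == 0) { converged <- TRUE; break }
      alpha <- gam / qq
      x <- x + alpha * p
      r <- r - alpha * q
      iter <- iter + 1L
      hist <- c(hist, sqrt(sum(r^2)))
      s <- At(r)
      gam_new <- sum(s^2)
      if (sqrt(gam_new) <= cfg$rel_tol * s0) { converged <- TRUE; break }
      p <- s + (gam_new / gam) * p
      gam <- gam_new
    }
    if (!converged)
      warning("PDF did not reach the residual tolerance within ",
              cfg$max_iter, " iterations")
  }
  chi_ext <- mc * x
  b_bg <- field_map(apply_dipole(kernel, chi_ext), grid, "background")
  structure(list(chi_ext = chi_ext, b_bg = b_bg, iterations = iter,
                 residual_history = hist,
                 cg_relative_residual = if (s0 > 0) sqrt(sum(At(r)^2)) / s0 else 0,
                 converged = converged),
            class = "qsm_pdf_fit")
}

#' @export
print.qsm_pdf_fit <- function(x, ...) {
  cat(sprintf("PDF background fit: %d CG iterations, final relative CG residual %.3g (%s)\n",
              x$iterations, x$cg_relative_residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Subtract the background field inside the brain
#'
#' @param b_meas,b_bg total and background [field_map()]s on one grid.
#' @param brain_mask 0/1 array.
#' @return local-field [field_map()] (zero outside the mask).
#' @export
subtract_background <- function(b_meas, b_bg, brain_mask) {
  stopifnot(inherits(b_meas, "qsm_field_map"), inherits(b_bg, "qsm_field_map"))
  check_dims(b_bg$values, b_meas$grid)
  check_dims(brain_mask, b_meas$grid)
  field_map((b_meas$values - b_bg$values) * (brain_mask > 0),
            b_meas$grid, "local")
}

hann_window_1d <- function(width) {
  n <- 0:(width - 1)
  0.5 * (1 - cos(2 * pi * n / (width - 1)))
}

# centered k-space low-pass window of `width` voxels on an axis of size n,
# returned in DFT (wrap-around) order
hann_axis <- function(n, width) {
  if (width > n) stop("Hanning window wider than the grid")
  w <- numeric(n)
  centre <- n %/% 2 + 1
  idx <- centre - width %/% 2 + 0:(width - 1)
  w[idx] <- hann_window_1d(width)
  # shift so the window centre sits on the DC bin
  c(w[centre:n], w[1:(centre - 1)])
}

#' SWI-style homodyne high-pass phase filtering
#'
#' The comparison arm to PDF background removal: the complex image is
#' divided by its Hanning-windowed low-pass version and the residual phase
#' returned. Supports 2D (slicewise, the scanner-console convention) and
#' 3D isotropic windows; typical widths are 32, 64 and 128 voxels in 2D
#' and 3D, and the 100-voxel 2D window used on the console.
#'
#' @param magnitude,phase magnitude and wrapped-phase volumes.
#' @param width Hanning window width in voxels (default 100).
#' @param ndim 2 for slicewise filtering (axial slices, third axis), 3 for
#'   a volumetric window.
#' @return high-pass filtered phase volume in (-pi, pi].
#' @export
hanning_highpass <- function(magnitude, phase, width = 100, ndim = 2) {
  stopifnot(identical(dim(magnitude), dim(phase)))
  if (!ndim %in% c(2, 3)) stop("'ndim' must be 2 or 3")
  d <- dim(magnitude)
  z <- magnitude * exp(1i * phase)
  if (ndim == 2) {
    win <- outer(hann_axis(d[1], width), hann_axis(d[2], width))
    lp <- array(0i, d)
    for (k in seq_len(d[3])) {
      zk <- matrix(z[, , k], d[1], d[2])
      lp[, , k] <- stats::fft(win * stats::fft(zk), inverse = TRUE) /
        (d[1] * d[2])
    }
  } else {
    win <- axis_array(hann_axis(d[1], width), d, 1L) *
      axis_array(hann_axis(d[2], width), d, 2L) *
      axis_array(hann_axis(d[3], width), d, 3L)
    lp <- stats::fft(win * stats::fft(z), inverse = TRUE) / length(z)
  }
  # Arg(z / lp) computed as Arg(z * Conj(lp)) to avoid division blow-ups
  array(Arg(z * Conj(lp)), d)
}
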