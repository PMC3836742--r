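#' Solver configuration for regularised dipole inversion
#'
#' @param norm_p gradient-penalty norm: 2 for the Tikhonov-like squared-l2
#'   penalty, 1 for the MEDI-style l1 penalty (smoothed as
#'   `sqrt(g^2 + l1_epsilon)`).
#' @param lam regularisation parameter lambda > 0. It multiplies the
#'   data-fidelity term, so larger lambda means weaker regularisation:
#'   lambda = 200 gives a heavily attenuated solution, lambda = 1e4
#'   effectively suppresses the regulariser.
#' @param l1_epsilon smoothing constant for the l1 penalty (default 1e-6).
#' @param rel_stop relative stopping tolerance: iterate until the absolute
#'   cost difference between successive iterations falls below `rel_stop`
#'   times the data-fidelity term value after the first iteration.
#' @param max_iter iteration cap (default 100).
#' @param ls_shrink,ls_c1,ls_max backtracking line-search controls:
#'   step-shrink factor, Armijo sufficient-decrease constant, and maximum
#'   number of backtracks.
#' @export
solver_config <- function(norm_p = 2, lam = 1250, l1_epsilon = 1e-6,
                          rel_stop = 1e-4, max_iter = 100L,
                          ls_shrink = 0.5, ls_c1 = 1e-4, ls_max = 20L) {
  if (!norm_p %in% c(1, 2)) stop("'norm_p' must be 1 or 2")
  if (!is.finite(lam) || lam <= 0) stop("'lam' must be positive")
  structure(list(norm_p = norm_p, lam = lam, l1_epsilon = l1_epsilon,
                 rel_stop = rel_stop, max_iter = as.integer(max_iter),
                 ls_shrink = ls_shrink, ls_c1 = ls_c1,
                 ls_max = as.integer(ls_max)),
            class = "qsm_solver_config")
}

# regulariser value, gradient and directional curvature estimate
reg_value <- function(gx, gy, gz, m, p, eps) {
  if (p == 2) sum(m * (gx^2 + gy^2 + gz^2))
  else sum(m * (sqrt(gx^2 + eps) + sqrt(gy^2 + eps) + sqrt(gz^2 + eps)))
}

reg_gradient <- function(chi, m, p, eps) {
  g <- gradient_field(chi)
  if (p == 2) {
    gf <- structure(list(x = m * g$x, y = m * g$y, z = m * g$z),
                    class = "qsm_gradient_field")
    -2 * divergence(gf)
  } else {
    gf <- structure(list(x = m * g$x / sqrt(g$x^2 + eps),
                         y = m * g$y / sqrt(g$y^2 + eps),
                         z = m * g$z / sqrt(g$z^2 + eps)),
                    class = "qsm_gradient_field")
    -divergence(gf)
  }
}

#' Weighted data-fidelity residual
#'
#' The squared weighted misfit `|| W o (D chi - dB) ||_2^2` between the
#' field induced by a susceptibility map and the measured local field; the
#' quantity plotted in lambda-sweep fidelity diagnostics.
#'
#' @param chi susceptibility volume (ppm) or a `qsm_inversion` fit.
#' @param local_field local-field [field_map()].
#' @param w weighting volume.
#' @param kernel dipole kernel.
#' @return scalar residual.
#' @export
fidelity_residual <- function(chi, local_field, w, kernel) {
  if (inherits(chi, "qsm_inversion")) chi <- chi$chi
  stopifnot(inherits(local_field, "qsm_field_map"))
  check_dims(chi, kernel$grid)
  sum((w * (apply_dipole(kernel, chi) - local_field$values))^2)
}

#' Regularised field-to-susceptibility dipole inversion
#'
#' Estimates the susceptibility map chi (ppm) from the local field dB (ppm)
#' by minimising
#' `E(chi) = lambda * || W o (D chi - dB) ||_2^2 + || M_G o grad chi ||_p`
#' with p = 2 (squared; Tikhonov-like conditioning of the gradient) or
#' p = 1 (MEDI-style sparsity of the masked gradient, smoothed by
#' `l1_epsilon`). The minimiser is nonlinear conjugate gradient
#' (Polak-Ribiere, restarted) with a backtracking line search; iterations
#' stop when the cost decrease per iteration falls below `rel_stop` times
#' the data-fidelity term after the first iteration, so under-regularised
#' runs terminate once conjugate-gradient progress stagnates. The solution
#' support is confined to the brain mask; the edge mask confines the
#' regulariser only, never the fidelity term.
#'
#' @param local_field local-field [field_map()] (ppm), zero outside brain.
#' @param w weighting volume from [compute_weight_map()].
#' @param mg edge-exclusion mask from [compute_edge_mask()] (1 = regularise).
#' @param kernel dipole kernel on the acquisition grid.
#' @param cfg a [solver_config()].
#' @param brain_mask solution support; defaults to `w > 0`.
#' @return object of class `qsm_inversion`: `chi` (ppm, zero outside the
#'   brain), `lambda`, `norm_p`, `iterations`, `converged`, `cost_history`
#'   (non-increasing), `fidelity_residual`, plus grid/config/inputs needed
#'   by the methods.
#' @seealso [lambda_sweep()], [fidelity_residual()]
#' @export
dipole_inversion <- function(local_field, w, mg, kernel,
                             cfg = solver_config(),
                             brain_mask = NULL) {
  stopifnot(inherits(local_field, "qsm_field_map"),
            inherits(kernel, "qsm_dipole_kernel"),
            inherits(cfg, "qsm_solver_config"))
  grid <- kernel$grid
  b <- local_field$values
  check_dims(b, grid); check_dims(w, grid); check_dims(mg, grid)
  if (is.null(brain_mask)) brain_mask <- (w > 0) * 1
  check_dims(brain_mask, grid)
  mb <- (brain_mask > 0) * 1
  m <- (mg > 0) * 1
  lam <- cfg$lam; p <- cfg$norm_p; eps <- cfg$l1_epsilon
  w2 <- w^2

  cost <- function(fx, x) {
    g <- gradient_field(x)
    lam * sum(w2 * (fx - b)^2) + reg_value(g$x, g$y, g$z, m, p, eps)
  }

  x <- array(0, grid$dims)
  fx <- array(0, grid$dims)       # D x, cached
  E <- cost(fx, x)
  cost_hist <- E
  fid_after_1 <- NA_real_
  g_prev <- NULL; d <- NULL
  converged <- FALSE
  iterations <- 0L

  for (iter in seq_len(cfg$max_iter)) {
    iterations <- iter
    grad <- mb * (2 * lam * apply_dipole(kernel, w2 * (fx - b)) +
                    reg_gradient(x, m, p, eps))
    gg <- sum(grad^2)
    if (gg < 1e-30) { converged <- TRUE; break }
    if (is.null(d)) {
      d <- -grad
    } else {
      beta <- max(0, sum(grad * (grad - g_prev)) / sum(g_prev^2))
      d <- -grad + beta * d
      if (sum(grad * d) >= 0) d <- -grad  # restart on non-descent
    }
    g_prev <- grad
    gd <- sum(grad * d)

    fd <- apply_dipole(kernel, d)
    gdir <- gradient_field(d)
    curv <- 2 * lam * sum((w * fd)^2) +
      if (p == 2) 2 * reg_value(gdir$x, gdir$y, gdir$z, m, 2, 0)
      else {
        gc <- gradient_field(x)
        sum(m * (gdir$x^2 / sqrt(gc$x^2 + eps) +
                 gdir$y^2 / sqrt(gc$y^2 + eps) +
                 gdir$z^2 / sqrt(gc$z^2 + eps)))
      }
    alpha <- if (curv > 0) -gd / curv else 1
    ok <- FALSE
    for (bt in 0:cfg$ls_max) {
      E_new <- cost(fx + alpha * fd, x + alpha * d)
      if (E_new <= E + cfg$ls_c1 * alpha * gd) { ok <- TRUE; break }
      alpha <- alpha * cfg$ls_shrink
    }
    if (!ok) { converged <- FALSE; break }  # divergent line search
    x <- x + alpha * d
    fx <- fx + alpha * fd
    E_prev <- E
    E <- E_new
    cost_hist <- c(cost_hist, E)
    if (iter == 1L) fid_after_1 <- lam * sum(w2 * (fx - b)^2)
    if (iter > 1L && abs(E_prev - E) <= cfg$rel_stop * fid_after_1) {
      converged <- TRUE
      break
    }
  }

  chi <- mb * x
  structure(list(chi = chi, lambda = lam, norm_p = p,
                 iterations = iterations, converged = converged,
                 cost_history = cost_hist,
                 fidelity_residual = sum(w2 * (fx - b)^2),
                 grid = grid, cfg = cfg, brain_mask = mb,
                 w = w, local_field = b, field_fit = fx,
                 call = match.call()),
            class = "qsm_inversion")
}

#' @export
print.qsm_inversion <- function(x, ...) {
  cat(sprintf("Regularised dipole inversion (L%d, lambda = %g)\n",
              x$norm_p, x$lambda))
  cat(sprintf("  %d iterations (%s), fidelity residual %.4g\n",
              x$iterations,
              if (x$converged) "converged" else "not converged",
              x$fidelity_residual))
  cat(sprintf("  chi range in brain: [%.4g, %.4g] ppm\n",
              min(x$chi[x$brain_mask > 0]), max(x$chi[x$brain_mask > 0])))
  invisible(x)
}

#' @export
summary.qsm_inversion <- function(object, ...) {
  chi_b <- object$chi[object$brain_mask > 0]
  out <- list(lambda = object$lambda, norm_p = object$norm_p,
              iterations = object$iterations, converged = object$converged,
              fidelity_residual = object$fidelity_residual,
              final_cost = utils::tail(object$cost_history, 1),
              chi_quartiles = stats::quantile(chi_b, c(0.25, 0.5, 0.75)),
              n_brain_voxels = length(chi_b))
  class(out) <- "summary.qsm_inversion"
  out
}

#' @export
print.summary.qsm_inversion <- function(x, ...) {
  cat(sprintf("L%d dipole inversion, lambda = %g: %d iterations (%s)\n",
              x$norm_p, x$lambda, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  fidelity residual: %.5g, final cost: %.5g\n",
              x$fidelity_residual, x$final_cost))
  cat(sprintf("  brain chi quartiles (ppm): %.4g / %.4g / %.4g over %d voxels\n",
              x$chi_quartiles[1], x$chi_quartiles[2], x$chi_quartiles[3],
              x$n_brain_voxels))
  invisible(x)
}

#' @export
coef.qsm_inversion <- function(object, ...) object$chi

#' @export
fitted.qsm_inversion <- function(object, ...) {
  field_map(object$field_fit, object$grid, "local")
}

#' @export
residuals.qsm_inversion <- function(object, ...) {
  object$w * (object$field_fit - object$local_field)
}

#' @export
plot.qsm_inversion <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- dim(x$chi)[3] %/% 2
  graphics::image(x$chi[, , slice], asp = 1, useRaster = TRUE,
                  col = grDevices::gray.colors(128),
                  main = sprintf("chi (ppm), L%d lambda = %g, slice %d",
                                 x$norm_p, x$lambda, slice), ...)
  invisible(x)
}

#' The regularisation-parameter grid used throughout
#'
#' @return the ten-value lambda grid 200, 300, 500, 750, 1250, 1750, 2250,
#'   2750, 3250, 1e4.
#' @export
qsm_lambda_grid <- function() {
  c(200, 300, 500, 750, 1250, 1750, 2250, 2750, 3250, 1e4)
}

#' Sweep the regularisation parameter and record fidelity diagnostics
#'
#' Runs one inversion per lambda and tabulates the data-fidelity residual
#' and per-region median susceptibilities, the ingredients of the
#' fidelity-versus-lambda diagnostic (whose concave shape with an interior
#' minimum indicates the optimally constrained reconstruction) and of
#' attenuation curves.
#'
#' @inheritParams dipole_inversion
#' @param lambdas non-empty numeric vector (default [qsm_lambda_grid()]).
#' @param labels optional integer label array with a `region_names`
#'   attribute; when given, per-region medians are added as columns
#'   `median_<name>`.
#' @param reference_mask optional reference region; when given, maps are
#'   reference-normalised before region medians are taken.
#' @param keep_fits keep the full `qsm_inversion` objects (attribute
#'   `fits`); default FALSE.
#' @return data.frame sorted by lambda with columns `lambda`,
#'   `fidelity_residual`, `iterations`, `converged`, and region medians.
#' @export
lambda_sweep <- function(local_field, w, mg, kernel,
                         lambdas = qsm_lambda_grid(),
                         cfg = solver_config(), labels = NULL,
                         reference_mask = NULL, keep_fits = FALSE) {
  if (length(lambdas) < 1L) stop("'lambdas' must be non-empty")
  lambdas <- sort(as.numeric(lambdas))
  rows <- vector("list", length(lambdas))
  fits <- if (keep_fits) vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    cfg_i <- cfg
    cfg_i$lam <- lambdas[i]
    fit <- dipole_inversion(local_field, w, mg, kernel, cfg_i)
    row <- data.frame(lambda = lambdas[i],
                      fidelity_residual = fit$fidelity_residual,
                      iterations = fit$iterations,
                      converged = fit$converged)
    if (!is.null(labels)) {
      chi <- fit$chi
      if (!is.null(reference_mask))
        chi <- reference_normalize(chi, reference_mask)
      st <- extract_region_stats(chi, labels)$stats
      med <- stats::setNames(st$median_ppm, paste0("median_", st$region))
      row <- cbind(row, as.data.frame(as.list(med)))
    }
    rows[[i]] <- row
    if (keep_fits) fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Match an L1 regularisation parameter to an L2 region median
#'
#' Selects from an L1 lambda sweep the parameter whose median
#' susceptibility in a target region is closest to a given value
#' (typically the region median of the optimal L2 reconstruction); ties go
#' to the smaller lambda. Errors rather than extrapolating when the target
#' lies outside the swept range.
#'
#' @param target_region_median target median in ppm.
#' @param sweep_table a [lambda_sweep()] result containing a
#'   `median_<region>` column.
#' @param region region name.
#' @return the matching lambda (scalar).
#' @export
calibrate_matching_lambda <- function(target_region_median, sweep_table,
                                      region) {
  col <- paste0("median_", region)
  if (!col %in% names(sweep_table))
    stop("sweep table has no region medians for '", region, "'")
  med <- sweep_table[[col]]
  if (target_region_median < min(med) || target_region_median > max(med))
    stop("target median ", target_region_median,
         " ppm lies outside the swept range [", min(med), ", ", max(med), "]")
  dif <- abs(med - target_region_median)
  cand <- which(dif == min(dif))
  min(sweep_table$lambda[cand])
}
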