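# shift with zero fill (voxels pulled from beyond the boundary are 0)
shift_zero <- function(x, axis, by) {
  if (by == 0) return(x)
  d <- dim(x)
  n <- d[axis]
  out <- array(0, d)
  src <- seq_len(n) + by
  keep <- src >= 1 & src <= n
  if (!any(keep)) return(out)
  dst <- which(keep)
  src <- src[keep]
  switch(axis,
         out[dst, , ] <- x[src, , ],
         out[, dst, ] <- x[, src, ],
         out[, , dst] <- x[, , src])
  out
}

#' Binary mask erosion with a cubic kernel
#'
#' A voxel is kept only if the full `width`^3 cube around it lies inside
#' the input mask (equivalent to convolving with the cubic kernel and
#' keeping full-support voxels); voxels whose cube extends past the grid
#' boundary are removed. Used to trim the brain mask by 6x6x6 voxels
#' before background fitting so that unreliable edge phase stays out of
#' the weighting.
#'
#' @param mask 0/1 3D array.
#' @param width cube width in voxels (default 6). For even widths the cube
#'   is offset by half a voxel (offsets `-(width/2 - 1) ... width/2`).
#' @return eroded 0/1 array.
#' @export
erode_mask <- function(mask, width = 6L) {
  stopifnot(length(dim(mask)) == 3L)
  if (!all(mask %in% c(0, 1))) stop("'mask' must be binary")
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1")
  offsets <- 0:(width - 1L) - ((width - 1L) %/% 2L)
  out <- mask
  for (axis in 1:3) {
    acc <- NULL
    for (o in offsets) {
      sh <- shift_zero(out, axis, o)
      acc <- if (is.null(acc)) sh else pmin(acc, sh)
    }
    out <- acc
  }
  out
}

#' Magnitude-derived noise weighting matrix W
#'
#' Phase noise standard deviation is inversely proportional to signal
#' magnitude, so the least-squares weighting is the magnitude itself,
#' restricted to the brain and scaled so that its mean over a reference
#' region is exactly 1 (double-precision division).
#'
#' @param magnitude magnitude volume (bias-corrected).
#' @param brain_mask 0/1 array.
#' @param reference_mask 0/1 array, non-empty subset of the brain mask.
#' @return weighting volume, zero outside the brain, unit mean over the
#'   reference region.
#' @export
compute_weight_map <- function(magnitude, brain_mask, reference_mask) {
  stopifnot(identical(dim(magnitude), dim(brain_mask)),
            identical(dim(magnitude), dim(reference_mask)))
  ref <- reference_mask > 0
  if (!any(ref)) stop("empty reference mask")
  if (any(ref & !(brain_mask > 0)))
    stop("reference mask must lie inside the brain mask")
  m <- mean(magnitude[ref])
  if (m <= 0) stop("reference region has non-positive mean magnitude")
  magnitude * (brain_mask > 0) / m
}

#' Edge-exclusion mask M_G from magnitude gradients
#'
#' Scores each voxel by the l1 sum of absolute forward differences of the
#' magnitude image and labels the top `edge_fraction` of brain voxels as
#' edges; the returned mask is 1 where the gradient regulariser applies
#' (brain, non-edge) and 0 at edges and outside the brain. Susceptibility
#' boundaries coincide with magnitude edges, where the dipole-kernel
#' approximation breaks down, so the regulariser must ignore them.
#'
#' @param magnitude magnitude volume.
#' @param brain_mask 0/1 array.
#' @param edge_fraction fraction of brain voxels to label as edge
#'   (default 0.30). Voxels strictly above the (1 - edge_fraction)
#'   within-brain quantile of the score are edges, so a uniform magnitude
#'   yields no edges.
#' @return 0/1 array with attributes `edge_fraction` (requested) and
#'   `achieved_fraction`.
#' @export
compute_edge_mask <- function(magnitude, brain_mask, edge_fraction = 0.30) {
  stopifnot(identical(dim(magnitude), dim(brain_mask)))
  if (edge_fraction <= 0 || edge_fraction >= 1)
    stop("'edge_fraction' must be in (0, 1)")
  g <- gradient_field(magnitude)
  score <- abs(g$x) + abs(g$y) + abs(g$z)
  brain <- brain_mask > 0
  thr <- stats::quantile(score[brain], 1 - edge_fraction, names = FALSE)
  edge <- brain & (score > thr)
  mask <- array(0, dim(magnitude))
  mask[brain & !edge] <- 1
  attr(mask, "edge_fraction") <- edge_fraction
  attr(mask, "achieved_fraction") <- sum(edge) / sum(brain)
  mask
}
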