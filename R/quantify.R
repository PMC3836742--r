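#' Normalise a susceptibility map to a reference region
#'
#' Dipole-kernel inversions leave a global offset undetermined (the k-space
#' kernel is singular at the origin), so maps are reported relative to a
#' homogeneous reference region baselined at 0 ppm. Subtracts the mean
#' (default; the median is available) over the reference mask from the
#' whole map. Idempotent, offset-invariant, and preserves all pairwise
#' voxel differences exactly.
#'
#' @param chi susceptibility volume (ppm) or a `qsm_inversion` fit.
#' @param reference_mask non-empty 0/1 array.
#' @param stat baseline statistic, "mean" (default) or "median".
#' @return normalised susceptibility array (ppm).
#' @export
reference_normalize <- function(chi, reference_mask,
                                stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (inherits(chi, "qsm_inversion")) chi <- chi$chi
  ref <- reference_mask > 0
  if (!identical(dim(chi), dim(reference_mask)))
    stop("reference mask dimensions do not match the map")
  if (!any(ref)) stop("empty reference mask")
  base <- if (stat == "mean") mean(chi[ref]) else stats::median(chi[ref])
  chi - base
}

#' Regional medians and histograms from a susceptibility map
#'
#' Regional distributions can be skewed, so the per-region summary used
#' for group testing is the median. Histograms use fixed bin edges across
#' subjects (default 0.005 ppm bins over [-0.3, 0.3] ppm, values clamped
#' into the end bins) so they remain comparable.
#'
#' @param chi susceptibility array (ppm) or `qsm_inversion` fit.
#' @param labels integer label array with a `region_names` character
#'   attribute (code i -> region_names[i]); 0 = unlabelled.
#' @param subject,group identifiers recorded in the output rows.
#' @param hist_breaks histogram bin edges in ppm.
#' @return list with `stats` (data.frame: subject, group, region,
#'   median_ppm, n_voxels, flagged) and `histograms` (named list of
#'   counts). Empty regions yield a flagged row with NA median, never a
#'   silent zero.
#' @export
extract_region_stats <- function(chi, labels, subject = "s01", group = NA,
                                 hist_breaks = seq(-0.3, 0.3, by = 0.005)) {
  if (inherits(chi, "qsm_inversion")) chi <- chi$chi
  if (!identical(dim(chi), dim(labels)))
    stop("label volume dimensions do not match the map")
  nm <- attr(labels, "region_names")
  if (is.null(nm)) nm <- as.character(sort(unique(labels[labels > 0])))
  rows <- vector("list", length(nm))
  hists <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    v <- chi[labels == i]
    if (length(v) == 0L) {
      rows[[i]] <- data.frame(subject = subject, group = group,
                              region = nm[i], median_ppm = NA_real_,
                              n_voxels = 0L, flagged = TRUE)
      hists[i] <- list(NULL)
    } else {
      rows[[i]] <- data.frame(subject = subject, group = group,
                              region = nm[i],
                              median_ppm = stats::median(v),
                              n_voxels = length(v), flagged = FALSE)
      vc <- pmin(pmax(v, min(hist_breaks)), max(hist_breaks))
      hists[[i]] <- graphics::hist(vc, breaks = hist_breaks,
                                   plot = FALSE)$counts
    }
  }
  names(hists) <- nm
  list(stats = do.call(rbind, rows), histograms = hists)
}

# rank-sum W of group a within the pooled mid-ranks
ranksum_W <- function(ranks, n1) sum(ranks[seq_len(n1)])

#' Exact two-tailed Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Computes the two-tailed P-value by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the pooled mid-ranks when
#' `n1 + n2 <= 20` (for the study's 8-vs-8 design this is the exhaustive
#' 12,870-permutation test); larger samples fall back on the normal
#' approximation with tie and continuity corrections. Ties are handled
#' with mid-ranks in both branches.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return object of class `qsm_ranksum`: `U`, `W` (rank sum of `a`),
#'   `p_value` (two-tailed), `n1`, `n2`, `n_assignments` (exact branch),
#'   `method` ("exact" or "normal-approximation").
#' @export
ranksum_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  ranks <- rank(c(a, b))           # mid-ranks for ties
  W <- sum(ranks[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * (n + 1) / 2
  if (n <= 20L) {
    combs <- utils::combn(n, n1)
    Wperm <- colSums(matrix(ranks[combs], nrow = n1))
    dev <- abs(W - mu)
    p <- mean(abs(Wperm - mu) >= dev - 1e-9)
    method <- "exact"
    nass <- ncol(combs)
  } else {
    ties <- table(ranks)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- max(0, abs(W - mu) - 0.5)  # continuity correction
    p <- min(1, 2 * stats::pnorm(dev / sqrt(sigma2), lower.tail = FALSE))
    method <- "normal-approximation"
    nass <- NA_integer_
  }
  structure(list(U = U, W = W, p_value = p, n1 = n1, n2 = n2,
                 n_assignments = nass, method = method),
            class = "qsm_ranksum")
}

#' @export
print.qsm_ranksum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: U = %g, n = %d vs %d, two-tailed P = %.4g (%s)\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Bonferroni per-test threshold
#'
#' @param family_alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (default 10, the number of regions
#'   tested per reconstruction).
#' @return per-test threshold, e.g. 0.005 for 0.05 over 10 tests.
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, n_tests = 10L) {
  family_alpha / n_tests
}

#' Region-wise two-group comparison with significance tiers
#'
#' Runs the exact rank-sum test per region on per-subject medians and
#' flags each region as not significant, P < 0.05 (lenient) or P < 0.005
#' (stringent; the Bonferroni per-test level for a family alpha of 0.05
#' over 10 regions). Also reports the rank-sum deviation from its null
#' expectation for effect-direction bar plots.
#'
#' @param stats_table data.frame with columns `subject`, `group`, `region`,
#'   `median_ppm` (e.g. row-bound [extract_region_stats()] outputs).
#' @param regions regions to test (default: all in the table).
#' @param thresholds lenient and stringent two-tailed thresholds.
#' @return data.frame: region, n1, n2, U, W, rank_sum_deviation, p_value,
#'   method, tier (factor "NS" / "P<0.05" / "P<0.005").
#' @export
compare_groups <- function(stats_table, regions = NULL,
                           thresholds = c(0.05, 0.005)) {
  need <- c("subject", "group", "region", "median_ppm")
  if (!all(need %in% names(stats_table)))
    stop("stats table must have columns ", paste(need, collapse = ", "))
  thresholds <- sort(as.numeric(thresholds), decreasing = TRUE)
  if (is.null(regions)) regions <- unique(stats_table$region)
  groups <- sort(unique(as.character(stats_table$group)))
  if (length(groups) != 2L) stop("exactly two groups are required")
  rows <- lapply(regions, function(rg) {
    sub <- stats_table[stats_table$region == rg & !is.na(stats_table$median_ppm), ]
    a <- sub$median_ppm[sub$group == groups[1]]
    b <- sub$median_ppm[sub$group == groups[2]]
    if (length(a) < 2L || length(b) < 2L)
      stop("region '", rg, "' lacks data in one of the groups")
    rs <- ranksum_exact(a, b)
    mu <- rs$n1 * (rs$n1 + rs$n2 + 1) / 2
    tier <- if (rs$p_value < thresholds[2]) sprintf("P<%g", thresholds[2])
            else if (rs$p_value < thresholds[1]) sprintf("P<%g", thresholds[1])
            else "NS"
    data.frame(region = rg, n1 = rs$n1, n2 = rs$n2, U = rs$U, W = rs$W,
               rank_sum_deviation = rs$W - mu, p_value = rs$p_value,
               method = rs$method, tier = tier)
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- thresholds
  attr(out, "groups") <- groups
  out
}

#' Attenuation curves: region medians across the lambda grid
#'
#' Long-format table of per-subject region medians as a function of the
#' regularisation parameter, with per-group mean and SD at each lambda --
#' the diagnostic showing susceptibility attenuation under heavy
#' regularisation and group separation across the stable lambda range.
#'
#' @param medians_long data.frame with columns `subject`, `group`,
#'   `lambda`, `region`, `median_ppm` (same subjects at every lambda).
#' @param region region to summarise (default: the single region present).
#' @return list with `table` (input rows for the region, sorted) and
#'   `summary` (per group x lambda: n, mean_ppm, sd_ppm; SD is NA for a
#'   single subject).
#' @export
attenuation_curve <- function(medians_long, region = NULL) {
  need <- c("subject", "group", "lambda", "region", "median_ppm")
  if (!all(need %in% names(medians_long)))
    stop("input must have columns ", paste(need, collapse = ", "))
  if (is.null(region)) {
    region <- unique(medians_long$region)
    if (length(region) != 1L)
      stop("multiple regions present; pick one with 'region ='")
  }
  tab <- medians_long[medians_long$region == region, ]
  per_subj <- table(tab$subject)
  if (length(unique(per_subj)) != 1L)
    stop("all subjects must appear at the same lambdas")
  tab <- tab[order(tab$group, tab$subject, tab$lambda), ]
  agg <- do.call(rbind, lapply(split(tab, list(tab$group, tab$lambda),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1], lambda = d$lambda[1], n = nrow(d),
               mean_ppm = mean(d$median_ppm),
               sd_ppm = if (nrow(d) > 1) stats::sd(d$median_ppm) else NA_real_)
  }))
  agg <- agg[order(agg$group, agg$lambda), ]
  rownames(agg) <- NULL
  rownames(tab) <- NULL
  list(table = tab, summary = agg)
}

#' Truth-level regional statistics for a simulated cohort
#'
#' Generates a cohort without signal simulation and extracts per-subject
#' region medians directly from the susceptibility truths -- the
#' statistics-level view of the two-group design, used for type-I-error
#' and power simulations where thousands of full reconstructions would be
#' pointless.
#'
#' @param cohort a [cohort_spec()].
#' @param base a [phantom_spec()].
#' @return data.frame of per-subject region stats (see
#'   [extract_region_stats()]).
#' @export
cohort_truth_stats <- function(cohort, base) {
  subjects <- make_cohort(cohort, base, signal = FALSE)
  do.call(rbind, lapply(subjects, function(s)
    extract_region_stats(s$chi_truth, s$labels, subject = s$id,
                         group = s$group)$stats))
}
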