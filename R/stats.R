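#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) two-sided t-test with Welch-Satterthwaite
#' degrees of freedom. The sign convention puts the first sample first:
#' positive `t` means `a` has the larger mean. Used with the
#' fixed-color-trained condition as `a`, a positive statistic indicates
#' higher activation intensity in that condition.
#'
#' @param a,b Numeric samples; each needs at least 2 values, and at least
#'   one must have non-zero variance.
#' @return A list with `t`, `df`, `p_uncorrected`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      # identical degenerate samples: no evidence of difference
      return(list(
        t = 0, df = length(a) + length(b) - 2, p_uncorrected = 1,
        mean_a = mean(a), mean_b = mean(b)
      ))
    }
    stop("both samples have zero variance")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_uncorrected = ht$p.value, mean_a = mean(a), mean_b = mean(b)
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a family of p-values; monotone (adjusted values
#' never fall below the raw ones) and permutation-equivariant.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Significance level applied to the adjusted values.
#' @return A list with `p_fdr` (adjusted p-values) and `significant`
#'   (logical flags, `p_fdr < alpha`).
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(p_fdr = adj, significant = adj < alpha)
}

#' Compare activation-intensity distributions between conditions
#'
#' For each layer scope (1, 2, 3, all) the distribution of per-(image,
#' filter) mean activation values of the fixed-color-trained network (FR) is
#' tested against that of the random-color-trained network (RR) with a Welch
#' two-sample t-test, FR first; the four tests are jointly FDR-corrected.
#' Distribution summaries (mean, sd, 1%/99% tail quantiles) are attached so
#' the heavier-tails pattern can be inspected.
#'
#' @param rr_filters,fr_filters Lists of the three per-layer filter-mean
#'   matrices (`n x M`) for each condition, e.g. from
#'   [condition_features()][dimensionality_table] at filter level, computed
#'   on the same test images.
#' @param alpha Significance level for the corrected tests.
#' @param unit Sampling unit: `"image_filter"` (default; one value per test
#'   image and filter) or `"image"` (sensitivity mode: filter means are
#'   averaged within each image first, one value per image).
#' @return An `activation_comparison` data frame: one row per scope with
#'   `t`, `df`, `p_uncorrected`, `p_fdr`, `significant`, per-condition means,
#'   sds and tail quantiles.
#' @export
compare_conditions <- function(rr_filters, fr_filters, alpha = 0.05,
                               unit = c("image_filter", "image")) {
  unit <- match.arg(unit)
  stopifnot(length(rr_filters) == 3L, length(fr_filters) == 3L)
  scopes <- c("1", "2", "3", "all")
  samples <- function(mats, i) {
    m <- if (i <= 3) mats[[i]] else do.call(cbind, mats)
    if (unit == "image") rowMeans(m) else as.numeric(m)
  }
  rows <- lapply(seq_along(scopes), function(i) {
    fr <- samples(fr_filters, i)
    rr <- samples(rr_filters, i)
    tt <- two_sample_t(fr, rr)
    data.frame(
      scope = scopes[i], t = tt$t, df = tt$df,
      p_uncorrected = tt$p_uncorrected,
      mean_fr = mean(fr), mean_rr = mean(rr),
      sd_fr = sd(fr), sd_rr = sd(rr),
      q99_fr = unname(quantile(fr, 0.99)), q99_rr = unname(quantile(rr, 0.99)),
      n_fr = length(fr), n_rr = length(rr)
    )
  })
  out <- do.call(rbind, rows)
  corr <- fdr_correct(out$p_uncorrected, alpha)
  out$p_fdr <- corr$p_fdr
  out$significant <- corr$significant
  class(out) <- c("activation_comparison", "data.frame")
  out
}
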