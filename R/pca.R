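#' PCA configuration for phase-space modelling
#'
#' @param matrix_type `"covariance"` (standard PCA on mean-centered
#'   activations; the default) or `"correlation"` (zero-variance features are
#'   dropped, remaining ones standardised). The eigenvalue-greater-than-one
#'   threshold of [wsd()] is applied on whichever scale is chosen.
#' @param max_components Maximum number of leading components retained for
#'   large feature matrices; explained-variance ratios remain exact because
#'   total variance is taken from the feature-variance sum.
#' @return A `pca_config` object.
#' @export
pca_config <- function(matrix_type = c("covariance", "correlation"),
                       max_components = 600L) {
  matrix_type <- match.arg(matrix_type)
  stopifnot(max_components >= 2L)
  structure(
    list(matrix_type = matrix_type, max_components = as.integer(max_components)),
    class = "pca_config"
  )
}

#' Principal-component spectrum of a feature matrix
#'
#' Mean-centers (and for correlation PCA, standardises) the columns and
#' computes the eigenvalue spectrum of the implied covariance or correlation
#' matrix. For feature counts up to 512 the N x N matrix is eigendecomposed
#' exactly; for wider matrices the spectrum is obtained from the singular
#' values of the centered data (exact for all `min(n-1, N)` non-null
#' components, of which at most `max_components` are kept). Explained
#' variance ratios divide by the total feature variance, so they are exact
#' for every retained component regardless of truncation.
#'
#' @param x Numeric feature matrix, samples in rows.
#' @param config A [pca_config()].
#' @return A `psm_pca` object: list with `eigenvalues` (descending),
#'   `ev_ratio`, `cumulative`, `n_samples`, `n_features`, `total_variance`,
#'   `matrix_type`.
#' @export
run_pca <- function(x, config = pca_config()) {
  stopifnot(is.matrix(x), inherits(config, "pca_config"))
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples")
  storage.mode(x) <- "double"
  cv <- colVars(x)
  keep <- cv > 0
  if (!any(keep)) stop("degenerate input: all features are constant")
  if (config$matrix_type == "correlation") {
    x <- x[, keep, drop = FALSE]
    cv <- cv[keep]
    x <- sweep(x, 2L, sqrt(cv), "/")
    cv <- rep(1, ncol(x))
  }
  total_var <- sum(cv)
  nfeat <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x), "-")
  if (nfeat <= 512L) {
    eig <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eig <- svd(xc, nu = 0L, nv = 0L)$d^2 / (n - 1)
  }
  eig <- pmax(eig, 0)
  eig <- sort(eig, decreasing = TRUE)
  eig <- head(eig, config$max_components)
  ev_ratio <- eig / total_var
  structure(
    list(
      eigenvalues = eig, ev_ratio = ev_ratio, cumulative = cumsum(ev_ratio),
      n_samples = n, n_features = nfeat, total_variance = total_var,
      matrix_type = config$matrix_type
    ),
    class = "psm_pca"
  )
}

colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' @export
print.psm_pca <- function(x, ...) {
  cat(
    "<psm_pca>", x$matrix_type, "spectrum;", length(x$eigenvalues),
    "components over", x$n_features, "features,", x$n_samples, "samples\n"
  )
  invisible(x)
}

#' Weight of primary dimensions
#'
#' Cumulative explained variance of the first two principal components, as a
#' percentage. Operationalises the share of the phase space carried by the
#' two primary dimensions of meaning.
#'
#' @param pca A `psm_pca` object.
#' @return Percentage in `[0, 100]`.
#' @export
wpd <- function(pca) {
  stopifnot(inherits(pca, "psm_pca"))
  if (length(pca$ev_ratio) < 2L) stop("need at least 2 retained components")
  100 * (pca$ev_ratio[1] + pca$ev_ratio[2])
}

#' Weight of secondary dimensions
#'
#' Cumulative explained variance of the components after the first two whose
#' eigenvalue strictly exceeds 1 (a Kaiser-like retention criterion), as a
#' percentage, together with the number of such components. An empty
#' secondary set yields 0% and count 0.
#'
#' @param pca A `psm_pca` object.
#' @return List with `wsd` (percent) and `n_secondary` (count).
#' @export
wsd <- function(pca) {
  stopifnot(inherits(pca, "psm_pca"))
  idx <- which(pca$eigenvalues > 1)
  idx <- idx[idx > 2L]
  list(
    wsd = if (length(idx)) 100 * sum(pca$ev_ratio[idx]) else 0,
    n_secondary = length(idx)
  )
}

#' Components needed to explain 90% of variance
#'
#' The smallest number of leading principal components whose cumulative
#' explained variance reaches 90%.
#'
#' @param pca A `psm_pca` object.
#' @return Integer count.
#' @export
d90 <- function(pca) {
  stopifnot(inherits(pca, "psm_pca"))
  m <- which(pca$cumulative >= 0.90)[1]
  if (is.na(m)) {
    stop(
      "retained components explain only ",
      sprintf("%.1f%%", 100 * max(pca$cumulative)),
      " of variance; raise max_components"
    )
  }
  as.integer(m)
}

#' All dimensionality indices of one spectrum
#'
#' @param pca A `psm_pca` object.
#' @param include_wsd Whether to compute the secondary-dimension index
#'   (omitted at filter level, where at most one secondary component ever
#'   appears).
#' @return One-row data frame with `wpd`, `wsd`, `n_secondary`, `d90`.
#' @export
dimensionality_indices <- function(pca, include_wsd = TRUE) {
  s <- if (include_wsd) wsd(pca) else list(wsd = NA_real_, n_secondary = NA_integer_)
  data.frame(
    wpd = wpd(pca), wsd = s$wsd, n_secondary = s$n_secondary, d90 = d90(pca)
  )
}

#' Dimensionality table comparing two trained networks
#'
#' For each convolutional layer and for all layers together, runs PCA on the
#' activation features of both networks over the same test set and tabulates
#' the dimensionality indices, at either single-pixel or per-filter-mean
#' granularity. The secondary-dimension index is reported only at pixel
#' level.
#'
#' @param rr_network,fr_network `trained_network`s for the two conditions
#'   (random-color-trained and fixed-color-trained).
#' @param test_set The shared `colored_digits` test set.
#' @param level `"pixel"` or `"filter"`.
#' @param config A [pca_config()].
#' @return Data frame with columns `scope`, `condition`, `wpd`, `wsd`,
#'   `n_secondary`, `d90`.
#' @export
dimensionality_table <- function(rr_network, fr_network, test_set,
                                 level = c("pixel", "filter"),
                                 config = pca_config()) {
  level <- match.arg(level)
  feats_rr <- condition_features(rr_network, test_set, level)
  feats_fr <- condition_features(fr_network, test_set, level)
  scope_table(list(RR = feats_rr, FR = feats_fr), level, config)
}

# Feature matrices (scopes 1,2,3,all) for one network at one granularity.
condition_features <- function(network, test_set, level) {
  tensors <- harvest_activations(network, test_set)
  per_layer <- lapply(tensors, if (level == "pixel") flatten_pixels else filter_means)
  c(per_layer, list(concat_scopes(per_layer)))
}

scope_table <- function(features_by_condition, level, config) {
  scopes <- c("1", "2", "3", "all")
  rows <- list()
  for (cond in names(features_by_condition)) {
    feats <- features_by_condition[[cond]]
    for (i in seq_along(scopes)) {
      pca <- run_pca(unclass(feats[[i]]), config)
      idx <- dimensionality_indices(pca, include_wsd = (level == "pixel"))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scope = scopes[i], condition = cond), idx
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}
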