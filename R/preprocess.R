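#' Fit the omics preprocessing pipeline on training data
#'
#' The pipeline, applied in this order:
#' 1. drop features whose missing fraction exceeds `missing_threshold`;
#' 2. impute remaining missing entries with the per-feature median of the
#'    observed values;
#' 3. log-transform as `log2(x + 1)` when the matrix is non-negative
#'    (skipped with a warning when negative values are present, as for
#'    methylation M-values);
#' 4. drop zero-variance features, then keep the `top_k` features with the
#'    largest variance (ties broken by original column order);
#' 5. standardize each kept feature to mean 0, standard deviation 1.
#'
#' Fitting records the selected features, imputation medians, log decision
#' and standardization statistics so the identical transform can be applied
#' to held-out samples with [preprocess_apply()] without touching their data.
#'
#' @param m An [omics_matrix()].
#' @param missing_threshold Maximum tolerated missing fraction per feature.
#' @param top_k Number of top-variance features to keep. If fewer survive
#'   the missing-value filter, all survivors are kept with a warning.
#' @return A `preprocess_fit` object.
#' @export
preprocess_fit <- function(m, missing_threshold = 0.10, top_k) {
  stopifnot(inherits(m, "omics_matrix"), top_k >= 1)
  X <- m$values
  miss_frac <- colMeans(is.na(X))
  keep1 <- which(miss_frac <= missing_threshold)
  if (length(keep1) == 0L)
    stop("no features survive the missing-value filter in '", m$omics_name, "'")
  X <- X[, keep1, drop = FALSE]

  medians <- apply(X, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[j]
  }

  use_log <- min(X) >= 0
  if (!use_log)
    warning("negative values in '", m$omics_name,
            "': skipping the log2(x + 1) step")
  if (use_log) X <- log2(X + 1)

  v <- apply(X, 2L, stats::var)
  pos <- which(v > 0)
  if (length(pos) == 0L)
    stop("all features have zero variance in '", m$omics_name, "'")
  if (length(pos) < top_k)
    warning(sprintf("'%s': only %d features survive filtering (top_k = %d); keeping all",
                    m$omics_name, length(pos), top_k))
  ord <- pos[order(-v[pos], pos)]           # variance-descending, stable
  sel <- sort(ord[seq_len(min(top_k, length(ord)))])  # original column order
  X <- X[, sel, drop = FALSE]

  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  structure(list(omics_name = m$omics_name,
                 features = colnames(X),
                 medians = medians[sel],
                 use_log = use_log,
                 center = mu, scale = sdv,
                 missing_threshold = missing_threshold,
                 top_k = top_k),
            class = "preprocess_fit")
}

#' Apply a fitted preprocessing transform
#'
#' Subsets to the training-selected features, imputes missing entries with
#' the training medians, applies the training log decision, and standardizes
#' with the training means and standard deviations. Sample order is never
#' permuted.
#'
#' @param fit A `preprocess_fit` from [preprocess_fit()].
#' @param m An [omics_matrix()] containing at least the fitted features.
#' @return A preprocessed [omics_matrix()].
#' @export
preprocess_apply <- function(fit, m) {
  stopifnot(inherits(fit, "preprocess_fit"), inherits(m, "omics_matrix"))
  missing_feat <- setdiff(fit$features, colnames(m$values))
  if (length(missing_feat) > 0L)
    stop("omics matrix lacks ", length(missing_feat),
         " features selected at fit time (first: ", missing_feat[1], ")")
  X <- m$values[, fit$features, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- fit$medians[j]
  }
  if (fit$use_log) {
    if (min(X) < 0)
      stop("negative values at apply time but the fit used a log transform")
    X <- log2(X + 1)
  }
  X <- sweep(X, 2L, fit$center, "-")
  X <- sweep(X, 2L, fit$scale, "/")
  omics_matrix(X, m$omics_name)
}

#' Preprocess an omics matrix (fit and apply on the same data)
#'
#' Convenience wrapper equal to `preprocess_apply(preprocess_fit(m, ...), m)`.
#' For held-out evaluation fit on training samples only and apply to test
#' samples separately.
#'
#' @inheritParams preprocess_fit
#' @return A preprocessed [omics_matrix()] with `min(top_k, survivors)`
#'   features, each standardized to mean 0 and standard deviation 1.
#' @export
preprocess_omics <- function(m, missing_threshold = 0.10, top_k) {
  preprocess_apply(preprocess_fit(m, missing_threshold, top_k), m)
}
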