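# End-to-end evaluation harness: leak-free train/test pipeline, repeated
# holdout, neighbourhood-size selection, and hidden-node feature analysis.

# Fit the full pipeline on a training index set and score held-out
# samples. All data-dependent statistics (preprocessing medians, variance
# ranking, standardization, graph kernel parameters) are fitted on the
# training rows only; held-out samples are attached to the training graph
# inductively, and their outcomes are never touched before evaluation.
.fit_split <- function(omics, surv, train_idx, test_idx, variant, cfg,
                       K, mu = NULL, top_k = NULL, epochs = NULL) {
  pp <- lapply(omics, function(m) {
    tk <- top_k %||% ncol(m$values)
    preprocess_fit(omics_matrix(m$values[train_idx, , drop = FALSE],
                                m$omics_name),
                   top_k = tk)
  })
  Xtr <- mapply(function(f, m)
    preprocess_apply(f, omics_matrix(m$values[train_idx, , drop = FALSE],
                                     m$omics_name))$values,
    pp, omics, SIMPLIFY = FALSE)
  surv_tr <- survival_table(surv$sample_id[train_idx], surv$time[train_idx],
                            surv$event[train_idx])

  graph_layers <- if (variant == "sgt") cfg$omics_index else seq_along(Xtr)
  graph <- NULL
  if (.needs_graph(variant))
    graph <- build_fused_graph(Xtr[graph_layers], K = K,
                               mu = if (is.null(mu)) NULL else mu[graph_layers])

  model <- build_model(variant, vapply(Xtr, ncol, integer(1)), cfg)
  model <- fit_model(model, Xtr, surv_tr, graph, epochs = epochs)

  test_scores <- NULL
  if (length(test_idx) > 0) {
    Xte <- mapply(function(f, m)
      preprocess_apply(f, omics_matrix(m$values[test_idx, , drop = FALSE],
                                       m$omics_name))$values,
      pp, omics, SIMPLIFY = FALSE)
    Xall <- mapply(function(a, b) rbind(a, b), Xtr, Xte, SIMPLIFY = FALSE)
    g_all <- NULL
    if (.needs_graph(variant))
      g_all <- extend_graph(graph, Xtr[graph_layers], Xte[graph_layers])
    sc <- predict_risk(model, Xall, g_all)
    test_scores <- sc[length(train_idx) + seq_along(test_idx)]
  }
  list(model = model, preprocess = pp, graph = graph,
       train_scores = predict_risk(model, Xtr, graph),
       test_scores = test_scores)
}

#' Repeated-holdout evaluation
#'
#' Repeatedly splits the cohort into training and test fractions,
#' refits the whole pipeline on the training part only (preprocessing
#' statistics, fused graph, model), attaches the test samples to the
#' training graph inductively, and evaluates the concordance index and
#' time-dependent AUC on the test part. Splits with no test events are
#' redrawn (with a warning, up to a cap).
#'
#' @param omics List of [omics_matrix()] objects, rows aligned with
#'   `surv`.
#' @param surv A [survival_table()].
#' @param variant Architecture tag, see [build_model()].
#' @param cfg A [coformer_config()].
#' @param K Neighbourhood size for the fused graph.
#' @param n_repeats Number of independent random partitions.
#' @param train_frac Fraction of samples assigned to training.
#' @param top_k Features kept per omics by the preprocessing variance
#'   filter (`NULL` keeps all).
#' @param epochs Optional override of `cfg$epochs`.
#' @param seed Master seed; each repeat derives its own split from it.
#' @return A list: `repeats` (data frame with one row per repeat:
#'   `c_index`, `auc`, `n_test`) and `summary` (means and standard
#'   deviations).
#' @export
repeated_holdout <- function(omics, surv, variant = "coformersurv",
                             cfg = coformer_config(), K = 10,
                             n_repeats = 50, train_frac = 0.8,
                             top_k = NULL, epochs = NULL, seed = 1L) {
  n <- length(surv$time)
  res <- data.frame(c_index = numeric(0), auc = numeric(0),
                    n_test = integer(0))
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max, n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(split_seeds[r])
    tries <- 0
    repeat {
      train_idx <- sort(sample.int(n, round(train_frac * n)))
      test_idx <- setdiff(seq_len(n), train_idx)
      ok <- sum(surv$event[train_idx]) >= 1 && sum(surv$event[test_idx]) >= 1
      if (ok) break
      tries <- tries + 1
      if (tries > 25) stop("could not draw a split with events in both parts")
      warning("split without events in both parts; redrawing")
    }
    fit <- .fit_split(omics, surv, train_idx, test_idx, variant, cfg,
                      K = K, top_k = top_k, epochs = epochs)
    surv_te <- survival_table(surv$sample_id[test_idx], surv$time[test_idx],
                              surv$event[test_idx])
    ci <- concordance_index(fit$test_scores, surv_te)$c_index
    auc <- tryCatch(time_dependent_auc(fit$test_scores, surv_te)$auc,
                    error = function(e) NA_real_)
    res <- rbind(res, data.frame(c_index = ci, auc = auc,
                                 n_test = length(test_idx)))
  }
  list(repeats = res,
       summary = c(c_index_mean = mean(res$c_index),
                   c_index_sd = stats::sd(res$c_index),
                   auc_mean = mean(res$auc, na.rm = TRUE),
                   auc_sd = stats::sd(res$auc, na.rm = TRUE)))
}

#' Select the graph neighbourhood size by cross-validation
#'
#' Inner cross-validation on training data only: for each candidate `K`
#' the pipeline is refitted on each fold's training part and scored on the
#' held-out part; the `K` with the highest mean concordance index wins,
#' ties going to the smaller `K`.
#'
#' @inheritParams repeated_holdout
#' @param grid Candidate neighbourhood sizes.
#' @param folds Number of cross-validation folds.
#' @return A list: `best_K` and `cv` (data frame of per-K mean concordance).
#' @export
select_K <- function(omics, surv, grid, variant = "coformersurv",
                     cfg = coformer_config(), folds = 3, top_k = NULL,
                     epochs = NULL, seed = 1L) {
  stopifnot(length(grid) >= 1)
  n <- length(surv$time)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  cv <- data.frame(K = grid, c_index = NA_real_)
  for (gi in seq_along(grid)) {
    cis <- numeric(0)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      if (sum(surv$event[tr]) < 1 || sum(surv$event[te]) < 1) next
      fit <- .fit_split(omics, surv, tr, te, variant, cfg, K = grid[gi],
                        top_k = top_k, epochs = epochs)
      surv_te <- survival_table(surv$sample_id[te], surv$time[te],
                                surv$event[te])
      cis <- c(cis, concordance_index(fit$test_scores, surv_te)$c_index)
    }
    cv$c_index[gi] <- mean(cis)
  }
  best <- cv$K[which.max(cv$c_index)]   # which.max takes the first maximum;
  # grid is scanned in the given order, so pass an ascending grid to make
  # ties resolve to the smaller K
  ord <- order(-cv$c_index, cv$K)
  list(best_K = cv$K[ord[1]], cv = cv)
}

#' Correlate raw features with hidden-node representations
#'
#' For each hidden column of the output-layer embedding `Z^h`, computes
#' the Pearson correlation with every raw feature and reports the top
#' features per node by absolute correlation (signed correlations are
#' returned). Zero-variance hidden columns are skipped with a warning.
#'
#' @param X_raw Raw feature matrix (or [omics_matrix()]), rows aligned
#'   with `Zh`.
#' @param Zh Hidden embedding matrix from
#'   [predict_risk()] with `what = "embedding"`.
#' @param top_m Number of top features to report per hidden node.
#' @return Data frame with columns `node`, `rank`, `feature`, `r`.
#' @export
feature_correlation_analysis <- function(X_raw, Zh, top_m = 10) {
  if (inherits(X_raw, "omics_matrix")) X_raw <- X_raw$values
  X_raw <- as.matrix(X_raw); Zh <- as.matrix(Zh)
  stopifnot(nrow(X_raw) == nrow(Zh))
  feats <- colnames(X_raw) %||% paste0("f", seq_len(ncol(X_raw)))
  out <- NULL
  for (h in seq_len(ncol(Zh))) {
    z <- Zh[, h]
    if (stats::sd(z) == 0) {
      warning("hidden node ", h, " has zero variance; skipped")
      next
    }
    keep <- which(apply(X_raw, 2L, stats::sd) > 0)
    r <- as.numeric(stats::cor(X_raw[, keep, drop = FALSE], z))
    ord <- keep[order(-abs(r))][seq_len(min(top_m, length(keep)))]
    rr <- r[match(ord, keep)]
    out <- rbind(out, data.frame(node = h, rank = seq_along(ord),
                                 feature = feats[ord], r = rr))
  }
  out
}
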