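# Model assembly for the collaborative transformer and its ablation
# variants, with a hand-written reverse-mode pass and full-batch Adam
# training of the Cox partial likelihood.

.variants <- c("coformersurv", "sgt", "mgt", "crosst", "crosst_segcn",
               "crosst_sa")

#' Model configuration
#'
#' Tunable dimensions and training settings shared by [build_model()] and
#' [fit_model()].
#'
#' @param n_heads Number of inter-omics attention heads.
#' @param d_latent Per-omics latent embedding width.
#' @param d_c Inter-omics head projection width.
#' @param d_combined Width of the combined multi-omics representation
#'   `Z^c` (split evenly across heads).
#' @param d_h Inter-sample attention / final embedding width.
#' @param activation Activation used throughout (`"relu"`, `"tanh"`,
#'   `"linear"`).
#' @param attention_scale `"dim"` divides attention scores by the
#'   projection width as in the model definition; `"sqrt_dim"` uses the
#'   conventional square-root scaling.
#' @param lr Adam learning rate.
#' @param epochs Full-batch training epochs.
#' @param risk_set Risk-set convention for the partial likelihood, see
#'   [cox_partial_loss()].
#' @param omics_index Omics layer used by the single-omics `sgt` variant.
#' @param seed Seed for parameter initialization.
#' @return A `coformer_config` list.
#' @export
coformer_config <- function(n_heads = 2, d_latent = 64, d_c = 32,
                            d_combined = 64, d_h = 32,
                            activation = "relu", attention_scale = "dim",
                            lr = 2e-4, epochs = 300,
                            risk_set = "inclusive",
                            omics_index = 1L, seed = 1L) {
  stopifnot(n_heads >= 1, d_combined %% n_heads == 0)
  structure(as.list(environment()), class = "coformer_config")
}

#' Build a model of a given architectural variant
#'
#' Initializes all learnable parameters for one of the six wirings:
#' * `coformersurv` - embed each omics, inter-omics multi-head attention,
#'   head combination, structure-biased inter-sample attention, projection,
#'   Cox head (the full collaborative transformer);
#' * `sgt` - one omics layer with its own graph through the inter-sample
#'   graph transformer (no inter-omics block);
#' * `mgt` - concatenated per-omics embeddings through the inter-sample
#'   graph transformer (no inter-omics block);
#' * `crosst` - combined inter-omics features straight to the Cox head
#'   (no inter-sample block);
#' * `crosst_segcn` - inter-omics features aggregated by the fixed-weight
#'   graph convolution instead of attention;
#' * `crosst_sa` - inter-omics features through plain self-attention with
#'   no graph structure.
#'
#' Weights use scaled uniform fan-in initialization under `cfg$seed`; the
#' Cox coefficients start at zero.
#'
#' @param variant One of the tags above.
#' @param p Integer vector of per-omics feature counts (after
#'   preprocessing).
#' @param cfg A [coformer_config()].
#' @return A `coformer_model` with elements `variant`, `cfg`, `p`, and
#'   `params` (named list of weight matrices / vectors).
#' @export
build_model <- function(variant, p, cfg = coformer_config()) {
  variant <- match.arg(variant, .variants)
  L <- length(p)
  if (L < 2 && !variant %in% c("sgt"))
    stop("variant '", variant, "' requires >= 2 omics layers")
  set.seed(cfg$seed)
  P <- list()
  emb_layers <- if (variant == "sgt") cfg$omics_index else seq_len(L)
  for (l in emb_layers) {
    P[[paste0("emb", l, ".W")]] <- .init_weight(p[l], cfg$d_latent)
    P[[paste0("emb", l, ".b")]] <- numeric(cfg$d_latent)
  }
  uses_cross <- variant %in% c("coformersurv", "crosst", "crosst_segcn", "crosst_sa")
  if (uses_cross) {
    for (h in seq_len(cfg$n_heads)) {
      P[[paste0("head", h, ".Wq")]] <- .init_weight(cfg$d_latent, cfg$d_c)
      P[[paste0("head", h, ".Wv")]] <- .init_weight(cfg$d_latent, cfg$d_c)
    }
    P[["W1c"]] <- .init_weight(L * cfg$d_c, cfg$d_combined / cfg$n_heads)
  }
  d_zc <- switch(variant,
    coformersurv = , crosst = , crosst_segcn = , crosst_sa = cfg$d_combined,
    mgt = L * cfg$d_latent,
    sgt = cfg$d_latent)
  if (variant %in% c("coformersurv", "sgt", "mgt", "crosst_sa")) {
    P[["smp.Wq"]] <- .init_weight(d_zc, cfg$d_h)
    P[["smp.Wv"]] <- .init_weight(d_zc, cfg$d_h)
    P[["W1"]] <- .init_weight(cfg$d_h, cfg$d_h)
    d_out <- cfg$d_h
  } else if (variant == "crosst_segcn") {
    P[["W1"]] <- .init_weight(d_zc, cfg$d_h)
    d_out <- cfg$d_h
  } else {                                    # crosst
    d_out <- d_zc
  }
  P[["beta"]] <- numeric(d_out)
  structure(list(variant = variant, cfg = cfg, p = p, params = P),
            class = "coformer_model")
}

#' @export
print.coformer_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<coformer_model variant='%s', %d omics, %d parameters%s>\n",
              x$variant, length(x$p), np,
              if (isTRUE(x$fitted)) ", fitted" else ""))
  invisible(x)
}

.needs_graph <- function(variant)
  variant %in% c("coformersurv", "sgt", "mgt", "crosst_segcn")

# Full forward pass. X_list: preprocessed per-omics matrices (aligned
# rows); graph: fused_graph over the same rows (NULL for the graph-free
# variants). Returns scores, Zh, Zc and a cache for the backward pass.
.forward <- function(model, X_list, graph = NULL, want_cache = FALSE) {
  v <- model$variant; cfg <- model$cfg; P <- model$params
  act <- .activation(cfg$activation)
  X_list <- lapply(X_list, function(m)
    if (inherits(m, "omics_matrix")) m$values else as.matrix(m))
  if (.needs_graph(v)) {
    if (is.null(graph)) stop("variant '", v, "' requires a fused graph")
    gp <- .graph_parts(graph)
    if (nrow(gp$conv) != nrow(X_list[[1]]))
      stop("graph size does not match sample count")
  }
  cache <- list(X = X_list)

  emb_layers <- if (v == "sgt") model$cfg$omics_index else seq_along(X_list)
  Zl <- list(); pre <- list()
  for (l in emb_layers) {
    pre[[l]] <- sweep(X_list[[l]] %*% P[[paste0("emb", l, ".W")]], 2L,
                      P[[paste0("emb", l, ".b")]], "+")
    Zl[[l]] <- act$f(pre[[l]])
  }
  cache$pre <- pre; cache$Zl <- Zl

  if (v == "sgt") {
    Zc <- Zl[[cfg$omics_index]]
  } else if (v == "mgt") {
    Zc <- do.call(cbind, Zl)
  } else {
    if (length(X_list) < 2L)
      stop("cross-omics attention requires >= 2 layers")
    heads <- list()
    for (h in seq_len(cfg$n_heads))
      heads[[h]] <- .head_forward(Zl, P[[paste0("head", h, ".Wq")]],
                                  P[[paste0("head", h, ".Wv")]],
                                  cfg$attention_scale)
    cache$heads <- heads
    cache$head_pre <- lapply(heads, function(hc) hc$H %*% P[["W1c"]])
    Zc <- do.call(cbind, lapply(cache$head_pre, act$f))
  }
  cache$Zc <- Zc

  if (v %in% c("coformersurv", "sgt", "mgt", "crosst_sa")) {
    if (v == "crosst_sa") {
      n <- nrow(Zc)
      conv <- matrix(1, n, n); support <- matrix(TRUE, n, n)
    } else {
      conv <- gp$conv; support <- gp$support
    }
    sba <- .sba_forward(Zc, P[["smp.Wq"]], P[["smp.Wv"]], conv, support,
                        cfg$attention_scale)
    cache$sba <- sba
    proj <- .proj_forward(sba$Z, P[["W1"]], act)
    cache$proj <- proj
    Zh <- proj$Zh
  } else if (v == "crosst_segcn") {
    cache$conv <- gp$conv
    cache$AZ <- gp$conv %*% Zc
    cache$gcn_pre <- cache$AZ %*% P[["W1"]]
    Zh <- act$f(cache$gcn_pre)
  } else {                                    # crosst
    Zh <- Zc
  }
  cache$Zh <- Zh
  scores <- as.numeric(Zh %*% P[["beta"]])
  if (want_cache) list(scores = scores, Zh = Zh, Zc = Zc, cache = cache)
  else list(scores = scores, Zh = Zh, Zc = Zc)
}

# Reverse-mode pass: gradient of the loss wrt every parameter given the
# gradient wrt the risk scores. Mirrors .forward exactly.
.backward <- function(model, cache, dscores) {
  v <- model$variant; cfg <- model$cfg; P <- model$params
  act <- .activation(cfg$activation)
  G <- lapply(P, function(w) if (is.matrix(w)) w * 0 else w * 0)
  Zh <- cache$Zh
  G[["beta"]] <- as.numeric(crossprod(Zh, dscores))
  dZh <- tcrossprod(dscores, P[["beta"]])

  if (v %in% c("coformersurv", "sgt", "mgt", "crosst_sa")) {
    pb <- .proj_backward(cache$proj, cache$sba$Z, P[["W1"]], act, dZh)
    G[["W1"]] <- pb$dW1
    sb <- .sba_backward(cache$sba, cache$Zc, P[["smp.Wq"]], P[["smp.Wv"]],
                        pb$dZ)
    G[["smp.Wq"]] <- sb$dWq; G[["smp.Wv"]] <- sb$dWv
    dZc <- sb$dZc
  } else if (v == "crosst_segcn") {
    dPre <- dZh * act$df(cache$gcn_pre)
    G[["W1"]] <- crossprod(cache$AZ, dPre)
    dZc <- crossprod(cache$conv, dPre %*% t(P[["W1"]]))  # conv' = conv (symmetric)
  } else {                                    # crosst
    dZc <- dZh
  }

  if (v == "sgt") {
    dZl <- list(); dZl[[cfg$omics_index]] <- dZc
  } else if (v == "mgt") {
    dZl <- list()
    off <- 0L
    for (l in seq_along(cache$Zl)) {
      w <- ncol(cache$Zl[[l]])
      dZl[[l]] <- dZc[, off + seq_len(w), drop = FALSE]
      off <- off + w
    }
  } else {
    wh <- ncol(P[["W1c"]])
    dW1c <- P[["W1c"]] * 0
    dZl <- lapply(cache$Zl, function(Z) Z * 0)
    for (h in seq_len(cfg$n_heads)) {
      dCh <- dZc[, (h - 1L) * wh + seq_len(wh), drop = FALSE]
      dPh <- dCh * act$df(cache$head_pre[[h]])
      dW1c <- dW1c + crossprod(cache$heads[[h]]$H, dPh)
      dH <- dPh %*% t(P[["W1c"]])
      hb <- .head_backward(cache$heads[[h]], cache$Zl,
                           P[[paste0("head", h, ".Wq")]],
                           P[[paste0("head", h, ".Wv")]], dH)
      G[[paste0("head", h, ".Wq")]] <- hb$dWq
      G[[paste0("head", h, ".Wv")]] <- hb$dWv
      for (l in seq_along(dZl)) dZl[[l]] <- dZl[[l]] + hb$dZ[[l]]
    }
    G[["W1c"]] <- dW1c
  }

  emb_layers <- if (v == "sgt") cfg$omics_index else seq_along(cache$X)
  for (l in emb_layers) {
    dPre <- dZl[[l]] * act$df(cache$pre[[l]])
    G[[paste0("emb", l, ".W")]] <- crossprod(cache$X[[l]], dPre)
    G[[paste0("emb", l, ".b")]] <- colSums(dPre)
  }
  G
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a model by full-batch Adam on the Cox partial likelihood
#'
#' Minimizes the negative log partial likelihood of the risk scores
#' produced by the model's forward pass. Training is full-batch because
#' the partial likelihood couples all samples through the risk sets, and
#' the graph-biased attention couples them through the fused graph. The
#' run is deterministic given the model (initialization is seeded in
#' [build_model()]); the per-epoch loss is recorded.
#'
#' @param model A `coformer_model` from [build_model()].
#' @param X_list Per-omics preprocessed matrices, rows aligned with
#'   `surv`.
#' @param surv A [survival_table()] with at least one event.
#' @param graph A `fused_graph` over the same samples (required by the
#'   graph-using variants, ignored otherwise).
#' @param epochs,lr Override the config values.
#' @return The fitted model, with elements `trace` (loss per epoch) and
#'   `fitted = TRUE` added.
#' @export
fit_model <- function(model, X_list, surv, graph = NULL,
                      epochs = NULL, lr = NULL) {
  stopifnot(inherits(model, "coformer_model"))
  if (sum(surv$event) < 1) stop("training requires at least one event")
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  P <- model$params
  mstate <- lapply(P, function(w) w * 0)
  vstate <- lapply(P, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  X_list <- lapply(X_list, function(m)
    if (inherits(m, "omics_matrix")) m$values else as.matrix(m))
  for (ep in seq_len(epochs)) {
    model$params <- P
    fw <- .forward(model, X_list, graph, want_cache = TRUE)
    lg <- .cox_loss_grad(fw$scores, surv$time, surv$event, cfg$risk_set)
    if (!is.finite(lg$loss))
      stop("non-finite loss at epoch ", ep)
    trace[ep] <- lg$loss
    if (lr == 0) next
    G <- .backward(model, fw$cache, lg$grad)
    corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
    for (k in names(P)) {
      g <- G[[k]]
      mstate[[k]] <- b1 * mstate[[k]] + (1 - b1) * g
      vstate[[k]] <- b2 * vstate[[k]] + (1 - b2) * g^2
      P[[k]] <- P[[k]] - lr * (mstate[[k]] / corr1) /
        (sqrt(vstate[[k]] / corr2) + eps)
    }
  }
  model$params <- P
  model$trace <- trace
  model$fitted <- TRUE
  # Breslow baseline on the training cohort
  fw <- .forward(model, X_list, graph)
  model$baseline <- breslow_baseline(fw$scores, surv)
  model
}

#' Predict risk scores (and optionally embeddings) from a fitted model
#'
#' Runs the forward pass over the supplied samples. For graph-using
#' variants pass a graph covering exactly these rows; to score held-out
#' samples build it with [extend_graph()] so the new samples attach to
#' the training graph inductively.
#'
#' @param model A (fitted) `coformer_model`.
#' @param X_list Per-omics matrices, rows aligned.
#' @param graph A `fused_graph` over the same rows, where required.
#' @param what `"scores"` (numeric vector), `"embedding"` (`Z^h` matrix)
#'   or `"all"` (list with both and `Zc`).
#' @return See `what`.
#' @export
predict_risk <- function(model, X_list, graph = NULL,
                         what = c("scores", "embedding", "all")) {
  what <- match.arg(what)
  fw <- .forward(model, X_list, graph)
  switch(what, scores = fw$scores, embedding = fw$Zh, all = fw)
}

#' Save / load a fitted model
#'
#' Plain `saveRDS`/`readRDS` round trip; all state is ordinary R objects,
#' so reload reproduces identical predictions.
#'
#' @param model A `coformer_model`.
#' @param path File path.
#' @return `read_model` returns the model; `write_model` its path,
#'   invisibly.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
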