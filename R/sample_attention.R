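# Inter-sample attention: plain transformer attention, graph-biased
# attention (kernel multiplied by the fused-graph convolution matrix and
# restricted to fused-graph neighbourhoods), the fixed-weight GCN
# aggregation used in ablations, and the final projection.

.graph_parts <- function(graph) {
  if (inherits(graph, "fused_graph"))
    list(conv = graph$conv, support = graph$support)
  else
    list(conv = as.matrix(graph$conv), support = graph$support)
}

# Forward: Q = Zc Wq, V = Zc Wv, scores q_i'q_j / div; kernel multiplied by
# conv entries, support-restricted, row-normalized; Z = A V.
.sba_forward <- function(Zc, W_q, W_v, conv, support, scale = "dim") {
  div <- .attn_divisor(ncol(W_v), scale)
  Q <- Zc %*% W_q
  V <- Zc %*% W_v
  S <- tcrossprod(Q) / div
  if (anyNA(S)) stop("NaN in attention scores")
  A <- .masked_softmax(S, B = conv, support = support)
  list(Z = A %*% V, A = A, Q = Q, V = V, div = div, support = support)
}

.sba_backward <- function(cache, Zc, W_q, W_v, dZ) {
  A <- cache$A; Q <- cache$Q; V <- cache$V
  dA <- dZ %*% t(V)
  dV <- crossprod(A, dZ)
  dS <- A * (dA - rowSums(dA * A))   # multiplicative bias is constant in S
  dQ <- (dS + t(dS)) %*% Q / cache$div
  list(dWq = crossprod(Zc, dQ), dWv = crossprod(Zc, dV),
       dZc = dQ %*% t(W_q) + dV %*% t(W_v))
}

.proj_forward <- function(Z, W1, act) {
  P <- Z %*% W1
  list(Zh = act$f(P), P = P)
}

.proj_backward <- function(cache, Z, W1, act, dZh) {
  dP <- dZh * act$df(cache$P)
  list(dW1 = crossprod(Z, dP), dZ = dP %*% t(W1))
}

#' Structure-biased inter-sample attention
#'
#' Transformer attention over samples whose exponential kernel is
#' multiplied entrywise by the fused-graph convolution matrix and whose
#' support is restricted to each sample's fused-graph neighbourhood
#' (including the sample itself; the convolution matrix has a positive
#' diagonal, so no row can lose all mass):
#' \deqn{\hat\alpha(i,j) = \frac{\exp(q_i^\top q_j / d)\,\hat A(i,j)}
#'   {\sum_{j' \in N_i} \exp(q_i^\top q_{j'} / d)\,\hat A(i,j')},\qquad
#'   z_i = \sum_{j \in N_i} \hat\alpha(i,j)\, v_j.}
#'
#' @param Zc Combined multi-omics feature matrix (n rows).
#' @param graph A `fused_graph` from [build_fused_graph()] (or a list with
#'   elements `conv` and logical `support`).
#' @param W_q,W_v Query/value projections, `ncol(Zc)` by `d`.
#' @param scale `"dim"` or `"sqrt_dim"` score divisor.
#' @return A list: `Z` (aggregated features, n by `d`) and `weights`
#'   (n-by-n attention matrix, rows summing to 1, zero outside the
#'   neighbourhoods).
#' @export
structure_biased_attention <- function(Zc, graph, W_q, W_v, scale = "dim") {
  Zc <- as.matrix(Zc)
  gp <- .graph_parts(graph)
  if (nrow(gp$conv) != nrow(Zc))
    stop("graph was built over ", nrow(gp$conv), " samples but Zc has ",
         nrow(Zc), " rows")
  cache <- .sba_forward(Zc, W_q, W_v, gp$conv, gp$support, scale)
  list(Z = cache$Z, weights = cache$A)
}

#' Plain transformer attention over samples
#'
#' The unbiased kernel `Z = rowsoftmax(Q Q^T / d) V` over all samples,
#' used by the CrossT-SA ablation variant (no graph structure).
#'
#' @inheritParams structure_biased_attention
#' @return A list: `Z` and `weights` as in [structure_biased_attention()].
#' @export
plain_attention <- function(Zc, W_q, W_v, scale = "dim") {
  Zc <- as.matrix(Zc)
  n <- nrow(Zc)
  cache <- .sba_forward(Zc, W_q, W_v,
                        conv = matrix(1, n, n),
                        support = matrix(TRUE, n, n), scale = scale)
  list(Z = cache$Z, weights = cache$A)
}

#' Project aggregated sample embeddings
#'
#' Final fully connected layer `z_i^h = f(z_i W1)`.
#'
#' @param Z Aggregated feature matrix.
#' @param W1 Projection matrix, `ncol(Z)` by `d_h`.
#' @param activation Activation name.
#' @return The projected matrix `Z^h`.
#' @export
project_embeddings <- function(Z, W1, activation = "relu") {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(W1))
    stop("width ", ncol(Z), " does not match projection input width ", nrow(W1))
  act <- .activation(activation)
  .proj_forward(Z, W1, act)$Zh
}

#' Graph-convolution aggregation (ablation)
#'
#' Fixed-weight neighbourhood aggregation `Z^h = f(\hat A Z^c W1)` used by
#' the CrossT-SEGCN variant: the convolution matrix replaces learned
#' attention entirely.
#'
#' @inheritParams structure_biased_attention
#' @param W1 Weight matrix, `ncol(Zc)` by `d_h`.
#' @param activation Activation name.
#' @return The aggregated, projected matrix.
#' @export
gcn_layer <- function(Zc, graph, W1, activation = "relu") {
  Zc <- as.matrix(Zc)
  gp <- .graph_parts(graph)
  if (ncol(Zc) != nrow(W1))
    stop("width ", ncol(Zc), " does not match W1 input width ", nrow(W1))
  act <- .activation(activation)
  act$f(gp$conv %*% Zc %*% W1)
}
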