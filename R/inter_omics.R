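#' Embed one omics layer into the latent space
#'
#' One affine layer followed by an activation:
#' `Z = f(X W + b)`. This is the per-omics feature-extraction layer that
#' maps a preprocessed high-dimensional omics matrix to a compact latent
#' representation used by the inter-omics attention block.
#'
#' @param X Numeric matrix (or [omics_matrix()]), samples in rows.
#' @param W Weight matrix, `ncol(X)` by `d_latent`.
#' @param b Bias vector of length `d_latent`.
#' @param activation `"relu"`, `"tanh"` or `"linear"`.
#' @return The latent matrix `Z` (n by `d_latent`).
#' @export
embed_omics <- function(X, W, b = NULL, activation = "relu") {
  if (inherits(X, "omics_matrix")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != nrow(W))
    stop("feature width ", ncol(X), " does not match embedding input width ", nrow(W))
  if (is.null(b)) b <- numeric(ncol(W))
  act <- .activation(activation)
  act$f(sweep(X %*% W, 2L, b, "+"))
}

# Forward pass of one inter-omics attention head over v latent matrices.
# Shared W_q (keys == queries) and W_v across omics; per-sample v x v
# attention. Returns the stacked head features H = [Z^(1,c) | ... | Z^(v,c)]
# plus everything the backward pass needs.
.head_forward <- function(Z_list, W_q, W_v, scale = "dim") {
  v <- length(Z_list)
  n <- nrow(Z_list[[1]])
  d_c <- ncol(W_q)
  div <- .attn_divisor(d_c, scale)
  Q <- lapply(Z_list, function(Z) Z %*% W_q)
  V <- lapply(Z_list, function(Z) Z %*% W_v)
  S <- array(0, dim = c(n, v, v))
  for (u1 in seq_len(v)) for (u2 in seq_len(v))
    S[, u1, u2] <- rowSums(Q[[u1]] * Q[[u2]]) / div
  A <- array(0, dim = c(n, v, v))
  for (u1 in seq_len(v)) {
    Su <- matrix(S[, u1, ], nrow = n, ncol = v)
    A[, u1, ] <- .masked_softmax(Su)
  }
  H <- matrix(0, n, v * d_c)
  for (u1 in seq_len(v)) {
    Zu <- matrix(0, n, d_c)
    for (u2 in seq_len(v)) Zu <- Zu + A[, u1, u2] * V[[u2]]
    H[, (u1 - 1L) * d_c + seq_len(d_c)] <- Zu
  }
  list(H = H, Q = Q, V = V, A = A, div = div, d_c = d_c, v = v)
}

# Backward pass of .head_forward. dH: gradient wrt the stacked output.
# Returns gradients wrt W_q, W_v and each Z^(l).
.head_backward <- function(cache, Z_list, W_q, W_v, dH) {
  v <- cache$v; d_c <- cache$d_c; div <- cache$div
  n <- nrow(dH)
  A <- cache$A; Q <- cache$Q; V <- cache$V
  dQ <- lapply(Q, function(q) q * 0)
  dV <- lapply(V, function(q) q * 0)
  dZu <- lapply(seq_len(v), function(u1)
    dH[, (u1 - 1L) * d_c + seq_len(d_c), drop = FALSE])
  dAh <- array(0, dim = c(n, v, v))
  for (u1 in seq_len(v)) for (u2 in seq_len(v)) {
    dV[[u2]] <- dV[[u2]] + A[, u1, u2] * dZu[[u1]]
    dAh[, u1, u2] <- rowSums(dZu[[u1]] * V[[u2]])
  }
  # softmax backward over u2 for each (i, u1)
  dS <- array(0, dim = c(n, v, v))
  for (u1 in seq_len(v)) {
    Au <- matrix(A[, u1, ], ncol = v)
    dAu <- matrix(dAh[, u1, ], ncol = v)
    dS[, u1, ] <- Au * (dAu - rowSums(dAu * Au))
  }
  for (u1 in seq_len(v)) for (u2 in seq_len(v)) {
    g <- dS[, u1, u2] / div
    dQ[[u1]] <- dQ[[u1]] + g * Q[[u2]]
    dQ[[u2]] <- dQ[[u2]] + g * Q[[u1]]
  }
  dWq <- matrix(0, nrow(W_q), ncol(W_q))
  dWv <- matrix(0, nrow(W_v), ncol(W_v))
  dZ <- lapply(Z_list, function(Z) Z * 0)
  for (l in seq_len(v)) {
    dWq <- dWq + crossprod(Z_list[[l]], dQ[[l]])
    dWv <- dWv + crossprod(Z_list[[l]], dV[[l]])
    dZ[[l]] <- dZ[[l]] + dQ[[l]] %*% t(W_q) + dV[[l]] %*% t(W_v)
  }
  list(dWq = dWq, dWv = dWv, dZ = dZ)
}

#' Cross-omics attention (one head)
#'
#' Within each sample, attends across omics layers: queries double as keys
#' (one shared projection `W_q`), raw scores are inner products divided by
#' the head width `d_c` (or its square root when `scale = "sqrt_dim"`),
#' softmax-normalized over the source omics, and used to aggregate the
#' value projections. The head output stacks the per-omics contextualized
#' features along the feature axis, giving an `n` by `v * d_c` matrix.
#' No mixing across samples happens here.
#'
#' @param Z_list List of `v >= 2` latent matrices (n by `d_latent` each).
#' @param W_q,W_v Shared query/value projections, `d_latent` by `d_c`.
#' @param scale `"dim"` (divide scores by `d_c`, the default) or
#'   `"sqrt_dim"` (conventional transformer scaling).
#' @return A list: `features` (n by `v * d_c`) and `weights`
#'   (n by v by v array of attention weights, rows summing to 1 over the
#'   last index).
#' @export
cross_omics_attention <- function(Z_list, W_q, W_v, scale = "dim") {
  if (length(Z_list) < 2L)
    stop("cross-omics attention requires >= 2 omics layers")
  dims <- vapply(Z_list, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all latent matrices must share n and d_latent")
  cache <- .head_forward(Z_list, W_q, W_v, scale)
  list(features = cache$H, weights = cache$A)
}

#' Combine attention heads into the multi-omics representation
#'
#' Each head's stacked features are compressed through the same learnable
#' matrix `W1c` and activation, then concatenated along the feature axis:
#' `Z^c = f(H_1 W1c) | f(H_2 W1c) | ...`. With a single head no
#' concatenation happens.
#'
#' @param heads List of per-head feature matrices (equal shapes).
#' @param W1c Shared compression matrix, `ncol(heads[[1]])` by the per-head
#'   output width.
#' @param activation Activation name.
#' @return The combined matrix `Z^c`, `n` by `length(heads) * ncol(W1c)`.
#' @export
combine_heads <- function(heads, W1c, activation = "relu") {
  stopifnot(length(heads) >= 1L)
  dims <- vapply(heads, dim, integer(2))
  if (any(dims != dims[, 1])) stop("head outputs must have equal shapes")
  if (ncol(heads[[1]]) != nrow(W1c))
    stop("head width ", ncol(heads[[1]]), " does not match W1c input width ", nrow(W1c))
  act <- .activation(activation)
  do.call(cbind, lapply(heads, function(H) act$f(H %*% W1c)))
}
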