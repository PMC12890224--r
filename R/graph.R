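#' K-nearest-neighbour exponential-kernel similarity graph
#'
#' Builds a directed KNN graph over samples and weights each retained edge
#' with an exponential similarity kernel on squared Euclidean distance,
#' `w(i, j) = exp(-d2(i, j) / (mu * delta_sq))` for `j` among the `K`
#' nearest neighbours of `i` (self excluded), 0 otherwise. `delta_sq` is the
#' median of the squared Euclidean distances over all unordered distinct
#' sample pairs. The directed graph is then symmetrized with an elementwise
#' maximum (union of directed edges; kernel values are preserved because the
#' kernel itself is symmetric).
#'
#' @param X Numeric matrix, samples in rows.
#' @param K Neighbourhood size, `1 <= K <= n - 1`.
#' @param mu Positive kernel scaling; smaller values sharpen the kernel.
#' @param delta_sq Optional distance normalizer; defaults to the median
#'   squared pairwise distance of `X`. Supply the training value when
#'   attaching held-out samples.
#' @return Symmetric non-negative n-by-n adjacency matrix with zero
#'   diagonal and entries in `[0, 1]`, with attributes `delta_sq`, `K`,
#'   `mu`.
#' @export
knn_kernel_graph <- function(X, K, mu, delta_sq = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(K >= 1, n >= K + 1, mu > 0)
  D2 <- as.matrix(stats::dist(X))^2
  if (is.null(delta_sq)) delta_sq <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(delta_sq) || delta_sq <= 0)
    stop("degenerate distance distribution: median squared pairwise distance is 0")
  W <- matrix(0, n, n)
  Kern <- exp(-D2 / (mu * delta_sq))
  for (i in seq_len(n)) {
    d <- D2[i, ]
    d[i] <- Inf
    nn <- order(d)[seq_len(K)]       # stable: ties broken by sample index
    W[i, nn] <- Kern[i, nn]
  }
  A <- pmax(W, t(W))
  dimnames(A) <- list(rownames(X), rownames(X))
  attr(A, "delta_sq") <- delta_sq
  attr(A, "K") <- K
  attr(A, "mu") <- mu
  A
}

#' Fuse per-omics adjacency matrices
#'
#' Elementwise mean of the adjacency matrices; the fused edge set is the
#' union of the input edge sets (an edge present in only one of `L` layers
#' contributes `weight / L`).
#'
#' @param adjacencies List of equal-shape symmetric non-negative matrices.
#' @return The fused adjacency matrix.
#' @export
fuse_graphs <- function(adjacencies) {
  stopifnot(is.list(adjacencies), length(adjacencies) >= 1L)
  dims <- vapply(adjacencies, dim, integer(2))
  if (any(dims != dims[, 1])) stop("adjacency shape mismatch across omics")
  Reduce(`+`, lapply(adjacencies, unclass)) / length(adjacencies)
}

#' Spectral convolution matrix of an adjacency matrix
#'
#' Adds self-loops and symmetrically normalizes by degree:
#' `A_hat = D_tilde^{-1/2} (A + I) D_tilde^{-1/2}` with
#' `d_tilde_i = sum_j (A + I)_ij`. Because of the added identity every
#' `d_tilde_i >= 1`, so the transform is always defined.
#'
#' @param A Non-negative square matrix.
#' @return The convolution matrix `A_hat`, symmetric when `A` is.
#' @export
spectral_normalize <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), all(A >= 0))
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  s <- 1 / sqrt(d)
  Ahat <- At * tcrossprod(s)
  dimnames(Ahat) <- dimnames(A)
  Ahat
}

#' Build the fused multi-omics graph
#'
#' Constructs one KNN kernel graph per omics layer ([knn_kernel_graph()]),
#' fuses them by edge-union averaging ([fuse_graphs()]) and computes the
#' spectral convolution matrix ([spectral_normalize()]). Neighbour sets for
#' graph-biased attention are read off the fused adjacency and always
#' include the node itself (the convolution matrix has positive diagonal).
#'
#' @param X_list List of preprocessed feature matrices (or
#'   [omics_matrix()] objects), one per omics, rows aligned.
#' @param K Neighbourhood size shared by all layers.
#' @param mu Per-omics kernel scalings, recycled to the number of layers.
#'   Defaults to 0.3 for the first (gene-like) layer, 0.2 for the second
#'   (microRNA-like) layer and 0.3 for any further layer.
#' @return A `fused_graph` object with elements `per_omics` (list of
#'   adjacencies), `fused`, `conv` (the convolution matrix), `support`
#'   (logical mask: fused edges plus self-loops), `K`, `mu`, `delta_sq`.
#' @export
build_fused_graph <- function(X_list, K, mu = NULL) {
  X_list <- lapply(X_list, function(m) if (inherits(m, "omics_matrix")) m$values else as.matrix(m))
  L <- length(X_list)
  if (is.null(mu)) mu <- if (L >= 2) c(0.3, 0.2, rep(0.3, L - 2))[seq_len(L)] else 0.3
  mu <- rep_len(mu, L)
  per <- mapply(function(X, m) knn_kernel_graph(X, K, m), X_list, mu,
                SIMPLIFY = FALSE)
  fused <- fuse_graphs(per)
  conv <- spectral_normalize(fused)
  n <- nrow(fused)
  support <- fused > 0 | diag(n) > 0
  structure(list(per_omics = per, fused = fused, conv = conv,
                 support = support, K = K, mu = mu,
                 delta_sq = vapply(per, attr, numeric(1), "delta_sq"),
                 n_train = n),
            class = "fused_graph")
}

#' Attach held-out samples to a training graph inductively
#'
#' New samples are linked by KNN to *training* samples only, using the
#' training kernel parameters (`delta_sq`, `mu`, `K`); edges among new
#' samples are excluded, and the convolution matrix is recomputed on the
#' combined graph. Training outcomes play no role here, so no label
#' information can leak into the held-out rows.
#'
#' @param graph A `fused_graph` fitted on training samples.
#' @param X_train_list,X_new_list Per-omics feature matrices for the
#'   training and new samples (same feature spaces, rows aligned within
#'   each set).
#' @return A `fused_graph` over the `n_train + n_new` combined samples
#'   (training rows first) with the training block equal to the original
#'   graph.
#' @export
extend_graph <- function(graph, X_train_list, X_new_list) {
  stopifnot(inherits(graph, "fused_graph"),
            length(X_train_list) == length(graph$per_omics),
            length(X_new_list) == length(X_train_list))
  as_mat <- function(m) if (inherits(m, "omics_matrix")) m$values else as.matrix(m)
  X_train_list <- lapply(X_train_list, as_mat)
  X_new_list <- lapply(X_new_list, as_mat)
  n_tr <- nrow(X_train_list[[1]])
  n_new <- nrow(X_new_list[[1]])
  K <- graph$K
  per <- vector("list", length(X_train_list))
  for (l in seq_along(X_train_list)) {
    Xtr <- X_train_list[[l]]; Xnw <- X_new_list[[l]]
    d2 <- outer(rowSums(Xnw^2), rowSums(Xtr^2), "+") - 2 * tcrossprod(Xnw, Xtr)
    d2[d2 < 0] <- 0
    Wc <- matrix(0, n_new, n_tr)
    Kern <- exp(-d2 / (graph$mu[l] * graph$delta_sq[l]))
    kk <- min(K, n_tr)
    for (i in seq_len(n_new)) {
      nn <- order(d2[i, ])[seq_len(kk)]
      Wc[i, nn] <- Kern[i, nn]
    }
    A <- matrix(0, n_tr + n_new, n_tr + n_new)
    A[seq_len(n_tr), seq_len(n_tr)] <- graph$per_omics[[l]]
    A[n_tr + seq_len(n_new), seq_len(n_tr)] <- Wc
    A[seq_len(n_tr), n_tr + seq_len(n_new)] <- t(Wc)
    per[[l]] <- A
  }
  fused <- fuse_graphs(per)
  conv <- spectral_normalize(fused)
  structure(list(per_omics = per, fused = fused, conv = conv,
                 support = fused > 0 | diag(n_tr + n_new) > 0,
                 K = K, mu = graph$mu, delta_sq = graph$delta_sq,
                 n_train = n_tr),
            class = "fused_graph")
}

#' Write a fused graph as an edge list with a JSON sidecar
#'
#' Emits a TSV `i  j  weight` over the upper triangle of the fused
#' adjacency plus `<path>.json` recording `K`, `mu` and `delta_sq`.
#'
#' @param graph A `fused_graph`.
#' @param path Output TSV path.
#' @export
write_graph <- function(graph, path) {
  A <- graph$fused
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2], weight = A[idx])
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(K = graph$K, mu = graph$mu,
                            delta_sq = graph$delta_sq),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
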