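# Graph transformer network over the three interaction edge types: soft
# meta-path composition via learned convex combinations of typed adjacencies,
# graph convolution of fingerprint features, and channel attention pooling.
#
# The exported operations are plain-numeric and feed the test oracles; the
# ad_* forward used in training is built from the same autodiff primitives and
# is checked against them.

#' Initialise graph transformer parameters
#'
#' Edge-type convolution weights start near zero so the initial softmax is
#' close to uniform over the three edge types; projection and attention
#' parameters use fan-average Gaussian scaling.
#'
#' @param m Fingerprint dimension (input features).
#' @param d Embedding dimension (default 32).
#' @param C Number of channels (default 2).
#' @param L Number of composition layers (meta-paths up to length `L + 1`);
#'   `L + 1` edge-type weight matrices are created.
#' @param h Attention hidden size (default `d`).
#' @param seed Optional seed.
#' @return A `gtn_params` object.
#' @export
gtn_params <- function(m, d = 32L, C = 2L, L = 2L, h = d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edge_conv <- lapply(seq_len(L + 1L), function(l) {
    matrix(stats::rnorm(3L * C, sd = 0.01), 3L, C)
  })
  structure(
    list(
      edge_conv = edge_conv,
      projection = matrix(stats::rnorm(m * d, sd = sqrt(2 / (m + d))), m, d),
      attention_proj = matrix(stats::rnorm(d * h, sd = sqrt(2 / (d + h))), d, h),
      attention_query = stats::rnorm(h, sd = sqrt(1 / h)),
      attention_bias = numeric(h),
      C = C, L = L, d = d, h = h, m = m
    ),
    class = "gtn_params"
  )
}

softmax_cols <- function(w) {
  w <- sweep(w, 2L, apply(w, 2L, max), "-")
  e <- exp(w)
  sweep(e, 2L, colSums(e), "/")
}

#' Edge-type convolution
#'
#' Collapses the three typed adjacency slices into `C` channel-specific
#' matrices: channel `c` is the convex combination of the slices with weights
#' `softmax(W)[, c]`, the softmax taken over the edge-type axis.
#'
#' @param tensor The `n x n x 3` interaction tensor.
#' @param W A `3 x C` weight matrix.
#' @return An `n x n x C` array.
#' @export
edge_type_conv <- function(tensor, W) {
  dims <- dim(tensor)
  if (length(dims) != 3L || dims[3] != 3L) stop("`tensor` must be n x n x 3")
  if (nrow(W) != 3L) stop("`W` must have 3 rows (edge types)")
  sm <- softmax_cols(W)
  C <- ncol(W)
  out <- array(0, dim = c(dims[1], dims[2], C))
  for (c in seq_len(C)) {
    out[, , c] <- tensor[, , 1] * sm[1, c] + tensor[, , 2] * sm[2, c] +
      tensor[, , 3] * sm[3, c]
  }
  out
}

row_normalize <- function(x, eps = 1e-12) {
  d <- rowSums(abs(x))
  d[d < eps] <- 1
  x / d
}

#' Compose soft meta-path adjacencies
#'
#' Builds, per channel, the degree-normalised chained product of edge-type
#' convolutions: `A^(1) = D^{-1} Q^(1) Q^(2)` and
#' `A^(l) = D^{-1} A^(l-1) Q^(l+1)` for `l = 2..L`, where `D` is the row-sum
#' degree of the unnormalised product at each step (zero rows pass through).
#' Entry `(i, j)` of channel `c` aggregates soft meta-paths of length `l + 1`
#' from drug `i` to drug `j`.
#'
#' @param tensor The `n x n x 3` interaction tensor.
#' @param edge_conv List of `L + 1` weight matrices, each `3 x C`.
#' @return An `n x n x C` array (the channels of the final layer).
#' @export
compose_adjacency <- function(tensor, edge_conv) {
  L <- length(edge_conv) - 1L
  if (L < 1L) stop("need at least 2 edge-type weight matrices (L >= 1)")
  C <- ncol(edge_conv[[1]])
  q <- lapply(edge_conv, function(w) edge_type_conv(tensor, w))
  n <- dim(tensor)[1]
  out <- array(0, dim = c(n, n, C))
  for (c in seq_len(C)) {
    a <- row_normalize(q[[1]][, , c] %*% q[[2]][, , c])
    if (L >= 2L) {
      for (l in 2:L) a <- row_normalize(a %*% q[[l + 1L]][, , c])
    }
    out[, , c] <- a
  }
  out
}

#' Graph convolution over composed adjacencies
#'
#' Per channel: add self-loops to the composed adjacency, row-normalise by
#' degree, propagate fingerprint features, project, and rectify:
#' `Z_c = ReLU(D~^{-1} (A_c + I) X W)`.
#'
#' @param composite `n x n x C` array from [compose_adjacency()].
#' @param X `n x m` fingerprint matrix.
#' @param projection `m x d` projection matrix.
#' @return An `n x d x C` array of per-channel embeddings.
#' @export
gtn_embed <- function(composite, X, projection) {
  if (!all(is.finite(composite)) || !all(is.finite(X))) {
    stop("non-finite input to gtn_embed")
  }
  n <- dim(composite)[1]
  if (nrow(X) != n) stop("fingerprint row count must equal drug count")
  C <- dim(composite)[3]
  d <- ncol(projection)
  xw <- X %*% projection
  out <- array(0, dim = c(n, d, C))
  for (c in seq_len(C)) {
    a_tilde <- composite[, , c] + diag(n)
    out[, , c] <- pmax(row_normalize(a_tilde) %*% xw, 0)
  }
  out
}

#' Channel attention pooling
#'
#' Scores each channel by a tanh attention head averaged over drugs,
#' `a_c = mean_i q' tanh(Z_c[i, ] P + b)`, softmaxes the scores into channel
#' weights `beta`, and returns the beta-weighted sum of channel embeddings.
#'
#' @param Z `n x d x C` array of per-channel embeddings.
#' @param params A `gtn_params` (uses `attention_query`, `attention_proj`,
#'   `attention_bias`).
#' @return List with `scores` (length `C`), `weights` (softmax of scores,
#'   sums to 1), and `pooled` (`n x d`).
#' @export
channel_attention_pool <- function(Z, params) {
  C <- dim(Z)[3]
  scores <- vapply(seq_len(C), function(c) {
    t_c <- tanh(sweep(Z[, , c, drop = TRUE] %*% params$attention_proj, 2L,
                      params$attention_bias, "+"))
    mean(t_c %*% params$attention_query)
  }, numeric(1))
  e <- exp(scores - max(scores))
  beta <- e / sum(e)
  pooled <- matrix(0, dim(Z)[1], dim(Z)[2])
  for (c in seq_len(C)) pooled <- pooled + beta[c] * Z[, , c, drop = TRUE]
  list(scores = scores, weights = beta, pooled = pooled)
}

#' Fuse global and local drug features
#'
#' Concatenates, row-wise, the Tucker-derived global embedding and the graph
#' transformer's local embedding: row `i` of the result is the interaction
#' feature of drug `i` in that cell line.
#'
#' @param U `n x R1` global embedding.
#' @param Z `n x d` local embedding.
#' @return An `n x (R1 + d)` matrix.
#' @export
fuse_global_local <- function(U, Z) {
  if (nrow(U) != nrow(Z)) {
    stop(sprintf("row-count mismatch: U has %d rows, Z has %d", nrow(U), nrow(Z)))
  }
  cbind(U, Z)
}

# ---- autodiff forward (training path) ---------------------------------------

# Parameters as ad nodes, mirroring gtn_params fields.
gtn_param_nodes <- function(params) {
  list(
    edge_conv = lapply(params$edge_conv, ad_param),
    projection = ad_param(params$projection),
    attention_proj = ad_param(params$attention_proj),
    attention_query = ad_param(matrix(params$attention_query, ncol = 1L)),
    attention_bias = ad_param(params$attention_bias)
  )
}

# Full GTN forward on the tape; `tensor` is the numeric interaction tensor,
# `X` the numeric fingerprint matrix, `nodes` from gtn_param_nodes() (or
# ad_const-wrapped for inference). Returns the pooled n x d node.
gtn_forward <- function(tensor, X, nodes, C, L) {
  n <- dim(tensor)[1]
  slices <- lapply(1:3, function(l) ad_const(tensor[, , l]))
  sm <- lapply(nodes$edge_conv, ad_softmax_cols)
  q <- lapply(seq_len(L + 1L), function(l) {
    lapply(seq_len(C), function(c) ad_weighted_sum(slices, ad_col(sm[[l]], c)))
  })
  eye <- ad_const(diag(n))
  xw <- ad_matmul(ad_const(X), nodes$projection)
  z_channels <- vector("list", C)
  for (c in seq_len(C)) {
    a <- ad_row_normalize(ad_matmul(q[[1]][[c]], q[[2]][[c]]))
    if (L >= 2L) {
      for (l in 2:L) a <- ad_row_normalize(ad_matmul(a, q[[l + 1L]][[c]]))
    }
    a_tilde <- ad_row_normalize(ad_add(a, eye))
    z_channels[[c]] <- ad_relu(ad_matmul(a_tilde, xw))
  }
  score_nodes <- lapply(z_channels, function(z) {
    t_c <- ad_tanh(ad_add_bias(ad_matmul(z, nodes$attention_proj),
                               nodes$attention_bias))
    ad_mean(ad_matmul(t_c, nodes$attention_query))
  })
  beta <- ad_softmax_vec(ad_concat_scalars(score_nodes))
  ad_weighted_sum(z_channels, beta)
}

# Numeric convenience: run the full local-feature pipeline without a tape.
gtn_local_features <- function(tensor, X, params) {
  composite <- compose_adjacency(tensor, params$edge_conv)
  Z <- gtn_embed(composite, X, params$projection)
  channel_attention_pool(Z, params)$pooled
}
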