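# Reverse-mode automatic differentiation on a flat tape.
#
# Every trainable component in the package (graph transformer, molecular GCN,
# fusion MLPs with batch normalisation) is expressed with the primitives below,
# so gradients are exact to machine precision and can be verified against
# central finite differences. Nodes are environments holding a numeric value
# and a backward closure; the tape records creation order, and ad_backward()
# replays it in reverse. Constants are untracked: no gradient buffers are
# allocated for them and backward work is skipped where no input is tracked.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' @noRd
ad_tape_begin <- function(capacity = NULL) {
  tp <- new.env(parent = emptyenv())
  tp$last <- NULL
  .ad$tape <- tp
  invisible(tp)
}

#' @noRd
ad_tape_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

# Create a node. `track` marks nodes whose gradient is needed (parameters and
# anything downstream of one). The tape is an intrusive linked list: each
# tracked node points at the previously recorded one, so recording is O(1)
# and walking `prev` pointers visits nodes in reverse creation order.
ad_new <- function(value, track, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$track <- track
  nd$backward <- backward
  if (track) {
    tp <- .ad$tape
    if (!is.null(tp)) {
      nd$prev <- tp$last
      tp$last <- nd
    }
  }
  nd
}

ad_const <- function(value) ad_new(value, track = FALSE)
ad_param <- function(value) ad_new(value, track = TRUE)

ad_is_node <- function(x) is.environment(x) && !is.null(x$value)

# Wrap plain numerics so ops accept either nodes or raw arrays.
ad_wrap <- function(x) if (ad_is_node(x)) x else ad_const(x)

ad_acc <- function(node, g) {
  if (!node$track) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @noRd
ad_backward <- function(loss) {
  tp <- .ad$tape
  if (is.null(tp)) stop("no active tape; call ad_tape_begin() first")
  if (length(loss$value) != 1L) stop("backward requires a scalar loss")
  loss$grad <- 1
  nd <- tp$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
    nd <- nd$prev
  }
  invisible(NULL)
}

# ---- primitives -------------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  v <- a$value %*% b$value
  tr <- a$track || b$track
  ad_new(v, tr, backward = if (tr) function(g) {
    if (a$track) ad_acc(a, g %*% t(b$value))
    if (b$track) ad_acc(b, crossprod(a$value, g))
  })
}

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  tr <- a$track || b$track
  ad_new(a$value + b$value, tr, backward = if (tr) function(g) {
    if (a$track) ad_acc(a, g)
    if (b$track) ad_acc(b, g)
  })
}

# Broadcast a length-k vector across the rows of a B x k matrix
# (column-major recycling; avoids sweep()'s aperm overhead).
row_bcast <- function(vec, nrow) {
  rep.int(as.numeric(vec), rep.int(nrow, length(vec)))
}

# Add a length-k bias vector to every row of a B x k matrix.
ad_add_bias <- function(a, bias) {
  a <- ad_wrap(a); bias <- ad_wrap(bias)
  v <- a$value + row_bcast(bias$value, nrow(a$value))
  tr <- a$track || bias$track
  ad_new(v, tr, backward = if (tr) function(g) {
    if (a$track) ad_acc(a, g)
    if (bias$track) ad_acc(bias, colSums(g))
  })
}

# Fused affine map x W + b (one node instead of two).
ad_affine <- function(x, W, b) {
  x <- ad_wrap(x); W <- ad_wrap(W); b <- ad_wrap(b)
  v <- x$value %*% W$value
  v <- v + row_bcast(b$value, nrow(v))
  tr <- x$track || W$track || b$track
  ad_new(v, tr, backward = if (tr) function(g) {
    if (x$track) ad_acc(x, g %*% t(W$value))
    if (W$track) ad_acc(W, crossprod(x$value, g))
    if (b$track) ad_acc(b, colSums(g))
  })
}

# Fused graph-convolution layer ReLU(S H W) with a constant propagation
# operator S; cuts per-layer node count for the molecular encoder.
ad_gcn_layer <- function(s_hat, h, W) {
  h <- ad_wrap(h); W <- ad_wrap(W)
  sh <- s_hat %*% h$value
  pre <- sh %*% W$value
  mask <- pre > 0
  v <- pre * mask
  tr <- h$track || W$track
  ad_new(v, tr, backward = if (tr) function(g) {
    gm <- g * mask
    if (h$track) ad_acc(h, crossprod(s_hat, gm %*% t(W$value)))
    if (W$track) ad_acc(W, crossprod(sh, gm))
  })
}

ad_scale <- function(a, s) {
  a <- ad_wrap(a)
  ad_new(a$value * s, a$track, backward = if (a$track) function(g) ad_acc(a, g * s))
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  tr <- a$track || b$track
  ad_new(a$value * b$value, tr, backward = if (tr) function(g) {
    if (a$track) ad_acc(a, g * b$value)
    if (b$track) ad_acc(b, g * a$value)
  })
}

ad_relu <- function(a) {
  a <- ad_wrap(a)
  mask <- a$value > 0
  v <- a$value * mask
  ad_new(v, a$track, backward = if (a$track) function(g) ad_acc(a, g * mask))
}

ad_tanh <- function(a) {
  a <- ad_wrap(a)
  v <- tanh(a$value)
  ad_new(v, a$track, backward = if (a$track) function(g) ad_acc(a, g * (1 - v^2)))
}

# Column-wise softmax of a matrix (used over the edge-type axis, one column
# per channel).
ad_softmax_cols <- function(a) {
  a <- ad_wrap(a)
  x <- a$value
  x <- sweep(x, 2L, apply(x, 2L, max), "-")
  e <- exp(x)
  v <- sweep(e, 2L, colSums(e), "/")
  ad_new(v, a$track, backward = if (a$track) function(g) {
    ad_acc(a, v * sweep(g, 2L, colSums(g * v), "-"))
  })
}

ad_softmax_vec <- function(a) {
  a <- ad_wrap(a)
  x <- as.numeric(a$value)
  e <- exp(x - max(x))
  v <- e / sum(e)
  ad_new(v, a$track, backward = if (a$track) function(g) {
    g <- as.numeric(g)
    ad_acc(a, v * (g - sum(g * v)))
  })
}

ad_sum <- function(a) {
  a <- ad_wrap(a)
  shape <- dim(a$value)
  len <- length(a$value)
  ad_new(sum(a$value), a$track, backward = if (a$track) function(g) {
    gr <- rep(as.numeric(g), len)
    if (!is.null(shape)) dim(gr) <- shape
    ad_acc(a, gr)
  })
}

ad_mean <- function(a) {
  a <- ad_wrap(a)
  n <- length(a$value)
  ad_scale(ad_sum(a), 1 / n)
}

ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, ad_wrap)
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  v <- do.call(cbind, lapply(nodes, function(n) n$value))
  tr <- any(vapply(nodes, function(n) n$track, logical(1)))
  ad_new(v, tr, backward = if (tr) function(g) {
    off <- 0L
    for (k in seq_along(nodes)) {
      if (nodes[[k]]$track) {
        ad_acc(nodes[[k]], g[, off + seq_len(widths[k]), drop = FALSE])
      }
      off <- off + widths[k]
    }
  })
}

ad_rbind <- function(nodes) {
  nodes <- lapply(nodes, ad_wrap)
  heights <- vapply(nodes, function(n) nrow(n$value), integer(1))
  v <- do.call(rbind, lapply(nodes, function(n) n$value))
  tr <- any(vapply(nodes, function(n) n$track, logical(1)))
  ad_new(v, tr, backward = if (tr) function(g) {
    off <- 0L
    for (k in seq_along(nodes)) {
      if (nodes[[k]]$track) {
        ad_acc(nodes[[k]], g[off + seq_len(heights[k]), , drop = FALSE])
      }
      off <- off + heights[k]
    }
  })
}

# Extract column j as a column vector node.
ad_col <- function(a, j) {
  a <- ad_wrap(a)
  v <- a$value[, j, drop = FALSE]
  ad_new(v, a$track, backward = if (a$track) function(g) {
    gr <- matrix(0, nrow(a$value), ncol(a$value))
    gr[, j] <- g
    ad_acc(a, gr)
  })
}

ad_concat_scalars <- function(nodes) {
  nodes <- lapply(nodes, ad_wrap)
  v <- vapply(nodes, function(n) as.numeric(n$value), numeric(1))
  tr <- any(vapply(nodes, function(n) n$track, logical(1)))
  ad_new(v, tr, backward = if (tr) function(g) {
    g <- as.numeric(g)
    for (k in seq_along(nodes)) if (nodes[[k]]$track) ad_acc(nodes[[k]], g[k])
  })
}

# y = sum_c w[c] * M_c for a list of equally shaped matrices and a length-C
# weight vector; both sides may require gradients (channel attention pooling).
ad_weighted_sum <- function(mats, w) {
  mats <- lapply(mats, ad_wrap)
  w <- ad_wrap(w)
  wv <- as.numeric(w$value)
  v <- mats[[1]]$value * wv[1]
  if (length(mats) > 1L) {
    for (c in 2:length(mats)) v <- v + mats[[c]]$value * wv[c]
  }
  tr <- w$track || any(vapply(mats, function(n) n$track, logical(1)))
  ad_new(v, tr, backward = if (tr) function(g) {
    if (w$track) {
      gw <- vapply(mats, function(m) sum(g * m$value), numeric(1))
      ad_acc(w, gw)
    }
    for (c in seq_along(mats)) {
      if (mats[[c]]$track) ad_acc(mats[[c]], g * wv[c])
    }
  })
}

# Row-degree normalisation D^{-1} X with degree d_i = sum_j |x_ij|; rows with
# (near-)zero degree are passed through unchanged, mirroring isolated drugs.
ad_row_normalize <- function(a, eps = 1e-12) {
  a <- ad_wrap(a)
  x <- a$value
  d <- rowSums(abs(x))
  fixed <- d < eps
  d[fixed] <- 1
  v <- x / d
  ad_new(v, a$track, backward = if (a$track) function(g) {
    inner <- rowSums(g * x) / d^2
    inner[fixed] <- 0
    ad_acc(a, g / d - sign(x) * inner)
  })
}

ad_mse <- function(pred, y) {
  pred <- ad_wrap(pred)
  yv <- as.numeric(y)
  pv <- as.numeric(pred$value)
  n <- length(yv)
  v <- mean((pv - yv)^2)
  ad_new(v, pred$track, backward = if (pred$track) function(g) {
    gr <- 2 * (pv - yv) / n * as.numeric(g)
    dim(gr) <- dim(pred$value)
    ad_acc(pred, gr)
  })
}

# Batch normalisation over the batch (row) dimension. `state` is an
# environment carrying running_mean / running_var (biased, momentum update) so
# evaluation-mode forward passes are deterministic.
ad_batch_norm <- function(a, gamma, beta, state, training = TRUE,
                          momentum = 0.1, eps = 1e-5) {
  a <- ad_wrap(a); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  x <- a$value
  nb <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - row_bcast(mu, nb)
    va <- colMeans(xc^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- x - row_bcast(mu, nb)
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * row_bcast(inv_sd, nb)
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  v <- xhat * row_bcast(gv, nb) + row_bcast(bv, nb)
  tr <- a$track || gamma$track || beta$track
  ad_new(v, tr, backward = if (tr) function(g) {
    if (gamma$track) ad_acc(gamma, colSums(g * xhat))
    if (beta$track) ad_acc(beta, colSums(g))
    if (a$track) {
      dxhat <- g * row_bcast(gv, nb)
      if (training) {
        m1 <- colMeans(dxhat)
        m2 <- colMeans(dxhat * xhat)
        dx <- (dxhat - row_bcast(m1, nb) - xhat * row_bcast(m2, nb)) *
          row_bcast(inv_sd, nb)
      } else {
        dx <- dxhat * row_bcast(inv_sd, nb)
      }
      ad_acc(a, dx)
    }
  })
}

# Inverted dropout; the mask is drawn from the session RNG so runs are
# reproducible under set.seed().
ad_dropout <- function(a, rate, training = TRUE) {
  a <- ad_wrap(a)
  if (!training || rate <= 0) return(a)
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) < keep) / keep
  ad_new(a$value * mask, a$track,
         backward = if (a$track) function(g) ad_acc(a, g * mask))
}

# ---- optimiser --------------------------------------------------------------

# Adam over a named list of parameter arrays, operating on one flattened
# vector internally so the update is a handful of vectorised operations.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  lens <- vapply(params, length, integer(1))
  ends <- cumsum(lens)
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    lens = lens, starts = ends - lens + 1L, ends = ends,
    m = numeric(sum(lens)), v = numeric(sum(lens))
  )
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  nm <- names(params)
  gl <- vector("list", length(nm))
  for (k in seq_along(nm)) {
    g <- grads[[nm[k]]]
    gl[[k]] <- if (is.null(g)) numeric(state$lens[k]) else as.numeric(g)
  }
  gv <- unlist(gl, use.names = FALSE)
  pv <- unlist(params, use.names = FALSE)
  state$m <- state$beta1 * state$m + (1 - state$beta1) * gv
  state$v <- state$beta2 * state$v + (1 - state$beta2) * gv^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  pv <- pv - state$lr * mhat / (sqrt(vhat) + state$eps)
  for (k in seq_along(nm)) {
    newv <- pv[state$starts[k]:state$ends[k]]
    dim(newv) <- dim(params[[k]])
    params[[k]] <- newv
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
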