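# Shared fixtures and oracles, all generated in code.

# Random symmetric 0/1 adjacency slices with pairwise-disjoint support.
random_disjoint_tensor <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  tens <- array(0, dim = c(n, n, 3))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        l <- sample.int(3, 1)
        tens[i, j, l] <- 1
        tens[j, i, l] <- 1
      }
    }
  }
  tens
}

# Triple-loop evaluation of the mode-n product's scalar definition.
mode_n_oracle <- function(tensor, mat, mode) {
  dims <- dim(tensor)
  out_dims <- dims
  out_dims[mode] <- nrow(mat)
  out <- array(0, dim = out_dims)
  idx_grid <- expand.grid(lapply(out_dims, seq_len))
  for (r in seq_len(nrow(idx_grid))) {
    pos <- as.integer(idx_grid[r, ])
    acc <- 0
    for (k in seq_len(dims[mode])) {
      src <- pos
      src[mode] <- k
      acc <- acc + do.call(`[`, c(list(tensor), as.list(src))) * mat[pos[mode], k]
    }
    out[matrix(pos, 1)] <- acc
  }
  out
}

# Small synthetic study shared by several training tests.
tiny_study <- function(n_drugs = 8, n_cell_lines = 2, density = 1,
                       sigma = 0.1, seed = 42) {
  make_synthetic_study(synthetic_spec(
    n_drugs = n_drugs, n_cell_lines = n_cell_lines, density = density,
    sigma = sigma, n_genes = 30, seed = seed
  ))
}

# Fast training configuration for smoke tests.
tiny_config <- function(...) {
  synergy_config("desk", epochs = 5L, ...)
}

# Relative difference between analytic and finite-difference gradients,
# norm-based over the stacked parameter list.
gradcheck <- function(loss_fn, params, h = 1e-5) {
  got <- loss_fn(params)
  g_ad <- got$grads
  g_fd <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  for (k in names(params)) {
    for (i in seq_along(params[[k]])) {
      pp <- params; pp[[k]][i] <- pp[[k]][i] + h
      pm <- params; pm[[k]][i] <- pm[[k]][i] - h
      g_fd[[k]][i] <- (loss_fn(pp)$value - loss_fn(pm)$value) / (2 * h)
    }
  }
  va <- unlist(lapply(names(params), function(k) as.numeric(g_ad[[k]] %||% 0)))
  vf <- unlist(lapply(names(params), function(k) as.numeric(g_fd[[k]])))
  sqrt(sum((va - vf)^2)) / max(sqrt(sum(va^2)), sqrt(sum(vf^2)), 1e-10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
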