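test_that("edge-type convolution is the softmax-weighted slice combination", {
  tens <- random_disjoint_tensor(4, seed = 21)
  # saturated softmax picks out one slice
  w_sat <- matrix(c(1e6, 0, 0), 3, 1)
  q <- edge_type_conv(tens, w_sat)
  expect_lt(max(abs(q[, , 1] - tens[, , 1])), 1e-6)
  # all-zero weights average the three slices
  q0 <- edge_type_conv(tens, matrix(0, 3, 2))
  avg <- (tens[, , 1] + tens[, , 2] + tens[, , 3]) / 3
  expect_lt(max(abs(q0[, , 1] - avg)), 1e-12)
  expect_lt(max(abs(q0[, , 2] - avg)), 1e-12)
  # loop oracle for random weights
  set.seed(22)
  w <- matrix(stats::rnorm(6), 3, 2)
  q <- edge_type_conv(tens, w)
  sm <- apply(w, 2, function(col) exp(col) / sum(exp(col)))
  for (c in 1:2) {
    oracle <- matrix(0, 4, 4)
    for (t in 1:3) oracle <- oracle + sm[t, c] * tens[, , t]
    expect_lt(max(abs(q[, , c] - oracle)), 1e-10)
  }
  # convexity: entries stay inside the entrywise slice envelope
  lo <- pmin(tens[, , 1], tens[, , 2], tens[, , 3])
  hi <- pmax(tens[, , 1], tens[, , 2], tens[, , 3])
  expect_true(all(q[, , 1] >= lo - 1e-12 & q[, , 1] <= hi + 1e-12))
})

test_that("identity slices compose to the identity", {
  tens <- array(0, dim = c(4, 4, 3))
  for (l in 1:3) tens[, , l] <- diag(4)
  ec <- list(matrix(0, 3, 2), matrix(0, 3, 2), matrix(0, 3, 2))
  comp <- compose_adjacency(tens, ec)
  for (c in 1:2) expect_lt(max(abs(comp[, , c] - diag(4))), 1e-12)
})

test_that("composition equals the explicit chained normalized product", {
  tens <- random_disjoint_tensor(5, seed = 23)
  set.seed(24)
  ec <- lapply(1:3, function(l) matrix(stats::rnorm(6, sd = 0.5), 3, 2))
  comp <- compose_adjacency(tens, ec)  # L = 2, C = 2
  norm1 <- function(x) {
    d <- rowSums(abs(x)); d[d < 1e-12] <- 1; x / d
  }
  sm <- lapply(ec, function(w) apply(w, 2, function(col) exp(col) / sum(exp(col))))
  for (c in 1:2) {
    q <- lapply(sm, function(s) {
      s[1, c] * tens[, , 1] + s[2, c] * tens[, , 2] + s[3, c] * tens[, , 3]
    })
    oracle <- norm1(norm1(q[[1]] %*% q[[2]]) %*% q[[3]])
    expect_lt(max(abs(comp[, , c] - oracle)), 1e-8)
  }
  # recursion unrolling: L = 2 equals one more step applied to the L = 1 result
  comp1 <- compose_adjacency(tens, ec[1:2])
  for (c in 1:2) {
    q3 <- sm[[3]][1, c] * tens[, , 1] + sm[[3]][2, c] * tens[, , 2] +
      sm[[3]][3, c] * tens[, , 3]
    expect_lt(max(abs(comp[, , c] - norm1(comp1[, , c] %*% q3))), 1e-12)
  }
  # with binary symmetric slices the composed rows are sub-stochastic
  expect_true(all(rowSums(abs(comp[, , 1])) <= 1 + 1e-10))
})

test_that("graph convolution matches a row-by-row loop oracle", {
  tens <- random_disjoint_tensor(5, seed = 25)
  set.seed(26)
  ec <- lapply(1:2, function(l) matrix(stats::rnorm(6, sd = 0.3), 3, 2))
  comp <- compose_adjacency(tens, ec)
  X <- matrix(stats::rnorm(5 * 6), 5, 6)
  W <- matrix(stats::rnorm(6 * 3), 6, 3)
  Z <- gtn_embed(comp, X, W)
  for (c in 1:2) {
    a_tilde <- comp[, , c] + diag(5)
    oracle <- matrix(0, 5, 3)
    for (i in 1:5) {
      row <- a_tilde[i, ] / sum(abs(a_tilde[i, ]))
      oracle[i, ] <- pmax((row %*% X) %*% W, 0)
    }
    expect_lt(max(abs(Z[, , c] - oracle)), 1e-8)
  }
  # zero projection collapses the embedding to zero
  expect_true(all(gtn_embed(comp, X, W * 0) == 0))
  # isolated nodes (zero composite): self-loop only, a pure feature transform
  z_iso <- gtn_embed(array(0, dim = c(5, 5, 2)), X, W)
  expect_lt(max(abs(z_iso[, , 1] - pmax(X %*% W, 0))), 1e-10)
  expect_error(gtn_embed(comp, X * NA, W), "non-finite")
})

test_that("channel attention pooling matches the scalar oracle", {
  set.seed(27)
  n <- 4; d <- 3; C <- 3; h <- 5
  Z <- array(stats::rnorm(n * d * C), dim = c(n, d, C))
  params <- gtn_params(m = 2, d = d, C = C, L = 1, h = h, seed = 28)
  got <- channel_attention_pool(Z, params)
  scores <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (i in seq_len(n)) {
      acc <- acc + sum(params$attention_query *
                         tanh(Z[i, , c] %*% params$attention_proj +
                                params$attention_bias))
    }
    scores[c] <- acc / n
  }
  beta <- exp(scores) / sum(exp(scores))
  pooled <- matrix(0, n, d)
  for (c in seq_len(C)) pooled <- pooled + beta[c] * Z[, , c]
  expect_lt(max(abs(got$scores - scores)), 1e-10)
  expect_lt(max(abs(got$weights - beta)), 1e-10)
  expect_lt(max(abs(got$pooled - pooled)), 1e-10)
  expect_lt(abs(sum(got$weights) - 1), 1e-12)
  expect_true(all(got$weights > 0))
})

test_that("degenerate channel configurations pool as forced by symmetry", {
  set.seed(29)
  Z1 <- array(stats::rnorm(4 * 3), dim = c(4, 3, 1))
  p1 <- gtn_params(m = 2, d = 3, C = 1, L = 1, h = 4, seed = 30)
  got1 <- channel_attention_pool(Z1, p1)
  expect_equal(got1$weights, 1)
  expect_equal(got1$pooled, Z1[, , 1])
  # identical channels: uniform weights, pooled equals any channel
  Zc <- array(rep(Z1[, , 1], 3), dim = c(4, 3, 3))
  p3 <- gtn_params(m = 2, d = 3, C = 3, L = 1, h = 4, seed = 31)
  got3 <- channel_attention_pool(Zc, p3)
  expect_lt(max(abs(got3$weights - 1 / 3)), 1e-12)
  expect_lt(max(abs(got3$pooled - Z1[, , 1])), 1e-12)
})

test_that("global-local fusion is an exact block concatenation", {
  set.seed(32)
  U <- matrix(stats::rnorm(6 * 2), 6, 2)
  Z <- matrix(stats::rnorm(6 * 3), 6, 3)
  H <- fuse_global_local(U, Z)
  expect_equal(dim(H), c(6, 5))
  expect_equal(H[, 1:2], U)
  expect_equal(H[, 3:5], Z)
  H0 <- fuse_global_local(U * 0, Z)
  expect_true(all(H0[, 1:2] == 0))
  expect_equal(fuse_global_local(matrix(1, 1, 2), matrix(2, 1, 3)),
               matrix(c(1, 1, 2, 2, 2), 1))
  expect_error(fuse_global_local(U[1:3, ], Z), "mismatch")
})

test_that("softmax normalisation holds for every edge-conv layer", {
  p <- gtn_params(m = 4, d = 3, C = 2, L = 2, seed = 33)
  for (w in p$edge_conv) {
    sm <- apply(w, 2, function(col) exp(col) / sum(exp(col)))
    expect_lt(max(abs(colSums(sm) - 1)), 1e-12)
  }
})

test_that("the training-path forward agrees with the numeric pipeline", {
  tens <- random_disjoint_tensor(5, seed = 34)
  X <- matrix(stats::rnorm(5 * 7), 5, 7)
  p <- gtn_params(m = 7, d = 4, C = 2, L = 2, h = 3, seed = 35)
  z_num <- synergraph:::gtn_local_features(tens, X, p)
  nodes <- synergraph:::gtn_param_nodes(p)
  z_ad <- synergraph:::gtn_forward(tens, X, nodes, C = p$C, L = p$L)
  expect_lt(max(abs(z_ad$value - z_num)), 1e-12)
})

test_that("gradients of every parameter match central finite differences", {
  tens <- random_disjoint_tensor(4, seed = 36)
  X <- matrix(stats::rnorm(4 * 5), 4, 5)
  p <- gtn_params(m = 5, d = 3, C = 2, L = 1, h = 3, seed = 37)
  target <- matrix(0.3, 4, 3)
  flat <- c(stats::setNames(p$edge_conv, paste0("ec", seq_along(p$edge_conv))),
            list(proj = p$projection, attP = p$attention_proj,
                 attq = matrix(p$attention_query, ncol = 1),
                 attb = p$attention_bias))
  loss_fn <- function(fp) {
    synergraph:::ad_tape_begin()
    nodes <- list(
      edge_conv = lapply(fp[grep("^ec", names(fp))], synergraph:::ad_param),
      projection = synergraph:::ad_param(fp$proj),
      attention_proj = synergraph:::ad_param(fp$attP),
      attention_query = synergraph:::ad_param(fp$attq),
      attention_bias = synergraph:::ad_param(fp$attb)
    )
    out <- synergraph:::gtn_forward(tens, X, nodes, C = 2, L = 1)
    loss <- synergraph:::ad_mse(out, target)
    synergraph:::ad_backward(loss)
    synergraph:::ad_tape_end()
    grads <- c(lapply(nodes$edge_conv, function(n) n$grad),
               list(proj = nodes$projection$grad,
                    attP = nodes$attention_proj$grad,
                    attq = nodes$attention_query$grad,
                    attb = nodes$attention_bias$grad))
    names(grads)[seq_along(nodes$edge_conv)] <-
      paste0("ec", seq_along(nodes$edge_conv))
    list(value = loss$value, grads = grads)
  }
  expect_lt(gradcheck(loss_fn, flat), 1e-4)
})
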