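#' Mode-n unfolding of a tensor
#'
#' Flattens an N-way array into a matrix whose rows index the chosen mode. The
#' layout is the standard one: element `(i_1, ..., i_N)` lands in row `i_n` and
#' the remaining modes vary in increasing order, fastest first. For a
#' three-way `n x n x 3` interaction tensor this places entry `(i, j, k)` of
#' the mode-1 unfolding at row `i`, column `j + n (k - 1)`.
#'
#' @param tensor A numeric array.
#' @param mode Integer mode along which to unfold (1-based).
#' @return A matrix with `dim(tensor)[mode]` rows.
#' @seealso [fold_tensor()], [mode_n_product()]
#' @export
unfold_tensor <- function(tensor, mode) {
  dims <- dim(tensor)
  if (is.null(dims)) stop("`tensor` must be an array")
  if (mode < 1 || mode > length(dims)) stop("`mode` out of range")
  perm <- c(mode, seq_along(dims)[-mode])
  matrix(aperm(tensor, perm), nrow = dims[mode])
}

#' Fold a mode-n unfolding back into a tensor
#'
#' Inverse of [unfold_tensor()]: `fold_tensor(unfold_tensor(x, m), m, dim(x))`
#' recovers `x`.
#'
#' @param mat Matrix produced by (or shaped like) a mode-`mode` unfolding.
#' @param mode The mode that indexes the rows of `mat`.
#' @param dims Dimensions of the target tensor; `dims[mode]` must equal
#'   `nrow(mat)`.
#' @return An array with dimensions `dims`.
#' @export
fold_tensor <- function(mat, mode, dims) {
  if (nrow(mat) != dims[mode]) {
    stop(sprintf("row count %d does not match dims[%d] = %d",
                 nrow(mat), mode, dims[mode]))
  }
  perm <- c(mode, seq_along(dims)[-mode])
  arr <- array(mat, dim = dims[perm])
  aperm(arr, order(perm))
}

#' Mode-n tensor-matrix product
#'
#' Contracts mode `mode` of `tensor` against the columns of `mat`:
#' the output entry at position `(i_1, ..., j, ..., i_N)` equals
#' `sum_k tensor[i_1, ..., k, ..., i_N] * mat[j, k]`. The output extent along
#' `mode` becomes `nrow(mat)`.
#'
#' @param tensor A numeric array.
#' @param mat A matrix with `ncol(mat) == dim(tensor)[mode]`.
#' @param mode Which mode to contract.
#' @return An array.
#' @examples
#' x <- array(rnorm(24), dim = c(3, 4, 2))
#' m <- matrix(rnorm(20), 5, 4)
#' dim(mode_n_product(x, m, 2))  # 3 5 2
#' @export
mode_n_product <- function(tensor, mat, mode) {
  dims <- dim(tensor)
  if (is.null(dims)) stop("`tensor` must be an array")
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (ncol(mat) != dims[mode]) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but tensor extent along mode %d is %d",
      nrow(mat), ncol(mat), mode, dims[mode]
    ))
  }
  out_dims <- dims
  out_dims[mode] <- nrow(mat)
  fold_tensor(mat %*% unfold_tensor(tensor, mode), mode, out_dims)
}

# Deterministic sign convention: flip each column so its largest-magnitude
# entry is positive (ties broken by the first such entry).
fix_signs <- function(u) {
  if (ncol(u) == 0L) return(u)
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

# Leading left singular vectors of a matrix, sign-fixed; falls back to
# canonical identity columns when the matrix is (numerically) zero.
leading_left_sv <- function(mat, k, tol = 1e-12) {
  n <- nrow(mat)
  if (k > n) stop(sprintf("rank %d exceeds extent %d", k, n))
  s <- svd(mat, nu = min(n, ncol(mat)), nv = 0)
  u <- s$u
  nz <- sum(s$d > tol * max(s$d[1], 1))
  if (nz == 0L) return(diag(n)[, seq_len(k), drop = FALSE])
  if (ncol(u) < k) {
    # pad with an orthonormal completion for rank-deficient inputs
    u <- qr.Q(qr(cbind(u, diag(n))))[, seq_len(k), drop = FALSE]
  }
  fix_signs(u[, seq_len(k), drop = FALSE])
}

#' Tucker decomposition of a three-way interaction tensor
#'
#' Factorises an `n x n x 3` (or any three-way) tensor as a small core tensor
#' multiplied along each mode by an orthonormal factor matrix, via higher-order
#' SVD: each factor holds the leading left singular vectors of the matching
#' mode unfolding, and the core is the tensor contracted against the factor
#' transposes. An optional alternating refinement (higher-order orthogonal
#' iteration) can be enabled; the plain HOSVD is deterministic and
#' quasi-optimal, and is the default.
#'
#' The mode-1 factor is the per-drug global embedding used downstream: row
#' `i` summarises how drug `i` participates in synergistic, additive and
#' antagonistic interactions across all partners.
#'
#' @param tensor A numeric three-way array with finite entries.
#' @param ranks Integer vector of length 3, componentwise at most
#'   `dim(tensor)`.
#' @param method `"hosvd"` (default) or `"hooi"` for alternating refinement.
#' @param max_iter,tol Refinement controls (ignored for `"hosvd"`).
#' @return An object of class `tucker_factors`: list with `core`, `factors`
#'   (list `U`, `V`, `J`), and `ranks`.
#' @seealso [tucker_reconstruct()], [global_features()]
#' @export
tucker_decompose <- function(tensor, ranks, method = c("hosvd", "hooi"),
                             max_iter = 25L, tol = 1e-8) {
  method <- match.arg(method)
  dims <- dim(tensor)
  if (length(dims) != 3L) stop("`tensor` must be three-way")
  if (!all(is.finite(tensor))) stop("`tensor` contains non-finite entries")
  ranks <- as.integer(ranks)
  if (length(ranks) != 3L) stop("`ranks` must have length 3")
  if (any(ranks > dims)) {
    stop(sprintf("ranks (%s) exceed tensor extents (%s)",
                 paste(ranks, collapse = ","), paste(dims, collapse = ",")))
  }
  if (any(ranks < 1L)) stop("ranks must be >= 1")

  factors <- lapply(1:3, function(m) leading_left_sv(unfold_tensor(tensor, m), ranks[m]))

  if (method == "hooi") {
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      for (m in 1:3) {
        proj <- tensor
        for (o in setdiff(1:3, m)) {
          proj <- mode_n_product(proj, t(factors[[o]]), o)
        }
        factors[[m]] <- leading_left_sv(unfold_tensor(proj, m), ranks[m])
      }
      core <- project_core(tensor, factors)
      err <- sqrt(max(0, sum(tensor^2) - sum(core^2)))
      if (abs(err_prev - err) < tol * max(1, err_prev)) break
      err_prev <- err
    }
  }

  core <- project_core(tensor, factors)
  structure(
    list(core = core,
         factors = list(U = factors[[1]], V = factors[[2]], J = factors[[3]]),
         ranks = ranks),
    class = "tucker_factors"
  )
}

project_core <- function(tensor, factors) {
  core <- tensor
  for (m in 1:3) core <- mode_n_product(core, t(factors[[m]]), m)
  core
}

#' Reconstruct a tensor from its Tucker factors
#'
#' @param x A `tucker_factors` object.
#' @return The reconstructed array `core x1 U x2 V x3 J`.
#' @export
tucker_reconstruct <- function(x) {
  stopifnot(inherits(x, "tucker_factors"))
  out <- x$core
  fac <- list(x$factors$U, x$factors$V, x$factors$J)
  for (m in 1:3) out <- mode_n_product(out, fac[[m]], m)
  out
}

#' @export
print.tucker_factors <- function(x, ...) {
  cat(sprintf(
    "Tucker factors: core %s, mode factors %s x %d / %s x %d / %s x %d\n",
    paste(dim(x$core), collapse = " x "),
    nrow(x$factors$U), x$ranks[1],
    nrow(x$factors$V), x$ranks[2],
    nrow(x$factors$J), x$ranks[3]
  ))
  invisible(x)
}

#' @export
tidy.tucker_factors <- function(x, ...) {
  u <- x$factors$U
  tibble::tibble(
    drug = rep(seq_len(nrow(u)), times = ncol(u)),
    component = rep(seq_len(ncol(u)), each = nrow(u)),
    loading = as.numeric(u)
  )
}

#' Global drug embeddings from the interaction tensor
#'
#' Extracts the mode-1 factor of the stacked interaction tensor: the top
#' `R1` left singular vectors of the mode-1 unfolding (truncated SVD, the
#' default), or the mode-1 factor of a full Tucker decomposition. Columns are
#' orthonormal with a deterministic sign convention. An all-zero tensor (a
#' cell line with no recorded interactions) yields canonical identity columns.
#'
#' @param tensor The `n x n x 3` interaction tensor.
#' @param R1 Number of embedding dimensions, `1 <= R1 <= n`.
#' @param algorithm `"truncated_svd"` (default), `"hosvd"`, or `"hooi"`.
#' @return An `n x R1` matrix with orthonormal columns.
#' @export
global_features <- function(tensor, R1,
                            algorithm = c("truncated_svd", "hosvd", "hooi")) {
  algorithm <- match.arg(algorithm)
  dims <- dim(tensor)
  if (length(dims) != 3L) stop("`tensor` must be three-way")
  n <- dims[1]
  if (R1 < 1 || R1 > n) {
    stop(sprintf("R1 = %d must lie in [1, %d]", R1, n))
  }
  if (algorithm == "truncated_svd") {
    leading_left_sv(unfold_tensor(tensor, 1L), R1)
  } else {
    ranks <- c(R1, min(R1, dims[2]), min(3L, dims[3]))
    tucker_decompose(tensor, ranks, method = if (algorithm == "hooi") "hooi" else "hosvd")$factors$U
  }
}

#' Largest principal angle between two column spaces
#'
#' @param a,b Matrices whose column spans are compared (need not be
#'   orthonormal).
#' @return The largest principal angle, in degrees.
#' @export
subspace_angle <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  s <- pmin(pmax(s, -1), 1)
  acos(min(s)) * 180 / pi
}
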