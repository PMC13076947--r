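# Heavy-atom molecular graphs from SMILES, a featurizer, and a learnable
# graph-convolutional encoder with symmetric degree normalisation.

# Element vocabulary for the one-hot atom featurizer: common organic and
# pharmaceutical elements, with everything else bucketed as "other". Frozen
# for reproducibility.
atom_elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
                   "Si", "Se", "Na", "K", "Li", "Ca", "Mg", "Zn", "Fe", "As")
degree_buckets <- 0:4  # degree 4 bucket also holds >4

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Reads the organic subset of the OpenSMILES grammar: aliphatic and aromatic
#' organic-subset atoms, bracket atoms (charges and explicit hydrogens are
#' accepted and dropped), single/double/triple/aromatic bonds, branches, and
#' ring-bond closures (including `%nn`). Hydrogens are implicit: one node per
#' heavy atom, one undirected edge per bond. Aromaticity follows the SMILES
#' notation itself (lowercase atoms are aromatic).
#'
#' @param smiles A single SMILES string.
#' @return A `mol_graph`: list with `n_atoms`, `atom_symbols`, `aromatic`
#'   (logical), `adjacency` (symmetric 0/1 matrix), `atom_features` (one-hot
#'   matrix over element, degree bucket and aromatic flag), and `smiles`.
#' @examples
#' g <- smiles_to_graph("c1ccccc1")  # benzene: 6 atoms, 6 edges
#' sum(g$adjacency) / 2
#' @export
smiles_to_graph <- function(smiles) {
  if (length(smiles) != 1L || !is.character(smiles) || is.na(smiles)) {
    stop("`smiles` must be a single string")
  }
  chars <- strsplit(smiles, "")[[1]]
  if (length(chars) == 0L) stop("empty SMILES string")

  symbols <- character(0)
  aromatic <- logical(0)
  edges <- matrix(integer(0), ncol = 3)  # from, to, order
  prev_stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NA_integer_
  ring_open <- list()  # closure digit -> c(atom, bond order)

  add_atom <- function(sym, arom) {
    symbols <<- c(symbols, sym)
    aromatic <<- c(aromatic, arom)
    at <- length(symbols)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending_bond)) pending_bond else 1L
      edges <<- rbind(edges, c(prev, at, ord))
    }
    pending_bond <<- NA_integer_
    prev <<- at
  }

  close_ring <- function(key) {
    if (!is.null(ring_open[[key]])) {
      opened <- ring_open[[key]]
      ord <- if (!is.na(pending_bond)) pending_bond else opened[2]
      if (is.na(ord)) ord <- 1L
      edges <<- rbind(edges, c(opened[1], prev, ord))
      ring_open[[key]] <<- NULL
      pending_bond <<- NA_integer_
    } else {
      ring_open[[key]] <<- c(prev, if (!is.na(pending_bond)) pending_bond else NA_integer_)
      pending_bond <<- NA_integer_
    }
  }

  i <- 1L
  n_chars <- length(chars)
  while (i <= n_chars) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n_chars && chars[j] != "]") j <- j + 1L
      if (j > n_chars) stop("unbalanced bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      # strip isotope, charge, explicit H count, atom-map suffix
      m <- regmatches(body, regexec("^[0-9]*([A-Za-z][a-z]?)", body))[[1]]
      if (length(m) < 2L || m[2] == "") {
        stop("cannot read bracket atom '[", body, "]' in SMILES: ", smiles)
      }
      sym <- m[2]
      arom <- sym == tolower(sym) && toupper(substr(sym, 1, 1)) %in% c(atom_elements, "H")
      if (arom) sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      if (sym == "H") {  # explicit hydrogen atom: skip (implicit-H convention)
        i <- j + 1L
        next
      }
      add_atom(sym, arom)
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n_chars) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE)
        i <- i + 2L
      } else {
        add_atom(ch, FALSE)
        i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch == "-") { pending_bond <- 1L; i <- i + 1L
    } else if (ch == "=") { pending_bond <- 2L; i <- i + 1L
    } else if (ch == "#") { pending_bond <- 3L; i <- i + 1L
    } else if (ch == ":") { pending_bond <- 1L; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { i <- i + 1L  # stereo bonds: plain single
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in SMILES: ", smiles)
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n_chars) stop("truncated %nn ring closure in SMILES: ", smiles)
      close_ring(paste0(chars[i + 1], chars[i + 2]))
      i <- i + 3L
    } else if (ch == ".") {
      stop("multi-component SMILES are not supported: ", smiles)
    } else {
      stop("unrecognised SMILES character '", ch, "' in: ", smiles)
    }
  }
  if (length(prev_stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(ring_open) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  n <- length(symbols)
  if (n == 0L) stop("SMILES contains no heavy atoms: ", smiles)

  adjacency <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      adjacency[edges[e, 1], edges[e, 2]] <- 1
      adjacency[edges[e, 2], edges[e, 1]] <- 1
    }
  }
  structure(
    list(n_atoms = n, atom_symbols = symbols, aromatic = aromatic,
         adjacency = adjacency, bond_orders = edges,
         atom_features = atom_feature_matrix(symbols, aromatic, adjacency),
         smiles = smiles),
    class = "mol_graph"
  )
}

atom_feature_matrix <- function(symbols, aromatic, adjacency) {
  n <- length(symbols)
  n_elem <- length(atom_elements) + 1L
  n_deg <- length(degree_buckets)
  feat <- matrix(0, n, n_elem + n_deg + 1L)
  elem_idx <- match(symbols, atom_elements)
  elem_idx[is.na(elem_idx)] <- n_elem
  deg <- pmin(rowSums(adjacency), max(degree_buckets))
  for (i in seq_len(n)) {
    feat[i, elem_idx[i]] <- 1
    feat[i, n_elem + deg[i] + 1L] <- 1
    if (aromatic[i]) feat[i, n_elem + n_deg + 1L] <- 1
  }
  colnames(feat) <- c(atom_elements, "other",
                      paste0("deg", degree_buckets), "aromatic")
  feat
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, %d aromatic\n",
              x$smiles, x$n_atoms, sum(x$adjacency) / 2, sum(x$aromatic)))
  invisible(x)
}

#' Initialise molecular GCN parameters
#'
#' @param n_layers Number of graph-convolution layers.
#' @param d_out Output embedding dimension.
#' @param d_hidden Hidden width of intermediate layers.
#' @param seed Optional seed for reproducible initialisation.
#' @return A `gcn_params` object: list of layer weight matrices.
#' @export
gcn_params <- function(n_layers = 3L, d_out = 64L, d_hidden = d_out,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d_in <- length(atom_elements) + 1L + length(degree_buckets) + 1L
  dims <- c(d_in, rep(d_hidden, n_layers - 1L), d_out)
  weights <- lapply(seq_len(n_layers), function(l) {
    fan <- sqrt(2 / (dims[l] + dims[l + 1]))
    matrix(stats::rnorm(dims[l] * dims[l + 1], sd = fan), dims[l], dims[l + 1])
  })
  structure(list(weights = weights, n_layers = n_layers, dims = dims),
            class = "gcn_params")
}

# Symmetric-normalised propagation operator with self-loops:
# D~^{-1/2} (A + I) D~^{-1/2}.
gcn_propagator <- function(adjacency) {
  a_tilde <- adjacency + diag(nrow(adjacency))
  d_inv_sqrt <- 1 / sqrt(rowSums(a_tilde))
  a_tilde * outer(d_inv_sqrt, d_inv_sqrt)
}

# Constant per-molecule pieces, computed once and reused every training step.
mol_precompute <- function(graph) {
  list(prop = gcn_propagator(graph$adjacency),
       feats = graph$atom_features,
       pool = matrix(1 / graph$n_atoms, 1L, graph$n_atoms))
}

# All molecules batched into one block-diagonal propagation operator, so a
# whole GCN layer over every drug is a single matrix product. `pool` maps
# stacked atom rows back to one mean-pooled row per drug.
mol_block_precompute <- function(graphs) {
  sizes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  total <- sum(sizes)
  prop <- matrix(0, total, total)
  feats <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  pool <- matrix(0, length(graphs), total)
  off <- 0L
  for (k in seq_along(graphs)) {
    idx <- off + seq_len(sizes[k])
    prop[idx, idx] <- gcn_propagator(graphs[[k]]$adjacency)
    pool[k, idx] <- 1 / sizes[k]
    off <- off + sizes[k]
  }
  list(prop = prop, feats = feats, pool = pool)
}

# Tape-aware forward pass over precomputed molecule constants; weights may be
# ad nodes (training) or constants (inference). Returns the pooled 1 x d node.
gcn_forward <- function(pre, weights) {
  h <- ad_gcn_layer(pre$prop, ad_const(pre$feats), weights[[1]])
  if (length(weights) > 1L) {
    for (l in 2:length(weights)) h <- ad_gcn_layer(pre$prop, h, weights[[l]])
  }
  # global average pooling over atoms: (1/a) * 1^T H
  ad_matmul(ad_const(pre$pool), h)
}

#' Encode a molecular graph into a structure embedding
#'
#' Applies `n_layers` graph-convolution steps `H <- ReLU(S H W)` with the
#' symmetric-normalised, self-loop-augmented propagation operator
#' `S = D~^{-1/2} (A + I) D~^{-1/2}`, then global average pooling over atoms.
#' The result is invariant to atom reordering.
#'
#' @param graph A `mol_graph` from [smiles_to_graph()].
#' @param params A [gcn_params()] object.
#' @return A numeric vector of length `d_out`.
#' @export
gcn_encode <- function(graph, params) {
  stopifnot(inherits(graph, "mol_graph"), inherits(params, "gcn_params"))
  out <- gcn_forward(mol_precompute(graph), lapply(params$weights, ad_const))
  as.numeric(out$value)
}

#' Deterministic fallback fingerprint from hashed substructures
#'
#' A structural stand-in used when no pretrained fingerprint matrix is
#' supplied: circular substructure labels up to radius 2 (an atom's initial
#' label combines element, degree and aromaticity; each round appends the
#' sorted labels of its neighbours) are hashed into count buckets and
#' projected to `m` dimensions with a seeded Gaussian random projection.
#' Identical SMILES always map to identical vectors.
#'
#' @param smiles A SMILES string.
#' @param m Output dimension (default 300, matching the expected fingerprint
#'   width).
#' @param seed Seed for the shared projection matrix.
#' @param n_buckets Number of hash buckets before projection.
#' @return A numeric vector of length `m`.
#' @export
fallback_fingerprint <- function(smiles, m = 300L, seed = 42L,
                                 n_buckets = 1024L) {
  graph <- smiles_to_graph(smiles)
  # initial atom label: element | degree | aromatic | sorted incident bond
  # orders (the last distinguishes e.g. formaldehyde from methanol)
  bonds <- graph$bond_orders
  incident <- vapply(seq_len(graph$n_atoms), function(i) {
    ords <- c(bonds[bonds[, 1] == i, 3], bonds[bonds[, 2] == i, 3])
    paste(sort(ords), collapse = "")
  }, character(1))
  labels <- paste(graph$atom_symbols,
                  rowSums(graph$adjacency),
                  as.integer(graph$aromatic), incident, sep = "|")
  counts <- numeric(n_buckets)
  bump <- function(lbls) {
    for (lb in lbls) {
      b <- string_bucket(lb, n_buckets)
      counts[b] <<- counts[b] + 1
    }
  }
  bump(labels)
  current <- labels
  neighbours <- apply(graph$adjacency > 0, 1, which, simplify = FALSE)
  for (radius in 1:2) {
    current <- vapply(seq_len(graph$n_atoms), function(i) {
      # radix sort: byte-wise, independent of the session locale
      nb <- sort(current[neighbours[[i]]], method = "radix")
      paste0(radius, ":", current[i], "(", paste(nb, collapse = ","), ")")
    }, character(1))
    bump(current)
  }
  proj <- projection_matrix(n_buckets, m, seed)
  as.numeric(crossprod(proj, counts)) / sqrt(n_buckets)
}

# Polynomial string hash, exact in double precision, 1-based bucket.
string_bucket <- function(s, n_buckets) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1048573
  (h %% n_buckets) + 1L
}

# Cache one projection matrix per (n_buckets, m, seed); generated from an
# isolated RNG stream so callers' seeds are untouched.
.fp_cache <- new.env(parent = emptyenv())
projection_matrix <- function(n_buckets, m, seed) {
  key <- paste(n_buckets, m, seed, sep = "_")
  if (is.null(.fp_cache[[key]])) {
    rs <- .Random.seed_save()
    set.seed(seed)
    .fp_cache[[key]] <- matrix(stats::rnorm(n_buckets * m), n_buckets, m)
    .Random.seed_restore(rs)
  }
  .fp_cache[[key]]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  invisible(NULL)
}
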