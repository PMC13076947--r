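#' Build the heterogeneous drug-drug interaction graph for one cell line
#'
#' For a given cell line the observed drug pairs are labelled by the metric's
#' threshold scheme and split into three type-specific subgraphs —
#' synergistic, additive, antagonistic — each stored as a symmetric `n x n`
#' adjacency matrix over the full drug set (zero diagonal, disjoint edge
#' sets). In `"binary"` mode entries are 0/1; in `"score"` mode the entry
#' carries the continuous synergy score.
#'
#' `edge_source` restricts which records contribute edges. During
#' cross-validation the graphs are built from training-fold records only, so
#' no held-out pair leaks its label into the embeddings.
#'
#' @param dataset A [synergy_dataset()].
#' @param cell_line Cell-line identifier.
#' @param metric Metric column used both for scores and for labelling.
#' @param scheme Threshold scheme; defaults to the metric's published cuts.
#' @param edge_source Optional integer vector of record row indices allowed to
#'   contribute edges (default: all records).
#' @param edge_weights `"binary"` (default) or `"score"`.
#' @return A `hetero_graph`: list with `cell_line`, `n`, `adjacency` (list of
#'   three matrices, in the order synergistic / additive / antagonistic), and
#'   `edge_weights_mode`.
#' @export
build_cell_graph <- function(dataset, cell_line, metric = "loewe",
                             scheme = NULL, edge_source = NULL,
                             edge_weights = c("binary", "score")) {
  edge_weights <- match.arg(edge_weights)
  if (!cell_line %in% dataset$cell_lines) {
    stop("unknown cell line: ", cell_line)
  }
  if (!metric %in% names(dataset$records)) {
    stop("metric column not present in records: ", metric)
  }
  if (is.null(scheme)) scheme <- threshold_scheme(metric)
  n <- nrow(dataset$drugs)
  rec <- dataset$records
  idx <- seq_len(nrow(rec))
  if (!is.null(edge_source)) idx <- intersect(idx, edge_source)
  idx <- idx[rec$cell_line[idx] == cell_line & !is.na(rec[[metric]][idx])]

  adj <- replicate(3, matrix(0, n, n), simplify = FALSE)
  names(adj) <- interaction_levels[c(3, 2, 1)]  # synergistic, additive, antagonistic
  if (length(idx) > 0) {
    i <- drug_index(dataset, rec$drug_i[idx])
    j <- drug_index(dataset, rec$drug_j[idx])
    if (any(is.na(i)) || any(is.na(j))) {
      stop("record references a drug missing from the dataset drug list")
    }
    score <- rec[[metric]][idx]
    lab <- label_interaction(score, scheme)
    slice <- match(as.character(lab), c("synergistic", "additive", "antagonistic"))
    w <- if (edge_weights == "binary") rep(1, length(idx)) else score
    for (k in seq_along(idx)) {
      adj[[slice[k]]][i[k], j[k]] <- w[k]
      adj[[slice[k]]][j[k], i[k]] <- w[k]
    }
  }
  structure(
    list(cell_line = cell_line, n = n, adjacency = adj,
         edge_weights_mode = edge_weights, metric = metric),
    class = "hetero_graph"
  )
}

#' @export
print.hetero_graph <- function(x, ...) {
  counts <- vapply(x$adjacency, function(a) sum(a != 0) / 2, numeric(1))
  cat(sprintf(
    "<hetero_graph %s> %d drugs | edges: %d synergistic, %d additive, %d antagonistic (%s)\n",
    x$cell_line, x$n, counts[1], counts[2], counts[3], x$edge_weights_mode
  ))
  invisible(x)
}

#' Stack a heterogeneous graph into a three-way interaction tensor
#'
#' Frontal slice `l` of the returned `n x n x 3` array equals the `l`-th
#' type-specific adjacency matrix, in the fixed order synergistic, additive,
#' antagonistic.
#'
#' @param graph A `hetero_graph`.
#' @return A numeric `n x n x 3` array.
#' @seealso [unstack_tensor()]
#' @export
stack_tensor <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  arr <- array(0, dim = c(graph$n, graph$n, 3L))
  for (l in 1:3) arr[, , l] <- graph$adjacency[[l]]
  arr
}

#' Recover a heterogeneous graph from an interaction tensor
#'
#' Inverse of [stack_tensor()] up to metadata.
#'
#' @param tensor An `n x n x 3` array.
#' @param cell_line Identifier to attach.
#' @param edge_weights Mode flag to attach.
#' @return A `hetero_graph`.
#' @export
unstack_tensor <- function(tensor, cell_line = "unknown",
                           edge_weights = "binary") {
  stopifnot(length(dim(tensor)) == 3L, dim(tensor)[3] == 3L)
  adj <- lapply(1:3, function(l) tensor[, , l])
  names(adj) <- c("synergistic", "additive", "antagonistic")
  structure(
    list(cell_line = cell_line, n = dim(tensor)[1], adjacency = adj,
         edge_weights_mode = edge_weights, metric = NA_character_),
    class = "hetero_graph"
  )
}

#' Export a heterogeneous graph as an edge-list tibble
#'
#' One row per undirected edge with columns `drug_i`, `drug_j` (indices),
#' `type` and `weight`; suitable for writing as delimited text.
#'
#' @param graph A `hetero_graph`.
#' @return A tibble.
#' @export
graph_edge_list <- function(graph) {
  out <- purrr::map_dfr(names(graph$adjacency), function(type) {
    a <- graph$adjacency[[type]]
    idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
    tibble::tibble(
      drug_i = idx[, 1], drug_j = idx[, 2],
      type = type, weight = a[idx]
    )
  })
  dplyr::arrange(out, .data$type, .data$drug_i, .data$drug_j)
}
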