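metric_names <- c("loewe", "bliss", "zip", "hsa")

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a synergy table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header)
#' with columns `drug_i`, `drug_j`, `cell_line` and at least one synergy
#' metric column among `loewe`, `bliss`, `zip`, `hsa`. Drug pairs are
#' unordered: each record is canonicalised so `drug_i` sorts before `drug_j`,
#' and replicate measurements of the same (pair, cell line) triplet are
#' aggregated.
#'
#' @param path Path to the delimited file.
#' @param duplicate How to reduce replicate triplets: arithmetic `"mean"`
#'   (default), `"median"`, `"first"`, or `"error"` to refuse duplicates.
#' @return A tibble of canonical synergy records, one row per unordered
#'   (drug pair, cell line) triplet.
#' @seealso [write_synergy_table()], [synergy_dataset()]
#' @export
read_synergy_table <- function(path,
                               duplicate = c("mean", "median", "first", "error")) {
  duplicate <- match.arg(duplicate)
  delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("drug_i", "drug_j", "cell_line")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("synergy table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  metrics <- intersect(metric_names, names(raw))
  if (length(metrics) == 0) {
    stop("synergy table has no metric column (expected one of: ",
         paste(metric_names, collapse = ", "), ")")
  }
  for (m in metrics) {
    vals <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- which(!is.na(raw[[m]]) & raw[[m]] != "" & is.na(vals))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric %s score at data row(s) %s (e.g. '%s')",
                   m, paste(utils::head(bad, 5), collapse = ", "),
                   raw[[m]][bad[1]]))
    }
    raw[[m]] <- vals
  }
  if (any(raw$drug_i == raw$drug_j)) {
    bad <- which(raw$drug_i == raw$drug_j)
    stop("self-combination (drug_i == drug_j) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  records <- canonicalize_records(
    dplyr::select(raw, dplyr::all_of(c(required, metrics))),
    duplicate = duplicate
  )
  records
}

canonicalize_records <- function(records, duplicate = "mean") {
  metrics <- intersect(metric_names, names(records))
  # order the pair endpoints byte-wise (locale-independent)
  lv <- sort(unique(c(records$drug_i, records$drug_j)), method = "radix")
  ri <- match(records$drug_i, lv)
  rj <- match(records$drug_j, lv)
  swap <- ri > rj
  a <- ifelse(swap, records$drug_j, records$drug_i)
  b <- ifelse(swap, records$drug_i, records$drug_j)
  records$drug_i <- a
  records$drug_j <- b
  key <- paste(a, b, records$cell_line, sep = "\r")
  if (anyDuplicated(key)) {
    if (duplicate == "error") {
      stop("duplicate (drug_i, drug_j, cell_line) triplets present")
    }
    agg <- switch(duplicate,
      mean = function(x) mean(x, na.rm = TRUE),
      median = function(x) stats::median(x, na.rm = TRUE),
      first = function(x) x[!is.na(x)][1]
    )
    records <- records |>
      dplyr::group_by(.data$drug_i, .data$drug_j, .data$cell_line) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(metrics),
                                     ~ agg(.x)), .groups = "drop")
    for (m in metrics) records[[m]][is.nan(records[[m]])] <- NA_real_
  }
  dplyr::arrange(tibble::as_tibble(records),
                 .data$cell_line, .data$drug_i, .data$drug_j)
}

#' Write a synergy table
#'
#' Writes records in the canonical comma-delimited layout accepted by
#' [read_synergy_table()]; writing then reading is an identity on canonical
#' tables.
#'
#' @param records Tibble of synergy records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synergy_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a drug table (id, SMILES)
#'
#' @param path Delimited text with columns `drug_id` and `smiles`.
#' @return A tibble with one row per drug.
#' @export
read_drug_table <- function(path) {
  delim <- detect_delim(path)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("drug_id", "smiles") %in% names(tbl))) {
    stop("drug table must have columns drug_id and smiles")
  }
  if (anyDuplicated(tbl$drug_id)) stop("duplicate drug_id in drug table")
  tibble::as_tibble(tbl[, c("drug_id", "smiles")])
}

#' Read a delimited numeric matrix with an index column
#'
#' Shared reader for fingerprint matrices (drugs x features) and expression
#' matrices (cell lines x genes). The first column is taken as the row index.
#'
#' @param path Delimited text file.
#' @return A numeric matrix with rownames from the index column.
#' @export
read_feature_matrix <- function(path) {
  delim <- detect_delim(path)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  idx <- tbl[[1]]
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    mode(mat) <- "numeric"
    if (any(is.na(mat))) stop("non-numeric entries in feature matrix ", path)
  }
  rownames(mat) <- as.character(idx)
  mat
}

#' Write a numeric matrix with an index column
#'
#' @param mat Matrix with rownames.
#' @param path Output path.
#' @param index_name Name for the index column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(mat, path, index_name = "id") {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  tbl <- tibble::as_tibble(mat, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(!!index_name := rownames(mat)), tbl)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Assemble a synergy dataset
#'
#' Bundles the four input tables into one validated object: canonical synergy
#' records, the drug list with SMILES, a per-drug fingerprint matrix, and a
#' per-cell-line expression matrix. Every record must resolve against the drug
#' and cell-line indices. When no fingerprint matrix is supplied, the
#' deterministic structural fallback featurizer ([fallback_fingerprint()]) is
#' used, with a warning, since hashed substructure fingerprints are not
#' comparable to pretrained embeddings.
#'
#' @param records Tibble from [read_synergy_table()] (or built in code).
#' @param drugs Tibble with `drug_id`, `smiles`.
#' @param fingerprints Optional numeric matrix, one row per drug (rownames =
#'   drug ids).
#' @param expression Numeric matrix, one row per cell line (rownames = cell
#'   line ids).
#' @param fingerprint_dim Dimension for the fallback featurizer when
#'   `fingerprints` is `NULL`.
#' @return A `synergy_dataset` object.
#' @export
synergy_dataset <- function(records, drugs, fingerprints = NULL, expression,
                            fingerprint_dim = 300L) {
  records <- canonicalize_records(tibble::as_tibble(records))
  drugs <- tibble::as_tibble(drugs)
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)))
  used <- unique(c(records$drug_i, records$drug_j))
  unknown <- setdiff(used, drugs$drug_id)
  if (length(unknown) > 0) {
    stop("records reference drugs absent from the drug table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  unknown_cl <- setdiff(unique(records$cell_line), rownames(expression))
  if (length(unknown_cl) > 0) {
    stop("records reference cell lines absent from the expression matrix: ",
         paste(utils::head(unknown_cl, 5), collapse = ", "))
  }
  if (is.null(fingerprints)) {
    warning("no fingerprint matrix supplied; using the hashed-substructure ",
            "fallback featurizer (not comparable to pretrained fingerprints)")
    fingerprints <- t(vapply(
      drugs$smiles,
      function(s) fallback_fingerprint(s, m = fingerprint_dim),
      numeric(fingerprint_dim)
    ))
    rownames(fingerprints) <- drugs$drug_id
  }
  miss_fp <- setdiff(drugs$drug_id, rownames(fingerprints))
  if (length(miss_fp) > 0) {
    stop("fingerprint matrix is missing drugs: ",
         paste(utils::head(miss_fp, 5), collapse = ", "))
  }
  fingerprints <- fingerprints[drugs$drug_id, , drop = FALSE]
  cell_lines <- rownames(expression)
  structure(
    list(records = records, drugs = drugs, fingerprints = fingerprints,
         cell_lines = cell_lines, expression = expression),
    class = "synergy_dataset"
  )
}

#' @export
print.synergy_dataset <- function(x, ...) {
  metrics <- intersect(metric_names, names(x$records))
  cat(sprintf(
    "<synergy_dataset> %d records | %d drugs | %d cell lines | metrics: %s\n",
    nrow(x$records), nrow(x$drugs), length(x$cell_lines),
    paste(metrics, collapse = ", ")
  ))
  invisible(x)
}

#' Available metric columns of a dataset
#' @param dataset A `synergy_dataset`.
#' @return Character vector of metric column names present.
#' @export
dataset_metrics <- function(dataset) {
  intersect(metric_names, names(dataset$records))
}

# Integer drug index of each record endpoint, against the dataset drug order.
drug_index <- function(dataset, ids) {
  match(ids, dataset$drugs$drug_id)
}

#' Write the four dataset tables to a directory
#'
#' Emits `synergy.csv`, `drugs.csv`, `fingerprints.csv` and `expression.csv`
#' in the formats the readers accept.
#'
#' @param dataset A `synergy_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_synergy_table(dataset$records, file.path(dir, "synergy.csv"))
  readr::write_csv(dataset$drugs, file.path(dir, "drugs.csv"), progress = FALSE)
  write_feature_matrix(dataset$fingerprints, file.path(dir, "fingerprints.csv"),
                       index_name = "drug_id")
  write_feature_matrix(dataset$expression, file.path(dir, "expression.csv"),
                       index_name = "cell_line")
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the four standard tables.
#' @return A `synergy_dataset`.
#' @export
read_dataset <- function(dir) {
  synergy_dataset(
    records = read_synergy_table(file.path(dir, "synergy.csv")),
    drugs = read_drug_table(file.path(dir, "drugs.csv")),
    fingerprints = read_feature_matrix(file.path(dir, "fingerprints.csv")),
    expression = read_feature_matrix(file.path(dir, "expression.csv"))
  )
}
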