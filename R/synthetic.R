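# Self-contained synthetic studies with the statistical structure the model
# assumes: low-rank multi-relational interaction tensors, bilinear
# latent-factor synergy surfaces with drug and cell-line main effects, toy
# SMILES, hashed-substructure fingerprints and Gaussian expression profiles.

#' Packaged toy SMILES
#'
#' A fixed list of valid single-component SMILES for common small molecules,
#' used to populate synthetic studies without any external chemistry input.
#'
#' @return A character vector of length >= 50.
#' @export
toy_smiles <- function() {
  c(
    "C", "CC", "CCC", "CCCC", "CC(C)C", "CCO", "CC(=O)O", "C=O", "C#N",
    "CO", "CCN", "CCCl", "CBr", "CI", "CC=O", "CC(C)=O", "CCOCC", "COC",
    "C=C", "C#C", "CC#N", "OCC(O)CO", "C(Cl)(Cl)Cl", "CS", "CCS", "CSC",
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
    "Clc1ccccc1", "Brc1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
    "c1cc[nH]c1", "c1cnc[nH]1", "Cc1ccncc1", "COc1ccccc1",
    "CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Nc1ccc(O)cc1", "OC(=O)c1ccccc1",
    "NC(=O)c1ccccc1", "O=Cc1ccccc1", "CC(=O)c1ccccc1", "OCc1ccccc1",
    "N#Cc1ccccc1", "CN(C)C", "CCCCCC", "C1CCCCC1", "C1CCNCC1", "C1CCOC1",
    "C1CCOCC1", "OC1CCCCC1", "O=C1CCCCC1", "NC1CCCCC1", "CC1CCCCC1",
    "CCOC(=O)C", "CC(O)C", "OCCO", "NCCO", "NCCN", "OC(=O)CC(=O)O",
    "CC(N)C(=O)O", "NCC(=O)O", "CNC", "CCNCC", "C1CC1", "C1CCC1", "C1CCCC1"
  )
}

#' Specify a synthetic synergy study
#'
#' The generator plants the structure the model is designed to recover. The
#' continuous score of pair (i, j) in cell line r combines drug main effects
#' (linear in the drugs' fingerprints), a cell-line shift (linear in its
#' expression profile), and a bilinear interaction `u_i' Lambda_r u_j` of
#' per-drug latent vectors through a symmetric per-cell-line loading, with
#' relative weights set by the `main_effect_weight` and `interaction_weight`
#' fields. The combined signal is standardized,
#' Gaussian noise of sd `sigma` added, and the result affinely mapped onto the
#' metric's score scale so the published cuts reproduce `class_props`
#' (defaults follow the observed composition of a large oncology screen:
#' about 8.7% synergistic, 53.2% additive, 38.1% antagonistic under Loewe).
#'
#' @param n_drugs,n_cell_lines Study size.
#' @param metric Metric column to generate (its scheme drives the rescaling).
#' @param latent_dim Dimension of the planted per-drug latent vectors.
#' @param sigma Noise sd relative to the unit-variance signal.
#' @param class_props Target proportions, in the order antagonistic /
#'   additive / synergistic.
#' @param density Fraction of all (pair, cell line) triplets observed.
#' @param n_genes Expression profile length.
#' @param m Fingerprint dimension.
#' @param main_effect_weight,interaction_weight Relative sd of the additive
#'   and bilinear signal parts.
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 20L, n_cell_lines = 3L, metric = "loewe",
                           latent_dim = 4L, sigma = 0.1,
                           class_props = c(antagonistic = 0.381,
                                           additive = 0.532,
                                           synergistic = 0.087),
                           density = 0.8, n_genes = 100L, m = 300L,
                           main_effect_weight = 1, interaction_weight = 0.5,
                           seed = 1L) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  if (abs(sum(class_props) - 1) > 1e-8) stop("class_props must sum to 1")
  if (n_drugs > length(toy_smiles())) {
    stop("n_drugs exceeds the packaged toy SMILES list (",
         length(toy_smiles()), ")")
  }
  structure(
    list(n_drugs = as.integer(n_drugs), n_cell_lines = as.integer(n_cell_lines),
         metric = metric, latent_dim = as.integer(latent_dim), sigma = sigma,
         class_props = class_props, density = density,
         n_genes = as.integer(n_genes), m = as.integer(m),
         main_effect_weight = main_effect_weight,
         interaction_weight = interaction_weight, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a planted low-rank interaction tensor
#'
#' Draws orthonormal factors and a random core, forms
#' `G x1 U x2 V x3 J + noise`, and symmetrises the frontal slices. With
#' `symmetric = TRUE` (default) the mode-2 factor equals the mode-1 factor
#' and the core is symmetric in its first two modes, so slices are exactly
#' symmetric and the mode-1 subspace is recoverable; the returned truth
#' carries the planted factors for recovery tests.
#'
#' @param n Drug count.
#' @param ranks Planted ranks `(R1, R2, R3)` with `R3 <= 3`.
#' @param sigma Entrywise Gaussian noise sd.
#' @param seed RNG seed.
#' @param symmetric Plant a slice-symmetric tensor (default).
#' @return List with `tensor` (`n x n x 3`) and `truth` (planted `U`, `V`,
#'   `J`, `core`).
#' @export
make_planted_tensor <- function(n, ranks = c(4L, 4L, 3L), sigma = 0.01,
                                seed = 1L, symmetric = TRUE) {
  ranks <- as.integer(ranks)
  if (length(ranks) != 3L || any(ranks < 1L)) stop("ranks must be 3 positive integers")
  if (ranks[1] > n || ranks[2] > n || ranks[3] > 3L) {
    stop("ranks exceed tensor extents")
  }
  set.seed(seed)
  U <- qr.Q(qr(matrix(stats::rnorm(n * ranks[1]), n, ranks[1])))
  V <- if (symmetric && ranks[2] == ranks[1]) U else {
    qr.Q(qr(matrix(stats::rnorm(n * ranks[2]), n, ranks[2])))
  }
  J <- qr.Q(qr(matrix(stats::rnorm(3L * ranks[3]), 3L, ranks[3])))
  core <- array(stats::rnorm(prod(ranks)), dim = ranks)
  if (symmetric && ranks[2] == ranks[1]) {
    for (k in seq_len(ranks[3])) core[, , k] <- (core[, , k] + t(core[, , k])) / 2
  }
  tensor <- mode_n_product(mode_n_product(mode_n_product(core, U, 1), V, 2), J, 3)
  if (sigma > 0) {
    tensor <- tensor + array(stats::rnorm(length(tensor), sd = sigma),
                             dim = dim(tensor))
  }
  for (k in 1:3) tensor[, , k] <- (tensor[, , k] + t(tensor[, , k])) / 2
  list(tensor = tensor,
       truth = list(U = U, V = V, J = J, core = core, ranks = ranks,
                    sigma = sigma))
}

#' Generate a synthetic synergy study
#'
#' Builds a complete [synergy_dataset()] plus the generating truth from a
#' [synthetic_spec()]: toy SMILES drugs, fallback fingerprints, Gaussian
#' expression with per-cell-line mean shifts, and continuous synergy scores
#' from the planted main-effect + bilinear surface described in
#' [synthetic_spec()].
#'
#' @param spec A `synthetic_spec`.
#' @return List with `dataset` and `truth` (planted latents, loadings, signal
#'   parts, labels and per-class counts).
#' @export
make_synthetic_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_drugs
  R <- spec$n_cell_lines
  smiles <- toy_smiles()[seq_len(n)]
  drug_ids <- sprintf("drug_%02d", seq_len(n))
  cell_ids <- sprintf("cl_%02d", seq_len(R))

  fingerprints <- t(vapply(smiles, fallback_fingerprint, numeric(spec$m),
                           m = spec$m))
  rownames(fingerprints) <- drug_ids

  shift <- stats::rnorm(R)
  expression <- matrix(stats::rnorm(R * spec$n_genes), R, spec$n_genes) + shift
  rownames(expression) <- cell_ids
  colnames(expression) <- sprintf("g%03d", seq_len(spec$n_genes))

  # planted structure
  q <- spec$latent_dim
  u <- matrix(stats::rnorm(n * q), n, q)
  lambda <- lapply(seq_len(R), function(r) {
    l <- matrix(stats::rnorm(q * q), q, q)
    (l + t(l)) / 2
  })
  w_fp <- stats::rnorm(spec$m) / sqrt(spec$m)
  w_expr <- stats::rnorm(spec$n_genes) / sqrt(spec$n_genes)
  a_drug <- as.numeric(scale(fingerprints %*% w_fp))
  c_cell <- as.numeric(expression %*% w_expr)
  if (R > 1) c_cell <- as.numeric(scale(c_cell))

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  grid <- tidyr::expand_grid(pair = seq_len(nrow(pairs)), r = seq_len(R))
  i <- pairs[grid$pair, 1]
  j <- pairs[grid$pair, 2]
  r <- grid$r
  main_part <- (a_drug[i] + a_drug[j] + c_cell[r]) / sqrt(3)
  inter_part <- vapply(seq_along(i), function(t) {
    u[i[t], ] %*% lambda[[r[t]]] %*% u[j[t], ]
  }, numeric(1))
  inter_part <- inter_part / stats::sd(inter_part)
  signal <- spec$main_effect_weight * main_part +
    spec$interaction_weight * inter_part
  signal <- signal / stats::sd(signal)
  score_raw <- signal + stats::rnorm(length(signal), sd = spec$sigma)

  # observe a density fraction of triplets
  n_obs <- max(1L, floor(spec$density * length(score_raw)))
  keep <- sort(sample.int(length(score_raw), n_obs))

  # affine map onto the metric scale so the published cuts yield the target
  # class proportions
  scheme <- threshold_scheme(spec$metric)
  p_ant <- spec$class_props[["antagonistic"]]
  p_syn <- spec$class_props[["synergistic"]]
  q_lo <- stats::quantile(score_raw[keep], p_ant, names = FALSE)
  q_hi <- stats::quantile(score_raw[keep], 1 - p_syn, names = FALSE)
  slope <- (scheme$synergy_min - scheme$additive_low) / (q_hi - q_lo)
  score <- scheme$additive_low + (score_raw - q_lo) * slope

  records <- tibble::tibble(
    drug_i = drug_ids[i[keep]], drug_j = drug_ids[j[keep]],
    cell_line = cell_ids[r[keep]]
  )
  records[[spec$metric]] <- score[keep]

  labels <- label_interaction(score[keep], scheme)
  dataset <- synergy_dataset(
    records = records,
    drugs = tibble::tibble(drug_id = drug_ids, smiles = smiles),
    fingerprints = fingerprints,
    expression = expression
  )
  truth <- list(
    spec = spec, latents = u, loadings = lambda,
    drug_effects = a_drug, cell_effects = c_cell,
    signal = signal[keep], noise_sd = spec$sigma,
    observed = keep, labels = labels,
    # per-triplet truth rows are in generator order; dataset records are
    # re-sorted canonically, so join on the triplet key when aligning
    triplets = tibble::tibble(drug_i = drug_ids[i[keep]],
                              drug_j = drug_ids[j[keep]],
                              cell_line = cell_ids[r[keep]],
                              score = score[keep], label = labels),
    class_counts = table(labels), scheme = scheme,
    score_slope = slope
  )
  list(dataset = dataset, truth = truth)
}
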