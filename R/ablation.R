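#' Component ablation study
#'
#' Trains and evaluates the six component configurations of the progressive
#' exclusion design — full model; without the molecular GCN (A); without A
#' and Tucker; without A and the graph transformer; without Tucker and the
#' graph transformer; without all three (fingerprint + expression MLPs only)
#' — under one shared fold assignment, optionally averaged over several
#' training seeds. The comparison table carries MSE, RMSE, the 95% t-interval
#' of the fold MSEs, and PCC.
#'
#' @param dataset A [synergy_dataset()].
#' @param metric Metric to predict.
#' @param config A [synergy_config()].
#' @param k Folds for the shared assignment (default 3; each configuration is
#'   trained on each fold's complement and scored on the fold).
#' @param seeds Integer vector of training seeds to average over.
#' @return An `ablation_report`: tibble with one row per configuration,
#'   plus per-seed detail in `attr(, "detail")`.
#' @export
run_ablation <- function(dataset, metric = "loewe",
                         config = synergy_config("desk"), k = 3L,
                         seeds = config$seed) {
  configs <- list(
    "full" = all_components,
    "w/o A" = c("tucker_global", "gtn_local"),
    "w/o A&Tucker" = "gtn_local",
    "w/o A&GTN" = "tucker_global",
    "w/o Tucker&GTN" = "molecular_gcn",
    "w/o A&Tucker&GTN" = character(0)
  )
  scores <- dataset$records[[metric]]
  usable <- which(!is.na(scores))
  labs <- label_interaction(scores[usable], threshold_scheme(metric))
  fold_of <- rep(NA_integer_, nrow(dataset$records))
  fold_of[usable] <- stratified_kfold(as.character(labs), k = k,
                                      seed = config$seed)
  detail <- purrr::map_dfr(names(configs), function(nm) {
    purrr::map_dfr(seeds, function(s) {
      cfg <- config
      cfg$seed <- s
      cv <- cross_validate(dataset, metric = metric, config = cfg,
                           components = configs[[nm]], folds = fold_of)
      g <- glance(cv)
      tibble::tibble(configuration = nm, seed = s,
                     mse = g$mse_mean, rmse = g$rmse_mean,
                     ci_lo = g$mse_ci_lo, ci_hi = g$mse_ci_hi,
                     pcc = g$pcc_mean)
    })
  })
  report <- detail |>
    dplyr::group_by(.data$configuration) |>
    dplyr::summarise(
      mse = mean(.data$mse), rmse = mean(.data$rmse),
      ci_lo = mean(.data$ci_lo), ci_hi = mean(.data$ci_hi),
      pcc = mean(.data$pcc), .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$configuration, names(configs)))
  attr(report, "detail") <- detail
  class(report) <- c("ablation_report", class(report))
  report
}

#' Empirical training-cost scaling probe
#'
#' Measures per-epoch wall time while the number of training triplets grows
#' (drug and cell-line counts fixed), then reports the R-squared of a linear
#' fit of time against sample count. Informational: absolute times depend on
#' the machine, but the per-sample cost of an epoch should scale linearly
#' once graph-side costs are fixed.
#'
#' @param sample_sizes Integer vector of triplet counts to probe.
#' @param n_drugs,n_cell_lines Fixed study shape.
#' @param config Training configuration (only a few epochs are timed).
#' @param epochs Epochs to time per point.
#' @param seed Study seed.
#' @return A `scaling_probe` tibble (`n_samples`, `sec_per_epoch`) with the
#'   linear-fit R-squared in `attr(, "r_squared")`.
#' @export
scaling_probe <- function(sample_sizes, n_drugs = 20L, n_cell_lines = 3L,
                          config = synergy_config("desk", epochs = 3L),
                          epochs = config$epochs, seed = 1L) {
  max_triplets <- n_drugs * (n_drugs - 1) / 2 * n_cell_lines
  if (any(sample_sizes > max_triplets)) {
    stop("sample size exceeds available triplets (", max_triplets, ")")
  }
  config$epochs <- as.integer(epochs)
  res <- purrr::map_dfr(sample_sizes, function(ns) {
    spec <- synthetic_spec(n_drugs = n_drugs, n_cell_lines = n_cell_lines,
                           density = ns / max_triplets, seed = seed)
    study <- make_synthetic_study(spec)
    elapsed <- system.time(
      train_synergy_model(study$dataset, metric = spec$metric, config = config)
    )[["elapsed"]]
    tibble::tibble(n_samples = nrow(study$dataset$records),
                   sec_per_epoch = elapsed / config$epochs)
  })
  fit <- stats::lm(sec_per_epoch ~ n_samples, data = res)
  attr(res, "r_squared") <- summary(fit)$r.squared
  class(res) <- c("scaling_probe", class(res))
  res
}
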