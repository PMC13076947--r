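# End-to-end synergy regression: four modality MLPs (expression, molecular
# structure, fingerprints, graph-derived interaction features), concatenation,
# and a three-layer prediction head, trained jointly with the molecular GCN
# and the per-cell-line graph transformers under an MSE objective.

#' Training and model configuration
#'
#' Bundles every tunable of the pipeline. Named presets carry the published
#' per-dataset training settings (`"oneil"`/`"cloud"`: dropout 0.2, 200
#' epochs; `"almanac"`: no dropout, 500 epochs); the `"desk"` preset scales
#' widths and epochs down for small synthetic studies. Any field can be
#' overridden through `...`.
#'
#' Key fields: `d` (graph transformer embedding size, default 32), `C`
#' (channels, default 2), `L` (meta-path composition layers), `R1` (Tucker
#' mode-1 rank, capped at the drug count), `d_s` (molecular embedding size),
#' `latent`/`hidden` (modality MLP sizes), `pred_hidden` (prediction head
#' widths), `lr` (Adam learning rate, default 0.001), `epochs`, `dropout`,
#' `batch_size`, `symmetric_augmentation` (train and evaluate on both pair
#' orderings), `edge_policy` (`"train_only"` builds interaction graphs from
#' training-fold records so held-out labels cannot leak; `"all"` uses every
#' record), `edge_weights` (`"binary"` or `"score"`), and `seed`.
#'
#' @param preset One of `"desk"`, `"oneil"`, `"cloud"`, `"almanac"`.
#' @param ... Field overrides.
#' @return A `synergy_config` list.
#' @export
synergy_config <- function(preset = c("oneil", "cloud", "almanac", "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    d = 32L, C = 2L, L = 2L, h = 32L,
    R1 = 32L, gcn_layers = 3L, d_s = 64L,
    latent = 128L, hidden = 256L, pred_hidden = c(256L, 64L),
    lr = 0.001, epochs = 200L, dropout = 0.2, batch_size = 256L,
    symmetric_augmentation = TRUE,
    edge_policy = "train_only", edge_weights = "binary",
    duplicate = "mean", seed = 1L, preset = preset
  )
  tweaks <- switch(preset,
    oneil = list(),
    cloud = list(),
    almanac = list(dropout = 0, epochs = 500L),
    desk = list(epochs = 150L, lr = 0.005, dropout = 0, R1 = 8L,
                hidden = 32L, latent = 16L, pred_hidden = c(48L, 24L),
                d_s = 16L, gcn_layers = 2L, batch_size = 1024L)
  )
  cfg[names(tweaks)] <- tweaks
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown config field(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "synergy_config")
}

all_components <- c("molecular_gcn", "tucker_global", "gtn_local")

check_components <- function(components) {
  bad <- setdiff(components, all_components)
  if (length(bad) > 0) stop("unknown component(s): ", paste(bad, collapse = ", "))
  components
}

# ---- parameter construction -------------------------------------------------

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
fan_avg <- function(nr, nc) sqrt(2 / (nr + nc))

mlp2_params <- function(prefix, d_in, hidden, latent) {
  p <- list(
    rnorm_mat(d_in, hidden, fan_avg(d_in, hidden)), numeric(hidden),
    rep(1, hidden), numeric(hidden),
    rnorm_mat(hidden, latent, fan_avg(hidden, latent)), numeric(latent)
  )
  names(p) <- paste0(prefix, c(".W1", ".b1", ".g1", ".be1", ".W2", ".b2"))
  p
}

init_fusion_params <- function(ctx) {
  cfg <- ctx$config
  params <- list()
  if ("molecular_gcn" %in% ctx$components) {
    gp <- gcn_params(cfg$gcn_layers, cfg$d_s)
    for (l in seq_along(gp$weights)) params[[paste0("gcn.", l)]] <- gp$weights[[l]]
  }
  if (ctx$use_h) {
    for (r in seq_along(ctx$cell_lines)) {
      if ("gtn_local" %in% ctx$components) {
        gt <- gtn_params(ctx$m, cfg$d, cfg$C, cfg$L, cfg$h)
        for (l in seq_along(gt$edge_conv)) {
          params[[paste0("gtn.", r, ".ec", l)]] <- gt$edge_conv[[l]]
        }
        params[[paste0("gtn.", r, ".proj")]] <- gt$projection
        params[[paste0("gtn.", r, ".attP")]] <- gt$attention_proj
        params[[paste0("gtn.", r, ".attq")]] <- matrix(gt$attention_query, ncol = 1)
        params[[paste0("gtn.", r, ".attb")]] <- gt$attention_bias
      }
    }
  }
  params <- c(params, mlp2_params("mg", ctx$G, cfg$hidden, cfg$latent))
  if ("molecular_gcn" %in% ctx$components) {
    params <- c(params, mlp2_params("ms", cfg$d_s, cfg$hidden, cfg$latent))
  }
  params <- c(params, mlp2_params("mx", ctx$m, cfg$hidden, cfg$latent))
  if (ctx$use_h) {
    params <- c(params, mlp2_params("mh", ctx$in_h, cfg$hidden, cfg$latent))
  }
  z_dim <- cfg$latent * (1L + 2L * (("molecular_gcn" %in% ctx$components) + 1L +
                                      ctx$use_h))
  ph <- cfg$pred_hidden
  pred <- list(
    rnorm_mat(z_dim, ph[1], fan_avg(z_dim, ph[1])), numeric(ph[1]),
    rep(1, ph[1]), numeric(ph[1]),
    rnorm_mat(ph[1], ph[2], fan_avg(ph[1], ph[2])), numeric(ph[2]),
    rep(1, ph[2]), numeric(ph[2]),
    rnorm_mat(ph[2], 1, fan_avg(ph[2], 1)), numeric(1)
  )
  names(pred) <- paste0("pr", c(".W1", ".b1", ".g1", ".be1",
                                ".W2", ".b2", ".g2", ".be2", ".W3", ".b3"))
  c(params, pred)
}

bn_state_new <- function(width) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(width)
  st$running_var <- rep(1, width)
  st
}

init_bn_states <- function(ctx) {
  cfg <- ctx$config
  states <- list(mg = bn_state_new(cfg$hidden), mx = bn_state_new(cfg$hidden),
                 pr1 = bn_state_new(cfg$pred_hidden[1]),
                 pr2 = bn_state_new(cfg$pred_hidden[2]))
  if ("molecular_gcn" %in% ctx$components) states$ms <- bn_state_new(cfg$hidden)
  if (ctx$use_h) states$mh <- bn_state_new(cfg$hidden)
  states
}

# ---- forward pass -----------------------------------------------------------

selector <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# Constant per-batch inputs, built once per batch (and only once per training
# run in the full-batch regime).
prepare_batch <- function(ctx, rows) {
  b <- list(rows = rows,
            g_in = ctx$exprs[rows$cl, , drop = FALSE],
            x_i = ctx$X[rows$i, , drop = FALSE],
            x_j = ctx$X[rows$j, , drop = FALSE])
  if ("molecular_gcn" %in% ctx$components) {
    b$sel_i <- selector(rows$i, ctx$n)
    b$sel_j <- selector(rows$j, ctx$n)
  }
  if (ctx$use_h) {
    nh <- ctx$n * length(ctx$cell_lines)
    b$sel_hi <- selector((rows$cl - 1L) * ctx$n + rows$i, nh)
    b$sel_hj <- selector((rows$cl - 1L) * ctx$n + rows$j, nh)
  }
  b
}

mlp2_forward <- function(x, pn, prefix, state, training) {
  h <- ad_affine(x, pn[[paste0(prefix, ".W1")]], pn[[paste0(prefix, ".b1")]])
  h <- ad_batch_norm(h, pn[[paste0(prefix, ".g1")]], pn[[paste0(prefix, ".be1")]],
                     state, training = training)
  h <- ad_relu(h)
  ad_affine(h, pn[[paste0(prefix, ".W2")]], pn[[paste0(prefix, ".b2")]])
}

gtn_nodes_for <- function(pn, r, L) {
  list(
    edge_conv = lapply(seq_len(L + 1L), function(l) pn[[paste0("gtn.", r, ".ec", l)]]),
    projection = pn[[paste0("gtn.", r, ".proj")]],
    attention_proj = pn[[paste0("gtn.", r, ".attP")]],
    attention_query = pn[[paste0("gtn.", r, ".attq")]],
    attention_bias = pn[[paste0("gtn.", r, ".attb")]]
  )
}

# Build the prediction node for a prepared batch of triplets (see
# prepare_batch()). Everything constant comes from ctx and the batch;
# parameters arrive as a named list of nodes.
fusion_forward <- function(pn, ctx, batch, bn, training) {
  cfg <- ctx$config
  comp <- ctx$components
  blocks <- list()

  blocks$g <- mlp2_forward(ad_const(batch$g_in), pn, "mg", bn$mg, training)

  if ("molecular_gcn" %in% comp) {
    hmol <- ad_gcn_layer(ctx$mol_block$prop, ad_const(ctx$mol_block$feats),
                         pn[["gcn.1"]])
    if (cfg$gcn_layers > 1L) {
      for (l in 2:cfg$gcn_layers) {
        hmol <- ad_gcn_layer(ctx$mol_block$prop, hmol, pn[[paste0("gcn.", l)]])
      }
    }
    S_all <- ad_matmul(ad_const(ctx$mol_block$pool), hmol)
    s_i <- ad_matmul(ad_const(batch$sel_i), S_all)
    s_j <- ad_matmul(ad_const(batch$sel_j), S_all)
    blocks$s_i <- mlp2_forward(s_i, pn, "ms", bn$ms, training)
    blocks$s_j <- mlp2_forward(s_j, pn, "ms", bn$ms, training)
  }

  blocks$x_i <- mlp2_forward(ad_const(batch$x_i), pn, "mx", bn$mx, training)
  blocks$x_j <- mlp2_forward(ad_const(batch$x_j), pn, "mx", bn$mx, training)

  if (ctx$use_h) {
    h_blocks <- lapply(seq_along(ctx$cell_lines), function(r) {
      parts <- list()
      if ("tucker_global" %in% comp) parts <- c(parts, list(ad_const(ctx$U[[r]])))
      if ("gtn_local" %in% comp) {
        parts <- c(parts, list(gtn_forward(ctx$tensors[[r]], ctx$X,
                                           gtn_nodes_for(pn, r, cfg$L),
                                           C = cfg$C, L = cfg$L)))
      }
      if (length(parts) == 1L) parts[[1]] else ad_cbind(parts)
    })
    H_all <- ad_rbind(h_blocks)
    h_i <- ad_matmul(ad_const(batch$sel_hi), H_all)
    h_j <- ad_matmul(ad_const(batch$sel_hj), H_all)
    blocks$h_i <- mlp2_forward(h_i, pn, "mh", bn$mh, training)
    blocks$h_j <- mlp2_forward(h_j, pn, "mh", bn$mh, training)
  }

  # concatenation order: g', s_i', s_j', x_i', x_j', h_i', h_j'
  order_keys <- intersect(c("g", "s_i", "s_j", "x_i", "x_j", "h_i", "h_j"),
                          names(blocks))
  z <- ad_cbind(blocks[order_keys])

  h1 <- ad_affine(z, pn[["pr.W1"]], pn[["pr.b1"]])
  h1 <- ad_batch_norm(h1, pn[["pr.g1"]], pn[["pr.be1"]], bn$pr1, training)
  h1 <- ad_dropout(ad_relu(h1), cfg$dropout, training)
  h2 <- ad_affine(h1, pn[["pr.W2"]], pn[["pr.b2"]])
  h2 <- ad_batch_norm(h2, pn[["pr.g2"]], pn[["pr.be2"]], bn$pr2, training)
  h2 <- ad_dropout(ad_relu(h2), cfg$dropout, training)
  ad_affine(h2, pn[["pr.W3"]], pn[["pr.b3"]])
}

augment_rows <- function(rows, y = NULL) {
  out <- list(i = c(rows$i, rows$j), j = c(rows$j, rows$i),
              cl = c(rows$cl, rows$cl))
  if (!is.null(y)) out$y <- c(y, y)
  out
}

# ---- training ---------------------------------------------------------------

build_model_context <- function(dataset, metric, config, train_idx, components) {
  scheme <- threshold_scheme(metric)
  n <- nrow(dataset$drugs)
  use_h <- any(c("tucker_global", "gtn_local") %in% components)
  R1_eff <- min(n, config$R1)
  tensors <- NULL
  U <- NULL
  if (use_h) {
    edge_source <- if (config$edge_policy == "train_only") train_idx else NULL
    tensors <- lapply(dataset$cell_lines, function(cl) {
      stack_tensor(build_cell_graph(dataset, cl, metric = metric,
                                    scheme = scheme, edge_source = edge_source,
                                    edge_weights = config$edge_weights))
    })
    if ("tucker_global" %in% components) {
      U <- lapply(tensors, global_features, R1 = R1_eff)
    }
  }
  in_h <- R1_eff * ("tucker_global" %in% components) +
    config$d * ("gtn_local" %in% components)
  list(
    config = config, components = components, scheme = scheme, metric = metric,
    n = n, m = ncol(dataset$fingerprints), G = ncol(dataset$expression),
    cell_lines = dataset$cell_lines,
    exprs = dataset$expression, X = dataset$fingerprints,
    mol_block = if ("molecular_gcn" %in% components) {
      mol_block_precompute(lapply(dataset$drugs$smiles, smiles_to_graph))
    } else NULL,
    tensors = tensors, U = U, use_h = use_h, in_h = in_h,
    R1_eff = R1_eff, drug_ids = dataset$drugs$drug_id
  )
}

record_rows <- function(dataset, idx) {
  list(
    i = drug_index(dataset, dataset$records$drug_i[idx]),
    j = drug_index(dataset, dataset$records$drug_j[idx]),
    cl = match(dataset$records$cell_line[idx], dataset$cell_lines)
  )
}

#' Train the synergy prediction model
#'
#' Builds per-cell-line interaction graphs from the training records, extracts
#' global (Tucker) features, and jointly trains the graph transformers, the
#' molecular GCN and the fusion MLPs with Adam on a standardized-score MSE
#' loss. The Tucker factors are computed once and kept fixed (no gradients
#' flow through the SVD); everything else trains end-to-end. With symmetric
#' pair augmentation each training triplet is presented in both orderings.
#'
#' @param dataset A [synergy_dataset()].
#' @param metric Which synergy metric to predict.
#' @param config A [synergy_config()].
#' @param train_idx Integer record rows used for training (and for graph
#'   construction under the default leakage policy); defaults to all records
#'   with a non-missing score.
#' @param components Character subset of
#'   `c("molecular_gcn", "tucker_global", "gtn_local")`; removing one drops
#'   the corresponding feature block (ablation).
#' @return A `synergy_model`.
#' @export
train_synergy_model <- function(dataset, metric = "loewe",
                                config = synergy_config(),
                                train_idx = NULL,
                                components = all_components) {
  components <- check_components(components)
  stopifnot(inherits(dataset, "synergy_dataset"))
  if (!metric %in% names(dataset$records)) stop("metric not in records: ", metric)
  scores <- dataset$records[[metric]]
  if (is.null(train_idx)) train_idx <- seq_len(nrow(dataset$records))
  train_idx <- train_idx[!is.na(scores[train_idx])]
  if (length(train_idx) == 0L) stop("empty training fold")

  set.seed(config$seed)
  ctx <- build_model_context(dataset, metric, config, train_idx, components)
  params <- init_fusion_params(ctx)
  bn <- init_bn_states(ctx)
  opt <- adam_init(params, lr = config$lr)

  y <- scores[train_idx]
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  y_std <- (y - y_center) / y_scale
  rows <- record_rows(dataset, train_idx)

  n_train <- length(train_idx)
  batch_size <- min(config$batch_size, n_train)
  full_batch <- batch_size >= n_train
  if (full_batch) {
    br <- rows
    by <- y_std
    if (config$symmetric_augmentation) {
      aug <- augment_rows(br, by)
      br <- aug; by <- aug$y
    }
    batch_cache <- prepare_batch(ctx, br)
    y_cache <- by
  }
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    if (full_batch) {
      batches <- list(list(batch = batch_cache, y = y_cache, n = n_train))
    } else {
      ord <- sample.int(n_train)
      batches <- lapply(split(ord, ceiling(seq_along(ord) / batch_size)),
                        function(b) {
        br <- list(i = rows$i[b], j = rows$j[b], cl = rows$cl[b])
        by <- y_std[b]
        if (config$symmetric_augmentation) {
          aug <- augment_rows(br, by)
          br <- aug; by <- aug$y
        }
        list(batch = prepare_batch(ctx, br), y = by, n = length(b))
      })
    }
    ep_loss <- 0
    for (bt in batches) {
      ad_tape_begin(4096L)
      pn <- lapply(params, ad_param)
      pred <- fusion_forward(pn, ctx, bt$batch, bn, training = TRUE)
      loss <- ad_mse(pred, bt$y)
      ad_backward(loss)
      ad_tape_end()
      if (!is.finite(loss$value)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }
      grads <- lapply(pn, function(nd) nd$grad)
      upd <- adam_step(params, grads, opt)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss$value * bt$n
    }
    history[epoch] <- ep_loss / n_train * y_scale^2
  }

  structure(
    list(params = params, bn = bn, ctx = ctx, metric = metric,
         scheme = ctx$scheme, components = components, config = config,
         y_center = y_center, y_scale = y_scale,
         loss_history = tibble::tibble(epoch = seq_len(config$epochs),
                                       mse = history),
         train_idx = train_idx),
    class = "synergy_model"
  )
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf(
    "<synergy_model %s> %d drugs, %d cell lines | components: %s | final training MSE %.4g\n",
    x$metric, x$ctx$n, length(x$ctx$cell_lines),
    paste(x$components, collapse = "+"),
    utils::tail(x$loss_history$mse, 1)
  ))
  invisible(x)
}

#' Predict synergy scores for drug pair / cell line triplets
#'
#' Evaluation-mode forward pass (batch normalisation uses running statistics,
#' dropout off). Under symmetric augmentation the two pair orderings are both
#' evaluated and averaged, so predictions are order-invariant.
#'
#' @param object A `synergy_model`.
#' @param newdata Tibble with columns `drug_i`, `drug_j`, `cell_line`;
#'   defaults to the training records.
#' @param ... Unused.
#' @return `newdata` with a `y_hat` column appended.
#' @export
predict.synergy_model <- function(object, newdata = NULL, ...) {
  ctx <- object$ctx
  if (is.null(newdata)) stop("supply `newdata` with drug_i, drug_j, cell_line")
  newdata <- tibble::as_tibble(newdata)
  i <- match(newdata$drug_i, ctx$drug_ids)
  j <- match(newdata$drug_j, ctx$drug_ids)
  cl <- match(newdata$cell_line, ctx$cell_lines)
  if (any(is.na(i)) || any(is.na(j))) stop("unknown drug id in newdata")
  if (any(is.na(cl))) stop("unknown cell line in newdata")
  rows <- list(i = i, j = j, cl = cl)
  pn <- lapply(object$params, ad_const)
  pred <- fusion_forward(pn, ctx, prepare_batch(ctx, rows), object$bn,
                         training = FALSE)$value
  if (object$config$symmetric_augmentation) {
    rows_sw <- list(i = j, j = i, cl = cl)
    pred_sw <- fusion_forward(pn, ctx, prepare_batch(ctx, rows_sw), object$bn,
                              training = FALSE)$value
    pred <- (pred + pred_sw) / 2
  }
  newdata$y_hat <- as.numeric(pred) * object$y_scale + object$y_center
  newdata
}

#' Mean squared error of paired observations and predictions
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return The mean of squared residuals.
#' @export
mse_loss <- function(y, y_hat) {
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(y_hat)) stop("length mismatch")
  mean((y - y_hat)^2)
}

#' @export
tidy.synergy_model <- function(x, ...) x$loss_history

#' @export
glance.synergy_model <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    components = paste(x$components, collapse = "+"),
    epochs = x$config$epochs,
    n_train = length(x$train_idx),
    final_mse = utils::tail(x$loss_history$mse, 1)
  )
}

# ---- cross-validation -------------------------------------------------------

#' Stratified k-fold cross-validation of the synergy model
#'
#' Assigns records to folds stratified on the three-class threshold label of
#' the target metric (spreading rare synergistic cases across folds), trains
#' one model per fold on the remaining records — interaction graphs included,
#' so no held-out label leaks into the fold's embeddings — and evaluates
#' regression and classification metrics on the held-out fold.
#'
#' @param dataset A [synergy_dataset()].
#' @param metric Metric to predict.
#' @param k Number of folds (default 10).
#' @param config A [synergy_config()].
#' @param components Feature components (see [train_synergy_model()]).
#' @param folds Optional pre-computed fold vector (overrides `k`).
#' @return A `synergy_cv` object: per-fold metrics, pooled predictions, and
#'   the fold assignment.
#' @export
cross_validate <- function(dataset, metric = "loewe", k = 10L,
                           config = synergy_config(),
                           components = all_components, folds = NULL) {
  scores <- dataset$records[[metric]]
  usable <- which(!is.na(scores))
  if (is.null(folds)) {
    labs <- label_interaction(scores[usable], threshold_scheme(metric))
    fold_of <- rep(NA_integer_, nrow(dataset$records))
    fold_of[usable] <- stratified_kfold(as.character(labs), k = k,
                                        seed = config$seed)
  } else {
    fold_of <- folds
    k <- max(folds, na.rm = TRUE)
  }
  scheme <- threshold_scheme(metric)
  preds <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- setdiff(usable, test_idx)
    model <- train_synergy_model(dataset, metric = metric, config = config,
                                 train_idx = train_idx,
                                 components = components)
    test_tbl <- dataset$records[test_idx,
                                c("drug_i", "drug_j", "cell_line", metric)]
    names(test_tbl)[4] <- "y"
    out <- predict(model, test_tbl)
    out$fold <- f
    preds[[f]] <- out
    reg <- regression_metrics(out$y, out$y_hat)
    clf <- classification_metrics(
      binarize_labels(label_interaction(out$y, scheme)),
      out$y_hat, threshold = scheme$synergy_min
    )
    fold_metrics[[f]] <- tibble::tibble(
      fold = f, n_test = nrow(out),
      mse = reg$mse, rmse = reg$rmse, pcc = reg$pcc,
      auc = clf$auc, aupr = clf$aupr, acc = clf$acc, f1 = clf$f1,
      kappa = clf$kappa
    )
  }
  fold_metrics <- dplyr::bind_rows(fold_metrics)
  structure(
    list(metric = metric, k = k, fold_assignment = fold_of,
         fold_metrics = fold_metrics,
         predictions = dplyr::bind_rows(preds),
         mse_ci = mse_confidence_interval(fold_metrics$mse),
         config = config, components = components),
    class = "synergy_cv"
  )
}

#' @export
print.synergy_cv <- function(x, ...) {
  s <- glance(x)
  cat(sprintf(
    "<synergy_cv %s, %d folds> MSE %.4g +/- %.3g | RMSE %.4g | PCC %.3f | AUC %.3f\n",
    x$metric, x$k, s$mse_mean, s$mse_sd, s$rmse_mean, s$pcc_mean, s$auc_mean
  ))
  cat(sprintf("  95%% CI of MSE: [%.4g, %.4g]\n", x$mse_ci["lo"], x$mse_ci["hi"]))
  invisible(x)
}

#' @export
tidy.synergy_cv <- function(x, ...) x$fold_metrics

#' @export
glance.synergy_cv <- function(x, ...) {
  fm <- x$fold_metrics
  tibble::tibble(
    metric = x$metric, k = x$k,
    mse_mean = mean(fm$mse), mse_sd = stats::sd(fm$mse),
    rmse_mean = mean(fm$rmse), rmse_sd = stats::sd(fm$rmse),
    pcc_mean = mean(fm$pcc, na.rm = TRUE),
    auc_mean = mean(fm$auc, na.rm = TRUE),
    aupr_mean = mean(fm$aupr, na.rm = TRUE),
    acc_mean = mean(fm$acc), f1_mean = mean(fm$f1, na.rm = TRUE),
    kappa_mean = mean(fm$kappa, na.rm = TRUE),
    mse_ci_lo = x$mse_ci["lo"], mse_ci_hi = x$mse_ci["hi"]
  )
}

#' Per-cell-line metric breakdown of a cross-validation run
#'
#' @param cv A `synergy_cv`.
#' @return A tibble of pooled regression metrics per cell line.
#' @export
cell_line_breakdown <- function(cv) {
  cv$predictions |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(
      n = dplyr::n(),
      mse = mean((.data$y - .data$y_hat)^2),
      rmse = sqrt(mean((.data$y - .data$y_hat)^2)),
      pcc = if (stats::sd(.data$y) > 0 && stats::sd(.data$y_hat) > 0)
        stats::cor(.data$y, .data$y_hat) else NA_real_,
      .groups = "drop"
    )
}
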