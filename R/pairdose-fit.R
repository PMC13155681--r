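#' Fit the hybrid global-local dose-response model
#'
#' The main entry point. Trains the global synergy network end-to-end on the
#' combination table (drug CNN + sinusoidal dose embedding + expression MLP
#' + dense head, MSE loss), then trains the learnable aggregator on the
#' global model's held-out validation slice, where each validation sample
#' receives both a global prediction and a local (retrieval + per-query
#' GCN) prediction. The returned object predicts new (drug, drug, dose,
#' dose, cell) tuples with [predict.pairdose()], combining both routes and
#' degenerating exactly to the global model whenever no local information
#' exists.
#'
#' @param combo Combo table `data.frame` (columns `drug1`, `drug2`, `dose1`,
#'   `dose2`, `cell`, `response`; see [read_combo_table()]).
#' @param drugs Drug library `data.frame` (`drug_id`, `smiles`).
#' @param cells Numeric expression matrix, `rownames` = cell ids.
#' @param mono Optional monotherapy table (enables the Bliss fallback).
#' @param global A [global_model_config()].
#' @param local A [local_gcn_config()].
#' @param aggregator An [aggregator_config()].
#' @param mono_scale Scale of `mono` responses (`"fraction"` or
#'   `"percent"`).
#' @return An object of class `pairdose` with components `global`
#'   (the trained [train_global()] model), `aggregator`, `local_config`,
#'   the training tables, and the matched call.
#' @seealso [run_experiment()] for scenario-based cross-validation of the
#'   same pipeline.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_drugs = 4, n_cells = 2, seed = 7))
#' fit <- pairdose(ds$combo, ds$drugs, ds$expression, mono = ds$mono,
#'                 global = global_model_config(epochs = 5))
#' predict(fit, ds$combo[1:3, ])
#' @export
pairdose <- function(combo, drugs, cells, mono = NULL,
                     global = global_model_config(),
                     local = local_gcn_config(),
                     aggregator = aggregator_config(),
                     mono_scale = c("fraction", "percent")) {
  mono_scale <- match.arg(mono_scale)
  cl <- match.call()
  gm <- train_global(combo, drugs, cells, global)

  agg <- if (length(gm$val_idx) > 0L && aggregator$mode == "learned-mlp") {
    val_df <- combo[gm$val_idx, , drop = FALSE]
    vp <- predict_global(gm, val_df)
    vpairs <- local_prediction_table(gm, val_df, combo, mono, "auto", local,
                                     mono_scale, "gcn",
                                     sub_seed(local$seed, 500000L), vp)
    suppressWarnings(train_aggregator(vpairs, aggregator))
  } else {
    suppressWarnings(train_aggregator(
      data.frame(global_pred = numeric(0), local_pred = numeric(0),
                 local_available = logical(0), k = integer(0),
                 response = numeric(0)), aggregator))
  }

  structure(list(global = gm, aggregator = agg, local_config = local,
                 combo = combo, mono = mono, drugs = drugs, cells = cells,
                 mono_scale = mono_scale, call = cl),
            class = "pairdose")
}

#' Predict dose-responses for new drug-dose-cell tuples
#'
#' For each row of `newdata`: the global network produces a prediction; the
#' local path retrieves same-pair/same-cell measurements (falling back to
#' the Bliss pseudo-curve, then to feature-similarity retrieval, under
#' `local = "auto"`), builds the dose-neighborhood graph and trains the
#' per-query GCN; the aggregator fuses the two. Queries without local
#' information receive the global prediction exactly.
#'
#' @param object A fitted [pairdose()] model.
#' @param newdata Combo table rows to predict (the `response` column is not
#'   required).
#' @param local Local-path mode: `"auto"`, `"exact"`, `"bliss"`,
#'   `"feature"`, or `"off"`.
#' @param details If `TRUE`, return a `data.frame` with the query fields,
#'   `global_pred`, `local_pred`, `local_source`, `k` and `final_pred`
#'   instead of the bare prediction vector.
#' @param ... Unused.
#' @return Numeric vector of final predictions (or a details data frame).
#' @export
predict.pairdose <- function(object, newdata,
                             local = c("auto", "exact", "bliss", "feature", "off"),
                             details = FALSE, ...) {
  local <- match.arg(local)
  if (!"response" %in% names(newdata)) newdata$response <- NA_real_
  gp <- predict_global(object$global, newdata)
  pairs <- local_prediction_table(object$global, newdata, object$combo,
                                  object$mono, local, object$local_config,
                                  object$mono_scale, "gcn",
                                  object$local_config$seed, gp)
  final <- aggregate_predictions(pairs, object$aggregator)
  if (!details) return(final)
  cbind(newdata[, c("drug1", "drug2", "dose1", "dose2", "cell"), drop = FALSE],
        data.frame(global_pred = pairs$global_pred,
                   local_pred = pairs$local_pred,
                   local_source = pairs$local_source, k = pairs$k,
                   final_pred = final))
}

#' @export
print.pairdose <- function(x, ...) {
  cat("Hybrid global-local dose-response model\n")
  cat("  training samples:", nrow(x$combo),
      " drugs:", nrow(x$drugs),
      " cell lines:", nrow(x$cells), "\n")
  cat("  global: drug CNN ->", x$global$config$drug$out_dim,
      "dims; dose embedding ->", x$global$config$dose$dim,
      "dims; cell MLP ->", x$global$config$cell$out_dim, "dims\n")
  cat("  epochs run:", nrow(x$global$log), "\n")
  cat("  aggregator mode:", x$aggregator$cfg$mode,
      if (is.null(x$aggregator$par) && x$aggregator$cfg$mode == "learned-mlp")
        "(identity: no local pairs seen)" else "", "\n")
  invisible(x)
}

#' @export
summary.pairdose <- function(object, ...) {
  res <- residuals(object)
  log <- object$global$log
  out <- list(
    n = nrow(object$combo),
    training_mse = mean(res^2),
    training_pcc = tryCatch(pearson_cc(fitted(object), object$combo$response),
                            error = function(e) NA_real_),
    final_epoch = nrow(log),
    final_train_mse = log$train_mse[nrow(log)],
    best_val_mse = if (all(is.na(log$val_mse))) NA_real_ else
      min(log$val_mse, na.rm = TRUE),
    aggregator_mode = object$aggregator$cfg$mode
  )
  class(out) <- "summary.pairdose"
  out
}

#' @export
print.summary.pairdose <- function(x, ...) {
  cat("Hybrid dose-response model -- training summary\n")
  cat(sprintf("  samples: %d\n  training MSE: %.5f\n  training PCC: %.4f\n",
              x$n, x$training_mse, x$training_pcc))
  cat(sprintf("  epochs: %d (final train MSE %.5f", x$final_epoch,
              x$final_train_mse))
  if (!is.na(x$best_val_mse)) cat(sprintf(", best val MSE %.5f", x$best_val_mse))
  cat(")\n")
  cat("  aggregator:", x$aggregator_mode, "\n")
  invisible(x)
}

#' @export
fitted.pairdose <- function(object, ...) {
  predict_global(object$global, object$combo)
}

#' @export
residuals.pairdose <- function(object, ...) {
  object$combo$response - fitted(object)
}

#' Model coefficients (trained weight arrays)
#'
#' @param object A fitted `pairdose` model.
#' @param ... Unused.
#' @return Nested list of the trained numeric arrays: `global` (drug
#'   encoder, cell encoder, synergy head) and `aggregator` (possibly
#'   `NULL`).
#' @export
coef.pairdose <- function(object, ...) {
  list(global = object$global$par, aggregator = object$aggregator$par)
}

#' Plot the global model's training log
#'
#' Training (and, when present, validation) mean squared error per epoch.
#'
#' @param x A fitted `pairdose` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pairdose <- function(x, ...) {
  log <- x$global$log
  graphics::plot(log$epoch, log$train_mse, type = "l", xlab = "epoch",
                 ylab = "MSE", main = "Global model training", ...)
  if (!all(is.na(log$val_mse))) {
    graphics::lines(log$epoch, log$val_mse, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}
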