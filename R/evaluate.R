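# Scenario-based cross-validation and the ablation harness.
#
# Scenarios mirror the standard regimes of combination screens:
#   S1        matrix completion: random cells of every dose-response matrix
#             are held out; monotherapy data stay available.
#   S2        new combinations: whole pair matrices (across all cell lines)
#             are held out; monotherapy data stay available, so the local
#             path falls back to the Bliss pseudo-curve.
#   S3        as S2 but with all monotherapy data removed; the local path
#             falls back to feature-similarity retrieval.
#   new-combo one whole (pair, cell) matrix per held-out unit.
#   new-drug  whole drugs held out: a test triplet involves at least one
#             unseen drug.
#   new-cell  whole cell lines held out.

#' Pearson correlation between predictions and observations
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2,
#'   neither constant).
#' @return The product-moment correlation, in \[-1, 1\].
#' @export
pearson_cc <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(predicted) < 2L) stop("need at least two observations", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("correlation is undefined for a constant input", call. = FALSE)
  }
  stats::cor(predicted, observed)
}

# deal a unit vector into n_folds balanced random groups; returns fold labels
deal_folds <- function(n_units, n_folds) {
  sizes <- rep(n_units %/% n_folds, n_folds) +
    (seq_len(n_folds) <= n_units %% n_folds)
  sample(rep.int(seq_len(n_folds), sizes))
}

#' Scenario-based cross-validation splits
#'
#' Builds `n_folds` train/test splits according to the scenario's held-out
#' unit. Fold test sets partition the unit population, so every unit is
#' tested exactly once; `train` and `test` indices are always disjoint.
#' For `"new-drug"`, a test sample involves at least one held-out drug (it
#' is assigned to the fold of its lowest-fold drug) and the training set
#' contains only samples with both drugs unseen in that fold's test drugs.
#'
#' @param combos A combo table.
#' @param scenario One of `"S1"`, `"S2"`, `"S3"`, `"new-combo"`,
#'   `"new-drug"`, `"new-cell"`.
#' @param n_folds Number of folds (>= 2).
#' @param fraction Per-fold held-out share for S1; the folds partition each
#'   matrix, so this must equal `1/n_folds` (a differing value is ignored
#'   with a warning).
#' @param seed Split seed.
#' @return A list of `scenario_split` objects: `scenario`, `fold`,
#'   `train_idx`, `test_idx`, `mono_included`.
#' @export
make_scenario_split <- function(combos, scenario = c("S1", "S2", "S3",
                                                     "new-combo", "new-drug",
                                                     "new-cell"),
                                n_folds = 5L, fraction = 1 / n_folds,
                                seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_folds >= 2L)
  if (nrow(combos) == 0L) stop("empty dataset", call. = FALSE)
  if (scenario == "S1" && abs(fraction - 1 / n_folds) > 1e-8) {
    warning("S1 folds partition each matrix; fraction is fixed at 1/n_folds")
  }
  n <- nrow(combos)
  mono_included <- scenario != "S3"
  with_seed(seed, {
    if (scenario == "S1") {
      # unit: a single measured cell within its (pair, cell-line) matrix
      matrix_id <- canonical_pair_key(combos)
      fold_of <- integer(n)
      for (m in split(seq_len(n), matrix_id)) {
        fold_of[m] <- deal_folds(length(m), n_folds)
      }
    } else if (scenario %in% c("S2", "S3")) {
      d1 <- pmin(combos$drug1, combos$drug2)
      d2 <- pmax(combos$drug1, combos$drug2)
      pair_id <- paste(d1, d2, sep = "\x1f")
      units <- unique(pair_id)
      if (length(units) < n_folds) {
        stop("fewer drug pairs (", length(units), ") than folds", call. = FALSE)
      }
      unit_fold <- deal_folds(length(units), n_folds)
      fold_of <- unit_fold[match(pair_id, units)]
    } else if (scenario == "new-combo") {
      matrix_id <- canonical_pair_key(combos)
      units <- unique(matrix_id)
      if (length(units) < n_folds) {
        stop("fewer (pair, cell) matrices than folds", call. = FALSE)
      }
      unit_fold <- deal_folds(length(units), n_folds)
      fold_of <- unit_fold[match(matrix_id, units)]
    } else if (scenario == "new-cell") {
      units <- unique(combos$cell)
      if (length(units) < n_folds) {
        stop("fewer cell lines (", length(units), ") than folds", call. = FALSE)
      }
      unit_fold <- deal_folds(length(units), n_folds)
      fold_of <- unit_fold[match(combos$cell, units)]
    } else { # new-drug
      units <- unique(c(combos$drug1, combos$drug2))
      if (length(units) < n_folds) {
        stop("fewer drugs (", length(units), ") than folds", call. = FALSE)
      }
      unit_fold <- deal_folds(length(units), n_folds)
      f1 <- unit_fold[match(combos$drug1, units)]
      f2 <- unit_fold[match(combos$drug2, units)]
      fold_of <- pmin(f1, f2)
      drug_folds <- list(f1 = f1, f2 = f2)
    }
    lapply(seq_len(n_folds), function(f) {
      test_idx <- which(fold_of == f)
      train_idx <- if (scenario == "new-drug") {
        which(drug_folds$f1 != f & drug_folds$f2 != f)
      } else {
        which(fold_of != f)
      }
      structure(list(scenario = scenario, fold = f, train_idx = train_idx,
                     test_idx = test_idx, mono_included = mono_included),
                class = "scenario_split")
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed fan-out, kept inside 32-bit integer range
sub_seed <- function(master, offset) {
  as.integer((as.double(master) * 1009 + offset) %% 2147480009)
}

build_global_config <- function(opts, seed) {
  opts <- opts %||% list()
  if (!is.null(opts$drug) && !inherits(opts$drug, "drug_encoder_config")) {
    opts$drug <- do.call(drug_encoder_config, opts$drug)
  }
  if (!is.null(opts$dose) && !inherits(opts$dose, "dose_embedder_config")) {
    opts$dose <- do.call(dose_embedder_config, opts$dose)
  }
  if (!is.null(opts$cell) && !inherits(opts$cell, "cell_encoder_config")) {
    opts$cell <- do.call(cell_encoder_config, opts$cell)
  }
  opts$seed <- seed
  do.call(global_model_config, opts)
}

build_local_config <- function(opts, seed) {
  opts <- opts %||% list()
  opts$mode <- NULL
  opts$seed <- seed
  do.call(local_gcn_config, opts)
}

# local predictions for every row of `queries`; returns a prediction-pair
# data.frame. Per-query GCN init seeds are seed_base + row.
local_prediction_table <- function(model, queries, pool, mono, mode, cfg,
                                   mono_scale, predictor, seed_base,
                                   global_pred) {
  n <- nrow(queries)
  need_features <- mode == "feature" || (mode == "auto" && is.null(mono))
  pool_features <- if (need_features && nrow(pool) > 0L) {
    global_features(model$par, model, pool)
  } else NULL
  local_pred <- rep(NA_real_, n)
  avail <- logical(n)
  source <- rep("none", n)
  kk <- integer(n)
  for (i in seq_len(n)) {
    cfg$seed <- sub_seed(seed_base, i)
    res <- predict_local(model, queries[i, , drop = FALSE], pool, mono = mono,
                         mode = mode, cfg = cfg, mono_scale = mono_scale,
                         train_features = pool_features, predictor = predictor)
    local_pred[i] <- res$pred
    avail[i] <- res$available
    source[i] <- res$source
    kk[i] <- res$k
  }
  data.frame(global_pred = global_pred, local_pred = local_pred,
             local_available = avail, local_source = source, k = kk,
             response = queries$response, stringsAsFactors = FALSE)
}

variant_predictions <- function(variant, pairs, agg, train_mean) {
  switch(variant,
    "full" = aggregate_predictions(pairs, agg),
    "global-only" = pairs$global_pred,
    "fixed-average" = aggregate_predictions(pairs, agg, mode = "fixed-average"),
    "local-only" = ifelse(pairs$local_available, pairs$local_pred, train_mean),
    stop("unknown variant: ", variant)
  )
}

#' Run a scenario-based cross-validation experiment
#'
#' For each fold: trains the global model on the training split, computes
#' local predictions for the test split with the scenario-appropriate
#' fallback (exact retrieval; Bliss pseudo-curve when monotherapy data are
#' included; feature similarity otherwise), trains the aggregator on the
#' global model's held-out validation slice (out-of-fold with respect to
#' its gradient training), and evaluates the Pearson correlation of each
#' requested model variant on the test split.
#'
#' Variants: `"full"` (learned aggregation), `"global-only"`,
#' `"local-only"` (unavailable queries fall back to the training-mean
#' response), `"fixed-average"`, `"local-mlp"` (graph-free local predictor
#' inside the full pipeline) and `"no-dose-embedding"` (global model
#' retrained on raw normalized doses); `variants = "all"` selects all six.
#'
#' @param config A nested list (or path to a YAML file) with blocks `data`
#'   (either `simulate = list(...)` forwarded to [synthetic_config()], or
#'   `files = list(combos=, drugs=, cells=, mono=)`), `scenario`
#'   (`name`, `folds`, `run_folds`), `global`, `local` (including `mode`),
#'   `aggregator`, `variants` and `seed`. All randomness fans out from
#'   `seed`.
#' @param variants Optional override of `config$variants`.
#' @return An object of class `evaluation_report`: per-fold/per-variant
#'   results, summary means, the per-sample prediction table, the config
#'   snapshot and the derived sub-seeds.
#' @export
run_experiment <- function(config, variants = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  master <- as.integer(config$seed %||% 1L)
  variants <- variants %||% config$variants %||% "full"
  all_variants <- c("full", "global-only", "local-only", "fixed-average",
                    "local-mlp", "no-dose-embedding")
  if (identical(variants, "all")) variants <- all_variants
  if (!all(variants %in% all_variants)) {
    stop("unknown variant(s): ",
         paste(setdiff(variants, all_variants), collapse = ", "), call. = FALSE)
  }

  # ---- data ----
  dat <- config$data %||% stop("config$data is required", call. = FALSE)
  if (!is.null(dat$simulate)) {
    sim_opts <- dat$simulate
    sim_opts$seed <- sim_opts$seed %||% sub_seed(master, 1L)
    scfg <- do.call(synthetic_config, sim_opts)
    ds <- generate_dataset(scfg)
    combo <- ds$combo
    mono_all <- ds$mono
    drugs <- ds$drugs
    cells <- ds$expression
    mono_scale <- scfg$scale
  } else if (!is.null(dat$files)) {
    combo <- read_combo_table(dat$files$combos)
    drugs <- read_drug_library(dat$files$drugs)
    cells <- read_expression_matrix(dat$files$cells)
    mono_all <- if (!is.null(dat$files$mono)) read_mono_table(dat$files$mono)
    mono_scale <- dat$mono_scale %||% "fraction"
  } else {
    stop("config$data must contain either 'simulate' or 'files'", call. = FALSE)
  }

  scn <- config$scenario %||% list()
  scenario <- scn$name %||% "S1"
  n_folds <- as.integer(scn$folds %||% 5L)
  local_mode <- (config$local %||% list())$mode %||% "auto"
  if (local_mode == "bliss" && is.null(mono_all)) {
    stop("local mode 'bliss' requires a monotherapy table", call. = FALSE)
  }

  splits <- make_scenario_split(combo, scenario, n_folds = n_folds,
                                seed = sub_seed(master, 2L))
  run_folds <- scn$run_folds %||% seq_along(splits)

  results <- list()
  predictions <- list()
  seeds <- list(master = master, data = sub_seed(master, 1L),
                split = sub_seed(master, 2L))

  for (f in run_folds) {
    split <- splits[[f]]
    train_df <- combo[split$train_idx, , drop = FALSE]
    test_df <- combo[split$test_idx, , drop = FALSE]
    rownames(train_df) <- rownames(test_df) <- NULL
    mono <- if (split$mono_included) mono_all else NULL
    if (!is.null(mono) && mono_scale == "fraction") {
      mono$response <- pmin(pmax(mono$response, 0), 1)
    }

    gseed <- sub_seed(master, 10L + f)
    lseed <- sub_seed(master, 100L + f)
    aseed <- sub_seed(master, 200L + f)
    seeds[[paste0("fold", f)]] <- c(global = gseed, local = lseed, agg = aseed)

    gcfg <- build_global_config(config$global, gseed)
    lcfg <- build_local_config(config$local, lseed)
    acfg_opts <- config$aggregator %||% list()
    acfg_opts$seed <- aseed
    acfg <- do.call(aggregator_config, acfg_opts)

    gm <- train_global(train_df, drugs, cells, gcfg)
    train_mean <- mean(train_df$response)

    # out-of-fold aggregator training pairs from the validation slice
    val_df <- train_df[gm$val_idx, , drop = FALSE]
    agg <- if (nrow(val_df) > 0L && acfg$mode == "learned-mlp") {
      vp <- predict_global(gm, val_df)
      vpairs <- local_prediction_table(gm, val_df, train_df, mono, local_mode,
                                       lcfg, mono_scale, "gcn",
                                       sub_seed(lseed, 500000L), vp)
      suppressWarnings(train_aggregator(vpairs, acfg))
    } else {
      empty <- data.frame(global_pred = numeric(0), local_pred = numeric(0),
                          local_available = logical(0), k = integer(0),
                          response = numeric(0))
      suppressWarnings(train_aggregator(empty, acfg))
    }

    gp <- predict_global(gm, test_df)
    pairs <- local_prediction_table(gm, test_df, train_df, mono, local_mode,
                                    lcfg, mono_scale, "gcn", lseed, gp)

    fold_preds <- cbind(test_df,
                        data.frame(fold = f, global_pred = pairs$global_pred,
                                   local_pred = pairs$local_pred,
                                   local_available = pairs$local_available,
                                   local_source = pairs$local_source,
                                   k = pairs$k))

    for (v in variants) {
      pv <- if (v == "local-mlp") {
        mp <- local_prediction_table(gm, test_df, train_df, mono, local_mode,
                                     lcfg, mono_scale, "mlp",
                                     sub_seed(lseed, 600000L), gp)
        aggregate_predictions(mp, agg)
      } else if (v == "no-dose-embedding") {
        raw_opts <- config$global %||% list()
        raw_opts$dose <- list(transform = "log-min-max", sinusoidal = FALSE)
        gcfg2 <- build_global_config(raw_opts, sub_seed(gseed, 7L))
        gm2 <- train_global(train_df, drugs, cells, gcfg2)
        gp2 <- predict_global(gm2, test_df)
        p2 <- local_prediction_table(gm2, test_df, train_df, mono, local_mode,
                                     lcfg, mono_scale, "gcn",
                                     sub_seed(lseed, 700000L), gp2)
        val2 <- train_df[gm2$val_idx, , drop = FALSE]
        agg2 <- if (nrow(val2) > 0L && acfg$mode == "learned-mlp") {
          v2 <- local_prediction_table(gm2, val2, train_df, mono, local_mode,
                                       lcfg, mono_scale, "gcn",
                                       sub_seed(lseed, 800000L),
                                       predict_global(gm2, val2))
          suppressWarnings(train_aggregator(v2, acfg))
        } else agg
        aggregate_predictions(p2, agg2)
      } else {
        variant_predictions(v, pairs, agg, train_mean)
      }
      pcc <- tryCatch(pearson_cc(pv, test_df$response), error = function(e) NA_real_)
      results[[length(results) + 1L]] <-
        data.frame(fold = f, variant = v, pcc = pcc, n_test = nrow(test_df))
      if (v == variants[[1L]]) fold_preds$final_pred <- pv
    }
    predictions[[length(predictions) + 1L]] <- fold_preds
  }

  results <- do.call(rbind, results)
  summary_df <- do.call(rbind, lapply(split(results, results$variant), function(d) {
    data.frame(variant = d$variant[1L], mean_pcc = mean(d$pcc, na.rm = TRUE),
               sd_pcc = stats::sd(d$pcc), n_folds = nrow(d))
  }))
  rownames(summary_df) <- NULL

  structure(list(scenario = scenario, results = results, summary = summary_df,
                 predictions = do.call(rbind, predictions),
                 config = config, seeds = seeds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Cross-validated dose-response prediction -- scenario", x$scenario, "\n")
  cat("Folds run:", length(unique(x$results$fold)),
      " test samples:", sum(x$results$n_test[!duplicated(x$results$fold)]), "\n\n")
  cat("Mean Pearson correlation by variant:\n")
  s <- x$summary[order(-x$summary$mean_pcc), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %6.3f", s$variant[i], s$mean_pcc[i]))
    if (!is.na(s$sd_pcc[i])) cat(sprintf(" (sd %.3f)", s$sd_pcc[i]))
    cat("\n")
  }
  invisible(x)
}
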