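# The global synergy model: the three encoders feeding a dense regression
# head Ns, trained jointly end-to-end by minimizing the mean squared error
# between Ns(Ed(d1), Ed(d2), Er(r1), Er(r2), Ec(c)) and the measured
# response, over all available combination samples.

#' Configure the global synergy model
#'
#' @param drug A [drug_encoder_config()].
#' @param dose A [dose_embedder_config()]; its dose range is filled from the
#'   training doses if unset.
#' @param cell A [cell_encoder_config()].
#' @param head_hidden Hidden widths of the synergy head MLP.
#' @param learning_rate Adam learning rate; must lie in the model's search
#'   range \[1e-5, 1e-1\].
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement) when a validation slice exists.
#' @param val_fraction Fraction of training rows held out for early stopping
#'   (and later reused as out-of-fold data for the aggregator).
#' @param pair_augment If `TRUE` (default) every training row is also
#'   presented with the two (drug, dose) slots swapped, encouraging the
#'   physically expected symmetry of the prediction under pair reordering.
#' @param max_length SMILES tokenization length.
#' @param seed Integer seed controlling initialization, the validation split
#'   and batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `global_model_config`.
#' @export
global_model_config <- function(drug = drug_encoder_config(),
                                dose = dose_embedder_config(),
                                cell = cell_encoder_config(),
                                head_hidden = c(64L, 32L),
                                learning_rate = 1e-3,
                                batch_size = 256L,
                                epochs = 300L,
                                patience = 20L,
                                val_fraction = 0.1,
                                pair_augment = TRUE,
                                max_length = 128L,
                                seed = 1L,
                                verbose = FALSE) {
  if (learning_rate < 1e-5 || learning_rate > 1e-1) {
    stop("learning_rate must lie in [1e-5, 1e-1]", call. = FALSE)
  }
  stopifnot(batch_size >= 1L, epochs >= 1L, patience >= 1L,
            val_fraction >= 0, val_fraction < 1)
  structure(list(drug = drug, dose = dose, cell = cell,
                 head_hidden = as.integer(head_hidden),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, pair_augment = isTRUE(pair_augment),
                 max_length = as.integer(max_length),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "global_model_config")
}

# resolve sample ids against the model's libraries; errors name the id
resolve_ids <- function(ids, known, what) {
  idx <- match(ids, known)
  if (anyNA(idx)) {
    stop("unknown ", what, " '", ids[which(is.na(idx))[1L]], "'", call. = FALSE)
  }
  idx
}

# joint feature matrix for combo rows under the given parameters
global_features <- function(par, model, samples) {
  i1 <- resolve_ids(samples$drug1, model$drug_ids, "drug_id")
  i2 <- resolve_ids(samples$drug2, model$drug_ids, "drug_id")
  ic <- resolve_ids(samples$cell, model$cell_ids, "cell_id")
  Zd <- drug_forward_batch(par$drug, model$tokens, model$config$drug)
  Zc <- mlp_forward(par$cell, model$expr, act = "relu",
                    out_act = model$config$cell$final_activation)$out
  R1 <- embed_dose(samples$dose1, model$config$dose)
  R2 <- embed_dose(samples$dose2, model$config$dose)
  cbind(Zd[i1, , drop = FALSE], Zd[i2, , drop = FALSE], R1, R2,
        Zc[ic, , drop = FALSE])
}

global_forward_samples <- function(par, model, samples) {
  X <- global_features(par, model, samples)
  unname(drop(mlp_forward(par$head, X)$out))
}

#' Train the global synergy model
#'
#' Joint end-to-end training of the drug CNN, the cell-line MLP and the
#' synergy head by Adam on the mean-squared-error loss; the sinusoidal dose
#' embedding is a fixed map. A `val_fraction` slice of the rows is held out
#' for early stopping; training is reproducible given `config$seed`.
#'
#' @param combo Combo table `data.frame` (see [read_combo_table()]).
#' @param drugs Drug library `data.frame` with `drug_id`, `smiles`.
#' @param cells Numeric expression matrix, `rownames` = cell ids.
#' @param config A [global_model_config()].
#' @return An object of class `global_model`: trained parameters, the
#'   vocabulary and tokenized library, the dose embedder with its training
#'   dose range, a per-epoch training log, and the indices of the held-out
#'   validation rows.
#' @export
train_global <- function(combo, drugs, cells, config = global_model_config()) {
  stopifnot(inherits(config, "global_model_config"))
  validate_combo_table(combo)
  if (nrow(combo) == 0L) stop("empty training set", call. = FALSE)
  resolve_ids(c(combo$drug1, combo$drug2), drugs$drug_id, "drug_id")
  resolve_ids(combo$cell, rownames(cells), "cell_id")

  vocab <- smiles_vocabulary(drugs$smiles, max_length = config$max_length)
  tokens <- tokenize_library(drugs$smiles, vocab)
  rownames(tokens) <- drugs$drug_id
  if (config$dose$transform == "log-min-max" && is.null(config$dose$dose_range)) {
    config$dose <- set_dose_range(config$dose, c(combo$dose1, combo$dose2))
  }
  dose_dim <- config$dose$dim
  feat_dim <- 2L * config$drug$out_dim + 2L * dose_dim + config$cell$out_dim

  model <- list(drug_ids = drugs$drug_id, cell_ids = rownames(cells),
                tokens = tokens, expr = cells, vocab = vocab, config = config,
                feature_dim = feat_dim)

  with_seed(config$seed, {
    par <- list(
      drug = drug_encoder_init(vocab, config$drug),
      cell = cell_encoder_init(ncol(cells), config$cell),
      head = mlp_init(c(feat_dim, config$head_hidden, 1L))
    )
    # start the head at the response mean so optimization only has to carry
    # the residual structure, whatever the dataset's response scale
    par$head$b[[length(par$head$b)]][] <- mean(combo$response)

    n <- nrow(combo)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val >= 1L) sort(sample.int(n, n_val)) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    train_df <- combo[tr_idx, , drop = FALSE]
    if (config$pair_augment) {
      swapped <- train_df
      swapped$drug1 <- train_df$drug2
      swapped$drug2 <- train_df$drug1
      swapped$dose1 <- train_df$dose2
      swapped$dose2 <- train_df$dose1
      train_df <- rbind(train_df, swapped)
    }
    val_df <- combo[val_idx, , drop = FALSE]

    # fixed per-sample pieces
    i1 <- match(train_df$drug1, drugs$drug_id)
    i2 <- match(train_df$drug2, drugs$drug_id)
    ic <- match(train_df$cell, rownames(cells))
    R1 <- embed_dose(train_df$dose1, config$dose)
    R2 <- embed_dose(train_df$dose2, config$dose)
    y <- train_df$response
    nd <- nrow(tokens)
    ncell <- nrow(cells)
    Dd <- config$drug$out_dim
    Dc <- config$cell$out_dim

    st <- adam_init(par)
    nt <- nrow(train_df)
    bs <- min(config$batch_size, nt)
    log_epoch <- numeric(0)
    log_train <- numeric(0)
    log_val <- numeric(0)
    best_val <- Inf
    best_par <- par
    stall <- 0L

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nt)
      starts <- seq(1L, nt, by = bs)
      ep_loss <- 0
      for (s in starts) {
        b <- ord[s:min(s + bs - 1L, nt)]
        nb <- length(b)
        dfw <- drug_forward_batch(par$drug, tokens, config$drug, keep = TRUE)
        cfw <- mlp_forward(par$cell, cells, act = "relu",
                           out_act = config$cell$final_activation)
        X <- cbind(dfw$out[i1[b], , drop = FALSE], dfw$out[i2[b], , drop = FALSE],
                   R1[b, , drop = FALSE], R2[b, , drop = FALSE],
                   cfw$out[ic[b], , drop = FALSE])
        hfw <- mlp_forward(par$head, X)
        pred <- drop(hfw$out)
        resid <- pred - y[b]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; reduce the learning rate", call. = FALSE)
        }
        ep_loss <- ep_loss + loss * nb
        hbw <- mlp_backward(par$head, hfw, matrix(2 * resid / nb, ncol = 1L))
        dX <- hbw$dX
        # split the joint-feature gradient back into its blocks
        dZ1 <- dX[, seq_len(Dd), drop = FALSE]
        dZ2 <- dX[, Dd + seq_len(Dd), drop = FALSE]
        dZc <- dX[, 2L * Dd + 2L * dose_dim + seq_len(Dc), drop = FALSE]
        dZd_all <- matrix(0, nd, Dd)
        a1 <- rowsum(dZ1, group = i1[b])
        dZd_all[as.integer(rownames(a1)), ] <- dZd_all[as.integer(rownames(a1)), ] + a1
        a2 <- rowsum(dZ2, group = i2[b])
        dZd_all[as.integer(rownames(a2)), ] <- dZd_all[as.integer(rownames(a2)), ] + a2
        dZc_all <- matrix(0, ncell, Dc)
        ac <- rowsum(dZc, group = ic[b])
        dZc_all[as.integer(rownames(ac)), ] <- ac
        g <- list(
          drug = drug_backward_batch(par$drug, tokens, dfw, dZd_all, config$drug),
          cell = mlp_backward(par$cell, cfw, dZc_all, act = "relu",
                              out_act = config$cell$final_activation)$grads,
          head = hbw$grads
        )
        upd <- adam_step(par, g, st, config$learning_rate)
        par <- upd$par
        st <- upd$state
      }
      train_mse <- ep_loss / nt
      val_mse <- NA_real_
      if (length(val_idx) > 0L) {
        vp <- global_forward_samples(par, model, val_df)
        val_mse <- mean((vp - val_df$response)^2)
        if (val_mse < best_val - 1e-12) {
          best_val <- val_mse
          best_par <- par
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      log_epoch <- c(log_epoch, epoch)
      log_train <- c(log_train, train_mse)
      log_val <- c(log_val, val_mse)
      if (config$verbose) {
        message(sprintf("epoch %d  train MSE %.6f  val MSE %s", epoch, train_mse,
                        if (is.na(val_mse)) "-" else sprintf("%.6f", val_mse)))
      }
      if (length(val_idx) > 0L && stall >= config$patience) break
    }
    if (length(val_idx) > 0L) par <- best_par

    model$par <- par
    model$log <- data.frame(epoch = log_epoch, train_mse = log_train,
                            val_mse = log_val)
    model$val_idx <- val_idx
    class(model) <- "global_model"
    model
  })
}

#' Predict responses with a trained global model
#'
#' Deterministic forward pass of the trained network for each row of
#' `samples`. Drugs or cell lines absent from the training libraries may be
#' supplied through `drugs` / `cells`.
#'
#' @param model A trained [train_global()] object.
#' @param samples Combo table rows (the `response` column is ignored and may
#'   be absent; it is filled with `NA` internally).
#' @param drugs Optional additional drug library rows.
#' @param cells Optional additional expression rows.
#' @return Numeric vector of predicted responses, one per row.
#' @export
predict_global <- function(model, samples, drugs = NULL, cells = NULL) {
  stopifnot(inherits(model, "global_model"))
  if (!"response" %in% names(samples)) samples$response <- NA_real_
  if (!is.null(drugs)) {
    new <- drugs[!drugs$drug_id %in% model$drug_ids, , drop = FALSE]
    if (nrow(new) > 0L) {
      tok <- tokenize_library(new$smiles, model$vocab)
      rownames(tok) <- new$drug_id
      model$tokens <- rbind(model$tokens, tok)
      model$drug_ids <- c(model$drug_ids, new$drug_id)
    }
  }
  if (!is.null(cells)) {
    new <- cells[!rownames(cells) %in% model$cell_ids, , drop = FALSE]
    if (nrow(new) > 0L) {
      model$expr <- rbind(model$expr, new)
      model$cell_ids <- c(model$cell_ids, rownames(new))
    }
  }
  global_forward_samples(model$par, model, samples)
}
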