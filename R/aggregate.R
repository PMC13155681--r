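# Aggregation of the global and local predictions. The learnable mode is a
# small MLP over [global_pred, local_pred, availability flag, log(1+k)]
# parameterized as a residual on the global prediction (the last layer is
# zero-initialized, so the untrained aggregator already equals the global
# model). Whatever the mode, a query with no local prediction receives the
# global prediction bit-exactly.

#' Configure the prediction aggregator
#'
#' @param mode `"learned-mlp"` (default), `"fixed-average"` or
#'   `"global-only"`.
#' @param hidden Hidden widths of the learned aggregator MLP.
#' @param extra_inputs If `TRUE` (default) the MLP also receives the
#'   local-availability flag and `log(1 + k)` (k = retrieved-sample count)
#'   beyond the two predictions.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param weight_decay L2 penalty on the MLP weights (not biases); keeps the
#'   residual network close to the global prediction when the local signal
#'   is uninformative.
#' @param seed Initialization seed.
#' @return An object of class `aggregator_config`.
#' @export
aggregator_config <- function(mode = c("learned-mlp", "fixed-average", "global-only"),
                              hidden = 8L, extra_inputs = TRUE,
                              learning_rate = 5e-3, epochs = 200L,
                              weight_decay = 1e-3, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(learning_rate > 0, epochs >= 1L, weight_decay >= 0)
  structure(list(mode = mode, hidden = as.integer(hidden),
                 extra_inputs = isTRUE(extra_inputs),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "aggregator_config")
}

# prediction-pair table -> MLP input matrix
aggregator_inputs <- function(pairs, cfg) {
  l <- ifelse(pairs$local_available, pairs$local_pred, 0)
  if (cfg$extra_inputs) {
    cbind(g = pairs$global_pred, l = l,
          avail = as.numeric(pairs$local_available), lk = log1p(pairs$k))
  } else {
    cbind(g = pairs$global_pred, l = l)
  }
}

#' Train the learnable aggregator
#'
#' Trains the aggregator MLP by MSE on prediction pairs that carry a local
#' prediction; pairs without one are excluded (they reduce to the global
#' prediction by construction). The pairs should come from data held out of
#' the global model's gradient training (out-of-fold), to avoid rewarding
#' memorized global predictions.
#'
#' @param pairs `data.frame` with columns `global_pred`, `local_pred`,
#'   `local_available` (logical), `k` and `response` (the measured value).
#' @param cfg An [aggregator_config()].
#' @return An object of class `aggregator`. When no pair has a local
#'   prediction (or the mode needs no training), an identity-on-global
#'   aggregator is returned (with a warning in the learned mode).
#' @export
train_aggregator <- function(pairs, cfg = aggregator_config()) {
  stopifnot(inherits(cfg, "aggregator_config"))
  out <- structure(list(cfg = cfg, par = NULL), class = "aggregator")
  if (cfg$mode != "learned-mlp") return(out)
  avail <- which(pairs$local_available)
  if (length(avail) == 0L) {
    warning("no pairs with a local prediction; returning the identity-on-global aggregator")
    return(out)
  }
  X <- aggregator_inputs(pairs[avail, , drop = FALSE], cfg)
  g <- pairs$global_pred[avail]
  y <- pairs$response[avail]
  with_seed(cfg$seed, {
    par <- mlp_init(c(ncol(X), cfg$hidden, 1L), zero_last = TRUE)
    st <- adam_init(par)
    for (epoch in seq_len(cfg$epochs)) {
      fw <- mlp_forward(par, X)
      resid <- g + drop(fw$out) - y  # residual parameterization on top of global
      grads <- mlp_backward(par, fw, matrix(2 * resid / length(y), ncol = 1L))$grads
      if (cfg$weight_decay > 0) {
        for (l in seq_along(grads$W)) {
          grads$W[[l]] <- grads$W[[l]] + 2 * cfg$weight_decay * par$W[[l]]
        }
      }
      upd <- adam_step(par, grads, st, cfg$learning_rate)
      par <- upd$par
      st <- upd$state
    }
    out$par <- par
    out
  })
}

#' Aggregate global and local predictions
#'
#' Vectorized over prediction pairs. In every mode, a pair without a local
#' prediction yields the global prediction bit-exactly (the documented
#' degeneration to the global model). Otherwise: `"learned-mlp"` adds the
#' trained residual network's output to the global prediction;
#' `"fixed-average"` returns the mean of the two predictions;
#' `"global-only"` ignores the local prediction.
#'
#' @param pairs `data.frame` with columns `global_pred`, `local_pred`,
#'   `local_available`, `k`.
#' @param model A trained [train_aggregator()] object.
#' @param mode Optional mode override (defaults to the model's configured
#'   mode).
#' @return Numeric vector of final predictions.
#' @export
aggregate_predictions <- function(pairs, model, mode = NULL) {
  stopifnot(inherits(model, "aggregator"))
  cfg <- model$cfg
  if (!is.null(mode)) cfg$mode <- match.arg(mode, c("learned-mlp", "fixed-average", "global-only"))
  out <- pairs$global_pred
  avail <- which(pairs$local_available)
  if (length(avail) == 0L || cfg$mode == "global-only") return(out)
  if (cfg$mode == "fixed-average") {
    out[avail] <- (pairs$global_pred[avail] + pairs$local_pred[avail]) / 2
  } else {
    if (is.null(model$par)) return(out)  # identity aggregator
    X <- aggregator_inputs(pairs[avail, , drop = FALSE], cfg)
    out[avail] <- pairs$global_pred[avail] + drop(mlp_forward(model$par, X)$out)
  }
  out
}
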