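# The local model: for each query, retrieve the measured samples sharing the
# query's (unordered) drug pair and cell line at other doses, build a small
# graph over the k retrieved samples plus the query (nodes connected to
# their nearest neighbors in log-dose space), and train a semi-supervised
# graph convolutional network per query that propagates the retrieved
# labels to the unlabeled query node.
#
# Two fallbacks cover queries with no same-pair measurements: when both
# monotherapy curves exist, their pointwise product (Bliss independence)
# provides a pseudo-labeled response curve to retrieve from; otherwise the
# nearest training samples in the joint feature space are retrieved.

#' Configure the local semi-supervised GCN
#'
#' @param layers Number of graph-convolution layers (final layer is a linear
#'   scalar output).
#' @param hidden Hidden width of the intermediate layers.
#' @param learning_rate Adam learning rate; must lie in the local search
#'   range \[1e-6, 1e-2\].
#' @param epochs Full-batch training epochs per query graph.
#' @param k_min Minimum number of retrieved samples for the graph path; with
#'   fewer the local path reports itself unavailable. The default 2 resolves
#'   the boundary case of a single retrieved sample to the fallback path (a
#'   one-neighbor graph gives the GCN nothing to regularize).
#' @param knn Nearest neighbors per node in log-dose space (default 4),
#'   capped at the number of other nodes.
#' @param K Pool size for the feature-similarity fallback (commonly 20, 50
#'   or 100).
#' @param seed Seed for per-query weight initialization.
#' @return An object of class `local_gcn_config`.
#' @export
local_gcn_config <- function(layers = 3L, hidden = 16L, learning_rate = 1e-2,
                             epochs = 300L, k_min = 2L, knn = 4L, K = 20L,
                             seed = 1L) {
  if (learning_rate < 1e-6 || learning_rate > 1e-2) {
    stop("learning_rate must lie in [1e-6, 1e-2]", call. = FALSE)
  }
  stopifnot(layers >= 1L, hidden >= 1L, epochs >= 1L, k_min >= 1L, knn >= 1L,
            K >= 1L)
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 k_min = as.integer(k_min), knn = as.integer(knn),
                 K = as.integer(K), seed = as.integer(seed)),
            class = "local_gcn_config")
}

# typed "local path unavailable" outcome (not an error)
local_unavailable <- function(reason) {
  structure(list(reason = reason), class = "local_unavailable")
}

#' @rdname local_gcn_config
#' @param x An object.
#' @export
is_local_unavailable <- function(x) inherits(x, "local_unavailable")

retrieval_result <- function(samples, source, k_min) {
  structure(list(samples = samples, k = nrow(samples), source = source,
                 available = nrow(samples) >= k_min),
            class = "retrieval_result")
}

#' Retrieve same-pair / same-cell training samples
#'
#' Returns every training sample sharing the query's unordered drug pair and
#' cell line but measured at other doses. Samples stored in the swapped
#' orientation are flipped so that their doses align with the query's drug
#' slots; the query's own dose combination is excluded.
#'
#' @param query A single combo row (one-row `data.frame` or list with the
#'   canonical fields).
#' @param train Combo table to retrieve from.
#' @param k_min Availability threshold (see [local_gcn_config()]).
#' @return A `retrieval_result`: `samples` (oriented combo rows), `k`,
#'   `source = "exact-match"`, `available = (k >= k_min)`.
#' @export
retrieve_matching_samples <- function(query, train, k_min = 2L) {
  qkey <- canonical_pair_key(query$drug1, query$drug2, query$cell)
  hit <- train[canonical_pair_key(train) == qkey, , drop = FALSE]
  if (nrow(hit) > 0L) {
    if (query$drug1 == query$drug2) {
      # self-pair: orientation is ambiguous, match on the dose multiset
      same <- (pmin(hit$dose1, hit$dose2) == min(query$dose1, query$dose2)) &
        (pmax(hit$dose1, hit$dose2) == max(query$dose1, query$dose2))
    } else {
      flip <- hit$drug1 != query$drug1
      if (any(flip)) {
        tmp <- hit$dose1[flip]
        hit$dose1[flip] <- hit$dose2[flip]
        hit$dose2[flip] <- tmp
        hit$drug1[flip] <- query$drug1
        hit$drug2[flip] <- query$drug2
      }
      same <- hit$dose1 == query$dose1 & hit$dose2 == query$dose2
    }
    hit <- hit[!same, , drop = FALSE]
  }
  rownames(hit) <- NULL
  retrieval_result(hit, "exact-match", k_min)
}

#' Bliss-independence pseudo response curve
#'
#' When no combination measurements exist for a pair but both monotherapy
#' curves do, the combination's response surface is approximated by the
#' Bliss independence null: the expected combined growth fraction is the
#' product of the single-drug growth fractions, evaluated on the outer
#' product of the two mono dose grids. Responses on the percent-growth scale
#' are divided by 100 (and clipped into \[0, 1\], with a warning) before
#' multiplication.
#'
#' @param mono1,mono2 Monotherapy tables (columns `drug`, `dose`, `cell`,
#'   `response`) for the two drugs; each must contain exactly one drug and,
#'   after filtering by `cell_id`, one cell line.
#' @param cell_id Optional cell line to filter both tables to.
#' @param scale `"fraction"` (responses already in \[0, 1\]) or `"percent"`.
#' @return A combo table of pseudo-labeled samples, one per dose-grid cell,
#'   with an extra logical column `pseudo = TRUE`.
#' @export
bliss_pseudo_curve <- function(mono1, mono2, cell_id = NULL,
                               scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  if (!is.null(cell_id)) {
    mono1 <- mono1[mono1$cell == cell_id, , drop = FALSE]
    mono2 <- mono2[mono2$cell == cell_id, , drop = FALSE]
  }
  if (nrow(mono1) == 0L || nrow(mono2) == 0L) {
    stop("both monotherapy curves must be non-empty", call. = FALSE)
  }
  cell <- unique(c(mono1$cell, mono2$cell))
  if (length(cell) != 1L) stop("monotherapy curves span different cell lines", call. = FALSE)
  d1 <- unique(mono1$drug)
  d2 <- unique(mono2$drug)
  if (length(d1) != 1L || length(d2) != 1L) {
    stop("each monotherapy table must contain a single drug", call. = FALSE)
  }
  g1 <- mono1$response
  g2 <- mono2$response
  if (scale == "percent") {
    g1 <- g1 / 100
    g2 <- g2 / 100
    if (any(g1 < 0 | g1 > 1) || any(g2 < 0 | g2 > 1)) {
      warning("growth fractions outside [0, 1] after percent rescaling were clipped")
      g1 <- pmin(pmax(g1, 0), 1)
      g2 <- pmin(pmax(g2, 0), 1)
    }
  } else if (any(g1 < 0 | g1 > 1) || any(g2 < 0 | g2 > 1)) {
    stop("monotherapy responses must be growth fractions in [0, 1]; ",
         "use scale = \"percent\" for percent-growth data", call. = FALSE)
  }
  grid <- expand.grid(i = seq_len(nrow(mono1)), j = seq_len(nrow(mono2)))
  out <- data.frame(
    drug1 = d1, drug2 = d2,
    dose1 = mono1$dose[grid$i], dose2 = mono2$dose[grid$j],
    cell = cell,
    response = g1[grid$i] * g2[grid$j],
    pseudo = TRUE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Retrieve training samples by cosine similarity in feature space
#'
#' Fallback when neither same-pair measurements nor monotherapy curves
#' exist: the `K` training samples whose joint feature vectors have the
#' smallest cosine distance to the query's are retrieved (ties broken by
#' training index; `K` is capped at the pool size).
#'
#' @param query_feature Numeric query feature vector.
#' @param train_features Numeric matrix, one training feature per row.
#' @param K Number of samples to retrieve.
#' @param samples Optional combo table aligned with `train_features`; when
#'   given, the retrieved rows are attached to the result.
#' @param k_min Availability threshold.
#' @return A `retrieval_result` with `source = "feature-similarity"` and an
#'   extra `indices` field (rows of `train_features` retrieved, in
#'   increasing distance order).
#' @export
retrieve_by_feature_similarity <- function(query_feature, train_features, K,
                                           samples = NULL, k_min = 2L) {
  stopifnot(K >= 1L)
  if (!is.matrix(train_features)) train_features <- matrix(train_features, nrow = 1L)
  if (length(query_feature) != ncol(train_features)) {
    stop("feature dimensions disagree", call. = FALSE)
  }
  qn <- sqrt(sum(query_feature^2))
  norms <- sqrt(rowSums(train_features^2))
  if (qn == 0 || any(norms == 0)) {
    stop("zero-norm feature vector: cosine distance undefined", call. = FALSE)
  }
  dist <- 1 - drop(train_features %*% query_feature) / (norms * qn)
  ord <- order(dist, seq_along(dist))
  idx <- ord[seq_len(min(K, length(ord)))]
  smp <- if (!is.null(samples)) samples[idx, , drop = FALSE] else
    data.frame()[seq_along(idx), , drop = FALSE]
  rownames(smp) <- NULL
  res <- retrieval_result(smp, "feature-similarity", k_min)
  res$k <- length(idx)
  res$available <- res$k >= k_min
  res$indices <- idx
  res
}

#' Build the per-query semi-supervised graph
#'
#' Nodes are the k retrieved samples plus the query (last node). Each node's
#' feature vector is the joint embedding of its (drug, drug, dose, dose,
#' cell) tuple under the trained global model's encoders (kept frozen). For
#' each node, edges are drawn to its `knn` nearest neighbors by Euclidean
#' distance in (log dose1, log dose2) space (capped at the number of other
#' nodes); the adjacency is then symmetrized by union and given a unit
#' diagonal. Retrieved nodes carry their responses as labels; the query node
#' is the single unlabeled node.
#'
#' @param query A single combo row.
#' @param retrieval A `retrieval_result` (must be available).
#' @param model A trained [train_global()] model providing the encoders.
#' @param knn Neighbors per node.
#' @return An object of class `semisupervised_graph`: `features`
#'   ((k+1) x F), `adjacency` ((k+1) x (k+1), symmetric, unit diagonal),
#'   `labels` (length k+1, `NA` at the query), `labeled_mask`,
#'   `query_index = k + 1`. If the retrieval is unavailable, a typed
#'   `local_unavailable` outcome is returned instead.
#' @export
build_semisupervised_graph <- function(query, retrieval, model, knn = 4L) {
  stopifnot(inherits(retrieval, "retrieval_result"), inherits(model, "global_model"))
  if (!retrieval$available) {
    return(local_unavailable(sprintf("only %d retrieved sample(s)", retrieval$k)))
  }
  query <- as.data.frame(query, stringsAsFactors = FALSE)
  cols <- c("drug1", "drug2", "dose1", "dose2", "cell", "response")
  if (!"response" %in% names(query)) query$response <- NA_real_
  nodes <- rbind(retrieval$samples[, cols, drop = FALSE], query[, cols, drop = FALSE])
  n <- nrow(nodes)
  feats <- global_features(model$par, model, nodes)
  A <- knn_dose_adjacency(log(nodes$dose1), log(nodes$dose2), knn)
  labels <- c(retrieval$samples$response, NA_real_)
  structure(
    list(features = feats, adjacency = A, labels = labels,
         labeled_mask = c(rep(TRUE, n - 1L), FALSE), query_index = n,
         source = retrieval$source, k = retrieval$k),
    class = "semisupervised_graph"
  )
}

# directed kNN in (log r1, log r2) -> union-symmetrized + unit diagonal
knn_dose_adjacency <- function(x, y, knn) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  A <- matrix(0, n, n)
  kk <- min(knn, n - 1L)
  if (kk >= 1L) {
    for (i in seq_len(n)) {
      d <- D[i, ]
      d[i] <- Inf
      nb <- order(d, seq_len(n))[seq_len(kk)]
      A[i, nb] <- 1
    }
  }
  A <- pmax(A, t(A))  # union symmetrization
  diag(A) <- 1
  A
}

#' Symmetric degree-normalization of an adjacency matrix
#'
#' Computes the standard graph-convolution propagation operator
#' \eqn{\hat A = D^{-1/2} A D^{-1/2}} with D the diagonal degree (row-sum)
#' matrix. Requires a symmetric binary adjacency with unit diagonal (so no
#' degree is zero).
#'
#' @param adjacency Symmetric binary matrix with unit diagonal.
#' @return The normalized (symmetric) propagation matrix.
#' @export
normalize_adjacency <- function(adjacency) {
  if (!isSymmetric(unname(adjacency))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 1)) stop("adjacency must have a unit diagonal", call. = FALSE)
  dinv <- 1 / sqrt(rowSums(adjacency))
  adjacency * outer(dinv, dinv)
}

gcn_init <- function(feat_dim, cfg) {
  sizes <- c(feat_dim, rep(cfg$hidden, cfg$layers - 1L), 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- nn_mat(sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' GCN forward pass
#'
#' Layered propagation \eqn{H^{(l+1)} = \sigma(\hat A H^{(l)} W^{(l)})} with
#' ReLU between layers and a linear final layer; \eqn{\hat A} is the
#' degree-normalized adjacency of the graph. Deterministic for fixed
#' weights and equivariant under node permutation.
#'
#' @param graph A `semisupervised_graph`.
#' @param params List with `W` (list of weight matrices) and optionally `b`
#'   (bias vectors; zero if absent).
#' @param activation Hidden-layer activation (`"relu"` or `"identity"`).
#' @return Numeric vector of per-node outputs (or a matrix when the final
#'   weight has more than one column).
#' @export
gcn_forward <- function(graph, params, activation = "relu") {
  fw <- gcn_forward_cache(graph, params, activation)
  out <- fw$H[[length(fw$H)]]
  if (ncol(out) == 1L) drop(out) else out
}

gcn_forward_cache <- function(graph, params, activation = "relu", Ahat = NULL) {
  if (is.null(Ahat)) Ahat <- normalize_adjacency(graph$adjacency)
  L <- length(params$W)
  b <- params$b
  if (is.null(b)) b <- lapply(params$W, function(w) numeric(ncol(w)))
  H <- vector("list", L + 1L)
  M <- vector("list", L)  # M[[l]] = Ahat %*% H[[l]] (needed for gradients)
  H[[1L]] <- graph$features
  for (l in seq_len(L)) {
    M[[l]] <- Ahat %*% H[[l]]
    Z <- M[[l]] %*% params$W[[l]]
    Z <- Z + rep(b[[l]], each = nrow(Z))
    H[[l + 1L]] <- if (l < L) apply_act(Z, activation) else Z
  }
  list(H = H, M = M, Ahat = Ahat)
}

gcn_backward <- function(graph, params, fw, dOut, activation = "relu") {
  L <- length(params$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dH <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- if (l < L) act_backward(dH, fw$H[[l + 1L]], activation) else dH
    gW[[l]] <- crossprod(fw$M[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    # Ahat is symmetric, so the adjoint of H -> Ahat H is Ahat itself
    dH <- fw$Ahat %*% (dZ %*% t(params$W[[l]]))
  }
  list(W = gW, b = gb)
}

#' Train the per-query GCN and predict the query's response
#'
#' Full-batch Adam training of the semi-supervised GCN with MSE computed on
#' the labeled nodes only; the trained network's output at the unlabeled
#' query node is returned. Reproducible given `cfg$seed`.
#'
#' @param graph A `semisupervised_graph`, or a `local_unavailable` outcome
#'   (passed through).
#' @param cfg A [local_gcn_config()].
#' @return The query prediction (numeric scalar), or a `local_unavailable`
#'   outcome when fewer than `cfg$k_min` labeled nodes exist.
#' @export
train_local_predict <- function(graph, cfg = local_gcn_config()) {
  stopifnot(inherits(cfg, "local_gcn_config"))
  if (is_local_unavailable(graph)) return(graph)
  lab <- which(graph$labeled_mask)
  if (length(lab) < cfg$k_min) {
    return(local_unavailable(sprintf("only %d labeled node(s)", length(lab))))
  }
  # standardize the labeled responses so the network fits an O(1) target
  # regardless of the dataset's response scale; undo on output
  mu <- mean(graph$labels[lab])
  sdev <- stats::sd(graph$labels[lab])
  if (!is.finite(sdev) || sdev == 0) sdev <- 1
  y <- (graph$labels[lab] - mu) / sdev
  n <- length(graph$labels)
  Ahat <- normalize_adjacency(graph$adjacency)
  with_seed(cfg$seed, {
    par <- gcn_init(ncol(graph$features), cfg)
    st <- adam_init(par)
    for (epoch in seq_len(cfg$epochs)) {
      fw <- gcn_forward_cache(graph, par, Ahat = Ahat)
      pred <- drop(fw$H[[length(fw$H)]])
      resid <- pred[lab] - y
      if (!all(is.finite(resid))) {
        stop("non-finite loss in local GCN training", call. = FALSE)
      }
      dOut <- matrix(0, n, 1L)
      dOut[lab, 1L] <- 2 * resid / length(lab)
      g <- gcn_backward(graph, par, fw, dOut)
      upd <- adam_step(par, g, st, cfg$learning_rate)
      par <- upd$par
      st <- upd$state
    }
    fw <- gcn_forward_cache(graph, par, Ahat = Ahat)
    mu + sdev * drop(fw$H[[length(fw$H)]])[graph$query_index]
  })
}

#' Graph-free local predictor (ablation)
#'
#' Replaces the GCN by a plain multilayer perceptron over the retrieved
#' samples: each node's input is its own joint feature concatenated with the
#' mean feature of the labeled nodes; the MLP is trained on the labeled
#' nodes and evaluated at the query.
#'
#' @inheritParams train_local_predict
#' @return The query prediction, or a `local_unavailable` outcome.
#' @export
local_mlp_predict <- function(graph, cfg = local_gcn_config()) {
  stopifnot(inherits(cfg, "local_gcn_config"))
  if (is_local_unavailable(graph)) return(graph)
  lab <- which(graph$labeled_mask)
  if (length(lab) < cfg$k_min) {
    return(local_unavailable(sprintf("only %d labeled node(s)", length(lab))))
  }
  ctx <- colMeans(graph$features[lab, , drop = FALSE])
  X <- cbind(graph$features,
             matrix(ctx, nrow(graph$features), length(ctx), byrow = TRUE))
  mu <- mean(graph$labels[lab])
  sdev <- stats::sd(graph$labels[lab])
  if (!is.finite(sdev) || sdev == 0) sdev <- 1
  y <- (graph$labels[lab] - mu) / sdev
  with_seed(cfg$seed, {
    par <- mlp_init(c(ncol(X), cfg$hidden, 1L))
    st <- adam_init(par)
    for (epoch in seq_len(cfg$epochs)) {
      fw <- mlp_forward(par, X[lab, , drop = FALSE])
      resid <- drop(fw$out) - y
      g <- mlp_backward(par, fw, matrix(2 * resid / length(lab), ncol = 1L))$grads
      upd <- adam_step(par, g, st, cfg$learning_rate)
      par <- upd$par
      st <- upd$state
    }
    mu + sdev * drop(mlp_forward(par, X[graph$query_index, , drop = FALSE])$out)
  })
}

#' Local prediction for one query with fallback cascade
#'
#' Implements the full local path: exact same-pair/same-cell retrieval
#' first; if unavailable and both monotherapy curves exist, retrieval from
#' the Bliss pseudo-curve; otherwise feature-similarity retrieval from the
#' training pool. Each path builds the dose-neighborhood graph and trains
#' the per-query GCN.
#'
#' @param model A trained [train_global()] model (frozen encoders).
#' @param query A single combo row.
#' @param train Combo table used as the retrieval pool.
#' @param mono Optional monotherapy table.
#' @param mode `"auto"` (cascade), or force one of `"exact"`, `"bliss"`,
#'   `"feature"`; `"off"` disables the local path.
#' @param cfg A [local_gcn_config()].
#' @param mono_scale Scale of the monotherapy responses (see
#'   [bliss_pseudo_curve()]).
#' @param train_features Optional precomputed joint features of `train`
#'   (rows aligned), to amortize the feature-similarity fallback.
#' @param predictor `"gcn"` (default) or `"mlp"` (the graph-free ablation).
#' @return List with `pred` (numeric or `NA`), `available`, `source`
#'   (`"exact-match"`, `"bliss-pseudo"`, `"feature-similarity"` or `"none"`)
#'   and `k`.
#' @export
predict_local <- function(model, query, train, mono = NULL,
                          mode = c("auto", "exact", "bliss", "feature", "off"),
                          cfg = local_gcn_config(),
                          mono_scale = c("fraction", "percent"),
                          train_features = NULL,
                          predictor = c("gcn", "mlp")) {
  mode <- match.arg(mode)
  mono_scale <- match.arg(mono_scale)
  predictor <- match.arg(predictor)
  miss <- list(pred = NA_real_, available = FALSE, source = "none", k = 0L)
  if (mode == "off") return(miss)

  retrieval <- NULL
  if (mode %in% c("auto", "exact")) {
    res <- retrieve_matching_samples(query, train, k_min = cfg$k_min)
    if (res$available) retrieval <- res
    else if (mode == "exact") return(within_miss(miss, res$k))
  }
  if (is.null(retrieval) && mode %in% c("auto", "bliss")) {
    if (!is.null(mono)) {
      m1 <- mono[mono$drug == query$drug1 & mono$cell == query$cell, , drop = FALSE]
      m2 <- mono[mono$drug == query$drug2 & mono$cell == query$cell, , drop = FALSE]
      if (mono_scale == "fraction") {
        # measurement noise can push growth fractions slightly out of [0, 1]
        m1$response <- pmin(pmax(m1$response, 0), 1)
        m2$response <- pmin(pmax(m2$response, 0), 1)
      }
      if (nrow(m1) > 0L && nrow(m2) > 0L) {
        pseudo <- bliss_pseudo_curve(m1, m2, scale = mono_scale)
        # pseudo-labels go back onto the dataset's response scale
        if (mono_scale == "percent") pseudo$response <- pseudo$response * 100
        res <- retrieval_result(pseudo, "bliss-pseudo", cfg$k_min)
        if (res$available) retrieval <- res
      }
    }
    if (is.null(retrieval) && mode == "bliss") return(miss)
  }
  if (is.null(retrieval) && mode %in% c("auto", "feature")) {
    if (nrow(train) > 0L) {
      if (is.null(train_features)) {
        train_features <- global_features(model$par, model, train)
      }
      qf <- drop(global_features(model$par, model, as.data.frame(query)))
      res <- retrieve_by_feature_similarity(qf, train_features, K = cfg$K,
                                            samples = train, k_min = cfg$k_min)
      if (res$available) retrieval <- res
    }
  }
  if (is.null(retrieval)) return(miss)

  graph <- build_semisupervised_graph(query, retrieval, model, knn = cfg$knn)
  pred <- if (predictor == "gcn") train_local_predict(graph, cfg)
          else local_mlp_predict(graph, cfg)
  if (is_local_unavailable(pred)) return(miss)
  list(pred = pred, available = TRUE, source = retrieval$source, k = retrieval$k)
}

within_miss <- function(miss, k) {
  miss$k <- k
  miss
}
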