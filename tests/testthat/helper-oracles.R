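# Independent straight-line oracles (explicit loops, no reuse of package
# internals) and small fixture builders shared across the test files.

# Eq-style sinusoidal embedding, one frequency at a time
naive_dose_embed <- function(d, freqs) {
  out <- numeric(2 * length(freqs))
  for (i in seq_along(freqs)) {
    out[2 * i - 1] <- sin(2 * pi * freqs[i] * d)
    out[2 * i] <- cos(2 * pi * freqs[i] * d)
  }
  out
}

# explicit-loop dense network: weights W[[l]] (in x out), biases b[[l]]
naive_mlp <- function(x, W, b, act = "relu", out_act = "identity") {
  h <- x
  for (l in seq_along(W)) {
    z <- numeric(ncol(W[[l]]))
    for (j in seq_len(ncol(W[[l]]))) {
      s <- b[[l]][j]
      for (i in seq_len(nrow(W[[l]]))) s <- s + h[i] * W[[l]][i, j]
      z[j] <- s
    }
    a <- if (l < length(W)) act else out_act
    h <- if (a == "relu") pmax(z, 0) else z
  }
  h
}

# explicit-loop 1D CNN: embedding lookup, valid convolutions + ReLU,
# global max-pool, linear projection
naive_drug_encode <- function(tokens, par, kernels) {
  X <- par$emb[tokens + 1, , drop = FALSE]
  H <- X
  for (l in seq_along(par$conv)) {
    k <- kernels[l]
    W <- par$conv[[l]]$W
    bb <- par$conv[[l]]$b
    n_out <- ncol(W)
    Lout <- nrow(H) - k + 1
    Z <- matrix(0, Lout, n_out)
    for (t in seq_len(Lout)) {
      # the conv weight rows are laid out as k offset blocks of channels
      w <- numeric(0)
      for (j in 0:(k - 1)) w <- c(w, H[t + j, ])
      for (f in seq_len(n_out)) {
        s <- bb[f]
        for (i in seq_along(w)) s <- s + w[i] * W[i, f]
        Z[t, f] <- s
      }
    }
    H <- pmax(Z, 0)
  }
  pooled <- apply(H, 2, max)
  out <- numeric(ncol(par$proj$W))
  for (j in seq_along(out)) {
    s <- par$proj$b[j]
    for (i in seq_along(pooled)) s <- s + pooled[i] * par$proj$W[i, j]
    out[j] <- s
  }
  out
}

# brute-force directed kNN in (x, y) with union symmetrization + self-loops
naive_knn_adjacency <- function(x, y, knn) {
  n <- length(x)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i) d[j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    nb <- order(d, seq_len(n))[seq_len(min(knn, n - 1))]
    A[i, nb] <- 1
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (A[i, j] == 1) A[j, i] <- 1
  diag(A) <- 1
  A
}

naive_normalize_adjacency <- function(A) {
  n <- nrow(A)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sum(A[i, ])
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- A[i, j] / sqrt(d[i] * d[j])
  out
}

naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# small hand-built combo table
tiny_combo <- function() {
  data.frame(
    drug1 = c("A", "A", "B", "A", "C"),
    drug2 = c("B", "B", "A", "C", "B"),
    dose1 = c(0.1, 0.5, 1.0, 0.1, 0.2),
    dose2 = c(1.0, 1.0, 0.5, 0.3, 0.4),
    cell = c("c1", "c1", "c1", "c1", "c2"),
    response = c(0.9, 0.7, 0.55, 0.8, 0.6),
    stringsAsFactors = FALSE
  )
}

# a quickly trained tiny global model over a small synthetic dataset, used
# wherever tests need real encoders / features; cached per session
tiny_fit_env <- new.env()
tiny_global_model <- function() {
  if (is.null(tiny_fit_env$gm)) {
    ds <- generate_dataset(synthetic_config(n_drugs = 4, n_cells = 2, seed = 11))
    cfg <- global_model_config(
      drug = drug_encoder_config(embed_dim = 8, filters = c(8, 8),
                                 kernels = c(3, 3), out_dim = 8),
      dose = dose_embedder_config(n_freq = 4),
      cell = cell_encoder_config(hidden = c(16, 8), out_dim = 4),
      head_hidden = c(16), epochs = 15, max_length = 32, seed = 5
    )
    tiny_fit_env$ds <- ds
    tiny_fit_env$gm <- train_global(ds$combo, ds$drugs, ds$expression, cfg)
  }
  list(gm = tiny_fit_env$gm, ds = tiny_fit_env$ds)
}
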