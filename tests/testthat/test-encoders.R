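test_that("SMILES tokenization pads, truncates and maps unknowns to UNK", {
  vocab <- smiles_vocabulary(c("CCO", "c1ccncc1"), max_length = 5)
  expect_equal(vocab$pad, 0L)
  expect_equal(vocab$unk, 1L)
  # contiguous indices from 0
  expect_equal(sort(c(vocab$pad, vocab$unk, unname(vocab$index))),
               0:(vocab$size - 1L))

  toks <- tokenize_smiles("CCO", vocab)
  expect_length(toks, 5)
  expect_equal(toks[1:3], unname(vocab$index[c("C", "C", "O")]))
  expect_equal(toks[4:5], c(0L, 0L))

  toks2 <- tokenize_smiles("C%O", vocab)  # % not in vocabulary
  expect_equal(toks2[2], vocab$unk)

  long <- strrep("C", 200)
  expect_length(tokenize_smiles(long, smiles_vocabulary("C", 128)), 128)
  expect_error(tokenize_smiles("", vocab), "non-empty")
})

test_that("dose embedding matches the analytic sinusoid values", {
  cfg <- dose_embedder_config(n_freq = 3, transform = "identity")
  e0 <- drop(embed_dose(0, cfg))
  expect_equal(e0[seq(1, 6, 2)], rep(0, 3))  # sin(0)
  expect_equal(e0[seq(2, 6, 2)], rep(1, 3))  # cos(0)

  cfg1 <- dose_embedder_config(n_freq = 1, f_min = 0.25, f_max = 0.26,
                               transform = "identity")
  cfg1$frequencies <- 0.25
  e1 <- drop(embed_dose(1, cfg1))
  expect_equal(e1, c(1, 0), tolerance = 1e-12)

  cfg4 <- dose_embedder_config(n_freq = 4, f_min = 0.1, f_max = 10,
                               transform = "identity")
  expect_equal(drop(embed_dose(0.37, cfg4)),
               naive_dose_embed(0.37, cfg4$frequencies), tolerance = 1e-12)
})

test_that("dose embedding norm and frequency spacing invariants hold", {
  set.seed(1)
  for (rep in 1:25) {
    c_ <- sample(2:16, 1)
    f_min <- runif(1, 0.01, 1)
    f_max <- f_min * runif(1, 2, 100)
    cfg <- dose_embedder_config(n_freq = c_, f_min = f_min, f_max = f_max,
                                transform = "identity")
    # strict log spacing: constant successive ratios
    ratios <- cfg$frequencies[-1] / cfg$frequencies[-c_]
    expect_lt(max(abs(ratios - ratios[1])), 1e-9 * ratios[1])
    d <- runif(1, 0, 50)
    e <- drop(embed_dose(d, cfg))
    pair_norms <- e[seq(1, 2 * c_, 2)]^2 + e[seq(2, 2 * c_, 2)]^2
    expect_equal(pair_norms, rep(1, c_), tolerance = 1e-12)
    expect_equal(sum(e^2), c_, tolerance = 1e-10)
  }
})

test_that("log-min-max transform validates doses and uses the training range", {
  cfg <- dose_embedder_config(n_freq = 2)
  expect_error(embed_dose(1, cfg), "dose_range")
  cfg <- set_dose_range(cfg, c(0.01, 100))
  expect_error(embed_dose(-1, cfg), "positive")
  # the grid midpoint maps to d' = 0.5
  mid <- sqrt(0.01 * 100)
  expect_equal(drop(embed_dose(mid, cfg)),
               naive_dose_embed(0.5, cfg$frequencies), tolerance = 1e-12)
  # raw-dose ablation bypasses the sinusoids
  raw <- dose_embedder_config(sinusoidal = FALSE, dose_range = c(0.01, 100))
  expect_equal(drop(embed_dose(mid, raw)), 0.5, tolerance = 1e-12)
  expect_equal(raw$dim, 1L)
})

test_that("drug encoder is deterministic and matches the explicit-loop oracle", {
  vocab <- smiles_vocabulary(c("CCO", "CCN"), max_length = 8)
  cfg <- drug_encoder_config(embed_dim = 3, filters = c(4, 5),
                             kernels = c(3, 2), out_dim = 6)
  set.seed(0)
  par <- drug_encoder_init(vocab, cfg)
  toks <- tokenize_smiles("CCO", vocab)
  e1 <- encode_drug(toks, par, cfg)
  e2 <- encode_drug(toks, par, cfg)
  expect_identical(e1, e2)
  expect_length(e1, 6)
  expect_equal(e1, naive_drug_encode(toks, par, cfg$kernels), tolerance = 1e-5)

  # all-PAD input with zero weights gives a zero embedding
  zero <- par
  zero$emb[] <- 0
  for (l in seq_along(zero$conv)) {
    zero$conv[[l]]$W[] <- 0
    zero$conv[[l]]$b[] <- 0
  }
  zero$proj$W[] <- 0
  zero$proj$b[] <- 0
  expect_equal(encode_drug(rep(0L, 8), zero, cfg), rep(0, 6))
})

test_that("drug encoder ignores trailing padding beyond the last token", {
  set.seed(3)
  for (rep in 1:10) {
    s <- paste0(sample(c("C", "N", "O", "c", "1"), sample(3:6, 1),
                       replace = TRUE), collapse = "")
    v_short <- smiles_vocabulary(c("CNOc1", s), max_length = 10)
    v_long <- smiles_vocabulary(c("CNOc1", s), max_length = 25)
    cfg <- drug_encoder_config(embed_dim = 4, filters = c(5), kernels = c(3),
                               out_dim = 5)
    par <- drug_encoder_init(v_long, cfg)
    e_long <- encode_drug(tokenize_smiles(s, v_long), par, cfg)
    e_short <- encode_drug(tokenize_smiles(s, v_short), par, cfg)
    expect_equal(e_long, e_short, tolerance = 1e-12)
  }
})

test_that("cell-line encoder matches the explicit-loop MLP oracle", {
  cfg <- cell_encoder_config(hidden = c(7, 6), out_dim = 4)
  set.seed(0)
  par <- cell_encoder_init(5, cfg)
  x <- rnorm(5)
  e <- encode_cell_line(x, par, cfg)
  expect_length(e, 4)
  expect_identical(e, encode_cell_line(x, par, cfg))
  expect_equal(e, naive_mlp(x, par$W, par$b, out_act = "relu"),
               tolerance = 1e-5)
  # zero profile with zero biases stays zero through the ReLU stack
  expect_equal(encode_cell_line(rep(0, 5), par, cfg), rep(0, 4))
  expect_error(encode_cell_line(rnorm(9), par, cfg), "dimension")
})

test_that("joint features concatenate in fixed block order", {
  d1 <- rnorm(8); d2 <- rnorm(8); r1 <- rnorm(4); r2 <- rnorm(4); cell <- rnorm(6)
  f <- build_joint_feature(d1, d2, r1, r2, cell)
  expect_length(f, 30)
  expect_equal(f[1:8], d1)
  expect_equal(f[9:16], d2)
  expect_equal(f[17:20], r1)
  expect_equal(f[21:24], r2)
  expect_equal(f[25:30], cell)
  swapped <- build_joint_feature(d2, d1, r2, r1, cell)
  expect_equal(swapped[1:8], d2)
  expect_equal(swapped[17:20], r2)
  expect_equal(sort(f), sort(swapped))
})
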