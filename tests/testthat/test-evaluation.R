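test_that("Pearson correlation matches the textbook formula", {
  expect_equal(pearson_cc(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_cc(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(50)
    y <- 0.3 * x + rnorm(50)
    expect_equal(pearson_cc(x, y), naive_pearson(x, y), tolerance = 1e-10)
    expect_equal(pearson_cc(x, y), pearson_cc(y, x))
  }
  expect_error(pearson_cc(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_cc(1:3, 1:4), "equal length")
})

test_that("scenario splits hold out the right units and partition them", {
  ds <- generate_dataset(synthetic_config(n_drugs = 5, n_cells = 2, seed = 41))
  combo <- ds$combo  # 10 pairs x 2 cells x 25

  s2 <- make_scenario_split(combo, "S2", n_folds = 5, seed = 2)
  pair_of <- function(d) paste(pmin(d$drug1, d$drug2), pmax(d$drug1, d$drug2))
  for (sp in s2) {
    expect_length(intersect(sp$train_idx, sp$test_idx), 0)
    test_pairs <- unique(pair_of(combo[sp$test_idx, ]))
    expect_length(test_pairs, 2)  # 10 pairs / 5 folds
    # the whole matrix of a held-out pair is in test, for every cell
    expect_equal(sum(sp$test_idx %in% which(pair_of(combo) %in% test_pairs)),
                 length(sp$test_idx))
    expect_false(any(pair_of(combo[sp$train_idx, ]) %in% test_pairs))
    expect_true(sp$mono_included)
  }
  # folds partition the pair set
  all_test <- unlist(lapply(s2, function(sp) sp$test_idx))
  expect_equal(sort(all_test), seq_len(nrow(combo)))

  s3 <- make_scenario_split(combo, "S3", n_folds = 5, seed = 2)
  expect_false(any(vapply(s3, `[[`, logical(1), "mono_included")))

  # S1: each fold holds out 5 of the 25 cells of every matrix; the folds
  # jointly exhaust each matrix
  s1 <- make_scenario_split(combo, "S1", n_folds = 5, seed = 3)
  key <- canonical_pair_key(combo)
  for (sp in s1) {
    per_matrix <- table(key[sp$test_idx])
    expect_true(all(per_matrix == 5))
  }
  expect_equal(sort(unlist(lapply(s1, `[[`, "test_idx"))), seq_len(nrow(combo)))

  # new-cell and new-drug hold out whole units
  nc <- make_scenario_split(combo, "new-cell", n_folds = 2, seed = 4)
  for (sp in nc) {
    expect_length(intersect(unique(combo$cell[sp$train_idx]),
                            unique(combo$cell[sp$test_idx])), 0)
  }
  nd <- make_scenario_split(combo, "new-drug", n_folds = 5, seed = 4)
  for (sp in nd) {
    train_drugs <- unique(c(combo$drug1[sp$train_idx], combo$drug2[sp$train_idx]))
    held <- setdiff(unique(c(combo$drug1, combo$drug2)), train_drugs)
    test_rows <- combo[sp$test_idx, ]
    expect_true(all(test_rows$drug1 %in% held | test_rows$drug2 %in% held))
    expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  }
  expect_equal(sort(unlist(lapply(nd, `[[`, "test_idx"))), seq_len(nrow(combo)))

  expect_error(make_scenario_split(combo, "new-cell", n_folds = 5), "fewer")
})

test_that("a smoke experiment produces a complete, deterministic report", {
  cfg <- list(
    data = list(simulate = list(n_drugs = 4, n_cells = 2, noise_sd = 0.05)),
    scenario = list(name = "S1", folds = 5, run_folds = 1),
    global = list(epochs = 15,
                  drug = list(embed_dim = 6, filters = 8, kernels = 3, out_dim = 8),
                  dose = list(n_freq = 4),
                  cell = list(hidden = c(16, 8), out_dim = 4),
                  head_hidden = 16, max_length = 32),
    local = list(epochs = 40, hidden = 16),
    seed = 6
  )
  rep1 <- run_experiment(cfg, variants = c("full", "global-only"))
  expect_s3_class(rep1, "evaluation_report")
  expect_true(all(is.finite(rep1$results$pcc)))
  expect_true(all(rep1$results$pcc >= -1 & rep1$results$pcc <= 1))
  expect_equal(sort(unique(rep1$results$variant)), c("full", "global-only"))
  expect_equal(nrow(rep1$predictions), rep1$results$n_test[1])
  expect_true(all(c("global_pred", "local_pred", "local_source", "final_pred")
                  %in% names(rep1$predictions)))
  expect_named(rep1$seeds, c("master", "data", "split", "fold1"))

  # rerunning with the same master seed reproduces the report exactly
  rep2 <- run_experiment(cfg, variants = c("full", "global-only"))
  expect_identical(rep1$results, rep2$results)
  expect_identical(rep1$predictions, rep2$predictions)

  expect_output(print(rep1), "global-only")
})

test_that("forcing the global-only aggregator reproduces the standalone global model", {
  cfg <- list(
    data = list(simulate = list(n_drugs = 4, n_cells = 2, noise_sd = 0.05)),
    scenario = list(name = "S1", folds = 5, run_folds = 1),
    global = list(epochs = 15,
                  drug = list(embed_dim = 6, filters = 8, kernels = 3, out_dim = 8),
                  dose = list(n_freq = 4),
                  cell = list(hidden = c(16, 8), out_dim = 4),
                  head_hidden = 16, max_length = 32),
    local = list(epochs = 30, hidden = 16),
    aggregator = list(mode = "global-only"),
    seed = 9
  )
  rep <- run_experiment(cfg, variants = c("full", "global-only"))
  pcc <- with(rep$results, split(pcc, variant))
  expect_identical(pcc$`full`, pcc$`global-only`)
  expect_identical(rep$predictions$final_pred, rep$predictions$global_pred)
})

test_that("forcing the Bliss path without monotherapy data is rejected", {
  ds <- generate_dataset(synthetic_config(n_drugs = 4, n_cells = 2, seed = 3))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  cfg <- list(
    data = list(files = list(combos = file.path(dir, "combos.csv"),
                             drugs = file.path(dir, "drugs.csv"),
                             cells = file.path(dir, "expression.csv"))),
    scenario = list(name = "S2", folds = 3, run_folds = 1),
    local = list(mode = "bliss"),
    seed = 1
  )
  expect_error(run_experiment(cfg), "mono")
})
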