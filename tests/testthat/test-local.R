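test_that("exact retrieval matches on the unordered pair and excludes the query's doses", {
  train <- data.frame(
    drug1 = c("A", "A", "B", "C", "C"),
    drug2 = c("B", "B", "A", "D", "D"),
    dose1 = c(0.1, 0.2, 2.0, 0.1, 0.2),
    dose2 = c(1.0, 1.0, 0.3, 1.0, 1.0),
    cell = "c1",
    response = 1:5 / 10,
    stringsAsFactors = FALSE
  )
  query <- list(drug1 = "A", drug2 = "B", dose1 = 0.5, dose2 = 0.5, cell = "c1")
  res <- retrieve_matching_samples(query, train)
  expect_s3_class(res, "retrieval_result")
  expect_equal(res$k, 3)
  expect_equal(res$source, "exact-match")
  expect_true(res$available)
  # the row stored as (B, A) was flipped into the query orientation,
  # with its doses travelling along
  expect_equal(res$samples$drug1, rep("A", 3))
  expect_equal(res$samples$dose1[3], 0.3)
  expect_equal(res$samples$dose2[3], 2.0)

  # the query's own dose combination is excluded (also when stored swapped)
  q2 <- list(drug1 = "A", drug2 = "B", dose1 = 0.3, dose2 = 2.0, cell = "c1")
  expect_equal(retrieve_matching_samples(q2, train)$k, 2)

  none <- retrieve_matching_samples(
    list(drug1 = "X", drug2 = "Y", dose1 = 1, dose2 = 1, cell = "c1"), train)
  expect_equal(none$k, 0)
  expect_false(none$available)
})

test_that("Bliss pseudo-curves are the outer product of the mono curves", {
  m1 <- data.frame(drug = "A", dose = c(0.1, 1), cell = "c1",
                   response = c(0.5, 0.5), stringsAsFactors = FALSE)
  m2 <- data.frame(drug = "B", dose = c(0.2, 2), cell = "c1",
                   response = c(0.4, 1.0), stringsAsFactors = FALSE)
  ps <- bliss_pseudo_curve(m1, m2)
  expect_equal(nrow(ps), 4)
  expect_true(all(ps$pseudo))
  expect_equal(ps$response[ps$dose1 == 0.1 & ps$dose2 == 0.2], 0.5 * 0.4)

  # an inactive partner (g2 = 1) reproduces drug 1's curve
  m2b <- transform(m2, response = 1)
  psb <- bliss_pseudo_curve(m1, m2b)
  expect_equal(psb$response, rep(m1$response, times = 2))

  # 5 x 5 grids: all 25 cells equal the explicit two-loop outer product
  set.seed(8)
  g1 <- runif(5); g2 <- runif(5)
  m5a <- data.frame(drug = "A", dose = 10^(0:4 - 2), cell = "c1", response = g1)
  m5b <- data.frame(drug = "B", dose = 10^(0:4 - 2), cell = "c1", response = g2)
  ps5 <- bliss_pseudo_curve(m5a, m5b)
  expect_equal(nrow(ps5), 25)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(ps5$response[ps5$dose1 == m5a$dose[i] & ps5$dose2 == m5b$dose[j]],
                 g1[i] * g2[j], tolerance = 1e-12)
  }

  # percent-growth inputs are rescaled before multiplication
  p1 <- transform(m1, response = response * 100)
  p2 <- transform(m2, response = response * 100)
  expect_equal(bliss_pseudo_curve(p1, p2, scale = "percent")$response, ps$response)
  expect_warning(
    bliss_pseudo_curve(transform(m1, response = c(105, 50)), p2, scale = "percent"),
    "clip")
  expect_error(bliss_pseudo_curve(transform(m1, response = c(1.2, 0.5)), m2),
               "\\[0, 1\\]")
})

test_that("feature-similarity retrieval matches a brute-force cosine ranking", {
  q <- c(1, 0, 0)
  pool <- rbind(c(2, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 0, 0), c(1, 0.1, 0))
  res <- retrieve_by_feature_similarity(q, pool, K = 2)
  expect_equal(res$indices[1], 1L)  # collinear vector ranks first
  expect_equal(res$source, "feature-similarity")

  expect_equal(retrieve_by_feature_similarity(q, pool, K = 100)$k, 5L)

  set.seed(4)
  for (rep in 1:20) {
    pool <- matrix(rnorm(10 * 6), 10, 6)
    qf <- rnorm(6)
    got <- retrieve_by_feature_similarity(qf, pool, K = 3)$indices
    cosd <- apply(pool, 1, function(r)
      1 - sum(r * qf) / sqrt(sum(r^2) * sum(qf^2)))
    expect_equal(got, order(cosd, seq_along(cosd))[1:3])
  }
  expect_error(retrieve_by_feature_similarity(c(0, 0, 0), pool[, 1:3], K = 1),
               "zero-norm")
})

test_that("graph construction reproduces a brute-force 4-NN dose adjacency", {
  tf <- tiny_global_model()
  gm <- tf$gm
  ds <- tf$ds
  key <- canonical_pair_key(ds$combo)
  rows <- ds$combo[key == key[1], ]
  query <- rows[13, ]
  pool <- rows[-13, ]
  res <- retrieve_matching_samples(query, pool)
  g <- build_semisupervised_graph(query, res, gm)
  expect_s3_class(g, "semisupervised_graph")
  n <- res$k + 1
  expect_equal(dim(g$adjacency), c(n, n))
  expect_true(isSymmetric(g$adjacency))
  expect_equal(diag(g$adjacency), rep(1, n))
  expect_equal(sum(!g$labeled_mask), 1)
  expect_equal(g$query_index, n)
  expect_true(is.na(g$labels[n]))
  expect_equal(ncol(g$features), gm$feature_dim)

  nodes <- rbind(res$samples[, 1:6], cbind(query[, 1:6]))
  oracle <- naive_knn_adjacency(log(nodes$dose1), log(nodes$dose2), 4)
  expect_equal(unname(g$adjacency), oracle)

  # 3 retrieved nodes with knn = 4: capped at n - 1, complete graph
  res3 <- res
  res3$samples <- res$samples[1:3, ]
  res3$k <- 3L
  g3 <- build_semisupervised_graph(query, res3, gm)
  expect_equal(unname(g3$adjacency), matrix(1, 4, 4))

  # unavailable retrieval yields a typed outcome, not an error
  res0 <- res
  res0$samples <- res$samples[0, ]
  res0$k <- 0L
  res0$available <- FALSE
  expect_true(is_local_unavailable(build_semisupervised_graph(query, res0, gm)))
})

test_that("random small graphs match the exhaustive kNN oracle", {
  set.seed(6)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    A <- pairdose:::knn_dose_adjacency(x, y, 4L)
    expect_equal(A, naive_knn_adjacency(x, y, 4))
    expect_true(isSymmetric(A))
    expect_equal(diag(A), rep(1, n))
    expect_true(all(rowSums(A) >= 1))  # no isolated nodes
  }
})

test_that("adjacency normalization matches the explicit-loop formula", {
  expect_equal(normalize_adjacency(diag(4)), diag(4))
  A2 <- matrix(1, 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))
  set.seed(9)
  for (rep in 1:10) {
    n <- 6
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A <- pmax(A, t(A))
    diag(A) <- 1
    Ahat <- normalize_adjacency(A)
    expect_equal(Ahat, naive_normalize_adjacency(A), tolerance = 1e-12)
    expect_true(isSymmetric(Ahat))
    # the propagation operator is non-expansive: spectral radius <= 1
    expect_lte(max(abs(eigen(Ahat, symmetric = TRUE)$values)), 1 + 1e-12)
  }
  expect_error(normalize_adjacency(matrix(c(1, 1, 0, 1), 2, 2)), "symmetric")
})

test_that("GCN forward is exact on toy graphs and permutation-equivariant", {
  toy <- structure(list(
    features = matrix(c(1, 0, 2, -1, 3, 1), 3, 2, byrow = TRUE),
    adjacency = matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3),
    labels = c(0.5, 1, NA), labeled_mask = c(TRUE, TRUE, FALSE),
    query_index = 3L), class = "semisupervised_graph")

  # zero weights give zero output
  par0 <- list(W = list(matrix(0, 2, 4), matrix(0, 4, 1)),
               b = list(numeric(4), numeric(1)))
  expect_equal(gcn_forward(toy, par0), rep(0, 3))

  # one identity layer, no nonlinearity: output is exactly Ahat X
  parI <- list(W = list(diag(2)))
  Ahat <- naive_normalize_adjacency(toy$adjacency)
  expect_equal(gcn_forward(toy, parI, activation = "identity"),
               Ahat %*% toy$features, tolerance = 1e-10)

  # permuting the nodes permutes the outputs identically
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    A <- pairdose:::knn_dose_adjacency(rnorm(n), rnorm(n), 3L)
    X <- matrix(rnorm(n * 5), n, 5)
    par <- list(W = list(matrix(rnorm(5 * 4), 5, 4), matrix(rnorm(4), 4, 1)),
                b = list(rnorm(4), rnorm(1)))
    g1 <- structure(list(features = X, adjacency = A),
                    class = "semisupervised_graph")
    out1 <- gcn_forward(g1, par)
    perm <- sample(n)
    g2 <- structure(list(features = X[perm, , drop = FALSE],
                         adjacency = A[perm, perm]),
                    class = "semisupervised_graph")
    expect_equal(gcn_forward(g2, par), out1[perm], tolerance = 1e-10)
  }
})

test_that("per-query GCN training recovers constant and smooth label fields", {
  tf <- tiny_global_model()
  gm <- tf$gm
  ds <- tf$ds
  key <- canonical_pair_key(ds$combo)
  rows <- ds$combo[key == key[1], ]
  query <- rows[13, ]  # center of the 5 x 5 grid
  pool <- rows[-13, ]

  res <- retrieve_matching_samples(query, pool)
  g <- build_semisupervised_graph(query, res, gm)

  # constant labels are recovered on a connected graph
  gc <- g
  gc$labels[gc$labeled_mask] <- 5.0
  pred <- train_local_predict(gc, local_gcn_config(epochs = 300, seed = 1))
  expect_lt(abs(pred - 5.0), 0.1)

  # noise-free linear field over (log r1, log r2), query at the grid center
  gl <- g
  nodes <- rbind(res$samples[, 1:6], cbind(query[, 1:6]))
  lin <- 0.2 * log(nodes$dose1) - 0.1 * log(nodes$dose2) + 1
  gl$labels <- ifelse(gl$labeled_mask, lin, NA)
  predl <- train_local_predict(gl, local_gcn_config(epochs = 300, seed = 1))
  rng <- diff(range(lin))
  expect_lt(abs(predl - lin[length(lin)]), 0.1 * rng)

  # reproducibility and the k_min threshold
  expect_identical(train_local_predict(gc, local_gcn_config(epochs = 50, seed = 3)),
                   train_local_predict(gc, local_gcn_config(epochs = 50, seed = 3)))
  g1 <- g
  keep <- c(1, nrow(g$features))
  g1$features <- g$features[keep, , drop = FALSE]
  g1$adjacency <- matrix(1, 2, 2)
  g1$labels <- g$labels[keep]
  g1$labeled_mask <- c(TRUE, FALSE)
  g1$query_index <- 2L
  expect_true(is_local_unavailable(train_local_predict(g1, local_gcn_config(k_min = 2))))
})

test_that("the graph-free local MLP predicts from retrieved samples", {
  tf <- tiny_global_model()
  gm <- tf$gm
  ds <- tf$ds
  key <- canonical_pair_key(ds$combo)
  rows <- ds$combo[key == key[2], ]
  query <- rows[13, ]
  res <- retrieve_matching_samples(query, rows[-13, ])
  g <- build_semisupervised_graph(query, res, gm)
  gc <- g
  gc$labels[gc$labeled_mask] <- 2.0
  pred <- local_mlp_predict(gc, local_gcn_config(epochs = 300, seed = 2))
  expect_lt(abs(pred - 2.0), 0.15)
})

test_that("the local cascade falls back from exact to Bliss to features", {
  tf <- tiny_global_model()
  gm <- tf$gm
  ds <- tf$ds
  q <- ds$combo[1, ]
  pool <- ds$combo
  cfg <- local_gcn_config(epochs = 30)

  r1 <- predict_local(gm, q, pool, mono = ds$mono, mode = "auto", cfg = cfg)
  expect_true(r1$available)
  expect_equal(r1$source, "exact-match")

  # drop the query's pair from the pool: Bliss fallback
  key <- canonical_pair_key(pool)
  pool2 <- pool[key != canonical_pair_key(q), ]
  r2 <- predict_local(gm, q, pool2, mono = ds$mono, mode = "auto", cfg = cfg)
  expect_true(r2$available)
  expect_equal(r2$source, "bliss-pseudo")

  # no monotherapy data either: feature-similarity fallback
  r3 <- predict_local(gm, q, pool2, mono = NULL, mode = "auto", cfg = cfg)
  expect_true(r3$available)
  expect_equal(r3$source, "feature-similarity")
  expect_equal(r3$k, cfg$K)

  r4 <- predict_local(gm, q, pool2, mono = NULL, mode = "off", cfg = cfg)
  expect_false(r4$available)
  expect_equal(r4$source, "none")
})
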