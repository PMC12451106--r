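test_that("fused similarity mixes attribute and structure blocks", {
  v <- random_views(3, 4, seed = 2)
  Zc <- rbind(v$Z_v1, v$Z_v2)
  Ec <- rbind(v$E_v1, v$E_v2)
  expect_equal(fused_similarity(v, 1), Zc %*% t(Zc))
  expect_equal(fused_similarity(v, 0), Ec %*% t(Ec))
  S <- fused_similarity(v, 0.3)
  expect_equal(S, 0.3 * Zc %*% t(Zc) + 0.7 * Ec %*% t(Ec))
  expect_true(all(abs(S) <= 1 + 1e-12))
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_error(fused_similarity(v, 1.5), "alpha")

  u <- matrix(c(1, 0), 1, 2)
  v1 <- list(Z_v1 = u, Z_v2 = u, E_v1 = u, E_v2 = u, Z_fused = u)
  expect_equal(fused_similarity(v1, 0.5), matrix(1, 2, 2))
})

test_that("pseudo-labeling recovers planted blobs at the target count", {
  blobs <- make_blobs(2, n_per = 30, seed = 4)
  pl <- pseudo_labels(blobs$X, K_target = 2, graph_k = 10)
  expect_equal(pl$K, 2L)
  expect_equal(ari(pl$labels, blobs$labels), 1)
  expect_equal(unname(pl$centers),
               unname(rowsum(blobs$X, pl$labels) /
                      as.vector(table(pl$labels))))

  # identical points collapse to one community
  same <- matrix(1, 10, 3) + 0
  pl1 <- pseudo_labels(same, K_target = 1, graph_k = 3)
  expect_equal(pl1$K, 1L)

  expect_error(pseudo_labels(blobs$X, K_target = 0), "K_target")
  expect_error(pseudo_labels(matrix(rnorm(6), 2), K_target = 3),
               "more cells")
  expect_warning(pseudo_labels(matrix(rnorm(8), 4), K_target = 4,
                               graph_k = 2),
                 "closest partition")
})

test_that("high-confidence selection keeps the closest floor(tau m) cells", {
  blobs <- make_blobs(2, n_per = 5, seed = 6)
  pl <- pseudo_labels(blobs$X, K_target = 2, graph_k = 3)
  expect_equal(high_confidence_set(pl, 1), 1:10)
  expect_length(high_confidence_set(pl, 0.9), 9L)

  # a planted outlier is the one cell dropped at tau = (m-1)/m
  X <- matrix(c(0, 0.1, -0.1, 0.05, 50, 10, 10.1, 9.9, 10.05, 9.95), ncol = 1)
  pl2 <- pseudo_labels(X, K_target = 2, graph_k = 3)
  H <- high_confidence_set(pl2, 0.9)
  expect_false(5L %in% H)  # the cell at 50 is farthest from its center
  expect_error(high_confidence_set(pl2, 0), "tau")
})

test_that("indicator matrix encodes label equality", {
  expect_equal(indicator_matrix(c(0, 0, 1)),
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3))
  expect_equal(indicator_matrix(rep(2, 4)), matrix(1, 4, 4))
  expect_equal(indicator_matrix(1:3), diag(3))
})

test_that("weight matrix follows the focusing law", {
  m <- 3
  set.seed(8)
  S <- matrix(runif(36, -1, 1), 6, 6)
  S <- (S + t(S)) / 2
  Q <- indicator_matrix(c(1, 1, 2))
  H <- c(1, 2)
  W <- weight_matrix(S, Q, H, beta = 2)
  rng <- range(S)
  Sn <- (S - rng[1]) / (rng[2] - rng[1])
  # weighted only where both cells are high-confidence (cell of row r is
  # ((r - 1) mod m) + 1)
  inH <- rep(1:3 %in% H, 2)
  expect_true(all(W[!outer(inH, inH, `&`)] == 1))
  expect_equal(W[1, 2], abs(Q[1, 2] - Sn[1, 2])^2)
  expect_equal(W[1, 5], abs(Q[1, 2] - Sn[1, 5])^2)  # cross-view pair (1,2)

  # closed-form corners: easiest positive -> 0, hardest negative -> 1
  S2 <- matrix(c(0, 1, 1, 0), 2, 2)
  Wpos <- weight_matrix(S2, matrix(1, 1, 1), 1L, beta = 3)
  expect_equal(Wpos[1, 2], 0)   # Q = 1, Norm(S) = 1
  Wneg <- weight_matrix(S2, matrix(0, 1, 1), 1L, beta = 3)
  expect_equal(Wneg[1, 2], 1)   # Q = 0, Norm(S) = 1
  # |1 - 0.5|^2 = 0.25
  S3 <- matrix(c(0, 0.5, 0.5, 1), 2, 2)
  W3 <- weight_matrix(S3, matrix(1, 1, 1), 1L, beta = 2)
  expect_equal(W3[1, 2], 0.25)

  expect_warning(Wd <- weight_matrix(matrix(1, 2, 2), matrix(1, 1, 1),
                                     1L, beta = 2),
                 "degenerate")
  expect_equal(Wd[1, 2], abs(1 - 0.5)^2)
  expect_error(weight_matrix(S, Q, H, beta = -1), "beta")
})

test_that("weighting law holds on random draws", {
  set.seed(123)
  for (rep in 1:1000) {
    m <- sample(2:6, 1)
    S <- matrix(runif(4 * m * m, -1, 1), 2 * m, 2 * m)
    Q <- indicator_matrix(sample(1:2, m, replace = TRUE))
    H <- sort(sample(m, sample(m, 1)))
    beta <- sample(c(0, 0.5, 1, 2, 5), 1)
    W <- weight_matrix(S, Q, H, beta)
    expect_true(all(W >= 0 & W <= 1))
    inH <- rep(seq_len(m) %in% H, 2)
    expect_true(all(W[!outer(inH, inH, `&`)] == 1))
    if (beta == 0) expect_true(all(W == 1))
  }
  # monotonicity in Norm(S): increasing for Q=0 pairs, decreasing for Q=1
  set.seed(99)
  S <- matrix(runif(16, -1, 1), 4, 4); S <- (S + t(S)) / 2
  rngS <- range(S)
  Sn <- (S - rngS[1]) / (rngS[2] - rngS[1])
  for (beta in c(0.5, 1, 2)) {
    W0 <- weight_matrix(S, matrix(0, 2, 2), 1:2, beta)  # all pairs negative
    W1 <- weight_matrix(S, matrix(1, 2, 2), 1:2, beta)  # all pairs positive
    expect_equal(W0, Sn^beta)
    expect_equal(W1, (1 - Sn)^beta)
    ord <- order(Sn)
    expect_true(all(diff(W0[ord]) >= -1e-12))
    expect_true(all(diff(W1[ord]) <= 1e-12))
  }
})

test_that("hard-sample loss matches the scalar InfoNCE oracle", {
  # single cell: no negatives, loss is exactly zero
  v1 <- random_views(1, 3, seed = 1)
  S1 <- fused_similarity(v1, 0.5)
  expect_equal(hard_sample_loss(S1, matrix(1, 2, 2), 1), 0)

  set.seed(31)
  for (m in 2:8) {
    v <- random_views(m, 4, seed = m)
    S <- fused_similarity(v, 0.5)
    W1 <- matrix(1, 2 * m, 2 * m)
    expect_equal(hard_sample_loss(S, W1, m), infonce_oracle(S, W1, m),
                 tolerance = 1e-6)
    # and with a genuine non-uniform weight matrix
    Q <- indicator_matrix(sample(1:2, m, replace = TRUE))
    W <- weight_matrix(S, Q, seq_len(m), beta = 2)
    expect_equal(hard_sample_loss(S, W, m), infonce_oracle(S, W, m),
                 tolerance = 1e-6)
  }
})

test_that("beta = 0 weighting reproduces the unweighted loss exactly", {
  m <- 5
  v <- random_views(m, 4, seed = 9)
  S <- fused_similarity(v, 0.5)
  Q <- indicator_matrix(c(1, 1, 2, 2, 2))
  W0 <- weight_matrix(S, Q, 1:5, beta = 0)
  expect_identical(hard_sample_loss(S, W0, m),
                   hard_sample_loss(S, matrix(1, 2 * m, 2 * m), m))
})

test_that("loss is invariant under a common permutation of the cells", {
  m <- 6
  v <- random_views(m, 4, seed = 11)
  S <- fused_similarity(v, 0.4)
  base <- hard_sample_loss(S, matrix(1, 2 * m, 2 * m), m)
  for (rep in 1:5) {
    perm <- sample(m)
    vp <- v
    for (nm in c("Z_v1", "Z_v2", "E_v1", "E_v2"))
      vp[[nm]] <- v[[nm]][perm, , drop = FALSE]
    Sp <- fused_similarity(vp, 0.4)
    expect_equal(hard_sample_loss(Sp, matrix(1, 2 * m, 2 * m), m), base,
                 tolerance = 1e-12)
  }
})

test_that("raising a positive-pair similarity lowers the loss", {
  m <- 4
  v <- random_views(m, 4, seed = 13)
  S <- fused_similarity(v, 0.5)
  W <- matrix(1, 2 * m, 2 * m)
  base <- hard_sample_loss(S, W, m)
  S2 <- S
  S2[1, 1 + m] <- S2[1, 1 + m] + 0.05
  S2[1 + m, 1] <- S2[1 + m, 1] + 0.05
  expect_lt(hard_sample_loss(S2, W, m), base)
})

test_that("the analytic similarity gradient matches finite differences", {
  m <- 3
  v <- random_views(m, 4, seed = 17)
  S <- fused_similarity(v, 0.5)
  Q <- indicator_matrix(c(1, 2, 2))
  W <- weight_matrix(S, Q, 1:3, beta = 2)
  g <- schsc:::hard_sample_loss_grad(S, W, m)$grad_S
  h <- 1e-6
  for (idx in list(c(1, 2), c(2, 5), c(4, 6), c(1, 4))) {
    Sp <- S; Sp[idx[1], idx[2]] <- Sp[idx[1], idx[2]] + h
    Sm <- S; Sm[idx[1], idx[2]] <- Sm[idx[1], idx[2]] - h
    fd <- (hard_sample_loss(Sp, W, m) - hard_sample_loss(Sm, W, m)) / (2 * h)
    expect_equal(g[idx[1], idx[2]], fd, tolerance = 1e-5)
  }
})
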