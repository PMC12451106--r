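test_that("NB log pmf matches closed forms and the stats oracle", {
  # x = 0 collapses to theta * log(theta / (theta + mu))
  for (mu in c(0.5, 2, 7)) {
    for (th in c(0.4, 1, 3)) {
      expect_equal(nb_log_pmf(0, mu, th), th * log(th / (th + mu)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(nb_log_pmf(0, 1, 1), log(1 / 2), tolerance = 1e-12)
  # independent oracle: R's dnbinom in the (size, mu) parameterization
  set.seed(2)
  x <- rpois(50, 4)
  mu <- runif(50, 0.1, 20)
  th <- runif(50, 0.2, 50)
  expect_equal(nb_log_pmf(x, mu, th),
               dnbinom(x, size = th, mu = mu, log = TRUE),
               tolerance = 1e-10)
})

test_that("NB pmf normalizes to one over the support", {
  for (mu in c(0.5, 2, 5, 10)) {
    for (th in c(0.3, 1, 2, 10)) {
      expect_equal(sum(exp(nb_log_pmf(0:2000, mu, th))), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("NB approaches the Poisson at large dispersion", {
  for (mu in c(0.5, 2, 10)) {
    x <- 0:20
    expect_equal(nb_log_pmf(x, mu, 1e6), dpois(x, mu, log = TRUE),
                 tolerance = 1e-3)
  }
})

test_that("ZINB log pmf mixes the zero mass correctly", {
  # pi = 0 degenerates to the NB
  x <- c(0, 1, 5)
  expect_equal(zinb_log_pmf(x, 0, 2, 1), nb_log_pmf(x, 2, 1))
  # hand value: 0.5 + 0.5 * NB(0; 1, 1) = 0.75
  expect_equal(zinb_log_pmf(0, 0.5, 1, 1), log(0.75), tolerance = 1e-12)
  # positive counts: delta mass vanishes
  for (pi in c(0.1, 0.5, 0.9)) {
    expect_equal(zinb_log_pmf(3, pi, 2, 1.5),
                 log(1 - pi) + nb_log_pmf(3, 2, 1.5), tolerance = 1e-12)
  }
  # normalization of the mixture
  expect_equal(sum(exp(zinb_log_pmf(0:2000, 0.3, 5, 2))), 1,
               tolerance = 1e-8)
})

test_that("the batch NLL is an elementwise double sum", {
  prm1 <- structure(list(Pi = matrix(0.5), Mu = matrix(1),
                         Theta = matrix(1)), class = "schsc_zinb_params")
  expect_equal(zinb_nll(matrix(0), prm1), -log(0.75), tolerance = 1e-12)

  # all zeros fully explained by dropout
  pz <- structure(list(Pi = matrix(1 - 1e-6, 2, 3),
                       Mu = matrix(1, 2, 3), Theta = matrix(1, 2, 3)),
                  class = "schsc_zinb_params")
  expect_lt(abs(zinb_nll(matrix(0, 2, 3), pz)), 1e-4)

  # scalar-loop oracle on a random 3 x 4 instance
  set.seed(4)
  x <- matrix(rpois(12, 2), 3, 4)
  Pi <- matrix(runif(12, 0.05, 0.6), 3, 4)
  Mu <- matrix(runif(12, 0.5, 6), 3, 4)
  Th <- matrix(runif(12, 0.5, 4), 3, 4)
  oracle <- 0
  for (i in 1:3) {
    for (j in 1:4) {
      nb <- dnbinom(x[i, j], size = Th[i, j], mu = Mu[i, j])
      p <- (1 - Pi[i, j]) * nb + if (x[i, j] == 0) Pi[i, j] else 0
      oracle <- oracle - log(p)
    }
  }
  prm <- structure(list(Pi = Pi, Mu = Mu, Theta = Th),
                   class = "schsc_zinb_params")
  expect_equal(zinb_nll(x, prm), oracle, tolerance = 1e-8)
  expect_error(zinb_nll(matrix(-1), prm1), "negative")
})

test_that("NLL gradients match central finite differences", {
  set.seed(6)
  x <- matrix(c(0, 0, 2, 5, 1, 0), 2, 3)
  Pi <- matrix(runif(6, 0.1, 0.7), 2, 3)
  Mu <- matrix(runif(6, 0.5, 5), 2, 3)
  Th <- matrix(runif(6, 0.5, 3), 2, 3)
  nll <- function(Pi, Mu, Th) {
    -sum(zinb_log_pmf(x, Pi, Mu, Th))
  }
  g <- schsc:::zinb_nll_grad(x, Pi, Mu, Th)
  h <- 1e-6
  for (i in seq_len(6)) {
    bump <- function(M, d) { M[i] <- M[i] + d; M }
    expect_equal(g$d_pi[i],
                 (nll(bump(Pi, h), Mu, Th) - nll(bump(Pi, -h), Mu, Th)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(g$d_mu[i],
                 (nll(Pi, bump(Mu, h), Th) - nll(Pi, bump(Mu, -h), Th)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(g$d_th[i],
                 (nll(Pi, Mu, bump(Th, h)) - nll(Pi, Mu, bump(Th, -h))) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("the NLL is minimized in pi at the excess-zero fraction", {
  set.seed(8)
  mu <- 3; th <- 2; pi_true <- 0.3
  x <- rnbinom(20000, size = th, mu = mu)
  x[runif(20000) < pi_true] <- 0
  grid <- seq(0.01, 0.9, by = 0.01)
  nll_of <- vapply(grid, function(p) -sum(zinb_log_pmf(x, p, mu, th)),
                   numeric(1))
  expect_equal(grid[which.min(nll_of)], pi_true, tolerance = 0.05)
})

test_that("moving mu toward the sample mean lowers the NLL", {
  set.seed(10)
  x <- rnbinom(5000, size = 2, mu = 4)
  nll_at <- function(mu) -sum(zinb_log_pmf(x, 1e-6, mu, 2))
  expect_lt(nll_at(3.5), nll_at(3))
  expect_lt(nll_at(mean(x)), nll_at(3.5))
  expect_lt(nll_at(4.5), nll_at(6))
})

test_that("loss combination follows the smoothing recursion", {
  st <- omega_state("fixed", value = 1)
  out <- combine_losses(2, 3, st)
  expect_equal(out$breakdown$total, 5)
  expect_equal(out$breakdown$omega, 1)

  # dynamic: initialized to the ratio, then exponentially smoothed
  st <- omega_state("dynamic")
  out1 <- combine_losses(4, 4, st)
  expect_equal(out1$breakdown$omega, 1)  # equal losses -> ratio 1
  out2 <- combine_losses(3, 6, out1$state)
  expect_equal(out2$breakdown$omega, 0.9 * 1 + 0.1 * (3 / 6),
               tolerance = 1e-12)
  out3 <- combine_losses(1, 8, out2$state)
  expect_equal(out3$breakdown$omega,
               0.9 * out2$breakdown$omega + 0.1 * (1 / 8),
               tolerance = 1e-12)
  expect_equal(out3$breakdown$total,
               1 + out3$breakdown$omega * 8, tolerance = 1e-12)

  expect_error(combine_losses(NaN, 1, omega_state("dynamic")), "non-finite")
  expect_error(omega_state("fixed"), "positive omega")
})
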