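#' Negative binomial log pmf (mean/dispersion parameterization)
#'
#' `log NB(x; mu, theta)` with
#' `NB(x) = Gamma(x + theta) / (Gamma(x + 1) Gamma(theta)) *
#' (theta / (theta + mu))^theta * (mu / (theta + mu))^x`,
#' computed via log-gamma for stability. Variance is
#' `mu + mu^2 / theta`; `theta -> Inf` recovers the Poisson.
#' All arguments are vectorized and recycled.
#'
#' @param x non-negative integer counts.
#' @param mu positive means.
#' @param theta positive dispersions.
#' @return log probability mass, same shape as the recycled arguments.
#' @export
nb_log_pmf <- function(x, mu, theta) {
  term_x <- x * (log(mu) - log(theta + mu))
  term_x[x == 0] <- 0                   # avoid 0 * log(0) at tiny mu
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) + term_x
}

#' Zero-inflated negative binomial log pmf
#'
#' `ZINB(x) = pi * delta_0(x) + (1 - pi) * NB(x; mu, theta)`. At `x = 0`
#' the mixture is evaluated in log space via log-sum-exp.
#'
#' @param x non-negative integer counts.
#' @param pi dropout probabilities in `[0, 1)`.
#' @param mu,theta NB parameters as in [nb_log_pmf()].
#' @return log probability mass.
#' @export
zinb_log_pmf <- function(x, pi, mu, theta) {
  nb <- nb_log_pmf(x, mu, theta)
  res <- log1p(-pi) + nb
  z <- x == 0
  if (any(z)) {
    pi_z <- if (length(pi) == 1L) rep(pi, sum(z)) else pi[z]
    a <- log(pi_z)
    b <- res[z]
    mx <- pmax(a, b)
    res[z] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  res
}

#' ZINB negative log-likelihood of raw counts
#'
#' Sum (not mean) of the elementwise negative log pmf of the raw counts
#' of a batch under per-entry decoder parameters; the double sum runs
#' over cells and selected genes. Reported per batch; the dynamic
#' balance weight absorbs the scale.
#'
#' @param x_raw m x p raw count matrix (HVG-restricted).
#' @param params a [zinb_decode()] result (fields `Pi`, `Mu`, `Theta`).
#' @return Scalar negative log-likelihood.
#' @export
zinb_nll <- function(x_raw, params) {
  if (any(x_raw < 0)) stop("negative counts")
  stopifnot(all(dim(x_raw) == dim(params$Pi)))
  -sum(zinb_log_pmf(x_raw, params$Pi, params$Mu, params$Theta))
}

# Gradients of the NLL with respect to Pi, Mu, Theta (matrices).
zinb_nll_grad <- function(x, Pi, Mu, Theta) {
  z <- x == 0
  d_pi <- matrix(0, nrow(x), ncol(x))
  d_mu <- matrix(0, nrow(x), ncol(x))
  d_th <- matrix(0, nrow(x), ncol(x))

  # x > 0: log p = log(1 - pi) + log NB(x)
  if (any(!z)) {
    xi <- x[!z]; p <- Pi[!z]; m <- Mu[!z]; t <- Theta[!z]
    d_pi[!z] <- -1 / (1 - p)
    d_mu[!z] <- xi / m - (xi + t) / (t + m)
    d_th[!z] <- digamma(xi + t) - digamma(t) +
      log(t / (t + m)) + 1 - (xi + t) / (t + m)
  }
  # x = 0: log p = log(pi + (1 - pi) NB0), NB0 = (theta/(theta+mu))^theta
  if (any(z)) {
    p <- Pi[z]; m <- Mu[z]; t <- Theta[z]
    log_nb0 <- t * (log(t) - log(t + m))
    nb0 <- exp(log_nb0)
    D <- p + (1 - p) * nb0
    d_pi[z] <- (1 - nb0) / D
    d_mu[z] <- (1 - p) * nb0 * (-t / (t + m)) / D
    d_th[z] <- (1 - p) * nb0 * (log(t / (t + m)) + 1 - t / (t + m)) / D
  }
  # NLL = -sum(log p)
  list(d_pi = -d_pi, d_mu = -d_mu, d_th = -d_th)
}

#' Balance-weight state for the combined objective
#'
#' The total objective is `L = L_hs + omega * L_zinb`. In dynamic mode
#' `omega` tracks the loss-scale ratio by exponential smoothing, updated
#' once per epoch:
#' `omega <- lambda * omega + (1 - lambda) * L_hs / max(L_zinb, eps)`,
#' initialized to the plain ratio the first time it is evaluated. In
#' fixed mode `omega` is a user constant.
#'
#' @param mode `"dynamic"` (default) or `"fixed"`.
#' @param value the fixed `omega` (required when `mode = "fixed"`).
#' @param lambda smoothing factor (default 0.9).
#' @param eps denominator guard (default 1e-8).
#' @return An object of class `schsc_omega`.
#' @export
omega_state <- function(mode = c("dynamic", "fixed"), value = NULL,
                        lambda = 0.9, eps = 1e-8) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(value) || value <= 0))
    stop("fixed mode requires a positive omega value")
  structure(list(mode = mode, value = value, lambda = lambda, eps = eps,
                 omega = if (mode == "fixed") value else NULL),
            class = "schsc_omega")
}

#' Combine the contrastive and ZINB losses
#'
#' Updates the balance weight (dynamic mode) from the detached loss
#' values, then returns the breakdown `total = L_hs + omega * L_zinb`.
#'
#' @param L_hs hard-sample contrastive loss (detached scalar).
#' @param L_zinb ZINB negative log-likelihood (detached scalar).
#' @param state an [omega_state()].
#' @return list with `breakdown` (`L_hs`, `L_zinb`, `omega`, `total`) and
#'   the updated `state`.
#' @export
combine_losses <- function(L_hs, L_zinb, state) {
  stopifnot(inherits(state, "schsc_omega"))
  if (!is.finite(L_hs) || !is.finite(L_zinb))
    stop(sprintf("non-finite loss: L_hs = %g, L_zinb = %g", L_hs, L_zinb))
  if (state$mode == "dynamic") {
    ratio <- L_hs / max(L_zinb, state$eps)
    state$omega <- if (is.null(state$omega)) ratio
                   else state$lambda * state$omega + (1 - state$lambda) * ratio
  }
  omega <- state$omega
  list(breakdown = list(L_hs = L_hs, L_zinb = L_zinb, omega = omega,
                        total = L_hs + omega * L_zinb),
       state = state)
}
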