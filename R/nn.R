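# Minimal dense neural-network machinery with hand-written reverse-mode
# gradients. Kept deliberately small: affine layers, ELU hidden
# activations, row-wise l2 normalization, and Adam. All randomness goes
# through with_seed() so initialization is reproducible.

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(pre) ifelse(pre > 0, 1, exp(pre))

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize an MLP
#'
#' Layers are affine maps with uniform fan-in initialization
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))` for weights and biases).
#'
#' @param dims integer vector of layer widths, input first.
#' @param seed integer seed for the initialization draw.
#' @return list of layers, each `list(W, b)`.
#' @keywords internal
mlp_init <- function(dims, seed) {
  stopifnot(length(dims) >= 2)
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fi <- dims[l]; fo <- dims[l + 1L]
      lim <- 1 / sqrt(fi)
      list(W = matrix(stats::runif(fi * fo, -lim, lim), fi, fo),
           b = stats::runif(fo, -lim, lim))
    })
  })
}

# Forward pass; hidden layers use ELU, output layer is linear.
# Returns list(out, cache) where cache holds per-layer inputs and
# pre-activations for the backward pass.
mlp_forward <- function(layers, X) {
  L <- length(layers)
  inputs <- vector("list", L)
  pres <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    inputs[[l]] <- H
    pre <- H %*% layers[[l]]$W
    pre <- sweep(pre, 2L, layers[[l]]$b, `+`)
    pres[[l]] <- pre
    H <- if (l < L) elu(pre) else pre
  }
  list(out = H, cache = list(inputs = inputs, pres = pres))
}

# Backward pass given dLoss/dOut; returns list(grads, dX).
mlp_backward <- function(layers, cache, G) {
  L <- length(layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (l < L) G <- G * elu_grad(cache$pres[[l]])
    grads[[l]] <- list(W = crossprod(cache$inputs[[l]], G),
                       b = colSums(G))
    G <- G %*% t(layers[[l]]$W)
  }
  list(grads = grads, dX = G)
}

# Row-wise l2 normalization with cached norms for the backward pass.
l2_normalize <- function(Z, eps = 1e-12) {
  nr <- pmax(row_norms(Z), eps)
  list(Zn = Z / nr, norms = nr)
}

# Backward through row normalization: for z = u/||u||,
# du = (g - z (z . g)) / ||u||.
l2_normalize_backward <- function(Zn, norms, G) {
  (G - Zn * rowSums(Zn * G)) / norms
}

# ---- generic nested parameter containers --------------------------------

# Apply f over the leaves of parallel nested lists (leaves are numeric).
param_mapn <- function(structs, f) {
  if (is.list(structs[[1L]])) {
    out <- lapply(seq_along(structs[[1L]]),
                  function(i) param_mapn(lapply(structs, `[[`, i), f))
    names(out) <- names(structs[[1L]])
    out
  } else {
    f(structs)
  }
}

param_map <- function(p, f) param_mapn(list(p), function(xs) f(xs[[1L]]))

param_zeros <- function(p) param_map(p, function(x) x * 0)

adam_init <- function(params) {
  list(m = param_zeros(params), v = param_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_mapn(list(state$m, grads),
                        function(xs) beta1 * xs[[1L]] + (1 - beta1) * xs[[2L]])
  state$v <- param_mapn(list(state$v, grads),
                        function(xs) beta2 * xs[[1L]] + (1 - beta2) * xs[[2L]]^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- param_mapn(list(params, state$m, state$v), function(xs) {
    xs[[1L]] - lr * (xs[[2L]] / c1) / (sqrt(xs[[3L]] / c2) + eps)
  })
  list(params = params, state = state)
}
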