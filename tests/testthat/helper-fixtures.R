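# Shared fixtures built in code at test time.

# Well-separated Gaussian blobs: K clusters of n_per points in d dims.
make_blobs <- function(K, n_per = 40, d = 4, sep = 8, noise = 0.5,
                       seed = 1) {
  set.seed(seed)
  centers <- matrix(0, K, d)
  for (c in seq_len(K)) {
    centers[c, ((c - 1L) %% d) + 1L] <- sep * ceiling(c / d)
  }
  labels <- rep(seq_len(K), each = n_per)
  X <- centers[labels, , drop = FALSE] +
    matrix(rnorm(length(labels) * d, sd = noise), ncol = d)
  list(X = X, labels = labels)
}

# Small preprocessed bundle for fast training tests.
tiny_bundle <- function(seed = 7) {
  gen <- generate_counts(synthetic_spec(K = 3, n_per_cluster = 20,
                                        n_genes = 40,
                                        n_marker_genes_per_cluster = 8,
                                        marker_fold = 6, theta = 2,
                                        pi = 0.1, seed = seed))
  list(bundle = suppressWarnings(preprocess_counts(gen$counts, p = 40)),
       labels = gen$labels)
}

# Random unit-row embeddings packaged as an encode_views()-style object.
random_views <- function(m, d, seed = 1) {
  set.seed(seed)
  unit <- function() {
    Z <- matrix(rnorm(m * d), m, d)
    Z / sqrt(rowSums(Z^2))
  }
  v <- list(Z_v1 = unit(), Z_v2 = unit(), E_v1 = unit(), E_v2 = unit())
  v$Z_fused <- (v$Z_v1 + v$Z_v2) / 2
  class(v) <- "schsc_views"
  v
}

# Scalar double-loop InfoNCE oracle over 2m stacked embeddings with
# elementwise weighted logits; independent of the vectorized code path.
infonce_oracle <- function(S, W, m) {
  n2 <- 2L * m
  pos_of <- function(r) if (r <= m) r + m else r - m
  total <- 0
  for (r in seq_len(n2)) {
    logits <- S[r, ] * W[r, ]
    num <- exp(logits[pos_of(r)])
    den <- 0
    for (c in seq_len(n2)) if (c != r) den <- den + exp(logits[c])
    total <- total - log(num / den)
  }
  total / n2
}

# Memoized full training run on the small 5-cluster fixture under the
# default configuration, shared by the slow end-to-end tests.
.fixture_runs <- new.env(parent = emptyenv())

trained_fixture <- function(key = "default", use_weighting = TRUE) {
  if (!is.null(.fixture_runs[[key]])) return(.fixture_runs[[key]])
  fx <- fixture_small()
  bundle <- suppressWarnings(preprocess_counts(fx$counts, p = 2000))
  cfg <- train_config(K_target = 5, use_weighting = use_weighting)
  fit <- train_schsc(bundle, cfg)
  emb <- embed_all(fit)
  cl <- final_clustering(emb, k = cfg$k, K_target = 5, seed = cfg$seed)
  res <- list(fx = fx, bundle = bundle, cfg = cfg, fit = fit,
              emb = emb, cl = cl,
              scores = score_clustering(cl$labels, fx$labels))
  .fixture_runs[[key]] <- res
  res
}
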