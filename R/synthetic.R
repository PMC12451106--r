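#' Specification for a synthetic ZINB count matrix
#'
#' Describes a count matrix with planted cluster structure drawn from
#' the same zero-inflated negative binomial data model the method
#' assumes: each cluster has a mean profile equal to `base_mean` with a
#' disjoint block of `n_marker_genes_per_cluster` marker genes elevated
#' by `marker_fold`; per-cell size factors are log-uniform on
#' `[1/library_size_spread, library_size_spread]`; counts are
#' `NB(mean * size_factor, theta)` and then zeroed independently with
#' probability `pi` (gene-independent dropout).
#'
#' @param K number of clusters.
#' @param n_per_cluster integer vector (recycled to length K) of cells
#'   per cluster.
#' @param n_genes total gene count.
#' @param n_marker_genes_per_cluster markers per cluster
#'   (`K * markers <= n_genes`).
#' @param base_mean baseline NB mean per gene.
#' @param marker_fold fold-change of marker genes (> 1).
#' @param theta shared NB dispersion.
#' @param pi dropout (zero-inflation) probability in `[0, 1)`.
#' @param library_size_spread size-factor spread (>= 1).
#' @param seed RNG seed.
#' @return An object of class `schsc_synth_spec`.
#' @export
synthetic_spec <- function(K = 5, n_per_cluster = 100, n_genes = 300,
                           n_marker_genes_per_cluster = 20,
                           base_mean = 0.5, marker_fold = 8,
                           theta = 2, pi = 0.2,
                           library_size_spread = 2, seed = 0) {
  n_per_cluster <- rep_len(as.integer(n_per_cluster), K)
  stopifnot(K >= 1, all(n_per_cluster >= 1), n_genes >= 1,
            K * n_marker_genes_per_cluster <= n_genes,
            base_mean > 0, marker_fold > 1, theta > 0,
            pi >= 0, pi < 1, library_size_spread >= 1)
  structure(list(K = as.integer(K), n_per_cluster = n_per_cluster,
                 n_genes = as.integer(n_genes),
                 n_marker_genes_per_cluster =
                   as.integer(n_marker_genes_per_cluster),
                 base_mean = base_mean, marker_fold = marker_fold,
                 theta = theta, pi = pi,
                 library_size_spread = library_size_spread,
                 seed = as.integer(seed)),
            class = "schsc_synth_spec")
}

#' Generate a synthetic count matrix with planted clusters
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` (a [count_matrix()] carrying the true
#'   labels), `labels` (integer vector), and `params` (list with the
#'   cluster `means` matrix (K x genes), per-cell `size_factors`,
#'   `theta`, `pi`, and `marker_index` per cluster).
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "schsc_synth_spec"))
  set.seed(spec$seed)
  K <- spec$K; G <- spec$n_genes
  nm <- spec$n_marker_genes_per_cluster
  means <- matrix(spec$base_mean, K, G)
  marker_index <- vector("list", K)
  for (c in seq_len(K)) {
    if (nm > 0) {
      idx <- ((c - 1L) * nm + 1L):(c * nm)
      means[c, idx] <- spec$base_mean * spec$marker_fold
      marker_index[[c]] <- idx
    }
  }
  labels <- rep(seq_len(K), spec$n_per_cluster)
  N <- length(labels)
  ls <- log(spec$library_size_spread)
  sf <- exp(stats::runif(N, -ls, ls))
  mu <- means[labels, , drop = FALSE] * sf
  counts <- matrix(stats::rnbinom(N * G, size = spec$theta, mu = mu), N, G)
  if (spec$pi > 0) {
    drop <- matrix(stats::runif(N * G) < spec$pi, N, G)
    counts[drop] <- 0L
  }
  cm <- count_matrix(counts, labels = labels)
  list(counts = cm, labels = labels,
       params = list(means = means, size_factors = sf,
                     theta = spec$theta, pi = spec$pi,
                     marker_index = marker_index))
}

#' Preconfigured small 5-cluster fixture
#'
#' 5 clusters x 100 cells, 300 genes with 20 markers per cluster at
#' 8-fold elevation, dispersion 2, dropout 0.2, seed 0 -- sized so full
#' training completes in minutes on one CPU while remaining clearly
#' clusterable.
#'
#' @return As [generate_counts()].
#' @export
fixture_small <- function() {
  generate_counts(synthetic_spec(K = 5, n_per_cluster = 100, n_genes = 300,
                                 n_marker_genes_per_cluster = 20,
                                 base_mean = 0.5, marker_fold = 8,
                                 theta = 2, pi = 0.2,
                                 library_size_spread = 2, seed = 0))
}
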