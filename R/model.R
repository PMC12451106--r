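#' Encoder/decoder architecture configuration
#'
#' Describes the dual attribute encoders (input: filtered expression,
#' p features), the dual structure encoders (input: adjacency rows over
#' all N cells) and the embedding width shared by all four. Defaults are
#' this package's choices: attribute encoders p -> 512 -> 256 -> d,
#' structure encoders N -> 256 -> d, ELU activations, d = 32.
#'
#' @param input_dim_attr number of genes p after preprocessing.
#' @param input_dim_struct number of cells N (adjacency row length).
#' @param hidden_attr hidden widths of the attribute encoders.
#' @param hidden_struct hidden widths of the structure encoders.
#' @param embed_dim embedding dimension d (>= 2).
#' @param seed integer seed; the members of each encoder pair are
#'   initialized with `seed` and `seed + 1` offsets.
#' @return An object of class `schsc_config`.
#' @export
encoder_config <- function(input_dim_attr, input_dim_struct,
                           hidden_attr = c(512, 256),
                           hidden_struct = 256,
                           embed_dim = 32, seed = 0) {
  stopifnot(embed_dim >= 2, length(hidden_attr) >= 1,
            length(hidden_struct) >= 1)
  structure(list(input_dim_attr = as.integer(input_dim_attr),
                 input_dim_struct = as.integer(input_dim_struct),
                 hidden_attr = as.integer(hidden_attr),
                 hidden_struct = as.integer(hidden_struct),
                 embed_dim = as.integer(embed_dim),
                 activation = "elu",
                 seed = as.integer(seed)),
            class = "schsc_config")
}

#' Initialize all model weights
#'
#' Four encoder MLPs plus three affine ZINB decoder heads (d -> p) for
#' dropout, mean and dispersion. Each component draws from its own
#' seeded stream so the two members of a pair differ.
#'
#' @param cfg an [encoder_config()].
#' @return Nested list of parameter matrices/vectors.
#' @export
init_weights <- function(cfg) {
  stopifnot(inherits(cfg, "schsc_config"))
  d <- cfg$embed_dim
  p <- cfg$input_dim_attr
  s <- cfg$seed
  list(z1 = mlp_init(c(p, cfg$hidden_attr, d), s),
       z2 = mlp_init(c(p, cfg$hidden_attr, d), s + 1L),
       e1 = mlp_init(c(cfg$input_dim_struct, cfg$hidden_struct, d), s + 2L),
       e2 = mlp_init(c(cfg$input_dim_struct, cfg$hidden_struct, d), s + 3L),
       pi = mlp_init(c(d, p), s + 4L)[[1L]],
       mu = mlp_init(c(d, p), s + 5L)[[1L]],
       th = mlp_init(c(d, p), s + 6L)[[1L]])
}

#' Encode a batch through the four view encoders
#'
#' Runs the filtered expression rows through both attribute encoders and
#' the adjacency rows through both structure encoders, l2-normalizes
#' every embedding row (so dot products between embeddings are cosine
#' similarities), and fuses the two attribute views as
#' `Z = (Z_v1 + Z_v2) / 2`.
#'
#' @param X_sub m x p matrix of Laplacian-filtered features of the batch.
#' @param A_sub m x N matrix of (symmetrized) adjacency rows of the batch.
#' @param weights from [init_weights()].
#' @param keep_cache retain forward caches for backpropagation.
#' @return An object of class `schsc_views`: list with `Z_v1`, `Z_v2`,
#'   `E_v1`, `E_v2` (m x d, unit rows), `Z_fused`, and (if requested)
#'   `cache`.
#' @export
encode_views <- function(X_sub, A_sub, weights, keep_cache = FALSE) {
  if (ncol(X_sub) != nrow(weights$z1[[1L]]$W))
    stop("X_sub feature count does not match attribute encoder input")
  if (ncol(A_sub) != nrow(weights$e1[[1L]]$W))
    stop("A_sub column count does not match structure encoder input")
  if (nrow(X_sub) != nrow(A_sub)) stop("X_sub and A_sub row counts differ")
  fz1 <- mlp_forward(weights$z1, X_sub)
  fz2 <- mlp_forward(weights$z2, X_sub)
  fe1 <- mlp_forward(weights$e1, A_sub)
  fe2 <- mlp_forward(weights$e2, A_sub)
  nz1 <- l2_normalize(fz1$out); nz2 <- l2_normalize(fz2$out)
  ne1 <- l2_normalize(fe1$out); ne2 <- l2_normalize(fe2$out)
  out <- list(Z_v1 = nz1$Zn, Z_v2 = nz2$Zn,
              E_v1 = ne1$Zn, E_v2 = ne2$Zn,
              Z_fused = (nz1$Zn + nz2$Zn) / 2)
  if (keep_cache) {
    out$cache <- list(fz1 = fz1$cache, fz2 = fz2$cache,
                      fe1 = fe1$cache, fe2 = fe2$cache,
                      norms = list(z1 = nz1$norms, z2 = nz2$norms,
                                   e1 = ne1$norms, e2 = ne2$norms))
  }
  class(out) <- "schsc_views"
  out
}

#' Decode ZINB parameters from the fused embedding
#'
#' Three affine heads produce per-cell-per-gene dropout probabilities
#' `Pi = sigmoid(Z W_pi + b)`, means `Mu = s_i * exp(Z W_mu + b)` scaled
#' by the per-cell size factor `s_i = library_size_i /
#' median(library_size)`, and dispersions `Theta = exp(Z W_th + b)`.
#' Outputs are clamped for numeric safety: `Pi` to
#' `[1e-6, 1 - 1e-6]`, `Mu` and `Theta` to `[1e-6, 1e6]`.
#'
#' @param Z_fused m x d fused attribute embedding.
#' @param weights from [init_weights()] (heads `pi`, `mu`, `th`).
#' @param library_size positive per-cell raw totals of the batch.
#' @param keep_cache retain pre-activations for backpropagation.
#' @return An object of class `schsc_zinb_params`: list with `Pi`, `Mu`,
#'   `Theta` (m x p) and `size_factors`.
#' @export
zinb_decode <- function(Z_fused, weights, library_size, keep_cache = FALSE) {
  if (any(library_size <= 0)) stop("non-positive library size")
  if (length(library_size) != nrow(Z_fused))
    stop("library_size length must match batch size")
  sf <- library_size / stats::median(library_size)
  aff <- function(head) sweep(Z_fused %*% head$W, 2L, head$b, `+`)
  h_pi <- aff(weights$pi); h_mu <- aff(weights$mu); h_th <- aff(weights$th)
  Pi <- clamp(sigmoid(h_pi), 1e-6, 1 - 1e-6)
  Mu <- clamp(sf * exp(h_mu), 1e-6, 1e6)
  Theta <- clamp(exp(h_th), 1e-6, 1e6)
  out <- list(Pi = Pi, Mu = Mu, Theta = Theta, size_factors = sf)
  if (keep_cache) out$cache <- list(h_pi = h_pi, h_mu = h_mu, h_th = h_th)
  class(out) <- "schsc_zinb_params"
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the weight list, the
#' [encoder_config()] and an optional metadata list.
#'
#' @param weights,cfg,meta model state to store.
#' @param path file path for the archive.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns `list(weights, cfg, meta)`.
#' @export
save_checkpoint <- function(weights, cfg, path, meta = NULL) {
  saveRDS(list(weights = weights, cfg = cfg, meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
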