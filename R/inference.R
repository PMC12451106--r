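#' Embed every cell with the trained attribute encoders
#'
#' Forwards all cells' filtered expression rows through both attribute
#' encoders (in batches; the forward pass is per-row, so batching does
#' not change the result) and returns the fused, row-normalized
#' embedding `(Z_v1 + Z_v2) / 2`, order-preserving.
#'
#' @param fit a [train_schsc()] result.
#' @param batch_size forward-pass batch size (default 1000).
#' @return N x d embedding matrix.
#' @export
embed_all <- function(fit, batch_size = 1000) {
  stopifnot(inherits(fit, "schsc_fit"))
  X <- fit$X_filtered
  N <- nrow(X)
  d <- fit$encoder_config$embed_dim
  out <- matrix(0, N, d)
  starts <- seq(1L, N, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, N)
    z1 <- l2_normalize(mlp_forward(fit$weights$z1,
                                   X[idx, , drop = FALSE])$out)$Zn
    z2 <- l2_normalize(mlp_forward(fit$weights$z2,
                                   X[idx, , drop = FALSE])$out)$Zn
    out[idx, ] <- (z1 + z2) / 2
  }
  out
}

#' Final cluster assignment from embeddings
#'
#' Builds a KNN graph on the embeddings (same construction and tie
#' rules as during training) and applies Louvain community detection
#' with the binary-searched resolution targeting `K_target`; the
#' routine is shared with the in-training pseudo-labeling.
#'
#' @param embeddings N x d matrix.
#' @param k KNN neighbor count (default 15).
#' @param K_target desired number of clusters.
#' @param method community method, `"louvain"` (default) or `"leiden"`.
#' @param seed partition seed.
#' @return An object of class `schsc_clustering`: list with
#'   `embeddings`, `labels` (integers `1..K`), `K`,
#'   `resolution_used`.
#' @export
final_clustering <- function(embeddings, k = 15, K_target,
                             method = c("louvain", "leiden"), seed = 0) {
  method <- match.arg(method)
  pl <- pseudo_labels(embeddings, K_target = K_target, graph_k = k,
                      method = method, seed = seed)
  structure(list(embeddings = embeddings, labels = pl$labels,
                 K = pl$K, resolution_used = pl$resolution),
            class = "schsc_clustering")
}

#' @export
print.schsc_clustering <- function(x, ...) {
  cat(sprintf("schsc_clustering: %d cells in %d clusters (resolution %.4g)\n",
              length(x$labels), x$K, x$resolution_used))
  print(table(cluster = x$labels))
  invisible(x)
}
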