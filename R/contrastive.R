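#' Fused similarity matrix over two attribute and two structure views
#'
#' Stacks the two attribute embeddings as `rbind(Z_v1, Z_v2)` (and
#' likewise the structure embeddings) and returns
#' `S = alpha * Zc Zc' + (1 - alpha) * Ec Ec'`, the 2m x 2m block matrix
#' whose (i^{vk}, j^{vl}) entry mixes attribute and structure cosine
#' similarity with weight `alpha`. Row `r` corresponds to cell
#' `((r - 1) mod m) + 1` in view `ceiling(r / m)`.
#'
#' @param views an [encode_views()] result (rows l2-normalized).
#' @param alpha fusion weight in `[0, 1]`; `alpha = 1` uses attribute
#'   similarity only, `alpha = 0` structure similarity only.
#' @return 2m x 2m similarity matrix with entries in `[-1, 1]`.
#' @export
fused_similarity <- function(views, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  Zc <- rbind(views$Z_v1, views$Z_v2)
  Ec <- rbind(views$E_v1, views$E_v2)
  alpha * tcrossprod(Zc) + (1 - alpha) * tcrossprod(Ec)
}

# Binary search over the community-detection resolution so the number of
# communities matches K_target. Monotone bracketing on [lo, hi]; if the
# target count is unreachable within max_iter evaluations, the closest
# count wins (ties toward the smaller count).
resolution_search <- function(g, K_target, method = c("leiden", "louvain"),
                              seed = 0, lo = 1e-4, hi = 10, max_iter = 50) {
  method <- match.arg(method)
  run <- function(res) {
    memb <- with_seed(seed, {
      cl <- if (method == "leiden")
        igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = res, n_iterations = 3)
      else
        igraph::cluster_louvain(g, resolution = res)
      igraph::membership(cl)
    })
    as.integer(memb)
  }
  best <- NULL
  consider <- function(best, res, memb) {
    k <- length(unique(memb))
    cand <- list(resolution = res, membership = memb, k = k)
    if (is.null(best)) return(cand)
    if (abs(k - K_target) < abs(best$k - K_target)) return(cand)
    if (abs(k - K_target) == abs(best$k - K_target) && k < best$k) return(cand)
    best
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    memb <- run(mid)
    best <- consider(best, mid, memb)
    k <- length(unique(memb))
    if (k == K_target) break
    if (k < K_target) lo <- mid else hi <- mid
  }
  best
}

#' Pseudo-labels via Leiden/Louvain with binary-searched resolution
#'
#' Builds a KNN graph on the rows of `Z` (same construction and
#' tie-break rules as [knn_graph()]), then runs Leiden (default) or
#' Louvain community detection, binary-searching the resolution
#' parameter on `[1e-4, 10]` until the community count equals
#' `K_target` (at most 50 evaluations; otherwise the closest achievable
#' count is returned, ties toward fewer communities). The partition is
#' computed under a fixed seed so pseudo-labels are reproducible.
#'
#' @param Z m x d embedding matrix.
#' @param K_target desired number of communities (`>= 1`, `< m`).
#' @param graph_k KNN neighbor count for the embedding graph
#'   (default 15, reduced to `m - 1` for tiny inputs).
#' @param method `"leiden"` (default) or `"louvain"`.
#' @param seed seed for the partition.
#' @return An object of class `schsc_pseudo`: list with `labels`
#'   (integers `1..K`), `K` (attained count), `K_target`, `resolution`,
#'   `centers` (K x d cluster means), `dist_to_center` (per-cell
#'   Euclidean distance to its own center).
#' @export
pseudo_labels <- function(Z, K_target, graph_k = 15,
                          method = c("leiden", "louvain"), seed = 0) {
  method <- match.arg(method)
  m <- nrow(Z)
  if (K_target < 1) stop("K_target must be >= 1")
  if (m < K_target) stop("need more cells than target clusters")
  if (m == K_target)
    warning("K_target equals the number of cells; returning closest partition")
  graph_k <- min(graph_k, m - 1L)
  A <- knn_adjacency(Z, graph_k)
  A_sym <- A + Matrix::t(A)
  A_sym@x <- rep(1, length(A_sym@x))
  g <- igraph::graph_from_adjacency_matrix(A_sym, mode = "undirected")
  hit <- resolution_search(g, K_target, method = method, seed = seed)
  labels <- match(hit$membership, sort(unique(hit$membership)))
  K <- max(labels)
  centers <- rowsum(Z, labels) / as.vector(table(labels))
  diffs <- Z - centers[labels, , drop = FALSE]
  structure(list(labels = labels, K = K, K_target = K_target,
                 resolution = hit$resolution, centers = centers,
                 dist_to_center = sqrt(rowSums(diffs^2))),
            class = "schsc_pseudo")
}

#' High-confidence cell set
#'
#' The `floor(tau * m)` cells with the smallest Euclidean distance to
#' their own pseudo-cluster center, selected globally across clusters.
#' Distance ties are broken toward the lower cell index.
#'
#' @param pl a [pseudo_labels()] result.
#' @param tau confidence fraction in `(0, 1]` (default 0.9).
#' @return Sorted integer vector of cell indices.
#' @export
high_confidence_set <- function(pl, tau = 0.9) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  m <- length(pl$dist_to_center)
  nH <- floor(tau * m)
  ord <- order(pl$dist_to_center, seq_len(m))
  sort(ord[seq_len(nH)])
}

#' Pseudo-cluster indicator matrix
#'
#' `Q[i, j] = 1` iff cells `i` and `j` carry the same pseudo-label;
#' symmetric with unit diagonal.
#'
#' @param P vector of m labels.
#' @return m x m binary matrix.
#' @export
indicator_matrix <- function(P) {
  Q <- outer(P, P, `==`)
  storage.mode(Q) <- "double"
  Q
}

#' Hard-sample weight matrix
#'
#' For embedding pairs whose two underlying cells both belong to the
#' high-confidence set, the weight is
#' `|Q_ij - Norm(S)|^beta`, where `Norm` is min-max normalization of the
#' whole 2m x 2m similarity batch; all other pairs get weight 1. Hard
#' positives (same pseudo-cluster, low similarity) and hard negatives
#' (different pseudo-cluster, high similarity) are thereby up-weighted,
#' easy pairs down-weighted; `beta = 0` recovers uniform weights
#' (`0^0 := 1`).
#'
#' @param S 2m x 2m fused similarity matrix.
#' @param Q m x m indicator from [indicator_matrix()].
#' @param H integer index set from [high_confidence_set()].
#' @param beta focusing coefficient `>= 0` (default 2).
#' @return 2m x 2m weight matrix with entries in `[0, 1]`.
#' @export
weight_matrix <- function(S, Q, H, beta = 2) {
  if (beta < 0) stop("beta must be >= 0")
  m <- nrow(Q)
  if (nrow(S) != 2 * m) stop("S must be 2m x 2m for an m x m Q")
  rng <- range(S)
  if (rng[1] == rng[2]) {
    warning("degenerate similarity batch (all entries equal); Norm(S) := 0.5")
    Sn <- matrix(0.5, nrow(S), ncol(S))
  } else {
    Sn <- (S - rng[1]) / (rng[2] - rng[1])
  }
  Qfull <- rbind(cbind(Q, Q), cbind(Q, Q))
  W <- matrix(1, nrow(S), ncol(S))
  inH <- rep(seq_len(m) %in% H, 2L)
  mask <- outer(inH, inH, `&`)
  W[mask] <- abs(Qfull[mask] - Sn[mask])^beta
  W
}

#' Hard-sample contrastive loss
#'
#' InfoNCE over the 2m stacked embeddings with elementwise weighted
#' logits `S * W`. Each anchor's positive is the other view of the same
#' cell; the denominator runs over the positive plus all `2(m - 1)`
#' cross-cell pairs in both views (same-view self-pairs excluded). The
#' loss is averaged over all 2m anchors. With `W` identically 1 this is
#' the plain fused-similarity InfoNCE.
#'
#' @param S 2m x 2m fused similarity matrix.
#' @param W 2m x 2m weight matrix.
#' @param m batch size (number of cells).
#' @return Scalar loss.
#' @export
hard_sample_loss <- function(S, W, m) {
  hard_sample_loss_grad(S, W, m)$loss
}

# Loss plus gradient with respect to S (W treated as a constant).
hard_sample_loss_grad <- function(S, W, m) {
  if (m < 1) stop("m must be >= 1")
  n2 <- 2L * m
  stopifnot(nrow(S) == n2, ncol(S) == n2, all(dim(W) == dim(S)))
  L <- S * W
  diag(L) <- -Inf                       # exclude same-view self-pairs
  pos <- c((m + 1L):n2, seq_len(m))     # other view of the same cell
  mx <- apply(L, 1L, max)
  E <- exp(L - mx)
  denom <- rowSums(E)
  pos_idx <- cbind(seq_len(n2), pos)
  per_anchor <- -(L[pos_idx] - mx) + log(denom)
  P <- E / denom
  G <- P
  G[pos_idx] <- G[pos_idx] - 1
  G <- G / n2
  list(loss = mean(per_anchor), grad_S = G * W)
}
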