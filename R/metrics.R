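# Hungarian algorithm (Kuhn-Munkres with potentials, O(n^3)) for the
# optimal-assignment step of clustering accuracy. Cost matrix must be
# square; returns for each row its assigned column.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials, col 0 is the dummy at index 1
  p <- integer(n + 1L)   # p[j + 1]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

as_labels <- function(x) as.integer(factor(x))

#' Clustering accuracy (optimal label matching)
#'
#' `ACC = max_sigma (1/N) sum 1[truth_i = sigma(pred_i)]` over bijections
#' `sigma` between predicted and true labels, solved by optimal
#' assignment on the contingency table.
#'
#' @param pred,truth label vectors of equal length.
#' @return Accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  cont <- table(as_labels(pred), as_labels(truth))
  n <- max(dim(cont))
  C <- matrix(0, n, n)
  C[seq_len(nrow(cont)), seq_len(ncol(cont))] <- cont
  assign <- hungarian(max(C) - C)
  sum(C[cbind(seq_len(n), assign)]) / length(pred)
}

#' Normalized mutual information and adjusted Rand index
#'
#' NMI uses the arithmetic normalization `I(P; T) / ((H(P) + H(T)) / 2)`;
#' ARI is the standard permutation-adjusted pair-counting index. Both
#' are invariant to any relabeling of either partition.
#'
#' @param pred,truth label vectors of equal length.
#' @return Named numeric vector `c(nmi = ..., ari = ...)`.
#' @export
nmi_ari <- function(pred, truth) {
  c(nmi = nmi(pred, truth), ari = ari(pred, truth))
}

#' @rdname nmi_ari
#' @export
nmi <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  joint <- table(pred, truth) / length(pred)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(1)  # both partitions trivial
  2 * mi / (hx + hy)
}

#' @rdname nmi_ari
#' @export
ari <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  cont <- table(pred, truth)
  n <- length(pred)
  sum_ij <- sum(choose(cont, 2))
  a <- sum(choose(rowSums(cont), 2))
  b <- sum(choose(colSums(cont), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)  # degenerate (e.g. both trivial)
  (sum_ij - expected) / (max_index - expected)
}

#' Label-free cluster quality: compactness and separation
#'
#' Compactness is the mean Euclidean distance of cells to their own
#' cluster centroid (lower is tighter); Separation is the mean pairwise
#' Euclidean distance between cluster centroids (higher is better
#' separated). With a single cluster, Separation is undefined and
#' returned as `NA`.
#'
#' @param embeddings N x d matrix.
#' @param labels per-cell cluster labels.
#' @return Named numeric vector `c(compactness = ..., separation = ...)`.
#' @export
compactness_separation <- function(embeddings, labels) {
  if (nrow(embeddings) != length(labels))
    stop("labels length must match embedding rows")
  lab <- as_labels(labels)
  centers <- rowsum(embeddings, lab) / as.vector(table(lab))
  diffs <- embeddings - centers[lab, , drop = FALSE]
  comp <- mean(sqrt(rowSums(diffs^2)))
  K <- nrow(centers)
  sep <- if (K >= 2) mean(stats::dist(centers)) else NA_real_
  c(compactness = comp, separation = sep)
}

#' Score a clustering against reference labels
#'
#' @param pred,truth label vectors of equal length.
#' @return Named numeric vector with `acc`, `nmi`, `ari`.
#' @export
score_clustering <- function(pred, truth) {
  c(acc = clustering_accuracy(pred, truth),
    nmi = nmi(pred, truth),
    ari = ari(pred, truth))
}
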