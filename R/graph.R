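#' Exact KNN adjacency with deterministic tie-breaking
#'
#' Binary cells x cells adjacency where `A[i, j] = 1` iff `j` is among the
#' `k` nearest neighbors of `i` under Euclidean distance on the rows of
#' `X`, self excluded. Distance ties are broken toward the lower cell
#' index, so the matrix is fully deterministic.
#'
#' @param X numeric matrix, cells x features.
#' @param k neighbor count, `1 <= k < nrow(X)`.
#' @return A sparse binary `dgCMatrix` (possibly asymmetric).
#' @export
knn_adjacency <- function(X, k) {
  n <- nrow(X)
  if (k < 1 || k >= n) stop("need 1 <= k < number of cells")
  d <- as.matrix(stats::dist(X))
  js <- integer(n * k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    ord <- order(di, seq_len(n))
    js[((i - 1L) * k + 1L):(i * k)] <- ord[seq_len(k)]
  }
  Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = js, x = 1,
                       dims = c(n, n))
}

#' Build the KNN cell graph and its smoothing operator
#'
#' Constructs the KNN adjacency on the rows of `X`, symmetrizes it as
#' `max(A, t(A))` (the construction rule is row-wise but the graph is
#' treated as undirected), adds self-loops (`Atilde = I + A_sym`,
#' the renormalization trick) and forms the symmetrically normalized
#' smoothing operator `Dtilde^{-1/2} Atilde Dtilde^{-1/2}`, i.e.
#' `I - L_sym` for the renormalized symmetric Laplacian.
#'
#' @param X numeric matrix (typically the standardized HVG matrix),
#'   cells x features.
#' @param k neighbor count (default 15).
#' @return An object of class `schsc_graph`: list with `adjacency`
#'   (directed KNN matrix as constructed), `adjacency_sym`, `k`,
#'   `degrees` (of `Atilde`), and `operator` (sparse smoothing operator).
#' @export
knn_graph <- function(X, k = 15) {
  A <- knn_adjacency(X, k)
  A_sym <- A + Matrix::t(A)
  A_sym@x <- rep(1, length(A_sym@x))
  n <- nrow(A_sym)
  Atil <- A_sym + Matrix::Diagonal(n)
  deg <- Matrix::rowSums(Atil)
  Dhalf <- Matrix::Diagonal(n, 1 / sqrt(deg))
  op <- Dhalf %*% Atil %*% Dhalf
  structure(list(adjacency = A, adjacency_sym = A_sym, k = k,
                 degrees = deg, operator = op),
            class = "schsc_graph")
}

#' Apply the Laplacian smoothing filter to a feature matrix
#'
#' One pass of `X_filtered = (I - L_sym_tilde) X =
#' Dtilde^{-1/2} Atilde Dtilde^{-1/2} X`, smoothing each cell's profile
#' toward its graph neighborhood.
#'
#' @param g an [knn_graph()] object built on the same cells as `X`.
#' @param X numeric matrix, cells x features.
#' @return Dense filtered matrix with the shape of `X`.
#' @export
laplacian_filter <- function(g, X) {
  stopifnot(inherits(g, "schsc_graph"))
  if (nrow(X) != nrow(g$operator)) stop("graph and matrix cell counts differ")
  as.matrix(g$operator %*% X)
}

#' Export graph edges as a data frame
#'
#' @param g an [knn_graph()] object.
#' @param symmetric use the symmetrized adjacency (default `TRUE`).
#' @return data.frame with columns `source`, `target` (1-based indices).
#' @export
graph_edges <- function(g, symmetric = TRUE) {
  A <- if (symmetric) g$adjacency_sym else g$adjacency
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  data.frame(source = idx[, 1L], target = idx[, 2L])
}
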