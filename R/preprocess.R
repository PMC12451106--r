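#' Filter low-count genes and cells
#'
#' Removes genes whose total count across cells is below `min_counts`,
#' then cells whose total count across the remaining genes is below
#' `min_counts` (genes first, then cells; the order is fixed and
#' deterministic).
#'
#' @param cm a [count_matrix()] object.
#' @param min_counts non-negative integer threshold (default 1).
#' @return A filtered [count_matrix()].
#' @export
filter_min_counts <- function(cm, min_counts = 1) {
  stopifnot(inherits(cm, "schsc_counts"), min_counts >= 0)
  keep_g <- colSums(cm$counts) >= min_counts
  if (!any(keep_g)) stop("all genes removed by min_counts filter")
  counts <- cm$counts[, keep_g, drop = FALSE]
  keep_c <- rowSums(counts) >= min_counts
  if (!any(keep_c)) stop("all cells removed by min_counts filter")
  count_matrix(counts[keep_c, , drop = FALSE],
               cell_ids = cm$cell_ids[keep_c],
               gene_ids = cm$gene_ids[keep_g],
               labels = if (is.null(cm$labels)) NULL else cm$labels[keep_c])
}

#' Median-of-totals normalization and log1p transform
#'
#' Scales every cell so that its total count equals the median of the
#' per-cell totals, then applies `log1p` elementwise. The raw library
#' sizes (pre-scaling totals) are retained: they become the per-cell
#' size factors of the ZINB decoder.
#'
#' @param cm a [count_matrix()] object; every cell total must be positive.
#' @return list with `lognorm` (cells x genes real matrix) and
#'   `library_size` (the raw per-cell totals).
#' @export
normalize_and_log <- function(cm) {
  stopifnot(inherits(cm, "schsc_counts"))
  totals <- rowSums(cm$counts)
  if (any(totals <= 0)) stop("zero cell total; filter cells first")
  target <- stats::median(totals)
  scaled <- cm$counts * (target / totals)
  list(lognorm = log1p(scaled), library_size = totals)
}

#' Select highly variable genes (Seurat-flavor binned dispersion)
#'
#' Dispersion-based selection following the classic Seurat flavor of
#' Scanpy's `highly_variable_genes`: per-gene mean and dispersion
#' (variance/mean, sample variance) are computed on `expm1` of the
#' log-normalized values; the dispersion is log-transformed and the mean
#' `log1p`-transformed; genes are placed in `n_bins` equal-width bins of
#' the transformed mean; the log-dispersion is z-scored within each bin
#' (sample sd); and the top `p` genes by normalized dispersion are
#' returned. A gene alone in its bin (after removing zero-dispersion
#' genes, which are never selected ahead of others) gets normalized
#' dispersion 1; multi-gene bins with zero dispersion spread contribute
#' 0. Rank ties are broken toward the lower gene index.
#'
#' @param lognorm cells x genes matrix of log1p-normalized expression.
#' @param p number of genes to keep (default 2000).
#' @param n_bins number of equal-width mean bins (default 20).
#' @return Integer vector of column indices of the selected genes, in
#'   increasing order. If `p >= ncol(lognorm)` all genes are returned
#'   with a warning.
#' @export
select_hvg <- function(lognorm, p = 2000, n_bins = 20) {
  stopifnot(p >= 1)
  g <- ncol(lognorm)
  if (p >= g) {
    warning("p >= number of genes; keeping all ", g, " genes")
    return(seq_len(g))
  }
  vals <- expm1(lognorm)
  mu <- colMeans(vals)
  n <- nrow(vals)
  v <- colSums(sweep(vals, 2L, mu)^2) / max(n - 1L, 1L)
  disp <- log(ifelse(mu > 0, v / mu, 0))  # zero dispersion -> -Inf
  lmu <- log1p(mu)

  rng <- range(lmu)
  bins <- if (rng[1] < rng[2]) {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    findInterval(lmu, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  } else {
    rep(1L, g)
  }

  nd <- rep(-Inf, g)
  for (b in unique(bins)) {
    idx <- which(bins == b & is.finite(disp))
    if (length(idx) == 1L) {
      nd[idx] <- 1
    } else if (length(idx) > 1L) {
      s <- stats::sd(disp[idx])
      nd[idx] <- if (is.na(s) || s == 0) 0
                 else (disp[idx] - mean(disp[idx])) / s
    }
  }
  ord <- order(-nd, seq_len(g))
  sort(ord[seq_len(p)])
}

#' Standardize selected genes to zero mean and unit variance
#'
#' Centers and scales each selected gene column using the population
#' standard deviation (divide by n). Constant columns are centered to
#' zero and left unscaled so the feature count stays fixed.
#'
#' @param lognorm cells x genes matrix of log1p-normalized expression.
#' @param hvg_index column indices of the genes to keep.
#' @return An object of class `schsc_normalized`: list with `values`
#'   (cells x length(hvg_index) standardized matrix), `hvg_index`,
#'   `per_gene_mean`, `per_gene_sd`.
#' @export
standardize <- function(lognorm, hvg_index = seq_len(ncol(lognorm))) {
  sub <- lognorm[, hvg_index, drop = FALSE]
  n <- nrow(sub)
  mu <- colMeans(sub)
  centered <- sweep(sub, 2L, mu)
  sdp <- sqrt(colSums(centered^2) / n)
  scale_by <- ifelse(sdp > 0, sdp, 1)
  structure(list(values = sweep(centered, 2L, scale_by, `/`),
                 hvg_index = hvg_index,
                 per_gene_mean = mu,
                 per_gene_sd = sdp),
            class = "schsc_normalized")
}

#' Full preprocessing chain
#'
#' Applies, in order: gene/cell count filtering, median-of-totals
#' normalization, log1p, highly-variable-gene selection on the
#' log-normalized matrix, and per-gene standardization of the selected
#' genes. The raw counts of the kept cells restricted to the selected
#' genes are retained for the ZINB likelihood.
#'
#' @param cm a [count_matrix()] object.
#' @param p number of highly variable genes to keep (default 2000).
#' @param min_counts filtering threshold (default 1).
#' @return An object of class `schsc_bundle`: list with `values`
#'   (N x p standardized matrix), `raw` (N x p raw counts of the selected
#'   genes), `library_size`, `hvg_index`, `per_gene_mean`, `per_gene_sd`,
#'   `cell_ids`, `gene_ids` (selected genes), `labels`.
#' @export
preprocess_counts <- function(cm, p = 2000, min_counts = 1) {
  cm <- filter_min_counts(cm, min_counts)
  nl <- normalize_and_log(cm)
  hvg <- select_hvg(nl$lognorm, p = p)
  std <- standardize(nl$lognorm, hvg)
  structure(list(values = unname(std$values),
                 raw = unname(cm$counts[, hvg, drop = FALSE]),
                 library_size = unname(nl$library_size),
                 hvg_index = hvg,
                 per_gene_mean = std$per_gene_mean,
                 per_gene_sd = std$per_gene_sd,
                 cell_ids = cm$cell_ids,
                 gene_ids = cm$gene_ids[hvg],
                 labels = cm$labels),
            class = "schsc_bundle")
}
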