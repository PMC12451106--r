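#' Construct a raw count matrix object
#'
#' Container for a cells x genes matrix of non-negative integer transcript
#' counts together with cell/gene identifiers and an optional vector of
#' reference labels used only for evaluation. Raw counts are retained
#' throughout the pipeline because the ZINB reconstruction likelihood is
#' evaluated on them, not on normalized values.
#'
#' @param counts numeric matrix, cells x genes, non-negative integers.
#' @param cell_ids character vector of unique cell identifiers
#'   (default `cell_1..cell_N`).
#' @param gene_ids character vector of unique gene identifiers
#'   (default `gene_1..gene_G`).
#' @param labels optional per-cell category (factor/character/integer),
#'   carried along for evaluation only.
#' @return An object of class `schsc_counts`: a list with elements
#'   `counts`, `cell_ids`, `gene_ids`, `labels`.
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                         labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("non-integer count")
  n <- nrow(counts); g <- ncol(counts)
  cell_ids <- cell_ids %||% rownames(counts) %||% paste0("cell_", seq_len(n))
  gene_ids <- gene_ids %||% colnames(counts) %||% paste0("gene_", seq_len(g))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n || length(gene_ids) != g)
    stop("id lengths inconsistent with matrix shape")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels length must equal number of cells")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 labels = labels),
            class = "schsc_counts")
}

#' @export
print.schsc_counts <- function(x, ...) {
  cat(sprintf("schsc_counts: %d cells x %d genes (%.1f%% zeros)%s\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0),
              if (is.null(x$labels)) "" else ", with labels"))
  invisible(x)
}

#' @export
dim.schsc_counts <- function(x) dim(x$counts)

#' Read a raw count matrix from MTX, CSV or h5ad
#'
#' @param path For `"mtx"`, a directory containing `matrix.mtx`,
#'   `barcodes.tsv` and `features.tsv` (or the path of the `.mtx` file
#'   itself, with the two TSVs alongside). For `"csv"`, a file whose header
#'   row holds gene ids and whose first column holds cell ids. For
#'   `"h5ad"`, an AnnData container (read through the `anndata` Python
#'   package, which must be on the `python` found on `PATH`).
#' @param format one of `"mtx"`, `"csv"`, `"h5ad"`.
#' @param genes_in_rows for MTX only: whether the stored matrix is
#'   genes x cells (the 10x convention, default `TRUE`) and must be
#'   transposed to cells x genes on read.
#' @param layer for h5ad only: name of a `layers` entry holding raw counts;
#'   `NULL` (default) uses the main `X` matrix.
#' @return A [count_matrix()] object (cells x genes).
#' @export
read_counts <- function(path, format = c("mtx", "csv", "h5ad"),
                        genes_in_rows = TRUE, layer = NULL) {
  format <- match.arg(format)
  switch(format,
         mtx = read_counts_mtx(path, genes_in_rows = genes_in_rows),
         csv = read_counts_csv(path),
         h5ad = read_counts_h5ad(path, layer = layer))
}

read_counts_mtx <- function(path, genes_in_rows = TRUE) {
  if (dir.exists(path)) {
    dir <- path
    mtx <- file.path(dir, "matrix.mtx")
  } else {
    dir <- dirname(path)
    mtx <- path
  }
  bar <- file.path(dir, "barcodes.tsv")
  fea <- file.path(dir, "features.tsv")
  for (f in c(mtx, bar, fea))
    if (!file.exists(f)) stop("missing MTX triplet file: ", f)
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bar)
  feat <- utils::read.delim(fea, header = FALSE, stringsAsFactors = FALSE)
  features <- feat[[1L]]
  if (genes_in_rows) m <- t(m)
  if (nrow(m) != length(barcodes) || ncol(m) != length(features))
    stop("dimension mismatch between matrix and id files")
  lab_file <- file.path(dir, "labels.tsv")
  labels <- NULL
  if (file.exists(lab_file)) {
    lab <- utils::read.delim(lab_file, header = TRUE,
                             stringsAsFactors = FALSE)
    labels <- lab[[ncol(lab)]]
  }
  count_matrix(m, cell_ids = barcodes, gene_ids = features, labels = labels)
}

read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, row.names = 1L,
                        check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in CSV count matrix")
  count_matrix(m, cell_ids = rownames(df), gene_ids = colnames(df))
}

read_counts_h5ad <- function(path, layer = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("reading h5ad requires a 'python' with the anndata package on PATH")
  out <- tempfile("schsc_h5ad_")
  dir.create(out)
  script <- c(
    "import sys",
    "import anndata, numpy as np, scipy.sparse as sp, scipy.io",
    "path, out, layer = sys.argv[1], sys.argv[2], sys.argv[3]",
    "ad = anndata.read_h5ad(path)",
    "X = ad.layers[layer] if layer != '' else ad.X",
    "X = sp.csr_matrix(X)",
    "scipy.io.mmwrite(out + '/matrix.mtx', X.T)",  # genes x cells, 10x layout
    "open(out + '/barcodes.tsv', 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')",
    "open(out + '/features.tsv', 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')"
  )
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(py, c(sf, shQuote(path), shQuote(out),
                          shQuote(layer %||% "")),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("h5ad conversion failed:\n", paste(status, collapse = "\n"))
  read_counts_mtx(out, genes_in_rows = TRUE)
}

#' Write a count matrix as an MTX triplet
#'
#' Writes `matrix.mtx` (genes x cells, 10x layout), `barcodes.tsv`,
#' `features.tsv` and, when labels are present, `labels.tsv` into `dir`.
#'
#' @param cm a [count_matrix()] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "schsc_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(t(cm$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(cm$gene_ids, file.path(dir, "features.tsv"))
  if (!is.null(cm$labels)) {
    utils::write.table(
      data.frame(cell_id = cm$cell_ids, label = cm$labels),
      file.path(dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
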