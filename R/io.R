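# Readers and writers for the on-disk formats: MatrixMarket with
# barcodes/features sidecars, dense CSV, labels CSV, BED peaks, TSV gene
# annotation, and 0-based edge-list TSV.

# Write a cell_matrix as matrix.mtx + barcodes.tsv + features.tsv in `dir`.
write_mtx_dir <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  sp <- as(as(methods::as(m$values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(m$feature_ids, file.path(dir, "features.tsv"))
  invisible(dir)
}

read_ids_file <- function(path, what) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate %s id '%s' in '%s'", what, dup[1L], path),
         call. = FALSE)
  ids
}

#' Read a cell-by-feature matrix from disk
#'
#' Auto-detects the two supported layouts: a directory containing
#' `matrix.mtx` + `barcodes.tsv` + `features.tsv` (cells in rows), or a dense
#' CSV whose header holds feature ids and whose first column holds cell ids.
#'
#' @param path directory (MatrixMarket layout) or CSV file.
#' @param modality modality tag for the result, `"RNA"` or `"ATAC"`.
#' @param format_hint optional `"mtx"` or `"csv"` to skip auto-detection.
#' @return A [cell_matrix()]. Shape and sparsity are reported via `message()`.
#' @export
read_matrix <- function(path, modality = c("RNA", "ATAC"),
                        format_hint = c("auto", "mtx", "csv")) {
  modality <- match.arg(modality)
  format_hint <- match.arg(format_hint)
  fmt <- format_hint
  if (fmt == "auto")
    fmt <- if (dir.exists(path)) "mtx" else "csv"
  m <- if (fmt == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx))
      stop(sprintf("'%s' has no matrix.mtx", path), call. = FALSE)
    values <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    cells <- read_ids_file(file.path(path, "barcodes.tsv"), "cell")
    feats <- read_ids_file(file.path(path, "features.tsv"), "feature")
    if (nrow(values) != length(cells) || ncol(values) != length(feats))
      stop(sprintf(
        "matrix.mtx is %d x %d but sidecars list %d cells and %d features",
        nrow(values), ncol(values), length(cells), length(feats)),
        call. = FALSE)
    cell_matrix(values, cells, feats, modality)
  } else {
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
    feats <- header[-1L]
    dup <- feats[duplicated(feats)]
    if (length(dup))
      stop(sprintf("duplicate feature '%s' in CSV header of '%s'",
                   dup[1L], path), call. = FALSE)
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(values))
      stop(sprintf("non-numeric values in '%s'", path), call. = FALSE)
    cell_matrix(values, as.character(df[[1L]]), feats, modality)
  }
  nz <- if (is(m$values, "sparseMatrix")) length(m$values@x)
        else sum(m$values != 0)
  message(sprintf("read %s matrix: %d cells x %d features, %d non-zeros",
                  modality, nrow(m$values), ncol(m$values), nz))
  m
}

#' Write a cell-by-feature matrix to disk
#'
#' Mirrors [read_matrix()]: a directory path produces the MatrixMarket layout,
#' a `.csv` path the dense CSV layout.
#'
#' @param m a [cell_matrix()].
#' @param path output directory or `.csv` file path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "cell_matrix"))
  if (grepl("\\.csv$", path)) {
    df <- data.frame(cell_id = m$cell_ids, check.names = FALSE)
    df[m$feature_ids] <- as.data.frame(dense_values(m))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    write_mtx_dir(m, path)
  }
  invisible(path)
}

#' Read cell-type labels from CSV
#'
#' Expects a header `cell_id,cell_type`.
#'
#' @param path CSV file.
#' @return Named factor of cell types, names = cell ids.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cell_type") %in% names(df)))
    stop(sprintf("'%s' must have columns cell_id,cell_type", path),
         call. = FALSE)
  setNames(factor(df$cell_type), df$cell_id)
}

#' Read peak intervals from a BED-like file
#'
#' First three columns chrom, start, end; BED convention (0-based start,
#' exclusive end).
#'
#' @param path BED file (3+ tab-separated columns, no header).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_peaks_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 3L)
    stop(sprintf("'%s' needs at least 3 BED columns", path), call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]), end = as.integer(df[[3L]]))
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop(sprintf("'%s' line %d: start >= end", path, bad[1L]), call. = FALSE)
  out
}

#' Read a gene annotation table
#'
#' Tab-separated with header `gene_id chrom start end strand`; BED-style
#' 0-based half-open coordinates; strand `+` or `-`.
#'
#' @param path TSV file.
#' @return data.frame with those five columns.
#' @export
read_gene_annotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  df <- df[need]
  if (anyDuplicated(df$gene_id))
    stop(sprintf("duplicate gene_id '%s' in '%s'",
                 df$gene_id[duplicated(df$gene_id)][1L], path), call. = FALSE)
  if (any(df$start >= df$end))
    stop(sprintf("'%s': gene start >= end", path), call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop(sprintf("'%s': strand must be + or -", path), call. = FALSE)
  df
}

#' Read a joint-embedding CSV back into an embedding set
#'
#' Reads the `cell_id,modality,dim_0..` CSV written by [run_pipeline()].
#'
#' @param path embeddings CSV file.
#' @return An `embedding_set` (see [join_embeddings()]).
#' @export
read_embeddings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "modality") %in% names(df)))
    stop(sprintf("'%s' must have columns cell_id,modality,dim_*", path),
         call. = FALSE)
  z <- as.matrix(df[, grep("^dim_", names(df)), drop = FALSE])
  is_r <- df$modality == "RNA"
  z_r <- z[is_r, , drop = FALSE]
  z_a <- z[!is_r, , drop = FALSE]
  rownames(z_r) <- df$cell_id[is_r]
  rownames(z_a) <- df$cell_id[!is_r]
  join_embeddings(z_r, z_a, df$cell_id[is_r])
}

#' Export / import a cell graph as 0-based edge-list TSV
#'
#' @param g a `cell_graph` from [knn_edges()].
#' @param path output TSV (`src<TAB>dst`, 0-based node indices).
#' @return Invisibly `path` (write) / a `cell_graph` (read; `k` is recovered
#'   as the maximum out-degree).
#' @export
write_edges <- function(g, path) {
  stopifnot(inherits(g, "cell_graph"))
  df <- data.frame(src = g$edges[, 1L] - 1L, dst = g$edges[, 2L] - 1L)
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @param n_nodes node count of the stored graph.
#' @param modality modality tag.
#' @export
read_edges <- function(path, n_nodes, modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  df <- read.table(path, sep = "\t", header = TRUE)
  edges <- cbind(as.integer(df$src) + 1L, as.integer(df$dst) + 1L)
  cell_graph(n_nodes, edges, modality,
             k = if (nrow(edges)) max(tabulate(edges[, 1L], n_nodes)) else 0L)
}
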