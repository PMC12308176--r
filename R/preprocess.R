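#' Preprocessing configuration
#'
#' @param target_sum library-size target per cell before log transform.
#' @param n_hvg number of highly variable features to keep.
#' @param n_pca number of principal components (the shared encoder input
#'   dimension).
#' @param scale_clip absolute cap applied to standardised values.
#' @param promoter_upstream_bp strand-aware upstream extension of the gene
#'   body when scoring gene activity from ATAC peaks.
#' @return A validated list of class `preproc_config`.
#' @export
preproc_config <- function(target_sum = 1e4, n_hvg = 2000L, n_pca = 30L,
                           scale_clip = 10, promoter_upstream_bp = 2000L) {
  stop_if_not_scalar_number(target_sum, "target_sum", min = 1e-12)
  stop_if_not_scalar_number(n_hvg, "n_hvg", min = 1, integer = TRUE)
  stop_if_not_scalar_number(n_pca, "n_pca", min = 1, integer = TRUE)
  stop_if_not_scalar_number(scale_clip, "scale_clip", min = 1e-12)
  stop_if_not_scalar_number(promoter_upstream_bp, "promoter_upstream_bp",
                            min = 0, integer = TRUE)
  if (n_pca > n_hvg)
    stop("n_pca must not exceed n_hvg", call. = FALSE)
  structure(list(target_sum = target_sum, n_hvg = as.integer(n_hvg),
                 n_pca = as.integer(n_pca), scale_clip = scale_clip,
                 promoter_upstream_bp = as.integer(promoter_upstream_bp)),
            class = "preproc_config")
}

#' Convert an ATAC peak-count matrix to a gene-activity matrix
#'
#' Each gene's activity in a cell is the sum of counts over all peaks that
#' overlap the gene body extended `promoter_upstream_bp` upstream of the TSS
#' (strand-aware, clipped at position 0). Genes with no overlapping peak are
#' kept as all-zero columns so the feature universe matches the annotation.
#' Coordinates are BED-style 0-based half-open in both inputs.
#'
#' @param values cells x peaks non-negative count matrix.
#' @param peaks data.frame `chrom,start,end` (one row per peak column), e.g.
#'   from [read_peaks_bed()].
#' @param annotation data.frame `gene_id,chrom,start,end,strand`, e.g. from
#'   [read_gene_annotation()].
#' @param cfg a [preproc_config()] (only `promoter_upstream_bp` is used).
#' @param cell_ids optional cell identifiers (defaults to rownames).
#' @return A [cell_matrix()] with `modality = "ATAC"`, genes as features.
#' @export
peaks_to_gene_activity <- function(values, peaks, annotation,
                                   cfg = preproc_config(),
                                   cell_ids = rownames(values)) {
  if (nrow(annotation) == 0L)
    stop("empty gene annotation", call. = FALSE)
  if (nrow(peaks) != ncol(values))
    stop("peaks must have one row per matrix column", call. = FALSE)
  neg <- if (is(values, "Matrix")) any(values@x < 0) else any(values < 0)
  if (neg) stop("peak counts must be non-negative", call. = FALSE)

  up <- cfg$promoter_upstream_bp
  g_start0 <- ifelse(annotation$strand == "+",
                     pmax(annotation$start - up, 0L), annotation$start)
  g_end0 <- ifelse(annotation$strand == "+",
                   annotation$end, annotation$end + up)

  out <- matrix(0, nrow(values), nrow(annotation))
  if (length(intersect(unique(peaks$chrom), unique(annotation$chrom))) == 0L) {
    warning("no chromosome shared between peaks and annotation; ",
            "gene activity is all zero")
  } else {
    # 0-based half-open -> 1-based closed for IRanges
    pk <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
    gn <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(g_start0 + 1L, g_end0))
    hits <- GenomicRanges::findOverlaps(pk, gn)
    if (length(hits)) {
      ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                                  j = S4Vectors::subjectHits(hits), x = 1,
                                  dims = c(nrow(peaks), nrow(annotation)))
      out <- as.matrix(values %*% ind)
    }
  }
  cell_matrix(out, cell_ids %||% paste0("cell_", seq_len(nrow(values))),
              annotation$gene_id, "ATAC")
}

#' Library-size normalise and log-transform
#'
#' Scales each cell to total `target_sum`, then applies `log(1 + x)`. Cells
#' whose counts sum to zero are left all-zero with a warning.
#'
#' @param m a [cell_matrix()] of non-negative values.
#' @param cfg a [preproc_config()].
#' @return A [cell_matrix()] of the same shape.
#' @export
normalize_log <- function(m, cfg = preproc_config()) {
  m <- as_cell_matrix(m)
  v <- dense_values(m)
  if (any(v < 0))
    stop("normalize_log requires non-negative values", call. = FALSE)
  rs <- rowSums(v)
  zero <- rs == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero total count left as zeros (e.g. '%s')",
                    sum(zero), m$cell_ids[which(zero)[1L]]))
    rs[zero] <- 1
  }
  out <- log1p(v / rs * cfg$target_sum)
  cell_matrix(out, m$cell_ids, m$feature_ids, m$modality)
}

# Per-feature dispersion statistic used for HVG ranking: variance of the
# (log-normalised) values, n-1 denominator. Exposed for tests.
hvg_statistic <- function(v) {
  n <- nrow(v)
  if (n < 2) return(rep(0, ncol(v)))
  mu <- colMeans(v)
  (colSums(v^2) - n * mu^2) / (n - 1)
}

#' Select highly variable features
#'
#' Ranks features by variance of the log-normalised values and keeps the top
#' `n_hvg`, ordered by descending variance with ties broken by feature id.
#' Asking for more features than exist keeps them all (with a warning), still
#' in ranked order.
#'
#' @param m a log-normalised [cell_matrix()].
#' @param n_hvg number of features to keep.
#' @return A [cell_matrix()] with `n_hvg` (or fewer) columns.
#' @export
select_hvg <- function(m, n_hvg) {
  m <- as_cell_matrix(m)
  stop_if_not_scalar_number(n_hvg, "n_hvg", min = 1, integer = TRUE)
  v <- dense_values(m)
  disp <- hvg_statistic(v)
  if (n_hvg > ncol(v)) {
    warning(sprintf("n_hvg = %d exceeds %d features; keeping all",
                    n_hvg, ncol(v)))
    n_hvg <- ncol(v)
  }
  ord <- order(-disp, m$feature_ids)[seq_len(n_hvg)]
  cell_matrix(v[, ord, drop = FALSE], m$cell_ids, m$feature_ids[ord],
              m$modality)
}

#' Standardise features
#'
#' Centres each feature to mean zero and scales to unit variance using the
#' population (n) denominator; zero-variance features become all-zero. Values
#' are then clipped to `[-scale_clip, scale_clip]`.
#'
#' @param m a [cell_matrix()].
#' @param scale_clip absolute cap on standardised values.
#' @return A [cell_matrix()] of the same shape.
#' @export
scale_features <- function(m, scale_clip = 10) {
  m <- as_cell_matrix(m)
  v <- dense_values(m)
  mu <- colMeans(v)
  sdn <- sqrt(colMeans(v^2) - mu^2)   # population sd
  sdn[sdn < 1e-12] <- Inf             # zero-variance -> 0 after division
  out <- sweep(sweep(v, 2L, mu, "-"), 2L, sdn, "/")
  out[out > scale_clip] <- scale_clip
  out[out < -scale_clip] <- -scale_clip
  cell_matrix(out, m$cell_ids, m$feature_ids, m$modality)
}

#' Principal component scores
#'
#' Exact SVD of the column-centred matrix; returns the cells x `n_pca` score
#' matrix of the leading components. The sign of each component is fixed by
#' making its largest-magnitude loading entry positive, so results are
#' deterministic and invariant (up to that convention) to feature permutation.
#'
#' @param m a scaled [cell_matrix()].
#' @param n_pca number of components; at most `min(n_cells, n_features)`.
#' @return A [cell_matrix()] whose features are `PC1..PCn`.
#' @export
reduce_pca <- function(m, n_pca) {
  m <- as_cell_matrix(m)
  stop_if_not_scalar_number(n_pca, "n_pca", min = 1, integer = TRUE)
  v <- dense_values(m)
  if (n_pca > min(dim(v)))
    stop(sprintf("n_pca = %d exceeds min(n_cells, n_features) = %d",
                 n_pca, min(dim(v))), call. = FALSE)
  vc <- sweep(v, 2L, colMeans(v), "-")
  s <- svd(vc, nu = n_pca, nv = n_pca)
  flip <- vapply(seq_len(n_pca), function(j) {
    l <- s$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(s$u, 2L, s$d[seq_len(n_pca)] * flip, "*")
  cell_matrix(scores, m$cell_ids, paste0("PC", seq_len(n_pca)), m$modality)
}

#' Full preprocessing pipeline for one modality
#'
#' Composition normalise/log -> HVG -> scale -> PCA, preserving cell order and
#' identifiers throughout.
#'
#' @param m a raw [cell_matrix()].
#' @param cfg a [preproc_config()].
#' @return A cells x `n_pca` [cell_matrix()] of PC scores.
#' @export
preprocess_matrix <- function(m, cfg = preproc_config()) {
  m <- normalize_log(m, cfg)
  m <- select_hvg(m, cfg$n_hvg)
  m <- scale_features(m, cfg$scale_clip)
  reduce_pca(m, cfg$n_pca)
}
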