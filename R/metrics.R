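#' Join per-modality embeddings into one set
#'
#' Stacks all RNA rows then all ATAC rows, tagging each row with its cell id
#' and modality. Row `i` and row `N + i` are the two views of the same cell.
#'
#' @param z_r,z_a cells x `out_dim` embeddings in identical cell order; if
#'   both carry rownames these must agree (a permutation of one modality is
#'   an error, not silently reordered).
#' @param cell_ids cell identifiers in the shared order (defaults to
#'   rownames).
#' @return A list of class `embedding_set`: `z_r`, `z_a`, `joint`
#'   (2N x out_dim), `cell_id` and `modality` (length-2N tags).
#' @export
join_embeddings <- function(z_r, z_a, cell_ids = rownames(z_r)) {
  if (!all(dim(z_r) == dim(z_a)))
    stop("Z_R and Z_A must have identical shapes", call. = FALSE)
  if (!is.null(rownames(z_r)) && !is.null(rownames(z_a)) &&
      !identical(rownames(z_r), rownames(z_a)))
    stop("cell id mismatch between Z_R and Z_A", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(z_r)))
  if (length(cell_ids) != nrow(z_r))
    stop("cell_ids length mismatch", call. = FALSE)
  if (any(!is.finite(z_r)) || any(!is.finite(z_a)))
    stop("embeddings must be finite", call. = FALSE)
  joint <- rbind(z_r, z_a)
  rownames(joint) <- NULL
  structure(list(z_r = z_r, z_a = z_a, joint = joint,
                 cell_id = c(cell_ids, cell_ids),
                 modality = rep(c("RNA", "ATAC"), each = nrow(z_r))),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d cells x %d dims per modality\n",
              nrow(x$z_r), ncol(x$z_r)))
  invisible(x)
}

#' Transfer labels from RNA to ATAC cells by KNN vote
#'
#' Each ATAC cell takes the plurality label among its `k_classify` nearest
#' RNA cells (Euclidean distance in the embedding); vote ties are broken by
#' the label of the single nearest neighbour.
#'
#' @param z_r RNA embeddings (reference).
#' @param labels_r labels for every RNA cell.
#' @param z_a ATAC embeddings (query).
#' @param k_classify neighbourhood size; at most the number of RNA cells.
#' @return Factor of predicted labels, one per ATAC cell, with the levels of
#'   `labels_r`.
#' @export
transfer_labels <- function(z_r, labels_r, z_a, k_classify = 15L) {
  labels_r <- as.factor(labels_r)
  if (length(labels_r) != nrow(z_r))
    stop("labels_r must cover all RNA cells", call. = FALSE)
  if (anyNA(labels_r))
    stop("labels_r contains missing values", call. = FALSE)
  stop_if_not_scalar_number(k_classify, "k_classify", min = 1, integer = TRUE)
  if (k_classify > nrow(z_r))
    stop(sprintf("k_classify = %d exceeds the %d RNA cells",
                 k_classify, nrow(z_r)), call. = FALSE)
  d <- cross_distances(z_a, z_r)
  pred <- character(nrow(z_a))
  for (i in seq_len(nrow(z_a))) {
    nb <- order(d[i, ], seq_len(ncol(d)))[seq_len(k_classify)]
    votes <- table(labels_r[nb])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else as.character(labels_r[nb[1L]])
  }
  factor(pred, levels = levels(labels_r))
}

# Euclidean distances between rows of a (queries) and rows of b (refs).
cross_distances <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions under the permutation
#' model, computed from the contingency table.
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @return Scalar in `[-1, 1]`; 1 for identical partitions, ~0 for chance.
#' @export
ari <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(labels_true, labels_pred)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxindex <- (sum_a + sum_b) / 2
  if (maxindex == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maxindex - expected)
}

#' Normalised mutual information
#'
#' Mutual information between the two partitions divided by the arithmetic
#' mean of their entropies (natural-log internals, the normalisation cancels
#' the base). If either partition has a single class (zero entropy) the score
#' is 0 by convention.
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(labels_true, labels_pred)
  n <- sum(tab)
  p_ij <- tab / n
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_i <- ent(p_i); h_j <- ent(p_j)
  if (h_i == 0 || h_j == 0) return(0)
  nz <- p_ij > 0
  mi <- sum(p_ij[nz] * log(p_ij[nz] / outer(p_i, p_j)[nz]))
  max(0, min(1, mi / ((h_i + h_j) / 2)))
}

#' F1 score
#'
#' Per-class F1 from the confusion table, averaged. A predicted label absent
#' from the truth contributes its own class with zero recall support (macro
#' mean over the union of classes).
#'
#' @inheritParams ari
#' @param averaging `"macro"` (unweighted class mean, default) or
#'   `"weighted"` (weighted by true class frequency).
#' @return Scalar in `[0, 1]`.
#' @export
f1_score <- function(labels_true, labels_pred, averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length", call. = FALSE)
  classes <- union(unique(as.character(labels_true)),
                   unique(as.character(labels_pred)))
  truef <- factor(as.character(labels_true), levels = classes)
  predf <- factor(as.character(labels_pred), levels = classes)
  tab <- table(truef, predf)
  tp <- diag(tab)
  prec <- ifelse(colSums(tab) > 0, tp / colSums(tab), 0)
  rec <- ifelse(rowSums(tab) > 0, tp / rowSums(tab), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  if (averaging == "macro") mean(f1)
  else sum(f1 * rowSums(tab)) / sum(tab)
}

#' Batch entropy of modality mixing
#'
#' For each row of the joint embedding, the `k_be` nearest other rows are
#' found and `p` is the fraction coming from the RNA modality; the cell's
#' entropy is `-(p log2 p + (1-p) log2 (1-p))` (0 log 0 = 0) and the score is
#' the mean over cells. With two batches this already lies in `[0, 1]`:
#' 1 = perfectly mixed modalities, 0 = fully separated.
#'
#' @param joint an `embedding_set` from [join_embeddings()], or a matrix with
#'   `modality` supplied.
#' @param k_be neighbourhood size (must be `< 2N`).
#' @param modality row tags when `joint` is a bare matrix.
#' @return Scalar in `[0, 1]`.
#' @export
batch_entropy <- function(joint, k_be = 15L, modality = NULL) {
  if (inherits(joint, "embedding_set")) {
    modality <- joint$modality
    joint <- joint$joint
  }
  n <- nrow(joint)
  stop_if_not_scalar_number(k_be, "k_be", min = 1, integer = TRUE)
  if (k_be >= n)
    stop(sprintf("k_be = %d must be smaller than the %d joint rows", k_be, n),
         call. = FALSE)
  d <- pairwise_distances(joint)
  is_rna <- modality == "RNA"
  h <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di, seq_len(n))[seq_len(k_be)]
    p <- mean(is_rna[nb])
    h[i] <- entropy2(p)
  }
  mean(h)
}

entropy2 <- function(p) {
  terms <- c(p, 1 - p)
  terms <- terms[terms > 0]
  -sum(terms * log2(terms))
}

#' Silhouette coefficient
#'
#' Mean over cells of `(b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to the cell's own label (self excluded) and `b` the smallest mean
#' distance to any other label; cells in singleton labels contribute 0.
#'
#' @param z embedding matrix (or `embedding_set`, scored on its joint rows).
#' @param labels one label per row.
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(z, labels) {
  if (inherits(z, "embedding_set")) z <- z$joint
  labels <- as.factor(labels)
  if (length(labels) != nrow(z))
    stop("labels must have one entry per row", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2)
    stop("silhouette needs at least 2 labels", call. = FALSE)
  d <- pairwise_distances(z)
  lev <- levels(labels)
  sizes <- table(labels)
  # mean distance from each cell to each label group
  group_means <- sapply(lev, function(l) rowMeans(d[, labels == l, drop = FALSE]))
  s <- numeric(nrow(z))
  for (i in seq_len(nrow(z))) {
    li <- as.character(labels[i])
    ni <- sizes[[li]]
    if (ni <= 1) { s[i] <- 0; next }
    a <- group_means[i, li] * ni / (ni - 1)   # exclude self from own group
    b <- min(group_means[i, setdiff(lev, li)])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Biological signal loss
#'
#' `1 - Pearson r` between a feature's per-cell values before and after
#' integration: 0 means the profile is perfectly preserved, 2 means exact
#' anti-correlation.
#'
#' @param original_values,integrated_values equal-length numeric vectors
#'   (length >= 3, non-constant).
#' @return Scalar in `[0, 2]`.
#' @export
signal_loss <- function(original_values, integrated_values) {
  if (length(original_values) != length(integrated_values))
    stop("vectors must have equal length", call. = FALSE)
  if (length(original_values) < 3)
    stop("need at least 3 cells", call. = FALSE)
  if (sd(original_values) == 0 || sd(integrated_values) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  1 - cor(original_values, integrated_values)
}

#' Evaluate an integration end to end
#'
#' Transfers labels RNA -> ATAC, then scores the prediction (ARI, NMI, F1 and
#' their sum), the modality mixing (batch entropy on the joint embedding) and
#' the biological separation (silhouette on the joint embedding with the true
#' labels).
#'
#' @param embeddings an `embedding_set` from [join_embeddings()].
#' @param labels_true_r RNA cell labels (transfer reference and truth).
#' @param labels_true_a ATAC cell labels (truth for scoring; defaults to
#'   `labels_true_r`, the paired-data case).
#' @param k_classify KNN size for label transfer (30, mirroring the joint
#'   n_neighbors choice).
#' @param k_be KNN size for batch entropy (15).
#' @param averaging F1 averaging, `"macro"` or `"weighted"`.
#' @param normalize L2-normalise embedding rows before computing distances
#'   (default `TRUE`). The encoder is trained with a cosine-similarity
#'   objective, which leaves the norm of each embedding unconstrained and
#'   lets the two modalities drift to different scales; on the unit sphere
#'   Euclidean distance is monotone in cosine similarity, so normalising puts
#'   the Euclidean KNN metrics in the geometry the model was optimised for.
#' @return A list of class `metrics_report`: `ari`, `nmi`, `f1`, `sum_score`,
#'   `batch_entropy`, `silhouette`, `per_class_accuracy`, `confusion`
#'   (true x predicted counts), `predicted_labels`, and a `conventions` note.
#' @export
evaluate_integration <- function(embeddings, labels_true_r,
                                 labels_true_a = labels_true_r,
                                 k_classify = 15L, k_be = 15L,
                                 averaging = c("macro", "weighted"),
                                 normalize = TRUE) {
  stopifnot(inherits(embeddings, "embedding_set"))
  averaging <- match.arg(averaging)
  labels_true_r <- as.factor(labels_true_r)
  labels_true_a <- as.factor(labels_true_a)
  if (normalize) {
    ids <- embeddings$cell_id[seq_len(nrow(embeddings$z_r))]
    embeddings <- join_embeddings(
      normalize_rows(embeddings$z_r, ids, "Z_R"),
      normalize_rows(embeddings$z_a, ids, "Z_A"), ids)
  }
  pred <- transfer_labels(embeddings$z_r, labels_true_r, embeddings$z_a,
                          k_classify)
  a <- ari(labels_true_a, pred)
  m <- nmi(labels_true_a, pred)
  f <- f1_score(labels_true_a, pred, averaging)
  confusion <- table(true = labels_true_a,
                     predicted = factor(pred, levels = levels(labels_true_a)))
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  report <- list(
    ari = a, nmi = m, f1 = f, sum_score = a + m + f,
    batch_entropy = batch_entropy(embeddings, k_be),
    silhouette = silhouette_score(embeddings,
                                  c(as.character(labels_true_r),
                                    as.character(labels_true_a))),
    per_class_accuracy = setNames(as.numeric(per_class), rownames(confusion)),
    confusion = confusion, predicted_labels = pred,
    transfer_accuracy = mean(as.character(pred) ==
                               as.character(labels_true_a)),
    conventions = list(ari = "permutation model",
                       nmi = "arithmetic-mean normalisation",
                       f1 = averaging, k_classify = k_classify, k_be = k_be,
                       normalized_embeddings = normalize))
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  ARI %.3f | NMI %.3f | F1 %.3f | SUM %.3f\n",
              x$ari, x$nmi, x$f1, x$sum_score))
  cat(sprintf("  batch entropy %.3f | silhouette %.3f | transfer accuracy %.3f\n",
              x$batch_entropy, x$silhouette, x$transfer_accuracy))
  invisible(x)
}

#' 2-D UMAP layout of a joint embedding
#'
#' Delegates to the `uwot` package (optional dependency) with a fixed seed;
#' intended for figures only — no metric in this package depends on it.
#'
#' @param joint an `embedding_set` or matrix.
#' @param n_neighbors UMAP neighbourhood size (30).
#' @param seed layout seed.
#' @return A (rows x 2) coordinate matrix.
#' @export
umap_view <- function(joint, n_neighbors = 30L, seed = 1L) {
  if (inherits(joint, "embedding_set")) joint <- joint$joint
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("umap_view needs the optional 'uwot' package, which is not installed; ",
         "all metrics are computed on the embedding itself and are unaffected",
         call. = FALSE)
  with_seed(seed,
            uwot::umap(joint, n_neighbors = n_neighbors, ret_model = FALSE))
}
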