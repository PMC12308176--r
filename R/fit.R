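#' Fit a cross-modality contrastive integration model
#'
#' One-call interface over the whole pipeline: per-modality preprocessing
#' (library-size normalisation, log transform, HVG selection, scaling, PCA),
#' KNN graph construction with unidirectional edge pruning, contrastive
#' training of the shared encoder, embedding, and — when labels are supplied —
#' RNA-to-ATAC label transfer plus the integration metric suite.
#'
#' @param rna,atac paired [cell_matrix()]s (or plain matrices) over the same
#'   cells in the same order; `atac` is expected on the gene-activity scale
#'   (use [peaks_to_gene_activity()] for raw peak counts).
#' @param labels optional cell-type labels (one per cell, shared by both
#'   modalities since the data are paired).
#' @param preproc a [preproc_config()].
#' @param graph a [graph_config()].
#' @param model a [model_config()]; `in_dim` is overridden by
#'   `preproc$n_pca`.
#' @param train a [train_config()].
#' @param k_classify,k_be,averaging evaluation settings, see
#'   [evaluate_integration()].
#' @param verbose emit per-stage progress messages.
#' @return An object of class `omixcl`: list with `model` (trained
#'   `encoder_model`), `trace` (training trace), `embeddings`
#'   (`embedding_set`), `graphs`, `pca` (per-modality PC scores), `metrics`
#'   (`metrics_report` or `NULL`), `labels`, `configs` and `call`.
#' @examples
#' ds <- simulate_paired(sim_config(n_cells = 90, n_genes = 60, seed = 1))
#' fit <- omixcl(ds$rna, ds$atac, ds$labels,
#'               preproc = preproc_config(n_hvg = 60, n_pca = 10),
#'               graph = graph_config(k = 10),
#'               model = model_config(hidden_dim = 40, out_dim = 16),
#'               train = train_config(epochs = 40),
#'               k_classify = 5)
#' fit
#' @export
omixcl <- function(rna, atac, labels = NULL,
                   preproc = preproc_config(), graph = graph_config(),
                   model = model_config(), train = train_config(),
                   k_classify = 15L, k_be = 15L,
                   averaging = c("macro", "weighted"), verbose = FALSE) {
  averaging <- match.arg(averaging)
  rna <- as_cell_matrix(rna, "RNA")
  atac <- as_cell_matrix(atac, "ATAC")
  if (!identical(rna$cell_ids, atac$cell_ids))
    stop("unpaired inputs: RNA and ATAC cell ids differ", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(rna$cell_ids))
    stop("labels must have one entry per cell", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("preprocessing %d cells", length(rna$cell_ids))
  x_r <- preprocess_matrix(rna, preproc)
  x_a <- preprocess_matrix(atac, preproc)

  say("building %d-NN graphs (edge drop rate %.2f)", graph$k,
      graph$edge_drop_rate)
  g_r <- build_modality_graph(x_r, graph)
  g_a <- build_modality_graph(x_a, graph)

  model$in_dim <- preproc$n_pca
  enc <- init_model(model)
  say("training %s encoder for up to %d epochs (lr %g, tau %g, %s loss)",
      model$encoder_kind, train$epochs, train$lr, train$tau, train$loss_kind)
  fit <- train_encoder(enc, g_r, g_a, x_r, x_a, train)

  z_r <- embed_cells(fit$model, g_r, x_r)
  z_a <- embed_cells(fit$model, g_a, x_a)
  emb <- join_embeddings(z_r, z_a, rna$cell_ids)

  metrics <- NULL
  if (!is.null(labels)) {
    say("evaluating (k_classify %d, k_be %d)", k_classify, k_be)
    metrics <- evaluate_integration(emb, labels, labels, k_classify, k_be,
                                    averaging)
  }
  structure(list(model = fit$model, trace = fit$trace, embeddings = emb,
                 graphs = list(rna = g_r, atac = g_a),
                 pca = list(rna = x_r, atac = x_a), metrics = metrics,
                 labels = if (is.null(labels)) NULL else as.factor(labels),
                 configs = list(preproc = preproc, graph = graph,
                                model = model, train = train,
                                eval = list(k_classify = k_classify,
                                            k_be = k_be,
                                            averaging = averaging)),
                 call = match.call()),
            class = "omixcl")
}

#' @export
print.omixcl <- function(x, ...) {
  cat("Cross-modality graph contrastive integration fit\n")
  cat(sprintf("  %d cells, %s encoder, %d epochs run, final %s loss %.4f\n",
              nrow(x$embeddings$z_r), x$configs$model$encoder_kind,
              nrow(x$trace), x$configs$train$loss_kind,
              x$trace$loss[nrow(x$trace)]))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' @export
summary.omixcl <- function(object, ...) {
  x <- object
  cat("Cross-modality graph contrastive integration fit\n\n")
  cat(sprintf("Cells: %d   Encoder: %s (%d parameters)   Loss: %s\n",
              nrow(x$embeddings$z_r), x$configs$model$encoder_kind,
              n_parameters(x$model), x$configs$train$loss_kind))
  tr <- x$trace
  cat(sprintf("Training: %d epochs, loss %.4f -> %.4f, pair cosine %.3f -> %.3f\n",
              nrow(tr), tr$loss[1], tr$loss[nrow(tr)], tr$pair_cos[1],
              tr$pair_cos[nrow(tr)]))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat("\nIntegration metrics (RNA -> ATAC label transfer):\n")
    cat(sprintf("  ARI %.3f  NMI %.3f  F1 %.3f  SUM %.3f\n",
                m$ari, m$nmi, m$f1, m$sum_score))
    cat(sprintf("  batch entropy %.3f  silhouette %.3f  accuracy %.3f\n",
                m$batch_entropy, m$silhouette, m$transfer_accuracy))
    cat("\nPer-class transfer accuracy:\n")
    print(round(m$per_class_accuracy, 3))
  }
  invisible(x)
}

#' @export
coef.omixcl <- function(object, ...) {
  object$model[c("W0", "W1", "W2", "Wp1", "Wp2")]
}

#' Predict method: embeddings or transferred labels
#'
#' @param object an `omixcl` fit.
#' @param type `"labels"` returns the RNA-to-ATAC transferred labels,
#'   `"embedding"` the joint embedding matrix.
#' @param k_classify neighbourhood size when `type = "labels"` (defaults to
#'   the fit's setting).
#' @param ... unused.
#' @return Factor of predicted ATAC labels, or the 2N x out_dim joint
#'   embedding.
#' @export
predict.omixcl <- function(object, type = c("labels", "embedding"),
                           k_classify = NULL, ...) {
  type <- match.arg(type)
  if (type == "embedding") return(object$embeddings$joint)
  if (is.null(object$labels))
    stop("fit has no labels; supply `labels` to omixcl() for transfer",
         call. = FALSE)
  # same cosine-geometry convention as evaluate_integration()
  transfer_labels(normalize_rows(object$embeddings$z_r),
                  object$labels,
                  normalize_rows(object$embeddings$z_a),
                  k_classify %||% object$configs$eval$k_classify)
}

#' Plot a fitted integration
#'
#' Scatter of the joint embedding's first two principal components, coloured
#' by cell type (when known) with plotting symbol by modality. UMAP layouts
#' are available separately via [umap_view()] when `uwot` is installed.
#'
#' @param x an `omixcl` fit.
#' @param ... passed to [plot()].
#' @return Invisibly, the 2-D coordinates.
#' @export
plot.omixcl <- function(x, ...) {
  emb <- x$embeddings
  xy <- reduce_pca(cell_matrix(emb$joint, paste0("row_", seq_len(nrow(emb$joint))),
                               paste0("dim_", seq_len(ncol(emb$joint))), "RNA"),
                   n_pca = 2L)
  xy <- dense_values(xy)
  col <- if (!is.null(x$labels)) as.integer(x$labels) else 1L
  plot(xy[, 1], xy[, 2], col = rep(col, 2),
       pch = ifelse(emb$modality == "RNA", 1, 3),
       xlab = "embedding PC1", ylab = "embedding PC2", ...)
  if (!is.null(x$labels))
    graphics::legend("topright", legend = levels(x$labels),
                     col = seq_len(nlevels(x$labels)), pch = 16, cex = 0.8)
  invisible(xy)
}
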