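#' Configuration for the paired-data simulator
#'
#' Parameters of the shared-latent generative model used by
#' [simulate_paired()]. Each cell draws a type, its latent state is the type
#' centroid plus isotropic Gaussian scatter, RNA counts are negative binomial
#' around a softplus-linear mean, and the ATAC gene-activity value is the RNA
#' log-mean corrupted by Gaussian noise and dropout — so the two modalities
#' share per-cell state exactly as paired assays profile one physical cell.
#'
#' @param n_cells number of cells (>= 1).
#' @param n_types number of discrete cell types.
#' @param type_proportions probability vector of length `n_types` summing to 1.
#' @param n_genes number of features (shared by both modalities).
#' @param n_markers_per_type number of marker genes boosted per type.
#' @param latent_dim dimension of the shared latent state.
#' @param rna_dispersion negative binomial overdispersion alpha, with
#'   variance `mu + alpha * mu^2`.
#' @param atac_noise_sd standard deviation of additive Gaussian noise on the
#'   ATAC gene-activity values.
#' @param atac_dropout probability that an ATAC entry is zeroed.
#' @param rare_type_fraction optional: overall proportion assigned to the last
#'   type, the remainder split evenly across the others (overrides
#'   `type_proportions`).
#' @param seed integer seed; the whole dataset is drawn from one stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 600L, n_types = 3L,
                       type_proportions = rep(1 / n_types, n_types),
                       n_genes = 200L, n_markers_per_type = 10L,
                       latent_dim = 10L, rna_dispersion = 0.1,
                       atac_noise_sd = 0.3, atac_dropout = 0.3,
                       rare_type_fraction = NULL, seed = 1L) {
  stop_if_not_scalar_number(n_cells, "n_cells", min = 1, integer = TRUE)
  stop_if_not_scalar_number(n_types, "n_types", min = 1, integer = TRUE)
  stop_if_not_scalar_number(n_genes, "n_genes", min = 1, integer = TRUE)
  stop_if_not_scalar_number(n_markers_per_type, "n_markers_per_type", min = 0,
                            integer = TRUE)
  stop_if_not_scalar_number(latent_dim, "latent_dim", min = 1, integer = TRUE)
  stop_if_not_scalar_number(rna_dispersion, "rna_dispersion", min = 1e-12)
  stop_if_not_scalar_number(atac_noise_sd, "atac_noise_sd", min = 0)
  stop_if_not_scalar_number(atac_dropout, "atac_dropout", min = 0, max = 1)
  stop_if_not_scalar_number(seed, "seed", integer = TRUE)
  if (!is.null(rare_type_fraction)) {
    stop_if_not_scalar_number(rare_type_fraction, "rare_type_fraction",
                              min = 0, max = 1)
    if (n_types < 2)
      stop("rare_type_fraction needs n_types >= 2", call. = FALSE)
    type_proportions <- c(rep((1 - rare_type_fraction) / (n_types - 1),
                              n_types - 1), rare_type_fraction)
  }
  if (length(type_proportions) != n_types)
    stop("type_proportions must have length n_types", call. = FALSE)
  if (any(type_proportions < 0) || any(type_proportions > 1))
    stop("type_proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must sum to 1 (within 1e-9)", call. = FALSE)
  if (n_types > n_cells)
    stop("n_types must not exceed n_cells", call. = FALSE)
  if (n_markers_per_type * n_types > n_genes)
    stop("n_markers_per_type * n_types must not exceed n_genes", call. = FALSE)
  if (latent_dim < n_types)
    stop("latent_dim must be at least n_types (orthonormal type centroids)",
         call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), n_types = as.integer(n_types),
                 type_proportions = as.numeric(type_proportions),
                 n_genes = as.integer(n_genes),
                 n_markers_per_type = as.integer(n_markers_per_type),
                 latent_dim = as.integer(latent_dim),
                 rna_dispersion = rna_dispersion,
                 atac_noise_sd = atac_noise_sd, atac_dropout = atac_dropout,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Largest-remainder apportionment of n cells to proportions p, each type >= 1.
apportion_counts <- function(n, p) {
  quota <- n * p
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  while (any(counts == 0)) {
    counts[which.max(counts)] <- max(counts) - 1L
    counts[which(counts == 0)[1L]] <- 1L
  }
  as.integer(counts)
}

#' Simulate a paired RNA/ATAC dataset with known cell types
#'
#' Draws a dataset from the shared-latent model described in [sim_config()].
#' Cell `i` in the RNA matrix and cell `i` in the ATAC matrix are generated
#' from the same latent vector and label, so they form a ground-truth positive
#' pair for contrastive integration. Marker genes receive a loading boost
#' toward their assigned type's centroid and therefore show elevated group
#' means in both modalities.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_dataset` with elements `rna` and `atac`
#'   ([cell_matrix()]s over identical cells), `labels` (factor, one per cell),
#'   `latent` (cells x latent_dim matrix) and `marker_map` (named list:
#'   type -> marker gene ids; empty when `n_markers_per_type = 0`).
#' @examples
#' ds <- simulate_paired(sim_config(n_cells = 60, n_genes = 50, seed = 1))
#' table(ds$labels)
#' @export
simulate_paired <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  cfg <- config
  with_seed(cfg$seed, {
    types <- paste0("type_", seq_len(cfg$n_types))
    counts <- apportion_counts(cfg$n_cells, cfg$type_proportions)
    labels <- factor(rep(types, counts), levels = types)
    labels <- labels[sample.int(cfg$n_cells)]

    # orthonormalised Gaussian type centroids on the unit sphere: every pair
    # sits sqrt(2) apart, so type separation is set by the scatter scale
    # alone rather than the luck of the centroid draw
    centroids <- matrix(rnorm(cfg$n_types * cfg$latent_dim),
                        cfg$n_types, cfg$latent_dim)
    centroids <- t(qr.Q(qr(t(centroids))))
    latent <- centroids[as.integer(labels), , drop = FALSE] +
      matrix(rnorm(cfg$n_cells * cfg$latent_dim, sd = 0.1),
             cfg$n_cells, cfg$latent_dim)

    loadings <- matrix(rnorm(cfg$n_genes * cfg$latent_dim,
                             sd = 1 / sqrt(cfg$latent_dim)),
                       cfg$n_genes, cfg$latent_dim)
    genes <- paste0("gene_", seq_len(cfg$n_genes))
    marker_map <- list()
    if (cfg$n_markers_per_type > 0) {
      idx <- 0L
      for (t in seq_len(cfg$n_types)) {
        rows <- idx + seq_len(cfg$n_markers_per_type)
        idx <- idx + cfg$n_markers_per_type
        # boost the marker loadings toward the type centroid: cells of that
        # type (latent ~ centroid, |centroid| = 1) gain ~3 units of linear
        # predictor over other types
        loadings[rows, ] <- loadings[rows, ] +
          3 * matrix(centroids[t, ], length(rows), cfg$latent_dim,
                     byrow = TRUE)
        marker_map[[types[t]]] <- genes[rows]
      }
    }

    eta <- latent %*% Matrix::t(loadings)          # cells x genes
    mu <- softplus(eta)
    lib_size <- 2000
    mu <- mu / rowSums(mu) * lib_size
    rna <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                          size = 1 / cfg$rna_dispersion),
                  nrow = cfg$n_cells)

    log_mu <- log1p(mu)
    atac <- log_mu
    if (cfg$atac_noise_sd > 0)
      atac <- atac + matrix(rnorm(length(atac), sd = cfg$atac_noise_sd),
                            nrow = cfg$n_cells)
    atac <- pmax(atac, 0)
    if (cfg$atac_dropout > 0) {
      keep <- matrix(runif(length(atac)) >= cfg$atac_dropout,
                     nrow = cfg$n_cells)
      atac <- atac * keep
    }

    cells <- sprintf("cell_%04d", seq_len(cfg$n_cells))
    structure(list(
      rna = cell_matrix(rna, cells, genes, "RNA"),
      atac = cell_matrix(atac, cells, genes, "ATAC"),
      labels = labels, latent = latent, marker_map = marker_map,
      config = cfg), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d cells, %d genes, %d types (%s)\n",
              nrow(x$rna$values), ncol(x$rna$values), nlevels(x$labels),
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits one MatrixMarket file plus `barcodes.tsv`/`features.tsv` sidecars per
#' modality, a `labels.csv` (`cell_id,cell_type`), a `markers.json` when the
#' dataset carries markers, and a `manifest.json` listing the relative paths.
#' The files round-trip losslessly through [read_matrix()].
#'
#' @param ds a `synthetic_dataset` from [simulate_paired()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a named list of relative paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  manifest <- list()
  for (mod in c("rna", "atac")) {
    sub <- file.path(dir, mod)
    write_mtx_dir(ds[[mod]], sub)
    manifest[[mod]] <- list(matrix = file.path(mod, "matrix.mtx"),
                            barcodes = file.path(mod, "barcodes.tsv"),
                            features = file.path(mod, "features.tsv"))
  }
  labels_df <- data.frame(cell_id = ds$rna$cell_ids,
                          cell_type = as.character(ds$labels))
  write.csv(labels_df, file.path(dir, "labels.csv"), row.names = FALSE,
            quote = FALSE)
  manifest$labels <- "labels.csv"
  if (length(ds$marker_map)) {
    jsonlite::write_json(ds$marker_map, file.path(dir, "markers.json"))
    manifest$markers <- "markers.json"
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
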