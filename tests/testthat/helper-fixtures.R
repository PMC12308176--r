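# Small shared fixtures and a memo cache for the expensive end-to-end fits
# used by several acceptance checks.

tiny_sim <- function(seed = 1, ...) {
  simulate_paired(sim_config(n_cells = 120L, n_genes = 60L, latent_dim = 6L,
                             n_markers_per_type = 5L, seed = seed, ...))
}

tiny_model_cfg <- function(...) {
  model_config(in_dim = 10L, hidden_dim = 24L, out_dim = 8L, ...)
}

# Fit under the study conditions (600 cells, 3 balanced types, generator
# defaults, 300 epochs). Memoised because several checks share runs.
.fit_cache <- new.env(parent = emptyenv())

study_fit <- function(encoder_kind = "GCN", seed = 1L,
                      type_proportions = NULL) {
  key <- paste(encoder_kind, seed,
               paste(type_proportions %||% "balanced", collapse = "_"),
               sep = "|")
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  sc <- if (is.null(type_proportions)) sim_config(seed = 1L) else
    sim_config(seed = 1L, type_proportions = type_proportions)
  ds <- simulate_paired(sc)
  fit <- suppressWarnings(omixcl(
    ds$rna, ds$atac, ds$labels,
    model = model_config(encoder_kind = encoder_kind, seed = seed),
    train = train_config(epochs = 300L, seed = seed)))
  fit$dataset <- ds
  .fit_cache[[key]] <- fit
  fit
}
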