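#' Encoder/projector configuration
#'
#' A shared three-layer graph convolutional encoder
#' (`in_dim -> hidden -> hidden -> hidden`, ReLU after the first two layers,
#' none after the third) followed by a two-layer projection head
#' (`hidden -> hidden` with ReLU, then `hidden -> out_dim`). The MLP ablation
#' keeps the identical shape chain with the adjacency replaced by the
#' identity.
#'
#' @param in_dim input feature dimension (the PCA dimension).
#' @param hidden_dim hidden layer width; 300 by default.
#' @param out_dim projector output dimension (contrastive space); 128.
#' @param encoder_kind `"GCN"` or `"MLP"` (ablation).
#' @param self_loops add self-loops before symmetric normalisation so each
#'   node retains its own features during propagation (standard
#'   renormalisation); set `FALSE` for the bare degree-normalised adjacency.
#' @param tau InfoNCE temperature; 0.1.
#' @param seed seed for weight initialisation.
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(in_dim = 30L, hidden_dim = 300L, out_dim = 128L,
                         encoder_kind = c("GCN", "MLP"), self_loops = TRUE,
                         tau = 0.1, seed = 1L) {
  encoder_kind <- match.arg(encoder_kind)
  stop_if_not_scalar_number(in_dim, "in_dim", min = 1, integer = TRUE)
  stop_if_not_scalar_number(hidden_dim, "hidden_dim", min = 1, integer = TRUE)
  stop_if_not_scalar_number(out_dim, "out_dim", min = 1, integer = TRUE)
  stop_if_not_scalar_number(tau, "tau", min = 1e-12)
  stop_if_not_scalar_number(seed, "seed", integer = TRUE)
  stopifnot(is.logical(self_loops), length(self_loops) == 1L)
  structure(list(in_dim = as.integer(in_dim),
                 hidden_dim = as.integer(hidden_dim),
                 out_dim = as.integer(out_dim), encoder_kind = encoder_kind,
                 self_loops = self_loops, tau = tau, seed = as.integer(seed)),
            class = "model_config")
}

# Half-gain Glorot: U(+-0.5*sqrt(6/(fan_in+fan_out))). The smaller scale
# speeds full-batch Adam convergence (step sizes are parameter-relative) and
# loosens the ReLU "cone" the raw scheme starts embeddings in.
glorot_uniform <- function(fan_in, fan_out, gain = 0.5) {
  lim <- gain * sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialise encoder and projector weights
#'
#' Draws all five weight matrices (three encoder layers, two projector
#' layers) from a fan-based uniform Glorot scheme at half gain,
#' `U(+-0.5 sqrt(6 / (fan_in + fan_out)))`, deterministically given
#' `cfg$seed`. Layers are bias-free.
#'
#' @param cfg a [model_config()].
#' @return An object of class `encoder_model`: list of weight matrices
#'   `W0, W1, W2, Wp1, Wp2` plus `config`.
#' @export
init_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(cfg$seed, {
    h <- cfg$hidden_dim
    model <- list(W0 = glorot_uniform(cfg$in_dim, h),
                  W1 = glorot_uniform(h, h),
                  W2 = glorot_uniform(h, h),
                  Wp1 = glorot_uniform(h, h),
                  Wp2 = glorot_uniform(h, cfg$out_dim),
                  config = cfg)
    class(model) <- "encoder_model"
    model
  })
}

#' @export
print.encoder_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<encoder_model> %s %d -> %d -> %d -> %d | projector -> %d -> %d (%d parameters)\n",
    cfg$encoder_kind, cfg$in_dim, cfg$hidden_dim, cfg$hidden_dim,
    cfg$hidden_dim, cfg$hidden_dim, cfg$out_dim, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Closed form `in*h + 3*h*h + h*out` for bias-free layers.
#'
#' @param model an `encoder_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model[c("W0", "W1", "W2", "Wp1", "Wp2")], length, numeric(1)))
}

#' Symmetrically normalised adjacency matrix
#'
#' Symmetrises the directed edge set by union (an undirected edge exists if
#' either direction is present), optionally adds self-loops, and returns
#' `D^(-1/2) A D^(-1/2)` with `D` the degree matrix of the symmetrised `A`.
#' Isolated nodes (degree 0 without self-loops) get zero rows with a warning.
#'
#' @param g a `cell_graph`.
#' @param self_loops add the identity to `A` before normalisation.
#' @return A sparse symmetric `Matrix` whose spectral radius is at most 1.
#' @export
normalize_adjacency <- function(g, self_loops = TRUE) {
  stopifnot(inherits(g, "cell_graph"))
  n <- g$n_nodes
  if (nrow(g$edges)) {
    i <- c(g$edges[, 1L], g$edges[, 2L])
    j <- c(g$edges[, 2L], g$edges[, 1L])
    a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                              use.last.ij = TRUE)
    a@x[] <- 1   # union, not sum: duplicate/mutual edges collapse to 1
  } else {
    a <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  if (self_loops) a <- a + Matrix::Diagonal(n)
  a@x[] <- pmin(a@x, 1)
  deg <- Matrix::rowSums(a)
  if (any(deg == 0))
    warning(sprintf("%d isolated node(s) get zero rows in the normalised adjacency",
                    sum(deg == 0)))
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  methods::as(Matrix::Diagonal(n, dinv) %*% a %*% Matrix::Diagonal(n, dinv),
              "CsparseMatrix")
}

#' Three-layer GCN encoder forward pass
#'
#' `H1 = ReLU(A X W0)`, `H2 = ReLU(A H1 W1)`, `H3 = A H2 W2` — no activation
#' on the third layer (the projector supplies one).
#'
#' @param model an `encoder_model`.
#' @param a_hat normalised adjacency from [normalize_adjacency()].
#' @param x cells x `in_dim` input matrix.
#' @return Cells x `hidden_dim` matrix `H3`.
#' @export
gcn_forward <- function(model, a_hat, x) {
  x <- dense_values(x)
  check_shapes(model, x)
  if (nrow(a_hat) != nrow(x) || ncol(a_hat) != nrow(x))
    stop(sprintf("adjacency is %d x %d but x has %d cells",
                 nrow(a_hat), ncol(a_hat), nrow(x)), call. = FALSE)
  h1 <- relu(as.matrix(a_hat %*% x) %*% model$W0)
  h2 <- relu(as.matrix(a_hat %*% h1) %*% model$W1)
  as.matrix(a_hat %*% h2) %*% model$W2
}

#' MLP encoder forward pass (graph ablation)
#'
#' Identical layer count, shapes and activations to [gcn_forward()] with the
#' adjacency replaced by the identity.
#'
#' @inheritParams gcn_forward
#' @return Cells x `hidden_dim` matrix.
#' @export
mlp_forward <- function(model, x) {
  x <- dense_values(x)
  check_shapes(model, x)
  h1 <- relu(x %*% model$W0)
  h2 <- relu(h1 %*% model$W1)
  h2 %*% model$W2
}

check_shapes <- function(model, x) {
  if (ncol(x) != nrow(model$W0))
    stop(sprintf("input has %d features but W0 expects %d",
                 ncol(x), nrow(model$W0)), call. = FALSE)
  invisible(TRUE)
}

#' Contrastive projection head
#'
#' `Z = ReLU(H3 Wp1) Wp2`.
#'
#' @param model an `encoder_model`.
#' @param h3 encoder output (cells x `hidden_dim`).
#' @return Cells x `out_dim` matrix of contrastive-space representations.
#' @export
project_head <- function(model, h3) {
  if (ncol(h3) != nrow(model$Wp1))
    stop(sprintf("encoder output has %d columns but Wp1 expects %d",
                 ncol(h3), nrow(model$Wp1)), call. = FALSE)
  relu(h3 %*% model$Wp1) %*% model$Wp2
}

# Row-softmax of the scaled cosine-similarity matrix between two embeddings,
# via a numerically stable log-sum-exp. Shared by both losses and their
# gradients. Returns list(p = softmax matrix, log_diag = log p_ii).
cosine_softmax <- function(z_r, z_a, tau, ids = NULL) {
  if (!all(dim(z_r) == dim(z_a)))
    stop("Z_R and Z_A must have identical shapes", call. = FALSE)
  if (nrow(z_r) < 1L) stop("need at least one cell", call. = FALSE)
  u <- normalize_rows(z_r, ids, "Z_R")
  v <- normalize_rows(z_a, ids, "Z_A")
  s <- (u %*% t(v)) / tau
  lse <- row_logsumexp(s)
  list(p = exp(s - lse), log_diag = diag(s) - lse, u = u, v = v, s = s,
       lse = lse)
}

#' InfoNCE contrastive loss over paired embeddings
#'
#' `L = -(1/N) sum_i log( exp(sim(z_i^R, z_i^A)/tau) /
#' sum_j exp(sim(z_i^R, z_j^A)/tau) )` with `sim` the cosine similarity:
#' RNA-anchored, every other cell serving as a negative. With
#' `symmetric = TRUE` the ATAC-anchored term is averaged in.
#'
#' @param z_r,z_a cells x `out_dim` embeddings of the two views, row `i`
#'   being the same cell. All-zero rows are an error (cosine undefined).
#' @param tau temperature.
#' @param symmetric also average the ATAC-anchored direction (off by
#'   default).
#' @param cell_ids optional ids used in error messages.
#' @return Non-negative scalar loss.
#' @export
contrastive_loss <- function(z_r, z_a, tau = 0.1, symmetric = FALSE,
                             cell_ids = NULL) {
  cs <- cosine_softmax(z_r, z_a, tau, cell_ids)
  l <- -mean(cs$log_diag)
  if (symmetric) {
    cs2 <- cosine_softmax(z_a, z_r, tau, cell_ids)
    l <- (l - mean(cs2$log_diag)) / 2
  }
  l
}

#' Squared-error ablation of the contrastive loss
#'
#' `L = (1/N) sum_i (p_ii - 1)^2` where `p_ii` is the same normalised
#' diagonal softmax ratio as in [contrastive_loss()]; the cross-entropy is
#' replaced by a squared distance to the perfect-alignment value 1.
#'
#' @inheritParams contrastive_loss
#' @return Non-negative scalar loss.
#' @export
mse_ablation_loss <- function(z_r, z_a, tau = 0.1, cell_ids = NULL) {
  cs <- cosine_softmax(z_r, z_a, tau, cell_ids)
  mean((exp(cs$log_diag) - 1)^2)
}

#' Save / load a model checkpoint
#'
#' A versioned RDS archive holding the five weight matrices and the
#' configuration; the loader validates the shape chain before returning.
#'
#' @param model an `encoder_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint`: invisibly `path`. `load_checkpoint`: the
#'   validated `encoder_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "encoder_model"))
  saveRDS(list(format = "omixcl-checkpoint", version = 1L,
               weights = model[c("W0", "W1", "W2", "Wp1", "Wp2")],
               config = unclass(model$config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "omixcl-checkpoint"))
    stop(sprintf("'%s' is not an omixcl checkpoint", path), call. = FALSE)
  cfg <- do.call(model_config, ck$config)
  model <- c(ck$weights, list(config = cfg))
  class(model) <- "encoder_model"
  h <- cfg$hidden_dim
  want <- list(W0 = c(cfg$in_dim, h), W1 = c(h, h), W2 = c(h, h),
               Wp1 = c(h, h), Wp2 = c(h, cfg$out_dim))
  for (nm in names(want))
    if (!all(dim(model[[nm]]) == want[[nm]]))
      stop(sprintf("checkpoint weight %s has shape %s, expected %s", nm,
                   paste(dim(model[[nm]]), collapse = "x"),
                   paste(want[[nm]], collapse = "x")), call. = FALSE)
  model
}
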