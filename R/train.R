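#' Training configuration
#'
#' Full-batch contrastive training of the shared encoder on both modality
#' graphs: every epoch embeds all cells of both modalities, computes the loss
#' with all other cells as negatives, and takes one Adam step.
#'
#' @param lr Adam learning rate; 6e-4.
#' @param epochs number of full-graph epochs; 500 by default.
#' @param tau InfoNCE temperature (overrides the model config during
#'   training); 0.1.
#' @param loss_kind `"contrastive"` (InfoNCE) or `"mse"` (squared-error
#'   ablation).
#' @param log_every emit a `message()` with the loss every this many epochs;
#'   0 silences logging.
#' @param seed retained for provenance (initialisation randomness lives in
#'   [model_config()]; the training loop itself is deterministic).
#' @param early_stop_patience stop when the best loss has not improved by a
#'   relative 1e-4 for this many epochs; `NULL` disables early stopping.
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(lr = 6e-4, epochs = 500L, tau = 0.1,
                         loss_kind = c("contrastive", "mse"), log_every = 0L,
                         seed = 1L, early_stop_patience = NULL) {
  loss_kind <- match.arg(loss_kind)
  stop_if_not_scalar_number(lr, "lr", min = 0)
  stop_if_not_scalar_number(epochs, "epochs", min = 1, integer = TRUE)
  stop_if_not_scalar_number(tau, "tau", min = 1e-12)
  stop_if_not_scalar_number(log_every, "log_every", min = 0, integer = TRUE)
  stop_if_not_scalar_number(seed, "seed", integer = TRUE)
  if (!is.null(early_stop_patience))
    stop_if_not_scalar_number(early_stop_patience, "early_stop_patience",
                              min = 1, integer = TRUE)
  structure(list(lr = lr, epochs = as.integer(epochs), tau = tau,
                 loss_kind = loss_kind, log_every = as.integer(log_every),
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

# Forward pass keeping every intermediate needed for backprop.
# a_hat = NULL means the identity (MLP path).
forward_cache <- function(model, a_hat, x) {
  amul <- if (is.null(a_hat)) function(m) m
          else function(m) as.matrix(a_hat %*% m)
  p1 <- amul(x);  n1 <- p1 %*% model$W0; h1 <- relu(n1)
  p2 <- amul(h1); n2 <- p2 %*% model$W1; h2 <- relu(n2)
  p3 <- amul(h2); h3 <- p3 %*% model$W2
  m1 <- h3 %*% model$Wp1; q <- relu(m1)
  z <- q %*% model$Wp2
  list(p1 = p1, n1 = n1, h1 = h1, p2 = p2, n2 = n2, h2 = h2, p3 = p3,
       h3 = h3, m1 = m1, q = q, z = z, amul = amul)
}

# Backward pass: gradient of the loss w.r.t. the five weight matrices for one
# modality, given dL/dZ. The adjacency is symmetric, so its transpose-product
# is itself.
backward_cache <- function(model, cache, dz) {
  d_wp2 <- crossprod(cache$q, dz)
  dq <- dz %*% t(model$Wp2)
  dm1 <- dq * (cache$m1 > 0)
  d_wp1 <- crossprod(cache$h3, dm1)
  dh3 <- dm1 %*% t(model$Wp1)
  d_w2 <- crossprod(cache$p3, dh3)
  dh2 <- cache$amul(dh3 %*% t(model$W2))
  dn2 <- dh2 * (cache$n2 > 0)
  d_w1 <- crossprod(cache$p2, dn2)
  dh1 <- cache$amul(dn2 %*% t(model$W1))
  dn1 <- dh1 * (cache$n1 > 0)
  d_w0 <- crossprod(cache$p1, dn1)
  list(W0 = d_w0, W1 = d_w1, W2 = d_w2, Wp1 = d_wp1, Wp2 = d_wp2)
}

# dL/dS for the two losses (S = scaled-by-1/tau handled here), then chain
# through cosine normalisation back to the raw embeddings.
loss_and_grad_z <- function(z_r, z_a, tau, loss_kind, cell_ids = NULL) {
  cs <- cosine_softmax(z_r, z_a, tau, cell_ids)
  n <- nrow(z_r)
  if (loss_kind == "contrastive") {
    loss <- -mean(cs$log_diag)
    g_s <- (cs$p - diag(n)) / (n * tau)        # dL/dS_raw (S before /tau)
  } else {
    p_diag <- exp(cs$log_diag)
    loss <- mean((p_diag - 1)^2)
    coef <- 2 * (p_diag - 1) * p_diag / (n * tau)
    g_s <- (diag(n) - cs$p) * coef             # row i scaled by coef[i]
  }
  # S = U V^T: dL/dU = G V, dL/dV = G^T U; then through row normalisation
  du <- g_s %*% cs$v
  dv <- crossprod(g_s, cs$u)
  unnorm <- function(dunit, unit, z) {
    nrm <- sqrt(rowSums(z^2))
    (dunit - rowSums(dunit * unit) * unit) / nrm
  }
  list(loss = loss,
       dz_r = unnorm(du, cs$u, z_r), dz_a = unnorm(dv, cs$v, z_a),
       pair_cos = mean(rowSums(cs$u * cs$v)))
}

# Single loss + full gradient evaluation (exposed to tests for numerical
# gradient checks).
loss_and_gradients <- function(model, a_r, a_a, x_r, x_a, tau, loss_kind) {
  gcn <- model$config$encoder_kind == "GCN"
  c_r <- forward_cache(model, if (gcn) a_r else NULL, x_r)
  c_a <- forward_cache(model, if (gcn) a_a else NULL, x_a)
  lg <- loss_and_grad_z(c_r$z, c_a$z, tau, loss_kind)
  g_r <- backward_cache(model, c_r, lg$dz_r)
  g_a <- backward_cache(model, c_a, lg$dz_a)
  grads <- Map(`+`, g_r, g_a)   # shared weights: gradients sum over views
  list(loss = lg$loss, grads = grads, pair_cos = lg$pair_cos)
}

#' Train the shared encoder contrastively on both modality graphs
#'
#' Full-batch training: each epoch computes `Z_R` and `Z_A` with the shared
#' weights, evaluates the loss (positives = same cell across modalities,
#' negatives = all other cells) and takes one Adam step (default betas, no
#' weight decay, bias-free layers). Deterministic given the initial model;
#' aborts with the epoch index if the loss becomes non-finite.
#'
#' @param model an `encoder_model` from [init_model()].
#' @param g_r,g_a per-modality `cell_graph`s (ignored by the MLP ablation).
#' @param x_r,x_a cells x `in_dim` paired input matrices (same cells, same
#'   order); [cell_matrix()] inputs are checked for identical cell ids.
#' @param cfg a [train_config()].
#' @return A list of class `train_fit`: `model` (trained `encoder_model`) and
#'   `trace` (data.frame with per-epoch `loss`, `pair_cos` — the mean cosine
#'   similarity of positive pairs — and `seconds`).
#' @export
train_encoder <- function(model, g_r, g_a, x_r, x_a, cfg = train_config()) {
  stopifnot(inherits(model, "encoder_model"), inherits(cfg, "train_config"))
  if (inherits(x_r, "cell_matrix") && inherits(x_a, "cell_matrix") &&
      !identical(x_r$cell_ids, x_a$cell_ids))
    stop("unpaired inputs: RNA and ATAC cell ids differ", call. = FALSE)
  x_r <- dense_values(x_r); x_a <- dense_values(x_a)
  if (nrow(x_r) != nrow(x_a))
    stop("unpaired inputs: cell counts differ", call. = FALSE)
  if (ncol(x_r) != ncol(x_a))
    stop("shared encoder requires equal feature dimensions", call. = FALSE)

  gcn <- model$config$encoder_kind == "GCN"
  a_r <- a_a <- NULL
  if (gcn) {
    a_r <- normalize_adjacency(g_r, model$config$self_loops)
    a_a <- normalize_adjacency(g_a, model$config$self_loops)
  }

  wnames <- c("W0", "W1", "W2", "Wp1", "Wp2")
  adam_m <- lapply(model[wnames], function(w) w * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_tr <- cos_tr <- sec_tr <- numeric(0)
  best <- Inf; stall <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lg <- loss_and_gradients(model, a_r, a_a, x_r, x_a, cfg$tau,
                             cfg$loss_kind)
    if (!is.finite(lg$loss))
      stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
    for (nm in wnames) {
      g <- lg$grads[[nm]]
      adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
      adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
      mhat <- adam_m[[nm]] / (1 - b1^epoch)
      vhat <- adam_v[[nm]] / (1 - b2^epoch)
      model[[nm]] <- model[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
    }
    loss_tr[epoch] <- lg$loss
    cos_tr[epoch] <- lg$pair_cos
    sec_tr[epoch] <- proc.time()[["elapsed"]] - t0
    if (cfg$log_every > 0 && epoch %% cfg$log_every == 0)
      message(sprintf("epoch %d: %s loss = %.6f, pair cosine = %.4f",
                      epoch, cfg$loss_kind, lg$loss, lg$pair_cos))
    if (!is.null(cfg$early_stop_patience)) {
      if (lg$loss < best * (1 - 1e-4)) { best <- lg$loss; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  structure(list(model = model,
                 trace = data.frame(epoch = seq_along(loss_tr),
                                    loss = loss_tr, pair_cos = cos_tr,
                                    seconds = sec_tr)),
            class = "train_fit")
}

#' Embed cells with a trained model
#'
#' Deterministic forward pass (encoder then projector; there is no dropout
#' anywhere in the architecture). The MLP ablation ignores the graph.
#'
#' @param model an `encoder_model`.
#' @param g the modality's `cell_graph`.
#' @param x cells x `in_dim` input matrix.
#' @return Cells x `out_dim` embedding matrix; rownames carry cell ids when
#'   `x` is a [cell_matrix()].
#' @export
embed_cells <- function(model, g, x) {
  ids <- if (inherits(x, "cell_matrix")) x$cell_ids else rownames(x)
  xv <- dense_values(x)
  h3 <- if (model$config$encoder_kind == "GCN") {
    gcn_forward(model, normalize_adjacency(g, model$config$self_loops), xv)
  } else {
    mlp_forward(model, xv)
  }
  z <- project_head(model, h3)
  rownames(z) <- ids
  z
}
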