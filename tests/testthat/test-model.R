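test_that("normalize_adjacency matches hand-computed small cases", {
  two <- cell_graph(2, rbind(c(1, 2)), "RNA", k = 1)
  a0 <- as.matrix(normalize_adjacency(two, self_loops = FALSE))
  expect_equal(unname(a0), rbind(c(0, 1), c(1, 0)))
  a1 <- as.matrix(normalize_adjacency(two, self_loops = TRUE))
  expect_equal(unname(a1), matrix(0.5, 2, 2))

  iso <- cell_graph(3, rbind(c(1, 2)), "RNA", k = 1)
  expect_warning(ai <- normalize_adjacency(iso, self_loops = FALSE),
                 "isolated")
  expect_equal(unname(as.matrix(ai))[3, ], c(0, 0, 0))
})

test_that("normalized adjacency is symmetric with spectral radius at most 1", {
  set.seed(41)
  for (rep in 1:20) {
    g <- random_graph(sample(4:40, 1))
    for (sl in c(TRUE, FALSE)) {
      a <- as.matrix(suppressWarnings(normalize_adjacency(g, sl)))
      expect_lt(max(abs(a - t(a))), 1e-9)
      expect_true(all(a >= 0))
      expect_lte(max(abs(eigen(a, symmetric = TRUE,
                               only.values = TRUE)$values)), 1 + 1e-6)
    }
  }
})

test_that("disjoint components give a block-diagonal adjacency", {
  # two disconnected triangles
  tri <- function(off) rbind(c(1, 2), c(2, 3), c(1, 3)) + off
  g <- cell_graph(6, rbind(tri(0), tri(3)), "RNA", k = 2)
  a <- as.matrix(normalize_adjacency(g, self_loops = TRUE))
  expect_true(all(a[1:3, 4:6] == 0))
  expect_true(all(a[4:6, 1:3] == 0))
  expect_true(all(a[1:3, 1:3] > 0))
})

test_that("gcn_forward reduces to the plain network on the identity graph", {
  cfg <- model_config(in_dim = 6, hidden_dim = 6, out_dim = 4, seed = 2)
  model <- init_model(cfg)
  for (nm in c("W0", "W1", "W2")) model[[nm]] <- diag(6)
  edgeless <- cell_graph(5, matrix(integer(0), 0, 2), "RNA", k = 0)
  a_hat <- normalize_adjacency(edgeless, self_loops = TRUE)
  x <- matrix(abs(rnorm(30)), 5)        # non-negative survives the ReLUs
  expect_equal(gcn_forward(model, a_hat, x), x, ignore_attr = TRUE)

  model$W0 <- model$W0 * 0
  expect_true(all(gcn_forward(model, a_hat, x) == 0))
})

test_that("sparse gcn_forward equals the dense loop-built oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    g <- random_graph(n)
    cfg <- model_config(in_dim = 4, hidden_dim = 7, out_dim = 3,
                        seed = rep)
    model <- init_model(cfg)
    x <- matrix(rnorm(n * 4), n)
    for (sl in c(TRUE, FALSE)) {
      a_sparse <- suppressWarnings(normalize_adjacency(g, sl))
      expect_lt(max(abs(gcn_forward(model, a_sparse, x) -
                          oracle_gcn_dense(model, oracle_dense_adjacency(g, sl), x))),
                1e-5)
    }
  }
})

test_that("mlp_forward is the graph-free ablation of the same network", {
  cfg <- model_config(in_dim = 5, hidden_dim = 8, out_dim = 4, seed = 3,
                      encoder_kind = "MLP")
  model <- init_model(cfg)
  x <- matrix(rnorm(40), 8)
  expect_lt(max(abs(mlp_forward(model, x) - oracle_mlp_loop(model, x))), 1e-6)
  expect_true(all(mlp_forward(model, x * 0) == 0))
  # equals the GCN path on the edgeless graph with self-loops (A = I)
  edgeless <- cell_graph(8, matrix(integer(0), 0, 2), "RNA", k = 0)
  expect_equal(mlp_forward(model, x),
               gcn_forward(model, normalize_adjacency(edgeless, TRUE), x))
  expect_error(mlp_forward(model, matrix(0, 2, 7)), "features")
})

test_that("the projection head is ReLU then linear", {
  cfg <- model_config(in_dim = 4, hidden_dim = 5, out_dim = 5, seed = 4)
  model <- init_model(cfg)
  h3 <- matrix(rnorm(20), 4)
  expect_equal(project_head(model, h3),
               pmax(h3 %*% model$Wp1, 0) %*% model$Wp2)
  model$Wp2 <- model$Wp2 * 0
  expect_true(all(project_head(model, h3) == 0))
  model$Wp1 <- diag(5); model$Wp2 <- diag(5)
  hpos <- abs(h3)                       # non-negative input passes unchanged
  expect_equal(project_head(model, hpos), hpos)
})

test_that("contrastive loss matches hand-derived closed forms", {
  # a single cell: softmax over one term
  z <- matrix(c(1, 2), 1)
  expect_equal(contrastive_loss(z, z, tau = 0.5), 0)
  # orthonormal 2-cell case at tau = 1
  i2 <- diag(2)
  expect_equal(contrastive_loss(i2, i2, tau = 1), log(1 + exp(-1)),
               tolerance = 1e-9)
  expect_error(contrastive_loss(rbind(c(1, 0), c(0, 0)), i2, 1,
                                cell_ids = c("a", "b")),
               "cell 'b'")
})

test_that("both losses match the double-loop scalar oracle", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(2:16, 1)
    d <- sample(2:8, 1)
    z_r <- matrix(rnorm(n * d), n)
    z_a <- matrix(rnorm(n * d), n)
    tau <- runif(1, 0.05, 1)
    expect_equal(contrastive_loss(z_r, z_a, tau),
                 oracle_contrastive(z_r, z_a, tau), tolerance = 1e-6)
    expect_equal(mse_ablation_loss(z_r, z_a, tau),
                 oracle_mse(z_r, z_a, tau), tolerance = 1e-6)
  }
})

test_that("loss invariances: rotation, row rescaling, temperature sharpening", {
  set.seed(44)
  n <- 12; d <- 6
  z_r <- matrix(rnorm(n * d), n)
  z_a <- z_r + matrix(rnorm(n * d, sd = 0.1), n)   # diagonally dominant sims
  base <- contrastive_loss(z_r, z_a, tau = 0.2)

  q <- qr.Q(qr(matrix(rnorm(d * d), d)))           # common orthogonal rotation
  expect_equal(contrastive_loss(z_r %*% q, z_a %*% q, tau = 0.2), base,
               tolerance = 1e-9)

  s_r <- runif(n, 0.1, 5); s_a <- runif(n, 0.1, 5) # positive row rescaling
  expect_equal(contrastive_loss(z_r * s_r, z_a * s_a, tau = 0.2), base,
               tolerance = 1e-9)

  # sharper softmax on diagonally dominant similarities lowers the loss
  expect_lt(contrastive_loss(z_r, z_a, tau = 0.05), base)
  expect_lt(base, contrastive_loss(z_r, z_a, tau = 0.5))
})

test_that("the squared-error ablation handles degenerate similarity patterns", {
  z <- matrix(c(2, 1, 0.5), 1)
  expect_equal(mse_ablation_loss(z, z, tau = 0.3), 0)
  # all-equal similarities force softmax 1/N
  n <- 6
  z_r <- matrix(rnorm(n * 4), n)
  z_a <- matrix(rep(c(1, 0, 0, 0), each = n), n)   # identical rows
  expect_equal(mse_ablation_loss(z_r, z_a, tau = 0.7), (1 - 1 / n)^2,
               tolerance = 1e-9)
})

test_that("initialisation is seeded and follows the stated scale", {
  cfg <- model_config(seed = 10)
  m1 <- init_model(cfg)
  m2 <- init_model(cfg)
  expect_identical(m1$W1, m2$W1)
  m3 <- init_model(model_config(seed = 11))
  expect_false(identical(m1$W1, m3$W1))
  # half-gain Glorot: sd of U(-l, l) is l / sqrt(3), l = 0.5 sqrt(6 / 600)
  nominal <- 0.5 * sqrt(6 / 600) / sqrt(3)
  expect_lt(abs(sd(m1$W1) - nominal) / nominal, 0.2)
  # parameter count closed form: in*h + 3 h^2 + h*out
  expect_equal(n_parameters(m1), 30 * 300 + 3 * 300^2 + 300 * 128)
})

test_that("checkpoints round-trip and the loader validates shapes", {
  model <- init_model(model_config(in_dim = 5, hidden_dim = 7, out_dim = 3,
                                   seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back[c("W0", "W1", "W2", "Wp1", "Wp2")],
               model[c("W0", "W1", "W2", "Wp1", "Wp2")])
  expect_equal(back$config$tau, model$config$tau)

  broken <- model
  broken$W1 <- matrix(0, 2, 2)
  save_checkpoint(broken, path)
  expect_error(load_checkpoint(path), "W1.*2x2")
  saveRDS(list(a = 1), path)
  expect_error(load_checkpoint(path), "not an omixcl checkpoint")
})

test_that("analytic gradients agree with central differences", {
  set.seed(45)
  n <- 6
  cfg <- model_config(in_dim = 4, hidden_dim = 5, out_dim = 3, seed = 7)
  model <- init_model(cfg)
  x_r <- matrix(rnorm(n * 4), n)
  x_a <- matrix(rnorm(n * 4), n)
  a_r <- normalize_adjacency(random_graph(n, 2), TRUE)
  a_a <- normalize_adjacency(random_graph(n, 3), TRUE)
  eps <- 1e-6
  for (loss_kind in c("contrastive", "mse")) {
    lg <- omixcl:::loss_and_gradients(model, a_r, a_a, x_r, x_a, 0.3,
                                      loss_kind)
    for (nm in c("W0", "W1", "W2", "Wp1", "Wp2")) {
      for (idx in sample(length(model[[nm]]), 3)) {
        up <- model; up[[nm]][idx] <- up[[nm]][idx] + eps
        dn <- model; dn[[nm]][idx] <- dn[[nm]][idx] - eps
        num <- (omixcl:::loss_and_gradients(up, a_r, a_a, x_r, x_a, 0.3,
                                            loss_kind)$loss -
                omixcl:::loss_and_gradients(dn, a_r, a_a, x_r, x_a, 0.3,
                                            loss_kind)$loss) / (2 * eps)
        expect_equal(lg$grads[[nm]][idx], num, tolerance = 1e-4)
      }
    }
  }
})
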