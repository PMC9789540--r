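test_that("gcn_layer handles hand-checkable limits", {
  # single node: A~ = [1], D~ = [1], so output = H W
  expect_equal(gcn_layer(matrix(3), matrix(0, 1, 1), matrix(1), "identity"),
               matrix(3))
  # 2-node path: degrees 2,2 -> propagation matrix is all 1/2
  out <- gcn_layer(matrix(c(1, 0), 2, 1), matrix(c(0, 1, 1, 0), 2, 2),
                   matrix(1), "identity")
  expect_equal(out, matrix(c(0.5, 0.5), 2, 1))
  # ReLU clamps all-negative pre-activations to zero
  out2 <- gcn_layer(matrix(c(1, 1), 2, 1), matrix(c(0, 1, 1, 0), 2, 2),
                    matrix(-2), "relu")
  expect_equal(out2, matrix(0, 2, 1))
  expect_error(gcn_layer(matrix(1, 2, 3), matrix(0, 2, 2), matrix(1, 2, 1)),
               "columns")
})

test_that("gcn_layer agrees with the brute-force index oracle", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(2:6, 1); d <- sample(1:4, 1); dp <- sample(1:4, 1)
    A <- random_adjacency(n)
    H <- matrix(rnorm(n * d), n)
    W <- matrix(rnorm(d * dp), d)
    expect_equal(gcn_layer(H, A, W), brute_gcn(H, A, W), tolerance = 1e-10)
  }
})

test_that("pooling step algebra matches forced assignments", {
  set.seed(4)
  n <- 5L
  A <- random_adjacency(n)
  H <- matrix(rnorm(n * 3), n)
  # identity assignment leaves features and structure unchanged
  st <- diffpool_step(H, A, n_next = n, S = diag(n), hidden_dim = 4L)
  expect_equal(st$Z_next, st$Z)
  expect_equal(st$A_next, A)
  # all-ones column collapses to one supernode: column sums / grand sum
  st1 <- diffpool_step(H, A, n_next = 1L, S = matrix(1, n, 1), hidden_dim = 4L)
  expect_equal(dim(st1$Z_next), c(1L, 4L))
  expect_equal(as.numeric(st1$Z_next), colSums(st1$Z))
  expect_equal(st1$A_next, matrix(sum(A), 1, 1))
})

test_that("learned pooling step: softmax rows, symmetry, oracle agreement", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n)
    H <- matrix(rnorm(n * 3), n)
    n_next <- sample(2:(n - 1), 1)
    st <- diffpool_step(H, A, n_next, hidden_dim = 4L, seed = rep)
    expect_equal(rowSums(st$S), rep(1, n))
    expect_true(all(st$A_next >= -1e-12))
    expect_equal(st$A_next, t(st$A_next), tolerance = 1e-12)
    oracle <- brute_coarsen(st$S, st$Z, A)
    expect_equal(st$Z_next, oracle$Z_next, tolerance = 1e-10)
    expect_equal(st$A_next, oracle$A_next, tolerance = 1e-10)
  }
})

test_that("branch outputs have the configured length for any chain", {
  cfg <- fast_cfg()
  enc <- encoder_config(use_node2vec = FALSE)
  for (seq in c("FLPKACDY", paste(rep("KWFA", 10), collapse = ""))) {
    g <- build_graph(list(id = "x", sequence = seq, label = 0L), enc)
    params <- acpgcn:::init_params(cfg, ncol(g$X))
    expect_length(stacked_gcn_G(g$X, g$A, cfg, params), cfg$out_dim)
    expect_length(diffpool_branch_D(g$X, g$A, cfg, params), cfg$out_dim)
    expect_length(residual_branch_R(g$X, g$A, cfg, params), cfg$out_dim)
  }
})

test_that("pooling branch shrinks clusters by the assign-ratio schedule", {
  cfg <- model_config(assign_ratio = 0.5, n_pool_steps = 2L, max_nodes = 40L)
  expect_equal(acpgcn:::pool_schedule(40L, cfg), c(20L, 10L))
  cfg9 <- model_config(assign_ratio = 0.9, n_pool_steps = 2L)
  expect_equal(acpgcn:::pool_schedule(10L, cfg9), c(9L, 9L))
  cfg3 <- model_config(assign_ratio = 0.3, n_pool_steps = 3L)
  expect_equal(acpgcn:::pool_schedule(10L, cfg3), c(3L, 1L, 1L))
})

test_that("deep stacks (5 to 10 layers) run on a 50-residue chain", {
  enc <- encoder_config(use_node2vec = FALSE)
  g <- build_graph(list(id = "long", sequence = paste(rep("KWFAG", 10),
                                                      collapse = ""),
                        label = 0L), enc)
  for (L in c(5L, 10L)) {
    cfg <- model_config(hidden_dim = 8L, out_dim = 8L, n_layers = L, seed = 2L)
    params <- acpgcn:::init_params(cfg, ncol(g$X))
    expect_length(stacked_gcn_G(g$X, g$A, cfg, params), 8L)
    expect_length(residual_branch_R(g$X, g$A, cfg, params), 8L)
  }
})

test_that("residual branch reduces to the projected input when weights are zero", {
  cfg <- fast_cfg()
  enc <- encoder_config(use_node2vec = FALSE)
  g <- build_graph(list(id = "x", sequence = "FLPKACDY", label = 0L), enc)
  params <- acpgcn:::init_params(cfg, ncol(g$X))
  for (l in seq_len(cfg$n_layers)) params[[paste0("R.W", l)]][] <- 0
  got <- residual_branch_R(g$X, g$A, cfg, params)
  H0 <- g$X %*% params[["R.proj"]]
  expect_equal(got, as.numeric(matrix(colMeans(H0), 1) %*% params[["R.out"]]))
})

test_that("skip connections strengthen the gradient reaching the first layer", {
  enc <- encoder_config(use_node2vec = FALSE)
  g <- build_graph(list(id = "x", sequence = "KWKLFKKACDYWGHIL", label = 0L), enc)
  ratio_with_skip <- sapply(1:5, function(seed) {
    base <- list(hidden_dim = 8L, out_dim = 8L, n_layers = 10L, seed = seed)
    cfg_r <- do.call(model_config, c(base, list(branches = "R")))
    cfg_g <- do.call(model_config, c(base, list(branches = "G")))
    gr_r <- acpgcn:::batch_grads(acpgcn:::init_params(cfg_r, ncol(g$X)),
                                 list(g), cfg_r, 1)$grads
    gr_g <- acpgcn:::batch_grads(acpgcn:::init_params(cfg_g, ncol(g$X)),
                                 list(g), cfg_g, 1)$grads
    sqrt(sum(gr_r[["R.W1"]]^2)) / max(sqrt(sum(gr_g[["G.W2"]]^2)), 1e-30)
  })
  expect_gt(mean(ratio_with_skip), 1)
})

test_that("fusion head yields a proper distribution and ablation widths", {
  cfg <- fast_cfg()
  v <- rnorm(cfg$out_dim)
  p <- fuse_and_classify(v, v + 1, v - 1, cfg)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0 & p < 1))

  cfg_g <- fast_cfg(branches = "G")
  params_g <- acpgcn:::init_params(cfg_g, 51L)
  expect_equal(nrow(params_g[["head.W1"]]), cfg_g$out_dim)
  expect_error(fuse_and_classify(NULL, NULL, NULL, cfg_g), "missing branch")

  # zeroed final layer gives symmetric logits regardless of input
  params <- acpgcn:::init_params(cfg, 3L * cfg$out_dim)
  params[["head.W2"]][] <- 0
  params[["head.b2"]][] <- 0
  p2 <- fuse_and_classify(v, v, v, cfg, params)
  expect_equal(unname(p2), c(0.5, 0.5))
})

test_that("full-model probabilities are invariant to node relabeling", {
  enc <- encoder_config(use_node2vec = FALSE)
  cfg <- fast_cfg()
  g <- build_graph(list(id = "x", sequence = "KWKLFKKACDY", label = 0L), enc)
  params <- acpgcn:::init_params(cfg, ncol(g$X))
  p0 <- acpgcn:::forward_graph(params, g, cfg)
  set.seed(8)
  for (rep in 1:5) {
    perm <- sample(g$n)
    gp <- g
    gp$A <- g$A[perm, perm]
    gp$X <- g$X[perm, , drop = FALSE]
    pp <- acpgcn:::forward_graph(params, gp, cfg)
    expect_equal(pp, p0, tolerance = 1e-10)
  }
})

test_that("tape forward reproduces the plain numeric forward", {
  enc <- encoder_config(use_node2vec = FALSE)
  cfg <- fast_cfg()
  for (seq in c("FLPKACDY", "KWKLFKKGGSTV")) {
    g <- build_graph(list(id = "x", sequence = seq, label = 0L), enc)
    params <- acpgcn:::init_params(cfg, ncol(g$X))
    ft <- acpgcn:::forward_tape(params, g, cfg)
    p_tape <- as.numeric(acpgcn:::row_softmax(acpgcn:::tp_val(ft$tape, ft$logits)))
    p_num <- unname(acpgcn:::forward_graph(params, g, cfg))
    expect_equal(p_tape, p_num, tolerance = 1e-12)
  }
})

test_that("tape gradients match central finite differences", {
  enc <- encoder_config(use_node2vec = FALSE, use_ctd21 = FALSE)
  cfg <- model_config(hidden_dim = 4L, out_dim = 4L, n_layers = 2L,
                      n_pool_steps = 1L, max_nodes = 10L, seed = 3L)
  g <- build_graph(list(id = "x", sequence = "FLPKA", label = 0L), enc)
  params <- acpgcn:::init_params(cfg, ncol(g$X))
  analytic <- acpgcn:::batch_grads(params, list(g), cfg, 1)$grads
  loss_at <- function(par) {
    p <- acpgcn:::forward_graph(par, g, cfg)
    -log(p[["acp"]])
  }
  h <- 1e-5
  set.seed(10)
  for (nm in names(params)) {
    # probe a few random entries of each weight matrix
    for (probe in seq_len(min(3L, length(params[[nm]])))) {
      i <- sample(length(params[[nm]]), 1)
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(analytic[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})
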