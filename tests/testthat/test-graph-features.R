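test_that("a peptide becomes a path graph with alphabet-rank node labels", {
  enc <- encoder_config(use_node2vec = FALSE)
  g <- build_graph(list(id = "p", sequence = "FLPK", label = 0L), enc)
  expect_equal(g$n, 4L)
  expect_true(isSymmetric(g$A))
  expect_equal(diag(g$A), rep(0, 4))
  expect_equal(sum(g$A), 6)  # 3 undirected edges: F-L, L-P, P-K
  expect_equal(g$A[cbind(1:3, 2:4)], rep(1, 3))
  expect_equal(g$node_labels, c(5L, 10L, 13L, 9L))
  expect_equal(g$graph_label, 0L)
  # one-hot block agrees with node labels
  expect_equal(apply(g$X[, 1:20], 1L, which.max), g$node_labels)
  expect_equal(rowSums(g$X[, 1:20]), rep(1, 4))
})

test_that("adjacency of a length-n chain has exactly 2(n-1) nonzeros", {
  enc <- encoder_config(use_node2vec = FALSE)
  for (seq in c("AC", "ACDEFGH", paste(rep("K", 30), collapse = ""))) {
    g <- build_graph(list(id = "x", sequence = seq, label = 1L), enc)
    expect_equal(sum(g$A != 0), 2 * (g$n - 1))
  }
})

test_that("attribute width follows the enabled-encoder arithmetic", {
  g <- build_graph(list(id = "p", sequence = "FLPK", label = 0L),
                   encoder_config(node2vec_dim = 16L))
  expect_equal(ncol(g$X), 20L + 16L + 10L + 21L)  # 67
  expect_equal(encoder_width(encoder_config(node2vec_dim = 16L)), 67L)
  expect_equal(encoder_width(encoder_config(use_node2vec = FALSE)), 51L)
  expect_equal(encoder_width(encoder_config(use_onehot = FALSE,
                                            use_pc10 = FALSE,
                                            use_ctd21 = FALSE,
                                            node2vec_dim = 8L)), 8L)
  expect_error(encoder_config(use_onehot = FALSE, use_node2vec = FALSE,
                              use_pc10 = FALSE, use_ctd21 = FALSE),
               "at least one")
})

test_that("build_graph validates sequences", {
  enc <- encoder_config(use_node2vec = FALSE)
  expect_error(build_graph(list(id = "e", sequence = "", label = 0L), enc),
               "empty")
  expect_error(build_graph(list(id = "e", sequence = "FLX", label = 0L), enc),
               "'X'")
})

test_that("featurize_dataset maps records with constant width and skip option", {
  rec <- tiny_records()
  enc <- encoder_config(use_node2vec = FALSE)
  gs <- featurize_dataset(rec, enc)
  expect_length(gs, 4L)
  expect_equal(unique(sapply(gs, function(g) ncol(g$X))), 51L)
  expect_equal(sapply(gs, function(g) g$id), rec$id)

  expect_length(featurize_dataset(rec[0, ], enc), 0L)

  bad <- rbind(rec, data.frame(id = "bad", sequence = "FLZ", label = 0L))
  expect_error(featurize_dataset(bad, enc), "bad")
  expect_message(gs2 <- featurize_dataset(bad, enc, drop_invalid = TRUE),
                 "skipping")
  expect_length(gs2, 4L)
})

test_that("node2vec output has the right shape and is seed-deterministic", {
  enc <- encoder_config(node2vec_dim = 8L, seed = 42L)
  A <- matrix(0, 12, 12)
  A[cbind(1:11, 2:12)] <- A[cbind(2:12, 1:11)] <- 1
  e1 <- node2vec_embed(A, enc)
  expect_equal(dim(e1), c(12L, 8L))
  expect_true(all(is.finite(e1)))
  e2 <- node2vec_embed(A, enc)
  expect_identical(e1, e2)
  enc2 <- enc; enc2$seed <- 43L
  expect_false(identical(e1, node2vec_embed(A, enc2)))
})

test_that("node2vec rejects a window longer than the walk", {
  enc <- encoder_config(walk_length = 4L, window = 5L)
  A <- matrix(0, 5, 5); A[cbind(1:4, 2:5)] <- A[cbind(2:5, 1:4)] <- 1
  expect_error(node2vec_embed(A, enc), "walk_length")
})

test_that("chain neighbours embed closer than distant residues", {
  # depth-first-biased walks should make embeddings local along the chain
  n <- 30L
  A <- matrix(0, n, n)
  A[cbind(1:(n - 1), 2:n)] <- A[cbind(2:n, 1:(n - 1))] <- 1
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims_near <- c(); sims_far <- c()
  for (seed in 1:20) {
    enc <- encoder_config(node2vec_dim = 8L, seed = seed)
    E <- node2vec_embed(A, enc)
    near <- mean(sapply(1:(n - 1), function(i) cos(E[i, ], E[i + 1, ])))
    far_pairs <- which(outer(1:n, 1:n, function(i, j) j - i >= 10), arr.ind = TRUE)
    far <- mean(apply(far_pairs, 1L, function(ij) cos(E[ij[1], ], E[ij[2], ])))
    sims_near <- c(sims_near, near)
    sims_far <- c(sims_far, far)
  }
  expect_gt(mean(sims_near), mean(sims_far))
})

test_that("equal-length chains share the cached positional embedding", {
  rec <- peptide_records(c("a", "b"), c("FLPKAFLPKA", "ACDYWACDYW"), c(0L, 1L))
  enc <- encoder_config(node2vec_dim = 4L)
  gs <- featurize_dataset(rec, enc)
  n2v_cols <- 21:24
  expect_equal(gs[[1]]$X[, n2v_cols], gs[[2]]$X[, n2v_cols])
  # and matches a standalone call with the same seed
  expect_equal(gs[[1]]$X[, n2v_cols], node2vec_embed(gs[[1]]$A, enc))
})
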