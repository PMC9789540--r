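# Brute-force oracles and tiny fixtures shared across tests. Oracles are
# written as plain index loops, independent of the package's vectorized
# implementations.

# Entry-by-entry evaluation of act(D^-1/2 (A+I) D^-1/2 H W).
brute_gcn <- function(H, A, W, act = function(x) pmax(x, 0)) {
  n <- nrow(A)
  At <- A + diag(n)
  deg <- sapply(seq_len(n), function(i) sum(At[i, ]))
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    P[i, j] <- At[i, j] / sqrt(deg[i] * deg[j])
  }
  M <- matrix(0, n, ncol(H))
  for (i in seq_len(n)) for (k in seq_len(ncol(H))) {
    M[i, k] <- sum(sapply(seq_len(n), function(j) P[i, j] * H[j, k]))
  }
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) for (c in seq_len(ncol(W))) {
    out[i, c] <- act(sum(sapply(seq_len(ncol(H)), function(k) M[i, k] * W[k, c])))
  }
  out
}

# Triple-product coarsening computed index-by-index.
brute_coarsen <- function(S, Z, A) {
  nn <- ncol(S)
  Zn <- matrix(0, nn, ncol(Z))
  for (c in seq_len(nn)) for (k in seq_len(ncol(Z))) {
    Zn[c, k] <- sum(S[, c] * Z[, k])
  }
  An <- matrix(0, nn, nn)
  for (c1 in seq_len(nn)) for (c2 in seq_len(nn)) {
    acc <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
      acc <- acc + S[i, c1] * A[i, j] * S[j, c2]
    }
    An[c1, c2] <- acc
  }
  list(Z_next = Zn, A_next = An)
}

# AUC by exhaustive concordant-pair counting (ties count one half);
# positives are storage code 0.
brute_auc <- function(scores, labels) {
  pos <- which(labels == 0L)
  neg <- which(labels == 1L)
  acc <- 0
  for (i in pos) for (j in neg) {
    acc <- acc + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

# Random symmetric binary adjacency with zero diagonal; guarantees at least
# one edge for n >= 2.
random_adjacency <- function(n, p = 0.5) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  if (sum(A) == 0 && n >= 2) A[1, 2] <- A[2, 1] <- 1
  A
}

withr_tempfile <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

tiny_records <- function() {
  peptide_records(
    id = c("p1", "p2", "p3", "p4"),
    sequence = c("FLPKA", "ACDYW", "KKKRW", "GGSTV"),
    label = c(0L, 0L, 1L, 1L)
  )
}

# Small synthetic benchmark shared by experiment tests: short chains keep
# featurization and training fast.
small_benchmark <- function(n_pos = 10L, n_neg = 10L, seed = 11L) {
  generate(synth_config(n_pos, n_neg, length_range = c(10L, 16L), seed = seed))
}

fast_cfg <- function(seed = 5L, ...) {
  model_config(hidden_dim = 16L, out_dim = 16L, n_layers = 2L,
               n_pool_steps = 1L, max_nodes = 50L, seed = seed, ...)
}

fast_tcfg <- function(epochs = 10L, ...) {
  train_config(epochs = epochs, learning_rate = 0.01, seed = 5L, ...)
}
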