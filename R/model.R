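#' Network architecture configuration
#'
#' Hyperparameters of the three-branch graph network: a stacked GCN branch
#' G(X), a differentiable graph-collapse pooling branch D(X), and a residual
#' GCN branch R(X), fused by a two-layer fully connected head.
#'
#' @param hidden_dim Hidden width of every GCN layer (default 64).
#' @param out_dim Width of each branch's graph-level feature vector
#'   (default 64).
#' @param n_layers Depth of the stacked and residual GCN branches (>= 2;
#'   default 3 — short peptide chains need few message-passing rounds and
#'   deep stacks oversmooth a path graph; the sweep harness covers 5-10).
#' @param assign_ratio Multiplicative cluster shrink factor per pooling step,
#'   in (0, 1] (default 0.5; sweepable over 0.3-0.9).
#' @param n_pool_steps Learned pooling steps before the final all-ones
#'   collapse to a single supernode (default 2).
#' @param activation Nonlinearity, currently `"relu"`.
#' @param readout Node-to-graph aggregator for the G and R branches:
#'   `"mean"`, `"sum"` or `"max"`.
#' @param fusion How branch vectors enter the head: `"concat"` (default),
#'   `"mean"` or `"sum"`.
#' @param branches Character subset of `c("G", "D", "R")`; disabling branches
#'   reproduces the ablation variants.
#' @param dropout Dropout rate on the head's hidden layer during training.
#' @param max_nodes Largest chain length the pooling branch is sized for
#'   (default 50, the upper end of typical ACP lengths).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `model_config`.
#' @export
model_config <- function(hidden_dim = 64L, out_dim = 64L, n_layers = 3L,
                         assign_ratio = 0.5, n_pool_steps = 2L,
                         activation = "relu", readout = "mean",
                         fusion = "concat", branches = c("G", "D", "R"),
                         dropout = 0, max_nodes = 50L, seed = 1L) {
  stopifnot(hidden_dim >= 1L, out_dim >= 1L, n_layers >= 2L,
            assign_ratio > 0, assign_ratio <= 1, n_pool_steps >= 1L,
            dropout >= 0, dropout < 1, max_nodes >= 2L)
  readout <- match.arg(readout, c("mean", "sum", "max"))
  fusion <- match.arg(fusion, c("concat", "mean", "sum"))
  activation <- match.arg(activation, "relu")
  branches <- match.arg(branches, c("G", "D", "R"), several.ok = TRUE)
  structure(list(
    hidden_dim = as.integer(hidden_dim), out_dim = as.integer(out_dim),
    n_layers = as.integer(n_layers), assign_ratio = assign_ratio,
    n_pool_steps = as.integer(n_pool_steps), activation = activation,
    readout = readout, fusion = fusion, branches = branches,
    dropout = dropout, max_nodes = as.integer(max_nodes),
    seed = as.integer(seed)
  ), class = "model_config")
}

act_fun <- function(name) {
  switch(name, relu = function(x) pmax(x, 0),
         stop("unknown activation: ", name, call. = FALSE))
}

#' Single graph convolution layer
#'
#' Computes `act(D^{-1/2} %*% (A + I) %*% D^{-1/2} %*% H %*% W)` where `D` is
#' the degree matrix of the self-loop-augmented adjacency `A + I`. Self-loops
#' guarantee strictly positive degrees, so isolated nodes are well defined.
#'
#' @param H `n x d` node-feature matrix.
#' @param A `n x n` symmetric adjacency matrix (binary for the input chain;
#'   weighted nonnegative after pooling).
#' @param W `d x d'` weight matrix.
#' @param activation `"relu"`, `"identity"`, or a function.
#' @return `n x d'` matrix of propagated node features.
#' @export
gcn_layer <- function(H, A, W, activation = "relu") {
  H <- as.matrix(H); A <- as.matrix(A); W <- as.matrix(W)
  if (nrow(A) != ncol(A)) stop("A must be square", call. = FALSE)
  if (nrow(H) != nrow(A)) stop("H rows must match A", call. = FALSE)
  if (ncol(H) != nrow(W)) stop("H columns must match W rows", call. = FALSE)
  act <- if (is.function(activation)) activation
  else if (identical(activation, "identity")) identity
  else act_fun(activation)
  act(norm_adj(A) %*% H %*% W)
}

norm_adj <- function(A) {
  At <- A + diag(nrow(A))
  dn <- 1 / sqrt(rowSums(At))
  At * (dn %o% dn)
}

row_softmax <- function(M) {
  e <- exp(M - apply(M, 1L, max))
  e / rowSums(e)
}

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# Cluster-count schedule for the pooling branch: sizes after each learned
# step starting from n0 nodes.
pool_schedule <- function(n0, cfg) {
  sizes <- integer(cfg$n_pool_steps)
  n <- n0
  for (s in seq_len(cfg$n_pool_steps)) {
    n <- max(1L, as.integer(ceiling(cfg$assign_ratio * n)))
    sizes[s] <- n
  }
  sizes
}

# Flat named list of all trainable matrices. Pool assignment weights are
# sized for the schedule at cfg$max_nodes and column-sliced per graph.
init_params <- function(cfg, input_dim) {
  h <- cfg$hidden_dim; o <- cfg$out_dim
  withr_seed(cfg$seed, {
    p <- list()
    if ("G" %in% cfg$branches) {
      widths <- c(input_dim, rep(h, cfg$n_layers - 1L), o)
      for (l in seq_len(cfg$n_layers)) {
        p[[paste0("G.W", l)]] <- glorot(widths[l], widths[l + 1L])
      }
    }
    if ("R" %in% cfg$branches) {
      p[["R.proj"]] <- glorot(input_dim, h)
      for (l in seq_len(cfg$n_layers)) {
        p[[paste0("R.W", l)]] <- glorot(h, h)
      }
      p[["R.out"]] <- glorot(h, o)
    }
    if ("D" %in% cfg$branches) {
      cmax <- pool_schedule(cfg$max_nodes, cfg)
      d_in <- input_dim
      for (s in seq_len(cfg$n_pool_steps)) {
        p[[paste0("D.s", s, ".embed1")]] <- glorot(d_in, h)
        p[[paste0("D.s", s, ".embed2")]] <- glorot(h, h)
        p[[paste0("D.s", s, ".embed3")]] <- glorot(h, h)
        p[[paste0("D.s", s, ".pool1")]] <- glorot(d_in, h)
        p[[paste0("D.s", s, ".pool2")]] <- glorot(h, h)
        p[[paste0("D.s", s, ".pool3")]] <- glorot(h, cmax[s])
        d_in <- h
      }
      p[["D.final1"]] <- glorot(d_in, h)
      p[["D.final2"]] <- glorot(h, h)
      p[["D.final3"]] <- glorot(h, o)
    }
    head_in <- if (cfg$fusion == "concat") length(cfg$branches) * o else o
    p[["head.W1"]] <- glorot(head_in, h)
    p[["head.b1"]] <- matrix(0, 1L, h)
    p[["head.W2"]] <- glorot(h, 2L)
    p[["head.b2"]] <- matrix(0, 1L, 2L)
    p
  })
}

readout_fun <- function(name) {
  switch(name,
         mean = function(M) matrix(colMeans(M), 1L),
         sum = function(M) matrix(colSums(M), 1L),
         max = function(M) matrix(apply(M, 2L, max), 1L))
}

#' Stacked graph convolution branch G(X)
#'
#' Applies `cfg$n_layers` GCN layers (input -> hidden -> ... -> out_dim) and
#' reduces the node features to one graph-level vector with the configured
#' readout.
#'
#' @param X `n x d` node-attribute matrix.
#' @param A `n x n` adjacency matrix.
#' @param cfg A [model_config()].
#' @param params Optional parameter list from a trained model; freshly
#'   initialized from `cfg$seed` when `NULL`.
#' @return Numeric vector of length `cfg$out_dim`.
#' @export
stacked_gcn_G <- function(X, A, cfg = model_config(), params = NULL) {
  if (is.null(params)) params <- init_params(cfg, ncol(X))
  H <- as.matrix(X)
  for (l in seq_len(cfg$n_layers)) {
    H <- gcn_layer(H, A, params[[paste0("G.W", l)]], cfg$activation)
  }
  as.numeric(readout_fun(cfg$readout)(H))
}

#' One differentiable pooling step
#'
#' Runs the two independent three-layer GCN stacks of a pooling step: the
#' embedding stack producing node features `Z` and the assignment stack whose
#' row-softmax yields the soft cluster-assignment matrix `S` (`n x n_next`),
#' then coarsens features and structure as `Z' = t(S) %*% Z` and
#' `A' = t(S) %*% A %*% S`.
#'
#' @param H `n x d` node features entering the step.
#' @param A `n x n` adjacency (binary or pooled/weighted).
#' @param n_next Number of clusters after the step (1 <= n_next <= n).
#' @param weights Optional named list with elements `embed1..3`, `pool1..3`;
#'   initialized from `seed` when `NULL` (pool3 must have `n_next` columns).
#' @param S Optional fixed assignment matrix overriding the learned softmax
#'   assignment (e.g. the all-ones `n x 1` matrix collapsing the graph to a
#'   single supernode).
#' @param hidden_dim Hidden width of the two stacks.
#' @param seed Seed for the default weight draw.
#' @return List with `Z` (embedded node features, `n x hidden_dim`), `S`
#'   (`n x n_next`, rows summing to 1 when learned), `Z_next`
#'   (`n_next x hidden_dim`), `A_next` (`n_next x n_next`, symmetric
#'   nonnegative).
#' @export
diffpool_step <- function(H, A, n_next = NULL, weights = NULL, S = NULL,
                          hidden_dim = 64L, seed = 1L) {
  H <- as.matrix(H); A <- as.matrix(A)
  n <- nrow(A)
  if (is.null(n_next)) n_next <- if (is.null(S)) 1L else ncol(S)
  if (n_next < 1L) stop("n_next must be >= 1", call. = FALSE)
  if (n_next > n) stop("n_next (", n_next, ") exceeds node count (", n, ")",
                       call. = FALSE)
  if (is.null(weights)) {
    weights <- withr_seed(seed, list(
      embed1 = glorot(ncol(H), hidden_dim), embed2 = glorot(hidden_dim, hidden_dim),
      embed3 = glorot(hidden_dim, hidden_dim),
      pool1 = glorot(ncol(H), hidden_dim), pool2 = glorot(hidden_dim, hidden_dim),
      pool3 = glorot(hidden_dim, n_next)
    ))
  }
  Z <- gcn_layer(H, A, weights$embed1)
  Z <- gcn_layer(Z, A, weights$embed2)
  Z <- gcn_layer(Z, A, weights$embed3)
  if (is.null(S)) {
    P <- gcn_layer(H, A, weights$pool1)
    P <- gcn_layer(P, A, weights$pool2)
    P <- gcn_layer(P, A, weights$pool3[, seq_len(n_next), drop = FALSE],
                   "identity")
    S <- row_softmax(P)
  }
  list(Z = Z, S = S,
       Z_next = crossprod(S, Z),
       A_next = crossprod(S, A %*% S))
}

#' Graph-collapse pooling branch D(X)
#'
#' Applies `cfg$n_pool_steps` learned pooling steps with cluster counts
#' `n_{l+1} = max(1, ceiling(assign_ratio * n_l))`, then a final three-layer
#' embedding stack followed by a collapse with the assignment fixed to the
#' all-ones column, merging the remaining clusters into a single supernode
#' whose feature vector summarizes the whole chain.
#'
#' @inheritParams stacked_gcn_G
#' @return Numeric vector of length `cfg$out_dim`.
#' @export
diffpool_branch_D <- function(X, A, cfg = model_config(), params = NULL) {
  if (is.null(params)) params <- init_params(cfg, ncol(X))
  H <- as.matrix(X); Acur <- as.matrix(A)
  n <- nrow(Acur)
  if (n > cfg$max_nodes) {
    stop("graph has ", n, " nodes; raise cfg$max_nodes (", cfg$max_nodes, ")",
         call. = FALSE)
  }
  for (s in seq_len(cfg$n_pool_steps)) {
    n_next <- max(1L, as.integer(ceiling(cfg$assign_ratio * nrow(Acur))))
    w <- list(embed1 = params[[paste0("D.s", s, ".embed1")]],
              embed2 = params[[paste0("D.s", s, ".embed2")]],
              embed3 = params[[paste0("D.s", s, ".embed3")]],
              pool1 = params[[paste0("D.s", s, ".pool1")]],
              pool2 = params[[paste0("D.s", s, ".pool2")]],
              pool3 = params[[paste0("D.s", s, ".pool3")]])
    st <- diffpool_step(H, Acur, n_next, weights = w)
    H <- st$Z_next
    Acur <- st$A_next
  }
  Zf <- gcn_layer(H, Acur, params[["D.final1"]])
  Zf <- gcn_layer(Zf, Acur, params[["D.final2"]])
  Zf <- gcn_layer(Zf, Acur, params[["D.final3"]])
  as.numeric(colSums(Zf))  # all-ones collapse: t(S) %*% Z with S = 1
}

#' Residual graph convolution branch R(X)
#'
#' A stacked GCN with an identity skip connection around every layer
#' (`H_{l+1} = gcn_layer(H_l) + H_l`), preceded by a linear projection of the
#' input attributes to `hidden_dim` so widths match, and followed by the
#' configured readout and a linear map to `out_dim`. The skips keep gradients
#' flowing through deep stacks.
#'
#' @inheritParams stacked_gcn_G
#' @return Numeric vector of length `cfg$out_dim`.
#' @export
residual_branch_R <- function(X, A, cfg = model_config(), params = NULL) {
  if (is.null(params)) params <- init_params(cfg, ncol(X))
  H <- as.matrix(X) %*% params[["R.proj"]]
  for (l in seq_len(cfg$n_layers)) {
    H <- gcn_layer(H, A, params[[paste0("R.W", l)]], cfg$activation) + H
  }
  g <- readout_fun(cfg$readout)(H)
  as.numeric(g %*% params[["R.out"]])
}

#' Fuse branch features and classify
#'
#' Combines the enabled branch vectors (concatenation by default; mean or
#' elementwise sum as alternatives), passes them through two fully connected
#' layers (fused width -> hidden_dim with ReLU -> 2) and a softmax, and
#' returns the class probabilities. Class order follows the storage label
#' convention: position 1 is label 0 (ACP), position 2 is label 1 (non-ACP).
#'
#' @param gG,gD,gR Branch feature vectors of length `cfg$out_dim`; pass
#'   `NULL` for branches absent from `cfg$branches` (ablations).
#' @inheritParams stacked_gcn_G
#' @return Numeric vector of two probabilities summing to 1, named
#'   `"acp"` and `"non_acp"`.
#' @export
fuse_and_classify <- function(gG = NULL, gD = NULL, gR = NULL,
                              cfg = model_config(), params = NULL) {
  vecs <- list(G = gG, D = gD, R = gR)[cfg$branches]
  if (any(vapply(vecs, is.null, logical(1)))) {
    stop("missing branch vector for enabled branch(es): ",
         paste(cfg$branches[vapply(vecs, is.null, logical(1))], collapse = ", "),
         call. = FALSE)
  }
  fused <- switch(cfg$fusion,
                  concat = unlist(vecs, use.names = FALSE),
                  mean = Reduce(`+`, vecs) / length(vecs),
                  sum = Reduce(`+`, vecs))
  if (is.null(params)) params <- init_params(cfg, length(fused))
  h <- pmax(matrix(fused, 1L) %*% params[["head.W1"]] + params[["head.b1"]], 0)
  logits <- h %*% params[["head.W2"]] + params[["head.b2"]]
  p <- as.numeric(row_softmax(logits))
  names(p) <- c("acp", "non_acp")
  p
}

# Full numeric forward pass for one graph; used for prediction and as the
# cross-check counterpart of the tape forward used in training.
forward_graph <- function(params, graph, cfg) {
  X <- graph$X; A <- graph$A
  gG <- if ("G" %in% cfg$branches) stacked_gcn_G(X, A, cfg, params) else NULL
  gD <- if ("D" %in% cfg$branches) diffpool_branch_D(X, A, cfg, params) else NULL
  gR <- if ("R" %in% cfg$branches) residual_branch_R(X, A, cfg, params) else NULL
  fuse_and_classify(gG, gD, gR, cfg, params)
}

# ---- tape forward (training path) -----------------------------------------

# Three-layer GCN stack on the tape given a (constant or differentiable)
# normalized adjacency node.
tape_gcn <- function(t, H, nA, W_ids, act_last = TRUE) {
  k <- length(W_ids)
  for (l in seq_len(k)) {
    H <- tp_mm(t, tp_mm(t, nA, H), W_ids[[l]])
    if (l < k || act_last) H <- tp_relu(t, H)
  }
  H
}

tape_readout <- function(t, H, readout) {
  switch(readout,
         mean = tp_colmeans(t, H),
         sum = tp_colsums(t, H),
         max = tp_colmax(t, H))
}

# Builds the full forward computation of one graph on a fresh tape.
# Returns list(tape, logits = node id, pids = named map param name -> leaf id).
forward_tape <- function(params, graph, cfg, dropout_mask = NULL) {
  t <- tape_new()
  pids <- vapply(names(params), function(nm) tp_leaf(t, params[[nm]]),
                 integer(1))
  X <- tp_leaf(t, graph$X)
  nA0 <- tp_leaf(t, norm_adj(graph$A))
  branch_out <- list()
  if ("G" %in% cfg$branches) {
    H <- tape_gcn(t, X, nA0, pids[paste0("G.W", seq_len(cfg$n_layers))])
    branch_out$G <- tape_readout(t, H, cfg$readout)
  }
  if ("D" %in% cfg$branches) {
    n <- graph$n
    if (n > cfg$max_nodes) {
      stop("graph has ", n, " nodes; raise cfg$max_nodes (", cfg$max_nodes,
           ")", call. = FALSE)
    }
    H <- X
    Acur <- tp_leaf(t, graph$A)
    nA <- nA0
    ncur <- n
    for (s in seq_len(cfg$n_pool_steps)) {
      n_next <- max(1L, as.integer(ceiling(cfg$assign_ratio * ncur)))
      Z <- tape_gcn(t, H, nA, pids[paste0("D.s", s, ".embed", 1:3)])
      P <- tape_gcn(t, H, nA, pids[paste0("D.s", s, ".pool", 1:2)])
      pool3 <- tp_cols(t, pids[[paste0("D.s", s, ".pool3")]], seq_len(n_next))
      P <- tp_mm(t, tp_mm(t, nA, P), pool3)
      S <- tp_row_softmax(t, P)
      St <- tp_t(t, S)
      H <- tp_mm(t, St, Z)
      Acur <- tp_mm(t, tp_mm(t, St, Acur), S)
      nA <- tp_norm_adj(t, Acur)
      ncur <- n_next
    }
    Zf <- tape_gcn(t, H, nA, pids[c("D.final1", "D.final2", "D.final3")])
    branch_out$D <- tp_colsums(t, Zf)
  }
  if ("R" %in% cfg$branches) {
    H <- tp_mm(t, X, pids[["R.proj"]])
    for (l in seq_len(cfg$n_layers)) {
      H <- tp_add(t, tp_relu(t, tp_mm(t, tp_mm(t, nA0, H),
                                      pids[[paste0("R.W", l)]])), H)
    }
    g <- tape_readout(t, H, cfg$readout)
    branch_out$R <- tp_mm(t, g, pids[["R.out"]])
  }
  outs <- branch_out[cfg$branches]
  fused <- if (cfg$fusion == "concat") {
    tp_cbind(t, unlist(outs, use.names = FALSE))
  } else {
    acc <- outs[[1L]]
    for (o in outs[-1L]) acc <- tp_add(t, acc, o)
    if (cfg$fusion == "mean") tp_scale(t, acc, 1 / length(outs)) else acc
  }
  h <- tp_relu(t, tp_add_bias(t, tp_mm(t, fused, pids[["head.W1"]]),
                              pids[["head.b1"]]))
  if (!is.null(dropout_mask)) h <- tp_mul(t, h, tp_leaf(t, dropout_mask))
  logits <- tp_add_bias(t, tp_mm(t, h, pids[["head.W2"]]), pids[["head.b2"]])
  list(tape = t, logits = logits, pids = pids)
}
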