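# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape is an environment accumulating nodes in topological (creation)
# order. Every value is stored as a numeric matrix (row vectors are 1 x d).
# Each non-leaf node records its parent ids and a backward closure mapping
# the gradient at the node to gradients at its parents. tp_backward() seeds
# one or more output nodes and sweeps the tape once in reverse.
#
# Node-id arguments are force()d on entry: R would otherwise copy t$vals
# before evaluating a nested op passed as an argument, and index a stale tape.
#
# This is deliberately small: just the operations the network needs
# (matrix product, elementwise ops, row softmax, readouts, concatenation,
# column slicing, bias broadcast). Gradients are verified against finite
# differences in the test suite.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$vals <- list()
  t$parents <- list()
  t$bw <- list()
  t$n <- 0L
  t
}

tp_push <- function(t, value, parents = integer(0), backward = NULL) {
  t$n <- t$n + 1L
  t$vals[[t$n]] <- value
  t$parents[[t$n]] <- parents
  t$bw[[t$n]] <- backward
  t$n
}

tp_val <- function(t, id) t$vals[[id]]

tp_leaf <- function(t, value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  tp_push(t, value)
}

tp_mm <- function(t, a, b) {
  force(a); force(b)
  va <- t$vals[[a]]; vb <- t$vals[[b]]
  tp_push(t, va %*% vb, c(a, b), function(g) {
    list(g %*% t(vb), crossprod(va, g))
  })
}

tp_add <- function(t, a, b) {
  force(a); force(b)
  tp_push(t, t$vals[[a]] + t$vals[[b]], c(a, b), function(g) list(g, g))
}

tp_add_bias <- function(t, a, bias) {
  force(a); force(bias)
  vb <- t$vals[[bias]]  # 1 x d
  va <- t$vals[[a]]
  tp_push(t, sweep(va, 2L, as.numeric(vb), "+"), c(a, bias), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

tp_mul <- function(t, a, b) {
  force(a); force(b)
  va <- t$vals[[a]]; vb <- t$vals[[b]]
  tp_push(t, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

tp_scale <- function(t, a, s) {
  force(a)
  tp_push(t, t$vals[[a]] * s, a, function(g) list(g * s))
}

tp_relu <- function(t, a) {
  force(a)
  v <- t$vals[[a]]
  out <- pmax(v, 0)
  mask <- (v > 0) * 1
  tp_push(t, out, a, function(g) list(g * mask))
}

tp_epow <- function(t, a, p) {
  force(a)
  v <- t$vals[[a]]
  tp_push(t, v^p, a, function(g) list(g * p * v^(p - 1)))
}

tp_t <- function(t, a) {
  force(a)
  tp_push(t, t(t$vals[[a]]), a, function(g) list(t(g)))
}

tp_rowsums <- function(t, a) {
  force(a)
  v <- t$vals[[a]]
  nc <- ncol(v)
  tp_push(t, matrix(rowSums(v), ncol = 1L), a, function(g) {
    list(matrix(g, nrow(v), nc))
  })
}

tp_row_softmax <- function(t, a) {
  force(a)
  v <- t$vals[[a]]
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  y <- e / rowSums(e)
  tp_push(t, y, a, function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

tp_colmeans <- function(t, a) {
  force(a)
  v <- t$vals[[a]]
  n <- nrow(v)
  tp_push(t, matrix(colMeans(v), 1L), a, function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

tp_colsums <- function(t, a) {
  force(a)
  v <- t$vals[[a]]
  n <- nrow(v)
  tp_push(t, matrix(colSums(v), 1L), a, function(g) {
    list(matrix(rep(as.numeric(g), each = n), n))
  })
}

tp_colmax <- function(t, a) {
  force(a)
  v <- t$vals[[a]]
  idx <- max.col(t(v), ties.method = "first")  # row index of max per column
  tp_push(t, matrix(v[cbind(idx, seq_len(ncol(v)))], 1L), a, function(g) {
    out <- matrix(0, nrow(v), ncol(v))
    out[cbind(idx, seq_len(ncol(v)))] <- as.numeric(g)
    list(out)
  })
}

tp_cols <- function(t, a, idx) {
  force(a)
  v <- t$vals[[a]]
  tp_push(t, v[, idx, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(v), ncol(v))
    out[, idx] <- g
    list(out)
  })
}

tp_cbind <- function(t, ids) {
  force(ids)
  vals <- lapply(ids, function(i) t$vals[[i]])
  widths <- vapply(vals, ncol, integer(1))
  tp_push(t, do.call(cbind, vals), ids, function(g) {
    ends <- cumsum(widths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_along(widths), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# Symmetric normalization with self-loops, differentiable in A:
# P = D^{-1/2} (A + I) D^{-1/2} with D the degree matrix of A + I.
tp_norm_adj <- function(t, a) {
  force(a)
  n <- nrow(t$vals[[a]])
  at <- tp_add(t, a, tp_leaf(t, diag(n)))
  d <- tp_rowsums(t, at)
  dn <- tp_epow(t, d, -0.5)
  tp_mul(t, at, tp_mm(t, dn, tp_t(t, dn)))
}

# Reverse sweep. seeds: named list mapping node id (as character) to the
# output gradient at that node. Returns a list of gradients indexed by id
# (NULL where no gradient flowed).
tp_backward <- function(t, seeds) {
  grads <- vector("list", t$n)
  for (id_chr in names(seeds)) {
    id <- as.integer(id_chr)
    grads[[id]] <- seeds[[id_chr]]
  }
  for (id in rev(seq_len(t$n))) {
    g <- grads[[id]]
    if (is.null(g) || is.null(t$bw[[id]])) next
    pg <- t$bw[[id]](g)
    ps <- t$parents[[id]]
    for (j in seq_along(ps)) {
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}
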