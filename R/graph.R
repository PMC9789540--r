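#' Featurization configuration
#'
#' Controls which of the four node-attribute encoders are applied and the
#' node2vec hyperparameters. The node-attribute matrix `X` concatenates the
#' enabled encoders column-wise in the fixed order one-hot (20), node2vec
#' (`node2vec_dim`), ten-property physicochemical (10), CTD (21).
#'
#' @param use_onehot,use_node2vec,use_pc10,use_ctd21 Enable each encoder.
#' @param node2vec_dim Embedding dimension (default 16).
#' @param walks_per_node Random walks started from each node (default 10).
#' @param walk_length Steps per walk (default 20; capped at the chain length).
#' @param window Skip-gram context window (default 5).
#' @param p,q Node2vec return and in-out parameters; the defaults `p = 4`,
#'   `q = 0.25` bias walks depth-first along the chain.
#' @param node2vec_epochs Skip-gram passes over the walk corpus (default 5).
#' @param seed Integer seed for the embedding RNG.
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(use_onehot = TRUE, use_node2vec = TRUE,
                           use_pc10 = TRUE, use_ctd21 = TRUE,
                           node2vec_dim = 16L, walks_per_node = 10L,
                           walk_length = 20L, window = 5L,
                           p = 4, q = 0.25, node2vec_epochs = 5L,
                           seed = 1L) {
  if (!any(use_onehot, use_node2vec, use_pc10, use_ctd21)) {
    stop("at least one encoder must be enabled", call. = FALSE)
  }
  stopifnot(node2vec_dim >= 1L, walks_per_node >= 1L, walk_length >= 2L,
            window >= 1L, p > 0, q > 0, node2vec_epochs >= 1L)
  structure(list(
    use_onehot = use_onehot, use_node2vec = use_node2vec,
    use_pc10 = use_pc10, use_ctd21 = use_ctd21,
    node2vec_dim = as.integer(node2vec_dim),
    walks_per_node = as.integer(walks_per_node),
    walk_length = as.integer(walk_length), window = as.integer(window),
    p = p, q = q, node2vec_epochs = as.integer(node2vec_epochs),
    seed = as.integer(seed)
  ), class = "encoder_config")
}

#' Total node-attribute width of an encoder configuration
#'
#' @param enc An [encoder_config()].
#' @return Integer: `20*use_onehot + node2vec_dim*use_node2vec + 10*use_pc10 +
#'   21*use_ctd21`.
#' @export
encoder_width <- function(enc) {
  as.integer(20L * enc$use_onehot + enc$node2vec_dim * enc$use_node2vec +
               10L * enc$use_pc10 + 21L * enc$use_ctd21)
}

path_adjacency <- function(n) {
  A <- matrix(0, n, n)
  if (n >= 2L) {
    idx <- seq_len(n - 1L)
    A[cbind(idx, idx + 1L)] <- 1
    A[cbind(idx + 1L, idx)] <- 1
  }
  A
}

#' Build the graph representation of one peptide
#'
#' Converts a peptide record into a path graph: one node per residue, edges
#' between chain neighbours (the peptide bonds), node labels equal to each
#' residue's 1..20 rank in [aa_alphabet()], and a node-attribute matrix `X`
#' concatenating the enabled encoders.
#'
#' @param record One-row peptide record data frame, or a list with `id`,
#'   `sequence`, `label`.
#' @param enc An [encoder_config()].
#' @param node2vec_cache Optional environment used to reuse node2vec
#'   embeddings across same-length chains (embeddings of an unlabeled path
#'   graph depend only on its length, so this is lossless).
#' @return Object of class `peptide_graph`: list with `id`, `sequence`, `n`,
#'   `A` (n x n), `node_labels` (1..20), `X` (n x d), `graph_label`.
#' @export
build_graph <- function(record, enc = encoder_config(), node2vec_cache = NULL) {
  seq <- toupper(record$sequence[[1L]])
  if (is.na(seq) || !nzchar(seq)) stop("empty sequence", call. = FALSE)
  letters_in <- strsplit(seq, "")[[1L]]
  labs <- match(letters_in, aa_alphabet())
  if (anyNA(labs)) {
    stop("record '", record$id[[1L]], "' contains non-standard residue '",
         letters_in[which(is.na(labs))[1L]], "'", call. = FALSE)
  }
  n <- length(labs)
  A <- path_adjacency(n)
  blocks <- list()
  if (enc$use_onehot) {
    oh <- matrix(0, n, 20L)
    oh[cbind(seq_len(n), labs)] <- 1
    blocks$onehot <- oh
  }
  if (enc$use_node2vec) {
    if (n < 2L) stop("node2vec encoder needs chains of length >= 2", call. = FALSE)
    emb <- NULL
    key <- paste0("n", n)
    if (!is.null(node2vec_cache) && !is.null(node2vec_cache[[key]])) {
      emb <- node2vec_cache[[key]]
    } else {
      emb <- node2vec_embed(A, enc)
      if (!is.null(node2vec_cache)) node2vec_cache[[key]] <- emb
    }
    blocks$node2vec <- emb
  }
  if (enc$use_pc10) {
    blocks$pc10 <- t(vapply(letters_in, pc10_encode, numeric(10L)))
  }
  if (enc$use_ctd21) {
    blocks$ctd21 <- t(vapply(letters_in, ctd21_encode, numeric(21L)))
  }
  X <- do.call(cbind, blocks)
  dimnames(X) <- NULL
  rownames(X) <- NULL
  structure(list(
    id = as.character(record$id[[1L]]), sequence = seq, n = n, A = A,
    node_labels = labs, X = X,
    graph_label = as.integer(record$label[[1L]])
  ), class = "peptide_graph")
}

#' @export
print.peptide_graph <- function(x, ...) {
  cat("peptide_graph: ", x$id, " (", x$n, " residues, label ", x$graph_label,
      ", ", ncol(x$X), " node attributes)\n", sep = "")
  invisible(x)
}

#' Featurize a peptide dataset
#'
#' Maps [build_graph()] over all records, sharing one node2vec cache so
#' chains of equal length reuse the same positional embedding.
#'
#' @param records Peptide record data frame.
#' @param enc An [encoder_config()].
#' @param drop_invalid Skip records that fail validation (with a message)
#'   instead of raising an error.
#' @return List of `peptide_graph` objects with a constant attribute width.
#' @export
featurize_dataset <- function(records, enc = encoder_config(),
                              drop_invalid = FALSE) {
  if (nrow(records) == 0L) return(list())
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(records))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    g <- tryCatch(build_graph(records[i, ], enc, node2vec_cache = cache),
                  error = function(e) e)
    if (inherits(g, "error")) {
      if (drop_invalid) {
        message("skipping record '", records$id[i], "': ", conditionMessage(g))
        next
      }
      stop("record '", records$id[i], "': ", conditionMessage(g), call. = FALSE)
    }
    out[[i]] <- g
    keep[i] <- TRUE
  }
  out[keep]
}
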