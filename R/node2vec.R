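#' Node2vec embedding of a peptide graph
#'
#' Learns a dense per-node embedding of one peptide graph by running biased
#' second-order random walks over its chain and training a skip-gram model
#' with negative sampling on the sampled node sequences. The walk bias is
#' depth-first flavoured by default (return parameter `p > 1`, in-out
#' parameter `q < 1`), so walks tend to run along the chain and embeddings
#' capture positional proximity: residues close along the backbone receive
#' similar vectors. The result is deterministic for a fixed encoder seed.
#'
#' Because the walk process sees only graph structure (not residue identity),
#' the embedding of an unlabeled chain depends only on its length; it acts as
#' a learned positional encoding complementing the residue-identity encoders.
#'
#' @param graph A `peptide_graph` (see [build_graph()]) or a symmetric binary
#'   adjacency matrix.
#' @param enc An [encoder_config()].
#' @return Numeric matrix of shape `n x enc$node2vec_dim`, finite entries.
#' @export
node2vec_embed <- function(graph, enc) {
  A <- if (inherits(graph, "peptide_graph")) graph$A else graph
  n <- nrow(A)
  if (n < 2L) stop("node2vec needs at least 2 nodes", call. = FALSE)
  if (enc$walk_length < enc$window) {
    stop("walk_length (", enc$walk_length, ") must be >= window (",
         enc$window, ")", call. = FALSE)
  }
  adj <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  wl <- min(enc$walk_length, n)
  withr_seed(enc$seed, {
    walks <- .n2v_walks(adj, as.integer(enc$walks_per_node), as.integer(wl),
                        enc$p, enc$q)
    emb <- .n2v_train(walks, n, as.integer(enc$node2vec_dim),
                      as.integer(min(enc$window, wl)),
                      as.integer(enc$node2vec_epochs), 5L, 0.025)
  })
  emb
}
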