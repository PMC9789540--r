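#' Synthetic peptide generator configuration
#'
#' Defines a labelled random-peptide benchmark with a controllable signal.
#' Positives (ACPs, label 0) carry a planted cationic/aromatic motif with
#' probability `motif_rate` and are drawn from a composition biased toward
#' K, R, F and W, echoing the cationic amphipathic chemistry of real
#' anticancer peptides; negatives are drawn from a flat composition.
#' Lengths are uniform over `length_range` (default 10-50 residues, the
#' typical ACP length range).
#'
#' @param n_pos,n_neg Numbers of positive / negative records.
#' @param length_range Integer pair `(min, max)` of sequence lengths.
#' @param motif Residue string planted in positives.
#' @param motif_rate Probability that a positive carries the motif.
#' @param composition_bias Optional named list with per-letter sampling
#'   weights for each class (`pos` and/or `neg`), each a numeric vector of
#'   length 20 in [aa_alphabet()] order. Defaults: positives weight K, R, F, W
#'   threefold; negatives uniform.
#' @param seed Integer RNG seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_pos, n_neg, length_range = c(10L, 50L),
                         motif = "KWKLFKK", motif_rate = 1.0,
                         composition_bias = NULL, seed = 1L) {
  motif <- toupper(motif)
  if (!grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"), motif)) {
    stop("motif contains non-standard residues", call. = FALSE)
  }
  length_range <- as.integer(length_range)
  if (length_range[1L] < nchar(motif)) {
    stop("minimum length must be >= motif length (", nchar(motif), ")",
         call. = FALSE)
  }
  if (motif_rate < 0 || motif_rate > 1) stop("motif_rate must be in [0,1]",
                                             call. = FALSE)
  if (is.null(composition_bias)) {
    pos_w <- rep(1, 20)
    pos_w[match(c("K", "R", "F", "W"), aa_alphabet())] <- 3
    composition_bias <- list(pos = pos_w, neg = rep(1, 20))
  } else {
    if (is.null(composition_bias$pos)) composition_bias$pos <- rep(1, 20)
    if (is.null(composition_bias$neg)) composition_bias$neg <- rep(1, 20)
    stopifnot(length(composition_bias$pos) == 20L,
              length(composition_bias$neg) == 20L)
  }
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    length_range = length_range, motif = motif, motif_rate = motif_rate,
    composition_bias = composition_bias, seed = as.integer(seed)
  ), class = "synth_config")
}

random_seq <- function(len, weights) {
  paste(sample(aa_alphabet(), len, replace = TRUE, prob = weights),
        collapse = "")
}

plant_motif <- function(seq, motif) {
  n <- nchar(seq)
  m <- nchar(motif)
  start <- sample.int(n - m + 1L, 1L)
  paste0(substr(seq, 1L, start - 1L), motif, substr(seq, start + m, n))
}

#' Generate a synthetic labelled peptide dataset
#'
#' @param cfg A [synth_config()].
#' @return A peptide record data frame with `cfg$n_pos` ACPs (label 0)
#'   followed by `cfg$n_neg` non-ACPs (label 1); deterministic per seed.
#' @export
generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr_seed(cfg$seed, {
    lens_pos <- sample(seq(cfg$length_range[1L], cfg$length_range[2L]),
                       cfg$n_pos, replace = TRUE)
    pos <- vapply(lens_pos, function(len) {
      s <- random_seq(len, cfg$composition_bias$pos)
      if (stats::runif(1) <= cfg$motif_rate) s <- plant_motif(s, cfg$motif)
      s
    }, character(1))
    lens_neg <- sample(seq(cfg$length_range[1L], cfg$length_range[2L]),
                       cfg$n_neg, replace = TRUE)
    neg <- vapply(lens_neg, function(len) random_seq(len, cfg$composition_bias$neg),
                  character(1))
    peptide_records(
      id = c(sprintf("ACP%04d", seq_len(cfg$n_pos)),
             sprintf("NEG%04d", seq_len(cfg$n_neg))),
      sequence = c(pos, neg),
      label = rep(c(0L, 1L), c(cfg$n_pos, cfg$n_neg))
    )
  })
}

#' Generate a class-imbalanced synthetic dataset
#'
#' Wraps [generate()] with the negative count set to
#' `n_pos * ratio_neg / ratio_pos`, rounding down with a warning when the
#' implied count is fractional.
#'
#' @param cfg A [synth_config()]; its `n_neg` is overridden.
#' @param ratio_pos,ratio_neg Target positive:negative ratio.
#' @return A peptide record data frame.
#' @export
generate_imbalanced <- function(cfg, ratio_pos = 1L, ratio_neg = 1L) {
  n_neg <- cfg$n_pos * ratio_neg / ratio_pos
  if (n_neg != floor(n_neg)) {
    warning("implied negative count ", n_neg, " is not an integer; rounding down")
    n_neg <- floor(n_neg)
  }
  cfg$n_neg <- as.integer(n_neg)
  generate(cfg)
}

#' Motif-presence baseline classifier
#'
#' Labels a record as ACP iff its sequence contains the generator's motif.
#' With `motif_rate = 1` and no composition overlap this achieves perfect
#' accuracy by construction, so it serves as an upper-bound sanity oracle for
#' trained models on synthetic data.
#'
#' @param records Peptide record data frame.
#' @param motif Motif string.
#' @return Integer vector of predicted labels (0 = ACP, 1 = non-ACP).
#' @export
motif_baseline <- function(records, motif = "KWKLFKK") {
  ifelse(grepl(motif, records$sequence, fixed = TRUE), 0L, 1L)
}
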