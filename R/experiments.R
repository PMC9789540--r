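#' Stratified k-fold cross-validation
#'
#' Featurizes the records once, then trains one model per fold on the
#' remaining folds and evaluates on the held-out fold. Metrics are reported
#' per fold and aggregated either as the unweighted mean of fold metrics
#' (`"mean"`) or by pooling all held-out predictions into one confusion
#' table (`"pooled"`).
#'
#' @param records Peptide record data frame.
#' @param enc An [encoder_config()].
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param k Number of folds (default 10).
#' @param aggregate `"mean"` or `"pooled"`.
#' @param seed Seed for the fold assignment.
#' @param verbose Print per-fold progress.
#' @return List with `per_fold` (data frame of fold metrics), `summary`
#'   (aggregated metrics data frame row), `aggregate`, `folds` and
#'   `predictions` (pooled held-out prediction table).
#' @export
run_cv <- function(records, enc = encoder_config(), cfg = model_config(),
                   tcfg = train_config(), k = 10L,
                   aggregate = c("mean", "pooled"), seed = 1L,
                   verbose = FALSE) {
  aggregate <- match.arg(aggregate)
  graphs <- featurize_dataset(records, enc)
  folds <- make_folds(records, k = k, seed = seed)
  per_fold <- NULL
  pooled <- NULL
  for (f in seq_len(folds$k)) {
    test_idx <- which(folds$assignments == f)
    m <- train(graphs[-test_idx], cfg, tcfg, enc = enc)
    pr <- predict(m, graphs[test_idx])
    pr$fold <- f
    pooled <- rbind(pooled, pr)
    rep <- evaluate_predictions(pr$label, pr$prob_acp)
    row <- cbind(data.frame(fold = f), metrics_row(rep))
    per_fold <- rbind(per_fold, row)
    if (verbose) message("fold ", f, ": ACC ", sprintf("%.3f", rep$ACC))
  }
  summary_row <- if (aggregate == "mean") {
    as.data.frame(as.list(colMeans(per_fold[, -1L])))
  } else {
    metrics_row(evaluate_predictions(pooled$label, pooled$prob_acp))
  }
  list(per_fold = per_fold, summary = summary_row, aggregate = aggregate,
       folds = folds, predictions = pooled)
}

#' Independent-test evaluation
#'
#' Featurizes a labelled test set with the model's encoder configuration and
#' evaluates a single forward pass, mirroring the design of holding out an
#' imbalanced external test set (e.g. 82 ACPs vs 2628 non-ACPs).
#'
#' @param model A trained `acpgcn_model`.
#' @param test_records Labelled peptide record data frame.
#' @param enc Encoder config; defaults to the one stored in the model.
#' @return List with `report` (a `metrics_report` incl. AUC) and
#'   `predictions`.
#' @export
run_independent_test <- function(model, test_records, enc = NULL) {
  if (is.null(enc)) enc <- model$enc
  if (is.null(enc)) stop("no encoder config available", call. = FALSE)
  if (encoder_width(enc) != model$input_dim) {
    stop("encoder mismatch: model expects ", model$input_dim,
         " node attributes but the encoder config yields ",
         encoder_width(enc), call. = FALSE)
  }
  graphs <- featurize_dataset(test_records, enc)
  pr <- predict(model, graphs)
  list(report = evaluate_predictions(pr$label, pr$prob_acp), predictions = pr)
}

# Stratified train/validation split with the given train fraction.
split_train_val <- function(records, train_frac = 0.9, seed = 1L) {
  k <- max(2L, as.integer(round(1 / (1 - train_frac))))
  k <- min(k, min(table(factor(records$label, levels = c(0L, 1L)))))
  folds <- make_folds(records, k = k, seed = seed)
  val_idx <- which(folds$assignments == 1L)
  list(train = setdiff(seq_len(nrow(records)), val_idx), val = val_idx)
}

parse_variant <- function(v) {
  branches <- strsplit(gsub("[()X ]", "", v), "\\+")[[1L]]
  if (!length(branches) || !all(branches %in% c("G", "D", "R"))) {
    stop("unknown ablation variant: ", v, call. = FALSE)
  }
  branches
}

#' Branch ablation experiment
#'
#' Trains the network with subsets of its three branches enabled on a
#' stratified 9:1 train/validation split and reports Precision, Recall, ACC,
#' F1 and MCC per variant.
#'
#' @inheritParams run_cv
#' @param variants Character vector of branch combinations, e.g.
#'   `c("G", "G+R", "G+D", "G+D+R")`.
#' @param split_frac Training fraction of the split (default 0.9).
#' @return Data frame with one row per variant.
#' @export
run_ablation <- function(records, enc = encoder_config(),
                         cfg = model_config(), tcfg = train_config(),
                         variants = c("G", "G+R", "G+D", "G+D+R"),
                         split_frac = 0.9, seed = 1L, verbose = FALSE) {
  graphs <- featurize_dataset(records, enc)
  sp <- split_train_val(records, split_frac, seed)
  out <- NULL
  for (v in variants) {
    cfg_v <- cfg
    cfg_v$branches <- parse_variant(v)
    m <- train(graphs[sp$train], cfg_v, tcfg, enc = enc)
    pr <- predict(m, graphs[sp$val])
    rep <- evaluate_predictions(pr$label, pr$prob_acp)
    out <- rbind(out, data.frame(
      Model = v, Precision = rep$precision, Recall = rep$SE, ACC = rep$ACC,
      F1 = rep$F1, MCC = rep$MCC
    ))
    if (verbose) message(v, ": ACC ", sprintf("%.3f", rep$ACC))
  }
  out
}

#' Class-ratio experiment
#'
#' For each positive:negative training ratio, keeps all positives, subsamples
#' negatives to the ratio, trains on a stratified 9:1 split and evaluates on
#' the held-out tenth, reporting Precision, Recall, ACC, F1 and MCC.
#'
#' @inheritParams run_cv
#' @param ratios List of integer pairs `c(pos, neg)`, default 1:1, 1:5, 1:10.
#' @return Data frame with one row per ratio.
#' @export
run_ratio_experiment <- function(records, enc = encoder_config(),
                                 cfg = model_config(), tcfg = train_config(),
                                 ratios = list(c(1L, 1L), c(1L, 5L), c(1L, 10L)),
                                 seed = 1L, verbose = FALSE) {
  out <- NULL
  for (r in ratios) {
    sub <- subsample_ratio(records, r[1L], r[2L], seed = seed)
    graphs <- featurize_dataset(sub, enc)
    sp <- split_train_val(sub, 0.9, seed)
    m <- train(graphs[sp$train], cfg, tcfg, enc = enc)
    pr <- predict(m, graphs[sp$val])
    rep <- evaluate_predictions(pr$label, pr$prob_acp)
    out <- rbind(out, data.frame(
      Ratio = paste0(r[1L], ":", r[2L]), Precision = rep$precision,
      Recall = rep$SE, ACC = rep$ACC, F1 = rep$F1, MCC = rep$MCC
    ))
    if (verbose) message(paste0(r[1L], ":", r[2L]), ": ACC ",
                         sprintf("%.3f", rep$ACC))
  }
  out
}

#' Hyperparameter sweep
#'
#' Re-trains and evaluates the model for each value of one hyperparameter
#' (`learning_rate`, `n_layers` or `assign_ratio`), on a stratified 9:1
#' holdout split, and collates the metrics.
#'
#' @inheritParams run_cv
#' @param param One of `"learning_rate"`, `"n_layers"`, `"assign_ratio"`.
#' @param values Numeric vector of sweep values (e.g. `c(0.1, 0.01, 0.001)`
#'   for the learning rate, `5:10` for depth, `seq(0.3, 0.9, 0.1)` for the
#'   assign ratio).
#' @return Data frame with one row per value.
#' @export
sweep_param <- function(param, values, records, enc = encoder_config(),
                        cfg = model_config(), tcfg = train_config(),
                        seed = 1L, verbose = FALSE) {
  param <- match.arg(param, c("learning_rate", "n_layers", "assign_ratio"))
  graphs <- featurize_dataset(records, enc)
  sp <- split_train_val(records, 0.9, seed)
  out <- NULL
  for (v in values) {
    cfg_v <- cfg; tcfg_v <- tcfg
    if (param == "learning_rate") tcfg_v$learning_rate <- v
    else if (param == "n_layers") cfg_v$n_layers <- as.integer(v)
    else cfg_v$assign_ratio <- v
    m <- train(graphs[sp$train], cfg_v, tcfg_v, enc = enc)
    pr <- predict(m, graphs[sp$val])
    rep <- evaluate_predictions(pr$label, pr$prob_acp)
    out <- rbind(out, cbind(data.frame(param = param, value = v),
                            metrics_row(rep)))
    if (verbose) message(param, " = ", v, ": ACC ", sprintf("%.3f", rep$ACC))
  }
  out
}
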