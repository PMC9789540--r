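#' Training configuration
#'
#' @param epochs Training epochs (default 1000).
#' @param learning_rate Optimizer step size (default 0.01; the sweep harness
#'   covers 0.1, 0.01, 0.001).
#' @param batch_size Graphs per gradient step (default 32).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed Integer seed controlling epoch shuffling (weight
#'   initialization is governed by the model config seed).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, learning_rate = 0.01,
                         batch_size = 32L, optimizer = "adam", seed = 1L) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L)
  optimizer <- match.arg(optimizer, c("adam", "sgd"))
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Mean binary cross-entropy loss
#'
#' `-mean(y * log(p) + (1 - y) * log(1 - p))` with probabilities clamped away
#' from 0 and 1. `p` is the predicted probability that a sample is an ACP
#' (the positive class) and `y` is 1 for a true ACP — note this is the
#' positive-class orientation, not the 0 = ACP storage code.
#'
#' @param probs Numeric vector of predicted positive-class probabilities.
#' @param labels Numeric/integer vector of true positive-class indicators
#'   (1 = ACP).
#' @param eps Clamp width.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(probs, labels, eps = 1e-12) {
  if (length(probs) == 0L) stop("empty batch", call. = FALSE)
  if (length(probs) != length(labels)) {
    stop("probs and labels differ in length", call. = FALSE)
  }
  p <- pmin(pmax(probs, eps), 1 - eps)
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Gradient of the mean cross-entropy w.r.t. every parameter, accumulated over
# a batch of graphs; also returns the batch loss and per-graph ACP
# probabilities.
batch_grads <- function(params, graphs, cfg, scale) {
  grads <- NULL
  loss <- 0
  for (g in graphs) {
    ft <- forward_tape(params, g, cfg)
    logits <- tp_val(ft$tape, ft$logits)
    probs <- row_softmax(logits)
    target <- c(0, 0)
    target[g$graph_label + 1L] <- 1  # storage code 0 (ACP) -> class slot 1
    loss <- loss - log(max(probs[g$graph_label + 1L], 1e-12)) * scale
    dlogits <- (probs - matrix(target, 1L)) * scale
    seeds <- stats::setNames(list(dlogits), as.character(ft$logits))
    all_g <- tp_backward(ft$tape, seeds)
    if (is.null(grads)) {
      grads <- lapply(names(params), function(nm) {
        gg <- all_g[[ft$pids[[nm]]]]
        if (is.null(gg)) params[[nm]] * 0 else gg
      })
      names(grads) <- names(params)
    } else {
      for (nm in names(params)) {
        gg <- all_g[[ft$pids[[nm]]]]
        if (!is.null(gg)) grads[[nm]] <- grads[[nm]] + gg
      }
    }
  }
  list(grads = grads, loss = loss)
}

#' Train the three-branch graph network
#'
#' Minimizes the mean cross-entropy over the training graphs by mini-batch
#' gradient descent (Adam by default), with gradients computed by
#' reverse-mode differentiation of the full three-branch forward pass.
#' Deterministic for fixed model/config seeds.
#'
#' @param graphs List of `peptide_graph` objects (see [featurize_dataset()]).
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param enc Optional [encoder_config()] stored with the model so
#'   predictions on raw records can re-featurize consistently.
#' @param verbose Print the loss every 50 epochs.
#' @return Object of class `acpgcn_model`: list with `params`, `cfg`, `tcfg`,
#'   `enc`, `input_dim` and `loss_trace` (mean training loss per epoch).
#' @export
train <- function(graphs, cfg = model_config(), tcfg = train_config(),
                  enc = NULL, verbose = FALSE) {
  if (length(graphs) == 0L) stop("no training graphs", call. = FALSE)
  labs <- vapply(graphs, function(g) g$graph_label, integer(1))
  if (length(unique(labs)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  input_dim <- ncol(graphs[[1L]]$X)
  params <- init_params(cfg, input_dim)
  state <- adam_state(params)
  n <- length(graphs)
  trace <- numeric(tcfg$epochs)
  withr_seed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = tcfg$batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + tcfg$batch_size - 1L, n)]
        bg <- batch_grads(params, graphs[idx], cfg, scale = 1 / length(idx))
        if (!is.finite(bg$loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
        }
        ep_loss <- ep_loss + bg$loss * length(idx)
        if (tcfg$optimizer == "adam") {
          upd <- adam_update(params, bg$grads, state, tcfg$learning_rate)
          params <- upd$params
          state <- upd$state
        } else {
          for (nm in names(params)) {
            params[[nm]] <- params[[nm]] - tcfg$learning_rate * bg$grads[[nm]]
          }
        }
      }
      trace[ep] <- ep_loss / n
      if (verbose && (ep %% 50L == 0L || ep == 1L)) {
        message(sprintf("epoch %d  loss %.4f", ep, trace[ep]))
      }
    }
  })
  structure(list(params = params, cfg = cfg, tcfg = tcfg, enc = enc,
                 input_dim = input_dim, loss_trace = trace),
            class = "acpgcn_model")
}

#' @export
print.acpgcn_model <- function(x, ...) {
  cat("acpgcn_model: branches", paste(x$cfg$branches, collapse = "+"),
      "| input", x$input_dim, "| hidden", x$cfg$hidden_dim,
      "| trained", length(x$loss_trace), "epochs, final loss",
      sprintf("%.4f", utils::tail(x$loss_trace, 1L)), "\n")
  invisible(x)
}

#' Predict ACP probabilities
#'
#' Runs the forward pass on featurized graphs (or raw records, which are
#' featurized with the model's stored encoder config) and returns per-peptide
#' class probabilities and thresholded labels.
#'
#' @param object A trained `acpgcn_model`.
#' @param graphs List of `peptide_graph` objects, or a peptide record data
#'   frame when the model carries an encoder config.
#' @param threshold Decision threshold on the ACP probability (default 0.5).
#' @param ... Unused.
#' @return Data frame with columns `id`, `label` (true storage code, NA if
#'   unknown), `prob_acp`, `pred` (predicted storage code: 0 = ACP).
#' @export
predict.acpgcn_model <- function(object, graphs, threshold = 0.5, ...) {
  if (is.data.frame(graphs)) {
    if (is.null(object$enc)) {
      stop("model has no stored encoder config; featurize records first",
           call. = FALSE)
    }
    graphs <- featurize_dataset(graphs, object$enc)
  }
  if (length(graphs) &&
      ncol(graphs[[1L]]$X) != object$input_dim) {
    stop("encoder mismatch: model expects ", object$input_dim,
         " node attributes, got ", ncol(graphs[[1L]]$X), call. = FALSE)
  }
  probs <- vapply(graphs, function(g) {
    forward_graph(object$params, g, object$cfg)[["acp"]]
  }, numeric(1))
  data.frame(
    id = vapply(graphs, function(g) g$id, character(1)),
    label = vapply(graphs, function(g) as.integer(g$graph_label), integer(1)),
    prob_acp = probs,
    pred = ifelse(probs >= threshold, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned RDS file bundling the trained weights and
#' the model, training and encoder configurations needed to reproduce
#' predictions.
#'
#' @param model A trained `acpgcn_model`.
#' @param path Checkpoint file path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "acpgcn_model"))
  saveRDS(list(format = "acpgcn_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "acpgcn_checkpoint")) {
    stop("not an acpgcn checkpoint: ", path, call. = FALSE)
  }
  x$model
}
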