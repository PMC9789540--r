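#' Peptide record tables
#'
#' Peptide datasets are plain data frames with columns `id` (character),
#' `sequence` (character, 20-letter alphabet) and `label` (integer 0/1).
#' Following the on-disk convention used throughout this package, label 0
#' marks an anticancer peptide (ACP, the positive class for every metric)
#' and label 1 a non-ACP. [metrics][compute_metrics] and prediction
#' thresholding perform the single, centralized inversion from this storage
#' code to the conventional "ACP = positive" orientation.
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param label Integer vector of 0 (ACP) / 1 (non-ACP) class codes.
#' @param validate Check the sequence alphabet and label domain.
#' @return A data frame with columns `id`, `sequence`, `label`.
#' @export
peptide_records <- function(id, sequence, label, validate = TRUE) {
  rec <- data.frame(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    label = as.integer(label),
    stringsAsFactors = FALSE
  )
  if (validate) validate_records(rec)
  rec
}

#' @rdname peptide_records
#' @param records A peptide record data frame.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "label") %in% names(records)))
  bad_label <- which(!records$label %in% c(0L, 1L))
  if (length(bad_label)) {
    stop("record '", records$id[bad_label[1L]], "' has label ",
         records$label[bad_label[1L]], "; labels must be 0 (ACP) or 1 (non-ACP)",
         call. = FALSE)
  }
  if (any(!nzchar(records$sequence))) {
    stop("record '", records$id[which(!nzchar(records$sequence))[1L]],
         "' has an empty sequence", call. = FALSE)
  }
  ok <- paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$")
  bad <- which(!grepl(ok, records$sequence))
  if (length(bad)) {
    i <- bad[1L]
    letters_in <- strsplit(records$sequence[i], "")[[1L]]
    offending <- setdiff(unique(letters_in), aa_alphabet())[1L]
    stop("record '", records$id[i], "' contains non-standard residue '",
         offending, "'", call. = FALSE)
  }
  invisible(records)
}

drop_invalid_records <- function(records) {
  ok_re <- paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$")
  keep <- nzchar(records$sequence) & grepl(ok_re, records$sequence) &
    records$label %in% c(0L, 1L)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " invalid record(s): ",
            paste(utils::head(records$id[!keep], 5L), collapse = ", "))
  }
  records[keep, , drop = FALSE]
}

#' Read peptides from FASTA
#'
#' Reads a FASTA file and attaches a single class label to every entry.
#' Sequences are uppercased; entry order is preserved. Non-standard residues
#' (B, J, O, U, X, Z, ...) are rejected unless `drop_invalid = TRUE`, in
#' which case offending records are skipped with a message.
#'
#' @param path Path to a FASTA file.
#' @param label Class label for every record in the file: 0 = ACP, 1 = non-ACP.
#' @param drop_invalid Skip records with non-standard residues instead of
#'   raising an error.
#' @return A peptide record data frame (see [peptide_records()]).
#' @export
read_fasta <- function(path, label, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) && !startsWith(trimws(first[1L]), ">")) {
    stop("malformed FASTA at line 1 of ", path,
         ": expected a '>' header, got '", substr(first[1L], 1, 30), "'",
         call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) {
    return(peptide_records(character(0), character(0), integer(0)))
  }
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  rec <- peptide_records(ids, as.character(seqs), rep(label, length(seqs)),
                         validate = FALSE)
  if (drop_invalid) drop_invalid_records(rec) else validate_records(rec)
}

#' Write peptides to FASTA
#'
#' @param records Peptide record data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a TSV peptide manifest
#'
#' The manifest is a tab-separated file with a header row and columns
#' `id`, `sequence`, `label` (0 = ACP, 1 = non-ACP).
#'
#' @inheritParams read_fasta
#' @return A peptide record data frame.
#' @export
read_manifest <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", blank.lines.skip = TRUE)
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns id, sequence, label; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(peptide_records(character(0), character(0), integer(0)))
  }
  lab <- suppressWarnings(as.integer(df$label))
  if (any(is.na(lab)) || any(!lab %in% c(0L, 1L))) {
    i <- which(is.na(lab) | !lab %in% c(0L, 1L))[1L]
    stop("record '", df$id[i], "' has label '", df$label[i],
         "'; labels must be 0 or 1", call. = FALSE)
  }
  rec <- peptide_records(df$id, df$sequence, lab, validate = FALSE)
  if (drop_invalid) drop_invalid_records(rec) else validate_records(rec)
}

#' Write a TSV peptide manifest
#'
#' @param records Peptide record data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(records, path) {
  utils::write.table(records[, c("id", "sequence", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph dataset in the TU benchmark layout
#'
#' Serializes a list of peptide graphs into the multi-file plain-text layout
#' used by graph-classification benchmarks: `<name>_A.txt` (global directed
#' edge list, 1-based; each undirected edge stored as both ordered pairs),
#' `<name>_graph_indicator.txt` (graph id per node), `<name>_graph_labels.txt`,
#' `<name>_node_labels.txt`, and `<name>_node_attributes.txt` (comma-separated
#' rows).
#'
#' @param graphs List of `peptide_graph` objects (see [build_graph()]).
#' @param dir Output directory (created if absent).
#' @param name Dataset name used as the file prefix.
#' @return Invisibly, `dir`.
#' @export
write_graph_dataset <- function(graphs, dir, name = "ACP") {
  if (length(graphs) == 0L) stop("no graphs to write", call. = FALSE)
  widths <- vapply(graphs, function(g) ncol(g$X), integer(1))
  if (length(unique(widths)) != 1L) {
    stop("node-attribute width differs across graphs: ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pre <- file.path(dir, name)

  offs <- cumsum(c(0L, vapply(graphs, function(g) g$n, integer(1))))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    idx <- which(graphs[[i]]$A != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(matrix(integer(0), ncol = 2L))
    idx + offs[i]
  }))
  writeLines(sprintf("%d, %d", edges[, 1L], edges[, 2L]),
             paste0(pre, "_A.txt"))
  indicator <- rep(seq_along(graphs), vapply(graphs, function(g) g$n, integer(1)))
  writeLines(as.character(indicator), paste0(pre, "_graph_indicator.txt"))
  writeLines(as.character(vapply(graphs, function(g) g$graph_label, integer(1))),
             paste0(pre, "_graph_labels.txt"))
  writeLines(as.character(unlist(lapply(graphs, function(g) g$node_labels))),
             paste0(pre, "_node_labels.txt"))
  attr_mat <- do.call(rbind, lapply(graphs, function(g) g$X))
  writeLines(apply(attr_mat, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ", ")),
    paste0(pre, "_node_attributes.txt"))
  invisible(dir)
}

#' Read a TU-format graph dataset
#'
#' Inverse of [write_graph_dataset()]: reconstructs the per-graph adjacency
#' matrices, node labels, node attributes and graph labels.
#'
#' @param dir Directory holding the TU files.
#' @param name Dataset name / file prefix.
#' @return List of `peptide_graph` objects (sequences are not stored in the
#'   TU layout and are left `NA`).
#' @export
read_graph_dataset <- function(dir, name = "ACP") {
  pre <- file.path(dir, name)
  need <- paste0(pre, c("_A.txt", "_graph_indicator.txt", "_graph_labels.txt",
                        "_node_labels.txt", "_node_attributes.txt"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing TU files: ",
                            paste(basename(missing), collapse = ", "),
                            call. = FALSE)
  edges_raw <- readLines(need[1L])
  edges <- if (length(edges_raw)) {
    do.call(rbind, lapply(strsplit(edges_raw, ","), function(x) as.integer(trimws(x))))
  } else matrix(integer(0), ncol = 2L)
  indicator <- as.integer(readLines(need[2L]))
  glabels <- as.integer(readLines(need[3L]))
  nlabels <- as.integer(readLines(need[4L]))
  X_all <- do.call(rbind, lapply(strsplit(readLines(need[5L]), ","),
                                 function(x) as.numeric(trimws(x))))
  n_graphs <- length(glabels)
  offs <- cumsum(c(0L, tabulate(indicator, nbins = n_graphs)))
  lapply(seq_len(n_graphs), function(i) {
    nodes <- which(indicator == i)
    n <- length(nodes)
    A <- matrix(0, n, n)
    sel <- edges[, 1L] %in% nodes
    if (any(sel)) {
      e <- edges[sel, , drop = FALSE] - offs[i]
      A[e] <- 1
    }
    structure(list(
      id = NA_character_, sequence = NA_character_, n = n, A = A,
      node_labels = nlabels[nodes],
      X = X_all[nodes, , drop = FALSE],
      graph_label = glabels[i]
    ), class = "peptide_graph")
  })
}

#' Stratified k-fold assignment
#'
#' Partitions records into `k` folds such that every record lands in exactly
#' one fold, total fold sizes differ by at most one, and each class's
#' per-fold counts differ by at most one (stratification). Deterministic for
#' a fixed seed.
#'
#' @param records Peptide record data frame.
#' @param k Number of folds (>= 2).
#' @param seed Integer RNG seed.
#' @return Object of class `fold_split`: list with `k`, `seed`, and
#'   `assignments` (integer fold id per record row).
#' @export
make_folds <- function(records, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- nrow(records)
  class_counts <- table(factor(records$label, levels = c(0L, 1L)))
  if (any(class_counts < k)) {
    stop("k = ", k, " exceeds the minority class count (",
         min(class_counts), ")", call. = FALSE)
  }
  assignments <- integer(n)
  offset <- 0L
  # Rotate the fold cursor across classes so total fold sizes stay balanced
  # even when per-class counts are not multiples of k.
  withr_seed(seed, {
    for (lab in c(0L, 1L)) {
      members <- which(records$label == lab)
      members <- sample(members)
      f <- ((seq_along(members) - 1L + offset) %% k) + 1L
      assignments[members] <- f
      offset <- (offset + length(members)) %% k
    }
  })
  structure(list(k = k, seed = as.integer(seed), assignments = assignments),
            class = "fold_split")
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Subsample negatives to a positive:negative ratio
#'
#' Keeps every positive (ACP, label 0) record and randomly samples negatives
#' down to `ratio_neg / ratio_pos` times the positive count, emulating
#' class-ratio experiment designs such as 1:1, 1:5 and 1:10.
#'
#' @param records Peptide record data frame.
#' @param ratio_pos,ratio_neg Integers defining the target positive:negative
#'   ratio.
#' @param seed Integer RNG seed.
#' @return A peptide record data frame (positives first, then the sampled
#'   negatives).
#' @export
subsample_ratio <- function(records, ratio_pos = 1L, ratio_neg = 1L, seed = 1L) {
  stopifnot(ratio_pos >= 1L, ratio_neg >= 1L)
  pos <- records[records$label == 0L, , drop = FALSE]
  neg <- records[records$label == 1L, , drop = FALSE]
  target <- nrow(pos) * ratio_neg / ratio_pos
  if (target != floor(target)) {
    warning("implied negative count ", target, " is not an integer; rounding down")
    target <- floor(target)
  }
  target <- as.integer(target)
  if (nrow(neg) < target) {
    stop("need ", target, " negatives for a ", ratio_pos, ":", ratio_neg,
         " ratio but only ", nrow(neg), " are available", call. = FALSE)
  }
  keep <- withr_seed(seed, sample(nrow(neg), target))
  out <- rbind(pos, neg[sort(keep), , drop = FALSE])
  rownames(out) <- NULL
  out
}
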