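test_that("FASTA reading attaches labels, uppercases and preserves order", {
  f <- withr_tempfile(c(">p1", "flpk", ">p2", "ACDY"))
  rec <- read_fasta(f, 0L)
  expect_equal(rec$id, c("p1", "p2"))
  expect_equal(rec$sequence, c("FLPK", "ACDY"))
  expect_equal(rec$label, c(0L, 0L))
})

test_that("FASTA edge cases: empty file, bad residues, malformed input", {
  empty <- withr_tempfile(character(0))
  expect_equal(nrow(read_fasta(empty, 1L)), 0L)

  bad <- withr_tempfile(c(">x", "FLB"))
  expect_error(read_fasta(bad, 0L), "'x'.*'B'|'B'.*'x'")
  expect_equal(nrow(read_fasta(bad, 0L, drop_invalid = TRUE)), 0L)

  notfasta <- withr_tempfile(c("FLPK", "ACDY"))
  expect_error(read_fasta(notfasta, 0L), "malformed FASTA at line 1")
})

test_that("FASTA round-trip reproduces sequences and order exactly", {
  rec <- tiny_records()
  f <- tempfile(fileext = ".fasta")
  on.exit(unlink(f))
  write_fasta(rec, f)
  back <- read_fasta(f, 0L)
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
})

test_that("manifest reading parses rows and rejects bad labels", {
  f <- withr_tempfile(c("id\tsequence\tlabel", "p1\tFLPK\t0", "p2\tACDY\t1"))
  rec <- read_manifest(f)
  expect_equal(rec$id, c("p1", "p2"))
  expect_equal(rec$label, c(0L, 1L))

  hdr <- withr_tempfile("id\tsequence\tlabel")
  expect_equal(nrow(read_manifest(hdr)), 0L)

  bad <- withr_tempfile(c("id\tsequence\tlabel", "p1\tFLPK\t2"))
  expect_error(read_manifest(bad), "label")

  rt <- tempfile()
  on.exit(unlink(rt))
  write_manifest(rec, rt)
  expect_equal(read_manifest(rt), rec)
})

test_that("TU layout: path edges, indicator indexing, lossless round-trip", {
  enc <- encoder_config(use_node2vec = FALSE)
  g3 <- build_graph(list(id = "a", sequence = "FLP", label = 0L), enc)
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  write_graph_dataset(list(g3), d, name = "T")
  edges <- read.table(file.path(d, "T_A.txt"), sep = ",")
  expect_equal(nrow(edges), 4L)  # 2 undirected edges of a 3-node path
  expect_setequal(paste(edges$V1, edges$V2),
                  c("1 2", "2 1", "2 3", "3 2"))
  expect_equal(readLines(file.path(d, "T_graph_indicator.txt")),
               c("1", "1", "1"))

  two <- lapply(list(c("FL", 0L), c("KY", 1L)), function(x) {
    build_graph(list(id = "x", sequence = x[[1]], label = as.integer(x[[2]])), enc)
  })
  d2 <- tempfile()
  on.exit(unlink(d2, recursive = TRUE), add = TRUE)
  write_graph_dataset(two, d2, name = "T")
  expect_equal(readLines(file.path(d2, "T_graph_indicator.txt")),
               c("1", "1", "2", "2"))
  e2 <- read.table(file.path(d2, "T_A.txt"), sep = ",")
  expect_setequal(paste(e2$V1, e2$V2), c("1 2", "2 1", "3 4", "4 3"))

  back <- read_graph_dataset(d2, name = "T")
  for (i in 1:2) {
    expect_equal(back[[i]]$A, two[[i]]$A)
    expect_true(isSymmetric(back[[i]]$A))
    expect_equal(back[[i]]$node_labels, two[[i]]$node_labels)
    expect_equal(back[[i]]$X, two[[i]]$X)
    expect_equal(back[[i]]$graph_label, two[[i]]$graph_label)
  }
})

test_that("TU writing rejects attribute-width mismatches", {
  enc1 <- encoder_config(use_node2vec = FALSE)
  enc2 <- encoder_config(use_node2vec = FALSE, use_ctd21 = FALSE)
  g1 <- build_graph(list(id = "a", sequence = "FLP", label = 0L), enc1)
  g2 <- build_graph(list(id = "b", sequence = "KYA", label = 1L), enc2)
  expect_error(write_graph_dataset(list(g1, g2), tempfile()), "width")
})

test_that("fold assignment is a balanced stratified partition", {
  rec <- generate(synth_config(5, 5, length_range = c(10, 12), seed = 2))
  fs <- make_folds(rec, k = 5, seed = 9)
  expect_equal(sort(unique(fs$assignments)), 1:5)
  for (f in 1:5) {
    idx <- which(fs$assignments == f)
    expect_length(idx, 2L)
    expect_equal(sum(rec$label[idx] == 0L), 1L)  # forced stratification
  }
  expect_equal(make_folds(rec, k = 5, seed = 9)$assignments, fs$assignments)

  # balanced 250/250 set: every fold gets exactly 25 per class
  rec500 <- generate(synth_config(250, 250, length_range = c(10, 12), seed = 3))
  fs10 <- make_folds(rec500, k = 10, seed = 1)
  for (f in 1:10) {
    idx <- which(fs10$assignments == f)
    expect_equal(sum(rec500$label[idx] == 0L), 25L)
    expect_equal(sum(rec500$label[idx] == 1L), 25L)
  }
})

test_that("fold sizes and class counts stay within one for awkward n", {
  rec <- generate(synth_config(11, 13, length_range = c(10, 12), seed = 4))
  fs <- make_folds(rec, k = 10, seed = 7)
  sizes <- tabulate(fs$assignments, 10)
  expect_lte(diff(range(sizes)), 1L)
  pos_counts <- sapply(1:10, function(f) sum(rec$label[fs$assignments == f] == 0L))
  expect_lte(diff(range(pos_counts)), 1L)
  expect_error(make_folds(rec, k = 12), "minority")
})

test_that("ratio subsampling keeps positives and hits the target count", {
  rec <- generate(synth_config(20, 120, length_range = c(10, 12), seed = 5))
  sub <- subsample_ratio(rec, 1L, 5L, seed = 3)
  expect_equal(sum(sub$label == 0L), 20L)
  expect_equal(sum(sub$label == 1L), 100L)
  expect_true(all(sub$id[sub$label == 0L] %in% rec$id[rec$label == 0L]))
  expect_equal(subsample_ratio(rec, 1L, 5L, seed = 3), sub)  # deterministic

  bal <- generate(synth_config(10, 10, length_range = c(10, 12), seed = 6))
  expect_setequal(subsample_ratio(bal, 1L, 1L, seed = 1)$id, bal$id)

  small <- generate(synth_config(25, 10, length_range = c(10, 12), seed = 7))
  expect_error(subsample_ratio(small, 1L, 10L), "negatives")
})
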