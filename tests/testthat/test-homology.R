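# small synthetic segment tables for matrix tests
segments_from <- function(seqs, kinds = NULL, locus_id = 1L) {
  n <- length(seqs)
  kinds <- kinds %||% rep("IGR", n)
  labels <- ifelse(kinds == "IGR",
                   paste0("IGR", cumsum(kinds == "IGR")), kinds)
  data.frame(locus_id = locus_id, kind = kinds, label = labels,
             start = 0L, end = nchar(seqs), sequence = seqs,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical intergenic regions score 100 off-diagonal", {
  set.seed(61)
  x <- random_seq(400)
  seg <- segments_from(c(x, x))
  pm <- pairwise_pid_matrix(seg)
  expect_equal(pm$pid["IGR1", "IGR2"], 100)
  expect_true(all(diag(pm$pid) == 100))
})

test_that("matrices are symmetric with unit diagonal on simulated loci", {
  rl <- simulate_recency_locus(drift = 0.1, igr_length = 300, seed = 5)
  loci <- call_loci(rl$sim$genes, rl$sim$genes$gene_id, rl$sim$contigs)
  seg <- segment_locus(loci[[1]], rl$sim$contigs)
  pm <- pairwise_pid_matrix(seg)
  expect_identical(pm$pid, t(pm$pid))
  expect_true(all(diag(pm$pid) == 100))
  expect_true(all(pm$pid >= 0 & pm$pid <= 100))
})

test_that("random same-length segments stay below the null tail", {
  set.seed(67)
  seqs <- vapply(1:4, function(i) random_seq(500), "")
  pm <- pairwise_pid_matrix(segments_from(seqs))
  null <- shuffle_null(seqs[1], seqs[2], n_shuffles = 100, seed = 3)
  hi <- quantile(null, 0.99, names = FALSE)
  off <- pm$pid[upper.tri(pm$pid)]
  expect_true(all(off <= hi + 5))  # random pairs behave like the null
})

test_that("pairwise matrix rejects degenerate input", {
  expect_error(pairwise_pid_matrix(segments_from("ACGTACGT")), "two")
  seg <- segments_from(c("ACGT", "ACGTT"))  # both under min_len
  expect_error(pairwise_pid_matrix(seg), "two")
})

test_that("shuffle null is deterministic under seed and below identity", {
  set.seed(79)
  a <- random_seq(300); b <- random_seq(300)
  n1 <- shuffle_null(a, b, n_shuffles = 30, seed = 9)
  n2 <- shuffle_null(a, b, n_shuffles = 30, seed = 9)
  expect_identical(n1, n2)
  expect_true(mean(n1) < 100)
  # a true homolog at zero drift exceeds every null value
  obs <- align_overlap(a, a)$pid3
  expect_true(all(shuffle_null(a, a, 100, seed = 2) < obs))
})

test_that("zero-drift junctions are flagged recent, saturated ones not", {
  for (case in list(list(drift = 0, recent = TRUE),
                    list(drift = 1.0, recent = FALSE))) {
    rl <- simulate_recency_locus(drift = case$drift, igr_length = 500,
                                 seed = 17)
    loci <- call_loci(rl$sim$genes, rl$sim$genes$gene_id, rl$sim$contigs)
    seg <- segment_locus(loci[[1]], rl$sim$contigs)
    pm <- pairwise_pid_matrix(seg)
    rc <- call_recent_duplications(pm, seg, seed = 23)
    expect_equal(nrow(rc), 1)
    expect_equal(rc$is_recent, case$recent,
                 info = paste("drift", case$drift))
  }
})

test_that("a mixed locus flags exactly its recent junction", {
  fg <- simulate_family_genome(seed = 3)
  loci <- call_loci(fg$sim$genes, fg$sim$genes$gene_id, fg$sim$contigs)
  seg <- segment_locus(loci[[1]], fg$sim$contigs)
  pm <- pairwise_pid_matrix(seg)
  rc <- call_recent_duplications(pm, seg, seed = 29)
  expect_equal(nrow(rc), 2)
  flagged <- rc[rc$is_recent, c("igr_a", "igr_b")]
  expect_equal(unname(unlist(flagged)), fg$truth$recent_junctions[[1]])
})

test_that("recency calls are invariant to reversing locus orientation", {
  fg <- simulate_family_genome(seed = 31)
  loci <- call_loci(fg$sim$genes, fg$sim$genes$gene_id, fg$sim$contigs)
  seg <- segment_locus(loci[[1]], fg$sim$contigs)
  pm <- pairwise_pid_matrix(seg)
  rc <- call_recent_duplications(pm, seg, seed = 37)

  # reverse-complement the locus: segments in reverse order, IGR labels
  # renumbered symmetrically
  rev_seg <- seg[rev(seq_len(nrow(seg))), ]
  rev_seg$sequence <- vapply(rev_seg$sequence, revcomp, "",
                             USE.NAMES = FALSE)
  n_igr <- sum(seg$kind == "IGR")
  relabel <- function(lbl) {
    k <- as.integer(sub("IGR", "", lbl))
    paste0("IGR", n_igr - k + 1L)
  }
  rev_seg$label[rev_seg$kind == "IGR"] <-
    vapply(rev_seg$label[rev_seg$kind == "IGR"], relabel, "")
  pm2 <- pairwise_pid_matrix(rev_seg)
  rc2 <- call_recent_duplications(pm2, rev_seg, seed = 37)
  # junction flags correspond under the symmetric relabeling
  expect_equal(sort(paste(relabel(rc$igr_b), relabel(rc$igr_a))[
    rc$is_recent]),
    sort(paste(rc2$igr_a, rc2$igr_b)[rc2$is_recent]))
})

test_that("tiny intergenic regions are reported as not assessable", {
  set.seed(83)
  x <- random_seq(400)
  seg <- data.frame(
    locus_id = 1L, kind = c("GENE", "IGR", "GENE", "IGR", "GENE"),
    label = c("G1", "IGR1", "G2", "IGR2", "G3"), start = 0L, end = 1L,
    sequence = c(random_seq(100), "ACGT", random_seq(100), x,
                 random_seq(100)),
    stringsAsFactors = FALSE)
  pm <- pairwise_pid_matrix(seg)
  expect_true("IGR1" %in% pm$excluded)
  rc <- call_recent_duplications(pm, seg, seed = 41)
  expect_false(rc$assessable[1])
  expect_true(is.na(rc$is_recent[1]))
})

test_that("matrix TSV export round-trips values and the diagonal mask", {
  set.seed(89)
  seg <- segments_from(c(random_seq(200), random_seq(200),
                         random_seq(200)))
  pm <- pairwise_pid_matrix(seg)
  path <- tempfile(fileext = ".tsv")
  export_pid_matrix(pm, path)
  back <- read_pid_matrix(path)
  expect_equal(back$pid, pm$pid, tolerance = 1e-9)
  expect_equal(back$self_mask, pm$self_mask, ignore_attr = TRUE)
  pd <- pid_matrix_plot_data(pm)
  expect_true(all(is.na(pd$label[pd$row == pd$col])))
  expect_equal(pd$pid3[pd$row == "IGR1" & pd$col == "IGR2"],
               pm$pid["IGR1", "IGR2"])
})
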