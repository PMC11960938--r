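# toy two-contig genome with three genes, written and re-read through the
# real FASTA/GFF3 readers
toy_inputs <- function(dir = tempfile()) {
  dir.create(dir)
  set.seed(71)
  genome <- c(chrA = random_seq(30000), chrB = random_seq(12000))
  genes <- data.frame(
    gene_id = c("a1", "a2", "b1"),
    contig = c("chrA", "chrA", "chrB"),
    start = c(1000L, 4000L, 2000L),
    end = c(2000L, 5500L, 3500L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  fa <- file.path(dir, "g.fasta"); gff <- file.path(dir, "g.gff3")
  write_genome(genome, fa)
  write_gene_annotations(genes, gff)
  list(genome = genome, genes = genes, fa = fa, gff = gff)
}

test_that("FASTA and GFF3 round-trip preserves genes and coordinates", {
  ti <- toy_inputs()
  g2 <- read_genome(ti$fa)
  expect_identical(g2, ti$genome)
  genes2 <- read_gene_annotations(ti$gff)
  expect_equal(nrow(genes2), 3)
  rownames(genes2) <- NULL
  expect_identical(genes2[order(genes2$gene_id), ],
                   ti$genes[order(ti$genes$gene_id), ])
  # minus-strand gene keeps ascending coordinates
  b1 <- genes2[genes2$gene_id == "b1", ]
  expect_identical(b1$strand, "-")
  expect_true(b1$start < b1$end)
})

test_that("a gene outside its contig is rejected by name", {
  ti <- toy_inputs()
  bad <- rbind(ti$genes, data.frame(gene_id = "zz", contig = "chrB",
                                    start = 11000L, end = 13000L,
                                    strand = "+"))
  expect_error(check_genes_in_genome(bad, ti$genome), "zz")
  expect_error(check_genes_in_genome(bad, ti$genome), "chrB")
  bad2 <- ti$genes; bad2$contig[1] <- "chrC"
  expect_error(check_genes_in_genome(bad2, ti$genome), "chrC")
})

test_that("locus calling merges within max_gap and splits beyond it", {
  ti <- toy_inputs()
  # a1-a2 gap is 2 kb (< 20 kb) -> one locus; chrB gene is its own locus
  loci <- call_loci(ti$genes, c("a1", "a2", "b1"), ti$genome)
  df <- as.data.frame(loci)
  expect_equal(nrow(df), 2)
  expect_equal(df$n_genes[df$contig == "chrA"], 2)
  # with max_gap 1 kb the chrA pair splits
  loci2 <- call_loci(ti$genes, c("a1", "a2", "b1"), ti$genome,
                     max_gap = 1000)
  expect_equal(length(loci2), 3)
  expect_error(call_loci(ti$genes, c("a1", "nope"), ti$genome), "nope")
})

test_that("locus numbering follows contig size then position", {
  ti <- toy_inputs()
  loci <- call_loci(ti$genes, c("a1", "a2", "b1"), ti$genome)
  # chrA (30 kb) outranks chrB (12 kb)
  expect_equal(vapply(loci, function(l) l$contig, ""), c("chrA", "chrB"))
  expect_equal(vapply(loci, function(l) l$id, 1L), 1:2)
})

test_that("locus calling is invariant to gene order and contig renaming", {
  ti <- toy_inputs()
  base <- as.data.frame(call_loci(ti$genes, ti$genes$gene_id, ti$genome))
  shuf <- ti$genes[c(3, 1, 2), ]
  expect_identical(as.data.frame(call_loci(shuf, ti$genes$gene_id,
                                           ti$genome)), base)
  ren <- ti$genes
  ren$contig <- sub("chr", "scaffold_", ren$contig)
  genome2 <- setNames(ti$genome, sub("chr", "scaffold_",
                                     names(ti$genome)))
  ren_df <- as.data.frame(call_loci(ren, ren$gene_id, genome2))
  expect_identical(ren_df[, c("start", "end", "n_genes")],
                   base[, c("start", "end", "n_genes")])
})

test_that("segments tile the extended locus span exactly once", {
  ti <- toy_inputs()
  loci <- call_loci(ti$genes, c("a1", "a2"), ti$genome)
  seg <- segment_locus(loci[[1]], ti$genome)
  expect_identical(seg$label, c("LF", "G1", "IGR1", "G2", "RF"))
  expect_identical(seg$kind, c("LF", "GENE", "IGR", "GENE", "RF"))
  # contiguous tiling
  expect_identical(seg$start[-1], seg$end[-nrow(seg)])
  expect_equal(seg$start[1], 0)  # span start 1000 - flank 2500, clipped
  expect_equal(sum(nchar(seg$sequence)), seg$end[nrow(seg)] - seg$start[1])
  # sequences come from the contig
  expect_identical(seg$sequence[2], substr(ti$genome[["chrA"]], 1001, 2000))
})

test_that("flanks truncate at contig ends", {
  set.seed(73)
  genome <- c(c1 = random_seq(6000))
  genes <- data.frame(gene_id = "x", contig = "c1", start = 1000L,
                      end = 2000L, strand = "+")
  loci <- call_loci(genes, "x", genome)
  seg <- segment_locus(loci[[1]], genome)
  expect_equal(seg$end[1] - seg$start[1], 1000)  # LF clipped to contig
  expect_equal(seg$end[nrow(seg)], 4500)         # RF full 2.5 kb
})

test_that("orientation classification separates tandem arrangements", {
  genes <- data.frame(
    gene_id = c("f1", "f2", "f3", "x1"),
    contig = "c", start = c(100L, 500L, 900L, 600L),
    end = c(300L, 700L, 1100L, 650L), strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  loci <- call_loci(genes, c("f1", "f2", "f3"), max_gap = 1000)
  o <- classify_orientation(loci[[1]], genes, c("f1", "f2", "f3"))
  expect_equal(o$orientation, "unidirectional_head_to_tail")
  expect_true(o$has_intervening_genes)   # x1 sits inside the span

  genes2 <- genes[1:2, ]; genes2$strand <- c("+", "-")
  loci2 <- call_loci(genes2, c("f1", "f2"), max_gap = 1000)
  o2 <- classify_orientation(loci2[[1]], genes2, c("f1", "f2"))
  expect_equal(o2$orientation, "mixed")
  expect_false(o2$has_intervening_genes)

  o3 <- classify_orientation(call_loci(genes, "f1")[[1]], genes, "f1")
  expect_true(is.na(o3$orientation))
})

test_that("simulated genomes yield the planted loci and orientations", {
  for (s in c(2, 9)) {
    fg <- simulate_family_genome(seed = s)
    sim <- fg$sim
    loci <- call_loci(sim$genes, sim$genes$gene_id, sim$contigs)
    df <- as.data.frame(loci)
    expect_equal(df$contig, fg$truth$loci$contig)
    got_ids <- vapply(loci, function(l)
      paste(l$genes$gene_id, collapse = ","), "")
    expect_equal(got_ids, fg$truth$loci$gene_ids)
    census <- orientation_census(loci, sim$genes, sim$genes$gene_id)
    expect_equal(census$orientation[1], "unidirectional_head_to_tail")
    expect_false(any(census$has_intervening_genes))
  }
})
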