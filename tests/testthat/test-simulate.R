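test_that("the ancestral genome is deterministic with an SP-C-A gene", {
  s1 <- make_ancestral_genome(sim_config(seed = 5))
  s2 <- make_ancestral_genome(sim_config(seed = 5))
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$genes, s2$genes)
  s3 <- make_ancestral_genome(sim_config(seed = 6))
  expect_false(identical(s1$contigs, s3$contigs))

  expect_equal(nrow(s1$genes), 1)
  expect_equal(s1$domains$kind, c("SP", "C", "A"))
  # CDS length divisible by 3 and translates cleanly
  expect_equal(nchar(gene_cds(s1, "g1")) %% 3, 0)
  expect_true(audit_catalytic_motifs(domain_seq(s1, "g1", "A"))$intact)
  expect_equal(count_tarp_repeats(gene_protein(s1, "g1")), 9)
})

test_that("telomere planting caps the main contig", {
  s <- make_ancestral_genome(sim_config(seed = 5, telomeres = TRUE))
  rep <- find_telomeric_ends(s$contigs)
  expect_true(rep$telomere_at_5prime[rep$contig == "ctg1"])
  expect_true(rep$telomere_at_3prime[rep$contig == "ctg1"])
})

test_that("unequal crossover duplicates gene plus downstream region", {
  s <- make_ancestral_genome(sim_config(seed = 21,
                                        extra_contigs = integer(0)))
  s2 <- apply_unequal_crossover(s, "g1")
  expect_equal(nrow(s2$genes), 2)
  g <- s2$genes[order(s2$genes$start), ]
  # the copy is identical to the template
  expect_identical(gene_cds(s2, g$gene_id[1]), gene_cds(s2, g$gene_id[2]))
  # the junction intergenic region equals the duplicated template:
  # the sequence after the second gene starts with the same igr_length bp
  igr_len <- s$config$igr_length
  ctg <- s2$contigs[["ctg1"]]
  igr1 <- substr(ctg, g$end[1] + 1, g$end[1] + igr_len)
  tmpl <- substr(ctg, g$end[2] + 1, g$end[2] + igr_len)
  expect_identical(igr1, tmpl)
  # genome grew by exactly one unit
  expect_equal(nchar(ctg), nchar(s$contigs[["ctg1"]]) +
                 (g$end[1] - g$start[1]) + igr_len)
})

test_that("repeated crossovers yield n genes and n-1 intergenic regions", {
  s <- make_ancestral_genome(sim_config(seed = 23,
                                        extra_contigs = integer(0)))
  for (i in 1:3) {
    s <- apply_unequal_crossover(s, s$genes$gene_id[nrow(s$genes)])
  }
  loci <- call_loci(s$genes, s$genes$gene_id, s$contigs)
  seg <- segment_locus(loci[[1]], s$contigs)
  expect_equal(sum(seg$kind == "GENE"), 4)
  expect_equal(sum(seg$kind == "IGR"), 3)
  expect_identical(seg$start[-1], seg$end[-nrow(seg)])  # tiling holds
  # zero-drift copies: every consecutive junction is identical
  igr <- seg$sequence[seg$kind == "IGR"]
  expect_equal(length(unique(igr)), 1)
})

test_that("transposed copies land unlinked and initially identical", {
  s <- make_ancestral_genome(sim_config(seed = 25))
  s <- apply_transposition(s, "g1", "ctg2", 4000L)
  new_id <- s$events[[length(s$events)]]$copies
  expect_identical(gene_cds(s, "g1"), gene_cds(s, new_id))
  loci <- call_loci(s$genes, s$genes$gene_id, s$contigs)
  df <- as.data.frame(loci)
  expect_equal(nrow(df), 2)
  expect_true(loci_unlinked(loci[[1]], loci[[2]]))
})

test_that("Jukes-Cantor drift matches its substitution probability", {
  x <- strrep("ACGT", 2500)  # L = 10,000
  expect_identical(mutate_jc(x, 0, seed = 1), x)
  for (t in c(0.1, 0.5)) {
    p <- 0.75 * (1 - exp(-4 * t / 3))
    diffs <- vapply(1:8, function(s) {
      y <- mutate_jc(x, t, seed = s)
      mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, numeric(1))
    sd3 <- 3 * sqrt(p * (1 - p) / 10000)
    expect_true(all(abs(diffs - p) < sd3 + 3 * sd3 / sqrt(8)))
    expect_true(abs(mean(diffs) - p) < sd3)
  }
})

test_that("drift composes along time (Chapman-Kolmogorov)", {
  x <- strrep("ACGT", 5000)  # L = 20,000
  t1 <- 0.2; t2 <- 0.3
  y <- mutate_jc(mutate_jc(x, t1, seed = 31), t2, seed = 32)
  p_tot <- 0.75 * (1 - exp(-4 * (t1 + t2) / 3))
  obs <- mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  expect_true(abs(obs - p_tot) < 4 * sqrt(p_tot * (1 - p_tot) / 20000))
})

test_that("domain events rewrite architectures as planted", {
  s <- make_ancestral_genome(sim_config(seed = 33))
  as_hits <- function(sim) structure(sim$domains,
                                     class = c("domain_hits",
                                               "data.frame"))
  # C loss alone -> A_only subfamily of CA
  s1 <- plant_domain_event(s, "g1", "domain_loss", kind = "C")
  fc <- classify_family(as_hits(s1)[as_hits(s1)$gene_id == "g1", ])
  expect_equal(fc$family, "CA")
  expect_equal(fc$subfamily, "A_only")
  # TMD gain on top -> AnTMD
  s2 <- plant_domain_event(s1, "g1", "tmd_gain")
  fc2 <- classify_family(as_hits(s2)[as_hits(s2)$gene_id == "g1", ])
  expect_equal(fc2$family, "AnTMD")
  # the planted 15-bp insertion is recovered against the ancestor
  s3 <- plant_domain_event(s, "g1", "insertion_15bp", aa_offset = 80L)
  call <- detect_insertion(domain_seq(s3, "g1", "A", what = "nt"),
                           domain_seq(s, "g1", "A", what = "nt"))
  expect_true(call$has_insertion)
  expect_equal(call$insertion_length, 15)
  expect_equal(call$position, 240)
  # coding frame stays intact after every event
  expect_equal(nchar(gene_cds(s3, "g1")) %% 3, 0)
  expect_true(audit_catalytic_motifs(domain_seq(s3, "g1", "A"))$intact)
})

test_that("emitted files re-parse to the in-memory state", {
  fg <- simulate_family_genome(seed = 13)
  dir <- tempfile()
  paths <- emit_simulation(fg$sim, dir, tree = fg$truth$tree,
                           leaf_map = fg$truth$leaf_map,
                           truth = list(families = as.list(
                             fg$truth$families)))
  genome <- read_genome(paths[["genome"]])
  expect_identical(genome, fg$sim$contigs)
  genes <- read_gene_annotations(paths[["genes"]])
  rownames(genes) <- NULL
  expect_identical(
    genes[order(genes$contig, genes$start),
          c("gene_id", "contig", "start", "end", "strand")],
    fg$sim$genes[, c("gene_id", "contig", "start", "end", "strand")])
  doms <- read_domain_tsv(paths[["domains"]])
  expect_equal(nrow(doms), nrow(fg$sim$domains))
  truth <- read_truth_log(paths[["truth"]])
  expect_equal(truth$seed, 13)
  expect_equal(truth$truth$families$g5, "AnTMD")
  lm <- read_leaf_map(paths[["leaf_map"]])
  expect_equal(lm, fg$truth$leaf_map)

  # GFF3 on disk is 1-based inclusive
  raw <- readLines(paths[["genes"]])
  row1 <- strsplit(grep("\tgene\t", raw, value = TRUE)[1], "\t")[[1]]
  g1 <- fg$sim$genes[1, ]
  expect_equal(as.integer(row1[4]), g1$start + 1L)
  expect_equal(as.integer(row1[5]), g1$end)
})

test_that("emission is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- simulate_family_genome(seed = 19)
  f2 <- simulate_family_genome(seed = 19)
  emit_simulation(f1$sim, d1, tree = f1$truth$tree,
                  leaf_map = f1$truth$leaf_map)
  emit_simulation(f2$sim, d2, tree = f2$truth$tree,
                  leaf_map = f2$truth$leaf_map)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("simulated support trees cover every leaf and stay parseable", {
  st <- simulate_support_tree(seed = 3)
  expect_setequal(st$tree$tip.label, st$leaf_map$leaf)
  p <- tempfile(); writeLines(st$newick, p)
  tr <- read_support_tree(p)
  expect_setequal(tr$tip.label, st$leaf_map$leaf)
  expect_true(100L %in% tr$support)
})
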