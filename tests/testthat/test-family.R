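# build a hmmscan domtblout line (22 columns + description)
dom_line <- function(target, query, ievalue, from, to) {
  paste(target, "-", 300, query, "-", 500, "1e-50", 100, 0.1, 1, 1,
        "1e-40", ievalue, 90, 0.1, 1, 280, from, to, from, to, 0.9,
        "description here", sep = " ")
}

write_domtblout <- function(lines, path = tempfile()) {
  writeLines(c("#                 --- full sequence ---", lines,
               "# program ended"), path)
  path
}

hits_df <- function(kinds, starts, ends, gene = "g",
                    i_evalue = 1e-20) {
  data.frame(gene_id = gene, domain = kinds, kind = kinds,
             start = starts, end = ends, i_evalue = i_evalue,
             stringsAsFactors = FALSE)
}

test_that("domtblout parsing filters on i-evalue and orders domains", {
  p <- write_domtblout(c(
    dom_line("PL7", "gene1", "1e-20", 200, 400),
    dom_line("CBM32", "gene1", "1e-15", 30, 150),
    dom_line("PL7", "gene2", "5e-3", 10, 200)))
  hits <- read_domtblout(p)
  expect_equal(nrow(hits), 2)          # the 5e-3 hit is filtered
  g1 <- hits[hits$gene_id == "gene1", ]
  expect_equal(g1$kind, c("C", "A"))   # sorted by protein start
  expect_equal(g1$order_index, c(1, 1))

  # two A hits + one C hit get indices A1, A2, C1 by position
  p2 <- write_domtblout(c(
    dom_line("PL7", "g", "1e-30", 100, 300),
    dom_line("PL7", "g", "1e-25", 350, 550),
    dom_line("CBM32", "g", "1e-22", 10, 90)))
  h2 <- read_domtblout(p2)
  expect_equal(paste0(h2$kind, h2$order_index), c("C1", "A1", "A2"))
})

test_that("malformed domtblout lines are reported with their number", {
  p <- write_domtblout(c(dom_line("PL7", "g", "1e-20", 1, 100),
                         "only three fields here"))
  expect_error(read_domtblout(p), "line 2")
})

test_that("overlapping hits resolve to the hand-worked set", {
  # five hits on one protein; hand resolution keeps, in i-evalue order:
  # A@100-300 (1e-40); C@10-90 (1e-30); A@320-500 (1e-25);
  # drops A@150-350 (overlaps kept A@100-300 by 151/201 > 50%)
  # and C@50-120 (overlaps kept C@10-90 by 41/71 > 50%)
  p <- write_domtblout(c(
    dom_line("PL7", "g", "1e-40", 100, 300),
    dom_line("PL7", "g", "1e-10", 150, 350),
    dom_line("CBM32", "g", "1e-30", 10, 90),
    dom_line("CBM32", "g", "1e-08", 50, 120),
    dom_line("PL7", "g", "1e-25", 320, 500)))
  h <- read_domtblout(p)
  expect_equal(nrow(h), 3)
  expect_equal(h$start, c(10, 100, 320))
  expect_equal(h$kind, c("C", "A", "A"))
})

test_that("TSV fallback matches the domtblout reader", {
  p <- tempfile()
  writeLines(c("gene_id\tkind\tstart\tend\ti_evalue",
               "g1\tC\t21\t140\t1e-20",
               "g1\tA\t183\t382\t1e-20",
               "g1\tSP\t1\t20\t1e-20"), p)
  h <- read_domain_tsv(p)
  expect_equal(h$kind, c("SP", "C", "A"))
  expect_equal(h$order_index, c(1, 1, 1))
})

test_that("the three worked architectures classify to their families", {
  # single C + A preceded by a signal peptide: the ancestral CA layout
  ca <- classify_family(hits_df(c("SP", "C", "A"), c(1, 30, 200),
                                c(25, 180, 420)))
  expect_equal(ca$family, "CA")
  expect_equal(ca$subfamily, "none")

  # five alternating A/C units
  an_cn <- classify_family(hits_df(
    rep(c("A", "C"), 5), seq(1, by = 100, length.out = 10),
    seq(90, by = 100, length.out = 10)))
  expect_equal(an_cn$family, "AnCn")
  expect_equal(an_cn$n_A, 5)
  expect_equal(an_cn$n_C, 5)

  # three A-domains with a C-terminal TMD and no C-domain
  an_tmd <- classify_family(hits_df(c("A", "A", "A", "TMD"),
                                    c(1, 210, 420, 640),
                                    c(200, 410, 620, 661)))
  expect_equal(an_tmd$family, "AnTMD")
  expect_equal(an_tmd$n_A, 3)
})

test_that("CA subfamilies flag C duplication and C loss", {
  cca <- classify_family(hits_df(c("C", "C", "A"), c(1, 120, 260),
                                 c(110, 240, 460)))
  expect_equal(cca$family, "CA")
  expect_equal(cca$subfamily, "CCA")
  a_only <- classify_family(hits_df("A", 10, 210))
  expect_equal(a_only$family, "CA")
  expect_equal(a_only$subfamily, "A_only")
  none <- classify_family(hits_df(c("SP", "C"), c(1, 30), c(25, 180)))
  expect_true(is.na(none$family))
})

test_that("family rules are mutually exclusive and exhaustive", {
  set.seed(97)
  for (i in 1:200) {
    kinds <- sample(c("A", "C", "TMD", "SP"), sample(1:8, 1),
                    replace = TRUE)
    if (!"A" %in% kinds) kinds <- c(kinds, "A")
    starts <- cumsum(sample(50:200, length(kinds), replace = TRUE))
    fc <- classify_family(hits_df(kinds, starts, starts + 40))
    expect_true(fc$family %in% c("CA", "AnCn", "AnTMD"))
    # rule consistency
    if (fc$family == "AnTMD") expect_equal(fc$n_C, 0)
    if (fc$family == "AnCn") expect_true(fc$n_A >= 2 && fc$n_C >= 1)
    # architecture round-trips the hit order
    expect_equal(strsplit(fc$architecture, "-")[[1]], kinds)
  }
})

test_that("catalytic motif audit matches the three regions", {
  s <- paste0("MKL", "RAELR", "GGAW", "QIH", "PPL", "YFKAGAYAQ", "END")
  a <- audit_catalytic_motifs(s)
  expect_true(a$intact)
  b <- audit_catalytic_motifs(gsub("QIH", "NIH", s))
  expect_false(b$region_B)
  expect_false(b$intact)
  expect_true(audit_catalytic_motifs(gsub("RAELR", "RTEVR", s))$region_A)
  expect_false(audit_catalytic_motifs(gsub("RAELR", "KAELR", s))$region_A)
  expect_error(audit_catalytic_motifs("RAELR1"), "'1'")
})

test_that("insertion detection recovers planted in-frame insertions", {
  set.seed(101)
  ref <- random_seq(600)
  expect_false(detect_insertion(ref, ref)$has_insertion)

  ins15 <- paste0(substr(ref, 1, 300), "GGTACCGGTACCGGT",
                  substr(ref, 301, 600))
  call <- detect_insertion(ins15, ref)
  expect_true(call$has_insertion)
  expect_equal(call$insertion_length, 15)
  expect_equal(call$position, 300)

  # 7-bp indel: frame-breaking and below the default length
  ins7 <- paste0(substr(ref, 1, 300), "GGTACCG", substr(ref, 301, 600))
  expect_false(detect_insertion(ins7, ref)$has_insertion)
})

test_that("TARP repeats count non-overlapping consensus units", {
  expect_equal(count_tarp_repeats("TARPTPRPTSRPTVRP"), 4)
  expect_equal(count_tarp_repeats(""), 0)
  expect_equal(count_tarp_repeats("AAATARPAAATPRPAAA"), 2)
  expect_equal(count_tarp_repeats("TTRP"), 0)   # second position not APSV
  # nine tandem units, as in the longest natural linker blocks
  expect_equal(count_tarp_repeats(strrep("TARP", 9)), 9)
})

test_that("simulated genes classify to their planted architectures", {
  fg <- simulate_family_genome(seed = 11)
  hits <- structure(fg$sim$domains,
                    class = c("domain_hits", "data.frame"))
  fam <- classify_families(hits)
  expect_equal(setNames(fam$family, fam$gene_id), fg$truth$families)
  cen <- family_census(fam, orientation_census(
    call_loci(fg$sim$genes, fg$sim$genes$gene_id, fg$sim$contigs),
    fg$sim$genes, fg$sim$genes$gene_id))
  expect_equal(cen$n_family_genes, 6)
  expect_equal(cen$n_CA, 4)
  expect_equal(cen$n_loci, 3)
  expect_equal(cen$n_tandem_loci, 1)
  expect_equal(cen$n_unidirectional_no_intervening, 1)
})
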