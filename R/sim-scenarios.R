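# Canned simulation scenarios used throughout the test battery and the
# acceptance study.  Each is a deterministic function of its seed.

#' Simulate a tandem locus with one dated intergenic junction
#'
#' Builds a three-gene head-to-tail tandem locus whose two intergenic
#' regions start identical (they descend from the same duplication
#' template) and then lets each accumulate Jukes-Cantor drift for time
#' `drift` independently, so the pair diverges by `2 * drift`
#' substitutions per site in expectation.  This is the elementary unit of
#' the recency-calling study: a "recent" junction has small `drift`, an
#' "ancient" one large.
#'
#' @param drift drift time per copy since duplication (expected
#'   substitutions per site when `mu = 1`).
#' @param igr_length intergenic region length (default 800).
#' @param seed RNG seed.
#' @return list: `sim` (the `aly_sim`), `truth` (list with `junction`
#'   (`c("IGR1", "IGR2")`) and `drift_time`).
#' @export
simulate_recency_locus <- function(drift, igr_length = 800L, seed = 1L) {
  cfg <- sim_config(seed = seed, igr_length = igr_length,
                    extra_contigs = integer(0))
  sim <- make_ancestral_genome(cfg)
  sim <- apply_unequal_crossover(sim, "g1")
  sim <- apply_unequal_crossover(sim, "g2")
  g <- sim$genes
  igr_bounds <- cbind(g$end[1:2], g$start[2:3])
  for (k in 1:2) {
    sim <- mutate_region(sim, "ctg1", igr_bounds[k, 1], igr_bounds[k, 2],
                         t = drift, seed = child_seed(seed, k))
  }
  list(sim = sim,
       truth = list(junction = c("IGR1", "IGR2"), drift_time = drift))
}

#' Simulate a full gene-family genome with known history
#'
#' The default end-to-end scenario: a four-gene head-to-tail tandem locus
#' on the main contig with one recent junction (IGR1/IGR2) and one ancient
#' junction (IGR2/IGR3); the youngest gene transposed to two unlinked
#' contigs; domain events turning one dispersed copy into an AnTMD gene
#' (C loss, two A duplications, TMD gain, a 15-bp A-domain insertion) and
#' the other into an AnCn gene (A and C duplications); and a catalytic
#' motif knockout in one tandem gene.  Telomeric repeat blocks cap the
#' main contig.
#'
#' @param seed RNG seed.
#' @param recent_drift drift per copy for the recent junction (default
#'   0.01).
#' @param ancient_drift drift applied to the ancient junction's far
#'   intergenic region (default 1.0, saturating its homology to the
#'   recent pair).
#' @return list: `sim`, `truth` with elements `loci` (expected locus table
#'   after size-ordered numbering), `families` (gene_id -> family),
#'   `recent_junctions`, `ancient_junctions`, `transposed_loci` (locus id
#'   pair expected as a transposition event), `tree` (Newick string),
#'   `leaf_map`.
#' @export
simulate_family_genome <- function(seed = 1L, recent_drift = 0.01,
                                   ancient_drift = 1.0) {
  cfg <- sim_config(seed = seed, telomeres = TRUE,
                    extra_contigs = c(ctg2 = 9000L, ctg3 = 8000L))
  sim <- make_ancestral_genome(cfg)
  sim <- apply_unequal_crossover(sim, "g1")   # g2
  sim <- apply_unequal_crossover(sim, "g2")   # g3
  sim <- apply_unequal_crossover(sim, "g3")   # g4

  # junction drift: IGR1/IGR2 recent, IGR2/IGR3 ancient.  IGR2 drifts with
  # the recent clock; IGR1 matches it and IGR3 is saturated away from both.
  g <- sim$genes[order(sim$genes$start), ]
  igr <- cbind(g$end[1:3], g$start[2:4])
  sim <- mutate_region(sim, "ctg1", igr[1, 1], igr[1, 2], recent_drift,
                       child_seed(seed, 11))
  sim <- mutate_region(sim, "ctg1", igr[2, 1], igr[2, 2], recent_drift,
                       child_seed(seed, 12))
  sim <- mutate_region(sim, "ctg1", igr[3, 1], igr[3, 2], ancient_drift,
                       child_seed(seed, 13))

  # disperse the youngest gene to the two unlinked contigs
  sim <- apply_transposition(sim, "g4", "ctg2", 4000L)   # g5
  sim <- apply_transposition(sim, "g4", "ctg3", 4000L)   # g6

  # architecture evolution on the dispersed copies
  sim <- plant_domain_event(sim, "g5", "domain_loss", kind = "C")
  sim <- plant_domain_event(sim, "g5", "domain_duplication", kind = "A")
  sim <- plant_domain_event(sim, "g5", "domain_duplication", kind = "A")
  sim <- plant_domain_event(sim, "g5", "tmd_gain")
  sim <- plant_domain_event(sim, "g5", "insertion_15bp")
  sim <- plant_domain_event(sim, "g6", "domain_duplication", kind = "A")
  sim <- plant_domain_event(sim, "g6", "domain_duplication", kind = "C")
  sim <- plant_domain_event(sim, "g2", "motif_knockout", region = "B")

  # expected loci under size-descending contig ordering (main contig is
  # the largest)
  loci_truth <- data.frame(
    locus_id = 1:3,
    contig = c("ctg1", "ctg2", "ctg3"),
    gene_ids = c("g1,g2,g3,g4", "g5", "g6"),
    stringsAsFactors = FALSE)

  # A-domain tree: tandem genes as a ladder, the two dispersed copies of
  # g4 as a 100-support clade with their template
  leaf <- function(gid) {
    nA <- sum(sim$domains$gene_id == gid & sim$domains$kind == "A")
    paste0(gid, "_A", seq_len(nA))
  }
  tip <- function(x) paste0(x, ":0.05")
  clade_of <- function(leaves, support) {
    # left-fold a ladder, labelling every internal node with `support`
    s <- tip(leaves[1])
    for (k in seq_along(leaves)[-1]) {
      s <- paste0("(", s, ",", tip(leaves[k]), ")", support, ":0.05")
    }
    s
  }
  disp <- clade_of(c(leaf("g5"), leaf("g6")), 100)
  newick <- paste0("(", tip("g1_A1"), ",(", tip("g2_A1"), ",(",
                   tip("g3_A1"), ",(", tip("g4_A1"), ",", disp,
                   ")90:0.05)85:0.05)80:0.05);")
  leaves <- c("g1_A1", "g2_A1", "g3_A1", "g4_A1", leaf("g5"), leaf("g6"))
  locus_of_gene <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 1L, g5 = 2L,
                     g6 = 3L)
  leaf_map <- data.frame(
    leaf = leaves,
    gene_id = sub("_A\\d+$", "", leaves),
    domain_index = as.integer(sub("^.*_A", "", leaves)),
    locus_id = unname(locus_of_gene[sub("_A\\d+$", "", leaves)]),
    stringsAsFactors = FALSE)

  truth <- list(
    loci = loci_truth,
    families = c(g1 = "CA", g2 = "CA", g3 = "CA", g4 = "CA",
                 g5 = "AnTMD", g6 = "AnCn"),
    recent_junctions = list(c("IGR1", "IGR2")),
    ancient_junctions = list(c("IGR2", "IGR3")),
    transposed_loci = c(2L, 3L),
    motif_knockout = list(gene = "g2", region = "B"),
    insertion = list(gene = "g5", length = 15L),
    tree = newick,
    leaf_map = leaf_map)
  list(sim = sim, truth = truth)
}

#' Simulate a bootstrap support tree with planted transposition clades
#'
#' Generates an abstract domain phylogeny over several single-gene loci on
#' distinct contigs (hence pairwise unlinked): one planted cross-locus
#' clade with 100% bootstrap support, one decoy cross-locus clade at
#' support 80, and background leaves on a ladder with low supports.
#'
#' @param seed RNG seed.
#' @param n_loci number of loci (default 6; at least 5).
#' @return list: `tree` (a `phylo` with `support`), `newick`, `leaf_map`,
#'   `loci` (data frame), `truth` (list with `planted` and `decoy` locus id
#'   vectors).
#' @export
simulate_support_tree <- function(seed = 1L, n_loci = 6L) {
  stopifnot(n_loci >= 5L)
  with_seed(seed, {
    loci <- data.frame(locus_id = seq_len(n_loci),
                       contig = paste0("c", seq_len(n_loci)),
                       start = 0L, end = 2000L, stringsAsFactors = FALSE)
    picks <- sample(n_loci, 4L)
    planted <- sort(picks[1:2]); decoy <- sort(picks[3:4])
    n_leaves <- sample(2:3, n_loci, replace = TRUE)
    leaf_map <- do.call(rbind, lapply(seq_len(n_loci), function(l)
      data.frame(leaf = paste0("L", l, "g", seq_len(n_leaves[l])),
                 gene_id = paste0("L", l, "g", seq_len(n_leaves[l])),
                 domain_index = 1L, locus_id = l,
                 stringsAsFactors = FALSE)))

    tip <- function(x) paste0(x, ":0.1")
    ladder <- function(leaves, supports) {
      s <- tip(leaves[1])
      for (k in seq_along(leaves)[-1]) {
        s <- paste0("(", s, ",", tip(leaves[k]), ")", supports[k - 1],
                    ":0.1")
      }
      s
    }
    clade <- function(loci_ids, support) {
      lv <- leaf_map$leaf[leaf_map$locus_id %in% loci_ids]
      ladder(lv, rep(support, length(lv) - 1L))
    }
    bg <- leaf_map$leaf[!leaf_map$locus_id %in% c(planted, decoy)]
    bg_sup <- sample(10:70, max(1L, length(bg) - 1L), replace = TRUE)
    spine <- ladder(bg, bg_sup)
    newick <- paste0("((", clade(planted, 100), ",", clade(decoy, 80),
                     ")50:0.1,", spine, ");")
    tree <- tree_with_support(ape::read.tree(text = newick))
    list(tree = tree, newick = newick, leaf_map = leaf_map, loci = loci,
         truth = list(planted = planted, decoy = decoy))
  })
}
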