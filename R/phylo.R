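#' Read a Newick tree with integer bootstrap supports
#'
#' Internal node labels are parsed as integer bootstrap supports; labels
#' that are not integers become `NA`.
#'
#' @param path Newick file.
#' @return An `ape` `phylo` object with an extra `support` element (integer
#'   vector, one per internal node).
#' @export
read_support_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][1], call. = FALSE)
  tree_with_support(tr)
}

# attach the parsed support vector; tolerates missing labels as NA
tree_with_support <- function(tr) {
  lab <- tr$node.label
  if (is.null(lab)) lab <- rep(NA_character_, tr$Nnode)
  tr$support <- suppressWarnings(as.integer(lab))
  tr
}

#' Are two loci unlinked?
#'
#' Loci are unlinked when they lie on different contigs or are separated by
#' more than `min_unique_bp` of unique sequence on the same contig.  Genes
#' at unlinked loci cannot have arisen by local tandem expansion, so
#' supported monophyly across unlinked loci implicates transposition.
#'
#' @param locus_a,locus_b locus elements from [call_loci()], or rows of a
#'   loci data frame with `contig`, `start`, `end`.
#' @param min_unique_bp separation threshold in bp (default 10000).
#' @return logical.
#' @export
loci_unlinked <- function(locus_a, locus_b, min_unique_bp = 10000) {
  span <- function(l) {
    if (!is.null(l$span)) c(l$span[1], l$span[2]) else c(l$start, l$end)
  }
  if (locus_a$contig != locus_b$contig) return(TRUE)
  a <- span(locus_a); b <- span(locus_b)
  gap <- max(a[1], b[1]) - min(a[2], b[2])
  gap > min_unique_bp
}

#' Infer transposition-related locus sets from a support tree
#'
#' Reports maximal clades whose bootstrap support reaches `min_support`,
#' whose leaves span two or more pairwise-unlinked loci, and which contain
#' at least `min_locus_coverage` of each involved locus's domains.  Such
#' clades group genes that are closest relatives yet reside at loci that
#' tandem expansion alone cannot connect, the signature of dispersal by
#' transposition.  Unrooted trees are midpoint rooted first.
#'
#' @param tree a `phylo` from [read_support_tree()].
#' @param leaf_map data frame mapping each leaf: `leaf`, `gene_id`,
#'   `domain_index`, `locus_id`.
#' @param loci a `locus_set` from [call_loci()] or a data frame with
#'   `locus_id`, `contig`, `start`, `end`.
#' @param min_support minimum bootstrap support (default 100).
#' @param min_unique_bp unlinkedness threshold (default 10000).
#' @param min_locus_coverage minimum fraction of a locus's domains inside
#'   the clade for that locus to count as involved (default 0.5).
#' @return data frame of class `transposition_events`: one row per event
#'   with `node`, `support`, `loci` (comma-separated locus ids), `n_leaves`,
#'   `coverage` (comma-separated per-locus coverage fractions).
#' @export
infer_transpositions <- function(tree, leaf_map, loci,
                                 min_support = 100L,
                                 min_unique_bp = 10000,
                                 min_locus_coverage = 0.5) {
  unmapped <- setdiff(tree$tip.label, leaf_map$leaf)
  if (length(unmapped))
    stop("leaf not in leaf map: ", unmapped[1], call. = FALSE)

  if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree, node.labels = "support")
    tree <- tree_with_support(tree)
  }
  if (is.null(tree$support)) tree <- tree_with_support(tree)

  loci_df <- if (inherits(loci, "locus_set")) as.data.frame(loci) else loci
  loci_list <- split(loci_df, seq_len(nrow(loci_df)))
  names(loci_list) <- loci_df$locus_id
  locus_of <- setNames(leaf_map$locus_id, leaf_map$leaf)
  locus_sizes <- table(leaf_map$locus_id)

  ntip <- length(tree$tip.label)
  candidates <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    sup <- tree$support[node - ntip]
    if (is.na(sup) || sup < min_support) next
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    inv_loci <- unique(locus_of[tips])
    if (length(inv_loci) < 2L) next
    # all involved loci must be pairwise unlinked
    pairs <- utils::combn(as.character(inv_loci), 2)
    unlinked_all <- all(apply(pairs, 2, function(p)
      loci_unlinked(loci_list[[p[1]]], loci_list[[p[2]]], min_unique_bp)))
    if (!unlinked_all) next
    cov <- vapply(as.character(inv_loci), function(l)
      sum(locus_of[tips] == as.integer(l)) /
        as.numeric(locus_sizes[[l]]), numeric(1))
    if (any(cov < min_locus_coverage)) next
    candidates[[length(candidates) + 1L]] <- list(
      node = node, support = sup, tips = tips,
      loci = sort(as.integer(inv_loci)), coverage = cov)
  }

  # collapse nested qualifying clades into the maximal one
  if (length(candidates) > 1L) {
    keep <- rep(TRUE, length(candidates))
    for (i in seq_along(candidates)) {
      for (j in seq_along(candidates)) {
        if (i != j && keep[j] &&
            all(candidates[[i]]$tips %in% candidates[[j]]$tips) &&
            length(candidates[[i]]$tips) < length(candidates[[j]]$tips))
          keep[i] <- FALSE
      }
    }
    candidates <- candidates[keep]
  }

  out <- do.call(rbind, lapply(candidates, function(cd) data.frame(
    node = cd$node, support = cd$support,
    loci = paste(cd$loci, collapse = ","),
    n_leaves = length(cd$tips),
    coverage = paste(formatC(cd$coverage, format = "f", digits = 3),
                     collapse = ","),
    stringsAsFactors = FALSE
  )))
  if (is.null(out)) {
    out <- data.frame(node = integer(0), support = integer(0),
                      loci = character(0), n_leaves = integer(0),
                      coverage = character(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("transposition_events", "data.frame")
  out
}
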