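#' Assign a CAZyme family to one protein
#'
#' The family of the hit with the lowest independent domain E-value among
#' hits passing the stringent CAZyme cutoff; ties are broken
#' lexicographically for determinism.
#'
#' @param hits data frame of hits for one protein with `domain` (family
#'   label) and `i_evalue`.
#' @param i_evalue_max CAZyme cutoff (default 1e-10).
#' @return family label, or `NA_character_` when no hit survives.
#' @export
assign_cazyme_family <- function(hits, i_evalue_max = 1e-10) {
  h <- hits[hits$i_evalue < i_evalue_max, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  h <- h[order(h$i_evalue, h$domain), , drop = FALSE]
  h$domain[1]
}

#' Per-species CAZyme percentage profiles
#'
#' Converts per-species family counts into percentages of the species'
#' total CAZyme complement, the normalization used to compare CAZyme
#' repertoires across genomes of very different sizes.
#'
#' @param counts data frame with `species`, `family`, `count`, or a
#'   species x family count matrix.
#' @return A species x family numeric matrix whose rows each sum to 100.
#' @export
profile_percentages <- function(counts) {
  if (is.data.frame(counts)) {
    m <- tapply(counts$count, list(counts$species, counts$family), sum,
                default = 0)
  } else {
    m <- as.matrix(counts)
  }
  m[is.na(m)] <- 0
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("species with zero CAZyme counts: ",
         rownames(m)[totals == 0][1], call. = FALSE)
  sweep(m, 1, totals / 100, "/")
}

#' Bray-Curtis dissimilarity between two profile rows
#'
#' `sum(|x - y|) / sum(x + y)`, in \[0, 1\] for non-negative profiles.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Cluster profile rows for heatmap display
#'
#' Average-linkage (UPGMA) agglomeration on Bray-Curtis dissimilarities,
#' the conventional pairing for CAZyme profile heatmaps.
#'
#' @param mat species x family profile matrix.
#' @param method linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return list with `order` (row labels in display order) and `hclust`
#'   (the dendrogram object).
#' @export
cluster_profiles <- function(mat, method = "average") {
  d <- vegan::vegdist(mat, method = "bray")
  hc <- hclust(d, method = method)
  list(order = rownames(mat)[hc$order], hclust = hc)
}

#' Write a profile matrix and its clustering order
#' @param mat profile matrix from [profile_percentages()].
#' @param path output TSV for the matrix; the leaf order is written next to
#'   it with suffix `.order`.
#' @param method linkage method.
#' @export
write_profile <- function(mat, path, method = "average") {
  df <- data.frame(species = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- cluster_profiles(mat, method)
  writeLines(cl$order, paste0(path, ".order"))
  invisible(path)
}
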