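#' Read 12-column tabular similarity-search results
#'
#' Standard BLAST outfmt-6 columns: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path tabular file (no header).
#' @return data frame with the standard column names.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 12L)
    stop("expected 12 tab-separated columns, got ", ncol(df),
         call. = FALSE)
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Bit-score-binned random sampling of homology-search hits
#'
#' Reduces a large hit set to a representative sample across the similarity
#' range: hits are binned by bit score into `n_bins` bins of width
#' `bin_width` anchored at the minimum score (scores above the top boundary
#' fall into the last bin), `per_bin` hits are drawn uniformly without
#' replacement from each bin (all if fewer), then an optional description
#' filter is applied and multiple hits from one species are collapsed to
#' the single highest-scoring one.
#'
#' @param hits data frame with at least `sseqid` and `bitscore` columns
#'   (see [read_blast_tab()]); optional `species` and `description`
#'   columns drive deduplication and filtering.
#' @param bin_width bit-score bin width (default 50).
#' @param n_bins number of bins (default 10).
#' @param per_bin hits sampled per bin (default 25).
#' @param seed RNG seed (sampling is deterministic under it).
#' @param species_dedupe keep one hit per species (default TRUE; requires a
#'   `species` column, otherwise a no-op).
#' @param label_filter optional predicate on the `description` column;
#'   rows where it returns `FALSE` are dropped after sampling.
#' @return An object of class `sampled_hits`: list with `bins` (data frame:
#'   `bin`, `lower`, `upper`, `n_total`, `n_sampled`), `hits` (the retained
#'   rows), `seed`.
#' @export
sample_blast_hits <- function(hits, bin_width = 50, n_bins = 10L,
                              per_bin = 25L, seed = 1L,
                              species_dedupe = TRUE,
                              label_filter = NULL) {
  if (!"bitscore" %in% names(hits) || anyNA(hits$bitscore))
    stop("hits must carry a complete bitscore column", call. = FALSE)
  lo <- min(hits$bitscore)
  bin <- pmin(floor((hits$bitscore - lo) / bin_width) + 1L, n_bins)

  sampled <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_bins), function(b) {
      rows <- which(bin == b)
      if (length(rows) > per_bin) rows <- sample(rows, per_bin)
      hits[sort(rows), , drop = FALSE]
    }))
  })
  bins <- data.frame(
    bin = seq_len(n_bins),
    lower = lo + (seq_len(n_bins) - 1L) * bin_width,
    upper = c(lo + seq_len(n_bins - 1L) * bin_width, Inf),
    n_total = as.vector(table(factor(bin, levels = seq_len(n_bins)))),
    n_sampled = NA_integer_
  )
  bins$n_sampled <- pmin(bins$n_total, per_bin)

  if (!is.null(label_filter) && "description" %in% names(sampled)) {
    sampled <- sampled[vapply(sampled$description, label_filter, TRUE), ,
                       drop = FALSE]
  }
  if (isTRUE(species_dedupe) && "species" %in% names(sampled)) {
    sampled <- sampled[order(-sampled$bitscore), , drop = FALSE]
    sampled <- sampled[!duplicated(sampled$species), , drop = FALSE]
    sampled <- sampled[order(sampled$bitscore), , drop = FALSE]
  }
  rownames(sampled) <- NULL
  structure(list(bins = bins, hits = sampled, seed = seed),
            class = "sampled_hits")
}

#' @export
print.sampled_hits <- function(x, ...) {
  cat("sampled_hits:", nrow(x$hits), "hits retained from",
      sum(x$bins$n_total), "across", nrow(x$bins), "bit-score bins\n")
  invisible(x)
}
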