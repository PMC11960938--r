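#' All-vs-all PID3 matrix over locus segments
#'
#' Aligns every unordered pair of segments with [align_overlap()] and
#' records the PID3 percent identity.  The diagonal is fixed at 100 and
#' flagged by the self-comparison mask.  Residual homology between
#' consecutive intergenic regions is the signature of recent tandem
#' duplication, since unequal crossing over copies a gene together with its
#' downstream intergenic region.
#'
#' @param segments data frame from [segment_locus()].
#' @param params a [scoring_params()] object.
#' @param subset `"all"` or `"intergenic_only"`.
#' @param min_len segments shorter than this are excluded as not assessable
#'   (default 30 bp; PID3 on tiny segments is meaningless).
#' @return An object of class `pid_matrix`: list with `locus_id`, `labels`,
#'   `pid` (symmetric numeric matrix), `self_mask` (logical matrix, TRUE on
#'   the diagonal), `excluded` (labels dropped as too short).
#' @export
pairwise_pid_matrix <- function(segments, params = scoring_params(),
                                subset = c("all", "intergenic_only"),
                                min_len = 30L) {
  subset <- match.arg(subset)
  seg <- segments
  if (subset == "intergenic_only")
    seg <- seg[seg$kind == "IGR", , drop = FALSE]
  too_short <- nchar(seg$sequence) < min_len
  excluded <- seg$label[too_short]
  seg <- seg[!too_short, , drop = FALSE]
  n <- nrow(seg)
  if (n < 2L) stop("need at least two assessable segments", call. = FALSE)

  pid <- matrix(100, n, n, dimnames = list(seg$label, seg$label))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- align_overlap(seg$sequence[i], seg$sequence[j], params)$pid3
      pid[i, j] <- p
      pid[j, i] <- p
    }
  }
  structure(list(locus_id = unique(seg$locus_id), labels = seg$label,
                 pid = pid, self_mask = diag(n) == 1,
                 excluded = excluded),
            class = "pid_matrix")
}

#' @export
print.pid_matrix <- function(x, ...) {
  cat("pid_matrix for locus", x$locus_id, "over",
      length(x$labels), "segments\n")
  print(round(x$pid, 1))
  if (length(x$excluded))
    cat("not assessable (too short):", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}

#' Shuffle null distribution for a PID3 comparison
#'
#' Empirical distribution of PID3 between `seq_a` and mononucleotide
#' shuffles of `seq_b`.  Overlap alignments of short random sequences can
#' attain inflated PID3, so observed values are judged against this null
#' rather than against a fixed cutoff alone.
#'
#' @param seq_a,seq_b DNA strings.
#' @param n_shuffles number of shuffles (default 100).
#' @param seed RNG seed (applied locally; the caller's RNG is untouched).
#' @param params a [scoring_params()] object.
#' @return Numeric vector of `n_shuffles` PID3 values.
#' @export
shuffle_null <- function(seq_a, seq_b, n_shuffles = 100L, seed = 1L,
                         params = scoring_params()) {
  stopifnot(n_shuffles >= 1L)
  chars <- strsplit(toupper(seq_b), "")[[1]]
  with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      shuf <- paste(sample(chars), collapse = "")
      align_overlap(seq_a, shuf, params)$pid3
    }, numeric(1))
  })
}

#' Flag recent tandem duplications from consecutive intergenic homology
#'
#' For each consecutive intergenic pair (IGRk, IGRk+1) of a locus, the
#' observed PID3 is compared with its shuffle null; the pair is flagged
#' `is_recent` when the observed value exceeds the empirical
#' `1 - alpha` null quantile and also reaches an absolute floor.
#' Consecutive intergenic homology dates the duplication: copies made by
#' unequal crossing over start identical and degrade by neutral drift.
#'
#' @param matrix a `pid_matrix` built over the same segments.
#' @param segments data frame from [segment_locus()].
#' @param n_shuffles shuffles per pair (default 100).
#' @param alpha null tail probability (default 0.05).
#' @param floor absolute minimum PID3 percent to call recency (default 50).
#' @param seed RNG seed.
#' @param params a [scoring_params()] object.
#' @param min_len IGRs shorter than this are reported as not assessable
#'   (default 30 bp).
#' @return data frame of class `recency_calls`: `locus_id`, `igr_a`,
#'   `igr_b`, `pid3`, `null_quantile` (percent of null values below the
#'   observed PID3), `assessable`, `is_recent` (NA when not assessable).
#'   Loci with fewer than two intergenic regions yield zero rows.
#' @export
call_recent_duplications <- function(matrix, segments, n_shuffles = 100L,
                                     alpha = 0.05, floor = 50,
                                     seed = 1L, params = scoring_params(),
                                     min_len = 30L) {
  igr <- segments[segments$kind == "IGR", , drop = FALSE]
  igr <- igr[order(as.integer(sub("IGR", "", igr$label))), , drop = FALSE]
  out <- data.frame(locus_id = integer(0), igr_a = character(0),
                    igr_b = character(0), pid3 = numeric(0),
                    null_quantile = numeric(0), assessable = logical(0),
                    is_recent = logical(0), stringsAsFactors = FALSE)
  if (nrow(igr) < 2L) {
    class(out) <- c("recency_calls", "data.frame")
    return(out)
  }
  for (k in seq_len(nrow(igr) - 1L)) {
    la <- igr$label[k]; lb <- igr$label[k + 1L]
    assessable <- nchar(igr$sequence[k]) >= min_len &&
      nchar(igr$sequence[k + 1L]) >= min_len &&
      la %in% matrix$labels && lb %in% matrix$labels
    if (!assessable) {
      out[nrow(out) + 1L, ] <- list(igr$locus_id[k], la, lb, NA_real_,
                                    NA_real_, FALSE, NA)
      next
    }
    obs <- matrix$pid[la, lb]
    null <- shuffle_null(igr$sequence[k], igr$sequence[k + 1L],
                         n_shuffles, seed = child_seed(seed, k), params)
    nq <- 100 * mean(null < obs)
    cutoff <- quantile(null, 1 - alpha, names = FALSE, type = 1)
    out[nrow(out) + 1L, ] <- list(igr$locus_id[k], la, lb, obs, nq, TRUE,
                                  obs > cutoff && obs >= floor)
  }
  class(out) <- c("recency_calls", "data.frame")
  out
}

#' Export a PID3 matrix as TSV
#' @param matrix a `pid_matrix`.
#' @param path output file.
#' @export
export_pid_matrix <- function(matrix, path) {
  m <- matrix$pid
  m[matrix$self_mask] <- NA
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PID3 matrix TSV written by [export_pid_matrix()]
#' @param path input file.
#' @return A `pid_matrix` (self-comparison cells masked as NA are restored
#'   to 100 with the mask set).
#' @export
read_pid_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- df$label
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  mask <- is.na(m) & diag(nrow(m)) == 1
  m[mask] <- 100
  structure(list(locus_id = NA_integer_, labels = labels, pid = m,
                 self_mask = mask, excluded = character(0)),
            class = "pid_matrix")
}

#' Long-format plot payload for a PID3 matrix
#'
#' @param matrix a `pid_matrix`.
#' @param digits digits for the per-cell percent labels.
#' @return data frame with `row`, `col`, `pid3`, `label` (formatted percent,
#'   `NA` on masked self-comparisons), ready for a heatmap layer.
#' @export
pid_matrix_plot_data <- function(matrix, digits = 0) {
  m <- matrix$pid
  idx <- expand.grid(row = rownames(m), col = colnames(m),
                     stringsAsFactors = FALSE)
  idx$pid3 <- as.vector(m)
  idx$label <- formatC(idx$pid3, format = "f", digits = digits)
  idx$label[as.vector(matrix$self_mask)] <- NA_character_
  idx
}
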