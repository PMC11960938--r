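#' Overlap alignment of two DNA sequences
#'
#' Global (Needleman-Wunsch) alignment with affine gap costs in which gap
#' runs touching either sequence end are free by default, so a short
#' sequence can align inside a longer one without terminal penalties.  This
#' is the alignment mode used throughout the package to compare locus
#' segments of unequal length.  Tie-breaking is deterministic: diagonal
#' moves are preferred over gaps in the second sequence, which are preferred
#' over gaps in the first.
#'
#' @param a,b DNA sequences as single strings (IUPAC codes; lowercase input
#'   is uppercased on ingestion).
#' @param params a [scoring_params()] object.
#' @return An object of class `overlap_alignment` with elements
#'   `aligned_a`, `aligned_b` (gapped strings), `score`, `n_identical`
#'   (aligned columns with identical residues), `len_shorter`, and `pid3`
#'   (`100 * n_identical / len_shorter`).
#' @examples
#' aln <- align_overlap("ACGT", "TTACGTTT")
#' aln$pid3   # 100: the 4-mer is contained in the 8-mer
#' @seealso [pid3()], [scoring_params()]
#' @export
align_overlap <- function(a, b, params = scoring_params()) {
  alphabet <- rownames(params$substitution_matrix)
  a <- prepare_dna(a, "first sequence", alphabet)
  b <- prepare_dna(b, "second sequence", alphabet)
  res <- align_overlap_cpp(a, b, params$substitution_matrix,
                           paste(alphabet, collapse = ""),
                           params$gap_open, params$gap_extend,
                           params$free_end_gaps)
  stopifnot(res$n_identical <= res$len_shorter)
  res$pid3 <- 100 * res$n_identical / res$len_shorter
  class(res) <- "overlap_alignment"
  res
}

#' @export
print.overlap_alignment <- function(x, ...) {
  cat("overlap_alignment: score =", x$score,
      " identities =", x$n_identical, "/", x$len_shorter,
      sprintf(" (PID3 = %.1f%%)\n", x$pid3))
  if (nchar(x$aligned_a) <= 100) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' PID3 percent identity
#'
#' Percent identity normalized by the shorter sequence:
#' `100 * identical positions / length of shorter sequence`.  End-gap
#' columns contribute nothing to the identity count.
#'
#' @param result an `overlap_alignment` from [align_overlap()].
#' @return A percentage in \[0, 100\].
#' @export
pid3 <- function(result) {
  stopifnot(inherits(result, "overlap_alignment"))
  100 * result$n_identical / result$len_shorter
}

#' Self-comparison dot matrix
#'
#' Window-summed substitution scores of a sequence against itself, the
#' qualitative diagnostic for spotting tandem repeat structure in a locus:
#' a tandem copy of period p appears as an off-diagonal ridge at offset p.
#'
#' @param seq DNA sequence (single string).
#' @param window odd window width in bases.
#' @param min_score display cutoff stored alongside the matrix; cells below
#'   it are zeroed in `thresholded()`.
#' @param params a [scoring_params()] object (only the matrix is used).
#' @return An object of class `dot_matrix`: list with `scores` (n x n
#'   symmetric numeric matrix), `window`, `threshold`.
#' @export
dotplot_self <- function(seq, window = 11L, min_score = 0L,
                         params = scoring_params()) {
  alphabet <- rownames(params$substitution_matrix)
  seq <- prepare_dna(seq, "sequence", alphabet)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window > nchar(seq))
    stop("window larger than sequence", call. = FALSE)
  scores <- dotplot_self_cpp(seq, window, params$substitution_matrix,
                             paste(alphabet, collapse = ""))
  structure(list(scores = scores, window = window, threshold = min_score),
            class = "dot_matrix")
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat("dot_matrix:", nrow(x$scores), "x", ncol(x$scores),
      "window", x$window, "threshold", x$threshold, "\n")
  invisible(x)
}

#' Apply the display threshold of a dot matrix
#'
#' @param x a `dot_matrix`.
#' @return The score matrix with cells below the threshold set to 0.
#' @export
thresholded <- function(x) {
  stopifnot(inherits(x, "dot_matrix"))
  s <- x$scores
  s[s < x$threshold] <- 0
  s
}
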