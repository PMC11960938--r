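#' NUC.4.4 (EDNAFULL) nucleotide substitution matrix
#'
#' The standard NCBI DNA scoring matrix over the 15 IUPAC nucleotide codes:
#' +5 for an identical unambiguous base, -4 for a mismatch, with graded
#' scores for ambiguity codes.
#'
#' @return A symmetric 15 x 15 integer matrix with IUPAC letters as dimnames.
#' @examples
#' nuc44()["A", "A"]  # 5
#' nuc44()["A", "T"]  # -4
#' @export
nuc44 <- function() {
  letters15 <- c("A", "T", "G", "C", "S", "W", "R", "Y", "K", "M",
                 "B", "V", "H", "D", "N")
  m <- matrix(c(
     5, -4, -4, -4, -4,  1,  1, -4, -4,  1, -4, -1, -1, -1, -2,
    -4,  5, -4, -4, -4,  1, -4,  1,  1, -4, -1, -4, -1, -1, -2,
    -4, -4,  5, -4,  1, -4,  1, -4,  1, -4, -1, -1, -4, -1, -2,
    -4, -4, -4,  5,  1, -4, -4,  1, -4,  1, -1, -1, -1, -4, -2,
    -4, -4,  1,  1, -1, -4, -2, -2, -2, -2, -1, -1, -3, -3, -1,
     1,  1, -4, -4, -4, -1, -2, -2, -2, -2, -3, -3, -1, -1, -1,
     1, -4,  1, -4, -2, -2, -1, -4, -2, -2, -3, -1, -3, -1, -1,
    -4,  1, -4,  1, -2, -2, -4, -1, -2, -2, -1, -3, -1, -3, -1,
    -4,  1,  1, -4, -2, -2, -2, -2, -1, -4, -1, -3, -3, -1, -1,
     1, -4, -4,  1, -2, -2, -2, -2, -4, -1, -3, -1, -1, -3, -1,
    -4, -1, -1, -1, -1, -3, -3, -1, -1, -3, -1, -2, -2, -2, -1,
    -1, -4, -1, -1, -1, -3, -1, -3, -3, -1, -2, -1, -2, -2, -1,
    -1, -1, -4, -1, -3, -1, -3, -1, -3, -1, -2, -2, -1, -2, -1,
    -1, -1, -1, -4, -3, -1, -1, -3, -1, -3, -2, -2, -2, -1, -1,
    -2, -2, -2, -2, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1
  ), nrow = 15, byrow = TRUE, dimnames = list(letters15, letters15))
  storage.mode(m) <- "integer"
  m
}

#' Alignment scoring parameters
#'
#' Bundles the substitution matrix and affine gap costs used by
#' [align_overlap()].  The defaults reproduce a stringent overlap-alignment
#' parameterization for detecting contiguous blocks of high DNA similarity:
#' the NUC.4.4/EDNAFULL matrix, gap opening 25, gap extension 10, and free
#' end gaps at both sequence ends.  A gap run of length L costs
#' `gap_open + gap_extend * L`.
#'
#' @param substitution_matrix symmetric integer matrix with IUPAC dimnames.
#' @param gap_open non-negative integer cost for opening a gap run.
#' @param gap_extend non-negative integer cost per gapped position.
#' @param free_end_gaps if `TRUE`, gap runs touching either end of either
#'   sequence cost nothing ("overlap" alignment).
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(substitution_matrix = nuc44(),
                           gap_open = 25L, gap_extend = 10L,
                           free_end_gaps = TRUE) {
  stopifnot(is.matrix(substitution_matrix),
            !is.null(rownames(substitution_matrix)),
            identical(rownames(substitution_matrix),
                      colnames(substitution_matrix)))
  if (!isTRUE(all(substitution_matrix == t(substitution_matrix))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative", call. = FALSE)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 free_end_gaps = isTRUE(free_end_gaps)),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("scoring_params: gap_open =", x$gap_open,
      "gap_extend =", x$gap_extend,
      "free_end_gaps =", x$free_end_gaps, "\n")
  cat("  alphabet:", paste(rownames(x$substitution_matrix), collapse = ""),
      "\n")
  invisible(x)
}

# validate and uppercase a DNA string; error names the offending character
prepare_dna <- function(x, what = "sequence", alphabet) {
  assert_scalar_string(x, what)
  x <- toupper(x)
  if (nchar(x) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), alphabet)
  if (length(bad))
    stop("non-IUPAC character '", bad[1], "' in ", what, call. = FALSE)
  x
}
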