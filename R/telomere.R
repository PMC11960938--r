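#' Detect telomeric repeats at contig ends
#'
#' A contig end is called telomeric when at least `min_copies` tandem copies
#' of the telomeric hexamer (or its reverse complement, whichever fits the
#' end's orientation) occur within `window` bp of that end.  Requiring
#' tandem copies avoids counting chance occurrences of a single hexamer.
#'
#' @param genome named character vector of contigs.
#' @param motif telomeric repeat unit (default `"TTAGGG"`).
#' @param min_copies minimum number of tandem copies (default 3).
#' @param window how far from the contig end to search, in bp (default 500).
#' @return An object of class `telomere_report`: data frame with `contig`,
#'   `telomere_at_5prime`, `telomere_at_3prime`, plus attribute
#'   `total_telomeric_ends`.
#' @seealso [infer_min_chromosomes()]
#' @export
find_telomeric_ends <- function(genome, motif = "TTAGGG",
                                min_copies = 3L, window = 500L) {
  fwd <- strrep(toupper(motif), min_copies)
  rev <- strrep(revcomp(toupper(motif)), min_copies)
  has_block <- function(s) grepl(fwd, s, fixed = TRUE) ||
    grepl(rev, s, fixed = TRUE)
  p5 <- vapply(genome, function(ctg)
    has_block(substr(ctg, 1L, min(window, nchar(ctg)))), TRUE)
  p3 <- vapply(genome, function(ctg)
    has_block(substr(ctg, max(1L, nchar(ctg) - window + 1L), nchar(ctg))),
    TRUE)
  out <- data.frame(contig = names(genome),
                    telomere_at_5prime = unname(p5),
                    telomere_at_3prime = unname(p3),
                    stringsAsFactors = FALSE)
  attr(out, "total_telomeric_ends") <- sum(p5) + sum(p3)
  class(out) <- c("telomere_report", "data.frame")
  out
}

#' Minimum chromosome number from a telomere census
#'
#' Each chromosome contributes two telomeric ends, so an assembly with `k`
#' telomeric contig ends derives from at least `ceiling(k / 2)` chromosomes.
#'
#' @param report a `telomere_report` from [find_telomeric_ends()], or a
#'   plain count of telomeric ends.
#' @return integer minimum chromosome number.
#' @examples
#' # one contig telomeric at both ends plus 22 contigs telomeric at one end
#' infer_min_chromosomes(2 + 22)  # 12
#' @export
infer_min_chromosomes <- function(report) {
  k <- if (is.numeric(report)) report
       else attr(report, "total_telomeric_ends")
  as.integer(ceiling(k / 2))
}

#' Write a telomere report as TSV
#' @param report a `telomere_report`.
#' @param path output file.
#' @export
write_telomere_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# total_telomeric_ends\t",
                    attr(report, "total_telomeric_ends")), con)
  writeLines(paste0("# min_chromosomes\t", infer_min_chromosomes(report)),
             con)
  write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
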