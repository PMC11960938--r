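#' Read a genome assembly from FASTA
#'
#' @param path FASTA file.
#' @return A named character vector of uppercase contig sequences; names are
#'   truncated at the first whitespace.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(out)))
    stop("duplicate contig name in ", path, call. = FALSE)
  out
}

#' Write a genome to FASTA
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package's
#' internal 0-based half-open convention on ingestion.
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return A data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, sorted by contig then start.
#' @export
read_gene_annotations <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    nm <- gr$Name
    ids <- if (is.null(ids)) nm else ifelse(is.na(ids), nm, ids)
  }
  if (is.null(ids) || anyNA(ids))
    stop("every ", feature_type, " feature needs an ID or Name attribute",
         call. = FALSE)
  genes <- data.frame(
    gene_id = as.character(ids),
    contig  = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr) - 1L,
    end     = GenomicRanges::end(gr),
    strand  = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genes[order(genes$contig, genes$start), , drop = FALSE]
}

#' Write gene annotations to GFF3
#' @param genes gene data frame (0-based half-open, see
#'   [read_gene_annotations()]).
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @export
write_gene_annotations <- function(genes, path, source = "tandemtrace") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# check every gene fits inside its contig; error names gene and contig
check_genes_in_genome <- function(genes, genome) {
  for (i in seq_len(nrow(genes))) {
    ctg <- genes$contig[i]
    if (!ctg %in% names(genome))
      stop("gene ", genes$gene_id[i], " references unknown contig ", ctg,
           call. = FALSE)
    if (genes$start[i] < 0 || genes$end[i] > nchar(genome[[ctg]]))
      stop("gene ", genes$gene_id[i], " lies outside contig ", ctg,
           call. = FALSE)
    if (genes$start[i] >= genes$end[i])
      stop("gene ", genes$gene_id[i], " has start >= end", call. = FALSE)
  }
  invisible(genes)
}

#' Call gene-family loci by single-linkage clustering
#'
#' Family genes on the same contig are merged into one locus when the gap
#' between consecutive members is at most `max_gap`.  Loci are numbered by
#' position on contigs ordered from largest to smallest, the convention used
#' for presenting expanded families across an assembly.
#'
#' @param genes gene data frame (see [read_gene_annotations()]).
#' @param family_ids character vector of gene ids belonging to the family.
#' @param genome named character vector (used for contig sizes); if `NULL`,
#'   contigs are ordered alphabetically.
#' @param max_gap maximum gap in bp between consecutive family genes of one
#'   locus (default 20000).
#' @return An object of class `locus_set`: a list of loci, each a list with
#'   `id`, `contig`, `genes` (data frame rows, sorted by start), `span`
#'   (0-based half-open `c(start, end)` covering all member genes).
#' @export
call_loci <- function(genes, family_ids, genome = NULL, max_gap = 20000) {
  if (length(family_ids) == 0L)
    stop("family_ids must be non-empty", call. = FALSE)
  unknown <- setdiff(family_ids, genes$gene_id)
  if (length(unknown))
    stop("unknown family gene id: ", unknown[1], call. = FALSE)
  fam <- genes[genes$gene_id %in% family_ids, , drop = FALSE]
  fam <- fam[order(fam$contig, fam$start), , drop = FALSE]

  contigs <- unique(fam$contig)
  if (!is.null(genome)) {
    sizes <- nchar(genome[contigs])
    contigs <- contigs[order(-sizes, contigs)]
  } else {
    contigs <- sort(contigs)
  }

  loci <- list()
  for (ctg in contigs) {
    g <- fam[fam$contig == ctg, , drop = FALSE]
    grp <- cumsum(c(1L, (g$start[-1] - g$end[-nrow(g)]) > max_gap))
    for (k in unique(grp)) {
      rows <- g[grp == k, , drop = FALSE]
      loci[[length(loci) + 1L]] <- list(
        id = length(loci) + 1L,
        contig = ctg,
        genes = rows,
        span = c(min(rows$start), max(rows$end))
      )
    }
  }
  structure(loci, class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set with", length(x), "loci;",
      sum(vapply(x, function(l) nrow(l$genes), 1L)), "family genes\n")
  for (l in x[seq_len(min(10, length(x)))]) {
    cat(sprintf("  L%d %s:%d-%d (%d genes)\n", l$id, l$contig,
                l$span[1], l$span[2], nrow(l$genes)))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Summarize a locus set as a data frame
#' @param x a `locus_set`.
#' @param ... unused.
#' @return data frame with `locus_id`, `contig`, `start`, `end`, `n_genes`.
#' @method as.data.frame locus_set
#' @export
as.data.frame.locus_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(l) data.frame(
    locus_id = l$id, contig = l$contig,
    start = l$span[1], end = l$span[2],
    n_genes = nrow(l$genes), stringsAsFactors = FALSE
  )))
}

#' Segment a locus into flanks, genes and intergenic regions
#'
#' Extracts the locus span with `flank` bp extensions on each side (or until
#' the contig ends) and tiles it as LF, G1, IGR1, G2, ..., Gn, RF.  IGRk is
#' the sequence strictly between consecutive genes; zero-length IGRs are
#' kept for abutting genes.  All sequences are taken from the forward strand
#' of the contig.
#'
#' @param locus one element of a [call_loci()] `locus_set`.
#' @param genome named character vector of contigs.
#' @param flank flank length in bp (default 2500).
#' @return data frame with `locus_id`, `kind` (LF/GENE/IGR/RF), `label`,
#'   `start`, `end` (0-based half-open), `sequence`.
#' @export
segment_locus <- function(locus, genome, flank = 2500) {
  ctg <- genome[[locus$contig]]
  if (is.null(ctg)) stop("contig ", locus$contig, " not in genome",
                         call. = FALSE)
  clen <- nchar(ctg)
  g <- locus$genes
  lf0 <- max(0L, locus$span[1] - as.integer(flank))
  rf1 <- min(clen, locus$span[2] + as.integer(flank))

  starts <- integer(0); ends <- integer(0)
  kinds <- character(0); labels <- character(0)
  add <- function(kind, label, s, e) {
    starts <<- c(starts, s); ends <<- c(ends, e)
    kinds <<- c(kinds, kind); labels <<- c(labels, label)
  }
  add("LF", "LF", lf0, g$start[1])
  for (i in seq_len(nrow(g))) {
    add("GENE", paste0("G", i), g$start[i], g$end[i])
    if (i < nrow(g)) add("IGR", paste0("IGR", i), g$end[i], g$start[i + 1])
  }
  add("RF", "RF", g$end[nrow(g)], rf1)

  data.frame(
    locus_id = locus$id, kind = kinds, label = labels,
    start = starts, end = ends,
    sequence = substring(ctg, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
}

#' Classify the orientation of a multi-gene locus
#'
#' A tandem locus is `unidirectional_head_to_tail` when all its family genes
#' lie on the same strand; otherwise `mixed`.  Also reports whether any
#' non-family gene intrudes into the span between the first and last family
#' gene.
#'
#' @param locus one element of a `locus_set`.
#' @param all_genes the full gene data frame (family and non-family).
#' @param family_ids character vector of family gene ids.
#' @return list with `orientation` (`NA` for single-gene loci),
#'   `has_intervening_genes`.
#' @export
classify_orientation <- function(locus, all_genes, family_ids) {
  g <- locus$genes
  span <- c(min(g$start), max(g$end))
  others <- all_genes[all_genes$contig == locus$contig &
                        !all_genes$gene_id %in% family_ids, , drop = FALSE]
  intervening <- any(others$start < span[2] & others$end > span[1])
  if (nrow(g) < 2L) {
    return(list(orientation = NA_character_,
                has_intervening_genes = intervening))
  }
  orientation <- if (length(unique(g$strand)) == 1L)
    "unidirectional_head_to_tail" else "mixed"
  list(orientation = orientation, has_intervening_genes = intervening)
}

#' Orientation census over a locus set
#' @param loci a `locus_set`.
#' @param all_genes full gene data frame.
#' @param family_ids family gene ids.
#' @return data frame with one row per locus: `locus_id`, `n_genes`,
#'   `orientation`, `has_intervening_genes`.
#' @export
orientation_census <- function(loci, all_genes, family_ids) {
  do.call(rbind, lapply(loci, function(l) {
    o <- classify_orientation(l, all_genes, family_ids)
    data.frame(locus_id = l$id, n_genes = nrow(l$genes),
               orientation = o$orientation,
               has_intervening_genes = o$has_intervening_genes,
               stringsAsFactors = FALSE)
  }))
}

#' Write locus segments as BED (0-based half-open)
#' @param segments data frame from [segment_locus()] (may be several loci
#'   row-bound together); needs a `contig` column or a single `contig`
#'   argument.
#' @param loci the `locus_set` the segments came from.
#' @param path output BED file.
#' @export
write_segments_bed <- function(segments, loci, path) {
  contigs <- vapply(loci, function(l) l$contig, "")
  ids <- vapply(loci, function(l) l$id, 1L)
  bed <- data.frame(
    chrom = contigs[match(segments$locus_id, ids)],
    start = segments$start, end = segments$end,
    name = paste0("L", segments$locus_id, "_", segments$label)
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write locus segments as FASTA
#' @inheritParams write_segments_bed
#' @param path output FASTA file.
#' @export
write_segments_fasta <- function(segments, path) {
  keep <- nchar(segments$sequence) > 0
  ss <- Biostrings::DNAStringSet(segments$sequence[keep])
  names(ss) <- paste0("L", segments$locus_id[keep], "_",
                      segments$label[keep])
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
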