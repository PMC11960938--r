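# Domain-level events: duplication, loss, TMD acquisition, in-frame
# insertion, catalytic-motif knockout.  All simulated genes sit on the +
# strand, so protein coordinate k maps to nucleotides
# gene_start + 3*(k-1) .. gene_start + 3*k on the contig.

gene_row <- function(sim, gene_id) {
  g <- sim$genes[sim$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene ", gene_id, call. = FALSE)
  g
}

#' Extract the coding sequence of a simulated gene
#' @param sim an `aly_sim`.
#' @param gene_id gene id.
#' @return CDS nucleotide string (including the stop codon).
#' @export
gene_cds <- function(sim, gene_id) {
  g <- gene_row(sim, gene_id)
  substr(sim$contigs[[g$contig]], g$start + 1L, g$end)
}

#' Translate the protein of a simulated gene
#' @inheritParams gene_cds
#' @return amino-acid string (stop removed).
#' @export
gene_protein <- function(sim, gene_id) {
  cds <- gene_cds(sim, gene_id)
  p <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  sub("\\*$", "", p)
}

#' Extract one domain's sequence from a simulated gene
#' @inheritParams gene_cds
#' @param kind domain kind (`"A"`, `"C"`, ...).
#' @param index which domain of that kind, N- to C-terminal (default 1).
#' @param what `"protein"` or `"nt"`.
#' @export
domain_seq <- function(sim, gene_id, kind, index = 1L,
                       what = c("protein", "nt")) {
  what <- match.arg(what)
  d <- sim$domains[sim$domains$gene_id == gene_id &
                     sim$domains$kind == kind, ]
  d <- d[order(d$start), ][index, ]
  if (anyNA(d$start)) stop("no such domain", call. = FALSE)
  if (what == "protein") {
    substr(gene_protein(sim, gene_id), d$start, d$end)
  } else {
    substr(gene_cds(sim, gene_id), 3L * (d$start - 1L) + 1L, 3L * d$end)
  }
}

# insert `nt` (length divisible by 3) at protein position aa_pos0 (0-based,
# counted from the gene's first residue) of `gene_id`, updating contig,
# gene bounds, downstream genes and this gene's domain coordinates
insert_inframe <- function(sim, gene_id, aa_pos0, nt) {
  stopifnot(nchar(nt) %% 3L == 0L)
  g <- gene_row(sim, gene_id)
  pos0 <- g$start + 3L * aa_pos0
  sim$contigs[[g$contig]] <- splice_at(sim$contigs[[g$contig]], pos0, nt)
  # widen this gene, then shift everything downstream of the insertion
  sel <- sim$genes$gene_id == gene_id
  sim$genes$end[sel] <- sim$genes$end[sel] + nchar(nt)
  move <- sim$genes$contig == g$contig & sim$genes$start > pos0 &
    sim$genes$gene_id != gene_id
  sim$genes$start[move] <- sim$genes$start[move] + nchar(nt)
  sim$genes$end[move] <- sim$genes$end[move] + nchar(nt)
  aa_len <- nchar(nt) / 3L
  dsel <- sim$domains$gene_id == gene_id
  grow <- dsel & sim$domains$start <= aa_pos0 & sim$domains$end > aa_pos0
  sim$domains$end[grow] <- sim$domains$end[grow] + aa_len
  after <- dsel & sim$domains$start > aa_pos0
  sim$domains$start[after] <- sim$domains$start[after] + aa_len
  sim$domains$end[after] <- sim$domains$end[after] + aa_len
  sim
}

# delete the protein span [aa_start, aa_end] (1-based inclusive) of gene_id
delete_inframe <- function(sim, gene_id, aa_start, aa_end) {
  g <- gene_row(sim, gene_id)
  nt0 <- g$start + 3L * (aa_start - 1L)
  nt1 <- g$start + 3L * aa_end
  delta <- nt1 - nt0
  sim$contigs[[g$contig]] <- delete_span(sim$contigs[[g$contig]], nt0, nt1)
  sel <- sim$genes$gene_id == gene_id
  sim$genes$end[sel] <- sim$genes$end[sel] - delta
  move <- sim$genes$contig == g$contig & sim$genes$start >= nt1 &
    sim$genes$gene_id != gene_id
  sim$genes$start[move] <- sim$genes$start[move] - delta
  sim$genes$end[move] <- sim$genes$end[move] - delta
  aa_len <- aa_end - aa_start + 1L
  dsel <- sim$domains$gene_id == gene_id
  drop <- dsel & sim$domains$start >= aa_start & sim$domains$end <= aa_end
  after <- dsel & sim$domains$start > aa_end
  sim$domains$start[after] <- sim$domains$start[after] - aa_len
  sim$domains$end[after] <- sim$domains$end[after] - aa_len
  sim$domains <- sim$domains[!drop, ]
  rownames(sim$domains) <- NULL
  sim
}

#' Plant a domain-level event in a simulated gene
#'
#' Supported events: `"domain_duplication"` (tandem copy of one domain),
#' `"domain_loss"` (delete one domain), `"tmd_gain"` (append a C-terminal
#' transmembrane segment), `"insertion_15bp"` (in-frame insertion inside an
#' A-domain; any length divisible by 3), `"motif_knockout"` (point
#' substitution destroying one catalytic motif region).
#'
#' @param sim an `aly_sim`.
#' @param gene_id target gene.
#' @param type event type (above).
#' @param kind domain kind for duplication/loss (default `"C"` for loss,
#'   `"A"` for duplication).
#' @param index which domain of that kind (default 1).
#' @param aa_offset for `insertion_15bp`: 0-based residue offset inside the
#'   A-domain at which to insert (default 100).
#' @param insert_nt for `insertion_15bp`: the inserted nucleotides (default
#'   a fixed 15-mer).
#' @param region for `motif_knockout`: `"A"`, `"B"` or `"C"` (default
#'   `"B"`).
#' @return The updated `aly_sim` with the event logged.
#' @export
plant_domain_event <- function(sim, gene_id,
                               type = c("domain_duplication",
                                        "domain_loss", "tmd_gain",
                                        "insertion_15bp",
                                        "motif_knockout"),
                               kind = NULL, index = 1L,
                               aa_offset = 100L,
                               insert_nt = "GGTACCGGTACCGGT",
                               region = "B") {
  type <- match.arg(type)
  g <- gene_row(sim, gene_id)
  if (type == "domain_duplication") {
    kind <- kind %||% "A"
    d <- sim$domains[sim$domains$gene_id == gene_id &
                       sim$domains$kind == kind, ]
    d <- d[order(d$start), ][index, ]
    if (anyNA(d$start)) stop("no ", kind, " domain to duplicate",
                             call. = FALSE)
    seg <- substr(gene_cds(sim, gene_id), 3L * (d$start - 1L) + 1L,
                  3L * d$end)
    sim <- insert_inframe(sim, gene_id, d$end, seg)
    # register the new copy right after the template
    aa_len <- d$end - d$start + 1L
    sim$domains <- rbind(sim$domains, data.frame(
      gene_id = gene_id, kind = kind, start = d$end + 1L,
      end = d$end + aa_len, i_evalue = 1e-20, stringsAsFactors = FALSE))
    sim$domains <- sim$domains[order(sim$domains$gene_id,
                                     sim$domains$start), ]
    rownames(sim$domains) <- NULL
  } else if (type == "domain_loss") {
    kind <- kind %||% "C"
    d <- sim$domains[sim$domains$gene_id == gene_id &
                       sim$domains$kind == kind, ]
    d <- d[order(d$start), ][index, ]
    if (anyNA(d$start)) stop("no ", kind, " domain to delete",
                             call. = FALSE)
    sim <- delete_inframe(sim, gene_id, d$start, d$end)
  } else if (type == "tmd_gain") {
    tmd_aa <- 21L
    tmd_prot <- paste(rep(c("L", "V", "A", "I", "F", "L", "L"), 3L),
                      collapse = "")
    tmd_nt <- with_seed(child_seed(sim$config$seed, sim$next_gene + 777L),
                        reverse_translate(tmd_prot))
    prot_len <- nchar(gene_protein(sim, gene_id))
    sim <- insert_inframe(sim, gene_id, prot_len, tmd_nt)
    sim$domains <- rbind(sim$domains, data.frame(
      gene_id = gene_id, kind = "TMD", start = prot_len + 1L,
      end = prot_len + tmd_aa, i_evalue = 1e-20,
      stringsAsFactors = FALSE))
    sim$domains <- sim$domains[order(sim$domains$gene_id,
                                     sim$domains$start), ]
    rownames(sim$domains) <- NULL
  } else if (type == "insertion_15bp") {
    d <- sim$domains[sim$domains$gene_id == gene_id &
                       sim$domains$kind == "A", ]
    d <- d[order(d$start), ][index, ]
    if (anyNA(d$start)) stop("no A domain for insertion", call. = FALSE)
    sim <- insert_inframe(sim, gene_id, d$start - 1L + aa_offset,
                          insert_nt)
  } else if (type == "motif_knockout") {
    m <- sim_motifs()[[region]]
    d <- sim$domains[sim$domains$gene_id == gene_id &
                       sim$domains$kind == "A", ]
    d <- d[order(d$start), ][index, ]
    hit <- regexpr(m$seq, domain_seq(sim, gene_id, "A", index),
                   fixed = TRUE)
    if (hit == -1L) stop("motif region ", region, " not present",
                         call. = FALSE)
    # replace the motif's first residue codon with a proline codon,
    # which matches none of the motif alternatives
    aa_pos <- d$start - 1L + as.integer(hit)
    nt0 <- g$start + 3L * (aa_pos - 1L)
    ctg <- sim$contigs[[g$contig]]
    substr(ctg, nt0 + 1L, nt0 + 3L) <- "CCA"
    sim$contigs[[g$contig]] <- ctg
  }
  sim$events <- c(sim$events, list(list(
    type = type, gene = gene_id, kind = kind, index = index,
    region = if (type == "motif_knockout") region else NULL,
    length = if (type == "insertion_15bp") nchar(insert_nt) else NULL,
    aa_offset = if (type == "insertion_15bp") aa_offset else NULL)))
  sim
}
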