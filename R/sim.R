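# Ground-truth genome-evolution simulator: a contig bearing an ancestral
# three-part gene (C-domain, TARP linker, A-domain) that expands by
# head-to-tail tandem duplication (gene + downstream intergenic region
# duplicated together), disperses by transposition, undergoes domain
# events, and accumulates neutral Jukes-Cantor substitutions in intergenic
# DNA.  Every emitted file is a deterministic function of (config, seed).

#' Simulator configuration
#'
#' @param seed RNG seed controlling every random choice downstream.
#' @param sp_len_aa signal peptide length (aa).
#' @param c_len_aa C-domain (carbohydrate-binding module) length (aa).
#' @param n_tarp TARP repeat units in the linker.
#' @param linker_pad_aa non-repeat residues on each side of the TARP block.
#' @param a_len_aa A-domain (catalytic lyase) length (aa).
#' @param igr_length intergenic region length duplicated alongside a gene
#'   (bp; default 800).
#' @param flank_length flank length around the ancestral gene (bp; default
#'   2500).
#' @param mu substitution rate per site per unit drift time (default 1, so
#'   drift times are expected substitutions per site).
#' @param extra_contigs named integer vector of additional random contig
#'   lengths (transposition destinations).
#' @param telomeres plant telomeric repeat blocks at both ends of the main
#'   contig.
#' @param telomere_copies tandem copies per planted block.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, sp_len_aa = 20L, c_len_aa = 120L,
                       n_tarp = 9L, linker_pad_aa = 3L, a_len_aa = 200L,
                       igr_length = 800L, flank_length = 2500L, mu = 1,
                       extra_contigs = c(ctg2 = 9000L, ctg3 = 8000L),
                       telomeres = FALSE, telomere_copies = 5L) {
  stopifnot(igr_length > 0, flank_length > 0, a_len_aa > 30,
            c_len_aa > 10, mu > 0)
  structure(list(seed = as.integer(seed), sp_len_aa = sp_len_aa,
                 c_len_aa = c_len_aa, n_tarp = n_tarp,
                 linker_pad_aa = linker_pad_aa, a_len_aa = a_len_aa,
                 igr_length = as.integer(igr_length),
                 flank_length = as.integer(flank_length), mu = mu,
                 extra_contigs = extra_contigs, telomeres = telomeres,
                 telomere_copies = telomere_copies),
            class = "sim_config")
}

# catalytic motif instances planted in every ancestral A-domain, with
# their aa offsets (1-based) inside the domain
sim_motifs <- function() {
  list(A = list(seq = "RAELR", offset = 30L),
       B = list(seq = "QIH", offset = 90L),
       C = list(seq = "YFKAGAYAQ", offset = 150L))
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# reverse-translate with uniformly sampled synonymous codons
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(x) {
    cand <- names(gc)[gc == x]
    cand[sample.int(length(cand), 1L)]
  }, "")
  paste(codons, collapse = "")
}

splice_at <- function(s, pos0, insert) {
  # insert `insert` so that it starts at 0-based position pos0
  paste0(substr(s, 1L, pos0), insert, substr(s, pos0 + 1L, nchar(s)))
}

delete_span <- function(s, start0, end0) {
  paste0(substr(s, 1L, start0), substr(s, end0 + 1L, nchar(s)))
}

# shift gene and (implicitly aa-coordinate-free) bookkeeping after inserting
# `delta` bp at 0-based position pos0 on `contig`
shift_genes <- function(sim, contig, pos0, delta) {
  on_ctg <- sim$genes$contig == contig
  move <- on_ctg & sim$genes$start >= pos0
  sim$genes$start[move] <- sim$genes$start[move] + delta
  sim$genes$end[move] <- sim$genes$end[move] + delta
  sim
}

#' Build the ancestral genome
#'
#' One main contig carrying a single SP-C-A gene with a TARP linker and
#' intact catalytic motifs, flanked by random sequence, plus optional extra
#' random contigs and optional telomeric repeat blocks.
#'
#' @param config a [sim_config()].
#' @return An object of class `aly_sim`: list with `contigs` (named
#'   character vector), `genes`, `domains` data frames, `events` list,
#'   `config`.
#' @export
make_ancestral_genome <- function(config = sim_config()) {
  with_seed(config$seed, {
    sp <- paste0("M", random_protein(config$sp_len_aa - 1L))
    cdom <- random_protein(config$c_len_aa)
    tarp_units <- replicate(config$n_tarp, paste0(
      "T", sample(c("A", "P", "S", "V"), 1L), "RP"))
    linker <- paste0(random_protein(config$linker_pad_aa),
                     paste(tarp_units, collapse = ""),
                     random_protein(config$linker_pad_aa))
    adom <- random_protein(config$a_len_aa)
    for (m in sim_motifs()) {
      substr(adom, m$offset, m$offset + nchar(m$seq) - 1L) <- m$seq
    }
    protein <- paste0(sp, cdom, linker, adom)
    cds <- paste0(reverse_translate(protein), "TAA")

    aa_off <- function(n) n  # readability
    sp_start <- 1L
    c_start <- config$sp_len_aa + 1L
    link_start <- c_start + config$c_len_aa
    a_start <- link_start + nchar(linker)
    domains <- data.frame(
      gene_id = "g1",
      kind = c("SP", "C", "A"),
      start = c(sp_start, c_start, a_start),
      end = c(config$sp_len_aa, link_start - 1L,
              a_start + config$a_len_aa - 1L),
      i_evalue = 1e-20,
      stringsAsFactors = FALSE
    )

    left <- random_dna(config$flank_length)
    right <- random_dna(config$flank_length + config$igr_length)
    ctg1 <- paste0(left, cds, right)
    if (isTRUE(config$telomeres)) {
      tel <- strrep("TTAGGG", config$telomere_copies)
      ctg1 <- paste0(revcomp(tel), ctg1, tel)
      shift <- nchar(tel)
    } else shift <- 0L

    contigs <- c(ctg1 = ctg1)
    for (nm in names(config$extra_contigs)) {
      contigs[[nm]] <- random_dna(config$extra_contigs[[nm]])
    }
    genes <- data.frame(
      gene_id = "g1", contig = "ctg1",
      start = config$flank_length + shift,
      end = config$flank_length + shift + nchar(cds),
      strand = "+", stringsAsFactors = FALSE
    )
    structure(list(contigs = contigs, genes = genes, domains = domains,
                   events = list(), config = config, next_gene = 2L),
              class = "aly_sim")
  })
}

#' @export
print.aly_sim <- function(x, ...) {
  cat("aly_sim:", length(x$contigs), "contigs,", nrow(x$genes), "genes,",
      length(x$events), "events (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Duplicate a gene and its downstream intergenic region in tandem
#'
#' Emulates unequal crossing over: the gene plus the `igr_length` bp
#' immediately downstream are duplicated head-to-tail, so the new copy and
#' the new intergenic junction start identical to the template.
#'
#' @param sim an `aly_sim`.
#' @param gene_id gene to duplicate.
#' @return The updated `aly_sim`; a `tandem_duplication` record is appended
#'   to the event log.
#' @export
apply_unequal_crossover <- function(sim, gene_id) {
  g <- sim$genes[sim$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene ", gene_id, call. = FALSE)
  igr <- sim$config$igr_length
  ctg <- sim$contigs[[g$contig]]
  unit_end <- g$end + igr
  if (unit_end > nchar(ctg))
    stop("no room downstream of ", gene_id, " for the duplication unit",
         call. = FALSE)
  unit <- substr(ctg, g$start + 1L, unit_end)
  sim$contigs[[g$contig]] <- splice_at(ctg, unit_end, unit)
  sim <- shift_genes(sim, g$contig, unit_end, nchar(unit))

  new_id <- paste0("g", sim$next_gene)
  sim$next_gene <- sim$next_gene + 1L
  sim$genes <- rbind(sim$genes, data.frame(
    gene_id = new_id, contig = g$contig,
    start = g$start + nchar(unit), end = g$end + nchar(unit),
    strand = g$strand, stringsAsFactors = FALSE))
  sim$genes <- sim$genes[order(sim$genes$contig, sim$genes$start), ]
  rownames(sim$genes) <- NULL
  dd <- sim$domains[sim$domains$gene_id == gene_id, ]
  dd$gene_id <- new_id
  sim$domains <- rbind(sim$domains, dd)
  rownames(sim$domains) <- NULL
  sim$events <- c(sim$events, list(list(
    type = "tandem_duplication", template = gene_id, copy = new_id,
    contig = g$contig, junction = c(g$end, unit_end), drift_time = 0)))
  sim
}

#' Transpose a block of genes to a new genomic location
#'
#' Copies the span from the start of the first to the end of the last
#' listed gene (including any internal intergenic sequence) and inserts it
#' at `dest_pos` on `dest_contig`; the copy starts identical to the source.
#'
#' @param sim an `aly_sim`.
#' @param gene_ids contiguous source genes, in genomic order.
#' @param dest_contig destination contig name.
#' @param dest_pos 0-based insertion position on the destination contig.
#' @return The updated `aly_sim`; a `transposition` record is appended.
#' @export
apply_transposition <- function(sim, gene_ids, dest_contig, dest_pos) {
  src <- sim$genes[match(gene_ids, sim$genes$gene_id), ]
  if (anyNA(src$start)) stop("unknown gene in gene_ids", call. = FALSE)
  stopifnot(length(unique(src$contig)) == 1L,
            dest_contig %in% names(sim$contigs))
  span <- c(min(src$start), max(src$end))
  block <- substr(sim$contigs[[src$contig[1]]], span[1] + 1L, span[2])

  # genes inserted mid-contig must not split an existing gene
  dctg <- sim$genes[sim$genes$contig == dest_contig, ]
  if (any(dctg$start < dest_pos & dctg$end > dest_pos))
    stop("destination position splits a gene", call. = FALSE)

  sim$contigs[[dest_contig]] <- splice_at(sim$contigs[[dest_contig]],
                                          dest_pos, block)
  sim <- shift_genes(sim, dest_contig, dest_pos, nchar(block))

  new_ids <- character(nrow(src))
  for (i in seq_len(nrow(src))) {
    new_ids[i] <- paste0("g", sim$next_gene)
    sim$next_gene <- sim$next_gene + 1L
    off <- src$start[i] - span[1]
    sim$genes <- rbind(sim$genes, data.frame(
      gene_id = new_ids[i], contig = dest_contig,
      start = dest_pos + off, end = dest_pos + off + (src$end[i] -
                                                        src$start[i]),
      strand = src$strand[i], stringsAsFactors = FALSE))
    dd <- sim$domains[sim$domains$gene_id == src$gene_id[i], ]
    dd$gene_id <- new_ids[i]
    sim$domains <- rbind(sim$domains, dd)
  }
  sim$genes <- sim$genes[order(sim$genes$contig, sim$genes$start), ]
  rownames(sim$genes) <- NULL
  rownames(sim$domains) <- NULL
  sim$events <- c(sim$events, list(list(
    type = "transposition", source = gene_ids, copies = new_ids,
    dest_contig = dest_contig, dest_pos = dest_pos)))
  sim
}

#' Jukes-Cantor neutral drift on a DNA string
#'
#' Each site is substituted with probability
#' `p = 3/4 * (1 - exp(-4 * mu * t / 3))`, the Jukes-Cantor probability
#' that a site differs from its ancestor after drift time `t`; replacement
#' bases are uniform over the three alternatives.
#'
#' @param seq DNA string (ACGT).
#' @param t drift time (expected substitutions per site when `mu = 1`).
#' @param mu substitution rate.
#' @param seed RNG seed (applied locally).
#' @return The mutated string.
#' @export
mutate_jc <- function(seq, t, mu = 1, seed = 1L) {
  if (t == 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * mu * t / 3))
  chars <- strsplit(seq, "")[[1]]
  with_seed(seed, {
    hit <- runif(length(chars)) < p
    if (any(hit)) {
      alts <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
      chars[hit] <- vapply(chars[hit], function(b) {
        k <- sample.int(3L, 1L)
        substr(alts[[b]], k, k)
      }, "", USE.NAMES = FALSE)
    }
    paste(chars, collapse = "")
  })
}

#' Apply neutral drift to a genomic region
#'
#' @param sim an `aly_sim`.
#' @param contig contig name.
#' @param start,end 0-based half-open region (typically an intergenic
#'   region; coding regions are held fixed by default elsewhere).
#' @param t drift time.
#' @param seed RNG seed.
#' @return The updated `aly_sim` with a `drift` record appended.
#' @export
mutate_region <- function(sim, contig, start, end, t, seed = 1L) {
  ctg <- sim$contigs[[contig]]
  region <- substr(ctg, start + 1L, end)
  mutated <- mutate_jc(region, t, sim$config$mu, seed)
  sim$contigs[[contig]] <- paste0(substr(ctg, 1L, start), mutated,
                                  substr(ctg, end + 1L, nchar(ctg)))
  sim$events <- c(sim$events, list(list(
    type = "drift", contig = contig, start = start, end = end, t = t,
    seed = seed)))
  sim
}
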