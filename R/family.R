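# Domain kinds: A = catalytic polysaccharide-lyase (PL7) domain,
# C = carbohydrate-binding module (CBM32), TMD = transmembrane domain,
# SP = signal peptide.  SP/TMD come from upstream predictors as annotations.

default_domain_kind_map <- c(
  PL7 = "A", Alginate_lyase2 = "A", Alginate_lyase = "A",
  CBM32 = "C", CBM_32 = "C",
  TMD = "TMD", SP = "SP", A = "A", C = "C"
)

#' Parse HMMER domtblout domain hits
#'
#' Reads hmmscan `--domtblout` output (22 fixed whitespace-separated columns
#' plus description), filters on the independent domain E-value, resolves
#' overlapping hits, and assigns per-kind order indices (A1, A2, C1, ...)
#' from N- to C-terminus.
#'
#' @param path domtblout file.
#' @param i_evalue_max maximum independent E-value (default 1e-3; use 1e-10
#'   for CAZyme annotation).
#' @param kind_map named character vector mapping HMM target names to domain
#'   kinds; unmapped targets keep their raw name as kind.
#' @return data frame of class `domain_hits`: `gene_id`, `domain`
#'   (raw target name), `kind`, `start`, `end` (1-based protein
#'   coordinates), `i_evalue`, `order_index`, sorted by gene then start.
#' @export
read_domtblout <- function(path, i_evalue_max = 1e-3,
                           kind_map = default_domain_kind_map) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  hits <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout line ", i, ": expected >= 22 fields",
           call. = FALSE)
    ie <- suppressWarnings(as.numeric(f[13]))
    st <- suppressWarnings(as.integer(f[18]))
    en <- suppressWarnings(as.integer(f[19]))
    if (is.na(ie) || is.na(st) || is.na(en))
      stop("malformed domtblout line ", i, ": non-numeric coordinates",
           call. = FALSE)
    data.frame(gene_id = f[4], domain = f[1], start = st, end = en,
               i_evalue = ie, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), domain = character(0),
                       start = integer(0), end = integer(0),
                       i_evalue = numeric(0))
  }
  finish_domain_hits(hits, i_evalue_max, kind_map)
}

#' Read domain hits from the simple TSV schema
#'
#' Columns: `gene_id`, `kind`, `start`, `end`, `i_evalue` (tab-separated,
#' with header).  Protein coordinates are 1-based inclusive.
#'
#' @inheritParams read_domtblout
#' @return A `domain_hits` data frame (see [read_domtblout()]).
#' @export
read_domain_tsv <- function(path, i_evalue_max = 1e-3,
                            kind_map = default_domain_kind_map) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, comment.char = "#")
  names(df)[names(df) == "kind"] <- "domain"
  finish_domain_hits(df, i_evalue_max, kind_map)
}

# shared post-processing: e-value filter, overlap resolution, ordering
finish_domain_hits <- function(hits, i_evalue_max, kind_map) {
  hits <- hits[hits$i_evalue < i_evalue_max, , drop = FALSE]
  hits$kind <- ifelse(hits$domain %in% names(kind_map),
                      unname(kind_map[hits$domain]), hits$domain)
  hits <- do.call(rbind, lapply(split(hits, hits$gene_id),
                                resolve_overlaps))
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), domain = character(0),
                       start = integer(0), end = integer(0),
                       i_evalue = numeric(0), kind = character(0))
  }
  hits <- hits[order(hits$gene_id, hits$start), , drop = FALSE]
  hits$order_index <- stats::ave(
    seq_len(nrow(hits)),
    hits$gene_id, hits$kind,
    FUN = seq_along
  )
  rownames(hits) <- NULL
  class(hits) <- c("domain_hits", "data.frame")
  hits
}

# keep hits greedily by ascending i-evalue; drop a hit overlapping an
# already-kept hit by more than half the shorter hit's length
resolve_overlaps <- function(h) {
  h <- h[order(h$i_evalue, h$start), , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1L
      shorter <- min(h$end[i] - h$start[i], h$end[j] - h$start[j]) + 1L
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  h[keep, , drop = FALSE]
}

#' Classify a gene into an architecture-defined family
#'
#' Families are defined by overall domain organization: `AnTMD` genes carry
#' no C-domain but several A-domains and a C-terminal transmembrane domain;
#' `AnCn` genes carry repeated A- and C-domain units; everything else with
#' at least one A-domain is `CA`, the ancestral single C + single A
#' arrangement.  `CA` subfamilies flag C-domain copy-number oddities: `CCA`
#' (a duplicated C, architecture containing C-C-A) and `A_only` (C lost).
#'
#' Rules applied in order: (1) any TMD C-terminal to the last A-domain and
#' no C-domain gives `AnTMD`; (2) at least two A and at least one C gives
#' `AnCn`; (3) otherwise `CA`.
#'
#' @param hits `domain_hits` rows for one gene.
#' @return An object of class `family_call`: list with `gene_id`,
#'   `architecture` (e.g. `"SP-C-A"`), `family`, `subfamily`, `n_A`, `n_C`,
#'   `has_SP`, `has_TMD`.  A gene with no A-domain returns family `NA`
#'   (not a family member).
#' @examples
#' h <- data.frame(gene_id = "g", domain = c("SP", "CBM32", "PL7"),
#'                 kind = c("SP", "C", "A"),
#'                 start = c(1, 30, 200), end = c(25, 180, 420),
#'                 i_evalue = 1e-20)
#' classify_family(h)$family  # "CA"
#' @export
classify_family <- function(hits) {
  stopifnot(length(unique(hits$gene_id)) <= 1L)
  h <- hits[order(hits$start), , drop = FALSE]
  arch <- paste(h$kind, collapse = "-")
  n_A <- sum(h$kind == "A"); n_C <- sum(h$kind == "C")
  has_SP <- any(h$kind == "SP"); has_TMD <- any(h$kind == "TMD")
  if (n_A == 0L) {
    return(structure(list(gene_id = unique(hits$gene_id),
                          architecture = arch, family = NA_character_,
                          subfamily = "none", n_A = 0L, n_C = n_C,
                          has_SP = has_SP, has_TMD = has_TMD),
                     class = "family_call"))
  }
  last_A_end <- max(h$end[h$kind == "A"])
  cterm_tmd <- any(h$kind == "TMD" & h$start >= last_A_end - 10L)
  family <- if (cterm_tmd && n_C == 0L) "AnTMD"
            else if (n_A >= 2L && n_C >= 1L) "AnCn"
            else "CA"
  subfamily <- "none"
  if (family == "CA") {
    if (grepl("C-C-A", arch, fixed = TRUE)) subfamily <- "CCA"
    else if (n_C == 0L) subfamily <- "A_only"
  }
  structure(list(gene_id = unique(h$gene_id), architecture = arch,
                 family = family, subfamily = subfamily,
                 n_A = n_A, n_C = n_C,
                 has_SP = has_SP, has_TMD = has_TMD),
            class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("%s: %s -> %s%s (n_A=%d, n_C=%d)\n", x$gene_id,
              x$architecture, ifelse(is.na(x$family), "not a member",
                                     x$family),
              ifelse(x$subfamily == "none", "",
                     paste0("/", x$subfamily)), x$n_A, x$n_C))
  invisible(x)
}

#' Classify every gene in a domain hit table
#' @param hits a `domain_hits` data frame.
#' @return data frame with one row per gene: `gene_id`, `architecture`,
#'   `family`, `subfamily`, `n_A`, `n_C`, `has_SP`, `has_TMD`.
#' @export
classify_families <- function(hits) {
  rows <- lapply(split(as.data.frame(hits), hits$gene_id), function(h) {
    fc <- classify_family(h)
    data.frame(gene_id = fc$gene_id, architecture = fc$architecture,
               family = fc$family, subfamily = fc$subfamily,
               n_A = fc$n_A, n_C = fc$n_C, has_SP = fc$has_SP,
               has_TMD = fc$has_TMD, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Audit the three catalytic motif regions of an A-domain
#'
#' Checks the protein sequence for the conserved catalytic regions
#' A: `RXE(L/V)R`, B: `Q(I/V)H`, C: `YFKXGXYXQ` (X = any residue).  A
#' domain is catalytically intact only when all three regions match.
#'
#' @param a_domain_protein_seq amino-acid sequence of one A-domain.
#' @return list of class `motif_audit` with per-region logicals
#'   `region_A`, `region_B`, `region_C` and `intact`.
#' @export
audit_catalytic_motifs <- function(a_domain_protein_seq) {
  assert_scalar_string(a_domain_protein_seq, "protein sequence")
  s <- toupper(a_domain_protein_seq)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
  bad <- setdiff(unique(strsplit(s, "")[[1]]), aa)
  if (length(bad))
    stop("non-amino-acid character '", bad[1], "' in protein sequence",
         call. = FALSE)
  res <- list(region_A = grepl("R.E[LV]R", s),
              region_B = grepl("Q[IV]H", s),
              region_C = grepl("YFK.G.Y.Q", s))
  res$intact <- res$region_A && res$region_B && res$region_C
  class(res) <- "motif_audit"
  res
}

#' Detect a shared coding-sequence insertion relative to a reference domain
#'
#' Globally aligns two nucleotide A-domain sequences (end gaps penalized)
#' and reports the longest internal gap opened in the reference, i.e. the
#' longest block present in the query but absent from the reference.  A
#' shared in-frame insertion at one position across genes marks descent
#' from a common ancestor that acquired it.
#'
#' @param a_domain_nt query nucleotide sequence.
#' @param reference_a_domain_nt reference nucleotide sequence.
#' @param min_len minimum insertion length to call (default 15 bp).
#' @param require_inframe if `TRUE` (default) the insertion length must be
#'   divisible by 3.
#' @param params scoring parameters; end gaps are always penalized here.
#' @return list of class `insertion_call`: `has_insertion`,
#'   `insertion_length` (bp, 0 if none), `position` (reference coordinate
#'   preceding the insertion, 0-based).
#' @export
detect_insertion <- function(a_domain_nt, reference_a_domain_nt,
                             min_len = 15L, require_inframe = TRUE,
                             params = scoring_params()) {
  params$free_end_gaps <- FALSE
  aln <- align_overlap(a_domain_nt, reference_a_domain_nt, params)
  ref <- strsplit(aln$aligned_b, "")[[1]]
  gaps <- rle(ref == "-")
  len <- 0L; pos <- NA_integer_
  if (any(gaps$values)) {
    ends <- cumsum(gaps$lengths)
    starts <- ends - gaps$lengths + 1L
    internal <- gaps$values & starts > 1L & ends < length(ref)
    if (any(internal)) {
      k <- which(internal)[which.max(gaps$lengths[internal])]
      len <- gaps$lengths[k]
      pos <- sum(ref[seq_len(starts[k] - 1L)] != "-")
    }
  }
  has <- len >= min_len && (!require_inframe || len %% 3L == 0L)
  structure(list(has_insertion = has, insertion_length = len,
                 position = pos),
            class = "insertion_call")
}

#' Count TARP repeats in a linker sequence
#'
#' Counts non-overlapping matches of the tetrapeptide consensus
#' T-(A/P/S/V)-R-P scanning from N- to C-terminus.  These
#' arginine-containing repeats populate the low-complexity linkers between
#' the C- and A-domains and bind alginate electrostatically.
#'
#' @param linker_protein_seq amino-acid sequence (may be empty).
#' @return integer repeat count.
#' @examples
#' count_tarp_repeats("TARPTPRPTSRPTVRP")  # 4
#' @export
count_tarp_repeats <- function(linker_protein_seq) {
  if (!is.character(linker_protein_seq) || length(linker_protein_seq) != 1L)
    stop("linker must be a single string", call. = FALSE)
  if (nchar(linker_protein_seq) == 0L) return(0L)
  m <- gregexpr("T[APSV]RP", toupper(linker_protein_seq))[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Write a family classification table as TSV
#' @param families data frame from [classify_families()].
#' @param path output file.
#' @export
write_family_table <- function(families, path) {
  write.table(families, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Family census summary
#'
#' Tallies the counts usually reported for an expanded family: total family
#' members, members with at least one C-domain, members per family, loci
#' count, tandem loci (two or more genes), and unidirectional tandem loci
#' without intervening genes.
#'
#' @param families data frame from [classify_families()].
#' @param census data frame from [orientation_census()] (optional).
#' @return named list of counts.
#' @export
family_census <- function(families, census = NULL) {
  member <- !is.na(families$family)
  out <- list(
    n_family_genes = sum(member),
    n_with_C = sum(member & families$n_C >= 1L),
    n_CA = sum(member & families$family == "CA"),
    n_AnCn = sum(member & families$family == "AnCn"),
    n_AnTMD = sum(member & families$family == "AnTMD")
  )
  if (!is.null(census)) {
    out$n_loci <- nrow(census)
    out$n_tandem_loci <- sum(census$n_genes >= 2L)
    out$n_unidirectional_no_intervening <- sum(
      census$n_genes >= 2L &
        census$orientation == "unidirectional_head_to_tail" &
        !census$has_intervening_genes, na.rm = TRUE)
  }
  out
}
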