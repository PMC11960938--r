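#' Default pipeline configuration
#'
#' All tunable thresholds of the analysis in one list, each echoed into the
#' headers of stage outputs for provenance: 2.5 kb locus flanks, 20 kb
#' locus gap, overlap-alignment scoring (EDNAFULL, gap open 25, gap extend
#' 10, free end gaps), the recency shuffle null (100 shuffles, alpha 0.05,
#' 50% floor), transposition thresholds (support 100, 10 kb unlinkedness,
#' 0.5 locus coverage), and domain i-evalue cutoffs (1e-3 general, 1e-10
#' CAZyme).
#'
#' @param ... overrides for individual entries.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    flank_bp = 2500, max_gap = 20000,
    gap_open = 25, gap_extend = 10, free_end_gaps = TRUE,
    recency_alpha = 0.05, recency_floor = 50, n_shuffles = 100,
    min_support = 100, min_unique_bp = 10000, min_locus_coverage = 0.5,
    i_evalue_general = 1e-3, i_evalue_cazyme = 1e-10,
    telomere_motif = "TTAGGG", telomere_min_copies = 3,
    telomere_window = 500,
    bin_width = 50, n_bins = 10, per_bin = 25,
    seed = 1L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @return `pipeline_config` with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_scoring <- function(cfg) {
  scoring_params(gap_open = cfg$gap_open, gap_extend = cfg$gap_extend,
                 free_end_gaps = cfg$free_end_gaps)
}

# write a TSV with threshold provenance in comment headers
write_stage_tsv <- function(df, path, cfg, keys) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in keys) writeLines(paste0("# ", k, ": ", cfg[[k]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stage dispatcher wiring the package's modules into a file-in/file-out
#' pipeline.  Stages: `"simulate"` (write a seeded synthetic genome),
#' `"segment"` (loci, segments, orientation census), `"matrix"` (per-locus
#' PID3 matrices and recency calls), `"classify"` (family table),
#' `"transpose"` (transposition events), `"telomeres"` (telomere report),
#' `"profile"` (CAZyme percentages and clustering order), `"sample-hits"`
#' (bit-score-binned hit sample).
#'
#' @param stage stage name (above).
#' @param config a [pipeline_config()], or path to a YAML file.
#' @param inputs named list of input paths; which keys are needed depends
#'   on the stage: `genome`, `annotations`, `family_ids` (text file, one
#'   gene id per line), `domains` (TSV or domtblout), `tree`, `leaf_map`,
#'   `counts`, `hits`.
#' @param outdir output directory.
#' @return Named list of written output paths (and the stage's main result
#'   object), invisibly.
#' @export
run_pipeline <- function(stage = c("simulate", "segment", "matrix",
                                   "classify", "transpose", "telomeres",
                                   "profile", "sample-hits"),
                         config = pipeline_config(), inputs = list(),
                         outdir = ".") {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config_scoring(config)

  need <- function(key) {
    p <- inputs[[key]]
    if (is.null(p) || !file.exists(p))
      stop("stage '", stage, "': missing input '", key, "'",
           call. = FALSE)
    p
  }

  if (stage == "simulate") {
    fg <- simulate_family_genome(seed = config$seed)
    truth <- fg$truth[setdiff(names(fg$truth), c("tree", "leaf_map"))]
    truth$families <- as.list(truth$families)  # keep names in JSON
    paths <- emit_simulation(fg$sim, outdir, tree = fg$truth$tree,
                             leaf_map = fg$truth$leaf_map,
                             truth = truth)
    writeLines(fg$sim$genes$gene_id,
               file.path(outdir, "family_ids.txt"))
    paths[["family_ids"]] <- file.path(outdir, "family_ids.txt")
    return(invisible(as.list(paths)))
  }

  if (stage == "segment") {
    genome <- read_genome(need("genome"))
    genes <- read_gene_annotations(need("annotations"))
    check_genes_in_genome(genes, genome)
    family_ids <- readLines(need("family_ids"))
    loci <- call_loci(genes, family_ids, genome, config$max_gap)
    segments <- do.call(rbind, lapply(loci, segment_locus, genome = genome,
                                      flank = config$flank_bp))
    census <- orientation_census(loci, genes, family_ids)
    out <- list(
      loci = file.path(outdir, "loci.tsv"),
      segments_bed = file.path(outdir, "segments.bed"),
      segments_fasta = file.path(outdir, "segments.fasta"),
      orientation = file.path(outdir, "orientation.tsv"))
    write_stage_tsv(as.data.frame(loci), out$loci, config,
                    c("max_gap", "flank_bp", "seed"))
    write_segments_bed(segments, loci, out$segments_bed)
    write_segments_fasta(segments, out$segments_fasta)
    write_stage_tsv(census, out$orientation, config, "max_gap")
    out$result <- list(loci = loci, segments = segments, census = census)
    return(invisible(out))
  }

  if (stage == "matrix") {
    genome <- read_genome(need("genome"))
    genes <- read_gene_annotations(need("annotations"))
    family_ids <- readLines(need("family_ids"))
    loci <- call_loci(genes, family_ids, genome, config$max_gap)
    out <- list(recency = file.path(outdir, "recency.tsv"))
    calls <- list()
    for (l in loci) {
      seg <- segment_locus(l, genome, config$flank_bp)
      if (sum(seg$kind == "IGR") < 2L) next
      pm <- pairwise_pid_matrix(seg, params)
      mat_path <- file.path(outdir, sprintf("matrix_L%d.tsv", l$id))
      export_pid_matrix(pm, mat_path)
      out[[sprintf("matrix_L%d", l$id)]] <- mat_path
      calls[[length(calls) + 1L]] <- call_recent_duplications(
        pm, seg, config$n_shuffles, config$recency_alpha,
        config$recency_floor, seed = child_seed(config$seed, l$id),
        params = params)
    }
    rec <- if (length(calls)) do.call(rbind, calls) else
      data.frame(locus_id = integer(0))
    write_stage_tsv(rec, out$recency, config,
                    c("recency_alpha", "recency_floor", "n_shuffles",
                      "seed"))
    out$result <- rec
    return(invisible(out))
  }

  if (stage == "classify") {
    dom_path <- need("domains")
    hits <- if (grepl("domtblout", dom_path))
      read_domtblout(dom_path, config$i_evalue_general)
    else read_domain_tsv(dom_path, config$i_evalue_general)
    families <- classify_families(hits)
    out <- list(families = file.path(outdir, "families.tsv"))
    write_stage_tsv(families, out$families, config, "i_evalue_general")
    out$result <- families
    return(invisible(out))
  }

  if (stage == "transpose") {
    tree <- read_support_tree(need("tree"))
    leaf_map <- read_leaf_map(need("leaf_map"))
    genome <- read_genome(need("genome"))
    genes <- read_gene_annotations(need("annotations"))
    family_ids <- readLines(need("family_ids"))
    loci <- call_loci(genes, family_ids, genome, config$max_gap)
    events <- infer_transpositions(tree, leaf_map, loci,
                                   config$min_support,
                                   config$min_unique_bp,
                                   config$min_locus_coverage)
    out <- list(events = file.path(outdir, "transpositions.tsv"))
    write_stage_tsv(as.data.frame(events), out$events, config,
                    c("min_support", "min_unique_bp",
                      "min_locus_coverage"))
    out$result <- events
    return(invisible(out))
  }

  if (stage == "telomeres") {
    genome <- read_genome(need("genome"))
    report <- find_telomeric_ends(genome, config$telomere_motif,
                                  config$telomere_min_copies,
                                  config$telomere_window)
    out <- list(report = file.path(outdir, "telomeres.tsv"))
    write_telomere_report(report, out$report)
    out$result <- report
    return(invisible(out))
  }

  if (stage == "profile") {
    counts <- read.table(need("counts"), sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
    mat <- profile_percentages(counts)
    out <- list(profile = file.path(outdir, "cazyme_profile.tsv"))
    write_profile(mat, out$profile)
    out$result <- mat
    return(invisible(out))
  }

  # stage == "sample-hits"
  hits <- read_blast_tab(need("hits"))
  sh <- sample_blast_hits(hits, config$bin_width, config$n_bins,
                          config$per_bin, seed = config$seed)
  out <- list(sampled = file.path(outdir, "sampled_hits.tsv"))
  write_stage_tsv(sh$hits, out$sampled, config,
                  c("bin_width", "n_bins", "per_bin", "seed"))
  out$result <- sh
  invisible(out)
}
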