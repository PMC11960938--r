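#' Emit a simulation to disk
#'
#' Writes `genome.fasta`, `genes.gff3`, `domains.tsv`, `truth.json`, and,
#' when a tree is supplied, `tree.nwk` and `leaf_map.tsv`.  The seed is
#' recorded in the headers of the tabular outputs and in the truth log so
#' a run can be reproduced exactly.
#'
#' @param sim an `aly_sim`.
#' @param outdir output directory (created if missing).
#' @param tree optional Newick string or `phylo`.
#' @param leaf_map optional leaf map data frame.
#' @param truth optional extra ground-truth list stored alongside the
#'   event log.
#' @return Named character vector of written paths, invisibly.
#' @export
emit_simulation <- function(sim, outdir, tree = NULL, leaf_map = NULL,
                            truth = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fasta"),
             genes = file.path(outdir, "genes.gff3"),
             domains = file.path(outdir, "domains.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_genome(sim$contigs, paths[["genome"]])
  write_gene_annotations(sim$genes, paths[["genes"]])

  con <- file(paths[["domains"]], "w")
  writeLines(paste0("# seed: ", sim$config$seed), con)
  dom <- sim$domains
  names(dom)[names(dom) == "kind"] <- "kind"
  write.table(data.frame(gene_id = dom$gene_id, kind = dom$kind,
                         start = dom$start, end = dom$end,
                         i_evalue = dom$i_evalue),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  jsonlite::write_json(
    list(seed = sim$config$seed,
         config = unclass(sim$config),
         events = sim$events,
         truth = truth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, null = "null")

  if (!is.null(tree)) {
    paths[["tree"]] <- file.path(outdir, "tree.nwk")
    if (inherits(tree, "phylo")) {
      ape::write.tree(tree, paths[["tree"]])
    } else {
      writeLines(tree, paths[["tree"]])
    }
  }
  if (!is.null(leaf_map)) {
    paths[["leaf_map"]] <- file.path(outdir, "leaf_map.tsv")
    con <- file(paths[["leaf_map"]], "w")
    writeLines(paste0("# seed: ", sim$config$seed), con)
    write.table(leaf_map, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read a simulation truth log
#' @param path `truth.json` written by [emit_simulation()].
#' @return list with `seed`, `config`, `events`, `truth`.
#' @export
read_truth_log <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame =
                        FALSE, simplifyMatrix = FALSE)
}

#' Read a leaf map TSV
#' @param path `leaf_map.tsv` written by [emit_simulation()].
#' @return data frame with `leaf`, `gene_id`, `domain_index`, `locus_id`.
#' @export
read_leaf_map <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
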