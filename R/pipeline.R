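#' @importFrom jsonlite write_json toJSON
NULL

#' Pipeline configuration
#'
#' Bundles the paths and the per-stage parameters (each defaulting to the
#' module defaults) for \code{runPipeline}.
#'
#' @param genomeFasta,annotation input files.
#' @param outDir output directory (created if missing).
#' @param donorLen,acceptorLen splice-window sizes for intron extraction.
#' @param minCount,probPercentile,entropyPercentile,maxDepth consensus
#'   discovery parameters.
#' @param alpha Fisher significance threshold.
#' @param u12Window,topFraction branch-point scan parameters.
#' @param pwm branch-point PWM (default \code{u12BranchPwm()}).
#' @param seed integer seed for any stochastic step.
#' @return validated config list of class \code{splicePipelineConfig}.
#' @export
pipelineConfig <- function(genomeFasta, annotation, outDir,
                           donorLen = 10L, acceptorLen = 10L,
                           minCount = 100L, probPercentile = 0.95,
                           entropyPercentile = 0.05, maxDepth = 10L,
                           alpha = 0.001, u12Window = 60L,
                           topFraction = 0.05, pwm = u12BranchPwm(),
                           seed = 1L) {
  stopifnot(probPercentile > 0, probPercentile <= 1,
            entropyPercentile >= 0, entropyPercentile < 1,
            alpha >= 0, alpha <= 1, topFraction > 0, topFraction <= 1,
            minCount >= 1, maxDepth >= 2, u12Window >= ncol(pwm))
  structure(list(
    genomeFasta = genomeFasta, annotation = annotation, outDir = outDir,
    donorLen = as.integer(donorLen), acceptorLen = as.integer(acceptorLen),
    minCount = as.integer(minCount), probPercentile = probPercentile,
    entropyPercentile = entropyPercentile, maxDepth = as.integer(maxDepth),
    alpha = alpha, u12Window = as.integer(u12Window),
    topFraction = topFraction, pwm = pwm, seed = as.integer(seed)),
    class = "splicePipelineConfig")
}

#' Run the whole splicing-code pipeline
#'
#' Composes the stages in order: load + pre-filter the annotation, classify
#' exons and label introns, discover the paired-consensus table, Fisher
#' enrichment and code table, U12 branch-point scan, within-gene rank
#' co-occurrence, and a summary (per-class intron counts and fractions,
#' motif count, significant code cells). All stage outputs are written as
#' TSV under \code{outDir}, plus a JSON and a plain-text summary. Stage
#' errors are re-thrown with a stage tag.
#'
#' @param config a \code{splicePipelineConfig}.
#' @return list with all stage objects (\code{introns}, \code{table},
#'   \code{assignments}, \code{enrichment}, \code{code}, \code{u12},
#'   \code{cooccurrence}, \code{summary}), invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "splicePipelineConfig"))
  cfg <- config
  if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  loaded <- stage("load", loadGenomeAnnotation(cfg$genomeFasta,
                                               cfg$annotation))
  introns <- stage("classify", {
    x <- extractIntrons(loaded$transcripts, loaded$genome,
                        donorLen = cfg$donorLen,
                        acceptorLen = cfg$acceptorLen)
    labelIntrons(x, loaded$transcripts)
  })
  table <- stage("discover", buildPairedConsensusTable(
    introns, minCount = cfg$minCount,
    probPercentile = cfg$probPercentile,
    entropyPercentile = cfg$entropyPercentile, maxDepth = cfg$maxDepth))
  assignments <- stage("assign", assignMotifs(introns, table))
  enrichment <- stage("enrich", fisherEnrichment(
    assignments, intronClasses(introns), alpha = cfg$alpha))
  code <- stage("code-table", buildCodeTable(enrichment, alpha = cfg$alpha))
  u12 <- stage("u12-scan", scanBranchpoints(
    introns, cfg$pwm, window = cfg$u12Window,
    topFraction = cfg$topFraction, genome = loaded$genome))
  cooc <- stage("cooccur", {
    sets <- geneRankSets(introns, assignments)
    if (length(sets) >= 2) buildCooccurrence(sets) else NULL
  })

  classTab <- table(intronClasses(introns))
  summary <- list(
    n_introns = length(introns),
    n_genes = length(unique(geneIds(introns))),
    n_motifs = length(table),
    n_assigned = sum(!is.na(assignments)),
    n_code_cells_up = sum(codeEntries(code)$sig_up),
    n_code_cells_down = sum(codeEntries(code)$sig_down),
    u12_hits = sum(u12$hits$passes),
    class_counts = as.list(classTab),
    class_fractions = as.list(round(100 * classTab / sum(classTab), 2)))

  op <- function(f) file.path(cfg$outDir, f)
  stage("write", {
    writeIntronTsv(introns, op("introns.tsv"))
    writeConsensusTsv(table, op("consensus_table.tsv"))
    writeCodeTsv(code, op("code_table.tsv"))
    write.table(enrichment, op("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(u12$hits, op("u12_hits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(cooc))
      write.table(cooc, op("cooccurrence.tsv"), sep = "\t", quote = FALSE)
    write_json(summary, op("summary.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("introns: %d in %d genes", summary$n_introns,
              summary$n_genes),
      sprintf("consensus motifs: %d (assigned introns: %d)",
              summary$n_motifs, summary$n_assigned),
      sprintf("significant code cells: %d enriched, %d depleted",
              summary$n_code_cells_up, summary$n_code_cells_down),
      sprintf("U12 branch-point hits: %d", summary$u12_hits),
      "class fractions (%):",
      sprintf("  %s: %s", names(classTab),
              round(100 * classTab / sum(classTab), 2))),
      op("summary.txt"))
  })
  invisible(list(introns = introns, table = table,
                 assignments = assignments, enrichment = enrichment,
                 code = code, u12 = u12, cooccurrence = cooc,
                 summary = summary))
}
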