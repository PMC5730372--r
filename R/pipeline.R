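# End-to-end orchestration: each run* function composes the package's
# stages in the fixed order read -> fold change -> significance filter ->
# ROC -> call -> write, with stage-labeled errors and deterministic output.

#' Read a pipeline run configuration
#'
#' YAML file whose keys mirror the arguments of the \code{run*} functions
#' (input paths plus \code{alpha}, \code{min_pre_fpkm}, \code{pseudocount},
#' \code{quantile}, \code{seed}, \code{out_dir}, ...). Referenced input
#' paths are checked at read time; numeric parameters are validated by the
#' stage that consumes them.
#'
#' @param path path to the YAML configuration.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration error: file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (key in grep("(_path|_file)$", names(cfg), value = TRUE))
    if (!file.exists(cfg[[key]]))
      stop(sprintf("configuration error: %s does not exist: %s",
                   key, cfg[[key]]))
  cfg
}

.stage <- function(name, expr, outputs = character(0)) {
  tryCatch(expr, error = function(e) {
    existing <- outputs[file.exists(outputs)]
    if (length(existing)) unlink(existing)
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the simulation stage
#'
#' Generates a synthetic experiment and writes the four input tables plus
#' the ground truth: \code{expression.tsv}, \code{annotation.tsv},
#' \code{tp.txt} / \code{fp.txt}, and \code{truth.tsv}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
runSimulate <- function(config = simulationConfig(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             annotation = file.path(out_dir, "annotation.tsv"),
             tp = file.path(out_dir, "tp.txt"),
             fp = file.path(out_dir, "fp.txt"),
             truth = file.path(out_dir, "truth.tsv"))
  .stage("simulate", {
    sim <- simulateExpression(config)
    writeExpressionTable(sim$experiment, paths["expression"])
    writeAnnotationTable(sim$annotation, paths["annotation"])
    writeReferenceSets(sim$refs, paths["tp"], paths["fp"])
    con <- file(paths["truth"], open = "wb")
    writeLines(c(paste(colnames(sim$truth), collapse = "\t"),
                 do.call(paste, c(list(sim$truth$gene_id,
                                       sim$truth$is_target,
                                       sim$truth$is_off_target,
                                       .fmtNum(sim$truth$true_log2_effect),
                                       sim$truth$biotype),
                                  list(sep = "\t")))), con, sep = "\n")
    close(con)
  }, outputs = paths)
  invisible(paths)
}

#' Run the enrichment-calling stage
#'
#' Fixed stage order: read the expression table and reference sets, compute
#' fold changes, apply the significance/abundance filter, run ROC analysis,
#' call the enriched list at the chosen cutoff, and write
#' \code{enriched.tsv} and \code{roc.tsv}. Outputs carry the threshold and
#' parameter provenance in their metadata headers; a failed stage removes
#' any partial outputs.
#'
#' @param expression_path path to the expression table.
#' @param tp_path,fp_path reference gene-set files.
#' @param out_dir output directory.
#' @param label compartment name.
#' @param alpha p-value cutoff.
#' @param min_pre_fpkm abundance floor (FPKM) for the filter.
#' @param pseudocount FPKM pseudocount for fold changes.
#' @param dialect expression-table column mapping.
#' @return invisibly, a list with the \linkS4class{EnrichedList},
#'   \linkS4class{RocCurve} and output paths.
#' @export
runCall <- function(expression_path, tp_path, fp_path, out_dir,
                    label = "", alpha = 0.05, min_pre_fpkm = 0,
                    pseudocount = 0, dialect = expressionDialect()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(enriched = file.path(out_dir, "enriched.tsv"),
             roc = file.path(out_dir, "roc.tsv"))
  x <- .stage("read", readExpressionTable(expression_path,
                                          dialect = dialect))
  refs <- .stage("read", readReferenceSets(tp_path, fp_path, label = label))
  fc <- .stage("fold-change", computeFoldChanges(x, pseudocount))
  sig <- .stage("filter", filterSignificant(fc, alpha, min_pre_fpkm))
  roc <- .stage("roc", rocCurve(sig, refs))
  enriched <- .stage("call", callEnriched(sig, chosenThreshold(roc),
                                          alpha = NULL, label = label))
  # alpha was already applied by the filter stage; record it on the list
  enriched <- EnrichedList(enrichedRecords(enriched), label = label,
                           threshold = chosenThreshold(roc), alpha = alpha)
  .stage("write", {
    writeEnrichedList(enriched, paths["enriched"])
    writeRocCurve(roc, paths["roc"])
  }, outputs = paths)
  invisible(list(enriched = enriched, roc = roc, paths = paths))
}

#' Run the benchmarking stage
#'
#' @param enriched_path path to a written enriched list.
#' @param out_dir output directory (writes \code{benchmark.tsv}).
#' @param annotation_path optional annotation table.
#' @param off_target_path,reference_path optional one-id-per-line gene
#'   sets.
#' @param quantile sensitivity-floor quantile.
#' @return invisibly, a list with the \linkS4class{BenchmarkReport} and the
#'   output path.
#' @export
runBenchmark <- function(enriched_path, out_dir, annotation_path = NULL,
                         off_target_path = NULL, reference_path = NULL,
                         quantile = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, "benchmark.tsv")
  readIds <- function(p) {
    x <- trimws(readLines(p)); x[nzchar(x) & !startsWith(x, "#")]
  }
  el <- .stage("read", readEnrichedList(enriched_path))
  annot <- if (!is.null(annotation_path))
    .stage("read", readAnnotation(annotation_path)) else NULL
  offT <- if (!is.null(off_target_path))
    .stage("read", readIds(off_target_path)) else NULL
  ref <- if (!is.null(reference_path))
    .stage("read", readIds(reference_path)) else NULL
  rep <- .stage("benchmark",
                benchmarkReport(el, annot = annot, off_target = offT,
                                reference = ref, quantile = quantile))
  .stage("write", writeBenchmarkReport(rep, out), outputs = out)
  invisible(list(report = rep, path = out))
}

#' Run the compartment-overlap stage
#'
#' Intersects two written enriched lists inside a universe, writes the
#' overlap summary with global and per-class hypergeometric p-values
#' (\code{overlap.tsv}) and, when annotation is given, the lamina-candidate
#' table (\code{laminar_candidates.tsv}).
#'
#' @param enriched_a_path,enriched_b_path written enriched lists (A is
#'   treated as the nuclear list in the candidate workflow, B as the ER
#'   list).
#' @param universe_path one-id-per-line universe file; defaults to the
#'   union of both lists' records.
#' @param annotation_path optional annotation table.
#' @param out_dir output directory.
#' @return invisibly, a list with the \linkS4class{OverlapResult}, the
#'   \linkS4class{LaminarCandidates} (or NULL) and output paths.
#' @export
runOverlap <- function(enriched_a_path, enriched_b_path, out_dir,
                       universe_path = NULL, annotation_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(overlap = file.path(out_dir, "overlap.tsv"),
             laminar = file.path(out_dir, "laminar_candidates.tsv"))
  a <- .stage("read", readEnrichedList(enriched_a_path))
  b <- .stage("read", readEnrichedList(enriched_b_path))
  uni <- if (!is.null(universe_path)) {
    .stage("read", {
      x <- trimws(readLines(universe_path))
      x[nzchar(x) & !startsWith(x, "#")]
    })
  } else union(enrichedGenes(a), enrichedGenes(b))
  annot <- if (!is.null(annotation_path))
    .stage("read", readAnnotation(annotation_path)) else NULL
  ov <- .stage("overlap", overlapAnalysis(a, b, uni, annot = annot))
  lam <- if (!is.null(annot))
    .stage("overlap", laminarCandidates(a, b, annot)) else NULL
  .stage("write", {
    con <- file(paths["overlap"], open = "wb")
    writeLines(c(sprintf("# lists=%s,%s", ov@listALabel, ov@listBLabel),
                 sprintf("# N=%d n1=%d n2=%d k=%d", ov@universeSize,
                         ov@sizeA, ov@sizeB, length(ov@overlap)),
                 sprintf("# p_upper=%s", .fmtNum(ov@pUpper)),
                 "class\tk\tn1\tn2\tN\tp_upper"), con, sep = "\n")
    if (nrow(ov@perClass))
      writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%s", ov@perClass$class,
                         ov@perClass$k, ov@perClass$n1, ov@perClass$n2,
                         ov@perClass$N, .fmtNum(ov@perClass$p_upper)),
                 con, sep = "\n")
    close(con)
    if (!is.null(lam)) {
      con <- file(paths["laminar"], open = "wb")
      membership <- ifelse(lam@allOverlap %in% lam@candidates,
                           "candidate", "removed_secretory_mrna")
      writeLines(c(sprintf("# candidates=%d of %d (mRNA=%d noncoding=%d)",
                           length(lam@candidates), length(lam@allOverlap),
                           lam@classCounts[["mRNA"]],
                           lam@classCounts[["noncoding"]]),
                   "gene_id\tmembership",
                   sprintf("%s\t%s", sort(lam@allOverlap),
                           membership[order(lam@allOverlap)])),
                 con, sep = "\n")
      close(con)
    }
  }, outputs = paths)
  invisible(list(overlap = ov, laminar = lam, paths = paths))
}

#' Run the qPCR yield stage
#'
#' @param ct_path long-format Ct table (see \code{\link{readCtTable}}).
#' @param primers_path TSV with columns \code{target}, \code{efficiency}
#'   and optional \code{efficiency_sd}.
#' @param out_dir output directory (writes \code{qpcr_yields.tsv}).
#' @param input_fraction fraction of lysate removed as input.
#' @param reference optional reference target for fold enrichments.
#' @return invisibly, a list with the yields data.frame and output path.
#' @export
runQpcr <- function(ct_path, primers_path, out_dir, input_fraction = 0.2,
                    reference = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, "qpcr_yields.tsv")
  ct <- .stage("read", readCtTable(ct_path))
  pr <- .stage("read", {
    df <- utils::read.delim(primers_path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE)
    primerPairs(df$target, df$efficiency,
                if ("efficiency_sd" %in% colnames(df)) df$efficiency_sd
                else 0)
  })
  yields <- .stage("qpcr", qpcrYields(ct, pr,
                                      input_fraction = input_fraction,
                                      reference = reference))
  .stage("write", {
    con <- file(out, open = "wb")
    numCols <- vapply(yields, is.numeric, logical(1))
    body <- vapply(seq_len(nrow(yields)), function(i)
      paste(vapply(seq_along(yields), function(j)
        if (numCols[j]) .fmtNum(yields[i, j])
        else as.character(yields[i, j]), character(1)), collapse = "\t"),
      character(1))
    writeLines(c(sprintf("# input_fraction=%s", .fmtNum(input_fraction)),
                 paste(colnames(yields), collapse = "\t"), body),
               con, sep = "\n")
    close(con)
  }, outputs = out)
  invisible(list(yields = yields, path = out))
}
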