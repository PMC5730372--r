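# Fixtures built in code: tiny expression tables, annotations and oracles
# shared across the test files.

# A RipExperiment from parallel pre/post FPKM vectors (one row per gene).
makeExperiment <- function(pre, post, p = NULL, biotype = NULL,
                           ids = NULL) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(pre)))
  rownames(pre) <- rownames(post) <- ids
  RipExperiment(pre, post, pValue = p, biotype = biotype)
}

# Fold-change records with all required columns, defaulting the rest.
makeRecords <- function(gene_id, log2_fc, mean_pre = 1, mean_post = 2,
                        p_value = 0.01, biotype = NULL) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id, log2_fc = rep_len(log2_fc, n),
                   mean_pre = rep_len(mean_pre, n),
                   mean_post = rep_len(mean_post, n),
                   p_value = rep_len(p_value, n), stringsAsFactors = FALSE)
  if (!is.null(biotype)) df$biotype <- biotype
  df
}

makeEnriched <- function(gene_id, ...) {
  EnrichedList(makeRecords(gene_id, ...), label = "test")
}

# Minimal annotation rows.
makeAnnotation <- function(gene_id, biotype = "protein_coding",
                           phobius = FALSE, tmhmm = FALSE, signalp = FALSE,
                           gocc = FALSE, is_mito = FALSE,
                           submito = "unknown") {
  data.frame(gene_id = gene_id, biotype = biotype,
             secretory_phobius = rep_len(phobius, length(gene_id)),
             secretory_tmhmm = rep_len(tmhmm, length(gene_id)),
             secretory_signalp = rep_len(signalp, length(gene_id)),
             secretory_gocc = rep_len(gocc, length(gene_id)),
             is_mito = rep_len(is_mito, length(gene_id)),
             submito_location = rep_len(submito, length(gene_id)),
             stringsAsFactors = FALSE)
}

# Independent ROC oracle: exhaustively evaluates one representative
# threshold per real interval (midpoints plus the observed values and the
# open intervals beyond the extremes), counting calls directly. Returns the
# maximal Youden J and the most stringent observed-or-sentinel threshold
# attaining it.
rocBruteForce <- function(fcTp, fcFp) {
  vals <- sort(unique(c(fcTp, fcFp)))
  reps <- sort(unique(c(vals, vals - 0.5, utils::head(vals, -1) +
                          diff(vals) / 2, max(vals) + 1)))
  jAt <- function(t) {
    sum(fcTp >= t) / length(fcTp) - sum(fcFp >= t) / length(fcFp)
  }
  jBest <- max(vapply(reps, jAt, numeric(1)))
  candidates <- c(vals, Inf)
  attains <- vapply(candidates, function(t) jAt(t) >= jBest - 1e-12,
                    logical(1))
  list(j = jBest, threshold = max(candidates[attains]))
}

# Independent hypergeometric oracle: enumerate every draw of size n2 from a
# universe of size N whose first n1 elements are marked, and count draws
# overlapping the marked set in at least k elements. Exact for N <= 12.
hyperEnumerate <- function(k, n1, n2, N) {
  if (n2 == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n2)
  overlaps <- colSums(draws <= n1)
  mean(overlaps >= k)
}

# Simulation at the reference study conditions, returning the benchmark
# quantities against ground truth.
runRecoveryPipeline <- function(seed, ...) {
  cfg <- simulationConfig(seed = seed, ...)
  sim <- suppressMessages(simulateExpression(cfg))
  fc <- suppressMessages(computeFoldChanges(sim$experiment))
  sig <- suppressMessages(filterSignificant(fc, alpha = 0.05))
  roc <- suppressMessages(rocCurve(sig, sim$refs))
  el <- suppressMessages(callEnriched(sig, chosenThreshold(roc),
                                      alpha = NULL, label = "sim"))
  targets <- sim$truth$gene_id[sim$truth$is_target]
  offT <- sim$truth$gene_id[sim$truth$is_off_target]
  list(recall = recall(el, targets),
       contamination = suppressWarnings(
         contaminationFrequency(el, offT)),
       threshold = chosenThreshold(roc), j = chosenJ(roc),
       enriched = el, sim = sim)
}
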