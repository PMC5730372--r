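# Core enrichment analysis: fold changes, significance filtering, ROC
# threshold selection, and the final compartment calls.

#' Compute log2 fold enrichments
#'
#' For every gene, the fold enrichment is the ratio of post- to
#' pre-streptavidin-pulldown mean abundance, on the log2 scale:
#' \deqn{log2FC = \log_2\frac{\overline{FPKM}_{post} + c}
#'                          {\overline{FPKM}_{pre} + c}}
#' where the means are arithmetic means across replicates and \eqn{c} is an
#' optional pseudocount guarding against zero denominators (default 0, i.e.
#' the plain ratio; 0.1 FPKM is a reasonable choice when zero-FPKM genes
#' must be retained). Genes with zero mean abundance in both conditions
#' carry no information and are dropped with a logged count.
#'
#' @param x a \linkS4class{RipExperiment}.
#' @param pseudocount non-negative FPKM offset added to both means.
#' @return data.frame with columns \code{gene_id}, \code{log2_fc},
#'   \code{mean_pre}, \code{mean_post}, \code{p_value} and (when available)
#'   \code{biotype}.
#' @examples
#' pre <- matrix(c(1, 3), 1, dimnames = list("g1", NULL))
#' post <- matrix(c(8, 8), 1, dimnames = list("g1", NULL))
#' computeFoldChanges(RipExperiment(pre, post))  # log2(8/2) = 2
#' @export
computeFoldChanges <- function(x, pseudocount = 0) {
  stopifnot(is(x, "RipExperiment"))
  if (nrow(x) == 0L) stop("expression table is empty")
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("'pseudocount' must be a non-negative number")
  meanPre <- rowMeans(fpkmPre(x))
  meanPost <- rowMeans(fpkmPost(x))
  keep <- meanPre > 0 | meanPost > 0
  .logFilter("fold-change: zero in both conditions", length(keep), sum(keep))
  out <- data.frame(
    gene_id = rownames(x)[keep],
    log2_fc = log2((meanPost[keep] + pseudocount) /
                   (meanPre[keep] + pseudocount)),
    mean_pre = meanPre[keep],
    mean_post = meanPost[keep],
    p_value = unname(pValues(x)[keep]),
    stringsAsFactors = FALSE
  )
  bt <- biotypes(x)
  if (!all(is.na(bt))) out$biotype <- unname(bt[keep])
  rownames(out) <- NULL
  out
}

#' Compute combined fold changes between two post-enrichment datasets
#'
#' For paired compartment experiments (e.g. nucleus-targeted versus
#' cytosol-targeted constructs) the informative quantity is the ratio of the
#' two post-enrichment abundances:
#' \eqn{\log_2[(\overline{FPKM}_{post,A}+c)/(\overline{FPKM}_{post,B}+c)]}.
#' Positive values favor compartment A. The returned records store
#' \code{mean_post} = A and \code{mean_pre} = B so the ratio convention
#' matches \code{\link{computeFoldChanges}}. Genes present in only one
#' table are dropped with a logged count; identifiers are version-stripped
#' for the join.
#'
#' @param a,b \linkS4class{RipExperiment} objects for the two constructs.
#' @param pseudocount non-negative FPKM offset.
#' @param p_values optional named numeric vector of differential p-values
#'   for the A-versus-B comparison (names are gene identifiers); when
#'   omitted, records carry \code{NA} p-values and significance filtering
#'   must be disabled or supplied later.
#' @return data.frame as in \code{\link{computeFoldChanges}}.
#' @export
computeCombinedFoldChanges <- function(a, b, pseudocount = 0,
                                       p_values = NULL) {
  stopifnot(is(a, "RipExperiment"), is(b, "RipExperiment"))
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("'pseudocount' must be a non-negative number")
  idsA <- normalizeGeneIds(rownames(a))
  idsB <- normalizeGeneIds(rownames(b))
  common <- intersect(idsA, idsB)
  if (length(common) == 0L)
    stop("the two expression tables share no gene identifiers")
  .logFilter("combined fold-change: unmatched genes",
             length(union(idsA, idsB)), length(common))
  iA <- match(common, idsA); iB <- match(common, idsB)
  mA <- rowMeans(fpkmPost(a))[iA]
  mB <- rowMeans(fpkmPost(b))[iB]
  keep <- mA > 0 | mB > 0
  .logFilter("combined fold-change: zero in both datasets",
             length(keep), sum(keep))
  pv <- rep(NA_real_, length(common))
  if (!is.null(p_values))
    pv <- unname(p_values[match(common, normalizeGeneIds(names(p_values)))])
  out <- data.frame(
    gene_id = rownames(a)[iA][keep],
    log2_fc = log2((mA[keep] + pseudocount) / (mB[keep] + pseudocount)),
    mean_pre = mB[keep],
    mean_post = mA[keep],
    p_value = pv[keep],
    stringsAsFactors = FALSE
  )
  btA <- biotypes(a)
  if (!all(is.na(btA))) out$biotype <- unname(btA[iA][keep])
  rownames(out) <- NULL
  out
}

#' Filter fold-change records on significance and input abundance
#'
#' Retains records whose differential p-value is present and at most
#' \code{alpha}, and whose pre-enrichment mean FPKM is at least
#' \code{min_pre_fpkm} (both comparisons inclusive). Genes without a
#' p-value were not assessed by the upstream differential test and are
#' treated as not significant.
#'
#' @param records data.frame of fold-change records.
#' @param alpha p-value cutoff in (0, 1].
#' @param min_pre_fpkm abundance floor on \code{mean_pre} (FPKM).
#' @return the filtered data.frame.
#' @export
filterSignificant <- function(records, alpha = 0.05, min_pre_fpkm = 0) {
  .assertScalarNum(alpha, "alpha", lower = .Machine$double.xmin, upper = 1)
  .assertScalarNum(min_pre_fpkm, "min_pre_fpkm", lower = 0)
  keep <- !is.na(records$p_value) & records$p_value <= alpha &
    records$mean_pre >= min_pre_fpkm
  .logFilter("significance/abundance filter", nrow(records), sum(keep))
  records[keep, , drop = FALSE]
}

#' ROC analysis of candidate enrichment thresholds
#'
#' Sweeps every observed log2 fold change among the reference genes as a
#' candidate cutoff (plus an \code{Inf} sentinel at which nothing is
#' called), computing at each the true-positive rate (fraction of
#' true-positive genes called enriched) and false-positive rate. The cutoff
#' maximizing Youden's \eqn{J = TPR - FPR} is selected; when several
#' cutoffs attain the maximum, the largest (most stringent, i.e. lowest
#' contamination) is chosen and the convention is recorded in the output.
#' Reference genes absent from \code{records} are dropped from the rate
#' denominators with a logged count.
#'
#' @param records data.frame of fold-change records (typically already
#'   passed through \code{\link{filterSignificant}}, mirroring the order of
#'   operations of the calling workflow).
#' @param refs a \linkS4class{ReferenceSets} object.
#' @return A \linkS4class{RocCurve}.
#' @examples
#' rec <- data.frame(gene_id = c("t1", "t2", "f1", "f2"),
#'                   log2_fc = c(2, 3, 0, 1),
#'                   mean_pre = 1, mean_post = 1, p_value = 0.01)
#' rocCurve(rec, ReferenceSets(c("t1", "t2"), c("f1", "f2")))
#' @export
rocCurve <- function(records, refs) {
  stopifnot(is(refs, "ReferenceSets"))
  fc <- stats::setNames(records$log2_fc, normalizeGeneIds(records$gene_id))
  tpIds <- normalizeGeneIds(truePositives(refs))
  fpIds <- normalizeGeneIds(falsePositives(refs))
  tpIn <- intersect(tpIds, names(fc))
  fpIn <- intersect(fpIds, names(fc))
  .logFilter("ROC: true positives absent from records",
             length(tpIds), length(tpIn))
  .logFilter("ROC: false positives absent from records",
             length(fpIds), length(fpIn))
  if (length(tpIn) == 0L)
    stop("no true-positive reference genes present in the records")
  if (length(fpIn) == 0L)
    stop("no false-positive reference genes present in the records")
  fcTp <- fc[tpIn]; fcFp <- fc[fpIn]
  thresholds <- c(sort(unique(c(fcTp, fcFp))), Inf)
  tpr <- vapply(thresholds, function(t) mean(fcTp >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(fcFp >= t), numeric(1))
  j <- tpr - fpr
  best <- max(j)
  chosen <- max(thresholds[j >= best - 1e-12])
  RocCurve(thresholds, tpr, fpr, chosenThreshold = chosen, chosenJ = best,
           nTruePositives = length(tpIn), nFalsePositives = length(fpIn),
           label = compartmentLabel(refs))
}

#' Call a compartment-enriched transcript list
#'
#' Retains genes whose log2 fold change is at least \code{threshold}
#' (inclusive) and, unless \code{alpha} is \code{NULL}, whose p-value is
#' present and at most \code{alpha}.
#'
#' @param records data.frame of fold-change records.
#' @param threshold log2 fold-change cutoff, typically
#'   \code{chosenThreshold(rocCurve(...))}; \code{-Inf} calls every
#'   significant gene.
#' @param alpha p-value cutoff, or \code{NULL} if the records were already
#'   significance-filtered.
#' @param label compartment name recorded in the list.
#' @return An \linkS4class{EnrichedList}.
#' @export
callEnriched <- function(records, threshold, alpha = 0.05, label = "") {
  .assertScalarNum(threshold, "threshold")
  keep <- records$log2_fc >= threshold
  if (!is.null(alpha)) {
    .assertScalarNum(alpha, "alpha", lower = .Machine$double.xmin, upper = 1)
    keep <- keep & !is.na(records$p_value) & records$p_value <= alpha
  }
  .logFilter("enrichment call", nrow(records), sum(keep))
  EnrichedList(records[keep, , drop = FALSE], label = label,
               threshold = threshold,
               alpha = if (is.null(alpha)) NA_real_ else alpha)
}

#' Bidirectional calling from combined fold changes
#'
#' For a combined A-versus-B experiment (A = nucleus-targeted, B =
#' cytosol-targeted), the nuclear list is called on the combined log2 fold
#' change with the nuclear reference sets, and the cytosolic list on the
#' negated fold change with the cytosolic reference sets, so that cytosolic
#' genes satisfy \eqn{log2FC \le -t_{cyt}}. The cytosolic list's records
#' store the negated fold changes (its threshold applies to B-over-A
#' enrichment); its label metadata records the orientation. When the two
#' derived cutoffs overlap on the fold-change axis (which can only happen
#' if at least one is non-positive), genes falling in both windows are
#' removed from both lists with a logged count so the outputs stay
#' disjoint.
#'
#' @param records combined fold-change records from
#'   \code{\link{computeCombinedFoldChanges}}.
#' @param refsNuclear,refsCytosolic \linkS4class{ReferenceSets} for the two
#'   compartments (the cytosolic sets are matched against the negated fold
#'   changes).
#' @param alpha p-value cutoff applied to both calls, or \code{NULL}.
#' @return list with elements \code{nuclear} and \code{cytosolic}
#'   (\linkS4class{EnrichedList}) and \code{roc} (list of the two
#'   \linkS4class{RocCurve} objects).
#' @export
callBidirectional <- function(records, refsNuclear, refsCytosolic,
                              alpha = 0.05) {
  rocNuc <- rocCurve(records, refsNuclear)
  negated <- records
  negated$log2_fc <- -negated$log2_fc
  rocCyt <- rocCurve(negated, refsCytosolic)
  nuclear <- callEnriched(records, chosenThreshold(rocNuc), alpha = alpha,
                          label = compartmentLabel(refsNuclear))
  cytosolic <- callEnriched(negated, chosenThreshold(rocCyt), alpha = alpha,
                            label = compartmentLabel(refsCytosolic))
  shared <- intersect(normalizeGeneIds(enrichedGenes(nuclear)),
                      normalizeGeneIds(enrichedGenes(cytosolic)))
  if (length(shared)) {
    message(sprintf(
      "[bidirectional call] %d genes fell within both cutoffs and were removed from both lists",
      length(shared)))
    dropShared <- function(el) {
      rec <- enrichedRecords(el)
      rec <- rec[!normalizeGeneIds(rec$gene_id) %in% shared, , drop = FALSE]
      EnrichedList(rec, label = compartmentLabel(el),
                   threshold = callThreshold(el), alpha = callAlpha(el))
    }
    nuclear <- dropShared(nuclear)
    cytosolic <- dropShared(cytosolic)
  }
  list(nuclear = nuclear, cytosolic = cytosolic,
       roc = list(nuclear = rocNuc, cytosolic = rocCyt))
}
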