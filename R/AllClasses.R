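#' RipExperiment: pre/post-pulldown expression container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' gene-level FPKM assay whose columns are the pre-enrichment (input) and
#' post-enrichment (pulldown) replicates of a single RIP experiment.
#' \code{colData} carries a \code{condition} factor (\code{"pre"} /
#' \code{"post"}) and a \code{replicate} index; \code{rowData} carries
#' \code{gene_name}, \code{biotype} and the differential \code{p_value}
#' consumed from the upstream quantification (CuffDiff-style). FPKM values
#' must be non-negative, each condition must have at least one replicate,
#' p-values (where present) must lie in [0, 1], and gene identifiers
#' (rownames) must be unique.
#'
#' @param fpkmPre,fpkmPost numeric matrices (genes x replicates) of FPKM
#'   values; rownames are gene identifiers and must agree between the two.
#'   Vectors are accepted for single-replicate data.
#' @param pValue optional numeric vector of per-gene differential-expression
#'   p-values in [0, 1]; \code{NA} marks genes the upstream test did not
#'   assess.
#' @param biotype optional character vector of GENCODE-style biotypes
#'   (e.g. \code{"protein_coding"}, \code{"lincRNA"}).
#' @param geneName optional character vector of gene symbols.
#' @return A \code{RipExperiment} object.
#' @examples
#' pre <- matrix(c(1, 3, 2, 2), 2, dimnames = list(c("g1", "g2"), NULL))
#' post <- matrix(c(8, 8, 2, 2), 2, dimnames = list(c("g1", "g2"), NULL))
#' RipExperiment(pre, post, pValue = c(0.01, 0.8))
#' @aliases RipExperiment-class
#' @export
RipExperiment <- function(fpkmPre, fpkmPost, pValue = NULL, biotype = NULL,
                          geneName = NULL) {
  fpkmPre <- .asFpkmMatrix(fpkmPre, "fpkmPre")
  fpkmPost <- .asFpkmMatrix(fpkmPost, "fpkmPost")
  if (nrow(fpkmPre) > 0L &&
      (is.null(rownames(fpkmPre)) || is.null(rownames(fpkmPost))))
    stop("FPKM matrices must carry gene identifiers as rownames")
  if (!identical(rownames(fpkmPre), rownames(fpkmPost)))
    stop("'fpkmPre' and 'fpkmPost' must cover the same genes in the same order")
  n <- nrow(fpkmPre)
  rd <- S4Vectors::DataFrame(
    gene_name = if (is.null(geneName)) rownames(fpkmPre) else geneName,
    biotype   = if (is.null(biotype)) rep(NA_character_, n) else biotype,
    p_value   = if (is.null(pValue)) rep(NA_real_, n) else as.numeric(pValue),
    row.names = rownames(fpkmPre)
  )
  assayMat <- cbind(fpkmPre, fpkmPost)
  colnames(assayMat) <- c(paste0("pre_", seq_len(ncol(fpkmPre))),
                          paste0("post_", seq_len(ncol(fpkmPost))))
  cd <- S4Vectors::DataFrame(
    condition = factor(rep(c("pre", "post"),
                           c(ncol(fpkmPre), ncol(fpkmPost))),
                       levels = c("pre", "post")),
    replicate = c(seq_len(ncol(fpkmPre)), seq_len(ncol(fpkmPost))),
    row.names = colnames(assayMat)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = assayMat), rowData = rd, colData = cd)
  new("RipExperiment", se)
}

.asFpkmMatrix <- function(x, name) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                   dimnames = list(names(x), NULL))
  storage.mode(x) <- "double"
  if (ncol(x) < 1L) stop(sprintf("'%s' needs at least one replicate", name))
  x
}

setClass("RipExperiment", contains = "SummarizedExperiment")

setValidity("RipExperiment", function(object) {
  msg <- character(0)
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fpkm' is required")
  else if (any(SummarizedExperiment::assay(object, "fpkm") < 0, na.rm = TRUE))
    msg <- c(msg, "FPKM values must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% colnames(cd) ||
      !all(c("pre", "post") %in% cd$condition))
    msg <- c(msg, "colData$condition must contain both 'pre' and 'post'")
  rd <- SummarizedExperiment::rowData(object)
  if ("p_value" %in% colnames(rd)) {
    p <- rd$p_value
    if (any(p < 0 | p > 1, na.rm = TRUE))
      msg <- c(msg, "p-values must lie in [0, 1]")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (length(msg)) msg else TRUE
})

#' ReferenceSets: true/false-positive gene sets anchoring ROC analysis
#'
#' Compartment-specific reference gene sets used to place the enrichment
#' cutoff: \code{truePositives} are transcripts known to reside in the
#' labeled compartment (e.g. the 13 mitochondrial-encoded mRNAs for a
#' mitochondrial-matrix experiment, expressed lncRNAs for a nuclear one);
#' \code{falsePositives} are transcripts known to reside elsewhere. The two
#' sets must be disjoint (after identifier normalization) and non-empty.
#'
#' @param truePositives,falsePositives character vectors of gene identifiers.
#' @param label compartment name recorded in downstream output.
#' @return A \code{ReferenceSets} object.
#' @examples
#' ReferenceSets(c("g1", "g2"), c("g3"), label = "mito")
#' @aliases ReferenceSets-class
#' @export
ReferenceSets <- function(truePositives, falsePositives, label = "") {
  new("ReferenceSets",
      truePositives = unique(as.character(truePositives)),
      falsePositives = unique(as.character(falsePositives)),
      label = as.character(label))
}

setClass("ReferenceSets",
         representation(truePositives = "character",
                        falsePositives = "character",
                        label = "character"))

setValidity("ReferenceSets", function(object) {
  msg <- character(0)
  if (length(object@truePositives) == 0L)
    msg <- c(msg, "true-positive set is empty")
  if (length(object@falsePositives) == 0L)
    msg <- c(msg, "false-positive set is empty")
  shared <- intersect(normalizeGeneIds(object@truePositives),
                      normalizeGeneIds(object@falsePositives))
  if (length(shared))
    msg <- c(msg, sprintf(
      "true- and false-positive sets must be disjoint (%d shared)",
      length(shared)))
  if (length(msg)) msg else TRUE
})

#' RocCurve: ROC analysis of enrichment thresholds
#'
#' Holds the full ROC curve traced over candidate log2 fold-enrichment
#' cutoffs, together with the selected cutoff. At each candidate threshold
#' \eqn{t}, TPR is the fraction of (present) true-positive genes with
#' log2 fold change \eqn{\ge t} and FPR the analogous fraction of
#' false positives; the chosen threshold maximizes Youden's
#' \eqn{J = TPR - FPR}, taking the largest (most stringent) threshold on
#' ties. A sentinel threshold of \code{Inf} (nothing called) closes the
#' curve.
#'
#' @param thresholds sorted candidate log2 fold-change cutoffs (the
#'   observed reference values plus the \code{Inf} sentinel).
#' @param tpr,fpr true/false-positive rates at each threshold.
#' @param chosenThreshold,chosenJ the selected cutoff and its Youden J.
#' @param nTruePositives,nFalsePositives reference genes present in the
#'   records (the rate denominators).
#' @param label compartment name.
#' @name RocCurve-class
#' @seealso \code{\link{rocCurve}}, which constructs these objects.
#' @aliases RocCurve
#' @export RocCurve
RocCurve <- function(thresholds, tpr, fpr, chosenThreshold, chosenJ,
                     nTruePositives, nFalsePositives, label = "") {
  new("RocCurve", thresholds = thresholds, tpr = tpr, fpr = fpr,
      youden = tpr - fpr, chosenThreshold = chosenThreshold,
      chosenJ = chosenJ, nTruePositives = as.integer(nTruePositives),
      nFalsePositives = as.integer(nFalsePositives), label = label)
}

setClass("RocCurve",
         representation(thresholds = "numeric", tpr = "numeric",
                        fpr = "numeric", youden = "numeric",
                        chosenThreshold = "numeric", chosenJ = "numeric",
                        nTruePositives = "integer",
                        nFalsePositives = "integer",
                        label = "character"))

setValidity("RocCurve", function(object) {
  msg <- character(0)
  n <- length(object@thresholds)
  if (length(object@tpr) != n || length(object@fpr) != n ||
      length(object@youden) != n)
    msg <- c(msg, "thresholds, tpr, fpr and youden must have equal length")
  if (any(object@tpr < 0 | object@tpr > 1) ||
      any(object@fpr < 0 | object@fpr > 1))
    msg <- c(msg, "tpr and fpr must lie in [0, 1]")
  if (is.unsorted(object@thresholds))
    msg <- c(msg, "thresholds must be sorted increasingly")
  if (is.unsorted(rev(object@tpr)) || is.unsorted(rev(object@fpr)))
    msg <- c(msg, "tpr and fpr must be non-increasing in the threshold")
  if (any(object@youden < -1 - 1e-12 | object@youden > 1 + 1e-12))
    msg <- c(msg, "youden values must lie in [-1, 1]")
  if (length(object@chosenJ) == 1L && n > 0L &&
      abs(object@chosenJ - max(object@youden)) > 1e-12)
    msg <- c(msg, "chosenJ must equal max(youden)")
  if (length(msg)) msg else TRUE
})

#' EnrichedList: a called compartment transcript list
#'
#' The final product of an APEX-RIP calling run: the set of genes whose
#' log2 fold enrichment meets the (ROC-derived) threshold and whose
#' differential p-value passes the significance cutoff, together with the
#' provenance of both parameters and the surviving fold-change records.
#'
#' @param records data.frame of fold-change records (as produced by
#'   \code{\link{computeFoldChanges}}) restricted to the called genes.
#' @param label compartment name.
#' @param threshold log2 fold-enrichment cutoff (inclusive) used for the
#'   call.
#' @param alpha p-value cutoff used for the call; \code{NA} when no
#'   significance filter was applied.
#' @return An \code{EnrichedList} object.
#' @seealso \code{\link{callEnriched}}, which constructs these objects from
#'   fold-change records.
#' @aliases EnrichedList-class
#' @export
EnrichedList <- function(records, label = "", threshold = -Inf,
                         alpha = NA_real_) {
  new("EnrichedList", label = as.character(label),
      genes = as.character(records$gene_id),
      threshold = as.numeric(threshold), alpha = as.numeric(alpha),
      records = as.data.frame(records))
}

setClass("EnrichedList",
         representation(label = "character", genes = "character",
                        threshold = "numeric", alpha = "numeric",
                        records = "data.frame"))

setValidity("EnrichedList", function(object) {
  msg <- character(0)
  req <- c("gene_id", "log2_fc", "mean_pre", "mean_post", "p_value")
  miss <- setdiff(req, colnames(object@records))
  if (length(miss))
    msg <- c(msg, paste("records lack columns:", paste(miss, collapse = ", ")))
  else {
    if (!setequal(object@genes, object@records$gene_id))
      msg <- c(msg, "genes and records$gene_id must agree")
    if (anyDuplicated(object@records$gene_id))
      msg <- c(msg, "duplicate gene identifiers in records")
    if (any(object@records$log2_fc < object@threshold))
      msg <- c(msg, "all records must satisfy log2_fc >= threshold")
    if (!is.na(object@alpha)) {
      p <- object@records$p_value
      if (any(is.na(p)) || any(p > object@alpha))
        msg <- c(msg, "all records must satisfy p_value <= alpha")
    }
  }
  if (length(msg)) msg else TRUE
})

#' BenchmarkReport: quality metrics for a called transcript list
#'
#' Aggregates the specificity, contamination, recall, sensitivity-floor and
#' composition metrics for one \linkS4class{EnrichedList}. Rates that are
#' undefined for the given inputs (e.g. contamination of an empty list) are
#' stored as \code{NA}. All denominators are retained so every rate is
#' auditable.
#'
#' @param label compartment name.
#' @param nEnriched called list size.
#' @param contaminationFrequency,secretorySpecificity,recallValue rates in
#'   [0, 1] (or \code{NA} when undefined).
#' @param sensitivityFloorFpkm input-abundance quantile (FPKM).
#' @param biotypeCounts named integer counts per biotype.
#' @param submitoFractions named fractions over OMM/IMM/matrix/IMS.
#' @param denominators list of the denominators behind every rate.
#' @name BenchmarkReport-class
#' @seealso \code{\link{benchmarkReport}}
#' @aliases BenchmarkReport
#' @export BenchmarkReport
BenchmarkReport <- function(label, nEnriched, contaminationFrequency,
                            secretorySpecificity, recallValue,
                            sensitivityFloorFpkm, biotypeCounts,
                            submitoFractions, denominators) {
  new("BenchmarkReport", label = label, nEnriched = as.integer(nEnriched),
      contaminationFrequency = contaminationFrequency,
      secretorySpecificity = secretorySpecificity, recall = recallValue,
      sensitivityFloorFpkm = sensitivityFloorFpkm,
      biotypeCounts = biotypeCounts, submitoFractions = submitoFractions,
      denominators = denominators)
}

setClass("BenchmarkReport",
         representation(label = "character", nEnriched = "integer",
                        contaminationFrequency = "numeric",
                        secretorySpecificity = "numeric",
                        recall = "numeric",
                        sensitivityFloorFpkm = "numeric",
                        biotypeCounts = "integer",
                        submitoFractions = "numeric",
                        denominators = "list"))

setValidity("BenchmarkReport", function(object) {
  msg <- character(0)
  rates <- c(object@contaminationFrequency, object@secretorySpecificity,
             object@recall)
  if (any(rates < -1e-12 | rates > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "rates must lie in [0, 1]")
  if (length(object@biotypeCounts) &&
      sum(object@biotypeCounts) != object@nEnriched)
    msg <- c(msg, "biotype counts must sum to the list size")
  if (length(object@submitoFractions) &&
      !all(is.na(object@submitoFractions)) &&
      abs(sum(object@submitoFractions) - 1) > 1e-9)
    msg <- c(msg, "sub-mitochondrial fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' OverlapResult: intersection of two compartment lists
#'
#' Result of \code{\link{overlapAnalysis}}: the overlap between two called
#' lists inside a declared gene universe, its upper-tail hypergeometric
#' p-value, and the per-biotype-class breakdown (each class tested within
#' the universe restricted to that class).
#'
#' @param listALabel,listBLabel compartment names of the two lists.
#' @param universeSize,sizeA,sizeB hypergeometric parameters N, n1, n2.
#' @param overlap shared (normalized) gene identifiers.
#' @param pUpper upper-tail hypergeometric p-value.
#' @param perClass per-biotype-class data.frame of (k, n1, n2, N,
#'   p_upper).
#' @name OverlapResult-class
#' @aliases OverlapResult
#' @export OverlapResult
OverlapResult <- function(listALabel, listBLabel, universeSize, sizeA, sizeB,
                          overlap, pUpper, perClass) {
  new("OverlapResult", listALabel = listALabel, listBLabel = listBLabel,
      universeSize = as.integer(universeSize), sizeA = as.integer(sizeA),
      sizeB = as.integer(sizeB), overlap = overlap, pUpper = pUpper,
      perClass = perClass)
}

setClass("OverlapResult",
         representation(listALabel = "character", listBLabel = "character",
                        universeSize = "integer", sizeA = "integer",
                        sizeB = "integer", overlap = "character",
                        pUpper = "numeric", perClass = "data.frame"))

setValidity("OverlapResult", function(object) {
  msg <- character(0)
  k <- length(object@overlap)
  if (k > min(object@sizeA, object@sizeB))
    msg <- c(msg, "overlap cannot exceed the smaller list")
  if (object@sizeA > object@universeSize ||
      object@sizeB > object@universeSize)
    msg <- c(msg, "list sizes cannot exceed the universe")
  if (object@pUpper < 0 || object@pUpper > 1)
    msg <- c(msg, "pUpper must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' LaminarCandidates: interface-localized candidate transcripts
#'
#' Result of the nuclear-lamina candidate workflow
#' (\code{\link{laminarCandidates}}): the full nuclear/ER overlap, the
#' candidates that survive removal of secretory-protein mRNAs (whose
#' gene-level quantification may convolve nuclear pre-mRNAs with mature
#' ER-localized transcripts), the removed set, and candidate counts split
#' into mRNA versus noncoding classes.
#'
#' @param allOverlap all genes called in both compartments.
#' @param candidates surviving candidates after secretory-mRNA removal.
#' @param removedSecretory the removed secretory-protein mRNAs.
#' @param classCounts named integer counts (mRNA, noncoding).
#' @name LaminarCandidates-class
#' @aliases LaminarCandidates
#' @export LaminarCandidates
LaminarCandidates <- function(allOverlap, candidates, removedSecretory,
                              classCounts) {
  new("LaminarCandidates", allOverlap = allOverlap, candidates = candidates,
      removedSecretory = removedSecretory, classCounts = classCounts)
}

setClass("LaminarCandidates",
         representation(allOverlap = "character", candidates = "character",
                        removedSecretory = "character",
                        classCounts = "integer"))

setValidity("LaminarCandidates", function(object) {
  msg <- character(0)
  if (!setequal(union(object@candidates, object@removedSecretory),
                object@allOverlap))
    msg <- c(msg, "candidates and removed set must partition the overlap")
  if (length(intersect(object@candidates, object@removedSecretory)))
    msg <- c(msg, "candidates and removed set must be disjoint")
  if (length(msg)) msg else TRUE
})
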