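# Accessors and show methods for the S4 classes.

#' @rdname apexrip-accessors
setMethod("fpkmPre", "RipExperiment", function(x) {
  a <- SummarizedExperiment::assay(x, "fpkm")
  a[, SummarizedExperiment::colData(x)$condition == "pre", drop = FALSE]
})

#' @rdname apexrip-accessors
setMethod("fpkmPost", "RipExperiment", function(x) {
  a <- SummarizedExperiment::assay(x, "fpkm")
  a[, SummarizedExperiment::colData(x)$condition == "post", drop = FALSE]
})

#' @rdname apexrip-accessors
setMethod("pValues", "RipExperiment", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$p_value, rownames(x)))

#' @rdname apexrip-accessors
setMethod("biotypes", "RipExperiment", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$biotype, rownames(x)))

setMethod("show", "RipExperiment", function(object) {
  cat(sprintf("RipExperiment: %d genes, %d pre- and %d post-enrichment replicates\n",
              nrow(object), ncol(fpkmPre(object)), ncol(fpkmPost(object))))
  p <- pValues(object)
  cat(sprintf("  differential p-values present for %d genes\n",
              sum(!is.na(p))))
  invisible(NULL)
})

#' @rdname apexrip-accessors
setMethod("truePositives", "ReferenceSets", function(x) x@truePositives)

#' @rdname apexrip-accessors
setMethod("falsePositives", "ReferenceSets", function(x) x@falsePositives)

#' @rdname apexrip-accessors
setMethod("compartmentLabel", "ReferenceSets", function(x) x@label)

setMethod("show", "ReferenceSets", function(object) {
  cat(sprintf("ReferenceSets '%s': %d true positives, %d false positives\n",
              object@label, length(object@truePositives),
              length(object@falsePositives)))
  invisible(NULL)
})

#' @rdname apexrip-accessors
setMethod("chosenThreshold", "RocCurve", function(x) x@chosenThreshold)

#' @rdname apexrip-accessors
setMethod("chosenJ", "RocCurve", function(x) x@chosenJ)

#' @rdname apexrip-accessors
setMethod("compartmentLabel", "RocCurve", function(x) x@label)

#' Coerce a RocCurve to a data.frame
#'
#' @param x a \linkS4class{RocCurve}.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return data.frame with columns threshold, tpr, fpr, youden.
#' @export
as.data.frame.RocCurve <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(threshold = x@thresholds, tpr = x@tpr, fpr = x@fpr,
             youden = x@youden)
}

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve '%s': %d thresholds over %d TP / %d FP reference genes\n",
              object@label, length(object@thresholds),
              object@nTruePositives, object@nFalsePositives))
  cat(sprintf("  chosen log2 fold-change cutoff: %.4g (Youden J = %.4g; ties broken toward the most stringent cutoff)\n",
              object@chosenThreshold, object@chosenJ))
  invisible(NULL)
})

#' @rdname apexrip-accessors
setMethod("enrichedGenes", "EnrichedList", function(x) x@genes)

#' @rdname apexrip-accessors
setMethod("enrichedRecords", "EnrichedList", function(x) x@records)

#' @rdname apexrip-accessors
setMethod("callThreshold", "EnrichedList", function(x) x@threshold)

#' @rdname apexrip-accessors
setMethod("callAlpha", "EnrichedList", function(x) x@alpha)

#' @rdname apexrip-accessors
setMethod("compartmentLabel", "EnrichedList", function(x) x@label)

#' Number of called genes in an EnrichedList
#' @param x an \code{EnrichedList}.
#' @return integer list size.
#' @aliases length,EnrichedList-method
#' @export
setMethod("length", "EnrichedList", function(x) length(x@genes))

setMethod("show", "EnrichedList", function(object) {
  cat(sprintf("EnrichedList '%s': %d genes\n", object@label,
              length(object@genes)))
  cat(sprintf("  log2 fold-change threshold >= %.4g; p-value cutoff %s\n",
              object@threshold,
              if (is.na(object@alpha)) "none" else format(object@alpha)))
  invisible(NULL)
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport '%s' (%d enriched genes)\n",
              object@label, object@nEnriched))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4g", v)
  d <- object@denominators
  cat(sprintf("  contamination frequency: %s (off-target set n = %s)\n",
              fmt(object@contaminationFrequency),
              d$off_target %||% "?"))
  cat(sprintf("  secretory specificity:   %s (of %s mRNAs; matched-only %s of %s)\n",
              fmt(object@secretorySpecificity), d$n_mrna %||% "?",
              fmt(d$secretory_specificity_matched %||% NA_real_),
              d$n_mrna_matched %||% "?"))
  cat(sprintf("  recall:                  %s (reference n = %s)\n",
              fmt(object@recall), d$reference %||% "?"))
  cat(sprintf("  sensitivity floor:       %s FPKM (quantile %s)\n",
              fmt(object@sensitivityFloorFpkm), d$quantile %||% "?"))
  if (length(object@biotypeCounts)) {
    cat("  biotype counts: ",
        paste(names(object@biotypeCounts), object@biotypeCounts,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (length(object@submitoFractions) &&
      !all(is.na(object@submitoFractions))) {
    cat(sprintf("  sub-mitochondrial fractions (n annotated = %s): %s\n",
                d$submito_annotated %||% "?",
                paste(names(object@submitoFractions),
                      sprintf("%.3f", object@submitoFractions),
                      sep = "=", collapse = ", ")))
  }
  invisible(NULL)
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult '%s' x '%s': k = %d (n1 = %d, n2 = %d, N = %d)\n",
              object@listALabel, object@listBLabel, length(object@overlap),
              object@sizeA, object@sizeB, object@universeSize))
  cat(sprintf("  hypergeometric P(X >= k) = %.4g\n", object@pUpper))
  if (nrow(object@perClass)) {
    cat("  per-class tests:\n")
    print(object@perClass, row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "LaminarCandidates", function(object) {
  cat(sprintf("LaminarCandidates: %d candidates of %d overlapping RNAs (%d secretory mRNAs removed)\n",
              length(object@candidates), length(object@allOverlap),
              length(object@removedSecretory)))
  cat("  classes: ",
      paste(names(object@classCounts), object@classCounts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
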