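# Benchmarking of called transcript lists: specificity, contamination,
# recall, sensitivity floor, and composition.

.joinAnnotation <- function(geneIds, annot) {
  idx <- match(normalizeGeneIds(geneIds),
               normalizeGeneIds(annot$gene_id))
  nUnmatched <- sum(is.na(idx))
  if (nUnmatched > 0L)
    message(sprintf("[annotation join] %d of %d genes lack annotation",
                    nUnmatched, length(geneIds)))
  list(idx = idx, nUnmatched = nUnmatched)
}

#' Contamination frequency of an enriched list
#'
#' The ratio of enriched off-target RNAs to total enriched RNAs -- the
#' specificity measure of the calling workflow. Off-target genes are
#' typically markers of a different compartment (e.g. ER-proximal mRNAs
#' when benchmarking a nuclear list).
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param off_target character vector of off-target gene identifiers.
#' @return fraction in [0, 1]; \code{NA} with a warning for an empty list.
#' @examples
#' el <- EnrichedList(data.frame(gene_id = letters[1:4], log2_fc = 1,
#'                               mean_pre = 1, mean_post = 2, p_value = 0.01))
#' contaminationFrequency(el, c("c", "x"))  # 0.25
#' @export
contaminationFrequency <- function(list, off_target) {
  stopifnot(is(list, "EnrichedList"))
  g <- normalizeGeneIds(enrichedGenes(list))
  if (length(g) == 0L) {
    warning("contamination frequency undefined for an empty list")
    return(NA_real_)
  }
  length(intersect(g, normalizeGeneIds(off_target))) / length(g)
}

#' Secretory specificity of an ER-proximal mRNA list
#'
#' Fraction of the list's protein-coding genes carrying any form of
#' secretory annotation (logical OR of the Phobius, TMHMM, SignalP and GOCC
#' prediction flags). Genes without an annotation record are counted in the
#' denominator as unannotated (the conservative convention); the
#' matched-only variant, which drops them, is attached as attributes
#' \code{matched_only} and \code{n_matched} alongside \code{n_mrna} and
#' \code{n_unmatched}. The protein-coding restriction uses the records'
#' biotype when present, otherwise the annotation table's.
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param annot annotation data.frame from \code{\link{readAnnotation}}.
#' @return fraction in [0, 1] with denominator attributes; \code{NA} with a
#'   warning when the list contains no protein-coding genes.
#' @export
secretorySpecificity <- function(list, annot) {
  stopifnot(is(list, "EnrichedList"))
  rec <- enrichedRecords(list)
  join <- .joinAnnotation(rec$gene_id, annot)
  bt <- if ("biotype" %in% colnames(rec)) rec$biotype
        else annot$biotype[join$idx]
  isMrna <- !is.na(bt) & bt == "protein_coding"
  if (!any(isMrna)) {
    warning("secretory specificity undefined: no protein-coding genes in list")
    return(NA_real_)
  }
  idx <- join$idx[isMrna]
  anySec <- rep(FALSE, sum(isMrna))
  matched <- !is.na(idx)
  if (any(matched)) {
    flags <- annot[idx[matched], .SECRETORY_FLAGS, drop = FALSE]
    anySec[matched] <- Reduce(`|`, flags)
  }
  out <- mean(anySec)
  attr(out, "matched_only") <- if (any(matched)) mean(anySec[matched])
                               else NA_real_
  attr(out, "n_mrna") <- sum(isMrna)
  attr(out, "n_matched") <- sum(matched)
  attr(out, "n_unmatched") <- sum(!matched)
  out
}

#' Recall (coverage) of a reference gene set
#'
#' Fraction of a reference standard set recovered by the enriched list --
#' e.g. expressed lncRNAs for a nuclear list, or established ER-resident
#' protein mRNAs for an ER list.
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param reference non-empty character vector of reference identifiers.
#' @return fraction in [0, 1].
#' @export
recall <- function(list, reference) {
  stopifnot(is(list, "EnrichedList"))
  reference <- unique(normalizeGeneIds(reference))
  if (length(reference) == 0L)
    stop("'reference' must be non-empty")
  length(intersect(normalizeGeneIds(enrichedGenes(list)), reference)) /
    length(reference)
}

#' Sensitivity floor: input-abundance quantile of enriched genes
#'
#' The q-th quantile (linear interpolation between order statistics) of the
#' pre-enrichment mean FPKM over the called genes. At the default q = 0.05
#' this is the "95\% of enriched transcripts have input abundances of X
#' FPKM or higher" statistic: a lower floor indicates a method that can
#' enrich lowly expressed transcripts.
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param quantile quantile in (0, 1); default 0.05.
#' @return FPKM value; \code{NA} with a warning for an empty list.
#' @export
sensitivityFloor <- function(list, quantile = 0.05) {
  stopifnot(is(list, "EnrichedList"))
  .assertScalarNum(quantile, "quantile", lower = .Machine$double.xmin,
                   upper = 1 - .Machine$double.eps)
  v <- enrichedRecords(list)$mean_pre
  if (length(v) == 0L) {
    warning("sensitivity floor undefined for an empty list")
    return(NA_real_)
  }
  unname(stats::quantile(v, probs = quantile, type = 7))
}

#' Biotype composition of an enriched list
#'
#' Counts of called genes per GENCODE biotype; genes without a biotype are
#' binned as \code{"unknown"}. Counts always sum to the list size.
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param annot optional annotation data.frame used to fill in biotypes
#'   missing from the list's records.
#' @return named integer vector of counts.
#' @export
biotypeComposition <- function(list, annot = NULL) {
  stopifnot(is(list, "EnrichedList"))
  rec <- enrichedRecords(list)
  if (nrow(rec) == 0L) return(integer(0))
  bt <- if ("biotype" %in% colnames(rec)) rec$biotype
        else rep(NA_character_, nrow(rec))
  if (!is.null(annot) && any(is.na(bt))) {
    idx <- match(normalizeGeneIds(rec$gene_id),
                 normalizeGeneIds(annot$gene_id))
    fill <- is.na(bt) & !is.na(idx)
    bt[fill] <- annot$biotype[idx[fill]]
  }
  bt[is.na(bt)] <- "unknown"
  tab <- table(bt)
  stats::setNames(as.integer(tab), names(tab))
}

#' Sub-mitochondrial composition of an enriched list
#'
#' Among the list's genes encoding mitochondrial proteins, the fraction
#' destined for each sub-mitochondrial compartment (outer membrane, inner
#' membrane, matrix, intermembrane space). Only genes with an available
#' compartment-specific annotation (\code{submito_location != "unknown"})
#' enter the denominator, which is attached as attribute
#' \code{n_annotated}.
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param annot annotation data.frame from \code{\link{readAnnotation}}.
#' @return named numeric vector of fractions over OMM/IMM/matrix/IMS
#'   summing to 1; \code{NA}s with a warning when no gene is annotated.
#' @export
submitoComposition <- function(list, annot) {
  stopifnot(is(list, "EnrichedList"))
  join <- .joinAnnotation(enrichedGenes(list), annot)
  loc <- annot$submito_location[join$idx]
  loc <- loc[!is.na(loc) & loc != "unknown"]
  lev <- setdiff(.SUBMITO_LEVELS, "unknown")
  if (length(loc) == 0L) {
    warning("no genes with sub-mitochondrial annotation in list")
    out <- stats::setNames(rep(NA_real_, length(lev)), lev)
    attr(out, "n_annotated") <- 0L
    return(out)
  }
  tab <- table(factor(loc, levels = lev))
  out <- as.numeric(tab) / length(loc)
  names(out) <- lev
  attr(out, "n_annotated") <- length(loc)
  out
}

#' Transmembrane enrichment among mitochondrial mRNAs
#'
#' Compares the fraction of TMHMM-predicted transmembrane proteins among
#' the list's mitochondrial genes with the same fraction in a background
#' set of mitochondrial genes (e.g. all nuclear-encoded mitochondrial
#' genes).
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param annot annotation data.frame (uses \code{is_mito} and
#'   \code{secretory_tmhmm}).
#' @param background non-empty character vector of background gene
#'   identifiers.
#' @return named numeric vector \code{c(fraction_in_list,
#'   fraction_in_background)} with denominator attributes; \code{NA}s with
#'   a warning when the list has no mitochondrial genes.
#' @export
transmembraneEnrichment <- function(list, annot, background) {
  stopifnot(is(list, "EnrichedList"))
  if (length(background) == 0L) stop("'background' must be non-empty")
  tmFraction <- function(ids) {
    idx <- match(normalizeGeneIds(ids), normalizeGeneIds(annot$gene_id))
    idx <- idx[!is.na(idx)]
    idx <- idx[annot$is_mito[idx]]
    if (length(idx) == 0L) return(c(NA_real_, 0L))
    c(mean(annot$secretory_tmhmm[idx]), length(idx))
  }
  inList <- tmFraction(enrichedGenes(list))
  inBg <- tmFraction(background)
  if (is.na(inList[1L]))
    warning("no mitochondrial genes in the enriched list")
  out <- c(fraction_in_list = inList[1L],
           fraction_in_background = inBg[1L])
  attr(out, "n_list") <- as.integer(inList[2L])
  attr(out, "n_background") <- as.integer(inBg[2L])
  out
}

#' Assemble a benchmark report for an enriched list
#'
#' Convenience wrapper computing all benchmark metrics that the supplied
#' inputs permit; metrics whose inputs are missing are reported as
#' \code{NA}. Denominators for every rate are stored alongside the rates.
#'
#' @param list an \linkS4class{EnrichedList}.
#' @param annot optional annotation data.frame.
#' @param off_target optional off-target identifier set.
#' @param reference optional reference (standard) identifier set.
#' @param quantile sensitivity-floor quantile.
#' @return A \linkS4class{BenchmarkReport}.
#' @export
benchmarkReport <- function(list, annot = NULL, off_target = NULL,
                            reference = NULL, quantile = 0.05) {
  stopifnot(is(list, "EnrichedList"))
  n <- length(list)
  contam <- if (!is.null(off_target) && n > 0L)
    contaminationFrequency(list, off_target) else NA_real_
  spec <- specAttrs <- NULL
  if (!is.null(annot) && n > 0L) {
    spec <- suppressWarnings(secretorySpecificity(list, annot))
    specAttrs <- attributes(spec)
  }
  rec <- if (!is.null(reference) && n >= 0L)
    recall(list, reference) else NA_real_
  floor <- if (n > 0L) sensitivityFloor(list, quantile) else NA_real_
  submito <- if (!is.null(annot) && n > 0L)
    suppressWarnings(submitoComposition(list, annot))
  else stats::setNames(rep(NA_real_, 4L),
                       setdiff(.SUBMITO_LEVELS, "unknown"))
  BenchmarkReport(
    label = compartmentLabel(list), nEnriched = n,
    contaminationFrequency = contam,
    secretorySpecificity = if (is.null(spec)) NA_real_ else as.numeric(spec),
    recallValue = rec,
    sensitivityFloorFpkm = floor,
    biotypeCounts = biotypeComposition(list, annot),
    submitoFractions = as.numeric(submito) |>
      stats::setNames(names(submito)),
    denominators = list(
      off_target = if (is.null(off_target)) NULL else length(unique(
        normalizeGeneIds(off_target))),
      n_mrna = specAttrs$n_mrna,
      n_mrna_matched = specAttrs$n_matched,
      secretory_specificity_matched = specAttrs$matched_only,
      n_unmatched = specAttrs$n_unmatched,
      reference = if (is.null(reference)) NULL else length(unique(
        normalizeGeneIds(reference))),
      quantile = quantile,
      submito_annotated = attr(submito, "n_annotated"),
      quantile_method = "linear interpolation between order statistics (type 7)"
    ))
}

#' Write a benchmark report as TSV
#'
#' One metric per row with its value and denominator, so published-style
#' rates remain auditable from the file alone.
#'
#' @param x a \linkS4class{BenchmarkReport}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBenchmarkReport <- function(x, path) {
  stopifnot(is(x, "BenchmarkReport"))
  d <- x@denominators
  rows <- rbind(
    c("n_enriched", as.character(x@nEnriched), ""),
    c("contamination_frequency", .fmtNum(x@contaminationFrequency),
      as.character(d$off_target %||% "")),
    c("secretory_specificity", .fmtNum(x@secretorySpecificity),
      as.character(d$n_mrna %||% "")),
    c("secretory_specificity_matched_only",
      .fmtNum(d$secretory_specificity_matched %||% NA_real_),
      as.character(d$n_mrna_matched %||% "")),
    c("recall", .fmtNum(x@recall), as.character(d$reference %||% "")),
    c("sensitivity_floor_fpkm", .fmtNum(x@sensitivityFloorFpkm),
      .fmtNum(d$quantile %||% NA_real_)))
  if (length(x@biotypeCounts))
    rows <- rbind(rows, cbind(paste0("biotype_", names(x@biotypeCounts)),
                              as.character(x@biotypeCounts), ""))
  if (length(x@submitoFractions) && !all(is.na(x@submitoFractions)))
    rows <- rbind(rows, cbind(paste0("submito_", names(x@submitoFractions)),
                              .fmtNum(x@submitoFractions),
                              as.character(d$submito_annotated %||% "")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", x@label),
               sprintf("# quantile_method=%s", d$quantile_method %||% ""),
               "metric\tvalue\tdenominator",
               apply(rows, 1L, paste, collapse = "\t")), con, sep = "\n")
  invisible(path)
}
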