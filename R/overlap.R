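# Compartment-intersection analysis: set intersections, hypergeometric
# significance, the nuclear-lamina candidate workflow, and Venn counts.

#' Intersect two enriched lists
#'
#' Exact set intersection on version-normalized gene identifiers.
#'
#' @param a,b \linkS4class{EnrichedList} objects or character vectors of
#'   gene identifiers.
#' @return character vector of shared (normalized) identifiers.
#' @export
intersectLists <- function(a, b) {
  intersect(.asGeneSet(a), .asGeneSet(b))
}

.asGeneSet <- function(x) {
  ids <- if (is(x, "EnrichedList")) enrichedGenes(x) else as.character(x)
  unique(normalizeGeneIds(ids))
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} where \eqn{X} counts the overlap of two sets of sizes
#' \eqn{n_1} and \eqn{n_2} drawn without replacement from a universe of
#' size \eqn{N}. Computed in log space (via \code{phyper}), so it is
#' numerically stable for universes well beyond \eqn{10^5} genes.
#'
#' @param k observed overlap, \eqn{0 \le k \le \min(n_1, n_2)}.
#' @param n1,n2 sizes of the two sets, each at most \code{N}.
#' @param N universe size.
#' @return probability in [0, 1].
#' @examples
#' hypergeometricUpper(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeometricUpper <- function(k, n1, n2, N) {
  for (v in list(k = k, n1 = n1, n2 = n2, N = N))
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("k, n1, n2 and N must be single non-negative integers")
  if (n1 > N || n2 > N)
    stop("n1 and n2 cannot exceed the universe size N")
  if (k > min(n1, n2))
    stop("k cannot exceed min(n1, n2)")
  if (k == 0) return(1)
  stats::phyper(k - 1, m = n1, n = N - n1, k = n2, lower.tail = FALSE)
}

#' Overlap analysis of two compartment lists
#'
#' Computes the intersection of two called lists within a declared gene
#' universe and its upper-tail hypergeometric p-value, globally and per
#' biotype class (each class tested within the universe restricted to that
#' class, so the per-class overlap counts sum to the global count). The
#' enrichment (upper) tail only is tested. An optional Benjamini-Hochberg
#' correction across the per-class tests can be requested; it is off by
#' default, matching the convention of reporting raw hypergeometric
#' p-values.
#'
#' @param a,b \linkS4class{EnrichedList} objects (or character vectors).
#' @param universe character vector of gene identifiers containing every
#'   gene of both lists; a sensible default is all genes expressed at
#'   >= 1 FPKM in both experiments. The choice is recorded in the result.
#' @param annot optional annotation data.frame supplying biotypes for the
#'   per-class tests; genes without annotation are classed
#'   \code{"unknown"}.
#' @param bhCorrect apply Benjamini-Hochberg correction across per-class
#'   p-values (adds column \code{p_adjusted}).
#' @return An \linkS4class{OverlapResult}.
#' @export
overlapAnalysis <- function(a, b, universe, annot = NULL,
                            bhCorrect = FALSE) {
  setA <- .asGeneSet(a); setB <- .asGeneSet(b)
  uni <- unique(normalizeGeneIds(as.character(universe)))
  stray <- setdiff(union(setA, setB), uni)
  if (length(stray))
    stop(sprintf("universe does not contain %d list gene(s): %s",
                 length(stray),
                 paste(utils::head(stray, 5L), collapse = ", ")))
  ov <- intersect(setA, setB)
  pGlobal <- hypergeometricUpper(length(ov), length(setA), length(setB),
                                 length(uni))
  perClass <- data.frame(class = character(0), k = integer(0),
                         n1 = integer(0), n2 = integer(0), N = integer(0),
                         p_upper = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(annot)) {
    idx <- match(uni, normalizeGeneIds(annot$gene_id))
    cls <- ifelse(is.na(idx), "unknown", annot$biotype[idx])
    for (cl in sort(unique(cls))) {
      uc <- uni[cls == cl]
      ac <- intersect(setA, uc); bc <- intersect(setB, uc)
      kc <- length(intersect(ac, bc))
      perClass <- rbind(perClass, data.frame(
        class = cl, k = kc, n1 = length(ac), n2 = length(bc),
        N = length(uc),
        p_upper = hypergeometricUpper(kc, length(ac), length(bc),
                                      length(uc)),
        stringsAsFactors = FALSE))
    }
    if (bhCorrect)
      perClass$p_adjusted <- stats::p.adjust(perClass$p_upper,
                                             method = "BH")
  }
  OverlapResult(
    listALabel = if (is(a, "EnrichedList")) compartmentLabel(a) else "A",
    listBLabel = if (is(b, "EnrichedList")) compartmentLabel(b) else "B",
    universeSize = length(uni), sizeA = length(setA), sizeB = length(setB),
    overlap = ov, pUpper = pGlobal, perClass = perClass)
}

#' Nominate nuclear-lamina candidate RNAs
#'
#' The nuclear envelope's intermembrane space is contiguous with the ER
#' lumen, so an ER-lumen-anchored pulldown can also capture RNAs at the
#' nuclear lamina. Candidates are the transcripts called enriched in
#' \emph{both} the nuclear and the ER experiments, minus protein-coding
#' genes carrying any secretory annotation -- for those, gene-level
#' quantification may convolve nuclear-retained pre-mRNAs with mature
#' ER-localized transcripts, so they are set aside as potential false
#' positives. Surviving candidates are split into mRNA (protein-coding)
#' versus noncoding classes. The result is invariant to the order of the
#' two input lists.
#'
#' @param nuclear,er \linkS4class{EnrichedList} objects for the nuclear and
#'   ER compartments.
#' @param annot annotation data.frame supplying biotypes and secretory
#'   flags; genes without annotation are retained and classed as
#'   noncoding-or-unknown.
#' @return A \linkS4class{LaminarCandidates} object.
#' @export
laminarCandidates <- function(nuclear, er, annot) {
  ov <- intersectLists(nuclear, er)
  idx <- match(ov, normalizeGeneIds(annot$gene_id))
  bt <- ifelse(is.na(idx), NA_character_, annot$biotype[idx])
  isMrna <- !is.na(bt) & bt == "protein_coding"
  anySec <- rep(FALSE, length(ov))
  ok <- !is.na(idx)
  if (any(ok))
    anySec[ok] <- Reduce(`|`, annot[idx[ok], .SECRETORY_FLAGS,
                                    drop = FALSE])
  removed <- ov[isMrna & anySec]
  cand <- setdiff(ov, removed)
  candMrna <- isMrna[match(cand, ov)]
  LaminarCandidates(
    allOverlap = ov, candidates = cand, removedSecretory = removed,
    classCounts = c(mRNA = sum(candMrna),
                    noncoding = sum(!candMrna)))
}

#' Exclusive-region counts for 2- or 3-way Venn comparisons
#'
#' Counts every exclusive region of a 2- or 3-set Venn decomposition of
#' called lists; regions sum to the size of the union.
#'
#' @param ... two or three \linkS4class{EnrichedList} objects or character
#'   vectors, or a single list of them. Region names use the lists'
#'   compartment labels (or A/B/C).
#' @return named integer vector of exclusive-region counts.
#' @examples
#' vennCounts(c("a", "b"), c("b", "c"))
#' @export
vennCounts <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !is(args[[1L]], "EnrichedList"))
    args <- args[[1L]]
  if (length(args) < 2L || length(args) > 3L)
    stop("vennCounts supports exactly 2 or 3 lists")
  sets <- lapply(args, .asGeneSet)
  labels <- vapply(seq_along(args), function(i) {
    if (is(args[[i]], "EnrichedList") &&
        nzchar(compartmentLabel(args[[i]])))
      compartmentLabel(args[[i]]) else LETTERS[i]
  }, character(1))
  n <- length(sets)
  member <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  counts <- apply(member, 1L, function(m) {
    inSets <- Reduce(intersect, sets[as.logical(m)])
    outSets <- sets[!as.logical(m)]
    length(setdiff(inSets, Reduce(union, c(outSets, list(character(0))))))
  })
  names(counts) <- apply(member, 1L, function(m)
    paste(labels[as.logical(m)], collapse = "&"))
  stats::setNames(as.integer(counts), names(counts))
}
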