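# Reading and writing the delimited-text interchange formats: expression
# tables (generic wide or CuffDiff-style), annotation tables / GENCODE GTF,
# reference gene sets, and the enriched-list / ROC output files.

#' Column mapping for expression tables
#'
#' Describes how the columns of a delimited expression table map onto the
#' fields of a \linkS4class{RipExperiment}. Replicate FPKM columns are
#' selected by regular expression so that any number of replicates can be
#' ingested without per-file configuration.
#'
#' @param gene_id,gene_name,biotype,p_value column names; \code{gene_name},
#'   \code{biotype} and \code{p_value} may be \code{NULL} when absent.
#' @param fpkm_pre,fpkm_post regular expressions matched against the header
#'   to select the pre-/post-enrichment replicate columns.
#' @return A named list usable as the \code{dialect} argument of
#'   \code{\link{readExpressionTable}}.
#' @examples
#' expressionDialect()
#' cuffdiffDialect()
#' @export
expressionDialect <- function(gene_id = "gene_id", gene_name = "gene_name",
                              biotype = "biotype", p_value = "p_value",
                              fpkm_pre = "^fpkm_pre", fpkm_post = "^fpkm_post") {
  list(gene_id = gene_id, gene_name = gene_name, biotype = biotype,
       p_value = p_value, fpkm_pre = fpkm_pre, fpkm_post = fpkm_post)
}

#' @rdname expressionDialect
#' @export
cuffdiffDialect <- function() {
  expressionDialect(gene_id = "gene_id", gene_name = "gene",
                    biotype = NULL, p_value = "p_value",
                    fpkm_pre = "^value_1$", fpkm_post = "^value_2$")
}

#' Read a gene-level expression table
#'
#' Parses a delimited text file of per-gene FPKM values measured before and
#' after streptavidin enrichment, plus the upstream differential p-value,
#' into a \linkS4class{RipExperiment}. Lines starting with \code{#} are
#' treated as comments.
#'
#' @param path path to the delimited file.
#' @param dialect column mapping, see \code{\link{expressionDialect}}.
#' @param sep field separator (tab by default, \code{","} for CSV).
#' @return A \linkS4class{RipExperiment}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tfpkm_pre_1\tfpkm_pre_2\tfpkm_post_1\tfpkm_post_2\tp_value",
#'              "g1\t1\t3\t8\t8\t0.01"), tf)
#' readExpressionTable(tf)
#' @export
readExpressionTable <- function(path, dialect = expressionDialect(),
                                sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  hdr <- colnames(df)
  needCol <- function(col, what) {
    if (!is.null(col) && !col %in% hdr)
      stop(sprintf("configuration error: column '%s' (%s) not found in %s",
                   col, what, path), call. = FALSE)
  }
  needCol(dialect$gene_id, "gene_id")
  preCols <- grep(dialect$fpkm_pre, hdr, value = TRUE)
  postCols <- grep(dialect$fpkm_post, hdr, value = TRUE)
  if (length(preCols) == 0L)
    stop(sprintf("configuration error: no column matches fpkm_pre pattern '%s'",
                 dialect$fpkm_pre), call. = FALSE)
  if (length(postCols) == 0L)
    stop(sprintf("configuration error: no column matches fpkm_post pattern '%s'",
                 dialect$fpkm_post), call. = FALSE)
  if (nrow(df) == 0L) {
    warning(sprintf("expression table %s contains a header but no rows", path))
  }
  ids <- as.character(df[[dialect$gene_id]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("validation error: duplicate gene_id(s): %s",
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  asNum <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  pre <- asNum(preCols); post <- asNum(postCols)
  for (m in list(pre, post)) {
    bad <- which(apply(m < 0, 1L, any))
    if (length(bad))
      stop(sprintf("validation error: negative FPKM at row %d (gene %s)",
                   bad[1L], ids[bad[1L]]), call. = FALSE)
  }
  getOpt <- function(col) {
    if (is.null(col) || !col %in% hdr) NULL else df[[col]]
  }
  pv <- getOpt(dialect$p_value)
  if (!is.null(pv)) pv <- suppressWarnings(as.numeric(pv))
  RipExperiment(pre, post, pValue = pv,
                biotype = getOpt(dialect$biotype),
                geneName = getOpt(dialect$gene_name))
}

.SUBMITO_LEVELS <- c("OMM", "IMM", "matrix", "IMS", "unknown")
.SECRETORY_FLAGS <- c("secretory_phobius", "secretory_tmhmm",
                      "secretory_signalp", "secretory_gocc")

#' Read a gene annotation table or GENCODE-style GTF
#'
#' Annotation records carry, per gene: the GENCODE biotype, the four
#' secretory-prediction flags (Phobius, TMHMM, SignalP, GO cellular
#' component), a mitochondrial flag, and the predicted sub-mitochondrial
#' destination (OMM / IMM / matrix / IMS / unknown). Files ending in
#' \code{.gtf} are parsed as GENCODE-dialect GTF, taking gene-level records'
#' \code{gene_type} attribute as the biotype; all prediction flags then
#' default to \code{FALSE}. Other files are read as delimited text with at
#' least \code{gene_id} and \code{biotype} columns; missing flag columns
#' default to \code{FALSE}, missing \code{submito_location} to
#' \code{"unknown"}.
#'
#' @param path path to a TSV annotation table or a \code{.gtf} file.
#' @param sep field separator for the delimited form.
#' @return data.frame with columns \code{gene_id}, \code{biotype},
#'   the four \code{secretory_*} logical flags, \code{is_mito} and
#'   \code{submito_location}.
#' @export
readAnnotation <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
    return(.readAnnotationGtf(path))
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (col in c("gene_id", "biotype"))
    if (!col %in% colnames(df))
      stop(sprintf("configuration error: column '%s' not found in %s",
                   col, path), call. = FALSE)
  out <- data.frame(gene_id = as.character(df$gene_id),
                    biotype = as.character(df$biotype),
                    stringsAsFactors = FALSE)
  for (fl in c(.SECRETORY_FLAGS, "is_mito")) {
    out[[fl]] <- if (fl %in% colnames(df)) .asLogical(df[[fl]], fl)
                 else rep(FALSE, nrow(df))
  }
  out$submito_location <-
    if ("submito_location" %in% colnames(df)) {
      sm <- as.character(df$submito_location)
      bad <- setdiff(unique(sm), .SUBMITO_LEVELS)
      if (length(bad))
        stop(sprintf("validation error: unknown submito_location '%s'",
                     bad[1L]), call. = FALSE)
      sm
    } else rep("unknown", nrow(df))
  conflict <- which(out$submito_location != "unknown" & !out$is_mito)
  if (length(conflict))
    stop(sprintf(
      "validation error: submito_location set but is_mito is FALSE for gene %s (row %d)",
      out$gene_id[conflict[1L]], conflict[1L]), call. = FALSE)
  out
}

.asLogical <- function(x, name) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- !v %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "na")
  if (any(bad))
    stop(sprintf("validation error: cannot parse '%s' as logical in column %s",
                 x[which(bad)[1L]], name), call. = FALSE)
  out
}

.readAnnotationGtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop(sprintf("unparseable GTF %s: %s", path,
                                conditionMessage(e)), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(md)) {
    keep <- md$type == "gene"
    gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  }
  if (!"gene_id" %in% colnames(md))
    stop(sprintf("GTF %s lacks a gene_id attribute", path), call. = FALSE)
  bt <- if ("gene_type" %in% colnames(md)) md$gene_type
        else if ("gene_biotype" %in% colnames(md)) md$gene_biotype
        else rep("unknown", length(gr))
  n <- length(gr)
  data.frame(gene_id = as.character(md$gene_id),
             biotype = as.character(bt),
             secretory_phobius = rep(FALSE, n),
             secretory_tmhmm = rep(FALSE, n),
             secretory_signalp = rep(FALSE, n),
             secretory_gocc = rep(FALSE, n),
             is_mito = rep(FALSE, n),
             submito_location = rep("unknown", n),
             stringsAsFactors = FALSE)
}

#' Read true/false-positive reference gene sets
#'
#' Each file lists one gene identifier per line (blank lines and \code{#}
#' comments ignored).
#'
#' @param tpPath,fpPath paths to the true-positive and false-positive lists.
#' @param label compartment name.
#' @return A \linkS4class{ReferenceSets} object.
#' @export
readReferenceSets <- function(tpPath, fpPath, label = "") {
  readSet <- function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
    x <- readLines(p)
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
  }
  ReferenceSets(readSet(tpPath), readSet(fpPath), label = label)
}

#' Write / read an enriched transcript list
#'
#' The on-disk form is a TSV with \code{#}-prefixed metadata lines recording
#' the compartment label, the chosen log2 fold-change threshold, the p-value
#' cutoff and the tie-break convention, followed by the called records
#' sorted by descending fold change (ties by gene identifier). Numbers are
#' written so that \code{readEnrichedList} reproduces them exactly, and
#' re-writing an unchanged list yields a byte-identical file.
#'
#' @param x an \linkS4class{EnrichedList}.
#' @param path output (input) file path.
#' @return \code{writeEnrichedList} returns \code{path} invisibly;
#'   \code{readEnrichedList} returns the reconstructed
#'   \linkS4class{EnrichedList}.
#' @export
writeEnrichedList <- function(x, path) {
  stopifnot(is(x, "EnrichedList"))
  rec <- x@records
  ord <- order(-rec$log2_fc, rec$gene_id)
  rec <- rec[ord, , drop = FALSE]
  cols <- c("gene_id", "log2_fc", "mean_pre", "mean_post", "p_value",
            intersect("biotype", colnames(rec)))
  rec <- rec[, cols, drop = FALSE]
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop(sprintf("cannot write %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  meta <- c(sprintf("# label=%s", x@label),
            sprintf("# threshold=%s", .fmtNum(x@threshold)),
            sprintf("# alpha=%s", .fmtNum(x@alpha)),
            "# threshold_rule=log2_fc >= threshold; ties broken toward the most stringent cutoff")
  writeLines(meta, con, sep = "\n")
  body <- vapply(seq_len(nrow(rec)), function(i) {
    vals <- vapply(cols, function(cl) {
      v <- rec[[cl]][i]
      if (is.numeric(v)) .fmtNum(v) else as.character(v)
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
  writeLines(c(paste(cols, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

#' @rdname writeEnrichedList
#' @export
readEnrichedList <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key) {
    ln <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(sprintf("^# %s=", key), "", ln[1L])
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character"))
  asNum <- function(s) if (is.na(s) || s == "NA") NA_real_
                       else as.numeric(s)
  EnrichedList(df, label = getMeta("label"),
               threshold = asNum(getMeta("threshold")),
               alpha = asNum(getMeta("alpha")))
}

#' Write a ROC curve as TSV
#'
#' Emits threshold, TPR, FPR and Youden J per candidate cutoff, with
#' \code{#} metadata recording the chosen cutoff.
#'
#' @param x a \linkS4class{RocCurve}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRocCurve <- function(x, path) {
  stopifnot(is(x, "RocCurve"))
  df <- as.data.frame(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", x@label),
               sprintf("# chosen_threshold=%s", .fmtNum(x@chosenThreshold)),
               sprintf("# chosen_j=%s", .fmtNum(x@chosenJ)),
               sprintf("# n_tp=%d", x@nTruePositives),
               sprintf("# n_fp=%d", x@nFalsePositives),
               paste(colnames(df), collapse = "\t")), con, sep = "\n")
  body <- apply(df, 1L, function(r) paste(.fmtNum(as.numeric(r)),
                                          collapse = "\t"))
  if (length(body)) writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Write an expression table
#'
#' Inverse of \code{\link{readExpressionTable}} under the default dialect:
#' columns \code{gene_id}, \code{gene_name}, \code{biotype},
#' \code{fpkm_pre_<i>}, \code{fpkm_post_<i>}, \code{p_value}. Numbers are
#' formatted so that a write/read round trip reproduces every field
#' exactly.
#'
#' @param x a \linkS4class{RipExperiment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(x, path) {
  stopifnot(is(x, "RipExperiment"))
  pre <- fpkmPre(x); post <- fpkmPost(x)
  rd <- SummarizedExperiment::rowData(x)
  hdr <- c("gene_id", "gene_name", "biotype",
           paste0("fpkm_pre_", seq_len(ncol(pre))),
           paste0("fpkm_post_", seq_len(ncol(post))),
           "p_value")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con, sep = "\n")
  if (nrow(x) > 0L) {
    body <- vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], as.character(rd$gene_name[i]),
              as.character(rd$biotype[i]),
              .fmtNum(pre[i, ]), .fmtNum(post[i, ]),
              .fmtNum(rd$p_value[i])), collapse = "\t")
    }, character(1))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Write an annotation table
#'
#' Inverse of the delimited form accepted by \code{\link{readAnnotation}}.
#'
#' @param x annotation data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationTable <- function(x, path) {
  cols <- c("gene_id", "biotype", .SECRETORY_FLAGS, "is_mito",
            "submito_location")
  stopifnot(all(cols %in% colnames(x)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  if (nrow(x))
    writeLines(do.call(paste, c(lapply(x[cols], as.character),
                                list(sep = "\t"))), con, sep = "\n")
  invisible(path)
}

#' Write reference gene sets
#'
#' One identifier per line, one file per set.
#'
#' @param x a \linkS4class{ReferenceSets} object.
#' @param tpPath,fpPath output paths for the two sets.
#' @return invisibly, \code{c(tpPath, fpPath)}.
#' @export
writeReferenceSets <- function(x, tpPath, fpPath) {
  stopifnot(is(x, "ReferenceSets"))
  for (p in list(list(tpPath, truePositives(x)),
                 list(fpPath, falsePositives(x)))) {
    con <- file(p[[1L]], open = "wb")
    writeLines(p[[2L]], con, sep = "\n")
    close(con)
  }
  invisible(c(tpPath, fpPath))
}
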