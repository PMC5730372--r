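#' Normalize gene identifiers
#'
#' Strips a trailing GENCODE/Ensembl version suffix (\code{".N"}) from gene
#' identifiers so that tables annotated against different GENCODE releases
#' can be joined. The operation is idempotent; identifiers without a version
#' suffix are returned unchanged. Version suffixes are stripped only for
#' joins -- output files always preserve the identifiers as read.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of the same length with version suffixes removed.
#' @examples
#' normalizeGeneIds(c("ENSG00000123456.7", "ENSG00000000003"))
#' @export
normalizeGeneIds <- function(ids) {
  if (!is.character(ids)) ids <- as.character(ids)
  sub("\\.[0-9]+$", "", ids)
}

# Numeric formatting used for all on-disk output: shortest representation
# that survives an exact read -> write -> read round trip.
.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

# Filter logging: every count-changing step reports (n_before, n_after).
.logFilter <- function(stage, n_before, n_after) {
  if (n_before != n_after) {
    message(sprintf("[%s] %d -> %d records (%d removed)",
                    stage, n_before, n_after, n_before - n_after))
  }
  invisible(NULL)
}

# Vectorised Welch (unequal-variance) two-sample t-test on the rows of two
# matrices. Degenerate rows (zero variance in both groups) get p = 1 when the
# group means agree and p = 0 otherwise, so that noise-free simulations
# remain usable by the significance filter.
.welchP <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1L, stats::var); vy <- apply(y, 1L, stats::var)
  sem2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(sem2)
  df <- sem2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- sem2 == 0 | !is.finite(df)
  p[degen] <- ifelse(abs(mx[degen] - my[degen]) < .Machine$double.eps^0.5,
                     1, 0)
  p
}

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
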