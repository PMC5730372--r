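# qRT-PCR percent-yield analysis: volume-corrected Ct values, delta-Ct
# yields scaled by per-primer amplification efficiency, and first-order
# propagation of measurement uncertainty.

#' Primer-pair table with amplification efficiencies
#'
#' Per-primer amplification efficiencies (epsilon, the per-cycle gain above
#' doubling-at-1: a perfect primer has epsilon = 1) are consumed as input,
#' e.g. from amplification-curve fitting software. Pairs with efficiency
#' below 0.90 are flagged for exclusion rather than silently dropped.
#'
#' @param target character vector of target gene names.
#' @param efficiency per-cycle amplification efficiencies in [0, 1].
#' @param efficiency_sd non-negative standard errors of the efficiencies.
#' @return data.frame with columns \code{target}, \code{efficiency},
#'   \code{efficiency_sd} and logical \code{flagged}.
#' @export
primerPairs <- function(target, efficiency, efficiency_sd = 0) {
  if (any(efficiency < 0 | efficiency > 1))
    stop("amplification efficiencies must lie in [0, 1]")
  if (any(efficiency_sd < 0))
    stop("'efficiency_sd' must be non-negative")
  data.frame(target = as.character(target),
             efficiency = as.numeric(efficiency),
             efficiency_sd = rep_len(as.numeric(efficiency_sd),
                                     length(target)),
             flagged = efficiency < 0.90,
             stringsAsFactors = FALSE)
}

#' Volume-corrected mean Ct
#'
#' Averages Ct replicates and, for input samples, subtracts
#' \eqn{\log_{1+\epsilon}(1 / f)} cycles, where \eqn{f} is the fraction of
#' the lysate removed as input (default 0.2): lowering the input Ct by the
#' number of cycles the full lysate would have saved makes yields relative
#' to total lysate rather than to the input aliquot. Pulldown (RIP)
#' samples are left uncorrected. An additional per-sample cycle
#' \code{offset} is available for other volume corrections; it is
#' subtracted as-is.
#'
#' @param ct numeric vector of replicate Ct values (> 0).
#' @param efficiency per-cycle amplification efficiency epsilon in (0, 1].
#' @param sample \code{"input"} or \code{"RIP"}.
#' @param input_fraction fraction of lysate taken as input, in (0, 1].
#' @param offset extra cycles to subtract (default 0).
#' @return list with elements \code{value} (corrected mean Ct), \code{sd}
#'   (sample standard deviation of the replicates, n - 1), \code{se} (the
#'   standard error of the mean, \code{sd / sqrt(n)} -- the uncertainty the
#'   yield pipeline propagates, since the corrected Ct is a replicate
#'   mean) and \code{n_replicates}.
#' @examples
#' correctedCt(c(20, 20.2), efficiency = 1, sample = "input",
#'             input_fraction = 0.25)  # subtracts log2(4) = 2 cycles
#' @export
correctedCt <- function(ct, efficiency, sample = c("RIP", "input"),
                        input_fraction = 0.2, offset = 0) {
  sample <- match.arg(sample)
  if (!is.numeric(ct) || length(ct) < 1L || any(ct <= 0))
    stop("'ct' must contain positive cycle values")
  .assertScalarNum(efficiency, "efficiency",
                   lower = .Machine$double.xmin, upper = 1)
  if (!is.numeric(input_fraction) || length(input_fraction) != 1L ||
      input_fraction <= 0 || input_fraction > 1)
    stop("'input_fraction' must lie in (0, 1]")
  corr <- if (sample == "input")
    log(1 / input_fraction, base = 1 + efficiency) else 0
  s <- if (length(ct) > 1L) stats::sd(ct) else 0
  list(value = mean(ct) - corr - offset, sd = s,
       se = s / sqrt(length(ct)), n_replicates = length(ct))
}

#' Percent yield by the delta-Ct method
#'
#' \deqn{yield = 100 \times (1+\epsilon)^{\Delta C_t}, \quad
#'       \Delta C_t = C_t^{input,corr} - C_t^{RIP,corr}}
#' A pulldown recovering all of the input gives \eqn{\Delta C_t = 0} and
#' 100\% yield; each cycle the pulldown lags behind divides the yield by
#' \eqn{1+\epsilon}. Uncertainty: \eqn{\sigma_{\Delta C_t}} by the
#' difference rule, then the first-derivative rule for the exponential,
#' \eqn{\sigma_{yield} = \sigma_{\Delta C_t} \times yield \times
#' \ln(1+\epsilon)}.
#'
#' @param ct_input,ct_rip corrected Ct values as \code{list(value, sd)}
#'   (from \code{\link{correctedCt}}) or plain numbers (sd 0).
#' @param efficiency per-cycle amplification efficiency in (0, 1].
#' @param target optional target name carried into the result.
#' @return list with \code{target}, \code{delta_ct}, \code{delta_ct_sd},
#'   \code{yield_percent} and \code{yield_sd}.
#' @examples
#' percentYield(18, 19, efficiency = 1)  # one cycle behind: 50%
#' @export
percentYield <- function(ct_input, ct_rip, efficiency, target = NA_character_) {
  ct_input <- .asMeasurement(ct_input)
  ct_rip <- .asMeasurement(ct_rip)
  .assertScalarNum(efficiency, "efficiency",
                   lower = .Machine$double.xmin, upper = 1)
  d <- propagateDifference(ct_input$value, ct_rip$value,
                           ct_input$sd, ct_rip$sd)
  yield <- 100 * (1 + efficiency)^d$value
  list(target = target,
       delta_ct = d$value, delta_ct_sd = d$sd,
       yield_percent = yield,
       yield_sd = d$sd * yield * log(1 + efficiency))
}

.asMeasurement <- function(x) {
  if (is.list(x)) {
    stopifnot(!is.null(x$value))
    # outputs of correctedCt carry a standard error of the mean; that is
    # the uncertainty of the corrected value, so it takes precedence
    list(value = as.numeric(x$value),
         sd = as.numeric(x$se %||% x$sd %||% 0))
  } else list(value = as.numeric(x), sd = 0)
}

#' Propagate uncertainty through a difference
#'
#' For \eqn{D = A - B} with independent errors,
#' \eqn{\sigma_D = \sqrt{\sigma_A^2 + \sigma_B^2}}.
#'
#' @param a,b the two values.
#' @param sd_a,sd_b their non-negative standard errors.
#' @return list with \code{value} and \code{sd}.
#' @examples
#' propagateDifference(10, 4, 3, 4)  # sd 5
#' @export
propagateDifference <- function(a, b, sd_a = 0, sd_b = 0) {
  if (any(c(sd_a, sd_b) < 0)) stop("standard errors must be non-negative")
  list(value = a - b, sd = sqrt(sd_a^2 + sd_b^2))
}

#' Propagate uncertainty through a product or quotient
#'
#' For \eqn{P = A \times B} or \eqn{A / B} with independent errors,
#' relative variances add:
#' \eqn{\sigma_P = |P| \sqrt{(\sigma_A/A)^2 + (\sigma_B/B)^2}}. Zero-valued
#' operands have undefined relative error and are rejected.
#'
#' @param a,b the two values (non-zero).
#' @param sd_a,sd_b their non-negative standard errors.
#' @param op \code{"multiply"} or \code{"divide"}.
#' @return list with \code{value} and \code{sd}.
#' @examples
#' propagateProduct(10, 10, 1, 1)  # 100 +/- 14.14
#' @export
propagateProduct <- function(a, b, sd_a = 0, sd_b = 0,
                             op = c("multiply", "divide")) {
  op <- match.arg(op)
  if (a == 0 || b == 0)
    stop("relative error undefined for zero-valued operands")
  if (any(c(sd_a, sd_b) < 0)) stop("standard errors must be non-negative")
  value <- if (op == "multiply") a * b else a / b
  list(value = value,
       sd = abs(value) * sqrt((sd_a / a)^2 + (sd_b / b)^2))
}

#' Propagate uncertainty through a differentiable function
#'
#' First-derivative approximation \eqn{\sigma_{f(x)} = \sigma_x |f'(x)|}.
#' When no analytic derivative is supplied it is estimated by central
#' difference with step \eqn{10^{-6} \max(|x|, 1)}.
#'
#' @param x the value.
#' @param sd_x its non-negative standard error.
#' @param f a scalar function.
#' @param dfdx optional analytic derivative function.
#' @return list with \code{value} (\code{f(x)}) and \code{sd}.
#' @examples
#' propagateFunction(3, 0.1, function(x) x^2)  # sd 0.6
#' @export
propagateFunction <- function(x, sd_x, f, dfdx = NULL) {
  if (sd_x < 0) stop("'sd_x' must be non-negative")
  deriv <- if (!is.null(dfdx)) dfdx(x) else {
    h <- 1e-6 * max(abs(x), 1)
    (f(x + h) - f(x - h)) / (2 * h)
  }
  list(value = f(x), sd = sd_x * abs(deriv))
}

#' Fold enrichment of a target yield over a reference gene
#'
#' Ratio of the target's percent yield to that of a reference gene
#' (e.g. a cytosolic marker such as GAPDH), with the quotient rule for the
#' uncertainty.
#'
#' @param target,reference yield results from \code{\link{percentYield}}
#'   (the reference yield must be positive).
#' @return list with \code{fold} and \code{sd}.
#' @export
foldEnrichmentVsReference <- function(target, reference) {
  if (reference$yield_percent <= 0)
    stop("reference yield must be positive")
  p <- propagateProduct(target$yield_percent, reference$yield_percent,
                        target$yield_sd, reference$yield_sd, op = "divide")
  list(fold = p$value, sd = p$sd)
}

#' Read a long-format Ct table
#'
#' Expects columns \code{sample} (\code{input} / \code{RIP}),
#' \code{target}, \code{replicate} and \code{ct}.
#'
#' @param path path to the TSV file.
#' @return data.frame of Ct measurements.
#' @export
readCtTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "target", "replicate", "ct")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("configuration error: Ct table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(df$sample %in% c("input", "RIP")))
    stop("validation error: 'sample' must be 'input' or 'RIP'")
  if (any(df$ct <= 0)) stop("validation error: Ct values must be positive")
  df
}

#' Percent yields for every target on a qPCR plate
#'
#' Applies \code{\link{correctedCt}} and \code{\link{percentYield}} per
#' target, and optionally reports each target's fold enrichment over a
#' reference gene.
#'
#' @param ct_table long-format Ct data.frame (see \code{\link{readCtTable}}).
#' @param primers primer table from \code{\link{primerPairs}}; targets
#'   flagged for low efficiency are still computed but keep their flag in
#'   the output.
#' @param input_fraction fraction of lysate removed as input.
#' @param reference optional reference target name for fold enrichments.
#' @return data.frame with one row per target: delta-Ct, percent yield and
#'   propagated uncertainties, efficiency, low-efficiency flag, and (when a
#'   reference is given) fold enrichment over the reference.
#' @export
qpcrYields <- function(ct_table, primers, input_fraction = 0.2,
                       reference = NULL) {
  targets <- unique(ct_table$target)
  known <- targets %in% primers$target
  if (!all(known))
    stop(sprintf("no primer efficiency for target(s): %s",
                 paste(targets[!known], collapse = ", ")))
  one <- function(tg) {
    eff <- primers$efficiency[match(tg, primers$target)]
    ctIn <- ct_table$ct[ct_table$target == tg & ct_table$sample == "input"]
    ctRip <- ct_table$ct[ct_table$target == tg & ct_table$sample == "RIP"]
    if (length(ctIn) == 0L || length(ctRip) == 0L)
      stop(sprintf("target %s lacks input or RIP measurements", tg))
    y <- percentYield(
      correctedCt(ctIn, eff, "input", input_fraction = input_fraction),
      correctedCt(ctRip, eff, "RIP"),
      efficiency = eff, target = tg)
    data.frame(target = tg, efficiency = eff,
               flagged = primers$flagged[match(tg, primers$target)],
               delta_ct = y$delta_ct, delta_ct_sd = y$delta_ct_sd,
               yield_percent = y$yield_percent, yield_sd = y$yield_sd,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(targets, one))
  if (!is.null(reference)) {
    if (!reference %in% out$target)
      stop(sprintf("reference target '%s' not on the plate", reference))
    ref <- out[out$target == reference, ]
    refY <- list(yield_percent = ref$yield_percent, yield_sd = ref$yield_sd)
    folds <- lapply(seq_len(nrow(out)), function(i)
      foldEnrichmentVsReference(
        list(yield_percent = out$yield_percent[i],
             yield_sd = out$yield_sd[i]), refY))
    out$fold_vs_reference <- vapply(folds, `[[`, numeric(1), "fold")
    out$fold_sd <- vapply(folds, `[[`, numeric(1), "sd")
  }
  rownames(out) <- NULL
  out
}
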