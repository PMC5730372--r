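# Synthetic-data generation with known ground truth. The generator emulates
# the statistical structure the calling workflow assumes: a heavy-tailed
# (log-normal) FPKM abundance distribution, multiplicative log-normal
# replicate noise, compartment-specific multiplicative enrichment of target
# genes, milder off-target leakage, a stand-in differential test, and qPCR
# plates produced by inverting the delta-Ct yield equation.

#' Simulation configuration
#'
#' Validated parameter set for \code{\link{simulateExpression}}. The
#' defaults describe a typical proximity-labeling pulldown: 5000 genes with
#' log-normal baseline FPKM (log10 mean 0, sd 1, so about half the genes
#' exceed 1 FPKM), three replicates per condition with 20\% replicate
#' coefficient of variation, 15\% of genes truly enriched at a mean effect
#' of 2 log2 units (with 0.1 log2 units of per-gene jitter), and 5\% of
#' genes subject to mild off-target leakage (0.5 log2 units).
#'
#' @param n_genes number of genes.
#' @param fraction_enriched fraction of genes truly enriched in the
#'   compartment.
#' @param fraction_off_target fraction subject to off-target leakage
#'   (\code{fraction_enriched + fraction_off_target <= 1}).
#' @param effect_log2 mean true log2 enrichment of targets.
#' @param contaminant_log2 mean log2 enrichment of off-target leakage.
#' @param effect_jitter_sd per-gene sd of the true effect (log2 units).
#' @param baseline_log10_fpkm_mean,baseline_log10_fpkm_sd parameters of the
#'   log10-normal baseline abundance distribution.
#' @param replicate_cv coefficient of variation of FPKM across replicates
#'   (log-normal multiplicative noise, mean 1).
#' @param n_replicates replicates per condition (>= 2).
#' @param biotype_mix named fractions per biotype, summing to 1.
#' @param secretory_rate_targets,secretory_rate_background probability that
#'   a target / non-target protein-coding gene carries secretory
#'   annotation.
#' @param mito_rate fraction of genes encoding mitochondrial proteins.
#' @param submito_known_rate fraction of mitochondrial genes with an
#'   available sub-mitochondrial annotation.
#' @param submito_mix fractions over OMM/IMM/matrix/IMS for annotated
#'   mitochondrial genes (defaults follow a typical bulk mitochondrial
#'   proteome: 18\% OMM, 42\% IMM, 30\% matrix, 10\% IMS).
#' @param ref_set_size genes sampled per reference set for ROC anchoring.
#'   The default (500, comparable to the reference list sizes used for
#'   real compartments) keeps the false-positive set usable after the
#'   significance prefilter: unenriched background genes carry roughly
#'   uniform p-values, so only a few percent of them survive it, and the
#'   set must be large enough that the surviving handful still anchors
#'   the false-positive rate.
#' @param seed integer seed; all randomness flows from it through one
#'   substream per generated table.
#' @return validated configuration list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_genes = 5000L,
                             fraction_enriched = 0.15,
                             fraction_off_target = 0.05,
                             effect_log2 = 2,
                             contaminant_log2 = 0.5,
                             effect_jitter_sd = 0.1,
                             baseline_log10_fpkm_mean = 0,
                             baseline_log10_fpkm_sd = 1,
                             replicate_cv = 0.2,
                             n_replicates = 3L,
                             biotype_mix = c(protein_coding = 0.60,
                                             lincRNA = 0.20,
                                             antisense = 0.15,
                                             processed_pseudogene = 0.05),
                             secretory_rate_targets = 0.95,
                             secretory_rate_background = 0.5,
                             mito_rate = 0.05,
                             submito_known_rate = 0.3,
                             submito_mix = c(OMM = 0.18, IMM = 0.42,
                                             matrix = 0.30, IMS = 0.10),
                             ref_set_size = 500L,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              fraction_enriched = fraction_enriched,
              fraction_off_target = fraction_off_target,
              effect_log2 = effect_log2,
              contaminant_log2 = contaminant_log2,
              effect_jitter_sd = effect_jitter_sd,
              baseline_log10_fpkm_mean = baseline_log10_fpkm_mean,
              baseline_log10_fpkm_sd = baseline_log10_fpkm_sd,
              replicate_cv = replicate_cv,
              n_replicates = as.integer(n_replicates),
              biotype_mix = biotype_mix,
              secretory_rate_targets = secretory_rate_targets,
              secretory_rate_background = secretory_rate_background,
              mito_rate = mito_rate,
              submito_known_rate = submito_known_rate,
              submito_mix = submito_mix,
              ref_set_size = as.integer(ref_set_size),
              seed = as.integer(seed))
  .validateSimulationConfig(cfg)
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

.validateSimulationConfig <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L) stop("n_genes must be positive")
    for (f in c(fraction_enriched, fraction_off_target,
                secretory_rate_targets, secretory_rate_background,
                mito_rate, submito_known_rate))
      if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
    if (fraction_enriched + fraction_off_target > 1)
      stop("fraction_enriched + fraction_off_target must not exceed 1")
    if (replicate_cv < 0) stop("replicate_cv must be non-negative")
    if (effect_jitter_sd < 0) stop("effect_jitter_sd must be non-negative")
    if (n_replicates < 2L) stop("n_replicates must be at least 2")
    if (abs(sum(biotype_mix) - 1) > 1e-9)
      stop("biotype_mix must sum to 1")
    if (abs(sum(submito_mix) - 1) > 1e-9)
      stop("submito_mix must sum to 1")
    if (ref_set_size < 1L) stop("ref_set_size must be positive")
  })
  invisible(cfg)
}

# Log-normal multiplicative noise with mean 1 and the requested CV.
.replicateNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

#' Simulate an APEX-RIP expression experiment with known ground truth
#'
#' Per gene, a baseline FPKM is drawn log-normally; pre-enrichment
#' replicates are the baseline times mean-1 log-normal noise at the
#' configured CV, and post-enrichment replicates are additionally scaled by
#' \eqn{2^{effect}}, where the effect is \code{effect_log2} for targets,
#' \code{contaminant_log2} for off-target genes and 0 otherwise, plus
#' per-gene Gaussian jitter. Stand-in differential p-values come from an
#' unequal-variance two-sample test on log2 replicates (the dispersion
#' model of count-based differential tools is deliberately not replicated,
#' since in real use the p-value is consumed from upstream). Reference
#' true/false-positive sets are sampled from the targets and the unaffected
#' background. Everything is reproducible from \code{config$seed}, with one
#' RNG substream per generated table so that regenerating one table leaves
#' the others unchanged.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{RipExperiment}), \code{annotation} (data.frame as from
#'   \code{\link{readAnnotation}}), \code{refs}
#'   (\linkS4class{ReferenceSets}) and \code{truth} (data.frame with
#'   \code{gene_id}, \code{is_target}, \code{is_off_target},
#'   \code{true_log2_effect}, \code{biotype}).
#' @export
simulateExpression <- function(config = simulationConfig()) {
  .validateSimulationConfig(config)
  n <- config$n_genes
  ids <- sprintf("SIMG%06d.1", seq_len(n))

  # substream 0: gene roles, baselines, effects, expression noise
  set.seed(config$seed)
  nT <- round(n * config$fraction_enriched)
  nO <- round(n * config$fraction_off_target)
  role <- rep("background", n)
  role[sample.int(n, nT + nO)] <- c(rep("target", nT), rep("off_target", nO))
  baseline <- 10^stats::rnorm(n, config$baseline_log10_fpkm_mean,
                              config$baseline_log10_fpkm_sd)
  effect <- numeric(n)
  effect[role == "target"] <- config$effect_log2 +
    stats::rnorm(nT, 0, config$effect_jitter_sd)
  effect[role == "off_target"] <- config$contaminant_log2 +
    stats::rnorm(nO, 0, config$effect_jitter_sd)
  reps <- config$n_replicates
  pre <- baseline * matrix(.replicateNoise(n * reps, config$replicate_cv),
                           n, reps)
  post <- baseline * 2^effect *
    matrix(.replicateNoise(n * reps, config$replicate_cv), n, reps)
  rownames(pre) <- rownames(post) <- ids
  p <- .welchP(log2(post + 1e-8), log2(pre + 1e-8))

  # substream 1: annotation (biotypes, secretory flags, mito classes)
  set.seed(config$seed + 1L)
  biotype <- sample(names(config$biotype_mix), n, replace = TRUE,
                    prob = config$biotype_mix)
  secRate <- ifelse(role == "target", config$secretory_rate_targets,
                    config$secretory_rate_background)
  coding <- biotype == "protein_coding"
  anySec <- coding & stats::runif(n) < secRate
  # the four predictors overlap heavily on true secretory proteins; each
  # flags a secretory gene with prob 0.8 (at least one is guaranteed)
  flags <- matrix(FALSE, n, 4L,
                  dimnames = list(NULL, .SECRETORY_FLAGS))
  for (j in seq_len(4L))
    flags[, j] <- anySec & stats::runif(n) < 0.8
  none <- anySec & !rowSums(flags)
  flags[none, sample.int(4L, 1L)] <- TRUE
  isMito <- coding & stats::runif(n) < config$mito_rate
  submito <- rep("unknown", n)
  known <- isMito & stats::runif(n) < config$submito_known_rate
  submito[known] <- sample(names(config$submito_mix), sum(known),
                           replace = TRUE, prob = config$submito_mix)
  annotation <- data.frame(gene_id = ids, biotype = biotype,
                           flags, is_mito = isMito,
                           submito_location = submito,
                           stringsAsFactors = FALSE)

  # substream 2: reference sets for ROC anchoring
  set.seed(config$seed + 2L)
  tgt <- ids[role == "target"]; bg <- ids[role == "background"]
  if (length(tgt) == 0L) {
    # null simulation: both reference sets come from the (unenriched)
    # background, drawn disjointly, so ROC sees no real separation
    k <- min(config$ref_set_size, floor(length(bg) / 2))
    pick <- sample(bg, 2L * k)
    refs <- ReferenceSets(pick[seq_len(k)], pick[k + seq_len(k)],
                          label = "simulated-null")
  } else {
    refs <- ReferenceSets(
      sample(tgt, min(config$ref_set_size, length(tgt))),
      sample(bg, min(config$ref_set_size, length(bg))),
      label = "simulated")
  }

  experiment <- RipExperiment(pre, post, pValue = p, biotype = biotype)
  truth <- data.frame(gene_id = ids,
                      is_target = role == "target",
                      is_off_target = role == "off_target",
                      true_log2_effect = effect,
                      biotype = biotype,
                      stringsAsFactors = FALSE)
  list(experiment = experiment, annotation = annotation, refs = refs,
       truth = truth)
}

#' Simulate a qPCR plate from known yields
#'
#' Inverts the delta-Ct yield equation: for each target,
#' \eqn{\Delta C_t = \log_{1+\epsilon}(yield / 100)}; the pulldown Ct is
#' the corrected input Ct minus \eqn{\Delta C_t}, and the raw input Ct
#' re-applies the input-fraction volume offset. Gaussian noise of sd
#' \code{ct_noise_sd} is added per replicate. With zero noise,
#' \code{\link{qpcrYields}} on the output recovers the specified yields
#' exactly.
#'
#' @param yield_truth named vector of true percent yields (> 0) per target.
#' @param efficiencies named vector of per-primer efficiencies in (0, 1].
#' @param ct_noise_sd per-replicate Gaussian Ct noise (cycles).
#' @param n_replicates technical replicates per well (default 4).
#' @param seed integer seed.
#' @param input_ct baseline corrected input Ct assigned to every target.
#' @param input_fraction fraction of lysate removed as input.
#' @return list with \code{ct} (long-format Ct data.frame) and
#'   \code{primers} (a \code{\link{primerPairs}} table).
#' @export
simulateQpcr <- function(yield_truth, efficiencies, ct_noise_sd = 0,
                         n_replicates = 4L, seed = 1L, input_ct = 20,
                         input_fraction = 0.2) {
  if (any(yield_truth <= 0)) stop("yields must be positive")
  if (any(efficiencies <= 0 | efficiencies > 1))
    stop("efficiencies must lie in (0, 1]")
  targets <- names(yield_truth)
  if (is.null(targets) || is.null(names(efficiencies)))
    stop("'yield_truth' and 'efficiencies' must be named by target")
  miss <- setdiff(targets, names(efficiencies))
  if (length(miss))
    stop(sprintf("no efficiency for target(s): %s",
                 paste(miss, collapse = ", ")))
  set.seed(seed)
  rows <- lapply(targets, function(tg) {
    eps <- efficiencies[[tg]]
    deltaCt <- log(yield_truth[[tg]] / 100, base = 1 + eps)
    ctRip <- input_ct - deltaCt
    ctInputRaw <- input_ct + log(1 / input_fraction, base = 1 + eps)
    noise <- function(mu) mu + stats::rnorm(n_replicates, 0, ct_noise_sd)
    rbind(
      data.frame(sample = "input", target = tg,
                 replicate = seq_len(n_replicates),
                 ct = noise(ctInputRaw), stringsAsFactors = FALSE),
      data.frame(sample = "RIP", target = tg,
                 replicate = seq_len(n_replicates),
                 ct = noise(ctRip), stringsAsFactors = FALSE))
  })
  list(ct = do.call(rbind, rows),
       primers = primerPairs(targets,
                             unname(efficiencies[targets])))
}
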