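# apexrip

Downstream analysis of **APEX-RIP** experiments: proximity-labeling RNA
immunoprecipitation, in which an engineered peroxidase (APEX2 or HRP)
targeted to a subcellular compartment biotinylates nearby proteins in live
cells, formaldehyde crosslinks those proteins to proximal RNAs, and
streptavidin pulldown enriches the compartment's transcriptome. The package
is for analysts who receive the *quantified* output of such an experiment —
gene-level FPKM tables measured before ("input") and after pulldown, with a
differential p-value per gene from the upstream quantification — and need
to turn it into defensible compartment transcript lists and quality
metrics. Read alignment and quantification are upstream and out of scope.

## The method

For each gene, enrichment is summarized on the log2 scale,

```
log2FC = log2( mean(FPKM_post) / mean(FPKM_pre) )
```

(optionally pseudocounted), paired compartments are compared by the
combined ratio `log2(FPKM_postA / FPKM_postB)`. Genes with differential
p-value > α (default 0.05) are removed, and the remaining genes are
thresholded by **ROC analysis**: given compartment-specific true-positive
and false-positive reference gene sets, every observed log2FC is a
candidate cutoff *t*, with

```
TPR(t) = |{TP : log2FC >= t}| / |TP|     FPR(t) analogously
```

and the chosen cutoff maximizes Youden's **J = TPR − FPR** (ties broken
toward the most stringent cutoff). Called lists are benchmarked by
contamination frequency (enriched off-target / total enriched), secretory
specificity (fraction of called mRNAs with any Phobius / TMHMM / SignalP /
GOCC secretory annotation), recall of reference standards, and the
sensitivity floor (the 5th percentile of input abundance among called
genes). Compartment lists are intersected under a hypergeometric null,
`P(X >= k)` for overlap *k* of lists of sizes *n1*, *n2* in a universe of
size *N* — including the nuclear-lamina candidate workflow (nuclear ∩ ER,
minus secretory mRNAs). qRT-PCR pulldown yields use the ΔCt method,

```
yield = 100 × (1 + ε)^ΔCt,   ΔCt = Ct_input,corr − Ct_RIP,corr
```

with per-primer amplification efficiency ε, input-fraction volume
correction, and first-order error propagation (σ of differences, products,
quotients and arbitrary differentiable functions).

A synthetic-data generator (`simulateExpression`, `simulateQpcr`) produces
expression tables, annotations, reference sets and qPCR plates with known
ground truth, so every stage is testable without any external download.

## Worked example

```r
library(apexrip)

cfg <- simulationConfig(seed = 7)          # 5000 genes, 3 replicates, effect 2 log2
sim <- simulateExpression(cfg)
fc  <- computeFoldChanges(sim$experiment)
sig <- filterSignificant(fc, alpha = 0.05)
roc <- rocCurve(sig, sim$refs)
roc
#> RocCurve 'simulated': 514 thresholds over 500 TP / 13 FP reference genes
#>   chosen log2 fold-change cutoff: 1.233 (Youden J = 1; ties broken toward
#>   the most stringent cutoff)

el <- callEnriched(sig, chosenThreshold(roc), alpha = NULL, label = "synthetic")
el
#> EnrichedList 'synthetic': 749 genes
#>   log2 fold-change threshold >= 1.233; p-value cutoff none

recall(el, sim$truth$gene_id[sim$truth$is_target])          # 0.999
contaminationFrequency(el,
  sim$truth$gene_id[sim$truth$is_off_target])               # 0
secretorySpecificity(el, sim$annotation)                    # 0.958
sensitivityFloor(el)                                        # 0.026 FPKM
```

The ROC anchored the cutoff at 1.233 log2 units (perfect reference
separation, J = 1); the called list recovers 99.9% of the truly enriched
genes with no off-target contamination, 95.8% of its mRNAs carry secretory
annotation (the generator plants 95%), and 95% of called genes have input
abundance above 0.026 FPKM. Note the logged counts: of 500 false-positive
reference genes only 13 survive the significance prefilter, which is why
reference sets must be generously sized.

qPCR yields with propagated uncertainties:

```r
q <- simulateQpcr(c(MT_ND1 = 40, GAPDH = 0.8),
                  c(MT_ND1 = 0.95, GAPDH = 0.9), ct_noise_sd = 0.1, seed = 7)
qpcrYields(q$ct, q$primers, reference = "GAPDH")
#>   target efficiency flagged delta_ct delta_ct_sd yield_percent yield_sd fold_vs_reference fold_sd
#> 1 MT_ND1       0.95   FALSE    -1.34      0.0881        40.858   2.4040              50.7  3.9892
#> 2  GAPDH       0.90   FALSE    -7.51      0.0814         0.806   0.0421               1.0  0.0739
```

The mitochondrial marker is recovered at 40.9 ± 2.4% yield (truth 40%),
50.7-fold enriched over the cytosolic GAPDH reference.

A thin command-line front end (`inst/scripts/apex-rip`) exposes the same
stages as `simulate | call | benchmark | overlap | qpcr` subcommands.

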