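---
title: "Calling compartment-enriched RNAs from proximity-labeling RIP data"
author: "apexrip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling compartment-enriched RNAs from proximity-labeling RIP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexrip)
```

## The analysis problem

APEX-RIP experiments map subcellular transcriptomes by targeting a
peroxidase (APEX2, or HRP for the ER lumen) to a compartment of interest,
biotinylating proximal proteins in live cells, crosslinking them to nearby
RNAs with dilute formaldehyde, and enriching the crosslinked complexes on
streptavidin. Sequencing the RNA before ("input") and after pulldown, and
quantifying both at the gene level, yields the data this package consumes:
per-gene FPKM values for several replicates of each state, plus a
differential-expression p-value computed upstream (CuffDiff-style). The
analysis question is: *which transcripts are enriched by the pulldown,
at what evidence threshold, and how good is the resulting list?*

`apexrip` implements the downstream arm of that workflow as composable,
deterministic stages. The central container is `RipExperiment` (a
`SummarizedExperiment` with a single `fpkm` assay whose columns are the
pre/post replicates); called lists, ROC curves and reference sets are S4
objects with validity checks, so malformed intermediates fail early.

## Model and procedure

**Fold enrichment.** For gene $g$,
$$\mathrm{log2FC}_g \;=\; \log_2
  \frac{\overline{\mathrm{FPKM}}^{\mathrm{post}}_g + c}
       {\overline{\mathrm{FPKM}}^{\mathrm{pre}}_g + c},$$
with arithmetic replicate means and pseudocount $c \ge 0$. The default is
$c = 0$ (the plain ratio); genes with zero abundance in both states are
uninformative and dropped with a logged count, and $c = 0.1$ FPKM is the
suggested setting when zero-input genes must be ranked rather than mapped
to $\pm\infty$. For paired constructs probing complementary compartments
(nucleus- versus cytosol-targeted), the informative statistic is the
combined ratio of the two *post*-enrichment abundances
(`computeCombinedFoldChanges`), positive toward the first compartment.

**Significance filter.** Genes with differential p-value above $\alpha$
(default 0.05) are removed *before* threshold selection; genes without a
p-value were not assessed upstream and are treated as not significant. An
optional input-abundance floor (`min_pre_fpkm`, inclusive) supports
protocols that discard lowly quantified genes. Both comparisons are
inclusive ($\le \alpha$, $\ge$ floor).

**ROC threshold selection.** Enrichment cutoffs are not fixed constants:
they are derived per experiment from compartment-specific reference sets —
genes known to reside in the compartment (true positives) and genes known
to reside elsewhere (false positives). Every observed log2FC among the
reference genes is a candidate cutoff $t$ (plus an $\infty$ sentinel at
which nothing is called); at each,
$\mathrm{TPR}(t)$ and $\mathrm{FPR}(t)$ are the fractions of present
true/false positives with $\mathrm{log2FC} \ge t$, and the cutoff
maximizing Youden's $J = \mathrm{TPR} - \mathrm{FPR}$ is selected.
Numerical choices, made once and surfaced in the output metadata:

* **Inclusive comparison** (`>=`) at the threshold, matching the
  convention used for published cutoffs of this type.
* **Ties toward stringency**: when several cutoffs attain the maximal
  $J$, the largest is chosen. This favors specificity (low contamination)
  at a marginal cost in recall, consistent with the method's emphasis on
  clean lists. In particular, when the reference classes separate
  perfectly the chosen cutoff is the *smallest true-positive* fold change,
  not the midpoint of the gap.
* **Reference drop-out**: reference genes absent from the filtered
  records are excluded from the rate denominators (with a logged count)
  rather than counted as misses — an absent gene says nothing about where
  the threshold should sit. A consequence of filtering *before* ROC is
  that unenriched false-positive reference genes rarely survive the
  p-value filter, so false-positive sets must be generously sized (see
  the generator notes below); an empty effective set is an error, not a
  silent degenerate curve.
* The sentinel threshold ($\infty$, nothing called) closes the curve and
  is selectable: with inverted separation (true positives *below* false
  positives) the best achievable $J$ is 0 and calling nothing is the
  correct answer.

**Calling.** `callEnriched` retains genes with $\mathrm{log2FC} \ge t$
and, when $\alpha$ is supplied, p-value $\le \alpha$; the result records
both parameters. `callBidirectional` calls the nuclear list on the
combined fold change and the cytosolic list on its negation, each with its
own reference sets; if the two derived windows overlap on the fold-change
axis (possible only when a derived cutoff is non-positive), shared genes
are removed from both lists with a logged count so the outputs are always
disjoint.

## Benchmark metrics

* **Contamination frequency** — enriched off-target RNAs over total
  enriched RNAs, the workflow's specificity measure against a marker set
  of a different compartment.
* **Secretory specificity** — among called protein-coding genes, the
  fraction carrying *any* secretory annotation (logical OR of the
  Phobius, TMHMM, SignalP and GO-CC flags). Genes missing from the
  annotation count in the denominator as unannotated (conservative); the
  matched-only variant is reported alongside, since published
  denominators do not always state which convention they use.
* **Recall** — fraction of a reference standard recovered.
* **Sensitivity floor** — the $q$-th quantile (default $q = 0.05$,
  linear interpolation between order statistics, type-7) of input FPKM
  over called genes: "95% of called transcripts have input abundance of
  X or higher". Lower floors indicate better sensitivity to rare
  transcripts.
* **Composition** — biotype counts (missing biotypes binned `unknown`,
  counts always summing to the list size); sub-mitochondrial destination
  fractions over OMM/IMM/matrix/IMS, computed only over genes with an
  available compartment-specific annotation (the denominator is
  reported); and transmembrane (TMHMM) enrichment among mitochondrial
  mRNAs relative to a background set.

## Compartment intersection and lamina candidates

Overlaps between called lists are tested against the hypergeometric null:
$P(X \ge k)$ for overlap $k$ of lists of sizes $n_1, n_2$ in a universe of
$N$ genes, computed via `phyper` (log-space internally, stable to
$N > 10^5$). Only the enrichment (upper) tail is tested. The universe is a
declared input — a sensible default is genes expressed at $\ge 1$ FPKM in
both experiments — and is recorded in the result, since the null is only
as meaningful as the universe is honest. Per-biotype-class tests restrict
the universe to each class (so class overlaps sum to the global overlap);
Benjamini–Hochberg correction across classes is available but off by
default, matching the convention of reporting raw hypergeometric
p-values.

The nuclear-lamina workflow exploits the continuity of the nuclear
envelope's intermembrane space with the ER lumen: RNAs called in *both*
the nuclear and ER-lumen experiments are lamina candidates, after removing
protein-coding genes with any secretory flag — for those, gene-level
quantification can conflate nuclear-retained pre-mRNAs with mature
ER-localized transcripts, so they are set aside as likely false positives
rather than deleted silently. Identifier joins strip GENCODE version
suffixes (annotation releases drift between tables); outputs preserve the
identifiers as read.

## qPCR yields and uncertainty

Pulldown yield for a target follows the ΔCt method with per-primer
amplification efficiency $\varepsilon \in (0, 1]$ (consumed as input from
amplification-curve analysis; primers with $\varepsilon < 0.90$ are
flagged, not silently dropped):
$$\mathrm{yield} = 100 \times (1+\varepsilon)^{\Delta C_t}, \qquad
  \Delta C_t = C_t^{\mathrm{input,corr}} - C_t^{\mathrm{RIP,corr}}.$$
Because only a fraction $f$ of the lysate (default 0.2) is taken as input,
the input Ct is lowered by $\log_{1+\varepsilon}(1/f)$ cycles so yields
are relative to the total lysate; a generic per-sample cycle offset
accommodates any further volume corrections. Uncertainty is propagated to
first order: $\sigma_D = \sqrt{\sigma_A^2 + \sigma_B^2}$ for differences,
relative variances adding for products and quotients, and
$\sigma_{f(x)} = \sigma_x\,|f'(x)|$ in general, giving
$\sigma_{\mathrm{yield}} = \sigma_{\Delta C_t} \cdot \mathrm{yield} \cdot
\ln(1+\varepsilon)$.

One estimator choice deserves emphasis. `correctedCt` reports both the
sample standard deviation of the Ct replicates ($n-1$ denominator) and the
standard error of the mean; the yield pipeline propagates the **standard
error**, because the corrected Ct is a replicate mean and the quantity
being propagated is the uncertainty of that mean. Propagating the raw
replicate sd would overstate the across-plate spread of recovered yields
by $\sqrt{n}$ — the Monte-Carlo recovery test in the suite checks exactly
this calibration. Callers composing the propagation rules directly (with
explicit $\sigma$ values) are unaffected.

## What the synthetic generator emulates — and what it does not

`simulateExpression` draws, per gene: a baseline FPKM from a log10-normal
distribution (mean 0, sd 1, so about half of genes exceed 1 FPKM — the
expression floor used for reference-set construction lands mid-scale);
mean-1 log-normal multiplicative replicate noise at a configurable CV
(default 20%); and a true log2 enrichment — `effect_log2` (default 2) for
targets (default 15% of genes), `contaminant_log2` (default 0.5) for
off-target leakage (default 5% of genes), 0 otherwise, each with 0.1 log2
units of per-gene jitter. Differential p-values come from an
unequal-variance two-sample test on log2 replicates; this is a stand-in
for the upstream count-based test, deliberately *not* replicating its
dispersion model, since in real use the p-value is consumed, not
computed. Annotations plant secretory flags at 95% among targets versus
50% in the background (mirroring the contrast reported for ER lists
against the expressed-mRNA background), and sub-mitochondrial destinations
at the bulk-proteome mix (18% OMM, 42% IMM, 30% matrix, 10% IMS) for the
30% of mitochondrial genes given a known destination. Reference sets of
500 genes per class are sampled from the targets and the background; in a
null simulation with no targets both sets come from the background, so ROC
correctly finds nothing to separate. All randomness flows from one seed
through one substream per table (expression, annotation, reference draws),
so regenerating a single table leaves the others unchanged.

What passing tests on this generator do **not** show about real data: the
generator has no count noise (FPKM is treated as a continuous measurement,
so its p-values are better behaved than CuffDiff's at low counts), no
compositional coupling between genes (strong enrichment of one gene does
not depress the FPKM of others, though in a real pulldown library it
does), no correlation structure among replicates, no isoform-level
ambiguity, and gene-independent annotation errors only. Recovery rates on
synthetic data are therefore upper bounds on real-data performance, and
the recovery tests validate the *pipeline logic* — threshold placement,
list arithmetic, metric definitions — rather than the upstream
quantification.

`simulateQpcr` inverts the yield equation exactly: from a true yield it
derives $\Delta C_t$, assigns the pulldown Ct relative to a fixed
corrected input Ct (default 20 cycles), re-applies the input-fraction
offset to produce the raw input Ct, and adds Gaussian per-replicate noise.
At zero noise the analysis recovers the specified yields exactly — the
round-trip identity used throughout the tests.

## Problem sizes and numerical conventions

The validation suite runs at deliberately chosen scales: ROC selection is
checked against exhaustive brute force on 200 random instances of up to 20
genes; the hypergeometric tail against complete draw enumeration for every
universe up to $N = 12$ (tolerance $10^{-12}$); error propagation against
$10^6$-draw Monte Carlo at relative errors $\le 10\%$ (agreement within
10%); and full-pipeline recovery at 5000 genes × 3 replicates × 20 seeds
at effect 2 and CV 0.2, requiring recall $\ge 0.9$ and contamination
$\le 0.05$ per seed. Degradation of both metrics is checked to be
monotone (within a 0.03 sampling allowance) across effects $\{1, 2, 4\}$
and CVs $\{0.1, 0.2\}$.

On-disk numbers are written with the shortest decimal representation that
survives an exact read/write round trip, rows in deterministic order
(descending fold change, ties by identifier), and `#`-prefixed metadata
recording thresholds, α, and tie-break conventions — re-running any stage
on unchanged inputs yields byte-identical files. Degenerate inputs follow
one rule: quantities whose denominator is empty (contamination of an
empty list, specificity of a list with no mRNAs, sub-mitochondrial
fractions with no annotated genes) are reported as `NA` with a warning,
while violated preconditions (empty reference sets, universe violations,
negative FPKM) are errors naming the offender.

## Known limitations

Gene-level only (no isoform resolution); the hypergeometric universe is
the user's responsibility; the ROC cutoff is only as good as the reference
sets, and with very small effective sets after filtering the FPR estimate
is coarse (the curve object reports both denominators so this is
auditable); p-values are consumed, never recomputed from counts; and the
qPCR module assumes independent errors between input and pulldown
measurements, which ignores plate-level covariance.
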