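---
title: "Methods: Bayesian pathway activity, coverage uniformity QC and driver screening"
author: "wntscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian pathway activity, coverage uniformity QC and driver screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntscreen)
```

# The model

`wntscreen` scores the activity of a transcriptional program — by default the
canonical Wnt program driven by the TCF4/β-catenin transcription complex — in
individual samples or single cells, from gene expression alone. The model is
a three-layer Bayesian network:

* a single latent binary root node, the **transcription complex** (TC),
  active or inactive;
* one binary **target-gene** node per panel gene, transcriptionally up or
  down, with conditional probability table (CPT)
  `P(up | TC active) = p_up_given_active`,
  `P(up | TC inactive) = p_up_given_inactive`;
* one binary **measurement** node per gene — observed expression above or
  below the gene's calibrated threshold — with CPT
  `P(high | up) = p_high_given_up`, `P(high | down) = p_high_given_down`.

Target genes are conditionally independent given the TC, and each
measurement depends only on its own gene, so after marginalising the gene
layer every measurement contributes a composite likelihood ratio and the
posterior odds factorise into a product over genes. `inferLogOdds()`
computes this factorised form exactly; `inferLogOddsBruteforce()` recomputes
it by enumerating every configuration of the TC and all gene states (summing
both measurement states per gene under the evidence weights) and exists only
to check the factorisation — the two agree to below 1e−9 over randomised
model suites in the tests.

## Soft evidence

Measurements enter as *virtual evidence*, not as clamped states: the
measurement node for gene *g* receives likelihood weights `q_g : 1 − q_g`
for its high/low states, where `q_g` is the probability that the gene's
expression lies above threshold. This matches how the evidence is actually
produced (a logistic soft call near the threshold, below) and makes the
per-gene contribution a continuous, strictly increasing function of `q_g`
bounded by the hard-call likelihood ratios. A missing measurement (`NA`)
weighs both states equally and contributes exactly zero log-odds — dropout
of a gene never biases the call.

## Default CPTs and the five-fold weighting

The only quantitative constraint we impose on the default tables is the
asymmetry between up- and down-weighting: an above-threshold call multiplies
the odds of activity by `lr_high = 5`, while a below-threshold call divides
them by only `5^(1/5)` (`lr_low = 5^(−1/5) ≈ 0.725`), i.e. in log-odds an
up-regulated gene counts five times as much as a non-up-regulated one:
`ln(lr_high) / |ln(lr_low)| = 5`. The rationale is biological noise:
confounders can suppress an individual target gene even when the pathway is
active — especially in single cells, where lowly expressed targets drop out
of the library — so absence of up-regulation is weak evidence, while
presence is strong. Genuinely repressed (negatively regulated) targets are
out of scope; the model requires `p_up_given_active > p_up_given_inactive`
for every gene.

The gene layer defaults to `p_up_given_active = 0.95`,
`p_up_given_inactive = 0.05`. Given those, the two measurement-layer entries
are determined by requiring the composite ratios to hit `(5, 5^(−1/5))`;
both constraints are linear in the two unknowns, so `buildModel()` solves
the 2×2 system exactly, yielding `p_high_given_up ≈ 0.336`,
`p_high_given_down ≈ 0.050`. All four entries can be overridden globally or
per gene through the panel TSV. The TC prior odds default to 1
(uninformative): the decision boundary then sits at posterior odds 1, which
is also where `classifyActivity()` draws it (ties conservatively to
inactive). Internally everything is natural-log; the pipeline's odds table
also reports log10 for plotting.

## The bundled panel

The default panel (`wntTargetPanel()`) lists 34 canonical TCF4/β-catenin
target genes from the colorectal Wnt literature (AXIN2, ASCL2, LGR5, MYC,
…). It is a representative, curated panel: the point of carrying 34 genes is
robustness — with the default CPTs a single cell can lose several target
genes to dropout and still be scored correctly, because the remaining
up-regulated genes each contribute `ln 5` while each loss costs only
`ln 5 / 5`.

# Calibration

Thresholds are fit on labelled samples (`fitThresholds()`): per gene, the
threshold is the midpoint between the mean log2 RPKM of the active-labelled
and inactive-labelled calibration samples. We chose the midpoint rule over
an optimal-split search because it is deterministic and well-behaved with
very small calibration classes (two samples per class is the intended
regime); genes whose classes are not separated in the right direction are
flagged and *kept* with a warning rather than dropped — the Bayesian
combination tolerates individual noisy genes, and silently shrinking the
panel would change the evidence budget.

Raw RPKM matrices are transformed as `log2(RPKM + pseudocount)` with
pseudocount 1 (configurable): single-cell dropout produces exact zeros, and
a pseudocount of 1 maps them to log2 expression 0. Soft calls use a logistic
ramp of width `softness = 0.25` log2 units by default — wide enough that
values within about a quarter of a log2 unit of the threshold are treated as
genuinely ambiguous (q near 0.5), narrow enough that a one-unit excursion is
a confident call (q > 0.98). `softness = 0` recovers hard calls. Gene names
are matched case-insensitively after trimming, since calibration matrices,
panels and test matrices routinely come from different sources.

# Coverage uniformity QC

Whole-genome amplification of single-cell DNA is biased: some loci amplify
massively, others not at all. From a per-sample depth histogram (read either
from a `bedtools genomecov`-style summary or from BED4 depth intervals,
0-based half-open), the package computes:

* the **Lorenz curve** — cumulative fraction of reads against cumulative
  fraction of genome bases, bases sorted by increasing depth. Uncovered
  bases count toward the genome axis but carry no reads, so the fraction of
  the genome with zero coverage is visible as the initial flat segment. The
  diagonal is perfect uniformity; the curve is by construction convex,
  non-decreasing and below the diagonal.
* the **coverage profile** — fraction of bases at depth ≥ d, the curve from
  which one reads how much of the genome reaches the 20× or 30× needed for
  confident SNP calling.
* summary statistics: mean depth, breadth `C` (fraction ≥ 1×), fraction
  uncovered, fractions ≥ 20× and ≥ 30×, and the **Gini coefficient**
  (1 − 2 × trapezoidal area under the Lorenz curve; 0 at perfect uniformity).

Curves are returned at exact depth-class boundaries, with no interpolation
grid — any downsampling for plotting is presentation-layer. Gini is
invariant to uniformly scaling all depths and to duplicating the genome,
and moving read mass outward (a mean-preserving spread) cannot decrease it;
all three properties are tested.

# Driver-panel screening

The screening rule (`screenSample()`) is deliberately conservative about
wild-type calls. Per sample:

1. **Breadth gate.** If the cell's genome breadth `C` is below 0.70, every
   panel entry reports `sample_excluded`; too little of the genome was
   recovered for any mutation statement.
2. Otherwise a panel site is `mutant` if the VCF contains a record matching
   exactly on (chrom, pos, ref, alt) after multi-allelic decomposition, with
   FILTER `PASS` or `.`, and — when genotypes are present — at least one
   alternate allele in GT.
3. A site with no matching record is `wild_type` only if it lies inside the
   sample's callable-region evidence (BED, 0-based half-open); otherwise it
   is `insufficient_coverage`. Absence from a variants-only VCF is *not*
   evidence of reference: under amplification dropout, an uncovered hotspot
   simply was not seen.

Left-alignment/normalisation of indel representations is assumed done
upstream and is documented, not performed; the panel file owns the genome
build, and HGVS labels (`c.134C>T`, `S45F`) are carried as metadata, never
mapped to coordinates. The bundled panel holds the three colorectal hotspot
entries (CTNNB1, KRAS, PIK3CA) with standard GRCh37 coordinates supplied in
the file itself.

# The synthetic-data generator

The generator exists so every stage — calibration, inference, QC, screening
— can be exercised end to end with known truth. It emulates the statistical
*structure* the analysis assumes, not any particular experiment:

* **Expression** (`simulateExpression()`): gene *g* in an active sample is
  `Normal(mu_g + delta_g, noiseSd)`, in an inactive sample
  `Normal(mu_g, noiseSd)`, on the log2 RPKM scale. Defaults: baselines
  `mu_g` spread evenly over 2–8 log2 RPKM, effect `delta = 2`, noise
  `sd = 0.5` — a clearly separable but noisy regime; two calibration samples
  per class mirrors the small-calibration design the threshold rule targets.
  In `single_cell` mode a value drops to 0 with probability
  `min(1, dropoutBase + dropoutSlope · max(0, dropoutRef − mu_g))`
  (defaults 0.05, 0.15/log2, reference 4 log2 RPKM): dropout rises linearly
  as the baseline falls below the reference, embodying the observation that
  lowly expressed targets are the ones lost in single cells, without
  claiming that functional form for real chemistry.
* **Depth** (`simulateDepth()`): per genome bin, zero with probability
  `zeroInflation`, else negative-binomial with mean `depthMean` and
  overdispersion `depthDispersion` = α (variance μ(1+αμ)); α = 0 takes an
  exact Poisson branch. Overdispersion and zero-inflation are the two
  independent knobs that amplification bias needs: α drives the Gini upward
  and zero-inflation drives the uncovered fraction, and both monotonicities
  are asserted in the tests. Defaults (mean 16×, α = 0.5, 10% zero
  inflation) produce summaries in the range realistic for
  amplified single-cell genomes — roughly 11% of bases uncovered at ~14×
  mean depth in the default configuration.
* **Variants** (`writeVariantCalls()`): minimal valid VCF 4.2 per sample
  containing exactly the planted panel records (FILTER PASS, GT 0/1), a
  callable BED covering panel sites except those marked uncallable, and a
  truth manifest. Screening generator output must recover the manifest
  exactly; that identity is a test.

Everything is deterministic given the config seed (sub-seeds are derived per
stage so expression and depth draws are decoupled).

What the generator does **not** emulate: heavy-tailed expression noise,
gene–gene correlation beyond the shared TC state, amplification chemistry at
read level (no FASTQ), transcript-length effects in RPKM, or real effect
sizes of any particular cell line. Passing the parameter-recovery suite
therefore shows the pipeline is correct and well-conditioned under its own
assumptions, not that those assumptions hold for any given dataset.

# Numerical and design choices

* **Fisher exact test** (`fisherExactTwoSided()`): two-sided by the
  minimum-likelihood rule — sum the hypergeometric probabilities of all
  margin-consistent tables no more probable than the observed one, with a
  relative tie tolerance of 1e−7. Under this convention a perfectly
  separated 7-vs-6 confusion table gives p = 1/1716 ≈ 0.0006. The
  implementation enumerates the support via `dhyper`; tests cross-check it
  against an independent binomial-coefficient enumeration for every 2×2
  table with total ≤ 40, and against `stats::fisher.test` on random tables.
* **Degenerate inputs**: empty panels, all-missing evidence vectors,
  zero-read histograms, header-only panel files and absent label classes
  all error (or warn, where the spec of the operation is to keep going) with
  explicit messages; the pipeline validates every referenced file before
  writing any output so a failing run leaves no partial bundle.
* **Serialisation**: model panels round-trip through TSV at full double
  precision (`%.17g`); cluster matrices export q at 4 decimals with `NA`
  for missing, which is the display precision of the heat-map they feed.
* **Problem sizes** in the test and acceptance runs — 1000 random models of
  ≤ 10 genes for the oracle suite, 200 single cells for parameter recovery,
  10^5 genome bins for depth simulations — were chosen as the smallest sizes
  at which the checked properties are stable, keeping the full suite fast
  enough to run routinely.

# Known limitations

* Only positively regulated target genes are supported; a program with
  repressed targets needs a sign extension of the gene layer.
* CPTs are asserted, not learned; calibration tunes thresholds only.
* One pathway model per run; multi-pathway screening is future scope.
* The per-sample odds carry no uncertainty intervals — the posterior odds is
  a point functional of the soft calls.
* Coverage QC is genome-global (no per-chromosome stratification) and starts
  from depth histograms; computing them from BAM pileups is upstream of this
  package.

# A minimal end-to-end run

```{r example, eval = FALSE}
model <- readModelPanel(wntTargetPanel())
cal <- simulateExpression(syntheticConfig(nActive = 2, nInactive = 2, seed = 11))
th <- fitThresholds(cal$matrix, cal$labels)
sc <- simulateExpression(syntheticConfig(nActive = 7, nInactive = 6,
                                         mode = "single_cell", seed = 12))
lo <- sapply(sampleNames(sc$matrix), function(s)
  logOdds(inferLogOdds(model, evidenceFromSample(sc$matrix, s, th))))
evaluateClassification(lo, sc$labels)$fisher_p
```
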