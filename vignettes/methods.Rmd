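---
title: "Models and methods: time-course transcriptome and proteome analysis of differentiating neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neurodevomics` analyzes a three-timepoint (day 1, 3, 7) study of
hiPSC-derived neuron cultures profiled in parallel at the RNA level
(bulk RNA-seq counts; two biological replicates, each with two
technical replicates) and at the protein level (one TMT-6plex run: the
three days of each biological replicate on reporter channels 126-128
and 129-131). This vignette explains the statistical models, the
defaults and their units, the synthetic-data generator used to
validate everything, and the numerical and design choices that were
genuinely open.

## RNA: nested-replicate ANOVA with Tukey contrasts

Counts are scaled to reads per million (RPM) per sample, computed
before any gene filtering so each column total reflects the full
library. Genes observed (nonzero raw count) in fewer than 5 of the 12
samples are excluded; "observed" is deliberately the simplest reading
— a nonzero raw count.

For each remaining gene, expression is modeled by ordinary least
squares as

$$ y_{tbr} = \mu + \tau_t + \beta_b + \gamma_{r(b)} + \varepsilon_{tbr}, $$

with timepoint $\tau_t$ (2 df), biological replicate $\beta_b$ (1 df)
and technical replicate nested in biological replicate
$\gamma_{r(b)}$ (2 df), leaving 6 residual df in the default design.
The timepoint effect is tested with the extra-sum-of-squares F
statistic against the reduced model without $\tau$; on this balanced
design the sequential and Type-II F coincide. For speed the fit is a
QR projection of the whole gene matrix onto the two design spaces —
algebraically identical to per-gene `lm()` + `anova()`, which the test
suite verifies to 1e-10.

Pairwise timepoint differences (d3−d1, d7−d1, d7−d3; later minus
earlier) use the Tukey studentized-range distribution with family size
3 and the full model's residual df (Tukey-Kramer standard errors in
the unbalanced case). Each contrast family is adjusted across genes by
Benjamini-Hochberg; genes with zero residual variance are flagged
degenerate, reported separately, and excluded from the BH family size.
A gene is called up (down) for a contrast when the adjusted p is
strictly below $\alpha = 0.05$ and the mean difference is positive
(negative); an exact zero difference is never assigned a direction.

**Modeling scale.** The model is fit to raw RPM by default, the most
literal reading of the procedure; `scale = "log2"` fits
$\log_2(\mathrm{RPM}+1)$ instead. Count noise is multiplicative, so
the log scale matches the error model better and is what the packaged
validation studies use for power; the raw scale remains the default
for fidelity. Whether the nested technical replicate should enter as a
fixed factor or as an error stratum is equally open; the balanced OLS
encoding chosen gives a well-defined timepoint F under either reading.

## Proteomics: TMT ratio QC and archetype clustering

Within each replicate, reporter ratios day3/day1, day7/day1 and
day7/day3 are formed per peptide, and every ratio column is divided by
its across-peptide median (column median exactly 1 afterwards;
applying the normalization twice is a no-op). The protein-level ratio
per (comparison, replicate) is the **median** over peptides — the
summarization statistic is not dictated by the upstream convention, and
the median is robust to single aberrant peptides. Reporter-ion
variability is the percent coefficient of variation (100·SD/mean) of
the peptide-level ratios; with exactly two replicates the "median log2
fold-change between the replicates" reduces to the absolute difference
of the two log2 ratios, which is how the replicate discordance is
computed (generalizing to the median of pairwise absolute differences
for more replicates).

The QC cascade excludes a protein iff it has fewer than 3 peptides, or
a variability above 100% in at least one ratio, or a replicate
discordance above 0.4 in at least one comparison — all strict
inequalities, so boundary values are kept; the reported reason is the
first triggered rule but the exclusion set is order-independent.
QC-passing proteins are regulated when any of the three replicate-mean
log2 fold-changes strictly exceeds 0.3 in magnitude.

Note one algebraic subtlety: the identity
$\overline{\log_2}(d7/d3) = \overline{\log_2}(d7/d1) -
\overline{\log_2}(d3/d1)$ holds for ratios computed from the same
normalized channels, but independent median normalization of the three
ratio columns (and the median-over-peptides summarization) breaks it
by a small amount; the package normalizes each ratio column
independently, so the identity is only exact when the column medians
are already 1.

Regulated proteins are clustered on the feature vector
$(\overline{\log_2} d3/d1,\ \overline{\log_2} d7/d1)$ — the third
comparison is linearly dependent and would double-weight one direction
— with `stats::kmeans` (Hartigan-Wong) under a fixed seed and 50
random restarts, keeping the best-inertia solution. R's own k-means
with many restarts was preferred over a k-means++ single start because
it is the estimator practitioners in this field actually run and the
restart scheme makes it deterministic given the seed. Labels are then
re-assigned by sorting centroids on the d7/d1 coordinate in decreasing
order, so clusters 1-3 are the upregulated and 4-6 the downregulated
trajectories regardless of the internal k-means labeling.

## Enrichment

Over-representation of a query gene set in a GO-style term uses the
hypergeometric upper tail $P(X \ge k)$ with the annotated-in-universe
count $K$, query size $n$ and universe size $N$. The universe is the
analysis background: genes passing the detection filter (RNA) or
QC-passing quantified proteins, intersected with the annotated genes —
the conservative choice when the original background is unstated.
Terms with $K < 2$ are untestable singletons and are skipped. BH
correction is applied per category (CC/BP/MF), matching the
per-category presentation of enrichment panels; a pooled family is
available. No GO-graph ancestor propagation is performed.

## Integration

Layers are joined on upper-cased gene symbol. Duplicate transcript
rows for one symbol are collapsed by summing linear-scale means before
re-computing the fold-change; duplicate protein rows keep the entry
with the most peptides — deterministic rules, logged via attributes,
chosen because name-based matching alone does not dictate them. The
joined records yield the Pearson correlation of RNA vs protein
day7/day1 log2 fold-changes (two-sided p from the t transform) and the
trend concordance: fold-change pairs with equal sign. Values within
1e-12 of zero are snapped to zero and count as concordant only with
another exact zero, so float noise cannot inflate concordance. Marker
heatmap rows are ordered by hierarchical clustering with Euclidean
distance and average linkage (the linkage was an open choice; average
is a stable middle ground between single's chaining and complete's
outlier sensitivity).

## The synthetic-data generator

The generator plants known truth with the statistical structure the
analysis assumes, at the study's own scale where one exists:

* **Counts.** Negative binomial (variance $\mu + \phi\mu^2$, default
  $\phi = 0.05$) around a log-linear mean with per-gene
  biological-replicate (SD 0.1 log2) and technical-replicate (SD 0.05
  log2) effects and log-normal library-size factors (CV 0.1 around
  2e6). Exactly `round(n · de_fraction)` genes are DE — deterministic
  truth makes power assertions exact — half up, half down, monotone
  over time, |log2FC| 2 at day 7 by default. The count-noise family of
  the original protocol is not knowable from desk data; NB is an
  assumption. Two continuous families exist for methodological
  studies: `"gaussian"` (within-gene homoskedastic additive noise, the
  exact null of the OLS F test, used for type-I calibration) and
  `"lognormal"` (log2-scale residual SD, used for power studies).
* **TMT.** Six archetype profiles — (0.2, 0.5), (0.1, 1.2),
  (0.9, 1.0) in (log2 d3/d1, log2 d7/d1) and their negatives:
  slight-steady, late and early rises and their mirrored declines —
  are planted in a configurable fraction (default 0.4) of clean
  proteins; the rest are flat. Peptide noise is log-normal, calibrated
  so peptide-ratio CV matches `peptide_cv_percent` (default 20%). QC
  violators of each class are planted in deterministic counts:
  contaminants get `CON_`/keratin-style accessions, few-peptide
  proteins get 1-2 peptides, high-variability proteins get 300% CV,
  discordant proteins get a 0.8 log2 shift in one replicate — margins
  far enough from the 100% / 0.4 thresholds that planted truth and
  realized QC status coincide.
* **Annotations.** Random term sizes (10-40 genes) over CC/BP/MF;
  enriched terms over-sample DE genes at odds ratio 10.
* **Linkage.** Paired fold-changes constructed as
  $y = \rho x + \sqrt{1-\rho^2}\,z$, giving exact control of the true
  correlation (default 0.51) and, for centered marginals, a known
  concordance expectation $1/2 + \arcsin(\rho)/\pi \approx 0.670$.

What the generator does **not** emulate: compositional library
effects beyond what planting induces, batch effects, missing TMT
channels, peptide-to-protein misassignment, isotope impurity, GO-term
overlap structure, and mean-variance trends beyond a single global
dispersion. Passing tests therefore show the procedures are correct
and calibrated under their stated assumptions, not that real data
meet those assumptions.

One consequence worth knowing: on small gene panels with strong
asymmetric regulation, RPM renormalization shifts null genes in the
opposite direction (a compositional artifact inherent to
total-count scaling), which slightly inflates the false discovery
rate among calls in that direction. The effect is visible on the
packaged 200-gene fixture and negligible at genome scale.

## Problem sizes and determinism

The packaged validation studies use 5,000 null genes (type-I
calibration; the raw ANOVA p's fraction below 0.05 must sit in
[0.04, 0.06]), 10,000 genes with 10% planted DE (sensitivity and FDR),
600 regulated proteins over six archetypes at noise SD 0.1 (adjusted
Rand index vs truth), 4,536 linked symbols at true correlation 0.51,
full hypergeometric enumeration up to universe size 30, 100,000
Monte-Carlo draws per residual-df setting for the studentized range,
and 1,000 random p-vectors for the BH closed form — sizes at which
the Monte-Carlo error bands are tight enough to be informative while
the whole suite runs comfortably on a laptop. Every stochastic step
takes an explicit seed; reruns are byte-identical, which the pipeline
manifest verifies by MD5 checksum.

The packaged fixture (200 genes, 60 proteins, 30 terms, seed-fixed,
fully synthetic) ships as plain TSV under `inst/extdata/` together
with its ground truth; `scripts/make_fixture.R` regenerates and
self-validates it.
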