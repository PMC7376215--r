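---
title: "Statistical methods for 8-oxoG RIP-seq enrichment inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for 8-oxoG RIP-seq enrichment inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxripseq)
```

## The scientific problem

Reactive oxygen species convert guanine in RNA to
8-oxo-7,8-dihydroguanine (8-oxoG). Profiling which transcripts carry this
mark — e.g. after exposing cultured airway epithelial cells to an
oxidizing air-pollution mixture — uses RNA immunoprecipitation
sequencing (RIP-seq): an anti-8-oxoG antibody captures modified
transcripts (the *rip* fraction) out of an rRNA-depleted pool, and the
unenriched pool (the *input* fraction) is sequenced alongside as the
abundance baseline. A transcript is a candidate oxidation target when its
representation in the rip library exceeds what its input abundance
predicts.

Three statistical problems follow, and this package implements all of
them on transcript-level count matrices:

1. **Enrichment testing** — is a transcript over-represented in rip
   versus input, within one exposure condition?
2. **Discrimination** — of the enriched transcripts in exposed cells,
   which reflect the exposure rather than basal oxidation or
   sample-preparation artifacts?
3. **Interpretation** — are the induced transcripts biased toward
   particular expression strata, toward expression downregulation, or
   toward particular gene sets?

The accompanying bench assays (competitive ELISA of free 8-oxoG,
scintillation-based IP efficiency, dot-blot dose linearity,
reverse-transcription truncation, densitometry) each need a small piece
of quantification arithmetic; those are implemented as pure functions in
the `bench_assays` group.

## Count model

Counts are modeled as negative binomial (NB) with the mean–variance
parameterization $\mathrm{Var}(Y) = \mu + \alpha\mu^2$, where $\alpha$
is the per-transcript dispersion. For transcript $i$ in library $j$ the
two-group generalized linear model with log link is

$$\log \mu_{ij} = \log s_j + \beta_{0i} + \beta_{1i} x_j,$$

with $s_j$ the library size factor and $x_j$ the indicator of the test
group (rip in the enrichment contrast; exposed in the expression
contrast). $\beta_{1i}/\ln 2$ is the reported log2 fold change.

This is the standard inferential scheme for IP-versus-input designs.
The package deliberately implements a *documented, simple* variant of
each component rather than replicating any specific tool's internals
bit-for-bit (no Cox–Reid adjusted profile likelihood, no parametric
dispersion trend, no fold-change shrinkage, no optimized independent
filtering); the tests then characterize its operating characteristics
directly by simulation. The scientific scheme, not a particular
implementation of it, is what the package commits to.

### Size factors

`estimate_size_factors()` uses median-of-ratios: over transcripts with
strictly positive counts in every library,
$s_j = \mathrm{median}_i \, y_{ij} / (\prod_k y_{ik})^{1/n}$, with no
post-hoc rescaling. A positive-entry pseudo-reference fallback exists
behind a flag for degenerate matrices with no all-positive transcript;
strict mode errors instead so that silent fallback cannot mask a broken
input. Note that the absolute scale of median-of-ratios factors is tied
to the geometric-mean reference, so the meaningful quantity is the ratio
between factors; rescaling one library by $c$ changes its factor by $c$
*relative to the others*.

### Dispersion

`estimate_dispersions()` is a gene-wise method-of-moments estimator on
normalized counts, pooled within the two design groups so a true group
effect does not masquerade as dispersion: with pooled within-group
variance $s^2$ and overall mean $\bar m$,
$\hat\alpha = \max(\text{floor}, (s^2 - \bar m)/\bar m^2)$, floor
$10^{-8}$. Because per-transcript moments are noisy at 2–3 replicates,
the estimate is optionally (and by default) shrunk toward the
across-transcript median on the log scale with weight 0.5. This is a
deliberately transparent stabilizer: it has one parameter, an obvious
limit at weight 0 (pure moments) and weight 1 (one shared dispersion),
and its effect on error rates is measured by the calibration tests
rather than assumed.

### Wald test

`nb_wald_test()` fits the GLM per transcript by Fisher-scoring IRLS with
expected-information weights $w = \mu/(1+\alpha\mu)$, vectorized across
transcripts (each iteration solves the per-transcript 2×2 weighted
normal equations in closed form). Tolerance is $10^{-8}$ on the
coefficients, at most 100 iterations. The statistic
$\beta_1/\mathrm{SE}(\beta_1)$, with the SE from the inverse expected
Fisher information, is referred to a standard normal, two-sided.

Degenerate transcripts degrade gracefully rather than crash: all-zero
transcripts get missing p-values, and fits walking toward an infinite
MLE (one group all zeros) are flagged non-converged with missing
p-values. The test suite verifies against a brute-force NB likelihood
maximizer that converged fits are maximum-likelihood estimates, and a
null simulation (20,000 transcripts, 6 libraries per group, known
dispersions drawn log-uniformly from [0.01, 0.3], base means ≥ 50)
checks that the empirical type-I error at nominal 0.05 stays in
[0.035, 0.065].

### Multiple testing

`bh_adjust()` is Benjamini–Hochberg step-up over the non-missing
p-values; transcripts removed by the mean-count filter
(`low_count_filter()`, default mean normalized count ≥ 1) are excluded
from the BH denominator and get missing adjusted p-values. BH is the
conventional choice wherever results are reported as "adjusted
p-values" in this field.

## The two contrasts and their thresholds

`rip_enrichment()` subsets one condition and contrasts rip vs input; a
transcript is *8-oxoG-enriched* when `padj < padj_max` and linear fold
change exceeds `min_fc` (default 2, i.e. log2fc > 1). The adjusted-p
ceiling is exposure-intensity-dependent in practice: 0.1 for low-level
exposure runs (the default) and 0.05 for high-level runs; both are plain
configuration.

`diff_expression()` contrasts exposed vs control on input libraries
only, classifying transcripts as up (FC > 2) or down (FC < 0.5) at
`padj < 0.05` by default. All fold-change thresholds act on the linear
scale, the standard reading of "fold change > 2".

## Discriminating exposure-induced oxidation

Basal oxidation and immunoprecipitation artifacts also enrich
transcripts in control cells, so `discriminate_induced()` applies the
two-branch rule: an exposed-enriched transcript is *induced* when it is
(A) absent from the control enriched set, or (B) present in both but
with a linear enrichment fold-change ratio (exposed over control,
$2^{\Delta \log_2 \mathrm{FC}}$) strictly greater than 1.5. The ratio
uses the raw (unshrunken) fold-change estimates; the summary
`min_log2fc` reports the smallest exposed-condition enrichment among
members. `overlap_conditions()` partitions two induced sets (e.g. two
exposure intensities) into shared and unique members with paired effect
sizes, and `cluster_enrichment_profiles()` orders transcripts by
average-linkage (UPGMA) clustering of Euclidean distances between their
enrichment profiles. Linkage and metric are a package choice — the
display convention in this literature specifies only the dendrogram
plotting, not the linkage — and missing profile entries are imputed as 0
for distances (flagged in the result). Rows are sorted by transcript ID
before clustering, which makes the leaf order deterministic and
permutation-invariant.

## Selectivity and downregulation concordance

`assign_expression_bins()` splits detected transcripts (base mean > 0)
into ten equal-count bins by ranked expression ("averagely divided"
read as deciles; an equal-width variant is available behind a flag —
deciles keep per-bin denominators stable, which a ratio display needs).
Remainder transcripts are distributed one-per-bin from the top bin
down; ties break by transcript ID. `selectivity_profile()` reports the
oxidized fraction per bin plus a chi-square goodness-of-fit test of the
oxidized counts against a proportional-to-detected expectation, pooling
bins with expected count < 1. The GOF statistic is an addition beyond
the usual scatter display and is labeled as such; because the oxidized
set is a without-replacement draw from the detected universe, the test
is mildly conservative (finite-population correction), which the
property tests acknowledge by asserting spread and non-anticonservatism
rather than exact uniformity. `downreg_concordance()` reports how many
induced transcripts are significantly downregulated and what fraction
sit in the negative fold-change region of the expression contrast.

## Gene-set over-representation

`fisher_overrepresentation()` computes the one-sided hypergeometric
upper-tail p per set (members intersected with the universe first; the
universe defaults, in the pipeline, to transcripts detected in the
input fraction rather than the genome), BH-adjusts across sets, and
ranks by the combined score
$c = -\ln(p) \cdot z$, where $z$ standardizes the observed overlap
against its hypergeometric null mean and variance. Published web-tool
combined scores calibrate $z$ from many random query lists; the
analytic $z$ used here needs no calibration corpus, at the cost that
*rankings* (not the Fisher p-values) may differ from those tools.
Degenerate margins (zero null variance, $p = 1$, or $k$ exactly at its
expectation) give a combined score of 0. Ties rank by p-value, then set
name.

## Bench-assay quantification

* **Competitive ELISA.** The standard curve is linearized as
  $\mathrm{logit}(B/B_0) = a + b\ln(\text{conc})$ and fitted by OLS over
  standards inside the assay's linear range (default 10.3–3000 pg/ml).
  Within that range the logit-log line and a four-parameter logistic
  coincide, and the line inverts in closed form —
  $\text{conc} = \exp((\mathrm{logit}(B/B_0) - a)/b)$ — so a 4PL fit is
  deliberately not implemented. The sensitivity (B/B0 = 0.8) and
  midpoint (B/B0 = 0.5, $e^{-a/b}$) follow from the fit; a
  non-negative slope is rejected as "not a competitive curve".
  Sample quantification interpolates each dilution, corrects antibody
  cross-reactivity with the kit factor 0.38 (direction is a mode switch
  — `divide`, the default, treats the factor as relative reactivity
  toward the RNA analyte, which makes the kit under-read; `multiply` is
  the constant relabeling in the other direction, since published
  values are consistent with either convention), and requires the
  dilution estimates to agree within 20% disparity
  ($100 \cdot (\max - \min)/\text{mean}$).
* **Unit conversion.** $\text{pg}/\mu g = \text{nM} \times M \times v$
  with molar mass $M = 299.24$ g/mol (8-oxoguanosine) and assay volume
  per RNA input $v = 0.1505$ ml/µg. Both are parameters: $v$ is
  reconstructed from the two published nM ↔ pg/µg concentration pairs,
  and the acceptance suite verifies that both pairs are consistent with
  these defaults to within 1%.
* **IP efficiency** is
  $100(\text{eluted}-\text{bg})/(\text{input}-\text{bg})$, clipped to
  [0, 100] with a flag.
* **Truncation assay.** Chemically adducted 8-oxoG stops reverse
  transcription, depleting the distal (full-length) PCR product. The
  index is the exposed/control ratio of normalizer-corrected
  distal/proximal ratios; oxidation is called below 0.8 — a package
  default, since the underlying readout is defined only as "a
  reduction".
* **Dot blot / densitometry** are ordinary least squares and ratio
  arithmetic, respectively.

## The simulator and what passing tests mean

`simulate_ripseq()` draws counts from
$\mathrm{NB}\!\left(s_j \mu_i \, 2^{e_i(c_j)[f_j=\text{rip}]} \,
2^{d_i [c_j = \text{exposed}]},\ \alpha_i\right)$: baseline log2 means
Normal(5, 2), dispersions log-uniform on [0.01, 0.3], library factors
log-uniform on [0.5, 2]. Planted truth: 100 transcripts enriched only
under exposure (log2 effect Uniform(3, 8), emulating the strong
enrichment effects this assay produces), 50 enriched in both conditions
with exposed/control ratio Uniform(1, 3) (straddling the 1.5 decision
boundary on purpose), and 50 + 50 differentially expressed with |log2|
effect Uniform(1, 3). The default is 3 replicates per cell for stable
dispersion moments; `n_replicates = 2` reproduces the shallower bench
design, whose weaker recovery is characterized but not asserted. One
root seed is split into fixed substream offsets (counts 0, gene sets
1000, ELISA 2000) so adding a generator never shifts existing streams.

In recovery runs, a false discovery is an induced call for a transcript
with *no* planted exposed-condition enrichment at all; both-condition
transcripts whose planted ratio sits near the 1.5 boundary are not
counted against the pipeline, since either decision is defensible under
sampling noise of the effect estimates.

What the simulator does *not* emulate: GC or length biases, positional
antibody bias (5′-proximal marks escape capture), correlated
transcript families, batch structure, or count dependence between
fractions of the same biological sample. Recovery results on synthetic
data therefore demonstrate correctness of the inference machinery under
the stated model, not performance guarantees on real libraries.

`simulate_gmt()` adds a spiked gene set drawn mostly from the planted
enriched transcripts as a known positive for over-representation;
`simulate_elisa()` generates triplicate standards and two sample
dilutions with Gaussian noise on the logit scale.

## Pipeline, configuration and provenance

`run_pipeline()` chains enrichment (both conditions), discrimination,
differential expression, selectivity, concordance and (when gene sets
are supplied) over-representation, writing each table as TSV plus a
JSON manifest with input MD5 checksums, configuration echo, package
version and stage summaries; reruns on identical inputs are
byte-identical. Configuration is a plain R list (`run_config()`) or a
YAML file — YAML because it is the configuration format the surrounding
R toolchain reads natively. Cross-exposure overlap
(`overlap_conditions()`) operates on two induced sets from separate
runs and is exposed as a function rather than a pipeline stage, since a
single run has one exposure design. The package's interface is its
functions and this document; the analyses it supports are interactive
R analyses, so no shell entry point is shipped.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| dispersion floor | 1e-8 | keeps NB weights finite; below any biological dispersion |
| dispersion shrinkage | weight 0.5 to log-median | stabilizes 2–3-replicate moments |
| IRLS tolerance / iterations | 1e-8 / 100 | coefficient-scale convergence |
| divergence guard | abs(log fold change) ≥ 30·ln2 | flags infinite MLEs |
| mean-count filter | ≥ 1 normalized count | excludes noise-dominated transcripts from BH |
| GOF pooling | expected < 1 merged downward | chi-square reference validity |
| equal-count remainder | one-per-bin from the top | matches "extra in the top bin" convention |
| tie-breaks | lexicographic transcript / set ID | determinism |

Test problem sizes (20,000-transcript null calibration; 2,000-transcript
recovery runs; 100–1,000-case oracle sweeps) were chosen so each suite
verifies its property with comfortable Monte-Carlo margin while the
whole suite stays quick to iterate on.

## Known limitations

* Two-level designs only: no interaction model across exposure
  intensities, no covariates, no paired-sample correlation between rip
  and input fractions derived from the same RNA pool.
* The moments-plus-shrinkage dispersion estimator is anticonservative
  relative to nominal when dispersions must be estimated from 2–3
  replicates (the calibration suite quantifies the Wald test itself at
  known dispersion); results at bench-scale replication should be read
  with thresholds, as in the intended workflow, not as exact error
  rates.
* The analytic combined score is not numerically comparable to
  rank-calibrated web-tool scores.
* The logit-log ELISA model is valid only inside the linear range;
  out-of-range interpolations are flagged, not extrapolated reliably.
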