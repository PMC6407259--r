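---
title: "Copy-number calling and trait association from array CGH: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling and trait association from array CGH: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghcnv)
```

## The measurement model

Two-colour array CGH hybridises a test genome (here, a bull) against a
single reference genome (a cow) and reports, per oligonucleotide probe, the
log2 ratio of test to reference fluorescence.  Under ideal normalisation a
probe inside a region of copy number $c$ in the test animal has expected
log2 ratio

$$\mathrm{E}[x] = \log_2(c / 2),$$

so diploid sequence sits at 0, a single-copy loss at $-1$, and a
single-copy gain at $\log_2(3/2) \approx +0.585$.  Because the test animals
are male and the reference female, the X chromosome is hemizygous in every
test sample and its baseline sits near $-1$; the pipeline therefore
recentres each male sample's chrX profile on its own median before calling,
so that genuine chrX CNVs deviate from the recentred single-copy baseline.
A homozygous deletion ($c = 0$) has no finite log2 ratio; the simulator
emits it at a documented floor of $-4$, far below any calling threshold but
finite, so downstream arithmetic never meets an infinity.

The synthetic-data module exists because a realistic study of this design
(~2.1M probes at ~1.2 kb mean spacing, 47 bulls) cannot be shipped or
downloaded at test time.  The generator emulates the features the analysis
actually consumes: probe maps at a target mean spacing with ±25% uniform
positional jitter (only the mean spacing of such arrays is ever published);
planted CNV loci of 3.6 kb–2.1 Mb (the span of high-confidence calls
reported for this array class); per-locus direction types (loss / gain /
mixed at 0.55 / 0.30 / 0.15) so that region-level state proportions
resemble real catalogues, where losses outnumber gains roughly two to one
and mixed regions are a small minority; Gaussian per-probe noise plus a
per-sample baseline shift; self-to-self (noise-only) hybridisations for
false-positive calibration; and 41 correlated traits in four blocks
(6 production / 9 reproduction / 8 health / 18 type) with block-structured
residual correlation.  What the generator does **not** emulate: wave
artefacts and GC tracking along the genome, probe-specific response,
segmental-duplication cross-hybridisation, and relatedness among animals.
Passing tests therefore demonstrate correctness of the algorithms under the
stated noise model, not robustness to every artefact of a physical array.

Every stochastic routine takes one integer seed; sub-seeds for internal
stages are derived deterministically from it and a stage label, so a whole
run is byte-reproducible while stages can be re-run in isolation.

## Segmentation

Each (sample, chromosome) profile is normalised (autosomal median to 0) and
partitioned by exact penalized least-squares dynamic programming, minimising

$$\sum_{\text{segments}} \sum_{i \in \text{seg}} (x_i - \bar{x}_{\text{seg}})^2
  \;+\; \lambda \cdot \#\text{segments}$$

over *all* contiguous partitions.  This objective — squared error around
segment means — is the published description of the vendor segmentation
used for such arrays; the vendor's penalty and model-selection rule are not
public, so the package states its own: the DP is exact for a given
$\lambda$ (verified against exhaustive enumeration on short profiles), and
$\lambda$ is chosen per profile from the candidate grid
$\{0.5, 1, 2, 4\} \cdot \hat\sigma^2 \ln n$ by minimising the BIC-type score
$n \ln(\mathrm{SSE}/n) + (2k - 1)\ln n$, where $k$ is the number of
segments and $2k-1$ counts the free parameters ($k$ means, $k-1$
breakpoints).  Counting parameters rather than segments matters: with a
penalty of only $k \ln n$, pure-noise profiles of 1,000 probes fragment in
the majority of replicates, while the parameter count keeps them whole in
≥95% and still recovers a planted 20-probe single-copy loss with
breakpoints within ±2 probes in ≥95% of replicates at probe SD 0.15.

Numerical choices: $\hat\sigma^2$ is the squared MAD of lag-1 differences
divided by 2 (robust to the CNVs themselves), floored at $10^{-8}$ so a
noise-free profile still has a strictly positive penalty — this makes the
DP prefer the fewest segments among zero-SSE ties and keeps noiseless
truth recovery exact.  Missing probe values are dropped before optimisation
with index bookkeeping preserved, so segments always tile the probe range.
The DP is $O(n^2)$ per profile with an optional band (maximum segment
length in probes) giving $O(n \cdot \text{band})$; the unbanded DP is the
reference implementation and the band is used for cohort-scale runs (the
packaged demo uses a 500-probe ≈ 600 kb band, well above its largest
planted event).  Ties inside the DP break toward fewer segments, then the
longer last segment, so results are deterministic.

## Calling and CNVR construction

A segment becomes a CNV call when $|\bar{x}| \ge 0.5$ over $\ge 5$
consecutive probes — the conservative "0.5_5" rule under which self-to-self
hybridisations yield no calls (the analytic bound
$P(\text{5 consecutive probes beyond } 0.5) \approx (2\Phi(-0.5/0.15))^5$
per window is astronomically small at probe SD 0.15, and the simulated
false-positive count is 0).  Adjacent qualifying same-state segments merge
into one call; sub-threshold gaps are *not* bridged (an open choice —
bridging is not described for the original pipeline, and not bridging is
the conservative reading).  Calls are then length-filtered with **strict**
inequalities: only $1\,\text{kb} < \text{length} < 5\,\text{Mb}$ survives;
the boundary values themselves are removed, consistent with a filter
described as removing "≤ 1 kb and ≥ 5 Mb".  Interval lengths are
end − start + 1 throughout (all internal coordinates are 1-based
inclusive; only BED files are 0-based half-open, converted at the I/O
boundary).

CNV regions (CNVRs) are the connected components of calls across all
samples under ≥1 bp overlap.  Book-ended calls (end + 1 = start) do not
merge: aggregation of *overlapping* calls implies genuine sharing.  A CNVR
is classified `loss`, `gain`, or `both` by its members' states, and
unplaced ("chrUn"-like) chromosomes are flagged and excluded from
association.  The merge is implemented on IRanges and tested against an
independent quadratic union-find oracle.

## Association

Per CNVR, the member-probe log2 ratios are reduced to one score per sample
by the first principal component, sign-oriented to correlate positively
with the mean probe value so the score rises with copy number.  (The
literature on this method mentions clustering the first three components;
the same description defines the signal as one-dimensional, and a
univariate mixture needs one dimension — the package uses PC1 only and
records this as a deliberate reading.)

Scores are genotyped by univariate Gaussian mixtures with 1–3 components,
fitted by EM with a deterministic quantile initialisation plus 5 seeded
random restarts (tolerance $10^{-8}$ on the log-likelihood, 500-iteration
cap, component SD floor $10^{-3}$), the component count chosen by BIC.  A
fit is declared *non-converged* — and its CNVR excluded from testing,
mirroring the fact that in real data only a fraction of regions genotype
cleanly — when EM hits the iteration cap, any weight falls below $2/n$, or
adjacent means are closer than 0.5 pooled SDs.  Genotype classes are
ordinal labels ranked by component mean (single-component fits are class 2,
the diploid convention).  Labels are invariant to adding a constant to all
scores and equivariant under negation; no absolute-position anchoring is
used, since a shift-dependent rule would contradict that invariance.

Each trait (a predicted transmitting ability, PTA — an estimated additive
genetic merit with fixed effects already removed, hence no covariates in
the model) is regressed by OLS on the posterior-expected genotype dosage;
regression on hard class labels is available behind a flag, as the original
description does not say which was used.  Two-sided p-values come from the
slope t-statistic.  Bonferroni correction uses an explicit family size m =
the number of converged CNVRs (per-trait families; a global family is
configurable).  The per-CNVR "variance explained" is the squared Pearson
correlation between the PC1 score and the trait — an approximation, and
exactly the $R^2$ of the simple regression of trait on score.  PTA
reliabilities are read but unused by default; optional weighted least
squares sits behind a flag.

Trait profiles are clustered by transforming the CNVR × trait p-value
matrix to $-\log_{10}$, correlating trait columns (Pearson), and applying
average-linkage hierarchical clustering on distance $1 - r$; constant
columns are placed at the maximal distance 2 with a warning.

## The demo cohort and its power design

The packaged demo (`pipeline_config()` defaults) is a 24 Mb four-chromosome
genome (incl. chrX) at 1.2 kb spacing — 20,000 probes — with 47 male
samples, 30 planted loci, probe SD 0.15, sample-shift SD 0.05, 8 traits
(two per block), and one dosage effect on Dtr_Preg_Rate.  The end-to-end
power study uses a further scaled-down single-chromosome cohort
(3 Mb, ~2,500 probes, 4 loci, 47 samples) so that hundreds of replicates
fit in a routine test run; these problem sizes are the package's own
choices for a reproducible desk-scale study.

The planted effect size is a design decision made by power analysis
*before* simulation: at $n = 47$ with a Bonferroni family of ~4 converged
CNVRs (corrected $\alpha \approx 0.0125$), the noncentral-t power at a
locus explaining 10% of trait variance is only ≈0.5, whereas at 25% it is
≈0.9.  The demo therefore plants its effect at 25% of the trait's
variance — comfortably above the ≥10% regime the design targets — and the
measured detection power over 200 replicates is ≈0.9.  A separate design
check plants a locus at 14.3% (the magnitude reported for a strong
fertility-associated region in real data) and verifies the realized squared
correlation at $n = 500$; effect sizes are solved in closed form from the
variance partition
$R^2 = \beta^2 V_d / (\beta^2 V_d + \sigma^2)$ with $V_d$ the empirical
dosage variance.

## Annotation

Gene overlap expands genes by a flank (3 kb for genome-wide content; 5 kb
when reporting significant regions) and records every (CNVR, gene) pair
sharing ≥1 bp; CNVRs with no overlap get their nearest same-chromosome gene
and edge-to-edge distance, ties broken toward the lexicographically smaller
symbol.  QTL annotation first discards QTLs with confidence intervals
longer than 30 Mb, then requires the *union* of retained QTLs to cover at
least 50% of the CNV's length (the union, not the best single QTL, is the
conservative reading of "covered by QTLs").  Cross-study CNVR comparison
marks a region as supported when the union of the other study's regions
covers ≥50% of its length.  The "more than 1 bp in common" phrase in the
field's usual wording is implemented as overlap ≥ 1 bp, the standard
practice; the cutoff is configurable.  All three operations are tested
against quadratic all-pairs oracles, and the worked public coordinates of a
known fertility-associated region and its cytochrome P450 gene (overlap
12,079 bp) pin the coordinate conventions.

## Known limitations

* The segmentation penalty rule is a stated stand-in for an undocumented
  vendor algorithm; it matches the published objective, not the vendor's
  internals.
* Genotype classes are capped at three; loci segregating more than three
  copy states in a cohort genotype poorly and usually fail the convergence
  gate (by design — such regions are excluded, not mis-tested).
* No kinship or mixed-model correction: cohort members are treated as
  unrelated, which real half-sib bull cohorts are not.
* The Gaussian noise model makes threshold behaviour analysable but is
  optimistic about array artefacts; the per-probe noise level of the real
  instrument is not published, and the defaults here are chosen for
  testability.
* Association power at $n \approx 47$ is adequate only for large effects;
  this is a property of the study design being emulated, not of the
  implementation.
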