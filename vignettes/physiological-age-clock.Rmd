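---
title: "A transcriptomic clock for physiological age: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A transcriptomic clock for physiological age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioclock)
```

## The problem

Chronological age is an imprecise proxy for the state of an organism: genes,
environment and chance shift the intrinsic rate of aging by tens of percent.
Because a sizeable fraction of the transcriptome changes with age in
reproducible, monotone ways, a reference time course of control expression
profiles can act as a standard curve, and any sample — in particular a young
mutant suspected of aging too fast — can be assigned a *physiological age*
by where its profile falls on that curve. `physioclock` implements this
programme for probe-level log2 expression matrices (microarray-style data;
the head/thorax dissection design it emulates uses ages 3, 10, 30 and 45
days with five replicates per cell), from raw-matrix preprocessing to the
fitted clock and percent-acceleration estimates.

## Preprocessing model

**Batch baseline correction.** Two hybridization batches sharing one common
technical replicate are reconciled per probe: the offset
$\delta_p = \mathrm{tech}_B[p] - \mathrm{tech}_A[p]$ is subtracted from
every batch-B column, which by construction makes the two technical
replicate columns identical and leaves only technical noise as residual
batch signal; the redundant copy is then dropped. This is a per-probe
location correction only — it assumes batch effects are additive on the
log2 scale and shared by all samples of a batch. With more than two batches,
each non-reference batch needs its own copy of the technical replicate.

**Quantile normalization** (via `limma::normalizeQuantiles`, ties averaged)
is applied jointly across all samples *after* baseline subtraction,
following the narrative order of the workflow the package models. Whether
the original analysis normalized jointly or within batch is not knowable
from the outside; joint normalization was chosen because after baseline
subtraction the batches are nominally on one scale, and normalizing them
together avoids re-introducing a batch difference through separate target
distributions.

**Noise floor.** Low-intensity values are noise-dominated. `fitNoiseFloor`
computes per-probe mean and coefficient of variation (CV = SD/mean of the
log2 values — the scale on which the matrix arrives; the CV scale is a
package choice and configurable), smooths CV against mean with lowess
(span 0.3), anchors a straight line on the raw points of the upper half of
the mean range (where signal dominates), and reports the largest mean in the
*lower* half at which the smooth deviates from the line by more than
`tolFactor` (default 2) times the residual SD of that high-end fit. Two
details matter and are deliberate: the tolerance is derived from the raw
high-end scatter, not from the smooth (whose roughness is near zero and
would trigger everywhere); and the search is restricted to the lower half,
since the high-end fit's own residual exceedances would otherwise place the
floor spuriously high. A flat CV–mean relationship returns the minimum
observed mean (nothing to censor). In the emulated design the floor sits
near 7.5 log2 units, and `applyNoiseFloor` clamps values below the floor to
it and discards probes that never exceed it. Outlier *samples* are removed
only via an explicit exclusion list (`excludeSamples`): the original
criterion — visual inspection of box plots and PCA — is not algorithmic, and
the package does not pretend to automate it.

## Aging-gene selection

Expression is related to ordinal age class by the **polyserial
correlation**: the correlation between the continuous variable and the
latent standard normal variable assumed to underlie the ordinal one. The
package uses the classical two-step estimator,

$$\hat\rho \;=\; \sqrt{\tfrac{n-1}{n}}\;
  \frac{r_{xy}\, s_y}{\sum_k \varphi(\tau_k)},$$

with $r_{xy}$ the Pearson correlation of expression with the integer-coded
classes, $s_y$ the sample SD of the codes, and $\tau_k$ the standard normal
quantiles of the cumulative class proportions. The $\sqrt{(n-1)/n}$ factor
makes the scaling population-consistent, as in standard implementations; it
cancels exactly in the permutation-null comparison below, because the null
shares the label multiset. Age classes are coded by rank (1..K) by default —
the estimator treats age as ordinal — with raw-day coding available
(`coding = "days"`). The tests check the two-step estimate against an
independently written maximum-likelihood fit (direct likelihood
maximization over $\rho$ with empirical thresholds); the two agree to well
under 0.03 across random configurations, and recover a generating latent
correlation of 0.5 at $n = 20{,}000$ within 0.02.

**Permutation null.** Significance cutoffs come from randomizing age labels:
for each of $B$ rounds (default 20, configurable — the original count is not
recoverable) one permutation is shared by all probes, preserving the
inter-gene correlation structure of the null; all $B \times n_\text{probes}$
estimates are pooled and probes outside mean ± 2 SD are flagged, with
direction the sign of $\hat\rho$. Under a Gaussian null the band captures
~95.4% of estimates, so the procedure's type-I error is ≈ 4.6% and bounded
by 5% — this is exactly what `scripts/acceptance.R` recomputes on a 2,000 ×
19 global-null simulation. Per-probe independent permutation is available
(`perProbe = TRUE`) but not the default.

## Differential expression and set statistics

Probes affected by a genotype are identified by one-way ANOVA with *sample
class* (genotype × age cell within a tissue) as the factor, BH correction
across probes, Tukey-HSD post hoc tests computed only for probes passing the
corrected ANOVA gate (q < 0.05), and a fold-change rule
$|\Delta \log_2| \ge \log_2 1.5 \approx 0.585$ — the standard log2-difference
reading of "1.5-fold" for data already on the log2 scale. The per-probe
F and studentized-range p-values are computed vectorised (via `pf`/`ptukey`)
for speed and are oracle-checked against `aov`/`TukeyHSD` in the tests. With
five replicates per class the per-probe variance estimate carries only 8
degrees of freedom, so even a 1.0-log2 planted shift at noise SD 0.25 is
recovered at ~85% sensitivity, not 100% — the tests assert the honest rate.
By default the ANOVA spans all classes jointly (per-pair analysis is a
matter of passing a two-class subset), which mirrors the observation that
adding datasets can shift borderline significance calls.

Overlap between probe sets is tested by χ² with Yates' continuity
correction on the 2×2 membership table over the probe universe; concordance
between fold-change vectors reports $r^2$ and the percent of sign-matching
probes; rescue calls follow the rule: *full* if affected in null-vs-control
but no longer affected in rescue-vs-control, *partial* if still ≥ 1.5-fold
from control but shifted toward it (smaller |fold change| with the same
sign, or a sign loss — sign loss counts as trending toward control).

## The clock

**Classifier selection.** One leave-one-out round per control sample: the
differential-expression feature step (same thresholds as above, age class as
the factor, any pairwise class contrast) is run on the remaining samples,
and the round's features drive a k-NN classification (Euclidean distance on
log2 values) of the held-out sample. Probes selected in *every* round are
the aging classifiers; selection frequencies are exact multiples of
1/n_rounds by construction. `k = 3` by default — the smallest odd
neighbourhood that is robust with 4–5 replicates per class — with majority
vote and a deterministic distance-weighted tie-break (the tie is broken by
summed inverse distance, then by the single nearest neighbour); the distance
metric and k are configurable. Rounds yielding zero features are recorded as
failed with a warning and count in the denominator, so a global-null input
produces an empty classifier set. Class imbalance (four day-3 replicates
versus five elsewhere) is left unweighted.

**PC-seeded AIC-optimised linear model.** Classifier expression of the
training controls is centred by training means and decomposed by PCA
(centering only, no per-probe scaling — classifier values already share the
log2 scale; a scaling toggle exists). Candidate components are those needed
to reach 95% cumulative variance, capped at $n_\text{samples} - 2$ to keep
the regression honest; both the variance rule and the cap are module
choices. Numeric age in days is then regressed on the components by
*forward-only* stepwise selection: at each step the component whose addition
most decreases AIC enters, and the search stops when no addition decreases
it. Forward-only search keeps the trace strictly decreasing and the
procedure deterministic. In the exactly linear, noise-free limit one
component is selected and training residuals are zero (a test).

**Prediction.** A new profile is centred with the *training* means,
projected onto the training loadings, and passed through the linear
coefficients; predictions are not clipped to the training range.
Acceleration is $100(\hat a - a)/a$ against the metadata chronological age.
Predictions depend only on the classifier rows, so adding unrelated probes
to the input changes nothing (a test). Group summaries report mean ± SEM
with one-way ANOVA and Tukey correction applied to the predictions
themselves.

## Profile similarity

Over the intersection of aging-related and mutant-affected probes, each
mutant sample is Pearson-correlated with each control sample and the r
values are grouped by control age (5 mutants × 19 controls = 95 pairs in the
head-like design). The per-sample pairing follows the analysis methods the
package models; a `onMeans = TRUE` mode reproduces the alternative reading
in which group mean profiles are compared (one r per control age). Raw log2
profiles are correlated, so between-probe baseline variation contributes to
every pair equally and the age signal appears as the *ordering* of the
per-age means; the r values are invariant to per-sample affine rescalings.

## The synthetic-data generator

The generator is the package's test bed and defines the conditions under
which the pipeline's properties are demonstrated. Aging probes follow
$b_0 + \beta \cdot \text{age}$ on the log2 scale — the simplest monotone
form, matching the linear age model downstream; real aging trends need not
be linear. Defaults: 2,000 probes, 20% aging (within the 2–30% range
reported across systems), slope magnitudes |N(0, 0.05)| log2/day with
balanced signs (or a fixed magnitude via `slopeValue`, used where a
homogeneous planted effect is needed), homoscedastic Gaussian noise
(SD 0.25 log2), baselines N(9, 1.5) so a realistic low-expression tail falls
under the 7.5 floor, per-probe batch-2 offsets N(0, 0.3), and a technical
replicate duplicated across batches with technical noise SD 0.05 — an order
of magnitude below biological noise, as technical replicates are. Mutants
are the control law evaluated at effective age
$a \cdot \text{age}_\text{chron}$ plus fixed ≥ log2(1.5) shifts on a
disjoint set of mutant-specific probes. The generator does *not* emulate
probe-level artifacts (GC bias, cross-hybridization), count-based noise, or
non-monotone trends; passing tests therefore demonstrate correctness of the
procedures under the stated generative model, not performance on any real
array.

## Problem sizes, determinism and degenerate inputs

The test suite and the acceptance script run at desk scale: 500–2,000 probes
and the 19–20-sample study layout, sizes at which every stage completes in
seconds while leaving the statistics (permutation pooling, BH, LOO rounds)
fully exercised. All randomness flows from one integer seed fanned out to
per-stage child seeds (`childSeed(seed, stage)`), so stages can be rerun
independently and the full pipeline is byte-deterministic (a test).
Degenerate inputs fail loudly rather than silently: constant probes yield
`NA` polyserial estimates and are never flagged; a constant matrix is an
error for the noise-floor fit; classes with fewer than two replicates, a
missing technical replicate (named by batch), missing clock probes (listed),
and an empty aging ∩ affected intersection are all hard errors.

## Known limitations

The clock is tissue-specific by design — transferring a fitted clock across
tissues is out of scope. The 2-SD permutation rule controls the *per-probe*
false-flag rate near 5% but is not an FDR procedure. The acceleration
estimate inherits the linear-trend assumption: under strongly saturating
trends the effective-age mapping would compress at the old end. Probe-level
analysis only: collapsing probes to genes requires an external map and is
reporting, not inference.
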