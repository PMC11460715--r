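---
title: "Methods: day-by-day connectivity and daily behavior in a densely sampled subject"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-by-day connectivity and daily behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denseFC)
```

## The design and its statistical object

A dense-sampling study scans one participant repeatedly — here emulated as
30 sessions on a Monday/Friday grid (day offsets 0, 4, 7, 11, ...) inside a
133-day record of daily behavioral, physiological and lifestyle factors.
Each session yields one weighted connectome; the analysis asks how the
*sequence* of connectomes covaries with the *sequence* of daily factors.
Because n is the number of sessions (tens, not thousands), every inference
in this package is nonparametric — permutation or surrogate based — and
every multiple-comparison family is controlled with Benjamini–Hochberg FDR.

Two time scales are modeled. The previous-day models pair the session on
day *d* with the factors of day *d − 1*; by this convention the sleep
factors of day *d − 1* describe the night ending on the morning of day
*d − 1* (the night-versus-day bookkeeping is a configuration choice,
`lag`, with 1 as default). The lagged models extend the question to lags
1–15 days; lag 0 is excluded because the contemporaneous case belongs to
the previous-day family, and the grid stops at 15 because twice-weekly
sampling of 30 sessions leaves little information beyond three weeks.

## Behavioral preprocessing

PANAS negative/positive affect are sums of five fixed items each (afraid,
nervous, upset, hostile, ashamed; active, determined, attentive, inspired,
alert); a response missing any required item yields a missing score rather
than a zero-filled one, and daily aggregation (median for affect; mean,
min, max, sd for sensor streams) marks empty days as missing. The SD of a
single sample is defined as 0 so that sparse sensors keep aligned
mean/max/sd columns. Missing cells are mean-imputed per variable — the
weakest assumption compatible with largely-complete data, and one that
preserves each variable's mean exactly.

Collinearity screening runs after imputation and in two passes: first
iterative VIF (drop the largest until all VIF ≤ 5; a constant column is
removed beforehand since VIF is undefined for it), then pairwise rank
correlation (|ρ| > 0.7 keeps only the variable earlier in a user-supplied
priority order, defaulting to column order). Two points here were genuinely
open and are fixed as package policy: the order VIF-then-correlation, and
reading the ρ of the correlation rule as Spearman's rank correlation (the
conventional referent of the symbol). Both choices are recorded in the
screen's drop report, which lists every removal with its trigger value.

## Signal conditioning

`cleanSession()` applies, in order: Savitzky–Golay detrending (window 240 s,
polynomial order 3 — the order is not dictated by the design and is
exposed as a parameter; the window length in volumes is rounded to the
nearest odd integer), confound regression (confounds are passed through the
same Savitzky–Golay filter first so filtering artifacts are not
re-introduced; rank-deficient confound sets lose their dependent columns
with a warning; a session without confound recordings skips the step with a
message), and a discrete-cosine high-pass at 0.01 Hz. The DCT projection
was chosen over an IIR filter for zero phase distortion and exactness on
finite input: basis functions with frequency k/(2·N·TR) below the cutoff
are regressed out. Detrending and filtering re-add the per-ROI mean —
downstream correlations are mean-invariant, but preserved means keep the
cleaned series physically interpretable.

Motion scrubbing censors volumes with FD strictly above 0.2 mm (a volume at
exactly 0.2 is kept; the comparison convention is tested explicitly).
Union scrubbing censors a volume everywhere if flagged anywhere;
percentage scrubbing censors when flagged in at least ⌈pct · n_sessions⌉
sessions — the ceiling is forced by the design's two printed examples
(10% → 3 of 30, 5% → 2 of 30). Censoring is row deletion, never
interpolation, so the correlation support stays identical across ROIs.

## Connectivity estimation

Rest and movie sessions use Pearson correlation between ROI time courses
over retained volumes. Task sessions use beta-series correlation: one
canonical double-gamma HRF regressor per trial fitted simultaneously
(least-squares-all) together with an intercept and linear drift. The
simultaneous fit follows the reading that every trial is modeled with a
separate covariate; least-squares-separate (`method = "lss"`) is available
where trial overlap makes the joint design ill-conditioned, and a
near-singular design triggers a condition-number warning with a small
ridge fallback. Zero-variance ROIs or beta columns produce missing links
with a warning, never silent zeros.

Adjacencies are Fisher-transformed (r = ±1 clipped to ±(1 − 10⁻⁷)), the
session-mean FD is regressed out of every link across sessions, and the
result is mapped back through tanh. The residualization restores the
per-link intercept — output = across-session mean + residual — so
residualized matrices keep the scale of connectivity and the across-session
mean of every link is preserved exactly; a constant FD vector makes the
step an identity (logged).

## Graph construction and metrics

Binarization must not disconnect the graph, so thresholding is anchored on
the maximum spanning tree: Kruskal over links ordered by weight descending
with deterministic ties (smaller node pair first), then the strongest
remaining *positive* links until the edge count reaches density·n(n−1)/2,
at the three conventional densities 0.10/0.20/0.30. Negative links are
only ever used if the MST itself needs them to connect. If the MST already
exceeds the requested density the MST is returned and the realized density
is reported. The whole-graph matrix is thresholded first and subdivided
afterwards — the participation coefficient needs the whole graph in any
case — but `metricSeries(mode = "subnetwork")` offers the alternative of
thresholding each network block separately, since the opposite reading of
the procedure is defensible.

Participation coefficient and within-network global efficiency are
computed on the binarized graph (unweighted shortest paths). Degenerate
conventions: an isolated node has PC 0; disconnected pairs contribute 0 to
efficiency (1/∞); a singleton network has no pairs and reports NA. Both
metrics are cross-checked in the test suite against brute-force oracles
(direct edge counting; Floyd–Warshall distances).

## Permutation regression

All regressions standardize predictors and response (z-scores, n − 1
denominator), report standardized β and t, and build the null by permuting
the response rows (10,000 draws at study scale), two-sided on |t| with the
add-one rule p = (1 + #{|t*| ≥ |t|})/(1 + n_perm) so p = 0 is unattainable.
Simple response permutation was chosen as the scheme because it is exact
under the global null being tested and calibrates correctly (verified by
simulation); Freedman–Lane residual permutation is available
(`scheme = "freedman-lane"`) for models where a nuisance covariate — such
as the prolonged-eye-closure percentage in the resting-state family —
should be held out of the permuted part. FDR families follow the design:
per predictor across links, or across networks for the metric models.

## Lagged cross-correlation with phase surrogates

The null for the lag-1..15 analysis must preserve the factor's
autocorrelation, otherwise smooth factors would inflate significance at
every lag. Surrogates therefore randomize the Fourier phases of the factor
series on the *full daily grid* (conjugate-symmetric phases; DC and
Nyquist fixed, so the output is real and the mean exact) and are then
subsampled to the lagged session days, preserving the irregular
twice-weekly sampling. The observed statistic is the Pearson correlation
of metric and lagged factor (a rank option exists; product-moment is the
default), tested two-sided on |ρ|, with BH across networks separately for
each variable-lag pair — each tuple treated as independent, with an
optional stricter correction across the 15 lags left to the user. A
constant metric series yields NA, not zero.

## Inter-day representational similarity

The brain matrix is the day × day correlation of one ROI's time courses
over a shared censoring mask (percentage scrubbing at 5% by default — the
compromise that keeps enough common volumes). The behavioral matrix
rank-transforms the per-day values to [0, 1] and uses either
nearest-neighbors similarity, −|r_i − r_j|, or the Anna-Karenina form,
(r_i + r_j)/2, in which high-scoring days resemble each other and
low-scoring days are idiosyncratic; the exact formulas are not dictated by
the framework that names these structures, so both are stated here and the
mean-rank AK form is the default. The Mantel statistic is the Spearman
correlation of upper triangles under simultaneous row/column permutation,
one-sided positive by default (the directional hypothesis is "more similar
days, more similar brains"), switchable to two-sided. p is invariant to
monotone transforms of either matrix.

## Time-segment identification

Movie runs are cut into 25-TR windows advanced by 1 TR (946 segments for a
970-volume run; 14.85 s at TR 0.594 s; steps of 2 and 4 TRs are supported).
For each left-out session and each spatial unit, every segment is matched
by Pearson correlation against the across-session average of each
candidate segment; the argmax is the prediction, ties resolve to the
smallest index and zero-variance templates are never selected. Accuracy is
the fraction of correctly placed segments; chance is 1/n_segments.
Spatial units are atlas ROIs — the desk-scale stand-in for searchlight
spheres, whose radius remains a concept for voxel-level data only.
Segments overlapping censored volumes are dropped with a reported count.
Accuracy maps are analyzed with the same permutation-regression engine,
BH-corrected across units, in place of voxelwise permutation machinery.

## The synthetic generator: what it emulates, and what not

`genSessions()` draws each session from a multivariate normal whose
correlation matrix combines a community block baseline (within-network
correlation 0.3, between 0) with session-specific target-link values; the
matrix is eigenvalue-clipped to positive semidefinite, rescaled to unit
diagonal, and Cholesky-sampled. An explicit target matrix was preferred
over a latent-factor construction because it gives *exact* control of the
injected link correlations — the quantity the recovery tests measure —
at a cost that is negligible for ≤ 300 ROIs.

Injected couplings enter on the Fisher-z scale,

  r(d) = tanh( atanh(base) + slope · factor(d − lag) ),

not additively on r. The additive form cannot hold for standardized
factors and useful slopes (slope 0.4 at ±4 SD leaves the unit interval);
the tanh link is valid for any factor value, monotone, and preserves sign
and lag of the effect, which is exactly what the recovery criteria need.
The realized generating correlation of every target link is recorded as
ground truth. Behavioral factors are AR(1) series (coefficient 0.5 by
default — realistic week-scale persistence for sleep and physiology),
standardized, with 5% missingness injected completely at random; FD traces
keep a sub-threshold baseline with spikes above 0.2 at a configurable
rate; trial onsets accumulate uniform 2–10 s inter-trial intervals.

What the generator does *not* emulate: voxel-level BOLD, hemodynamic
nonlinearity, scanner artifacts, non-Gaussian heavy-tailed noise,
task-evoked mean shifts (couplings act on connectivity, not activation),
and structured missingness. Passing calibration and recovery tests on this
generator therefore demonstrates the correctness and statistical behavior
of the pipeline under its own model assumptions — not that real
recordings satisfy those assumptions.

## Problem sizes and numerical choices in the shipped checks

The test and acceptance suites run the calibration studies at 500
replicates with 500 permutations/surrogates, and the recovery studies at
50 replicates of 30 sessions × 800 volumes × 20 ROIs — sizes chosen so the
full suite completes in minutes on a single core while keeping Monte-Carlo
bands tight enough to be informative (the 99% binomial band at 500
replicates is ±0.025 around 0.05). Floor p-values are 1/(n+1) by the
add-one rule; Fisher round-trips are exact to 10⁻¹²; surrogate amplitude
spectra to 10⁻¹⁰; graph oracles agree exactly. Where a tie, a degenerate
input, or a boundary (FD exactly at threshold, MST exceeding the requested
density, all-missing series) has a convention, the convention is asserted
by a test rather than left implicit.

## Known limitations

Inference is mass-univariate: no mixed-effects, autoregressive or
multivariate lag models (the lagged analysis treats each variable-lag pair
independently). The permutation scheme assumes exchangeable sessions under
the null; strong session-to-session autocorrelation in the *metric* series
would not be respected by response permutation (the surrogate test handles
it on the factor side only). Beta-series estimation at short inter-trial
intervals is ill-conditioned by construction; the ridge fallback trades a
little bias for stability and warns when it engages. The NN/AK similarity
forms and the Mantel sidedness are conventions, switchable but defaulted
as documented above.
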