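# denseFC

Dense-sampling, single-subject functional connectivity analysis: estimate
day-by-day brain networks from tens of fMRI sessions collected over months,
and relate their fluctuations to the daily life of the same individual —
sleep, physical activity, autonomic physiology and mood.

## Who this is for

Precision-neuroimaging studies scan one participant many times instead of
many participants once. With ~30 sessions on a twice-weekly (Monday/Friday)
schedule embedded in a ~133-day behavioral record, each session yields one
estimate of the subject's functional connectome, and the day-to-day variation
of that connectome becomes the object of inference. `denseFC` implements the
full analysis chain for such designs, together with a synthetic-data
generator with known ground truth, so every stage can be calibrated and
power-checked without any recordings.

## What it computes

**Signal conditioning.** Savitzky–Golay detrending (240 s window),
regression of filtered confounds, discrete-cosine high-pass at 0.01 Hz, and
motion scrubbing: volumes with framewise displacement FD > 0.2 mm are
censored, either by union over sessions or by the percentage rule (censor
everywhere when flagged in ≥ ⌈pct · n_sessions⌉ sessions; with 30 sessions,
10% → 3 and 5% → 2).

**Connectivity.** Per session, the ROI × ROI Pearson correlation matrix
(rest/movie) or the beta-series correlation matrix (task runs: one
HRF-convolved regressor per trial, least-squares-all), Fisher-transformed
(z = atanh r), with session-mean FD regressed out of every link and mapped
back with tanh.

**Graph metrics.** Each adjacency matrix is binarized at proportional
densities 10/20/30% anchored on its maximum spanning tree (so the graph is
always connected), then summarized by the participation coefficient

    PC_i = 1 − Σ_s (k_is / k_i)²

(between-network integration, averaged per network) and by within-network
global efficiency, the mean inverse shortest-path length among a network's
nodes.

**Inference.**

- *Previous-day regression* (H1–H3): standardized multiple regression of
  each link or network metric on the previous day's factors, permutation
  p-values (response permutation, two-sided on |t|, add-one rule), BH-FDR
  per predictor across links or networks.
- *Lagged cross-correlation* (H5–H7): correlation of metric series with
  factors lagged 1–15 days, calibrated against Fourier phase-randomized
  surrogates of the factor (amplitude spectrum, hence autocovariance,
  preserved exactly).
- *Inter-day RSA* (H4): day × day ROI time-course correlation matrices
  (single-subject ISC) compared with nearest-neighbors or Anna-Karenina
  behavioral similarity via a Mantel test on rank-correlated upper
  triangles.
- *Time-segment identification* (H8): 25-TR sliding windows (14.85 s at
  TR 0.594 s; a 970-volume run gives 946 segments, chance 1/946),
  leave-one-session-out correlation matching, and permutation regression of
  the accuracy maps on daily factors.

## Worked example

Simulate a 30-session study in which the previous night's sleep drives two
default-mode links, then recover the injected effect:

```r
library(denseFC)

atlas <- genAtlas(nRois = 20, nNetworks = 4, seed = 1)
cfg   <- synthConfig(nSessions = 30, nDays = 133, nRois = 20,
                     nNetworks = 4, nTime = 800, missingFraction = 0)
dmn   <- which(atlas$network == "DMN")
spec  <- effectSpec(rbind(c(dmn[1], dmn[2]), c(dmn[2], dmn[3])),
                    "total_sleep", lagDays = 1, slope = 0.4,
                    baseCorr = 0.2)
beh <- genBehavior(cfg, seed = 2)
gen <- genSessions(cfg, atlas, beh$truth, list(spec), seed = 3)
gen$sessions[[1]]
#> SessionSeries: 800 volumes x 20 ROIs, TR 0.594 s, task 'rest', day 16

stack <- lapply(gen$sessions, pearsonAdjacency)
mstThreshold(stack[[1]], density = 0.10)
#> BinaryGraph: 20 nodes, 19 edges (density 0.100, requested 0.100)

res <- modelLinks(stack, beh$truth, "total_sleep", atlas,
                  networks = c("DMN", "FPN"), nPerm = 1000, seed = 4)
head(res[order(res$q), ], 3)
#>    i  j   predictor  beta     t        p      q
#> 2  1  5 total_sleep 0.991 38.80 0.000999 0.0225
#> 19 5  9 total_sleep 0.992 41.58 0.000999 0.0225
#> 32 9 13 total_sleep 0.500  3.05 0.005994 0.0899
```

The two injected links (ROIs 1–5 and 5–9, both in the DMN) surface with the
smallest attainable permutation p (1/1001) and survive FDR across the 45
candidate links; their standardized β ≈ 0.99 reflects the near-noiseless
800-volume sessions. At 19 edges, the 10%-density graph of 20 nodes is
exactly its maximum spanning tree.

`runPipeline(runConfig(...))` chains all stages — simulation, cleaning,
shared scrubbing mask, adjacency, metrics, and the analyses of any subset of
the H1–H8 presets (`hypothesisPreset("H1")` lists each one's task, factors
and networks) — and writes TSV tables plus a `manifest.json` that
reproduces the run byte-for-byte under the same seed.

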