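---
title: "Methods: resting-state fNIRS small-world network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state fNIRS small-world network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis chain

`neglectnet` implements a complete resting-state functional near-infrared
spectroscopy (fNIRS) network analysis for two-group clinical contrasts, of
the kind used to study right-hemisphere cortical reorganisation in
post-stroke unilateral spatial neglect:

1. **Hemodynamic conversion.** Dual-wavelength optical-density changes
   (695/830 nm) are converted to oxy- and deoxyhemoglobin concentration
   changes with the modified Beer–Lambert law, solving per sample and
   channel the 2×2 linear system
   ΔOD_λ = (α_Hb,λ Δ[Hb] + α_HbO₂,λ Δ[HbO₂]) · DPF_λ · d.
   Only Δ[HbO₂] is analysed downstream (higher signal-to-noise); Δ[Hb] is
   computed and carried along.
2. **Preprocessing.** Common average referencing (CAR) subtracts the
   across-channel mean at every sample, removing channel-common
   superficial interference; a zero-phase 3rd-order Butterworth band-pass
   (0.01–0.1 Hz, applied forward–backward) isolates spontaneous
   fluctuations; the first and last 3 s are trimmed and a stable 3-min
   analysis window is selected.
3. **Connectivity.** Pearson correlations between all channel pairs (22
   channels → 231 pairs), Fisher r-to-z, then proportional binarization:
   at threshold θ the strongest `round((1 − θ) · 231)` absolute z-values
   become edges, so every subject's network has identical density at a
   given θ ("compared under the same connection"). The threshold range is
   0.30–0.80 in steps of 0.01 (51 levels).
4. **Graph metrics.** Per binary network: clustering coefficient C,
   characteristic path length L, global efficiency GE, local efficiency
   LE, and the normalized ratios γ = C/C_rand, λ = L/L_rand,
   σ = γ/λ, with C_rand and L_rand averaged over 100 degree-preserving
   (double-edge-swap) random reference networks. σ > 1 indicates
   small-world organisation.
5. **Statistics.** Metric-versus-threshold curves are compared between
   groups with two-sample t-tests at every threshold, FDR-corrected
   (Benjamini–Hochberg) within each metric's threshold family; each curve
   is also summarised by its trapezoidal area over θ ∈ [0.3, 0.8]
   (threshold-AUC), and AUC features with raw p < 0.05 become classifier
   features.
6. **Classification.** A linear SVM (cost C = 3) under leave-one-out
   cross-validation, features standardized by training-fold statistics
   only; performance is reported as sensitivity, specificity, accuracy and
   the ROC area over pooled out-of-fold decision scores.

## The synthetic cohort generator

Because no patient recordings are distributed, the package ships a seeded
generator whose defaults emulate the study conditions: 21 "A" subjects and
12 "B" subjects, 22 channels (the 3×5 alternating source–detector grid: 8
sources, 7 detectors, 22 nearest-neighbour pairs at 3 cm), 10 Hz sampling,
6-min recordings.

**Ground-truth topology.** Each subject's truth network is a ring lattice
(degree k = 4) with Watts–Strogatz rewiring, rewiring probability
p = 0.1 for group A (lattice-like: high clustering, long paths) and
p = 0.3 for group B (random-like: high global efficiency). Rewiring
preserves the edge count (44) and draws are redone until connected.

**Covariance model.** The truth adjacency A is mapped to a correlation
model with a random-walk (resolvent) kernel,
Σ₀ ∝ (I − αA)⁻¹ rescaled to unit diagonal, α = coupling/λ_max(A).
The kernel yields graded correlations that decay with topological
distance, the way functional coupling spreads over a connectome, and is
positive-definite for every coupling in (0, 1). An earlier linear variant
(Σ = I + wA) was abandoned: it ties all non-adjacent pairs at exactly
zero, so after CAR their ranking is governed entirely by a
degree-dependent offset and the absolute-value ranking promotes spurious
edges between high-degree pairs — the recovered clustering contrast then
*inverts*. The default coupling 0.9 was chosen for ranking fidelity: about
91% of the top-44 model-ranked pairs are true edges, with mean adjacent
correlation ≈ 0.43 versus ≈ 0.17 for non-adjacent pairs. An optional
`base` term mixes in a channel-common correlation floor
(Σ = (1 − b)Σ₀ + bJ) representing systemic physiology; it is what the
calibration to a target mean functional connectivity adjusts.

**Signal synthesis.** Latent Δ[HbO₂] series are band-limited
(0.01–0.1 Hz) Gaussian draws mixed by the Cholesky factor of Σ. The
band-limiting is done by frequency-domain shaping with the squared
Butterworth magnitude (the zero-phase response), and the draws are
empirically whitened before mixing so the realized full-series covariance
equals the model exactly — narrowband draws otherwise carry sampling
cross-correlations of order 1/√n_eff that a near-critical kernel amplifies
into appreciable correlation errors. Δ[Hb] is an anticorrelated mixture
(−0.5 · Δ[HbO₂] plus independent band-limited noise). Nuisance terms are
then added: one channel-common slow interference series (sd 1.0, in latent
sd units), per-channel linear drift (slope sd 0.005 /s), sinusoids at
cardiac (1.1 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz)
frequencies with channel-specific phases (amplitude 0.5), and white sensor
noise (sd 0.3). Interference on the signal's own scale and oscillations at
half that scale make preprocessing consequential without making recovery
impossible. Finally the series are pushed through the forward Beer–Lambert
model to optical density. Per-subject seeds derive from the master seed
(`seed + i` for noise, `seed + 10000 + i` for the topology of subject
`i`), so a specification reproduces its cohort bit for bit.

**What the generator does not emulate.** Channel-specific optode coupling
gains (all channels share one amplitude scale), hemodynamic
response-function structure, motion-artifact spikes, photon-transport
physics, and any spatial embedding of the probe beyond the channel count.
Consequences of the first omission are discussed below.

## Numerical and procedural choices

- **Extinction coefficients.** Not fixed by the emulated acquisition
  description; defaults are standard tabulated values at 695/830 nm in
  1/(mM·cm) (Hb 1.85/0.693, HbO₂ 0.30/0.974), DPF 6 at both wavelengths,
  d = 3 cm. Generator and inverter share one configuration, and all
  downstream statistics are correlations, hence invariant to the table.
- **Filter.** 3rd-order Butterworth, forward–backward (`filtfilt`) for
  zero phase — correlations are phase-sensitive. Odd-reflection padding
  (1.5 periods of the low edge) suppresses edge transients.
- **Window selection.** "Relatively stable" segment selection is
  operationalised as the 1-s-stride contiguous window minimising summed
  across-channel variance; `fixed_start` is available for strict
  reproducibility, and a user-supplied sample-exclusion mask (the stand-in
  for manual artifact rejection) disqualifies overlapping windows.
- **Binarization conventions.** The worked rule "threshold 0.6 keeps the
  top 40%" fixes retained fraction = 1 − θ (the default); the alternative
  `theta` convention is a flag. Edge counts round half away from zero;
  ties in |z| break by stable row-major pair order, so output is
  deterministic. Because a single ranking generates the whole stack, edge
  sets are nested across thresholds.
- **Degenerate graphs.** C_i = 0 for nodes of degree < 2; GE of a
  neighbour subgraph with < 2 nodes is 0. For fragmenting sparse networks
  the path length excludes disconnected pairs by default
  (`policy = "exclude"`); `"substitute"` scores them with pseudo-distance
  N. Local efficiency defaults to the 1/N mean (`standard`); a `printed`
  option reproduces a 1/(N(N−1)) prefactor variant found in print.
- **Null networks.** Maslov–Sneppen double-edge swaps, 10× edge count
  attempts, preserving the degree sequence exactly; complete/empty graphs
  are their own reference (σ ≡ 1, flagged). Replicate r at threshold
  index t uses seed `master + t`, replicates consuming the stream
  sequentially — reproducible level by level.
- **Statistics.** The pooled-variance Student test is the default (the
  classical two-independent-sample test), Welch by flag; FDR families are
  per-metric across thresholds (the tests sharing one curve panel) with a
  global-family flag. Degenerate thresholds where a metric is constant in
  both groups (at high densities L and GE are functions of the fixed edge
  count alone) yield t = NaN and are never significant. AUC-feature
  selection uses raw p < 0.05, the literal selection rule; `select_on =
  "fdr"` tightens it.
- **Classifier.** Positive class = group A (the patient-like group).
  Standardization parameters and any grid search live strictly inside each
  training fold; the per-fold parameters are exposed so leakage can be
  audited. The default skips the grid and uses the reported optimum
  (linear kernel, C = 3).

## What validation shows — and what it cannot

The test suite validates every metric against exhaustive brute-force
oracles (Floyd–Warshall distances, explicit neighbour-pair counts) on
hundreds of small random graphs, the Beer–Lambert inversion as an exact
round trip, ROC-AUC against the normalized Mann–Whitney U, and FDR against
a hand-written step-up. End-to-end, synthetic cohorts at the study scale
show: small-world organisation (both groups' mean σ > 1 at threshold 0.5,
100 random references), calibrated type-I error of the threshold-wise
tests under label permutation, and robust directional recovery of the
clustering and local-efficiency contrast (higher in the lattice-like
group).

Three structural findings deserve emphasis, because they mark limits of
what any pipeline of this design can recover:

- **CAR pins the grand mean of connectivity.** After subtracting the
  across-channel mean, every sample's channel sum is zero, so the sample
  covariance rows sum to zero and the sum of off-diagonal covariances
  equals minus the sum of variances. With homogeneous channel variances
  the post-CAR mean off-diagonal correlation is forced to about −1/(n−1),
  *regardless* of the model's true mean connectivity: the common mode that
  carries a high mean lies in the ones-direction, which CAR annihilates
  exactly. A generator calibrated to a mean functional connectivity of
  0.745 therefore comes back from the full preprocessing chain near
  −0.04 — the corresponding round-trip check fails by design of the
  chain, not by implementation error. High post-CAR mean connectivity in
  real recordings is only possible with strong channel-variance
  heterogeneity (CAR then re-injects dominant channels into all others);
  the generator deliberately does not model such heterogeneity, and
  tuning it until the round trip closes would make the check circular.
- **Absolute-value ranking interacts with CAR on path-length metrics.**
  CAR shifts pair correlations by a term involving the channels' mean
  correlation levels; for ring-like networks the topologically most
  distant pairs become the most *negative*, and the absolute-value
  ranking then readmits them as edges. These antipodal shortcuts shorten
  paths specifically in the lattice-like group, so the recovered L and GE
  group differences at mid thresholds run opposite to the truth-level
  contrast. Clustering and local efficiency, which are driven by local
  neighbourhoods, recover correctly.
- **σ ordering of Watts–Strogatz groups.** At the truth level, a p = 0.1
  graph is *more* small-world than a p = 0.3 graph (that is the
  small-world regime), so under this generator the lattice-like group's σ
  cannot come out lower. An empirical pattern of higher C and L together
  with *lower* σ in one group implies that group's networks trade off γ
  and λ differently than Watts–Strogatz graphs do; reproducing that
  pattern would require a different ground-truth family.

Passing tests on synthetic cohorts show the machinery is correct and the
recoverable contrasts are recovered; they do not show that real fNIRS
recordings satisfy the generator's assumptions (stationary Gaussian
band-limited signals, perfectly common interference, homogeneous channel
gains).

## Problem sizes

Validation runs at the emulated study scale where it matters (33 subjects,
22 channels, 6-min recordings, 51 thresholds, 100 random references for
the headline small-world check) and at reduced scale elsewhere (12-channel
7-subject cohorts for pipeline plumbing, 12–15 random references per
threshold in multi-cohort batteries, σ evaluated at the three mid
thresholds 0.50/0.55/0.60 in the 20-cohort directional battery, and the
20-cohort classifier check built on the four deterministic metric AUCs).
These sizes are stated in the tests themselves.

## File formats

Cohorts are written and read as plain CSV: per-subject optical density
with wavelength-suffixed channel columns (`ch01_w695`, `ch01_w830`, …), a
`manifest.csv` with subject ids, group labels and sampling rates, and
per-subject truth edge lists. Configurations serialize to YAML; reports
and feature selections to JSON. HDF5-based containers are not supported.
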