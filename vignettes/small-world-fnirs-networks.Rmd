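---
title: "Methods: small-world network analysis of fNIRS connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-world network analysis of fNIRS connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsnet)
```

## The analysis model

`nirsnet` treats a multichannel fNIRS recording as a weighted functional
network: each source–detector channel is a node, and the edge weight between
two nodes is the Pearson correlation of their oxyhemoglobin (HbO2) time
courses. The analysis asks two questions: does the network have small-world
topology (more clustered than random, yet with near-random path lengths),
and do two behavioral conditions differ in their network indices?

The processing chain per subject and condition is:

1. **Band-pass filter** the continuous HbO2 traces to 0.01–0.3 Hz. This
   removes slow drift below 0.01 Hz and respiratory/cardiac oscillations
   above 0.3 Hz while keeping the hemodynamic response band.
2. **Segment** the recording into 13-s epochs around each trial marker of
   the requested case: 2 s of pre-stimulus baseline and 11 s of
   post-stimulus response and recovery.
3. **Normalize** each epoch per channel: subtract the pre-stimulus mean
   and scale to unit pre-stimulus standard deviation. The trial mean of the
   normalized epochs is the run average.
4. **Correlate**: the Pearson correlation between every channel pair over
   the concatenated normalized epochs of the case gives a symmetric
   24 × 24 matrix with unit diagonal.
5. **Binarize** at a threshold $T$: the adjacency is
   $a_{ij} = 1 \iff i \neq j \text{ and } |r_{ij}| \ge T$. The absolute
   value means strong negative couplings also count as edges; the boundary
   $|r| = T$ is included.
6. **Characterize** the binary network:
   - clustering coefficient $C = \frac{1}{N}\sum_i C_i$ with
     $C_i = E_i / \binom{k_i}{2}$, where $k_i$ is the degree of node $i$
     and $E_i$ the number of edges among its neighbors ($C_i = 0$ when
     $k_i < 2$, where the ratio is undefined);
   - average path length $L$, the mean breadth-first-search geodesic over
     unordered node pairs;
   - average degree $K = 2E/N$.
7. **Reference ensemble**: 100 degree-preserving randomizations of the
   network via the Markov-chain double-edge-swap algorithm. Their mean
   clustering $C_{rand}$ and mean path length $L_{rand}$ define the
   small-worldness measure
   $$\sigma = \frac{C / C_{rand}}{L / L_{rand}},$$
   with $\sigma > 1$ read as small-world organization.
8. **Threshold sweep and group statistics**: steps 5–7 are repeated on an
   inclusive grid of thresholds (default $0.275, 0.300, \ldots, 0.625$;
   15 values) for every subject; per threshold and metric the two groups
   are compared with a two-sample t-test.

The grid end points are not arbitrary: `check_bounds()` reports the
smallest grid value at which a correlation of that magnitude is
individually significant (two-sided test of $\rho = 0$ via
$t = r\sqrt{(n-2)/(1-r^2)}$) and the largest value at which every subject
network keeps mean degree at least $\ln N$, the usual connectivity
heuristic. Both are diagnostics, never silently enforced.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `low`, `high` (filter band) | 0.01, 0.3 | Hz | standard fNIRS hemodynamic band |
| filter `order` | 4 | — | 4th-order Butterworth band-pass, zero-phase via forward–backward application |
| `pre_s`, `post_s` (epoch) | 2, 11 | s | 13-s trial runs |
| threshold grid | 0.275–0.625 by 0.025 | — | spans edge-significance to connectivity bounds |
| `null_n` | 100 | networks | reference ensemble size |
| `swap_factor` | 10 | attempts / edge | conventional mixing heuristic for the double-edge-swap chain |
| t-test | Welch | — | robust to unequal variances; nearly identical to pooled at equal n |

## Numerical and design choices

- **Filter realization.** `signal::butter(order/2, c(low, high)/(fs/2),
  "pass")` gives a band-pass whose polynomial order equals `order`;
  `signal::filtfilt` applies it forward and backward, squaring the
  magnitude response and canceling the phase so epoch timing is preserved.
  The implementation exposes the analytic frequency response for
  verification; the test suite checks DC attenuation > 99%, 0.1-Hz passband
  gain within [0.9, 1.1] and 1-Hz attenuation > 90%, both analytically and
  on filtered sinusoids.
- **Normalization fallback.** A channel whose pre-stimulus SD is zero
  (e.g., a constant signal) is baseline-subtracted but not scaled, avoiding
  division by zero. A channel with zero variance overall receives
  correlation 0 (with a warning), not `NaN`.
- **Which series enters the correlation.** The Pearson matrix is computed
  on the per-trial normalized epochs concatenated within a case (default)
  or on the run average (`series = "averaged"`). Concatenation is the
  default because it uses every retained sample (10 trials × 130 samples)
  rather than 130 averaged ones, making the per-subject correlation
  estimates far less noisy; both options are exposed since the choice is a
  genuine methodological fork.
- **Disconnected networks.** At high thresholds individual networks can
  fragment. $L$ is then the mean over *reachable* pairs only, a
  `connected` flag is recorded per network, and the sweep reports
  per-threshold disconnection counts for both groups. This avoids
  infinities while flagging the regime that the connectivity bound of the
  sweep protocol is designed to exclude; group comparisons of $L$ at
  thresholds where most networks are fragmented should be read with the
  disconnection counts in hand.
- **Null-model chain.** Each ensemble member is an independent chain of
  $\lceil 10 E \rceil$ attempted double-edge swaps starting from the
  source network. An attempt draws two edges $(a,b), (c,d)$ and proposes
  $(a,d), (c,b)$; proposals creating self-loops or duplicate edges are
  rejected *but still count toward the attempt budget*, so the chain
  consumes a fixed number of RNG draws and any run is bit-reproducible
  given the seed. Degree sequences are conserved exactly — this is tested
  for every run, not just on average. Ensemble members draw from one
  seeded RNG stream rather than per-member sub-seeds; the members remain
  independent and the whole ensemble is reproducible from the single seed.
- **Small-worldness edge cases.** $\sigma$ requires $C_{rand} > 0$ and
  positive path lengths; for very sparse networks (fewer than 2 edges, or
  a triangle-free reference ensemble) it is reported as `NA` in the sweep
  and an error in direct calls, with a diagnostic pointing at sparsity.
- **Seed discipline.** Cohort generation derives one seed per (subject,
  group) from the master seed by a fixed mixing rule, so any recording can
  be regenerated in isolation. `subject_metrics()` runs under a single
  local seed (`withr::with_seed`), leaving the caller's RNG state intact.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of a block-design deception study:
24 subjects per condition, 24 channels at 10 Hz, ten trials for each of the
three case labels (win-win, lose-win, lose-lose), 13-s epochs, and HbO2
amplitudes on the order of 0.05 mM·mm. Channel signals are built from:

- **Structured background**: smooth Gaussian latent sources at every
  channel site, mixed with loadings that decay exponentially with
  inter-optode distance (length scale `spatial_decay`, default 3 grid
  units) across two bilateral 4 × 3 patches separated by `patch_gap`.
  After row normalization, the structured signals have unit variance and a
  smooth spatial correlation profile. The group coupling (default 0.97
  spontaneous, 0.90 control) sets the share of each channel's standard
  deviation carried by this shared background — the generative encoding of
  "one condition's networks are denser and more strongly correlated".
  A per-channel, per-subject loading jitter (±12%) creates the
  heterogeneity that makes the threshold sweep informative: pair
  correlations span the whole grid rather than clustering at one value.
- **Evoked responses**: a double-gamma HRF (peak 5 s, undershoot near
  15 s, unit peak) convolved with the trial onsets, at amplitude 0.2
  relative to the background.
- **Physiological oscillations**: sinusoids at 0.1 Hz (Mayer), 0.3 Hz
  (respiration) and 1 Hz (cardiac) with channel-specific phases, plus
  white measurement noise.

The defaults were calibrated once, at design time, so that the subject-level
correlation distributions of both groups span the threshold grid and the
pipeline recovers the intended qualitative contrast (higher $C$ and $K$,
lower $L$ for the stronger-coupled group; $\sigma > 1$ for both) — this is
what makes the generator a usable end-to-end test harness, and it is the
stated design goal of the module, not an empirical discovery.

The generator does **not** emulate: raw optical intensities or the
Beer–Lambert conversion (signals are generated directly as HbO2), motion
artifacts, deoxyhemoglobin channels, systemic confounds with genuine
spatial covariance (the oscillation phases are independent across
channels), subject-specific anatomy or probe registration, or any actual
neuro-cognitive difference between deception conditions. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* recovers known
generative structure — not that any particular empirical claim about
deception holds in real data.

## Statistical choices

- **Welch vs pooled vs paired.** The default two-sample test is Welch's;
  `var_equal = TRUE` gives the pooled-variance test and `paired = TRUE` a
  paired test for within-subject designs. With equal group sizes the Welch
  and pooled statistics are numerically identical; the choice matters only
  under variance heterogeneity.
- **No multiple-testing correction by default.** Significance is flagged
  per threshold at $\alpha = 0.05$, matching the per-threshold convention
  of sweep curves; `fdr = TRUE` adds Benjamini–Hochberg adjusted p values
  across the 15 thresholds per metric for users who prefer controlled
  error rates.
- **Raw vs Fisher-z averaging.** Group-average correlation matrices use
  the arithmetic mean of coefficients by default, with
  `fisher_z = TRUE` available; the difference is small at these
  correlation magnitudes but the z-average is less biased near ±1.

## Problem sizes in the test suite

The packaged tests exercise the full study geometry where it matters and
scaled-down versions elsewhere: metric correctness is checked exactly
against exhaustive oracles on 200 random graphs of up to 15 nodes;
degree-sequence conservation on 100 random graphs; null self-consistency
($\sigma \approx 1$ for Erdős–Rényi graphs) and small-world detection
(24-node rewired ring lattices) over 20 seeds with 100-network ensembles;
and the end-to-end group-difference recovery on a full 24 + 24 subject
cohort with 100-network ensembles at all 15 thresholds. Unit tests use
2-subject cohorts with 3 trials per case.

## Known limitations

- Reachable-pair $L$ makes path lengths of heavily fragmented networks
  systematically short; comparisons in that regime are flagged, not
  prevented.
- The double-edge-swap chain with 10·E attempts is a mixing heuristic, not
  a guarantee of uniform sampling from the degree-sequence ensemble;
  extremely constrained degree sequences (e.g., near-complete graphs) mix
  slowly, though they are also nearly unique so the bias is immaterial.
- The synthetic generator's correlation structure is stationary within a
  recording; real fNIRS connectivity is not.
- Binarization discards edge-weight information by design; weighted-network
  generalizations are out of scope.
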