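---
title: "Graph-closeness intersubject similarity for naturalistic fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-closeness intersubject similarity for naturalistic fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsgraph)
```

## The problem

Multichannel fNIRS recorded under naturalistic stimulation — children
watching a movie, free conversation — has no block or event structure, so
there is no design matrix for a general linear model, and a channel-by-frame
mass-univariate search (20 channels × 2100 frames ≈ 42,000 tests) has no
power left after multiplicity control. The question this package answers is
different and global: *does the stimulus drive participants into similar
cortical states at at least some moments*, and if so, *when* and *where*?

## The statistic

Let $x_p(t) \in \mathbb{R}^C$ be participant $p$'s hemodynamic state at
frame $t$: the vector of the $C$ long-channel values after preprocessing.
For each frame:

1. **Distance matrix.** $d_{ij}(t) = \lVert x_i(t) - x_j(t) \rVert_2$ for
   all participant pairs.
2. **Graph.** The matrix is read as the adjacency of a complete undirected
   weighted graph with one node per participant; weights are edge
   *lengths* (a larger distance means farther apart), not connection
   strengths.
3. **Closeness.** Node closeness is the Freeman-normalised form
   $c_i(t) = (N-1) / \sum_{j} \delta_{ij}(t)$, with $\delta_{ij}$ the
   shortest-path distance. Because Euclidean distances satisfy the triangle
   inequality, the direct edge is always the shortest path, so
   $\delta_{ij} = d_{ij}$ and closeness reduces to a row-sum reciprocal;
   the test suite verifies this identity against an explicit
   Dijkstra-based oracle. The per-frame score is
   $\bar c(t) = \tfrac1N \sum_i c_i(t)$.
4. **Test statistic.** $S = \tfrac1T \sum_t \bar c(t)$, the mean closeness
   across all frames. One number per dataset, one hypothesis test, no
   multiplicity problem.

The $(N-1)$ normalisation is a package choice — the underlying method
literature cites closeness without committing to a constant. Any constant
factor cancels in the permutation test, so the choice is
inference-neutral; normalising makes values comparable across group sizes.

## Inference: circular permutation

Under the null hypothesis that hemodynamic dynamics are unrelated to the
(shared) stimulus, each participant's series can be rotated in time without
changing its distribution: a circular shift preserves the participant's
autocorrelation and within-participant cross-channel correlation *exactly*
(all channels shift together), while destroying alignment across
participants. The null sample is built from $B$ permutations (default
1000); in each, every participant independently receives a uniform random
offset from $\{1, \dots, T-1\}$. Offset 0 is excluded so that every
permuted dataset differs from the observed one; whether one participant
should be held fixed is not determined by the method description, and
independent offsets for all participants were adopted. The p-value is the
add-one Monte-Carlo form

$$p = \frac{1 + \#\{S_b^\ast \ge S\}}{B + 1},$$

one-sided, because intersubject similarity is *high* closeness. Its
minimum attainable value is $1/(B+1)$ — with $B = 1000$, $p = 1/1001
\approx 0.001$, the granularity at which a fully separated observed
statistic is reported. The observed dataset is not included in the null
sample; it contributes the $+1$. All offsets are drawn from a single
seeded generator in permutation-major, participant-minor order, so runs
are reproducible bit for bit; the seed argument is mandatory.

## Post-hoc mapping (descriptive, not inferential)

Run only after the global test rejects, and deliberately free of
per-frame or per-channel p-values:

* **Top frames.** The $k = \lceil(1-q)T\rceil$ frames with the highest
  closeness, default $q = 0.95$ (top 5%). Count-based top-$k$ with
  earliest-frame tie-breaks was chosen over a value-above-quantile rule;
  the two differ only at ties, and top-$k$ is deterministic. A small
  epsilon guards the $\lceil\cdot\rceil$ against floating-point artifacts
  (e.g. $(1-0.95) \cdot 100 = 5.0000\ldots4$).
* **Timestamps.** The vascular response lags neural activity; frame $t$ is
  mapped back to stimulus time $t_0 + t/f_s - \Delta$ with
  $\Delta = 5$ s by default, clipped at zero, and rendered `MM:SS` for
  matching against the stimulus timeline.
* **Channel relevance.** For each channel, the closeness series is
  recomputed with that channel removed (leave one channel out). Per frame,
  channels are ranked by the *drop* (full minus leave-one-out closeness);
  the top $\lceil 0.25\,C\rceil$ are marked relevant, and a channel's
  relevance frequency is the fraction of frames in which it is marked.
  Ranking by drop is provably identical to ranking by ascending
  leave-one-out closeness (the full-series term is constant within a
  frame); the implementation is tested for exact agreement between both
  routes, and frequencies conserve their sum
  ($\sum_c f_c = \lceil 0.25\,C \rceil$) by construction. The per-frame
  percentile conversion in the method description is read as ranking
  across channels within a frame — the only reading under which "frequency
  of being in the top 25% set" is well defined per channel. Only the
  descriptive steps are recomputed per channel; running a fresh
  permutation test per left-out channel would reintroduce exactly the
  multiplicity the method exists to avoid.

Both thresholds (5% frames, 25% channels) are acknowledged as arbitrary
descriptive conventions and are exposed as parameters.

## Preprocessing chain

Stage order follows the conditioning chain the analysis was designed
around: optical density → modified Beer–Lambert → z-transform → wavelet
despiking → band-pass → short-channel regression → variance-one rescale.
Each stage preserves series length, and the final per-channel variance is
exactly 1 — required so that no participant or channel dominates the
between-participant distances.

* **Optical density**: $-\log_{10}(I(t)/\bar I)$ per channel; requires
  strictly positive intensities.
* **Modified Beer–Lambert**: per frame, the two-wavelength system
  $\Delta OD_\lambda = L\, \mathrm{DPF}_\lambda (\varepsilon_{\lambda,HbO}
  \Delta HbO + \varepsilon_{\lambda,HbR} \Delta HbR)$ is solved by 2×2
  inversion. Packaged defaults (DPF 6.0; extinction coefficients in
  mM⁻¹cm⁻¹ at 760/850 nm) are standard tabulated values and are explicitly
  replaceable; because every channel is later rescaled to unit variance,
  downstream results depend on them only through a near-linear rescaling.
* **Wavelet despiking**: periodized orthogonal Daubechies-4 DWT (8-tap,
  4 vanishing moments), depth $\lfloor \log_2 T\rfloor - 2$. Detail
  coefficients in the finest `spike_levels = 2` levels whose magnitude
  exceeds $\lambda\,\hat\sigma\sqrt{2\ln T}$ — $\hat\sigma$ the MAD-based
  scale of the finest level, $\lambda = 0.1$ — are clipped to the
  threshold. Restricting the rule to fine scales is the package's
  resolution of an internal tension in the method description: applied to
  *all* levels, a threshold of $0.1\,\hat\sigma\sqrt{2\ln T}$ flattens the
  coarse-scale coefficients that carry any smooth physiological signal
  (a noiseless 0.04 Hz sinusoid would lose most of its RMS), which
  contradicts the explicit intent of removing *only spikes*. Motion
  artifacts are fast, high-amplitude excursions whose energy concentrates
  at fine scales (above ~1 Hz at 7.81 Hz sampling), far from the
  0.01–0.08 Hz band of interest; clipping only there removes them while
  leaving smooth signal essentially untouched. The 8-tap wavelet was
  chosen over the 4-tap variant (both are called "Daubechies-4" in
  different conventions) because its high-pass response decays like
  $\omega^4$ at low frequency, so clipping distortion leaks an order of
  magnitude less into the hemodynamic band.
* **Band-pass**: order-3 Butterworth, 0.01–0.08 Hz, realised as
  second-order sections (numerically essential for so narrow a band at
  7.81 Hz sampling) and applied forward–backward for zero phase, with
  steady-state initial conditions so a constant input maps exactly to
  zero. Verified against analytic gain expectations in the tests.
* **Short-channel regression**: each long channel is regressed (OLS, with
  intercept) on *all* short channels, keeping residuals; nearest-short
  pairing is deliberately not the default, as the method description
  refers to the short-channel signals collectively. Rank-deficient
  regressor sets fall back to the pivoted least-squares solution with a
  warning.
* **Unequal recording lengths** are truncated to the common minimum; the
  analysis requires frame-aligned matrices.
* Only oxyhemoglobin is analysed by default (`chromophore = "HbO"`);
  deoxyhemoglobin is available as a pass-through option but is not part of
  the analysis path.

## The synthetic world

`simulate_group()` emulates the statistical structure the test assumes:

* **Noise**: per participant, AR(1) in time (coefficient $\phi = 0.95$ at
  the sample level) with equicorrelated innovations across channels
  ($\rho = 0.3$), unit stationary variance. This is the *minimal* model
  exhibiting exactly the two properties circular permutation preserves.
  Defaults (19 participants, 20 long + 8 short channels, 7.81 Hz, 2100
  frames) mirror a typical pediatric prefrontal montage.
* **Response**: a boxcar at the configured event onsets convolved with a
  canonical double-gamma HRF (peak ≈ 5 s, undershoot ≈ 15 s, peak
  normalised to 1), scaled by $\beta(1 + 0.1 z_p)$ per participant —
  shared but not identical, as in real groups.
* **Variability quenching** — the load-bearing modelling decision. A
  purely additive common signal cannot create momentary intersubject
  similarity: Euclidean distances are invariant under adding the same
  vector to every participant's state, and with per-participant gain
  jitter an additive response makes response frames strictly *less*
  similar. Moments of similarity require the idiosyncratic
  between-participant spread itself to shrink. The generator therefore
  damps the noise in responsive channels by
  $1/\sqrt{1 + (\beta s(t))^2}$ while the shared component enters
  additively — stimulus-evoked suppression of idiosyncratic variability,
  a well-documented cortical phenomenon. With $\beta = 0$ the model
  reduces exactly to the pure null. Under this world the permutation test
  is calibrated (it is calibrated under the additive world too), and the
  post-hoc frame/channel recovery targets are attainable; under a purely
  additive world they are mathematically not.
* **Ground truth**: response frames are defined as those where the
  noiseless convolved response is at least half its peak — unambiguous
  and implementation-checkable.
* **Confounds**: an optional per-participant superficial AR(1) signal
  (coefficient 0.98, so most of its power survives the band-pass) is
  added to every long channel and emitted as the short channels, which
  carry it plus small sensor noise.
* `simulate_raw()` pushes the same dynamics through the *forward*
  Beer–Lambert model around a unit baseline (1 µM per noise-SD,
  $\Delta HbR = -0.25\,\Delta HbO$) to produce strictly positive
  dual-wavelength intensities for end-to-end pipeline testing.

What the generator does **not** emulate: 1/f background, cardiac
(~1 Hz) and respiratory peaks, Mayer waves, optode-coupling drift,
realistic motion-artifact morphology, or photon-transport geometry. A
green test therefore establishes that the statistics behave as designed
under the stated correlation structure — not that the pipeline is robust
to every artifact class of real recordings.

## Numerical choices and degenerate inputs

* Frames where some participants coincide exactly (a node at distance zero
  from all others) raise an error naming the frame rather than returning
  infinite closeness; silent infinities would poison the mean statistic,
  and noisy data never hit this.
* Frames are 0-based internally; user-facing timestamps convert via `fs`
  and `t0`.
* Ties in top-frame and channel rankings break toward the earlier frame /
  earlier channel: deterministic and reproducible.
* The permutation engine restores the caller's RNG state on exit; package
  randomness never leaks into, or depends on, the global stream.
* Text serialisation uses 17 significant digits, so write → read
  round-trips are lossless and equal-seed runs are byte-identical.

## Limitations

* The statistic is global: a significant result says similarity exists at
  *some* moments; the frame and channel maps are descriptive follow-ups,
  not localised inference.
* Circular shifting assumes approximate stationarity within a recording;
  strong slow nonstationarities shared across participants (e.g. group
  fatigue) can inflate similarity for reasons unrelated to the stimulus.
* Anatomical interpretation of channel relevance requires a registration
  step outside this package's scope.
* SNIRF support covers continuous-wave amplitude recordings with indexed
  measurement lists; other SNIRF data types are rejected with a clear
  error rather than guessed at.
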