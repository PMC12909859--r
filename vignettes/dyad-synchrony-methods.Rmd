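---
title: "Measuring mother-infant brain-to-brain synchrony with dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mother-infant brain-to-brain synchrony with dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

When a caregiver and an infant interact, their electroencephalograms show
weak but measurable phase coupling — *inter-brain synchrony*. dyadsync
implements a complete analysis chain for two-person ("hyperscanning") EEG
recorded during a five-phase smartphone-adapted Still-Face Paradigm (SFP):
two minutes of free play (FP1), a still-face phase in which the caregiver
disengages into a smartphone (SF1), a second free play (FP2), a second
still-face (SF2), and a reunion (RU). The scientific question the chain
answers is whether cross-brain synchrony drops while the caregiver is
absorbed by the phone and recovers on reunion.

Because raw dual-EEG of this kind is rarely shareable, the package also
contains a first-class synthetic dyad generator with known ground-truth
coupling, so that every stage — filtering, epoching, artifact screening,
connectivity, surrogate validation, statistics, topography — can be tested
end to end against construction.

## The synchrony measure

For a mother channel $j$ and an infant channel $k$, both restricted to a
fixed 12-channel montage (F3, F4, F7, F8, C3, C4, T7, T8, P3, P4, P7, P8),
signals are band-passed into infant theta (3–5 Hz) or infant alpha (6–9 Hz),
and instantaneous phases $\varphi(t)$ are taken from the analytic (Hilbert)
signal. With $\Delta\varphi_i = \varphi^{M}_j(t_i) - \varphi^{I}_k(t_i)$
over the $N$ samples of one 2-s hyper-epoch, the weighted Phase Lag Index is

$$
\mathrm{wPLI} \;=\;
\frac{\bigl|\tfrac1N\sum_{i=1}^{N} |\sin\Delta\varphi_i|\,
      \operatorname{sign}(\sin\Delta\varphi_i)\bigr|}
     {\tfrac1N\sum_{i=1}^{N} |\sin\Delta\varphi_i|},
$$

the magnitude of the signed mean of $\sin\Delta\varphi$ normalized by its
mean magnitude. It is 1 when one brain consistently leads or lags the other
and 0 when leads and lags balance. Two conventions are deliberate:

* **Outer absolute value.** The bare ratio is signed in $[-1, 1]$; we take
  its magnitude (the original definition of the measure), which is what
  makes the index symmetric under swapping mother and infant. This also
  matches the index's stated range of 0 to 1.
* **$N$ means samples within one epoch.** The per-epoch index is computed
  over time samples, and epochs are then averaged per condition
  ("trial-averaged" wPLI). A `granularity` switch controls whether
  surrogate-based exclusion removes individual pair-epochs (default) or
  whole epochs.
* **Zero-lag degeneracy.** If $\sin\Delta\varphi_i = 0$ for all $i$ (pure
  zero-lag coupling, the signature of volume conduction), the denominator is
  0 and the index is defined as 0. Blindness to zero-lag coupling is the
  point of the measure.

The Phase Locking Value, $\mathrm{PLV} = |\tfrac1N\sum e^{i\Delta\varphi_i}|$,
is computed alongside as a comparison measure; unlike wPLI it rewards
zero-lag coupling.

## Surrogate validation

Each pair-epoch's observed wPLI is compared against an empirical null built
by permuting the time order of the mother's phase series (one fresh uniform
permutation per surrogate per pair; 200 surrogates at a 5% level by
default). A value is retained iff it strictly exceeds at least
$\lceil 0.95 \cdot n_{\mathrm{surr}} \rceil$ surrogate values; ties count
against retention. Under the test's own null — phase series with no temporal
structure — this retains $11/201 \approx 5.5\%$ of pair-epochs, which the
test suite verifies.

An important and deliberate caveat: a time permutation destroys not only
cross-member phase alignment but also the *temporal autocorrelation* of the
phase series. Band-limited phases are strongly autocorrelated, so even fully
independent members retain far more than 5% of pair-epochs once signals have
been band-passed — retention above 90% is typical in our simulations. This
reproduces, and we think explains, the very high epoch-inclusion rates
(>95%) reported for this procedure on real infant–mother EEG. The surrogate
stage should therefore be read as a screen against gross artifacts rather
than a calibrated hypothesis test per pair-epoch; the package's inferential
weight rests on the condition contrasts, not on per-epoch validation. PLV
behaves even more permissively under the same scheme (its observed value
also rises under autocorrelation alone), and the test suite pins down the
direction: under a zero-lag common source, PLV surrogate validation retains
more than wPLI's does.

## Aggregation and inference

Retained pair-epoch values are averaged per channel pair (trial-averaged
wPLI, a 12×12 mother × infant matrix per dyad, condition and band) and the
matrix mean is the scalar **global wPLI** — ten values per dyad (5
conditions × 2 bands). Cohort inference then mirrors standard practice for
such designs:

1. **Outlier screening**: per (band, condition) column, values more than 3
   SD from the column mean are flagged and blanked (configurable; `"none"`
   disables). The omnibus test needs complete blocks, so a blanked cell
   drops that dyad listwise for its band's Friedman test, while Wilcoxon
   post hocs drop pairwise.
2. **Friedman omnibus** across the five conditions per band
   ($\chi^2$, df = 4). A rank test admits no covariates, so infant age and
   sex are handled by (a) separate covariate screening — Welch two-sample
   *t* by sex, Pearson correlation with age, per cell — and (b) a
   parametric repeated-measures sensitivity analysis (split-plot ANOVA with
   condition × covariate interactions).
3. **Pairwise Wilcoxon signed-rank post hocs** over the 10 condition pairs,
   two-sided, with Benjamini–Hochberg FDR per band. The reported statistic
   W is the smaller of the two signed-rank sums; the null distribution is
   exact up to n = 25 without ties and a continuity-corrected normal
   approximation otherwise (the convention is recorded in the output).
4. **Topography**: electrodes are grouped into five regions — frontal
   (F7, F8), central-parietal (C3, C4), occipital (P7, P8), left temporal
   (T7), right temporal (T8); F3/F4/P3/P4 stay unassigned by default,
   following the five-region grouping this design replicates, but the map
   is configurable. Per band, each of the 25 region pairs is tested with a
   paired one-sided *t*-test of combined still-face (mean of SF1, SF2)
   against combined free-play/reunion (mean of FP1, FP2, RU), and BH-FDR is
   applied over all 50 tests jointly (a per-band family is available).
   Averaging order is conditions first, then electrode pairs, unweighted.

## The synthetic dyad generator

`generate_dyad()` emulates the study conditions this package targets: 33
dyads, 512 Hz, 12 channels per person, five 120-s condition blocks. Each
channel carries independent $1/f$ background noise (default exponent 1, RMS
10 µV). Within each block, a shared narrow-band oscillator (band-passed
white noise, one per band) is added to the configured channels of both
members at amplitude $A \cdot \kappa(\text{condition}, \text{band})$, with
the infant's copy phase-delayed by a constant $\delta$ (default $\pi/4$)
through the analytic signal. Movement artifacts are injected as Hann-windowed
low-frequency bursts on the infant's channels (default 3/min, 400 µV,
0.5 s), sized so that amplitude screening removes roughly the 10–20% of
epochs typical of infant EEG.

Defaults that define the emulated conditions, chosen once:

* $\kappa = 0.5$ in FP1/FP2/RU and $0.35$ in SF1/SF2 (a still-face drop of
  0.15) in both bands;
* oscillator amplitude $A = 2.5$ µV RMS at $\kappa = 1$, calibrated so that
  free-play global wPLI lands in the 0.35–0.45 range reported for real
  parent–infant cohorts (the observed level is largely an estimator floor
  plus coupling, exactly as in real data);
* `lag_phase` must not be $0 \pmod{\pi}$ when coupling is present, since
  zero-lag coupling is invisible to wPLI by design — the constructor
  enforces this.

What the generator does **not** emulate: volume conduction and head
geometry, heterogeneous per-dyad coupling topographies (unless configured
via the `coupling` channel subsets), non-stationary coupling within a block,
stereotyped ocular/cardiac artifacts, and inter-dyad variability in noise
spectra. Passing recovery tests on this generator therefore demonstrates
that the pipeline measures what it claims under its own model, not that any
particular real-data effect is genuine.

## Numerical choices

* **Filters**: zero-phase forward–backward Butterworth (order 4 high-pass at
  1 Hz, order 4 low-pass at 30 Hz, order 2 band-stop at 50 ± 2 Hz; order 4
  band-pass for the analysis bands), applied identically to both members so
  cross-member phase relations are untouched. The forward–backward pass uses
  odd-reflection end padding (three filter lengths). Per-epoch band-passing
  of 2-s segments leaves edge transients that cost a few percent of wPLI at
  perfect coupling; they affect both members symmetrically.
* **Phases**: analytic signal via FFT (one-sided spectrum doubling); phases
  in $(-\pi, \pi]$.
* **Interpolation**: a flagged channel is replaced by the mean of its
  immediate montage neighbours (a hand-specified adjacency for the
  12-channel montage); at most 10% of a member's channels may be repaired —
  beyond that the dyad should be excluded. Spherical-spline interpolation is
  out of scope at 12 channels.
* **Artifact screening**: peak-to-peak thresholds, 100 µV (mother) and
  200 µV (infant) by default. The original study did not publish its
  rejection criteria; this rule is a configurable stand-in, not a
  reconstruction.
* **Epoch grid**: half-open `[start, start + 2 s)` windows every 1 s within
  each block; a 120-s block yields 119 epochs of 1024 samples, at least
  three cycles of the lowest analysis frequency.
* **Determinism**: dyad $i$ of a cohort is generated under seed
  `base_seed + i`, and the surrogate draws of dyad $i$ are seeded the same
  way, so whole runs replay byte-identically from the run manifest.
* **Degenerate inputs**: all-tie Friedman tables return $\chi^2 = 0$,
  $p = 1$; all-zero Wilcoxon differences return $W = 0$, $p = 1$;
  numerically-zero ANOVA strata are reported as $F = 0$; identical
  condition groups in the topographical contrast give $t = 0$ with
  one-sided $p = 0.5$, while zero-variance nonzero differences are reported
  degenerate with $p = 1$.

## Problem sizes used by the tests and the acceptance script

Simulation-backed checks run at desk scale, chosen once as the smallest
sizes at which the tested property is stable: surrogate calibration on
2160 white-phase pair-epochs with 200 surrogates; coupling monotonicity on a
six-point $\kappa$ grid × 10 seeds with single 30-s blocks; still-face
recovery on 50 cohorts of 33 dyads with 12-s condition blocks (theta band),
plus 15 null cohorts for the type-I side; the acceptance cohort uses 33
dyads, 16-s blocks, both bands, and 100 surrogates per pair-epoch. The
generator's scientific defaults (120-s blocks, 200 surrogates) are never
changed by tests; only block counts and surrogate counts are scaled for the
experiments, and each experiment states its size in its output (`n`).

## Known limitations

* The surrogate stage is not a calibrated per-pair-epoch test on band-limited
  data (see above); it is kept because it is the published procedure this
  package replicates, with its behaviour characterized rather than silently
  accepted.
* Neighbour-mean interpolation is crude below dense montages.
* The EDF/BDF reader/writer covers continuous, single-rate, dual-member
  recordings with a JSON sidecar for annotations — not the full EDF+
  specification.
* Within-brain connectivity, source-space analysis, and other connectivity
  metrics (coherence, PPC, debiased wPLI²) are out of scope.
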