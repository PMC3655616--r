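---
title: "Methods: band power, wavelet bicoherence and the up-down threshold"
author: "eegbico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, wavelet bicoherence and the up-down threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(eegbico)
```

This vignette documents the models and estimators the package implements,
the conventions and tunable parameters behind them, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## The analysis chain

A session is a multichannel epidural EEG recording (channels × samples,
microvolts, with a sampling rate, channel labels and a planar montage).
The pipeline applies, in this fixed order:

1. resampling to the analysis rate (default 256 Hz) if needed;
2. zero-phase band-pass, default 1–45 Hz;
3. rereferencing to the average of retained channels;
4. channel rejection by peak-to-peak amplitude;
5. epoching into 2 s windows with 75% overlap, then epoch-level artifact
   rejection;
6. Morlet wavelet power and band summaries;
7. harmonic-wavelet bicoherence, optional surrogate filtering, band-pair
   coupling totals;
8. session statistics: change rates, paired/unpaired *t*, Wilcoxon
   rank-sum, per-electrode significance masks and topographic maps.

Filtering precedes epoching because filtering short epochs individually
would spread edge transients through every window; the order is part of the
method, not an implementation accident.

## Morlet power

For analysis frequency $f$ the complex Morlet wavelet (central angle
frequency $\omega = 6$ cycles) is applied in the frequency domain: the
epoch's spectrum is multiplied by a Gaussian centred on $f$ with width
$\sigma_f = f/\omega$, negative frequencies are zeroed, and the product is
inverted. The response is peak-normalised, so the resulting analytic band
signal $W(f,t)$ satisfies $\langle|W|^2\rangle/2 = A^2/2$ for a pure
sinusoid of amplitude $A$ at $f$ — power is calibrated in variance units
(µV²). Doubling an input's amplitude quadruples its power exactly, and
relative band powers are invariant under global rescaling.

Two conventions matter and are deliberate:

* **Cone of influence.** Samples within $2\sigma_t$ ($\sigma_t =
  \omega/2\pi f$) of an epoch edge are excluded from the time average,
  *capped so the central quarter of the epoch is always retained*. The cap
  is necessary: at 1 Hz, $2\sigma_t \approx 1.9$ s would otherwise exclude
  an entire 2 s epoch. The consequence is that delta-band estimates from
  2 s epochs rest on roughly two cycles and carry wide variance; treat
  single-channel delta numbers with caution.
* **Band endpoints.** The canonical bands (δ 1–4, θ 4–8, α 8–13, β 13–30,
  γ 30–45 Hz) share endpoints. Grid points are assigned half-open
  $[lo, hi)$ — a shared endpoint belongs to the upper band — with gamma
  closed at 45. No grid point is counted twice.

`absolute` band power is the mean of the spectrum over in-band grid points
(matching the "average power" convention); `relative` divides each band's
in-band *sum* by the five-band total, so relative values sum to one per
channel. Normalising by the five analysed bands, rather than by power at
unanalysed frequencies, is the documented resolution of an ambiguity: the
total power outside 1–45 Hz is removed by the band-pass anyway. Note one
property of any constant-Q analysis: a component of fixed variance
contributes to the grid sum in proportion to its frequency (the Gaussian
response width grows with $f$), so relative power weights high-frequency
activity more heavily than a flat-bandwidth (e.g. Welch) analysis would.

Session change is reported as $(\text{After}-\text{Before})/\text{Before}
\times 100\%$ per channel and band; zero-baseline cells are flagged
`undefined`, never dropped silently.

## Harmonic-wavelet bicoherence

Quadratic phase coupling (QPC) between $f_1$, $f_2$ and $f_1+f_2$ means
$\varphi(f_1{+}f_2) = \varphi(f_1)+\varphi(f_2)$. The package measures it
with the generalized harmonic wavelet, whose defining feature is box-shaped
spectral support: the coefficients $W(f,t)$ for a 2 Hz band centred on each
1 Hz grid point are obtained exactly by masking the epoch's DFT to that
band (positive frequencies, doubled) and inverting. The squared-normalised
bicoherence is

$$b^2(f_j,f_k)=\frac{\left|\left\langle W(f_j)W(f_k)W^*(f_j+f_k)\right\rangle\right|^2}
{\left\langle |W(f_j)W(f_k)|^2\right\rangle\left\langle |W(f_j+f_k)|^2\right\rangle},$$

with $\langle\cdot\rangle$ pooling time samples within epochs and across
epochs. By Cauchy–Schwarz $b^2 \in [0,1]$ for any input, and the statistic
is invariant to amplitude scaling. Only the principal domain $f_k \le f_j$,
$f_j + f_k \le 45$ Hz is computed; band pairs whose cells would require
sums above the grid cap (gamma–gamma in particular) return an `NA`
sentinel with a warning rather than a misleading zero.

**Convention for stored values and band totals.** The object stores the
*squared* bicoherence (`value_type = "squared"`). The band-pair statistic
$b = \sum\sum b^2(f_j,f_k)$ therefore sums stored values as-is; if an
object is constructed with magnitude storage instead, `total_band_coupling()`
squares before summing. Both conventions are supported behind the
`square_values` flag because published formulations differ on whether the
tabulated quantity is the magnitude or its square; the default here keeps
the summand equal to $b^2$ either way.

**Significance filtering.** The "filtered" coupling estimate zeroes cells
that do not exceed a null threshold. The default null is surrogate-based:
the channel's continuous signal is phase-randomised (amplitude spectrum
preserved) and re-epoched with the same length and overlap, 40 surrogates
by default, per-cell threshold at the 95th percentile. Randomising the
continuous signal rather than each epoch is essential with 75% overlap:
overlapping epochs are strongly dependent, and a null built from
independently randomised epochs is anticonservative. A fixed numeric
threshold is available as the simpler alternative. Known limitation: the
surrogate ensemble is Gaussian-like; for signals that are ensembles of
pure sinusoids with piecewise-constant phases (an extreme the synthetic
generator can produce), the real null floor exceeds the surrogate null and
the filter passes more cells than the nominal rate. On realistic
noise-dominated backgrounds the pass rate matches the nominal quantile,
which is what the test suite checks.

**Estimator character.** The wavelet estimator and a single-bin direct-FFT
bispectrum estimator agree closely on stationary fixtures (one global
locked phase). On the segmented synthetic triplets (phases redrawn every
2 s) the single-bin estimator reads systematically lower because the phase
jumps spread energy across bins; the band-integrating wavelet estimator is
the more faithful of the two there. Tests compare the estimators where
they estimate the same quantity — on the stationary fixture.

## Session statistics

Paired *t* within group, Welch *t* between groups (variances are not
assumed equal), and Wilcoxon rank-sum for the coupling totals, all
two-sided. Rank-sum p-values are exact for combined $n \le 20$ without
ties, normal-approximated with tie correction otherwise, and the method
used is recorded in the output. Per-electrode screens are reported
uncorrected at $\alpha = 0.05$ by default — the convention for descriptive
electrode maps — with a Benjamini–Hochberg switch whose use is always
recorded in the output. Degenerate inputs (zero-variance differences,
all-identical samples) are flagged, not silently propagated. The
experimental unit for group comparisons is the animal: per-rat values are
channel-averaged before testing.

## Topography

Per-electrode values are interpolated on the planar montage with
barycentric linear interpolation on a Delaunay triangulation (computed
directly by Bowyer–Watson — a dozen nodes need no geometry library). The
interpolant is exact at electrodes, bounded between the electrode
extremes, and masked outside the convex hull; a thin-plate spline (exact,
smoother, not bounded) is the alternative. Maps are descriptive artifacts:
no quantitative claim in the package is read off an interpolated surface.

The packaged 14-electrode montage keeps the printed coordinates verbatim.
The source's centrofrontal entry carries a "±" on the anterior coordinate
for nominally frontal channels; the fixture resolves it by placing the
frontal pair at +1.5 mm and the parietal pair at −1.5 mm, left lateral
negative. Reference and ground rows are flagged `scalp = FALSE` and take
no part in maps.

## The up-down threshold estimator

The staircase steps down one filament after a withdrawal, up after none,
and stops six stimuli after the first response change. The 50% threshold
is $10^{X_f + k\delta}/10^4$ grams, where $X_f$ is the last filament force
in log units of 0.1 mg — the only convention under which the $10^4$
divisor returns grams for the printed forces — and $\delta = 0.224$ is the
mean log10 spacing of the 0.41–15.10 g ladder.

The correction $k$ depends on the response pattern. No usable table is
printed in the sources this estimator descends from, so the package
*derives* one: for each terminal pattern reachable under the termination
rule, stimulus levels are reconstructed in ladder-step units and $k$ is
the maximum-likelihood 50% point under a normal psychometric function with
$\sigma$ equal to one ladder step — the same construction that produced
the classical tabulations. The table ships as a plain CSV
(`inst/extdata/k_table.csv`, regenerated by `scripts/make_ktable.R`) and is
validated in the tests against fresh ML fits, not against any published
numbers; its provenance is derived, not transcribed.

Boundary handling is explicit: when no weaker/stronger filament exists the
boundary filament is repeated; a sequence that reaches a boundary and sits
there four times before any response change terminates as *saturated* and
is reported as a censored bound (≤ 0.41 g or ≥ 15.10 g), never a point
estimate. Sequences that touch a boundary after the first change no longer
match the interior reconstruction behind the table, and fall back to the
same ML fit evaluated on the forces actually delivered (`method =
"ml_direct"` in the output). An interior pattern missing from the table is
an error. The simulated responder is logistic in $\log_{10}$(force) —
consistent with the log-spaced ladder — with `slope = Inf` as the
deterministic step case.

## The synthetic generator

Every generator is a pure function of its parameters and seed.

* **Background**: white Gaussian noise shaped in the frequency domain by
  $f^{-\text{slope}/2}$ — exact spectral-slope control, with the RMS set
  explicitly (default 10 µV, a realistic epidural amplitude scale).
* **Band components**: narrow-band-filtered Gaussian noise scaled to an
  exact RMS — realistic non-sinusoidal band power, channel-selective.
* **QPC triplets**: three sinusoids at $f_1, f_2, f_1+f_2$ with phases
  redrawn every 2 s segment; the sum component's phase equals
  $\varphi_1+\varphi_2$ on a controllable fraction `strength` of segments
  (chosen deterministically as `round(strength × n_segments)` to cut
  variance). With constant amplitudes the asymptotic squared bicoherence
  at the coupled cell is approximately `strength`². A short raised-cosine
  taper (default 0.1 s) at segment edges suppresses the broadband clicks
  the phase jumps would otherwise inject into high-frequency bands.

`synth_study()` composes these into the standard validation study: three
sessions (baseline, incision-like, treatment-like) for eight subjects. The
baseline is delta-dominant (delta component RMS 14 µV against 4 µV
theta/alpha/beta and 3 µV gamma, on a 1/f background), as in awake rodent
EEG. The incision-like session attenuates delta (×5/14) and adds three
fully coupled triplets — (9, 5), (14, 5), (17, 9) Hz — whose components and
sum frequencies deliver the raised theta/alpha/beta power *and* the
beta-to-low-frequency coupling; their frequencies are placed in analysis
bands clear of the band components so each sinusoid keeps usable
signal-to-noise for coupling estimation. The delta attenuation is sized so
the constant-Q-weighted spectral total is approximately conserved, which
is what leaves gamma's relative power neutral — the declared study
condition. The treatment-like session drops the beta-involving triplets
(keeping the alpha–theta one), withdrawing the beta excess and the
beta–low coupling. Between-subject variability is a 15% lognormal
amplitude trait per subject and band, stable across sessions, plus an
independent 10% per-session factor.

What the generator does **not** emulate: volume conduction and shared
sources across channels (channels are independent realisations),
stimulation artifacts, non-stationary arousal drift, or realistic spatial
covariance on the montage. Passing tests therefore demonstrate that the
estimators recover known spectral and coupling structure and effect
directions at realistic amplitudes and n — not that the pipeline is robust
to every property of in-vivo recordings.

## Numerical choices

* **Band-pass**: linear-phase windowed-sinc FIR (Hamming, default 2 s
  kernel) applied as a centred convolution with reflection padding —
  exactly zero-phase, which bicoherence requires. A 4th-order Butterworth,
  even run forward-backward, attenuates 50 Hz by only ~10 dB with a 45 Hz
  edge, and IIR orders high enough to meet a 20 dB spec are numerically
  fragile with a 1 Hz edge at 256 Hz; the FIR meets > 50 dB at 50 Hz and
  < 1 dB passband ripple. The kernel shortens automatically (with a
  warning) for recordings too short to support it.
* **Resampling**: Fourier (sinc) — spectrum truncation/zero-padding —
  phase-exact for band-limited signals; chosen after the available
  polyphase routine showed uncompensated group delay.
* **Epoch grid**: integer sample arithmetic throughout; epoch $i$ covers
  the half-open sample range $[(i-1)\,\text{step},\ (i-1)\,\text{step}+L)$
  and the count is $\lfloor (N-L)/\text{step}\rfloor + 1$. No resampling
  drift is possible.
* **Degenerate inputs**: all-zero epochs give zero spectra and zero
  bicoherence (denominator guarded); zero-variance test inputs are
  flagged; all-channel rejection is a hard, named error.
* **Problem sizes**: validation runs use 40 s sessions, 12 channels,
  8 subjects, bicoherence on one representative channel, and surrogate
  filtering disabled in the pattern-recovery study; these sizes give the
  paired tests ample power for the constructed effects while keeping the
  whole validation reproducible in minutes on a laptop. Longer sessions
  (the 25–30 min scale the pipeline defaults assume) only tighten the
  estimates.

## Known limitations

Delta estimates from 2 s epochs are noisy by construction; the surrogate
null is liberal for pure-sinusoid ensembles; EDF output quantises to 16
bits per sample (round-trip error bounded by the channel range / 2¹⁵); and
the electrode montage's printed ambiguity is resolved by convention, as
documented above. The per-electrode screens are uncorrected by design and
should be read as descriptive maps, not confirmatory tests.
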