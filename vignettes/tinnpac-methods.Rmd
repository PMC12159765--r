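---
title: "Methods: cross-frequency coupling analysis in tinnpac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-frequency coupling analysis in tinnpac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tinnpac` analyses resting-state EEG for cross-frequency coupling
differences between bothersome-tinnitus (BT), non-bothersome-tinnitus
(NBT) and healthy-control (HC) groups. This vignette documents the models,
the parameters that matter, the numerical choices, and the limits of what
the synthetic validation can show.

## The modulation index

The central statistic is the Kullback–Leibler modulation index. For a
phase series $\phi(t)$ (from a low-frequency band) and an amplitude
envelope $A(t)$ (from a high-frequency band), phases are sorted into
$N = 18$ bins of 20°, the mean amplitude per bin is normalized into a
distribution $P$, and

$$\mathrm{MI} = \frac{\log N - H(P)}{\log N}, \qquad
  H(P) = -\sum_j P_j \log P_j .$$

This is the KL divergence of $P$ from the uniform distribution, normalized
so that $\mathrm{MI}\in[0,1]$: 0 when amplitude is independent of phase,
1 when all amplitude mass falls in one bin. The normalizer $\log N$ is the
standard choice in the KL-MI lineage; it makes values comparable across
binnings and is what bounds the index to the unit interval. MI is exactly
invariant to amplitude rescaling and to circular relabeling of bins (both
are tested properties). An empty phase bin is treated as an error rather
than silently imputed — it indicates too short a signal for 18-bin
occupancy, i.e. fewer than a handful of phase cycles.

## Filter bank and envelope extraction

Phase bands have lower edges 1, 3, 5, 7 Hz and amplitude bands 7, 9, …,
149 Hz, each 2 Hz wide, so band centres are 2–8 Hz (phase) and 8–150 Hz
(amplitude). A pair is admissible when the phase band's upper edge lies
below the amplitude band's lower edge. The band-averaged theta–beta and
theta–gamma PAC values are the arithmetic means of the admissible MI cells
whose phase centre falls in 4–8 Hz and amplitude centre in 13–30 Hz or
30–70 Hz respectively; with this bank the theta box selects centres
{4, 6, 8} Hz.

Filters are windowed-sinc FIR band-passes of order
$3\,\mathrm{round}(f_s/f_{\mathrm{low}})$ (three cycles of the band's
lower edge, the eegfilt convention), applied zero-phase. Two consequences
of this convention are worth making explicit:

* **Zero-phase application is done in the frequency domain.** Forward–
  backward filtering with kernel $h$ is equivalent to filtering once with
  $|H(f)|^2$; we apply that response directly by FFT. On a 150,000-sample
  record this is orders of magnitude faster than time-domain `filtfilt`
  with a several-thousand-tap kernel and is numerically the same
  operation (up to the treatment of the record's ends, which the epoch
  trimming below discards anyway).
* **High-frequency amplitude filters are deliberately shallow.** An
  amplitude modulation at $f_p$ places sidebands at $f_a \pm f_p$ —
  outside a sharply-realized 2-Hz passband. The three-cycle order rule
  gives high-frequency bands short kernels with transition bands of tens
  of Hz, which keeps those sidebands inside the effective passband; a
  bandwidth-matched sharp filter would strip them and with them the
  coupling itself. The price is spectral smearing of the comodulogram
  along the amplitude axis, which is why localization claims are stated
  at ±2 Hz rather than per-cell.

Hilbert phase and amplitude come from the FFT analytic signal (no
installed R package provides it; it is five lines and tested against the
closed form for tones). For epoched data the record is filtered
concatenated, re-split into its 2-s epochs, 0.25 s is trimmed from each
epoch edge to drop filter transients, and bin statistics are pooled across
epochs. Pooling (rather than averaging per-epoch MI values) was chosen
because a 2-s epoch contains only ~12 theta cycles — too few for stable
18-bin occupancy on its own; pooling uses every sample once and needs no
per-epoch occupancy guarantee.

## The synthetic cohort as study conditions

The generator plants exactly the structure the estimator assumes:

$$x(t) = \sin(2\pi f_p t)
  + [1 + m\cos(2\pi f_p t)]\,c\,\sin(2\pi f_a t) + \epsilon(t),$$

with $f_p = 6$ Hz (theta), carriers at 20 Hz (beta) and 40 Hz (gamma),
modulation depth $m\in[0,1]$ per ROI per band, and 1/f Gaussian background
$\epsilon$. The defaults are carrier amplitude 0.3 and background SD 1.5
(relative to a unit theta oscillation). These were fixed once, on the
physical argument that in real resting EEG the gamma-band oscillation sits
at or below the broadband 1/f floor, and matter more than they may appear
to: because MI is amplitude-scale invariant, a noiseless amplitude-
modulated signal has the paradoxical property that partially attenuating
the carrier *raises* the relative envelope modulation, so the comodulogram
maximum of a clean AM signal migrates away from the carrier. It is the
un-modulated background picked up by off-carrier bands that anchors the
maximum at the true pair — comodulogram localization is only meaningful in
the background-dominated regime, which is also the realistic one.

Cohort structure follows the study design the package targets: 21 BT /
27 NBT / 21 HC, THI scores drawn from truncated normals (BT 44.43 ± 9.32
above 36, NBT 18.52 ± 11.22 at or below 36, clipped to 0–100, integer);
HC subjects carry no score. The default ROI set is a desk-scale eight-ROI
design (bilateral HES, STG, ORBinf, PCG) with BT showing enhanced
theta–beta/theta–gamma depths in auditory and posterior-cingulate ROIs and
*reduced* theta–gamma depth in inferior orbitofrontal cortex, NBT
intermediate, HC low — the qualitative pattern reported for tinnitus.
Source signals are mixed to sensors through an abstract full-rank Gaussian
leadfield (no electrode or cortical geometry; 32 sensors by default as a
desk-scale stand-in for a high-density net), with white sensor noise at
20 dB SNR. All randomness fans out from one master seed through a string-
hash stream splitter, so subjects are independent and every run is
bit-reproducible.

What the generator does **not** emulate: ocular/muscle/cardiac artifacts
(the rejection stage is exercised with planted amplitude spikes instead),
volume-conduction geometry and its zero-lag correlation structure, phase
drift and nonstationarity of real oscillations, 1/f slope variation across
subjects, and any true relationship between THI and coupling (THI is
sampled independently of the planted depths). Passing the recovery tests
therefore demonstrates the *computational* correctness of the chain, not
the biological claims.

One limitation follows directly from the periodic modulator: circular-
shift ("phase-shuffled") surrogates rotate the preferred coupling phase of
a strictly periodic signal without destroying its coupling, so the
surrogate threshold is a valid null only for aperiodic/noisy signals (the
use it is put to). Significance of the planted coupling is instead
demonstrated by parameter recovery (monotonicity in $m$, argmax location,
oracle equivalence).

## Preprocessing

The chain is band-pass 0.5–150 Hz (zero-phase FIR) and 50 Hz second-order
IIR notch (applied forward–backward), rational resampling to 500 Hz, 2-s
segmentation, and peak-to-peak rejection: an epoch is kept only if every
channel's peak-to-peak lies within [flatline, absolute] bounds (defaults
1e-6 µV and ±100 µV-scale; the pipeline default is 500 for the synthetic
units). This deterministic rule replaces manual inspection and ICA, which
are irreproducible and out of scope; consequently the package makes no
attempt to remove structured artifacts, only gross ones. Resampling is
implemented as zero-stuffing + zero-phase anti-alias FIR + decimation,
because the available polyphase resampler introduces an uncompensated
group delay of a few samples — enough to matter for phase-sensitive
downstream analysis (a tested property).

## Source inversion

The inverse is the classical minimum-norm estimate
$\hat S = L^\top(LL^\top + \lambda I)^{-1}X$ with scalar (fixed-
orientation) sources. The default regularization follows the standard
SNR rule $\lambda = \mathrm{tr}(LL^\top)/(n_{\mathrm{sens}}\,SNR^2)$ with
$SNR = 3$; recovery on the synthetic cohort is nearly flat in $\lambda$
over two orders of magnitude, so the default is not critical. "Noise
regressed in the time dimension" is realized as per-epoch mean and linear
trend removal — the simplest reading consistent with an unspecified
regressor, and idempotent. ROI series are the signed mean over each ROI's
sources; signed averaging can cancel opposed sources (a documented,
tested behaviour) but is the faithful reading of "a time series per
region" absent orientation information. When recovery is quantified
against ground truth, the truth series are detrended the same way, so the
comparison measures inversion error rather than the detrending itself.
At the reference geometry (32 sensors, 52 sources, 26 ROIs, 20 dB) the
median true-vs-estimated ROI correlation is ~0.88, limited by crosstalk
from compressing 26 independent regional signals into 32 sensor channels,
not by sensor noise.

## Spectral measures and connectivity

PSD is Welch with non-overlapping 2-s Hann windows (0.5 Hz resolution),
scaled so the integral reproduces the variance (Parseval, tested at 1%).
Relative band power divides band-integrated power by the broadband
(0.5–150 Hz) integral. Amplitude–amplitude coupling correlates squared
Fourier moduli across epochs (Pearson on power, matching the cited
approach; Spearman optional) on a 2–70 Hz grid at 0.5 Hz. Power–power
coupling is a Spearman correlation with exact p for n ≤ 10 and the
t-approximation above; the pipeline applies it across subjects to
ROI-mean relative band powers (the across-epoch path is available by
calling the same function on per-epoch values).

Connectivity uses the standard epoch-wise estimators — magnitude-squared
coherence, PLV $|\mathrm{E}\,e^{i\arg S_{xy}}|$, PLI
$|\mathrm{E}\,\mathrm{sign}\,\Im S_{xy}|$, wPLI
$|\mathrm{E}\,\Im S_{xy}|/\mathrm{E}|\Im S_{xy}|$ — with expectations as
means over epochs and band values as unweighted means over in-band FFT
bins. A vanishing wPLI denominator (exactly zero-lag signals) yields 0 by
definition rather than NaN. Group contrasts are two-sided Welch t-tests
per edge, Fisher-z transformed for the correlation-like metrics
(coherence, PLV), with Benjamini–Hochberg correction across edges.

## Inference

The group analysis is a classical mixed-design ANOVA (ROI within-subject,
Group between-subject) computed per group pair and band, with a Bonferroni
family of 4 (two bands × two patient-vs-control pairs) — the family is a
package choice, stated rather than inherited. Sphericity is uncorrected by
default with a Greenhouse–Geisser flag (`gg_correction = TRUE`); at two
within-levels the correction is exactly null, which is tested. Post-hoc
comparisons bootstrap subjects within group (1000 resamples), centre the
resampled differences on the observed difference to form the null (the
shift method — chosen because it is calibration-testable), and take the
two-sided exceedance fraction with the +1 correction; BH correction is
applied across ROIs. Because the bootstrap is already distribution-free,
no automatic parametric-vs-rank routing is layered on top; the
Shapiro–Wilk screen is provided for descriptive routing (mean ± SD vs
median/IQR reporting). PAC–THI correlation is Pearson (the standardized
regression slope), Spearman by flag, computed within the NBT group in the
pipeline.

## Classification

Features are per-ROI band PAC values (2 × ROIs), connectivity upper-
triangle edges per band, and per-ROI relative band powers. Per-feature
z-scoring and Fisher-discriminant reduction are fit inside each
leave-one-out fold, never on the held-out subject; the no-leakage property
(a subject's label cannot influence its own prediction) is tested
directly. "Fisher's linear discriminant" is ambiguous between the
canonical projection (one component for two classes) and per-feature
discriminant-ratio scoring; both are implemented, with score-based top-10
selection as the default because a single projected dimension discards too
much for KNN at these sample sizes. KNN uses k = 5 (odd, to avoid vote
ties; k is not specified by the targeted design), Euclidean distance on
standardized features. Sensitivity is BT recall and specificity NBT
recall, i.e. BT is the positive class. Ablation runs share identical
folds across feature combinations, so accuracy differences are paired.

## Problem sizes and numerical details

The default pipeline study is 69 subjects × 8 ROIs × 60 s at 500 Hz; the
test suite exercises planted-pair recovery at 300 s, surrogate nulls with
200 circular shifts, null calibrations with 200 (ANOVA) and 50 (bootstrap)
simulated studies, and determinism with 15-subject runs — sizes chosen so
the full suite completes in minutes on one core while keeping every
statistical check at the scale its error rates were stated for. FFT
lengths are padded to 2-3-5-smooth sizes. EDF I/O is a minimal in-package
16-bit codec (header + one data record, linear physical/digital scaling);
round-trip error is bounded by half a digital step over the per-channel
range, i.e. range/2¹⁶. The delimited format stores channels as rows with
an `fs` header line at full double precision. KNN distance ties (measure-
zero for continuous features) fall back to the seeded tie-break of the
underlying implementation, so reports remain reproducible.
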