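# tinnpac

Source-level EEG phase–amplitude coupling analysis for tinnitus cohorts.

Chronic tinnitus — and in particular the distinction between *bothersome*
tinnitus (BT, Tinnitus Handicap Inventory score above 36) and
*non-bothersome* tinnitus (NBT, THI ≤ 36) — has been linked to
thalamocortical dysrhythmia: pathological low-frequency oscillations whose
phase entrains high-frequency activity in auditory and limbic cortex.
`tinnpac` implements the complete resting-state EEG analysis chain used to
probe that hypothesis:

1. **Preprocessing** — band-pass (0.5–150 Hz) + 50 Hz notch filtering
   (zero-phase), resampling to 500 Hz, segmentation into 2-s epochs, and
   deterministic peak-to-peak amplitude rejection.
2. **Source inversion** — minimum-norm estimation
   (Ŝ = Lᵀ(LLᵀ + λI)⁻¹X) through a supplied or synthetic leadfield,
   with per-epoch detrending and signed-mean aggregation into 26 AAL
   regions of interest (13 bilateral pairs: Heschl gyrus, superior/middle/
   inferior temporal, orbitofrontal cortex, cingulate, hippocampus,
   parahippocampal gyrus, insula).
3. **Phase–amplitude coupling** — the package's central statistic. Signals
   are passed through an FIR filter bank (phase bands 1–7 Hz lower edges,
   amplitude bands 7–149 Hz, 2-Hz steps and bandwidths), Hilbert phase and
   amplitude are extracted, phases are sorted into 18 bins (20° width), and
   the Kullback–Leibler modulation index

   MI = (log 18 − H(P)) / log 18,  P_j ∝ mean amplitude in phase bin j

   is computed for every admissible pair, giving comodulograms and
   band-averaged theta–beta (4–8 → 13–30 Hz) and theta–gamma (4–8 →
   30–70 Hz) PAC, one value per ROI per subject.
4. **Auxiliary couplings** — Welch PSD, relative band power, Spearman
   power–power coupling, and amplitude–amplitude coupling (across-epoch
   correlation of spectral power, 2–70 Hz at 0.5 Hz).
5. **Connectivity** — epoch-wise coherence, PLV, PLI and wPLI between ROI
   series, with FDR-corrected edge-wise group contrasts.
6. **Statistics** — Shapiro–Wilk screening, mixed-design ROI × Group
   repeated-measures ANOVA (Greenhouse–Geisser optional), bootstrap
   (1000×) post-hoc tests with Benjamini–Hochberg correction, and PAC–THI
   correlations.
7. **Classification** — BT vs NBT via Fisher-discriminant dimensionality
   reduction and k-nearest-neighbour with leave-one-out cross-validation,
   over configurable feature combinations (PAC, connectivity, power).

Because raw clinical EEG of this kind is rarely shareable, the package
ships a first-class **synthetic cohort generator**: theta oscillators whose
phase modulates beta/gamma carriers at planted per-ROI, per-group
modulation depths, embedded in 1/f background noise, mixed to sensors
through a full-rank leadfield, with THI scores drawn from per-group
truncated normals consistent with the 36-point threshold. Every stage of
the pipeline is validated by recovering what the generator planted.

## Worked example

Plant a strong theta→gamma coupling (6 Hz phase modulating a 40 Hz
carrier, depth 0.9) and recover it:

```r
library(tinnpac)

sig <- generate_coupled_signal(
  coupling_spec(phase_freq = 6, amp_freq = 40, modulation_depth = 0.9),
  duration_s = 120, fs = 500, seed = 42)
com <- comodulogram(sig, fs = 500)
com
#> <comodulogram> 4 phase x 72 amplitude bands; max MI 0.004428 at (6, 40) Hz
band_pac(com, c(4, 8), c(13, 30))   # theta-beta:  0.00004
band_pac(com, c(4, 8), c(30, 70))   # theta-gamma: 0.00084
```

The grid maximum falls exactly on the planted (6, 40) Hz pair, and the
band-averaged theta–gamma MI is ~20× the theta–beta MI, as planted. The
absolute MI values are small because the carrier sits well below the 1/f
background, as gamma oscillations do in real resting EEG.

A small end-to-end cohort study (8 BT / 8 NBT / 8 HC, 30 s each, default
group coupling profiles over 8 ROIs):

```r
cfg <- pipeline_config(seed = 1, out_dir = tempfile(),
  cohort = list(n_bt = 8, n_nbt = 8, n_hc = 8, duration_s = 30, fs = 500,
                n_sensors = 16, sensor_snr_db = 20))
res <- run_pipeline(cfg)
res$cv
#>  feature_set accuracy sensitivity specificity
#>          PAC    1.000       1.000       1.000
#>       FC+PAC    1.000       1.000       1.000
#>          all    1.000       1.000       1.000
#>           FC    0.375       0.375       0.375
#>     FC+power    0.375       0.500       0.250
```

PAC features separate BT from NBT perfectly here (the generator plants the
group difference in PAC only), while connectivity-only features hover at
chance — the ablation logic the classifier module exists to expose. The
ROI × Group interaction for theta–gamma PAC between BT and HC is strongly
significant (F(7, 98) = 11.11, p = 2.8e-10), while theta–beta at this
small scale is not (F = 1.32, p = 0.25); all tables are written to
`out_dir` alongside a manifest of seeds and checksums.

A thin CLI wraps the same functions:

```sh
exec/tinnpac run-all --seed 1 --out runs/demo
exec/tinnpac simulate --subjects 5 --duration 20 --out sim/
```

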