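---
title: "Interhemispheric gamma coherence under dual-site 40 Hz tACS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interhemispheric gamma coherence under dual-site 40 Hz tACS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When an ambiguous stroboscopic alternative motion (SAM) display is perceived
as *horizontal* motion, visual information from both hemifields must be
integrated across the hemispheres; the *vertical* percept needs no such
integration. The working hypothesis is that interhemispheric gamma-band
coherence over parieto-occipital cortex indexes this integration, and that
driving both hemispheres with 40 Hz transcranial alternating-current
stimulation (tACS) at 0° ("in-phase") versus 180° ("anti-phase") relative
phase can bias that coherence — and with it the percept.

`gammacoh` implements the complete sensor-level analysis chain for this
paradigm, plus a synthetic-data generator with known ground truth, so every
estimator can be validated end to end without access to human recordings.

## Analysis pipeline

### Preprocessing

Recordings (31 channels, nominally 5,000 Hz) are band-passed 1–100 Hz with a
two-pass (forward–backward, hence zero-phase) FIR filter and down-sampled to
1,000 Hz after anti-alias filtering. A two-pass Butterworth band-stop
(35–45 Hz, composite order 8) removes the stimulation artifact; it is applied
to *all* conditions — sham, stimulation, post — so estimates remain
comparable. The band-stop is realized as a cascade of two order-4 sections:
a direct transfer-function realization of the full order is numerically
unstable for so narrow a stop band, while the cascade is stable with the same
composite order. Reflection padding (point-mirrored continuation) absorbs
filter transients; the pad is trimmed afterwards, and for the narrow notch it
is sized generously (several times the reciprocal bandwidth).

Task data are cut into 3,000 ms epochs starting 500 ms after each reported
perceptual switch, labeled with the new percept. Epochs that would cross the
next report or a trial boundary are dropped; this guarantees percept purity
at the cost of discarding short dominance periods (the alternative —
allowing overlap — is not offered, because mixed-percept epochs would bias
the contrast toward zero). Resting-state data are cut into non-overlapping
1 s segments. Artifact rejection is automated with a peak-to-peak threshold
(default 150 µV) standing in for visual inspection, and segment counts are
balanced across cells by seeded subsampling to avoid sample-size bias in
coherence estimates.

### Spectra and connectivity

Spectral estimation uses two regimes on a 1 Hz grid:

* **1–35 Hz** — sliding 500 ms Hanning windows, 50 % overlap, zero-padded to
  1 s so window spectra land exactly on the integer grid.
* **36–100 Hz** — DPSS (Slepian) multitapers with ±10 Hz half-bandwidth.
  Tapers span the whole epoch; with `K = 2TW − 1` this yields 59 tapers on
  3 s task epochs and 19 on 1 s resting segments. A sliding-taper-window
  alternative (`taper_window`) is available, but the whole-epoch default is
  the one whose taper counts match the design above. The tapers themselves
  are computed from the standard symmetric tridiagonal eigenproblem and
  memoised per (length, bandwidth); no installed package provides them.

Magnitude-squared coherence `C = |S_xy|² / (S_xx S_yy)` is computed per
frequency for the 13 mirror-symmetric interhemispheric channel pairs, then
averaged within bands (delta/theta 1–7, alpha 8–12, beta₁ 13–25, beta₂
26–35, gamma₁ 36–45, gamma₂ 46–70, gamma₃ 71–100 Hz). Wherever
stimulation-condition data are involved, gamma₁ is excluded (the notch
removed the 40 Hz artifact there and whatever survives is uninterpretable).
The phase-locking value — the modulus of the mean phase-difference phasor
after band-passing and the analytic-signal transform — serves as an
amplitude-free control for every coherence result. MSC is reported as such
(not its square root) and labeled accordingly. Percept effects are
quantified as the relative coherence increase for horizontal over vertical
motion, `(C_h − C_v)/C_v`, the vertical percept acting as a within-condition
baseline that cancels volume conduction and reference-electrode effects.

### Entrainment markers

The instantaneous phase (band-pass + analytic signal) is sampled at each
stimulation trigger — one every 30 cycles (0.75 s at 40 Hz), at the rising
zero crossing; for sham/post, dummy triggers are laid down at exactly the
same cadence starting at the first sample. Non-uniformity of the resulting
phase distributions is tested with Rao's spacing test (its statistic is
sensitive to multimodal departures, which matters with two sessions), with
p-values from a Monte-Carlo uniform null at matched n — memoised per sample
size — rather than critical-value tables, because the Monte-Carlo null is
exact at any n and reproducible under a seed. Between-condition differences
use Kuiper's two-sample test (rotation-invariant); its asymptotic p-values
are conservative at moderate n, which the type-I-control tests acknowledge.
Group-level significance uses the binomial criterion: more than 26 of 28
per-subject-and-session comparisons individually significant at the
Bonferroni-corrected threshold 0.05/31 ≈ 0.0016.

Shannon spectral entropy acts as a surrogate regularity marker: at each
frequency the power estimates are normalized *across channels* and treated
as probabilities, and `H = −Σ S log S` (natural log; the base only rescales)
is accumulated over four bands (delta/theta, alpha, pooled beta 13–35,
pooled gamma 46–100). The normalization sentence this implements is
ambiguous in its source; the per-frequency-across-channels reading is the
default, and a `normalize = "frequencies"` switch provides the per-channel
alternative, under which the uniform-power maximum is `log(bandwidth in
bins)`. Under the default the uniform maximum is `(B/31)·log 31` for a
B-bin band — both values are asserted in the tests by direct evaluation.

### Cross-frequency coupling

The alpha-amplitude × gamma-envelope chain is implemented exactly in the
diagrammed operator order, even though a single demodulation would be
simpler: (I) zero-phase FIR band-pass 8–12 Hz, analytic amplitude `Aα`;
(II) band-pass 46–70 Hz, analytic amplitude `Aγ`; (III) band-pass `Aγ`
8–12 Hz (same filter family as step I) and a second analytic amplitude,
the gamma envelope `Eγ`. Per 1 s segment, 100 ms are trimmed at each edge
after filtering, `Aα` and `Eγ` are Pearson-correlated, correlations are
Fisher-z-transformed, and z is averaged per channel.

### Cluster-based permutation inference

Element-wise paired t-tests (sensor pairs × frequencies; adjacency links
spatial neighbors at one frequency and the same element at neighboring 1 Hz
bins, crossing band boundaries) are thresholded two-sided at the cluster
alpha (5 %); supra-threshold elements are clustered separately for positive
and negative t, the cluster statistic is the summed t, and the null is the
largest |cluster sum| under within-subject condition-label switching (sign
flips), 1,000 iterations. A cluster is significant when its statistic
exceeds the 95th percentile of that null. Two-sided clustering with the max
over both signs is used because it is the cited toolbox's default behavior.

The permuted-correlation variant correlates a per-subject scalar (the
baseline-corrected motion index `MI = (MR_In − MR_ShamIn) − (MR_Anti −
MR_ShamAnti)`) with per-subject difference maps (`ΔCoh = Coh_In −
Coh_Anti`), transforms r to t via `t = r√(n−2)/√(1−r²)`, forms clusters at a
20 % alpha, and requires at least two adjacent channels and permutation
p < 0.05. Its null sign-flips the difference maps per subject while MI stays
fixed — the condition-label-switching reading — with MI shuffling across
subjects available behind `scheme = "shuffle_mi"`. Ties at the cluster
threshold are excluded (strict inequality). Permutation p-values include the
observed labeling, so p ≥ 1/(n_perm + 1).

### Behavior and eye tracking

The motion ratio is `MR = time_horizontal / time_total` after (a) excluding
the first 3 s of each trial — an interval spanning that boundary keeps its
tail if more than 1 s remains — (b) discarding percept intervals of at most
1 s from numerator *and* denominator (the conservative reading; a
`short_mode = "reassign"` switch folds them into the flanking percept
instead), and (c) collapsing redundant same-label presses. The trailing
percept runs to the trial end. The switch rate counts transitions between
consecutive *accepted* intervals per accepted minute.

Microsaccade detection follows the two-step velocity-threshold scheme:
a prefilter masks blinks, excursions outside 0.05°–1.6°, and ±1 s around
button presses, then drops epochs retaining under 80 % of samples; the
detector computes 2D velocity with the 5-sample moving-difference kernel,
thresholds at λ = 8 median-based robust standard deviations per axis
(elliptical criterion; an arithmetic mean/SD switch exists), merges
supra-threshold runs closer than 20 ms, and keeps events of at least 10 ms
duration and 0.05°–1° amplitude. The median-based estimator is the default
because the underlying algorithm family defines it that way; the kernel
width (unstated in the source description) is the canonical 5 samples.

## The synthetic generator

`sim_config()` fixes the study conditions: 31 channels at 5,000 Hz, 1-minute
trials, gamma-distributed dominance durations (shape 2, means 10 s), a 40 Hz
gamma carrier of 10 Hz bandwidth, 1/f background (exponent 1), a 40 Hz
artifact with a trigger every 30 cycles, 500 Hz gaze with 1.5 microsaccades/s
of 0.1°–0.5° amplitude. Where a quantity had to be invented (coupling
weights, modulation depths, amplitudes in µV), it was chosen once at values
a practitioner would call physiologically plausible and is documented in
`?sim_config`; validation tests select their own explicit values for the
quantity under test rather than moving these defaults.

Mechanics worth knowing when interpreting test results:

* The interhemispheric gamma *oscillator* is narrowband-filtered noise, not
  a sinusoid, so coherence stays below 1 and the PLV is informative. Each
  hemisphere mixes a common analytic process (weight κ, right hemisphere
  rotated by the phase lag) with an independent one; for matched unit
  spectra the long-run MSC of this construction is κ⁴, which the
  monotonicity tests exploit. κ switches instantaneously at report events —
  no reaction-time lag is modeled.
* The alpha rhythm is a quasi-sinusoid whose amplitude, and a dedicated
  γ₂-range oscillator whose alpha-frequency envelope-ripple depth, share a
  slow (1–2.5 Hz) modulator pair correlated at ρ. The γ₂ carrier is itself
  quasi-sinusoidal (constant intrinsic envelope) and sits at carrier + 18 Hz
  so both AM sidebands stay inside the γ₂ band: with a noisy narrowband
  carrier, intrinsic envelope fluctuations would swamp the designed ripple
  and the envelope-of-envelope chain could not read ρ back. Channels where
  the 40 Hz oscillator dominates still show attenuated correlations — the
  recovery tests therefore read the chain at a channel dominated by the γ₂
  oscillator.
* 1/f noise is synthesized by spectral shaping of white noise; gaze drift is
  a mean-reverting random walk; microsaccades have raised-cosine velocity
  profiles at Poisson onsets thinned to ≥120 ms separation.
* Determinism: every generator seeds base R's Mersenne-Twister from
  `seed` via fixed per-stage offsets, so outputs are bit-identical across
  runs and platforms for a given configuration.

What the generator does *not* emulate: volume conduction with realistic head
geometry, non-stationary artifacts (muscle, electrode drift), reaction-time
lags between percept and report, plasticity dynamics after stimulation
(beyond whatever κ schedule a test imposes), and binocular eye movements.
Passing tests therefore demonstrate estimator correctness under the stated
statistical structure, not robustness to everything real data can do.

## Numerical and design choices

* "Finite element response" filters are read as finite *impulse* response
  (two-pass, zero-phase), the common usage of the toolbox tradition this
  pipeline follows; FIR order defaults to three periods of the low corner.
* The printed 250 ms multitaper window is inconsistent with 59 tapers at
  ±10 Hz (which implies T = 3 s); the default tapers whole epochs and
  reproduces the printed taper counts, while `taper_window = 0.25` keeps the
  literal reading available.
* Undefined cells (zero power, zero variance, empty trials) propagate as
  `NA` with counts, never as zeros.
* Rising zero crossings define trigger placement; falling is configurable
  at the event-stream level by shifting trigger times by half a period.
* The r→t transform uses the standard Student form, `n` = number of
  subjects.
* Cohen's d is the paired-design form (mean difference over SD of
  differences); identical samples give d = 0, constant nonzero differences
  are undefined and flagged.
* Supported recording dialects are a lossless float64 binary with text
  sidecar and a delimited-text matrix; event, gaze and ground-truth tables
  are tab-separated text. Results containers serialize with `saveRDS` and
  carry seed, configuration hash and package version.

## Problem sizes used in validation

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the smallest at which each property is decisively measurable:
family-wise error over 400 null replicates (14 simulated subjects, 31
sensors, 1,000 permutations each — fully vectorized sign-flip nulls make
this cheap); parameter recovery from 240 s of simulated EEG at 1,000 Hz;
estimator oracles at 12–200 segments; microsaccade performance over 120 s of
gaze at 500 Hz. Group-scale in-vivo effect sizes are not reproducible from
scratch at a desk, and no test pretends otherwise.

## Known limitations

* EDF input is not supported in this build; the two text/binary dialects
  cover the package's own round trips. (No EDF reader exists in the
  dependency set this package builds against.)
* Kuiper p-values are asymptotic and conservative for n below ~50 per
  sample; the Rao test's Monte-Carlo null is exact but discrete.
* Source reconstruction (beamforming), electric-field modeling and
  repeated-measures ANOVA wrappers are intentionally out of scope; standard
  R tooling (`aov`, `car`) applies directly to the tables this package
  produces.
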