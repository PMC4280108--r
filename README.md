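# gammacoh

Sensor-level analysis of interhemispheric gamma-band coherence in EEG
recorded during dual-site 40 Hz transcranial alternating-current stimulation
(tACS) and bistable motion perception — with a ground-truth synthetic-data
generator that makes every estimator testable end to end.

## Who this is for

Researchers analyzing multichannel EEG from stimulation experiments on
bistable perception (stroboscopic alternative motion and relatives), and
methodologists who need a validated reference implementation of this
analysis chain: coherence/phase-locking over symmetric electrode pairs,
trigger-locked circular statistics, spectral entropy, alpha–gamma envelope
coupling, cluster-based permutation inference, behavioral scoring, and
microsaccade controls.

## The statistics at its core

For interhemispheric channel pairs (x, y) the pipeline estimates, on a 1 Hz
grid over 1–100 Hz (sliding 500 ms Hanning windows below 36 Hz, DPSS
multitapers with ±10 Hz half-bandwidth above; K = 2TW − 1 tapers),

- magnitude-squared coherence `C_xy(f) = |S_xy(f)|² / (S_xx(f) S_yy(f))`,
  pooled over seven canonical bands, and the amplitude-free phase-locking
  value `PLV = |⟨exp(i(φ_x − φ_y))⟩|` as a control;
- percept contrasts `(C_h − C_v)/C_v` (vertical percept as baseline);
- Rao spacing and two-sample Kuiper tests on instantaneous phases sampled
  at stimulation triggers (one per 30 cycles), with a >26/28 binomial group
  criterion at Bonferroni-corrected thresholds;
- Shannon spectral entropy `H = −Σ S log S` on per-frequency
  channel-normalized spectra;
- alpha-amplitude × gamma-envelope correlations (Fisher-z averaged) via the
  three-step filter–Hilbert chain;
- cluster-based permutation tests (dependent-samples t, and a permuted
  correlation of the motion index `MI = (MR_In − MR_ShamIn) − (MR_Anti −
  MR_ShamAnti)` against coherence differences with `t = r√(n−2)/√(1−r²)`);
- motion ratio `MR = time_horizontal/time_total` with the 3 s / >1 s
  acceptance rules, and Engbert-style velocity-threshold microsaccade
  detection (λ = 8 robust SDs, ≥10 ms, 0.05°–1°).

## Worked example

Simulate one session where the horizontal percept couples the hemispheres
more strongly than the vertical percept, run the pipeline, and contrast the
percepts at the parieto-occipital pair of interest:

```r
library(gammacoh)

cfg <- sim_config(duration = 240, rate = 1000, kappa_h = 0.85,
                  kappa_v = 0.35, mu_h = 7, mu_v = 7, noise_scale = 3,
                  seed = 103)
ev  <- generate_percept_stream(cfg)
rec <- generate_recording(cfg, ev)

ep  <- balance_segments(epoch_percepts(rec, ev), seed = 1, by = "percept")
coh <- lapply(c("horizontal", "vertical"), function(p) {
  msc(estimate_spectra(subset_epochs(ep, ep$labels$percept == p)))
})
pc <- percept_contrast(coh[[1]], coh[[2]])
subset(pc, pair == 13 & band %in% c("gamma1", "alpha"))
#> # A tibble: 2 x 5
#>    pair band   coherence_h coherence_v rel_change_pct
#>   <int> <fct>        <dbl>       <dbl>          <dbl>
#> 1    13 alpha        0.993      0.993        -0.00330
#> 2    13 gamma1       0.581      0.0779      645.
```

The gamma-band coherence at the pair of interest is far higher during the
strongly coupled (horizontal) percept. The alpha band is near-perfectly
coherent in *both* percepts — the simulated alpha rhythm is one shared
posterior source, a volume-conduction-like situation — which is exactly why
the pipeline contrasts percepts instead of interpreting absolute coherence:
the alpha contrast is ~0 while the gamma contrast tracks the coupling the
generator injected. The behavioral stream scores as expected for symmetric
dominance durations:

```r
bs <- behavior_summary(generate_percept_stream(
  sim_config(duration = 30 * 60, mu_h = 6, mu_v = 6, seed = 44)))
bs$aggregate
#> # A tibble: 1 x 3
#>      mr switch_rate n_trials
#>   <dbl>       <dbl>    <int>
#> 1 0.473        8.45       30
```

(`mr` ≈ 0.5 because both percepts have equal mean dominance; the switch
rate sits below the renewal-process value 60/6 = 10 per minute because
dominance periods of 1 s or less are rejected by the acceptance rules.)

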