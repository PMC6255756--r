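# circwave

Waveform analysis of circadian protein turnover, and the phase theory of
the two-component clock feedback loop.

## The problem

Circadian clock proteins oscillate with ~24-h period. The *shape* of an
abundance waveform x(t) — not just its period, amplitude and phase — is
informative about the biochemistry underneath. Because x(t) obeys

    dx/dt = g(t) − r(t) x(t),      x(t) = x(t + T),

with synthesis g ≥ 0 and first-order degradation r ≥ 0, two things follow:

* **A degradation-rate bound.** r(t) ≥ R(t) ≡ max{−x′(t)/x(t), 0} for any
  synthesis profile. Its maximum r_min = max_t R(t) is the smallest
  *constant* degradation rate the waveform tolerates, attained at a single
  "hotspot" t_R near the trough. A constant rate would force the
  half-life below ln2 / r_min at *all* times of day.
* **A biosynthetic cost.** Periodicity makes the mean synthesis equal the
  mean degradation, c = ⟨g⟩ = ⟨r·x⟩. Under a constant rate the cost
  cannot fall below c_g = r_min·⟨x⟩; a rhythmic r(t) that is large only
  near the hotspot cuts the cost by the fraction (c_g − c)/c_g.

`circwave` computes R(t), r_min, costs and cost reductions from sampled
profiles; reconstructs the full time-varying r(t) from an mRNA profile
plus sparse measured rates (with the capping / flooring / artifact-window
rules used for plant clock proteins, and an anchors-only estimator for
the mammalian PER2-style case); fits chase-assay decay rates; and
implements the negative-feedback phase theory for active CLOCK–BMAL1
versus free PER–CRY (limit-cycle simulation, feasibility floors,
closed-form and numeric peak-time differences, regime classification,
waveform-symmetry index). A seeded synthetic-data generator provides
ground-truth scenarios for validation.

## Worked example

The packaged profiles are *synthetic stand-ins* (see the vignette) that
emulate published plant-clock data. The PRR7-like pipeline:

```r
library(circwave)
report <- run_pipeline(list(
  x       = circwave_example("prr7_protein_synthetic.csv"),
  g_m     = circwave_example("prr7_mrna_synthetic.csv"),
  anchors = circwave_example("prr7_anchors_synthetic.csv"),
  cap   = list(rule = "window_max", window = c(20, 22)),
  floor = list(rule = "min_anchor"),
  artifact_window = c(2, 10), artifact_anchor_times = c(4, 12)))
report
#> <pipeline_report>
#>  - loaded protein series 'PRR7_protein_synthetic' (12 samples, T = 24 h)
#>  - peak-normalized protein series
#>  - R(t): r_min = 0.8836 1/h at t_R = 21.46 h
#>  - anchor check: 3/3 measured rates satisfy r >= R
#>  - translation model: constant k = 0.285
#>  - bounds applied: cap = 1.104, floor = 0.18
#>  - artifact window [2, 10] h corrected via anchors at t = {4, 12} h
#>  - cost: c = 0.1177, c_g = 0.3927, reduction = 0.700
#>  - anchor-sd sensitivity: cost reduction in [0.675, 0.725]
```

Reading: the waveform alone forces any constant degradation rate above
0.88 per hour (half-life under ~47 min at every time of day, and at
least ~21× the standing protein level synthesized per day). The
reconstructed rhythmic r(t) instead costs c ≈ 0.12 per hour against the
constant-rate floor c_g ≈ 0.39 — a ~70% saving, moving within
[0.67, 0.73] as the measured ZT18 rate varies by its ±0.11 s.d.

The feedback phase theory, on the analytic sinusoid x(t) with L = 3/h,
h0 = 2:

```r
s <- sinusoid_waveform(L = 3, h0 = 2, period = 24)
phase_constant_drive(s, g = 3)
#> <phase_solution> t_x = 12.000 h, t_y = 23.388 h, phi = 2.9814 rad (0.949 pi)
#>   regime: constant_drive
```

A constant activation drive pins the free-inhibitor peak near the
activator trough (phase difference ≈ 0.95π); with an oscillating drive
(`phase_oscillating_drive`, `phase_sweep`) the same waveform admits
nearly any phase relationship.

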