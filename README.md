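# jtpeak

Automated measurement of the **J-Tpeak** and **Tpeak-Tend** ECG
intervals on the vector magnitude lead, for cardiac safety (proarrhythmia
risk) assessment.

QTc prolongation is a sensitive but unspecific torsade de pointes
marker: drugs that block the hERG potassium current together with inward
(late sodium / L-type calcium) currents prolong QTc without
proportionate risk.  Splitting repolarization at the T-wave peak into an
early part, J-Tpeak (J-point to T-peak), and a late part, Tpeak-Tend,
separates these mechanisms — J-Tpeak changes flag the presence of
inward-current block.  The package is aimed at ECG methodologists and
cardiac-safety pharmacologists who need a fully automated, deterministic
and auditable implementation of this measurement.

## What it implements

The complete measurement chain, on the vector magnitude lead
`vm(t) = sqrt(X² + Y² + Z²)` (X, Y, Z reconstructed from leads I, II,
V1–V6 by a configurable 3×8 transform; Kors regression matrix bundled):

* **Preprocessing** — cubic-spline baseline-wander removal (one
  PR-segment knot per beat), an energy-based substitute QRS trigger
  detector, sample-wise median beats upsampled to 1 kHz.
* **T-wave delineation**, two stages:
  1. a search window from J+25 ms to 40% of the preceding RR; candidates
     as (local max, following local min) pairs of the smoothed
     derivative; width ≥ 10 ms and apex ≥ 100 uV retention rules;
     peak/slur labelling by derivative zero-crossing; a decision-tree
     classifier for the offset-relevance of trailing slurs; cleanup
     rules (merge / remove / convert); **T-peak = apex of the highest
     surviving peak**, with notch detection;
  2. **T-end** by the tangent method (steepest descending slope
     intersected with the isoelectric line), refined over local minima
     of a cumulative energy signal by minimizing
     `w1·(c − Tpeak)/(QRSnext − Tpeak) + w2·E(c)`.
* **Intervals** — QT, J-Tpeak, Tpeak-Tend with pluggable heart-rate
  correction (Fridericia for QT, power-law exponent 0.58 for J-Tpeak).
* **Synthetic generator** — Gaussian-bump beats, 10 s records and full
  crossover-study corpora with analytic ground-truth fiducials, covering
  normal / flat / notched / slurred T-wave morphologies.
* **Method-comparison statistics** — Bland-Altman agreement,
  intra-time-point replicate SD with paired test, time-profile coverage
  fractions.

I/O: CSV and a WFDB subset (format 16) for records; CSV for annotations
and per-beat results.  Thin command-line wrappers live in `inst/cli/`
(`delineate.R`, `synth.R`, `evaluate.R`).

## Worked example

Simulate a 10 s, 12-lead record with a notched T-wave, 5 uV noise and
0.3 Hz baseline wander, then run the full chain:

```r
library(jtpeak)

spec <- synthetic_spec("notched", noise_sd_uv = 5, wander_amp_uv = 100, seed = 42)
sim  <- generate_record(spec)

res <- process_record(sim$record,
                      list(qrs_onset_ms = -22, qrs_offset_ms = 30))  # trigger-relative
res$triggers
#> <beat_triggers> 10 triggers, median RR 1000 ms
res$fiducials
#> <fiducial_set> Tpeak 565.0 ms, Tend 609.0 ms, notched (secondary 501.0 ms) (J 330.0 ms)
res$intervals
#> <interval_set> RR 1000 | QT 331.0 (QTc 331.0) | J-Tpeak 235.0 (c 235.0) | Tpeak-Tend 44.0 ms
```

All ten beats were found, the median beat was assembled, and the
delineator identified a notched T-wave: primary peak at 565 ms (the
generator's analytic truth is 564.6 ms), secondary at 501 ms, T-end at
609 ms (truth 609.0 ms).  Intervals are reported raw and rate-corrected
(identical here because RR = 1000 ms); times are ms from the start of
the median beat, whose QRS trigger sits at 300 ms.  Unmeasurable beats
(e.g. T amplitude below the 100 uV floor) come back with
`measurable = FALSE` and a machine-readable reason code instead of
numbers.

See `vignettes/jtpeak-methods.Rmd` for the model, the parameter
defaults and their rationale, and known limitations.

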