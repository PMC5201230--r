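---
title: "Measuring J-Tpeak and Tpeak-Tend on the vector magnitude lead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring J-Tpeak and Tpeak-Tend on the vector magnitude lead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jtpeak)
```

## Why these two intervals

Prolongation of the heart-rate-corrected QT interval is the classic
surrogate for torsade de pointes risk, but it is unspecific: drugs that
block the hERG potassium current *and* inward (late sodium or L-type
calcium) currents prolong QTc while carrying little torsadogenic risk.
Splitting ventricular repolarization at the peak of the T-wave separates
an early component, J-Tpeak (J-point to T-peak), which is sensitive to
inward-current block, from a late component, Tpeak-Tend.  Measuring the
two sub-intervals therefore helps distinguish selective hERG block from
balanced multichannel block in Phase-1 ECG studies.

Both intervals are measured here on the **vector magnitude lead**

$$\mathrm{vm}(t) = \sqrt{X(t)^2 + Y(t)^2 + Z(t)^2},$$

the Euclidean norm of the orthogonal X, Y, Z leads reconstructed from
the eight independent leads (I, II, V1-V6) of the standard 12-lead ECG.
The norm yields a nonnegative, lead-placement-robust global
repolarization signal at the price of a strictly positive baseline noise
floor.

### The lead transform is data

X, Y, Z are obtained by a fixed $3\times 8$ linear map applied
sample-wise.  Several published matrices exist (inverse Dower, Kors
regression, Guldenring).  The package bundles the Kors regression matrix
as its default (`inst/extdata/xyz_transform_kors.txt`) because its
coefficients are published, widely validated and reproducible; any other
$3\times 8$ matrix can be dropped in via
`jt_config(vm = list(transform_matrix = ...))` or a file in the same
format.  Everything downstream is transform-agnostic: the delineator
only sees the vm series, and the synthetic validation beats are
generated directly in XYZ space.

## Preprocessing

* **Baseline wander** is removed per lead by subtracting an
  interpolating cubic spline through one isoelectric knot per beat,
  placed 80 ms before each QRS trigger (a PR-segment proxy) with the
  knot amplitude taken as the median of a 20 ms window.  The residual at
  the knots is exactly zero.  With one knot per beat the spline tracks
  respiratory-band wander (about 0.3 Hz) to a few microvolts at normal
  heart rates; the attenuation degrades as RR approaches the wander
  period.
* **QRS triggers** come either from an external annotation file or from
  a deliberately simple substitute detector (zero-phase 5-25 Hz
  band-pass, squared derivative, adaptive threshold at 30% of the
  running 2 s maximum, 200 ms refractory, apex refinement).  The package
  does not delineate QRS onset/offset: the J-point must be supplied,
  which mirrors how the measurement is deployed (QRS fiducials are
  adjudicated upstream).
* **Median beats**: beats are aligned on the triggers with the window
  $[t_\mathrm{trig} - 300, t_\mathrm{trig} + \min(700,\ 0.9\,\mathrm{RR}_\mathrm{med})]$ ms,
  the sample-wise median is taken per lead (robust to a single
  artifactual beat), and the result is upsampled to exactly 1 ms
  resolution by cubic spline interpolation.  All later processing
  assumes the 1 kHz grid.

## Stage 1 - T-peak and slur/peak candidates

A search window opens 25 ms after the J-point and closes at 40% of the
preceding RR interval.  The window end is anchored at the QRS trigger,
the only rate-linked landmark a median beat retains; this anchor is a
design choice the data format cannot decide, and it is exposed through
`window_rr_frac`.

The vm series is low-pass filtered (zero-phase 4th-order Butterworth,
25 Hz cutoff - zero phase so that fiducial timing is not biased) and
differentiated by central differences.  Every pair of (local maximum,
following local minimum) of this smoothed derivative inside the window
is a **candidate**; candidates narrower than 10 ms (noise) or whose apex
amplitude is below the 100 uV detection floor are discarded.  A
candidate whose derivative crosses zero between its bounding extrema
contains a true local maximum and is labelled a **peak**; otherwise the
derivative only dips - a shoulder on a limb - and it is a **slur**.

The 25 Hz cutoff slightly widens very narrow T-waves: for a Gaussian
T-wave of width $\sigma = 15$ ms the tangent offset moves by about
1.5 ms; for $\sigma \ge 20$ ms the effect is below 1 ms.

Three cleanup rules follow, in order (thresholds configurable):

1. **merge** two adjacent candidates when the lowest amplitude strictly
   *between* their apexes is at least 0.90 of the lower apex - a summit
   split in two by a ripple.  The interior-valley requirement matters:
   on the monotone descent onto a trailing slur the minimum sits at the
   slur apex itself, and such pairs must not merge;
2. **remove** a peak falling short of the highest peak by more than
   0.50 of the highest apex;
3. **convert** a peak to a slur when either limb is nearly horizontal
   (limb angle below 5 degrees, with time in ms and amplitude in uV).

The **T-peak is the apex of the highest surviving peak**; if two peaks
survive, the beat is flagged notched and the second is reported.  An
alternative convention (first discernible peak) exists in the field;
the highest-peak rule is implemented because it is the one the
automated procedure defines, and the notch flag plus secondary-peak
diagnostic preserve the information needed to apply the other
convention downstream.

### Slur relevance

Only slurs trailing the last peak matter for the offset: a genuine
late-repolarization shoulder means the T-wave extends beyond the main
descent, whereas a shallow far-tail shelf (U-wave-like activity) must
not drag the offset out.  Twenty geometric features of the (peak, slur)
pair are computed - amplitude/time ratios against their limb-line
junction, limb angles, rotation angles - and a pruned classification
tree decides `relevant`/`irrelevant` from three of them: the slur's
limb-slope angle, the angle between the peak's falling and the slur's
rising slope, and the peak/slur amplitude ratio.  Limb slopes are
least-squares fits between the bounding derivative extremum and the
apex, falling back to the instantaneous derivative where the segment
degenerates (a descending slur's apex coincides with its rise point).
The plain amplitude ratio is used rather than the variant based on the
limb-bisector intersection with the signal, which requires a numeric
curve intersection that can fail on degenerate geometry; the variant is
still computed and reported.

The bundled default tree was trained with `train_relevance_tree()`
(CART, depth 4, fixed seed) on `make_slur_corpus(n = 500, seed = 7)`:
noiseless beats mixing genuine adjacent shoulders (gap
$1.1$-$2.2\,\sigma_p$, width 12-28 ms) with broad shallow far-tail
shelves (gap $2.6$-$3.6\,\sigma_p$, width 36-60 ms).  The label is
derived from the generator, never from the classifier: a shoulder is
relevant when anchoring the tangent after it moves the dense-grid
tangent offset by more than 8 ms.  The two populations are kept
geometrically separated so the labels are a well-posed function of the
observable waveform; mixing them continuously would label identical
geometries differently, an irreducible error no classifier can resolve.
The tree is plain JSON data, versioned and overridable.

## Stage 2 - T-wave offset

The initial offset uses the **tangent method**: the steepest descending
slope after the last relevant candidate's apex is found on the smoothed
derivative, and the tangent line there is intersected with the
isoelectric level (0 uV after baseline removal; configurable).  For a
Gaussian limb of width $\sigma$ the tangent point is the inflection at
$\mu + \sigma$ and the intersection is exactly $\mu + 2\sigma$; because
the intersection is stationary with respect to the tangent point at the
inflection, the method is first-order insensitive to jitter in locating
the steepest sample - the main reason for its noise robustness.

Extreme T-wave flattening can leave a long, shallow shelf before the
tangent intersection.  To handle it, a **cumulative energy signal** is
built over the interval from the last candidate's falling extremum to
the tangent offset: the signal falls by the derivative magnitude where
the derivative increases sample-to-sample and rises by it otherwise,
then is min-max normalized to $[0, 1]$.  The qualitative definition of
this signal admits two sign conventions; the one implemented is the one
under which a convex decaying tail yields a monotone decrease from 1 at
the window start to 0 at the end, which is the stated normalization
contract - under the opposite convention the contract cannot hold.  A
flat shelf followed by a further drop produces an interior local
minimum at the shelf end; these minima are alternative offset
candidates.  The offset is the candidate minimizing

$$w_1\,\frac{c - T_\mathrm{peak}}{\mathrm{QRS}_\mathrm{next} - T_\mathrm{peak}} + w_2\,E(c),$$

with $w_1 = w_2 = 0.5$ (the weights are unstated in the method's public
description; equal weighting is the minimal assumption and both are
configuration), ties broken to the earliest candidate, and the tangent
offset itself always in the candidate set.  A median beat has no literal
next QRS; it is projected as `alignment + median RR`.

## Intervals

With QRS onset/offset supplied, `measure_intervals()` returns
QT $= T_\mathrm{end} - \mathrm{QRS}_\mathrm{on}$,
J-Tpeak $= T_\mathrm{peak} - \mathrm{QRS}_\mathrm{off}$ and
Tpeak-Tend $= T_\mathrm{end} - T_\mathrm{peak}$, so
QT $=$ (QRS width) $+$ J-Tpeak $+$ Tpeak-Tend identically.  Heart-rate
correction is pluggable: Fridericia for QT
($/\,(\mathrm{RR}/1000)^{1/3}$) and a power law with exponent 0.58 for
J-Tpeak, the exponent used for this interval in prior clinical work;
Tpeak-Tend is reported uncorrected.  Corrections are the identity at
RR = 1000 ms.

## The synthetic generator and what passing means

Clinical trial ECGs cannot ship with a package, so every stage is
validated against `generate_beat()` / `generate_record()` /
`generate_study()`, which emit sums of Gaussian bumps (triphasic QRS,
one or two T components) along a fixed dipole direction in XYZ space,
with per-lead white noise, sinusoidal baseline wander with random phase,
and 2.5 uV amplitude quantization at 500 Hz for records.  Ground truth
is analytic: the true T-peak is the dense-grid argmax of the noiseless
T-wave and the true T-end is the terminal component's $\mu + 2\sigma$
(verified against an independent dense-grid tangent computation to
within 0.5 ms).  Four morphology classes cover the shapes that matter:
normal (400 uV, $\sigma$ 30 ms), flat (120 uV - near the 100 uV floor),
notched (350/420 uV, separated peaks), and slurred (an ascending-limb
shoulder).

The generator emulates morphology, noise scale and wander - not real
electrophysiology.  It does not produce asymmetric T-waves,
rate-dependent morphology change, ectopy, muscle-artifact spectra, or
the continuum of borderline notches that drives reader disagreement in
real data.  Passing the validation therefore shows the chain is
*internally correct* (it recovers known fiducials under known
corruptions at the millisecond scale); it does not certify clinical
accuracy on pathological recordings.

Validation problem sizes, chosen to exercise the study structure at
desk scale: 500 noiseless beats across the four classes for fiducial
recovery; 200 seeds per morphology of baseline/on-effect record pairs
(5 uV noise, 100 uV 0.3 Hz wander, +20 ms T-shift) for single-delta
agreement; and a 22-subject x 8-time-point x 3-replicate study for
replicate consistency.  `scripts/acceptance.R` re-runs all three.

## Numerical conventions and degenerate inputs

* Times are milliseconds from the start of the record/beat, 0-based
  samples, half-open windows $[start, end)$.
* Tree splits route `<=` to the left child; cost ties break to the
  earliest candidate; `which.max` ties break to the earliest sample.
* A window whose end does not exceed its start (extreme tachycardia or
  a late J-point), absence of candidates (e.g. T amplitude below
  100 uV), no surviving peak, a tail shorter than 50 ms, or a
  non-descending tail each yield `measurable = FALSE` with a
  machine-readable reason code instead of an error.
* The pipeline is deterministic for fixed input, configuration and
  tree; all randomness in the generator flows from explicit seeds.

## Known limitations

* Behavior under extreme tachycardia is unvalidated (the search window
  itself degenerates when 40% of RR falls before J + 25 ms).
* No signal-quality scoring: poor-quality records should be excluded
  upstream.
* QRS onset/offset must be supplied; the built-in detector only
  provides alignment triggers.
* The bundled relevance tree is trained on synthetic geometry; for
  clinical use it should be retrained on adjudicated slurs
  (`train_relevance_tree()` + `write_relevance_tree()`), which is
  exactly how it is meant to be replaced.
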