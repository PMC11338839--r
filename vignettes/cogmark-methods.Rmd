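---
title: "Computing cognitive-effort and tension indices from single-channel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing cognitive-effort and tension indices from single-channel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmark)
```

## The problem

Performance on a bedside cognitive screen such as the Montreal Cognitive
Assessment (MoCA) reflects more than cognitive ability: a patient who
invests too little effort scores below their true ability, and a patient
under too much test-related stress may do the same. `cogmark` implements
two per-segment markers computed from one frontal EEG channel recorded
while the test is administered, so that the examiner can ask whether the
score was obtained under effective effort and ordinary alertness:

* the **Cognitive Effort Index (CEI)** tracks the variability of delta-band
  (1--4 Hz) activity at the sub-second scale, a surrogate for the dynamics
  of sustained attention;
* the **Tension Index (TensI)** tracks high-beta (23--30 Hz) power relative
  to a running baseline drawn from periods of effective attention, a
  surrogate for alertness / stress effect.

Both are ratios of a single "power" primitive and are therefore invariant
to amplifier gain, which is what makes them practical for an uncalibrated
single-sticker frontal recording.

## The marker model

### Power primitive

The recording inside the annotated test window is cut into consecutive
10 s segments (a trailing partial segment is dropped). Power of a piece of
signal $x_1,\dots,x_n$ sampled at $f_s$ is the rectified integral

$$P = \frac{1}{f_s}\sum_i |x_i| \quad [\mu V\,s],$$

not the squared energy. $P$ is positively homogeneous of degree 1, so
every ratio built from it cancels the channel gain. CEI, a ratio of
like quantities, is unaffected by this choice of exponent; it matters only
for how strongly beta bursts move TensI.

### CEI

Each 10 s segment is band-passed to 1--4 Hz and split into 20 epochs of
500 ms. With epoch powers $P_1,\dots,P_{20}$,

$$\mathrm{CEI} = \frac{\sigma(P)}{\bar P},$$

where $\sigma$ is the **population** standard deviation (divide by 20):
the 20 epochs are the entire segment, not a sample from it, and this
convention makes a segment alternating between powers 1 and 3 land exactly
on CEI = 0.5. A ratio above 1 is treated as muscle/motion noise and the
segment is excluded ("no value"); an all-zero segment is excluded as flat.
The test-level summary **%CEIm** is the fraction of valid CEI points
inside the middle third $[1/3, 2/3]$ -- the band read as effective
attentional effort; points below it suggest too little effort, points
above it attention captured by something stressful. The interval is closed
on both ends (ties at exactly 1/3 or 2/3 are measure-zero on real data;
the choice is configurable). Excluded segments are not part of the CEI
sample and so do not enter the %CEIm denominator -- a segment with no
value cannot be classified.

### TensI

Each segment also gets a high-beta (23--30 Hz) power. Segments whose CEI
lies in the middle third are **baseline segments**; the baseline beta mean
is updated after every one of them. For segment $k$ with beta power $B_k$
and baseline mean $\bar B_{<k}$ over baseline segments strictly before it,

$$\mathrm{TensI}_k = \min\!\left(1, \frac{B_k / \bar B_{<k}}{2}\right).$$

Power equal to baseline gives exactly 0.5; twice the baseline (or more)
clamps to 1. Causality is strict: a segment's own power never enters the
baseline it is compared against, which is also what a real-time monitor
must do. Segments before the first baseline segment are undefined and are
not part of the TensI sample. Internally the baseline state is the pair
(count, running sum) with the mean exposed as sum/count -- algebraically
identical to updating the mean by $(n\bar B + v)/(n+1)$, but it lets the
incremental (streaming) path and the batch path produce bit-identical
values, which we verify. Noisy (CEI-excluded) segments still receive a
TensI value when a baseline exists -- only baseline membership is gated on
CEI -- with `tensi_config(skip_noisy = TRUE)` available for the stricter
reading. **%TensI-high** is the fraction of defined points strictly above
2/3.

### Filtering

The band filter is a 4th-order Butterworth run forward and backward
(zero phase) on each segment independently. Zero phase keeps epoch
boundaries from being smeared by group delay in offline analysis; per-
segment filtering means the series has no cross-segment state, so a
streaming replay one segment at a time reproduces batch output exactly.
For true sample-causal operation a linear-phase FIR of about 1 s is
available (`filter = "fir"`); its group delay shifts epoch boundaries by
half the filter length and moves individual CEI values by about 0.06
(median) on synthetic recordings, a discrepancy bounded by a test. One
numerical caveat worth knowing: at $f_s = 128$ Hz the delta band occupies
a narrow slice of the normalized axis, and the IIR recursion amplifies
double-precision rounding to about $10^{-7}$ relative; tests of linearity
and gain invariance use tolerances reflecting that conditioning rather
than the formal $10^{-16}$.

### Epoching at awkward sampling rates

The defining constants are 10 s segments and 20 epochs of 500 ms. At
sampling rates where `round(10 * fs)` is not divisible by 20 (e.g.
125 Hz), epoch boundaries are placed at `round(k * n / 20)`: always
exactly 20 epochs, each within one sample of 500 ms, partitioning the
segment with nothing dropped or padded. Sampling rates below 64 Hz are
rejected (the 23--30 Hz band would not be resolvable); 128 Hz is the
conventional export rate for the single-channel monitor this tool targets
and is the synthetic default.

## Cohort model and comparison machinery

A cohort table (one row per patient; see `cohort_schema()`) carries
pre/post MoCA totals and the seven standard subscores, pre/post HADS, and
the per-test marker summaries. Preoperative totals are stratified a priori
into lower (<= 20), intermediate (21--25) and higher (>= 26) ranges, and
perioperative change is categorized at 1/2/3-point thresholds (the
categories nest). `table1_counts()` produces the range-by-threshold
bookkeeping with integer percents (round half up, matching how such tables
are conventionally printed).

`run_stratified_comparisons()` mirrors the study design: within every
range x threshold cell it compares the decrease and increase groups with
the Mann--Whitney U test on the marker summaries (markers are bounded
fractions and visibly non-normal), Welch t-tests on age and HADS (Welch
rather than pooled because group variances differ visibly; pooled is a
flag), and paired t-tests on each subscore pre vs post within group.
Within-group pre-vs-post marker comparisons use the unpaired Mann--Whitney
by default -- a deliberate design choice to match the stated method even
though a paired Wilcoxon would be natural; `paired_markers = TRUE` gives
the paired variant. The Mann--Whitney uses the exact null distribution
when the pooled sample is at most 20 without ties, and the tie-corrected
normal approximation otherwise. No multiple-testing correction is applied:
raw per-comparison p-values are reported, as is conventional for this kind
of exploratory clinical table.

Any comparison where either group has fewer than five patients is flagged
`suppressed` (the display convention for the accompanying figures); rows
are kept so the consumer decides whether to hide them.

`quadrant_analysis()` implements the marker-interaction display: each
patient is a point (preoperative %CEIm, postoperative %TensI-high), the
medians are computed over the pooled decrease+increase groups, membership
in the upper-right quadrant is strict (> both medians), and group vs
quadrant occupancy is tested with the 1-df 2x2 chi-square without
continuity correction (the statistic then equals the closed-form
$(ad-bc)^2 N / $ margin-product formula, which a test checks). Fisher's
exact test is available for small tables.

## The synthetic generators

No EEG or per-patient data ship with the package, so both generators are
first-class, tested code; every claim in the test suite is demonstrated on
their output.

**EEG** (`generate_eeg()`): band-limited Gaussian noise carriers for delta
and high-beta, a pink 1/f broadband floor, and optional triangular
100 ms artifact spikes. Each carrier is amplitude-flattened (divided by
its smoothed analytic-signal envelope) before the controllable envelope is
applied. This is the one place the generator deliberately departs from
real EEG: raw band-limited noise has strong intrinsic envelope
fluctuations at the 500 ms scale, which would make the CEI of an
"unmodulated" recording broad and uncontrollable. Flattening makes the
stated control knobs true: `delta_mod_depth` (sinusoidal envelope depth)
moves the CEI essentially monotonically -- depth 0 concentrates CEI near
0.17, depth 0.9 centers it in the middle third, so deep modulation is how
tests hold the TensI baseline gate open -- and `beta_burst_gain` over
`burst_windows` moves TensI (a x4 burst clamps it to 1). Defaults
(delta 20 uV RMS, beta 5 uV RMS, pink floor 2 uV, 128 Hz) are plausible
magnitudes for a frontal surface channel. What passing tests on this
generator do **not** show: behavior under real blink morphology, frontalis
EMG, electrode pops, or nonstationary rhythms -- the markers deliberately
treat blink- and EMG-contaminated delta/beta content as informative rather
than separable, and no artifact decomposition is attempted.

**Cohorts** (`generate_cohort()`): exact patient counts per (range x
change) cell -- the default composition reproduces the package's reference
117-patient perioperative distribution -- with subscores drawn uniformly
among the arrangements summing to each total, truncated-normal markers on
[0, 1] (mean 0.5 for %CEIm, 0.3 for %TensI-high, SD 0.25 -- bounded scores
with interquartile ranges of the size seen in practice), age ~ N(65, 10)
years (an elective cardiac-surgery population), and HADS subscales
~ N(6, 4) truncated to 0--21. Group effects enter as additive shifts on
the decrease group's preoperative %CEIm and postoperative %TensI-high --
the two headline effect directions -- so a null cohort is shifts = 0.

## Calibration and power checks

The stochastic suite fixes all seeds. Null calibration draws 500 null
cohorts and checks each test's rejection rate at alpha = 0.05 against the
binomial 95% band around 0.05. The Mann--Whitney and t-tests are
calibrated at the study-condition group sizes (20 vs 45). The quadrant
chi-square is an asymptotic test: at 20 vs 45 its expected in-quadrant
cell count sits at about 5, the textbook boundary of the approximation's
validity, so its calibration check uses 30 vs 60 where the expected counts
comfortably satisfy the approximation's conditions; at smaller sizes the
Fisher option is the right tool. Effect recovery generates cohorts with a
+0.25 shift at 20 vs 45 and requires p < 0.05 in at least 80% of 200
replicates, and a fully separated configuration must make the quadrant
chi-square significant.

Problem sizes used throughout the suite -- 500 calibration replicates, 200
recovery replicates, synthetic recordings of 2--5 minutes -- were chosen
as the smallest sizes at which the binomial bands and power statements are
meaningful.

## Known limitations

* EDF support covers continuous EDF/EDF+C with 16-bit samples and
  `test_start`/`test_end` annotations; discontinuous (EDF+D) files and
  proprietary monitor exports are out of scope (convert to EDF or the
  two-column CSV first).
* The exclusion rule (SD/mean > 1) is the only artifact handling; there is
  no blink or EMG separation, by design.
* The markers' clinical meaning (effort, stress effect) is an
  interpretation layered on top of the computation; the package computes
  the indices and the comparison machinery, and assigns no diagnostic
  labels.
* The generator's amplitude-flattened carriers make marker control exact
  but idealized; power/calibration results transfer to real recordings
  only to the extent that real epoch-power variability behaves like the
  modeled envelopes.
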