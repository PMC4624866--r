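---
title: "Frequency-band-specific ALFF/fALFF analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-band-specific ALFF/fALFF analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Spontaneous low-frequency oscillations (LFO, roughly 0.01–0.1 Hz) of the
resting BOLD signal carry information about intrinsic brain activity, and
their amplitude is altered in a range of clinical conditions, including
chronic tinnitus. The LFO range is not homogeneous: it decomposes into
canonical sub-bands (slow-6 through slow-2), and group differences can be
confined to specific bands. This package implements the full analysis chain
for asking *whether and where amplitude abnormalities are frequency
specific*: band-restricted amplitude maps per subject, a voxelwise
group-by-band mixed ANOVA, Monte Carlo cluster-extent correction, and
correlation of regional amplitudes with clinical scores — together with a
synthetic cohort generator that makes every stage testable against planted
ground truth.

## Amplitude measures

For a voxel time series $x(t)$ sampled at TR $= 2$ s ($N$ volumes after
discarding), the discrete Fourier transform $X_k$ gives the one-sided
amplitude spectrum

$$a_k = \frac{2\,|X_k|}{N}, \qquad 0 < k < N/2,$$

so that a pure sinusoid of amplitude $A$ centred on bin $k$ reads off as
$a_k = A$. The DC and Nyquist bins, which have no conjugate partner, are
stored unscaled by the factor 2 and flagged. "Square root of the power
spectrum" conventions differ only by a fixed positive scale, which cancels
in both normalized ALFF and fALFF; the sinusoid-calibrated convention was
chosen because it makes unit tests directly interpretable.

* **ALFF** of band $B$: the arithmetic mean of $a_k$ over bins whose centre
  frequency lies in $B$ (DC always excluded). For group analysis each
  subject's map is divided by its in-mask mean ("global-mean
  normalization"), removing between-subject scale differences.
* **fALFF** of band $B$: $\sum_{k \in B} a_k \big/ \sum_{k > 0} a_k$, the
  fraction of total detectable amplitude (up to the Nyquist frequency,
  0.25 Hz) contributed by the band. Voxels with zero total amplitude are
  flagged `NA` rather than raising an error.

The canonical bands are slow-6 $[0, 0.01)$, slow-5 $[0.01, 0.027)$, slow-4
$[0.027, 0.073)$, slow-3 $[0.073, 0.198)$ and slow-2 $[0.198, 0.25]$ Hz.
Intervals are half-open with the upper band closed at Nyquist, so the five
bands partition $(0, 0.25]$ exactly and $\sum_B \text{fALFF}_B = 1$ for
every voxel — a property the test suite checks to $10^{-9}$. A bin centre
exactly on an edge (e.g. 0.027 Hz) belongs to the *higher* band. Slow-4 and
slow-5 are the bands carried into group analysis; slow-6, slow-3 and slow-2
are computed but conventionally discarded as drift-, white-matter- and
physiological-noise-dominated respectively.

## Preprocessing: why there is no 0.01–0.08 Hz pre-filter

Classic single-band ALFF pipelines band-pass filter (0.01–0.08 Hz) before
the FFT. A band-*specific* analysis cannot do that: the filter would
truncate band edges and, worse, destroy the slow-3/slow-2 content that the
fALFF denominator requires. This package therefore restricts to bands *in
the spectral domain* — each band's ALFF integrates only its own bins, and
the fALFF denominator uses the full detrended spectrum. This is the
standard resolution of a known internal tension in band-specific pipelines,
and it is the single most consequential preprocessing decision in the
package, so it is stated here prominently. Retained preprocessing stages
are linear detrending (exact OLS line removal per voxel) and isotropic
Gaussian spatial smoothing (FWHM 6 mm by default,
$\sigma = \text{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units, unit-sum
kernel, replicate-edge boundary, applied *before* spectral analysis,
mirroring the usual preprocessing order). Quality control discards the
first 10 volumes (240 → 230 by default) and excludes any run whose
realignment trace exceeds 2.0 mm translation or 2.0° rotation on any single
axis at any volume — a strict `>`, so a parameter exactly at the limit
keeps the run.

## The 2 × 2 mixed ANOVA

With two within-subject levels (slow-4, slow-5) and two groups, the
split-plot ANOVA collapses exactly into t-tests on derived scores. Writing
$m_i = (y^{(4)}_i + y^{(5)}_i)/2$ and $d_i = y^{(4)}_i - y^{(5)}_i$:

* group main effect: pooled-variance two-sample $t$ on $\{m_i\}$;
* group × band interaction: pooled-variance two-sample $t$ on $\{d_i\}$;
* band main effect: $t$ for the *unweighted* mean of the two group means of
  $d$ against zero, $\mathrm{SE} = s_d\sqrt{(1/n_1 + 1/n_2)/4}$,

all on $n_1 + n_2 - 2$ degrees of freedom. $t^2$ equals the classical
split-plot $F$ for every effect — verified in the tests against an
independently coded `stats::aov` split-plot oracle on hundreds of random
balanced designs. For unbalanced groups the band effect weights the two
groups equally (the Type-III convention); signed $t$ maps are reported
(band = slow-4 − slow-5, group and interaction = group 1 − group 2), with
$F$ recoverable as $t^2$. Voxels with zero pooled variance are flagged
degenerate and masked `NA` rather than erroring, since a single dead voxel
should not abort a whole-brain analysis.

## Monte Carlo cluster-extent correction

Voxel-level thresholding at $p < 0.05$ leaves far too many false positives;
the correction retains only clusters larger than a null-calibrated extent.
The AlphaSim-style estimate simulates, per iteration, a field of
independent standard Gaussian noise on the mask's bounding box, smooths it
at the analysis smoothness (6 mm — the applied smoothing kernel, since the
synthetic data's intrinsic smoothness is exactly the applied kernel; a
residual-based smoothness estimator is a natural extension hook for real
data), standardizes within the mask, thresholds two-tailed at the voxel
$p$, and records the maximum cluster size across both signs (clusters are
formed separately within each sign, matching the separate
increase/decrease maps of group studies). The extent threshold is the
smallest $k$ with $\hat P(\max \ge k) \le \alpha$. Cluster formation uses
26-connectivity by default (the most inclusive standard choice;
configurable to 6 or 18). When a threshold is instead quoted in mm³ with a
strict ">" (e.g. "cluster size > 3591 mm³" at 27 mm³ voxels),
`cluster_threshold_from_mm3()` converts it to the smallest strictly
exceeding voxel count (134).

## The synthetic cohort generator

Because the package is exercised end-to-end without patient data, the
generator is first-class, tested code. Each subject's run is

$$\text{baseline} + \text{linear drift} + \text{white noise} +
  \text{planted band-limited signal in ROI voxels},$$

with the band-limited signal built by spectrally masking white noise
(zeroing all FFT bins outside the band) and rescaling to an exact sample
SD — keeping the broadband character of BOLD LFO rather than a sum of a few
sinusoids, and giving construction-exact spectral purity. Group structure
enters through per-ROI amplitude multipliers (equal multipliers in a band
in both groups = a pure band effect; unequal in one band = an interaction).
Each subject's amplitude additionally carries log-normal jitter (SD 0.3 on
the log scale) — without between-subject amplitude variation there would be
nothing for clinical covariates to correlate with. Covariates (THQ,
duration) are generated from the *noiseless* planted amplitudes via
$y = r\,z(a) + \sqrt{1 - r^2}\,e$, so recovery error downstream reflects
only the measurement pipeline, and are then mapped to their natural scales
(THQ 43.5 ± 21.3 clipped to 0–100, duration in months floored at 1;
clipping is rare and attenuates the planted correlation only marginally).
Motion traces are smoothed Gaussian walks scaled to stay below 0.8 mm/°;
designated outliers (round(fraction × n) per group, the first k after a
seeded shuffle) receive a smooth bump driving one axis past the exclusion
limit. All randomness flows from one master seed through named sub-streams
(per subject, per stage), so cohorts are byte-identical across runs and any
subject's run can be regenerated on demand — large cohorts stream through
the pipeline one subject at a time instead of holding ~1 GB of 4D data.

Default conditions: 240 volumes at TR = 2 s on a 24 × 28 × 24 grid of 3 mm
voxels — full method coverage at roughly an eighth of MNI-grid cost —
noise SD 1, drift-slope SD 0.005 per volume (a slow trend comparable in
total excursion to the noise SD over a run, removed exactly by
detrending), planted base amplitudes of 1 with group multipliers 1.4–1.5.
These choices put planted effects at realistic detectability (per-voxel
interaction $t \approx 4$–5 at $n = 20$/group by a Rayleigh-bin power
calculation) rather than at ceiling. What the generator does *not*
emulate: slice-timing offsets, realignment residuals, field inhomogeneity,
cardiac/respiratory waveforms, spatially correlated noise, or non-Gaussian
artefacts — so passing tests demonstrate correctness of the measures and
inference machinery under a known generative model, not robustness to real
scanner physics.

## Numerical choices and degenerate inputs

* Band membership comparisons carry a $10^{-12}$ Hz guard so bin centres
  equal to an edge up to floating-point rounding land on the correct side.
* The DC bin is excluded everywhere (series are detrended, so DC ≈ 0
  regardless); whether a literal "0–0.25 Hz" denominator includes DC is
  moot after detrending, and excluding it keeps fALFF well defined.
* Connected components use vectorised minimum-label propagation over a
  precomputed foreground adjacency; labels are deterministic (scan order).
* All-constant runs error at normalization ("degenerate input"); empty
  cluster reports are valid results, not errors; an unattainable AlphaSim
  alpha raises an explicit error.
* Voxel indices are 0-based in reports; mm coordinates are
  origin + index × voxel size.

## Problem sizes

The test suite and the acceptance script exercise: exact spectral oracles
at $N = 100$–230; ANOVA oracle equivalence on hundreds of random designs;
null calibration and effect recovery on 20 + 20-subject cohorts on the
24 × 28 × 24 grid; AlphaSim with 1000 iterations; family-wise error
measured over 200 simulated null statistic maps; and correlation recovery
at $n = 39$ patients over 20 seeds on a reduced grid (the coupling
machinery is grid-size independent, so a 12 × 12 × 10 grid exercises it
fully). These sizes give stable Monte Carlo estimates while keeping a full
run at desk scale.

## Known limitations

* The Monte Carlo extent threshold is calibrated against its own null model
  — smoothed *Gaussian* fields — and is exactly calibrated there (measured
  family-wise rate 0.05 over 200 fresh null statistic maps). Applied to
  t-fields built from real voxelwise ANOVAs at moderate df, it is
  anticonservative at lenient voxel thresholds: with df = 38 and voxel
  p < 0.05 we measure a per-effect family-wise cluster rate near 0.2,
  because the spatially smooth variance-estimate field inflates excursions
  of the t-field — the well-documented failure mode of cluster-extent
  correction at lenient cluster-forming thresholds. Users wanting strict
  FWER control on real group maps should use a stricter voxel p (0.001) or
  permutation inference; this package reports the classical procedure as
  practised.
* Global-mean normalization couples voxels: a genuine regional amplitude
  surplus in one group slightly *depresses* that group's normalized values
  everywhere else, which can surface as spurious-looking opposite-signed
  clusters far from the true effect. This is a property of the measure
  itself, visible in the synthetic runs precisely because ground truth is
  known; fALFF does not share it (its denominator is per-voxel).
* The band main effect uses the equal-group-weight convention; software
  using Type-I sums of squares will differ for unbalanced designs (the
  interaction and group effects agree regardless).
* Simulation smoothness equals the applied smoothing kernel; for real data
  with intrinsic smoothness, plug a residual-based estimate into
  `alphasim_threshold()`'s `fwhm_mm`.
* No anatomical labelling of cluster peaks; reports give indices and mm
  coordinates only.
* No nonparametric correlations, no GRF or permutation cluster inference,
  and no polynomial detrending beyond linear — deliberately out of scope.
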