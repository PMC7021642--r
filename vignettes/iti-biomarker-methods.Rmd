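---
title: "Methods: the inter-train-interval EEG biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the inter-train-interval EEG biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itimarker)
```

## The scientific problem

High-frequency repetitive transcranial magnetic stimulation (rTMS) of the
right prefrontal cortex is a candidate treatment for adult ADHD. A central
question for any such treatment is whether early electrophysiology predicts
who will benefit. `itimarker` implements an analysis pipeline for this
question built around a spectral biomarker computed from EEG recorded
*during* the first treatment session: in the quiet inter-train intervals
(ITIs) between 18 Hz stimulation trains, the ratio of low-gamma (30--40 Hz)
to alpha (8--14.5 Hz) band power in the first post-train segment (1--3 s
after each train ends). The rationale is asymmetric in time and physiology:
low-gamma activity reflects the cortical response elicited by the train and
decays over seconds, while alpha power behaves like a stable subject trait.
Their ratio therefore captures the individual's acute cortical
responsiveness normalized by their tonic state.

The pipeline covers every analysis stage such a trial needs:

* a fixed 64-channel 10-10 montage with homologous left/right pairs and a
  scalp adjacency graph (`standard_montage()`);
* ITI segmentation, TEP epoching, average-reference (AVR) and
  spherical-spline current-source-density (CSD) transforms;
* Welch spectra, band powers, the marker, whole-scalp correlation maps with
  cluster-based Monte-Carlo permutation correction, inter-hemispheric
  partial-correlation models with FDR control, ITI power dynamics, and
  rest-vs-treatment correlations;
* TEP component (N45, P60, N75, N100, P180) amplitudes and pre/post x
  group contrasts;
* the clinical outcome layer: two-way mixed ANOVA, partial eta squared,
  Cohen's d, the 25%-reduction responder rule and Fisher exact contrasts.

Because no subject-level data are distributed with the trial this design
follows, every stage is validated on synthetic cohorts with *planted*,
ground-truthed effects.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions: three arms (Real, active
control, Sham) of 15/14/14 subjects; treatment sessions of 40 trains, 2 s
long at 18 Hz, separated by 20 s inter-train intervals (1440 pulses per
session); TEP sessions of 50 single pulses 5 s apart; 120 s of eyes-closed
rest; 500 Hz sampling.

Each subject draws latent traits: a log-normal alpha source amplitude
(median 15 uV), a log-normal evoked low-gamma amplitude (median 10 uV), a
smaller ongoing low-gamma amplitude (median 1.4 uV) present in all
sessions, an exponential post-train gamma decay constant (3 s), a left-right
alpha asymmetry coefficient (SD 0.15, expressed as hemisphere weights
$1 \pm a/2$), and a TEP gain. Signals are built from:

* per-channel 1/f background noise (3 uV RMS), shaped by a compiled IIR
  filter;
* band-limited alpha and ongoing-gamma activity modelled as a fixed
  low-rank mixture: eight latent unit-RMS band sources projected through a
  fixed random mixing matrix with unit-norm rows. Channels are therefore
  only *partially* coherent -- as scalp oscillations are -- so the average
  reference does not cancel the activity, while each channel's RMS equals
  its trait-determined gain exactly. The mixing matrix is deterministic and
  shared by all subjects and sessions, playing the role of fixed source
  geometry;
* an evoked 30--40 Hz component, coherent across channels, whose envelope
  after each train is $g\,e^{-t/\tau}$ and whose topography is a Gaussian
  on the sphere centred at FC4 (width 0.6 rad), scaled per arm (Real 1,
  active control 0.5, Sham 0);
* saturated, flagged samples during trains (the analysis windows avoid
  them by construction, so only the avoidance logic needs exercising --
  realistic TMS artifact shapes are deliberately out of scope);
* TEP sessions: a stereotyped component template (Gaussian deflections at
  45/60/75/100/180 ms with polarities $-,+,-,-,+$) peaked near F4, plus a
  flagged artifact burst at $-2$..$10$ ms around each pulse.

The signal-to-floor ratios (evoked gamma well above the ongoing gamma and
the 1/f floor inside 30--40 Hz; alpha far above the floor inside
8--14.5 Hz) were chosen so that first-segment spectra are dominated by the
planted oscillations, mirroring the clean ITI spectra the analysis assumes;
the ongoing gamma is kept above the noise floor so that, in the Sham arm,
ITI gamma remains correlated with resting gamma across subjects while in
the Real arm the evoked response overwrites that correlation.

### The planted clinical coupling

Improvement (pre minus post total-symptom t-score) is generated as
$$\Delta_i = \beta_{0,g(i)} + \beta_1\,(m_i - \mu_m) + \beta_2\,a_i + \varepsilon_i,$$
where $m_i$ is the subject's *noise-free* first-segment log gamma/alpha
marker at FC4 -- including the decay-envelope integral over the 1--3 s
window and the asymmetry weighting the generator itself induces -- and
$a_i$ the asymmetry trait. Control arms receive their own $\beta_0$ with
matched residual noise ($\beta_1 = \beta_2 = 0$). The per-arm means default
to 8.3/2.8/1.9 t-score points, mirroring the arm structure the design
targets; the residual SD defaults to 7.

Defining the coupling on the noise-free marker gives `planted_r` an exact
meaning: with $\beta_2 = 0$,
$\beta_1 = r\,\sigma_\varepsilon / (\sigma_m \sqrt{1 - r^2})$, with
$\sigma_m$ computed once from the trait-distribution moments by a large
fixed-seed Monte Carlo (`calibrate_beta1()`). A population check at
$n = 20000$ recovers the planted correlation to the third decimal. Because
the measured marker adds spectral-estimation noise and band-power floors on
top of $m_i$, the *measured* correlation is mildly attenuated (by roughly
2--3% at the default signal-to-noise settings); recovery tests account for
this with their stated tolerances rather than by inflating the planted
effect.

With the spec of the clinical model above, a planted coupling necessarily
makes the Real arm's total improvement variance larger than the control
arms' (the marker term adds variance on top of the shared residual). This
is why Cohen's d against Sham is not a calibrated quantity of the
generator, and why the pipeline reports it from data rather than asserting
a target value for it.

### What the generator does not emulate

Volume conduction through a realistic head model, ocular and muscle
artifacts, realistic TMS artifact decay shapes, electrode drift, and any
nonstationarity of alpha beyond sampling noise. Passing tests therefore
demonstrate that the *analysis machinery* is correct and calibrated --
unbiased under the null, able to recover planted effects of realistic size
-- not that real EEG satisfies the generator's assumptions.

## Preprocessing choices

**ITI segmentation.** Epochs of 2 s are cut from each inter-train interval
starting 1 s after the train ends and stopping 5 s before the next train
begins; with the protocol's 20 s intervals this yields exactly 7 segments,
indexed 1..7. "20 s apart" is read as 20 s from train end to next train
onset -- the only reading that yields 7 segments
($1 + 7 \times 2 + 5 = 20$). The final interval is bounded by the end of
the recording (there is no next train to anticipate), and the segmentation
operates on actual event times, so recordings with other spacings work
unchanged. Epochs overlapping artifact-flagged samples are dropped; an
amplitude-threshold rejector (default 100 uV) stands in for a full
artifact pipeline.

**Referencing.** Both AVR and CSD are supported and reported separately.
CSD is implemented as a Perrin-style spherical-spline surface Laplacian
with stiffness $m = 4$, regularization $\lambda = 10^{-5}$ and 50 Legendre
terms -- the community defaults -- since the method is named but not
specified in this literature. CSD output is reference-free: raw and
average-referenced input give identical results, and a spatially constant
potential maps to zero; both properties are tested, as is the commutation
of referencing with epoch selection.

**TEP epochs.** One epoch per pulse in a $\pm 0.5$ s window; samples in the
$-2$..$10$ ms artifact window are replaced by linear interpolation between
the window edges and excluded from amplitude statistics; the baseline is
$-200$..$-10$ ms. The artifact window clears the earliest component TOI
(35 ms) by a wide margin. Component TOIs default to N45 [35, 55], P60
[55, 70], N75 [70, 90], N100 [90, 130], P180 [150, 250] ms; only the N75
range has a conventional anchor (60--90 ms), the rest are symmetric
heuristics around the canonical latencies, all user-overridable. Mean
amplitude over the TOI is the default statistic, with peak amplitude as an
option.

## Spectral and statistical choices

**Spectra.** Welch's method with 1 s Hann segments at 50% overlap on the
2 s epochs gives 1 Hz resolution; band powers integrate the PSD by the
trapezoid rule with interpolation at band edges (so the 14.5 Hz alpha edge
is handled exactly). Band power is additive over disjoint bands and
satisfies Parseval against time-domain variance; both are tested.

**The marker's direction.** The marker is low-gamma divided by alpha. The
component correlations that motivate it (gamma positively, alpha negatively
correlated with improvement) only produce a positively-correlated composite
in this direction; a configuration switch restores the inverse convention.
Correlations involving the marker are computed on log values by default --
power ratios are right-skewed -- with a flag for the linear scale. Power
is averaged across the first-segment epochs before the ratio is taken
(ratio of means); a ratio-of-epochs option exists.

**Cluster-based permutation.** Per-channel statistics (Pearson r against a
covariate, pooled-variance independent t, paired t, or one-way F) are
thresholded at the two-tailed 5% critical value; suprathreshold channels
are clustered by spatial adjacency separately per sign; cluster mass is
the sum of member statistics; the null is the maximum absolute cluster
mass over random relabelings, and $p = (1 + \#\{null \ge obs\})/(1 + B)$,
which cannot return zero. Exhaustive enumeration replaces sampling for
small designs and is verified against an independent brute-force oracle.
Zero-variance channels are excluded with a warning. Under the global null
the family-wise rate of any significant cluster is calibrated (tested at
200 replicates).

**Inter-hemispheric balance.** For each of the 54 lateral channels, the
partial correlation between the (log) marker at that channel and
improvement, controlling for the homologous contralateral channel, using
the first-order formula, a parametric two-tailed t test on $n - 3$ degrees
of freedom, and Benjamini-Hochberg FDR over the 54 channels. A restricted
variant targets the 8 prefrontal channels (FC4, FC2, F4, F2 and left
homologues) for the resting-alpha model, with FDR over that set. The
partial correlation is verified against a residual-regression oracle to
1e-10, and the table is antisymmetric-consistent under a left-right data
swap.

**Mixed ANOVA.** The clinical pre/post by group analysis uses the
classical balanced sums-of-squares decomposition (between: group,
subjects-within-groups; within: time, time x group, time x subject error),
verified to match `aov()` with `Error(subject)` strata exactly; post-hoc
per-group pre-vs-post contrasts are tested against the within error term
with Bonferroni correction. Unequal group sizes are handled by the
sequential between-group sums of squares. The ITI-dynamics analysis is a
two-factor within-subject ANOVA (segment 2..7 by band) on
segment-1-normalized power via `aov()` error strata; its degrees of
freedom are derived from the design and reported as such.

**Fisher exact test.** Two-sided by the probability-mass rule (the
convention of `fisher.test`), which reproduces the marginal p = 0.08 for a
6/15 vs 1/14 responder split; the odds ratio reported is the sample
$ad/bc$.

## Numerical and degenerate-input conventions

Zero alpha power is an error in marker computation (degenerate input), as
are constant improvement vectors, collinear partial-correlation controls,
baselines overlapping the TEP artifact window, and adjacency thresholds
that disconnect the scalp graph. Permutation seeds are mandatory and
recorded in every result object; the cohort seed determines every
recording through per-subject derived seeds, so `cohort_session()` can
regenerate any session on demand -- large cohorts are processed streaming
with flat memory.

## Problem sizes used by the validation suites

The generator's defaults are the full protocol (500 Hz, 40 trains, 50
pulses, arms of 15/14/14). The simulation-heavy validation suites run at
reduced sizes chosen to keep the whole suite in the tens of minutes on a
single core while leaving the tested effects overwhelmingly detectable:
200 Hz sampling; 8--20 trains per treatment session and 25 TEP pulses; 5
replicates for the dynamics and TEP power checks (the planted effects give
per-replicate detection probabilities near 1); 200--400 null replicates
for calibration checks; recovery cohorts of 100--400 subjects. The
acceptance script reports, among other quantities, the FC4
marker-improvement correlation recovered from a 400-subject cohort with a
planted coupling of 0.85.

## Known limitations

* The generator's alpha topography is spatially uniform up to the
  asymmetry weighting; real alpha is posterior-dominant. Whole-scalp maps
  from synthetic data are therefore more homogeneous than real ones, and
  cluster extents are not comparable to published cluster sizes.
* The clinical model's residual-noise semantics (shared residual SD,
  coupling variance added on top in the Real arm) make arm SDs unequal
  when a coupling is planted; standardized effect sizes against control
  arms depend on this choice.
* CSD on 64 channels sharpens but cannot localize; no source modelling is
  attempted.
* The EDF interchange format is not read or written; cohorts persist as
  RDS session files with CSV/JSON sidecars, and the montage as a
  plain-text table.
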