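---
title: "EEG complexity analysis with eegentropy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG complexity analysis with eegentropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegentropy)
```

## The scientific problem

Cognitive impairment in schizophrenia has repeatedly been linked to altered
*complexity* of the electroencephalogram, but studies disagree on the
direction of the alteration. One resolution is that the deficit subtype
(dominated by primary negative symptoms) and the non-deficit subtype
(dominated by positive symptoms) change EEG complexity in opposite
directions, and that the change is band- and region-specific. Testing that
idea requires a pipeline that (i) quantifies complexity with sample entropy
and multiscale entropy, (ii) conditions multichannel EEG the same way for
every subject, (iii) compares three groups per electrode and per scalp
region, and (iv) relates band-limited complexity to working-memory task
performance. `eegentropy` implements that pipeline, together with a
synthetic cohort generator that makes every stage testable without clinical
recordings.

## Entropy estimators

**Sample entropy.** For a series $\{x(i)\}_{i=1}^N$, templates of length $m$
are $X(i) = (x(i), \ldots, x(i+m-1))$, compared under the Chebyshev distance
$d(X(i), X(j)) = \max_k |x(i+k) - x(j+k)|$. With tolerance $r$,

$$\mathrm{SampEn}(m, r) = -\ln \frac{A}{B},$$

where $B$ counts ordered template pairs ($i \neq j$) of length $m$ within
$r$ and $A$ the subset that still match at length $m+1$. Self-matches are
excluded. Both counts run over the same start-index range $1..N-m$, so the
pair sets nest, $A \le B$, and the estimate is never negative. When $A$ or
$B$ is zero the estimate is *undefined* and propagated as `NA` — never as
infinity — and skipped (with the skip count visible in the curve) by every
aggregate downstream.

**Tolerance.** $r$ = `r_coeff` × SD of the series, default `r_coeff` = 0.15
with $m = 2$ — field-standard settings for EEG sample entropy; both are
exposed in `entropy_params()`. A machine-epsilon floor on $r$ makes constant
series return 0 (every template matches) rather than failing on $r = 0$.

**Multiscale entropy.** The series is coarse-grained by non-overlapping
mean smoothing: scale $\tau$ replaces the series by
$y_j = \tau^{-1}\sum_{i=(j-1)\tau+1}^{j\tau} x_i$, $j = 1..\lfloor N/\tau
\rfloor$, and SampEn is recomputed per scale, $\tau = 1..20$ by default.
Under the default tolerance policy (`fixed_from_original`) the absolute $r$
is computed once from the scale-1 series and reused at every scale, the
canonical procedure: recomputing $r$ per scale (available as `per_scale`)
would mask the variance reduction that coarse-graining causes and flatten
the white-noise curve. Group statistics use the arithmetic mean of the
curve over scales 10–20 (configurable), the coarse range where long-range
temporal structure dominates and where case-control differences in this
design are expected.

The template-matching inner loop is compiled (Rcpp); at $N = 20000$ a full
20-scale curve takes a few seconds, which is what makes the
simulation-based checks below affordable.

## Preprocessing chain

The conditioning chain mirrors standard ERP-lab practice: common-average
re-referencing; zero-phase band-pass 0.1–40 Hz (4th-order Butterworth run
forward and backward — entropy estimates are sensitive to phase distortion,
so zero phase is a requirement, not a nicety); polyphase resampling to
500 Hz; band extraction with conventional edges α = 8–13 Hz and
β = 13–30 Hz (configurable; the source study does not state its edges).

**Epoching.** Resting recordings are cut into consecutive non-overlapping
10 s windows between 10 s and 180 s, each baseline-corrected by the mean of
the preceding 500 ms. Task recordings are cut −200..+3000 ms around each
stimulus onset with the −200..0 ms mean as baseline. All windows are
half-open sample intervals `[start, end)` with ms→sample conversion rounded
to the nearest sample; events whose window leaves the recording are dropped
and counted.

**Artifact rules.** Four amplitude rules mark (never delete) epochs:
a first-difference jump > 50 µV between adjacent samples; peak-to-peak
range > 200 µV within any sliding 200 ms window; whole-epoch max−min
> 100 µV; and a flatline rule that fires when some channel stays below
0.5 µV range in *every* sliding 100 ms window. The "±50 µV" phrasing of
such rules is read as a symmetric bound on the signed first difference,
i.e. an absolute threshold; the flatline rule requires flatness everywhere
because a single quiet window is physiological, a dead channel is not.
Sliding windows advance sample by sample (the non-overlapping reading of
"within 200 ms" would miss straddling artifacts). Note that under these
defaults any peak-to-peak violation (> 200 µV) necessarily also violates
the 100 µV whole-epoch range rule; attribution is therefore reported per
rule rather than as a single label. Subjects enter the statistics only if
strictly more than 70 % of their trials survive ("more than" makes the
boundary strict: 112/160 is excluded, 120/160 included). Ocular/EMG ICA
cleaning is out of scope: the pipeline expects pre-cleaned input and
implements only the amplitude rules.

## Synthetic cohort generator

No clinical recordings are distributed with the study this design follows,
so the generator is the package's substitute subject pool, built to make
band-limited entropy and its behavioral coupling *controllable*:

* **Background**: spectrally synthesized $1/f$ noise (exponent per group,
  default 1), 6 µV RMS.
* **Band components**: one narrowband component per band (α: 10 ± 2 Hz,
  6 µV; β: 20 ± 5 Hz, 4 µV). Each interpolates, through a per-subject
  *regularity* parameter in [0, 1], between band-filtered noise
  (regularity 0, high SampEn) and a fixed-phase sinusoid (regularity 1,
  low SampEn). Regularity is the single latent dial: group shifts and
  subject-level variance are expressed on it.
* **Broadband complexity**: a separate regularity mixes the *slow*
  (< 8 Hz) part of the background with a harmonic comb confined below the
  alpha band. Confinement matters: the coarse-scale multiscale-entropy
  aggregate is dominated by slow dynamics, so this dial moves it, while
  the α/β in-band background stays untouched and band entropy remains
  uncontaminated by broadband manipulations.
* **Latents and shifts**: each subject draws standardized latent entropy
  scores $z$ (one per band plus broadband). Group/state/region effects are
  standardized shifts $d$ added to $z$; regularity is
  `base_regularity − regularity_sd · (z + d)`, so higher latent entropy
  means lower regularity. Defaults: base 0.55, between-subject SD 0.12.
* **Behavior**: per condition, a latent performance score
  $s = \text{group shift} + \text{condition shift} + \sum_b \rho_b z_b +
  \sqrt{1 - \sum_b \rho_b^2}\,\varepsilon$ feeds a logistic accuracy link
  $\mathrm{ACC} = \mathrm{plogis}(2.2 + 0.7 s)$ and a log-normal reaction
  time $\mathrm{RT} = 0.8\, e^{-0.3 s}$ s (median 0.8 s, σ = 0.3). The
  performance ratio ACC/RT is then a monotone function of $s$, so the
  designed correlations $\rho_b$ between latent band entropy and
  performance hold in expectation without further noise injection.
* **Amplitudes** were chosen so clean synthetic EEG sits near a realistic
  10 µV total RMS; that keeps artifact-free epochs clear of the 100 µV
  whole-epoch range rule by construction.

The default design tables (`default_entropy_shift()`,
`default_behavior_coupling()`) encode the three-group study pattern this
package targets: resting α entropy reduced occipitally in both patient
groups (d ≈ −0.6); task-state broadband complexity reduced centrally in
the deficit group and elevated everywhere in the non-deficit group; task
β entropy elevated parietally in the deficit group and in all regions
(d 0.49–0.83) in the non-deficit group; and coupling coefficients of
±0.33–0.49 between band entropy and performance that differ in sign by
group and difficulty. Default sizes are 30/19/19 subjects, 62 scalp
channels at 1000 Hz, 3-minute resting runs and 80 trials per set-size
condition.

**What the generator does not emulate**: volume conduction and channel
covariance, ERP waveform morphology, eye/muscle artifacts, non-stationary
state changes. Passing tests therefore demonstrate that the *pipeline*
recovers what the generative model puts in — not that the model is a
faithful simulator of patient EEG. The only distributional facts the
source study fixes are spectral shape and the entropy/coupling ordering,
and those are exactly what the generator controls.

**Determinism.** One master seed; per-subject streams derived by a stable
integer hash of (seed, subject index). Identical design ⇒ bit-identical
cohort; latents, events and behavior are drawn before the signals, so the
cheap `signals = FALSE` mode reproduces them exactly.

## Statistics layer

Levene's check (one-way ANOVA on absolute deviations from group means),
one-way between-subject ANOVA with partial eta squared
$SS_b/(SS_b+SS_w)$, Bonferroni pairwise pooled-variance t-tests (two-sided,
p × number of pairs, capped at 1 — the conventional reading even where
source tables look one-tailed) with pooled-SD Cohen's d, and a split-plot
two-way ANOVA for group × condition with subject-level error strata. With
only two within-subject levels sphericity is automatic, so no correction
is applied. A note on degrees of freedom: studies that report
group-by-condition ANOVAs with error df near the number of *observations*
have treated repeated measurements as independent; this package reports
the proper split-plot df (error df = subjects − groups for the between
effect). Entropy–behavior association is Pearson's r with the two-sided
t-test, per electrode (uncorrected across electrodes, flagged as such in
the output metadata — matching the per-electrode significance maps such
studies print) and as a headline per group × band × condition value using
each subject's all-electrode mean band entropy, the natural summary when
the source shows one scatter point per subject. Undefined entropy values
are dropped pairwise, never imputed.

Epoch-to-subject reduction computes entropy per epoch and averages across
retained epochs rather than concatenating epochs, because concatenation
splices unrelated samples into template windows at the boundaries.

## Validation scale and numerical choices

Simulation-based validation (direction recovery, calibration, determinism)
runs on `validation_design()`: 8 channels (two per scalp region), 100 Hz,
40 s resting, 6 trials per condition — while keeping the full group sizes
(30/19/19) and every designed effect size and coupling. Two channels per
region, not one: common-average re-referencing mixes a 1/C fraction of
every channel into each channel, so with very few channels
region-specific group shifts are diluted (the own-signal power fraction
after re-referencing is roughly (C−1)/C); at the full 62-channel montage
the dilution is negligible, and 8 channels keeps it modest while staying
cheap.
These problem sizes are the package's chosen compromise between replicate
count and per-replicate cost; at this scale the latent-to-measured
fidelity (correlation between a subject's latent band score and the
pipeline's estimate) is ≈ 0.98, so recovery rates are dominated by
the designed effect sizes at the designed n, as they should be. The
companion `validation_config()` aggregates a 10-scale MSE curve over
scales 5–10, the coarse half, mirroring the role of the 10–20 range at
full scale.

A deliberate consequence of the designed effect sizes: with d ≈ 0.5–0.8
and |ρ| ≈ 0.33–0.49 at n = (30, 19, 19), individual signs are recovered
with probability ≈ 0.92–0.99 per replicate, but the *joint* event (all
seven signs at once) cannot exceed ≈ 0.75 even for an error-free
pipeline. Recovery is therefore asserted per sign (each ≥ 80 % of
replicates), which is the claim the study conditions can support.

Other numerical choices: zero-SD series get a machine-epsilon tolerance
floor (SampEn 0); undefined entropy propagates as `NA` and aggregates
skip it; resampling conforms output length to `round(n · target/rate)`;
run manifests omit wall-clock timestamps unless requested so that
identical runs are byte-identical; all output tables are plain TSV.

## Known limitations

* No EDF reader: input is the delimited matrix + YAML sidecar interchange
  format (or in-memory recordings).
* No ICA, bad-channel interpolation, or reference schemes beyond the
  common average.
* Per-electrode correlation maps are uncorrected for multiplicity, by
  design parity with the analyses they mirror.
* The generator's realism ends at spectral shape and entropy ordering;
  absolute entropy levels are not calibrated to any clinical population.
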