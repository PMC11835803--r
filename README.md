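# eegentropy

Sample-entropy and multiscale-entropy analysis of multichannel EEG, built
for three-group case-control designs: healthy controls versus the deficit
and non-deficit subtypes of schizophrenia, compared at rest and during a
visual working-memory (change-detection) task. The package provides the
full chain — entropy estimators, EEG conditioning, amplitude-based artifact
rejection, group statistics per electrode and scalp region, and
entropy–behavior correlations — plus a synthetic cohort generator with
controllable complexity structure, so every stage is testable without
clinical recordings.

## The measures

For a series $\{x(i)\}_{i=1}^N$, sample entropy with template length $m$
and tolerance $r$ is

$$\mathrm{SampEn}(m, r) = -\ln \frac{A}{B},$$

where $B$ counts ordered pairs of length-$m$ templates within Chebyshev
distance $r$ (self-matches excluded) and $A$ the subset still matching at
length $m+1$. Defaults are $m = 2$ and $r = 0.15 \times$ SD. Multiscale
entropy (MSE) recomputes SampEn after coarse-graining the series by
non-overlapping mean smoothing at scales $\tau = 1..20$, with $r$ fixed
from the original series; group statistics use the mean over scales 10–20.
Lower values mean a more regular signal; the band-limited variants (alpha
8–13 Hz, beta 13–30 Hz) localize complexity in frequency.

The preprocessing chain mirrors the conventions of ERP laboratories:
common-average re-reference, zero-phase 0.1–40 Hz band-pass, resampling to
500 Hz, resting segmentation into 10 s windows, stimulus-locked epochs
−200..3000 ms, four amplitude artifact rules (±50 µV step, 200 µV
peak-to-peak in 200 ms, 100 µV whole-epoch range, 0.5 µV flatline in
100 ms) and a strict "more than 70 % of trials retained" inclusion rule.

## Worked example

Entropy of a regular versus an irregular signal:

```r
library(eegentropy)
set.seed(42)
x <- rnorm(2000)                                        # white noise
y <- sin(2 * pi * 10 * seq_len(2000) / 500) + 0.3 * rnorm(2000)
p <- entropy_params(m = 2, r_coeff = 0.15)
sample_entropy(x, p)                                    # 2.473
sample_entropy(y, p)                                    # 1.728  (more regular)
aggregate_scales(multiscale_entropy(x, p, tau_max = 20))  # 1.221
```

A reduced synthetic study, end to end (8 channels, two per scalp region,
100 Hz, 30/19/19 subjects; the full-scale default design is 62 channels
at 1000 Hz with 80 trials per condition):

```r
des  <- validation_design(seed = 1)
cfg  <- validation_config(des, measures = "band")
task <- run_task(cfg)
corr <- run_correlations(cfg, task = task)

task$region_tests[task$region_tests$measure == "sampen_beta" &
                  task$region_tests$comparison == "NDS vs H", ]
#>     region comparison    t df     p cohens_d
#>    central   NDS vs H 0.71 47 0.481     0.21
#>    frontal   NDS vs H 1.86 47 0.070     0.54
#>  occipital   NDS vs H 1.38 47 0.175     0.40
#>   parietal   NDS vs H 2.08 47 0.043     0.61
```

The non-deficit group shows elevated task-state beta-band entropy in every
region, as the cohort design encodes (designed d between 0.49 and 0.83;
single-seed estimates at this n scatter around the design values, with
some dilution from common-average re-referencing at this reduced channel
count). The headline entropy–performance correlations recover the designed
coupling signs:

```r
corr$summary[...]   # easy (1T) condition
#>  group      measure condition      r  n     p
#>     DS sampen_alpha        1T  0.704 19 0.001   (designed +0.370)
#>    NDS  sampen_beta        1T -0.119 19 0.629   (designed -0.362)
```

`run_resting()` computes the resting multiscale-entropy tables the same
way, and `run_all()` chains resting, task and correlation stages and
writes tidy TSV tables plus a YAML run manifest under `out_dir`. A thin
command-line wrapper with `simulate` / `resting` / `task` / `correlate` /
`all` subcommands lives at `inst/scripts/eegentropy-cli.R`.

EEG input is either in-memory recordings, a generated cohort, or a cohort
directory of delimited matrices with YAML sidecars (see `write_cohort()`);
events are plain tables of onset sample, condition, correctness and RT.

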