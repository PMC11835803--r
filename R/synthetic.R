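#' Cohort design for the synthetic three-group study
#'
#' Generative parameters for a synthetic cohort emulating a three-group
#' (healthy / deficit / non-deficit) resting + change-detection-task EEG
#' study. The defaults reproduce the study conditions this package targets:
#' group sizes 30/19/19, a 62-channel scalp montage at 1000 Hz, 3-minute
#' resting recordings, 80 task trials per set-size condition, 1/f-like
#' background activity, and alpha/beta narrowband components whose
#' *regularity* (the fraction of phase-locked sinusoid vs band-limited
#' noise) controls band-limited sample entropy.
#'
#' Group differences are expressed as standardized shifts (`entropy_shift`,
#' Cohen's d units of the between-subject regularity SD) of latent band
#' entropy per state/measure/region, and behavior is coupled to latent band
#' entropy through target Pearson correlations (`behavior_coupling`).
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param channels Channel label vector (default [default_montage()]).
#' @param rate Sampling rate in Hz.
#' @param resting_duration_s Resting recording length in seconds.
#' @param n_trials Task trials per condition (1T and 4T each).
#' @param spectral_exponent Named per-group 1/f exponent of the background.
#' @param background_rms Background RMS amplitude in microvolts.
#' @param band_components Named list per band: `center`, `bandwidth` (Hz) and
#'   `amplitude` (RMS microvolts).
#' @param base_regularity,regularity_sd Mean and between-subject SD of the
#'   latent regularity parameter (dimensionless, in \[0, 1\]).
#' @param entropy_shift Data frame (`group`, `state`, `measure`, `region`,
#'   `d`) of standardized latent-entropy shifts relative to the healthy
#'   group; `measure` is `"alpha"`, `"beta"` or `"broadband"`.
#' @param behavior_coupling Data frame (`group`, `band`, `condition`, `rho`)
#'   of target correlations between latent band entropy and task performance.
#' @param perf_group_shift Named per-group mean shift of the latent
#'   performance score (SD units).
#' @param condition_shift Named per-condition shift of the latent performance
#'   score (easy trials score higher).
#' @param region_map Region map used to localize entropy shifts.
#' @param isi_s,isi_jitter_s Inter-stimulus interval and uniform jitter (s).
#' @param seed Master seed; per-subject streams are derived from it.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(group_sizes = c(H = 30L, DS = 19L, NDS = 19L),
                          channels = default_montage(),
                          rate = 1000,
                          resting_duration_s = 180,
                          n_trials = 80L,
                          spectral_exponent = c(H = 1, DS = 1, NDS = 1),
                          background_rms = 6,
                          band_components = list(
                            alpha = list(center = 10, bandwidth = 4,
                                         amplitude = 6),
                            beta = list(center = 20, bandwidth = 10,
                                        amplitude = 4)),
                          base_regularity = 0.55,
                          regularity_sd = 0.12,
                          entropy_shift = default_entropy_shift(),
                          behavior_coupling = default_behavior_coupling(),
                          perf_group_shift = c(H = 0.95, DS = -1.0,
                                               NDS = -0.35),
                          condition_shift = c("1T" = 0.35, "4T" = 0),
                          region_map = default_region_map(),
                          isi_s = 3.5, isi_jitter_s = 0.5,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(group_sizes < 1L))
    stop("group_sizes must be a named vector of positive counts")
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  if (base_regularity < 0 || base_regularity > 1)
    stop("base_regularity must lie in [0, 1]")
  if (any(abs(behavior_coupling$rho) >= 1))
    stop("|target correlations| must be < 1")
  if (nrow(behavior_coupling)) {
    rho_ss <- stats::aggregate(rho ~ group + condition,
                               transform(behavior_coupling, rho = rho^2), sum)
    if (any(rho_ss$rho >= 1))
      stop("sum of squared couplings per (group, condition) must be < 1")
  }
  structure(list(group_sizes = group_sizes, channels = channels, rate = rate,
                 resting_duration_s = resting_duration_s,
                 n_trials = as.integer(n_trials),
                 spectral_exponent = spectral_exponent,
                 background_rms = background_rms,
                 band_components = band_components,
                 base_regularity = base_regularity,
                 regularity_sd = regularity_sd,
                 entropy_shift = entropy_shift,
                 behavior_coupling = behavior_coupling,
                 perf_group_shift = perf_group_shift,
                 condition_shift = condition_shift,
                 region_map = region_map,
                 isi_s = isi_s, isi_jitter_s = isi_jitter_s,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default latent-entropy shift table
#'
#' Standardized shifts (vs the healthy group) of latent band/broadband
#' entropy per state and scalp region encoded in the default synthetic
#' design: resting alpha entropy reduced occipitally in both patient groups;
#' task-state broadband complexity reduced centrally in the deficit group and
#' elevated in all regions in the non-deficit group; task-state beta entropy
#' elevated parietally in the deficit group and in all regions in the
#' non-deficit group.
#'
#' @return Data frame with columns `group`, `state`, `measure`, `region`, `d`.
#' @export
default_entropy_shift <- function() {
  rbind(
    data.frame(group = "DS", state = "rest", measure = "alpha",
               region = "occipital", d = -0.616),
    data.frame(group = "NDS", state = "rest", measure = "alpha",
               region = "occipital", d = -0.574),
    data.frame(group = "DS", state = "task", measure = "broadband",
               region = "central", d = -0.518),
    data.frame(group = "NDS", state = "task", measure = "broadband",
               region = c("frontal", "central", "parietal", "occipital"),
               d = c(0.620, 0.678, 0.624, 0.678)),
    data.frame(group = "DS", state = "task", measure = "beta",
               region = "parietal", d = 0.556),
    data.frame(group = "NDS", state = "task", measure = "beta",
               region = c("frontal", "central", "parietal", "occipital"),
               d = c(0.831, 0.489, 0.572, 0.695))
  )
}

#' Default entropy-behavior coupling table
#'
#' Target Pearson correlations between latent band entropy and task
#' performance (ACC/RT) per group and set-size condition in the default
#' synthetic design: positive alpha coupling in healthy (easy trials) and
#' deficit subjects (both difficulties), negative alpha/beta coupling in
#' non-deficit subjects, and a positive beta coupling in healthy subjects on
#' difficult trials.
#'
#' @return Data frame with columns `group`, `band`, `condition`, `rho`.
#' @export
default_behavior_coupling <- function() {
  data.frame(
    group = c("H", "H", "DS", "NDS", "NDS", "H", "DS", "NDS"),
    band = c("alpha", "beta", "alpha", "alpha", "beta",
             "beta", "alpha", "beta"),
    condition = c("1T", "1T", "1T", "1T", "1T", "4T", "4T", "4T"),
    rho = c(0.372, -0.411, 0.370, -0.451, -0.362, 0.486, 0.351, -0.331)
  )
}

# deterministic per-subject stream seed from the master seed; kept < 2^31
subject_stream_seed <- function(seed, index) {
  as.integer((((seed %% 100000L) + 1) * 1000003 + index * 7919) %% 2147483647)
}

# region label per channel (NA when the channel is in no region)
region_of <- function(labels, map) {
  out <- rep(NA_character_, length(labels))
  for (rg in names(map)) out[labels %in% map[[rg]]] <- rg
  names(out) <- labels
  out
}

shift_for <- function(design, group, state, measure, region) {
  tab <- design$entropy_shift
  if (is.na(region) || is.null(tab) || nrow(tab) == 0L) return(0)
  hit <- tab$group == group & tab$state == state &
    tab$measure == measure & tab$region == region
  if (!any(hit)) 0 else sum(tab$d[hit])
}

# Gaussian noise with an arbitrary one-sided amplitude envelope amp(f):
# random phases per positive-frequency bin, hermitian-symmetrized inverse
# FFT. Returned unnormalized so relative powers of spectral pieces are
# preserved when parts are synthesized separately.
spectral_noise <- function(n, rate, amp_fn) {
  nf <- (n - 1L) %/% 2L
  f <- (1:nf) * rate / n
  coef <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) *
    amp_fn(f)
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1L)] <- coef
  spec[n:(n - nf + 1L)] <- Conj(coef)
  if (n %% 2L == 0L)
    spec[nf + 2L] <- complex(real = stats::rnorm(1)) *
      amp_fn((nf + 1) * rate / n)
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# spectrally synthesized 1/f^exponent noise, unit RMS
colored_noise <- function(n, exponent, rate) {
  unit_rms(spectral_noise(n, rate, function(f) f^(-exponent / 2)))
}

# band-limited unit-RMS noise with raised-cosine edge rolloff
band_noise <- function(n, rate, lo, hi) {
  w <- 0.15 * (hi - lo)
  amp <- function(f) {
    a <- numeric(length(f))
    inside <- f >= lo & f <= hi
    a[inside] <- 1
    rl <- f >= lo - w & f < lo
    a[rl] <- 0.5 * (1 + cos(pi * (lo - f[rl]) / w))
    rh <- f > hi & f <= hi + w
    a[rh] <- 0.5 * (1 + cos(pi * (f[rh] - hi) / w))
    a
  }
  unit_rms(spectral_noise(n, rate, amp))
}

unit_rms <- function(x) {
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# periodic comb: harmonics of f0 with 1/f-shaped amplitudes and random
# (but per-call fixed) phases; the regular pole of the broadband regularity
# mixture. Harmonics stay below the alpha band so broadband-complexity
# manipulations do not contaminate the band-limited entropy measures; the
# coarse-scale multiscale-entropy aggregate is dominated by exactly this
# slow (< 8 Hz) range.
periodic_comb <- function(n, rate, exponent, f0 = 2, fmax = 7) {
  t <- (seq_len(n) - 1L) / rate
  ks <- seq_len(floor(fmax / f0))
  x <- numeric(n)
  for (k in ks)
    x <- x + (k * f0)^(-exponent / 2) *
      sin(2 * pi * k * f0 * t + stats::runif(1, 0, 2 * pi))
  unit_rms(x)
}

#' Generate one synthetic EEG channel
#'
#' A channel is the sum of a broadband background and one narrowband
#' component per configured band. The background interpolates, via
#' `bg_regularity`, between 1/f^exponent noise (irregular pole) and a
#' harmonic comb with the same spectral envelope (regular pole). Each band
#' component interpolates, via its `regularity`, between band-limited noise
#' (regularity 0, high sample entropy) and a fixed-phase sinusoid at the band
#' center (regularity 1, low sample entropy). All components are RMS-scaled
#' to their configured microvolt amplitudes.
#'
#' Randomness is taken from the current RNG state; callers seed it.
#'
#' @param design A [cohort_design()].
#' @param group Group label (indexes `spectral_exponent`).
#' @param duration_s Signal length in seconds.
#' @param regularity Named per-band regularity in \[0, 1\]; defaults to the
#'   design's `base_regularity` for every band.
#' @param bg_regularity Broadband background regularity in \[0, 1\].
#' @return Numeric vector of `duration_s * rate` samples (microvolts).
#' @export
generate_channel_signal <- function(design, group, duration_s,
                                    regularity = NULL, bg_regularity = 0) {
  stopifnot(inherits(design, "cohort_design"))
  n <- as.integer(round(duration_s * design$rate))
  rate <- design$rate
  expo <- design$spectral_exponent[[group]]
  if (bg_regularity > 0) {
    # broadband regularity acts on the slow (< 8 Hz) part of the background
    # only, leaving the in-band (alpha/beta) background untouched so that
    # broadband-complexity manipulations cannot leak into band entropy.
    # Slow and fast parts are synthesized from the same spectral envelope
    # over disjoint frequency ranges, which is distributionally identical
    # to splitting one realization.
    f_split <- 7.5
    env <- function(f) f^(-expo / 2)
    slow <- spectral_noise(n, rate, function(f) ifelse(f < f_split, env(f), 0))
    fast <- spectral_noise(n, rate, function(f) ifelse(f >= f_split, env(f), 0))
    comb <- periodic_comb(n, rate, expo)
    slow_mix <- stats::sd(slow) *
      unit_rms((1 - bg_regularity) * unit_rms(slow) + bg_regularity * comb)
    bg <- unit_rms(slow_mix + fast)
  } else {
    bg <- colored_noise(n, expo, rate)
  }
  x <- design$background_rms * bg
  t <- (seq_len(n) - 1L) / rate
  for (bn in names(design$band_components)) {
    bc <- design$band_components[[bn]]
    reg <- if (is.null(regularity)) design$base_regularity
           else regularity[[bn]]
    nb <- band_noise(n, rate, bc$center - bc$bandwidth / 2,
                     bc$center + bc$bandwidth / 2)
    sine <- sin(2 * pi * bc$center * t + stats::runif(1, 0, 2 * pi)) * sqrt(2)
    comp <- unit_rms(reg * sine + (1 - reg) * nb)
    x <- x + bc$amplitude * comp
  }
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate one synthetic subject
#'
#' Draws the subject's latent standardized entropy scores (one per band plus
#' a broadband score), converts them — together with the design's group /
#' state / region shifts — into per-channel regularity parameters, and
#' synthesizes a resting recording, a task recording with a jittered event
#' list (`n_trials` per condition), and condition-level behavior.
#'
#' Behavior is generated from a latent performance score
#' `s = group shift + condition shift + sum_b rho_b * z_b + noise`, with the
#' noise variance chosen so the latent performance-entropy correlation hits
#' the design target in expectation. Accuracy follows a logistic link
#' (`plogis(2.2 + 0.7 s)`) and reaction time is log-normal
#' (`0.8 * exp(-0.3 s)` seconds, i.e. median 0.8 s, sigma 0.3), so the
#' performance ratio ACC/RT is a monotone function of `s`.
#'
#' @param design A [cohort_design()].
#' @param group Group label.
#' @param id Subject identifier (character).
#' @param seed Integer seed of the subject's RNG stream.
#' @param signals Which EEG recordings to synthesize: `TRUE`/"all" (default),
#'   `"task"` (task recording only, the expensive repeated path of
#'   simulation studies), or `FALSE`/"none" (latent scores, events and
#'   behavior only, for design calibration checks). Draws are ordered
#'   latents, events/behavior, task signals, resting signals, so each
#'   reduced mode is a prefix of the full stream and everything it produces
#'   is bit-identical to the full run.
#' @return A `synthetic_subject`: list with `id`, `group`, `resting`
#'   ([eeg_recording()]), `task` (recording), `events` ([event_list()]),
#'   `behavior` (per-condition data frame) and `latent` (named z-scores).
#' @export
generate_subject <- function(design, group, id, seed, signals = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  signals <- if (isTRUE(signals)) "all"
             else if (isFALSE(signals)) "none"
             else match.arg(signals, c("all", "task", "none"))
  set.seed(as.integer(seed))
  bands <- names(design$band_components)
  z <- stats::rnorm(length(bands) + 1L)
  names(z) <- c(bands, "broadband")
  regions <- region_of(design$channels, design$region_map)

  reg_for <- function(state, measure, ch_region) {
    # higher latent entropy (z + d) means lower regularity
    clamp(design$base_regularity -
            design$regularity_sd *
            (z[[measure]] + shift_for(design, group, state, measure,
                                      ch_region)),
          0.02, 0.98)
  }

  make_recording <- function(state, duration_s) {
    dat <- matrix(NA_real_, length(design$channels),
                  as.integer(round(duration_s * design$rate)))
    for (i in seq_along(design$channels)) {
      rg <- regions[[i]]
      reg <- vapply(bands, function(b) reg_for(state, b, rg), numeric(1))
      dat[i, ] <- generate_channel_signal(
        design, group, duration_s, regularity = reg,
        bg_regularity = reg_for(state, "broadband", rg))
    }
    eeg_recording(dat, design$channels, design$rate)
  }

  conds <- sample(rep(c("1T", "4T"), each = design$n_trials))
  gaps <- design$isi_s + stats::runif(length(conds), 0, design$isi_jitter_s)
  onsets_s <- 2 + cumsum(c(0, gaps[-length(gaps)]))
  task_dur <- onsets_s[length(onsets_s)] + design$isi_s + 1

  # behavior first (condition-level), then per-trial correctness / RT
  couple <- design$behavior_coupling
  beh <- do.call(rbind, lapply(c("1T", "4T"), function(cond) {
    rows <- couple[couple$group == group & couple$condition == cond, ]
    rho <- structure(rows$rho, names = rows$band)
    sig <- sum(rho * z[rows$band])
    s <- design$perf_group_shift[[group]] +
      design$condition_shift[[cond]] + sig +
      sqrt(max(0, 1 - sum(rho^2))) * stats::rnorm(1)
    acc <- stats::plogis(2.2 + 0.7 * s)
    rt <- 0.8 * exp(-0.3 * s)
    data.frame(subject = id, group = group, condition = cond,
               acc = acc, rt = rt, performance = acc / rt)
  }))

  correct <- stats::rbinom(length(conds), 1,
                           beh$acc[match(conds, beh$condition)]) == 1
  rt_trial <- beh$rt[match(conds, beh$condition)] *
    exp(stats::rnorm(length(conds), 0, 0.15))
  events <- event_list(onset_sample = as.integer(round(onsets_s *
                                                         design$rate)) + 1L,
                       condition = conds, correct = correct,
                       rt_s = rt_trial)

  resting <- NULL; task <- NULL
  if (signals %in% c("all", "task"))
    task <- make_recording("task", task_dur)
  if (signals == "all")
    resting <- make_recording("rest", design$resting_duration_s)

  structure(list(id = id, group = group, resting = resting, task = task,
                 events = events, behavior = beh, latent = z),
            class = "synthetic_subject")
}

#' Generate a full synthetic cohort
#'
#' Deterministic given the design (which includes the master seed):
#' per-subject RNG streams are derived by stable integer hashing of
#' (seed, subject index), so cohorts are reproducible bit for bit and
#' subjects are independent.
#'
#' @param design A [cohort_design()].
#' @return A `synthetic_cohort`: list with `subjects` (list of
#'   [generate_subject()] results), `behavior` (stacked per-condition
#'   behavior table) and `manifest` (design parameters and per-subject
#'   stream seeds).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- rep(names(design$group_sizes), design$group_sizes)
  ids <- paste0(groups, ".", unlist(lapply(design$group_sizes, seq_len)))
  seeds <- vapply(seq_along(ids), function(i)
    subject_stream_seed(design$seed, i), integer(1))
  subjects <- lapply(seq_along(ids), function(i)
    generate_subject(design, groups[i], ids[i], seeds[i]))
  names(subjects) <- ids
  behavior <- do.call(rbind, lapply(subjects, `[[`, "behavior"))
  rownames(behavior) <- NULL
  manifest <- list(
    design = design[setdiff(names(design), c("region_map"))],
    subject_ids = ids, subject_groups = groups, subject_seeds = seeds)
  structure(list(subjects = subjects, behavior = behavior,
                 manifest = manifest),
            class = "synthetic_cohort")
}

#' Reduced design for simulation studies
#'
#' A [cohort_design()] that keeps the study-defining parameters — group
#' sizes 30/19/19, the default entropy-shift and behavior-coupling tables,
#' 1/f background with alpha/beta components — but shrinks the problem size
#' (8 channels, two per region; 100 Hz; 40 s resting; 6 trials per
#' condition) so that repeated end-to-end pipeline replicates are cheap.
#' Used for direction-recovery and calibration simulations. The montage is
#' kept at two channels per region rather than one because common-average
#' re-referencing mixes a 1/C fraction of every channel into each; with
#' very few channels that mixing dilutes region-specific group shifts that
#' are essentially undiluted at the full 62-channel scale.
#'
#' @param seed Master seed.
#' @param ... Further arguments passed to [cohort_design()] (e.g.
#'   `group_sizes`, `n_trials`).
#' @return A `cohort_design`.
#' @export
validation_design <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    channels = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
    rate = 100, resting_duration_s = 40, n_trials = 6L, seed = seed)
  do.call(cohort_design, utils::modifyList(defaults, args))
}

#' Matching reduced analysis configuration
#'
#' An [analysis_config()] tuned to [validation_design()]: no further
#' resampling (the design rate is already low), resting segmentation over
#' the available 40 s, and a 10-scale multiscale-entropy curve aggregated
#' over scales 5-10 (the coarse half, playing the role the 10-20 aggregate
#' plays at full scale).
#'
#' @param design A [validation_design()].
#' @param ... Overrides passed to [analysis_config()].
#' @return An `analysis_config`.
#' @export
validation_config <- function(design = validation_design(), ...) {
  args <- list(...)
  defaults <- list(
    design = design, resample_rate = design$rate,
    rest_window = list(start_ms = 5000, end_ms = 40000, window_ms = 10000,
                       baseline_ms = 500),
    tau_max = 10L, agg_range = c(5L, 10L))
  do.call(analysis_config, utils::modifyList(defaults, args))
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' One directory per subject containing the resting and task recordings
#' (delimited matrix + YAML sidecar, see [write_recording()]) and the events
#' table, plus a cohort-level behavior table and a YAML manifest.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_recording(s$resting, file.path(sd, "resting.tsv"))
    write_recording(s$task, file.path(sd, "task.tsv"))
    write_events(s$events, file.path(sd, "events.tsv"))
  }
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  man <- cohort$manifest
  man$design <- lapply(man$design, function(x)
    if (is.data.frame(x)) as.list(x) else x)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
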