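small_design <- function(seed = 1L, ...) {
  args <- list(resting_duration_s = 20, n_trials = 2L, ...)
  if (!"group_sizes" %in% names(args)) args$group_sizes <- c(H = 2L)
  do.call(validation_design, c(list(seed = seed), args))
}

test_that("background spectra follow the configured 1/f exponent", {
  des <- validation_design(1L, band_components = list(), background_rms = 1)
  slope <- function(x, rate) {
    s <- spec.pgram(ts(x, frequency = rate), plot = FALSE, spans = 9)
    sel <- s$freq >= 1 & s$freq <= 40
    unname(coef(lm(log(s$spec[sel]) ~ log(s$freq[sel])))[2])
  }
  set.seed(5)
  des$spectral_exponent <- c(H = 0, DS = 0, NDS = 0)
  expect_equal(slope(generate_channel_signal(des, "H", 60), des$rate), 0,
               tolerance = 0.3)
  des$spectral_exponent <- c(H = 1, DS = 1, NDS = 1)
  expect_equal(slope(generate_channel_signal(des, "H", 60), des$rate), -1,
               tolerance = 0.3)
})

test_that("higher regularity lowers band-limited sample entropy", {
  des <- validation_design(2L)
  p <- entropy_params()
  band_sampen <- function(reg, seed) {
    set.seed(seed)
    x <- generate_channel_signal(des, "H", 40,
                                 regularity = c(alpha = reg, beta = 0.5))
    rec <- eeg_recording(matrix(x, 1), "Cz", des$rate)
    b <- extract_band(rec, list(name = "alpha", low = 8, high = 13))
    sample_entropy(b$data[1, 201:2200], p)
  }
  for (seed in 1:4)
    expect_lt(band_sampen(1, seed), band_sampen(0, seed))
})

test_that("subject generation is deterministic and behavior is well-formed", {
  des <- small_design()
  s1 <- generate_subject(des, "H", "H.1", 123)
  s2 <- generate_subject(des, "H", "H.1", 123)
  expect_identical(s1, s2)
  s3 <- generate_subject(des, "H", "H.1", 124)
  expect_false(identical(s1$task$data, s3$task$data))

  expect_true(all(s1$behavior$acc >= 0 & s1$behavior$acc <= 1))
  expect_true(all(s1$behavior$rt > 0))
  expect_equal(s1$behavior$performance, s1$behavior$acc / s1$behavior$rt)
  expect_identical(nrow(s1$events), 2L * des$n_trials)
  expect_true(!is.unsorted(s1$events$onset_sample, strictly = TRUE))

  # the light mode reproduces latents, events and behavior exactly
  s4 <- generate_subject(des, "H", "H.1", 123, signals = FALSE)
  expect_identical(s4$latent, s1$latent)
  expect_identical(s4$behavior, s1$behavior)
  expect_identical(s4$events, s1$events)
  expect_null(s4$task)
})

test_that("behavior coupling is calibrated to its target correlation", {
  des <- validation_design(9L)
  zs <- numeric(200); perf <- numeric(200)
  for (i in 1:200) {
    s <- generate_subject(des, "H", paste0("H.", i), 5000 + i,
                          signals = FALSE)
    zs[i] <- s$latent[["alpha"]]
    perf[i] <- s$behavior$performance[s$behavior$condition == "1T"]
  }
  # design target for (H, alpha, 1T) is +0.372
  expect_gt(cor(zs, perf), 0.25)
  expect_lt(cor(zs, perf), 0.55)

  # a null-coupling design yields a near-zero correlation
  des0 <- validation_design(9L, behavior_coupling = data.frame(
    group = character(), band = character(), condition = character(),
    rho = numeric()))
  z0 <- numeric(200); p0 <- numeric(200)
  for (i in 1:200) {
    s <- generate_subject(des0, "H", paste0("H.", i), 7000 + i,
                          signals = FALSE)
    z0[i] <- s$latent[["alpha"]]
    p0[i] <- s$behavior$performance[s$behavior$condition == "1T"]
  }
  expect_lt(abs(cor(z0, p0)), 0.15)
})

test_that("cohort generation is deterministic with per-subject streams", {
  des <- small_design(3L, group_sizes = c(H = 2L, DS = 1L))
  co1 <- generate_cohort(des)
  co2 <- generate_cohort(des)
  expect_identical(co1, co2)
  expect_identical(names(co1$subjects), c("H.1", "H.2", "DS.1"))
  expect_identical(vapply(co1$subjects, `[[`, "", "group"),
                   c(H.1 = "H", H.2 = "H", DS.1 = "DS"))
  expect_identical(nrow(co1$behavior), 6L)

  des2 <- small_design(4L, group_sizes = c(H = 2L, DS = 1L))
  co3 <- generate_cohort(des2)
  expect_false(identical(co1$subjects$H.1$task$data, co3$subjects$H.1$task$data))
  expect_identical(lengths(co1$manifest), lengths(co3$manifest))

  # full-scale default design carries the 30/19/19 group structure
  expect_identical(sum(cohort_design()$group_sizes), 68L)
})

test_that("cohorts round-trip through the on-disk interchange format", {
  des <- small_design(8L, group_sizes = c(H = 1L))
  co <- generate_cohort(des)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  rec <- read_recording(file.path(dir, "H.1", "task.tsv"))
  expect_equal(rec$rate, des$rate)
  expect_identical(rec$labels, des$channels)
  expect_equal(rec$data, co$subjects$H.1$task$data, tolerance = 1e-6)
  ev <- read_events(file.path(dir, "H.1", "events.tsv"))
  expect_equal(ev$onset_sample, co$subjects$H.1$events$onset_sample)
})
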