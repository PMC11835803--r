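make_rec <- function(data, rate = 500, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  eeg_recording(data, labels, rate)
}

test_that("common-average re-referencing zeroes the channel sum", {
  rec <- make_rec(matrix(c(3, -1), nrow = 2, ncol = 4))
  out <- rereference_average(rec)
  expect_equal(out$data[, 1], c(ch1 = 2, ch2 = -2))
  expect_equal(out$reference, "average")
  expect_error(rereference_average(out), "already")

  set.seed(1)
  rec2 <- make_rec(matrix(rnorm(5 * 100), 5))
  out2 <- rereference_average(rec2)
  expect_lt(max(abs(colSums(out2$data))), 1e-9)

  zero <- rereference_average(make_rec(matrix(0, 3, 10)))
  expect_true(all(zero$data == 0))
})

test_that("band-pass filtering passes in-band and rejects out-of-band tones", {
  fs <- 500
  t <- seq(0, 8, by = 1 / fs)
  s5 <- sin(2 * pi * 5 * t)
  s80 <- sin(2 * pi * 80 * t)
  rec <- make_rec(rbind(s5, s80), rate = fs)
  out <- bandpass_filter(rec, 0.1, 40)
  edge <- seq(fs, length(t) - fs)  # ignore filtfilt edge transients
  expect_equal(sd(out$data[1, edge]) / sd(s5[edge]), 1, tolerance = 0.05)
  expect_lt(sd(out$data[2, edge]) / sd(s80[edge]), 0.1)
  expect_identical(dim(out$data), dim(rec$data))
  expect_identical(out$labels, rec$labels)
  expect_error(bandpass_filter(rec, 10, 300), "invalid")
})

test_that("filtering is zero-phase", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)
  s10 <- sin(2 * pi * 10 * t)
  out <- bandpass_filter(make_rec(rbind(s10), rate = fs), 8, 13)
  cc <- ccf(out$data[1, ], s10, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band extraction isolates the target rhythm", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)
  alpha <- list(name = "alpha", low = 8, high = 13)
  beta <- list(name = "beta", low = 13, high = 30)
  edge <- seq(fs, length(t) - fs)

  a10 <- extract_band(make_rec(rbind(sin(2 * pi * 10 * t)), rate = fs), alpha)
  expect_equal(sd(a10$data[1, edge]) / sd(sin(2 * pi * 10 * t)[edge]), 1,
               tolerance = 0.05)
  expect_identical(attr(a10, "band"), "alpha")

  a25 <- extract_band(make_rec(rbind(sin(2 * pi * 25 * t)), rate = fs), alpha)
  expect_lt(sd(a25$data[1, edge]) / sd(sin(2 * pi * 25 * t)[edge]), 0.1)

  mix <- sin(2 * pi * 10 * t) + sin(2 * pi * 25 * t)
  b <- extract_band(make_rec(rbind(mix), rate = fs), beta)
  sp <- spec.pgram(ts(b$data[1, edge], frequency = fs), plot = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], 25, tolerance = 0.5)
})

test_that("resampling halves the sample count and keeps spectral content", {
  fs <- 1000
  n <- 10000
  rec <- make_rec(matrix(rnorm(n), 1), rate = fs)
  out <- resample_recording(rec, 500)
  expect_identical(ncol(out$data), 5000L)
  expect_equal(out$rate, 500)

  same <- resample_recording(rec, 1000)
  expect_identical(ncol(same$data), as.integer(n))

  t <- seq(0, 10, by = 1 / fs)
  tone <- make_rec(rbind(sin(2 * pi * 20 * t)), rate = fs)
  dn <- resample_recording(tone, 500)
  sp <- spec.pgram(ts(dn$data[1, 500:4500], frequency = 500), plot = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], 20, tolerance = 0.5)
  expect_error(resample_recording(rec, -5), "> 0")
})

test_that("resting segmentation yields consecutive baseline-corrected windows", {
  fs <- 100
  rec <- make_rec(matrix(rnorm(2 * 180 * fs), 2), rate = fs)
  ep <- epoch_resting(rec)
  expect_identical(dim(ep$data), c(17L, 2L, 1000L))

  rec25 <- make_rec(matrix(rnorm(25 * fs), 1), rate = fs)
  ep25 <- epoch_resting(rec25)
  expect_identical(dim(ep25$data)[1], 1L)

  # constant-offset channel is zeroed by baseline subtraction
  recc <- make_rec(matrix(7, 1, 180 * fs), rate = fs)
  epc <- epoch_resting(recc)
  expect_equal(max(abs(epc$data)), 0)

  expect_error(epoch_resting(make_rec(matrix(rnorm(500), 1), rate = fs)),
               "shorter")
})

test_that("task segmentation is stimulus-locked with strict bounds handling", {
  fs <- 500
  n <- 30 * fs
  rec <- make_rec(matrix(rnorm(2 * n), 2), rate = fs)
  onsets <- as.integer(seq(2, 26, length.out = 10) * fs)
  ev <- event_list(onsets, rep(c("1T", "4T"), 5), rep(TRUE, 10),
                   rep(0.8, 10))
  ep <- epoch_task(rec, ev)
  expect_identical(dim(ep$data), c(10L, 2L, 1600L))
  expect_identical(attr(ep, "n_out_of_bounds"), 0L)
  expect_identical(ep$meta$condition, ev$condition)

  # an event too close to the recording start is dropped and counted
  ev2 <- event_list(c(10L, onsets), c("1T", ev$condition),
                    c(TRUE, ev$correct), c(0.5, ev$rt_s))
  ep2 <- epoch_task(rec, ev2)
  expect_identical(dim(ep2$data)[1], 10L)
  expect_identical(attr(ep2, "n_out_of_bounds"), 1L)

  # DC offset removed over the baseline interval
  recdc <- make_rec(matrix(5, 1, n), rate = fs)
  epdc <- epoch_task(recdc, ev)
  expect_equal(max(abs(epdc$data)), 0)

  expect_error(epoch_task(rec, ev[0, ]), "non-empty")
})

test_that("each artifact rule fires on its construction and only there", {
  fs <- 500
  ns <- 1000
  t <- seq_len(ns) / fs
  clean <- function() rbind(10 * sin(2 * pi * 7 * t), 10 * sin(2 * pi * 11 * t))
  data <- array(0, dim = c(6, 2, ns))
  data[1, , ] <- clean()
  data[2, , ] <- clean()
  step_ep <- clean(); step_ep[1, 500] <- step_ep[1, 499] + 60  # 60 uV jump
  data[3, , ] <- step_ep
  p2p_ep <- clean(); p2p_ep[2, ] <- p2p_ep[2, ] + 120 * sin(2 * pi * 40 * t)
  data[4, , ] <- p2p_ep                       # 240 uV p2p inside 200 ms
  # slow drift: large whole-epoch range, small jumps, sliding p2p small
  range_ep <- clean(); range_ep[1, ] <- range_ep[1, ] + seq(0, 120, length.out = ns)
  data[5, , ] <- range_ep
  flat_ep <- clean(); flat_ep[2, ] <- 0.01 * sin(2 * pi * 7 * t)  # dead channel
  data[6, , ] <- flat_ep

  ep <- eegentropy:::new_epoch_set(data, fs, c("A", "B"),
                                   meta = data.frame(idx = 1:6))
  out <- reject_artifacts(ep, rejection_rules())
  expect_identical(out$rejected, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_true(out$rules_hit[3, "step"])
  expect_true(out$rules_hit[4, "p2p"])
  expect_true(out$rules_hit[5, "range"])
  expect_true(out$rules_hit[6, "flat"])
  # the drift epoch must not trip the step or p2p rules
  expect_false(out$rules_hit[5, "step"])
  expect_false(out$rules_hit[5, "p2p"])
  # marking is pure: same epoch count, data untouched
  expect_identical(dim(out$data), dim(ep$data))
  expect_identical(out$data, ep$data)

  # a clean 30 uV 10 Hz sine is retained
  sine <- array(0, dim = c(1, 1, ns)); sine[1, 1, ] <- 30 * sin(2 * pi * 10 * t)
  eps <- eegentropy:::new_epoch_set(sine, fs, "A", meta = data.frame(idx = 1))
  expect_false(reject_artifacts(eps)$rejected)

  # loosening every rule can only shrink the rejected set
  loose <- rejection_rules(step_limit = 500, p2p_limit = 2000,
                           absolute_limit = 1000, flat_limit = 0.001)
  out_loose <- reject_artifacts(ep, loose)
  expect_true(all(out$rejected | !out_loose$rejected))
})

test_that("the retained-trial inclusion boundary is strict", {
  mk <- function(total, retained) {
    data <- array(0, dim = c(total, 1, 10))
    ep <- eegentropy:::new_epoch_set(data, 100, "A",
                                     meta = data.frame(idx = seq_len(total)))
    ep$rejected <- rep(c(FALSE, TRUE), c(retained, total - retained))
    ep
  }
  expect_true(subject_included(mk(160, 120)))   # 0.75 > 0.70
  expect_false(subject_included(mk(160, 112)))  # 0.70 is not > 0.70
  expect_false(subject_included(mk(160, 0)))
})
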