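#' Re-reference to the common average
#'
#' Subtracts the instantaneous across-channel mean from every sample, so the
#' channel-wise sum is (numerically) zero at every time point.
#'
#' @param rec An [eeg_recording()] with `reference = "original"`.
#' @return The recording with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference == "average")
    stop("recording is already average-referenced")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "average"
  rec
}

ms_to_samples <- function(ms, rate) as.integer(round(ms * rate / 1000))

butter_bandpass <- function(low, high, rate) {
  nyq <- rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band (%g, %g) Hz invalid for rate %g Hz", low, high, rate))
  signal::butter(4, c(low, high) / nyq, type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift — entropy estimates are
#' sensitive to phase distortion, so linear/zero phase is required here.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @return Filtered recording, shape and labels unchanged.
#' @export
bandpass_filter <- function(rec, low, high) {
  stopifnot(inherits(rec, "eeg_recording"))
  flt <- butter_bandpass(low, high, rec$rate)
  rec$data <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(flt, ch)))
  rownames(rec$data) <- rec$labels
  rec
}

#' Extract a frequency band
#'
#' Band-pass specialization that records the band name on the output, for
#' provenance in downstream tables. Conventional defaults elsewhere in the
#' package are alpha = 8-13 Hz and beta = 13-30 Hz.
#'
#' @param rec An [eeg_recording()].
#' @param band A list/vector with elements `name`, `low`, `high`.
#' @return Filtered recording with attribute `band` set to the band name.
#' @export
extract_band <- function(rec, band) {
  out <- bandpass_filter(rec, band$low, band$high)
  attr(out, "band") <- band$name
  out
}

#' Resample a recording
#'
#' Polyphase resampling (`signal::resample`) with implicit anti-alias
#' filtering; the output is conformed to exactly
#' `round(n_samples * target / rate)` samples.
#'
#' @param rec An [eeg_recording()].
#' @param target Target rate in Hz (`0 < target <= rate`).
#' @return Recording at the target rate.
#' @export
resample_recording <- function(rec, target) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("target rate must be > 0")
  if (target > rec$rate) stop("upsampling not supported: target > rate")
  if (target == rec$rate) return(rec)
  frac <- .ratio_int(target, rec$rate)
  n_out <- as.integer(round(n_samples(rec) * target / rec$rate))
  res <- t(apply(rec$data, 1L, function(ch) {
    y <- signal::resample(ch, frac[1], frac[2])
    length(y) <- n_out                       # pad with NA if short by one
    y[is.na(y)] <- y[max(which(!is.na(y)))]  # repeat last sample
    y
  }))
  rownames(res) <- rec$labels
  rec$data <- res
  rec$rate <- target
  rec
}

# small-integer ratio p/q ~= target/rate
.ratio_int <- function(target, rate) {
  for (q in 1:1000) {
    p <- target * q / rate
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("cannot express target/rate as a small integer ratio")
}

new_epoch_set <- function(data, rate, labels, meta, rejected = NULL,
                          rules_hit = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1]
  if (is.null(rejected)) rejected <- rep(FALSE, n)
  structure(list(data = data, rate = rate, labels = labels, meta = meta,
                 rejected = rejected, rules_hit = rules_hit),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (%d rejected)\n",
              d[1], d[2], d[3], x$rate, sum(x$rejected)))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[1]

#' Segment a resting recording into consecutive windows
#'
#' Cuts non-overlapping consecutive windows of `window_ms` between `start_ms`
#' and `end_ms` (clipped to the recording length), each baseline-corrected by
#' subtracting, per channel, the mean of the `baseline_ms` immediately
#' preceding the window. Sample intervals are half-open `[start, end)`.
#'
#' @param rec An [eeg_recording()].
#' @param start_ms,end_ms Analysis window in ms from recording start
#'   (defaults 10000 and 180000).
#' @param window_ms Segment length in ms (default 10000).
#' @param baseline_ms Baseline length in ms preceding each segment
#'   (default 500).
#' @return An `eeg_epochs` object with `meta$rest_index`.
#' @export
epoch_resting <- function(rec, start_ms = 10000, end_ms = 180000,
                          window_ms = 10000, baseline_ms = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate
  w <- ms_to_samples(window_ms, rate)
  b <- ms_to_samples(baseline_ms, rate)
  s0 <- ms_to_samples(start_ms, rate)
  if (s0 - b < 0) stop("recording does not cover the first baseline")
  last <- min(ms_to_samples(end_ms, rate), n_samples(rec))
  k <- (last - s0) %/% w
  if (k < 1L) stop("recording shorter than one resting window")
  nch <- nrow(rec$data)
  data <- array(NA_real_, dim = c(k, nch, w))
  for (e in seq_len(k)) {
    from <- s0 + (e - 1L) * w          # 0-based start of half-open window
    seg <- rec$data[, (from + 1L):(from + w), drop = FALSE]
    base <- rowMeans(rec$data[, (from - b + 1L):from, drop = FALSE])
    data[e, , ] <- seg - base
  }
  new_epoch_set(data, rate, rec$labels,
                meta = data.frame(rest_index = seq_len(k)))
}

#' Segment a task recording around stimulus events
#'
#' One epoch per event, covering `[tmin_ms, tmax_ms)` relative to the onset
#' sample (the onset is time 0), baseline-corrected per channel by the mean
#' over `[-baseline_ms, 0)`. Events whose window falls outside the recording
#' are dropped; the dropped count is recorded in attribute `n_out_of_bounds`.
#'
#' @param rec An [eeg_recording()].
#' @param events An [event_list()].
#' @param tmin_ms,tmax_ms Epoch window in ms relative to onset (defaults
#'   -200 and 3000).
#' @param baseline_ms Baseline length in ms before onset (default 200).
#' @return An `eeg_epochs` object carrying the event metadata.
#' @export
epoch_task <- function(rec, events, tmin_ms = -200, tmax_ms = 3000,
                       baseline_ms = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!inherits(events, "event_list") || nrow(events) == 0L)
    stop("events must be a non-empty event_list")
  rate <- rec$rate
  o0 <- ms_to_samples(tmin_ms, rate)   # offset of first sample, signed
  o1 <- ms_to_samples(tmax_ms, rate)   # half-open end offset
  b <- ms_to_samples(baseline_ms, rate)
  len <- o1 - o0
  ns <- n_samples(rec)
  # onset_sample is 1-based; sample at offset k is onset_sample + k
  first <- events$onset_sample + pmin(o0, -b)
  last <- events$onset_sample + o1 - 1L
  keep <- first >= 1L & last <= ns
  n_oob <- sum(!keep)
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no event window lies inside the recording")
  nch <- nrow(rec$data)
  data <- array(NA_real_, dim = c(nrow(ev), nch, len))
  for (e in seq_len(nrow(ev))) {
    on <- ev$onset_sample[e]
    seg <- rec$data[, (on + o0):(on + o1 - 1L), drop = FALSE]
    base <- rowMeans(rec$data[, (on - b):(on - 1L), drop = FALSE])
    data[e, , ] <- seg - base
  }
  meta <- data.frame(condition = ev$condition, correct = ev$correct,
                     rt_s = ev$rt_s, onset_sample = ev$onset_sample)
  out <- new_epoch_set(data, rate, rec$labels, meta = meta)
  attr(out, "n_out_of_bounds") <- n_oob
  out
}

#' Amplitude-based artifact rejection rules
#'
#' Thresholds, all in microvolts: `step_limit` for instantaneous jumps
#' between adjacent samples, `p2p_limit` for peak-to-peak range within a
#' sliding `p2p_window_ms` window, `absolute_limit` for the max-minus-min
#' range over the whole epoch, and `flat_limit` for the minimum fluctuation
#' a live channel must show — a channel flat (range below `flat_limit`)
#' in *every* sliding `flat_window_ms` window marks the epoch.
#'
#' @param step_limit,p2p_limit,absolute_limit,flat_limit Positive thresholds
#'   in microvolts; defaults 50, 200, 100 and 0.5.
#' @param p2p_window_ms,flat_window_ms Window lengths in ms (defaults 200
#'   and 100).
#' @return A `rejection_rules` object.
#' @export
rejection_rules <- function(step_limit = 50, p2p_limit = 200,
                            absolute_limit = 100, flat_limit = 0.5,
                            p2p_window_ms = 200, flat_window_ms = 100) {
  lims <- c(step_limit, p2p_limit, absolute_limit, flat_limit,
            p2p_window_ms, flat_window_ms)
  if (!all(is.finite(lims) & lims > 0)) stop("all limits must be > 0")
  structure(list(step_limit = step_limit, p2p_limit = p2p_limit,
                 absolute_limit = absolute_limit, flat_limit = flat_limit,
                 p2p_window_ms = p2p_window_ms,
                 flat_window_ms = flat_window_ms),
            class = "rejection_rules")
}

#' Mark artifact-contaminated epochs
#'
#' Pure marking: no epoch is deleted. An epoch is marked rejected when any
#' channel violates any rule: (step) an absolute first difference above
#' `step_limit`; (p2p) a sliding-window peak-to-peak range above `p2p_limit`;
#' (range) a whole-epoch max-minus-min above `absolute_limit`; (flat) some
#' channel whose range stays below `flat_limit` in every sliding window
#' (a dead channel). Sliding windows advance sample by sample. The per-rule
#' attribution is kept in `rules_hit` (epochs x rules logical matrix).
#'
#' @param epochs An `eeg_epochs` object.
#' @param rules A [rejection_rules()] object.
#' @return The epoch set with `rejected` and `rules_hit` filled in.
#' @export
reject_artifacts <- function(epochs, rules = rejection_rules()) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(rules, "rejection_rules"))
  n <- n_epochs(epochs)
  hit <- matrix(FALSE, n, 4L,
                dimnames = list(NULL, c("step", "p2p", "range", "flat")))
  if (n == 0L) {
    epochs$rules_hit <- hit
    return(epochs)
  }
  ns <- dim(epochs$data)[3]
  w_p2p <- min(ms_to_samples(rules$p2p_window_ms, epochs$rate), ns)
  w_flat <- min(ms_to_samples(rules$flat_window_ms, epochs$rate), ns)
  for (e in seq_len(n)) {
    for (c in seq_len(dim(epochs$data)[2])) {
      x <- epochs$data[e, c, ]
      if (!hit[e, "step"] && max(abs(diff(x))) > rules$step_limit)
        hit[e, "step"] <- TRUE
      rr_p2p <- rolling_range_cpp(x, w_p2p)
      if (!hit[e, "p2p"] && max(rr_p2p) > rules$p2p_limit)
        hit[e, "p2p"] <- TRUE
      if (!hit[e, "range"] && diff(range(x)) > rules$absolute_limit)
        hit[e, "range"] <- TRUE
      rr_flat <- if (w_flat == w_p2p) rr_p2p else rolling_range_cpp(x, w_flat)
      if (!hit[e, "flat"] && max(rr_flat) < rules$flat_limit)
        hit[e, "flat"] <- TRUE
    }
  }
  epochs$rejected <- rowSums(hit) > 0L
  epochs$rules_hit <- hit
  epochs
}

#' Subject inclusion rule
#'
#' A subject is included when strictly more than `threshold` of their trials
#' survive artifact rejection (retained / total > threshold; the boundary is
#' excluded, matching a "more than 70%" rule).
#'
#' @param epochs An `eeg_epochs` object after [reject_artifacts()].
#' @param threshold Retained-fraction threshold (default 0.7).
#' @return Logical scalar.
#' @export
subject_included <- function(epochs, threshold = 0.7) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- n_epochs(epochs)
  if (n == 0L) return(FALSE)
  sum(!epochs$rejected) / n > threshold
}
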