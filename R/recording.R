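#' Multichannel EEG recording
#'
#' A channels-by-samples numeric matrix (microvolts) with unique channel
#' labels, a sampling rate and a reference state.
#'
#' @param data Numeric matrix, channels in rows.
#' @param labels Character vector of unique channel labels, one per row.
#' @param rate Sampling rate in Hz (> 0).
#' @param reference `"original"` or `"average"`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, labels, rate,
                          reference = c("original", "average")) {
  if (!is.matrix(data) || !is.numeric(data)) stop("data must be a numeric matrix")
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) stop("one label per channel row required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) stop("rate must be > 0")
  reference <- match.arg(reference)
  rownames(data) <- labels
  structure(list(data = data, labels = labels, rate = rate,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              x$reference))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Write / read a recording as a delimited matrix with a sidecar
#'
#' The on-disk form is a tab-separated samples-by-channels table with one
#' header row of channel labels, plus a YAML sidecar (`<path>.yaml`) holding
#' the sampling rate, the reference state and the unit.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path for the matrix file.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- t(rec$data)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = rec$labels, quote = FALSE)
  yaml::write_yaml(list(rate_hz = rec$rate, reference = rec$reference,
                        unit = "uV"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  eeg_recording(t(as.matrix(tab)), labels = colnames(tab),
                rate = side$rate_hz,
                reference = if (identical(side$reference, "average"))
                  "average" else "original")
}

#' Task event list
#'
#' Stimulus events for the change-detection task: onset (sample index into
#' the task recording), set-size condition (`"1T"` or `"4T"`), response
#' correctness and reaction time in seconds. Onsets must be strictly
#' increasing.
#'
#' @param onset_sample Integer vector of onset sample indices (1-based).
#' @param condition Character/factor vector of `"1T"`/`"4T"`.
#' @param correct Logical vector.
#' @param rt_s Numeric reaction times (seconds).
#' @return A data frame of class `event_list`.
#' @export
event_list <- function(onset_sample, condition, correct, rt_s) {
  onset_sample <- as.integer(onset_sample)
  condition <- as.character(condition)
  if (!all(condition %in% c("1T", "4T"))) stop("condition must be 1T or 4T")
  if (length(onset_sample) == 0L) stop("empty event list")
  if (is.unsorted(onset_sample, strictly = TRUE))
    stop("onsets must be strictly increasing")
  structure(data.frame(onset_sample = onset_sample, condition = condition,
                       correct = as.logical(correct), rt_s = as.numeric(rt_s)),
            class = c("event_list", "data.frame"))
}

#' @rdname event_list
#' @param events An `event_list`.
#' @param path File path for the tab-separated events table.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname event_list
#' @export
read_events <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  event_list(tab$onset_sample, tab$condition, tab$correct, tab$rt_s)
}
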