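#' Entropy estimation parameters
#'
#' Bundle of the sample-entropy settings shared across the package: the
#' template (embedding) length `m`, the matching tolerance expressed as a
#' fraction `r_coeff` of the series' standard deviation, and the policy for
#' deriving the absolute tolerance at coarse-grained scales.
#'
#' With `r_policy = "fixed_from_original"` (the canonical multiscale-entropy
#' procedure) the absolute tolerance is computed once from the scale-1 series
#' and reused at every scale, so changes in entropy across scales reflect the
#' coarse-grained dynamics rather than a rescaled matching radius.
#' `"per_scale"` recomputes `r` from each coarse-grained series instead.
#'
#' @param m Template length (positive integer). Default 2, the standard
#'   choice for EEG sample entropy.
#' @param r_coeff Tolerance as a fraction of the series SD (positive).
#'   Default 0.15.
#' @param r_policy `"fixed_from_original"` or `"per_scale"`.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r_coeff = 0.15,
                           r_policy = c("fixed_from_original", "per_scale")) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  if (!is.numeric(r_coeff) || length(r_coeff) != 1L || r_coeff <= 0)
    stop("r_coeff must be a positive number")
  r_policy <- match.arg(r_policy)
  structure(list(m = m, r_coeff = r_coeff, r_policy = r_policy),
            class = "entropy_params")
}

check_series <- function(x, min_len = 2L) {
  if (!is.numeric(x)) stop("series must be numeric")
  if (length(x) < min_len)
    stop(sprintf("series too short: length %d < %d", length(x), min_len))
  if (!all(is.finite(x))) stop("series contains non-finite values")
  invisible(x)
}

# Absolute tolerance from a series SD with a floor at machine-epsilon scale,
# so constant (zero-variance) series match everywhere and return SampEn 0
# instead of failing on r = 0.
tolerance_from_sd <- function(x, r_coeff) {
  s <- stats::sd(x)
  r <- r_coeff * s
  floor_r <- .Machine$double.eps * max(1, mean(abs(x)))
  max(r, floor_r)
}

#' Coarse-grain a time series
#'
#' Replaces a series by the means of consecutive non-overlapping windows of
#' length `tau` (mean smoothing). Output length is `floor(N / tau)`; trailing
#' samples that do not fill a window are dropped. `tau = 1` returns the
#' series unchanged.
#'
#' @param x Numeric vector.
#' @param tau Scale factor (positive integer, `tau <= length(x)`).
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  check_series(x, min_len = 1L)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) stop("tau must be a positive integer")
  if (tau > length(x)) stop("tau exceeds series length")
  if (tau == 1L) return(x)
  nw <- length(x) %/% tau
  colMeans(matrix(x[seq_len(nw * tau)], nrow = tau))
}

#' Template match counts for sample entropy
#'
#' Counts ordered template pairs (i, j), i != j, whose Chebyshev distance is
#' at most `r`, for template lengths `m` and `m + 1`. Both counts run over the
#' same start-index range `1..N-m`, so the length-(m+1) matches are a subset
#' of the length-m matches and `count_m1 <= count_m` always holds.
#'
#' @param x Numeric vector, length at least `m + 2`.
#' @param m Template length.
#' @param r Absolute matching tolerance (> 0).
#' @return Named numeric vector `c(count_m, count_m1)`.
#' @export
match_counts <- function(x, m, r) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  check_series(x, min_len = m + 2L)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("r must be a positive number")
  cnt <- sampen_counts_cpp(as.numeric(x), m, r)
  c(count_m = cnt[1], count_m1 = cnt[2])
}

#' Sample entropy
#'
#' The negative logarithm of the conditional probability that two sequences
#' matching for `m` points (within tolerance `r`, Chebyshev distance,
#' self-matches excluded) also match at the next point:
#' `SampEn = -ln(count_m1 / count_m)`, in nats. Lower values indicate a more
#' regular signal. Returns `NA` (the undefined marker) when either count is
#' zero, i.e. when no template pairs match.
#'
#' @param x Numeric vector, length at least `m + 2`.
#' @param params An [entropy_params()] object.
#' @param r Optional absolute tolerance; when `NULL` (default) it is derived
#'   as `r_coeff * sd(x)` with a machine-epsilon floor.
#' @return Sample entropy in nats, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(x, params = entropy_params(), r = NULL) {
  check_series(x, min_len = params$m + 2L)
  if (is.null(r)) r <- tolerance_from_sd(x, params$r_coeff)
  cnt <- match_counts(x, params$m, r)
  if (cnt[["count_m"]] == 0 || cnt[["count_m1"]] == 0) return(NA_real_)
  -log(cnt[["count_m1"]] / cnt[["count_m"]])
}

#' Multiscale entropy
#'
#' Sample entropy of successively coarse-grained versions of a series, for
#' scale factors `tau = 1..tau_max`. Under the default tolerance policy
#' (`fixed_from_original`) the absolute tolerance is computed once from the
#' scale-1 series and reused at every scale.
#'
#' @param x Numeric vector, length at least `tau_max * (m + 2)`.
#' @param params An [entropy_params()] object.
#' @param tau_max Largest scale factor (default 20).
#' @return An object of class `mse_curve`: a data frame with columns `scale`
#'   and `sampen` (one row per scale; `sampen` may be `NA` where no template
#'   pairs matched), with the parameters attached as attributes.
#' @export
multiscale_entropy <- function(x, params = entropy_params(), tau_max = 20L) {
  tau_max <- as.integer(tau_max)
  if (is.na(tau_max) || tau_max < 1L) stop("tau_max must be a positive integer")
  check_series(x, min_len = tau_max * (params$m + 2L))
  r_fixed <- if (params$r_policy == "fixed_from_original")
    tolerance_from_sd(x, params$r_coeff) else NULL
  vals <- vapply(seq_len(tau_max), function(tau) {
    xs <- coarse_grain(x, tau)
    sample_entropy(xs, params, r = r_fixed)
  }, numeric(1))
  structure(data.frame(scale = seq_len(tau_max), sampen = vals),
            params = params, tau_max = tau_max,
            class = c("mse_curve", "data.frame"))
}

#' Aggregate a multiscale-entropy curve over a scale range
#'
#' Arithmetic mean of the defined (non-`NA`) curve values for scales in
#' `[lo, hi]`. Undefined scales are skipped; the result is `NA` only when
#' every scale in the range is undefined. The default range 10-20 targets the
#' coarse scales where long-range temporal structure dominates.
#'
#' @param curve An `mse_curve` from [multiscale_entropy()].
#' @param lo,hi Scale range bounds, `1 <= lo <= hi <= tau_max`.
#' @return Scalar mean entropy (nats), or `NA_real_`.
#' @export
aggregate_scales <- function(curve, lo = 10L, hi = 20L) {
  if (!inherits(curve, "mse_curve")) stop("curve must be an mse_curve")
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (is.na(lo) || is.na(hi) || lo < 1L || hi < lo)
    stop("need 1 <= lo <= hi")
  if (hi > attr(curve, "tau_max")) stop("hi exceeds tau_max of the curve")
  v <- curve$sampen[curve$scale >= lo & curve$scale <= hi]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}
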