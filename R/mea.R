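#' Band-pass filter a voltage trace
#'
#' Zero-phase band-pass used before spike detection to remove
#' low-frequency local field potentials, drift and line noise as well as
#' high-frequency noise. A 2nd-order Butterworth design applied
#' forward--backward (`signal::filtfilt`) gives an effective 4th-order,
#' phase-distortion-free filter, so spike timestamps are not shifted.
#'
#' @param trace a [voltage_trace()].
#' @param low,high band edges, Hz (defaults 200 and 3000).
#' @return A band-passed [voltage_trace()] of the same length with its
#'   `filtered` provenance flag set.
#' @export
#' @examples
#' tr <- generate_trace(trace_spec(duration_s = 1, sampling_rate_hz = 10000,
#'                                 spike_times_s = numeric(0)))
#' bp <- bandpass(tr$trace)
bandpass <- function(trace, low = 200, high = 3000) {
  stopifnot(inherits(trace, "voltage_trace"))
  nyq <- trace$sampling_rate_hz / 2
  if (!(low > 0 && low < high && high < nyq)) {
    rlang::abort("band edges must satisfy 0 < low < high < sampling_rate/2.",
                 class = "enspff_validation_error")
  }
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  filt <- signal::filtfilt(bf, trace$samples)
  out <- trace
  out$samples <- as.numeric(filt)
  out$filtered <- TRUE
  out
}

#' Detect spikes by negative threshold crossing
#'
#' Estimates the noise floor of a band-passed trace, sets the detection
#' threshold at `-k_sd` noise standard deviations, and timestamps each
#' below-threshold excursion at its local minimum. Excursions beginning
#' within `dead_time` of an accepted spike are suppressed to avoid double
#' counting multi-sample crossings.
#'
#' The noise SD is estimated robustly by default (median absolute deviation
#' scaled to the Gaussian SD), because spikes inflate the plain standard
#' deviation; `sd_method = "sd"` selects the plain estimator. The method
#' used is recorded in the result.
#'
#' @param trace a band-passed [voltage_trace()] (see [bandpass()]).
#' @param k_sd threshold multiplier (default 5: threshold at -5 SD).
#' @param dead_time minimum separation between accepted spikes, seconds.
#' @param sd_method `"mad"` (robust, default) or `"sd"`.
#' @return An object of class `spike_train`: `spike_times_s` (sorted),
#'   `threshold_uv`, `noise_sd_uv`, `k_sd`, `dead_time_s`, `sd_method`,
#'   `duration_s` and the trace metadata.
#' @export
detect_spikes <- function(trace, k_sd = 5, dead_time = 0.001,
                          sd_method = c("mad", "sd")) {
  stopifnot(inherits(trace, "voltage_trace"))
  sd_method <- match.arg(sd_method)
  if (!trace$filtered) {
    rlang::abort("trace must be band-passed before spike detection (see bandpass()).",
                 class = "enspff_validation_error")
  }
  x <- trace$samples
  noise_sd <- if (sd_method == "mad") stats::mad(x) else stats::sd(x)
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    rlang::abort("trace has no noise floor (zero variance); cannot set a threshold.",
                 class = "enspff_detection_error")
  }
  threshold <- -k_sd * noise_sd
  fs <- trace$sampling_rate_hz

  below <- x < threshold
  times <- numeric(0)
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    cand <- vapply(runs, function(i) {
      seg <- starts[i]:ends[i]
      seg[which.min(x[seg])]
    }, integer(1))
    cand_t <- (cand - 1L) / fs
    last <- -Inf
    keep <- logical(length(cand_t))
    for (i in seq_along(cand_t)) {
      if (cand_t[i] - last >= dead_time) {
        keep[i] <- TRUE
        last <- cand_t[i]
      }
    }
    times <- cand_t[keep]
  }

  structure(
    list(spike_times_s = times, threshold_uv = threshold,
         noise_sd_uv = noise_sd, k_sd = k_sd, dead_time_s = dead_time,
         sd_method = sd_method,
         duration_s = length(x) / fs,
         electrode_id = trace$electrode_id, well_id = trace$well_id,
         replicate_id = trace$replicate_id, day = trace$day,
         stimulus = trace$stimulus),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in %.1f s (threshold %.2f uV = -%g x %s SD)\n",
              length(x$spike_times_s), x$duration_s, x$threshold_uv, x$k_sd,
              x$sd_method))
  invisible(x)
}

#' Count spikes in a recording window
#'
#' Number of spikes in the half-open window `[0, window_s)` — the per-
#' electrode outcome (spike count per 5-minute recording by default) that
#' feeds the zero-inflated negative-binomial model.
#'
#' @param spikes a `spike_train` (or bare numeric vector of spike times).
#' @param window_s window length, seconds (default 300 = 5 min).
#' @return integer spike count.
#' @export
count_spikes <- function(spikes, window_s = 300) {
  if (window_s <= 0) {
    rlang::abort("window_s must be > 0.", class = "enspff_validation_error")
  }
  times <- if (inherits(spikes, "spike_train")) spikes$spike_times_s else spikes
  sum(times >= 0 & times < window_s)
}

#' Detect bursts (>= n spikes within a short span)
#'
#' An electrode bursts when at least `n` consecutive spikes fall within
#' `span_s` seconds (default: 4 spikes in 0.1 s, i.e. an instantaneous rate
#' of 40 Hz). Every window of `n` consecutive spikes spanning at most
#' `span_s` marks its spikes as bursting; maximal runs of marked spikes are
#' reported as single bursts.
#'
#' @param spikes a `spike_train` or sorted numeric spike times (s).
#' @param n minimum spikes per burst window.
#' @param span_s maximum span of `n` consecutive spikes, seconds.
#' @return An object of class `burst_set`: tibble `bursts` with columns
#'   `start_s`, `end_s`, `n_spikes`, and logical `bursting`.
#' @export
#' @examples
#' detect_bursts(c(0, 0.02, 0.05, 0.09))$bursting  # TRUE: 4 spikes in 90 ms
#' detect_bursts(c(0, 0.05, 0.10, 0.15))$bursting  # FALSE: span 150 ms
detect_bursts <- function(spikes, n = 4L, span_s = 0.1) {
  times <- if (inherits(spikes, "spike_train")) spikes$spike_times_s else spikes
  if (is.unsorted(times)) {
    rlang::abort("spike times must be sorted.", class = "enspff_validation_error")
  }
  k <- length(times)
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          n_spikes = integer(0))
  if (k < n) {
    return(structure(list(bursts = empty, bursting = FALSE),
                     class = "burst_set"))
  }
  qualifies <- which(times[seq_len(k - n + 1L) + (n - 1L)] -
                       times[seq_len(k - n + 1L)] <= span_s)
  if (length(qualifies) == 0) {
    return(structure(list(bursts = empty, bursting = FALSE),
                     class = "burst_set"))
  }
  marked <- logical(k)
  for (q in qualifies) marked[q:(q + n - 1L)] <- TRUE
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  bursts <- tibble::tibble(
    start_s = times[starts[runs]],
    end_s = times[ends[runs]],
    n_spikes = as.integer(ends[runs] - starts[runs] + 1L)
  )
  structure(list(bursts = bursts, bursting = nrow(bursts) > 0),
            class = "burst_set")
}

#' Expected false-crossing rate of a -k SD threshold on band-limited noise
#'
#' Rice's formula for the mean rate of down-crossings of level `-k * sd` by
#' a zero-mean Gaussian process: `nu0 * exp(-k^2 / 2)`, where `nu0` is the
#' RMS frequency of the process's power spectrum. For a band-pass filtered
#' white noise the spectrum is the filter's squared magnitude response,
#' which is integrated numerically here.
#'
#' @param low,high band edges, Hz.
#' @param sampling_rate_hz sampling rate used for the digital design.
#' @param k_sd threshold multiplier.
#' @return expected crossings per second.
#' @export
rice_crossing_rate <- function(low = 200, high = 3000,
                               sampling_rate_hz = 25000, k_sd = 5) {
  nyq <- sampling_rate_hz / 2
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  f <- seq(0, nyq, length.out = 4096)
  h <- signal::freqz(bf$b, bf$a, f, Fs = sampling_rate_hz)
  # forward-backward application squares the magnitude response
  s <- abs(h$h)^4
  nu0 <- sqrt(sum(f^2 * s) / sum(s))
  nu0 * exp(-k_sd^2 / 2)
}
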