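#' Specification of a synthetic extracellular voltage trace
#'
#' Describes a microvolt-scale trace containing biphasic extracellular spike
#' waveforms (sharp negative lobe followed by a smaller positive rebound)
#' embedded in Gaussian noise, optionally contaminated with a low-frequency
#' field-potential sinusoid and 60 Hz line noise — the components the
#' 200--3000 Hz band-pass stage is designed to separate.
#'
#' Spike times may be given explicitly or drawn as a homogeneous Poisson
#' process at `spike_rate`. `spike_amplitude` is the depth of the negative
#' lobe (µV, so a negative number); its magnitude relative to `noise_sd` is
#' recorded so detection tests can reason in noise-SD units.
#'
#' @param sampling_rate_hz sampling rate, Hz; must be at least twice any
#'   band edge applied downstream (default 25 kHz).
#' @param duration_s trace duration, seconds.
#' @param noise_sd Gaussian noise SD, µV.
#' @param spike_times_s explicit spike times (s), or `NULL` to draw from a
#'   Poisson process.
#' @param spike_rate_hz Poisson spike rate (Hz), used when `spike_times_s`
#'   is `NULL`; 0 gives a spike-free trace.
#' @param spike_amplitude_uv negative-lobe amplitude, µV (negative).
#' @param spike_width_ms full width of the negative lobe, ms.
#' @param lfp_amplitude_uv,lfp_freq_hz low-frequency contamination sinusoid.
#' @param line_amplitude_uv 60 Hz line-noise amplitude, µV.
#' @param seed RNG seed.
#' @return An object of class `trace_spec`.
#' @seealso [generate_trace()]
#' @export
trace_spec <- function(sampling_rate_hz = 25000,
                       duration_s = 300,
                       noise_sd = 5,
                       spike_times_s = NULL,
                       spike_rate_hz = 1,
                       spike_amplitude_uv = -50,
                       spike_width_ms = 1,
                       lfp_amplitude_uv = 0, lfp_freq_hz = 5,
                       line_amplitude_uv = 0,
                       seed = 1L) {
  if (duration_s <= 0) {
    rlang::abort("duration_s must be > 0.", class = "enspff_validation_error")
  }
  if (sampling_rate_hz <= 0) {
    rlang::abort("sampling_rate_hz must be > 0.",
                 class = "enspff_validation_error")
  }
  if (!is.null(spike_times_s) &&
      any(spike_times_s < 0 | spike_times_s >= duration_s)) {
    rlang::abort("spike_times_s must lie in [0, duration_s).",
                 class = "enspff_validation_error")
  }
  if (spike_amplitude_uv > 0) {
    rlang::abort("spike_amplitude_uv must be negative (extracellular convention).",
                 class = "enspff_validation_error")
  }
  structure(
    list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
         noise_sd = noise_sd, spike_times_s = spike_times_s,
         spike_rate_hz = spike_rate_hz,
         spike_amplitude_uv = spike_amplitude_uv,
         spike_width_ms = spike_width_ms,
         lfp_amplitude_uv = lfp_amplitude_uv, lfp_freq_hz = lfp_freq_hz,
         line_amplitude_uv = line_amplitude_uv, seed = as.integer(seed),
         amplitude_in_sd = if (noise_sd > 0) abs(spike_amplitude_uv) / noise_sd
                           else Inf),
    class = "trace_spec"
  )
}

# Biphasic template: negative Gaussian lobe of depth `amp` (<0) at t = 0,
# followed by a positive rebound of 30% magnitude, 1.5x width, delayed by
# 1.2 lobe-widths. Peak value is exactly `amp`, so amplitude-in-SD is exact.
spike_template <- function(amp, width_ms, fs) {
  sigma_s <- (width_ms / 1000) / 2.355        # FWHM -> SD of the lobe
  half <- ceiling(4 * sigma_s * fs) + ceiling(1.2 * sigma_s * fs)
  t <- (-half:half) / fs
  neg <- exp(-t^2 / (2 * sigma_s^2))
  pos <- exp(-(t - 1.2 * sigma_s * 2.355)^2 / (2 * (1.5 * sigma_s)^2))
  tpl <- amp * neg - 0.3 * amp * pos
  tpl * (amp / min(tpl))   # rebound overlaps the trough; rescale so depth = amp
}

#' Generate a synthetic voltage trace with known spike times
#'
#' @param spec a [trace_spec()].
#' @return A list with elements:
#' \describe{
#'   \item{trace}{a [voltage_trace()] of `round(duration * rate)` samples.}
#'   \item{spike_times_s}{the spike times actually embedded (sorted, s).}
#' }
#' @export
#' @examples
#' tr <- generate_trace(trace_spec(duration_s = 2, spike_times_s = c(0.5, 1.2),
#'                                 noise_sd = 0))
#' length(tr$spike_times_s)
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  withr::with_seed(spec$seed, generate_trace_impl(spec))
}

generate_trace_impl <- function(spec) {
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  x <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else numeric(n)

  if (spec$lfp_amplitude_uv > 0) {
    x <- x + spec$lfp_amplitude_uv *
      sin(2 * pi * spec$lfp_freq_hz * (0:(n - 1)) / fs)
  }
  if (spec$line_amplitude_uv > 0) {
    x <- x + spec$line_amplitude_uv * sin(2 * pi * 60 * (0:(n - 1)) / fs)
  }

  times <- spec$spike_times_s
  if (is.null(times)) {
    k <- rpois(1, spec$spike_rate_hz * spec$duration_s)
    times <- sort(runif(k, 0, spec$duration_s))
  } else {
    times <- sort(times)
  }

  tpl <- spike_template(spec$spike_amplitude_uv, spec$spike_width_ms, fs)
  half <- (length(tpl) - 1L) %/% 2L
  for (tt in times) {
    centre <- round(tt * fs) + 1L
    lo <- centre - half; hi <- centre + half
    src <- max(1L, lo):min(n, hi)
    x[src] <- x[src] + tpl[src - lo + 1L]
  }

  trace <- voltage_trace(x, fs)
  list(trace = trace, spike_times_s = times)
}

#' Extracellular voltage trace
#'
#' @param samples numeric vector of voltages, µV.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param electrode_id,well_id,replicate_id,day,stimulus optional recording
#'   metadata; `stimulus` is one of `spontaneous`, `acetylcholine`,
#'   `dopamine`, `electrical`, `electrical+dopamine`.
#' @param filtered internal provenance flag set by [bandpass()].
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, sampling_rate_hz, electrode_id = NA,
                          well_id = NA, replicate_id = NA, day = NA,
                          stimulus = "spontaneous", filtered = FALSE) {
  if (!all(is.finite(samples))) {
    rlang::abort("trace samples must be finite.", class = "enspff_validation_error")
  }
  stim_levels <- c("spontaneous", "acetylcholine", "dopamine", "electrical",
                   "electrical+dopamine")
  if (!stimulus %in% stim_levels) {
    rlang::abort(paste0("unknown stimulus '", stimulus, "'."),
                 class = "enspff_validation_error")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate_hz = sampling_rate_hz,
         electrode_id = electrode_id, well_id = well_id,
         replicate_id = replicate_id, day = day, stimulus = stimulus,
         filtered = isTRUE(filtered)),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz,
              if (x$filtered) ", band-passed" else ""))
  invisible(x)
}

#' Write / read a voltage trace as CSV
#'
#' Two columns (`time_s`, `uV`) plus a JSON sidecar `<path>.json` carrying
#' the sampling rate, metadata, and — when written from a simulation — the
#' true spike times.
#'
#' @param trace a [voltage_trace()].
#' @param path CSV file path.
#' @param true_spike_times_s optional ground-truth spike times stored in the
#'   sidecar.
#' @export
write_trace_csv <- function(trace, path, true_spike_times_s = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  n <- length(trace$samples)
  utils::write.csv(
    data.frame(time_s = (0:(n - 1)) / trace$sampling_rate_hz,
               uV = trace$samples),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = trace$sampling_rate_hz,
         electrode_id = trace$electrode_id, well_id = trace$well_id,
         replicate_id = trace$replicate_id, day = trace$day,
         stimulus = trace$stimulus, units = "uV",
         true_spike_times_s = true_spike_times_s),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  voltage_trace(df$uV, meta$sampling_rate_hz,
                electrode_id = meta$electrode_id %||% NA,
                well_id = meta$well_id %||% NA,
                replicate_id = meta$replicate_id %||% NA,
                day = meta$day %||% NA,
                stimulus = meta$stimulus %||% "spontaneous")
}
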