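#' Describe a sinusoidal mechanical stimulus
#'
#' A stimulus specification fixes the period boundaries used to normalize
#' spike latencies: a sinusoid of `frequency_hz` starting at `onset_s` and
#' lasting `duration_s`. The exact period is `1000 / frequency_hz` ms; a
#' rounded `reporting_period_ms` (for example 16.6 ms at 60 Hz rather than
#' 16.667) may be supplied for converting latency fractions to
#' milliseconds in reports.
#'
#' @param frequency_hz Stimulus frequency in cycles per second (> 0).
#' @param onset_s Stimulus onset in seconds from the start of the
#'   recording.
#' @param duration_s Stimulus duration in seconds (> 0).
#' @param reporting_period_ms Optional period, in milliseconds, used only
#'   when converting latency fractions to milliseconds. Defaults to the
#'   exact `1000 / frequency_hz`.
#' @return An object of class `stimulus_spec`: a list with fields
#'   `frequency_hz`, `onset_s`, `duration_s`, `period_s`,
#'   `reporting_period_ms`.
#' @export
#' @examples
#' stimulus_spec(20, duration_s = 60)
#' stimulus_spec(60, duration_s = 60, reporting_period_ms = 16.6)
stimulus_spec <- function(frequency_hz, onset_s = 0, duration_s,
                          reporting_period_ms = NULL) {
  check_number(frequency_hz, "frequency_hz", lower = 0)
  check_number(duration_s, "duration_s", lower = 0)
  check_number(onset_s, "onset_s", lower = -Inf)
  period_ms <- reporting_period_ms %||% (1000 / frequency_hz)
  check_number(period_ms, "reporting_period_ms", lower = 0)
  structure(
    list(frequency_hz = frequency_hz, onset_s = onset_s,
         duration_s = duration_s, period_s = 1 / frequency_hz,
         reporting_period_ms = period_ms),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %g Hz sinusoid, onset %g s, duration %g s (period %.4g ms, reported as %.4g ms)\n",
              x$frequency_hz, x$onset_s, x$duration_s,
              1000 * x$period_s, x$reporting_period_ms))
  invisible(x)
}

#' Construct a spike train tibble
#'
#' Spike trains are tibbles with a strictly increasing `time_s` column
#' (seconds from the start of the recording) and an integer `sweep`
#' column. The recording duration, a free-text label and the generator
#' seed travel as attributes so that downstream rate and recovery
#' computations know the recorded extent.
#'
#' @param times_s Spike times in seconds; strictly increasing within each
#'   sweep.
#' @param duration_s Recording duration in seconds; all times must fall in
#'   `[0, duration_s)`.
#' @param label Free-text label (genotype, condition).
#' @param sweep Integer sweep index per spike (default all 1).
#' @param seed Generator seed, or `NA` for real data.
#' @return A `spike_train` tibble with columns `time_s`, `sweep`.
#' @export
#' @examples
#' spike_train(c(0.1, 0.3, 0.6), duration_s = 1)
spike_train <- function(times_s, duration_s, label = "unlabelled",
                        sweep = rep(1L, length(times_s)), seed = NA_integer_) {
  check_number(duration_s, "duration_s", lower = 0)
  times_s <- as.numeric(times_s)
  if (anyNA(times_s)) abort("Spike times must not contain NA.",
                            class = "afferent_bad_argument")
  if (length(times_s) && (min(times_s) < 0 || max(times_s) >= duration_s)) {
    abort("Spike times must lie in [0, duration_s).",
          class = "afferent_bad_argument")
  }
  tb <- tibble(time_s = times_s, sweep = as.integer(sweep))
  if (any(unlist(tapply(tb$time_s, tb$sweep, function(t) diff(t) <= 0)))) {
    abort("Spike times must be strictly increasing within each sweep.",
          class = "afferent_bad_argument")
  }
  new_spike_train(tb, duration_s = duration_s, label = label, seed = seed)
}

new_spike_train <- function(tb, duration_s, label, seed = NA_integer_) {
  structure(tb,
            class = c("spike_train", class(tibble())),
            duration_s = duration_s, label = label, seed = seed)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s (%s)\n",
              nrow(x), attr(x, "duration_s"), attr(x, "label")))
  NextMethod()
}

train_duration <- function(train, duration_s = NULL) {
  dur <- duration_s %||% attr(train, "duration_s")
  if (is.null(dur)) {
    abort("Recording duration unknown: supply `duration_s`.",
          class = "afferent_bad_argument")
  }
  dur
}
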