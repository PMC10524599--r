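#' Simulate a loose-patch action-current trace
#'
#' Renders a spike train as an extracellular current trace: Gaussian white
#' noise plus a stereotyped biphasic (negative-then-positive) waveform at
#' each spike time, passed through a single-pole low-pass at `lowpass_hz`
#' to mirror the acquisition filter. Amplitudes are defined on the
#' *recorded* (filtered) trace: the spike kernel is pre-scaled so its
#' filtered negative peak equals `spike_amplitude_au`, and the white-noise
#' input is pre-scaled by the inverse filter gain so the recorded baseline
#' SD equals `noise_sd_au`. The signal-to-noise ratio of a trace is
#' therefore simply `spike_amplitude_au / noise_sd_au`.
#'
#' Spikes closer together than `spike_width_s` are still rendered by
#' superposition; a message flags how many such pairs occurred.
#'
#' @param train A [spike_train()].
#' @param spike_amplitude_au Recorded negative-peak amplitude of each
#'   spike, arbitrary current units (>= 0; 0 gives a pure-noise trace).
#' @param spike_width_s Nominal biphasic waveform width, seconds; must be
#'   at least `2 * sample_interval_s`.
#' @param noise_sd_au Recorded baseline noise SD, arbitrary units.
#' @param sample_interval_s Sampling interval, seconds (default 50 us).
#' @param lowpass_hz Single-pole low-pass corner frequency, Hz; `Inf`
#'   disables filtering.
#' @param seed Integer seed.
#' @return An `ac_trace` tibble with columns `time_s`, `current_au` and
#'   attributes `sample_interval_s`, `duration_s`.
#' @export
#' @examples
#' tr <- sim_action_current_trace(
#'   sim_spontaneous_train("renewal", 0.05, 1, duration_s = 1, seed = 1),
#'   spike_amplitude_au = 10, seed = 1)
sim_action_current_trace <- function(train, spike_amplitude_au,
                                     spike_width_s = 1e-3, noise_sd_au = 1,
                                     sample_interval_s = 50e-6,
                                     lowpass_hz = 1000, seed = 0) {
  check_number(spike_amplitude_au, "spike_amplitude_au", lower = 0,
               allow_zero_lower = TRUE)
  check_number(noise_sd_au, "noise_sd_au", lower = 0, allow_zero_lower = TRUE)
  check_number(sample_interval_s, "sample_interval_s", lower = 0)
  if (spike_width_s < 2 * sample_interval_s) {
    abort("`spike_width_s` must be at least two sample intervals.",
          class = "afferent_bad_argument")
  }
  dur <- train_duration(train)
  n <- ceiling(dur / sample_interval_s)
  dt <- sample_interval_s

  # one-pole low-pass y[i] = a*x[i] + (1-a)*y[i-1]
  a <- if (is.finite(lowpass_hz)) {
    rc <- 1 / (2 * pi * lowpass_hz)
    dt / (rc + dt)
  } else 1
  noise_gain <- sqrt(a / (2 - a))  # white-noise SD gain of the one-pole

  kern <- spike_kernel(spike_width_s, dt, a)
  kern <- kern * spike_amplitude_au

  idx <- pmin(pmax(round(train$time_s / dt) + 1L, 1L), n)
  if (nrow(train) > 1L) {
    n_close <- sum(diff(train$time_s) < spike_width_s)
    if (n_close > 0) {
      rlang::inform(sprintf(
        "%d spike pair(s) closer than spike_width_s rendered by superposition.",
        n_close))
    }
  }
  sig <- numeric(n)
  half <- attr(kern, "center") - 1L
  for (k in idx) {
    lo <- k - half
    hi <- lo + length(kern) - 1L
    ks <- max(1L, 1L - lo + 1L)
    ke <- length(kern) - max(0L, hi - n)
    if (ks <= ke) {
      rng <- (lo + ks - 1L):(lo + ke - 1L)
      sig[rng] <- sig[rng] + kern[ks:ke]
    }
  }
  noise_in <- if (noise_sd_au > 0) {
    with_seed(seed, rnorm(n, sd = noise_sd_au / noise_gain))
  } else numeric(n)
  x <- sig + noise_in
  y <- if (a < 1) as.numeric(stats::filter(a * x, 1 - a, method = "recursive"))
       else x
  out <- tibble(time_s = (seq_len(n) - 1L) * dt, current_au = y)
  structure(out, class = c("ac_trace", class(tibble())),
            sample_interval_s = dt, duration_s = dur, seed = seed)
}

# Biphasic kernel on the sampling grid, pre-compensated so that after the
# one-pole filter its negative peak is exactly -1 and sits at lag 0.
spike_kernel <- function(spike_width_s, dt, a) {
  s <- spike_width_s / 5
  tau <- seq(-4 * s, 6 * s, by = dt)
  k <- -exp(-tau^2 / (2 * s^2)) + 0.6 * exp(-(tau - 2 * s)^2 / (2 * s^2))
  pad <- 50L
  kf <- as.numeric(stats::filter(a * c(numeric(pad), k), 1 - a,
                                 method = "recursive"))[-seq_len(pad)]
  k <- k / (-min(kf))
  # place the filtered negative peak at the spike sample
  center <- which.min(kf)
  structure(k, center = center)
}
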