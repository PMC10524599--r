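#' Simulate a phase-locked evoked spike train
#'
#' Emulates afferent firing entrained to a sinusoidal hair-cell stimulus:
#' each stimulus cycle fires at most one spike (with probability
#' `p_spike`), and the spike's latency within the cycle is drawn from a
#' wrapped normal distribution with mean `mean_fraction` and circular SD
#' `sd_fraction`, both expressed as fractions of the stimulus period. For
#' that distribution the population vector strength has the closed form
#' `r = exp(-2 * pi^2 * sd_fraction^2)`, which is what makes the generator
#' a usable oracle for the phase-locking analyses.
#'
#' Spikes falling within `refractory_s` of the previous emitted spike are
#' suppressed.
#'
#' @param stim A [stimulus_spec()].
#' @param mean_fraction Preferred latency as a fraction of the period, in
#'   `[0, 1)`.
#' @param sd_fraction Circular SD of the latency, as a fraction of the
#'   period (> 0; may be 0 for a degenerate, perfectly locked train).
#' @param p_spike Probability that a cycle emits a spike, in `[0, 1]`.
#' @param refractory_s Minimum gap between emitted spikes, seconds; must
#'   be shorter than the stimulus period.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   identical parameters and seed.
#' @param label Label recorded on the train.
#' @return A [spike_train()] covering `stim$onset_s + stim$duration_s`
#'   seconds.
#' @export
#' @examples
#' stim <- stimulus_spec(20, duration_s = 5)
#' sim_phase_locked_train(stim, 0.158, 0.0455, seed = 1)
sim_phase_locked_train <- function(stim, mean_fraction, sd_fraction,
                                   p_spike = 1, refractory_s = 1e-3,
                                   seed = 0, label = "evoked") {
  stopifnot(inherits(stim, "stimulus_spec"))
  check_number(mean_fraction, "mean_fraction", lower = 0, upper = 1,
               allow_zero_lower = TRUE)
  check_number(sd_fraction, "sd_fraction", lower = 0, allow_zero_lower = TRUE)
  check_number(p_spike, "p_spike", lower = 0, upper = 1,
               allow_zero_lower = TRUE)
  if (mean_fraction >= 1) {
    abort("`mean_fraction` must be < 1.", class = "afferent_bad_argument")
  }
  if (refractory_s >= stim$period_s) {
    abort("`refractory_s` must be shorter than the stimulus period.",
          class = "afferent_bad_argument")
  }
  n_cycles <- floor(stim$duration_s * stim$frequency_hz)
  duration_s <- stim$onset_s + stim$duration_s
  times <- with_seed(seed, {
    fired <- runif(n_cycles) < p_spike
    frac <- (mean_fraction + sd_fraction * rnorm(n_cycles)) %% 1
    cycle_start <- stim$onset_s + (seq_len(n_cycles) - 1) * stim$period_s
    t <- (cycle_start + frac * stim$period_s)[fired]
    t[t < duration_s]
  })
  if (length(times) > 1L) {
    keep <- rep(TRUE, length(times))
    last <- times[1]
    for (i in seq_along(times)[-1]) {
      if (times[i] - last < refractory_s) keep[i] <- FALSE else last <- times[i]
    }
    times <- times[keep]
  }
  out <- spike_train(times, duration_s = duration_s, label = label, seed = seed)
  attr(out, "stim") <- stim
  out
}

#' Simulate a spontaneous spike train
#'
#' Two firing regimes observed in lateral-line afferents are emulated.
#' `"renewal"` draws independent interspike intervals (ISIs) from a gamma
#' distribution with shape `1 / cv^2` and mean `mean_isi_s`, so `cv = 1`
#' gives Poisson-like firing and `cv -> 0` a near-periodic train.
#' `"bursty"` is a two-state Markov-modulated renewal process: between
#' spikes the train switches into a burst state with probability
#' `p_enter` and out of it with probability `p_exit`; within a burst, ISIs
#' are exponential with the (short) mean `isi_in_burst_s`, outside it they
#' follow the renewal rule. At matched mean ISI the bursty regime has a
#' higher empirical CV than the `cv = 1` renewal train.
#'
#' @param mode `"renewal"` or `"bursty"`.
#' @param mean_isi_s Mean ISI of the renewal (out-of-burst) process,
#'   seconds (> 0).
#' @param cv Target coefficient of variation of renewal ISIs (>= 0).
#' @param burst For `"bursty"`: list with `p_enter`, `p_exit` (per-ISI
#'   switching probabilities) and `isi_in_burst_s` (mean within-burst
#'   ISI, seconds).
#' @param duration_s Recording duration, seconds.
#' @param seed Integer seed.
#' @param label Label recorded on the train.
#' @return A [spike_train()].
#' @export
#' @examples
#' sim_spontaneous_train("renewal", mean_isi_s = 0.1, cv = 1,
#'                       duration_s = 10, seed = 1)
sim_spontaneous_train <- function(mode = c("renewal", "bursty"), mean_isi_s,
                                  cv = 1, burst = NULL, duration_s,
                                  seed = 0, label = mode) {
  mode <- match.arg(mode)
  check_number(mean_isi_s, "mean_isi_s", lower = 0)
  check_number(cv, "cv", lower = 0, allow_zero_lower = TRUE)
  check_number(duration_s, "duration_s", lower = 0)
  if (mode == "bursty") {
    if (is.null(burst) ||
        !all(c("p_enter", "p_exit", "isi_in_burst_s") %in% names(burst))) {
      abort("`burst` must supply p_enter, p_exit and isi_in_burst_s.",
            class = "afferent_bad_argument")
    }
    check_number(burst$p_enter, "p_enter", lower = 0, upper = 1,
                 allow_zero_lower = TRUE)
    check_number(burst$p_exit, "p_exit", lower = 0, upper = 1,
                 allow_zero_lower = TRUE)
    check_number(burst$isi_in_burst_s, "isi_in_burst_s", lower = 0)
    # a chain that can never enter the burst state is exactly the renewal
    # process; short-circuit so the identity holds spike for spike
    if (burst$p_enter == 0) mode <- "renewal"
  }
  draw_renewal <- function(n) {
    if (cv == 0) rep(mean_isi_s, n)
    else rgamma(n, shape = 1 / cv^2, scale = mean_isi_s * cv^2)
  }
  times <- with_seed(seed, {
    t <- numeric(0)
    now <- 0
    in_burst <- FALSE
    repeat {
      isi <- if (mode == "bursty" && in_burst) {
        rexp(1, rate = 1 / burst$isi_in_burst_s)
      } else {
        draw_renewal(1)
      }
      now <- now + isi
      if (now >= duration_s) break
      t <- c(t, now)
      if (mode == "bursty") {
        in_burst <- if (in_burst) runif(1) >= burst$p_exit
                    else runif(1) < burst$p_enter
      }
    }
    t
  })
  spike_train(times, duration_s = duration_s, label = label, seed = seed)
}

#' Simulate recovery of spontaneous firing after prolonged stimulation
#'
#' Inhomogeneous Poisson train with rate
#' `lambda(t) = baseline_rate_hz * (1 - exp(-max(t - recovery_delay_s, 0) /
#' recovery_tau_s))`: silent (in expectation) until the delay, then an
#' exponential approach to the baseline spontaneous rate. Times are
#' measured from the end of the stimulus. Simulated by thinning a
#' homogeneous Poisson process at the baseline rate.
#'
#' @param baseline_rate_hz Asymptotic spontaneous rate, spikes/s (> 0).
#' @param recovery_delay_s Dead time before firing resumes, seconds
#'   (>= 0).
#' @param recovery_tau_s Recovery time constant, seconds (> 0; values
#'   near 0 give an abrupt step to the baseline rate).
#' @param duration_s Post-stimulus observation window, seconds.
#' @param seed Integer seed.
#' @param label Label recorded on the train.
#' @return A [spike_train()] with times in seconds after stimulus offset.
#' @export
sim_recovery_train <- function(baseline_rate_hz, recovery_delay_s,
                               recovery_tau_s, duration_s, seed = 0,
                               label = "recovery") {
  check_number(baseline_rate_hz, "baseline_rate_hz", lower = 0)
  check_number(recovery_delay_s, "recovery_delay_s", lower = 0,
               allow_zero_lower = TRUE)
  check_number(recovery_tau_s, "recovery_tau_s", lower = 0)
  check_number(duration_s, "duration_s", lower = 0)
  times <- with_seed(seed, {
    n <- stats::rpois(1, baseline_rate_hz * duration_s)
    cand <- sort(runif(n, 0, duration_s))
    lam <- recovery_rate(cand, baseline_rate_hz, recovery_delay_s,
                         recovery_tau_s)
    cand[runif(n) < lam / baseline_rate_hz]
  })
  spike_train(times, duration_s = duration_s, label = label, seed = seed)
}

#' Recovery-rate profile and its integral
#'
#' `recovery_rate()` evaluates the delayed-exponential rate profile used
#' by [sim_recovery_train()]; `recovery_expected_count()` is its exact
#' integral from 0 to `t`, the expected cumulative spike count.
#'
#' @param t_s Times after stimulus offset, seconds.
#' @param baseline_rate_hz,recovery_delay_s,recovery_tau_s As in
#'   [sim_recovery_train()].
#' @return Numeric vector, spikes/s (`recovery_rate`) or expected counts
#'   (`recovery_expected_count`).
#' @export
recovery_rate <- function(t_s, baseline_rate_hz, recovery_delay_s,
                          recovery_tau_s) {
  u <- pmax(t_s - recovery_delay_s, 0)
  baseline_rate_hz * (1 - exp(-u / recovery_tau_s))
}

#' @rdname recovery_rate
#' @export
recovery_expected_count <- function(t_s, baseline_rate_hz, recovery_delay_s,
                                    recovery_tau_s) {
  u <- pmax(t_s - recovery_delay_s, 0)
  baseline_rate_hz * (u - recovery_tau_s * (1 - exp(-u / recovery_tau_s)))
}
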