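#' Detect spikes in an action-current trace
#'
#' Threshold detection for loose-patch recordings. The baseline noise SD
#' is estimated robustly as `mad(current)` (median absolute deviation
#' scaled by 1.4826) so that the spikes themselves do not inflate the
#' threshold, and the baseline level as the median. Samples deviating
#' from baseline by more than `threshold_sd` SDs in the chosen polarity
#' are grouped into contiguous supra-threshold excursions; the spike time
#' is the extremum within each excursion (robust to the exact threshold,
#' unlike the first crossing). Detections closer than `refractory_s` to
#' the previously accepted spike are discarded.
#'
#' Detection is invariant to adding a constant offset to the trace.
#'
#' @param trace An `ac_trace` tibble (or any tibble with `time_s`,
#'   `current_au`).
#' @param threshold_sd Threshold in multiples of the baseline noise SD
#'   (default 5).
#' @param polarity `"negative"` (extracellular action currents,
#'   default), `"positive"`, or `"absolute"`.
#' @param refractory_s Minimum separation between accepted spikes,
#'   seconds.
#' @param duration_s Recording duration; taken from the trace when
#'   absent.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(trace, threshold_sd = 5,
                          polarity = c("negative", "positive", "absolute"),
                          refractory_s = 1e-3, duration_s = NULL) {
  polarity <- match.arg(polarity)
  check_number(threshold_sd, "threshold_sd", lower = 0)
  check_number(refractory_s, "refractory_s", lower = 0,
               allow_zero_lower = TRUE)
  x <- trace$current_au
  if (length(x) == 0) abort("Empty trace.", class = "afferent_bad_argument")
  if (anyNA(x)) abort("Trace contains NA samples.",
                      class = "afferent_bad_argument")
  base <- median(x)
  noise_sd <- mad(x)
  if (noise_sd == 0) {
    abort("Baseline noise SD is zero (constant trace); cannot threshold.",
          class = "afferent_zero_sd")
  }
  dev <- switch(polarity,
                negative = base - x,
                positive = x - base,
                absolute = abs(x - base))
  over <- dev > threshold_sd * noise_sd
  dur <- duration_s %||% attr(trace, "duration_s") %||%
    (max(trace$time_s) + median(diff(trace$time_s)))
  if (!any(over)) {
    return(spike_train(numeric(0), duration_s = dur, label = "detected"))
  }
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  peaks <- purrr::map2_int(starts[keep], ends[keep], function(s, e) {
    s + which.max(dev[s:e]) - 1L
  })
  times <- trace$time_s[peaks]
  if (length(times) > 1L) {
    acc <- rep(TRUE, length(times))
    last <- times[1]
    for (i in seq_along(times)[-1]) {
      if (times[i] - last < refractory_s) acc[i] <- FALSE else last <- times[i]
    }
    times <- times[acc]
  }
  spike_train(times[times < dur], duration_s = dur, label = "detected")
}

#' Mean spike rate over a time window
#'
#' Counts spikes in `[t0_s, t1_s)` and divides by the window length.
#'
#' @param train A [spike_train()].
#' @param t0_s,t1_s Window bounds, seconds; must lie within the
#'   recording.
#' @param duration_s Recording duration override.
#' @return Rate in spikes per second.
#' @export
#' @examples
#' tr <- spike_train(seq(0.05, 59.95, length.out = 546), duration_s = 60)
#' spike_rate(tr, 0, 60)  # 9.1 spikes/s
spike_rate <- function(train, t0_s, t1_s, duration_s = NULL) {
  dur <- train_duration(train, duration_s)
  if (!(t1_s > t0_s)) abort("Need t1_s > t0_s.",
                            class = "afferent_bad_argument")
  if (t0_s < 0 || t1_s > dur) {
    abort("Rate window must lie within the recording.",
          class = "afferent_bad_argument")
  }
  sum(train$time_s >= t0_s & train$time_s < t1_s) / (t1_s - t0_s)
}

#' Interspike intervals of a train
#'
#' First differences of spike times. When the train carries multiple
#' sweeps (for instance spontaneous activity acquired as consecutive
#' 1-second sweeps), intervals are computed within each sweep only:
#' gaps spanning a sweep boundary are acquisition artifacts and are
#' excluded.
#'
#' @param train A [spike_train()] (>= 2 spikes overall, with at least
#'   one within-sweep interval).
#' @return A tibble with columns `isi_s` and `sweep`.
#' @export
#' @examples
#' compute_isi(spike_train(c(0.1, 0.3, 0.6), duration_s = 1))
compute_isi <- function(train) {
  if (nrow(train) < 2L) {
    abort("Need at least 2 spikes to form interspike intervals.",
          class = "afferent_too_few_spikes")
  }
  out <- as_tibble(train) |>
    group_by(.data$sweep) |>
    summarise(isi_s = list(diff(.data$time_s)), .groups = "drop") |>
    tidyr::unnest("isi_s") |>
    dplyr::select("isi_s", "sweep")
  if (nrow(out) == 0L) {
    abort("No within-sweep interspike intervals (one spike per sweep).",
          class = "afferent_too_few_spikes")
  }
  out
}

#' Re-index a concatenated recording into fixed-length sweeps
#'
#' Spontaneous activity is often acquired as consecutive fixed-length
#' sweeps that are concatenated for analysis. This assigns each spike a
#' sweep index from its time so that [compute_isi()] can exclude
#' intervals spanning sweep boundaries.
#'
#' @param train A [spike_train()].
#' @param sweep_length_s Sweep length, seconds.
#' @return The train with `sweep` recomputed.
#' @export
split_sweeps <- function(train, sweep_length_s) {
  check_number(sweep_length_s, "sweep_length_s", lower = 0)
  tb <- as_tibble(train)
  tb$sweep <- as.integer(floor(tb$time_s / sweep_length_s)) + 1L
  new_spike_train(tb, duration_s = attr(train, "duration_s"),
                  label = attr(train, "label"), seed = attr(train, "seed"))
}
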