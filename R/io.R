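#' Write / read a spike train as CSV plus JSON sidecar
#'
#' The CSV holds `time_s` and `sweep`; the sidecar (same path with
#' `.json` appended) records duration, label, seed and, when present,
#' the stimulus, so a round trip preserves the train and its metadata.
#'
#' @param train A [spike_train()].
#' @param path CSV path.
#' @return `write_spike_train()` the path, invisibly;
#'   `read_spike_train()` a [spike_train()].
#' @export
write_spike_train <- function(train, path) {
  readr::write_csv(as_tibble(train)[c("time_s", "sweep")], path)
  stim <- attr(train, "stim")
  meta <- list(duration_s = attr(train, "duration_s"),
               label = attr(train, "label"),
               seed = attr(train, "seed"))
  if (!is.null(stim)) {
    meta$stimulus <- list(frequency_hz = stim$frequency_hz,
                          onset_s = stim$onset_s,
                          duration_s = stim$duration_s,
                          reporting_period_ms = stim$reporting_period_ms)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("Missing sidecar metadata file: %s", sidecar),
          class = "afferent_missing_input")
  }
  meta <- jsonlite::fromJSON(sidecar)
  out <- spike_train(df$time_s, duration_s = meta$duration_s,
                     label = meta$label %||% "unlabelled",
                     sweep = df$sweep %||% rep(1L, nrow(df)),
                     seed = meta$seed %||% NA_integer_)
  if (!is.null(meta$stimulus)) {
    attr(out, "stim") <- stimulus_spec(
      meta$stimulus$frequency_hz, meta$stimulus$onset_s,
      meta$stimulus$duration_s,
      reporting_period_ms = meta$stimulus$reporting_period_ms)
  }
  out
}

#' Write / read an action-current trace as CSV
#'
#' Two columns, `time_s` and `current_au`; the sampling interval is
#' recovered from the time column on read.
#'
#' @param trace An `ac_trace`.
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[c("time_s", "current_au")], path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  dt <- median(diff(df$time_s))
  structure(as_tibble(df), class = c("ac_trace", class(tibble())),
            sample_interval_s = dt, duration_s = max(df$time_s) + dt)
}

#' Write a plate to long-format CSV
#'
#' @param plate A `plate` tibble.
#' @param path CSV path.
#' @export
write_plate <- function(plate, path) {
  readr::write_csv(as_tibble(plate), path)
  invisible(path)
}
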