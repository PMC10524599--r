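#' Normalize spike times to stimulus-cycle latency fractions
#'
#' Each spike inside the stimulus window is assigned its latency within
#' the stimulus cycle that contains it, expressed as a fraction of the
#' period: `fraction = ((t - onset) mod T) / T` with `T = 1 /
#' frequency_hz`. Spikes outside `[onset, onset + duration)` are
#' excluded. Shifting all spike times by an integer number of periods
#' leaves the fractions unchanged. Zero spikes in the window yields an
#' empty (valid) phase set.
#'
#' @param train A [spike_train()].
#' @param stim A [stimulus_spec()]; taken from the train attribute when
#'   omitted.
#' @return A `phase_set` tibble with columns `time_s`, `fraction` (in
#'   `[0, 1)`), carrying the stimulus as an attribute.
#' @export
#' @examples
#' stim <- stimulus_spec(20, duration_s = 1)
#' assign_phases(spike_train(0.1579, duration_s = 1), stim)  # 0.158
assign_phases <- function(train, stim = attr(train, "stim")) {
  if (is.null(stim)) abort("Supply a stimulus_spec.",
                           class = "afferent_bad_argument")
  stopifnot(inherits(stim, "stimulus_spec"))
  t0 <- stim$onset_s
  t1 <- stim$onset_s + stim$duration_s
  tt <- train$time_s[train$time_s >= t0 & train$time_s < t1]
  # snap away the float error of the modulus so whole-period times map to 0
  frac <- round(((tt - t0) / stim$period_s) %% 1, 12) %% 1
  structure(tibble(time_s = tt, fraction = frac),
            class = c("phase_set", class(tibble())), stim = stim)
}

#' Vector strength of a set of spike phases
#'
#' Each latency fraction becomes a unit vector at phase angle
#' `theta = 2 * pi * fraction`; the vector strength is the length of the
#' mean vector, `r = sqrt((sum cos theta)^2 + (sum sin theta)^2) / n`.
#' `r = 1` for perfect phase locking (all phases identical), `r = 0` for
#' phases spread uniformly around the cycle. The mean phase is
#' `atan2(sum sin, sum cos) / (2 * pi)` mapped to `[0, 1)`.
#'
#' @param phases A `phase_set` from [assign_phases()], or a tibble with a
#'   `fraction` column (n >= 1).
#' @return One-row tibble with `r`, `mean_phase_fraction`, `n`.
#' @export
#' @examples
#' vector_strength(tibble::tibble(fraction = c(0.1, 0.1, 0.1)))  # r = 1
vector_strength <- function(phases) {
  frac <- phases$fraction
  if (length(frac) == 0L) {
    abort("Vector strength is undefined for an empty phase set.",
          class = "afferent_empty_phases")
  }
  theta <- 2 * pi * frac
  cx <- sum(cos(theta))
  sy <- sum(sin(theta))
  r <- sqrt(cx^2 + sy^2) / length(theta)
  tibble(r = min(r, 1),
         mean_phase_fraction = (atan2(sy, cx) / (2 * pi)) %% 1,
         n = length(theta))
}

#' Latency histogram over one stimulus period
#'
#' Partitions `[0, 1)` into `n_bins` equal half-open bins and counts the
#' latency fractions in each; total counts equal the number of phases.
#'
#' @param phases A `phase_set` or tibble with `fraction`.
#' @param n_bins Number of bins (>= 4; default 50 per period).
#' @return A `latency_histogram` tibble with `bin`, `bin_mid`, `count`.
#' @export
latency_histogram <- function(phases, n_bins = 50) {
  if (n_bins < 4) abort("Need at least 4 bins.",
                        class = "afferent_bad_argument")
  frac <- phases$fraction
  bin <- pmin(floor(frac * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  structure(
    tibble(bin = seq_len(n_bins),
           bin_mid = (seq_len(n_bins) - 0.5) / n_bins,
           count = counts),
    class = c("latency_histogram", class(tibble())),
    n = length(frac), n_bins = n_bins, stim = attr(phases, "stim"))
}

#' Gaussian fit to a latency histogram
#'
#' Nonlinear least squares of `a * exp(-(x - mu)^2 / (2 * sigma^2))` to
#' bin centers versus counts, mirroring the field's practice of fitting
#' latency histograms rather than raw latencies. If the circular mean of
#' the histogram lies within two circular SDs of the 0/1 wrap boundary
#' the phases are rotated by half a period before fitting and the fitted
#' mean rotated back, so the linear Gaussian model stays well posed.
#' The peak latency in milliseconds is `mu * reporting_period_ms`;
#' supplying a rounded reporting period (16.6 ms at 60 Hz) reproduces
#' legend-style millisecond conversions.
#'
#' @param hist A `latency_histogram` (>= 5 nonzero bins).
#' @param reporting_period_ms Period used for the ms conversion; default
#'   is the exact period of the stimulus attached to the histogram, `NA`
#'   if none.
#' @return A `latency_fit` object; see [tidy.latency_fit()] /
#'   [glance.latency_fit()].
#' @export
fit_gaussian_latency <- function(hist, reporting_period_ms = NULL) {
  stopifnot(all(c("bin_mid", "count") %in% names(hist)))
  if (sum(hist$count > 0) < 5) {
    abort("Need at least 5 nonzero bins for a Gaussian fit.",
          class = "afferent_bad_argument")
  }
  stim <- attr(hist, "stim")
  period_ms <- reporting_period_ms %||%
    (if (!is.null(stim)) stim$reporting_period_ms else NA_real_)

  w <- hist$count
  x <- hist$bin_mid
  theta <- 2 * pi * x
  cm <- (atan2(sum(w * sin(theta)), sum(w * cos(theta))) / (2 * pi)) %% 1
  rbar <- sqrt(sum(w * cos(theta))^2 + sum(w * sin(theta))^2) / sum(w)
  s_hat <- sqrt(pmax(-2 * log(rbar), 1e-8)) / (2 * pi)

  recentered <- min(cm, 1 - cm) < 2 * s_hat
  x_fit <- if (recentered) (x + 0.5) %% 1 else x
  mu0 <- if (recentered) (cm + 0.5) %% 1 else cm

  df <- tibble(x = x_fit, y = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)),
                      data = df,
                      start = list(a = max(w), mu = mu0,
                                   sigma = max(s_hat, 1 / nrow(df))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf("Gaussian latency fit failed to converge: %s",
                    conditionMessage(e)),
            class = "afferent_fit_failure")
    })
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  mu <- if (recentered) (co[["mu"]] - 0.5) %% 1 else co[["mu"]] %% 1
  sigma <- abs(co[["sigma"]])
  structure(
    list(mu_fraction = mu, sigma_fraction = sigma,
         mu_se = se[["mu"]], sigma_se = se[["sigma"]],
         amplitude = co[["a"]],
         peak_latency_ms = mu * period_ms,
         reporting_period_ms = period_ms,
         recentered = recentered,
         histogram = as_tibble(hist)[c("bin_mid", "count")],
         fit = fit),
    class = "latency_fit")
}

#' @export
print.latency_fit <- function(x, ...) {
  cat(sprintf(
    "<latency_fit> mu = %.4f +/- %.4f, sigma = %.4f (fractions of period); peak %.4g ms%s\n",
    x$mu_fraction, x$mu_se, x$sigma_fraction, x$peak_latency_ms,
    if (x$recentered) " [re-centered across wrap]" else ""))
  invisible(x)
}

#' Tidy a Gaussian latency fit
#'
#' @param x A `latency_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`mu_fraction`,
#'   `sigma_fraction`, `amplitude`) with estimates and standard errors.
#'   `glance()`: one row with the headline quantities.
#' @export
tidy.latency_fit <- function(x, ...) {
  se <- sqrt(diag(vcov(x$fit)))
  tibble(term = c("mu_fraction", "sigma_fraction", "amplitude"),
         estimate = c(x$mu_fraction, x$sigma_fraction, x$amplitude),
         std.error = c(se[["mu"]], se[["sigma"]], se[["a"]]))
}

#' @rdname tidy.latency_fit
#' @export
glance.latency_fit <- function(x, ...) {
  tibble(mu_fraction = x$mu_fraction, mu_se = x$mu_se,
         sigma_fraction = x$sigma_fraction,
         peak_latency_ms = x$peak_latency_ms,
         reporting_period_ms = x$reporting_period_ms,
         recentered = x$recentered,
         rss = sum(stats::residuals(x$fit)^2))
}

#' @export
autoplot.latency_fit <- function(object, ...) {
  h <- object$histogram
  grid <- tibble(bin_mid = seq(0, 1, length.out = 401))
  mu <- object$mu_fraction
  # evaluate on the circle so a wrap-straddling peak draws correctly
  d <- (grid$bin_mid - mu + 0.5) %% 1 - 0.5
  grid$count <- object$amplitude * exp(-d^2 / (2 * object$sigma_fraction^2))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 1 / nrow(h), fill = "grey70") +
    ggplot2::geom_line(data = grid, colour = "black") +
    ggplot2::labs(x = "latency (fraction of stimulus period)",
                  y = "spike count") +
    ggplot2::theme_minimal()
}
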