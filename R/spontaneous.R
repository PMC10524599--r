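#' Interspike-interval summary statistics
#'
#' Mean ISI and coefficient of variation (sample SD with `n - 1`
#' denominator divided by the mean). CV is about 1 for Poisson-like
#' firing, near 0 for clock-like regular firing, and above 1 for bursty
#' trains.
#'
#' @param isis A tibble with an `isi_s` column (from [compute_isi()]) or
#'   a numeric vector of intervals; needs at least 2 intervals.
#' @return One-row tibble with `mean_isi_s`, `cv`, `n_isi`.
#' @export
#' @examples
#' isi_stats(c(0.1, 0.3))  # mean 0.2, cv ~ 0.707
isi_stats <- function(isis) {
  v <- isi_vector(isis)
  if (length(v) < 2L) {
    abort("Need at least 2 interspike intervals.",
          class = "afferent_too_few_spikes")
  }
  m <- mean(v)
  tibble(mean_isi_s = m, cv = sd(v) / m, n_isi = length(v))
}

isi_vector <- function(isis) {
  v <- if (is.data.frame(isis)) isis$isi_s else as.numeric(isis)
  if (is.null(v) || anyNA(v) || any(v <= 0)) {
    abort("Interspike intervals must be positive and non-missing.",
          class = "afferent_bad_argument")
  }
  v
}

#' Recurrence pairs of consecutive interspike intervals
#'
#' The return map of spike timing: each interval plotted against the one
#' before it. Regular firing collapses onto the diagonal; bursting
#' scatters pairs into the short-short quadrant (within bursts) and the
#' short-long / long-short quadrants (burst entry and exit). The
#' quadrant threshold defaults to the median ISI (scale-free) but may be
#' fixed.
#'
#' @param isis As in [isi_stats()]; needs >= 2 intervals.
#' @param threshold `"median"` or a fixed positive number of seconds.
#' @return A `recurrence_pairs` tibble with `isi_prev_s`, `isi_next_s`
#'   and a `threshold_s` attribute.
#' @export
#' @examples
#' isi_recurrence(c(1, 2, 3))  # pairs (1,2), (2,3)
isi_recurrence <- function(isis, threshold = "median") {
  v <- isi_vector(isis)
  if (length(v) < 2L) {
    abort("Need at least 2 intervals to form recurrence pairs.",
          class = "afferent_too_few_spikes")
  }
  thr <- if (identical(threshold, "median")) median(v) else {
    check_number(threshold, "threshold", lower = 0)
    threshold
  }
  structure(
    tibble(isi_prev_s = v[-length(v)], isi_next_s = v[-1]),
    class = c("recurrence_pairs", class(tibble())),
    threshold_s = thr, isis = v)
}

#' Quadrant fractions and burst-spread index of a recurrence map
#'
#' Each recurrence pair is classified by comparing both coordinates to
#' the quadrant threshold (ties count as "short"). The four quadrant
#' fractions sum to one. The burst-spread index is the observed
#' short-short quadrant fraction minus the same fraction expected when
#' the interval order carries no information, estimated by shuffling the
#' ISI sequence `n_shuffle` times and rebuilding the pairs. Clustering
#' of short intervals inside bursts is the defining recurrence-map
#' signature of bursting, so the index is centered at 0 for renewal
#' (order-free) trains — and exactly 0 for clock-like trains, where
#' every pair ties into short-short regardless of order — and positive
#' for burst-structured firing.
#'
#' @param rp A `recurrence_pairs` from [isi_recurrence()].
#' @param n_shuffle Number of permutations for the null (default 100).
#' @param seed Seed for the permutation stream.
#' @return One-row tibble with `q_short_short`, `q_short_long`,
#'   `q_long_short`, `q_long_long`, `burst_spread_index`,
#'   `threshold_s`, `n_pairs`.
#' @export
burst_metrics <- function(rp, n_shuffle = 100, seed = 0) {
  stopifnot(inherits(rp, "recurrence_pairs"))
  thr <- attr(rp, "threshold_s")
  v <- attr(rp, "isis")
  frac_table <- function(prev, nxt) {
    sp <- prev <= thr
    sn <- nxt <= thr
    c(ss = mean(sp & sn), sl = mean(sp & !sn),
      ls = mean(!sp & sn), ll = mean(!sp & !sn))
  }
  obs <- frac_table(rp$isi_prev_s, rp$isi_next_s)
  null_ss <- with_seed(seed, {
    map_dbl(seq_len(n_shuffle), function(i) {
      u <- sample(v)
      frac_table(u[-length(u)], u[-1])[["ss"]]
    })
  })
  tibble(q_short_short = obs[["ss"]], q_short_long = obs[["sl"]],
         q_long_short = obs[["ls"]], q_long_long = obs[["ll"]],
         burst_spread_index = obs[["ss"]] - mean(null_ss),
         threshold_s = thr, n_pairs = nrow(rp))
}

#' @export
autoplot.recurrence_pairs <- function(object, ...) {
  thr <- attr(object, "threshold_s")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$isi_prev_s, y = .data$isi_next_s)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = thr, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ISI n-1 (s)", y = "ISI n (s)") +
    ggplot2::theme_minimal()
}

# ISI histogram used by the exponential fits: 50 bins from 0 to the 99th
# percentile interval, trailing zero-count bins dropped.
isi_histogram <- function(v, n_bins = 50) {
  upper <- stats::quantile(v, 0.99, names = FALSE)
  edges <- seq(0, upper, length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  tibble(bin_mid = mids, count = counts)
}

#' Exponential fits to an interspike-interval histogram
#'
#' Least-squares fit of a one-phase (`A * exp(-t / tau)`) or two-phase
#' (`A1 * exp(-t / tau1) + A2 * exp(-t / tau2)`) exponential to the ISI
#' histogram (bin counts versus bin centers; 50 bins up to the 99th
#' percentile interval, zero-count bins excluded from the fit). Fitting
#' uses variable projection: time constants are optimized on the log
#' scale with the amplitudes solved linearly at each step, which is
#' deterministic and robust to starting values. Residual degrees of
#' freedom are the number of fitted (nonzero) bins minus the number of
#' parameters, as required by [extra_ss_f_test()].
#'
#' @param isis As in [isi_stats()]; two-phase fits need >= 50 intervals.
#' @param n_bins Histogram bins before zero-bin removal (default 50).
#' @param kind `"one_phase"` or `"two_phase"`.
#' @param bins Optional precomputed histogram tibble (`bin_mid`,
#'   `count`) overriding `isis`/`n_bins`; both fits of a nested pair
#'   must use the same histogram.
#' @return An `isi_exp_fit` object with fields `kind`, `params`
#'   (named vector), `ss`, `df`, `fitted` (tibble), `degenerate`.
#' @export
fit_isi_exponential <- function(isis, n_bins = 50,
                                kind = c("one_phase", "two_phase"),
                                bins = NULL) {
  kind <- match.arg(kind)
  if (is.null(bins)) {
    v <- isi_vector(isis)
    if (kind == "two_phase" && length(v) < 50) {
      abort("Two-phase fits need at least 50 intervals.",
            class = "afferent_bad_argument")
    }
    bins <- isi_histogram(v, n_bins)
  }
  fit_bins <- bins[bins$count > 0, ]
  x <- fit_bins$bin_mid
  y <- fit_bins$count
  n_par <- if (kind == "one_phase") 2L else 4L
  if (nrow(fit_bins) <= n_par) {
    abort("Too few nonzero bins for the requested fit.",
          class = "afferent_bad_argument")
  }

  # weighted first-moment starting scale
  tau0 <- max(sum(x * y) / sum(y), min(diff(sort(unique(x)))))

  if (kind == "one_phase") {
    obj <- function(lt) one_phase_ss(exp(lt), x, y)$ss
    opt <- optimize(obj, interval = log(tau0) + c(-6, 6), tol = 1e-12)
    sol <- one_phase_ss(exp(opt$minimum), x, y)
    params <- c(A = sol$A, tau = exp(opt$minimum))
    ss <- sol$ss
    fitted_y <- sol$A * exp(-bins$bin_mid / params[["tau"]])
    degenerate <- FALSE
  } else {
    obj <- function(p) two_phase_ss(exp(p[1]), exp(p[2]), x, y)$ss
    starts <- list(log(tau0 * c(0.25, 4)), log(tau0 * c(0.05, 1)),
                   log(tau0 * c(1, 10)))
    fits <- map(starts, function(s) {
      optim(s, obj, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-12))
    })
    best <- fits[[which.min(map_dbl(fits, "value"))]]
    taus <- sort(exp(best$par))
    sol <- two_phase_ss(taus[1], taus[2], x, y)
    params <- c(A1 = sol$A[1], tau1 = taus[1], A2 = sol$A[2], tau2 = taus[2])
    ss <- sol$ss
    fitted_y <- sol$A[1] * exp(-bins$bin_mid / taus[1]) +
      sol$A[2] * exp(-bins$bin_mid / taus[2])
    degenerate <- abs(log(taus[2] / taus[1])) < 0.01
    if (degenerate) {
      warn("Two-phase fit is degenerate (tau1 ~ tau2).",
           class = "afferent_degenerate_fit")
    }
  }
  structure(
    list(kind = kind, params = params, ss = ss,
         df = nrow(fit_bins) - n_par,
         n_bins_fit = nrow(fit_bins),
         fitted = mutate(bins, fitted = fitted_y),
         degenerate = degenerate),
    class = "isi_exp_fit")
}

one_phase_ss <- function(tau, x, y) {
  b <- exp(-x / tau)
  A <- sum(b * y) / sum(b * b)
  r <- y - A * b
  list(A = A, ss = sum(r^2))
}

two_phase_ss <- function(tau1, tau2, x, y) {
  b1 <- exp(-x / tau1)
  b2 <- exp(-x / tau2)
  g11 <- sum(b1 * b1); g12 <- sum(b1 * b2); g22 <- sum(b2 * b2)
  det <- g11 * g22 - g12^2
  if (det <= .Machine$double.eps * g11 * g22) {
    # collinear basis: fall back to the one-phase solution on b1
    A1 <- sum(b1 * y) / g11
    r <- y - A1 * b1
    return(list(A = c(A1, 0), ss = sum(r^2)))
  }
  c1 <- sum(b1 * y); c2 <- sum(b2 * y)
  A1 <- (g22 * c1 - g12 * c2) / det
  A2 <- (g11 * c2 - g12 * c1) / det
  r <- y - A1 * b1 - A2 * b2
  list(A = c(A1, A2), ss = sum(r^2))
}

#' @export
print.isi_exp_fit <- function(x, ...) {
  cat(sprintf("<isi_exp_fit> %s: %s; SS = %.4g on %d df\n", x$kind,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$ss, x$df))
  invisible(x)
}

#' @export
tidy.isi_exp_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.isi_exp_fit <- function(x, ...) {
  tibble(kind = x$kind, ss = x$ss, df = x$df, degenerate = x$degenerate)
}

#' @export
autoplot.isi_exp_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count),
                      width = diff(object$fitted$bin_mid[1:2]),
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "black") +
    ggplot2::labs(x = "interspike interval (s)", y = "count") +
    ggplot2::theme_minimal()
}

#' Extra sum-of-squares F test between nested exponential fits
#'
#' Compares a one-phase and a two-phase exponential fit of the same ISI
#' histogram: `F = ((SS1 - SS2) / (df1 - df2)) / (SS2 / df2)` with the p
#' value from the upper tail of `F(df1 - df2, df2)`. The two-phase model
#' is preferred when `p < alpha`. If the richer model fails to reduce
#' the residual sum of squares the simpler model is preferred outright.
#'
#' @param fit1 The one-phase `isi_exp_fit`.
#' @param fit2 The two-phase `isi_exp_fit` on the same histogram.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble with `f_stat`, `df_num`, `df_den`, `p`,
#'   `preferred`.
#' @export
extra_ss_f_test <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(inherits(fit1, "isi_exp_fit"), inherits(fit2, "isi_exp_fit"))
  if (fit1$kind != "one_phase" || fit2$kind != "two_phase") {
    abort("fit1 must be one_phase and fit2 two_phase.",
          class = "afferent_bad_argument")
  }
  if (fit1$n_bins_fit != fit2$n_bins_fit) {
    abort("Fits must come from the same histogram.",
          class = "afferent_bad_argument")
  }
  df_num <- fit1$df - fit2$df
  df_den <- fit2$df
  if (fit2$ss > fit1$ss) {
    return(tibble(f_stat = 0, df_num = df_num, df_den = df_den, p = 1,
                  preferred = "one_phase"))
  }
  if (fit2$ss == 0) {
    warn("Two-phase fit is exact (SS = 0); F is infinite.",
         class = "afferent_exact_fit")
    return(tibble(f_stat = Inf, df_num = df_num, df_den = df_den, p = 0,
                  preferred = "two_phase"))
  }
  f_stat <- ((fit1$ss - fit2$ss) / df_num) / (fit2$ss / df_den)
  p <- pf(f_stat, df_num, df_den, lower.tail = FALSE)
  tibble(f_stat = f_stat, df_num = df_num, df_den = df_den, p = p,
         preferred = if (p < alpha) "two_phase" else "one_phase")
}

#' Cumulative spike count after stimulus offset
#'
#' The recovery curve of spontaneous firing: cumulative number of spikes
#' at each spike time in `[stim_offset_s, stim_offset_s + horizon_s]`,
#' re-zeroed to the stimulus offset. Nondecreasing and starting at 0 by
#' construction.
#'
#' @param train A [spike_train()].
#' @param stim_offset_s Time of stimulus cessation, seconds.
#' @param horizon_s Length of the observation window after offset; must
#'   lie within the recording.
#' @return A `recovery_curve` tibble with `time_s` (since offset) and
#'   `cumulative_count`; the first row is `(0, 0)`.
#' @export
recovery_curve <- function(train, stim_offset_s = 0, horizon_s = NULL) {
  dur <- train_duration(train)
  horizon_s <- horizon_s %||% (dur - stim_offset_s)
  if (stim_offset_s < 0 || stim_offset_s + horizon_s > dur) {
    abort("Recovery window must lie within the recording.",
          class = "afferent_bad_argument")
  }
  tt <- train$time_s[train$time_s >= stim_offset_s &
                       train$time_s <= stim_offset_s + horizon_s] -
    stim_offset_s
  structure(
    tibble(time_s = c(0, tt),
           cumulative_count = c(0L, seq_along(tt))),
    class = c("recovery_curve", class(tibble())),
    horizon_s = horizon_s, label = attr(train, "label"))
}

#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$cumulative_count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time after stimulus offset (s)",
                  y = "cumulative spike count") +
    ggplot2::theme_minimal()
}

#' Summary metrics of a recovery curve
#'
#' Time to the k-th recovered spike (NA when not reached within the
#' horizon) and the late-phase firing rate, the least-squares slope of
#' the cumulative count over `late_window` (requires >= 2 curve points
#' in the window; 0 when the curve is flat there with a single anchor
#' point, NA when undefined).
#'
#' @param curve A `recovery_curve`.
#' @param k Spike count defining the recovery latency.
#' @param late_window Length-2 numeric `(t0, t1)` in seconds after
#'   offset.
#' @return One-row tibble with `time_to_k_spikes_s`, `k`,
#'   `late_rate_hz`.
#' @export
recovery_metrics <- function(curve, k = 100,
                             late_window = c(0.75, 1) * max(curve$time_s)) {
  stopifnot(inherits(curve, "recovery_curve"))
  check_number(k, "k", lower = 0)
  t_k <- if (max(curve$cumulative_count) >= k) {
    curve$time_s[match(TRUE, curve$cumulative_count >= k)]
  } else NA_real_
  inwin <- curve$time_s >= late_window[1] & curve$time_s <= late_window[2]
  late_rate <- if (sum(inwin) >= 2) {
    unname(coef(lm(cumulative_count ~ time_s, data = curve[inwin, ]))[2])
  } else if (sum(inwin) <= 1 &&
             sum(curve$cumulative_count > 0 & inwin) == 0) {
    warn("Fewer than 2 curve points in late_window; late rate set to 0.",
         class = "afferent_sparse_window")
    0
  } else NA_real_
  tibble(time_to_k_spikes_s = t_k, k = k, late_rate_hz = late_rate)
}
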