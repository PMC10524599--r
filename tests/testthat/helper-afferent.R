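# Shared fixtures and independent oracles used across the suite.

# Brute-force vector strength: explicit loop over spikes summing the unit
# vectors, kept deliberately separate from the package implementation.
vs_oracle <- function(fractions) {
  cx <- 0
  sy <- 0
  for (f in fractions) {
    cx <- cx + cos(2 * pi * f)
    sy <- sy + sin(2 * pi * f)
  }
  sqrt(cx^2 + sy^2) / length(fractions)
}

# Brute-force OLS slope via the normal equations, independent of lm().
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Wrapped-normal phase fractions, drawn directly (not via the generators).
wrapped_normal_phases <- function(n, mu, sigma, seed) {
  withr::with_seed(seed, (mu + sigma * rnorm(n)) %% 1)
}

# Circular mean of phase fractions, mapped to [0, 1).
circ_mean <- function(fractions) {
  (atan2(sum(sin(2 * pi * fractions)), sum(cos(2 * pi * fractions))) /
     (2 * pi)) %% 1
}

# Signed circular distance between two fractions, in (-0.5, 0.5].
circ_diff <- function(a, b) {
  (a - b + 0.5) %% 1 - 0.5
}

# Synthetic one-phase histogram with Gaussian noise: the regime where the
# extra-sum-of-squares F reference distribution is exact.
one_phase_noisy_bins <- function(amp = 100, tau = 0.1, noise_sd = 2,
                                 n_bins = 50, t_max = 0.5) {
  x <- seq(t_max / n_bins / 2, t_max, length.out = n_bins)
  y <- amp * exp(-x / tau) + rnorm(n_bins, sd = noise_sd)
  tibble::tibble(bin_mid = x, count = pmax(y, 1e-3))
}

# Construct a bare fit object for F-test arithmetic checks.
fake_exp_fit <- function(kind, ss, df, n_bins_fit = df + ifelse(kind == "one_phase", 2L, 4L)) {
  structure(list(kind = kind, params = c(A = 1, tau = 1), ss = ss, df = df,
                 n_bins_fit = n_bins_fit, degenerate = FALSE),
            class = "isi_exp_fit")
}
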