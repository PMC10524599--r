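test_that("phase-locked generator reproduces its wrapped-normal parameters", {
  stim <- stimulus_spec(20, duration_s = 60)

  # degenerate limits
  locked <- sim_phase_locked_train(stim, 0.3, 0, seed = 1)
  ph <- assign_phases(locked, stim)
  expect_equal(nrow(locked), 1200)
  expect_true(all(abs(ph$fraction - 0.3) < 1e-9))
  expect_equal(vector_strength(ph)$r, 1)
  expect_equal(nrow(sim_phase_locked_train(stim, 0.3, 0.05, p_spike = 0,
                                           seed = 1)), 0)

  # circular mean of emitted latencies tracks the generating mean
  mu_hat <- vapply(1:10, function(s) {
    tr <- sim_phase_locked_train(stim, 0.158, 0.0455, seed = s)
    circ_mean(assign_phases(tr, stim)$fraction)
  }, numeric(1))
  expect_lt(abs(mean(circ_diff(mu_hat, 0.158))), 3 * sd(mu_hat) / sqrt(10))

  # bit-reproducibility and refractory rejection
  expect_identical(sim_phase_locked_train(stim, 0.158, 0.0455, seed = 4)$time_s,
                   sim_phase_locked_train(stim, 0.158, 0.0455, seed = 4)$time_s)
  expect_error(sim_phase_locked_train(stim, 0.1, 0.05, refractory_s = 0.06),
               class = "afferent_bad_argument")
  expect_error(sim_phase_locked_train(stim, 0.1, 0.05, p_spike = 1.2),
               class = "afferent_bad_argument")
})

test_that("sample vector strength matches the wrapped-normal closed form", {
  stim <- stimulus_spec(20, duration_s = 500)  # 10,000 cycles
  for (sigma in c(0.03, 0.07, 0.10, 0.15)) {
    r_seed <- vapply(1:10, function(s) {
      tr <- sim_phase_locked_train(stim, 0.25, sigma, seed = 100 + s)
      vector_strength(assign_phases(tr, stim))$r
    }, numeric(1))
    r_theory <- exp(-2 * pi^2 * sigma^2)
    se <- sd(r_seed) / sqrt(length(r_seed))
    expect_lt(abs(mean(r_seed) - r_theory), 3 * se + 1e-4)
  }
})

test_that("renewal spontaneous trains hit their target mean ISI and CV", {
  stats_by_seed <- purrr::map(1:10, function(s) {
    tr <- sim_spontaneous_train("renewal", mean_isi_s = 0.1, cv = 1,
                                duration_s = 400, seed = s)
    isi_stats(compute_isi(tr))
  }) |> purrr::list_rbind()
  # exponential ISIs: CV = 1, mean = mean_isi_s
  expect_lt(abs(mean(stats_by_seed$cv) - 1),
            3 * sd(stats_by_seed$cv) / sqrt(10))
  expect_lt(abs(mean(stats_by_seed$mean_isi_s) - 0.1),
            3 * sd(stats_by_seed$mean_isi_s) / sqrt(10))

  # near-periodic limit
  reg <- sim_spontaneous_train("renewal", 0.1, cv = 1e-3, duration_s = 50,
                               seed = 2)
  expect_lt(isi_stats(compute_isi(reg))$cv, 0.01)

  # p_enter = 0 collapses the bursty chain onto the renewal process
  a <- sim_spontaneous_train("renewal", 0.1, cv = 1, duration_s = 100, seed = 9)
  b <- sim_spontaneous_train("bursty", 0.1, cv = 1, duration_s = 100, seed = 9,
                             burst = list(p_enter = 0, p_exit = 0.3,
                                          isi_in_burst_s = 0.01))
  expect_identical(a$time_s, b$time_s)

  expect_error(sim_spontaneous_train("renewal", -1, duration_s = 10),
               class = "afferent_bad_argument")
})

test_that("bursty trains are more variable than matched Poisson-like trains", {
  cvs <- purrr::map_dbl(1:8, function(s) {
    tr <- sim_spontaneous_train(
      "bursty", mean_isi_s = 0.3, cv = 1, duration_s = 400, seed = s,
      burst = list(p_enter = 0.1, p_exit = 0.3, isi_in_burst_s = 0.02))
    isi_stats(compute_isi(tr))$cv
  })
  cv_renewal <- purrr::map_dbl(1:8, function(s) {
    tr <- sim_spontaneous_train("renewal", 0.3, cv = 1, duration_s = 400,
                                seed = 100 + s)
    isi_stats(compute_isi(tr))$cv
  })
  expect_gt(mean(cvs), mean(cv_renewal))
})

test_that("recovery trains follow the delayed-exponential rate profile", {
  # near-homogeneous limit
  tr0 <- sim_recovery_train(5, recovery_delay_s = 1e-9,
                            recovery_tau_s = 1e-6, duration_s = 400,
                            seed = 1)
  expect_lt(abs(nrow(tr0) / 400 - 5), 3 * sqrt(5 / 400))

  # cumulative curve tracks the integrated rate within Poisson noise
  tr <- sim_recovery_train(5, 100, 60, duration_s = 900, seed = 3)
  curve <- recovery_curve(tr)
  for (t_probe in c(150, 300, 600, 900)) {
    expected <- recovery_expected_count(t_probe, 5, 100, 60)
    observed <- max(curve$cumulative_count[curve$time_s <= t_probe])
    expect_lt(abs(observed - expected), 3 * sqrt(expected))
  }
  expect_true(all(diff(curve$cumulative_count) >= 0))

  # shorter delay dominates in expectation at every probe time
  probes <- c(50, 100, 200, 400, 900)
  counts_at <- function(delay) {
    rowMeans(vapply(1:10, function(s) {
      tr <- sim_recovery_train(5, delay, 60, 900, seed = 200 + s)
      vapply(probes, function(p) sum(tr$time_s <= p), numeric(1))
    }, numeric(length(probes))))
  }
  expect_true(all(counts_at(10) >= counts_at(200)))
})

test_that("action-current traces have calibrated noise, amplitude and length", {
  empty <- spike_train(numeric(0), duration_s = 60)
  noise <- sim_action_current_trace(empty, 0, noise_sd_au = 1.5, seed = 1)
  expect_equal(sd(noise$current_au), 1.5, tolerance = 0.02)

  one_s <- sim_action_current_trace(spike_train(0.5, duration_s = 1), 0,
                                    noise_sd_au = 1, seed = 1)
  expect_equal(nrow(one_s), 20000)

  # recorded spike amplitude matches the requested (post-filter) peak
  quiet <- sim_action_current_trace(spike_train(0.5, duration_s = 1), 10,
                                    noise_sd_au = 0, seed = 1)
  expect_equal(min(quiet$current_au), -10, tolerance = 0.02)
  expect_lt(abs(quiet$time_s[which.min(quiet$current_au)] - 0.5), 5e-4)

  expect_error(
    sim_action_current_trace(empty, 1, spike_width_s = 1e-6),
    class = "afferent_bad_argument")
  expect_message(
    sim_action_current_trace(spike_train(c(0.5, 0.5004), duration_s = 1), 5,
                             seed = 1),
    "superposition")
})

test_that("plate generator produces the stated saturating curves", {
  flat_design <- plate_design(
    conditions = tibble::tibble(variant = "none", nsf_nM = 0,
                                complex_kind = "ternary", k_obs = 0,
                                f0_au = 100, fmax_au = 100,
                                drift_au_per_s = 0),
    replicates = 3, noise_sd_au = 1)
  flat <- sim_plate(flat_design, seed = 1)
  tr <- dplyr::filter(flat, replicate == 1)
  rr <- initial_rate(tr, 112.5)
  expect_lt(abs(rr$slope_au_per_s), 3 * rr$slope_se)

  # closed form at zero noise: F(112.5) = 100 + 100 * (1 - exp(-1.125))
  d <- plate_design(
    conditions = tibble::tibble(variant = "WT", nsf_nM = 8.3,
                                complex_kind = "ternary", k_obs = 0.01,
                                f0_au = 100, fmax_au = 200,
                                drift_au_per_s = 0),
    replicates = 3, noise_sd_au = 0, sample_interval_s = 2.5,
    duration_s = 600)
  pl <- sim_plate(d, seed = 1)
  t1 <- dplyr::filter(pl, replicate == 1)
  expect_equal(t1$fluorescence_au[t1$time_s == 112.5],
               100 + 100 * (1 - exp(-1.125)), tolerance = 1e-12)
  # noiseless replicates share the backbone exactly
  wide <- tidyr::pivot_wider(pl, names_from = "replicate",
                             values_from = "fluorescence_au")
  expect_equal(wide$`1`, wide$`2`)
  expect_equal(wide$`1`, wide$`3`)

  expect_error(plate_design(conditions = tibble::tibble(
    variant = "WT", nsf_nM = 0, complex_kind = "ternary", k_obs = 0.1,
    f0_au = 0, fmax_au = 1, drift_au_per_s = 0)),
    class = "afferent_bad_argument")
})
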