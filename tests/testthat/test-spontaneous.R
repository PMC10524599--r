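test_that("ISI statistics use the sample SD over the mean", {
  expect_equal(isi_stats(rep(0.1, 10)),
               tibble::tibble(mean_isi_s = 0.1, cv = 0, n_isi = 10L))
  # hand computation with the n-1 denominator
  st <- isi_stats(c(0.1, 0.3))
  expect_equal(st$mean_isi_s, 0.2)
  expect_equal(st$cv, sqrt(0.02) / 0.2, tolerance = 1e-12)

  ex <- sim_spontaneous_train("renewal", 0.1, 1, duration_s = 200, seed = 1)
  st2 <- isi_stats(compute_isi(ex))
  expect_lt(abs(st2$cv - 1), 3 / sqrt(st2$n_isi))

  expect_error(isi_stats(0.1), class = "afferent_too_few_spikes")
  expect_error(isi_stats(c(0.1, -0.2, 0.3)), class = "afferent_bad_argument")
})

test_that("recurrence pairs are consecutive-interval coordinates", {
  rp <- isi_recurrence(c(1, 2, 3))
  expect_equal(rp$isi_prev_s, c(1, 2))
  expect_equal(rp$isi_next_s, c(2, 3))
  expect_equal(attr(rp, "threshold_s"), 2)

  # periodic train: all pairs on the diagonal
  rp2 <- isi_recurrence(rep(0.25, 20))
  expect_true(all(rp2$isi_prev_s == 0.25 & rp2$isi_next_s == 0.25))

  rp3 <- isi_recurrence(c(1, 2, 3), threshold = 1.5)
  expect_equal(attr(rp3, "threshold_s"), 1.5)
  expect_error(isi_recurrence(0.5), class = "afferent_too_few_spikes")
})

test_that("burst metrics partition quadrants and center the index at zero", {
  # periodic train, median threshold: every pair ties into short-short
  bm <- burst_metrics(isi_recurrence(rep(0.25, 30)), seed = 1)
  expect_equal(bm$q_short_short, 1)
  expect_equal(bm$q_short_short + bm$q_short_long + bm$q_long_short +
                 bm$q_long_long, 1, tolerance = 1e-12)

  # renewal train: order carries no information, index ~ 0
  tr <- sim_spontaneous_train("renewal", 0.1, 1, duration_s = 400, seed = 2)
  rp <- isi_recurrence(compute_isi(tr))
  bm2 <- burst_metrics(rp, n_shuffle = 100, seed = 3)
  expect_equal(bm2$q_short_short + bm2$q_short_long + bm2$q_long_short +
                 bm2$q_long_long, 1, tolerance = 1e-12)
  # permutation-null spread at this n is well under 0.05
  expect_lt(abs(bm2$burst_spread_index), 0.05)
})

test_that("bursty generator trains score positive burst spread", {
  burst <- list(p_enter = 0.1, p_exit = 0.3, isi_in_burst_s = 0.03)
  res <- purrr::map(1:10, function(s) {
    btr <- sim_spontaneous_train("bursty", 0.3, 1, burst = burst,
                                 duration_s = 400, seed = s)
    rtr <- sim_spontaneous_train("renewal", 0.3, 1, duration_s = 400,
                                 seed = 400 + s)
    b <- burst_metrics(isi_recurrence(compute_isi(btr)), seed = s)
    r <- burst_metrics(isi_recurrence(compute_isi(rtr)), seed = s)
    tibble::tibble(bsi_bursty = b$burst_spread_index,
                   bsi_renewal = r$burst_spread_index,
                   qss_bursty = b$q_short_short,
                   qss_renewal = r$q_short_short)
  }) |> purrr::list_rbind()
  expect_gte(sum(res$bsi_bursty > 0), 9)
  # within-burst clustering concentrates pairs in the short-short quadrant
  expect_gt(mean(res$qss_bursty), mean(res$qss_renewal))
  expect_gt(mean(res$bsi_bursty), mean(res$bsi_renewal))
})

test_that("exponential ISI fits recover generating time constants", {
  # noiseless one-phase histogram: exact recovery
  x <- seq(0.005, 0.5, length.out = 50)
  bins <- tibble::tibble(bin_mid = x, count = 80 * exp(-x / 0.07))
  f <- fit_isi_exponential(bins = bins, kind = "one_phase")
  expect_lt(f$ss, 1e-8)
  expect_equal(unname(f$params["tau"]), 0.07, tolerance = 1e-4)
  expect_equal(unname(f$params["A"]), 80, tolerance = 1e-3)
  expect_equal(f$df, 48)

  # generator round trip: exponential ISIs, mean 0.1 s
  tr <- sim_spontaneous_train("renewal", 0.1, 1, duration_s = 600, seed = 4)
  f1 <- fit_isi_exponential(compute_isi(tr), kind = "one_phase")
  expect_equal(unname(f1$params["tau"]), 0.1, tolerance = 0.15)

  # two-phase mixture: both time constants within 20% at n = 5000
  isis <- withr::with_seed(8, {
    pick <- runif(5000) < 0.5
    ifelse(pick, rexp(5000, 1 / 0.02), rexp(5000, 1 / 0.5))
  })
  f2 <- fit_isi_exponential(isis, kind = "two_phase")
  taus <- sort(unname(f2$params[c("tau1", "tau2")]))
  expect_lt(abs(taus[1] - 0.02) / 0.02, 0.2)
  expect_lt(abs(taus[2] - 0.5) / 0.5, 0.2)
  expect_false(f2$degenerate)
  expect_equal(glance(f2)$df, f2$df)

  expect_error(fit_isi_exponential(rexp(20), kind = "two_phase"),
               class = "afferent_bad_argument")
})

test_that("extra sum-of-squares F test follows its arithmetic and nesting", {
  f1 <- fake_exp_fit("one_phase", ss = 2, df = 12)
  f2 <- fake_exp_fit("two_phase", ss = 1, df = 10, n_bins_fit = 14)
  res <- extra_ss_f_test(fake_exp_fit("one_phase", 2, 12, 14), f2)
  expect_equal(res$f_stat, 5)
  expect_equal(res$p, pf(5, 2, 10, lower.tail = FALSE))

  # equal residuals: F = 0, p = 1, simpler model wins
  eq <- extra_ss_f_test(fake_exp_fit("one_phase", 1, 12, 14),
                        fake_exp_fit("two_phase", 1, 10, 14))
  expect_equal(eq$f_stat, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$preferred, "one_phase")

  # richer model failing to improve: simpler model outright
  worse <- extra_ss_f_test(fake_exp_fit("one_phase", 1, 12, 14),
                           fake_exp_fit("two_phase", 1.1, 10, 14))
  expect_equal(worse$preferred, "one_phase")

  # perfect two-phase fit: infinite F, p = 0
  expect_warning(
    perfect <- extra_ss_f_test(fake_exp_fit("one_phase", 1, 12, 14),
                               fake_exp_fit("two_phase", 0, 10, 14)),
    class = "afferent_exact_fit")
  expect_equal(perfect$p, 0)
  expect_equal(perfect$preferred, "two_phase")

  expect_error(extra_ss_f_test(f2, f1), class = "afferent_bad_argument")
})

test_that("recovery curves accumulate spikes after stimulus offset", {
  # no post-offset spikes: flat zero curve, metrics degrade gracefully
  tr <- spike_train(c(1, 2), duration_s = 100)
  flat <- recovery_curve(tr, stim_offset_s = 50, horizon_s = 50)
  expect_equal(max(flat$cumulative_count), 0)
  expect_warning(m <- recovery_metrics(flat, k = 10,
                                       late_window = c(40, 50)),
                 class = "afferent_sparse_window")
  expect_true(is.na(m$time_to_k_spikes_s))
  expect_equal(m$late_rate_hz, 0)

  # homogeneous Poisson: curve tracks lambda * t
  pois <- sim_spontaneous_train("renewal", 0.2, 1, duration_s = 400,
                                seed = 6)
  curve <- recovery_curve(pois)
  for (t_probe in c(100, 200, 400)) {
    got <- max(curve$cumulative_count[curve$time_s <= t_probe])
    expect_lt(abs(got - 5 * t_probe), 3 * sqrt(5 * t_probe))
  }
  expect_true(all(diff(curve$cumulative_count) >= 0))

  # time to k-th spike for a 5-Hz train: gamma mean k/lambda
  mt <- recovery_metrics(curve, k = 10, late_window = c(300, 400))
  expect_lt(abs(mt$time_to_k_spikes_s - 2), 3 * sqrt(10) / 5)
  # late rate approaches the asymptotic spontaneous rate
  expect_lt(abs(mt$late_rate_hz - 5), 1)

  # delayed recovery stays below prompt recovery throughout
  probes <- c(100, 300, 600, 900)
  below <- vapply(1:10, function(s) {
    del <- recovery_curve(sim_recovery_train(5, 200, 60, 900, seed = s))
    imm <- recovery_curve(sim_recovery_train(5, 1e-6, 60, 900,
                                             seed = 500 + s))
    all(vapply(probes, function(p) {
      max(del$cumulative_count[del$time_s <= p]) <=
        max(imm$cumulative_count[imm$time_s <= p])
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(below), 9)

  expect_error(recovery_curve(tr, 50, 100), class = "afferent_bad_argument")
})

test_that("late recovery rate converges to the generator baseline", {
  tr <- sim_recovery_train(8, recovery_delay_s = 50, recovery_tau_s = 40,
                           duration_s = 900, seed = 12)
  curve <- recovery_curve(tr)
  mt <- recovery_metrics(curve, k = 100, late_window = c(600, 900))
  expect_lt(abs(mt$late_rate_hz - 8), 1.5)
})
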