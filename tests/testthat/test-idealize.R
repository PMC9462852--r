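make_const_trace <- function(value, n, fs = 1e5, fc = Inf, amp = 5) {
  popencycle:::new_sc_trace(rep(value, n), fs = fs, fc = fc, baseline = 0,
                            amp = amp)
}

test_that("the Gaussian filter has unit DC gain and a normalized kernel", {
  tr <- make_const_trace(2.5, 5000)
  out <- gaussian_filter(tr, 3000)
  expect_equal(out$samples, rep(2.5, 5000), tolerance = 1e-12)
  expect_equal(length(out$samples), 5000L)
  # unit impulse maps to the kernel, which sums to 1
  imp <- make_const_trace(0, 4001)
  imp$samples[2001] <- 1
  kout <- gaussian_filter(imp, 3000)
  expect_lt(abs(sum(kout$samples) - 1), 1e-9)
  # composed cutoff bookkeeping
  tr10 <- make_const_trace(0, 100, fc = 10000)
  expect_equal(gaussian_filter(tr10, 3000)$fc,
               1 / sqrt(1 / 10000^2 + 1 / 3000^2))
  expect_error(gaussian_filter(tr, 6e4), class = "popencycle_config_error")
})

test_that("white noise is attenuated by the kernel l2-norm", {
  set.seed(21)
  n <- 5e5
  tr <- popencycle:::new_sc_trace(rnorm(n), fs = 1e5, fc = Inf, baseline = 0,
                                  amp = 5)
  out <- gaussian_filter(tr, 3000)
  k <- popencycle:::gaussian_kernel(1e5, 3000)
  expect_lt(abs(sd(out$samples) - sqrt(sum(k^2))) / sqrt(sum(k^2)), 0.05)
})

test_that("resampling preserves duration and pulse widths", {
  tr <- make_const_trace(1, 300000, fs = 1e5, fc = 1e4)
  out <- resample(tr, 1e5 / 3)
  expect_equal(length(out$samples), 1e5, tolerance = 1)
  expect_true(all(out$samples == 1))
  expect_equal(out$fs, 1e5 / 3)
  # a 10 ms square pulse keeps its width to within one output sample
  d <- manual_dwells(open_ms = 10, shut_ms = numeric(0))
  d <- dplyr::bind_rows(
    tibble::tibble(record_id = "p", cluster_id = NA_integer_, state = "shut",
                   duration_ms = 20, amplitude_pA = 0, truth_state = "shut"),
    d,
    tibble::tibble(record_id = "p", cluster_id = NA_integer_, state = "shut",
                   duration_ms = 20, amplitude_pA = 0, truth_state = "shut")
  )
  pulse <- render_trace(d, fs = 1e5, amp = 5, fc = 1e4)
  down <- resample(pulse, 1e5 / 3)
  width_ms <- sum(down$samples > 2.5) / down$fs * 1000
  expect_lt(abs(width_ms - 10), 1000 / down$fs)
  # near-identity limit on a smooth input
  smooth <- popencycle:::new_sc_trace(sin(2 * pi * 5 * ((1:20000) - 0.5) / 1e5),
                                      fs = 1e5, fc = 100, baseline = 0, amp = 1)
  near <- resample(smooth, 1e5 / 1.0001)
  ref <- sin(2 * pi * 5 * ((seq_along(near$samples) - 0.5) / near$fs))
  expect_lt(max(abs(near$samples - ref)), 1e-6)
  expect_error(resample(tr, 2e5), class = "popencycle_config_error")
})

test_that("threshold idealization recovers noiseless alternating levels exactly", {
  d <- manual_dwells(open_ms = c(10, 10, 10), shut_ms = c(10, 10))
  fs <- 1e5
  tr <- render_trace(d, fs = fs, amp = 5, noise_sd = 0, fc = 2e4)
  ideal <- threshold_idealize(tr, idealization_settings(fc_post = 3000))
  expect_identical(nrow(ideal), nrow(d))
  expect_identical(ideal$state, d$state)
  expect_true(all(abs(ideal$duration_ms - d$duration_ms) <= 1000 / fs + 1e-9))
  expect_identical(ideal$censored, c(TRUE, rep(FALSE, nrow(d) - 2L), TRUE))
  # total idealized time equals trace duration within one sample
  expect_lt(abs(sum(ideal$duration_ms) - length(tr$samples) / fs * 1000),
            1000 / fs + 1e-9)
})

test_that("an all-baseline trace yields a single censored shut dwell", {
  tr <- make_const_trace(0, 5000)
  ideal <- threshold_idealize(tr, idealization_settings())
  expect_identical(nrow(ideal), 1L)
  expect_identical(ideal$state, "shut")
  expect_true(ideal$censored)
})

test_that("missing level metadata is an error unless estimation is enabled", {
  tr <- make_const_trace(0, 1000)
  tr$amp <- NA_real_
  expect_error(threshold_idealize(tr, idealization_settings()),
               class = "popencycle_data_error")
  # estimation path: two-level trace without metadata; the shut level is the
  # more populated one, as in a real recording
  d <- manual_dwells(open_ms = c(10, 10), shut_ms = 40)
  tr2 <- render_trace(d, fs = 5e4, amp = 5, noise_sd = 0.2, fc = 5e3, seed = 1)
  tr2$amp <- NA_real_
  lv <- estimate_levels(tr2)
  expect_lt(abs(lv$baseline), 0.25)
  expect_lt(abs(lv$amp - 5), 0.25)
  ideal <- threshold_idealize(tr2, idealization_settings(), estimate = TRUE)
  expect_identical(sum(ideal$state == "open"), 2L)
})

test_that("idealization is idempotent on its own noiseless reconstruction", {
  par <- gating_params(alpha = 40, beta = 40, desens_prob = 0.1,
                       mean_desens = 0.3, n_clusters = 2, seed = 8)
  truth <- simulate_dwells(par)
  fs <- 1e5
  tr <- render_trace(truth, fs = fs, amp = 5, noise_sd = 0, fc = 2e4)
  i1 <- threshold_idealize(tr, idealization_settings(fc_post = 5000))
  tr2 <- render_trace(i1, fs = fs, amp = 5, noise_sd = 0, fc = 2e4)
  i2 <- threshold_idealize(tr2, idealization_settings(fc_post = 5000))
  expect_identical(i1$state, i2$state)
  expect_true(all(abs(i1$duration_ms - i2$duration_ms) <= 1000 / fs + 1e-9))
})

test_that("double openings are flagged only when they outlast the rise time", {
  base <- manual_dwells(open_ms = c(10, 10), shut_ms = 10)
  fs <- 1e5; fc <- 1e4
  tr <- render_trace(base, fs = fs, amp = 5, fc = fc)
  expect_identical(nrow(detect_double_openings(tr, idealization_settings())), 0L)
  # inject a 5 ms excursion to twice the unitary amplitude
  tr2 <- tr
  tr2$samples[10000:10500] <- 10
  hits <- detect_double_openings(tr2, idealization_settings())
  expect_identical(nrow(hits), 1L)
  expect_lt(hits$start_ms, 100.01)
  expect_gt(hits$end_ms, 104.9)
  # an excursion shorter than one rise time is ignored
  tr3 <- tr
  rise_samples <- floor(popencycle:::gaussian_rise_time(tr$fc) * fs)
  tr3$samples[20000:(20000 + rise_samples - 2L)] <- 10
  expect_identical(nrow(detect_double_openings(tr3, idealization_settings())), 0L)
})

test_that("event recovery does not degrade as noise decreases", {
  par <- gating_params(alpha = 100, beta = 100, desens_prob = 0.05,
                       mean_desens = 0.2, n_clusters = 2, seed = 30)
  truth <- simulate_dwells(par)
  recovered <- vapply(c(1.5, 0.75, 0.25), function(noise) {
    tr <- render_trace(truth, fs = 1e5, amp = 5, noise_sd = noise, fc = 1e4,
                       seed = 31)
    tr <- resample(gaussian_filter(tr, 3000), 1e5 / 3)
    ideal <- threshold_idealize(tr, idealization_settings())
    mean(event_recovery(truth, ideal, min_duration_ms = 1)$recovered)
  }, numeric(1))
  expect_true(all(diff(recovered) >= 0))
})
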