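test_that("rise and decay times match bisection on the closed form", {
  A <- 100; tr_ms <- 1; td_ms <- 10
  trace <- generate_ipsc_trace(ipsc_params(amplitude = A, tau_rise = tr_ms,
                                           tau_decay = td_ms,
                                           noise_sigma = 0),
                               dt_ms = 0.001)
  m <- measure_ipsc(trace)
  pk <- synappose:::dexp_peak(tr_ms, td_ms)
  t20 <- ipsc_crossing_oracle(A, tr_ms, td_ms, 0.2 * A, 1e-9, pk$s)
  t80 <- ipsc_crossing_oracle(A, tr_ms, td_ms, 0.8 * A, 1e-9, pk$s)
  t33 <- ipsc_crossing_oracle(A, tr_ms, td_ms, 0.33 * A, pk$s, 200)
  expect_equal(m$rise_20_80_ms, t80 - t20, tolerance = 1e-4)
  expect_equal(m$decay_100_33_ms, t33 - pk$s, tolerance = 2e-3)
  expect_equal(m$amplitude_pA, A, tolerance = 1e-5)
  expect_equal(m$polarity, "inward")
})

test_that("kinetic metrics are scale-invariant and offset-invariant", {
  p1 <- ipsc_params(amplitude = 100, noise_sigma = 0)
  p2 <- ipsc_params(amplitude = 200, noise_sigma = 0)
  m1 <- measure_ipsc(generate_ipsc_trace(p1))
  m2 <- measure_ipsc(generate_ipsc_trace(p2))
  expect_equal(m1$rise_20_80_ms, m2$rise_20_80_ms, tolerance = 1e-9)
  expect_equal(m1$decay_100_33_ms, m2$decay_100_33_ms, tolerance = 1e-9)
  expect_equal(m2$amplitude_pA / m1$amplitude_pA, 2, tolerance = 1e-9)
  ## constant shift of the whole trace changes nothing
  tr <- generate_ipsc_trace(p1)
  tr_shift <- tr; tr_shift$current_pA <- tr$current_pA - 40
  m3 <- measure_ipsc(tr_shift)
  expect_equal(m3$amplitude_pA, m1$amplitude_pA, tolerance = 1e-9)
  expect_equal(m3$rise_20_80_ms, m1$rise_20_80_ms, tolerance = 1e-9)
  expect_equal(m3$decay_100_33_ms, m1$decay_100_33_ms, tolerance = 1e-9)
})

test_that("a flat trace reports zero amplitude and missing kinetics", {
  tr <- generate_ipsc_trace(ipsc_params(amplitude = 0, baseline = -5,
                                        noise_sigma = 0))
  m <- measure_ipsc(tr)
  expect_equal(m$amplitude_pA, 0)
  expect_true(is.na(m$rise_20_80_ms) && is.na(m$decay_100_33_ms))
})

test_that("an incomplete decay is reported missing with a warning", {
  tr <- generate_ipsc_trace(ipsc_params(amplitude = 100, tau_rise = 1,
                                        tau_decay = 400, noise_sigma = 0),
                            duration_ms = 40)
  expect_warning(m <- measure_ipsc(tr), "decay incomplete")
  expect_true(is.na(m$decay_100_33_ms))
  expect_gt(m$amplitude_pA, 0)
})

test_that("paired-pulse ratios are exact without overlap", {
  for (ppr in c(1, 2)) {
    tr <- generate_ipsc_trace(ipsc_params(amplitude = 100, ppr_true = ppr,
                                          stimulus_times_ms = c(10, 410),
                                          noise_sigma = 0))
    expect_equal(paired_pulse_ratio(tr)$ratio, ppr, tolerance = 1e-3)
  }
})

test_that("decay subtraction removes the short-interval overlap bias", {
  tr <- generate_ipsc_trace(ipsc_params(amplitude = 100, ppr_true = 0.8,
                                        stimulus_times_ms = c(10, 35),
                                        noise_sigma = 0))
  with_sub <- suppressWarnings(paired_pulse_ratio(tr))
  without <- suppressWarnings(paired_pulse_ratio(tr,
                                                 subtract_decay = FALSE))
  expect_equal(with_sub$ratio, 0.8, tolerance = 0.02 * 0.8)
  expect_gt(without$ratio, with_sub$ratio)   # overlap biases high
  ## the biased ratio equals the maximum of the analytic summed waveform
  ## in the response-2 window, relative to the first amplitude
  pk <- synappose:::dexp_peak(1, 10)
  g <- function(s) ifelse(s >= 0, exp(-s / 10) - exp(-s / 1), 0)
  tt <- seq(37, 120, by = 1e-4)              # after stimulus 2 + blank
  biased <- max(100 / pk$g * g(tt - 12) + 80 / pk$g * g(tt - 37)) / 100
  expect_equal(without$ratio, biased, tolerance = 2e-3)
})

test_that("a zero first response leaves the ratio undefined", {
  tr <- generate_ipsc_trace(ipsc_params(amplitude = 0,
                                        stimulus_times_ms = c(10, 60),
                                        noise_sigma = 0))
  expect_warning(p <- paired_pulse_ratio(tr), "undefined")
  expect_true(is.na(p$ratio))
})

test_that("paired-pulse recovery holds across intervals at realistic SNR", {
  set.seed(33)
  for (iv in c(25, 50, 100, 200, 400)) {
    tr <- generate_ipsc_trace(ipsc_params(amplitude = 400, ppr_true = 0.8,
                                          stimulus_times_ms = c(10, 10 + iv),
                                          noise_sigma = 5))
    p <- suppressWarnings(paired_pulse_ratio(tr))
    expect_equal(p$ratio, 0.8, tolerance = 0.02)
  }
})
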