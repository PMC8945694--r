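test_that("Savitzky-Golay (2,7) reproduces polynomials exactly everywhere", {
  t <- seq(0, 300, by = 10)
  x <- 2.5 - 0.03 * t + 4e-4 * t^2
  sg <- sg_smooth_deriv(x, 10)
  expect_equal(sg$smooth, x, tolerance = 1e-10)
  expect_equal(sg$deriv, -0.03 + 8e-4 * t, tolerance = 1e-10)
  expect_equal(sg$deriv2, rep(8e-4, length(t)), tolerance = 1e-10)
  # constant input: derivative identically zero
  sgc <- sg_smooth_deriv(rep(5, 20), 10)
  expect_equal(sgc$deriv, rep(0, 20), tolerance = 1e-12)
  expect_error(sg_smooth_deriv(1:6, 10), "7 samples")
})

test_that("SG(2,7) attenuates white noise by the closed-form factor", {
  # interior smoothing weights give variance factor sum(w^2) = 1/3
  set.seed(1)
  x <- rnorm(20000)
  sm <- sg_smooth_deriv(x, 1)$smooth
  interior <- 4:19997
  expect_equal(sd(sm[interior]), sqrt(1 / 3), tolerance = 0.02)
})

test_that("probe correction is linear, exact on steady and exponential traces", {
  x <- rep(4.2, 30)
  expect_equal(correct_probe(x, 10, 0.14), x, tolerance = 1e-10)
  # linearity: correct(a x + b) = a correct(x) + b
  set.seed(2)
  y <- cumsum(rnorm(40))
  expect_equal(correct_probe(3 * y + 7, 10, 0.14),
               3 * correct_probe(y, 10, 0.14) + 7, tolerance = 1e-9)
  # a measured exponential exp(r t) is amplified by (1 + r/k_probe)
  r <- 0.005  # 1/s, slow enough for the filter to differentiate exactly
  t <- seq(0, 600, by = 10)
  meas <- exp(r * t) / exp(3)
  corr <- correct_probe(meas, 10, 0.14)
  interior <- 10:50
  expect_equal(corr[interior], meas[interior] * (1 + r / 0.14),
               tolerance = 1e-3)
})

test_that("probe lag then correction round-trips band-limited signals", {
  dt <- 10
  t <- seq(0, 2000, by = 1)
  truth <- 6 + sin(2 * pi * t / 600) + 0.5 * sin(2 * pi * t / 900)
  meas <- apply_probe_lag(truth, 1, 0.14)
  keep <- seq(1, length(t), by = dt)
  rec <- correct_probe(meas[keep], dt, 0.14)
  interior <- 10:190
  err <- abs(rec[interior] - truth[keep][interior]) / diff(range(truth))
  expect_lt(max(err), 0.01)
})

test_that("zone segmentation finds the depletion inflection on synthetic data", {
  zones <- segment_zones(resp_aerated_57)
  m <- resp_meta(resp_aerated_57)
  # pulse after a 2-min pre-segment at 0.1 Hz: 12 Zone-1 samples
  expect_equal(length(zones$zone1), 12)
  expect_equal(zones$idx_pulse, 13)
  # detected inflection within 2 samples of the true maximum DO rise
  # (allowing the probe's first-order delay on the measured trace)
  tr <- simulate_pulse(pulse_config(csi = 57, xa = 1, seed = 42), lab)
  dco <- diff(tr$co) / diff(tr$time_min)
  t_max_rise <- tr$time_min[which.max(dco)] * 60 + m$t_pulse_s
  t_det <- resp_aerated_57$time_s[zones$idx_inflection]
  expect_lte(abs(t_det - (t_max_rise + 1 / m$k_probe)),
             2 * m$sample_interval)
  # and it sits shortly after the true cs = ks crossing
  t_ks <- attr(tr, "depletion_min") * 60 + m$t_pulse_s
  expect_gte(t_det, t_ks - m$sample_interval)
  expect_lte(t_det - t_ks, 60)
  # zones are disjoint, ordered, and Zone 3 is capped at 4 min
  expect_equal(zones$zone2[1], zones$idx_pulse)
  expect_equal(max(zones$zone2) + 1L, zones$zone3[1])
  expect_lte(length(zones$zone3), 4 * 60 / m$sample_interval + 1)
})

test_that("segmentation is invariant to offset and positive rescaling", {
  base <- segment_zones(resp_aerated_57)
  shifted <- resp_aerated_57
  shifted$do_mg_l <- 2.5 * shifted$do_mg_l + 3
  attr(shifted, "meta") <- attr(resp_aerated_57, "meta")
  class(shifted) <- class(resp_aerated_57)
  expect_equal(segment_zones(shifted)$idx_inflection, base$idx_inflection)
})

test_that("degenerate traces are rejected", {
  rising <- tibble::tibble(time_s = seq(0, 1000, 10),
                           do_mg_l = seq(2, 8, length.out = 101))
  attr(rising, "meta") <- list(t_pulse_s = 120, aerated = TRUE,
                               sample_interval = 10)
  class(rising) <- c("respirogram", class(rising))
  expect_error(segment_zones(rising), "incomplete consumption")
})
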