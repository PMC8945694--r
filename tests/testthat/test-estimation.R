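test_that("re-aeration fit recovers the mass-transfer coefficient exactly", {
  t <- seq(0, 240, by = 10)
  co <- 7.0 - (7.0 - 4.2) * exp(-1.11 * t / 60)
  s1 <- step1_fit_reaeration(t, co)
  expect_equal(s1$ka, 1.11, tolerance = 1e-4)
  expect_equal(s1$co_inf, 7.0, tolerance = 1e-4)
  # constant trace: unidentifiable
  expect_error(step1_fit_reaeration(t, rep(7, length(t))), "unidentifiable")
  expect_error(step1_fit_reaeration(t[1:3], co[1:3]), "30 s")
})

test_that("endogenous and polymer respiration steps are linear and floored", {
  co1 <- rep(7.72, 20)
  expect_equal(step2_endogenous(rep(8.3, 20), 1.11, 8.3, 10), 0)
  q_oe <- step2_endogenous(co1, 1.11, 8.3, 10)
  expect_equal(q_oe, 1.11 * (8.3 - 7.72))
  # doubling the deficit doubles the rate
  expect_equal(step2_endogenous(rep(8.3 - 2 * 0.58, 20), 1.11, 8.3, 10),
               2 * q_oe)
  # asymptote at the Zone-1 level: no polymer respiration
  expect_equal(step3_polymer_respiration(1.11, 8.3, 7.72, q_oe), 0,
               tolerance = 1e-9)
  expect_warning(q_op <- step3_polymer_respiration(1.11, 8.3, 8.0, q_oe),
                 "floor")
  expect_equal(q_op, 0)
})

test_that("substrate respiration and yield close the Zone-2 mass balance", {
  # steady DO at the endogenous level: no respiration on substrate
  q_oe <- 1.11 * (8.3 - 7.72)
  expect_equal(
    step4_substrate_respiration(rep(7.72, 10), rep(0, 10), 1.11, 8.3, q_oe),
    rep(0, 10)
  )
  # non-aerated rearrangement: Q_os = -dco/dt - Q_oe
  q_os <- step4_substrate_respiration(rep(5, 4), rep(-0.05, 4), 0, 8.3, 0.6)
  expect_equal(q_os, rep(0.05 * 60 - 0.6, 4))
  # trapezoidal integral, yield, and an exactly-zero substrate endpoint
  t <- seq(0, 180, by = 10)
  q <- 5 * sin(pi * t / 180)^2
  s5 <- step5_yield_and_substrate(t, q, csi = 30)
  expect_equal(s5$yos, s5$bod_s / 30)
  expect_equal(s5$c_s[length(t)], 0)
  expect_true(all(diff(s5$c_s) <= 1e-12))
  expect_error(step5_yield_and_substrate(t, rep(0, length(t)), 30), "BOD")
})

test_that("step-6 interpolation reads the half-maximum points off a clean trend", {
  # analytic trend built from the uptake law itself
  p <- kinetic_preset("lab")
  csi <- 57
  cs <- seq(csi, 0.001, length.out = 400)
  qs <- qs_max_upshift(csi, p) * induction_factor(csi, cs, p) *
    cs / (p$ks + cs + cs^2 / p$kh)
  qsi <- qs[1]
  s6 <- step6_kinetic_constants(cs, qs, csi, qsi, seed = 1)
  expect_equal(s6$qsm, qs_max_upshift(csi, p), tolerance = 0.1)
  expect_equal(s6$ks, p$ks, tolerance = 0.35)
  expect_equal(s6$ki, p$ki, tolerance = 0.5)
  expect_false(s6$flags$no_rising_limb)
  # no lag: rising limb absent, ki flagged undefined
  qs_nolag <- qs_max_upshift(csi, p) * cs / (p$ks + cs + cs^2 / p$kh)
  s6b <- step6_kinetic_constants(cs, qs_nolag, csi, qs_nolag[1], seed = 1)
  expect_true(s6b$flags$no_rising_limb)
  expect_true(is.na(s6b$ki))
})

test_that("the aerated pipeline recovers the generating kinetics", {
  fit <- estimate_experiment(resp_aerated_57, seed = 1)
  est <- fit$estimates
  expect_equal(est$ka, lab$ka, tolerance = 0.05)
  expect_equal(est$yos, lab$yos, tolerance = 0.05)
  expect_equal(est$qsm, qs_max_upshift(57, lab), tolerance = 0.08)
  expect_equal(est$ks, lab$ks, tolerance = 0.4)
  expect_equal(est$qop, qop_powerlaw(pha_content(pha_stored_cod(57, 0, lab),
                                                 1, lab), lab),
               tolerance = 0.15)
  # derived substrate trend is nonincreasing and spans [0, csi]
  expect_true(all(diff(fit$trend$c_s) <= 1e-9))
  expect_equal(max(fit$trend$c_s), 57)
  # tidy/glance surface
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(glance(fit)$mode, "aerated")
})

test_that("re-simulating with the estimated parameters reproduces the record", {
  # evaluated at a 0.02 mg/L logger-noise level so the bound is noise-
  # rather than parameter-error-dominated
  resp <- generate_respirogram(
    pulse_config(csi = 57, xa = 1, seed = 42, noise_sd = 0.02), lab
  )
  fit <- estimate_experiment(resp, seed = 1)
  est <- fit$estimates
  m <- resp_meta(resp)
  # independent forward integration at the estimated parameter values
  rhs <- function(t, y, pr) {
    co <- max(y[1], 0); cs <- min(max(y[2], 0), 57)
    oxy <- co / (0.05 + co)
    ind <- 1 - est$fi * est$ki / (est$ki + (57 - cs))
    qs <- est$qsm * ind * min(cs / (est$ks + cs + cs^2 / est$kh), oxy)
    dco <- est$ka * (8.3 - co) - est$q_oe - est$yos * qs -
      est$q_op * min(est$ks / (est$ks + cs), oxy)
    list(c(dco, -qs))
  }
  i0 <- fit$zones$idx_pulse
  idx <- i0:max(fit$zones$zone3)
  t_obs <- resp$time_s[idx] - resp$time_s[i0]
  co0 <- mean(resp$do_mg_l[(i0 - 3):(i0 - 1)])
  times <- seq(0, max(t_obs), by = 1) / 60
  sol <- deSolve::ode(c(co0, 57), times, rhs, NULL, rtol = 1e-6)
  lagged <- apply_probe_lag(pmax(sol[, 2], 0), 1, m$k_probe, y0 = co0)
  pred <- approx(times * 60, lagged, xout = t_obs)$y
  rmse <- sqrt(mean((resp$do_mg_l[idx] - pred)^2))
  expect_lt(rmse, 3 * m$noise_sd)
})

test_that("yield is intensive: invariant to biomass and aeration rate", {
  yos_at <- function(xa, ka) {
    cfg <- pulse_config(csi = 57, xa = xa, ka_true = ka, seed = 31)
    estimate_experiment(generate_respirogram(cfg, lab), seed = 1)$estimates$yos
  }
  base <- yos_at(1, 1.11)
  expect_equal(yos_at(2, 1.11), base, tolerance = 0.08)
  expect_equal(yos_at(1, 1.6), base, tolerance = 0.08)
})

test_that("the non-aerated variant fits the record it is given", {
  fit <- estimate_experiment(resp_nonaer_15, seed = 1)
  est <- fit$estimates
  expect_equal(fit$mode, "nonaerated")
  expect_equal(est$yos, lab$yos, tolerance = 0.1)
  expect_equal(est$qoe, lab$qoe, tolerance = 0.1)
  # internal consistency: fitted DO trace within 3x the logger noise
  rmse <- sqrt(mean((fit$trend$do_obs - fit$trend$do_fit)^2))
  expect_lt(rmse, 3 * resp_meta(resp_nonaer_15)$noise_sd)
})

test_that("a respirogram without a pulse tag is rejected", {
  broken <- resp_aerated_57
  meta <- attr(broken, "meta")
  meta$t_pulse_s <- NULL
  attr(broken, "meta") <- meta
  expect_error(estimate_experiment(broken), "pulse")
})

test_that("the upshift fit is exact on clean data and guards its inputs", {
  p <- kinetic_preset("lab")
  csi <- c(5, 15, 57, 150, 381, 500)
  df <- data.frame(csi = csi, qsm = qs_max_upshift(csi, p))
  up <- fit_upshift(df)
  expect_equal(up$qsr, p$qsr, tolerance = 1e-5)
  expect_equal(up$qsu, p$qsu, tolerance = 1e-5)
  expect_equal(up$ku, p$ku, tolerance = 1e-4)
  expect_equal(tidy(up)$estimate[3], p$ku, tolerance = 1e-4)
  expect_error(fit_upshift(df[1:2, ]), "4 distinct")
  # inverse-variance weighting discounts an unidentifiable point
  df2 <- df
  df2$qsm[1] <- 30  # corrupted low-pulse estimate
  df2$qsm_se <- c(1e3, rep(0.05, 5))
  up2 <- fit_upshift(df2)
  expect_equal(up2$ku, p$ku, tolerance = 0.05)
})
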