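test_that("population initialization conserves mass and is reproducible", {
  cfg <- process_config(kinetics = lab, n_elements = 1e5, seed = 3)
  pop <- init_population(cfg)
  # reference-scale parcel: 5 gVSS/L * 500 L / 1e5 = 25 mgVSS per element
  expect_equal(pop$xa[1], 0.025)
  expect_equal(sum(pop$xa), cfg$xa_total_conc * cfg$vm)
  expect_true(all(pop$zone == "maintenance"))
  cfg2 <- process_config(kinetics = lab, n_elements = 5000, seed = 3,
                         init_occupancy = TRUE)
  expect_identical(init_population(cfg2)$zone, init_population(cfg2)$zone)
  expect_gt(sum(init_population(cfg2)$zone == "stimulation"), 0)
})

test_that("element target rates follow the hysteretic uptake laws", {
  # never-stimulated element in 50 mgCOD/L
  r1 <- element_target_rate(50, c_ref = 0, f_pha = 0,
                            in_stimulation = FALSE, lab)
  expect_equal(r1$c_ref, 50)
  expect_equal(r1$target, 18.64, tolerance = 0.01)
  # element stimulated at 500 then held at 6: rate maintained high
  r2 <- element_target_rate(6, c_ref = 500, f_pha = 0,
                            in_stimulation = FALSE, lab)
  expect_equal(r2$target, 20.26, tolerance = 0.01)
  expect_gt(r2$target, r1$target * 6 / 50 * 52 / 56)  # hysteresis benefit
  # polymer-saturated element takes up nothing
  r3 <- element_target_rate(50, 0, lab$f_pha_max, FALSE, lab)
  expect_equal(r3$target, 0)
  # stimulation zone: memory updates but uptake is zero
  r4 <- element_target_rate(400, c_ref = 10, f_pha = 0,
                            in_stimulation = TRUE, lab)
  expect_equal(r4$c_ref, 400)
  expect_equal(r4$target, 0)
})

test_that("rate relaxation is the exact first-order response", {
  expect_equal(relax_rates(0, 10, dt = 15, tau_resp = 5), 10 * (1 - exp(-3)))
  expect_equal(relax_rates(0, 10, dt = 15, tau_resp = 5) / 10, 0.95,
               tolerance = 0.001)
  expect_equal(relax_rates(4, 4, 0.05, 5), 4)
  expect_equal(relax_rates(0, 10, dt = 1e4, tau_resp = 5), 10)
})

test_that("the loading controller matches the reference-scale arithmetic", {
  xa <- rep(0.025, 1e4)  # 250 g scaled population
  qf <- controller_flow(xa, rep(0, 1e4), rep(TRUE, 1e4), f_l = 0.7,
                        csf = 1000, lab)
  expect_equal(qf, 0.7 * 250 * (lab$qsr + lab$qsu) / 1000, tolerance = 1e-9)
  # scales linearly with the loading fraction
  expect_equal(controller_flow(xa, rep(0, 1e4), rep(TRUE, 1e4), 0.35,
                               1000, lab), qf / 2)
  # saturated population: no feed
  expect_equal(controller_flow(xa, rep(lab$f_pha_max, 1e4),
                               rep(TRUE, 1e4), 0.7, 1000, lab), 0)
})

test_that("transport conserves elements and matches renewal statistics", {
  set.seed(4)
  zone <- rep("maintenance", 400)
  out <- step_transport(zone, dt = 0.05, qm_ls = 0, qf_ls = 0,
                        vm = 500, vs = 25)
  expect_identical(out, zone)  # no flow, no transport
  # long-run mean residence in the stimulation zone ~ vs / (qm + qf)
  qm_ls <- 50 / 60; qf_ls <- 20 / 60; vs <- 25
  n <- 400
  zone <- rep("maintenance", n)
  entered <- rep(NA_real_, n)
  stays <- c()
  dt <- 0.5
  for (step in 1:6000) {
    prev <- zone
    zone <- step_transport(zone, dt, qm_ls, qf_ls, vm = 500, vs = vs)
    t_now <- step * dt
    gone_in <- which(prev == "maintenance" & zone == "stimulation")
    came_out <- which(prev == "stimulation" & zone == "maintenance")
    entered[gone_in] <- t_now
    stays <- c(stays, t_now - entered[came_out])
    expect_equal(length(zone), n)
  }
  expect_gt(length(stays), 500)
  expect_equal(mean(stays, na.rm = TRUE), vs / (qm_ls + qf_ls),
               tolerance = 0.15)
})

test_that("concentration updates honour equilibrium and the mixing balance", {
  # no feed, no uptake, equal concentrations: nothing changes
  eq <- integrate_concentrations(css = 30, csm = 30, qf_ls = 0,
                                 qm_ls = 1, csf = 1000, vs = 25, vm = 500,
                                 uptake_mg_s = 0, dt = 0.05)
  expect_equal(eq$css, 30)
  expect_equal(eq$csm, 30)
  # the stimulation zone balance is stationary at the closed-form mix
  qf <- 50 / 60; qm <- 50 / 60
  css_star <- (qf * 1000 + qm * 6) / (qf + qm)
  st <- integrate_concentrations(css_star, 6, qf, qm, 1000, 25, 500, 0, 0.05)
  expect_equal(st$css, css_star, tolerance = 1e-10)
  # uptake curtailment: substrate never goes negative
  cur <- integrate_concentrations(0, 0.001, 0, 0, 1000, 25, 500,
                                  uptake_mg_s = 100, dt = 0.05)
  expect_gte(cur$csm, 0)
  expect_lt(cur$scale, 1)
})

test_that("the compiled core agrees with the R operations without transport", {
  # no recirculation: deterministic, so the R composition must match
  cfg <- process_config(kinetics = lab, n_elements = 100, t_end = 1,
                        recirculate = FALSE, dt_max = 0.05,
                        macro_every = 1, record_every_s = 60, seed = 5)
  traj <- run_process(cfg)
  p <- lab
  xa_e <- cfg$xa_total_conc * cfg$vm / cfg$n_elements
  q <- rep(0, cfg$n_elements); c_ref <- rep(0, cfg$n_elements)
  f_pha <- rep(0, cfg$n_elements); csm <- 0
  relaxk <- 1 - exp(-cfg$dt_max / cfg$tau_resp)
  for (step in 0:(cfg$t_end * 60 / cfg$dt_max)) {
    qf_ls <- controller_flow(rep(xa_e, cfg$n_elements), f_pha,
                             rep(TRUE, cfg$n_elements), cfg$f_l,
                             cfg$csf, p) / 60
    tg <- element_target_rate(csm, c_ref, f_pha, rep(FALSE, cfg$n_elements), p)
    c_ref <- tg$c_ref
    q <- q + (tg$target - q) * relaxk
    uptake_mg_s <- sum(xa_e * q) / 60
    dcsm <- (qf_ls * cfg$csf - qf_ls * csm - uptake_mg_s) / cfg$vm
    csm <- max(csm + dcsm * cfg$dt_max, 0)
    f_pha <- pmin(f_pha + q * (1 - p$yos) * cfg$dt_max /
                    (60 * p$beta_phb * 1000), cfg$f_pha_max)
  }
  expect_equal(traj$csm[nrow(traj)], csm, tolerance = 1e-6)
})

test_that("process runs conserve COD and reproduce bit-identically", {
  cfg <- small_process(hrt_m = 10, t_end = 10)
  t1 <- run_process(cfg)
  t2 <- run_process(cfg)
  expect_identical(t1$csm, t2$csm)
  bal <- cod_balance(t1)
  expect_lt(abs(bal$closure), 0.005)
  expect_lt(abs(bal$storage_closure), 0.005)
})

test_that("stimulation lowers the steady effluent concentration", {
  unstim <- run_process(small_process(recirculate = FALSE, t_end = 15,
                                      seed = 21))
  stim <- run_process(small_process(hrt_m = 4, t_end = 15, seed = 22))
  expect_lt(steady_state(stim)$csm_ss, steady_state(unstim)$csm_ss)
  # and essentially all biomass is stimulated over about 3 x HRT_m
  el <- attr(stim, "elements")
  css_end <- tail(stim$css, 1)
  expect_gt(mean(el$c_ref > 0.9 * css_end), 0.9)
})

test_that("the analytic fixed point matches its limiting balances", {
  cfg <- process_config(kinetics = lab, f_l = 0.7)
  expect_equal(analytic_fixed_point(lab, cfg, "unstimulated"), 52.4,
               tolerance = 0.01)
  expect_equal(analytic_fixed_point(lab, cfg, "stimulated", css = 500),
               5.53, tolerance = 0.01)
  cfg_lo <- process_config(kinetics = lab, f_l = 1e-4)
  expect_lt(analytic_fixed_point(lab, cfg_lo, "unstimulated"), 0.1)
  expect_error(analytic_fixed_point(lab, cfg, "stimulated"), "css")
  # Monte Carlo limit agrees with the oracle
  tr <- run_process(small_process(recirculate = FALSE, t_end = 15))
  expect_equal(steady_state(tr)$csm_ss,
               analytic_fixed_point(lab, small_process(), "unstimulated"),
               tolerance = 0.15)
})

test_that("results are stable in the number of elements", {
  s1 <- steady_state(run_process(small_process(hrt_m = 10, t_end = 12,
                                               n_elements = 2000, seed = 8)))
  s2 <- steady_state(run_process(small_process(hrt_m = 10, t_end = 12,
                                               n_elements = 8000, seed = 9)))
  expect_equal(s1$csm_ss, s2$csm_ss, tolerance = 0.08)
})
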