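test_that("upshift law hits its resting, half-saturation and saturation points", {
  expect_equal(qs_max_upshift(0, lab), lab$qsr)
  expect_equal(qs_max_upshift(lab$ku, lab), lab$qsr + lab$qsu / 2)
  expect_equal(qs_max_upshift(1e9, lab), lab$qsr + lab$qsu, tolerance = 1e-6)
  # monotone nondecreasing and bounded
  grid <- qs_max_upshift(seq(0, 2000, by = 5), lab)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid <= lab$qsr + lab$qsu))
  expect_error(qs_max_upshift(-1, lab), "nonnegative")
})

test_that("Haldane-Monod uptake reduces to Monod and peaks at sqrt(ks*kh)", {
  p <- kinetic_preset("lab", kh = 1e12)  # effectively no inhibition
  expect_equal(qs_uptake(p$ks, 1e9, 10, p), 5, tolerance = 1e-6)
  expect_equal(qs_uptake(0, 5, 10, p), 0)
  # with kh large and co saturating, closed-form Monod agreement
  cs <- seq(0.1, 400, by = 0.7)
  expect_equal(qs_uptake(cs, 1e12, 7, p), 7 * cs / (p$ks + cs),
               tolerance = 1e-9)
  # substrate-term maximum located by independent numeric optimization
  p2 <- kinetic_preset("lab")  # kh = 2000
  f <- function(c) c / (p2$ks + c + c^2 / p2$kh)
  c_star <- optimize(f, c(0, 2000), maximum = TRUE)$maximum
  expect_equal(c_star, sqrt(p2$ks * p2$kh), tolerance = 1e-3)
})

test_that("induction factor recovers with substrate consumed", {
  p <- lab
  expect_equal(induction_factor(57, 57, p), 1 - p$fi)
  expect_equal(induction_factor(57, 57 - p$ki, p), 1 - p$fi / 2)
  expect_equal(induction_factor(57, 0, p), 1 - p$fi * p$ki / (p$ki + 57))
  # monotone increasing as substrate is consumed, bounded in (0, 1]
  cs <- seq(57, 0, by = -1)
  vals <- induction_factor(57, cs, p)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals > 0 & vals <= 1))
  # vanishing suppression: factor -> 1 for all cs
  p_nolag <- kinetic_preset("lab", fi = 1e-9)
  expect_equal(induction_factor(57, 30, p_nolag), 1, tolerance = 1e-8)
  expect_error(induction_factor(57, 60, p), "csi")
})

test_that("PHA inhibition spans [0, 1] with the documented exponent shape", {
  expect_equal(pha_inhibition(0, lab), 1)
  expect_equal(pha_inhibition(lab$f_pha_max, lab), 0)
  expect_equal(pha_inhibition(0.5 * lab$f_pha_max, lab), 1 - 0.5^lab$alpha)
  f <- seq(0, lab$f_pha_max, length.out = 100)
  vals <- pha_inhibition(f, lab)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_warning(res <- pha_inhibition(lab$f_pha_max * 1.1, lab), "clamp")
  expect_equal(res, 0)
})

test_that("polymer respiration switches on as substrate depletes", {
  expect_equal(qop_volumetric(0, 1e9, 1, 0.8, lab), 0.8, tolerance = 1e-6)
  expect_equal(qop_volumetric(lab$ks, 1e9, 1, 0.8, lab), 0.4,
               tolerance = 1e-6)
  expect_equal(qop_volumetric(5, 0, 1, 0.8, lab), 0)
  expect_lt(qop_volumetric(100 * lab$ks, 1e9, 1, 0.8, lab), 0.01)
})

test_that("the COD balance gives the worked 57 mgCOD/L storage example", {
  xp <- pha_stored_cod(57, 0, lab)
  expect_equal(xp, (1 - 0.26) * 57)
  # PHB COD equivalence: ~2.5% gPHA/gVSS at 1 gVSS/L
  expect_equal(100 * pha_content(xp, 1, lab), 2.5, tolerance = 0.05)
  expect_equal(pha_stored_cod(57, 57, lab), 0)
  expect_error(pha_stored_cod(57, 58, lab), "csi")
})

test_that("famine respiration follows the two-thirds power law", {
  expect_equal(qop_powerlaw(0, lab), 0)
  expect_equal(qop_powerlaw(0.2, lab) / qop_powerlaw(0.1, lab), 2^(2 / 3))
  # generate-and-refit: recover the coefficient from noisy pairs
  set.seed(5)
  f <- runif(40, 0.005, 0.2)
  q <- qop_powerlaw(f, lab) * (1 + rnorm(40, 0, 0.05))
  fit <- lm(log(q) ~ offset(2 / 3 * log(f)))
  expect_equal(exp(coef(fit)[[1]]), lab$qop_coeff, tolerance = 0.1)
})

test_that("specific and volumetric rates interconvert through the yield", {
  expect_equal(qs_specific(0, 2, lab), 0)
  expect_equal(qs_specific(lab$yos * 2, 2, lab), 1)
  expect_error(qs_specific(1, 0, lab), "positive")
})

test_that("presets encode the hysteresis premise and survive JSON round-trip", {
  for (nm in c("lab", "pilot")) {
    p <- kinetic_preset(nm)
    expect_lt(p$ks, p$ku)
  }
  # prior stimulation strictly raises the maintained rate on a grid
  p <- kinetic_preset("lab")
  for (c in c(5, 10, 20, 35)) {
    maintained <- function(c_ref) qs_max_upshift(c_ref, p) * c / (p$ks + c)
    expect_gt(maintained(c * 4), maintained(c))
  }
  path <- tempfile(fileext = ".json")
  write_kinetic_params(p, path)
  p2 <- read_kinetic_params(path)
  expect_equal(unclass(p2), unclass(p))
})

test_that("parameter validation rejects inadmissible sets", {
  expect_error(kinetic_params(ka = 1, qoe = 0.5, yos = 1.2, ks = 2,
                              ku = 30, qsr = 7, qsu = 20), "yos")
  expect_error(kinetic_params(ka = 1, qoe = 0.5, yos = 0.3, ks = 2,
                              ku = 30, qsr = 7, qsu = 20, fi = 1), "fi")
  expect_warning(kinetic_params(ka = 1, qoe = 0.5, yos = 0.3, ks = 50,
                                ku = 30, qsr = 7, qsu = 20), "hysteresis")
})
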