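trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

#' Step 1: oxygen mass-transfer coefficient from the Zone-3 re-aeration trend
#'
#' Fits the asymptotic re-aeration trend
#' `co(t) = co_inf - (co_inf - co(t0)) * exp(-ka * (t - t0))` by nonlinear
#' least squares, assuming constant endogenous and polymer respiration over
#' the window. `co_inf` sits below the aeration saturation level by
#' `(Q_oe + Q_op) / ka`.
#'
#' When `k_probe` is supplied the fit runs on the raw logged samples and
#' the model carries a second exponential at the (known) probe rate, which
#' absorbs both the sensor memory and the tail of substrate respiration
#' crossing the inflection; the noise is then white rather than
#' filter-correlated. Without `k_probe` a single exponential is fitted
#' (appropriate for an already-corrected trace).
#'
#' @param time_s sample times of the Zone-3 window, seconds (>= 30 s span).
#' @param co DO concentrations over the window, mgO2/L.
#' @param k_probe optional probe response constant, 1/s.
#' @return List with `ka` (1/min), `co_inf` (mgO2/L), `se` (asymptotic
#'   standard errors) and `rss`.
#' @export
step1_fit_reaeration <- function(time_s, co, k_probe = NULL) {
  if (length(co) < 4 || diff(range(time_s)) < 30) {
    stop("need at least 30 s of Zone-3 data", call. = FALSE)
  }
  if (sd(co) < 1e-6) {
    stop("Zone-3 trace is constant: ka is unidentifiable", call. = FALSE)
  }
  df <- data.frame(tmin = (time_s - time_s[1]) / 60, co = co)
  fit <- tryCatch({
    if (is.null(k_probe)) {
      minpack.lm::nlsLM(
        co ~ co_inf - (co_inf - c0) * exp(-ka * tmin),
        data = df,
        start = list(co_inf = max(co) + 0.2, ka = 1, c0 = co[1]),
        lower = c(co_inf = 0, ka = 1e-3, c0 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      kpm <- k_probe * 60
      minpack.lm::nlsLM(
        co ~ co_inf - b * exp(-ka * tmin) - cc * exp(-kpm * tmin),
        data = df,
        start = list(co_inf = max(co) + 0.2, b = diff(range(co)),
                     cc = 0.1, ka = 1),
        lower = c(co_inf = 0, b = 0, cc = -5, ka = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }},
    error = function(e) {
      stop("re-aeration fit failed to converge: ", conditionMessage(e),
           " (DO range ", signif(min(co), 3), "-", signif(max(co), 3), ")",
           call. = FALSE)
    }
  )
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)),
                                              names(cf)))
  if (is.finite(se[["ka"]]) && se[["ka"]] > 10 * cf[["ka"]]) {
    stop("ka is unidentifiable from this Zone-3 window", call. = FALSE)
  }
  list(ka = unname(cf[["ka"]]), co_inf = unname(cf[["co_inf"]]),
       se = se, rss = sum(residuals(fit)^2))
}

#' Step 2: endogenous respiration from the Zone-1 baseline
#'
#' Under steady pre-aeration the DO balance gives
#' `Q_oe = ka * (co_star - mean(co))`. If the baseline drifts (the smoothed
#' derivative is not negligible), the mean derivative is subtracted instead
#' of assuming steadiness, with a warning.
#'
#' @param co Zone-1 DO samples, mgO2/L.
#' @param ka mass-transfer coefficient, 1/min (from step 1).
#' @param co_star apparent oxygen saturation concentration, mgO2/L.
#' @param dt_s sampling interval, seconds.
#' @param steady_tol drift tolerance on the smoothed derivative, mgO2/L/s.
#' @return Volumetric endogenous respiration rate `Q_oe`, mgO2/L/min.
#' @export
step2_endogenous <- function(co, ka, co_star, dt_s, steady_tol = 2e-3) {
  q_oe <- ka * (co_star - mean(co))
  if (length(co) >= 7) {
    drift <- mean(sg_smooth_deriv(co, dt_s)$deriv)
    if (abs(drift) > steady_tol) {
      warning("Zone 1 is not steady (mean dDO/dt = ", signif(drift, 3),
              " mg/L/s); correcting the endogenous estimate for the drift",
              call. = FALSE)
      q_oe <- q_oe - drift * 60
    }
  }
  q_oe
}

#' Step 3: polymer respiration directly after substrate depletion
#'
#' `Q_op = ka * (co_star - co_inf) - Q_oe`: the respiration excess over the
#' endogenous baseline implied by the Zone-3 asymptote. Negative values are
#' floored at zero with a warning.
#'
#' @param ka mass-transfer coefficient, 1/min.
#' @param co_star apparent oxygen saturation concentration, mgO2/L.
#' @param co_inf fitted Zone-3 asymptote, mgO2/L.
#' @param q_oe volumetric endogenous respiration, mgO2/L/min.
#' @return Volumetric polymer respiration rate `Q_op`, mgO2/L/min.
#' @export
step3_polymer_respiration <- function(ka, co_star, co_inf, q_oe) {
  q_op <- ka * (co_star - co_inf) - q_oe
  if (q_op < 0) {
    warning("negative Q_op (", signif(q_op, 3), "); flooring at 0",
            call. = FALSE)
    q_op <- 0
  }
  q_op
}

#' Step 4: respiration-on-substrate trend over Zone 2
#'
#' Rearranges the DO balance: `Q_os(t) = ka * (co_star - co) - Q_oe -
#' dco/dt`, on the probe-corrected, smoothed trace. Values are floored at
#' zero.
#'
#' @param co probe-corrected Zone-2 DO, mgO2/L.
#' @param dco_dt_s its derivative, mgO2/L/s.
#' @param ka mass-transfer coefficient, 1/min (0 for non-aerated records).
#' @param co_star apparent oxygen saturation concentration, mgO2/L.
#' @param q_oe volumetric endogenous respiration, mgO2/L/min.
#' @return `Q_os(t)`, mgO2/L/min.
#' @export
step4_substrate_respiration <- function(co, dco_dt_s, ka, co_star, q_oe) {
  pmax(ka * (co_star - co) - q_oe - dco_dt_s * 60, 0)
}

#' Step 5: oxygen yield and the substrate-concentration trend
#'
#' Integrates `Q_os` over Zone 2 (trapezoidal rule at the logging rate) to
#' the cumulative biochemical oxygen demand on substrate, `BOD_s`; the
#' average yield is `yos = BOD_s / csi` and the substrate trend is
#' `C_s(t) = csi - (1/yos) * integral of Q_os`, which reaches zero at the
#' end of Zone 2 by construction.
#'
#' @param time_s Zone-2 sample times, seconds.
#' @param q_os Zone-2 respiration-on-substrate trend, mgO2/L/min.
#' @param csi initial substrate concentration, mgCOD/L.
#' @return List with `yos`, `bod_s` (mgO2/L) and `c_s` (mgCOD/L, same
#'   length as `q_os`).
#' @export
step5_yield_and_substrate <- function(time_s, q_os, csi) {
  tmin <- time_s / 60
  bod_s <- trapz(tmin, q_os)
  if (bod_s <= 0) stop("nonpositive BOD_s: no oxygen consumed on substrate",
                       call. = FALSE)
  yos <- bod_s / csi
  c_s <- pmin(pmax(csi - cumtrapz(tmin, q_os) / yos, 0), csi)
  list(yos = yos, bod_s = bod_s, c_s = c_s)
}

interp_crossing <- function(xa, xb, ya, yb, y0) {
  if (yb == ya) return((xa + xb) / 2)
  xa + (y0 - ya) * (xb - xa) / (yb - ya)
}

# substrate concentration at which the descending (late-time) limb of the
# trend crosses the given rate level (piecewise-linear interpolation)
descending_crossing <- function(c_s, q_s, level) {
  imax <- which.max(q_s)
  if (imax >= length(q_s)) return(NA_real_)
  below <- which(q_s[(imax + 1):length(q_s)] < level)
  if (!length(below)) return(NA_real_)
  k <- imax + below[1]
  interp_crossing(c_s[k - 1], c_s[k], q_s[k - 1], q_s[k], level)
}

#' Step 6: kinetic constants from the uptake-rate-versus-substrate trend
#'
#' From the derived `(C_s, q_s)` trend of one experiment: the downshift
#' affinity `ks` is interpolated as the substrate concentration at half the
#' observed maximum rate on the descending (late-time) limb, and the
#' induction constant `ki` as the substrate consumed at half recovery
#' between the initial rate `qsi` and the maximum on the rising limb (the
#' exact half-recovery point of the lag law). With `ks` and `ki` held at
#' their interpolated values, the plateau rate `qsm`, suppression `fi` and
#' Haldane constant `kh` are then estimated by multi-start nonlinear least
#' squares of the full uptake law over the trend. The observed maximum is a
#' biased-low reading of `qsm` (the Monod substrate term never reaches 1),
#' which is why the plateau is refitted rather than read off.
#'
#' @param c_s substrate-concentration trend, mgCOD/L (Zone 2).
#' @param q_s specific uptake-rate trend, mgCOD/gVSS/min.
#' @param csi initial substrate concentration, mgCOD/L.
#' @param qsi initial specific uptake rate (mean over the first 15 s after
#'   the pulse), mgCOD/gVSS/min.
#' @param exclude_before seconds after the pulse excluded from the NLS
#'   (the smoothing window plus probe memory make the first samples of the
#'   derived trend a filter transient, not kinetics); interpolations still
#'   use the full trend. Requires `t_since_pulse`.
#' @param t_since_pulse optional vector of sample times since the pulse,
#'   seconds.
#' @param n_starts number of multi-start NLS starting points.
#' @param seed seed for the start sampling.
#' @return List with `ks`, `ki`, `qsm`, `kh`, `fi`, `qsm_obs` (raw observed
#'   maximum), `rss`, and logical `flags` (`no_rising_limb`,
#'   `no_descending_limb`).
#' @export
step6_kinetic_constants <- function(c_s, q_s, csi, qsi,
                                    exclude_before = 0,
                                    t_since_pulse = NULL, n_starts = 5,
                                    seed = 1L) {
  stopifnot(length(c_s) == length(q_s), length(q_s) >= 5)
  imax <- which.max(q_s)
  qsm_obs <- q_s[imax]
  flags <- list(no_rising_limb = FALSE, no_descending_limb = FALSE)

  # descending limb: first half-maximum crossing after the peak
  half_max_crossing <- function(level) descending_crossing(c_s, q_s, level)
  ks <- half_max_crossing(qsm_obs / 2)
  if (is.na(ks)) {
    flags$no_descending_limb <- TRUE
  }

  # rising limb: half-recovery between qsi and the maximum
  ki <- NA_real_
  if (imax > 2 && qsi < 0.95 * qsm_obs) {
    q_half <- (qsi + qsm_obs) / 2
    above <- which(q_s[1:imax] >= q_half)
    if (length(above) && above[1] > 1) {
      k <- above[1]
      cs_half <- interp_crossing(c_s[k - 1], c_s[k], q_s[k - 1], q_s[k],
                                 q_half)
      ki <- csi - cs_half
    }
  }
  if (is.na(ki) || ki <= 0) {
    ki <- NA_real_
    flags$no_rising_limb <- TRUE
  }
  fi_init <- min(max(1 - qsi / qsm_obs, 1e-3), 0.9)

  # NLS of the plateau and Haldane constant; fi comes from the initial
  # rate (1 - qsi/qsm at the observed maximum) and ks, ki stay at their
  # interpolated values
  keep <- c_s > 1e-6
  if (!is.null(t_since_pulse) && exclude_before > 0) {
    keep2 <- keep & t_since_pulse > exclude_before
    if (sum(keep2) >= 4) keep <- keep2
  }
  df <- data.frame(cs = c_s[keep], qs = q_s[keep])
  refit <- function(ks_fit) {
    model_rss <- function(par) {
      qsm <- par[1]; kh <- exp(par[2])
      ind <- if (is.na(ki)) 1 else 1 - fi_init * ki / (ki + (csi - df$cs))
      pred <- qsm * ind * df$cs / (ks_fit + df$cs + df$cs^2 / kh)
      sum((df$qs - pred)^2)
    }
    set.seed(seed)
    starts <- cbind(
      qsm = qsm_obs * runif(n_starts, 1.0, 2.0),
      log_kh = log(c(2000, 500, 8000, 100, 20000))[seq_len(n_starts)]
    )
    best <- NULL
    for (s in seq_len(n_starts)) {
      opt <- tryCatch(
        optim(starts[s, ], model_rss, method = "L-BFGS-B",
              lower = c(qsm_obs * 0.8, log(10)),
              upper = c(qsm_obs * 6, log(1e6))),
        error = function(e) NULL
      )
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    best
  }
  ks_fit <- if (is.na(ks)) max(min(c_s[c_s > 0]), 0.1) else ks
  best <- refit(ks_fit)
  if (is.null(best)) {
    return(c(list(ks = ks, ki = ki, qsm = qsm_obs, kh = NA_real_,
                  fi = fi_init, qsm_obs = qsm_obs, rss = NA_real_),
             list(flags = modifyList(flags, list(nls_failed = TRUE)))))
  }
  # the observed maximum underestimates the plateau (the substrate Monod
  # term never reaches 1, and the induction lag suppresses the peak), so
  # the half-maximum interpolation is repeated at half the fitted plateau
  # and the NLS refitted once with the final ks
  ks2 <- half_max_crossing(best$par[1] / 2)
  if (!is.na(ks2) && ks2 > 0) {
    best2 <- refit(ks2)
    if (!is.null(best2)) {
      ks <- ks2
      best <- best2
    }
  }
  list(ks = unname(ks), ki = unname(ki), qsm = unname(best$par[1]),
       kh = unname(exp(best$par[2])), fi = unname(fi_init),
       qsm_obs = unname(qsm_obs), rss = best$value, flags = flags)
}

# Attenuation of a step change in respiration rate as seen by the derived
# trend at the first post-pulse samples: the probe memory and the smoothing
# window (which still covers pre-pulse samples there) scale the apparent
# initial rate down by a factor that depends only on the probe constant and
# the logging interval. Computed by pushing a unit step through the same
# measurement chain the estimator uses.
initial_rate_attenuation <- function(k_probe, dt, idx = 1L) {
  n_pre <- 7L
  m <- c(rep(0, n_pre), 1 - exp(-k_probe * dt * (0:12)))
  sg <- sg_smooth_deriv(m, dt)
  corr <- sg$smooth + sg$deriv / k_probe
  att <- corr[n_pre + 1L + idx]
  mean(pmin(pmax(att, 0.05), 1))
}

# Filter-aware refinement of the plateau rate and Haldane constant: the
# derived (C_s, q_s) trend is smeared by the logging rate, the smoothing
# window and the probe memory, which biases a trend-space NLS whenever the
# record is short (small pulses). This stage instead fits the Zone-2 DO
# trace itself: the mass balance is simulated forward with the
# already-estimated ka, Q_oe, Q_op, ks, ki and fi, pushed through the probe
# response, and compared to the logged samples. The smear is thereby part
# of the model rather than a bias.
refine_qsm_trace <- function(resp, zones, dt, k_probe, ka, co_star, q_oe,
                             q_op, xa, csi, ks, ki, fi, qsm_init, yos_init,
                             kh_init, seed = 1L, ko = 0.05,
                             ks_fixed = NULL) {
  n <- nrow(resp)
  i0 <- zones$idx_pulse
  n_pad <- ceiling((3 * dt + 2 / k_probe) / dt)
  fit_idx <- i0:min(zones$idx_inflection + n_pad, n)
  t_obs <- resp$time_s[fit_idx] - resp$time_s[i0]
  do_obs <- resp$do_mg_l[fit_idx]
  # initial state from the Zone-1 baseline: at the pulse sample itself the
  # filter window already overlaps the post-pulse drop
  base_idx <- seq.int(max(i0 - 3, 1), max(i0 - 1, 1))
  y_probe0 <- mean(resp$do_mg_l[base_idx])
  co0 <- y_probe0
  predict_do <- function(qsm, kh, yos_m, fi_m, ks_m, ki_m) {
    rhs <- function(t, y, pr) {
      co <- max(y[1], 0)
      cs <- min(max(y[2], 0), csi)
      oxy <- co / (ko + co)
      ind <- 1 - fi_m * ki_m / (ki_m + (csi - cs))
      qs <- qsm * ind * min(cs / (ks_m + cs + cs^2 / kh), oxy)
      dco <- ka * (co_star - co) - q_oe - yos_m * xa * qs -
        q_op * min(ks_m / (ks_m + cs), oxy)
      list(c(dco, -qs * xa))
    }
    times <- seq(0, max(t_obs), by = 1) / 60
    sol <- suppressWarnings(tryCatch(
      deSolve::ode(c(co0, csi), times, rhs, NULL, method = "lsoda",
                   rtol = 1e-6, atol = 1e-8),
      error = function(e) NULL
    ))
    if (is.null(sol) || nrow(sol) < length(times)) {
      return(rep(NA_real_, length(t_obs)))
    }
    lagged <- apply_probe_lag(pmax(sol[, 2], 0), dt_s = 1,
                              k_probe = k_probe, y0 = y_probe0)
    approx(times * 60, lagged, xout = t_obs, rule = 2)$y
  }
  # fi is confined to a band around its attenuation-corrected estimate
  # from the initial rate: letting it collapse to zero lets the fit trade
  # the induction transient against a biased-low plateau under noise
  fi_lo <- max(0.5 * fi, 0.01)
  fi_hi <- min(2 * fi, 0.95)
  ki_fix <- if (is.finite(ki) && ki > 0) ki else csi / 5
  # the induction constant is freed only when the rising limb is long
  # enough to resolve it; on short records it stays at the interpolated
  # value (freeing it there lets the lag soak up the whole trace)
  free_ki <- length(fit_idx) >= 40
  untransform <- function(par) {
    list(qsm = min(exp(par[1]), 500), kh = min(max(exp(par[2]), 10), 1e6),
         yos_m = 0.05 + 0.55 * plogis_(par[3]),
         fi_m = fi_lo + (fi_hi - fi_lo) * plogis_(par[4]),
         ks_m = if (is.null(ks_fixed)) min(max(exp(par[5]), 1e-3), 50)
                else ks_fixed,
         ki_m = if (free_ki) min(max(exp(par[6]), 0.1), 5 * csi) else ki_fix)
  }
  resid_fun <- function(par) {
    th <- untransform(par)
    r <- do_obs - predict_do(th$qsm, th$kh, th$yos_m, th$fi_m, th$ks_m,
                             th$ki_m)
    r[!is.finite(r)] <- 10
    r
  }
  yos_t <- qlogis_(min(max((yos_init - 0.05) / 0.55, 0.02), 0.98))
  ks_t <- log(if (is.finite(ks)) min(max(ks, 0.2), 10) else 1)
  qsm_t <- log(min(max(qsm_init, 1), 100))
  fi_t <- qlogis_(min(max((fi - fi_lo) / (fi_hi - fi_lo), 0.05), 0.95))
  kh_t <- log(min(max(kh_init, 100), 1e5))
  starts <- rbind(
    c(qsm_t, kh_t, yos_t, fi_t, ks_t),
    c(qsm_t + log(1.5), log(2000), yos_t, fi_t, log(2)),
    c(qsm_t, kh_t, yos_t, qlogis_(0.9), ks_t)
  )
  if (free_ki) {
    starts <- cbind(starts, c(log(ki_fix), log(ki_fix * 3), log(ki_fix)))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 60)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(NULL)
  th <- untransform(best$fit$par)
  # asymptotic relative SE of qsm (log-scale) from the fit Hessian; large
  # when the pulse is too small to separate qsm from the affinity constant
  qsm_se <- tryCatch({
    h <- best$fit$hessian
    # drop flat nuisance directions (e.g. a Haldane constant pegged at its
    # bound) before inverting; keep the plateau parameter itself
    keep <- union(1L, which(diag(h) > 1e-8 * max(diag(h))))
    dof <- max(length(do_obs) - length(keep), 1)
    covm <- solve(h[keep, keep, drop = FALSE]) * best$rss / dof
    th$qsm * sqrt(max(covm[1, 1], 0))
  }, error = function(e) Inf)  # singular: the plateau is unidentifiable
  c(th, list(rss = best$rss, qsm_se = qsm_se))
}

#' Estimate kinetic parameters from one respirogram
#'
#' Orchestrates the stepwise estimation pipeline on an aerated
#' pulse-respiration record: probe correction and smoothing, zone
#' segmentation, then steps 1-6 (re-aeration fit, endogenous baseline,
#' polymer respiration, respiration-on-substrate trend, oxygen yield and
#' substrate trend, kinetic constants). Non-aerated records instead fit the
#' full mass-balance model (with the probe response included) directly by
#' nonlinear least squares, yielding `yos`, `ks`, `ki` and `fi` jointly.
#'
#' @param resp a `respirogram`.
#' @param xa,csi,co_star experiment metadata overrides; defaults come from
#'   the respirogram metadata (`co_star` additionally defaults to 8.3
#'   mgO2/L).
#' @param qsm for the non-aerated variant: the maximum specific uptake rate
#'   at this pulse concentration (default: the upshift law of `p_ref`).
#' @param p_ref kinetic set supplying defaults for the non-aerated variant
#'   (`qsm`, `ko`, `kh`, `qop_coeff`); the laboratory preset by default.
#' @param ks_fixed optional substrate affinity constant (mgCOD/L) held
#'   fixed in the aerated trace refit -- used by [batch_estimate()] to pool
#'   the affinity across a battery, since it is a property of the biomass,
#'   not of the pulse size. The reported `ks` stays the per-experiment
#'   interpolated value.
#' @param seed seed for the multi-start refits.
#' @return A `pha_fit` object: list with `estimates` (named list), `trend`
#'   (tibble of derived Zone-2 series: `time_s`, `co_corr`, `q_os`, `c_s`,
#'   `q_s`), `zones`, `mode` ("aerated" or "nonaerated") and fit
#'   diagnostics. Supports [tidy()], [glance()] and [autoplot()].
#' @export
estimate_experiment <- function(resp, xa = NULL, csi = NULL, co_star = NULL,
                                qsm = NULL, p_ref = kinetic_preset("lab"),
                                ks_fixed = NULL, seed = 1L) {
  m <- resp_meta(resp)
  xa <- xa %||% m$xa
  csi <- csi %||% m$csi
  co_star <- co_star %||% m$co_star %||% 8.3
  k_probe <- m$k_probe %||% 0.14
  dt <- m$sample_interval
  if (is.null(csi) || is.null(xa)) {
    stop("respirogram metadata must provide `csi` and `xa`", call. = FALSE)
  }
  if (isTRUE(m$aerated)) {
    estimate_aerated(resp, xa, csi, co_star, k_probe, dt, seed,
                     ks_fixed = ks_fixed)
  } else {
    estimate_nonaerated(resp, xa, csi, k_probe, dt, qsm, p_ref, seed)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

estimate_aerated <- function(resp, xa, csi, co_star, k_probe, dt, seed,
                             ks_fixed = NULL) {
  zones <- segment_zones(resp)
  sg <- sg_smooth_deriv(resp$do_mg_l, dt)
  # probe-corrected trace and its derivative from a single filter pass
  # (re-filtering the corrected trace would double the smoothing window)
  co_corr <- sg$smooth + sg$deriv / k_probe
  dcorr <- sg$deriv + sg$deriv2 / k_probe

  s1 <- step1_fit_reaeration(resp$time_s[zones$zone3],
                             resp$do_mg_l[zones$zone3], k_probe = k_probe)
  q_oe <- step2_endogenous(co_corr[zones$zone1], s1$ka, co_star, dt)
  q_op <- step3_polymer_respiration(s1$ka, co_star, s1$co_inf, q_oe)
  z2 <- zones$zone2
  q_os <- step4_substrate_respiration(co_corr[z2], dcorr[z2], s1$ka,
                                      co_star, q_oe)
  s5 <- step5_yield_and_substrate(resp$time_s[z2], q_os, csi)
  q_s <- q_os / (s5$yos * xa)

  t_pulse <- resp$time_s[zones$idx_pulse]
  dt_pulse <- resp$time_s[z2] - t_pulse
  in_window <- dt_pulse > 0 & dt_pulse <= 15
  if (!any(in_window)) in_window <- seq_along(z2) <= 2
  qsi <- mean(q_s[in_window])
  s6 <- step6_kinetic_constants(
    s5$c_s, q_s, csi, qsi,
    exclude_before = 3 * dt + 2 / k_probe, t_since_pulse = dt_pulse,
    seed = seed
  )
  # reference the initial rate to the plateau: undo the measurement-chain
  # attenuation of the first post-pulse samples and the substrate Monod
  # factor before converting it into a suppression fraction
  att <- initial_rate_attenuation(k_probe, dt,
                                  idx = which(in_window) - which(dt_pulse > 0)[1] + 1L)
  kh_ref <- if (is.finite(s6$kh)) s6$kh else 2000
  ks_ref <- ks_fixed %||% (if (is.finite(s6$ks)) s6$ks else 1)
  f_sub <- csi / (ks_ref + csi + csi^2 / kh_ref)
  fi_start <- min(max(1 - (qsi / att) / (s6$qsm * f_sub), 0.02), 0.9)
  ref <- refine_qsm_trace(
    resp, zones, dt, k_probe, ka = s1$ka, co_star = co_star, q_oe = q_oe,
    q_op = q_op, xa = xa, csi = csi, ks = s6$ks, ki = s6$ki, fi = fi_start,
    qsm_init = s6$qsm, yos_init = s5$yos,
    kh_init = kh_ref, seed = seed, ks_fixed = ks_fixed
  )
  # one recalibration pass: the suppression band was referenced to the
  # trend-space plateau, which the trace fit has now improved on
  if (!is.null(ref)) {
    fi_start2 <- min(max(1 - (qsi / att) / (ref$qsm * f_sub), 0.02), 0.9)
    if (abs(fi_start2 - fi_start) > 0.03) {
      ref2 <- refine_qsm_trace(
        resp, zones, dt, k_probe, ka = s1$ka, co_star = co_star,
        q_oe = q_oe, q_op = q_op, xa = xa, csi = csi, ks = s6$ks,
        ki = s6$ki, fi = fi_start2, qsm_init = ref$qsm,
        yos_init = s5$yos, kh_init = kh_ref, seed = seed,
        ks_fixed = ks_fixed
      )
      if (!is.null(ref2)) ref <- ref2
    }
  }
  if (!is.null(ref)) {
    s6$qsm <- ref$qsm
    s6$kh <- ref$kh
    s6$fi <- ref$fi_m
    s6$ki <- unname(ref$ki_m)
    s6$qsm_se <- ref$qsm_se
  } else {
    s6$qsm_se <- NA_real_
  }

  trend <- tibble::tibble(
    time_s = resp$time_s[z2], co_corr = co_corr[z2],
    q_os = q_os, c_s = s5$c_s, q_s = q_s
  )
  estimates <- list(
    ka = s1$ka, co_inf = s1$co_inf, q_oe = q_oe, qoe = q_oe / xa,
    q_op = q_op, qop = q_op / xa, yos = s5$yos, bod_s = s5$bod_s,
    ks = s6$ks, ki = s6$ki, qsm = s6$qsm, kh = s6$kh, fi = s6$fi,
    qsi = qsi, qsm_obs = s6$qsm_obs, qsm_se = s6$qsm_se
  )
  structure(
    list(estimates = estimates, trend = trend, zones = zones,
         mode = "aerated", xa = xa, csi = csi, co_star = co_star,
         rss = s6$rss, flags = s6$flags, step1 = s1),
    class = "pha_fit"
  )
}

estimate_nonaerated <- function(resp, xa, csi, k_probe, dt, qsm, p_ref,
                                seed) {
  m <- resp_meta(resp)
  idx_pulse <- which(resp$time_s >= m$t_pulse_s)[1]
  if (is.na(idx_pulse) || idx_pulse < 3) {
    stop("non-aerated fit needs a pre-pulse baseline", call. = FALSE)
  }
  if (is.null(qsm)) qsm <- qs_max_upshift(csi, p_ref)

  # pre-pulse baseline: DO declines linearly under endogenous respiration;
  # the probe reading lags a ramp by slope/k_probe, which inverts exactly.
  # The first samples still carry the probe's start-up transient and are
  # dropped from the baseline fit.
  pre <- seq_len(idx_pulse - 1L)
  if (length(pre) > 6) pre <- pre[-(1:3)]
  base <- lm(do ~ t, data = data.frame(
    do = resp$do_mg_l[pre], t = resp$time_s[pre] - resp$time_s[idx_pulse]
  ))
  y_probe0 <- unname(coef(base)[1])
  slope <- unname(coef(base)[2])          # mgO2/L/s, negative
  co0 <- max(y_probe0 + slope / k_probe, 0.1)
  # the measured baseline slope already carries the oxygen Monod factor at
  # the baseline DO; divide it out since the model reapplies it
  q_oe_vol <- max(-slope * 60 / (co0 / (p_ref$ko + co0)), 1e-4)

  # the affinity information lives at the depletion corner; the long
  # famine tail afterwards only re-weights the baseline terms, so the fit
  # window ends shortly after consumption stops
  end_idx <- nrow(resp)
  corner <- tryCatch(segment_zones(resp)$idx_inflection,
                     error = function(e) NA_integer_)
  if (is.finite(corner)) {
    end_idx <- min(corner + ceiling(90 / dt), nrow(resp))
  }
  fit_idx <- idx_pulse:end_idx
  t_obs <- resp$time_s[fit_idx] - resp$time_s[idx_pulse]
  do_obs <- resp$do_mg_l[fit_idx]
  ko <- p_ref$ko
  qop_coeff <- p_ref$qop_coeff
  kh <- p_ref$kh
  beta <- p_ref$beta_phb

  predict_do <- function(yos, ks, ki, fi) {
    rhs <- function(t, y, pr) {
      co <- max(y[1], 0)
      cs <- min(max(y[2], 0), csi)
      oxy <- co / (ko + co)
      ind <- 1 - fi * ki / (ki + (csi - cs))
      qs <- qsm * ind * soft_min(cs / (ks + cs + cs^2 / kh), oxy)
      fpha <- ((1 - yos) * (csi - cs) / beta) / (1000 * xa)
      q_op <- xa * qop_coeff * fpha^(2 / 3) *
        soft_min(ks / (ks + cs), oxy)
      list(c(-q_oe_vol * oxy - yos * xa * qs - q_op, -qs * xa))
    }
    times <- seq(0, max(t_obs), by = 1) / 60
    sol <- suppressWarnings(tryCatch(
      deSolve::ode(c(co0, csi), times, rhs, NULL, method = "lsoda",
                   rtol = 1e-7, atol = 1e-9),
      error = function(e) NULL
    ))
    if (is.null(sol) || nrow(sol) < length(times)) {
      return(rep(NA_real_, length(t_obs)))
    }
    lagged <- apply_probe_lag(pmax(sol[, 2], 0), dt_s = 1,
                              k_probe = k_probe, y0 = y_probe0)
    approx(times * 60, lagged, xout = t_obs, rule = 2)$y
  }
  resid_fun <- function(par) {
    pred <- predict_do(0.05 + 0.55 * plogis_(par[1]), exp(par[2]),
                       exp(par[3]), 0.95 * plogis_(par[4]))
    r <- do_obs - pred
    r[!is.finite(r)] <- 10
    r
  }
  # the likelihood in ks is shallow at this logging rate and a free
  # optimizer is start-dependent; profile the affinity over a fixed log
  # grid (nuisance parameters refit at each point), then polish the full
  # fit from the profile minimum
  yos_t0 <- qlogis_((0.25 - 0.05) / 0.55)
  # stage 1: a free fit pins down the yield (set by the total DO drop)
  pre_fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(yos_t0, log(0.2), log(max(csi / 5, 0.5)), qlogis_(0.2)),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 50)
    )),
    error = function(e) NULL
  )
  yos_t1 <- if (is.null(pre_fit)) yos_t0 else pre_fit$par[1]
  # stage 2: profile the affinity with the yield frozen -- refitting it at
  # every grid point lets it alias the depletion corner and flattens the
  # profile
  nuis0 <- c(log(max(csi / 5, 0.5)), qlogis_(0.2))
  ks_grid <- exp(seq(log(0.01), log(1), length.out = 9))
  prof <- lapply(ks_grid, function(ks_g) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = nuis0,
        fn = function(q) resid_fun(c(yos_t1, log(ks_g), q[1], q[2])),
        control = minpack.lm::nls.lm.control(maxiter = 25)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) return(list(rss = Inf, par = c(yos_t1, nuis0)))
    list(rss = sum(fit$fvec^2), par = c(yos_t1, fit$par))
  })
  rss_prof <- vapply(prof, `[[`, numeric(1), "rss")
  if (!any(is.finite(rss_prof))) {
    stop("non-aerated model fit failed to converge", call. = FALSE)
  }
  i_best <- which.min(rss_prof)
  nb <- prof[[i_best]]$par
  polish <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(nb[1], log(ks_grid[i_best]), nb[2], nb[3]),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 100)
    )),
    error = function(e) NULL
  )
  if (!is.null(polish) && sum(polish$fvec^2) <= rss_prof[i_best]) {
    par <- polish$par
    best <- list(fit = polish, rss = sum(polish$fvec^2))
  } else {
    par <- c(nb[1], log(ks_grid[i_best]), nb[2], nb[3])
    best <- list(fit = prof[[i_best]], rss = rss_prof[i_best])
  }
  estimates <- list(
    ka = 0, q_oe = q_oe_vol, qoe = q_oe_vol / xa,
    yos = 0.05 + 0.55 * plogis_(par[1]), ks = exp(par[2]),
    ki = exp(par[3]), fi = 0.95 * plogis_(par[4]),
    qsm = qsm, bod_s = (0.05 + 0.55 * plogis_(par[1])) * csi
  )
  trend <- tibble::tibble(time_s = resp$time_s[fit_idx], do_obs = do_obs,
                          do_fit = do_obs - resid_fun(par))
  structure(
    list(estimates = estimates, trend = trend, zones = NULL,
         mode = "nonaerated", xa = xa, csi = csi, co_star = NA_real_,
         rss = best$rss, flags = list(), step1 = NULL,
         ks_profile = tibble::tibble(ks = ks_grid, rss = rss_prof)),
    class = "pha_fit"
  )
}

#' Pool the substrate affinity across non-aerated replicate experiments
#'
#' The affinity constant is a property of the biomass, and with only the
#' affinity shared across records the joint replicate fit factorizes: the
#' per-record profile residual curves (nuisance parameters re-optimized at
#' every affinity value) simply add. This sums the stored profiles of a
#' batch of non-aerated fits and returns the joint minimum, refined by
#' quadratic interpolation in log-affinity. A single small pulse barely
#' constrains the affinity on its own; a batch pins it down.
#'
#' @param fits a list of non-aerated `pha_fit` objects (one replicate
#'   batch, e.g. pulses of 5, 10 and 15 mgCOD/L).
#' @return The pooled affinity constant, mgCOD/L.
#' @export
pool_nonaerated_ks <- function(fits) {
  chi2 <- lapply(fits, function(f) {
    if (is.null(f$ks_profile)) {
      stop("all fits must be non-aerated fits carrying a ks profile",
           call. = FALSE)
    }
    # normalize each record's profile to a delta-chi-square curve so
    # records vote by their information, not by their residual scale
    rss <- f$ks_profile$rss
    df <- max(nrow(f$trend) - 4, 1)
    sig2 <- max(min(rss, na.rm = TRUE), 1e-12) / df
    (rss - min(rss, na.rm = TRUE)) / sig2
  })
  grid <- fits[[1]]$ks_profile$ks
  for (f in fits) stopifnot(isTRUE(all.equal(f$ks_profile$ks, grid)))
  total <- Reduce(`+`, chi2)
  i <- which.min(total)
  if (!all(is.finite(total)) || i == 1L || i == length(grid)) {
    return(grid[i])
  }
  # least-squares parabola in log-ks over up to five points around the
  # minimum; the vertex is clamped to the bracketing grid cells
  win <- max(i - 2, 1):min(i + 2, length(grid))
  lx <- log(grid[win])
  fit <- lm(total[win] ~ lx + I(lx^2))
  a <- coef(fit)[[3]]
  if (!is.finite(a) || a <= 0) return(grid[i])
  vertex <- -coef(fit)[[2]] / (2 * a)
  exp(min(max(vertex, log(grid[i - 1])), log(grid[i + 1])))
}

plogis_ <- function(x) 1 / (1 + exp(-x))
qlogis_ <- function(p) log(p / (1 - p))

#' Fit the upshift law across a battery of pulse experiments
#'
#' Nonlinear least squares of `qsm = qsr + qsu * csi / (ku + csi)` to
#' per-experiment maximum uptake-rate estimates, giving the resting
#' capacity `qsr`, the stimulable increment `qsu` and the upshift
#' half-saturation `ku`. If initial rates and acid doses are supplied, the
#' linear decline of `qsi` with the acid dose is fitted as well.
#'
#' If the table carries a `qsm_se` column (per-experiment asymptotic
#' standard errors, as produced by [estimate_experiment()]), the fit is
#' inverse-variance weighted, so experiments whose pulse was too small to
#' pin down the plateau rate contribute their actual information.
#'
#' @param experiments a data frame with columns `csi` and `qsm`
#'   (mgCOD/gVSS/min); optional columns `qsm_se`, `qsi` and `acid_dose`.
#' @return A `pha_upshift` object with `qsr`, `qsu`, `ku`, standard errors,
#'   the input table, and (optionally) the `qsi` linear trend. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
fit_upshift <- function(experiments) {
  stopifnot(is.data.frame(experiments),
            all(c("csi", "qsm") %in% names(experiments)))
  df <- dplyr::filter(experiments, is.finite(.data$qsm))
  if (dplyr::n_distinct(df$csi) < 4) {
    stop("need at least 4 distinct csi levels to identify the upshift law",
         call. = FALSE)
  }
  w <- rep(1, nrow(df))
  if ("qsm_se" %in% names(df) && any(is.finite(df$qsm_se))) {
    se <- pmax(df$qsm_se, 0.02 * df$qsm)  # floor: 2% relative
    w <- ifelse(is.finite(se) & se > 0, 1 / se^2, 0)
    if (all(w == 0)) w <- rep(1, nrow(df))
  }
  df$.w <- w / mean(w)
  start <- list(qsr = max(min(df$qsm), 0.1),
                qsu = max(diff(range(df$qsm)), 1),
                ku = median(df$csi))
  fit <- minpack.lm::nlsLM(
    qsm ~ qsr + qsu * csi / (ku + csi), data = df, start = start,
    weights = df$.w,
    lower = c(qsr = 0, qsu = 0, ku = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  qsi_fit <- NULL
  if (all(c("qsi", "acid_dose") %in% names(experiments))) {
    qdf <- dplyr::filter(experiments, is.finite(.data$qsi))
    if (nrow(qdf) >= 3) qsi_fit <- lm(qsi ~ acid_dose, data = qdf)
  }
  structure(
    list(qsr = unname(cf[["qsr"]]), qsu = unname(cf[["qsu"]]),
         ku = unname(cf[["ku"]]), se = se, fit = fit,
         experiments = tibble::as_tibble(experiments), qsi_fit = qsi_fit),
    class = "pha_upshift"
  )
}

#' @export
print.pha_fit <- function(x, ...) {
  cat("<pha_fit> (", x$mode, ") csi =", x$csi, "mgCOD/L, xa =", x$xa,
      "gVSS/L\n")
  est <- x$estimates
  show <- est[!vapply(est, is.na, logical(1))]
  cat(paste0("  ", names(show), " = ", signif(unlist(show), 4),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.pha_fit <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    term = names(est),
    estimate = unlist(est, use.names = FALSE)
  )
}

#' @export
glance.pha_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, csi = x$csi, xa = x$xa,
    rss = x$rss %||% NA_real_,
    nobs = nrow(x$trend)
  )
}

#' @export
autoplot.pha_fit <- function(object, ...) {
  if (object$mode == "aerated") {
    ggplot2::ggplot(object$trend, ggplot2::aes(.data$c_s, .data$q_s)) +
      ggplot2::geom_path(alpha = 0.6) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(
        x = expression(C[s] ~ "(mgCOD/L)"),
        y = expression(q[s] ~ "(mgCOD/gVSS/min)")
      )
  } else {
    ggplot2::ggplot(object$trend, ggplot2::aes(.data$time_s / 60)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$do_obs), size = 0.6) +
      ggplot2::geom_line(ggplot2::aes(y = .data$do_fit), colour = "red3") +
      ggplot2::labs(x = "time (min)", y = "DO (mg/L)")
  }
}

#' @export
print.pha_upshift <- function(x, ...) {
  cat("<pha_upshift> qsr =", signif(x$qsr, 4), "qsu =", signif(x$qsu, 4),
      "ku =", signif(x$ku, 4), "\n")
  invisible(x)
}

#' @export
tidy.pha_upshift <- function(x, ...) {
  tibble::tibble(
    term = c("qsr", "qsu", "ku"),
    estimate = c(x$qsr, x$qsu, x$ku),
    std.error = unname(x$se[c("qsr", "qsu", "ku")])
  )
}

#' @export
glance.pha_upshift <- function(x, ...) {
  tibble::tibble(
    nobs = sum(is.finite(x$experiments$qsm)),
    rss = sum(residuals(x$fit)^2),
    qsi_slope = if (is.null(x$qsi_fit)) NA_real_ else coef(x$qsi_fit)[[2]]
  )
}

#' @export
autoplot.pha_upshift <- function(object, ...) {
  grid <- tibble::tibble(csi = seq(0, max(object$experiments$csi), length.out = 200))
  grid$qsm <- object$qsr + object$qsu * grid$csi / (object$ku + grid$csi)
  ggplot2::ggplot(object$experiments, ggplot2::aes(.data$csi, .data$qsm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red3") +
    ggplot2::labs(
      x = expression(C[si] ~ "(mgCOD/L)"),
      y = expression(q[sm] ~ "(mgCOD/gVSS/min)")
    )
}
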