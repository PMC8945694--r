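#' Configuration of a two-zone continuous-flow accumulation process
#'
#' Describes the simulated flow-through PHA accumulation module: an aerated
#' maintenance volume `vm` holding the retained biomass at low substrate
#' concentration, and a small stimulation mixing zone `vs` receiving the
#' influent, through which mixed liquor is continuously recirculated at
#' flow `Qm = vm / hrt_m`. The stimulation zone volume is set from the
#' recirculation flow to give the prescribed `hrt_s` (`vs = Qm * hrt_s`).
#' Influent flow is adjusted by the loading controller to a fraction `f_l`
#' of the biomass maximum possible uptake rate.
#'
#' @param kinetics a [kinetic_params()] set (the laboratory preset is the
#'   characterized default).
#' @param vm maintenance volume, L.
#' @param hrt_m maintenance hydraulic residence time `vm/Qm`, minutes.
#' @param hrt_s stimulation zone residence time `vs/Qm`, seconds.
#' @param csf feed substrate concentration, mgCOD/L.
#' @param f_l applied fraction of the maximum possible organic loading rate,
#'   in (0, 1].
#' @param xa_total_conc active biomass concentration in `vm`, gVSS/L.
#' @param f_pha_max maximum PHA content, gPHA/gVSS (defaults to the kinetic
#'   set's value).
#' @param n_elements number of individually followed floc elements (>= 100).
#' @param tau_resp element first-order response time constant, seconds.
#' @param dt_max integration time step, seconds.
#' @param t_end simulated time, minutes.
#' @param seed integer seed.
#' @param recirculate logical; `FALSE` feeds the influent directly into
#'   `vm` (the unstimulated limit, no stimulation zone).
#' @param init_occupancy logical; start with elements assigned to the
#'   stimulation zone at its steady occupancy fraction
#'   `hrt_s / (hrt_s + 60 * hrt_m)` instead of all in maintenance.
#' @param cref_decay optional first-order forgetting rate of the
#'   stimulation memory, 1/s (0 = the remembered peak never decays).
#' @param macro_every number of time steps between controller /
#'   PHA-inhibition refreshes.
#' @param record_every_s recording stride of the output series, seconds.
#' @return A `process_config` object (named list, with derived `qm_l_min`
#'   and `vs`).
#' @export
process_config <- function(kinetics = kinetic_preset("lab"), vm = 500,
                           hrt_m = 10, hrt_s = 30, csf = 1000, f_l = 0.7,
                           xa_total_conc = 5, f_pha_max = NULL,
                           n_elements = 10000, tau_resp = 5, dt_max = 0.05,
                           t_end = 40, seed = 1L, recirculate = TRUE,
                           init_occupancy = FALSE, cref_decay = 0,
                           macro_every = 20, record_every_s = 5) {
  stopifnot(inherits(kinetics, "kinetic_params"),
            vm > 0, hrt_m > 0, hrt_s > 0, csf > 0,
            f_l > 0, f_l <= 1, xa_total_conc > 0,
            n_elements >= 100, tau_resp > 0, dt_max > 0, t_end > 0)
  qm <- vm / hrt_m             # L/min
  vs <- qm * hrt_s / 60        # L
  structure(
    list(
      kinetics = kinetics, vm = vm, hrt_m = hrt_m, hrt_s = hrt_s,
      csf = csf, f_l = f_l, xa_total_conc = xa_total_conc,
      f_pha_max = f_pha_max %||% kinetics$f_pha_max,
      n_elements = as.integer(n_elements), tau_resp = tau_resp,
      dt_max = dt_max, t_end = t_end, seed = as.integer(seed),
      recirculate = recirculate, init_occupancy = init_occupancy,
      cref_decay = cref_decay, macro_every = as.integer(macro_every),
      record_every_s = record_every_s,
      qm_l_min = qm, vs = vs
    ),
    class = "process_config"
  )
}

#' Initialize the floc element population
#'
#' Divides the retained biomass into `n_elements` equal parcels of active
#' mass `xa_total_conc * vm / n_elements` gVSS each, polymer-free and with
#' no stimulation memory. By default all elements start in the maintenance
#' zone; with `init_occupancy = TRUE` a seeded random subset starts in the
#' stimulation zone at its steady occupancy fraction.
#'
#' @param config a [process_config()].
#' @return A tibble with columns `id`, `xa` (gVSS), `m_pha` (mgCOD),
#'   `c_ref` (mgCOD/L), `q_cur` (mgCOD/gVSS/min), `zone`.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "process_config"))
  n <- config$n_elements
  zone <- rep("maintenance", n)
  if (config$init_occupancy && config$recirculate) {
    frac <- config$hrt_s / (config$hrt_s + 60 * config$hrt_m)
    set.seed(config$seed)
    zone[sample.int(n, round(frac * n))] <- "stimulation"
  }
  tibble::tibble(
    id = seq_len(n),
    xa = config$xa_total_conc * config$vm / n,
    m_pha = 0,
    c_ref = 0,
    q_cur = 0,
    zone = zone
  )
}

#' Hysteretic target uptake rate of floc elements
#'
#' Updates each element's stimulation memory (`c_ref`, the highest
#' substrate concentration experienced so far) and returns the target
#' specific uptake rate: upshift kinetics set the attainable maximum from
#' `c_ref`, downshift Monod kinetics scale it by the local concentration,
#' and accumulated polymer inhibits it. Elements in the stimulation zone
#' have target zero (anticipated DO limitation) but still update `c_ref`.
#'
#' @param cs_local local substrate concentration seen by each element,
#'   mgCOD/L (scalar or vector).
#' @param c_ref current stimulation memories, mgCOD/L.
#' @param f_pha current PHA contents, gPHA/gVSS.
#' @param in_stimulation logical vector; element currently in the
#'   stimulation zone?
#' @param p a [kinetic_params()] set.
#' @return List with updated `c_ref` and `target` rates (mgCOD/gVSS/min).
#' @export
element_target_rate <- function(cs_local, c_ref, f_pha, in_stimulation, p) {
  c_ref_new <- pmax(c_ref, cs_local)
  qsm_i <- qs_max_upshift(c_ref_new, p)
  target <- qsm_i * cs_local / (p$ks + cs_local) * pha_inhibition(f_pha, p)
  target[in_stimulation] <- 0
  list(c_ref = c_ref_new, target = target)
}

#' First-order relaxation of element uptake rates
#'
#' Exact, unconditionally stable update of the element response:
#' `q <- q + (target - q) * (1 - exp(-dt / tau))`, so 95% of a sustained
#' step change is realized after three time constants.
#'
#' @param q_cur current rates.
#' @param target target rates.
#' @param dt time step, seconds.
#' @param tau_resp response time constant, seconds.
#' @return Updated rates.
#' @export
relax_rates <- function(q_cur, target, dt, tau_resp) {
  stopifnot(dt > 0)
  q_cur + (target - q_cur) * (1 - exp(-dt / tau_resp))
}

#' Loading-controller influent flow
#'
#' Sets the influent flow so the substrate mass input rate equals a
#' fraction `f_l` of the maximum possible system uptake rate: `Qf * csf =
#' f_l * sum(xa_i * qsim_i)` over the maintenance population, with
#' `qsim_i` the polymer-inhibited saturated maximum `(qsr + qsu) *
#' (1 - (f_pha/f_pha_max)^alpha)`.
#'
#' @param xa element masses, gVSS.
#' @param f_pha element PHA contents, gPHA/gVSS.
#' @param in_maintenance logical vector.
#' @param f_l applied loading fraction.
#' @param csf feed concentration, mgCOD/L.
#' @param p a [kinetic_params()] set.
#' @return Influent flow, L/min.
#' @export
controller_flow <- function(xa, f_pha, in_maintenance, f_l, csf, p) {
  qsim <- (p$qsr + p$qsu) * pha_inhibition(f_pha, p)
  f_l * sum(xa[in_maintenance] * qsim[in_maintenance]) / csf
}

#' Random element transport between the zones
#'
#' Moves elements between maintenance and stimulation by uniform random
#' selection, in proportion to flow rate and element number density:
#' expected movers `m -> s` are `Qm * dt * n_m / vm` and `s -> m` are
#' `(Qm + Qf) * dt * n_s / vs`; fractional expectations are resolved by
#' stochastic rounding. No element leaves the system (ideal separator).
#'
#' @param zone character vector (`"maintenance"` / `"stimulation"`).
#' @param dt time step, seconds.
#' @param qm_ls,qf_ls recirculation and influent flows, L/s.
#' @param vm,vs zone volumes, L.
#' @return Updated zone vector.
#' @export
step_transport <- function(zone, dt, qm_ls, qf_ls, vm, vs) {
  in_m <- which(zone == "maintenance")
  in_s <- which(zone == "stimulation")
  stoch_round <- function(x) floor(x) + (runif(1) < x - floor(x))
  k_ms <- min(stoch_round(qm_ls * dt * length(in_m) / vm), length(in_m))
  k_sm <- min(stoch_round((qm_ls + qf_ls) * dt * length(in_s) / vs),
              length(in_s))
  if (k_ms > 0) zone[sample(in_m, k_ms)] <- "stimulation"
  if (k_sm > 0) zone[sample(in_s, k_sm)] <- "maintenance"
  zone
}

#' Advance the zone substrate concentrations by one step
#'
#' Explicit update of the two linear mixing balances with the biological
#' uptake held constant over the step; concentrations are floored at zero
#' with proportional uptake curtailment so substrate mass never goes
#' negative.
#'
#' @param css,csm current concentrations, mgCOD/L.
#' @param qf_ls,qm_ls influent and recirculation flows, L/s.
#' @param csf feed concentration, mgCOD/L.
#' @param vs,vm zone volumes, L.
#' @param uptake_mg_s total maintenance-zone uptake, mgCOD/s.
#' @param dt time step, seconds.
#' @return List with new `css`, `csm` and the uptake curtailment `scale`
#'   in \[0, 1\].
#' @export
integrate_concentrations <- function(css, csm, qf_ls, qm_ls, csf, vs, vm,
                                     uptake_mg_s, dt) {
  dcss <- (qf_ls * csf + qm_ls * csm - (qm_ls + qf_ls) * css) / vs
  dcsm <- ((qm_ls + qf_ls) * css - (qm_ls + qf_ls) * csm - uptake_mg_s) / vm
  css_new <- max(css + dcss * dt, 0)
  csm_new <- csm + dcsm * dt
  scale <- 1
  if (csm_new < 0) {
    avail <- csm + (dcsm + uptake_mg_s / vm) * dt
    need <- uptake_mg_s * dt / vm
    scale <- if (need > 0) min(max(avail, 0) / need, 1) else 0
    csm_new <- max(avail - scale * need, 0)
  }
  list(css = css_new, csm = csm_new, scale = scale)
}

#' Run the Monte Carlo accumulation process simulation
#'
#' Advances the element population and the two-zone substrate balances with
#' the loop controller-flow / element-targets / rate-relaxation /
#' random-transport / concentration-update at a fixed step `dt_max`,
#' recording the process series at a configurable stride. Fully
#' reproducible for a given seed.
#'
#' @param config a [process_config()].
#' @return A `pha_process` object: the trajectory tibble (`t_min`, `css`,
#'   `csm`, `qf_l_min`, `uptake_mg_min`, `uptake_frac`, `mean_fpha`,
#'   `cum_feed_mg`, `cum_effluent_mg`, `n_in_vs`) with the final element
#'   population, the mass ledger, and the configuration as attributes.
#' @export
run_process <- function(config) {
  stopifnot(inherits(config, "process_config"))
  pop <- init_population(config)
  p <- config$kinetics
  set.seed(config$seed)
  res <- process_core(
    n_elements = config$n_elements, vm = config$vm, vs = config$vs,
    qm_ls = config$qm_l_min / 60, csf = config$csf, f_l = config$f_l,
    xa_elem = pop$xa[1], f_pha_max = config$f_pha_max,
    beta_phb = p$beta_phb, alpha = p$alpha, yos = p$yos, qsr = p$qsr,
    qsu = p$qsu, ku = p$ku, ks = p$ks, tau_resp = config$tau_resp,
    dt = config$dt_max, t_end_s = config$t_end * 60,
    macro_every = config$macro_every,
    record_every_s = config$record_every_s,
    recirculate = config$recirculate, cref_decay = config$cref_decay,
    init_in_s = as.integer(pop$zone == "stimulation"),
    init_f_pha = rep(0, config$n_elements)
  )
  traj <- tibble::as_tibble(res$trajectory)
  attr(traj, "config") <- config
  attr(traj, "elements") <- tibble::as_tibble(res$elements)
  attr(traj, "ledger") <- res$ledger
  class(traj) <- c("pha_process", class(traj))
  traj
}

#' Steady-state summary of a process run
#'
#' Averages the recorded series over the trailing window of the run.
#'
#' @param traj a `pha_process` trajectory.
#' @param window_frac trailing fraction of the record to average over.
#' @return One-row tibble with `csm_ss`, `css_ss`, `uptake_frac_ss`,
#'   `qf_ss` and `mean_fpha_end`.
#' @export
steady_state <- function(traj, window_frac = 1 / 6) {
  t_end <- max(traj$t_min)
  w <- dplyr::filter(traj, .data$t_min >= t_end * (1 - window_frac))
  tibble::tibble(
    csm_ss = mean(w$csm),
    css_ss = mean(w$css),
    uptake_frac_ss = mean(w$uptake_frac),
    qf_ss = mean(w$qf_l_min),
    mean_fpha_end = traj$mean_fpha[nrow(traj)]
  )
}

#' COD conservation closure of a process run
#'
#' Checks the cumulative ledger: fed substrate COD must equal effluent COD
#' plus the dissolved inventory plus total biological uptake; and stored
#' polymer COD must equal `(1 - yos)` of the total uptake.
#'
#' @param traj a `pha_process` trajectory.
#' @return List with `closure` (relative ledger error) and
#'   `storage_closure` (relative stored-polymer error).
#' @export
cod_balance <- function(traj) {
  led <- attr(traj, "ledger")
  cfg <- attr(traj, "config")
  p <- cfg$kinetics
  el <- attr(traj, "elements")
  stored_cod <- sum(el$f_pha * cfg$xa_total_conc * cfg$vm /
                      cfg$n_elements) * 1000 * p$beta_phb
  closure <- (led$cum_feed_mg - led$cum_effluent_mg - led$dissolved_mg -
                led$cum_uptake_mg) / led$cum_feed_mg
  storage_closure <- (stored_cod - (1 - p$yos) * led$cum_uptake_mg) /
    max((1 - p$yos) * led$cum_uptake_mg, 1e-12)
  list(closure = closure, storage_closure = storage_closure)
}

#' Analytic steady-state of the maintenance-zone substrate balance
#'
#' Scalar fixed point of the loading balance `f_l * Umax = f_l * Umax *
#' c/csf + U(c)` solved by bracketed root finding, where `U(c)` is the
#' population uptake at concentration `c`: in the unstimulated mode the
#' biomass has only ever seen `c` itself (`c_ref = c`); in the stimulated
#' mode it has been exposed to the stimulation-zone concentration `css`.
#' Used as an independent oracle for the limiting behaviour of
#' [run_process()].
#'
#' @param p a [kinetic_params()] set.
#' @param config a [process_config()] (uses `vm`, `xa_total_conc`, `csf`,
#'   `f_l`).
#' @param mode `"unstimulated"` or `"stimulated"`.
#' @param css stimulation-zone concentration for the stimulated mode,
#'   mgCOD/L.
#' @param inhibition fixed PHA-inhibition factor applied to both the
#'   capacity and the uptake (default 1: polymer-free).
#' @return Steady maintenance-zone concentration, mgCOD/L.
#' @export
analytic_fixed_point <- function(p, config,
                                 mode = c("unstimulated", "stimulated"),
                                 css = NULL, inhibition = 1) {
  mode <- match.arg(mode)
  if (mode == "stimulated" && is.null(css)) {
    stop("`css` must be supplied in stimulated mode", call. = FALSE)
  }
  xa_tot <- config$xa_total_conc * config$vm
  u_max <- xa_tot * (p$qsr + p$qsu) * inhibition
  load <- config$f_l * u_max
  uptake <- function(c) {
    c_ref <- if (mode == "unstimulated") c else css
    xa_tot * qs_max_upshift(c_ref, p) * c / (p$ks + c) * inhibition
  }
  g <- function(c) load - load * c / config$csf - uptake(c)
  if (g(0) <= 0 || g(config$csf) >= 0) {
    stop("no steady state in (0, csf): the loading balance has no root",
         call. = FALSE)
  }
  uniroot(g, c(0, config$csf), tol = 1e-8)$root
}

#' Loading sweep of the accumulation process
#'
#' Runs the process over a grid of applied loading fractions and summarizes
#' each run: the achieved fraction of the maximum possible uptake rate, the
#' steady zone concentrations, the average specific PHA production rate at
#' 30 minutes, and the substrate utilization efficiency
#' `1 - (effluent COD out) / (feed COD in)`.
#'
#' @param config a [process_config()] (its `f_l` is overridden).
#' @param f_l_grid numeric vector of loading fractions in (0, 1].
#' @return A tibble with one row per grid point: `f_l`, `achieved_frac`,
#'   `csm_ss`, `css_ss`, `pha_rate_30min` (mgPHA/gVSS/min) and
#'   `efficiency`.
#' @export
sweep_loading <- function(config, f_l_grid = seq(0.5, 1, by = 0.05)) {
  stopifnot(all(f_l_grid > 0), all(f_l_grid <= 1))
  purrr::map_dfr(seq_along(f_l_grid), function(i) {
    cfg <- config
    cfg$f_l <- f_l_grid[i]
    cfg$seed <- config$seed + i
    traj <- run_process(cfg)
    ss <- steady_state(traj)
    i30 <- which.min(abs(traj$t_min - 30))
    tibble::tibble(
      f_l = f_l_grid[i],
      achieved_frac = ss$uptake_frac_ss,
      csm_ss = ss$csm_ss,
      css_ss = ss$css_ss,
      pha_rate_30min = traj$mean_fpha[i30] * 1000 / traj$t_min[i30],
      efficiency = 1 - traj$cum_effluent_mg[nrow(traj)] /
        traj$cum_feed_mg[nrow(traj)]
    )
  })
}

#' Locate the loading break point of a sweep
#'
#' The smallest loading fraction at which the achieved fraction of the
#' maximum uptake rate falls short of the target by more than `shortfall`
#' (relative): beyond it, further loading buys no productivity while the
#' effluent concentration rises steeply.
#'
#' @param sweep result of [sweep_loading()].
#' @param shortfall relative shortfall threshold (default 5%).
#' @return The break-point `f_l` (or `NA` if the sweep never falls short).
#' @export
find_breakpoint <- function(sweep, shortfall = 0.05) {
  short <- sweep$achieved_frac < (1 - shortfall) * sweep$f_l
  if (!any(short)) return(NA_real_)
  min(sweep$f_l[short])
}

#' @export
autoplot.pha_process <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "t_min", "csm", "css", "uptake_frac",
                  "mean_fpha"),
    -"t_min", names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t_min, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
}

#' @export
glance.pha_process <- function(x, ...) {
  cfg <- attr(x, "config")
  bal <- cod_balance(x)
  dplyr::bind_cols(
    tibble::tibble(f_l = cfg$f_l, hrt_m = cfg$hrt_m,
                   n_elements = cfg$n_elements, t_end = cfg$t_end),
    steady_state(x),
    tibble::tibble(cod_closure = bal$closure)
  )
}
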