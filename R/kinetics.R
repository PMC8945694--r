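#' Kinetic parameter set for a PHA-storing mixed culture
#'
#' Container for the full set of rate, affinity, yield and inhibition
#' constants that drive the respiration mass balance, the parameter
#' estimation pipeline and the accumulation process simulator. All rates are
#' per minute; concentrations are mgCOD/L (substrate) or mgO2/L (oxygen).
#'
#' @param ka aeration oxygen mass-transfer coefficient (1/min).
#' @param co_star apparent oxygen saturation concentration (mgO2/L).
#' @param qoe specific endogenous respiration rate (mgO2/gVSS/min).
#' @param yos oxygen-on-substrate yield (gO2/gCOD), in (0, 1).
#' @param ks downshift (consumption) substrate affinity constant (mgCOD/L).
#' @param ko oxygen affinity constant (mgO2/L).
#' @param kh Haldane substrate-inhibition constant (mgCOD/L).
#' @param ki induction (lag) substrate-consumed constant (mgCOD/L).
#' @param fi initial-rate suppression fraction, in (0, 1).
#' @param ku upshift half-saturation constant (mgCOD/L).
#' @param qsr resting (inherent) maximum specific substrate uptake rate
#'   (mgCOD/gVSS/min).
#' @param qsu stimulable increment of the maximum specific uptake rate
#'   (mgCOD/gVSS/min).
#' @param qop_coeff coefficient of the two-thirds power law linking specific
#'   respiration on stored polymer to polymer content
#'   (mgO2/gVSS/min per (gPHA/gVSS)^(2/3)).
#' @param f_pha_max maximum PHA-to-active-biomass mass ratio (gPHA/gVSS).
#' @param alpha PHA inhibition exponent (dimensionless, > 0).
#' @param beta_phb COD equivalent of PHB (gCOD/gPHB).
#' @param cod_per_vss biomass COD-to-VSS conversion factor (mgCOD/mgVSS).
#'
#' @details
#' The premise of the model is a hysteresis between upshift and downshift
#' kinetics: the substrate concentration needed to *stimulate* a given
#' uptake rate (`ku` scale) is much larger than the concentration needed to
#' *maintain* it once attained (`ks` scale). `ks < ku` is asserted for the
#' shipped presets and warned about for user-supplied sets.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [kinetic_preset()] for the shipped laboratory/pilot parameter
#'   sets, [qs_max_upshift()] and friends for the rate laws.
#' @export
#' @examples
#' p <- kinetic_preset("lab")
#' qs_max_upshift(57, p)
kinetic_params <- function(ka, co_star = 8.3, qoe, yos, ks, ko = 0.05,
                           kh = 2000, ki = 10, fi = 0.5, ku, qsr, qsu,
                           qop_coeff = 9.4, f_pha_max = 0.6, alpha = 1.24,
                           beta_phb = 1.674, cod_per_vss = 1.42) {
  p <- list(
    ka = ka, co_star = co_star, qoe = qoe, yos = yos, ks = ks, ko = ko,
    kh = kh, ki = ki, fi = fi, ku = ku, qsr = qsr, qsu = qsu,
    qop_coeff = qop_coeff, f_pha_max = f_pha_max, alpha = alpha,
    beta_phb = beta_phb, cod_per_vss = cod_per_vss
  )
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  nonneg <- c(
    "ka", "co_star", "qoe", "ks", "ko", "kh", "ki", "ku", "qsr", "qsu",
    "qop_coeff", "f_pha_max"
  )
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("kinetic parameter `", nm, "` must be a single nonnegative number",
           call. = FALSE)
    }
  }
  if (p$fi <= 0 || p$fi >= 1) stop("`fi` must lie in (0, 1)", call. = FALSE)
  if (p$yos <= 0 || p$yos >= 1) stop("`yos` must lie in (0, 1)", call. = FALSE)
  if (p$alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (p$beta_phb <= 0) stop("`beta_phb` must be positive", call. = FALSE)
  if (p$cod_per_vss <= 0) stop("`cod_per_vss` must be positive", call. = FALSE)
  if (p$ks >= p$ku) {
    warning("`ks` >= `ku`: no upshift/downshift hysteresis in this ",
            "parameter set", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  print(tibble::tibble(
    parameter = names(x),
    value = unlist(x, use.names = FALSE)
  ), n = length(x))
  invisible(x)
}

#' @export
format.kinetic_params <- function(x, ...) {
  paste0("<kinetic_params: ks=", x$ks, ", ku=", x$ku, ">")
}

#' Shipped parameter presets for the two characterized enrichment cultures
#'
#' Mean kinetic constants for a laboratory-scale and a pilot-scale
#' feast/famine sequencing-batch-reactor enrichment biomass, as estimated by
#' respirometric mass-balance characterization. `kh`, `ki`, `fi`,
#' `qop_coeff` and `ko` have no tabulated experimental means; they carry
#' documented modelling defaults (see the methods vignette) and are only
#' used by the synthetic-respirogram generator, never reported as measured
#' values.
#'
#' @param name `"lab"` or `"pilot"`.
#' @param ... named overrides for individual fields, e.g. `ks = 0.110`.
#' @return A [kinetic_params()] object.
#' @export
#' @examples
#' kinetic_preset("pilot")$ku
kinetic_preset <- function(name = c("lab", "pilot"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    lab = list(
      ka = 1.11, qoe = 0.64, yos = 0.26, ks = 2.0, ku = 38,
      qsr = 7.4, qsu = 21.1, f_pha_max = 0.6
    ),
    pilot = list(
      ka = 0.60, qoe = 0.25, yos = 0.23, ks = 1.8, ku = 20,
      qsr = 2.5, qsu = 6.8, f_pha_max = 0.43
    )
  )
  args <- modifyList(base, list(...))
  p <- do.call(kinetic_params, args)
  stopifnot(p$ks < p$ku) # hysteresis premise holds for shipped presets
  p
}

#' Maximum specific uptake rate stimulated by a peak substrate concentration
#'
#' Upshift Monod law: the maximum specific substrate uptake rate a famine
#' biomass expresses after exposure to peak substrate concentration `csi` is
#' `qsr + qsu * csi / (ku + csi)` -- a resting capacity plus a stimulable
#' increment saturating with half-saturation `ku`.
#'
#' @param csi peak (initial) substrate concentration, mgCOD/L. Vectorized.
#' @param p a [kinetic_params()] set.
#' @return Maximum specific uptake rate, mgCOD/gVSS/min.
#' @export
qs_max_upshift <- function(csi, p) {
  if (any(csi < 0)) stop("`csi` must be nonnegative", call. = FALSE)
  p$qsr + p$qsu * csi / (p$ku + csi)
}

#' Haldane-Monod specific substrate uptake rate
#'
#' Downshift law with substrate inhibition and oxygen limitation:
#' `qse * min(cs / (ks + cs + cs^2/kh), co / (ko + co))`.
#'
#' @param cs substrate concentration, mgCOD/L. Vectorized.
#' @param co dissolved oxygen concentration, mgO2/L.
#' @param qse extant maximum specific uptake rate, mgCOD/gVSS/min.
#' @param p a [kinetic_params()] set.
#' @return Specific uptake rate, mgCOD/gVSS/min.
#' @export
qs_uptake <- function(cs, co, qse, p) {
  if (any(cs < 0) || any(co < 0) || any(qse < 0)) {
    stop("`cs`, `co` and `qse` must be nonnegative", call. = FALSE)
  }
  sub_term <- cs / (p$ks + cs + cs^2 / p$kh)
  oxy_term <- co / (p$ko + co)
  qse * pmin(sub_term, oxy_term)
}

#' Induction (lag) factor of the extant uptake rate
#'
#' Time-implicit lag: directly after the pulse the biomass expresses only a
#' fraction `1 - fi` of its maximum rate; the rate recovers as substrate is
#' consumed, with half-recovery after `ki` mgCOD/L consumed:
#' `1 - fi * ki / (ki + (csi - cs))`.
#'
#' @param csi initial substrate concentration, mgCOD/L.
#' @param cs current substrate concentration, mgCOD/L (`cs <= csi`).
#' @param p a [kinetic_params()] set.
#' @return Fraction in (0, 1]. Vectorized over `cs`.
#' @export
induction_factor <- function(csi, cs, p) {
  if (any(cs < 0) || any(cs > csi)) {
    stop("`cs` must lie in [0, csi]", call. = FALSE)
  }
  1 - p$fi * p$ki / (p$ki + (csi - cs))
}

#' Uptake-rate inhibition by accumulated PHA
#'
#' Storage saturation: `1 - (f_pha / f_pha_max)^alpha`, equal to 1 for
#' polymer-free biomass and 0 at the maximum storage capacity. Contents
#' above `f_pha_max` are clamped to full inhibition with a warning.
#'
#' @param f_pha PHA-to-active-biomass mass ratio, gPHA/gVSS. Vectorized.
#' @param p a [kinetic_params()] set.
#' @return Fraction in \[0, 1\].
#' @export
pha_inhibition <- function(f_pha, p) {
  if (any(f_pha < 0)) stop("`f_pha` must be nonnegative", call. = FALSE)
  if (any(f_pha > p$f_pha_max)) {
    warning("`f_pha` above `f_pha_max`; clamping inhibition factor to 0",
            call. = FALSE)
  }
  pmax(0, 1 - (pmin(f_pha, p$f_pha_max) / p$f_pha_max)^p$alpha)
}

#' Volumetric respiration rate on stored polymer
#'
#' Switching law: respiration on stored PHA switches on as exogenous
#' substrate depletes, `xa * qop * min(ks / (ks + cs), co / (ko + co))`.
#'
#' @param cs substrate concentration, mgCOD/L. Vectorized.
#' @param co dissolved oxygen concentration, mgO2/L.
#' @param xa active biomass concentration, gVSS/L.
#' @param qop initial specific respiration rate on stored polymer,
#'   mgO2/gVSS/min.
#' @param p a [kinetic_params()] set.
#' @return Volumetric respiration rate, mgO2/L/min.
#' @export
qop_volumetric <- function(cs, co, xa, qop, p) {
  if (any(cs < 0) || any(co < 0) || any(xa < 0) || any(qop < 0)) {
    stop("all arguments must be nonnegative", call. = FALSE)
  }
  xa * qop * pmin(p$ks / (p$ks + cs), co / (p$ko + co))
}

#' Stored polymer from the COD mass balance
#'
#' With a constant oxygen yield and no active growth, consumed substrate COD
#' not respired is stored: `Xp = (1 - yos) * (csi - cs)` (mgCOD/L).
#'
#' @param csi initial substrate concentration, mgCOD/L.
#' @param cs current substrate concentration, mgCOD/L (`cs <= csi`).
#' @param p a [kinetic_params()] set.
#' @return Stored polymer concentration, mgCOD/L. Vectorized over `cs`.
#' @export
pha_stored_cod <- function(csi, cs, p) {
  if (any(cs < 0) || any(cs > csi)) {
    stop("`cs` must lie in [0, csi]", call. = FALSE)
  }
  (1 - p$yos) * (csi - cs)
}

#' Convert stored polymer COD to a biomass PHA content
#'
#' Divides the polymer COD by the PHB COD equivalent (`beta_phb`,
#' 1.674 gCOD/gPHB for poly-3-hydroxybutyrate) and by the active biomass to
#' give a gPHA/gVSS content.
#'
#' @param xp stored polymer, mgCOD/L.
#' @param xa active biomass, gVSS/L.
#' @param p a [kinetic_params()] set.
#' @return PHA content, gPHA/gVSS.
#' @export
#' @examples
#' # a 57 mgCOD/L acetate pulse at 1 gVSS/L stores about 2.5% gPHA/gVSS
#' p <- kinetic_preset("lab")
#' pha_content(pha_stored_cod(57, 0, p), xa = 1, p)
pha_content <- function(xp, xa, p) {
  if (any(xa <= 0)) stop("`xa` must be positive", call. = FALSE)
  (xp / p$beta_phb) / (1000 * xa)
}

#' Two-thirds power law for famine respiration on stored polymer
#'
#' The specific respiration rate directly after substrate depletion scales
#' with the stored polymer content as `qop_coeff * f_pha^(2/3)`, the
#' surface-to-volume scaling expected for intracellular granules.
#'
#' @param f_pha PHA content, gPHA/gVSS. Vectorized.
#' @param p a [kinetic_params()] set.
#' @return Specific respiration rate, mgO2/gVSS/min.
#' @export
qop_powerlaw <- function(f_pha, p) {
  if (any(f_pha < 0)) stop("`f_pha` must be nonnegative", call. = FALSE)
  p$qop_coeff * f_pha^(2 / 3)
}

#' Specific substrate uptake rate from a volumetric respiration rate
#'
#' Inverts the yield coupling `Qos = yos * xa * qs`:
#' `qs = Qos / (yos * xa)`.
#'
#' @param q_os volumetric respiration rate on substrate, mgO2/L/min.
#'   Vectorized.
#' @param xa active biomass concentration, gVSS/L (positive).
#' @param p a [kinetic_params()] set (uses `yos`).
#' @return Specific uptake rate, mgCOD/gVSS/min.
#' @export
qs_specific <- function(q_os, xa, p) {
  if (xa <= 0) stop("`xa` must be positive", call. = FALSE)
  if (p$yos <= 0) stop("`yos` must be positive", call. = FALSE)
  q_os / (p$yos * xa)
}

#' Serialize a kinetic parameter set to flat JSON
#'
#' @param p a [kinetic_params()] set.
#' @param path file path; the parameter set is written as a flat JSON object
#'   keyed by field name.
#' @return `path`, invisibly.
#' @export
write_kinetic_params <- function(p, path) {
  stopifnot(inherits(p, "kinetic_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kinetic parameter set from flat JSON
#'
#' @param path file path, or a preset name (`"lab"`, `"pilot"`).
#' @return A [kinetic_params()] object.
#' @export
read_kinetic_params <- function(path) {
  if (path %in% c("lab", "pilot")) {
    return(kinetic_preset(path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(kinetic_params, as.list(x))
}
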