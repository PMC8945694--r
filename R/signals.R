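#' Savitzky-Golay smoothing and first derivative
#'
#' Second-order, 7-point Savitzky-Golay filtering of a uniformly sampled
#' signal, returning the smoothed signal and its first derivative (per
#' second). Interior samples use the standard convolution weights; the first
#' and last three samples use the off-centre rows of the local polynomial
#' fit, so polynomials up to order 2 are reproduced exactly everywhere.
#'
#' @param x numeric signal, uniformly sampled, length >= 7.
#' @param dt_s sampling interval, seconds.
#' @return A tibble with columns `smooth`, `deriv` and `deriv2` (second
#'   derivative, per second squared).
#' @export
sg_smooth_deriv <- function(x, dt_s) {
  if (length(x) < 7) {
    stop("Savitzky-Golay (2, 7) filtering needs at least 7 samples",
         call. = FALSE)
  }
  stopifnot(dt_s > 0)
  tibble::tibble(
    smooth = signal::sgolayfilt(x, p = 2, n = 7, m = 0),
    deriv = signal::sgolayfilt(x, p = 2, n = 7, m = 1, ts = dt_s),
    deriv2 = signal::sgolayfilt(x, p = 2, n = 7, m = 2, ts = dt_s)
  )
}

#' Correct a measured trace for first-order probe dynamics
#'
#' Inverts the probe response ODE: if the probe obeys
#' `d(measured)/dt = k_probe * (actual - measured)`, then
#' `actual = measured + (1/k_probe) * d(measured)/dt`. The derivative is
#' taken from the Savitzky-Golay filter, so the correction is exact for
#' signals the filter differentiates exactly and within 1% for band-limited
#' inputs. Steady signals pass unchanged.
#'
#' @param x measured signal, uniformly sampled.
#' @param dt_s sampling interval, seconds.
#' @param k_probe probe response constant, 1/s.
#' @return Numeric vector: the interpreted actual signal.
#' @export
correct_probe <- function(x, dt_s, k_probe) {
  stopifnot(k_probe > 0)
  sg <- sg_smooth_deriv(x, dt_s)
  sg$smooth + sg$deriv / k_probe
}

#' Partition a respirogram into analysis zones
#'
#' Splits a pulse-respiration record into Zone 1 (pre-aeration before the
#' pulse), Zone 2 (substrate consumption) and Zone 3 (re-aeration after
#' consumption). The end of consumption is located implicitly: for aerated
#' records it is the maximum rate of DO increase (inflection point) after
#' the post-pulse DO minimum; for non-aerated records, the first point
#' after the pulse where the smoothed DO slope recovers above `-eps`
#' (consumption simply stops). Only the first 4 minutes of Zone 3 are
#' retained for analysis.
#'
#' Segmentation operates on the smoothed trace, so it is invariant to a
#' uniform DO offset and to positive rescaling.
#'
#' @param resp a `respirogram` with metadata carrying the pulse time stamp.
#' @param zone3_min length of the retained Zone 3 window, minutes.
#' @param eps slope threshold for the non-aerated rule, mgO2/L/s.
#' @return A `zone_partition`: list with sample indices `idx_pulse`,
#'   `idx_min`, `idx_inflection`, `zone3_window_end` and integer index
#'   vectors `zone1`, `zone2`, `zone3` (half-open, disjoint, ordered).
#' @export
segment_zones <- function(resp, zone3_min = 4, eps = 1e-3) {
  m <- resp_meta(resp)
  if (is.null(m$t_pulse_s)) {
    stop("respirogram metadata carries no pulse time stamp", call. = FALSE)
  }
  dt <- m$sample_interval
  n <- nrow(resp)
  idx_pulse <- which(resp$time_s >= m$t_pulse_s)[1]
  if (is.na(idx_pulse) || idx_pulse < 2) {
    stop("pulse time stamp outside the record", call. = FALSE)
  }
  sg <- sg_smooth_deriv(resp$do_mg_l, dt)

  aerated <- isTRUE(m$aerated)
  if (aerated) {
    post <- idx_pulse:n
    idx_min <- post[which.min(sg$smooth[post])]  # earliest global minimum
    if (sg$smooth[idx_min] > sg$smooth[idx_pulse] - 0.05) {
      stop("incomplete consumption: no post-pulse DO minimum in the record",
           call. = FALSE)
    }
    if (idx_min >= n - 3) {
      stop("incomplete consumption: no DO recovery after the pulse ",
           "within the record", call. = FALSE)
    }
    rise <- idx_min:n
    idx_inflection <- rise[which.max(sg$deriv[rise])]
  } else {
    idx_min <- NA_integer_
    post <- idx_pulse:n
    ok <- post[sg$deriv[post] > -eps]
    # skip the injection instant itself: require consumption to have started
    started <- post[sg$deriv[post] < -3 * eps]
    if (length(started)) ok <- ok[ok > started[1]]
    if (!length(ok)) {
      stop("incomplete consumption: DO slope never recovers above -eps",
           call. = FALSE)
    }
    idx_inflection <- ok[1]
  }
  zone3_end <- min(idx_inflection + ceiling(zone3_min * 60 / dt), n)
  structure(
    list(
      idx_pulse = idx_pulse,
      idx_min = idx_min,
      idx_inflection = idx_inflection,
      zone3_window_end = zone3_end,
      zone1 = seq_len(idx_pulse - 1L),
      zone2 = seq.int(idx_pulse, idx_inflection - 1L),
      zone3 = seq.int(idx_inflection, zone3_end)
    ),
    class = "zone_partition"
  )
}

#' @export
print.zone_partition <- function(x, ...) {
  cat("<zone_partition> pulse @", x$idx_pulse,
      "| inflection @", x$idx_inflection,
      "| zones:", length(x$zone1), "/", length(x$zone2), "/",
      length(x$zone3), "samples\n")
  invisible(x)
}
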