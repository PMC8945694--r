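#' Write a respirogram to CSV
#'
#' Comma-separated, '.' decimal, UTF-8, header `time_s,do_mg_l[,ph]`.
#' Metadata is written either as `#`-prefixed `key: value` header lines
#' (default) or as a JSON sidecar (`<path>.json`); [read_respirogram()]
#' accepts both dialects. Floats are fixed to 9 significant digits so
#' rewritten files are byte-stable.
#'
#' @param resp a `respirogram`.
#' @param path output file path.
#' @param sidecar logical; write the metadata as a JSON sidecar instead of
#'   `#` header lines.
#' @return `path`, invisibly.
#' @export
write_respirogram <- function(resp, path, sidecar = FALSE) {
  m <- resp_meta(resp)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!sidecar) {
    for (key in names(m)) {
      writeLines(sprintf("# %s: %s", key, format(m[[key]], digits = 9,
                                                 scientific = FALSE)), con)
    }
  }
  writeLines(paste(names(resp), collapse = ","), con)
  cols <- lapply(resp, function(x) {
    if (is.numeric(x)) signif(x, 9) else x
  })
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  if (sidecar) {
    jsonlite::write_json(m, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

parse_meta_value <- function(x) {
  x <- trimws(x)
  if (x %in% c("TRUE", "FALSE")) return(as.logical(x))
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

#' Read a respirogram from CSV
#'
#' Accepts both metadata dialects of [write_respirogram()]: a JSON sidecar
#' (`<path>.json`) or `#`-prefixed `key: value` header lines. Validates a
#' strictly increasing time column and uniform sampling within 1% jitter.
#'
#' @param path CSV file path.
#' @return A `respirogram` tibble.
#' @export
read_respirogram <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else if (length(meta_lines)) {
    for (ln in lines[meta_lines]) {
      kv <- sub("^#\\s*", "", ln)
      key <- sub(":.*$", "", kv)
      meta[[trimws(key)]] <- parse_meta_value(sub("^[^:]*:", "", kv))
    }
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  header <- strsplit(body[1], ",")[[1]]
  if (!all(c("time_s", "do_mg_l") %in% header)) {
    stop("malformed respirogram header at line ",
         length(meta_lines) + 1, ": expected `time_s,do_mg_l[,ph]`",
         call. = FALSE)
  }
  df <- read.csv(text = paste(body, collapse = "\n"), header = TRUE)
  if (any(!is.finite(df$time_s))) {
    stop("non-numeric time value at data line ",
         which(!is.finite(df$time_s))[1], call. = FALSE)
  }
  dts <- diff(df$time_s)
  if (any(dts <= 0)) {
    stop("non-monotone time column at data line ", which(dts <= 0)[1] + 1,
         call. = FALSE)
  }
  if (max(abs(dts - median(dts))) > 0.01 * median(dts)) {
    stop("non-uniform sampling: jitter exceeds 1% of the median interval",
         call. = FALSE)
  }
  if (is.null(meta$sample_interval)) meta$sample_interval <- median(dts)
  out <- tibble::as_tibble(df)
  attr(out, "meta") <- meta
  class(out) <- c("respirogram", class(out))
  out
}

#' Write / read a batch-experiment manifest
#'
#' A manifest lists the respirogram files of an experiment battery with
#' their metadata (biomass, pulse concentration, acid fraction, aeration,
#' probe constant), one row per experiment, as CSV with a schema-version
#' header line.
#'
#' @param manifest a data frame with columns `path`, `xa`, `csi`,
#'   `acid_fraction`, `aerated`, `co_star`, `k_probe`.
#' @param path manifest file path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_manifest <- function(manifest, path) {
  need <- c("path", "xa", "csi", "acid_fraction", "aerated", "co_star",
            "k_probe")
  stopifnot(all(need %in% names(manifest)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# schema_version: 1", con)
  write.csv(manifest, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  ver_line <- grep("^#\\s*schema_version", lines, value = TRUE)
  if (!length(ver_line) || parse_meta_value(sub("^[^:]*:", "", ver_line[1])) != 1) {
    stop("unsupported or missing manifest schema version", call. = FALSE)
  }
  df <- read.csv(text = paste(grep("^#", lines, value = TRUE,
                                   invert = TRUE), collapse = "\n"))
  absent <- df$path[!file.exists(df$path)]
  if (length(absent)) {
    warning("manifest entries not found on disk: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Generate the canonical synthetic experiment battery
#'
#' Writes the standard test battery of synthetic respirograms used by the
#' documentation and tests: both culture presets, pulse concentrations
#' spanning 5 to 500 mgCOD/L, aerated and non-aerated, at fixed derived
#' seeds, plus a manifest. Both regimes of the non-aerated experiments are
#' represented (complete consumption at low pulses, oxygen exhaustion at
#' high ones).
#'
#' @param outdir writable output directory (created if absent).
#' @param seed base seed; per-file seeds are derived deterministically.
#' @param csi_levels pulse concentrations, mgCOD/L.
#' @return The manifest tibble, invisibly; files are written under
#'   `outdir`.
#' @export
generate_fixture_suite <- function(outdir, seed = 1L,
                                   csi_levels = c(5, 15, 57, 150, 381, 500)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (preset in c("lab", "pilot")) {
    p <- kinetic_preset(preset)
    xa <- if (preset == "lab") 1 else 2
    for (aer in c(TRUE, FALSE)) {
      for (csi in csi_levels) {
        if (!aer && !csi %in% range(csi_levels)) next  # both regimes suffice
        sd_offset <- length(rows) + 1L
        cfg <- pulse_config(csi = csi, xa = xa, aerated = aer,
                            seed = seed * 1000L + sd_offset)
        resp <- generate_respirogram(cfg, p)
        fname <- sprintf("%s_%s_csi%03d.csv", preset,
                         if (aer) "aer" else "nonaer", round(csi))
        write_respirogram(resp, file.path(outdir, fname))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          path = file.path(outdir, fname), xa = xa, csi = csi,
          acid_fraction = 1, aerated = aer, co_star = p$co_star,
          k_probe = 0.14, preset = preset
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(outdir, "manifest.csv"))
  invisible(manifest)
}

#' Estimate a whole experiment battery
#'
#' Runs [estimate_experiment()] on every aerated record of a manifest and
#' returns the per-experiment estimates, ready for [fit_upshift()].
#'
#' With `pool_ks = TRUE` (the default) a second pass re-fits every record
#' holding the substrate affinity constant at the battery-level median of
#' the well-resolved interpolated estimates: the affinity is a property of
#' the biomass, not of the pulse size, and pooling it removes the
#' plateau/affinity ridge that makes the smallest pulses unidentifiable on
#' their own. Reported per-experiment `ks` values stay the independent
#' interpolated ones.
#'
#' @param manifest a manifest tibble (see [read_manifest()]).
#' @param pool_ks logical; pool the substrate affinity across the battery.
#' @return A tibble with one row per experiment (`csi`, `xa`, estimates,
#'   `qsi`, `acid_dose`).
#' @export
batch_estimate <- function(manifest, pool_ks = TRUE) {
  aer <- dplyr::filter(manifest, .data$aerated)
  one_pass <- function(ks_fixed) {
    purrr::map_dfr(seq_len(nrow(aer)), function(i) {
      resp <- read_respirogram(aer$path[i])
      fit <- estimate_experiment(resp, ks_fixed = ks_fixed)
      est <- fit$estimates
      tibble::tibble(
        path = aer$path[i], csi = aer$csi[i], xa = aer$xa[i],
        ka = est$ka, yos = est$yos, ks = est$ks, ki = est$ki,
        qsm = est$qsm, qsm_se = est$qsm_se, kh = est$kh, fi = est$fi,
        qsi = est$qsi, q_op = est$q_op,
        acid_dose = aer$csi[i] * aer$acid_fraction[i] / aer$xa[i]
      )
    })
  }
  first <- one_pass(NULL)
  if (!pool_ks) return(first)
  # the descending limb resolves ks only for mid-sized pulses: large
  # enough to outlast the filter transient, small enough that the record
  # is not oxygen-transfer limited
  ok <- is.finite(first$ks) & first$csi >= 30 & first$csi <= 200
  if (sum(ok) < 2) return(first)
  ks_pool <- median(first$ks[ok])
  second <- one_pass(ks_pool)
  second$ks <- first$ks  # report the independent interpolations
  second
}
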