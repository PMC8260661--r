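#' Spectral band definitions for the two instruments
#'
#' Returns the elementary spectral bands used to summarize per-wavelength
#' results: for the broad-range UV-Vis-NIR instrument, the near-ultraviolet
#' window, the visible colors (violet through red, CIE-style boundaries with
#' the visible range spanning 380-740 nm) and the two infrared sub-bands
#' IR-A (NIR, below 1400 nm) and IR-B (SWIR, above 1400 nm); for the
#' miniaturized NIR instrument, IR-A and IR-B only, with the boundary placed
#' on its 6-nm grid (IR-A ends at 1397 nm, IR-B starts at 1403 nm).
#'
#' Band membership is half-open: a wavelength belongs to band `[lo, hi)`,
#' except the last band of each instrument, which is closed at its upper end.
#'
#' @param instrument `"uvvisnir"` or `"micronir"`.
#' @return data.frame with columns `band`, `lo_nm`, `hi_nm`, `group`
#'   (`"ultraviolet"`, `"visible"` or `"infrared"`), ordered by `lo_nm`.
#' @export
band_table <- function(instrument = c("uvvisnir", "micronir")) {
  instrument <- match.arg(instrument)
  if (instrument == "uvvisnir") {
    data.frame(
      band  = c("ultraviolet", "violet", "blue", "cyan", "green", "yellow",
                "orange", "red", "IR-A", "IR-B"),
      lo_nm = c(350, 380, 450, 485, 500, 565, 590, 625, 740, 1400),
      hi_nm = c(380, 450, 485, 500, 565, 590, 625, 740, 1400, 1830),
      group = c("ultraviolet", rep("visible", 7L), "infrared", "infrared"),
      stringsAsFactors = FALSE
    )
  } else {
    # boundary at 1403 nm so that 1397 (= 905 + 6*82) closes IR-A
    data.frame(
      band  = c("IR-A", "IR-B"),
      lo_nm = c(905, 1403),
      hi_nm = c(1403, 1649),
      group = c("infrared", "infrared"),
      stringsAsFactors = FALSE
    )
  }
}

#' Assign every wavelength of a grid to a band
#'
#' @param grid A [wavelength_grid()].
#' @param bands A band table as returned by [band_table()].
#' @return Character vector (one band name per grid wavelength).
#' @export
assign_bands <- function(grid, bands) {
  stopifnot(inherits(grid, "wavelength_grid"))
  w <- grid$wavelengths
  bands <- bands[order(bands$lo_nm), , drop = FALSE]
  k <- findInterval(w, bands$lo_nm)
  last_hi <- bands$hi_nm[nrow(bands)]
  # half-open [lo, hi); the final band also owns its upper endpoint
  bad <- k < 1L | w > last_hi
  bad[!bad] <- w[!bad] >= bands$hi_nm[k[!bad]] & w[!bad] < last_hi
  if (any(bad))
    stop("wavelength not covered by any band: ", w[which(bad)[1L]], " nm")
  bands$band[k]
}

#' Summarize a per-wavelength scan by spectral band
#'
#' Aggregates a [wavelength_scan()] result into one row per band: number of
#' wavelengths, mean and SD (across wavelengths) of the mean absorbance,
#' average variance proportions in percent, and average intra-herd/batch
#' heritability. Proportions and heritability are averaged on the
#' per-wavelength ratio scale. Aggregate rows (`visible`, `infrared`,
#' `all`) are computed over their constituent wavelengths, not over
#' sub-band means.
#'
#' @param scan data.frame from [wavelength_scan()].
#' @param mapping Band name per scan row, from [assign_bands()].
#' @param bands Band table used for the mapping (for ordering/grouping).
#' @param absorbance Optional numeric vector of per-wavelength mean
#'   absorbance on the original (pre-standardization) scale, same length as
#'   the scan; fills the `mean_abs`/`sd_abs` columns.
#' @return data.frame with one row per elementary band plus aggregate rows,
#'   columns `band`, `n_wavelengths`, `mean_abs`, `sd_abs`, `pct_batch`,
#'   `pct_herd`, `pct_genetic`, `pct_residual`, `mean_h2`,
#'   `n_converged`.
#' @export
summarize_bands <- function(scan, mapping, bands, absorbance = NULL) {
  stopifnot(nrow(scan) == length(mapping))
  if (is.null(absorbance)) absorbance <- rep(NA_real_, nrow(scan))
  stopifnot(length(absorbance) == nrow(scan))

  one <- function(sel, name) {
    s <- scan[sel, , drop = FALSE]
    ok <- s$converged
    if (!any(ok)) {
      warning("band '", name, "' has no converged wavelengths")
      return(data.frame(band = name, n_wavelengths = sum(sel),
                        mean_abs = NA_real_, sd_abs = NA_real_,
                        pct_batch = NA_real_, pct_herd = NA_real_,
                        pct_genetic = NA_real_, pct_residual = NA_real_,
                        mean_h2 = NA_real_, n_converged = 0L,
                        stringsAsFactors = FALSE))
    }
    a <- absorbance[sel]
    data.frame(
      band = name,
      n_wavelengths = sum(sel),
      mean_abs = mean(a),
      sd_abs = stats::sd(a),
      pct_batch    = 100 * mean(s$p_batch[ok]),
      pct_herd     = 100 * mean(s$p_herd[ok]),
      pct_genetic  = 100 * mean(s$p_genetic[ok]),
      pct_residual = 100 * mean(s$p_residual[ok]),
      mean_h2 = mean(s$h2[ok]),
      n_converged = sum(ok),
      stringsAsFactors = FALSE
    )
  }

  bands <- bands[order(bands$lo_nm), , drop = FALSE]
  present <- bands$band %in% mapping  # bands absent from this grid are dropped
  rows <- lapply(bands$band[present], function(b) one(mapping == b, b))
  for (g in intersect(c("visible", "infrared"), unique(bands$group))) {
    members <- bands$band[bands$group == g & present]
    if (length(members) > 1L)
      rows <- c(rows, list(one(mapping %in% members, g)))
  }
  rows <- c(rows, list(one(rep(TRUE, nrow(scan)), "all")))
  do.call(rbind, rows)
}

#' Reference per-band variance architecture
#'
#' The package ships a reference variance architecture for beef absorbance
#' spectra: for each elementary band of each instrument, the share of
#' phenotypic variance attributed to slaughter batch, rearing herd, additive
#' genetics and residual (in percent), the implied intra-herd/batch
#' heritability, and the band's mean absorbance level. It is the default
#' truth profile of the spectra simulator, so simulated datasets reproduce a
#' realistic wavelength-dependent architecture: strong batch and genetic
#' signal in the ultraviolet/violet, the most heritable absorbances in the
#' blue-to-yellow colors, and low heritability with a dominant residual in
#' the infrared.
#'
#' @param instrument `"uvvisnir"` or `"micronir"`.
#' @return data.frame keyed by `band` with columns `pct_batch`, `pct_herd`,
#'   `pct_genetic`, `pct_residual`, `h2`, `mean_abs`, `sd_abs`.
#' @export
reference_band_profile <- function(instrument = c("uvvisnir", "micronir")) {
  instrument <- match.arg(instrument)
  if (instrument == "uvvisnir") {
    data.frame(
      band = c("ultraviolet", "violet", "blue", "cyan", "green", "yellow",
               "orange", "red", "IR-A", "IR-B"),
      pct_batch    = c(30, 30, 10,  9,  9, 10, 11, 14, 12, 18),
      pct_herd     = c( 5,  4,  9,  9,  8,  8,  6,  6,  7,  3),
      pct_genetic  = c(18, 14, 31, 33, 31, 29, 24, 10,  4,  4),
      pct_residual = c(47, 52, 50, 49, 52, 53, 59, 70, 77, 75),
      h2       = c(0.279, 0.206, 0.382, 0.401, 0.377, 0.357, 0.283, 0.130,
                   0.053, 0.046),
      mean_abs = c(1.223, 1.556, 1.104, 0.953, 1.145, 1.262, 0.769, 0.538,
                   0.847, 1.793),
      sd_abs   = c(0.021, 0.147, 0.108, 0.004, 0.131, 0.055, 0.132, 0.029,
                   0.292, 0.082),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      band = c("IR-A", "IR-B"),
      pct_batch    = c(13, 23),
      pct_herd     = c( 7,  1),
      pct_genetic  = c( 6,  8),
      pct_residual = c(74, 68),
      h2       = c(0.074, 0.102),
      mean_abs = c(0.962, 1.461),
      sd_abs   = c(0.215, 0.035),
      stringsAsFactors = FALSE
    )
  }
}
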