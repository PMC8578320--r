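#' Compile spectral reference statistics
#'
#' Outlier detection compares every well against reference distributions of
#' two spectral summaries: the absorbance at 310 nm, and the mean absorbance
#' over the 350-400 nm band (inclusive). The reference mean and standard
#' deviation of each summary are compiled across all wells of one or more
#' plates — ideally several independent experiments on the user's own
#' instrument. Standard deviations use the sample (n-1) convention.
#'
#' The package can generate fallback reference statistics from an ensemble
#' of simulated clean plates (see [reference_stats_default()]); these
#' characterize the simulator, not any real plate reader, and users should
#' recompile against their own data before trusting QC flags on real
#' measurements.
#'
#' @param plates a [spectra_plate()] or a list of them.
#' @return list of class `"reference_stats"` with `mean_310`, `sd_310`,
#'   `mean_350_400`, `sd_350_400`, `n_sources` (number of plates),
#'   `n_wells`.
#' @export
compile_reference_stats <- function(plates) {
  if (inherits(plates, "spectra_plate")) plates <- list(plates)
  if (length(plates) == 0L) stop("at least one plate is required")
  a310 <- unlist(lapply(plates, function(p) {
    p$absorbance[, wl_index(p$wavelengths, 310)]
  }))
  band <- unlist(lapply(plates, function(p) {
    rowMeans(p$absorbance[, wl_band(p$wavelengths, 350, 400), drop = FALSE])
  }))
  structure(list(
    mean_310 = mean(a310), sd_310 = stats::sd(a310),
    mean_350_400 = mean(band), sd_350_400 = stats::sd(band),
    n_sources = length(plates), n_wells = length(a310)),
    class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("reference_stats from %d plate(s), %d wells\n", x$n_sources, x$n_wells))
  cat(sprintf("  A310        : %.4f +/- %.4f AU\n", x$mean_310, x$sd_310))
  cat(sprintf("  A350-400 avg: %.4f +/- %.4f AU\n", x$mean_350_400, x$sd_350_400))
  invisible(x)
}

.pegsolve_env <- new.env(parent = emptyenv())

#' Default reference statistics from simulated clean plates
#'
#' Compiles [compile_reference_stats()] over an ensemble of eight simulated
#' artifact-free plates spanning the default design. Intended only as a
#' starting point for simulated data; recompile on real plates from your own
#' instrument for real QC.
#'
#' @param n_plates ensemble size.
#' @return a `"reference_stats"` object.
#' @export
reference_stats_default <- function(n_plates = 8L) {
  key <- paste0("refstats_", n_plates)
  if (!is.null(.pegsolve_env[[key]])) return(.pegsolve_env[[key]])
  plates <- lapply(seq_len(n_plates), function(i) {
    sim <- simulate_assay(truth = sim_truth(seed = 1000L + i, bubble_rate = 0))
    smooth_spectra(sim$plate)
  })
  ref <- compile_reference_stats(plates)
  .pegsolve_env[[key]] <- ref
  ref
}

#' Flag spectral outliers with the 4-sigma / 7-sigma rules
#'
#' A well is flagged as an outlier if its absorbance at 310 nm falls outside
#' the reference mean plus/minus `k310` standard deviations (default 4), or
#' if its mean absorbance over 350-400 nm falls outside the reference mean
#' plus/minus `k350400` standard deviations (default 7). Values exactly at a
#' threshold are inside the accepted range. Broad scattering from bubbles or
#' particulates inflates this spectral region, which is why these two
#' summaries discriminate failed wells.
#'
#' @param plate a (preferably smoothed) [spectra_plate()].
#' @param ref a `"reference_stats"` object.
#' @param k310,k350400 flagging thresholds in standard-deviation units.
#' @return data frame of class `"qc_flags"`: `well`, `flagged`, `reasons`
#'   (comma-separated subset of `a310_out_of_range`, `a350_400_out_of_range`),
#'   `z_310`, `z_350_400`.
#' @export
flag_outliers <- function(plate, ref = reference_stats_default(),
                          k310 = 4, k350400 = 7) {
  a310 <- plate$absorbance[, wl_index(plate$wavelengths, 310)]
  band <- rowMeans(plate$absorbance[, wl_band(plate$wavelengths, 350, 400),
                                    drop = FALSE])
  z310 <- z_or_zero(a310, ref$mean_310, ref$sd_310)
  z350 <- z_or_zero(band, ref$mean_350_400, ref$sd_350_400)
  use310 <- is.finite(ref$sd_310) && ref$sd_310 > 0
  use350 <- is.finite(ref$sd_350_400) && ref$sd_350_400 > 0
  if (!use310) warning("sd_310 is zero; the 310 nm criterion was skipped")
  if (!use350) warning("sd_350_400 is zero; the 350-400 nm criterion was skipped")
  hit310 <- use310 & abs(a310 - ref$mean_310) > k310 * ref$sd_310
  hit350 <- use350 & abs(band - ref$mean_350_400) > k350400 * ref$sd_350_400
  reasons <- mapply(function(h1, h2) {
    paste(c(if (h1) "a310_out_of_range", if (h2) "a350_400_out_of_range"),
          collapse = ",")
  }, hit310, hit350)
  out <- data.frame(well = wells_of(plate), flagged = hit310 | hit350,
                    reasons = reasons, z_310 = z310, z_350_400 = z350,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("qc_flags", "data.frame")
  out
}

z_or_zero <- function(x, m, s) {
  if (!is.finite(s) || s == 0) rep(NA_real_, length(x)) else (x - m) / s
}

#' Pipetting-accuracy check from a dye titration
#'
#' Validates liquid-handler accuracy in viscous PEG solutions: a free
#' fluorophore is added to the PEG stock and titrated like a normal run, so
#' fluorescence should increase linearly with the expected final PEG
#' concentration. A least-squares line `F = alpha + beta * peg` is fitted;
#' each well's realized PEG concentration is read back off the line as
#' `(F - alpha) / beta`, and its error is `|realized - expected|` in % w/v.
#'
#' @param expected_peg expected final PEG concentrations, % w/v.
#' @param fluorescence measured fluorescence, AU; same length, >= 3 points.
#' @return list of class `"dye_linearity"`: `alpha`, `beta`, `r_squared`,
#'   `realized_peg`, `errors` (per point, % w/v), `median_error`.
#' @export
dye_linearity_check <- function(expected_peg, fluorescence) {
  if (length(expected_peg) != length(fluorescence)) {
    stop("expected_peg and fluorescence must have equal length")
  }
  if (length(expected_peg) < 3L) stop("at least 3 points are required")
  if (length(unique(expected_peg)) < 2L) stop("expected_peg values are all equal")
  fit <- stats::lm(fluorescence ~ expected_peg)
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  if (!is.finite(beta) || abs(beta) < 1e-12 * max(abs(fluorescence), 1)) {
    stop("degenerate titration: fluorescence does not change with PEG")
  }
  realized <- (fluorescence - alpha) / beta
  errors <- abs(realized - expected_peg)
  structure(list(alpha = alpha, beta = beta,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 realized_peg = realized, errors = errors,
                 median_error = stats::median(errors)),
            class = "dye_linearity")
}

#' @export
print.dye_linearity <- function(x, ...) {
  cat(sprintf("dye titration linearity: F = %.4g + %.4g * PEG%%  (R^2 = %.5f)\n",
              x$alpha, x$beta, x$r_squared))
  cat(sprintf("  median |realized - expected| PEG error: %.4g %% w/v over %d wells\n",
              x$median_error, length(x$errors)))
  invisible(x)
}

#' Write QC flags to CSV
#' @param flags a `"qc_flags"` data frame.
#' @param path output path.
#' @export
write_qc_flags <- function(flags, path) {
  utils::write.csv(flags, path, row.names = FALSE)
  invisible(flags)
}
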