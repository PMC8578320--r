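#' Optical quantification settings
#'
#' Parameters for converting blanked absorbance spectra into soluble protein
#' concentrations. Concentration is computed from the blanked A280 further
#' corrected by subtracting the absorbance at `correction_wavelength`
#' (default 340 nm), which removes residual scattering that survives blank
#' subtraction:
#' `c = (A280 - A_corr) / (extinction_coeff * path_length) * dilution_factor`.
#'
#' @param extinction_coeff extinction coefficient at 280 nm, per (mg/mL) per
#'   cm; obtain it from the protein sequence.
#' @param path_length optical path in the measurement well, cm. Microplate
#'   paths depend on fill volume and well cross-section; supply your own or
#'   use [path_length_from_volume()].
#' @param dilution_factor supernatant-to-measurement-well dilution. With
#'   `t` uL of supernatant transferred into `p` uL of prefilled buffer this
#'   is `(p + t) / t`; the default assumes 6 uL into 10 uL prefill (16/6).
#' @param correction_wavelength scattering-correction wavelength, nm.
#' @return list of class `"quant_config"`.
#' @export
quant_config <- function(extinction_coeff = 1.0, path_length = 0.25,
                         dilution_factor = 16 / 6, correction_wavelength = 340) {
  stopifnot(extinction_coeff > 0, path_length > 0, dilution_factor > 0,
            correction_wavelength > 0)
  structure(list(extinction_coeff = extinction_coeff, path_length = path_length,
                 dilution_factor = dilution_factor,
                 correction_wavelength = correction_wavelength),
            class = "quant_config")
}

#' Path length from fill volume and well cross-section
#' @param volume_ul liquid volume in the well, uL.
#' @param well_area_mm2 well cross-sectional area, mm^2.
#' @return optical path, cm.
#' @export
path_length_from_volume <- function(volume_ul, well_area_mm2) {
  stopifnot(volume_ul > 0, well_area_mm2 > 0)
  (volume_ul / well_area_mm2) / 10  # uL/mm^2 = mm; /10 -> cm
}

#' Blank-subtract a spectrum
#'
#' Subtracts the pointwise mean of the blank spectra (PEG + buffer, no
#' protein, at the same PEG concentration as the sample) from a sample
#' spectrum.
#'
#' @param sample a `"spectrum_read"` (see [get_read()]).
#' @param blanks a `"spectrum_read"` or list of them on the same wavelength
#'   grid.
#' @return the blanked `"spectrum_read"`.
#' @export
subtract_blank <- function(sample, blanks) {
  if (inherits(blanks, "spectrum_read")) blanks <- list(blanks)
  if (length(blanks) == 0L) stop("at least one blank is required")
  for (b in blanks) {
    if (!identical(b$wavelengths, sample$wavelengths)) {
      stop("blank ", b$well, " is on a different wavelength grid")
    }
  }
  mean_blank <- Reduce(`+`, lapply(blanks, `[[`, "absorbance")) / length(blanks)
  out <- sample
  out$absorbance <- sample$absorbance - mean_blank
  out
}

#' Soluble protein concentration from a blanked spectrum
#'
#' `c = (A280 - A_corr) / (extinction_coeff * path_length) * dilution_factor`,
#' reported in the units of the original (undiluted) supernatant. A negative
#' corrected absorbance is clamped to a concentration of 0 (precipitation
#' cannot exceed the total protein); the returned value then carries
#' `attr(, "clamped") = TRUE`.
#'
#' @param blanked a blanked `"spectrum_read"` whose grid contains 280 nm and
#'   the correction wavelength.
#' @param q a [quant_config()].
#' @return concentration, mg/mL.
#' @export
concentration_from_absorbance <- function(blanked, q = quant_config()) {
  a280 <- blanked$absorbance[wl_index(blanked$wavelengths, 280)]
  acorr <- blanked$absorbance[wl_index(blanked$wavelengths, q$correction_wavelength)]
  conc <- (a280 - acorr) / (q$extinction_coeff * q$path_length) * q$dilution_factor
  clamped <- conc < 0
  if (clamped) {
    warning("negative corrected absorbance in well ", blanked$well,
            "; concentration clamped to 0")
    conc <- 0
  }
  attr(conc, "clamped") <- clamped
  conc
}

#' Turbidity of a sample
#'
#' Turbidity is defined as the blanked absorbance at 500 nm: scattering by
#' precipitated protein, measured without removing the precipitate.
#'
#' @inheritParams subtract_blank
#' @return blanked A500, AU.
#' @export
turbidity <- function(sample, blanks) {
  blanked <- subtract_blank(sample, blanks)
  blanked$absorbance[wl_index(blanked$wavelengths, 500)]
}

blank_wells_for <- function(plate, peg, blank_mode) {
  lay <- plate$layout
  if (blank_mode == "matched") {
    lay$well[lay$role == "blank" & lay$peg_pct == peg]
  } else {
    lay$well[lay$role == "blank"]
  }
}

#' Build the solubility curve from an annotated plate
#'
#' For every PEG concentration, blank-subtracts each unflagged sample well,
#' converts it to a soluble concentration (or, with
#' `readout = "turbidity"`, takes the blanked A500) and summarizes the wells
#' as mean and sample SD. Measurement wells derived from the same source
#' well are technical replicates and are simply pooled. Concentrations whose
#' wells are all flagged are dropped with a warning; fewer than 4 surviving
#' concentrations is an error because the sigmoid fit would be
#' under-determined.
#'
#' @param plate an [annotate_layout()]-ed plate (smooth it first with
#'   [smooth_spectra()] if desired).
#' @param flags optional [flag_outliers()] output; wells with
#'   `flagged = TRUE` are excluded and counted in `n_excluded`.
#' @param q a [quant_config()]; ignored for the turbidity readout.
#' @param blank_mode `"matched"` uses blanks at the same PEG concentration
#'   (error if missing); `"shared"` pools all blank wells regardless of PEG,
#'   usable because PEG barely absorbs at 280 nm.
#' @param readout `"concentration"` (blanked A280 corrected at A340) or
#'   `"turbidity"` (blanked A500).
#' @return data frame of class `"solubility_curve"` with columns `peg_pct`,
#'   `conc_mean`, `conc_sd`, `n_wells`, `n_excluded`; per-well replicate
#'   values are kept in `attr(, "replicates")` for bootstrap resampling.
#' @export
build_curve <- function(plate, flags = NULL, q = quant_config(),
                        blank_mode = c("matched", "shared"),
                        readout = c("concentration", "turbidity")) {
  blank_mode <- match.arg(blank_mode)
  readout <- match.arg(readout)
  if (is.null(plate$layout)) stop("plate has no layout; call annotate_layout() first")
  lay <- plate$layout
  flagged <- if (is.null(flags)) {
    stats::setNames(rep(FALSE, nrow(lay)), lay$well)
  } else {
    stats::setNames(flags$flagged, flags$well)
  }

  pegs <- sort(unique(lay$peg_pct[lay$role == "sample"]))
  pts <- list()
  reps <- list()
  dropped <- character(0)
  for (peg in pegs) {
    swells <- lay$well[lay$role == "sample" & lay$peg_pct == peg]
    bwells <- blank_wells_for(plate, peg, blank_mode)
    if (length(bwells) == 0L) {
      stop("no blank well available for PEG ", peg, "% w/v")
    }
    keep <- swells[!flagged[swells]]
    n_excl <- length(swells) - length(keep)
    if (length(keep) == 0L) {
      dropped <- c(dropped, format(peg))
      next
    }
    blanks <- lapply(bwells, get_read, plate = plate)
    vals <- vapply(keep, function(w) {
      blanked <- subtract_blank(get_read(plate, w), blanks)
      if (readout == "concentration") {
        as.numeric(suppressWarnings(concentration_from_absorbance(blanked, q)))
      } else {
        blanked$absorbance[wl_index(blanked$wavelengths, 500)]
      }
    }, numeric(1))
    pts[[length(pts) + 1L]] <- data.frame(
      peg_pct = peg, conc_mean = mean(vals),
      conc_sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
      n_wells = length(vals), n_excluded = n_excl)
    reps[[length(reps) + 1L]] <- unname(vals)
  }
  if (length(dropped)) {
    warning("all wells flagged at PEG ", paste(dropped, collapse = ", "),
            "% w/v; point(s) dropped")
  }
  if (length(pts) < 4L) {
    stop("fewer than 4 PEG concentrations survive QC; sigmoid fit infeasible")
  }
  curve <- do.call(rbind, pts)
  rownames(curve) <- NULL
  solubility_curve(curve, replicates = reps,
                   protein_id = lay$protein_id[1] %||% "protein",
                   readout = readout)
}

#' Construct a solubility curve object
#'
#' @param points data frame with at least `peg_pct` and `conc_mean`
#'   (strictly increasing `peg_pct`); optional `conc_sd`, `n_wells`,
#'   `n_excluded`.
#' @param replicates optional list (one vector per point) of per-well
#'   values, used for case-resampling bootstrap.
#' @param protein_id,readout metadata carried through to fits and outputs.
#' @return data frame of class `"solubility_curve"`.
#' @export
solubility_curve <- function(points, replicates = NULL,
                             protein_id = "protein", readout = "concentration") {
  stopifnot(is.data.frame(points), all(c("peg_pct", "conc_mean") %in% names(points)))
  if (is.unsorted(points$peg_pct, strictly = TRUE)) {
    stop("peg_pct must be strictly increasing")
  }
  if (is.null(points$conc_sd)) points$conc_sd <- NA_real_
  if (is.null(points$n_wells)) {
    points$n_wells <- if (is.null(replicates)) 1L else lengths(replicates)
  }
  if (is.null(points$n_excluded)) points$n_excluded <- 0L
  if (!is.null(replicates) && length(replicates) != nrow(points)) {
    stop("need one replicate vector per curve point")
  }
  structure(points, replicates = replicates, protein_id = protein_id,
            readout = readout, class = c("solubility_curve", "data.frame"))
}

#' Write a solubility curve to CSV
#' @param curve a `"solubility_curve"`.
#' @param path output path.
#' @param header optional `#` comment line content.
#' @export
write_curve <- function(curve, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(curve)
}
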