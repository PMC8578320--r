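#' Ground truth for a simulated assay
#'
#' Parameters of the synthetic data generator. The defaults describe a
#' typical screening-scale run: a protein at 1 mg/mL that half-precipitates
#' at 15% w/v PEG with unit slope, 3% multiplicative well-to-well
#' concentration noise (pipetting and evaporation variability), and 2 mAU
#' additive spectral noise typical of a benchtop plate reader.
#'
#' Spectral shapes are modeling choices: the protein contributes a
#' Gaussian-like band peaking at 280 nm scaled to `extinction x path x
#' concentration`; dissolved PEG adds a Rayleigh-like baseline decaying as
#' `lambda^-4`; residual particulates (incompletely pelleted precipitate)
#' scatter with a much gentler wavelength dependence, which is what the
#' 340 nm correction and the A500 turbidity readout respond to; bubbles add
#' a broad Gaussian scattering bump centered near 340 nm.
#'
#' @param peg_half true PEG1/2, % w/v.
#' @param s true slope, per % w/v.
#' @param c0 soluble concentration at 0% PEG, mg/mL.
#' @param conc_cv multiplicative SD of per-well concentration noise.
#' @param noise_sd additive spectral noise SD, AU.
#' @param bubble_rate probability that a sample well contains a bubble.
#' @param bubble_amp bubble scattering amplitude, AU.
#' @param evaporation_frac fraction of well volume lost to evaporation
#'   during incubation (concentrates the supernatant by `1/(1 - frac)`).
#' @param band_sigma width of the 280 nm protein band, nm.
#' @param peg_coef PEG baseline scattering, AU per % w/v at 500 nm.
#' @param turb_coef particulate scattering, AU at 500 nm per mg/mL of
#'   precipitated protein in the measurement well.
#' @param seed integer seed; a fixed seed gives byte-identical plates.
#' @return list of class `"sim_truth"`.
#' @export
sim_truth <- function(peg_half = 15, s = 1, c0 = 1.0, conc_cv = 0.03,
                      noise_sd = 0.002, bubble_rate = 0, bubble_amp = 0.5,
                      evaporation_frac = 0, band_sigma = 15,
                      peg_coef = 5e-4, turb_coef = 0.05, seed = 1L) {
  stopifnot(c0 > 0, conc_cv >= 0, noise_sd >= 0,
            bubble_rate >= 0, bubble_rate <= 1,
            evaporation_frac >= 0, evaporation_frac < 1)
  structure(list(peg_half = peg_half, s = s, c0 = c0, conc_cv = conc_cv,
                 noise_sd = noise_sd, bubble_rate = bubble_rate,
                 bubble_amp = bubble_amp, evaporation_frac = evaporation_frac,
                 band_sigma = band_sigma, peg_coef = peg_coef,
                 turb_coef = turb_coef, seed = as.integer(seed)),
            class = "sim_truth")
}

# True soluble supernatant concentration at PEG x (after evaporation).
true_conc <- function(truth, x) {
  truth$c0 / (1 - truth$evaporation_frac) / (1 + exp(truth$s * (x - truth$peg_half)))
}

#' Simulate a full measurement plate with known ground truth
#'
#' Plans the assay from `design`, maps it through the supernatant transfer
#' (so each source well yields `n_transfers` technical-replicate measurement
#' wells), and generates one absorbance spectrum (220-700 nm, 1 nm grid) per
#' measurement well: protein band + PEG scattering baseline + particulate
#' scattering proportional to the precipitated amount + i.i.d. noise, with
#' optional bubbles in sample wells and evaporation. Blank wells contain
#' only the baseline and noise.
#'
#' @param design a [design_config()].
#' @param truth a [sim_truth()].
#' @param quant the [quant_config()] describing the measurement optics; the
#'   same config inverts the spectra back to concentrations exactly in the
#'   noiseless limit.
#' @param v_per_transfer,n_transfers,prefill_volume see
#'   [plan_supernatant_transfer()].
#' @return list: `plate` (a [spectra_plate()]), `layout` (measurement-plate
#'   layout), `truth` (the input truth plus `bubble_wells`), `plan`,
#'   `transfer`.
#' @examples
#' sim <- simulate_assay(truth = sim_truth(seed = 42))
#' sim$plate
#' @export
simulate_assay <- function(design = design_config(), truth = sim_truth(),
                           quant = quant_config(), v_per_transfer = 3,
                           n_transfers = 2L, prefill_volume = 10) {
  plan <- plan_assay(design)
  tp <- plan_supernatant_transfer(plan, v_per_transfer = v_per_transfer,
                                  n_transfers = n_transfers,
                                  prefill_volume = prefill_volume)
  layout <- as_layout(tp)
  wl <- 220:700
  set.seed(truth$seed)

  # protein band truncated at 3 sigma: aromatic absorbance is gone well
  # before 340 nm, so the scattering correction there never clips protein
  band <- exp(-(wl - 280)^2 / (2 * truth$band_sigma^2)) *
    (abs(wl - 280) <= 3 * truth$band_sigma)
  peg_base <- (500 / wl)^4
  turb_shape <- 400 / wl          # large particles: weak wavelength dependence
  bubble_shape <- exp(-(wl - 340)^2 / (2 * 60^2))
  c0_evap <- truth$c0 / (1 - truth$evaporation_frac)

  n <- nrow(layout)
  A <- matrix(0, n, length(wl))
  bubble_wells <- character(0)
  for (i in seq_len(n)) {
    x <- layout$peg_pct[i]
    spec <- truth$peg_coef * x * peg_base
    if (layout$role[i] == "sample") {
      c_sup <- true_conc(truth, x) * max(0, 1 + stats::rnorm(1, 0, truth$conc_cv))
      c_meas <- c_sup / quant$dilution_factor
      p_meas <- max(c0_evap - c_sup, 0) / quant$dilution_factor
      spec <- spec +
        quant$extinction_coeff * quant$path_length * c_meas * band +
        truth$turb_coef * p_meas * turb_shape
      if (truth$bubble_rate > 0 && stats::runif(1) < truth$bubble_rate) {
        spec <- spec + truth$bubble_amp * bubble_shape
        bubble_wells <- c(bubble_wells, layout$well[i])
      }
    }
    A[i, ] <- spec + stats::rnorm(length(wl), 0, truth$noise_sd)
  }
  plate <- spectra_plate(wl, A, layout$well,
                         metadata = list(simulated = TRUE, seed = truth$seed))
  truth$bubble_wells <- bubble_wells
  list(plate = plate, layout = layout, truth = truth, plan = plan,
       transfer = tp)
}

#' Simulate a solubility curve directly (no spectra)
#'
#' Lightweight generator for fit-level studies: per PEG concentration it
#' draws `n_wells` replicate soluble concentrations around the true sigmoid
#' with multiplicative noise `truth$conc_cv`, skipping the optics entirely.
#'
#' @param peg PEG concentrations, % w/v, strictly increasing.
#' @param truth a [sim_truth()].
#' @param n_wells replicate wells per concentration.
#' @return a `"solubility_curve"` with per-point replicates.
#' @export
simulate_solubility_curve <- function(peg, truth = sim_truth(), n_wells = 4L) {
  set.seed(truth$seed)
  reps <- lapply(peg, function(x) {
    true_conc(truth, x) * pmax(0, 1 + stats::rnorm(n_wells, 0, truth$conc_cv))
  })
  pts <- data.frame(
    peg_pct = peg,
    conc_mean = vapply(reps, mean, numeric(1)),
    conc_sd = vapply(reps, stats::sd, numeric(1)),
    n_wells = n_wells, n_excluded = 0L)
  solubility_curve(pts, replicates = reps)
}

#' Simulate a dye-titration accuracy run
#'
#' Emulates the pipetting-accuracy control: the PEG stock carries a free
#' fluorophore, so fluorescence is strictly proportional to the realized PEG
#' concentration in each well. Gaussian volume noise (truncated at 0) is
#' added to every planned transfer; the realized PEG concentration follows
#' from the realized volumes.
#'
#' @param design a [design_config()].
#' @param volume_error_sd per-transfer volume noise SD, uL.
#' @param seed integer seed.
#' @param fluor_per_pct fluorescence yield, AU per % w/v PEG.
#' @return data frame `well,expected_peg_pct,fluorescence` (the dye-table
#'   CSV shape used by [dye_linearity_check()]).
#' @export
simulate_dye_titration <- function(design = design_config(),
                                   volume_error_sd = 0, seed = 1L,
                                   fluor_per_pct = 100) {
  plan <- plan_assay(design)
  set.seed(seed)
  jitter_vol <- function(v) {
    ifelse(v > 0, pmax(v + stats::rnorm(length(v), 0, volume_error_sd), 0), 0)
  }
  v_peg <- jitter_vol(plan$v_peg)
  v_buf <- jitter_vol(plan$v_buffer)
  v_pro <- jitter_vol(plan$v_protein)   # buffer stands in for protein here
  total <- v_peg + v_buf + v_pro
  stock <- ifelse(is.na(plan$peg_stock), 0, plan$peg_stock)
  realized <- ifelse(total > 0, v_peg * stock / total, 0)
  data.frame(well = plan$well, expected_peg_pct = plan$peg_pct,
             fluorescence = fluor_per_pct * realized,
             stringsAsFactors = FALSE)
}

#' Write / read the simulation-truth JSON sidecar
#' @param truth a `"sim_truth"` (possibly with `bubble_wells`).
#' @param path JSON path (conventionally `<plate>.truth.json`).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bw <- obj$bubble_wells
  obj$bubble_wells <- NULL
  truth <- do.call(sim_truth, obj)
  truth$bubble_wells <- bw
  truth
}
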