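# Blank subtraction, A280/A340 concentration, turbidity, curve assembly.

test_that("blank subtraction averages blanks pointwise", {
  wl <- c(280, 340, 500)
  s <- structure(list(well = "A1", wavelengths = wl,
                      absorbance = c(0.6, 0.1, 0.05)), class = "spectrum_read")
  b1 <- structure(list(well = "B1", wavelengths = wl,
                       absorbance = c(0.1, 0.02, 0.01)), class = "spectrum_read")
  b2 <- structure(list(well = "B2", wavelengths = wl,
                       absorbance = c(0.3, 0.02, 0.01)), class = "spectrum_read")
  out <- subtract_blank(s, list(b1, b2))
  expect_equal(out$absorbance[1], 0.6 - 0.2)  # mean blank 0.2 at 280

  # sample == blank -> all-zero spectrum
  zero <- subtract_blank(s, s)
  expect_equal(zero$absorbance, c(0, 0, 0))

  # grid mismatch is an error
  b3 <- structure(list(well = "B3", wavelengths = c(280, 350, 500),
                       absorbance = c(0, 0, 0)), class = "spectrum_read")
  expect_error(subtract_blank(s, b3), "grid")
})

test_that("concentration formula: (A280 - Acorr) / (eps * l) * dilution", {
  wl <- c(280, 340, 500)
  mk <- function(a280, a340) {
    structure(list(well = "A1", wavelengths = wl,
                   absorbance = c(a280, a340, 0)), class = "spectrum_read")
  }
  q <- quant_config(extinction_coeff = 1, path_length = 0.4, dilution_factor = 1)
  expect_equal(concentration_from_absorbance(mk(0.5, 0.1), q), 1.0,
               ignore_attr = TRUE)
  # full scattering correction: A280 == A340 -> 0
  expect_equal(concentration_from_absorbance(mk(0.1, 0.1), q), 0,
               ignore_attr = TRUE)
  # negative corrected absorbance clamps to 0 with a warning
  expect_warning(c0 <- concentration_from_absorbance(mk(0.05, 0.1), q), "clamped")
  expect_equal(as.numeric(c0), 0)
  expect_true(attr(c0, "clamped"))
})

test_that("concentration is linear in corrected absorbance, inverse in optics", {
  set.seed(7)
  wl <- c(280, 340, 500)
  for (i in 1:20) {
    a340 <- runif(1, 0, 0.2)
    a280 <- a340 + runif(1, 0, 1)
    eps <- runif(1, 0.3, 3); l <- runif(1, 0.1, 1); d <- runif(1, 1, 5)
    r <- structure(list(well = "A1", wavelengths = wl,
                        absorbance = c(a280, a340, 0)), class = "spectrum_read")
    got <- concentration_from_absorbance(
      r, quant_config(extinction_coeff = eps, path_length = l, dilution_factor = d))
    expect_equal(as.numeric(got), (a280 - a340) / (eps * l) * d, tolerance = 1e-12)
  }
})

test_that("simulator optics invert: known concentration recovered exactly", {
  # noiseless simulation, no particulate scattering so the spectrum is pure
  # protein band + PEG baseline: quantification must return the true
  # supernatant concentration at the wells before the transition
  truth <- sim_truth(peg_half = 100, s = 1, c0 = 1.0, conc_cv = 0,
                     noise_sd = 0, turb_coef = 0, seed = 9)
  sim <- simulate_assay(truth = truth)
  pl <- annotate_layout(sim$plate, sim$layout)
  lay <- pl$layout
  w <- lay$well[lay$role == "sample"][1]
  peg <- lay$peg_pct[lay$well == w]
  blanks <- lapply(lay$well[lay$role == "blank" & lay$peg_pct == peg],
                   get_read, plate = pl)
  blanked <- subtract_blank(get_read(pl, w), blanks)
  conc <- concentration_from_absorbance(blanked, quant_config())
  true_c <- 1.0 / (1 + exp(1 * (peg - 100)))
  expect_equal(as.numeric(conc), true_c, tolerance = 1e-9)
})

test_that("turbidity is the blanked A500 and orders precipitating above clear wells", {
  wl <- c(280, 340, 500)
  s <- structure(list(well = "A1", wavelengths = wl,
                      absorbance = c(0.5, 0.3, 0.27)), class = "spectrum_read")
  b <- structure(list(well = "B1", wavelengths = wl,
                      absorbance = c(0.0, 0.0, 0.02)), class = "spectrum_read")
  expect_equal(turbidity(s, b), 0.25)
  expect_equal(turbidity(b, b), 0)

  truth <- sim_truth(peg_half = 14, s = 1.2, conc_cv = 0, noise_sd = 0, seed = 2)
  sim <- simulate_assay(truth = truth)
  pl <- annotate_layout(sim$plate, sim$layout)
  curve <- build_curve(pl, readout = "turbidity")
  # precipitating (high PEG) wells scatter more at 500 nm than clear wells
  expect_gt(curve$conc_mean[nrow(curve)], curve$conc_mean[1])
})

test_that("build_curve pools technical replicates and books exclusions", {
  fix <- sim_annotated(sim_truth(peg_half = 14, s = 1.2, seed = 13))
  fl <- flag_outliers(fix$plate, ref_stats())
  curve <- build_curve(fix$plate, fl)
  expect_equal(nrow(curve), 12)
  expect_equal(curve$n_wells, rep(4L, 12))  # 2 replicates x 2 transfers
  expect_equal(curve$n_excluded, rep(0L, 12))
  expect_true(all(diff(curve$peg_pct) > 0))

  # flag one well manually: its point loses a well and gains an exclusion
  lay <- fix$plate$layout
  victim <- lay$well[lay$role == "sample"][1]
  fl2 <- fl; fl2$flagged[fl2$well == victim] <- TRUE
  curve2 <- build_curve(fix$plate, fl2)
  expect_equal(curve2$n_wells[1], 3L)
  expect_equal(curve2$n_excluded[1], 1L)
  # means over unflagged wells are unaffected by the flagged well's value
  expect_equal(curve2$conc_mean[-1], curve$conc_mean[-1])

  # all wells flagged at a concentration -> dropped with warning; fewer than
  # 4 surviving concentrations -> error
  fl3 <- fl
  drop_pegs <- sort(unique(lay$peg_pct))[1:9]
  fl3$flagged[fl3$well %in% lay$well[lay$role == "sample" &
                                       lay$peg_pct %in% drop_pegs]] <- TRUE
  expect_error(suppressWarnings(build_curve(fix$plate, fl3)), "fewer than 4")
})

test_that("shared-blank mode works and missing matched blanks are an error", {
  # without PEG-dependent baseline scattering, a shared blank is exactly
  # equivalent to matched blanks
  flat <- sim_truth(peg_half = 14, s = 1.2, conc_cv = 0, noise_sd = 0,
                    peg_coef = 0, seed = 6)
  fix0 <- sim_annotated(flat)
  expect_equal(build_curve(fix0$plate, blank_mode = "shared")$conc_mean,
               build_curve(fix0$plate)$conc_mean, tolerance = 1e-9)

  # with the default PEG baseline the shared blank mis-cancels the
  # wavelength-dependent scattering, so the two modes disagree: matched
  # blanks are the default for a reason
  fix <- sim_annotated(sim_truth(peg_half = 14, s = 1.2, conc_cv = 0,
                                 noise_sd = 0, seed = 6))
  c_matched <- build_curve(fix$plate)
  c_shared <- suppressWarnings(build_curve(fix$plate, blank_mode = "shared"))
  expect_equal(nrow(c_shared), nrow(c_matched))
  expect_gt(max(abs(c_shared$conc_mean - c_matched$conc_mean)), 1e-4)

  # remove the blanks at one PEG concentration: matched mode must error
  pl <- fix$plate
  lay <- pl$layout
  peg0 <- lay$peg_pct[lay$role == "blank"][1]
  keep <- !(lay$role == "blank" & lay$peg_pct == peg0)
  pl2 <- spectra_plate(pl$wavelengths, pl$absorbance[lay$well[keep], ],
                       lay$well[keep])
  pl2 <- annotate_layout(pl2, lay[keep, ])
  expect_error(build_curve(pl2), "blank")
})

test_that("curve means are permutation-invariant over wells", {
  fix <- sim_annotated(sim_truth(peg_half = 14, s = 1.2, seed = 17))
  pl <- fix$plate
  lay <- pl$layout
  set.seed(1)
  perm <- sample(nrow(lay))
  pl2 <- spectra_plate(pl$wavelengths, pl$absorbance[perm, ],
                       rownames(pl$absorbance)[perm])
  pl2 <- annotate_layout(pl2, lay[perm, ])
  c1 <- build_curve(pl)
  c2 <- build_curve(pl2)
  expect_equal(c2$conc_mean, c1$conc_mean, tolerance = 1e-12)
})
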