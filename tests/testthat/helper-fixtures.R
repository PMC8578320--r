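# Shared fixtures, built in code.

# A tiny 2-well plate on a 3-point grid, for parser round-trips.
tiny_plate <- function() {
  spectra_plate(c(280, 340, 500),
                rbind(c(0.5, 0.1, 0.02), c(0.45, 0.12, 0.03)),
                wells = c("A1", "A2"))
}

# Full-grid clean simulated assay (annotated, smoothed) with known truth.
sim_annotated <- function(truth = sim_truth(peg_half = 14, s = 1.2, seed = 3),
                          smooth = TRUE) {
  sim <- simulate_assay(truth = truth)
  pl <- if (smooth) smooth_spectra(sim$plate) else sim$plate
  list(plate = annotate_layout(pl, sim$layout), sim = sim)
}

# QC reference stats are expensive to recompile; share the package cache.
ref_stats <- function() reference_stats_default()

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
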