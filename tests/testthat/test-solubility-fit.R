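# Sigmoid fitting, normalization, bootstrap, onset, log-extrapolation.

# Independent oracle for the sigmoid least-squares problem: exhaustive grid
# over (s, peg_half) with plateaus solved in closed form, refined once. Slow
# but free of the package's optimizer path.
oracle_sigmoid_rss <- function(x, y, s_range = c(0.05, 8), ph_range = range(x)) {
  eval_rss <- function(s, ph) {
    z <- 1 / (1 + exp(s * (x - ph)))
    X <- cbind(1, z)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  best <- c(NA, NA, Inf)
  for (pass in 1:3) {
    s_grid <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = 40))
    ph_grid <- seq(ph_range[1], ph_range[2], length.out = 60)
    for (s in s_grid) for (ph in ph_grid) {
      r <- eval_rss(s, ph)
      if (r < best[3]) best <- c(s, ph, r)
    }
    s_range <- best[1] * c(0.7, 1.4)
    ph_range <- best[2] + c(-1, 1) * diff(ph_range) / 15
  }
  list(s = best[1], peg_half = best[2], rss = best[3])
}

test_that("noiseless sigmoid parameters are recovered to 1e-6", {
  x <- seq(0, 24, by = 2)
  y <- sigmoid(x, a = 1, b = 0, s = 1.5, peg_half = 12)
  fit <- fit_sigmoid(x, y)
  expect_true(fit$converged)
  expect_close(fit$a, 1, 1e-6)
  expect_close(fit$b, 0, 1e-6)
  expect_close(fit$s, 1.5, 1e-6)
  expect_close(fit$peg_half, 12, 1e-6)

  # model structure: midpoint value, plateau limits, monotone for s > 0
  expect_equal(sigmoid(12, 1, 0, 1.5, 12), 0.5)
  expect_equal(sigmoid(-1e6, 1, 0, 1.5, 12), 1)
  expect_equal(sigmoid(1e6, 1, 0, 1.5, 12), 0)
  grid <- sigmoid(seq(0, 30, length.out = 500), fit$a, fit$b, fit$s, fit$peg_half)
  expect_true(all(diff(grid) < 0))
})

test_that("fit agrees with an independent grid-search oracle on noisy data", {
  set.seed(11)
  x <- seq(0, 30, by = 3)
  y <- sigmoid(x, 1.1, 0.05, 0.9, 13) + rnorm(length(x), 0, 0.02)
  fit <- fit_sigmoid(x, y)
  orc <- oracle_sigmoid_rss(x, y)
  expect_lte(fit$rss, orc$rss + 1e-8)       # optimizer at least as good
  expect_close(fit$peg_half, orc$peg_half, 0.1)
  expect_close(fit$s, orc$s, 0.1)
})

test_that("increasing (turbidity-like) curves fit under the same parameterization", {
  x <- seq(0, 30, by = 3)
  y <- sigmoid(x, a = 0.01, b = 0.4, s = 1.2, peg_half = 15)  # a < b: rising
  fit <- fit_sigmoid(x, y)
  expect_true(fit$converged)
  expect_close(fit$peg_half, 15, 1e-5)
  expect_close(fit$s, 1.2, 1e-5)
  expect_lt(fit$a, fit$b)
})

test_that("degenerate inputs are rejected", {
  x <- seq(0, 24, by = 2)
  expect_error(fit_sigmoid(x, rep(0.5, length(x))), "no transition")
  expect_error(fit_sigmoid(x[1:3], c(1, 0.5, 0)), "4")
  # flat within the noise floor given point SDs
  y <- 0.5 + c(0.001, -0.001, rep(0, length(x) - 2))
  expect_error(fit_sigmoid(x, y, sd = rep(0.05, length(x))), "no transition")
})

test_that("plateau normalization maps a->1, b->0 and leaves peg_half invariant", {
  x <- seq(0, 24, by = 2)
  y <- sigmoid(x, 0.8, 0.1, 1.5, 12)
  curve <- solubility_curve(data.frame(peg_pct = x, conc_mean = y,
                                       conc_sd = rep(0.1, length(x))))
  fit <- fit_sigmoid(curve)
  ncv <- normalize_curve(curve, fit)
  # the transform itself: y' = (y - b)/(a - b), so y = a -> 1 and y = b -> 0
  expect_equal(ncv$conc_mean, (y - fit$b) / (fit$a - fit$b), tolerance = 1e-12)
  expect_equal(max(ncv$conc_mean), 1, tolerance = 1e-6)
  expect_equal(min(ncv$conc_mean), 0, tolerance = 1e-6)
  # SD scaling: sd / (a - b)
  expect_equal(ncv$conc_sd, rep(0.1 / 0.7, length(x)), tolerance = 1e-6)
  refit <- fit_sigmoid(ncv, fix_plateaus = TRUE,
                       start = list(s = fit$s, peg_half = fit$peg_half))
  expect_close(refit$peg_half, fit$peg_half, 1e-6)

  fit_eq <- fit; fit_eq$b <- fit_eq$a
  expect_error(normalize_curve(curve, fit_eq), "plateaus")
})

test_that("peg_half is invariant under affine rescaling of the response", {
  set.seed(3)
  x <- seq(0, 30, by = 3)
  y <- sigmoid(x, 1, 0, 1.2, 14) + rnorm(length(x), 0, 0.01)
  f1 <- fit_sigmoid(x, y)
  f2 <- fit_sigmoid(x, 3.7 * y + 0.9)   # change of units/offset
  expect_close(f2$peg_half, f1$peg_half, 1e-6)
  expect_close(f2$s, f1$s, 1e-6)
})

test_that("onset formula matches a numerical tangent construction to 1e-8", {
  fit <- fit_sigmoid(seq(0, 24, 2), sigmoid(seq(0, 24, 2), 1, 0, 1.5, 12))
  onset <- estimate_onset(fit)
  expect_close(onset, 12 - 2 / 1.5, 1e-8)

  # numerical tangent: slope at the inflection by central differences,
  # intersect with the upper plateau a
  h <- 1e-6
  slope <- (sigmoid(12 + h, fit$a, fit$b, fit$s, fit$peg_half) -
            sigmoid(12 - h, fit$a, fit$b, fit$s, fit$peg_half)) / (2 * h)
  y_mid <- sigmoid(12, fit$a, fit$b, fit$s, fit$peg_half)
  onset_num <- 12 + (fit$a - y_mid) / slope
  expect_close(onset, onset_num, 1e-8)

  # scaling: doubling s halves (peg_half - onset); s -> Inf collapses to peg_half
  f2 <- fit; f2$s <- 2 * fit$s
  expect_close(f2$peg_half - estimate_onset(f2),
               (fit$peg_half - onset) / 2, 1e-12)
  f3 <- fit; f3$s <- 1e9
  expect_close(estimate_onset(f3), fit$peg_half, 1e-6)
  f4 <- fit; f4$s <- -1
  expect_error(estimate_onset(f4), "positive")
})

test_that("log-extrapolation recovers an exact exponential decay", {
  # points on ln(c) = ln(5) - 0.3 x, shaped into a pseudo-sigmoid context:
  # build a curve whose transition region contains exact exponential points.
  # a shallow slope keeps >= 3 grid points inside the 20-80% window (the
  # window half-width is ln(4)/s around peg_half)
  x <- seq(0, 30, by = 2)
  y <- sigmoid(x, 1, 0, 0.4, 15)
  curve <- solubility_curve(data.frame(peg_pct = x, conc_mean = y))
  fit <- fit_sigmoid(curve)
  level <- (fit$fitted - fit$b) / (fit$a - fit$b)
  trans <- level > 0.2 & level < 0.8
  expect_gte(sum(trans), 3)
  # replace transition values by the exact exponential line
  y2 <- y
  y2[trans] <- 5 * exp(-0.3 * x[trans])
  curve2 <- solubility_curve(data.frame(peg_pct = x, conc_mean = y2))
  # reuse the same fit so the same points are 'transition'
  der <- extrapolate_apparent_solubility(curve2, fit)
  expect_close(der$apparent_solubility, 5, 1e-9)
  expect_close(der$log_slope, -0.3, 1e-12)

  # zero/negative points inside the region are excluded from the log fit
  y3 <- y2; y3[which(trans)[1]] <- 0
  curve3 <- solubility_curve(data.frame(peg_pct = x, conc_mean = y3))
  der3 <- extrapolate_apparent_solubility(curve3, fit)
  expect_equal(der3$extrapolation_points, sum(trans) - 1)

  # fewer than 3 usable points is an error
  y4 <- y; y4[trans] <- 0
  expect_error(extrapolate_apparent_solubility(
    solubility_curve(data.frame(peg_pct = x, conc_mean = y4)), fit), "3")
})

test_that("the apparent-solubility extrapolation is highly noise-sensitive", {
  th <- sim_truth(peg_half = 14, s = 0.4, conc_cv = 0, seed = 1)
  cv <- simulate_solubility_curve(seq(0, 30, by = 2), th)
  fit <- fit_sigmoid(cv)
  base <- extrapolate_apparent_solubility(cv, fit)$apparent_solubility
  # +/-10% on one transition point moves the estimate by far more than 10%
  level <- (fit$fitted - fit$b) / (fit$a - fit$b)
  i <- which(level > 0.2 & level < 0.8)[1]
  cv2 <- as.data.frame(cv); cv2$conc_mean[i] <- cv2$conc_mean[i] * 1.1
  pert <- extrapolate_apparent_solubility(
    solubility_curve(cv2), fit)$apparent_solubility
  rel_change <- abs(pert - base) / base
  expect_gt(rel_change, 0.10)   # amplified, not damped
})

test_that("bootstrap is seeded, degenerate at zero noise, and brackets the estimate", {
  th <- sim_truth(peg_half = 12, s = 1.5, conc_cv = 0, seed = 4)
  cv0 <- simulate_solubility_curve(seq(0, 24, by = 2), th)
  f0 <- fit_solubility(cv0, n_boot = 50, seed = 1)
  expect_lte(diff(f0$ci95_peg_half), 1e-4)
  expect_close(f0$peg_half, 12, 1e-6)

  th2 <- sim_truth(peg_half = 14, s = 1.2, seed = 19)
  cv <- simulate_solubility_curve(seq(0, 30, by = 3), th2)
  f1 <- fit_solubility(cv, n_boot = 100, seed = 7)
  f2 <- fit_solubility(cv, n_boot = 100, seed = 7)
  expect_identical(f1$ci95_peg_half, f2$ci95_peg_half)
  expect_identical(f1$ci95_s, f2$ci95_s)
  expect_lte(f1$ci95_peg_half[1], f1$peg_half)
  expect_gte(f1$ci95_peg_half[2], f1$peg_half)
  expect_lte(f1$ci95_s[1], f1$s)
  expect_gte(f1$ci95_s[2], f1$s)
  expect_equal(f1$bootstrap$scheme, "case")

  # residual-resampling fallback when no replicates are present
  single <- solubility_curve(data.frame(peg_pct = cv$peg_pct,
                                        conc_mean = cv$conc_mean))
  fs <- fit_solubility(single, n_boot = 100, seed = 3)
  expect_equal(fs$bootstrap$scheme, "residual")
  expect_gt(diff(fs$ci95_peg_half), 0)
})

test_that("peg_fit methods: coef, predict, residuals, simulate, print, plot", {
  th <- sim_truth(peg_half = 14, s = 1.2, seed = 23)
  cv <- simulate_solubility_curve(seq(0, 30, by = 3), th)
  fit <- fit_solubility(cv, n_boot = 50, seed = 2)

  co <- coef(fit)
  expect_named(co, c("a", "b", "s", "peg_half"))
  expect_equal(unname(co["peg_half"]), fit$peg_half)

  p <- predict(fit, newdata = c(0, fit$peg_half, 100))
  expect_equal(p[2], (fit$a + fit$b) / 2, tolerance = 1e-9)
  expect_equal(predict(fit, fit$peg_half, normalized = TRUE), 0.5,
               tolerance = 1e-12)
  expect_equal(residuals(fit), cv$conc_mean - predict(fit))

  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(cv), 4))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))

  expect_output(print(fit), "PEG1/2")
  expect_output(print(summary(fit)), "bootstrap scheme")

  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.size(tmp) > 0)

  # JSON serialization carries the documented keys
  jpath <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, jpath, extra = list(seed = 2))
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_true(all(c("a", "b", "s", "peg_half", "ci95_peg_half", "ci95_s",
                    "rss", "n_boot", "converged", "onset_peg",
                    "apparent_solubility") %in% names(back)))
  expect_equal(back$peg_half, fit$peg_half)
})

test_that("formula-free interfaces agree: vectors, data frame, curve object", {
  th <- sim_truth(peg_half = 14, s = 1.2, seed = 29)
  cv <- simulate_solubility_curve(seq(0, 30, by = 3), th)
  f_curve <- fit_solubility(cv, n_boot = 20, seed = 1)
  f_df <- fit_solubility(data.frame(peg_pct = cv$peg_pct,
                                    conc_mean = cv$conc_mean),
                         n_boot = 20, seed = 1)
  f_vec <- fit_solubility(cv$peg_pct, cv$conc_mean, n_boot = 20, seed = 1)
  expect_equal(f_df$peg_half, f_vec$peg_half, tolerance = 1e-12)
  expect_equal(f_curve$peg_half, f_df$peg_half, tolerance = 1e-6)
})
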