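# The precipitation sigmoid and its least-squares fitting.

#' Precipitation sigmoid
#'
#' The model fitted to PEG precipitation curves:
#' `y = (a - b) / (1 + exp(s * (x - peg_half))) + b`,
#' where `a` and `b` are the upper and lower plateaus, `s > 0` the slope and
#' `peg_half` the inflection point — the PEG concentration at which half the
#' protein remains soluble. With `a > b` the curve decreases (soluble
#' concentration); with `a < b` it increases (turbidity).
#'
#' @param x PEG concentration, % w/v.
#' @param a,b upper and lower plateaus.
#' @param s slope, per % w/v; positive.
#' @param peg_half inflection point, % w/v.
#' @return model values.
#' @export
sigmoid <- function(x, a, b, s, peg_half) {
  (a - b) / (1 + exp(s * (x - peg_half))) + b
}

# Initial guesses. Plateaus from the curve ends (so increasing turbidity
# curves work under the same s > 0 parameterization); peg_half at the point
# closest to the mid-level; s from the x-span between the 10% and 90% drop
# levels (a logistic falls from 90% to 10% over ~4.4/s).
sigmoid_start <- function(x, y) {
  n <- length(x)
  k <- min(2L, n)
  a0 <- mean(y[seq_len(k)])
  b0 <- mean(y[seq(n - k + 1L, n)])
  if (a0 == b0) { a0 <- max(y); b0 <- min(y) }
  mid <- (a0 + b0) / 2
  ph0 <- x[which.min(abs(y - mid))]
  lev <- (y - b0) / (a0 - b0)
  x10 <- x[which.min(abs(lev - 0.9))]
  x90 <- x[which.min(abs(lev - 0.1))]
  span <- abs(x90 - x10)
  if (span <= 0) span <- diff(range(x)) / 4
  list(a = a0, b = b0, s = 4 / span, peg_half = ph0)
}

# Coarse grid over slope and inflection; at each node the plateaus have a
# closed-form linear least-squares solution since y is linear in the
# logistic term z = 1/(1 + exp(s (x - ph))). Returns the lowest-RSS node as
# a starting point for the nonlinear optimizer.
sigmoid_grid_start <- function(x, y, fix_plateaus = FALSE) {
  xr <- diff(range(x))
  s_grid <- 4 / (xr * c(4, 2, 1, 0.5, 0.25, 0.12, 0.06, 0.03))
  ph_grid <- seq(min(x), max(x), length.out = 41L)
  best <- list(a = max(y), b = min(y), s = 4 / xr, peg_half = stats::median(x))
  best_rss <- Inf
  for (s in s_grid) {
    for (ph in ph_grid) {
      z <- 1 / (1 + exp(s * (x - ph)))
      if (fix_plateaus) {
        a <- 1; b <- 0
        rss <- sum((y - z)^2)
      } else {
        zc <- z - mean(z)
        denom <- sum(zc^2)
        if (denom < 1e-12) next
        slope <- sum(zc * (y - mean(y))) / denom
        b <- mean(y) - slope * mean(z)
        a <- b + slope
        rss <- sum((y - b - slope * z)^2)
      }
      if (rss < best_rss) {
        best_rss <- rss
        best <- list(a = a, b = b, s = s, peg_half = ph)
      }
    }
  }
  best
}

# Keep the converged fit, else the lower-RSS one.
best_lm <- function(f1, f2) {
  if (is.null(f1)) return(f2)
  if (is.null(f2)) return(f1)
  if (f1$converged != f2$converged) return(if (f2$converged) f2 else f1)
  if (f2$deviance < f1$deviance) f2 else f1
}

# Last-resort Nelder-Mead polish when the Levenberg-Marquardt fit errors
# outright; s is optimized on the log scale to stay positive.
sigmoid_optim_fallback <- function(x, y, st, fix_plateaus) {
  obj <- if (fix_plateaus) {
    function(p) sum((y - sigmoid(x, 1, 0, exp(p[1]), p[2]))^2)
  } else {
    function(p) sum((y - sigmoid(x, p[3], p[4], exp(p[1]), p[2]))^2)
  }
  p0 <- if (fix_plateaus) c(log(st$s), st$peg_half)
        else c(log(st$s), st$peg_half, st$a, st$b)
  o <- stats::optim(p0, obj, control = list(maxit = 2000, reltol = 1e-12))
  pars <- list(a = if (fix_plateaus) 1 else o$par[3],
               b = if (fix_plateaus) 0 else o$par[4],
               s = exp(o$par[1]), peg_half = o$par[2])
  fitted <- sigmoid(x, pars$a, pars$b, pars$s, pars$peg_half)
  res <- y - fitted
  structure(list(a = pars$a, b = pars$b, s = pars$s, peg_half = pars$peg_half,
                 rss = sum(res^2), fitted = fitted, residuals = res,
                 converged = o$convergence == 0, fixed_plateaus = fix_plateaus,
                 x = x, y = y),
            class = "sigmoid_fit")
}

#' Fit the precipitation sigmoid
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [sigmoid()] with the
#' slope constrained positive. Initial guesses come from the data: plateaus
#' from the curve ends, inflection at the point nearest the mid-level, slope
#' from the 10-90% span. If the optimizer fails to converge the best-effort
#' parameters are returned with `converged = FALSE`. Flat data with no
#' detectable transition (total drop below the noise floor, taken as 3x the
#' median point SD) is an error.
#'
#' @param x a numeric vector of PEG concentrations, or a
#'   `"solubility_curve"` (in which case `y` and `sd` are taken from it).
#' @param y responses (soluble concentration or turbidity).
#' @param sd optional per-point SDs, used only for the flat-data check.
#' @param fix_plateaus fix `a = 1`, `b = 0` and fit only `s` and `peg_half`
#'   (used for the refit after plateau normalization).
#' @param start optional named list overriding the automatic starting
#'   values.
#' @return list of class `"sigmoid_fit"`: `a`, `b`, `s`, `peg_half`, `rss`,
#'   `fitted`, `residuals`, `converged`, `x`, `y`.
#' @export
fit_sigmoid <- function(x, y = NULL, sd = NULL, fix_plateaus = FALSE,
                        start = NULL) {
  if (inherits(x, "solubility_curve")) {
    sd <- x$conc_sd
    y <- x$conc_mean
    x <- x$peg_pct
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("at least 4 points are required")
  if (length(unique(x)) < 4L) stop("at least 4 distinct concentrations are required")

  drop <- diff(range(y))
  floor_ <- 1e-12
  if (!is.null(sd) && any(is.finite(sd))) {
    floor_ <- max(floor_, 3 * stats::median(sd[is.finite(sd)]))
  }
  if (drop <= floor_) stop("no transition detected: curve is flat within noise")

  st <- sigmoid_start(x, y)
  if (!is.null(start)) st[names(start)] <- start

  if (fix_plateaus) {
    keep <- c("s", "peg_half")
    lower <- c(1e-8, -Inf)
    resid_fn <- function(p) y - sigmoid(x, 1, 0, p[1], p[2])
  } else {
    keep <- c("a", "b", "s", "peg_half")
    lower <- c(-Inf, -Inf, 1e-8, -Inf)
    resid_fn <- function(p) y - sigmoid(x, p[1], p[2], p[3], p[4])
  }
  st$s <- max(st$s, 1e-6)

  # Levenberg-Marquardt via nls.lm; info codes 1-4 mean the ftol/ptol/gtol
  # convergence criteria were met
  try_lm <- function(st) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = unlist(st[keep]), fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, maxfev = 2000,
                           ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(r)) r$converged <- r$info %in% 1:4
    r
  }

  fit <- try_lm(st)
  if (is.null(fit) || !fit$converged) {
    # fall back to a coarse (s, peg_half) grid with plateaus solved linearly
    st2 <- sigmoid_grid_start(x, y, fix_plateaus)
    fit2 <- try_lm(st2)
    fit <- best_lm(fit, fit2)
    if (is.null(fit)) {
      return(sigmoid_optim_fallback(x, y, st2, fix_plateaus))
    }
  }
  pars <- as.list(stats::setNames(fit$par, keep))
  converged <- fit$converged
  if (fix_plateaus) { pars$a <- 1; pars$b <- 0 }
  fitted <- sigmoid(x, pars$a, pars$b, pars$s, pars$peg_half)
  res <- y - fitted
  structure(list(a = pars$a, b = pars$b, s = pars$s, peg_half = pars$peg_half,
                 rss = sum(res^2), fitted = fitted, residuals = res,
                 converged = converged, fixed_plateaus = fix_plateaus,
                 x = x, y = y),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: a=%.4g b=%.4g s=%.4g peg_half=%.4g (rss=%.3g, %s)\n",
              x$a, x$b, x$s, x$peg_half, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Normalize a curve by its fitted plateaus
#'
#' Rescales responses to `y' = (y - b) / (a - b)` using the plateaus of an
#' initial fit, so the curve runs from 1 (fully soluble) to 0 (fully
#' precipitated) regardless of units or direction; SDs and replicate values
#' are scaled by `1 / |a - b|` and `1 / (a - b)` respectively.
#'
#' @param curve a `"solubility_curve"`.
#' @param fit the initial [fit_sigmoid()] on that curve.
#' @return the normalized `"solubility_curve"` (attribute
#'   `normalized = TRUE`).
#' @export
normalize_curve <- function(curve, fit) {
  if (fit$a == fit$b) stop("cannot normalize: plateaus are equal")
  scale <- fit$a - fit$b
  pts <- as.data.frame(curve)
  pts$conc_mean <- (pts$conc_mean - fit$b) / scale
  pts$conc_sd <- pts$conc_sd / abs(scale)
  reps <- attr(curve, "replicates")
  if (!is.null(reps)) reps <- lapply(reps, function(v) (v - fit$b) / scale)
  out <- solubility_curve(pts, replicates = reps,
                          protein_id = attr(curve, "protein_id"),
                          readout = attr(curve, "readout"))
  attr(out, "normalized") <- TRUE
  out
}

#' Bootstrap confidence intervals for PEG1/2 and the slope
#'
#' Bootstrap on the solubility curve. When any concentration has two or more
#' replicate wells, replicate values are case-resampled within each
#' concentration and the point means recomputed; the resampled deviations
#' are inflated by `sqrt(n/(n-1))`, the standard correction for the
#' downward bias of the resample-mean variance at small per-point n.
#' Without replicates, residuals of the fit are resampled and added back to
#' the fitted values. Each cycle refits the full sigmoid — plateaus included,
#' so the plateau-normalization uncertainty propagates into the interval —
#' starting from the point estimate. Cycles whose refit fails are dropped;
#' if more than 20% fail a warning is raised because the interval is then
#' unreliable.
#'
#' Two interval types are available. `"tboot"` (default) is a bootstrap-SE
#' interval: the point estimate plus/minus a Student-t quantile times the
#' bootstrap standard error (log scale for the slope, which is positive and
#' right-skewed); with only a few replicate wells per point this calibrates
#' noticeably better than raw percentiles. `"percentile"` returns the
#' classical percentile interval.
#'
#' @param curve the (un-normalized) `"solubility_curve"`.
#' @param fit the initial [fit_sigmoid()] on that curve.
#' @param n_cycles number of bootstrap cycles (default 500).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @param interval `"tboot"` or `"percentile"`.
#' @param estimate optional named vector `c(peg_half=, s=)` to center the
#'   `"tboot"` interval on (defaults to `fit`'s parameters).
#' @return list of class `"peg_bootstrap"`: `ci_peg_half`, `ci_s`
#'   (two-element vectors), `n_boot` (successful cycles), `scheme`,
#'   `interval`, `boot_peg_half`, `boot_s`.
#' @export
bootstrap_ci <- function(curve, fit, n_cycles = 500L, level = 0.95,
                         seed = NULL, interval = c("tboot", "percentile"),
                         estimate = NULL) {
  interval <- match.arg(interval)
  if (!is.null(seed)) set.seed(seed)
  x <- curve$peg_pct
  reps <- attr(curve, "replicates")
  case <- !is.null(reps) && any(lengths(reps) >= 2L)
  scheme <- if (case) "case" else "residual"
  start <- list(a = fit$a, b = fit$b, s = fit$s, peg_half = fit$peg_half)

  draw_y <- if (case) {
    m <- vapply(reps, mean, numeric(1))
    infl <- sqrt(lengths(reps) / pmax(lengths(reps) - 1L, 1L))
    function() {
      mb <- vapply(reps, function(v) mean(sample(v, length(v), replace = TRUE)),
                   numeric(1))
      m + (mb - m) * infl
    }
  } else {
    function() fit$fitted + sample(fit$residuals, length(fit$residuals),
                                   replace = TRUE)
  }

  ph <- s <- rep(NA_real_, n_cycles)
  for (i in seq_len(n_cycles)) {
    yb <- draw_y()
    fb <- tryCatch(
      suppressWarnings(fit_sigmoid(x, yb, start = start)),
      error = function(e) NULL)
    if (!is.null(fb) && fb$converged) {
      ph[i] <- fb$peg_half
      s[i] <- fb$s
    }
  }
  ok <- is.finite(ph)
  if (mean(!ok) > 0.2) {
    warning(sprintf("%.0f%% of bootstrap refits failed; interval is unreliable",
                    100 * mean(!ok)))
  }
  if (!any(ok)) stop("all bootstrap refits failed")
  alpha <- (1 - level) / 2
  est <- estimate %||% c(peg_half = fit$peg_half, s = fit$s)

  if (interval == "percentile") {
    ci_ph <- unname(stats::quantile(ph[ok], c(alpha, 1 - alpha)))
    ci_s <- unname(stats::quantile(s[ok], c(alpha, 1 - alpha)))
  } else {
    tq <- stats::qt(1 - alpha, df = max(length(x) - 4L, 1L))
    hw <- tq * stats::sd(ph[ok])
    if (!is.finite(hw)) hw <- 0
    ci_ph <- c(est[["peg_half"]] - hw, est[["peg_half"]] + hw)
    sd_log_s <- stats::sd(log(s[ok]))
    if (!is.finite(sd_log_s)) sd_log_s <- 0
    ci_s <- est[["s"]] * exp(c(-1, 1) * tq * sd_log_s)
  }
  structure(list(
    ci_peg_half = ci_ph, ci_s = ci_s,
    n_boot = sum(ok), scheme = scheme, interval = interval, level = level,
    boot_peg_half = ph[ok], boot_s = s[ok]),
    class = "peg_bootstrap")
}

#' Onset of precipitation
#'
#' The PEG concentration where precipitation begins, defined by the tangent
#' construction: the tangent at the inflection point (slope
#' `-s (a - b) / 4`) intersects the upper plateau at
#' `onset = peg_half - 2 / s`. As the curve steepens (`s -> Inf`) the onset
#' approaches `peg_half`.
#'
#' @param fit a converged `"sigmoid_fit"` with `s > 0`.
#' @return onset PEG concentration, % w/v.
#' @export
estimate_onset <- function(fit) {
  if (!fit$converged) stop("fit did not converge")
  if (fit$s <= 0) stop("onset requires a positive slope")
  fit$peg_half - 2 / fit$s
}

#' Apparent absolute solubility by log-extrapolation
#'
#' Extrapolates the transition-region decay of the soluble concentration to
#' 0% PEG: a straight line is fitted to `ln(concentration)` against PEG%
#' over the points whose fitted value lies between 20% and 80% of the total
#' drop, and the intercept is exponentiated. The result is only an
#' *apparent* solubility: it is extremely sensitive to small errors in the
#' transition points and should not be read as a thermodynamic solubility.
#'
#' @param curve the (un-normalized) `"solubility_curve"` in mg/mL.
#' @param fit the initial [fit_sigmoid()] on that curve.
#' @param window fraction-of-drop window defining the transition region.
#' @return list of class `"derived_solubility"`: `onset_peg`,
#'   `apparent_solubility` (mg/mL), `extrapolation_points`, `log_slope`.
#' @export
extrapolate_apparent_solubility <- function(curve, fit, window = c(0.2, 0.8)) {
  level <- (fit$fitted - fit$b) / (fit$a - fit$b)
  usable <- level > window[1] & level < window[2] & curve$conc_mean > 0
  if (sum(usable) < 3L) {
    stop("fewer than 3 positive transition-region points; cannot extrapolate")
  }
  lf <- stats::lm(log(conc) ~ peg,
                  data = data.frame(peg = curve$peg_pct[usable],
                                    conc = curve$conc_mean[usable]))
  structure(list(onset_peg = estimate_onset(fit),
                 apparent_solubility = exp(unname(stats::coef(lf)[1])),
                 extrapolation_points = sum(usable),
                 log_slope = unname(stats::coef(lf)[2])),
            class = "derived_solubility")
}
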