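#' Fit a PEG precipitation curve and estimate PEG1/2
#'
#' The central estimator of the package. Given a solubility curve (soluble
#' protein concentration — or turbidity — against PEG % w/v) it:
#'
#' 1. fits the four-parameter precipitation [sigmoid()] to locate the
#'    plateaus `a`, `b`, slope `s` and inflection `peg_half` (PEG1/2, the
#'    relative-solubility proxy);
#' 2. normalizes the curve by the fitted plateaus so it runs from 1 to 0 and
#'    refits `s` and `peg_half` on the normalized data;
#' 3. computes bootstrap confidence intervals for `peg_half` and `s`
#'    (default 500 cycles, 95% level) by case-resampling replicate wells
#'    within each concentration (falling back to residual resampling when no
#'    replicates are available) and refitting the full sigmoid each cycle;
#'    see [bootstrap_ci()] for the interval construction;
#' 4. derives the precipitation onset (`peg_half - 2/s`, the
#'    tangent-at-inflection construction) and, when at least three positive
#'    transition-region points exist, the log-extrapolated apparent absolute
#'    solubility at 0% PEG.
#'
#' @param x a `"solubility_curve"` (see [build_curve()] /
#'   [solubility_curve()]), a data frame with columns `peg_pct` and
#'   `conc_mean`, or a numeric vector of PEG concentrations.
#' @param y responses when `x` is a numeric vector.
#' @param n_boot bootstrap cycles (default 500).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @param ... passed on between methods.
#' @return an object of class `"peg_fit"`; see [print.peg_fit()],
#'   [summary.peg_fit()], [coef.peg_fit()], [predict.peg_fit()],
#'   [plot.peg_fit()].
#' @examples
#' truth <- sim_truth(peg_half = 14, s = 1.2, seed = 7)
#' curve <- simulate_solubility_curve(seq(0, 30, by = 3), truth)
#' fit <- fit_solubility(curve, n_boot = 100, seed = 1)
#' fit
#' coef(fit)
#' @export
fit_solubility <- function(x, ...) UseMethod("fit_solubility")

#' @rdname fit_solubility
#' @export
fit_solubility.default <- function(x, y, n_boot = 500L, level = 0.95,
                                   seed = NULL, ...) {
  curve <- solubility_curve(data.frame(peg_pct = x, conc_mean = y))
  fit_solubility(curve, n_boot = n_boot, level = level, seed = seed, ...)
}

#' @rdname fit_solubility
#' @export
fit_solubility.data.frame <- function(x, n_boot = 500L, level = 0.95,
                                      seed = NULL, ...) {
  if (inherits(x, "solubility_curve")) return(NextMethod())
  fit_solubility(solubility_curve(x), n_boot = n_boot, level = level,
                 seed = seed, ...)
}

#' @rdname fit_solubility
#' @param interval bootstrap interval type, `"tboot"` (bootstrap SE with a
#'   Student-t quantile) or `"percentile"`; see [bootstrap_ci()].
#' @export
fit_solubility.solubility_curve <- function(x, n_boot = 500L, level = 0.95,
                                            seed = NULL,
                                            interval = c("tboot", "percentile"),
                                            ...) {
  interval <- match.arg(interval)
  initial <- fit_sigmoid(x)
  ncurve <- normalize_curve(x, initial)
  nfit <- fit_sigmoid(ncurve, fix_plateaus = TRUE,
                      start = list(s = initial$s, peg_half = initial$peg_half))
  boot <- bootstrap_ci(x, initial, n_cycles = n_boot, level = level,
                       seed = seed, interval = interval,
                       estimate = c(peg_half = nfit$peg_half, s = nfit$s))
  derived <- tryCatch(extrapolate_apparent_solubility(x, initial),
                      error = function(e) NULL)
  onset <- tryCatch(estimate_onset(nfit), error = function(e) NA_real_)

  structure(list(
    curve = x, normalized_curve = ncurve,
    initial_fit = initial, normalized_fit = nfit,
    a = initial$a, b = initial$b,
    s = nfit$s, peg_half = nfit$peg_half,
    ci95_peg_half = boot$ci_peg_half, ci95_s = boot$ci_s,
    rss = nfit$rss, n_boot = boot$n_boot, bootstrap = boot,
    converged = initial$converged && nfit$converged,
    onset_peg = onset,
    apparent_solubility = if (is.null(derived)) NA_real_ else derived$apparent_solubility,
    derived = derived,
    level = level, seed = seed,
    protein_id = attr(x, "protein_id") %||% "protein",
    readout = attr(x, "readout") %||% "concentration",
    call = match.call()),
    class = "peg_fit")
}

#' @export
print.peg_fit <- function(x, digits = 4, ...) {
  cat(sprintf("PEG precipitation fit (%s readout) for %s\n",
              x$readout, x$protein_id))
  cat(sprintf("  PEG1/2 : %s %% w/v  [%s, %s] %d%% CI (%d bootstrap cycles)\n",
              signif(x$peg_half, digits),
              signif(x$ci95_peg_half[1], digits), signif(x$ci95_peg_half[2], digits),
              round(100 * x$level), x$n_boot))
  cat(sprintf("  slope  : %s per %% w/v  [%s, %s]\n",
              signif(x$s, digits),
              signif(x$ci95_s[1], digits), signif(x$ci95_s[2], digits)))
  cat(sprintf("  plateaus: a = %s, b = %s\n", signif(x$a, digits), signif(x$b, digits)))
  if (is.finite(x$onset_peg)) {
    cat(sprintf("  onset  : %s %% w/v\n", signif(x$onset_peg, digits)))
  }
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Summary of a PEG precipitation fit
#' @param object a `"peg_fit"`.
#' @param ... unused.
#' @export
summary.peg_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.peg_fit")
}

#' @export
print.summary.peg_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  residual SS (normalized): %.4g over %d points\n",
              f$rss, nrow(f$curve)))
  cat(sprintf("  bootstrap scheme: %s resampling\n", f$bootstrap$scheme))
  if (!is.null(f$derived)) {
    cat(sprintf("  apparent solubility (log-extrapolated to 0%% PEG): %.4g mg/mL over %d points\n",
                f$derived$apparent_solubility, f$derived$extrapolation_points))
    cat("    (apparent only: extremely sensitive to transition-point noise)\n")
  }
  cat("  curve:\n")
  print(as.data.frame(f$curve), row.names = FALSE)
  invisible(x)
}

#' @export
coef.peg_fit <- function(object, ...) {
  c(a = object$a, b = object$b, s = object$s, peg_half = object$peg_half)
}

#' Predicted curve values from a PEG fit
#' @param object a `"peg_fit"`.
#' @param newdata PEG concentrations (% w/v); defaults to the fitted ones.
#' @param normalized return values on the normalized 0-1 scale instead of
#'   the original units.
#' @param ... unused.
#' @export
predict.peg_fit <- function(object, newdata = NULL, normalized = FALSE, ...) {
  x <- newdata %||% object$curve$peg_pct
  if (is.data.frame(x)) x <- x$peg_pct
  yn <- sigmoid(x, 1, 0, object$s, object$peg_half)
  if (normalized) yn else yn * (object$a - object$b) + object$b
}

#' @export
residuals.peg_fit <- function(object, normalized = FALSE, ...) {
  if (normalized) {
    object$normalized_curve$conc_mean - predict(object, normalized = TRUE)
  } else {
    object$curve$conc_mean - predict(object)
  }
}

#' @export
fitted.peg_fit <- function(object, ...) predict(object)

#' Simulate curves from a fitted precipitation model
#'
#' Parametric simulation: new responses are the fitted curve plus Gaussian
#' noise with the residual standard deviation, mirroring what a repeat of
#' the same assay would measure under the fitted model.
#'
#' @param object a `"peg_fit"`.
#' @param nsim number of simulated curves.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with the PEG grid and one column per simulation.
#' @export
simulate.peg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sdr <- stats::sd(residuals(object))
  if (!is.finite(sdr)) sdr <- 0
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sdr)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(peg_pct = object$curve$peg_pct), out)
}

#' Plot a PEG precipitation fit
#'
#' Data points with error bars, the fitted sigmoid, a bootstrap confidence
#' band, and a vertical marker at PEG1/2.
#'
#' @param x a `"peg_fit"`.
#' @param normalized plot on the normalized 0-1 scale.
#' @param n_grid resolution of the fitted curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.peg_fit <- function(x, normalized = FALSE, n_grid = 200L, ...) {
  curve <- if (normalized) x$normalized_curve else x$curve
  xg <- seq(min(curve$peg_pct), max(curve$peg_pct), length.out = n_grid)
  yg <- predict(x, xg, normalized = normalized)
  scale <- if (normalized) c(1, 0) else c(x$a, x$b)
  bs <- x$bootstrap
  band <- vapply(seq_along(xg), function(i) {
    vals <- sigmoid(xg[i], scale[1], scale[2], bs$boot_s, bs$boot_peg_half)
    stats::quantile(vals, c((1 - x$level) / 2, 1 - (1 - x$level) / 2))
  }, numeric(2))
  ylab <- if (normalized) "soluble fraction (normalized)"
          else if (x$readout == "turbidity") "turbidity (blanked A500, AU)"
          else "soluble concentration (mg/mL)"
  graphics::plot(curve$peg_pct, curve$conc_mean, pch = 19,
                 xlab = "PEG (% w/v)", ylab = ylab,
                 ylim = range(curve$conc_mean, band, na.rm = TRUE), ...)
  graphics::polygon(c(xg, rev(xg)), c(band[1, ], rev(band[2, ])),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  # error bars; bars too small to draw at device resolution are skipped
  has_sd <- is.finite(curve$conc_sd) &
    curve$conc_sd > 1e-4 * diff(range(curve$conc_mean))
  if (any(has_sd)) {
    graphics::arrows(curve$peg_pct[has_sd],
                     (curve$conc_mean - curve$conc_sd)[has_sd],
                     curve$peg_pct[has_sd],
                     (curve$conc_mean + curve$conc_sd)[has_sd],
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::lines(xg, yg, col = "steelblue", lwd = 2)
  graphics::points(curve$peg_pct, curve$conc_mean, pch = 19)
  graphics::abline(v = x$peg_half, lty = 2, col = "grey40")
  graphics::mtext(sprintf("PEG1/2 = %.2f [%.2f, %.2f] %% w/v", x$peg_half,
                          x$ci95_peg_half[1], x$ci95_peg_half[2]),
                  side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes the fields `a,b,s,peg_half,ci95_peg_half,ci95_s,rss,n_boot,
#' converged,onset_peg,apparent_solubility` (plus metadata) to a JSON file.
#'
#' @param fit a `"peg_fit"`.
#' @param path output path.
#' @param extra named list of extra metadata (e.g. seed, config hash).
#' @export
write_fit_json <- function(fit, path, extra = list()) {
  payload <- c(list(
    protein_id = fit$protein_id, readout = fit$readout,
    a = fit$a, b = fit$b, s = fit$s, peg_half = fit$peg_half,
    ci95_peg_half = fit$ci95_peg_half, ci95_s = fit$ci95_s,
    rss = fit$rss, n_boot = fit$n_boot, converged = fit$converged,
    onset_peg = fit$onset_peg,
    apparent_solubility = fit$apparent_solubility), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
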