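# Four-parameter logistic (Hill-form) dose-response calibration and limit
# of detection.

#' Predict from a four-parameter logistic curve
#'
#' The 4PL (Hill) form used throughout:
#' \deqn{f(x) = d + \frac{a - d}{1 + (x/c)^b}}
#' with `a` the response at zero concentration, `d` the response at infinite
#' concentration, `c` the inflection concentration (same units as `x`) and
#' `b > 0` the slope factor. `f(0) = a` and `f(x) -> d` as `x -> Inf`;
#' the curve is monotone for `b > 0`.
#'
#' @param fit A `fourpl_fit` object or a list with elements `a`, `b`, `c`,
#'   `d`.
#' @param x Concentrations (>= 0).
#' @return Predicted responses.
#' @export
predict_4pl <- function(fit, x) {
  if (any(x < 0)) db_invalid("concentrations must be non-negative")
  ifelse(x == 0, fit$a, fit$d + (fit$a - fit$d) / (1 + (x / fit$c)^fit$b))
}

#' Invert a four-parameter logistic curve
#'
#' Closed-form inverse of [predict_4pl()]:
#' \deqn{x = c \left( \frac{a - d}{y - d} - 1 \right)^{1/b}}
#' defined for responses strictly between the asymptotes `a` and `d`.
#'
#' @param fit A `fourpl_fit` object.
#' @param y Response strictly between the asymptotes.
#' @return The concentration at which the fitted curve predicts `y`.
#' @export
invert_4pl <- function(fit, y) {
  lo <- min(fit$a, fit$d); hi <- max(fit$a, fit$d)
  if (any(y <= lo | y >= hi))
    db_invalid("response must lie strictly between the 4PL asymptotes")
  fit$c * ((fit$a - fit$d) / (y - fit$d) - 1)^(1 / fit$b)
}

#' Fit a four-parameter logistic calibration curve
#'
#' Fits [predict_4pl()] to calibration data by unweighted nonlinear least
#' squares (Levenberg-Marquardt) on linear concentration. The blank (zero
#' concentration), if present, is excluded from the residuals -- `x = 0` is a
#' removable boundary of the Hill form -- and is used only to initialize the
#' lower asymptote `a`; the LOD is later anchored to the blank via
#' [compute_lod()]. Robustness comes from a multi-start grid over the slope
#' factor (`b` in 0.5, 1, 2) and the inflection (`c` at the geometric
#' quartiles of the positive concentrations); the converged fit with the
#' lowest residual sum of squares is returned.
#'
#' @param concentrations Concentrations (ng/mL); at least 5 distinct
#'   positive values; zeros are treated as blanks.
#' @param responses Responses (AMB for the digital readout, a.u. for the
#'   analog readout), same length.
#' @param weights Optional per-point weights (e.g. inverse replicate
#'   variance); default unweighted.
#' @return An object of class `fourpl_fit`: `a`, `b`, `c`, `d`, `rss`,
#'   `n_points` (positive-concentration points used), plus the data.
#' @export
fit_4pl <- function(concentrations, responses, weights = NULL) {
  x <- concentrations; y <- responses
  if (length(x) != length(y))
    db_invalid("'concentrations' and 'responses' must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0))
    db_invalid("calibration data must be finite with non-negative concentrations")
  pos <- x > 0
  if (length(unique(x[pos])) < 5L)
    db_invalid("need at least 5 distinct positive concentrations")
  xb <- x[!pos]; yb <- y[!pos]
  xp <- x[pos]; yp <- y[pos]
  wp <- if (is.null(weights)) rep(1, sum(pos)) else weights[pos]

  if (diff(range(yp)) <= 1e-12 * max(1, max(abs(yp))))
    db_stop("responses are flat; a 4PL curve is not identifiable",
            "digibead_fit_failure")

  # warn (not error) if level means are non-monotone beyond replicate noise
  lev <- sort(unique(xp))
  mlev <- vapply(lev, function(l) mean(yp[xp == l]), numeric(1))
  slev <- vapply(lev, function(l) stats::sd(yp[xp == l]), numeric(1))
  noise <- stats::median(slev, na.rm = TRUE)
  if (!is.finite(noise) || is.na(noise)) noise <- 0
  drops <- diff(mlev)
  tol <- max(2 * noise, 0.02 * diff(range(mlev)))
  if (any(drops < -tol))
    warning("calibration responses are non-monotone beyond replicate noise",
            call. = FALSE)

  a0 <- if (length(yb) > 0) mean(yb) else min(yp)
  d0 <- mlev[length(mlev)]
  if (abs(d0 - a0) < 1e-12) d0 <- a0 + diff(range(yp))
  cq <- exp(stats::quantile(log(xp), c(0.25, 0.5, 0.75), names = FALSE))
  starts <- expand.grid(b = c(0.5, 1, 2), c = unique(cq))

  dat <- data.frame(x = xp, y = yp)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ d + (a - d) / (1 + (x / c)^b),
        data = dat,
        start = list(a = a0, d = d0, c = starts$c[i], b = starts$b[i]),
        lower = c(a = -Inf, d = -Inf, c = .Machine$double.eps, b = 1e-3),
        weights = wp,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best))
    db_stop("4PL fit failed to converge from all starting points",
            "digibead_fit_failure")
  co <- best$coef
  structure(
    list(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]),
         d = unname(co["d"]), rss = best$rss, n_points = nrow(dat),
         concentrations = x, responses = y),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit: f(x) = d + (a - d) / (1 + (x/c)^b)\n")
  cat(sprintf("  a = %.5g, b = %.5g, c = %.5g, d = %.5g\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  rss = %.5g over %d positive-concentration points\n",
              x$rss, x$n_points))
  invisible(x)
}

#' Limit of detection from a 4PL fit and blank statistics
#'
#' The LOD response level is the blank mean plus three blank standard
#' deviations (computed across blank replicates on the same readout scale as
#' the fit). The LOD concentration solves `f(x) = y_lod` via the closed-form
#' inverse ([invert_4pl()]), cross-checked internally against numerical
#' root-finding; the equivalent mass is `lod_concentration * sample_volume`
#' (ng/mL x uL = pg).
#'
#' @param fit A [fit_4pl()] result.
#' @param blank_mean,blank_sd Mean and SD of the blank readout across
#'   replicates (response units).
#' @param sample_volume Sample volume in microliters (default 2).
#' @return An object of class `lod_result`: `y_lod`, `lod_concentration`
#'   (ng/mL), `lod_mass` (pg), `sample_volume` (uL).
#' @export
compute_lod <- function(fit, blank_mean, blank_sd, sample_volume = 2) {
  check_scalar(blank_mean, "blank_mean")
  check_scalar(blank_sd, "blank_sd", lower = 0)
  check_scalar(sample_volume, "sample_volume", lower = 0)
  y_lod <- blank_mean + 3 * blank_sd
  lo <- min(fit$a, fit$d); hi <- max(fit$a, fit$d)
  if (!(y_lod > lo && y_lod < hi))
    db_stop(sprintf(
      "LOD response level %.5g is not strictly between the fitted asymptotes (%.5g, %.5g)",
      y_lod, lo, hi), "digibead_lod_undefined")
  x_lod <- invert_4pl(fit, y_lod)
  # guard the closed form with a numeric root
  g <- function(x) predict_4pl(fit, x) - y_lod
  bracket <- c(x_lod / 1e6, x_lod * 1e6)
  if (g(bracket[1]) * g(bracket[2]) < 0) {
    x_num <- stats::uniroot(g, bracket, tol = x_lod * 1e-10)$root
    if (abs(x_num - x_lod) > 1e-6 * max(x_lod, x_num))
      db_stop("closed-form LOD inversion disagrees with numeric root-finding",
              "digibead_internal_error")
  }
  structure(
    list(y_lod = y_lod, lod_concentration = x_lod,
         lod_mass = concentration_to_mass(x_lod, sample_volume),
         sample_volume = sample_volume),
    class = "lod_result"
  )
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf(
    "LOD: %.4g ng/mL at response %.4g (%.4g pg in %g uL)\n",
    x$lod_concentration, x$y_lod, x$lod_mass, x$sample_volume))
  invisible(x)
}

#' Convert a concentration to a mass in the sample volume
#'
#' `mass [pg] = concentration [ng/mL] * volume [uL]` (1 ng/mL over 1 uL is
#' 1 pg).
#'
#' @param concentration Concentration in ng/mL (>= 0); vectorized.
#' @param volume Sample volume in uL (>= 0).
#' @return Mass in pg.
#' @export
#' @examples
#' concentration_to_mass(0.36, 100)  # 36 pg
concentration_to_mass <- function(concentration, volume) {
  if (!is.numeric(concentration) || !is.numeric(volume) ||
      any(!is.finite(concentration)) || any(!is.finite(volume)) ||
      any(concentration < 0) || any(volume < 0))
    db_invalid("'concentration' and 'volume' must be finite and non-negative")
  concentration * volume
}
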