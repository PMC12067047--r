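#' Fit a Gaussian blank model and on/off threshold
#'
#' Fits the distribution of maximum bead intensities from the blank (zero
#' analyte) condition to a Gaussian by maximum likelihood -- the sample mean
#' and the n-1 sample standard deviation -- and sets the "on"/"off"
#' classification threshold two standard deviations above the mean. By
#' construction a true blank bead exceeds the threshold with probability
#' ~0.02275 (the upper 2-sigma Gaussian tail).
#'
#' @param blank_intensities Numeric vector of per-bead maximum intensities
#'   (a.u.) from the blank condition.
#' @param min_beads Minimum number of blank beads required (default 30).
#' @return An object of class `blank_model`: `mu_blank`, `sigma_blank`,
#'   `threshold` (`mu_blank + 2 * sigma_blank`) and `n_blank_beads`.
#' @export
#' @examples
#' fit_blank(rnorm(1000, 1500, 120))
fit_blank <- function(blank_intensities, min_beads = 30L) {
  x <- blank_intensities
  if (!is.numeric(x) || any(!is.finite(x)))
    db_invalid("'blank_intensities' must be finite numeric values")
  if (length(x) < min_beads)
    db_stop(sprintf("need at least %d blank beads, got %d",
                    min_beads, length(x)), "digibead_insufficient_blank")
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma == 0)
    db_stop("blank intensities have zero variance; cannot define a threshold",
            "digibead_degenerate_blank")
  structure(
    list(mu_blank = mu, sigma_blank = sigma,
         threshold = mu + 2 * sigma,
         n_blank_beads = length(x)),
    class = "blank_model"
  )
}

#' @export
print.blank_model <- function(x, ...) {
  cat(sprintf("Blank model: mu = %.4g, sigma = %.4g, threshold = %.4g (n = %d)\n",
              x$mu_blank, x$sigma_blank, x$threshold, x$n_blank_beads))
  invisible(x)
}

#' Classify beads as "on" or "off" against a blank threshold
#'
#' A bead is "on" when its maximum intensity is strictly greater than the
#' blank threshold (ties count as "off", the conservative choice for false
#' positives).
#'
#' @param intensities Numeric vector of per-bead maximum intensities (a.u.).
#' @param blank A [fit_blank()] model (or any list with a finite
#'   `threshold`).
#' @return A list with integer `n_on` and `n_total`.
#' @export
classify_beads <- function(intensities, blank) {
  if (length(intensities) == 0L)
    db_stop("no beads to classify", "digibead_empty_input")
  if (!is.numeric(intensities) || any(!is.finite(intensities)))
    db_invalid("'intensities' must be finite numeric values")
  thr <- blank$threshold
  if (!is.numeric(thr) || length(thr) != 1L || !is.finite(thr))
    db_invalid("blank threshold must be a single finite number")
  list(n_on = sum(intensities > thr), n_total = length(intensities))
}

#' Average molecules per bead from an on-fraction
#'
#' The Poisson inversion at the heart of the digital readout: if molecules
#' land on beads as Poisson(\eqn{\lambda}), the probability a bead carries at
#' least one molecule is \eqn{1 - e^{-\lambda}}, so
#' \deqn{AMB = -\ln(1 - f_{on})}
#' recovers \eqn{\lambda} from the observed on-fraction.
#'
#' @param f_on On-fraction in \[0, 1\].
#' @return The average number of molecules per bead.
#' @seealso [compute_amb()] for the counted version with saturation
#'   handling.
#' @export
#' @examples
#' amb_from_fraction(1 - exp(-1))   # exactly 1
amb_from_fraction <- function(f_on) {
  if (!is.numeric(f_on) || any(!is.finite(f_on)) || any(f_on < 0 | f_on > 1))
    db_invalid("'f_on' must be in [0, 1]")
  -log1p(-f_on)
}

#' Delta-method standard error of AMB
#'
#' For `n_on` out of `n_total` beads on, the binomial sampling error of
#' `f_on` propagates through `-ln(1 - f_on)` to
#' \eqn{SE(AMB) = \sqrt{f_{on} / ((1 - f_{on}) \, n)}}.
#'
#' @param f_on Observed on-fraction, strictly below 1.
#' @param n_total Number of beads counted.
#' @return The approximate standard error of the AMB estimate.
#' @export
amb_se <- function(f_on, n_total) {
  if (any(f_on >= 1)) db_invalid("'f_on' must be < 1 for a finite SE")
  sqrt(f_on / ((1 - f_on) * n_total))
}

#' Digital readout: on-fraction and AMB from bead counts
#'
#' Computes `f_on = n_on / n_total` and `AMB = -ln(1 - f_on)` (see
#' [amb_from_fraction()]). When the count is saturated -- all beads on, or
#' within one bead of it (`f_on >= 1 - 1/n_total`) -- the estimator has no
#' finite inverse, so AMB is capped at the value for `n_total - 0.5` beads on
#' and flagged via `saturated`; the readout is then a lower bound, not an
#' estimate.
#'
#' @param n_on Number of "on" beads (0..`n_total`).
#' @param n_total Total beads counted (> 0).
#' @return An object of class `digital_result`: `n_on`, `n_total`, `f_on`,
#'   `amb`, `saturated`.
#' @export
#' @examples
#' compute_amb(50, 1000)   # amb = -log(0.95)
compute_amb <- function(n_on, n_total) {
  check_scalar(n_total, "n_total", lower = 1, integer = TRUE)
  check_scalar(n_on, "n_on", lower = 0, integer = TRUE)
  if (n_on > n_total)
    db_stop(sprintf("n_on (%d) exceeds n_total (%d)", n_on, n_total),
            "digibead_invalid_count")
  f_on <- n_on / n_total
  saturated <- f_on >= 1 - 1 / n_total
  amb <- if (saturated) {
    -log1p(-(n_total - 0.5) / n_total)
  } else {
    amb_from_fraction(f_on)
  }
  structure(
    list(n_on = as.integer(n_on), n_total = as.integer(n_total),
         f_on = f_on, amb = amb, saturated = saturated),
    class = "digital_result"
  )
}

#' @export
print.digital_result <- function(x, ...) {
  cat(sprintf("Digital readout: %d / %d beads on (f_on = %.4g), AMB = %.4g%s\n",
              x$n_on, x$n_total, x$f_on, x$amb,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Analog readout: grand mean fluorescence intensity
#'
#' The comparator analog signal: the average pixel intensity over all
#' fluorescence frames, beads and background alike, with no masking. Frames
#' must share one shape, so the grand mean equals the mean of per-frame
#' means and is independent of frame order.
#'
#' @param fluorescence_frames List of numeric matrices of equal shape.
#' @return An object of class `analog_result`: `mean_intensity` (a.u.) and
#'   `n_frames`.
#' @export
analog_readout <- function(fluorescence_frames) {
  if (length(fluorescence_frames) == 0L)
    db_stop("no fluorescence frames", "digibead_empty_input")
  shp <- dim(fluorescence_frames[[1]])
  tot <- 0; npx <- 0
  for (f in fluorescence_frames) {
    if (!is.matrix(f) || !identical(dim(f), shp))
      db_invalid("all fluorescence frames must be matrices of one shape")
    tot <- tot + sum(f)
    npx <- npx + length(f)
  }
  structure(
    list(mean_intensity = tot / npx,
         n_frames = length(fluorescence_frames)),
    class = "analog_result"
  )
}

#' @export
print.analog_result <- function(x, ...) {
  cat(sprintf("Analog readout: mean intensity %.4g a.u. over %d frames\n",
              x$mean_intensity, x$n_frames))
  invisible(x)
}
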