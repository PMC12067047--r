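#' Assay parameters for the Poisson bead-loading model
#'
#' Describes one assay condition. The expected number of labeled analyte
#' molecules per bead is
#' \deqn{\lambda = \kappa \cdot C \cdot \eta}
#' where \eqn{C} is the analyte concentration (ng/mL), \eqn{\kappa}
#' (`capture_coeff`) converts concentration to molecules per bead, and
#' \eqn{\eta} (`labeling_efficiency`) is the probability that a captured
#' molecule yields an amplified, fluorescently labeled product. Defaults
#' correspond to a desk-scale assay: 2e4 beads (the low end of bead counts
#' used in practice) and \eqn{\kappa \eta = 0.08} per (ng/mL), which places a
#' 0.1--100 ng/mL dilution series across the digital dynamic range
#' (\eqn{\lambda} from below 0.01 up to saturation).
#'
#' @param concentration Analyte concentration in ng/mL (>= 0).
#' @param capture_coeff Molecules-per-bead per (ng/mL), > 0.
#' @param n_beads Total number of beads in the assay (integer > 0).
#' @param labeling_efficiency Probability in \[0, 1\] that a bound molecule is
#'   labeled.
#' @param seed Integer RNG seed; identical seeds reproduce identical
#'   populations bit-for-bit.
#' @return An object of class `assay_params`.
#' @seealso [simulate_bead_loading()]
#' @export
#' @examples
#' p <- assay_params(concentration = 2.5)
#' assay_lambda(p)
assay_params <- function(concentration,
                         capture_coeff = 0.1,
                         n_beads = 20000L,
                         labeling_efficiency = 0.8,
                         seed = 1L) {
  check_scalar(concentration, "concentration", lower = 0)
  check_scalar(capture_coeff, "capture_coeff")
  if (capture_coeff <= 0) db_invalid("'capture_coeff' must be > 0")
  check_scalar(n_beads, "n_beads", lower = 1, integer = TRUE)
  check_scalar(labeling_efficiency, "labeling_efficiency", lower = 0, upper = 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(concentration = concentration,
         capture_coeff = capture_coeff,
         n_beads = as.integer(n_beads),
         labeling_efficiency = labeling_efficiency,
         seed = as.integer(seed)),
    class = "assay_params"
  )
}

#' Expected molecules per bead for an assay condition
#'
#' @param params An [assay_params()] object.
#' @return The Poisson mean \eqn{\lambda = \kappa C \eta}.
#' @export
assay_lambda <- function(params) {
  stopifnot(inherits(params, "assay_params"))
  params$capture_coeff * params$concentration * params$labeling_efficiency
}

#' Optical and rendering parameters for synthetic micrographs
#'
#' Describes the simulated imaging system used by [render_frames()]. Bead
#' footprints are circular disks; "off" beads draw their peak fluorescence
#' from a Gaussian blank distribution and "on" beads from a log-normal (a
#' positive, right-skewed distribution matching the spread of amplified
#' signals). The localization channel renders dark disks on a bright field
#' (brightfield) or bright disks on a dark field (darkfield).
#'
#' Per-frame background jitter (`background_jitter_sd`) emulates illumination
#' and autofluorescence drift between fields of view. It shifts every pixel of
#' a fluorescence frame jointly, so it inflates the analog (frame-mean)
#' readout's variability while leaving the digital classification essentially
#' untouched (bead peaks and the blank-derived threshold shift together only
#' through the marginal blank distribution, which stays Gaussian).
#'
#' Intensity defaults are arbitrary 16-bit camera units chosen once for the
#' simulator: blank beads at 1500 +/- 120 a.u. over a 300 a.u. background, and
#' "on" beads with median 8000 a.u. -- comfortably separated from the
#' blank mean + 2 SD threshold, as the analysis assumes. A warning is issued
#' if parameters leave that separable regime.
#'
#' @param image_shape Integer (height, width) in pixels.
#' @param bead_radius_px Mean bead radius in pixels (>= 2).
#' @param radius_jitter Relative SD of the per-bead radius.
#' @param blank_mean,blank_sd Gaussian parameters of "off" bead peak
#'   intensity (a.u.).
#' @param on_intensity_mu,on_intensity_sigma Log-normal parameters
#'   (log-scale mean and SD) of "on" bead peak intensity (a.u.).
#' @param background_level Mean field background (a.u.).
#' @param background_jitter_sd SD of the per-frame background offset (a.u.).
#' @param read_noise_sd Per-pixel additive Gaussian read noise SD (a.u.).
#' @param bit_depth 8 or 16; intensities are clipped to `[0, 2^bit_depth - 1]`.
#' @param modality `"brightfield"` or `"darkfield"` localization channel.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(image_shape = c(256L, 256L),
                          bead_radius_px = 5,
                          radius_jitter = 0.05,
                          blank_mean = 1500,
                          blank_sd = 120,
                          on_intensity_mu = log(8000),
                          on_intensity_sigma = 0.4,
                          background_level = 300,
                          background_jitter_sd = 30,
                          read_noise_sd = 30,
                          bit_depth = 16L,
                          modality = c("brightfield", "darkfield")) {
  modality <- match.arg(modality)
  if (length(image_shape) != 2L || any(image_shape < 8) ||
      any(image_shape != round(image_shape)))
    db_invalid("'image_shape' must be two integers >= 8 (height, width)")
  check_scalar(bead_radius_px, "bead_radius_px", lower = 2)
  check_scalar(radius_jitter, "radius_jitter", lower = 0, upper = 0.5)
  check_scalar(blank_mean, "blank_mean", lower = 0)
  check_scalar(blank_sd, "blank_sd", lower = 0)
  check_scalar(on_intensity_mu, "on_intensity_mu")
  check_scalar(on_intensity_sigma, "on_intensity_sigma", lower = 0)
  check_scalar(background_level, "background_level", lower = 0)
  check_scalar(background_jitter_sd, "background_jitter_sd", lower = 0)
  check_scalar(read_noise_sd, "read_noise_sd", lower = 0)
  if (!bit_depth %in% c(8L, 16L)) db_invalid("'bit_depth' must be 8 or 16")
  if (exp(on_intensity_mu) <= blank_mean + 2 * blank_sd)
    warning("'on' intensity median does not exceed blank mean + 2 SD: ",
            "the on/off populations are not separable", call. = FALSE)
  structure(
    list(image_shape = as.integer(image_shape),
         bead_radius_px = bead_radius_px,
         radius_jitter = radius_jitter,
         blank_mean = blank_mean,
         blank_sd = blank_sd,
         on_intensity_mu = on_intensity_mu,
         on_intensity_sigma = on_intensity_sigma,
         background_level = background_level,
         background_jitter_sd = background_jitter_sd,
         read_noise_sd = read_noise_sd,
         bit_depth = as.integer(bit_depth),
         modality = modality),
    class = "optics_params"
  )
}

#' Bead detector parameters
#'
#' Parameterizes the gradient circular Hough detector in [detect_beads()].
#'
#' @param radius_min,radius_max Radius search range in pixels,
#'   `1 <= radius_min <= radius_max`.
#' @param sensitivity Detection threshold knob in (0, 1]; a circle is
#'   reported when its normalized accumulator score (pooled edge votes per
#'   unit perimeter) exceeds `1 - sensitivity`. Higher values accept fainter
#'   circles.
#' @param polarity `"dark"` for dark disks on a bright field (brightfield
#'   localization) or `"bright"` for the darkfield case.
#' @param min_separation Minimum distance between reported centers (pixels);
#'   closer detections are merged keeping the stronger accumulator peak.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(radius_min,
                             radius_max,
                             sensitivity = 0.7,
                             polarity = c("dark", "bright"),
                             min_separation = 1.5 * radius_min) {
  polarity <- match.arg(polarity)
  check_scalar(radius_min, "radius_min", lower = 1)
  check_scalar(radius_max, "radius_max", lower = 1)
  if (radius_min > radius_max)
    db_invalid("'radius_min' must not exceed 'radius_max'")
  check_scalar(sensitivity, "sensitivity")
  if (sensitivity <= 0 || sensitivity > 1)
    db_invalid("'sensitivity' must be in (0, 1]")
  check_scalar(min_separation, "min_separation")
  if (min_separation <= 0) db_invalid("'min_separation' must be > 0")
  structure(
    list(radius_min = radius_min, radius_max = radius_max,
         sensitivity = sensitivity, polarity = polarity,
         min_separation = min_separation),
    class = "detection_params"
  )
}

#' Default detector parameters matched to an optics configuration
#'
#' Radius search range is the nominal bead radius +/- 40%, and polarity
#' follows the localization modality (dark disks in brightfield, bright in
#' darkfield).
#'
#' @param optics An [optics_params()] object.
#' @param sensitivity Passed to [detection_params()].
#' @return A `detection_params` object.
#' @export
detection_params_for <- function(optics, sensitivity = 0.7) {
  stopifnot(inherits(optics, "optics_params"))
  r <- optics$bead_radius_px
  detection_params(
    radius_min = max(1, floor(r * 0.6)),
    radius_max = ceiling(r * 1.4),
    sensitivity = sensitivity,
    polarity = if (optics$modality == "brightfield") "dark" else "bright",
    min_separation = max(2, 1.5 * r)
  )
}

#' @export
print.assay_params <- function(x, ...) {
  cat("Assay parameters\n")
  cat(sprintf("  concentration: %g ng/mL\n", x$concentration))
  cat(sprintf("  capture_coeff: %g per (ng/mL); labeling efficiency: %g\n",
              x$capture_coeff, x$labeling_efficiency))
  cat(sprintf("  n_beads: %d; lambda = %g molecules/bead; seed: %d\n",
              x$n_beads, assay_lambda(x), x$seed))
  invisible(x)
}
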