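# Config-driven orchestration: simulate -> analyze -> calibrate. These are
# the programmatic entry points behind the command-line wrapper in
# inst/cli/digibead.R; each stage exchanges data through documented CSV/TIFF
# files so real micrographs can enter at the analyze stage.

config_get <- function(config, key, default = NULL) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- config
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) {
      if (!is.null(default)) return(default)
      db_stop(sprintf("config is missing required key '%s'", key),
              "digibead_config_error")
    }
    node <- node[[p]]
  }
  node
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is a plain-text YAML key-value file naming the assay
#' conditions, optics, imaging regime, detection parameters and readout
#' mode. Missing optional keys fall back to package defaults; missing
#' required keys raise a config error naming the key.
#'
#' @param path Path to a YAML config file, or a named list already parsed.
#' @return A validated list of parameter objects: `seed`, `concentrations`,
#'   `replicates`, `assay` ([assay_params()] template), `optics`
#'   ([optics_params()]), `detection` ([detection_params()]), `n_frames`,
#'   `imaged_fraction`, `readout_mode`, `sample_volume`.
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(config))
    db_stop("config must be a YAML mapping", "digibead_config_error")

  concentrations <- as.numeric(config_get(config, "conditions.concentrations"))
  replicates <- config_get(config, "conditions.replicates", 3L)
  seed <- config_get(config, "seed", 1L)

  oc <- config_get(config, "optics", list())
  optics <- optics_params(
    image_shape = unlist(config_get(oc, "image_shape", c(256L, 256L))),
    bead_radius_px = config_get(oc, "bead_radius_px", 5),
    radius_jitter = config_get(oc, "radius_jitter", 0.05),
    blank_mean = config_get(oc, "blank_mean", 1500),
    blank_sd = config_get(oc, "blank_sd", 120),
    on_intensity_mu = config_get(oc, "on_intensity_mu", log(8000)),
    on_intensity_sigma = config_get(oc, "on_intensity_sigma", 0.4),
    background_level = config_get(oc, "background_level", 300),
    background_jitter_sd = config_get(oc, "background_jitter_sd", 30),
    read_noise_sd = config_get(oc, "read_noise_sd", 30),
    bit_depth = config_get(oc, "bit_depth", 16L),
    modality = config_get(oc, "modality", "brightfield")
  )

  ac <- config_get(config, "assay", list())
  assay <- assay_params(
    concentration = 0,
    capture_coeff = config_get(ac, "capture_coeff", 0.1),
    n_beads = config_get(ac, "n_beads", 20000L),
    labeling_efficiency = config_get(ac, "labeling_efficiency", 0.8),
    seed = seed
  )

  dc <- config_get(config, "detection", list())
  det_default <- detection_params_for(optics)
  detection <- detection_params(
    radius_min = config_get(dc, "radius_min", det_default$radius_min),
    radius_max = config_get(dc, "radius_max", det_default$radius_max),
    sensitivity = config_get(dc, "sensitivity", det_default$sensitivity),
    polarity = config_get(dc, "polarity", det_default$polarity),
    min_separation = config_get(dc, "min_separation",
                                det_default$min_separation)
  )

  readout_mode <- config_get(config, "readout_mode", "both")
  if (!readout_mode %in% c("digital", "analog", "both"))
    db_stop("config key 'readout_mode' must be digital, analog or both",
            "digibead_config_error")

  list(
    seed = as.integer(seed),
    concentrations = concentrations,
    replicates = as.integer(replicates),
    assay = assay,
    optics = optics,
    detection = detection,
    n_frames = as.integer(config_get(config, "imaging.n_frames", 120L)),
    imaged_fraction = config_get(config, "imaging.imaged_fraction", 0.21),
    readout_mode = readout_mode,
    sample_volume = config_get(config, "sample_volume", 2),
    weighting = config_get(config, "calibration.weighting", "auto")
  )
}

write_resolved_config <- function(cfg, path) {
  out <- list(
    seed = cfg$seed,
    conditions = list(concentrations = cfg$concentrations,
                      replicates = cfg$replicates),
    assay = cfg$assay[c("capture_coeff", "n_beads", "labeling_efficiency")],
    optics = unclass(cfg$optics),
    detection = unclass(cfg$detection),
    imaging = list(n_frames = cfg$n_frames,
                   imaged_fraction = cfg$imaged_fraction),
    readout_mode = cfg$readout_mode,
    sample_volume = cfg$sample_volume
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Simulate a dilution series to disk
#'
#' Stage 1 of the pipeline: generates the configured dilution series with
#' [simulate_dilution_series()], writing per-run TIFF stacks, truth CSVs, a
#' `manifest.csv` and the fully resolved configuration
#' (`run_config.yaml`) to `out_dir`. Reruns with the same config and seed
#' are bit-identical.
#'
#' @param config Path to a YAML config or a parsed list (see
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
cli_simulate <- function(config, out_dir) {
  cfg <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- simulate_dilution_series(
    cfg$concentrations, cfg$assay, cfg$optics,
    replicates = cfg$replicates, n_frames = cfg$n_frames,
    imaged_fraction = cfg$imaged_fraction, seed = cfg$seed, dir = out_dir
  )
  write_resolved_config(cfg, file.path(out_dir, "run_config.yaml"))
  invisible(res$manifest)
}

# Shared analyze core for on-disk manifests and in-memory frame sets.
analyze_runs <- function(runs, cfg) {
  per_bead <- vector("list", length(runs))
  quant <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    det <- detect_frameset(run$frames, cfg$detection)
    det$condition <- run$condition
    det$concentration <- run$concentration
    det$replicate <- run$replicate
    per_bead[[i]] <- det
    analog <- if (cfg$readout_mode %in% c("analog", "both"))
      analog_readout(run$frames$fluorescence_frames)$mean_intensity
    else NA_real_
    quant[[i]] <- data.frame(
      condition = run$condition, concentration = run$concentration,
      replicate = run$replicate, n_detected = nrow(det),
      mean_intensity = analog
    )
  }
  per_bead_df <- do.call(rbind, per_bead)
  quant_df <- do.call(rbind, quant)

  digital <- cfg$readout_mode %in% c("digital", "both")
  quant_df$n_total <- NA_integer_; quant_df$n_on <- NA_integer_
  quant_df$f_on <- NA_real_; quant_df$amb <- NA_real_
  quant_df$saturated <- NA
  if (digital) {
    blank_int <- per_bead_df$max_intensity[per_bead_df$concentration == 0]
    if (length(blank_int) == 0L)
      db_stop("digital readout requires a blank (zero concentration) condition",
              "digibead_config_error")
    blank <- fit_blank(blank_int)
    for (i in seq_len(nrow(quant_df))) {
      ints <- per_bead_df$max_intensity[
        per_bead_df$condition == quant_df$condition[i] &
          per_bead_df$replicate == quant_df$replicate[i]]
      if (length(ints) == 0L) next
      cls <- classify_beads(ints, blank)
      dig <- compute_amb(cls$n_on, cls$n_total)
      quant_df$n_total[i] <- dig$n_total
      quant_df$n_on[i] <- dig$n_on
      quant_df$f_on[i] <- dig$f_on
      quant_df$amb[i] <- dig$amb
      quant_df$saturated[i] <- dig$saturated
    }
    attr(quant_df, "blank_model") <- blank
  }
  list(per_bead = per_bead_df, quantification = quant_df)
}

#' Analyze micrographs into digital and analog readouts
#'
#' Stage 2 of the pipeline: reads the manifest and TIFF stacks in
#' `image_dir`, detects beads in every localization frame, extracts per-bead
#' maximum fluorescence, fits the blank threshold from the pooled blank
#' condition, classifies beads and computes per-run `f_on`/AMB (digital) and
#' the frame-mean intensity (analog). Writes `beads.csv` (one row per
#' detected bead) and `quantification.csv` (one row per condition x
#' replicate) to `out_dir`.
#'
#' @param config Path to a YAML config or a parsed list.
#' @param image_dir Directory holding `manifest.csv` and the TIFF stacks
#'   (as written by [cli_simulate()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of the two result data.frames.
#' @export
cli_analyze <- function(config, image_dir, out_dir) {
  cfg <- read_run_config(config)
  manifest_path <- file.path(image_dir, "manifest.csv")
  if (!file.exists(manifest_path))
    db_stop(sprintf("no manifest.csv found in '%s'", image_dir),
            "digibead_empty_input")
  manifest <- utils::read.csv(manifest_path)
  if (nrow(manifest) == 0L)
    db_stop("manifest is empty: no image stacks to analyze",
            "digibead_empty_input")
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    list(
      condition = manifest$condition[i],
      concentration = manifest$concentration[i],
      replicate = manifest$replicate[i],
      frames = read_frameset(
        file.path(image_dir, manifest$localization_file[i]),
        file.path(image_dir, manifest$fluorescence_file[i]),
        bit_depth = cfg$optics$bit_depth
      )
    )
  })
  res <- analyze_runs(runs, cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(res$per_bead, file.path(out_dir, "beads.csv"),
                   row.names = FALSE)
  utils::write.csv(res$quantification,
                   file.path(out_dir, "quantification.csv"),
                   row.names = FALSE)
  invisible(res)
}

# Calibrate one readout column of a quantification table.
#
# For the digital (AMB) readout the response variance is known from counting
# statistics and spans orders of magnitude across a dilution ladder, so the
# fit is weighted by the inverse squared delta-method SE by default
# (`weighting = "binomial"`); saturated points (f_on at the all-on guard)
# carry only a lower bound and are excluded from the fit. The analog readout
# is roughly homoscedastic and is fitted unweighted.
calibrate_readout <- function(quant, response_col, sample_volume,
                              weighting = c("auto", "binomial", "none")) {
  weighting <- match.arg(weighting)
  ok <- is.finite(quant[[response_col]])
  q <- quant[ok, , drop = FALSE]
  digital <- response_col == "amb"
  if (digital && "saturated" %in% names(q))
    q <- q[!(q$saturated %in% TRUE), , drop = FALSE]
  x <- q$concentration
  y <- q[[response_col]]
  blank_y <- y[x == 0]
  if (length(blank_y) < 2L)
    db_stop("calibration needs at least 2 blank replicates for the LOD level",
            "digibead_insufficient_blank")
  use_binomial <- (weighting == "binomial") ||
    (weighting == "auto" && digital &&
       all(c("f_on", "n_total") %in% names(q)))
  w <- NULL
  if (use_binomial) {
    if (!all(c("f_on", "n_total") %in% names(q)))
      db_invalid("binomial weighting needs 'f_on' and 'n_total' columns")
    # clamp f_on away from {0, 1} so every point keeps a finite weight
    f_eff <- pmin(pmax(q$f_on, 0.5 / q$n_total), 1 - 0.5 / q$n_total)
    w <- 1 / amb_se(f_eff, q$n_total)^2
  }
  fit <- fit_4pl(x, y, weights = w)
  lod <- compute_lod(fit, mean(blank_y), stats::sd(blank_y),
                     sample_volume = sample_volume)
  list(fit = fit, lod = lod,
       report = data.frame(
         readout = response_col,
         a = fit$a, b = fit$b, c = fit$c, d = fit$d, rss = fit$rss,
         n_points = fit$n_points,
         blank_mean = mean(blank_y), blank_sd = stats::sd(blank_y),
         y_lod = lod$y_lod,
         lod_concentration = lod$lod_concentration,
         lod_mass = lod$lod_mass,
         sample_volume = lod$sample_volume
       ))
}

#' Calibrate readouts and compute limits of detection
#'
#' Stage 3 of the pipeline: fits a 4PL curve to each configured readout
#' (AMB for digital, mean intensity for analog) against concentration using
#' all replicate points, computes the LOD at three blank SDs above the blank
#' mean, and writes `calibration.csv` to `out_dir`.
#'
#' @param config Path to a YAML config or a parsed list.
#' @param quant Path to a `quantification.csv` from [cli_analyze()], or the
#'   data.frame itself.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with per-readout `fit`/`lod` objects and the
#'   combined report data.frame.
#' @export
cli_calibrate <- function(config, quant, out_dir) {
  cfg <- read_run_config(config)
  if (is.character(quant)) quant <- utils::read.csv(quant)
  results <- list()
  reports <- list()
  if (cfg$readout_mode %in% c("digital", "both")) {
    results$digital <- calibrate_readout(quant, "amb", cfg$sample_volume,
                                         weighting = cfg$weighting)
    reports <- c(reports, list(results$digital$report))
  }
  if (cfg$readout_mode %in% c("analog", "both")) {
    results$analog <- calibrate_readout(quant, "mean_intensity",
                                        cfg$sample_volume,
                                        weighting = "none")
    reports <- c(reports, list(results$analog$report))
  }
  report <- do.call(rbind, reports)
  report$readout <- ifelse(report$readout == "amb", "digital", "analog")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report, file.path(out_dir, "calibration.csv"),
                   row.names = FALSE)
  results$report <- report
  invisible(results)
}
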