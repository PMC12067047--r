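#' Simulate Poisson loading of analyte molecules onto beads
#'
#' Draws the number of labeled analyte molecules captured by each bead as
#' i.i.d. Poisson with mean \eqn{\lambda = \kappa C \eta} (see
#' [assay_params()]). A bead carrying at least one labeled molecule is "on":
#' amplification renders any single molecule detectable, which is the premise
#' that makes the on-fraction invertible to \eqn{\lambda} via
#' \eqn{AMB = -\ln(1 - f_{on})}.
#'
#' @param params An [assay_params()] object.
#' @return An object of class `bead_population` with elements
#'   `counts` (integer molecules per bead), `on_truth` (logical,
#'   `counts >= 1`), `lambda_true` (the Poisson mean used) and `params`.
#' @export
#' @examples
#' pop <- simulate_bead_loading(assay_params(concentration = 5, seed = 42))
#' mean(pop$on_truth)            # ~ 1 - exp(-lambda)
#' 1 - exp(-pop$lambda_true)
simulate_bead_loading <- function(params) {
  if (!inherits(params, "assay_params"))
    db_invalid("'params' must be an 'assay_params' object")
  lambda <- assay_lambda(params)
  counts <- with_seed(params$seed,
                      stats::rpois(params$n_beads, lambda))
  structure(
    list(counts = as.integer(counts),
         on_truth = counts >= 1L,
         lambda_true = lambda,
         params = params),
    class = "bead_population"
  )
}

#' @export
print.bead_population <- function(x, ...) {
  cat(sprintf("Bead population: %d beads, lambda = %g, %d (%.2f%%) on\n",
              length(x$counts), x$lambda_true, sum(x$on_truth),
              100 * mean(x$on_truth)))
  invisible(x)
}

# Rejection-sample non-overlapping centers for one frame.
# Coordinates are 0-based, center-of-pixel; a center must lie at least its
# radius inside the frame so no ground-truth bead is clipped.
place_beads <- function(radii, shape, sep_factor = 2.2, max_attempts = 200,
                        allow_overlap = FALSE, frame = NA_integer_) {
  n <- length(radii)
  rows <- numeric(n)
  cols <- numeric(n)
  h <- shape[1]; w <- shape[2]
  for (i in seq_len(n)) {
    r <- radii[i]
    if (2 * r >= h - 1 || 2 * r >= w - 1)
      db_stop(sprintf("bead radius %.2f px does not fit in a %dx%d frame",
                      r, h, w), "digibead_placement_failure")
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      pr <- stats::runif(1, r, (h - 1) - r)
      pc <- stats::runif(1, r, (w - 1) - r)
      if (!allow_overlap && i > 1L) {
        j <- seq_len(i - 1L)
        d2 <- (rows[j] - pr)^2 + (cols[j] - pc)^2
        lim <- (sep_factor * pmax(radii[j], r))^2
        if (any(d2 < lim)) next
      }
      rows[i] <- pr; cols[i] <- pc
      placed <- TRUE
      break
    }
    if (!placed)
      db_stop(sprintf(
        "could not place bead %d of %d in frame %d after %d attempts; reduce bead density or frame count",
        i, n, frame, max_attempts), "digibead_placement_failure")
  }
  list(row = rows, col = cols)
}

# Paint a disk into matrix `m` (1-based R indexing over 0-based pixel
# centers), keeping the pixel-wise maximum of `value` and the existing
# content so overlapping disks compose sensibly.
paint_disk <- function(m, row0, col0, radius, value) {
  h <- nrow(m); w <- ncol(m)
  r1 <- max(1L, floor(row0 - radius) + 1L); r2 <- min(h, ceiling(row0 + radius) + 1L)
  c1 <- max(1L, floor(col0 - radius) + 1L); c2 <- min(w, ceiling(col0 + radius) + 1L)
  rr <- (r1:r2) - 1L
  cc <- (c1:c2) - 1L
  mask <- outer((rr - row0)^2, (cc - col0)^2, `+`) <= radius^2
  sub <- m[r1:r2, c1:c2, drop = FALSE]
  sub[mask] <- pmax(sub[mask], value)
  m[r1:r2, c1:c2] <- sub
  m
}

#' Render a bead population into micrograph frame pairs
#'
#' Draws a Binomial(`n_beads`, `imaged_fraction`) subset of the population,
#' spreads it uniformly over `n_frames` fields of view, and renders each
#' field as a co-registered localization/fluorescence image pair. This
#' emulates the acquisition regime in which only a fraction of the bead
#' suspension (around 21% across 100--150 fields) is ever imaged.
#'
#' Centers are rejection-sampled so that no two beads in a frame are closer
#' than 2.2x their radius and no bead is clipped by the frame border
#' (overlapping placements can be enabled with `allow_overlap = TRUE` for
#' stress testing). In the localization channel each bead is a filled disk
#' contrasted against the field (dark-on-bright for brightfield,
#' bright-on-dark for darkfield). In the fluorescence channel each bead is a
#' flat disk whose maximum pixel equals its drawn peak intensity: "off"
#' beads draw peaks from Normal(`blank_mean`, `blank_sd`), "on" beads from
#' LogNormal(`on_intensity_mu`, `on_intensity_sigma`). Frames add a per-frame
#' background offset, per-pixel Gaussian read noise, and are clipped to the
#' bit range.
#'
#' @param population A [simulate_bead_loading()] result.
#' @param optics An [optics_params()] object.
#' @param n_frames Number of fields of view (>= 1).
#' @param imaged_fraction Fraction of the population imaged, in (0, 1].
#' @param seed Integer RNG seed for placement, intensities and noise.
#' @param allow_overlap Allow beads to overlap (default FALSE).
#' @return An object of class `frame_set`: lists `localization_frames` and
#'   `fluorescence_frames` of numeric matrices (a.u., row = image row), and
#'   `truth_table`, a data.frame with one row per rendered bead
#'   (`frame`, 1-based; `row`, `col` 0-based pixel-center coordinates;
#'   `radius` px; `on`; `peak` a.u.; `count` molecules).
#' @export
render_frames <- function(population, optics, n_frames = 120L,
                          imaged_fraction = 0.21, seed = 1L,
                          allow_overlap = FALSE) {
  if (!inherits(population, "bead_population"))
    db_invalid("'population' must be a 'bead_population' object")
  if (!inherits(optics, "optics_params"))
    db_invalid("'optics' must be an 'optics_params' object")
  check_scalar(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar(imaged_fraction, "imaged_fraction")
  if (imaged_fraction <= 0 || imaged_fraction > 1)
    db_invalid("'imaged_fraction' must be in (0, 1]")
  check_scalar(seed, "seed", integer = TRUE)

  n_frames <- as.integer(n_frames)
  shape <- optics$image_shape
  maxval <- 2^optics$bit_depth - 1
  n_beads <- length(population$counts)

  with_seed(seed, {
    n_imaged <- stats::rbinom(1L, n_beads, imaged_fraction)
    idx <- if (n_imaged > 0L) sort(sample.int(n_beads, n_imaged)) else integer(0)
    frame_of <- if (n_imaged > 0L)
      sample.int(n_frames, n_imaged, replace = TRUE) else integer(0)
    radii <- pmax(1, optics$bead_radius_px *
                    (1 + stats::rnorm(n_imaged, 0, optics$radius_jitter)))
    on <- population$on_truth[idx]
    peaks <- numeric(n_imaged)
    peaks[!on] <- stats::rnorm(sum(!on), optics$blank_mean, optics$blank_sd)
    peaks[on] <- stats::rlnorm(sum(on), optics$on_intensity_mu,
                               optics$on_intensity_sigma)
    peaks <- pmin(pmax(peaks, 0), maxval)

    # localization channel contrast levels
    if (optics$modality == "brightfield") {
      loc_bg <- 0.70 * maxval; loc_disk <- 0.20 * maxval
    } else {
      loc_bg <- 0.05 * maxval; loc_disk <- 0.60 * maxval
    }

    loc_frames <- vector("list", n_frames)
    flu_frames <- vector("list", n_frames)
    truth <- vector("list", n_frames)

    for (f in seq_len(n_frames)) {
      in_f <- which(frame_of == f)
      pos <- place_beads(radii[in_f], shape, allow_overlap = allow_overlap,
                         frame = f)
      bg_offset <- stats::rnorm(1, 0, optics$background_jitter_sd)

      loc <- matrix(loc_bg, shape[1], shape[2])
      flu <- matrix(optics$background_level + bg_offset, shape[1], shape[2])
      for (k in seq_along(in_f)) {
        i <- in_f[k]
        if (optics$modality == "brightfield") {
          # dark disk: paint_disk keeps the max, so paint on a negated image
          loc <- -paint_disk(-loc, pos$row[k], pos$col[k], radii[i], -loc_disk)
        } else {
          loc <- paint_disk(loc, pos$row[k], pos$col[k], radii[i], loc_disk)
        }
        # bead signal rides on the frame background offset so that with zero
        # jitter and zero noise the disk maximum equals the drawn peak exactly
        flu <- paint_disk(flu, pos$row[k], pos$col[k], radii[i],
                          peaks[i] + bg_offset)
      }
      if (optics$read_noise_sd > 0) {
        npx <- length(loc)
        loc <- loc + stats::rnorm(npx, 0, optics$read_noise_sd)
        flu <- flu + stats::rnorm(npx, 0, optics$read_noise_sd)
      }
      loc_frames[[f]] <- pmin(pmax(loc, 0), maxval)
      flu_frames[[f]] <- pmin(pmax(flu, 0), maxval)
      truth[[f]] <- data.frame(
        frame = rep.int(f, length(in_f)),
        row = pos$row, col = pos$col, radius = radii[in_f],
        on = on[in_f], peak = peaks[in_f],
        count = population$counts[idx[in_f]]
      )
    }

    structure(
      list(localization_frames = loc_frames,
           fluorescence_frames = flu_frames,
           truth_table = do.call(rbind, truth),
           optics = optics,
           n_frames = n_frames,
           imaged_fraction = imaged_fraction,
           seed = as.integer(seed)),
      class = "frame_set"
    )
  })
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("Frame set: %d frame pairs (%dx%d, %s), %d rendered beads\n",
              x$n_frames, x$optics$image_shape[1], x$optics$image_shape[2],
              x$optics$modality, nrow(x$truth_table)))
  invisible(x)
}

#' Simulate a dilution series of bead assays
#'
#' Generates one [render_frames()] frame set per (concentration, replicate)
#' pair, with per-run seeds derived reproducibly from `seed`, plus a manifest
#' describing every run. This is the standard calibration layout: a blank
#' (zero concentration) plus a ladder of positive concentrations, each with
#' `replicates` independent assays.
#'
#' @param concentrations Non-negative concentrations (ng/mL); the first entry
#'   may be 0 (blank). Sorted internally.
#' @param params_base An [assay_params()] template; its `concentration` and
#'   `seed` fields are overridden per run.
#' @param optics An [optics_params()] object.
#' @param replicates Replicates per positive concentration (integer >= 1).
#' @param blank_replicates Replicates for the blank (zero) condition;
#'   defaults to `replicates`. Limit-of-detection protocols commonly measure
#'   the blank more often than the calibrators, since the blank SD enters
#'   the LOD directly and is poorly estimated from few replicates.
#' @param n_frames,imaged_fraction Passed to [render_frames()].
#' @param seed Master seed; the same master seed reproduces the whole series
#'   bit-for-bit.
#' @param dir If non-NULL, each frame set is written to disk as TIFF stacks
#'   plus truth/manifest CSVs (see [write_frameset()]) and frame sets are not
#'   kept in memory.
#' @return A list with `manifest` (data.frame: `condition`, `concentration`,
#'   `replicate`, seeds, bead counts and, when `dir` is used, file names) and
#'   `framesets` (list of `frame_set` objects, or NULL when writing to
#'   `dir`).
#' @export
simulate_dilution_series <- function(concentrations, params_base, optics,
                                     replicates = 3L,
                                     blank_replicates = replicates,
                                     n_frames = 120L,
                                     imaged_fraction = 0.21, seed = 1L,
                                     dir = NULL) {
  if (length(concentrations) == 0L)
    db_invalid("'concentrations' must be a non-empty numeric vector")
  if (!is.numeric(concentrations) || any(!is.finite(concentrations)) ||
      any(concentrations < 0))
    db_invalid("'concentrations' must be finite and non-negative")
  if (!inherits(params_base, "assay_params"))
    db_invalid("'params_base' must be an 'assay_params' object")
  check_scalar(replicates, "replicates", lower = 1, integer = TRUE)
  check_scalar(blank_replicates, "blank_replicates", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  concentrations <- sort(concentrations)
  replicates <- as.integer(replicates)
  blank_replicates <- as.integer(blank_replicates)
  reps_of <- ifelse(concentrations == 0, blank_replicates, replicates)

  n_runs <- sum(reps_of)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max, 2L * n_runs),
                                  nrow = n_runs))
  to_disk <- !is.null(dir)
  if (to_disk && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  rows <- vector("list", n_runs)
  framesets <- if (to_disk) NULL else vector("list", n_runs)
  run <- 0L
  for (ci in seq_along(concentrations)) {
    for (rep_i in seq_len(reps_of[ci])) {
      run <- run + 1L
      p <- params_base
      p$concentration <- concentrations[ci]
      p$seed <- seeds[run, 1L]
      pop <- simulate_bead_loading(p)
      fs <- render_frames(pop, optics, n_frames = n_frames,
                          imaged_fraction = imaged_fraction,
                          seed = seeds[run, 2L])
      row <- data.frame(
        condition = ci,
        concentration = concentrations[ci],
        replicate = rep_i,
        seed_loading = seeds[run, 1L],
        seed_render = seeds[run, 2L],
        n_beads = p$n_beads,
        n_rendered = nrow(fs$truth_table),
        localization_file = NA_character_,
        fluorescence_file = NA_character_,
        truth_file = NA_character_
      )
      if (to_disk) {
        stem <- sprintf("c%02d_r%02d", ci, rep_i)
        row$localization_file <- paste0(stem, "_loc.tif")
        row$fluorescence_file <- paste0(stem, "_flu.tif")
        row$truth_file <- paste0(stem, "_truth.csv")
        write_frameset(fs,
                       file.path(dir, row$localization_file),
                       file.path(dir, row$fluorescence_file),
                       file.path(dir, row$truth_file))
      } else {
        framesets[[run]] <- fs
      }
      rows[[run]] <- row
    }
  }
  manifest <- do.call(rbind, rows)
  if (to_disk)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, framesets = framesets)
}
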