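dp_default <- detection_params(radius_min = 3, radius_max = 7,
                               polarity = "dark", min_separation = 7)

test_that("blank, constant and invalid frames are handled", {
  expect_identical(nrow(detect_beads(matrix(100, 64, 64), dp_default)), 0L)

  # background + read noise only, no beads
  opt <- optics_params(image_shape = c(64L, 64L))
  pop <- simulate_bead_loading(assay_params(concentration = 0, n_beads = 1L,
                                            seed = 1L))
  fs <- render_frames(pop, opt, n_frames = 1, imaged_fraction = 1e-9,
                      seed = 2L)
  expect_identical(nrow(detect_beads(fs$localization_frames[[1]], dp_default)),
                   0L)

  expect_error(detection_params(radius_min = 7, radius_max = 3),
               class = "digibead_invalid_parameter")
  bad <- matrix(1, 8, 8); bad[3, 3] <- NA
  expect_error(detect_beads(bad, dp_default),
               class = "digibead_invalid_parameter")
})

test_that("noiseless disks are recovered with sub-pixel accuracy", {
  opt <- noiseless_optics(image_shape = c(128L, 128L), bead_radius_px = 6)
  pop <- simulate_bead_loading(assay_params(concentration = 100,
                                            n_beads = 3L, seed = 11L))
  fs <- render_frames(pop, opt, n_frames = 1, imaged_fraction = 1, seed = 12L)
  dp <- detection_params_for(opt)
  det <- detect_beads(fs$localization_frames[[1]], dp)
  expect_identical(nrow(det), 3L)
  m <- match_detections(det, fs$truth_table, tol = 1.5)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_lt(max(m$center_err), 1)
  expect_lt(max(m$radius_err), 1)
})

test_that("dense noisy fields meet the recall and count contracts", {
  # ~200 beads at the default subsampling-regime density, default noise
  opt <- optics_params(image_shape = c(256L, 256L), bead_radius_px = 5)
  pop <- simulate_bead_loading(assay_params(concentration = 5,
                                            n_beads = 200L, seed = 41L))
  fs <- render_frames(pop, opt, n_frames = 6, imaged_fraction = 1, seed = 42L)
  det <- detect_frameset(fs, detection_params_for(opt))
  m <- match_detections(det, fs$truth_table, tol = 2)
  expect_gte(m$recall, 0.95)
  n_true <- nrow(fs$truth_table)
  expect_lte(abs(nrow(det) - n_true) / n_true, 0.05)
})

test_that("max intensity equals the brute-force pixel enumeration oracle", {
  set.seed(314)
  frame <- matrix(runif(200 * 180, 0, 1e4), 200, 180)
  n <- 100
  det <- data.frame(
    row = runif(n, 10, 189), col = runif(n, 10, 169),
    radius = runif(n, 2, 8), score = 1
  )
  got <- extract_bead_intensity(det, frame)
  # oracle: test every pixel center of the whole frame against the circle
  rows0 <- matrix(0:199, 200, 180)
  cols0 <- matrix(0:179, 200, 180, byrow = TRUE)
  for (i in seq_len(n)) {
    mask <- (rows0 - det$row[i])^2 + (cols0 - det$col[i])^2 <= det$radius[i]^2
    expect_identical(got$max_intensity[i], max(frame[mask]))
  }
  expect_identical(got[, c("row", "col", "radius")],
                   det[, c("row", "col", "radius")])
})

test_that("uniform and noiseless fluorescence give exact intensities", {
  det <- data.frame(row = c(20, 40), col = c(20, 40), radius = c(5, 6))
  uni <- matrix(123.5, 64, 64)
  expect_equal(extract_bead_intensity(det, uni)$max_intensity, c(123.5, 123.5))

  opt <- noiseless_optics(image_shape = c(128L, 128L), bead_radius_px = 5)
  pop <- simulate_bead_loading(assay_params(concentration = 50,
                                            n_beads = 10L, seed = 51L))
  fs <- render_frames(pop, opt, n_frames = 1, imaged_fraction = 1, seed = 52L)
  det <- detect_beads(fs$localization_frames[[1]], detection_params_for(opt))
  det <- extract_bead_intensity(det, fs$fluorescence_frames[[1]])
  m <- match_detections(det, fs$truth_table, tol = 1.5)
  expect_equal(m$recall, 1)
  # every truth peak appears among the extracted maxima, exactly
  expect_true(all(fs$truth_table$peak %in% det$max_intensity))
})

test_that("frameset detection is stateless, frame-wise and offset-invariant", {
  opt <- noiseless_optics(image_shape = c(96L, 96L), bead_radius_px = 5)
  pop <- simulate_bead_loading(assay_params(concentration = 20,
                                            n_beads = 12L, seed = 61L))
  fs <- render_frames(pop, opt, n_frames = 2, imaged_fraction = 1, seed = 62L)
  per_frame <- table(fs$truth_table$frame)
  dp <- detection_params_for(opt)

  det1 <- detect_frameset(fs, dp)
  det2 <- detect_frameset(fs, dp)
  expect_identical(det1, det2)
  expect_identical(nrow(det1), nrow(fs$truth_table))
  expect_identical(as.integer(table(det1$frame_index)),
                   as.integer(per_frame))

  # image-wide intensity offset within the bit range changes nothing
  shifted <- fs
  shifted$localization_frames <- lapply(fs$localization_frames, `+`, 500)
  det3 <- detect_frameset(shifted, dp)
  expect_equal(det3[, c("row", "col", "radius")],
               det1[, c("row", "col", "radius")])

  # zero frames and channel mismatches
  empty_fs <- list(localization_frames = list(), fluorescence_frames = list())
  expect_identical(nrow(detect_frameset(empty_fs, dp)), 0L)
  bad <- list(localization_frames = fs$localization_frames,
              fluorescence_frames = fs$fluorescence_frames[1])
  expect_error(detect_frameset(bad, dp), class = "digibead_structural_error")
})
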