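test_that("zero concentration yields an all-off population and bad inputs error", {
  pop <- simulate_bead_loading(assay_params(concentration = 0, n_beads = 500))
  expect_true(all(pop$counts == 0L))
  expect_false(any(pop$on_truth))
  expect_identical(pop$lambda_true, 0)

  expect_error(assay_params(concentration = -1),
               class = "digibead_invalid_parameter")
  expect_error(assay_params(concentration = NaN),
               class = "digibead_invalid_parameter")
  expect_error(assay_params(concentration = 1, labeling_efficiency = 1.2),
               class = "digibead_invalid_parameter")
  expect_error(assay_params(concentration = 1, capture_coeff = 0),
               class = "digibead_invalid_parameter")
})

test_that("Poisson loading matches the closed-form on-fraction and is seed-pure", {
  # lambda = 0.5: P(count >= 1) = 1 - exp(-0.5)
  p <- assay_params(concentration = 0.5, capture_coeff = 1,
                    labeling_efficiency = 1, n_beads = 1e6L, seed = 101L)
  pop <- simulate_bead_loading(p)
  expect_equal(pop$lambda_true, 0.5)
  p_on <- 1 - exp(-0.5)
  se <- sqrt(p_on * (1 - p_on) / 1e6)
  expect_lt(abs(mean(pop$on_truth) - p_on), 3 * se)
  expect_true(all(pop$on_truth == (pop$counts >= 1L)))

  # oracle: an independent second draw with the same seed is bit-identical
  p2 <- assay_params(concentration = 0.1, capture_coeff = 1,
                     labeling_efficiency = 1, n_beads = 1e5L, seed = 77L)
  expect_identical(simulate_bead_loading(p2)$counts,
                   simulate_bead_loading(p2)$counts)
  p3 <- p2; p3$seed <- 78L
  expect_false(identical(simulate_bead_loading(p2)$counts,
                         simulate_bead_loading(p3)$counts))

  # the generator must not disturb the caller's RNG stream
  set.seed(5); before <- .Random.seed
  invisible(simulate_bead_loading(p2))
  expect_identical(before, .Random.seed)
})

test_that("empirical on-probability tracks 1 - exp(-lambda) across the dynamic range", {
  for (lambda in c(0.01, 0.1, 0.5, 1, 3)) {
    p <- assay_params(concentration = lambda, capture_coeff = 1,
                      labeling_efficiency = 1, n_beads = 1e5L,
                      seed = 1000L + round(100 * lambda))
    pop <- simulate_bead_loading(p)
    p_on <- 1 - exp(-lambda)
    se <- sqrt(p_on * (1 - p_on) / 1e5)
    expect_lt(abs(mean(pop$on_truth) - p_on), 4 * se)
  }
})

test_that("noiseless rendering reproduces truth geometry and exact peaks", {
  opt <- noiseless_optics(image_shape = c(128L, 128L), bead_radius_px = 5)

  # empty population: pure background, empty truth
  pop0 <- simulate_bead_loading(assay_params(concentration = 0, n_beads = 1L))
  pop0$counts <- integer(0); pop0$on_truth <- logical(0)
  fs0 <- render_frames(pop0, opt, n_frames = 2, imaged_fraction = 1, seed = 1)
  expect_identical(nrow(fs0$truth_table), 0L)
  expect_true(all(vapply(fs0$fluorescence_frames,
                         function(m) all(m == opt$background_level),
                         logical(1))))

  # 50 beads, all imaged, one frame: 50 disks with exact fluorescence peaks
  pop <- simulate_bead_loading(assay_params(concentration = 10,
                                            capture_coeff = 0.1,
                                            n_beads = 50L, seed = 3L))
  fs <- render_frames(pop, opt, n_frames = 1, imaged_fraction = 1, seed = 9L)
  tt <- fs$truth_table
  expect_identical(nrow(tt), 50L)
  flu <- fs$fluorescence_frames[[1]]
  for (i in seq_len(nrow(tt))) {
    rr <- seq(max(0, floor(tt$row[i] - tt$radius[i])),
              min(127, ceiling(tt$row[i] + tt$radius[i])))
    cc <- seq(max(0, floor(tt$col[i] - tt$radius[i])),
              min(127, ceiling(tt$col[i] + tt$radius[i])))
    mask <- outer((rr - tt$row[i])^2, (cc - tt$col[i])^2, `+`) <= tt$radius[i]^2
    expect_equal(max(flu[rr + 1, cc + 1][mask]), tt$peak[i])
  }

  # placement invariants: in-bounds with no clipping, 2.2x radius separation
  expect_true(all(tt$row >= tt$radius & tt$row <= 127 - tt$radius))
  expect_true(all(tt$col >= tt$radius & tt$col <= 127 - tt$radius))
  d <- as.matrix(dist(cbind(tt$row, tt$col)))
  lim <- 2.2 * outer(tt$radius, tt$radius, pmax)
  off_diag <- upper.tri(d)
  expect_true(all(d[off_diag] >= lim[off_diag]))
})

test_that("frame subsampling follows the binomial imaged-fraction regime", {
  # ~21% of 1e4 beads imaged across 120 fields
  opt <- optics_params(image_shape = c(128L, 128L), bead_radius_px = 4)
  pop <- simulate_bead_loading(assay_params(concentration = 1, n_beads = 1e4L,
                                            seed = 21L))
  fs <- render_frames(pop, opt, n_frames = 120, imaged_fraction = 0.21,
                      seed = 22L)
  expected <- 1e4 * 0.21
  se <- sqrt(1e4 * 0.21 * 0.79)
  expect_lt(abs(nrow(fs$truth_table) - expected), 3 * se)
  expect_identical(length(fs$localization_frames), 120L)
  expect_identical(length(fs$fluorescence_frames), 120L)

  # infeasible density fails loudly, naming the frame
  tiny <- optics_params(image_shape = c(32L, 32L), bead_radius_px = 6)
  big <- simulate_bead_loading(assay_params(concentration = 1, n_beads = 200L,
                                            seed = 4L))
  expect_error(render_frames(big, tiny, n_frames = 1, imaged_fraction = 1,
                             seed = 5L),
               class = "digibead_placement_failure")
})

test_that("dilution series is counted, blank-true and master-seed deterministic", {
  opt <- optics_params(image_shape = c(64L, 64L), bead_radius_px = 3)
  base <- assay_params(concentration = 0, n_beads = 100L)

  sim <- simulate_dilution_series(c(0, 1, 2, 5, 10, 20), base, opt,
                                  replicates = 3, n_frames = 2,
                                  imaged_fraction = 0.5, seed = 31L)
  expect_identical(nrow(sim$manifest), 18L)
  expect_identical(length(sim$framesets), 18L)

  blanks <- simulate_dilution_series(0, base, opt, replicates = 3,
                                     n_frames = 2, imaged_fraction = 0.5,
                                     seed = 32L)
  expect_identical(nrow(blanks$manifest), 3L)
  for (fs in blanks$framesets) expect_false(any(fs$truth_table$on))

  again <- simulate_dilution_series(c(0, 1, 2, 5, 10, 20), base, opt,
                                    replicates = 3, n_frames = 2,
                                    imaged_fraction = 0.5, seed = 31L)
  expect_identical(sim$manifest, again$manifest)
  expect_identical(sim$framesets[[7]]$fluorescence_frames,
                   again$framesets[[7]]$fluorescence_frames)
  expect_identical(sim$framesets[[7]]$truth_table,
                   again$framesets[[7]]$truth_table)

  expect_error(simulate_dilution_series(numeric(0), base, opt),
               class = "digibead_invalid_parameter")
})
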