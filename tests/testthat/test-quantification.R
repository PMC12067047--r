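test_that("blank fit is the moment Gaussian with a mean + 2 SD threshold", {
  x <- c(90, 100, 110)  # sample mean 100, n-1 SD 10
  bm <- fit_blank(x, min_beads = 3)
  expect_equal(bm$mu_blank, 100)
  expect_equal(bm$sigma_blank, 10)
  expect_equal(bm$threshold, 120)
  expect_identical(bm$n_blank_beads, 3L)

  # sampling oracle: 1e5 draws recover (mu, sigma) within 3 SE
  set.seed(8)
  y <- rnorm(1e5, 200, 15)
  bm2 <- fit_blank(y)
  expect_lt(abs(bm2$mu_blank - 200), 3 * 15 / sqrt(1e5))
  expect_lt(abs(bm2$sigma_blank - 15), 3 * 15 / sqrt(2 * 1e5))
  # refitting the same list is bit-identical
  expect_identical(fit_blank(y), bm2)

  expect_error(fit_blank(rep(5, 100)), class = "digibead_degenerate_blank")
  expect_error(fit_blank(rnorm(10)), class = "digibead_insufficient_blank")
})

test_that("classification is strictly above-threshold", {
  bm <- list(threshold = 20)
  expect_identical(classify_beads(c(5, 25), bm),
                   list(n_on = 1L, n_total = 2L))
  expect_identical(classify_beads(rep(20, 10), bm)$n_on, 0L)
  expect_error(classify_beads(numeric(0), bm), class = "digibead_empty_input")

  # Gaussian tail oracle: true blanks cross their own 2-sigma threshold at
  # rate 0.02275 (one-tailed)
  set.seed(9)
  blanks <- rnorm(1e5, 1500, 120)
  cls <- classify_beads(blanks, fit_blank(blanks))
  p <- 1 - pnorm(2)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(cls$n_on / cls$n_total - p), 3 * se)
})

test_that("AMB is the Poisson inversion, with a saturation guard", {
  expect_equal(compute_amb(0, 1000)$amb, 0)
  expect_equal(amb_from_fraction(1 - exp(-1)), 1, tolerance = 1e-12)
  # high-precision oracle: -ln(0.95)
  expect_equal(compute_amb(50, 1000)$amb, 0.051293294387550578,
               tolerance = 1e-12)
  expect_equal(compute_amb(50, 1000)$f_on, 0.05)

  # monotone in f_on
  ambs <- vapply(0:98, function(k) compute_amb(k, 100)$amb, numeric(1))
  expect_true(all(diff(ambs) > 0))

  # saturation: all-on (or within one bead) is capped and flagged
  sat <- compute_amb(1000, 1000)
  expect_true(sat$saturated)
  expect_equal(sat$amb, -log1p(-999.5 / 1000))
  expect_true(compute_amb(999, 1000)$saturated)
  expect_false(compute_amb(998, 1000)$saturated)
  expect_true(is.finite(sat$amb))

  expect_error(compute_amb(11, 10), class = "digibead_invalid_count")
})

test_that("analog readout is the grand pixel mean over all frames", {
  expect_equal(analog_readout(list(matrix(7.5, 4, 4)))$mean_intensity, 7.5)
  expect_equal(analog_readout(list(matrix(10, 4, 4),
                                   matrix(30, 4, 4)))$mean_intensity, 20)

  set.seed(10)
  frames <- lapply(1:5, function(i) matrix(runif(300), 20, 15))
  got <- analog_readout(frames)
  # brute-force oracle over the concatenated pixel vector
  expect_equal(got$mean_intensity, mean(unlist(frames)))
  expect_identical(got$n_frames, 5L)
  # order invariance
  expect_equal(analog_readout(rev(frames))$mean_intensity,
               got$mean_intensity)

  expect_error(analog_readout(list()), class = "digibead_empty_input")
  expect_error(analog_readout(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               class = "digibead_invalid_parameter")
})

test_that("blank-corrected AMB recovers lambda within the delta-method error", {
  # perfect detection, separable intensities: intensities drawn directly
  set.seed(12)
  n <- 2e4
  blank_ref <- rnorm(n, 1500, 120)
  bm <- fit_blank(blank_ref)
  cls_b <- classify_beads(rnorm(n, 1500, 120), bm)
  dig_b <- compute_amb(cls_b$n_on, cls_b$n_total)
  for (lambda in c(0.01, 0.1, 0.5, 2)) {
    on <- rpois(n, lambda) >= 1
    ints <- ifelse(on, rlnorm(n, log(8000), 0.4), rnorm(n, 1500, 120))
    cls <- classify_beads(ints, bm)
    dig <- compute_amb(cls$n_on, cls$n_total)
    est <- dig$amb - dig_b$amb
    se <- sqrt(amb_se(dig$f_on, dig$n_total)^2 +
                 amb_se(dig_b$f_on, dig_b$n_total)^2)
    expect_lt(abs(est - lambda), 3 * se)
  }

  # the Poisson correction matters: at lambda = 1, raw f_on underestimates
  # lambda by about (1 - exp(-1))
  on <- rpois(4e4, 1) >= 1
  ints <- ifelse(on, rlnorm(4e4, log(8000), 0.4), rnorm(4e4, 1500, 120))
  cls <- classify_beads(ints, bm)
  dig <- compute_amb(cls$n_on, cls$n_total)
  expect_equal(dig$f_on, 1 - exp(-1), tolerance = 0.05)
  expect_gt(dig$amb / dig$f_on, 1.4)
})
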