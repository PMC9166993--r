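test_that("mse matches hand enumeration and is symmetric", {
  a <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  b <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(mse(a, b), 0.5)            # (1 + 0 + 1 + 0)/4
  expect_equal(mse(b, a), mse(a, b))
  expect_equal(mse(a, a), 0)
  expect_equal(mse(matrix(0, 3, 3), matrix(0.7, 3, 3)), 0.49)
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("emse is the square root of mse", {
  a <- matrix(c(0, 1, 1, 0), 2, 2); b <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(emse(a, b), sqrt(0.5))
  expect_equal(emse(a, a), 0)
  expect_equal(emse(matrix(0, 2, 2), matrix(-0.3, 2, 2)), 0.3)
  set.seed(4)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  expect_equal(emse(x, y)^2, mse(x, y), tolerance = 1e-12)
})

test_that("isnr follows its decibel formula", {
  expect_equal(isnr(1, 1), 0)
  expect_equal(isnr(10, 1), 10)
  expect_equal(isnr(2, 0.5), 10 * log10(4))
  expect_error(isnr(1, 0), "perfect")
  expect_error(isnr(0, 1), "mse_in")
})

test_that("psnr follows its decibel formula and is consistent with mse", {
  z <- matrix(0, 4, 4)
  expect_equal(psnr(z, matrix(1, 4, 4), peak = 1), 0)       # mse = peak^2
  expect_equal(psnr(z, matrix(0.1, 4, 4), peak = 1), 20)    # mse = 0.01
  set.seed(5)
  a <- image_grid(matrix(runif(64), 8, 8)); b <- image_grid(matrix(runif(64), 8, 8))
  expect_equal(psnr(a, b), 10 * log10(1) * 2 - 10 * log10(mse(a, b)))
  # halving the mse raises psnr by 10 log10(2)
  c1 <- matrix(0.2, 4, 4); c2 <- matrix(0.2 / sqrt(2), 4, 4)
  expect_equal(psnr(z, c1, peak = 1) + 10 * log10(2), psnr(z, c2, peak = 1))
  expect_error(psnr(a, a), "unbounded")
})

test_that("ssim is 1 on identity, symmetric, and matches the window formula", {
  set.seed(6)
  x <- image_grid(matrix(runif(144), 12, 12))
  expect_equal(ssim(x, x), 1)
  y <- image_grid(matrix(runif(144), 12, 12))
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)

  # single 8x8 window of two constant images: sigma terms vanish and the
  # value reduces to the luminance term, evaluated directly
  a <- matrix(0.5, 8, 8); b <- matrix(0.25, 8, 8)
  c1 <- (0.01 * 1)^2; c2 <- (0.03 * 1)^2
  lum <- (2 * 0.5 * 0.25 + c1) / (0.5^2 + 0.25^2 + c1)
  expect_equal(ssim(a, b, window = 8, dynamic_range = 1), lum * (c2 / c2))

  # general case against the explicit double-loop oracle
  expect_equal(ssim(x, y), oracle_ssim(unclass(x), unclass(y)), tolerance = 1e-10)

  expect_error(ssim(a, b, window = 9), "window")
})

test_that("ssim penalizes heavy noise and contrast stretching", {
  set.seed(7)
  ref <- image_grid(matrix(0.3 + 0.2 * sin(outer(1:32, 1:32, "+") / 3), 32, 32))
  noisy <- image_grid(pmin(pmax(unclass(ref) + matrix(rnorm(1024, sd = 0.5), 32, 32), 0), 1))
  expect_lt(ssim(ref, noisy), 0.5)
  stretched <- image_grid(0.5 * unclass(ref) + 0.25)
  expect_lt(ssim(ref, stretched), 1)
})

test_that("line profiles and total variation behave on known inputs", {
  expect_equal(total_variation(c(0, 1, 0, 1, 0)), 4)
  expect_equal(total_variation(rep(3, 10)), 0)

  step <- render_phantom(phantom_spec(16, list(
    el_ellipse(c(0, 0), c(4, 100), 0.8))))
  prof <- line_profile(step, 8, "row")
  expect_equal(total_variation(prof), 1.6)   # up 0.8 and back down
  expect_equal(sort(unique(prof)), c(0, 0.8))

  img <- image_grid(matrix(1:16, 4, 4))
  expect_equal(line_profile(img, 2, "row"), c(2, 6, 10, 14))
  expect_equal(line_profile(img, 3, "column"), c(9, 10, 11, 12))
  expect_error(line_profile(img, 5, "row"), "out of range")
})

test_that("metrics_report assembles consistent values and exports rows", {
  ph <- make_lung_phantom(64, seed = 7)
  cand <- image_grid(pmin(pmax(unclass(ph) +
    matrix(rnorm(4096, sd = 0.05), 64, 64), 0), 1), pixel_size = pixel_size(ph))
  rep_ <- metrics_report(ph, cand, baseline_mse = 4 * mse(ph, cand))
  expect_equal(rep_$emse^2, rep_$mse, tolerance = 1e-12)
  expect_equal(rep_$psnr, 10 * log10(1 / rep_$mse))
  expect_equal(rep_$isnr, 10 * log10(4), tolerance = 1e-12)
  expect_equal(rep_$ssim, ssim(ph, cand))
  row <- metrics_row(rep_, "toy")
  expect_equal(names(row), c("label", "mse", "emse", "psnr", "ssim", "isnr"))
})
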