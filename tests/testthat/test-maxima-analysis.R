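test_that("find_maxima handles impulses, separated spots, and plateaus", {
  im <- image2d(matrix(0, 9, 9), 25); im[5, 5] <- 10
  p <- find_maxima(im, prominence = 5)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$x_nm, p$y_nm), c(4.5 * 25, 4.5 * 25))

  # two Gaussian spots separated by 10 sigma
  spot <- function(c1, c2) unclass(gaussian_spot_image(
    60, amplitude = 100, centre = c(c1, c2), sigma_px = 2))
  two <- image2d(spot(15, 15) + spot(45, 45), 25)
  p2 <- find_maxima(two, prominence = 50)
  expect_equal(nrow(p2), 2L)
  px <- sorted_rows(pattern_to_px(p2, 25))
  expect_equal(px[, "row"], c(15, 45), tolerance = 1)
  expect_equal(px[, "col"], c(15, 45), tolerance = 1)

  # a 2x2 plateau of equal maximal value yields its centroid
  pl <- image2d(matrix(0, 8, 8), 25); pl[4:5, 4:5] <- 7
  p3 <- find_maxima(pl, prominence = 3)
  expect_equal(nrow(p3), 1L)
  expect_equal(unname(pattern_to_px(p3, 25)[1, ]), c(4.5, 4.5))

  expect_error(find_maxima(im, prominence = 0), "positive")
  expect_error(find_maxima(im, prominence = -2), "positive")
})

test_that("detection is translation-equivariant and offset-invariant", {
  set.seed(31)
  base <- matrix(0, 40, 40)
  for (k in 1:4) {
    rc <- sample(8:20, 2)
    base <- base + unclass(gaussian_spot_image(40, 80, rc, 1.5))
  }
  p1 <- find_maxima(image2d(base, 25), prominence = 30)
  shifted <- matrix(0, 40, 40)
  shifted[11:40, 6:40] <- base[1:30, 1:35]
  p2 <- find_maxima(image2d(shifted, 25), prominence = 30)
  s1 <- sorted_rows(pattern_to_px(p1, 25))
  s2 <- sorted_rows(pattern_to_px(p2, 25))
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s2[, "row"], s1[, "row"] + 10, tolerance = 1e-9)
  expect_equal(s2[, "col"], s1[, "col"] + 5, tolerance = 1e-9)

  p3 <- find_maxima(image2d(base + 123.4, 25), prominence = 30)
  expect_equal(pattern_to_px(p3, 25), pattern_to_px(p1, 25))
})

test_that("detection agrees exactly with the exhaustive prominence oracle", {
  set.seed(19)
  for (trial in 1:6) {
    m <- matrix(sample(0:9, 20 * 20, replace = TRUE), 20, 20)
    prom <- sample(2:5, 1)
    oracle <- brute_force_maxima(m, prom)
    got <- pattern_to_px(find_maxima(image2d(m, 25), prominence = prom), 25)
    expect_equal(nrow(got), nrow(oracle))
    expect_equal(unname(sorted_rows(got)),
                 unname(sorted_rows(oracle[, 1:2, drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("linescan fit recovers its own model exactly and applies QC rules", {
  # noiseless profile A=100, mu=15, sigma=3, offset=0
  img <- ridge_image(41, 100, 21, 3)
  pt <- c(20.5 * 25, 20.5 * 25)
  f <- fit_linescan(img, pt, orientation = "horizontal")
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  expect_equal(f$centre_px, 15, tolerance = 1e-6)
  expect_equal(f$sigma_px, 3, tolerance = 1e-6)
  expect_equal(f$offset, 0, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$fwhm_nm / 25, 2 * sqrt(2 * log(2)) * 3, tolerance = 1e-6)
  expect_true(f$qc_pass)

  # peak off the middle third (fitted centre near 3): QC fails
  off <- ridge_image(41, 100, 9, 3)
  f2 <- fit_linescan(off, pt, orientation = "horizontal")
  expect_false(f2$qc_pass)
  expect_match(f2$reason, "non-centred peak")
  expect_gt(f2$r2, 0.95)

  # corrupted profile: good centre but R2 below 0.8
  noisy <- unclass(img)
  for (r in 20:22) noisy[r, ] <- noisy[r, ] + rep(c(50, -50),
                                                  length.out = 41)
  f3 <- fit_linescan(image2d(noisy, 25), pt, orientation = "horizontal")
  expect_lt(f3$r2, 0.8)
  expect_false(f3$qc_pass)
  expect_match(f3$reason, "R2 below 0.8")

  # linescan leaving the frame fails QC instead of crashing
  f4 <- fit_linescan(img, c(2 * 25, 20.5 * 25), orientation = "horizontal")
  expect_false(f4$qc_pass)
  expect_match(f4$reason, "out of bounds")
})

test_that("maxima_size keeps the better orientation and drops QC failures", {
  img <- gaussian_spot_image(41, 100, c(21, 21), 3)   # isotropic 2-D spot
  # corrupt the vertical profile only (outside the horizontal 3-row band)
  m <- unclass(img)
  rows <- c(7:17, 25:35)
  m[rows, 21] <- m[rows, 21] + rep(c(25, -25), length.out = length(rows))
  img2 <- image2d(m, 25)
  pat <- find_maxima(img2, prominence = 50)
  sz <- maxima_size(img2, pat)
  expect_equal(sz$n_used, 1L)
  expect_equal(sz$table$orientation, "horizontal")
  expect_gt(sz$table$r2_horizontal, sz$table$r2_vertical)
  expect_equal(sz$mean_size_nm / 25, 2 * sqrt(2 * log(2)) * 3,
               tolerance = 0.01)

  # all maxima failing QC leaves the size undefined with a zero count
  edge <- image2d(matrix(0, 20, 20), 25); edge[3, 3] <- 50
  pe <- find_maxima(edge, prominence = 10)
  se <- maxima_size(edge, pe)
  expect_equal(se$n_used, 0L)
  expect_true(is.na(se$mean_size_nm))
})

test_that("rendered spot sizes are recovered within 5% across 60-200 nm", {
  for (fwhm in c(60, 100, 140, 200)) {
    measured <- roundtrip_fwhm(fwhm)
    expect_equal(measured, fwhm, tolerance = 0.05)
  }
})

test_that("maxima_density relates counts to area, matching Poisson sampling", {
  m <- image2d(matrix(0, 80, 80), 25)   # 2x2 um -> 4 um^2
  pat <- point_pattern(runif(44, 0, 2000), runif(44, 0, 2000), c(2000, 2000))
  expect_equal(maxima_density(pat, roi_full(m)), 11)
  empty <- point_pattern(numeric(0), numeric(0), c(2000, 2000))
  expect_equal(maxima_density(empty, roi_full(m)), 0)
  # CSR pattern at lambda = 11 on 100 um^2: estimate within 3 SE of 11
  p <- gen_csr(11, c(10, 10), seed = 123)
  se <- sqrt(11 / 100)
  expect_lt(abs(maxima_density(p) - 11), 3 * se)
})

test_that("planted low-density spots are counted within 5% after rendering", {
  lambda <- 3
  p <- gen_csr(lambda, c(5, 5), seed = 99)
  rs <- render_spec()     # default photon + read noise
  extra <- sqrt(80^2 - 65^2) / (2 * sqrt(2 * log(2)))
  img <- render_image(p, rs, intensity = 500, point_sigma_nm = extra,
                      noise = TRUE, seed = 7)
  det <- find_maxima(img, prominence = NULL)   # 5 x robust noise default
  expect_lt(abs(nrow(det) - nrow(p)) / nrow(p), 0.05)
})
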