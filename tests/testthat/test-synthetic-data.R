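test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_csr(10, c(5, 5), seed = 3),
                   gen_csr(10, c(5, 5), seed = 3))
  sp <- scene_spec(seed = 12)
  s1 <- simulate_scene(sp); s2 <- simulate_scene(sp)
  expect_identical(s1$cluster_image, s2$cluster_image)
  expect_identical(s1$crowd_image, s2$crowd_image)
  expect_identical(s1$crowds, s2$crowds)
})

test_that("gen_csr counts follow the Poisson mean and the empty limit", {
  p <- gen_csr(10, c(10, 10), seed = 41)
  expect_lt(abs(nrow(p) - 1000), 3 * sqrt(1000))
  expect_equal(nrow(gen_csr(0, c(10, 10), seed = 1)), 0L)
})

test_that("gen_clustered degenerates to its centres and keeps the process mean", {
  sp <- scene_spec(molecules_per_cluster = 1, cluster_sigma_nm = 0, seed = 5)
  cl <- gen_clustered(sp)
  expect_equal(cl$molecules$x_nm, cl$centres$x_nm)
  expect_equal(cl$molecules$y_nm, cl$centres$y_nm)

  sp2 <- scene_spec(seed = 6)
  cl2 <- gen_clustered(sp2)
  expected <- sp2$cluster_density * prod(sp2$window_um) *
    sp2$molecules_per_cluster
  expect_lt(abs(nrow(cl2$molecules) - expected) / expected, 0.1)
})

test_that("rendered cluster size matches the PSF-convolution closed form", {
  # apparent FWHM of a Gaussian object imaged by a Gaussian PSF:
  # sqrt(psf_fwhm^2 + (2.355 sigma_obj)^2)
  sp <- scene_spec(cluster_density = 2, coupling_p = 0, seed = 9,
                   window_um = c(4, 4))
  cl <- gen_clustered(sp)
  rs <- render_spec(photons_per_unit = 0, read_noise_sd = 0)
  img <- render_image(cl$molecules, rs, noise = FALSE)
  pat <- find_maxima(img, prominence = max(img) / 4)
  sz <- maxima_size(img, pat)
  expected <- sqrt(65^2 + (2 * sqrt(2 * log(2)) * sp$cluster_sigma_nm)^2)
  expect_equal(sz$mean_size_nm, expected, tolerance = 0.1)
})

test_that("uncoupled crowds are CSR relative to clusters; full coupling pins them", {
  sp <- scene_spec(window_um = c(10, 10), crowd_density = 100,
                   coupling_p = 0, seed = 30)
  cl <- gen_clustered(sp)
  crowds <- gen_coupled_crowds(cl$centres, sp)
  d <- nn_distances(crowds, cl$centres, margin_nm = 1000)
  lam <- pattern_density(cl$centres)
  ks <- suppressWarnings(
    stats::ks.test(d, function(r) csr_nn_cdf(lam, r))$statistic)
  expect_lt(ks, 0.02)

  sp1 <- scene_spec(window_um = c(10, 10), coupling_p = 1,
                    binding_distance_nm = 0, seed = 31)
  crowds1 <- gen_coupled_crowds(cl$centres, sp1)
  d1 <- nn_distances(crowds1, cl$centres)
  expect_equal(max(d1), 0, tolerance = 1e-9)

  sp2 <- scene_spec(window_um = c(10, 10), coupling_p = 1,
                    binding_distance_nm = 100, seed = 32)
  crowds2 <- gen_coupled_crowds(cl$centres, sp2)
  d2 <- nn_distances(crowds2, cl$centres, margin_nm = 150)
  expect_equal(unname(stats::quantile(d2, 0.9)), 100, tolerance = 0.01)

  empty <- point_pattern(numeric(0), numeric(0), c(10000, 10000))
  expect_error(gen_coupled_crowds(empty, sp1), "empty")
})

test_that("render_image conserves per-molecule intensity and the empty limit", {
  rs <- render_spec(photons_per_unit = 0, read_noise_sd = 0)
  one <- point_pattern(500, 500, c(1000, 1000))
  img <- render_image(one, rs, intensity = 123, noise = FALSE)
  expect_equal(sum(img), 123, tolerance = 123 * 1e-3)

  none <- point_pattern(numeric(0), numeric(0), c(1000, 1000))
  expect_true(all(unclass(render_image(none, rs, noise = FALSE)) == 0))

  # PSF-only round trip: 65 nm FWHM recovered within 5%
  expect_equal(roundtrip_fwhm(65), 65, tolerance = 0.05)
})

test_that("self-quenching dims close pairs and is monotone in crowding", {
  w <- c(1000, 1000)
  pairp <- point_pattern(c(500, 503), c(500, 500), w)
  expect_equal(apply_quenching(pairp, c(10, 10), 0, 5), c(10, 10))
  expect_equal(apply_quenching(pairp, c(10, 10), 1, 5), c(0, 0))
  lone <- point_pattern(c(100, 900), c(100, 900), w)
  expect_equal(apply_quenching(lone, 10, 1, 5), c(10, 10))

  # same molecule count packed ever denser: total intensity non-increasing
  set.seed(50)
  xs <- runif(200); ys <- runif(200)
  totals <- vapply(c(2000, 1000, 500, 250, 125), function(side) {
    p <- point_pattern(xs * side, ys * side, c(side, side))
    sum(apply_quenching(p, 10, 0.5, 15))
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
  expect_lt(totals[length(totals)], totals[1])
})

test_that("epitope shielding removes only at-risk labels, never adds", {
  sp <- scene_spec(seed = 70)
  cl <- gen_clustered(sp)
  keep_all <- apply_shielding(cl$molecules, cl$centres, 0, 40, seed = 1)
  expect_equal(nrow(keep_all), nrow(cl$molecules))

  # labels all within the shielding radius of a centre vanish at p = 1
  centres <- point_pattern(500, 500, c(1000, 1000))
  labels <- point_pattern(runif(50, 480, 520), runif(50, 480, 520),
                          c(1000, 1000))
  gone <- apply_shielding(labels, centres, 1, 60, seed = 2)
  expect_equal(nrow(gone), 0L)

  part <- apply_shielding(cl$molecules, cl$centres, 0.5, 40, seed = 3)
  expect_lte(nrow(part), nrow(cl$molecules))
  expect_gt(nrow(part), 0L)
})

test_that("stronger shielding flattens the label-vs-reference regression slope", {
  # several small sheets of varying expression level; the reference channel
  # sees all molecules, the label channel only unshielded ones
  slopes <- vapply(c(0, 0.4, 0.8), function(sp_shield) {
    means <- t(vapply(seq_len(6), function(k) {
      sp <- scene_spec(window_um = c(2, 2), cluster_density = 4 + 3 * k,
                       coupling_p = 0, seed = 200 + k)
      cl <- gen_clustered(sp)
      rs <- render_spec(photons_per_unit = 0, read_noise_sd = 0,
                        shield_p = sp_shield)
      ref_img <- render_image(cl$molecules, rs, noise = FALSE)
      surv <- apply_shielding(cl$molecules, cl$centres, sp_shield, 40,
                              seed = 900 + k)
      lab_img <- render_image(surv, rs, noise = FALSE)
      c(mean(ref_img), mean(lab_img))
    }, numeric(2)))
    linear_fit(means[, 1], means[, 2])$slope
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})
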