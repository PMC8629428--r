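test_that("nn_distances reproduces forced geometry", {
  w <- c(1000, 1000)
  ref <- point_pattern(0, 0, w)
  tgt <- point_pattern(300, 400, w)
  expect_equal(nn_distances(ref, tgt), 500)

  pair <- point_pattern(c(400, 580), c(500, 500), w)
  expect_equal(nn_distances(pair), c(180, 180))

  expect_error(nn_distances(ref, point_pattern(numeric(0), numeric(0), w)),
               "empty")
  expect_warning(d <- nn_distances(pair, tgt, margin_nm = 600), "excluded")
  expect_length(d, 0)
})

test_that("nn_distances equals exhaustive O(n^2) search exactly", {
  for (seed in c(5, 6)) {
    p <- gen_csr(5, c(10, 10), seed = seed)   # ~500 points
    brute <- vapply(seq_len(nrow(p)), function(i)
      min(sqrt((p$x_nm[i] - p$x_nm[-i])^2 + (p$y_nm[i] - p$y_nm[-i])^2)),
      numeric(1))
    expect_identical(nn_distances(p), brute)
    # cross-type against an independent pattern
    q <- gen_csr(3, c(10, 10), seed = seed + 50)
    bx <- vapply(seq_len(nrow(p)), function(i)
      min(sqrt((p$x_nm[i] - q$x_nm)^2 + (p$y_nm[i] - q$y_nm)^2)),
      numeric(1))
    expect_identical(nn_distances(p, q), bx)
  }
})

test_that("CSR nearest-neighbour statistics match the ideal-gas closed forms", {
  p <- gen_csr(11, c(30.2, 30.2), seed = 101)   # ~10^4 points
  d <- nn_distances(p, margin_nm = 1000)
  expect_equal(mean(d), 1 / (2 * sqrt(11e-6)), tolerance = 0.02)
  ks <- suppressWarnings(
    stats::ks.test(d, function(r) csr_nn_cdf(11, r))$statistic)
  expect_lt(ks, 0.02)
})

test_that("csr_nn_pdf vanishes at zero, peaks at the closed-form mode", {
  expect_equal(csr_nn_pdf(11, 0), 0)
  expect_error(csr_nn_pdf(-1, 10), "positive")
  r <- seq(0, 600, by = 0.1)
  mode_hat <- r[which.max(csr_nn_pdf(11, r))]
  expect_equal(mode_hat, 1 / sqrt(2 * pi * 11e-6), tolerance = 1e-3)
  # density integrates to ~1
  expect_equal(sum(csr_nn_pdf(11, r)) * 0.1, 1, tolerance = 1e-3)
})

test_that("radial cross-counts follow single-pair geometry and the CSR area law", {
  w <- c(2000, 2000)
  ref <- point_pattern(1000, 1000, w)
  tgt <- point_pattern(1100, 1000, w)
  h <- radial_cross_counts(ref, tgt, bin_edges = seq(0, 300, 50))
  expect_equal(h$mean_count, c(0, 0, 1, 0, 0, 0))

  empty <- point_pattern(numeric(0), numeric(0), w)
  h0 <- radial_cross_counts(ref, empty, bin_edges = seq(0, 300, 50))
  expect_equal(h0$mean_count, rep(0, 6))

  expect_error(radial_cross_counts(ref, tgt, bin_edges = c(100, 50)),
               "increasing")

  # CSR: mean annulus count -> lambda * pi * (hi^2 - lo^2) within 3 SE
  counts <- vapply(1:20, function(i) {
    p <- gen_csr(11, c(8, 8), seed = 300 + i)
    radial_cross_counts(p, bin_edges = c(100, 200),
                        margin_nm = 200)$mean_count
  }, numeric(1))
  expected <- 11e-6 * pi * (200^2 - 100^2)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("pair distribution is 1 for CSR, >1 for clusters, 0 inside hard cores", {
  p <- gen_csr(11, c(30.2, 30.2), seed = 77)
  g <- pair_distribution(p, bin_edges = seq(0, 500, 25), margin_nm = 500)
  # each bin within 3 standard errors of 1 (Poisson counts per annulus)
  total_counts <- g$mean_count * attr(g, "n_reference")
  se_g <- g$g / sqrt(pmax(total_counts, 1))
  expect_true(all(abs(g$g - 1) < 3 * pmax(se_g, 0.02)))

  cl <- gen_clustered(scene_spec(coupling_p = 0, seed = 8))
  gm <- pair_distribution(cl$molecules, bin_edges = seq(0, 500, 25),
                          margin_nm = 500)
  expect_gt(gm$g[1], 2)
  expect_gt(gm$g[2], 1)

  # grid pattern with 250 nm spacing: no pairs below the spacing
  gx <- as.vector(outer(seq(125, 4875, 250), rep(1, 20)))
  gy <- as.vector(outer(rep(1, 20), seq(125, 4875, 250)))
  grid <- point_pattern(gx, gy, c(5000, 5000))
  gh <- pair_distribution(grid, bin_edges = seq(0, 250, 50),
                          margin_nm = 250)
  expect_equal(gh$g, rep(0, 5))
})

test_that("csr_reference is seed-deterministic with honest envelopes", {
  p <- gen_csr(20, c(4, 4), seed = 55)
  bins <- seq(0, 300, 25)
  r1 <- csr_reference(p, n_replicates = 19, seed = 9, bin_edges = bins)
  r2 <- csr_reference(p, n_replicates = 19, seed = 9, bin_edges = bins)
  expect_identical(r1, r2)

  single <- csr_reference(p, n_replicates = 1, seed = 3, bin_edges = bins)
  expect_equal(single$nn_density$mean, single$nn_density$lo)
  expect_equal(single$nn_density$mean, single$nn_density$hi)

  # a CSR input should sit inside the 95% envelope in >= 90% of
  # well-populated bins
  dense <- gen_csr(20, c(8, 8), seed = 55)
  bins2 <- seq(0, 150, 15)
  obs <- nn_histogram(nn_distances(dense, margin_nm = 150), bins2)
  ref <- csr_reference(dense, n_replicates = 199, seed = 21,
                       bin_edges = bins2, margin_nm = 150)
  inside <- obs$density >= ref$nn_density$lo - 1e-12 &
    obs$density <= ref$nn_density$hi + 1e-12
  expect_gte(mean(inside), 0.9)
})

test_that("distance statistics are translation-invariant and scale-equivariant", {
  p <- gen_csr(30, c(3, 3), seed = 14)
  d0 <- nn_distances(p)
  # translation of both patterns (shift coordinates within a larger window)
  w2 <- pattern_window(p) + 2000
  shifted <- point_pattern(p$x_nm + 1000, p$y_nm + 1000, w2)
  base_in_w2 <- point_pattern(p$x_nm, p$y_nm, w2)
  expect_equal(nn_distances(shifted), nn_distances(base_in_w2))
  # uniform scaling scales distances linearly
  scaled <- point_pattern(p$x_nm * 3, p$y_nm * 3, pattern_window(p) * 3)
  expect_equal(nn_distances(scaled), 3 * d0, tolerance = 1e-12)
})

test_that("nn_mode_estimate recovers the CSR mode", {
  p <- gen_csr(11, c(30.2, 30.2), seed = 404)
  est <- nn_mode_estimate(nn_distances(p, margin_nm = 1000))
  expect_equal(est$shape, 2, tolerance = 0.1)
  expect_equal(est$mode_nm, 1 / sqrt(2 * pi * 11e-6), tolerance = 0.05)
})

test_that("stronger recruitment coupling shortens cross-type NN distances", {
  spec0 <- scene_spec(seed = 60)
  cl <- gen_clustered(spec0)
  meds <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cp) {
    sp <- scene_spec(coupling_p = cp, seed = 60)
    crowds <- gen_coupled_crowds(cl$centres, sp, seed = 61)
    median(nn_distances(crowds, cl$centres, margin_nm = 200))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})
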