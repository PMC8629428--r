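## Planar point-pattern statistics against an ideal-gas (complete spatial
## randomness) null: nearest-neighbour distances, radial cross-counts, the
## pair distribution function g(r), and seeded matched-density CSR
## reference envelopes. Border bias is handled by minus-sampling: only
## reference points farther than a margin from every window edge are used,
## while neighbours may lie anywhere in the window.

## Squared-distance matrix between two coordinate sets, computed in blocks
## to bound memory.
block_mindist <- function(rx, ry, tx, ty, self_index = NULL) {
  n <- length(rx)
  out <- numeric(n)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(rx[s:e], tx, "-")^2 + outer(ry[s:e], ty, "-")^2
    if (!is.null(self_index)) {
      si <- self_index[s:e]
      ok <- !is.na(si)
      if (any(ok)) d2[cbind(which(ok), si[ok])] <- Inf
    }
    out[s:e] <- sqrt(apply(d2, 1L, min))
  }
  out
}

include_margin <- function(pattern, margin_nm) {
  w <- pattern_window(pattern)
  pattern$x_nm >= margin_nm & pattern$x_nm <= w[1] - margin_nm &
    pattern$y_nm >= margin_nm & pattern$y_nm <= w[2] - margin_nm
}

#' Nearest-neighbour distances with minus-sampling border correction
#'
#' For every reference point farther than `margin_nm` from all window edges,
#' the Euclidean distance (nm) to the nearest target point. When the target
#' is the reference pattern itself the point's own zero distance is
#' excluded. Neighbours are allowed anywhere in the window (minus-sampling),
#' so the distances are unbiased up to `margin_nm`.
#'
#' @param reference a [point_pattern()].
#' @param target a [point_pattern()] sharing the window, or `NULL` for
#'   same-type distances within `reference`.
#' @param margin_nm border-exclusion margin (>= 0, nm).
#' @return numeric vector of distances, one per included reference point.
#' @export
nn_distances <- function(reference, target = NULL, margin_nm = 0) {
  same <- is.null(target)
  if (same) target <- reference
  if (margin_nm < 0) stop("'margin_nm' must be non-negative")
  if (!isTRUE(all.equal(pattern_window(reference), pattern_window(target))))
    stop("patterns must share an observation window")
  if (nrow(target) == 0L) stop("target pattern is empty")
  if (same && nrow(reference) < 2L)
    stop("same-type nearest neighbours need at least two points")
  keep <- include_margin(reference, margin_nm)
  if (!any(keep)) {
    warning("all reference points excluded by the border margin")
    return(numeric(0))
  }
  self_index <- if (same) which(keep) else NULL
  block_mindist(reference$x_nm[keep], reference$y_nm[keep],
                target$x_nm, target$y_nm, self_index)
}

#' Closed-form CSR nearest-neighbour distance density
#'
#' For a homogeneous planar Poisson process ("ideal gas") of intensity
#' lambda, the nearest-neighbour distance R has density
#' p(r) = 2 pi lambda r exp(-pi lambda r^2). Units: lambda in points per
#' square micrometre, r in nm, density per nm. The mode sits at
#' 1/sqrt(2 pi lambda) and the mean at 1/(2 sqrt(lambda)).
#'
#' @param lambda_per_um2 point intensity (> 0), points per um^2.
#' @param r_nm distances (nm), vectorized.
#' @return density values (per nm).
#' @export
csr_nn_pdf <- function(lambda_per_um2, r_nm) {
  if (!is.numeric(lambda_per_um2) || lambda_per_um2 <= 0)
    stop("'lambda_per_um2' must be positive")
  if (any(r_nm < 0)) stop("distances must be non-negative")
  lam <- lambda_per_um2 / 1e6   # per nm^2
  2 * pi * lam * r_nm * exp(-pi * lam * r_nm^2)
}

#' Closed-form CSR nearest-neighbour distance CDF
#' @inheritParams csr_nn_pdf
#' @return P(R <= r) = 1 - exp(-pi lambda r^2).
#' @export
csr_nn_cdf <- function(lambda_per_um2, r_nm) {
  lam <- lambda_per_um2 / 1e6
  1 - exp(-pi * lam * r_nm^2)
}

#' Mode of a nearest-neighbour distance sample
#'
#' Estimates the most likely nearest-neighbour distance by maximum-likelihood
#' fit of a two-parameter Weibull distribution and evaluation of its mode
#' `scale * ((shape - 1)/shape)^(1/shape)`. For a CSR pattern the NN
#' distance is exactly Weibull with shape 2 and scale `1/sqrt(pi lambda)`,
#' but the shape is left free here, so departures from the ideal-gas law
#' move the estimate; the estimator is far less variable than a histogram
#' or kernel-density argmax.
#'
#' @param distances positive NN distances (nm).
#' @return list: `mode_nm`, `shape`, `scale`.
#' @export
nn_mode_estimate <- function(distances) {
  d <- distances[distances > 0]
  if (length(d) < 10L) stop("need at least 10 positive distances")
  nll <- function(par) {
    sh <- exp(par[1]); sc <- exp(par[2])
    -sum(stats::dweibull(d, sh, sc, log = TRUE))
  }
  init <- c(log(1.2 / stats::sd(log(d))), log(stats::median(d) * 1.2))
  opt <- stats::optim(init, nll, method = "Nelder-Mead")
  sh <- exp(opt$par[1]); sc <- exp(opt$par[2])
  if (sh <= 1) return(list(mode_nm = 0, shape = sh, scale = sc))
  list(mode_nm = sc * ((sh - 1) / sh)^(1 / sh), shape = sh, scale = sc)
}

check_bins <- function(bin_edges) {
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be strictly increasing with at least two edges")
  if (any(bin_edges < 0)) stop("'bin_edges' must be non-negative")
}

dist_hist <- function(lo, hi, value, type, n_reference) {
  structure(data.frame(lo_nm = lo, hi_nm = hi, value = value),
            type = type, n_reference = n_reference,
            class = c("distance_histogram", "data.frame"))
}

#' Histogram of distances with half-open bins
#'
#' Bins a distance sample into half-open bins \[lo, hi) and reports counts
#' and the normalized probability density over the binned range.
#'
#' @param distances numeric distances (nm).
#' @param bin_edges ascending bin edges (nm).
#' @return data.frame of class `distance_histogram` with `lo_nm`, `hi_nm`,
#'   `count`, `density` columns.
#' @export
nn_histogram <- function(distances, bin_edges) {
  check_bins(bin_edges)
  b <- findInterval(distances, bin_edges, rightmost.closed = FALSE)
  nb <- length(bin_edges) - 1L
  counts <- tabulate(b[b >= 1L & b <= nb], nb)
  width <- diff(bin_edges)
  total <- sum(counts)
  h <- dist_hist(bin_edges[-length(bin_edges)], bin_edges[-1], counts,
                 "nn_histogram", length(distances))
  h$count <- counts
  h$density <- if (total > 0) counts / (total * width) else counts * 0
  h$value <- NULL
  h
}

annulus_mean_counts <- function(reference, target, bin_edges, margin_nm,
                                same) {
  keep <- include_margin(reference, margin_nm)
  n_ref <- sum(keep)
  nb <- length(bin_edges) - 1L
  if (n_ref == 0L) {
    warning("all reference points excluded by the border margin")
    return(list(mean_counts = rep(NA_real_, nb), n_reference = 0L))
  }
  rx <- reference$x_nm[keep]; ry <- reference$y_nm[keep]
  counts <- numeric(nb)
  block <- 512L
  for (s in seq(1L, n_ref, by = block)) {
    e <- min(s + block - 1L, n_ref)
    d <- sqrt(outer(rx[s:e], target$x_nm, "-")^2 +
              outer(ry[s:e], target$y_nm, "-")^2)
    if (same) {
      si <- which(keep)[s:e]
      d[cbind(seq_len(e - s + 1L), si)] <- Inf
    }
    b <- findInterval(d, bin_edges, rightmost.closed = FALSE)
    counts <- counts + tabulate(b[b >= 1L & b <= nb], nb)
  }
  list(mean_counts = counts / n_ref, n_reference = n_ref)
}

#' Radial cross-counts: mean neighbours per annulus
#'
#' For each included reference point, counts target points whose distance
#' falls in each half-open annulus \[lo, hi), and reports the mean count per
#' reference point per bin (e.g. the number of syntaxin-type maxima at a
#' given distance from SNAP25-type maxima). Under CSR the expectation per
#' bin is `lambda_target * pi * (hi^2 - lo^2)`.
#'
#' @inheritParams nn_distances
#' @param bin_edges ascending annulus edges (nm).
#' @return `distance_histogram` with `mean_count` per bin; attribute
#'   `n_reference` gives the number of included reference points.
#' @export
radial_cross_counts <- function(reference, target = NULL, bin_edges,
                                margin_nm = 0) {
  check_bins(bin_edges)
  same <- is.null(target)
  if (same) target <- reference
  if (!isTRUE(all.equal(pattern_window(reference), pattern_window(target))))
    stop("patterns must share an observation window")
  ac <- annulus_mean_counts(reference, target, bin_edges, margin_nm, same)
  h <- dist_hist(bin_edges[-length(bin_edges)], bin_edges[-1],
                 ac$mean_counts, "radial_cross_counts", ac$n_reference)
  names(h)[names(h) == "value"] <- "mean_count"
  h
}

#' Pair distribution function g(r)
#'
#' Ratio of the observed mean annulus count per reference point to the
#' count expected from an ideal gas of the target's density:
#' `g(r) = observed / (lambda_target * pi * (hi^2 - lo^2))`. g = 1 indicates
#' ideal-gas behaviour, g > 1 aggregation at that distance, g < 1 depletion
#' (e.g. hard-core exclusion). For same-pattern analysis the target
#' intensity uses (n - 1)/area, matching the exclusion of self-pairs.
#'
#' @inheritParams radial_cross_counts
#' @return `distance_histogram` with columns `mean_count` and `g`.
#' @export
pair_distribution <- function(reference, target = NULL, bin_edges,
                              margin_nm = 0) {
  same <- is.null(target)
  h <- radial_cross_counts(reference, target, bin_edges, margin_nm)
  tgt <- if (same) reference else target
  w <- pattern_window(tgt)
  n_t <- nrow(tgt) - if (same) 1L else 0L
  if (n_t <= 0L) stop("target intensity is zero; g(r) undefined")
  lam <- n_t / prod(w)    # per nm^2
  expected <- lam * pi * (h$hi_nm^2 - h$lo_nm^2)
  h$g <- h$mean_count / expected
  attr(h, "type") <- "pair_distribution"
  h
}

#' Matched-density CSR (ideal gas) reference with envelopes
#'
#' Simulates `n_replicates` uniform ("binomial") point patterns with exactly
#' the observed point count in the observed window, runs the same distance
#' statistics with the same margin and bins, and returns the pointwise mean
#' and 2.5/97.5 percentile envelopes. Deterministic under `seed`.
#'
#' @param pattern observed [point_pattern()].
#' @param n_replicates number of CSR replicates (>= 1).
#' @param seed integer seed (recorded in the output).
#' @param bin_edges ascending bin edges (nm) for the histograms.
#' @param margin_nm border-exclusion margin (nm); default: largest bin edge
#'   (standard minus-sampling choice).
#' @return list of class `csr_reference`: `mode`, `density_per_um2`,
#'   `window_nm`, `n_replicates`, `seed`, `margin_nm`, `bin_edges`, and for
#'   each statistic (`nn_density`, `radial_mean_count`, `g`) a data.frame
#'   with `lo_nm`, `hi_nm`, `mean`, `lo`, `hi` (envelope).
#' @export
csr_reference <- function(pattern, n_replicates, seed, bin_edges,
                          margin_nm = max(bin_edges)) {
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  check_bins(bin_edges)
  n <- nrow(pattern)
  w <- pattern_window(pattern)
  nb <- length(bin_edges) - 1L
  nn_mat <- matrix(NA_real_, n_replicates, nb)
  rc_mat <- matrix(NA_real_, n_replicates, nb)
  g_mat <- matrix(NA_real_, n_replicates, nb)
  with_seed(seed, {
    for (i in seq_len(n_replicates)) {
      p <- point_pattern(stats::runif(n, 0, w[1]), stats::runif(n, 0, w[2]),
                         w, attr(pattern, "channel"))
      nn_mat[i, ] <- nn_histogram(nn_distances(p, margin_nm = margin_nm),
                                  bin_edges)$density
      pd <- pair_distribution(p, bin_edges = bin_edges,
                              margin_nm = margin_nm)
      rc_mat[i, ] <- pd$mean_count
      g_mat[i, ] <- pd$g
    }
  })
  env <- function(m) data.frame(
    lo_nm = bin_edges[-length(bin_edges)], hi_nm = bin_edges[-1],
    mean = colMeans(m),
    lo = apply(m, 2L, stats::quantile, 0.025, na.rm = TRUE),
    hi = apply(m, 2L, stats::quantile, 0.975, na.rm = TRUE))
  structure(list(mode = "monte_carlo",
                 density_per_um2 = pattern_density(pattern),
                 window_nm = w, n_replicates = n_replicates, seed = seed,
                 margin_nm = margin_nm, bin_edges = bin_edges,
                 nn_density = env(nn_mat),
                 radial_mean_count = env(rc_mat),
                 g = env(g_mat)),
            class = "csr_reference")
}
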