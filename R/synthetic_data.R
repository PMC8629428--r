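## Ground-truth scene generator: point processes for tight syntaxin-like
## clusters and diffuse SNAP25-like crowds with tunable recruitment
## coupling, PSF rendering into two-channel images with photon/readout
## noise, and the intensity distortions of the recruitment mechanism —
## fluorophore self-quenching and epitope shielding — so every measurement
## stage is testable against known ground truth.

#' Scene specification for a two-species synthetic membrane sheet
#'
#' Defaults emulate the reported morphology of the two SNAREs on membrane
#' sheets: tight clusters of ~80 nm apparent diameter at ~11 per um^2
#' (syntaxin-like) and larger diffuse crowds of ~160 nm (SNAP25-like), with
#' a recruitment coupling that places a fraction of crowds at a fixed
#' binding offset from a cluster centre. Spatial spreads are chosen so that
#' cluster/crowd images rendered with a 65 nm FWHM PSF measure ~80 / ~160 nm:
#' `sqrt(psf_fwhm^2 + (2.355 sigma)^2)`.
#'
#' @param window_um observation window (width, height) in um.
#' @param cluster_density clusters per um^2.
#' @param cluster_sigma_nm Gaussian spread of molecules about a cluster
#'   centre (nm).
#' @param molecules_per_cluster labelled molecules per cluster.
#' @param crowd_density crowds per um^2.
#' @param crowd_sigma_nm Gaussian footprint of one crowd (nm).
#' @param molecules_per_crowd labelled molecules per crowd. The default
#'   carries the ~12-fold copy-number excess of the crowd species over the
#'   cluster species:
#'   `12 * cluster_density * molecules_per_cluster / crowd_density`.
#' @param coupling_p probability in \[0, 1\] that a crowd is recruited to a
#'   cluster rather than placed uniformly.
#' @param binding_distance_nm centre-to-centre offset of a recruited crowd.
#' @param seed integer seed recorded in all outputs.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(window_um = c(6.4, 6.4),
                       cluster_density = 11,
                       cluster_sigma_nm = 20,
                       molecules_per_cluster = 40,
                       crowd_density = 8,
                       crowd_sigma_nm = 62,
                       molecules_per_crowd = NULL,
                       coupling_p = 0.5,
                       binding_distance_nm = 80,
                       seed = 1L) {
  stopifnot(length(window_um) == 2L, all(window_um > 0),
            cluster_density >= 0, crowd_density >= 0,
            cluster_sigma_nm >= 0, crowd_sigma_nm >= 0,
            molecules_per_cluster >= 1,
            coupling_p >= 0, coupling_p <= 1,
            binding_distance_nm >= 0)
  if (is.null(molecules_per_crowd))
    molecules_per_crowd <- if (crowd_density > 0)
      12 * cluster_density * molecules_per_cluster / crowd_density else 1
  stopifnot(molecules_per_crowd >= 1)
  structure(as.list(environment()), class = "scene_spec")
}

#' Rendering specification: PSF, sampling, noise and distortions
#'
#' @param pixel_size_nm pixel edge (25 for STED-like, 266.67 for
#'   epifluorescence-like sampling).
#' @param psf_fwhm_nm full width at half maximum of the Gaussian PSF (nm).
#' @param intensity_per_molecule integrated intensity contributed by one
#'   molecule (arbitrary units).
#' @param photons_per_unit Poisson photon-noise scale: a pixel of intensity
#'   I draws `Poisson(I * photons_per_unit) / photons_per_unit`; 0 disables.
#' @param read_noise_sd additive Gaussian readout noise SD; 0 disables.
#' @param quench_q fractional intensity loss of a self-quenched fluorophore.
#' @param quench_radius_nm neighbour distance below which self-quenching
#'   acts (a few nm).
#' @param shield_p probability that a label close to a cluster core is
#'   inaccessible (epitope shielding).
#' @param shield_radius_nm distance to a cluster centre within which
#'   shielding applies.
#' @return list of class `render_spec`.
#' @export
render_spec <- function(pixel_size_nm = 25,
                        psf_fwhm_nm = 65,
                        intensity_per_molecule = 10,
                        photons_per_unit = 100,
                        read_noise_sd = 2,
                        quench_q = 0,
                        quench_radius_nm = 5,
                        shield_p = 0,
                        shield_radius_nm = 40) {
  stopifnot(pixel_size_nm > 0, psf_fwhm_nm > 0, intensity_per_molecule >= 0,
            photons_per_unit >= 0, read_noise_sd >= 0,
            quench_q >= 0, quench_q <= 1, quench_radius_nm >= 0,
            shield_p >= 0, shield_p <= 1, shield_radius_nm >= 0)
  structure(as.list(environment()), class = "render_spec")
}

#' Uniform (ideal gas / CSR) point pattern
#'
#' Poisson-distributed count with mean `density * area`, positions uniform
#' in the window; deterministic under `seed`.
#'
#' @param density_per_um2 intensity (points per um^2, >= 0).
#' @param window_um window (width, height) in um.
#' @param seed integer seed (or `NULL` to use the current RNG state).
#' @param channel channel label.
#' @return a [point_pattern()].
#' @export
gen_csr <- function(density_per_um2, window_um, seed = NULL, channel = "") {
  stopifnot(density_per_um2 >= 0, length(window_um) == 2L)
  w_nm <- window_um * 1000
  with_seed(seed, {
    n <- stats::rpois(1L, density_per_um2 * prod(window_um))
    point_pattern(stats::runif(n, 0, w_nm[1]), stats::runif(n, 0, w_nm[2]),
                  w_nm, channel)
  })
}

#' Thomas-type clustered pattern: parent centres plus Gaussian offspring
#'
#' Parent centres follow CSR at `cluster_density`; each parent spawns
#' `molecules_per_cluster` offspring with isotropic Gaussian spread
#' `cluster_sigma_nm`. Offspring falling outside the window are discarded
#' (matching an imaged sub-field), so realized molecule counts near the
#' border run slightly below the process mean.
#'
#' @param spec a [scene_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return list: `centres` (cluster-centre [point_pattern()]) and
#'   `molecules` ([point_pattern()] with a `parent` column).
#' @export
gen_clustered <- function(spec, seed = spec$seed) {
  w_nm <- spec$window_um * 1000
  with_seed(seed, {
    centres <- gen_csr(spec$cluster_density, spec$window_um, seed = NULL,
                       channel = "cluster_centres")
    k <- nrow(centres)
    m <- spec$molecules_per_cluster
    if (k == 0L) {
      mols <- point_pattern(numeric(0), numeric(0), w_nm, "cluster_molecules",
                            extra = data.frame(parent = integer(0)))
    } else {
      px <- rep(centres$x_nm, each = m) +
        stats::rnorm(k * m, 0, spec$cluster_sigma_nm)
      py <- rep(centres$y_nm, each = m) +
        stats::rnorm(k * m, 0, spec$cluster_sigma_nm)
      parent <- rep(seq_len(k), each = m)
      keep <- px >= 0 & px <= w_nm[1] & py >= 0 & py <= w_nm[2]
      mols <- point_pattern(px[keep], py[keep], w_nm, "cluster_molecules",
                            extra = data.frame(parent = parent[keep]))
    }
    list(centres = centres, molecules = mols)
  })
}

#' Crowd centres with recruitment coupling to cluster centres
#'
#' Draws a Poisson number of crowds at `crowd_density`; each crowd is, with
#' probability `coupling_p`, recruited to a uniformly chosen cluster centre
#' and placed at `binding_distance_nm` from it (uniform angle), otherwise
#' placed uniformly in the window. Recruited crowds pushed outside the
#' window are discarded, consistently with [gen_clustered()].
#'
#' @param clusters cluster-centre [point_pattern()].
#' @param spec a [scene_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return crowd-centre [point_pattern()] with a logical `recruited` column.
#' @export
gen_coupled_crowds <- function(clusters, spec, seed = spec$seed) {
  if (spec$coupling_p > 0 && nrow(clusters) == 0L)
    stop("coupling requested but the cluster pattern is empty")
  w_nm <- spec$window_um * 1000
  with_seed(seed, {
    n <- stats::rpois(1L, spec$crowd_density * prod(spec$window_um))
    if (n == 0L)
      return(point_pattern(numeric(0), numeric(0), w_nm, "crowd_centres",
                           extra = data.frame(recruited = logical(0))))
    recruited <- stats::runif(n) < spec$coupling_p
    x <- stats::runif(n, 0, w_nm[1])
    y <- stats::runif(n, 0, w_nm[2])
    nr <- sum(recruited)
    if (nr > 0L) {
      host <- sample.int(nrow(clusters), nr, replace = TRUE)
      ang <- stats::runif(nr, 0, 2 * pi)
      x[recruited] <- clusters$x_nm[host] + spec$binding_distance_nm * cos(ang)
      y[recruited] <- clusters$y_nm[host] + spec$binding_distance_nm * sin(ang)
    }
    keep <- x >= 0 & x <= w_nm[1] & y >= 0 & y <= w_nm[2]
    point_pattern(x[keep], y[keep], w_nm, "crowd_centres",
                  extra = data.frame(recruited = recruited[keep]))
  })
}

#' Render a point pattern into an image through a Gaussian PSF
#'
#' Each point contributes `intensity` times a normalized 2-D Gaussian of
#' FWHM `render$psf_fwhm_nm` (optionally broadened by a per-point physical
#' footprint `point_sigma_nm`, used to render diffuse crowds as blobs),
#' sampled at pixel centres on a grid of `render$pixel_size_nm`. Poisson
#' photon noise and additive Gaussian readout noise follow; deterministic
#' under `seed`. `noise = FALSE` yields the clean forward model.
#'
#' @param molecules a [point_pattern()].
#' @param render a [render_spec()].
#' @param intensity scalar or per-point vector of integrated intensities;
#'   default `render$intensity_per_molecule`.
#' @param point_sigma_nm additional isotropic Gaussian spread per point (nm).
#' @param noise apply the noise model?
#' @param seed RNG seed for the noise.
#' @param channel channel label of the output image.
#' @return an [image2d()] covering the pattern window.
#' @export
render_image <- function(molecules, render, intensity = NULL,
                         point_sigma_nm = 0, noise = TRUE, seed = NULL,
                         channel = attr(molecules, "channel")) {
  w_nm <- pattern_window(molecules)
  ps <- render$pixel_size_nm
  nc <- max(1L, round(w_nm[1] / ps))
  nr <- max(1L, round(w_nm[2] / ps))
  img <- matrix(0, nr, nc)
  n <- nrow(molecules)
  if (is.null(intensity)) intensity <- render$intensity_per_molecule
  intensity <- rep_len(intensity, max(n, 1L))
  sig_nm <- sqrt((render$psf_fwhm_nm / fwhm_factor)^2 + point_sigma_nm^2)
  sig_px <- sig_nm / ps
  r <- ceiling(5 * sig_px) + 1L
  for (i in seq_len(n)) {
    cc <- molecules$x_nm[i] / ps + 0.5   # fractional pixel coordinates
    rc <- molecules$y_nm[i] / ps + 0.5
    c0 <- max(1L, floor(cc) - r); c1 <- min(nc, floor(cc) + r)
    r0 <- max(1L, floor(rc) - r); r1 <- min(nr, floor(rc) + r)
    if (c0 > c1 || r0 > r1) next
    kx <- exp(-((c0:c1) - cc)^2 / (2 * sig_px^2))
    ky <- exp(-((r0:r1) - rc)^2 / (2 * sig_px^2))
    patch <- outer(ky, kx)
    tot <- 2 * pi * sig_px^2   # analytic kernel mass (truncation negligible)
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + intensity[i] * patch / tot
  }
  if (noise) {
    img <- with_seed(seed, {
      out <- img
      if (render$photons_per_unit > 0)
        out <- stats::rpois(length(out),
                            pmax(out, 0) * render$photons_per_unit) /
          render$photons_per_unit
      if (render$read_noise_sd > 0)
        out <- out + stats::rnorm(length(out), 0, render$read_noise_sd)
      matrix(out, nr, nc)
    })
  }
  image2d(img, ps, channel)
}

#' Self-quenching intensity penalty for closely spaced fluorophores
#'
#' A fluorophore with at least one neighbour within `quench_radius_nm`
#' (a few nm) loses the fraction `quench_q` of its intensity; isolated
#' fluorophores are unchanged. Models the signal underestimation expected
#' when identical dyes crowd within Förster-type distances.
#'
#' @param molecules a [point_pattern()].
#' @param intensities per-molecule intensities (recycled if scalar).
#' @param quench_q fractional loss in \[0, 1\].
#' @param quench_radius_nm interaction radius (nm).
#' @return numeric vector of adjusted intensities.
#' @export
apply_quenching <- function(molecules, intensities, quench_q,
                            quench_radius_nm = 5) {
  stopifnot(quench_q >= 0, quench_q <= 1, quench_radius_nm >= 0)
  n <- nrow(molecules)
  intensities <- rep_len(intensities, n)
  if (n < 2L || quench_q == 0) return(intensities)
  d <- block_mindist(molecules$x_nm, molecules$y_nm,
                     molecules$x_nm, molecules$y_nm,
                     self_index = seq_len(n))
  quenched <- d <= quench_radius_nm
  intensities[quenched] <- intensities[quenched] * (1 - quench_q)
  intensities
}

#' Epitope shielding: probabilistic label loss near cluster cores
#'
#' Each label within `shield_radius_nm` of any cluster centre is removed
#' with probability `shield_p`, modelling reduced probe accessibility for
#' molecules buried under a dense cluster. Labels farther away always
#' survive.
#'
#' @param labels a [point_pattern()] of label positions.
#' @param cluster_centres a [point_pattern()] of cluster centres.
#' @param shield_p removal probability in \[0, 1\].
#' @param shield_radius_nm shielding radius (nm).
#' @param seed RNG seed.
#' @return the surviving subset as a [point_pattern()].
#' @export
apply_shielding <- function(labels, cluster_centres, shield_p,
                            shield_radius_nm, seed = NULL) {
  stopifnot(shield_p >= 0, shield_p <= 1, shield_radius_nm >= 0)
  n <- nrow(labels)
  if (n == 0L || shield_p == 0 || nrow(cluster_centres) == 0L)
    return(labels)
  d <- block_mindist(labels$x_nm, labels$y_nm,
                     cluster_centres$x_nm, cluster_centres$y_nm)
  with_seed(seed, {
    at_risk <- d <= shield_radius_nm
    removed <- at_risk & (stats::runif(n) < shield_p)
    pattern_subset(labels, !removed)
  })
}

#' Simulate a complete two-channel scene
#'
#' Generates cluster centres + molecules and coupled crowd centres, applies
#' optional shielding to the cluster-channel labels and quenching to their
#' intensities, and renders both channels: the cluster channel from
#' individual molecules, the crowd channel from crowd centres as Gaussian
#' blobs of `crowd_sigma_nm`.
#'
#' @param spec a [scene_spec()].
#' @param render a [render_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return list: `cluster_image`, `crowd_image` ([image2d()]),
#'   `clusters`, `cluster_molecules`, `crowds` (point patterns), `spec`,
#'   `render`, `seed`.
#' @export
simulate_scene <- function(spec, render = render_spec(), seed = spec$seed) {
  cl <- gen_clustered(spec, seed = derive_seed(seed, 1))
  crowds <- gen_coupled_crowds(cl$centres, spec, seed = derive_seed(seed, 2))
  labels <- cl$molecules
  if (render$shield_p > 0)
    labels <- apply_shielding(labels, cl$centres, render$shield_p,
                              render$shield_radius_nm,
                              seed = derive_seed(seed, 3))
  inten <- rep(render$intensity_per_molecule, nrow(labels))
  if (render$quench_q > 0)
    inten <- apply_quenching(labels, inten, render$quench_q,
                             render$quench_radius_nm)
  cluster_image <- render_image(labels, render, intensity = inten,
                                seed = derive_seed(seed, 4),
                                channel = "cluster")
  crowd_image <- render_image(
    crowds, render,
    intensity = render$intensity_per_molecule * spec$molecules_per_crowd,
    point_sigma_nm = spec$crowd_sigma_nm,
    seed = derive_seed(seed, 5), channel = "crowd")
  list(cluster_image = cluster_image, crowd_image = crowd_image,
       clusters = cl$centres, cluster_molecules = cl$molecules,
       crowds = crowds, spec = spec, render = render, seed = seed)
}
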