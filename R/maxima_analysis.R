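## Maxima detection and sizing on STED-scale images.
##
## Detection follows the topographic-prominence definition: a local maximum
## (or connected equal-valued plateau) is reported iff every path from it to
## any strictly higher pixel descends by at least `prominence` below the peak
## value. Implemented as a single sweep over pixels in decreasing intensity
## with union-find merging of catchment components ("persistence"): when a
## component whose peak is p merges into a component with a higher peak
## through a saddle of value s, its peak is reported iff p - s >= prominence.
## Components with EQUAL peaks are not "higher regions" for each other, so
## both candidates stay alive until the merged component meets a strictly
## higher one. Connected plateaus of equal value yield one point at the
## plateau centroid.

## ---- flat zones ----------------------------------------------------------

## Label maximal connected regions of constant pixel value (8-connectivity).
## Returns integer matrix of zone ids (1..K, column-major discovery order).
flat_zones <- function(v) {
  nr <- nrow(v); nc <- ncol(v); n <- nr * nc
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- matrix(seq_len(n), nr, nc)
  # the four forward neighbour offsets cover all 8-neighbour pairs
  pairs <- rbind(
    cbind(as.vector(idx[-nr, ]),  as.vector(idx[-1, ])),        # down
    cbind(as.vector(idx[, -nc]),  as.vector(idx[, -1])),        # right
    cbind(as.vector(idx[-nr, -nc]), as.vector(idx[-1, -1])),    # down-right
    cbind(as.vector(idx[-nr, -1]),  as.vector(idx[-1, -nc])))   # down-left
  eq <- v[pairs[, 1]] == v[pairs[, 2]]
  pairs <- pairs[eq, , drop = FALSE]
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  matrix(match(root, sort(unique(root))), nr, nc)
}

## ---- detection -----------------------------------------------------------

#' Robust pixel-noise estimate within an ROI
#'
#' 1.4826 times the median absolute deviation of the residual between the
#' image and its 3 x 3 median filter — the standard robust estimator of the
#' pixel noise floor, insensitive to the structured signal. Used to default
#' the detection prominence (5 x noise).
#'
#' @param image an [image2d()].
#' @param roi optional [roi()]; defaults to the full frame.
#' @return noise sigma estimate (intensity units).
#' @export
robust_noise <- function(image, roi = NULL) {
  m <- unclass(image)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) {
    px <- if (is.null(roi)) as.numeric(m) else m[unclass(roi)]
    return(stats::mad(px))
  }
  # 3x3 median via 9 shifted copies of the interior
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  core <- function(dr, dc) as.vector(m[(2:(nr - 1)) + dr, (2:(nc - 1)) + dc])
  stack <- mapply(core, shifts$dr, shifts$dc)
  med <- apply(stack, 1L, stats::median)
  resid <- m
  resid[] <- 0
  resid[2:(nr - 1), 2:(nc - 1)] <- m[2:(nr - 1), 2:(nc - 1)] - med
  inner <- matrix(FALSE, nr, nc)
  inner[2:(nr - 1), 2:(nc - 1)] <- TRUE
  sel <- if (is.null(roi)) inner else inner & unclass(roi)
  if (!any(sel)) sel <- inner
  stats::mad(resid[sel])
}

#' Detect intensity maxima by topographic prominence
#'
#' Reports local maxima whose height exceeds the highest saddle to any
#' strictly higher region by at least `prominence` (the "noise tolerance" of
#' prominence-based spot detection). Plateaus of equal value yield one point
#' at the plateau centroid. Detection may run on a pre-smoothed copy of the
#' image (e.g. sigma 0.5 px for noisy diffuse channels) while coordinates
#' refer to the common pixel grid; linescan sizing is typically then done on
#' the raw image.
#'
#' @param image an [image2d()].
#' @param roi optional [roi()]; maxima outside it are dropped. Maxima whose
#'   peak pixel touches the image edge or a non-ROI pixel are kept but
#'   flagged `on_border`.
#' @param prominence minimum peak-over-saddle height (> 0). Default:
#'   `5 * robust_noise(image, roi)`.
#' @param presmooth_sigma_px Gaussian sigma (px) applied before detection;
#'   0 disables.
#' @return [point_pattern()] with columns `x_nm`, `y_nm`, `value` (peak
#'   height on the detection image) and `on_border`; coordinates are pixel
#'   centres, x along columns, y along rows, origin at the image corner.
#' @export
find_maxima <- function(image, roi = NULL, prominence = NULL,
                        presmooth_sigma_px = 0) {
  if (!is.null(roi)) check_congruent(image, roi)
  det <- if (presmooth_sigma_px > 0)
    gaussian_blur(image, presmooth_sigma_px) else image
  if (is.null(prominence)) {
    prominence <- 5 * robust_noise(det, roi)
    if (!is.finite(prominence) || prominence <= 0)
      stop("could not estimate a positive default prominence; supply one")
  }
  if (!is.numeric(prominence) || length(prominence) != 1L || prominence <= 0)
    stop("'prominence' must be a single positive number")

  v <- unclass(det)
  nr <- nrow(v); nc <- ncol(v)
  zone <- flat_zones(v)
  nz <- max(zone)
  zrows <- row(v); zcols <- col(v)
  zone_vec <- as.vector(zone)
  zval <- as.vector(rowsum(as.vector(v), zone_vec)) /
    tabulate(zone_vec, nz)
  zn <- tabulate(zone_vec, nz)
  zr <- as.vector(rowsum(as.vector(zrows), zone_vec)) / zn
  zc <- as.vector(rowsum(as.vector(zcols), zone_vec)) / zn

  # zone adjacency (unique unordered pairs across unequal values)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pr <- rbind(
    cbind(as.vector(idx[-nr, ]),  as.vector(idx[-1, ])),
    cbind(as.vector(idx[, -nc]),  as.vector(idx[, -1])),
    cbind(as.vector(idx[-nr, -nc]), as.vector(idx[-1, -1])),
    cbind(as.vector(idx[-nr, -1]),  as.vector(idx[-1, -nc])))
  za <- zone_vec[pr[, 1]]; zb <- zone_vec[pr[, 2]]
  keep <- za != zb
  za <- za[keep]; zb <- zb[keep]
  lo <- pmin(za, zb); hi <- pmax(za, zb)
  uq <- !duplicated(lo * (nz + 1) + hi)
  lo <- lo[uq]; hi <- hi[uq]
  # CSR-style adjacency: neighbours of z are nbr[(ptr[z]+1):ptr[z+1]]
  srcs <- c(lo, hi); dsts <- c(hi, lo)
  o <- order(srcs)
  nbr <- dsts[o]
  ptr <- c(0L, cumsum(tabulate(srcs, nz)))

  ord <- order(zval, decreasing = TRUE)
  processed <- logical(nz)
  parent <- seq_len(nz)
  peak <- zval                       # peak value of the component at root
  pend <- vector("list", nz)         # pending candidate maxima per root
  acc_r <- numeric(0); acc_c <- numeric(0); acc_v <- numeric(0)

  for (z in ord) {
    processed[z] <- TRUE
    a <- ptr[z] + 1L; b <- ptr[z + 1L]
    nb <- if (a > b) integer(0) else nbr[a:b]
    nb <- nb[processed[nb]]
    if (length(nb) == 0L) {
      # a plateau local maximum: starts its own component
      pend[[z]] <- list(list(r = zr[z], c = zc[z], v = zval[z]))
      next
    }
    roots <- integer(length(nb))
    for (j in seq_along(nb)) {       # inline union-find with path halving
      i <- nb[j]
      while (parent[i] != i) {
        parent[i] <- parent[parent[i]]
        i <- parent[i]
      }
      roots[j] <- i
    }
    roots <- unique(roots)
    s <- zval[z]                     # saddle value of every merge through z
    # attach z to the component with the highest peak; merge the rest in
    main <- roots[which.max(peak[roots])]
    parent[z] <- main
    for (rt in roots[roots != main]) {
      if (peak[rt] == peak[main]) {
        # equal peaks: neither side is a higher region; both stay pending
        pend[[main]] <- c(pend[[main]], pend[[rt]])
      } else if (peak[rt] - s >= prominence) {
        pd <- pend[[rt]]
        acc_r <- c(acc_r, vapply(pd, `[[`, 0, "r"))
        acc_c <- c(acc_c, vapply(pd, `[[`, 0, "c"))
        acc_v <- c(acc_v, vapply(pd, `[[`, 0, "v"))
      }
      pend[rt] <- list(NULL)
      parent[rt] <- main
    }
  }
  # surviving components (one per connected image region): accept pending
  for (rt in which(parent == seq_len(nz))) {
    pd <- pend[[rt]]
    if (is.null(pd) || length(pd) == 0L) next
    acc_r <- c(acc_r, vapply(pd, `[[`, 0, "r"))
    acc_c <- c(acc_c, vapply(pd, `[[`, 0, "c"))
    acc_v <- c(acc_v, vapply(pd, `[[`, 0, "v"))
  }

  ps <- pixel_size(image)
  # border / ROI handling at the nearest pixel to each peak centroid
  ri <- pmin(pmax(round(acc_r), 1L), nr)
  ci <- pmin(pmax(round(acc_c), 1L), nc)
  on_edge <- ri == 1L | ri == nr | ci == 1L | ci == nc
  if (!is.null(roi)) {
    m <- unclass(roi)
    inside <- m[cbind(ri, ci)]
    # flag peaks adjacent to a non-ROI pixel
    near_out <- vapply(seq_along(ri), function(i) {
      rr <- max(1L, ri[i] - 1L):min(nr, ri[i] + 1L)
      cc <- max(1L, ci[i] - 1L):min(nc, ci[i] + 1L)
      any(!m[rr, cc])
    }, logical(1))
    keep <- inside
    acc_r <- acc_r[keep]; acc_c <- acc_c[keep]; acc_v <- acc_v[keep]
    on_border <- (on_edge | near_out)[keep]
  } else {
    on_border <- on_edge
  }
  o <- order(acc_v, decreasing = TRUE)
  point_pattern(x_nm = (acc_c[o] - 0.5) * ps,
                y_nm = (acc_r[o] - 0.5) * ps,
                window_nm = c(nc * ps, nr * ps),
                channel = attr(image, "channel"),
                extra = data.frame(value = acc_v[o],
                                   on_border = on_border[o]))
}

## ---- linescan Gaussian sizing -------------------------------------------

fwhm_factor <- 2 * sqrt(2 * log(2))

gfit_fail <- function(orientation, reason) {
  structure(list(amplitude = NA_real_, centre_px = NA_real_,
                 sigma_px = NA_real_, offset = NA_real_, r2 = NA_real_,
                 fwhm_nm = NA_real_, orientation = orientation,
                 qc_pass = FALSE, reason = reason),
            class = "gaussian_fit")
}

## Fit amplitude * exp(-(x - mu)^2 / (2 sigma^2)) + offset to a profile
## sampled at x = 0 .. length(profile) - 1.
fit_gaussian_profile <- function(profile, pixel_size_nm, orientation,
                                 centre_range = NULL) {
  np <- length(profile)
  x <- seq_len(np) - 1
  if (is.null(centre_range)) centre_range <- c((np - 1) / 3, 2 * (np - 1) / 3)
  if (stats::sd(profile) == 0)
    return(gfit_fail(orientation, "degenerate profile"))
  try_fit <- function(start) tryCatch(
    minpack.lm::nlsLM(profile ~ A * exp(-(x - mu)^2 / (2 * sig^2)) + off,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  rsq <- function(fit) 1 - sum((profile - stats::predict(fit))^2) /
    sum((profile - mean(profile))^2)
  # multi-start: centred start, plus the profile argmax when it sits away
  # from the centre (the objective is multi-modal for off-centre peaks)
  fit <- try_fit(list(A = max(profile) - min(profile), mu = (np - 1) / 2,
                      sig = 3, off = min(profile)))
  amax <- which.max(profile) - 1
  if (abs(amax - (np - 1) / 2) > 2 || is.null(fit)) {
    alt <- try_fit(list(A = max(profile) - min(profile), mu = amax,
                        sig = 3, off = min(profile)))
    if (!is.null(alt) && (is.null(fit) || rsq(alt) > rsq(fit))) fit <- alt
  }
  if (is.null(fit)) return(gfit_fail(orientation, "fit failed"))
  cf <- stats::coef(fit)
  r2 <- rsq(fit)
  sig <- abs(cf[["sig"]])
  reasons <- character(0)
  if (!(r2 >= 0.8)) reasons <- c(reasons, "R2 below 0.8")
  if (!(cf[["mu"]] >= centre_range[1] && cf[["mu"]] <= centre_range[2]))
    reasons <- c(reasons, "non-centred peak")
  structure(list(amplitude = unname(cf[["A"]]), centre_px = unname(cf[["mu"]]),
                 sigma_px = sig, offset = unname(cf[["off"]]), r2 = r2,
                 fwhm_nm = fwhm_factor * sig * pixel_size_nm,
                 orientation = orientation,
                 qc_pass = length(reasons) == 0L,
                 reason = if (length(reasons)) paste(reasons, collapse = "; ")
                          else "ok"),
            class = "gaussian_fit")
}

#' Size one maximum by a linescan Gaussian fit
#'
#' Extracts a `length_px` x `width_px` linescan centred on the maximum
#' (horizontal: along columns; vertical: along rows), averages across the
#' width into a 1-D profile, and fits a Gaussian with constant offset by
#' nonlinear least squares. The full width at half maximum of the fitted
#' Gaussian, in nm, is the maximum's size. Quality control: the fit passes
#' iff R^2 >= 0.8 on the averaged profile and the fitted centre lies in the
#' middle third of the scan (positions 10..20 inclusive on the default
#' 31-sample, 0-based axis). A linescan not fully inside the image fails QC
#' with reason "out of bounds" rather than erroring.
#'
#' @param image an [image2d()] (normally the raw, un-smoothed channel).
#' @param point length-2 numeric (x_nm, y_nm) position of the maximum.
#' @param length_px,width_px linescan geometry (odd; defaults 31 and 3).
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return object of class `gaussian_fit`: `amplitude`, `centre_px`,
#'   `sigma_px`, `offset`, `r2`, `fwhm_nm`, `orientation`, `qc_pass`,
#'   `reason`.
#' @export
fit_linescan <- function(image, point, length_px = 31, width_px = 3,
                         orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  ps <- pixel_size(image)
  ci <- round(point[1] / ps + 0.5)
  ri <- round(point[2] / ps + 0.5)
  hl <- (length_px - 1) / 2
  hw <- (width_px - 1) / 2
  if (orientation == "horizontal") {
    rows <- (ri - hw):(ri + hw); cols <- (ci - hl):(ci + hl)
  } else {
    rows <- (ri - hl):(ri + hl); cols <- (ci - hw):(ci + hw)
  }
  if (min(rows) < 1L || max(rows) > nrow(image) ||
      min(cols) < 1L || max(cols) > ncol(image))
    return(gfit_fail(orientation, "out of bounds"))
  block <- unclass(image)[rows, cols, drop = FALSE]
  profile <- if (orientation == "horizontal") colMeans(block)
             else rowMeans(block)
  mid <- c((length_px - 1) / 3, 2 * (length_px - 1) / 3)
  if (length_px == 31) mid <- c(10, 20)   # exact middle-third convention
  fit_gaussian_profile(profile, ps, orientation, centre_range = mid)
}

#' Per-maximum sizes and per-ROI mean size
#'
#' For each detected maximum, fits both a horizontal and a vertical linescan
#' Gaussian on the raw image, keeps the orientation with the better fit
#' quality (higher R^2), drops maxima failing quality control, and averages
#' the surviving FWHM values. With zero survivors the mean size is `NA` and
#' flagged, never silently 0.
#'
#' @param image an [image2d()] (raw channel; sizes should not be
#'   blur-inflated, so pass the un-smoothed image even if detection was
#'   pre-smoothed).
#' @param pattern a [point_pattern()] of maxima detected on this image.
#' @param length_px,width_px linescan geometry.
#' @return list: `mean_size_nm`, `n_used`, `n_total`, and `table` — one row
#'   per maximum with both orientations' R^2, the chosen orientation,
#'   `fwhm_nm`, `qc_pass`, `reason`.
#' @export
maxima_size <- function(image, pattern, length_px = 31, width_px = 3) {
  n <- nrow(pattern)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- c(pattern$x_nm[i], pattern$y_nm[i])
    fh <- fit_linescan(image, p, length_px, width_px, "horizontal")
    fv <- fit_linescan(image, p, length_px, width_px, "vertical")
    r2h <- if (is.na(fh$r2)) -Inf else fh$r2
    r2v <- if (is.na(fv$r2)) -Inf else fv$r2
    best <- if (r2h >= r2v) fh else fv
    rows[[i]] <- data.frame(
      x_nm = p[1], y_nm = p[2], r2_horizontal = fh$r2, r2_vertical = fv$r2,
      orientation = best$orientation, fwhm_nm = best$fwhm_nm, r2 = best$r2,
      qc_pass = best$qc_pass, reason = best$reason,
      stringsAsFactors = FALSE)
  }
  tab <- if (n > 0L) do.call(rbind, rows) else
    data.frame(x_nm = numeric(0), y_nm = numeric(0),
               r2_horizontal = numeric(0), r2_vertical = numeric(0),
               orientation = character(0), fwhm_nm = numeric(0),
               r2 = numeric(0), qc_pass = logical(0), reason = character(0))
  ok <- tab$qc_pass
  list(mean_size_nm = if (any(ok)) mean(tab$fwhm_nm[ok]) else NA_real_,
       n_used = sum(ok), n_total = n, table = tab)
}

#' Maxima density per square micrometre
#'
#' Relates the number of detected maxima to the size of the analyzed area.
#'
#' @param pattern a [point_pattern()] of maxima.
#' @param roi an [roi()] with positive area (or `NULL` to use the pattern
#'   window area).
#' @return points per square micrometre.
#' @export
maxima_density <- function(pattern, roi = NULL) {
  area <- if (is.null(roi)) prod(pattern_window(pattern)) / 1e6
          else roi_area_um2(roi)
  if (!is.finite(area) || area <= 0) stop("ROI area must be positive")
  nrow(pattern) / area
}
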