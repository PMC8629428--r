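# In-code fixtures shared across test files.

# Image whose pixels sample a 2-D Gaussian spot (continuous model, pixel
# centres), on a constant offset.
gaussian_spot_image <- function(n = 41, amplitude = 100, centre = c(21, 21),
                                sigma_px = 3, offset = 0,
                                pixel_size_nm = 25, channel = "") {
  xs <- seq_len(n)
  m <- offset + amplitude * outer(exp(-(xs - centre[1])^2 / (2 * sigma_px^2)),
                                  exp(-(xs - centre[2])^2 / (2 * sigma_px^2)))
  image2d(m, pixel_size_nm, channel)
}

# Ridge image: every row carries the same Gaussian profile along columns,
# so a width-averaged horizontal linescan reproduces the profile exactly.
ridge_image <- function(n = 41, amplitude = 100, centre_col = 21,
                        sigma_px = 3, offset = 0, pixel_size_nm = 25) {
  prof <- offset + amplitude *
    exp(-(seq_len(n) - centre_col)^2 / (2 * sigma_px^2))
  image2d(matrix(prof, n, n, byrow = TRUE), pixel_size_nm)
}

# Binary disc of radius r_px centred at (row, col), scaled by `value`.
disc_image <- function(n, centre, r_px, value = 100, pixel_size_nm = 266.67) {
  m <- outer(seq_len(n), seq_len(n), function(r, c)
    ifelse((r - centre[1])^2 + (c - centre[2])^2 <= r_px^2, value, 0))
  image2d(m, pixel_size_nm)
}

# Render one isolated Gaussian spot of the given FWHM (nm) and measure it
# back through detection + dual linescan sizing.
roundtrip_fwhm <- function(fwhm_nm, pixel_size_nm = 25) {
  rs <- render_spec(pixel_size_nm = pixel_size_nm, psf_fwhm_nm = fwhm_nm,
                    photons_per_unit = 0, read_noise_sd = 0)
  w <- 40 * pixel_size_nm
  pp <- point_pattern(w / 2, w / 2, c(w, w))
  img <- render_image(pp, rs, intensity = 1000, noise = FALSE)
  pat <- find_maxima(img, prominence = max(img) / 2)
  maxima_size(img, pat)$mean_size_nm
}

# Exhaustive reference implementation of prominence-based maxima detection:
# a local-max plateau of value v is accepted iff no strictly higher pixel is
# reachable through pixels with value > v - prominence. O(n_max * n_pixels).
brute_force_maxima <- function(m, prominence) {
  nr <- nrow(m); nc <- ncol(m)
  neighbours <- function(i) {
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    rr <- max(1L, r - 1L):min(nr, r + 1L)
    cc <- max(1L, c - 1L):min(nc, c + 1L)
    setdiff(as.vector(outer(rr, (cc - 1L) * nr, "+")), i)
  }
  flood <- function(seed_set, keepable) {
    vis <- logical(nr * nc); vis[seed_set] <- TRUE
    frontier <- seed_set
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in frontier) for (j in neighbours(i)) {
        if (!vis[j] && keepable(j)) { vis[j] <- TRUE; nxt <- c(nxt, j) }
      }
      frontier <- nxt
    }
    which(vis)
  }
  seen <- logical(nr * nc)
  out <- NULL
  for (i in seq_len(nr * nc)) {
    if (seen[i]) next
    v <- m[i]
    plateau <- flood(i, function(j) m[j] == v)
    seen[plateau] <- TRUE
    ring <- setdiff(unique(unlist(lapply(plateau, neighbours))), plateau)
    if (any(m[ring] > v)) next                     # not a local max plateau
    region <- flood(plateau, function(j) m[j] > v - prominence)
    if (any(m[region] > v)) next                   # dominated within tolerance
    r <- (plateau - 1L) %% nr + 1L; c <- (plateau - 1L) %/% nr + 1L
    out <- rbind(out, c(row = mean(r), col = mean(c), value = v))
  }
  out
}

# Convert a point_pattern back to fractional pixel (row, col) coordinates.
pattern_to_px <- function(pattern, pixel_size_nm) {
  cbind(row = pattern$y_nm / pixel_size_nm + 0.5,
        col = pattern$x_nm / pixel_size_nm + 0.5)
}

sorted_rows <- function(m) {
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
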