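#' Planar point pattern in a rectangular observation window
#'
#' Detected maxima of one channel (or generated ground-truth molecule
#' positions): planar coordinates in nanometres inside a rectangular window
#' with its origin at (0, 0).
#'
#' @param x_nm,y_nm numeric coordinates in nm.
#' @param window_nm numeric length-2: window (width, height) in nm.
#' @param channel free-text channel label.
#' @param extra optional data.frame of per-point columns (same length).
#' @return data.frame of class `point_pattern` with columns `x_nm`, `y_nm`
#'   (plus any `extra` columns) and attributes `window_nm` and `channel`.
#' @export
point_pattern <- function(x_nm, y_nm, window_nm, channel = "", extra = NULL) {
  if (length(x_nm) != length(y_nm)) stop("x and y lengths differ")
  if (length(window_nm) != 2L || any(!is.finite(window_nm)) ||
      any(window_nm <= 0))
    stop("'window_nm' must be two positive numbers (width, height)")
  if (length(x_nm) > 0L) {
    eps <- 1e-9 * max(window_nm)
    if (any(x_nm < -eps | x_nm > window_nm[1] + eps |
            y_nm < -eps | y_nm > window_nm[2] + eps))
      stop("points outside the observation window")
  }
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm))
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(df))
    df <- cbind(df, extra)
  }
  structure(df, window_nm = as.numeric(window_nm),
            channel = as.character(channel),
            class = c("point_pattern", "data.frame"))
}

#' @export
print.point_pattern <- function(x, ...) {
  w <- attr(x, "window_nm")
  cat(sprintf(
    "point_pattern: %d points in %.4g x %.4g nm window (channel '%s')\n",
    nrow(x), w[1], w[2], attr(x, "channel")))
  cat(sprintf("  intensity (density): %.4g points per um^2\n",
              pattern_density(x)))
  invisible(x)
}

#' Window of a point pattern (nm)
#' @param pattern a `point_pattern`.
#' @export
pattern_window <- function(pattern) attr(pattern, "window_nm")

#' Point density in points per square micrometre
#' @param pattern a `point_pattern`.
#' @export
pattern_density <- function(pattern) {
  w <- attr(pattern, "window_nm")
  nrow(pattern) / (prod(w) / 1e6)
}

## subset rows, keeping attributes
pattern_subset <- function(pattern, keep) {
  point_pattern(pattern$x_nm[keep], pattern$y_nm[keep],
                attr(pattern, "window_nm"), attr(pattern, "channel"),
                extra = as.data.frame(unclass(pattern))[keep,
                  setdiff(names(pattern), c("x_nm", "y_nm")), drop = FALSE])
}
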