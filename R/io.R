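## File interfaces: grayscale TIFF images, point patterns and histograms as
## CSV with a JSON provenance sidecar, specs as YAML.

#' Read a single-channel grayscale TIFF as an image
#'
#' Integer TIFFs (8/16-bit) are read at their native integer scale; float
#' TIFFs as stored. Multi-sample images are reduced to their first channel.
#' If a `<path>.json` sidecar written by [write_image_tiff()] is present,
#' its intensity scale, pixel size and channel label are applied (explicit
#' arguments still win when supplied).
#'
#' @param path TIFF file path.
#' @param pixel_size_nm physical pixel size (nm) to attach; may be omitted
#'   when the sidecar carries it.
#' @param channel channel label.
#' @return an [image2d()].
#' @export
read_image_tiff <- function(path, pixel_size_nm = NULL, channel = NULL) {
  sidecar <- paste0(path, ".json")
  m <- tiff::readTIFF(path, as.is = !file.exists(sidecar))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    m <- m * meta$intensity_scale + meta$intensity_offset
    if (is.null(pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
    if (is.null(channel)) channel <- meta$channel
  }
  if (is.null(pixel_size_nm))
    stop("supply 'pixel_size_nm' (no sidecar found)")
  image2d(m, pixel_size_nm, if (is.null(channel)) "" else channel)
}

#' Write an image as a 32-bit float grayscale TIFF with a JSON sidecar
#'
#' TIFF float samples are stored normalized to \[0, 1\]; the normalization
#' factor, pixel size and channel label travel in a `<path>.json` sidecar so
#' [read_image_tiff()] restores the original intensities.
#'
#' @param image an [image2d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  m <- unclass(image)
  lo <- min(m)
  scale <- max(m) - lo
  if (scale <= 0) scale <- 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(intensity_scale = scale, intensity_offset = lo,
         pixel_size_nm = pixel_size(image),
         channel = attr(image, "channel")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a point pattern to CSV with a JSON sidecar
#'
#' The CSV holds the per-point columns; the sidecar (`<path>.json`) records
#' the window, channel, point count and any extra provenance (seed,
#' replicate counts) so stochastic outputs stay reproducible.
#'
#' @param pattern a [point_pattern()].
#' @param path CSV output path.
#' @param provenance named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_pattern_csv <- function(pattern, path, provenance = list()) {
  utils::write.csv(as.data.frame(unclass(pattern)), path,
                   row.names = FALSE)
  meta <- c(list(window_nm = pattern_window(pattern),
                 channel = attr(pattern, "channel"),
                 n_points = nrow(pattern)), provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a point pattern written by [write_pattern_csv()]
#' @param path CSV path (expects the `.json` sidecar next to it).
#' @return a [point_pattern()].
#' @export
read_pattern_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  point_pattern(df$x_nm, df$y_nm, meta$window_nm, meta$channel,
                extra = df[, setdiff(names(df), c("x_nm", "y_nm")),
                           drop = FALSE])
}

#' Write a distance histogram (optionally with its CSR envelope) to CSV
#'
#' @param hist a `distance_histogram`.
#' @param path CSV output path.
#' @param csr optional `csr_reference`; its matching envelope columns
#'   (`csr_mean`, `csr_lo`, `csr_hi`) are joined on the bins, and its seed
#'   and replicate count go into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path, csr = NULL) {
  out <- as.data.frame(unclass(hist))
  meta <- list(type = attr(hist, "type"),
               n_reference = attr(hist, "n_reference"))
  if (!is.null(csr)) {
    stat <- switch(attr(hist, "type"),
                   nn_histogram = csr$nn_density,
                   radial_cross_counts = csr$radial_mean_count,
                   pair_distribution = csr$g)
    if (!is.null(stat) && nrow(stat) == nrow(out)) {
      out$csr_mean <- stat$mean; out$csr_lo <- stat$lo
      out$csr_hi <- stat$hi
    }
    meta$csr_seed <- csr$seed
    meta$csr_replicates <- csr$n_replicates
  }
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a scene or render spec to YAML
#' @param spec a [scene_spec()] or [render_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a scene spec from YAML
#' @param path YAML path.
#' @return a [scene_spec()].
#' @export
read_scene_yaml <- function(path) {
  do.call(scene_spec, yaml::read_yaml(path))
}

#' Read a render spec from YAML
#' @param path YAML path.
#' @return a [render_spec()].
#' @export
read_render_yaml <- function(path) {
  do.call(render_spec, yaml::read_yaml(path))
}
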