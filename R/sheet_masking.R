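## Epifluorescence-scale stage: segment glass-adhered membrane sheets with
## the blur-and-threshold binary mask, measure per-sheet dual-channel mean
## intensities on the RAW images, and the confocal plasma-membrane fraction
## arithmetic.

#' Segment membrane sheets by blur, threshold and labelling
#'
#' Smooths the frame with a Gaussian blur (default sigma 3 px, which
#' defines the sheet outlines better than the raw image), thresholds
#' (default: Otsu on the blurred frame — parameter-free and
#' scale-invariant; or a fixed absolute threshold), labels connected
#' components (8-connectivity) and discards components smaller than
#' `min_area_um2`. The labels map back onto the raw image for intensity
#' measurement. Sheets touching the frame border are kept but flagged.
#'
#' @param image an [image2d()] (typically the GFP channel).
#' @param sigma_px blur sigma in px.
#' @param threshold `"otsu"` or a fixed numeric threshold on the blurred
#'   frame.
#' @param min_area_um2 minimum sheet area (um^2); smaller components are
#'   debris.
#' @return object of class `sheet_mask`: list with `labels` (integer
#'   matrix, 0 = background), `sheets` (data.frame `sheet_id`, `area_um2`,
#'   `on_border`), `sigma_px`, `threshold`. With no surviving component an
#'   empty mask is returned with a warning, not an error.
#' @export
segment_sheets <- function(image, sigma_px = 3, threshold = "otsu",
                           min_area_um2 = 4) {
  blurred <- gaussian_blur(image, sigma_px)
  v <- unclass(blurred)
  empty <- function(th) {
    warning("no membrane sheet survives segmentation")
    structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                   sheets = data.frame(sheet_id = integer(0),
                                       area_um2 = numeric(0),
                                       on_border = logical(0)),
                   sigma_px = sigma_px, threshold = th),
              class = "sheet_mask")
  }
  if (identical(threshold, "otsu")) {
    rng <- range(v)
    if (diff(rng) == 0) return(empty(NA_real_))
    th <- EBImage::otsu(EBImage::Image(v), range = rng)
  } else {
    th <- as.numeric(threshold)
  }
  bw <- v > th
  if (!any(bw)) return(empty(th))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  px_area_um2 <- (pixel_size(image) / 1000)^2
  counts <- tabulate(lab[lab > 0L])
  keep_ids <- which(counts * px_area_um2 >= min_area_um2)
  if (length(keep_ids) == 0L) return(empty(th))
  relabel <- integer(length(counts))
  relabel[keep_ids] <- seq_along(keep_ids)
  labels <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0L
  labels[sel] <- relabel[lab[sel]]
  nr <- nrow(labels); nc <- ncol(labels)
  border_ids <- unique(c(labels[1, ], labels[nr, ], labels[, 1],
                         labels[, nc]))
  sheets <- data.frame(
    sheet_id = seq_along(keep_ids),
    area_um2 = counts[keep_ids] * px_area_um2,
    on_border = seq_along(keep_ids) %in% border_ids)
  structure(list(labels = labels, sheets = sheets, sigma_px = sigma_px,
                 threshold = as.numeric(th)),
            class = "sheet_mask")
}

#' Per-sheet dual-channel mean intensities
#'
#' Measures the background-corrected mean intensity of every sheet (as
#' defined by the binary mask) on the two RAW channels — never on the
#' blurred image used for segmentation. The rows are the natural input to
#' [linear_fit()] for intensity-vs-intensity regression across sheets.
#'
#' @param raw_a,raw_b congruent raw [image2d()] channels.
#' @param mask a `sheet_mask` from [segment_sheets()] on the same field.
#' @param background_a,background_b scalar backgrounds subtracted from the
#'   per-sheet means.
#' @return data.frame: `sheet_id`, `area_um2`, `on_border`, `mean_a`,
#'   `mean_b`.
#' @export
sheet_intensity_table <- function(raw_a, raw_b, mask, background_a = 0,
                                  background_b = 0) {
  if (!all(dim(raw_a) == dim(mask$labels)) ||
      !all(dim(raw_b) == dim(mask$labels)))
    stop("image and mask dimensions do not match")
  sheets <- mask$sheets
  if (nrow(sheets) == 0L)
    return(cbind(sheets, mean_a = numeric(0), mean_b = numeric(0)))
  sel <- mask$labels > 0L
  ids <- mask$labels[sel]
  mean_a <- as.vector(rowsum(unclass(raw_a)[sel], ids)) /
    tabulate(ids) - background_a
  mean_b <- as.vector(rowsum(unclass(raw_b)[sel], ids)) /
    tabulate(ids) - background_b
  cbind(sheets, mean_a = mean_a, mean_b = mean_b)
}

#' Plasma membrane fraction from three nested ROIs
#'
#' From the background-corrected integrated densities (mean intensity times
#' area) of three nested regions drawn on an equatorial confocal section —
#' the cell outline (`outer_rim`), the cytoplasm (`inner_rim`) and the
#' `nucleus` — computes `plasma membrane signal = outer - inner`,
#' `cytoplasm signal = inner - nucleus`, and
#' `fraction = pm / (pm + cytoplasm)`.
#'
#' @param outer_rim,inner_rim,nucleus integrated densities with
#'   `outer_rim >= inner_rim >= nucleus >= 0`.
#' @return scalar fraction in \[0, 1\].
#' @export
plasma_membrane_fraction <- function(outer_rim, inner_rim, nucleus) {
  if (any(!is.finite(c(outer_rim, inner_rim, nucleus))))
    stop("integrated densities must be finite")
  if (nucleus < 0 || inner_rim < nucleus || outer_rim < inner_rim)
    stop("requires outer_rim >= inner_rim >= nucleus >= 0")
  pm <- outer_rim - inner_rim
  cyto <- inner_rim - nucleus
  if (pm + cyto <= 0)
    stop("plasma membrane fraction undefined: no signal outside the nucleus")
  pm / (pm + cyto)
}
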