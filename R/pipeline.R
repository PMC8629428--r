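## Orchestration: configuration-driven runs of the full measurement chain
## (detect -> size -> rSDM/PCC -> distance statistics) over sets of
## two-channel fields, and percent-of-control condition comparison.

#' Default analysis parameters
#'
#' All values default to the measurement conventions of the pipeline:
#' pre-smoothing sigma 0.5 px for the diffuse (crowd) channel and none for
#' the sharp (cluster) channel, 31 x 3 px linescans, R^2 >= 0.8 plus
#' middle-third centring for size QC, 25 nm bin width and minus-sampling
#' margin equal to the largest bin edge for the distance statistics.
#'
#' @param prominence_a,prominence_b detection prominence per channel
#'   (`NULL` = 5 x robust noise).
#' @param presmooth_a,presmooth_b detection pre-smoothing sigmas (px).
#' @param background_a,background_b scalar backgrounds.
#' @param linescan_length_px,linescan_width_px linescan geometry.
#' @param bin_edges_nm distance-histogram edges (nm).
#' @param margin_nm minus-sampling margin (nm).
#' @param csr_replicates CSR reference replicates.
#' @param seed integer seed for all stochastic steps.
#' @return named list of parameters.
#' @export
analysis_params <- function(prominence_a = NULL, prominence_b = NULL,
                            presmooth_a = 0, presmooth_b = 0.5,
                            background_a = 0, background_b = 0,
                            linescan_length_px = 31, linescan_width_px = 3,
                            bin_edges_nm = seq(0, 500, by = 25),
                            margin_nm = NULL, csr_replicates = 39,
                            seed = 1L) {
  if (is.null(margin_nm)) margin_nm <- max(bin_edges_nm)
  as.list(environment())
}

analyze_channel <- function(image, roi_, prominence, presmooth, background,
                            params) {
  stats_ <- roi_mean_intensity(image, roi_, background)
  pat <- find_maxima(image, roi_, prominence = prominence,
                     presmooth_sigma_px = presmooth)
  size <- maxima_size(image, pat, params$linescan_length_px,
                      params$linescan_width_px)
  list(pattern = pat,
       summary = data.frame(
         n_maxima = nrow(pat),
         density_per_um2 = maxima_density(pat, roi_),
         mean_size_nm = size$mean_size_nm,
         n_sized = size$n_used,
         mean_intensity = stats_$mean,
         rsdm = stats_$rsdm),
       sizes = size$table)
}

#' Run the full two-channel analysis over a set of fields
#'
#' For each field (a pair of congruent images plus an optional ROI) this
#' measures, per channel: maxima count, density, mean linescan size, mean
#' background-corrected ROI intensity and rSDM; across channels: PCC and
#' the flipped-channel control; and the cross-type nearest-neighbour
#' distances between the two maxima patterns. Identical config and seed
#' give identical outputs.
#'
#' @param fields list of fields; each a list with elements `id`,
#'   `image_a`, `image_b` ([image2d()]), optional `roi`.
#' @param params an [analysis_params()] list.
#' @return list of class `analysis_bundle`: `summary` (one row per field),
#'   `patterns` (per field, per channel), `cross_nn` (per field),
#'   `size_tables`, `params`, `provenance`.
#' @export
run_analysis <- function(fields, params = analysis_params()) {
  rows <- list(); patterns <- list(); cross_nn <- list(); sizes <- list()
  failures <- character(0)
  if (length(fields) == 0L) warning("empty field manifest")
  for (f in fields) {
    res <- tryCatch({
      roi_ <- if (!is.null(f$roi)) f$roi else roi_full(f$image_a)
      a <- analyze_channel(f$image_a, roi_, params$prominence_a,
                           params$presmooth_a, params$background_a, params)
      b <- analyze_channel(f$image_b, roi_, params$prominence_b,
                           params$presmooth_b, params$background_b, params)
      pcc_val <- pcc(f$image_a, f$image_b, roi_)
      pcc_flip <- pcc_flipped_control(f$image_a, f$image_b, roi_)
      xnn <- if (nrow(a$pattern) > 0L && nrow(b$pattern) > 0L)
        nn_distances(b$pattern, a$pattern, margin_nm = params$margin_nm)
      else numeric(0)
      names(a$summary) <- paste0(names(a$summary), "_a")
      names(b$summary) <- paste0(names(b$summary), "_b")
      list(row = cbind(data.frame(field_id = f$id), a$summary, b$summary,
                       data.frame(pcc = pcc_val, pcc_flipped = pcc_flip,
                                  median_cross_nn_nm =
                                    if (length(xnn)) stats::median(xnn)
                                    else NA_real_)),
           pats = list(a = a$pattern, b = b$pattern),
           xnn = xnn, sz = list(a = a$sizes, b = b$sizes))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("%s: %s", f$id, conditionMessage(res)))
      next
    }
    rows[[f$id]] <- res$row
    patterns[[f$id]] <- res$pats
    cross_nn[[f$id]] <- res$xnn
    sizes[[f$id]] <- res$sz
  }
  if (length(failures))
    warning("fields failed: ", paste(failures, collapse = "; "))
  structure(list(
    summary = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
              else data.frame(),
    patterns = patterns, cross_nn = cross_nn, size_tables = sizes,
    params = params,
    provenance = list(n_fields = length(fields), n_failed = length(failures),
                      failures = failures, seed = params$seed,
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "analysis_bundle")
}

#' Percent-of-control comparison of a metric between two bundles
#'
#' Relates the per-field values of one metric in a test bundle to the mean
#' of a control bundle (control mean set to 100%) and runs a two-tailed
#' t-test. Paired testing is used when both bundles carry aligned
#' `experiment_id` columns, otherwise Welch's unpaired test.
#'
#' @param control,test `analysis_bundle`s sharing the metric column.
#' @param metric column name in `summary` (e.g. `"rsdm_b"`).
#' @return list: `metric`, `mean_control`, `mean_test`,
#'   `percent_of_control`, `p`, `paired`, `n_control`, `n_test`.
#' @export
condition_compare <- function(control, test, metric) {
  for (b in list(control, test))
    if (!metric %in% names(b$summary))
      stop("metric '", metric, "' absent from bundle summary")
  x <- control$summary[[metric]]; y <- test$summary[[metric]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least two finite values per condition")
  paired <- "experiment_id" %in% names(control$summary) &&
    "experiment_id" %in% names(test$summary) &&
    identical(control$summary$experiment_id, test$summary$experiment_id) &&
    length(x) == length(y)
  tt <- stats::t.test(y, x, paired = paired)
  list(metric = metric, mean_control = mean(x), mean_test = mean(y),
       percent_of_control = 100 * mean(y) / mean(x),
       p = tt$p.value, paired = paired,
       n_control = length(x), n_test = length(y))
}
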