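## Regression and ratio arithmetic: per-sheet intensity-intensity ordinary
## least squares with slope comparison, the exponential
## clustering-vs-intensity decay fit, and copy-number ratio propagation.

#' Ordinary least-squares line fit
#'
#' @param x,y equal-length numeric vectors, n >= 3; `x` must vary.
#' @return list of class `linear_fit`: `slope`, `intercept`, `slope_se`,
#'   `n`, `r2`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x has zero variance; slope undefined")
  fit <- stats::lm(y ~ x)
  # noiseless inputs are legitimate here; silence summary.lm's perfect-fit note
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = unname(sm$coefficients[2L, 2L]),
                 n = length(x), r2 = sm$r.squared),
            class = "linear_fit")
}

#' Two-tailed comparison of two regression slopes
#'
#' Welch-style test: `t = (slope1 - slope2) / sqrt(se1^2 + se2^2)` with
#' Welch–Satterthwaite degrees of freedom built from the per-fit residual
#' degrees of freedom (n - 2); no equal-variance assumption across the two
#' datasets.
#'
#' @param fit1,fit2 [linear_fit()] objects.
#' @return list: `t`, `df`, `p` (two-sided).
#' @export
compare_slopes <- function(fit1, fit2) {
  se1 <- fit1$slope_se; se2 <- fit2$slope_se
  if (!is.finite(se1) || !is.finite(se2) || (se1 == 0 && se2 == 0))
    stop("slope standard errors undefined or both zero")
  tval <- (fit1$slope - fit2$slope) / sqrt(se1^2 + se2^2)
  df <- (se1^2 + se2^2)^2 /
    (se1^4 / (fit1$n - 2) + se2^4 / (fit2$n - 2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Exponential decay fit y = (a - b) exp(-d x) + b
#'
#' Nonlinear least squares for the saturating decay used to describe how
#' the clustering degree falls with staining intensity: value `a` at x = 0,
#' asymptote `b` as x grows, decay rate `d` per intensity unit. Default
#' initialization takes `a` from the smallest-x observation, `b` from the
#' largest-x observation, and `d` from a log-linearized first pass.
#' Constant data are returned with `a = b = mean(y)` and the rate flagged
#' unidentifiable.
#'
#' @param x non-negative predictor values (n >= 4).
#' @param y responses.
#' @param init optional named list/vector with `a`, `b`, `d` start values.
#' @return list of class `exp_decay_fit`: `a`, `b`, `d`, `r2`,
#'   `d_identifiable`.
#' @export
exp_decay_fit <- function(x, y, init = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4L) stop("need at least 4 points")
  if (any(x < 0)) stop("x must be non-negative")
  if (stats::sd(y) == 0)
    return(structure(list(a = y[1], b = y[1], d = NA_real_, r2 = 1,
                          d_identifiable = FALSE),
                     class = "exp_decay_fit"))
  if (is.null(init)) {
    b0 <- y[which.max(x)]
    a0 <- y[which.min(x)]
    shift <- y - b0
    usable <- abs(shift) > 1e-12 & sign(shift) == sign(a0 - b0)
    d0 <- if (sum(usable) >= 2L && stats::sd(x[usable]) > 0) {
      sl <- stats::coef(stats::lm(log(abs(shift[usable])) ~ x[usable]))[2L]
      max(abs(sl), 1e-6)
    } else 2 / diff(range(x))
    init <- list(a = a0, b = b0, d = unname(d0))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (a - b) * exp(-d * x) + b, start = init,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("exponential decay fit did not converge: ",
           conditionMessage(e)))
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(a = unname(cf[["a"]]), b = unname(cf[["b"]]),
                 d = unname(cf[["d"]]), r2 = r2, d_identifiable = TRUE),
            class = "exp_decay_fit")
}

#' Offset-corrected fold ratio of two percent-of-control stainings
#'
#' With both stainings expressed in percent of a control that includes an
#' endogenous contribution, the endogenous offset (typically 100%) is
#' subtracted from both before the fold ratio:
#' `(pct_a - offset) / (pct_b - offset)`.
#'
#' @param pct_a,pct_b staining levels in percent of control.
#' @param offset_pct offset to subtract (default 100).
#' @return fold ratio (> 0).
#' @export
relative_staining_increase <- function(pct_a, pct_b, offset_pct = 100) {
  if (pct_b - offset_pct <= 0)
    stop("denominator staining does not exceed the offset")
  if (pct_a - offset_pct <= 0)
    stop("numerator staining does not exceed the offset")
  (pct_a - offset_pct) / (pct_b - offset_pct)
}

#' Copy-number ratio scenario
#'
#' Describes how a baseline copy-number ratio between two species changes
#' when each is scaled by an expression fold and localized to the membrane
#' with some fraction.
#'
#' @param base_ratio baseline fold ratio (> 0), numerator over denominator.
#' @param fold_a,fold_b multiplicative expression changes (> 0) of the
#'   numerator / denominator species.
#' @param pm_fraction_a,pm_fraction_b plasma-membrane localized fractions
#'   in (0, 1\].
#' @return list of class `ratio_scenario`.
#' @export
ratio_scenario <- function(base_ratio, fold_a = 1, fold_b = 1,
                           pm_fraction_a = 1, pm_fraction_b = 1) {
  vals <- c(base_ratio, fold_a, fold_b, pm_fraction_a, pm_fraction_b)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all scenario fields must be positive")
  if (pm_fraction_a > 1 || pm_fraction_b > 1)
    stop("membrane fractions cannot exceed 1")
  structure(list(base_ratio = base_ratio, fold_a = fold_a, fold_b = fold_b,
                 pm_fraction_a = pm_fraction_a,
                 pm_fraction_b = pm_fraction_b),
            class = "ratio_scenario")
}

#' Propagated copy-number ratio of a scenario
#'
#' `base_ratio * (fold_a * pm_fraction_a) / (fold_b * pm_fraction_b)`:
#' e.g. a 12-fold baseline excess with the numerator raised 1.5-fold and
#' the denominator 2.5-fold shrinks to 7.2-fold.
#'
#' @param s a [ratio_scenario()].
#' @return fold ratio.
#' @export
expression_ratio <- function(s) {
  s$base_ratio * (s$fold_a * s$pm_fraction_a) /
    (s$fold_b * s$pm_fraction_b)
}
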