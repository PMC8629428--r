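#!/usr/bin/env Rscript

# The copy-number and staining ratio arithmetic, plus the exponential
# clustering-vs-intensity decay fit, on the published input values.

suppressMessages(library(sheetclust))

dir.create("results", showWarnings = FALSE)

# Offset-corrected staining fold between the two overexpression constructs:
# both stainings are in percent of control, which contains a 100%
# endogenous contribution.
fold <- relative_staining_increase(1154, 543, 100)
cat(sprintf("staining increase, offset-corrected: %.2f-fold (~%.1f)\n",
            fold, round(fold, 1)))

# 12-fold baseline crowd:cluster copy excess; numerator up 1.5-fold,
# denominator up 2.5-fold under double overexpression.
after <- expression_ratio(ratio_scenario(12, fold_a = 1.5, fold_b = 2.5))
cat(sprintf("copy ratio after overexpression: %.1f-fold (~%d-fold)\n",
            after, round(after)))

# With only 80% of the numerator species membrane-localized.
before_pm <- expression_ratio(ratio_scenario(12, pm_fraction_a = 0.8))
after_pm <- expression_ratio(
  ratio_scenario(12, fold_a = 1.5, fold_b = 2.5, pm_fraction_a = 0.8))
cat(sprintf("membrane-corrected: %.1f- to %.1f-fold, a %.0f%% reduction\n",
            before_pm, after_pm, 100 * (1 - after_pm / before_pm)))

# Exponential decay of clustering degree with staining intensity,
# y = (a - b) exp(-d x) + b, fitted to a noiseless curve sampled from the
# published parameter set as a recovery check.
x <- seq(0, 100, by = 10)
y <- (1.35 - 0.64) * exp(-0.042 * x) + 0.64
f <- exp_decay_fit(x, y)
cat(sprintf("exp decay fit: a = %.4f, b = %.4f, d = %.4f (r2 = %.6f)\n",
            f$a, f$b, f$d, f$r2))

jsonlite::write_json(
  list(staining_increase_fold = fold,
       copy_ratio_after_overexpression = after,
       membrane_corrected_before = before_pm,
       membrane_corrected_after = after_pm,
       exp_decay = list(a = f$a, b = f$b, d = f$d, r2 = f$r2)),
  "results/ratio_arithmetic.json", auto_unbox = TRUE, digits = NA)
cat("written to results/ratio_arithmetic.json\n")
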