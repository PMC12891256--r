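#!/usr/bin/env Rscript
# Segmented structure-function regressions between estimated GC counts (dB)
# and VF thresholds, stratified the way the clinical analysis is: healthy,
# suspect x defect status, glaucoma x defect status, plus pooled
# non-defective and defective models. Davies tests assess whether a
# breakpoint is supported; extra-sum-of-squares F tests compare stratified
# against pooled models. Requires results/sf_dataset.csv from
# analysis/01_simulate_cohort.R.

suppressPackageStartupMessages(library(gciplvf))
sf <- read.csv("results/sf_dataset.csv")
sf <- sf[!sf$excluded & is.finite(sf$count_dB), ]
sf$cell <- ifelse(sf$stratum == "healthy", "healthy",
                  paste(sf$stratum, sf$defect_status, sep = "."))

fit_one <- function(d, label) {
  m <- fit_segmented(d$count_dB, d$threshold_dB, init_breakpoint = 15.5)
  dv <- tryCatch(davies_test(d$count_dB, d$threshold_dB)$p_value,
                 error = function(e) NA_real_)
  data.frame(model = label, n = m$n, intercept = m$intercept,
             slope1 = m$slope1, breakpoint = m$breakpoint, slope2 = m$slope2,
             adj_r2 = m$adj_r2, f_vs_linear = m$f_stat, p_vs_linear = m$p_value,
             davies_p = dv, mae_dB = m$mae_dB, rmse_dB = m$rmse_dB)
}

cells <- sort(unique(sf$cell))
tab <- do.call(rbind, lapply(cells, function(cl) fit_one(sf[sf$cell == cl, ], cl)))
tab <- rbind(tab,
             fit_one(sf[sf$defect_status == "non-defective", ], "no-defect overall"),
             fit_one(sf[sf$defect_status == "defective", ], "defect overall"))
write.csv(tab, "results/sf_models.csv", row.names = FALSE)
cat("Segmented structure-function models (Table-2 shaped):\n")
print(tab, digits = 3, row.names = FALSE)

# stratified vs pooled comparisons
pooled_all <- fit_segmented(sf$count_dB, sf$threshold_dB, 15.5)
subs <- lapply(cells, function(cl)
  fit_segmented(sf$count_dB[sf$cell == cl], sf$threshold_dB[sf$cell == cl], 15.5))
f_all <- compare_nested_f(subs, pooled_all)
cat(sprintf("\nStratified vs single model: F = %.2f, p = %.3g\n",
            f_all$f, f_all$p_value))

nd <- sf[sf$defect_status == "non-defective", ]
subs_nd <- lapply(unique(nd$stratum), function(s)
  fit_segmented(nd$count_dB[nd$stratum == s], nd$threshold_dB[nd$stratum == s], 15.5))
f_nd <- compare_nested_f(subs_nd, fit_segmented(nd$count_dB, nd$threshold_dB, 15.5))
div_nd <- max_model_divergence(subs_nd, range(nd$count_dB))
cat(sprintf("Non-defective strata: F = %.2f, p = %.3g; max predicted difference %.2f dB\n",
            f_nd$f, f_nd$p_value, div_nd))

de <- sf[sf$defect_status == "defective", ]
de <- de[de$stratum != "healthy", ]
subs_d <- lapply(unique(de$stratum), function(s)
  fit_segmented(de$count_dB[de$stratum == s], de$threshold_dB[de$stratum == s], 15.5))
f_d <- compare_nested_f(subs_d, fit_segmented(de$count_dB, de$threshold_dB, 15.5))
div_d <- max_model_divergence(subs_d, range(de$count_dB))
cat(sprintf("Defective strata:     F = %.2f, p = %.3g; max predicted difference %.2f dB\n",
            f_d$f, f_d$p_value, div_d))

comp <- data.frame(
  comparison = c("all strata vs pooled", "non-defective strata", "defective strata"),
  f = c(f_all$f, f_nd$f, f_d$f),
  p = c(f_all$p_value, f_nd$p_value, f_d$p_value),
  max_divergence_dB = c(NA, div_nd, div_d))
write.csv(comp, "results/sf_model_comparisons.csv", row.names = FALSE)
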