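#!/usr/bin/env Rscript
# Fit the one-parameter BDI law to the family-size spectrum: closed-form
# Lambert-W maximum likelihood for theta, parametric-bootstrap KS goodness
# of fit, and the (T, N_s) trim scan locating the model-consistent core
# (largest families excluded at threshold T, N_s singletons removed).

suppressPackageStartupMessages(library(bdifam))

spectrum <- read.delim("results/size_spectrum.tsv")
sizes <- rep(spectrum$size, spectrum$n_families)
s <- size_sample(sizes)
print(s)

fit <- gof_pvalue(s, n_boot = 1000, seed = 31)
print(fit)
cat("whole-sample fit: the planted spikes and singleton excess should\n",
    "depress the p-value well below any acceptance level\n")

scan <- trim_scan(sizes, T_grid = c(45, 40, 30, 25, 20),
                  Ns_grid = seq(0, 100, 10), n_boot = 300, seed = 32)
print(scan)
write.table(scan$grid, "results/trim_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# core = the trim the scan accepts; on a clean trimmed sample the
# bootstrap p is uniform, so when no cell clears the 0.75 bar we fall
# back to the best-fitting cell of the grid (the heatmap is descriptive)
if (!is.na(scan$T_star)) {
  T_core <- scan$T_star
  ns_core <- round(mean(scan$Ns_accepted))
} else {
  best <- scan$grid[scan$grid$valid, ]
  best <- best[which.max(best$p_value), ]
  T_core <- best$T
  ns_core <- best$Ns
  cat(sprintf("no cell reached p >= %.2f; using the best cell instead\n",
              scan$accept_p))
}
kept <- sizes[sizes < T_core]
ones <- which(kept == 1)
if (ns_core > 0) kept <- kept[-ones[seq_len(min(ns_core, length(ones)))]]
core <- gof_pvalue(kept, n_boot = 1000, seed = 33)
cat(sprintf("core fit after trimming (T = %g, Ns = %d):\n", T_core, ns_core))
print(core)
report <- data.frame(
  sample = c("full", "core"),
  n_fam = c(fit$n_fam, core$n_fam),
  theta = c(fit$theta, core$theta),
  ks_D = c(fit$D, core$D),
  p_value = c(fit$p_value, core$p_value))
write.table(report, "results/fit_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
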