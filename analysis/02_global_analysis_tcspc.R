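#!/usr/bin/env Rscript
# Global analysis of synthetic TCSPC surfaces.
#
# Simulates time-resolved fluorescence of the Chl a/b complex (five DAS
# components, 92 ps IRF, Poisson noise at 2e4 peak counts), fits it by
# variable projection, and compares the recovered lifetimes and main-decay
# DAS area fractions with the generation truth.

library(lhcakin)
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

fx <- make_fixture("lhca4_ab_tcspc", seed = 7)
write_surface(fx$surface, "scratch/lhca4_ab_tcspc_surface.tsv")

fit <- fit_global(fx$surface, 5, fx$irf, tau_init = c(8, 150, 700, 2500, 5000))
truth <- fx$truth$das$lifetimes_ps
wl <- fit$das$wavelengths_nm
areas <- apply(fit$das$spectra[2:4, ], 1, function(s) pracma::trapz(wl, abs(s)))

out <- data.frame(
  component = 1:5,
  tau_true_ps = truth,
  tau_fit_ps = signif(fit$das$lifetimes_ps, 4),
  rel_err_pct = round(100 * (fit$das$lifetimes_ps - truth) / truth, 1))
write.table(out, "results/tcspc_lifetimes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(out)
cat("\nmain-decay DAS area fractions (truth 48:34:18):",
    paste(round(100 * areas / sum(areas)), collapse = ":"), "\n")
cat("fit cost", signif(fit$cost, 4), "in", fit$n_iterations, "iterations\n")
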