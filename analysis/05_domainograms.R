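#!/usr/bin/env Rscript

# Stage 5: domainograms and interacting-domain calls.
#
# The sparse genome-wide run is binarized (captured at least once or not)
# with a viewpoint-proximal mask; background coverage rates are estimated
# separately for far-cis and trans, and each running window of w
# consecutive analyzable ends is scored with the upper-tail binomial
# probability (the domainogram; display scale P = 1 .. 1e-10). Domains
# are called at one window size after Benjamini-Hochberg correction.
# A null calibration on i.i.d. coverage confirms the model is
# conservative at its nominal levels.

suppressMessages(library(allele4C))

sc <- readRDS("results/data/scenario.rds")
out <- "results/domainograms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts <- read_tsv("results/capture/counts_bcell_gw_A.tsv")
prof <- counts_profile(counts$count, sc$dbs$A, sc$vp$chrom, w = 21,
                       viewpoint = sc$vp$name, allele = "A")
cov <- binarize_coverage(prof, sc$dbs$A, sc$vp,
                         exclusion_radius = sc$exclusion_radius)
message(sprintf("background coverage: far-cis pi = %.3f, trans pi = %.3f",
                cov$far_cis$pi, cov$trans$pi))

domains <- list()
for (comp in c("far_cis", "trans")) {
  cc <- cov[[comp]]
  dg <- window_significance(cc$covered, cc$pi, 1:30)
  dom <- call_domains(dg, cc$ends, w_call = 11L, fdr = 0.05,
                      compartment = if (comp == "far_cis") "cis"
                                    else "trans")
  domains[[comp]] <- dom
  export_tracks(prof, dg, cc$ends, dom, dir = out,
                prefix = paste0("gw_", comp))
  message(sprintf("  %s: %d interacting domains spanning %.0f kb", comp,
                  nrow(dom$domains),
                  sum(dom$domains$end - dom$domains$start) / 1000))
}
saveRDS(domains, file.path(out, "domains.rds"))

cal <- null_calibration(pi = 0.2, W = c(5L, 20L, 50L), n_ends = 300L,
                        n_sims = 1000L, seed = 99)
write_tsv(cal, file.path(out, "null_calibration.tsv"))
message("null calibration (pi = 0.2):")
for (i in seq_len(nrow(cal))) {
  message(sprintf(
    "  w = %2d, alpha = %.2f: empirical FPR %.4f (exact tail mass %.4f)",
    cal$w[i], cal$alpha[i], cal$empirical[i], cal$exact[i]))
}
message("stage 5 done -> ", out)
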