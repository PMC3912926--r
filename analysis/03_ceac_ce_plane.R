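#!/usr/bin/env Rscript
# Decision uncertainty of the aspirin base case: cost-effectiveness plane
# quadrant shares and the acceptability curve over WTP 0-80,000 EUR/QALY.
# Reads the draws written by 02_psa.R (reruns the PSA if absent).
# Writes results/ceac_aspirin.csv and results/ce_plane_aspirin.csv.

suppressPackageStartupMessages(library(padscreen))
dir.create("results", showWarnings = FALSE)

draws_path <- "results/psa_draws_aspirin.csv"
psa <- if (file.exists(draws_path)) {
  structure(list(draws = read.csv(draws_path)), class = "psa_result")
} else {
  run_psa(default_parameter_table(), run_config(), n = 1000, seed = 1)
}

cc <- ceac(psa, seq(0, 80000, by = 1000))
write.csv(cc, "results/ceac_aspirin.csv", row.names = FALSE)
quad <- ce_plane_summary(psa)
write.csv(as.data.frame(t(quad)), "results/ce_plane_aspirin.csv",
          row.names = FALSE)

print(round(quad, 3))
for (w in c(0, 11000, 40000, 80000))
  cat(sprintf("P(cost-effective | WTP %5d EUR/QALY) = %.3f\n",
              w, cc$probability[cc$wtp == w]))
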