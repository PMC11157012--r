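#!/usr/bin/env Rscript
# Step 1: generate the synthetic GWAS summary-statistics "cohorts" used by
# the downstream analyses. Everything is reproducible from the seeds below;
# the tables land in results/sim_data/ in the canonical exchange format.

suppressMessages(library(mrpipe))

out_dir <- "results/sim_data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# a clean exposure-outcome pair: 50 strong valid instruments, causal 0.2
valid <- simulate_gwas_pair(scenario_presets("valid", seed = 101))
write_summary_table(valid$exposure, file.path(out_dir, "exposure_valid.tsv"))
write_summary_table(valid$outcome, file.path(out_dir, "outcome_valid.tsv"))
write.table(valid$truth, file.path(out_dir, "truth_valid.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(valid$ld$r2, file.path(out_dir, "ld_valid.tsv"),
            sep = "\t", quote = FALSE)

# the same causal model with two planted 10x outliers (for MR-PRESSO)
outl <- simulate_gwas_pair(scenario_presets("with_outliers", seed = 102))
write_summary_table(outl$exposure, file.path(out_dir, "exposure_outliers.tsv"))
write_summary_table(outl$outcome, file.path(out_dir, "outcome_outliers.tsv"))
write.table(outl$truth, file.path(out_dir, "truth_outliers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# an exposure-mediator-outcome triplet with true mediated proportion 0.25
trip <- simulate_mediation_triplet(scenario_presets("mediation", seed = 103))
for (nm in c("exposure", "mediator", "outcome")) {
  write_summary_table(trip[[nm]], file.path(out_dir, paste0(nm, "_triplet.tsv")))
}
write.table(trip$truth, file.path(out_dir, "truth_triplet.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated cohorts written to", out_dir, "\n")
cat(sprintf(" - valid pair: %d SNPs, causal beta %.2f\n",
            n_variants(valid$exposure), valid$config$causal_beta))
cat(sprintf(" - outlier pair: %d SNPs, %d planted outliers\n",
            n_variants(outl$exposure), sum(outl$truth$outlier)))
cat(sprintf(" - triplet: true total effect %.3f, true mediated proportion %.2f\n",
            trip$true_beta1, trip$true_proportion))
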