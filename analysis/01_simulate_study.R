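#!/usr/bin/env Rscript
# Step 1: generate the synthetic study that stands in for the real
# taxa-abundance and case-control GWAS inputs.
#
# 40 genus-level exposures (a scaled-down taxon panel), 40 variants
# each, 10 true instruments per taxon, at the real cohorts' sample
# sizes (n = 18,340 exposure; 69,501 cases / 105,974 controls). Three
# taxa are causal (log-OR +0.25, +0.2, -0.25 per SD of abundance), the
# rest null. A 150-individual reference panel with independent
# variants provides LD for clumping. Everything is written as TSV
# under results/data/ so the pipeline step can run purely from files.

library(taxaMR)

seed <- 20230823
out_dir <- "results/data"
dir.create(file.path(out_dir, "exposures"), recursive = TRUE,
           showWarnings = FALSE)

theta <- rep(0, 40)
theta[c(3, 17, 29)] <- c(0.25, 0.2, -0.25)
cfg <- sim_config(n_taxa = 40, variants_per_taxon = 40,
                  j_instruments = 10, theta = theta,
                  sigma_gamma = 0.12, seed = seed)
sim <- simulate_mr_dataset(cfg)

for (taxon in names(sim$exposures))
  write_summary_stats(sim$exposures[[taxon]],
                      file.path(out_dir, "exposures",
                                paste0(taxon, ".tsv")))
write_summary_stats(sim$outcome, file.path(out_dir, "outcome.tsv"))

vars <- do.call(rbind, lapply(sim$exposures, function(e)
  e$records[, c("variant_id", "chrom", "pos")]))
panel <- simulate_reference_panel(
  sim_config(ld_blocks = list(block_size = 1, r = 0,
                              n_individuals = 150)),
  variants = vars, seed = seed + 1)
write_reference_panel(panel, file.path(out_dir, "panel.tsv"))

write.table(sim$truth$variants, file.path(out_dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %d exposure datasets, outcome (%d variants), panel (%d x %d)\n",
            length(sim$exposures), nrow(sim$outcome$records),
            nrow(panel$dosages), ncol(panel$dosages)))
cat("causal taxa:",
    paste(names(sim$truth$theta)[sim$truth$theta != 0], collapse = ", "),
    "\n")
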