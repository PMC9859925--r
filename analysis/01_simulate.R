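#!/usr/bin/env Rscript
# Stage 1: generate the synthetic experiment.
#
# Emulates the wet-lab design: four PFASs, two independent studies,
# triplicate wells, two-fold concentration grids up to 100 uM (33 uM for the
# most potent compound). Writes the raw qPCR well table, the standard-curve
# dilution series, the plate design, and ready-made summary tables for both
# transcriptional endpoints (RAG1, RAG2) under results/data/.

suppressPackageStartupMessages(library(pfasrpf))

seed <- 20240901L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Shape parameters for a decreasing fold-change endpoint: plateau at 20% of
# background, moderate steepness. Potencies are set so the true BMC10 values
# sit at realistic micromolar magnitudes for these compounds.
bmc_factor <- bmc_closed_form(1, 1, 0.2, 1.5, -0.1)
truth <- list(
  RAG1 = c(PFOA = 9.8, PFOS = 11.7, PFNA = 6.1, PFHxS = 31.0) / bmc_factor,
  RAG2 = c(PFOA = 8.8, PFOS = 13.3, PFNA = 4.9, PFHxS = 33.2) / bmc_factor
)

for (ep in names(truth)) {
  d <- sim_design(b = truth[[ep]], c = 0.2, d = 1.5, cv = 0.15,
                  seed = seed + match(ep, names(truth)))
  tab <- simulate_summary_table(d, endpoint = ep)
  path <- file.path(out, paste0(ep, "_summary.tsv"))
  write_summary_table(tab, path)
  message("wrote ", path, " (", nrow(summary_rows(tab)), " groups)")
}

# Raw qPCR wells for the RAG1 endpoint (the quantification stage input)
d1 <- sim_design(b = truth$RAG1, c = 0.2, d = 1.5, cv = 0.15,
                 seed = seed + 1L)
sim <- simulate_qpcr_experiment(d1, target_gene = "RAG1",
                                reference_gene = "GAPDH")
write.table(sim$records, file.path(out, "RAG1_cq_records.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$design_map, file.path(out, "RAG1_plate_design.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (g in names(sim$dilution_series))
  write.table(cbind(gene = g, sim$dilution_series[[g]]),
              file.path(out, paste0(g, "_dilution_series.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote raw qPCR tables: ", nrow(sim$records), " well measurements")
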