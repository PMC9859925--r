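#!/usr/bin/env Rscript
# Stage 2: qPCR quantification.
#
# Fits per-gene standard curves from the dilution series, back-calculates
# relative quantities, normalizes RAG1 by GAPDH, expresses fold change
# versus the solvent controls, and aggregates wells into the summary table
# the modeling stage consumes. Run after 01_simulate.R.

suppressPackageStartupMessages(library(pfasrpf))

dat <- "results/data"
recs <- read.delim(file.path(dat, "RAG1_cq_records.tsv"))
design <- read.delim(file.path(dat, "RAG1_plate_design.tsv"))

curves <- lapply(c(RAG1 = "RAG1", GAPDH = "GAPDH"), function(g) {
  series <- read.delim(file.path(dat, paste0(g, "_dilution_series.tsv")))
  curve <- fit_standard_curve(series, gene = g)
  message(sprintf("%s standard curve: slope %.3f cycles/log10, efficiency %.1f%%, R2 %.4f",
                  g, curve$slope, 100 * curve$efficiency, curve$r_squared))
  curve
})

controls <- design$sample[design$concentration == 0]
folds <- quantify(recs, curves, target_gene = "RAG1",
                  reference_gene = "GAPDH", control_samples = controls)
message(sprintf("control fold-change mean: %.6f (should be 1 by construction)",
                mean(folds$fold_change[folds$sample %in% controls])))

tab <- summarize_to_table(folds, design, endpoint = "RAG1")
path <- file.path(dat, "RAG1_summary_from_qpcr.tsv")
write_summary_table(tab, path)
message("wrote ", path, " (", nrow(summary_rows(tab)), " groups)")
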