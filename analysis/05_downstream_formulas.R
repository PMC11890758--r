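#!/usr/bin/env Rscript
# The small formulas downstream of the screens: comparative-Ct relative
# expression, differential-expression threshold filtering, and caliper
# tumor-volume arithmetic. Writes results/downstream_summary.tsv.

suppressPackageStartupMessages(library(oncoscreen))

# qPCR: STING induction, treated vs control, normalized to GAPDH
ct <- data.frame(
  gene = rep(c("STING", "GAPDH"), each = 6),
  condition = rep(rep(c("treated", "control"), each = 3), 2),
  ct = c(24.1, 24.3, 24.2, 26.2, 26.3, 26.1,   # STING
         19.9, 20.1, 20.0, 20.0, 20.1, 19.9))  # GAPDH
fc <- ddct_from_table(ct, "STING", "GAPDH")
message(sprintf("STING relative expression (2^-ddCt): %.2f-fold", fc))

# DEG filter on a toy differential-expression table
degs <- data.frame(
  gene = c("STING", "CXCL10", "CCL5", "JAK1", "ACTB", "GAPDH"),
  log2fc = c(2.4, 3.1, 1.0, 0.8, 0.05, -0.02),
  padj = c(1e-8, 1e-6, 0.05, 0.2, 0.9, 0.95))
kept <- deg_filter(degs, lfc_cutoff = 1, padj_cutoff = 0.05)
message("DEGs retained at |log2FC| >= 1 & padj <= 0.05: ",
        paste(kept$gene, collapse = ", "))

# tumor volumes and treatment effect
vol_start <- tumor_volume(10.6, 7.5)   # ~300 mm^3 at treatment start
vol_end <- tumor_volume(8.9, 6.3)      # ~175 mm^3 at endpoint
reduction <- percent_reduction(vol_start, vol_end)
message(sprintf("tumor volume %.0f -> %.0f mm^3: %.1f%% reduction",
                vol_start, vol_end, reduction))
message(sprintf("printed-volume check: percent_reduction(300, 175) = %.1f%%",
                percent_reduction(300, 175)))

write_results(data.frame(
  quantity = c("sting_fold_change", "n_degs", "volume_start_mm3",
               "volume_end_mm3", "percent_reduction"),
  value = c(fc, nrow(kept), vol_start, vol_end, reduction)),
  "results/downstream_summary.tsv")
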