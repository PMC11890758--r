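#!/usr/bin/env Rscript
# Score the simulated BRET interaction screen: per-replicate saturation
# fits, common-bound AUCs, fold-of-change against the larger empty-vector
# control, Student's t-test, and hit calling at FOC >= 4.0 & p <= 0.001.
# Reads results/simulated/, writes results/bret_scores.tsv and
# results/bret_hits.tsv.

suppressPackageStartupMessages(library(oncoscreen))

inp <- "results/simulated"
meas <- read_plate_table(file.path(inp, "bret_plates.tsv"), geometry = 1536)
map <- read_plate_map(file.path(inp, "bret_map.tsv"), geometry = 1536)
truth <- utils::read.delim(file.path(inp, "bret_truth.tsv"))

scores <- run_bret_screen(meas, map, foc_cutoff = 4.0, p_cutoff = 0.001)
hits <- call_hits(scores)

write_results(scores, "results/bret_scores.tsv")
write_results(hits, "results/bret_hits.tsv")

planted <- truth$gene[truth$interactor]
message(nrow(scores), " gene pairs scored; ", nrow(hits),
        " hits at FOC >= 4.0 & p <= 0.001")
message("planted interactors recovered: ",
        sum(hits$acceptor %in% planted), "/", length(planted),
        "; false hits: ", sum(!hits$acceptor %in% planted))
message("FOC range among hits: ",
        sprintf("%.1f - %.1f", min(hits$foc), max(hits$foc)))
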