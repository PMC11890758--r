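#!/usr/bin/env Rscript
# Simulate the three input datasets downstream stages consume:
#   - an 85-gene BRET interaction screen with 16 planted interactors,
#   - a 2036-compound immune co-culture screen with 3 planted sensitizers,
#   - a STING-reporter dose-response table (potency 0.2 uM, 5% noise).
# Plate tables, plate maps and truth records land under results/simulated/.

suppressPackageStartupMessages(library(oncoscreen))

seed <- 7
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("BRET interaction screen: 85 genes, 16 interactors, 4 replicates")
bret <- generate_bret_screen(bret_screen_truth(bmax_hit = 0.2, seed = seed))
write_results(bret$measurements, file.path(out, "bret_plates.tsv"))
write_results(bret$map, file.path(out, "bret_map.tsv"))
write_results(bret$truth, file.path(out, "bret_truth.tsv"))
message("  wells: ", nrow(bret$measurements), " on ",
        length(unique(bret$measurements$plate_id)), " plates")

message("Immune co-culture screen: 2036 compounds, 3 sensitizers (SI 5)")
htip <- generate_htip_screen(htip_screen_truth(seed = seed))
write_results(htip$measurements, file.path(out, "htip_plates.tsv"))
write_results(htip$map, file.path(out, "htip_map.tsv"))
write_results(htip$truth, file.path(out, "htip_truth.tsv"))
message("  wells: ", nrow(htip$measurements), " across both arms")

message("STING-reporter dose-response: EC50 0.2 uM, 8 doses, 5% CV")
dr <- generate_dose_response(ic50 = 0.2e-6, noise_cv = 0.05, seed = seed)
write_results(dr$data, file.path(out, "sting_reporter_doses.tsv"))

message("done; inputs under ", out)
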