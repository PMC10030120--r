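#!/usr/bin/env Rscript
# Step 1: generate every synthetic dataset of the study design and write
# them in the formats the readers consume. Downstream steps only read these
# files, so the whole analysis is reproducible from this seed.

suppressPackageStartupMessages(library(fpnbind))
seed <- 20230101
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

# FP study plate: direct titrations (13 nM-6 uM, blocked 30 uM controls)
# for six constructs plus hepcidin-25/vamifeport displacement ladders at
# the per-construct protein concentration; 5 mP FP noise, 3 replicates.
plate <- gen_study_plate(seed = seed, noise_sd = 5)
write_plate(plate, "results/data/fp_plate.csv")
cat(sprintf("FP plate: %d wells, %d constructs\n", nrow(plate),
            length(unique(plate$construct))))

# Thermal stability: apo and vamifeport-bound melting series (4-75 C,
# normalized to the 4 C reference).
apo <- gen_melt(t_m = 47, noise_sd = 2, seed = seed + 1, condition = "apo")
holo <- gen_melt(t_m = 52, noise_sd = 2, seed = seed + 2,
                 condition = "+vamifeport")
utils::write.csv(apo, "results/data/melt_apo.csv", row.names = FALSE)
utils::write.csv(holo, "results/data/melt_vamifeport.csv", row.names = FALSE)
cat(sprintf("melt series: %d + %d points\n", nrow(apo), nrow(holo)))

# Calcein-quench transport traces across the Co2+ ladder (4 s sampling,
# valinomycin / CoCl2 / calcimycin events).
for (cc in c(0, 1, 10, 50, 200)) {
  g <- gen_transport_trace(cc, noise_sd = 0.2, seed = seed + 10 + cc)
  utils::write.csv(g$trace, sprintf("results/data/trace_%dum.csv", cc),
                   row.names = FALSE)
  jsonlite::write_json(g$events, sprintf("results/data/events_%dum.json", cc),
                       dataframe = "rows", na = "null")
}
cat("transport traces written for 0/1/10/50/200 uM Co2+\n")

# SPR ladders for the two high-affinity sybody analytes at their published
# concentration series.
sy3 <- gen_spr(conc_nm = c(3.4, 13.5, 54.5, 109, 217.5, 435, 870),
               k_on = 1e5, k_off = 0.05, noise_sd = 0.5, seed = seed + 20)
sy12 <- gen_spr(conc_nm = c(8, 32, 64, 128, 256, 512, 1024),
                k_on = 1e5, k_off = 1e5 * 308e-9, noise_sd = 0.5,
                seed = seed + 21)
utils::write.csv(sy3, "results/data/spr_sy3.csv", row.names = FALSE)
utils::write.csv(sy12, "results/data/spr_sy12.csv", row.names = FALSE)
cat("SPR ladders written (7 concentrations each)\n")
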