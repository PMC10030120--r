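#!/usr/bin/env Rscript
# Step 3: thermal stability (Tm and the ligand-induced shift) and
# proteoliposome transport (initial rates across the Co2+ ladder, KM).

suppressPackageStartupMessages(library(fpnbind))

apo <- fit_melt(read_melt("results/data/melt_apo.csv", "apo"))
holo <- fit_melt(read_melt("results/data/melt_vamifeport.csv", "+vamifeport"))
shift <- delta_tm(apo, holo)
cat(sprintf("Tm apo %.1f ± %.2f C; +vamifeport %.1f ± %.2f C; dTm %.1f ± %.2f C\n",
            apo$t_m, apo$t_m_se, holo$t_m, holo$t_m_se,
            shift$delta_tm, shift$se))

concs <- c(0, 1, 10, 50, 200)
rates <- vapply(concs, function(cc) {
  tr <- read_trace(sprintf("results/data/trace_%dum.csv", cc),
                   sprintf("results/data/events_%dum.json", cc))
  extract_initial_rate(tr$trace, tr$events, window_s = 30)$rate
}, 0)
km <- fit_km(rates, concs)
cat(sprintf("transport KM %.2f ± %.2f uM (vmax %.4g /s)%s\n",
            km$k_m, km$k_m_se, km$v_max,
            if (km$poorly_constrained) " [poorly constrained]" else ""))

out <- data.frame(
  quantity = c("tm_apo_c", "tm_vamifeport_c", "delta_tm_c",
               "km_um", "v_max_per_s"),
  value = c(apo$t_m, holo$t_m, shift$delta_tm, km$k_m, km$v_max),
  se = c(apo$t_m_se, holo$t_m_se, shift$se, km$k_m_se, km$v_max_se))
utils::write.table(out, "results/stability_transport.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
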