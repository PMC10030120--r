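#!/usr/bin/env Rscript
# Step 4: global 1:1 Langmuir kinetic fits of the two sybody SPR ladders.

suppressPackageStartupMessages(library(fpnbind))

out <- do.call(rbind, lapply(c("sy3", "sy12"), function(an) {
  f <- fit_spr(read_spr(sprintf("results/data/spr_%s.csv", an)))
  cat(sprintf("%-5s kon %.3g /M/s  koff %.3g /s  KD %.0f ± %.0f nM%s\n",
              an, f$k_on, f$k_off, f$k_d_nm, f$k_d_nm_se,
              if (f$flagged) " [flagged]" else ""))
  data.frame(analyte = an, k_on = f$k_on, k_on_se = f$k_on_se,
             k_off = f$k_off, k_off_se = f$k_off_se,
             r_max = f$r_max, k_d_nm = f$k_d_nm, k_d_nm_se = f$k_d_nm_se)
}))
utils::write.table(out, "results/spr.tsv", sep = "\t", row.names = FALSE,
                   quote = FALSE)
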