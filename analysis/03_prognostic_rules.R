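#!/usr/bin/env Rscript
# Evaluate the single-time-point comparator rules (Hy's law, new Hy's law,
# Robles-Diaz) on each patient's onset panel, together with the CIOMS
# injury-type classification.

library(dilipattern)

cohort <- read_cohort("results/labs.csv", "results/outcomes.csv")
uln <- uln_table()

rows <- lapply(cohort, function(p) {
  panel <- panel_from_patient(p, uln, at = "onset")
  v <- all_rules(panel)
  data.frame(patient_id = p$id,
             injury_type = classify_injury(r_value(panel$alt_fold,
                                                   panel$alp_fold)),
             hys_law = v[["hys_law"]], new_hys_law = v[["new_hys_law"]],
             robles_diaz = v[["robles_diaz"]])
})
verdicts <- do.call(rbind, rows)
write.csv(verdicts, "results/rule_verdicts.csv", row.names = FALSE)

cat("Injury types at onset:\n"); print(table(verdicts$injury_type))
cat("Rule positivity:\n")
print(colMeans(verdicts[, c("hys_law", "new_hys_law", "robles_diaz")]))
cat("Wrote results/rule_verdicts.csv\n")
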