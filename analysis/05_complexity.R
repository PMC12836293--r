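#!/usr/bin/env Rscript
# Stage 5 -- VMAT plan complexity: MU, CPs, PI, MCS, SAS10, MFA, MLG and
# MLT per beam, per isocenter group (cranial iso1 vs spinal iso2) and per
# plan, for both techniques.

suppressPackageStartupMessages(library(csieval))

rows <- list()
for (arm in c("sparing", "standard")) {
  plan <- read_beam_plan(sprintf("results/cohort/pt01_plan_%s.json", arm))
  rep <- aggregate_metrics(plan)
  rows[[arm]] <- cbind(arm = arm, rep)
}
out <- do.call(rbind, rows)
write.csv(out, "results/05_complexity.csv", row.names = FALSE)

iso <- out[out$scope == "isocenter", ]
cat("Complexity by isocenter group:\n")
print(iso[, c("arm", "id", "MU", "CPs", "PI", "MCS", "SAS10",
              "MFA_cm2", "MLG_cm", "MLT_cm")],
      row.names = FALSE, digits = 3)
plan_rows <- out[out$scope == "plan", ]
cat(sprintf("\nThe sparing plan is the more modulated one: MCS %.3f vs %.3f, SAS10 %.3f vs %.3f.\n",
            plan_rows$MCS[plan_rows$arm == "sparing"],
            plan_rows$MCS[plan_rows$arm == "standard"],
            plan_rows$SAS10[plan_rows$arm == "sparing"],
            plan_rows$SAS10[plan_rows$arm == "standard"]))
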