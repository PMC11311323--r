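#!/usr/bin/env Rscript

# Step 1: simulate the study cohort.
#
# 29 osteoarthritis patients and 15 volunteers each contribute paired
# plasma + serum specimens; three trailing volunteer cases are dropped so
# the analysed set is 58 patient and 27 volunteer cases. Four participants
# (floor of 10% of 44) are planted as contaminated - their log-scale means
# are shifted along an exaggerated patient-volunteer contrast - and ~3% of
# concentration cells are missing at random.

library(oadfa)

seed <- 3
cfg <- generator_config(seed = seed,
                        contamination_rate = 0.1,
                        missing_rate = 0.03,
                        drop_volunteer_cases = 3)
cohort <- generate_cohort(cfg)
truth <- true_parameters(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort_csv(cohort, "results/cohort.csv",
                 truth_path = "results/cohort_truth.csv")

cat(sprintf("simulated %d cases: %d patient, %d volunteer (seed %d)\n",
            nrow(cohort), sum(cohort$group == 1), sum(cohort$group == 2), seed))
cat(sprintf("planted contaminated participants: %s\n",
            paste(truth$contaminated, collapse = ", ")))
cat(sprintf("missing cells: %d of %d\n",
            sum(is.na(cohort[, c("il6", "tnfa", "mpo")])), 3 * nrow(cohort)))
cat("written: results/cohort.csv, results/cohort_truth.csv\n")
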