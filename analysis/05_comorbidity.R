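#!/usr/bin/env Rscript
# Stage 5: comorbidity scoring.
#
# Modified Charlson index from the generated ICD-10 specialist-care
# histories: 11-year lookback ending in the survey year, asthma and COPD
# excluded from the score (they enter the mortality models as individual
# flags instead).

library(respclust)

data_dir <- "results/data"
index_year <- 2008L

records <- read.csv(file.path(data_dir, "icd_histories.csv"))
records$date <- as.Date(records$date)
truth <- read.csv(file.path(data_dir, "truth_labels.csv"))
ids <- truth$subject_id

scores <- cci_scores(records, ids, index_year = index_year)
flags <- flag_asthma_copd(records, NULL, index_year = index_year,
                          subject_ids = ids)

out <- data.frame(subject_id = ids, cci = unname(scores),
                  cci_cat = cci_category(unname(scores)),
                  asthma = flags$asthma, copd = flags$copd)
write.csv(out, file.path(data_dir, "comorbidity.csv"), row.names = FALSE)

cat("modified CCI distribution:\n")
print(round(100 * prop.table(table(out$cci_cat)), 1))
cat(sprintf("register asthma: %.1f%%, register COPD: %.1f%%\n",
            100 * mean(out$asthma), 100 * mean(out$copd)))
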