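#!/usr/bin/env Rscript
# Stage 1: simulate the cohort.
#
# Draws a synthetic population with five planted respiratory-symptom
# clusters (shares 30.3/10.7/4.7/6.6/4.1% of the cohort, ~56%
# symptomatic overall), background covariates, ICD-10 specialist-care
# histories, competing-risks survival over 21 years, and 11.2% MCAR
# survey missingness.  Everything downstream reads the files written
# here.

library(respclust)

seed <- 20260901L
n <- 5000L
index_year <- 2008L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_subjects = n, seed = seed)
gen <- generate_cohort(cfg)
truth <- gen$truth

cat(sprintf("simulated %d subjects: %.1f%% symptomatic by construction\n",
            n, 100 * mean(truth$cluster > 0)))
shares <- 100 * tabulate(truth$cluster, 5) / n
cat("planted cluster shares (% of cohort):",
    paste(sprintf("%.1f", shares), collapse = " / "), "\n")

surv <- generate_survival(truth, gen$table$data, cfg$survival_model,
                          seed = seed + 1L)
cat(sprintf("survival: %d deaths over %g years of follow-up\n",
            sum(surv$event), cfg$survival_model$admin_end))
print(table(surv$cause[surv$event == 1L]))

hist_rec <- generate_icd_histories(cfg, truth, index_year = index_year,
                                   seed = seed + 2L)
cat(sprintf("ICD-10 histories: %d records for %d subjects\n",
            nrow(hist_rec), length(unique(hist_rec$subject_id))))

miss <- inject_missingness(gen$table, mechanism = cfg$missingness$mechanism,
                           rate = cfg$missingness$rate, seed = seed + 3L)
sv <- survey_vars(miss$schema)
cat(sprintf("injected %s missingness: %.1f%% of survey cells blank\n",
            cfg$missingness$mechanism,
            100 * mean(is.na(miss$data[, sv]))))

write_cohort(miss, file.path(out, "cohort.csv"))
write_schema(miss$schema, file.path(out, "schema.csv"))
write.csv(truth, file.path(out, "truth_labels.csv"), row.names = FALSE)
write.csv(surv, file.path(out, "survival_raw.csv"), row.names = FALSE)
write.csv(hist_rec, file.path(out, "icd_histories.csv"), row.names = FALSE)
cat("wrote cohort, schema, truth, survival and ICD history tables to ",
    out, "\n", sep = "")
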