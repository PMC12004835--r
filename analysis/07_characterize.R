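#!/usr/bin/env Rscript
# Stage 7: cluster characterisation.
#
# Descriptive table per consensus cluster (proportion / mean, with
# chi-square or Mann-Whitney p-values against all other clusters) and
# the symptom-count distribution averaged over the imputations.

library(respclust)

data_dir <- "results/data"

schema <- read_schema(file.path(data_dir, "schema.csv"))
iset <- read_imputation_set(file.path(data_dir, "imputations"), schema)
cons <- read.csv(file.path(data_dir, "consensus_labels.csv"))

pooled <- pool_descriptive(iset)
char <- characterize_clusters(cons$consensus, pooled)
write.csv(char, "results/cluster_characterization.csv", row.names = FALSE)

cat("per-cluster symptom prevalence (descriptively pooled data):\n")
show <- c("wheeze_12m", "productive_cough_chronic", "rhinitis_ever",
          "dyspnea_attack_cold_dust", "night_cough_waking")
wide <- reshape(char[char$variable %in% show,
                     c("variable", "cluster", "summary")],
                idvar = "variable", timevar = "cluster", direction = "wide")
print(wide, row.names = FALSE, digits = 2)

histo <- symptom_count_distribution(iset)
write.csv(histo, "results/symptom_count_distribution.csv", row.names = FALSE)
cat(sprintf("\n%% with no symptoms: %.1f; %% with >=5: %.1f; %% in top bin (>=20): %.2f\n",
            histo$pct[1],
            sum(histo$pct[-(1:5)]),
            histo$pct[nrow(histo)]))
cat("wrote cluster characterisation and symptom-count distribution\n")
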