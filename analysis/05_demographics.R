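#!/usr/bin/env Rscript
# Demographic prevalence statistics of the ADHD-200 training release,
# recomputed from the published site/diagnosis/gender count tables that
# ship with the package. Tables under results/demographics/.

suppressPackageStartupMessages(library(adhdml))
out <- "results/demographics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ph <- expand_site_counts()
pg <- expand_gender_counts()

overall <- prevalence_stats(ph)
no_td_only <- prevalence_stats(ph, exclude_td_only_sites = TRUE)
by_site <- prevalence_stats(ph, by = "site", include_adhd_h = FALSE)
by_gender <- prevalence_stats(pg, by = "gender")
by_site_gender <- prevalence_stats(pg, by = "site_gender", digits = 1)

utils::write.csv(by_site, file.path(out, "prevalence_by_site.csv"),
                 row.names = FALSE)
utils::write.csv(by_gender, file.path(out, "prevalence_by_gender.csv"),
                 row.names = FALSE)
utils::write.csv(by_site_gender, file.path(out, "prevalence_by_site_gender.csv"),
                 row.names = FALSE)

cat("ADHD prevalence, entire training set:      ", overall$prevalence_pct, "%\n")
cat("ADHD prevalence, excluding TD-only sites:  ", no_td_only$prevalence_pct, "%\n")
cat("female / male ADHD prevalence:             ",
    by_gender$prevalence_pct[by_gender$gender == "F"], "% /",
    by_gender$prevalence_pct[by_gender$gender == "M"], "%\n")
cat("highest site prevalence (ADHD-H excluded): ",
    max(by_site$prevalence_pct), "% at",
    by_site$site[which.max(by_site$prevalence_pct)], "\n")
cat("subtype ratio ADHD-C:ADHD-I at NI:         ",
    paste(subtype_ratio(ph, "NI"), collapse = ":"), "\n")
cat("subtype ratio ADHD-C:ADHD-I at Peking:     ",
    paste(subtype_ratio(ph, "Peking"), collapse = ":"), "\n")
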