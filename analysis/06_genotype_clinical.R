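#!/usr/bin/env Rscript

# Genotype association of the brachyury rs2305089 variant and the
# clinical cohort summary. Runs the association twice: on the observed
# case-control table and on the simulated cohort of stage 01.

suppressPackageStartupMessages(library(chordomics))

cohort <- "results/cohort"
out <- "results/genotype"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## observed table
tab <- chordoma_genotype_table()
rep_obs <- genotype_association_report(tab, monte_carlo = 100000L)
message(sprintf("observed table: chi2 = %.2f (df %d), p = %.4g (MC %.4g)",
                rep_obs$test$statistic, rep_obs$test$df, rep_obs$test$p_value,
                rep_obs$test$p_monte_carlo))
message(sprintf("carriers: chordoma %.0f%%, control %.0f%%; A-allele frequency in cases %.1f%%",
                100 * rep_obs$groups$chordoma$carrier_frequency,
                100 * rep_obs$groups$control$carrier_frequency,
                100 * rep_obs$groups$chordoma$allele_frequency))
jsonlite::write_json(rep_obs, file.path(out, "association_observed.json"),
                     auto_unbox = TRUE, digits = NA)

## simulated cohort
geno <- read_genotype_table(file.path(cohort, "genotypes.tsv"))
sim_tab <- genotype_counts(geno, groups = c("chordoma", "control"))
rep_sim <- genotype_association_report(sim_tab, monte_carlo = 0L)
message(sprintf("simulated cohort: chi2 = %.2f, p = %.4g",
                rep_sim$test$statistic, rep_sim$test$p_value))
jsonlite::write_json(rep_sim, file.path(out, "association_simulated.json"),
                     auto_unbox = TRUE, digits = NA)

## clinical summary
cl <- summarize_clinical(read_clinical_table(clinical_cohort_path()))
message(sprintf("clinical: n = %d, mean age %.1f (range %d-%d), GTR %d / STR %d",
                cl$n, cl$mean_age, cl$age_range[1], cl$age_range[2],
                cl$counts$extent[["GTR"]], cl$counts$extent[["STR"]]))
cl$counts <- lapply(cl$counts, as.list)
jsonlite::write_json(cl, file.path(out, "clinical_summary.json"),
                     auto_unbox = TRUE, digits = NA)
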