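#!/usr/bin/env Rscript

# Somatic mutation analysis of the simulated WES cohort: per-sample
# burden, 6-class spectrum, 96-trinucleotide-context matrix, NpCpG C>T
# prominence, and recurrently mutated genes.

suppressPackageStartupMessages(library(chordomics))

cohort <- "results/cohort"
out <- "results/spectrum"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(cohort, "genome.fa"))
variants <- read_variant_table(file.path(cohort, "somatic_variants.tsv"))
capture_mb <- sum(nchar(genome)) / 1e6

summaries <- list()
contexts <- list()
for (sample in sort(unique(variants$sample))) {
  sp <- build_spectrum(variants[variants$sample == sample, ], genome,
                       capture_mb = capture_mb)
  pr <- npcpg_prominence(sp)
  summaries[[sample]] <- data.frame(
    sample = sample, n_snvs = sp$n_snvs, n_indels = sp$n_indels,
    mut_per_mb = round(sp$mut_per_mb, 3), hypermutated = sp$hypermutated,
    npcpg_score = round(pr$score, 3), npcpg_flagged = pr$flagged,
    stringsAsFactors = FALSE)
  grid <- expand.grid(class = rownames(sp$context96),
                      five_prime = c("A", "C", "G", "T"),
                      three_prime = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid$count <- sp$context96[cbind(grid$class, grid$five_prime,
                                   grid$three_prime)]
  contexts[[sample]] <- cbind(sample = sample, grid)
}
summary <- do.call(rbind, summaries)
write_headed_tsv(summary, file.path(out, "sample_summary.tsv"))
write_headed_tsv(do.call(rbind, contexts), file.path(out, "context96.tsv"))

message("cohort mean burden: ",
        round(mean(summary$mut_per_mb[!summary$hypermutated]), 2),
        " mut/Mb (non-hypermutated)")
message("NpCpG-prominent samples: ",
        paste(summary$sample[summary$npcpg_flagged %in% TRUE], collapse = ", "))

rec <- recurrent_genes(variants, min_cases = 3L)
write_headed_tsv(rec$genes, file.path(out, "recurrent_genes.tsv"))
write_headed_tsv(rec$identical_changes,
                 file.path(out, "recurrent_identical_changes.tsv"))
message("genes mutated in >= 3 cases: ",
        paste(sprintf("%s (%d)", rec$genes$gene, rec$genes$n_cases),
              collapse = ", "))
if (nrow(rec$identical_changes)) {
  message("identical change shared by ", rec$identical_changes$n_cases[1],
          " cases in ", rec$identical_changes$gene[1], " (",
          rec$identical_changes$protein_change[1], ")")
}
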