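#!/usr/bin/env Rscript

# Build the synthetic chordoma-like cohort every later stage consumes:
# a 5 x 2 Mb genome with the fusion partner pair, paired-end RNA
# alignments for five "RNA-seq" samples (four fusion-positive, one
# negative), somatic variant tables for eight "WES" samples (four with
# NpCpG C>T enrichment, recurrent genes injected), tumor/normal depth
# windows, an expression count matrix and a genotype table.

suppressPackageStartupMessages(library(chordomics))

SEED <- 20160L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("genome: 5 chromosomes x 2 Mb, ", length(default_gene_specs()), " genes")
gw <- make_genome(seed = SEED)
write_fasta(gw$genome, file.path(out, "genome.fa"))
write_gene_table(gw$genes, file.path(out, "genes.tsv"))

## RNA samples: R1-R4 carry the SAMD5L-SASH1L fusion, R5 does not
fusion <- default_fusion_spec(gw$genes, expression_level = 0.4)
rna_samples <- paste0("R", 1:5)
for (i in seq_along(rna_samples)) {
  spec <- if (i < 5) fusion else NULL
  sim <- simulate_fusion_read_pairs(gw$genome, gw$genes, spec,
                                    n_pairs = 600L,
                                    seed = child_seed(SEED, i))
  write_sam_lite(sim$pairs, file.path(out, paste0(rna_samples[i], ".sam")),
                 chrom_lengths = gw$chrom_lengths)
  message(rna_samples[i], ": ", sim$truth[["fusion_discordant"]],
          " discordant fusion pairs, ", sim$truth[["junction_split"]],
          " junction-spanning reads")
}

## WES samples: burden 2.1 mut/Mb, four NpCpG-enriched, recurrent genes
wes_samples <- paste0("T", 1:8)
variants <- simulate_cohort_variants(
  gw$genome, gw$genes, wes_samples, mut_rate = 2.1,
  npcpg_enriched_samples = paste0("T", 1:4),
  recurrent_spec = list(MUC4L = c("T1", "T3", "T5", "T7"),
                        NBPF1L = c("T2", "T4", "T6")),
  shared_site_spec = list(gene = "NPIPB15L", samples = c("T1", "T2", "T8")),
  seed = child_seed(SEED, 20L))
write_variant_table(variants, file.path(out, "somatic_variants.tsv"))
message("variants: ", nrow(variants), " across ", length(wes_samples),
        " samples")

## depth windows for one tumor/normal pair on the CNA universe
d <- simulate_depth_profiles(default_cna_spec(), default_cna_chrom_lengths(),
                             n_windows = 1000L, seed = child_seed(SEED, 30L))
write_headed_tsv(d, file.path(out, "depth_windows.tsv"))

## expression counts: chordoma group overexpresses the fusion 5' gene and
## the brachyury analog
expr <- simulate_expression_counts(seed = child_seed(SEED, 40L))
write_tsv_matrix(expr$counts, file.path(out, "expression_counts.tsv"))
write_headed_tsv(data.frame(gene = names(expr$gene_lengths),
                            length = expr$gene_lengths),
                 file.path(out, "gene_lengths.tsv"))
write_headed_tsv(data.frame(sample = names(expr$groups),
                            group = unname(expr$groups)),
                 file.path(out, "sample_groups.tsv"))

## genotype cohort at the observed case/control frequencies
probs <- sweep(chordoma_genotype_table(), 1,
               rowSums(chordoma_genotype_table()), "/")
geno <- simulate_genotype_cohort(c(chordoma = 8L, control = 75L), probs,
                                 seed = child_seed(SEED, 50L))
write_genotype_table(geno$individuals, file.path(out, "genotypes.tsv"))

message("cohort written under ", out)
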