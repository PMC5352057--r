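test_that("genome generation is deterministic and validates gene placement", {
  g1 <- make_genome(n_chrom = 2L, chrom_length = 5000L,
                    gene_specs = list(), seed = 3L)
  g2 <- make_genome(n_chrom = 2L, chrom_length = 5000L,
                    gene_specs = list(), seed = 3L)
  expect_identical(g1$genome, g2$genome)
  expect_length(g1$genome, 2L)
  g3 <- make_genome(n_chrom = 2L, chrom_length = 5000L,
                    gene_specs = list(), seed = 4L)
  expect_false(identical(g1$genome, g3$genome))

  past_end <- list(gene_spec("g", "chr1", 4900L, exon_lengths = 500L))
  expect_error(make_genome(2L, 5000L, past_end, seed = 1L), "past chromosome end")

  overlapping <- list(gene_spec("g1", "chr1", 100L, exon_lengths = 500L),
                      gene_spec("g2", "chr1", 400L, exon_lengths = 500L))
  expect_error(make_genome(2L, 5000L, overlapping, seed = 1L), "overlapping")
})

test_that("gene specs realize exon structure and native codon phases", {
  gw <- tiny_genome()
  donor <- gw$genes$DONOR
  expect_equal(nrow(donor$exons), 3L)
  expect_equal(donor$exons[1L, ], c(start = 2001L, end = 2402L))
  expect_equal(donor$phase, c(0L, 0L, 0L))  # exon lengths are multiples of 3
  acceptor <- gw$genes$ACCEPTOR
  expect_equal(acceptor$phase[2L], 0L)
  expect_equal(gene_introns(donor)[1L, ], c(start = 2403L, end = 5402L),
               ignore_attr = TRUE)
})

test_that("read-pair simulator emits the declared mixture deterministically", {
  gw <- tiny_genome()
  fus <- tiny_fusion(gw$genes)
  a <- simulate_fusion_read_pairs(gw$genome, gw$genes, fus, n_pairs = 150, seed = 5)
  b <- simulate_fusion_read_pairs(gw$genome, gw$genes, fus, n_pairs = 150, seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$truth[c("background_concordant", "fusion_donor_concordant",
                             "fusion_acceptor_concordant", "fusion_discordant")]),
               150)
  expect_equal(unname(a$truth[["background_concordant"]]), 90)  # 1 - 0.4 of 150

  none <- simulate_fusion_read_pairs(gw$genome, gw$genes, NULL,
                                     n_pairs = 0, seed = 1)
  expect_equal(nrow(none$pairs), 0L)

  off <- simulate_fusion_read_pairs(
    gw$genome, gw$genes,
    tiny_fusion(gw$genes, expression_level = 0), n_pairs = 100, seed = 1)
  expect_equal(unname(off$truth[["fusion_discordant"]]), 0L)
  expect_equal(unname(off$truth[["background_concordant"]]), 100L)

  expect_error(
    simulate_fusion_read_pairs(gw$genome, gw$genes, NULL, n_pairs = 10,
                               insert_mean = 700, seed = 1),
    "insert size")
})

test_that("fusion mates always respect the injected junction geometry", {
  gw <- tiny_genome()
  fus <- tiny_fusion(gw$genes)
  sim <- simulate_fusion_read_pairs(gw$genome, gw$genes, fus,
                                    n_pairs = 300, seed = 9)
  fp <- sim$pairs[startsWith(sim$pairs$pair_id, "fus"), ]
  donor_span <- c(gene_start(gw$genes$DONOR), fus$bp5)
  acc_span <- c(fus$bp3, gene_end(gw$genes$ACCEPTOR))
  for (side in list(c("chrom1", "start1", "len1"), c("chrom2", "start2", "len2"))) {
    s <- fp[[side[2]]]; e <- s + fp[[side[3]]] - 1L
    donor_mate <- s <= fus$bp5
    expect_true(all(e[donor_mate] <= donor_span[2]))
    expect_true(all(s[donor_mate] >= donor_span[1]))
    expect_true(all(s[!donor_mate] >= acc_span[1] & e[!donor_mate] <= acc_span[2]))
  }
})

test_that("depth simulator hits its arm-level expectations", {
  lens <- default_cna_chrom_lengths(4L, 100000L)
  spec <- data.frame(chrom = rep(paste0("chr", 1:4), each = 2),
                     arm = rep(c("p", "q"), 4),
                     state = c("loss", "neutral", "neutral", "neutral",
                               "gain", "gain", "neutral", "neutral"),
                     stringsAsFactors = FALSE)
  d0 <- simulate_depth_profiles(spec, lens, n_windows = 200, mean_depth = 100,
                                dispersion = 0, seed = 1)
  expect_true(all(d0$tumor[d0$state == "neutral"] == d0$normal[d0$state == "neutral"]))
  expect_true(all(d0$tumor[d0$state == "loss"] / d0$normal[d0$state == "loss"] == 0.5))

  d <- simulate_depth_profiles(spec, lens, n_windows = 400, mean_depth = 100,
                               dispersion = 0.05, seed = 2)
  gain <- d$state == "gain"
  ratio <- d$tumor[gain] / d$normal[gain]
  se <- sd(ratio) / sqrt(sum(gain))
  expect_lt(abs(mean(ratio) - 1.5), 3 * se + 0.05)

  expect_identical(d, simulate_depth_profiles(spec, lens, n_windows = 400,
                                              mean_depth = 100,
                                              dispersion = 0.05, seed = 2))
  expect_error(simulate_depth_profiles(spec, lens, n_windows = 0, seed = 1),
               "n_windows")
  expect_error(simulate_depth_profiles(spec, lens, mean_depth = 0, seed = 1),
               "mean_depth")
})

test_that("variant simulator matches its Poisson burden expectation", {
  gw <- tiny_genome()  # 0.12 Mb total
  si <- build_site_index(gw$genome)
  expect_identical(
    simulate_variants(gw$genome, 50, site_index = si, seed = 4),
    simulate_variants(gw$genome, 50, site_index = si, seed = 4))
  expect_equal(nrow(simulate_variants(gw$genome, 0, site_index = si, seed = 1)), 0L)
  expect_error(simulate_variants(gw$genome, 1, signature_mix = c("C>T" = 1, "C>A" = 0.5),
                                 seed = 1))

  counts <- vapply(1:300, function(s) {
    nrow(simulate_variants(gw$genome, 100, site_index = si, seed = s))
  }, numeric(1))
  expected <- 100 * 0.12  # rate x genome Mb
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05 * expected)
})

test_that("simulated substitutions follow the signature mixture", {
  gw <- tiny_genome()
  si <- build_site_index(gw$genome)
  v <- do.call(rbind, lapply(1:40, function(s) {
    simulate_variants(gw$genome, 100, site_index = si, seed = 500 + s)
  }))
  snv <- v[v$kind == "SNV", ]
  freq <- prop.table(table(substitution_class(snv$ref, snv$alt)))
  mix <- default_signature_mix()
  for (cl in names(mix)) {
    se <- sqrt(mix[[cl]] * (1 - mix[[cl]]) / nrow(snv))
    expect_lt(abs(freq[[cl]] - mix[[cl]]), 4 * se)
  }
  expect_lt(mean(v$kind != "SNV"), 0.10)  # ~5% indels
})

test_that("cohort variant simulation injects recurrence ground truth", {
  gw <- tiny_genome()
  samples <- paste0("T", 1:5)
  v <- simulate_cohort_variants(
    gw$genome, gw$genes, samples, mut_rate = 30,
    recurrent_spec = list(DONOR = c("T1", "T2", "T3")),
    shared_site_spec = list(gene = "OTHER", samples = c("T1", "T3", "T4")),
    seed = 8)
  rec <- recurrent_genes(v, min_cases = 3L)
  expect_true("DONOR" %in% rec$genes$gene)
  expect_true("OTHER" %in% rec$genes$gene)
  shared <- rec$identical_changes
  expect_equal(shared$gene, "OTHER")
  expect_equal(shared$n_cases, 3L)
  expect_true(startsWith(shared$protein_change, "p."))
})

test_that("genotype cohort simulation reproduces the printed study counts", {
  counts <- chordoma_genotype_table()
  expect_equal(unname(rowSums(counts)), c(8, 75))
  expect_equal(unname(counts["chordoma", ]), c(1, 3, 4))
  expect_equal(unname(counts["control", ]), c(36, 32, 7))

  empty <- simulate_genotype_cohort(c(a = 0L, b = 0L),
                                    rbind(c(1, 0, 0), c(1, 0, 0)), seed = 1)
  expect_equal(sum(empty$counts), 0L)
  expect_equal(nrow(empty$individuals), 0L)

  hom <- simulate_genotype_cohort(c(a = 12L), rbind(c(1, 0, 0)), seed = 1)
  expect_equal(unname(hom$counts[1, ]), c(12L, 0L, 0L))

  expect_error(simulate_genotype_cohort(c(a = -1L), rbind(c(1, 0, 0)), seed = 1),
               "negative")
  expect_error(simulate_genotype_cohort(c(a = 1L), rbind(c(0.5, 0.1, 0.1)), seed = 1),
               "sum to 1")
})
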