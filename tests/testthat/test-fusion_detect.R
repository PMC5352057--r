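pair_row <- function(chrom1, start1, len1, chrom2, start2, len2) {
  data.frame(pair_id = "p", chrom1 = chrom1, start1 = start1, strand1 = "+",
             len1 = len1, chrom2 = chrom2, start2 = start2, strand2 = "-",
             len2 = len2, stringsAsFactors = FALSE)
}

test_that("read pairs are classified by the two filter criteria", {
  gw <- tiny_genome()
  genes <- gw$genes
  donor_exon <- gene_start(genes$DONOR)
  acc_exon <- gene_start(genes$ACCEPTOR)
  # criterion 1: each end aligns to a different gene
  expect_equal(classify_read_pair(
    pair_row("chrA", donor_exon, 100L, "chrA", acc_exon, 100L), genes),
    "discordant_gene_pair")
  # both mates in one gene
  expect_equal(classify_read_pair(
    pair_row("chrA", donor_exon, 100L, "chrA", donor_exon + 200L, 100L), genes),
    "concordant")
  # criterion 2 outranks concordant, but only for supported genes
  intron <- gene_introns(genes$DONOR)[1L, ]
  in_intron <- pair_row("chrA", donor_exon, 100L, "chrA",
                        intron[["start"]] + 50L, 100L)
  expect_equal(classify_read_pair(in_intron, genes), "concordant")
  expect_equal(classify_read_pair(in_intron, genes, supported_genes = "DONOR"),
               "intronic_breakpoint_support")
  # intergenic
  expect_equal(classify_read_pair(
    pair_row("chrA", 50000L, 100L, "chrB", 50000L, 100L), genes),
    "unassigned")
  expect_error(classify_read_pair(
    pair_row("chrZ", 1L, 10L, "chrA", donor_exon, 10L), genes,
    chrom_lengths = gw$chrom_lengths), "unknown chromosome")
})

test_that("pair classification agrees with a brute-force interval oracle", {
  gw <- tiny_genome()
  genes <- gw$genes
  supported <- c("DONOR", "ACCEPTOR")
  pairs <- with_seed(77, data.frame(
    pair_id = sprintf("r%04d", 1:400),
    chrom1 = sample(c("chrA", "chrB"), 400, TRUE),
    start1 = sample.int(59000, 400), strand1 = "+",
    len1 = sample(c(30L, 101L, 150L), 400, TRUE),
    chrom2 = sample(c("chrA", "chrB"), 400, TRUE),
    start2 = sample.int(59000, 400), strand2 = "-",
    len2 = sample(c(30L, 101L, 150L), 400, TRUE),
    stringsAsFactors = FALSE))
  got <- classify_pairs(pairs, genes, supported_genes = supported)
  want <- vapply(seq_len(nrow(pairs)), function(i) {
    oracle_classify(pairs[i, ], genes, supported)
  }, character(1))
  expect_identical(got, want)
  expect_true(length(unique(got)) >= 3)  # the instance exercises several labels
})

test_that("coverage accumulates aligned bases and is linear", {
  p1 <- pair_row("chrA", 1L, 10L, "chrB", 1000L, 10L)
  tr <- build_coverage(p1, "chrA", 1L, 20L)
  expect_equal(tr$depth, c(rep(1L, 10), rep(0L, 10)))
  tr2 <- build_coverage(rbind(p1, p1), "chrA", 1L, 20L)
  expect_equal(tr2$depth, 2L * tr$depth)

  pairs <- with_seed(5, data.frame(
    pair_id = sprintf("c%03d", 1:200),
    chrom1 = "chrA", start1 = sample.int(900, 200), strand1 = "+",
    len1 = sample(20:120, 200, TRUE),
    chrom2 = "chrA", start2 = sample.int(900, 200), strand2 = "-",
    len2 = sample(20:120, 200, TRUE), stringsAsFactors = FALSE))
  tr3 <- build_coverage(pairs, "chrA", 100L, 700L)
  naive <- integer(601)
  for (i in seq_len(nrow(pairs))) {
    for (side in list(c(pairs$start1[i], pairs$len1[i]),
                      c(pairs$start2[i], pairs$len2[i]))) {
      for (p in seq(side[1], side[1] + side[2] - 1L)) {
        if (p >= 100L && p <= 700L) naive[p - 99L] <- naive[p - 99L] + 1L
      }
    }
  }
  expect_equal(tr3$depth, naive)
  expect_equal(sum(tr3$depth), sum(naive))
})

test_that("breakpoint inference finds steps, reports no-breakpoint on flat tracks", {
  g <- gene_model("g", "chrA", "+", rbind(c(1, 100), c(301, 400)),
                  phase = c(0L, 1L))
  # clean step down inside the intron at position 200/201
  depth <- c(rep(100L, 200), rep(0L, 200))
  bp <- infer_breakpoint(make_track(depth), g, flank = 10L)
  expect_equal(bp$position, 201L)
  expect_equal(bp$direction, "drop")

  flat <- infer_breakpoint(make_track(rep(100L, 400)), g, flank = 10L)
  expect_true(is.na(flat$position))
  zero <- infer_breakpoint(make_track(rep(0L, 400)), g, flank = 10L)
  expect_true(is.na(zero$position))

  # palindromic track: the drop at 101 and the rise at 201 tie on the
  # global statistic; the leftmost split wins
  g2 <- gene_model("g2", "chrA", "+", rbind(c(1, 50), c(251, 300)),
                   phase = c(0L, 0L))
  depth2 <- c(rep(100L, 100), rep(0L, 100), rep(100L, 100))
  bp2 <- infer_breakpoint(make_track(depth2), g2, flank = 10L, min_delta = 1)
  expect_equal(bp2$position, 101L)
  expect_equal(bp2$direction, "drop")
})

test_that("breakpoint inference matches an exhaustive scan oracle", {
  g <- gene_model("g", "chrA", "+", rbind(c(1, 60), c(241, 300)),
                  phase = c(0L, 0L))
  for (seed in 1:25) {
    depth <- with_seed(seed, {
      step_at <- sample(80:220, 1)
      high <- sample(5:40, 1)
      base <- c(rep(high, step_at), rep(0L, 300 - step_at))
      pmax(0L, base + sample(-1:1, 300, TRUE) * rbinom(300, 1, 0.3))
    })
    track <- make_track(depth)
    got <- infer_breakpoint(track, g, flank = 15L)
    want <- oracle_breakpoint(track, g, flank = 15L)
    expect_equal(got$position, want, info = paste("seed", seed))
  }
})

test_that("the caller recovers an injected fusion exactly at deep coverage", {
  gw <- tiny_genome()
  fus <- tiny_fusion(gw$genes, expression_level = 0.5)
  sim <- simulate_fusion_read_pairs(gw$genome, gw$genes, fus,
                                    n_pairs = 1200, seed = 31)
  cands <- call_fusions(sim$pairs, gw$genes, min_support = 2L)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$gene5, "DONOR")
  expect_equal(cands$gene3, "ACCEPTOR")
  expect_equal(cands$breakpoint5, fus$bp5)
  expect_equal(cands$breakpoint3, fus$bp3)
  expect_equal(cands$frame_status, "in_frame")
  expect_true(cands$intrachromosomal)
  expect_gte(cands$n_junction_reads, 1L)

  # a threshold above the injected support silences the call
  high <- call_fusions(sim$pairs, gw$genes,
                       min_support = cands$n_discordant_pairs + 1L)
  expect_equal(nrow(high), 0L)

  # no fusion, background only: no candidate (no coverage-only calls)
  none <- simulate_fusion_read_pairs(gw$genome, gw$genes, NULL,
                                     n_pairs = 600, seed = 32)
  expect_equal(nrow(call_fusions(none$pairs, gw$genes)), 0L)
})

test_that("two injected fusions are reported ordered by discordant support", {
  gw <- make_genome(
    n_chrom = 2L, chrom_length = 80000L,
    gene_specs = {
      specs <- list(
        gene_spec("DONOR", "chrA", 2001L, c(402L, 300L, 450L), c(3000L, 2000L)),
        gene_spec("ACCEPTOR", "chrA", 30001L, c(201L, 300L, 600L), c(2500L, 1800L)),
        gene_spec("DONOR2", "chrB", 2001L, c(402L, 300L, 450L), c(3000L, 2000L)),
        gene_spec("ACCEPTOR2", "chrB", 30001L, c(201L, 300L, 600L), c(2500L, 1800L)))
      names(specs) <- vapply(specs, `[[`, character(1), "gene_id")
      specs
    }, chrom_names = c("chrA", "chrB"), seed = 13L)
  fus1 <- tiny_fusion(gw$genes, expression_level = 0.5)
  fus2 <- list(gene5 = "DONOR2", gene3 = "ACCEPTOR2",
               bp5 = gene_introns(gw$genes$DONOR2)[1L, "start"] + 999L,
               bp3 = sort(gw$genes$ACCEPTOR2$exons[, "start"])[2L],
               expression_level = 0.25)
  s1 <- simulate_fusion_read_pairs(gw$genome, gw$genes[c("DONOR", "ACCEPTOR")],
                                   fus1, n_pairs = 900, seed = 41)
  s2 <- simulate_fusion_read_pairs(gw$genome, gw$genes[c("DONOR2", "ACCEPTOR2")],
                                   fus2, n_pairs = 900, seed = 42)
  s2$pairs$pair_id <- sub("^", "x", s2$pairs$pair_id)
  pairs <- rbind(s1$pairs, s2$pairs)
  cands <- call_fusions(pairs, gw$genes, min_support = 2L)
  expect_equal(nrow(cands), 2L)
  expect_setequal(cands$gene5, c("DONOR", "DONOR2"))
  expect_setequal(cands$gene3, c("ACCEPTOR", "ACCEPTOR2"))
  expect_equal(cands$breakpoint5, rep(fus1$bp5, 2L))  # mirrored geometry
  # candidates come back sorted by discordant support, descending
  expect_false(is.unsorted(rev(cands$n_discordant_pairs)))
})

test_that("frame classification follows donor CDS length and acceptor phase", {
  genes <- list(
    D300 = gene_model("D300", "chr1", "+", rbind(c(1, 300), c(501, 700)),
                      phase = c(0L, 0L)),
    D301 = gene_model("D301", "chr1", "+", rbind(c(1001, 1301), c(1501, 1700)),
                      phase = c(0L, 1L)),
    NC = gene_model("NC", "chr1", "+", rbind(c(2001, 2300))),
    ACC = gene_model("ACC", "chr2", "+", rbind(c(1, 99), c(301, 500)),
                     phase = c(0L, 0L))
  )
  cand <- function(g5, bp5) {
    data.frame(gene5 = g5, gene3 = "ACC", breakpoint5 = bp5,
               breakpoint3 = 301L, stringsAsFactors = FALSE)
  }
  expect_equal(classify_frame(cand("D300", 300L), genes), "in_frame")
  expect_equal(classify_frame(cand("D301", 1301L), genes), "out_of_frame")
  expect_equal(classify_frame(cand("NC", 2300L), genes), "noncoding")
  expect_error(classify_frame(cand("D300", 900L), genes), "outside gene")
})

test_that("junction reconstruction matches manual sequence assembly", {
  genome <- c(chr1 = "AAAACCCCGGGGTTTTACGTACGTACGT",
              chr2 = "TTTTGGGGCCCCAAAATGCATGCATGCA")
  genes <- list(
    D = gene_model("D", "chr1", "+", rbind(c(1, 12), c(17, 24)), phase = c(0L, 0L)),
    A = gene_model("A", "chr2", "+", rbind(c(1, 8), c(13, 24)), phase = c(0L, 2L)),
    DM = gene_model("DM", "chr1", "-", rbind(c(17, 24), c(1, 12)), phase = c(0L, 2L))
  )
  cand <- data.frame(gene5 = "D", gene3 = "A", breakpoint5 = 12L,
                     breakpoint3 = 13L, stringsAsFactors = FALSE)
  expect_equal(reconstruct_junction(cand, genome, genes, k = 5L),
               paste0(substr(genome[["chr1"]], 8, 12),
                      substr(genome[["chr2"]], 13, 17)))
  # minus-strand donor: donor side is the reverse complement, read 3'->5'
  cand_m <- data.frame(gene5 = "DM", gene3 = "A", breakpoint5 = 17L,
                       breakpoint3 = 13L, stringsAsFactors = FALSE)
  donor_side <- chordomics:::reverse_complement(substr(genome[["chr1"]], 17, 21))
  expect_equal(reconstruct_junction(cand_m, genome, genes, k = 5L),
               paste0(donor_side, substr(genome[["chr2"]], 13, 17)))
  expect_error(reconstruct_junction(cand, genome, genes, k = 20L),
               "available sequence")
})

test_that("simulated junction reads align end-to-end on the reconstructed junction", {
  gw <- tiny_genome()
  fus <- tiny_fusion(gw$genes, expression_level = 0.5)
  sim <- simulate_fusion_read_pairs(gw$genome, gw$genes, fus,
                                    n_pairs = 900, seed = 55)
  expect_gt(length(sim$junction_read_sequences), 0L)
  k <- 120L
  jx <- reconstruct_junction(
    data.frame(gene5 = "DONOR", gene3 = "ACCEPTOR",
               breakpoint5 = fus$bp5, breakpoint3 = fus$bp3,
               stringsAsFactors = FALSE),
    gw$genome, gw$genes, k = k)
  for (rs in sim$junction_read_sequences) {
    expect_true(grepl(rs, jx, fixed = TRUE))
  }
})
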