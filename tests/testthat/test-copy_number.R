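test_that("fixed-count windows hold exactly the requested reads", {
  reads <- data.frame(chrom = "chr1", pos = seq(10L, 100000L, by = 100L),
                      stringsAsFactors = FALSE)  # 1000 uniform reads
  w <- make_windows(reads, reads_per_window = 100L,
                    chrom_lengths = c(chr1 = 100000L))
  expect_equal(nrow(w), 10L)
  expect_equal(count_reads_in_windows(w, reads), rep(100L, 10L))
  expect_equal(w$end[10L], 100000L)

  # nonuniform depth: variable widths, equal counts (cumulative-count oracle)
  pos <- with_seed(3, sort(sample.int(50000L, 600L)))
  reads2 <- data.frame(chrom = "chr1", pos = pos, stringsAsFactors = FALSE)
  w2 <- make_windows(reads2, reads_per_window = 100L,
                     chrom_lengths = c(chr1 = 50000L))
  counts <- count_reads_in_windows(w2, reads2)
  expect_true(all(counts[-length(counts)] == 100L))
  expect_gt(length(unique(w2$end - w2$start)), 1L)
  expect_equal(w2$end[-nrow(w2)], pos[seq_len(nrow(w2) - 1L) * 100L])

  # windows never span chromosomes
  reads3 <- rbind(reads2, data.frame(chrom = "chr2", pos = pos))
  w3 <- make_windows(reads3, 100L, c(chr1 = 50000L, chr2 = 50000L))
  expect_true(all(table(w3$chrom) >= 6L))
  expect_error(make_windows(reads3, reads_per_window = 10L,
                            chrom_lengths = c(chr1 = 1000L)),
               "reads_per_window")
  expect_warning(
    make_windows(data.frame(chrom = "chr1", pos = 1:10),
                 reads_per_window = 100L, chrom_lengths = c(chr1 = 5000L)),
    "whole-chromosome")
})

test_that("pseudo-normal reference is the library-normalized per-window median", {
  one <- matrix(c(10, 20, 30), ncol = 1)
  expect_equal(build_pseudo_normal(one), c(10, 20, 30))
  three_same <- cbind(c(10, 20), c(10, 20), c(10, 20))
  expect_equal(build_pseudo_normal(three_same), c(10, 20))
  # equal library sizes: plain median
  m <- cbind(c(10, 100), c(20, 90), c(90, 20))
  expect_equal(build_pseudo_normal(m)[1L], 20)
  expect_error(build_pseudo_normal(list(c(1, 2), c(1, 2, 3))), "mismatched")
})

test_that("log2 ratios are centered, scale-invariant and floored", {
  w <- data.frame(chrom = "chr1", start = seq(1, 1000, 100),
                  end = seq(100, 1000, 100), stringsAsFactors = FALSE)
  t <- rep(50, 10); r <- rep(50, 10)
  p <- compute_log2_ratio(w, t, r)
  expect_equal(p$log2_ratio, rep(0, 10))

  t2 <- c(rep(100, 5), rep(50, 5))
  p2 <- compute_log2_ratio(w, t2, r)
  # the doubled half sits ~1 above the neutral half after centering
  expect_equal(mean(p2$log2_ratio[1:5]) - mean(p2$log2_ratio[6:10]), 1,
               tolerance = 0.02)

  p3 <- compute_log2_ratio(w, 2 * t2, 2 * r)
  expect_equal(p3$log2_ratio, p2$log2_ratio)  # CPM scale: exact invariance

  expect_error(compute_log2_ratio(w, rep(0, 10), r), "all-zero")
})

test_that("segmentation recovers exact boundaries on noiseless steps", {
  w <- data.frame(chrom = "chr1", start = seq(1L, 2000L, 20L),
                  end = seq(20L, 2000L, 20L), stringsAsFactors = FALSE)
  flat <- w; flat$log2_ratio <- rep(0, 100)
  segs <- segment_profile(flat)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$call, "neutral")

  step <- w; step$log2_ratio <- c(rep(0, 60), rep(1, 40))
  segs2 <- segment_profile(step)
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$start[2L], w$start[61L])
  expect_equal(segs2$mean_log2, c(0, 1))
  expect_equal(segs2$call, c("neutral", "gain"))

  # exhaustive split-point oracle: the accepted boundary maximizes |t|
  x <- step$log2_ratio
  tstat <- vapply(4:97, function(b) {
    a <- x[1:(b - 1)]; c <- x[b:100]
    sp <- sqrt((sum((a - mean(a))^2) + sum((c - mean(c))^2)) / 98)
    if (sp == 0) Inf else abs(mean(a) - mean(c)) / (sp * sqrt(1 / length(a) + 1 / length(c)))
  }, numeric(1))
  expect_equal(which.max(tstat) + 3L, 61L)
})

test_that("segmentation matches an exhaustive first-split oracle on noisy profiles", {
  for (seed in 1:10) {
    x <- with_seed(seed, c(rnorm(40, 0, 0.15), rnorm(30, 1, 0.15),
                           rnorm(30, 0, 0.15)))
    w <- data.frame(chrom = "chr1", start = seq_along(x), end = seq_along(x),
                    log2_ratio = x, stringsAsFactors = FALSE)
    segs <- segment_profile(w, min_gap = 0.3)
    # conservation: segment means reconstruct window means exactly
    recon <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      idx <- w$start >= segs$start[i] & w$start <= segs$end[i]
      rep(mean(x[idx]), sum(idx))
    }))
    expect_equal(segs$mean_log2,
                 vapply(seq_len(nrow(segs)), function(i) {
                   mean(x[w$start >= segs$start[i] & w$start <= segs$end[i]])
                 }, numeric(1)))
    expect_equal(length(recon), length(x))
    # the first accepted boundary is the global argmax of the t statistic
    first_boundary <- segs$start[-1L]
    if (length(first_boundary)) {
      tstat <- vapply(4:98, function(b) {
        a <- x[1:(b - 1)]; c <- x[b:100]
        sp <- sqrt((sum((a - mean(a))^2) + sum((c - mean(c))^2)) / 98)
        abs(mean(a) - mean(c)) / (sp * sqrt(1 / length(a) + 1 / length(c)))
      }, numeric(1))
      expect_true((which.max(tstat) + 3L) %in% c(first_boundary, segs$start))
    }
  }
})

test_that("injected arm events are recovered with the correct sign", {
  lens <- default_cna_chrom_lengths()
  spec <- default_cna_spec()
  ok <- 0L
  for (seed in 1:10) {
    d <- simulate_depth_profiles(spec, lens, n_windows = 1000L,
                                 mean_depth = 100, dispersion = 0.05,
                                 seed = seed)
    prof <- compute_log2_ratio(d[c("chrom", "start", "end")], d$tumor, d$normal)
    segs <- segment_profile(prof)
    calls <- segment_window_calls(prof, segs)
    altered <- d$state != "neutral"
    frac <- mean(calls[altered] == ifelse(d$state[altered] == "gain",
                                          "gain", "loss"))
    if (frac >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("gene calls combine segment means across boundaries", {
  genes <- list(
    IN = gene_model("IN", "chr1", "+", rbind(c(100, 200))),
    MID = gene_model("MID", "chr1", "+", rbind(c(950, 1050))),
    OUT = gene_model("OUT", "chr9", "+", rbind(c(1, 50)))
  )
  segments <- data.frame(chrom = "chr1", start = c(1L, 1001L),
                         end = c(1000L, 2000L), n_windows = c(10L, 10L),
                         mean_log2 = c(1, 0), call = c("gain", "neutral"),
                         stringsAsFactors = FALSE)
  calls <- call_gene_copy_number(segments, genes[c("IN", "MID")])
  expect_equal(calls$call[calls$gene_id == "IN"], "gain")
  # 51 bases at +1, 50 at 0: weighted mean ~0.505 -> gain at +0.3
  mid <- calls[calls$gene_id == "MID", ]
  expect_equal(mid$mean_log2, (51 * 1 + 50 * 0) / 101)
  expect_equal(mid$call, "gain")
  expect_error(call_gene_copy_number(segments, genes["OUT"]), "outside")
  expect_error(call_gene_copy_number(segments, genes["IN"],
                                     gain_thresh = -0.1))

  neutral <- segments; neutral$mean_log2 <- c(0, 0)
  expect_equal(call_gene_copy_number(neutral, genes["IN"])$call, "neutral")
})

test_that("cohort frequencies count gained and lost samples per locus", {
  calls <- expand.grid(sample = paste0("S", 1:8), locus = c("L1", "L2"),
                       stringsAsFactors = FALSE)
  calls$call <- "neutral"
  calls$call[calls$locus == "L1" & calls$sample %in% paste0("S", 1:5)] <- "gain"
  calls$call[calls$locus == "L2" & calls$sample %in% paste0("S", 1:2)] <- "loss"
  freq <- cohort_frequency(calls)
  expect_equal(freq$n_gain[freq$locus == "L1"], 5L)
  expect_equal(freq$n_loss[freq$locus == "L2"], 2L)
  expect_equal(unique(freq$n_total), 8L)
  expect_equal(freq$n_gain[freq$locus == "L2"], 0L)
})

test_that("the cohort CNA pattern concentrates losses and gains on the designated arms", {
  lens <- default_cna_chrom_lengths()
  spec <- default_cna_spec()
  calls_all <- do.call(rbind, lapply(1:4, function(s) {
    d <- simulate_depth_profiles(spec, lens, n_windows = 660L, seed = 60 + s)
    prof <- compute_log2_ratio(d[c("chrom", "start", "end")], d$tumor, d$normal)
    segs <- segment_profile(prof)
    data.frame(sample = paste0("S", s),
               locus = paste(d$chrom, d$arm, sep = "_"),
               call = segment_window_calls(prof, segs),
               truth = d$state, stringsAsFactors = FALSE)
  }))
  freq <- cohort_frequency(calls_all[c("sample", "locus", "call")])
  loss_loci <- unique(calls_all$locus[calls_all$truth == "loss"])
  gain_loci <- unique(calls_all$locus[calls_all$truth == "gain"])
  # judge false positives on fully-neutral chromosomes (arm-boundary
  # windows on partially-altered chromosomes legitimately wobble)
  altered_chrom <- unique(sub("_.*", "", c(loss_loci, gain_loci)))
  neutral_loci <- freq$locus[!sub("_.*", "", freq$locus) %in% altered_chrom]
  expect_gt(min(freq$n_loss[freq$locus %in% loss_loci]), 2)
  expect_gt(min(freq$n_gain[freq$locus %in% gain_loci]), 2)
  expect_lt(max(freq$n_gain[freq$locus %in% neutral_loci] +
                  freq$n_loss[freq$locus %in% neutral_loci]), 3)
})
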