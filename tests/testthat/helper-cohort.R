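# Shared fixtures, built in code. The full-size cohort genome (5 x 2 Mb)
# is expensive, so it is created lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

cohort_genome <- function() {
  if (is.null(.fixture_env$gw)) {
    .fixture_env$gw <- make_genome(seed = 421)
    .fixture_env$site_index <- build_site_index(.fixture_env$gw$genome)
  }
  .fixture_env$gw
}

cohort_site_index <- function() {
  cohort_genome()
  .fixture_env$site_index
}

# a small two-chromosome universe for fast IO / unit tests
tiny_gene_specs <- function() {
  specs <- list(
    gene_spec("DONOR", "chrA", 2001L,
              exon_lengths = c(402L, 300L, 450L), intron_lengths = c(3000L, 2000L)),
    gene_spec("ACCEPTOR", "chrA", 30001L,
              exon_lengths = c(201L, 300L, 600L), intron_lengths = c(2500L, 1800L)),
    gene_spec("OTHER", "chrB", 5001L,
              exon_lengths = c(300L, 300L), intron_lengths = 1000L)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "gene_id")
  specs
}

tiny_genome <- function(seed = 11L) {
  make_genome(n_chrom = 2L, chrom_length = 60000L,
              gene_specs = tiny_gene_specs(),
              chrom_names = c("chrA", "chrB"), seed = seed)
}

tiny_fusion <- function(genes, expression_level = 0.4) {
  donor <- genes[["DONOR"]]; acceptor <- genes[["ACCEPTOR"]]
  intron1 <- gene_introns(donor)[1L, ]
  list(gene5 = "DONOR", gene3 = "ACCEPTOR",
       bp5 = as.integer(intron1[["start"]] + 999L),
       bp3 = as.integer(sort(acceptor$exons[, "start"])[2L]),
       expression_level = expression_level)
}

# brute-force per-pair classification oracle: plain interval containment,
# no vectorization shared with the implementation
oracle_classify <- function(pair, genes, supported = character(0)) {
  span_hits <- function(chrom, s, e) {
    hits <- character(0)
    for (g in genes) {
      if (g$chrom == chrom && s <= gene_end(g) && gene_start(g) <= e) {
        hits <- c(hits, g$gene_id)
      }
    }
    hits
  }
  e1 <- pair$start1 + pair$len1 - 1L
  e2 <- pair$start2 + pair$len2 - 1L
  g1 <- span_hits(pair$chrom1, pair$start1, e1)
  g2 <- span_hits(pair$chrom2, pair$start2, e2)
  distinct <- FALSE
  for (a in g1) for (b in g2) if (a != b) distinct <- TRUE
  if (distinct) return("discordant_gene_pair")
  in_intron_of_supported <- function(chrom, s, e) {
    for (gid in supported) {
      g <- genes[[gid]]
      if (is.null(g) || g$chrom != chrom) next
      introns <- gene_introns(g)
      for (k in seq_len(nrow(introns))) {
        if (introns[k, "start"] <= s && e <= introns[k, "end"]) return(TRUE)
      }
    }
    FALSE
  }
  if (in_intron_of_supported(pair$chrom1, pair$start1, e1) ||
      in_intron_of_supported(pair$chrom2, pair$start2, e2)) {
    return("intronic_breakpoint_support")
  }
  if (length(intersect(g1, g2)) > 0L) return("concordant")
  "unassigned"
}

# exhaustive re-computation of the two-stage breakpoint estimate
oracle_breakpoint <- function(track, gene, flank = 100L, min_delta = NULL,
                              local_window = 200L, refine_radius = 350L) {
  d <- as.numeric(track$depth)
  n <- length(d)
  introns <- gene_introns(gene)
  if (nrow(introns) == 0L) return(NA_integer_)
  is_candidate <- function(p) {
    any(introns[, "start"] - flank <= p & p <= introns[, "end"] + flank + 1L)
  }
  best_stat <- -Inf; best_b <- NA_integer_; best_signed <- 0
  for (b in 2:n) {
    p <- track$start + b - 1L
    if (!is_candidate(p)) next
    s <- mean(d[1:(b - 1L)]) - mean(d[b:n])
    if (abs(s) > best_stat) { best_stat <- abs(s); best_b <- b; best_signed <- s }
  }
  if (is.na(best_b)) return(NA_integer_)
  drop_side <- best_signed > 0
  if (is.null(min_delta)) {
    low <- if (drop_side) d[best_b:n] else d[1:(best_b - 1L)]
    min_delta <- max(1, 5 * median(low))
  }
  w <- min(local_window, best_b - 1L, n - best_b + 1L)
  local_delta <- abs(mean(d[(best_b - w):(best_b - 1L)]) -
                       mean(d[best_b:(best_b + w - 1L)]))
  if (local_delta < min_delta) return(NA_integer_)
  gap_len <- 101L
  lo <- if (drop_side) max(2L, best_b - refine_radius) else 2L
  hi <- if (drop_side) n else min(n, best_b + refine_radius)
  refined <- NA_integer_
  if (drop_side) {
    for (i in hi:lo) {
      run <- min(gap_len, n - i + 1L)
      if (d[i - 1L] > 0 && all(d[i:(i + run - 1L)] == 0)) { refined <- i; break }
    }
  } else {
    for (i in lo:hi) {
      run <- min(gap_len, i - 1L)
      if (d[i] > 0 && all(d[(i - run):(i - 1L)] == 0)) { refined <- i; break }
    }
  }
  if (!is.na(refined) && is_candidate(track$start + refined - 1L)) {
    best_b <- refined
  }
  as.integer(track$start + best_b - 1L)
}

make_track <- function(depth, chrom = "chrA", start = 1L) {
  structure(list(chrom = chrom, start = as.integer(start),
                 depth = as.integer(depth)),
            class = "coverage_track")
}
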