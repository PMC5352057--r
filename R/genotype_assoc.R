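check_group <- function(table, group) {
  if (!group %in% rownames(table)) stop("unknown group ", group)
  n <- sum(table[group, ])
  if (n == 0) stop("group ", group, " is empty")
  n
}

#' Risk-allele carrier frequency of a group
#'
#' Fraction of individuals with at least one risk allele:
#' `(het + hom) / n`.
#'
#' @param table groups x genotypes count matrix with columns ordered
#'   `(G/G, G/A, A/A)` — homozygous reference, heterozygous, homozygous
#'   risk.
#' @param group group (row) name.
#' @return proportion in `[0, 1]`.
#' @export
carrier_frequency <- function(table, group) {
  n <- check_group(table, group)
  unname((table[group, 2L] + table[group, 3L]) / n)
}

#' Risk-allele frequency of a group
#'
#' Fraction of chromosomes carrying the risk allele:
#' `(het + 2 * hom) / (2n)`. Note this is a different quantity from the
#' carrier frequency.
#'
#' @inheritParams carrier_frequency
#' @return proportion in `[0, 1]`.
#' @export
allele_frequency <- function(table, group) {
  n <- check_group(table, group)
  unname((table[group, 2L] + 2 * table[group, 3L]) / (2 * n))
}

#' Pearson's chi-squared test of genotype-frequency association
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` with expectations from
#' the row/column margins, `df = (r - 1)(c - 1)` and an upper-tail
#' chi-square p-value; no continuity correction (Yates applies to 2x2
#' tables only). Columns or rows with zero margin are dropped with a
#' warning. Because genotype tables from small case groups often have
#' small expected counts, a warning is emitted when any expectation falls
#' below `expected_warn` and a fixed-seed Monte-Carlo p-value over tables
#' with the same margins can be attached; the headline p-value remains the
#' asymptotic one.
#'
#' @param table groups x genotypes count matrix.
#' @param monte_carlo number of Monte-Carlo tables (0 disables).
#' @param mc_seed fixed seed for the Monte-Carlo null.
#' @param expected_warn small-expected-count warning threshold.
#' @return list with `statistic`, `df`, `p_value`, `expected`,
#'   `min_expected`, and `p_monte_carlo` when requested.
#' @export
pearson_chisq <- function(table, monte_carlo = 0L, mc_seed = 2305089L,
                          expected_warn = 5) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("negative count")
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin row(s)/column(s)")
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("degenerate table: need at least 2 rows and 2 columns with data")
  }
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  statistic <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  out <- list(statistic = statistic, df = df,
              p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
              expected = expected, min_expected = min(expected))
  if (min(expected) < expected_warn) {
    warning(sprintf("expected count %.2f below %g; asymptotic p-value is questionable",
                    min(expected), expected_warn))
  }
  if (monte_carlo > 0L) {
    obs <- statistic
    out$p_monte_carlo <- with_seed(mc_seed, {
      sims <- stats::r2dtable(monte_carlo, rowSums(m), colSums(m))
      stats_sim <- vapply(sims, function(s) sum((s - expected)^2 / expected),
                          numeric(1))
      # include the observed table in the null set (standard MC convention)
      (sum(stats_sim >= obs - 1e-12) + 1) / (monte_carlo + 1)
    })
  }
  out
}

#' Full genotype association report for a case-control table
#'
#' @param table groups x genotypes count matrix (see
#'   [chordoma_genotype_table()] for the observed cohort).
#' @param monte_carlo Monte-Carlo tables for the auxiliary p-value.
#' @return list with per-group `n`, `carrier_frequency`,
#'   `allele_frequency`, and the [pearson_chisq()] result under `test`.
#' @export
genotype_association_report <- function(table, monte_carlo = 100000L) {
  groups <- rownames(table)
  list(
    groups = setNames(lapply(groups, function(g) {
      list(n = sum(table[g, ]),
           carrier_frequency = carrier_frequency(table, g),
           allele_frequency = allele_frequency(table, g))
    }), groups),
    test = suppressWarnings(pearson_chisq(table, monte_carlo = monte_carlo))
  )
}
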