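#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = 1e9 * count / (library_size * gene_length_bp)`. All arguments
#' recycle elementwise, so a count matrix with per-gene lengths and
#' per-sample library sizes is handled by [rpkm_matrix()].
#'
#' @param counts read counts.
#' @param gene_length_bp gene length(s) in bp (>= 1); the package uses the
#'   union of exon intervals as a gene's length.
#' @param library_size total mapped reads per sample (>= 1).
#' @return RPKM values.
#' @export
rpkm <- function(counts, gene_length_bp, library_size) {
  if (any(gene_length_bp < 1)) stop("gene_length_bp must be >= 1")
  if (any(library_size < 1)) stop("library_size must be >= 1")
  1e9 * counts / (library_size * gene_length_bp)
}

#' RPKM-transform a gene-by-sample count matrix
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths named per-gene lengths (bp), aligned with rows.
#' @param library_sizes named per-sample totals; defaults to column sums.
#' @return gene x sample RPKM matrix.
#' @export
rpkm_matrix <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  stopifnot(nrow(counts) == length(gene_lengths),
            ncol(counts) == length(library_sizes))
  t(t(counts / gene_lengths) / library_sizes) * 1e9
}

#' Elementwise log2 with a pseudocount
#'
#' @param m numeric matrix or vector.
#' @param pseudocount positive value added before the log.
#' @return transformed values.
#' @export
log2_matrix <- function(m, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2(m + pseudocount)
}

#' Compare one gene's expression between two groups
#'
#' Wilcoxon rank-sum test on log2-transformed values: exact enumeration
#' when both groups have at most 10 samples and the values are untied,
#' otherwise the normal approximation with midrank tie correction and no
#' continuity correction (identical groups then give p = 1). Rank-based,
#' so invariant under monotone transforms of the data.
#'
#' @param mat gene x sample expression (RPKM) matrix.
#' @param gene gene (row) to test.
#' @param groups named sample -> group vector.
#' @param group_a,group_b group labels; the reported direction is
#'   `group_a` relative to `group_b`.
#' @param pseudocount for the log2 transform.
#' @return list with `gene`, `statistic` (rank-sum W of `group_a`),
#'   `p_value`, `direction` (`"higher"`/`"lower"`/`"equal"`),
#'   `median_log2_a`, `median_log2_b`.
#' @export
compare_groups <- function(mat, gene, groups, group_a, group_b,
                           pseudocount = 1) {
  if (!gene %in% rownames(mat)) stop("gene ", gene, " absent from matrix")
  a <- log2_matrix(mat[gene, names(groups)[groups == group_a]], pseudocount)
  b <- log2_matrix(mat[gene, names(groups)[groups == group_b]], pseudocount)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 samples")
  med_a <- stats::median(a); med_b <- stats::median(b)
  if (length(unique(c(a, b))) == 1L) {
    # fully degenerate data: the midrank convention gives no evidence
    return(list(gene = gene, statistic = length(a) * length(b) / 2,
                p_value = 1, direction = "equal",
                median_log2_a = med_a, median_log2_b = med_b))
  }
  exact <- length(a) <= 10L && length(b) <= 10L && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  list(gene = gene,
       statistic = unname(wt$statistic),
       p_value = wt$p.value,
       direction = if (med_a > med_b) "higher" else if (med_a < med_b) "lower" else "equal",
       median_log2_a = med_a, median_log2_b = med_b)
}

#' Expression of a gene in fusion-positive versus fusion-negative samples
#'
#' Reports per-partition mean RPKM and the fold difference; when both
#' partitions have at least two samples the rank-sum comparison of
#' [compare_groups()] is attached, otherwise the report is flagged
#' descriptive-only (as in a 4-versus-1 cohort split).
#'
#' @param mat gene x sample RPKM matrix.
#' @param gene gene to examine.
#' @param fusion_samples sample names harboring the fusion.
#' @return list with `mean_fusion`, `mean_other`, `fold`,
#'   `descriptive_only`, and (when testable) `test`.
#' @export
fusion_expression_check <- function(mat, gene, fusion_samples) {
  if (!gene %in% rownames(mat)) stop("gene ", gene, " absent from matrix")
  samples <- colnames(mat)
  fusion_samples <- intersect(fusion_samples, samples)
  other <- setdiff(samples, fusion_samples)
  if (length(fusion_samples) == 0L || length(other) == 0L) {
    stop("both partitions must be non-empty")
  }
  mean_fus <- mean(mat[gene, fusion_samples])
  mean_oth <- mean(mat[gene, other])
  descriptive <- length(fusion_samples) < 2L || length(other) < 2L
  out <- list(mean_fusion = mean_fus, mean_other = mean_oth,
              fold = mean_fus / mean_oth, descriptive_only = descriptive)
  if (!descriptive) {
    groups <- setNames(ifelse(samples %in% fusion_samples, "fusion", "other"),
                       samples)
    out$test <- compare_groups(mat, gene, groups, "fusion", "other")
  }
  out
}
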