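#' Simulate a gene-level read-count cohort with group-specific expression
#'
#' Per-gene baseline log2 RPKM values are drawn once (normal around
#' `base_log2_rpkm`), then per-sample log2 RPKM values add group shifts for
#' the designated up-regulated genes and within-group biological noise
#' `sigma` (log2 scale). Counts are derived from the RPKM values through
#' the library size and gene length, so quantification recovers the
#' injected pattern up to rounding.
#'
#' @param group_sizes named vector of samples per group (e.g.
#'   `c(chordoma = 5, glioma = 8, breast = 8, lung = 8)`).
#' @param n_genes number of background genes (named `BG001`...).
#' @param de_genes genes up-regulated in `up_group`.
#' @param up_group group carrying the shift.
#' @param log2_fold shift in log2 units for `de_genes` in `up_group`.
#' @param sigma within-group biological standard deviation, log2 scale.
#' @param base_log2_rpkm mean baseline expression, log2 RPKM units.
#' @param gene_length_bp gene length assigned to every gene (bp).
#' @param library_size per-sample sequenced read count.
#' @param seed integer seed.
#' @return list with `counts` (gene x sample matrix), `gene_lengths`,
#'   `library_sizes`, `groups` (named sample -> group vector) and
#'   `true_log2_rpkm`.
#' @export
simulate_expression_counts <- function(group_sizes = c(chordoma = 5L, glioma = 8L,
                                                       breast = 8L, lung = 8L),
                                       n_genes = 50L,
                                       de_genes = c("SAMD5L", "TBXTL"),
                                       up_group = "chordoma",
                                       log2_fold = 2, sigma = 0.35,
                                       base_log2_rpkm = 5,
                                       gene_length_bp = 2000L,
                                       library_size = 2e7, seed = 1L) {
  stopifnot(all(group_sizes >= 1L), !is.null(names(group_sizes)))
  genes <- c(de_genes, sprintf("BG%03d", seq_len(n_genes)))
  samples <- unlist(lapply(names(group_sizes), function(g) {
    sprintf("%s_%02d", g, seq_len(group_sizes[[g]]))
  }))
  groups <- setNames(rep(names(group_sizes), group_sizes), samples)
  with_seed(seed, {
    baseline <- stats::rnorm(length(genes), base_log2_rpkm, 1)
    shift <- outer(genes %in% de_genes, groups == up_group) * log2_fold
    noise <- matrix(stats::rnorm(length(genes) * length(samples), 0, sigma),
                    nrow = length(genes))
    log2rpkm <- baseline + shift + noise
    dimnames(log2rpkm) <- list(genes, samples)
    rpkm_true <- 2^log2rpkm
    counts <- round(rpkm_true * gene_length_bp * library_size / 1e9)
    list(counts = counts,
         gene_lengths = setNames(rep(as.integer(gene_length_bp), length(genes)), genes),
         library_sizes = setNames(rep(library_size, length(samples)), samples),
         groups = groups,
         true_log2_rpkm = log2rpkm)
  })
}
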