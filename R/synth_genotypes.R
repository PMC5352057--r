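GENOTYPES <- c("G/G", "G/A", "A/A")

#' Observed rs2305089 genotype counts of the chordoma case-control cohort
#'
#' The brachyury (T gene) Gly177Asp genotype table of the skull base
#' chordoma series versus its glioma control group: cases G/G 1, G/A 3,
#' A/A 4 (n = 8); controls G/G 36, G/A 32, A/A 7 (n = 75).
#'
#' @return 2 x 3 integer matrix (groups x genotypes).
#' @export
chordoma_genotype_table <- function() {
  m <- matrix(c(1L, 3L, 4L,
                36L, 32L, 7L),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("chordoma", "control"), GENOTYPES))
  m
}

#' Simulate a two-group genotype cohort
#'
#' @param group_sizes named non-negative integer vector of group sizes.
#' @param genotype_probs matrix (groups x genotypes) of per-group genotype
#'   probabilities; rows must sum to 1.
#' @param seed integer seed.
#' @return list with `individuals` (data.frame `sample_id`, `group`,
#'   `genotype`) and `counts` (groups x genotypes matrix).
#' @export
simulate_genotype_cohort <- function(group_sizes, genotype_probs, seed = 1L) {
  if (any(group_sizes < 0)) stop("negative group size")
  stopifnot(!is.null(names(group_sizes)),
            nrow(genotype_probs) == length(group_sizes))
  if (any(abs(rowSums(genotype_probs) - 1) > 1e-9)) {
    stop("genotype probabilities must sum to 1 per group")
  }
  individuals <- with_seed(seed, {
    rows <- lapply(seq_along(group_sizes), function(i) {
      n <- group_sizes[[i]]
      if (n == 0L) return(NULL)
      data.frame(
        sample_id = sprintf("%s_%03d", names(group_sizes)[i], seq_len(n)),
        group = names(group_sizes)[i],
        genotype = sample(GENOTYPES, n, replace = TRUE, prob = genotype_probs[i, ]),
        stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) {
      data.frame(sample_id = character(0), group = character(0),
                 genotype = character(0), stringsAsFactors = FALSE)
    } else {
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    }
  })
  list(individuals = individuals,
       counts = genotype_counts(individuals, groups = names(group_sizes)))
}

#' Tabulate genotype counts from per-individual records
#'
#' @param individuals data.frame with `group` and `genotype` columns.
#' @param groups group ordering (defaults to order of appearance).
#' @param genotypes genotype column ordering.
#' @return groups x genotypes integer matrix.
#' @export
genotype_counts <- function(individuals, groups = unique(individuals$group),
                            genotypes = GENOTYPES) {
  m <- matrix(0L, nrow = length(groups), ncol = length(genotypes),
              dimnames = list(groups, genotypes))
  if (nrow(individuals)) {
    t <- table(factor(individuals$group, levels = groups),
               factor(individuals$genotype, levels = genotypes))
    m[] <- as.integer(t)
  }
  m
}
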