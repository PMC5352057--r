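#' Specify arm-level copy-number states for a simulated sample
#'
#' The default pattern mirrors the recurrent chordoma lesions on a scaled
#' 11-chromosome universe: loss of 1p and of the two whole-chromosome
#' analogs of 10 and 13 (`chr6`, `chr8`), gain of the chromosome-7 analog
#' (`chr4`) and of a 17q analog (`chr11q`). Eight of the twenty-two arms
#' are altered, so the genome stays majority-neutral as median centering
#' assumes.
#'
#' @param chroms chromosome names.
#' @return data.frame with columns `chrom`, `arm` (`p`/`q`) and `state`
#'   (`gain`/`loss`/`neutral`), one row per arm.
#' @export
default_cna_spec <- function(chroms = paste0("chr", 1:11)) {
  spec <- expand.grid(arm = c("p", "q"), chrom = chroms,
                      stringsAsFactors = FALSE)[, c("chrom", "arm")]
  spec$state <- "neutral"
  set_state <- function(spec, chrom, arm, state) {
    i <- spec$chrom == chrom & spec$arm %in% arm
    spec$state[i] <- state
    spec
  }
  # loss 1p / 10 / 13 analogs; gain 7 / 17q analogs
  spec <- set_state(spec, "chr1", "p", "loss")
  spec <- set_state(spec, "chr6", c("p", "q"), "loss")
  spec <- set_state(spec, "chr8", c("p", "q"), "loss")
  spec <- set_state(spec, "chr4", c("p", "q"), "gain")
  spec <- set_state(spec, "chr11", "q", "gain")
  rownames(spec) <- NULL
  spec
}

#' Chromosome lengths of the scaled copy-number universe
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each, bp.
#' @return named integer vector.
#' @export
default_cna_chrom_lengths <- function(n_chrom = 11L, chrom_length = 2000000L) {
  setNames(rep(as.integer(chrom_length), n_chrom), paste0("chr", seq_len(n_chrom)))
}

#' Simulate tumor and normal per-window read depths
#'
#' Windows are allocated evenly over each chromosome (half per arm).
#' Normal depth is negative-binomial around `mean_depth`; tumor depth is
#' negative-binomial around `mean_depth` scaled by the arm state (gain
#' 1.5x, loss 0.5x, neutral 1x) and by `tumor_library_factor`. With
#' `dispersion = 0` counts equal their means exactly.
#'
#' @param cna_spec data.frame as from [default_cna_spec()].
#' @param chrom_lengths named chromosome lengths.
#' @param n_windows total number of windows across the genome.
#' @param mean_depth expected normal reads per window.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 means noiseless.
#' @param tumor_library_factor multiplicative tumor library-size factor.
#' @param gain_factor,loss_factor expected depth ratios for gained / lost
#'   arms.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `arm`, `state`,
#'   `normal`, `tumor`.
#' @export
simulate_depth_profiles <- function(cna_spec, chrom_lengths, n_windows = 1000L,
                                    mean_depth = 100, dispersion = 0.05,
                                    tumor_library_factor = 1,
                                    gain_factor = 1.5, loss_factor = 0.5,
                                    seed = 1L) {
  if (n_windows < 1L) stop("n_windows must be >= 1")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  chroms <- names(chrom_lengths)
  per_chrom <- max(2L, n_windows %/% length(chroms))
  rows <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    bounds <- round(seq(0, len, length.out = per_chrom + 1L))
    start <- as.integer(bounds[-length(bounds)] + 1L)
    end <- as.integer(bounds[-1L])
    arm <- ifelse(seq_along(start) <= per_chrom / 2, "p", "q")
    data.frame(chrom = ch, start = start, end = end, arm = arm,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, rows)
  key <- paste(win$chrom, win$arm)
  spec_key <- paste(cna_spec$chrom, cna_spec$arm)
  missing <- setdiff(unique(key), spec_key)
  if (length(missing)) stop("cna_spec lacks arm(s): ", paste(missing, collapse = ", "))
  win$state <- cna_spec$state[match(key, spec_key)]
  factor <- c(gain = gain_factor, loss = loss_factor, neutral = 1)[win$state]
  mu_n <- rep(mean_depth, nrow(win))
  mu_t <- mean_depth * factor * tumor_library_factor
  win[c("normal", "tumor")] <- with_seed(seed, {
    draw <- function(mu) {
      if (dispersion <= 0) return(round(mu))
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    list(normal = draw(mu_n), tumor = draw(mu_t))
  })
  rownames(win) <- NULL
  win
}
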