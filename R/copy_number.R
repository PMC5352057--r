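#' Build fixed-read-count windows from reference read positions
#'
#' aCGH-like windows: walking each chromosome left to right, a boundary is
#' placed after every `reads_per_window` reference reads, so every
#' non-terminal window holds exactly that many reads. A chromosome with
#' fewer reads than `reads_per_window` becomes a single whole-chromosome
#' window with a warning.
#'
#' @param read_positions data.frame with `chrom` and `pos` of reference
#'   reads.
#' @param reads_per_window reads per window (>= 50).
#' @param chrom_lengths named chromosome lengths (used to close the
#'   terminal window).
#' @return data.frame of windows (`chrom`, `start`, `end`).
#' @export
make_windows <- function(read_positions, reads_per_window = 1000L,
                         chrom_lengths) {
  if (reads_per_window < 50L) stop("reads_per_window must be >= 50")
  rows <- lapply(names(chrom_lengths), function(ch) {
    pos <- sort(read_positions$pos[read_positions$chrom == ch])
    len <- chrom_lengths[[ch]]
    n <- length(pos)
    if (n < reads_per_window) {
      warning("chromosome ", ch, " has fewer than ", reads_per_window,
              " reads; using one whole-chromosome window")
      return(data.frame(chrom = ch, start = 1L, end = as.integer(len),
                        stringsAsFactors = FALSE))
    }
    nwin <- n %/% reads_per_window
    bounds <- pos[seq_len(nwin) * reads_per_window]
    starts <- c(1L, bounds[-nwin] + 1L)
    ends <- bounds
    if (n %% reads_per_window > 0L) {
      starts <- c(starts, bounds[nwin] + 1L)
      ends <- c(ends, as.integer(len))
    } else {
      ends[nwin] <- as.integer(len)
    }
    data.frame(chrom = ch, start = as.integer(starts), end = as.integer(ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count reads per window
#'
#' @param windows data.frame from [make_windows()].
#' @param read_positions data.frame with `chrom`, `pos`.
#' @return integer vector, one count per window.
#' @export
count_reads_in_windows <- function(windows, read_positions) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(read_positions$chrom == windows$chrom[i] &
          read_positions$pos >= windows$start[i] &
          read_positions$pos <= windows$end[i])
  }, integer(1))
}

#' Build a pseudo-normal reference from unmatched normal profiles
#'
#' Per-window median of library-size-normalized counts across the normals,
#' rescaled to the mean library size. With a single normal this is the
#' normal itself.
#'
#' @param normal_counts matrix (windows x normal samples) of counts on a
#'   shared window set, or a list of equal-length count vectors.
#' @return numeric vector of pseudo-normal reference counts per window.
#' @export
build_pseudo_normal <- function(normal_counts) {
  if (is.list(normal_counts) && !is.data.frame(normal_counts)) {
    if (length(unique(lengths(normal_counts))) != 1L) {
      stop("normal profiles are on mismatched window sets")
    }
    normal_counts <- do.call(cbind, normal_counts)
  }
  normal_counts <- as.matrix(normal_counts)
  if (ncol(normal_counts) < 1L) stop("need at least one normal profile")
  lib <- colSums(normal_counts)
  if (any(lib == 0)) stop("normal profile with zero total count")
  scaled <- sweep(normal_counts, 2L, lib / mean(lib), "/")
  apply(scaled, 1L, stats::median)
}

#' Tumor/reference log2 copy-ratio profile
#'
#' Counts are normalized to counts per million within each profile, floored
#' by `offset`, log2-ratioed and median-centered (which assumes a
#' majority-neutral genome). The CPM scale makes the ratio exactly
#' invariant to joint library-size changes.
#'
#' @param windows data.frame of windows (`chrom`, `start`, `end`).
#' @param tumor_counts,ref_counts per-window counts.
#' @param offset floor offset added to both CPM values.
#' @param sample_id sample label.
#' @param reference_kind `"matched_normal"` or `"pseudo_normal"`.
#' @return data.frame of windows with `tumor`, `ref` and `log2_ratio`
#'   columns; attributes `sample_id` and `reference_kind`.
#' @export
compute_log2_ratio <- function(windows, tumor_counts, ref_counts, offset = 0.5,
                               sample_id = "tumor",
                               reference_kind = c("matched_normal", "pseudo_normal")) {
  reference_kind <- match.arg(reference_kind)
  stopifnot(nrow(windows) == length(tumor_counts),
            length(tumor_counts) == length(ref_counts))
  if (sum(tumor_counts) == 0) stop("all-zero tumor profile")
  if (sum(ref_counts) == 0) stop("all-zero reference profile")
  cpm_t <- tumor_counts / sum(tumor_counts) * 1e6
  cpm_r <- ref_counts / sum(ref_counts) * 1e6
  lr <- log2((cpm_t + offset) / (cpm_r + offset))
  out <- windows
  out$tumor <- tumor_counts
  out$ref <- ref_counts
  out$log2_ratio <- lr - stats::median(lr)
  attr(out, "sample_id") <- sample_id
  attr(out, "reference_kind") <- reference_kind
  out
}

# two-sample t statistic for every split of x; returns max and its boundary
max_split_t <- function(x, min_side) {
  n <- length(x)
  if (n < 2L * min_side) return(list(stat = -Inf, boundary = NA_integer_))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  b <- seq(min_side + 1L, n - min_side + 1L)  # split before index b
  nl <- b - 1L; nr <- n - nl
  ml <- cs[nl] / nl
  mr <- (cs[n] - cs[nl]) / nr
  ssl <- cs2[nl] - nl * ml^2
  ssr <- (cs2[n] - cs2[nl]) - nr * mr^2
  sp2 <- pmax((ssl + ssr) / pmax(n - 2L, 1L), 0)  # clamp float cancellation
  se <- sqrt(sp2 * (1 / nl + 1 / nr))
  t <- ifelse(se > 0, abs(ml - mr) / se,
              ifelse(abs(ml - mr) > 0, Inf, 0))
  i <- which.max(t)
  list(stat = t[i], boundary = b[i])
}

#' Segment a copy-ratio profile by recursive binary splitting
#'
#' A simplified circular-binary-segmentation variant: within each
#' chromosome the boundary maximizing the two-sample t statistic is
#' proposed and accepted when its permutation p-value (within-segment
#' shuffles, fixed seed) is below `alpha`; accepted splits recurse.
#' Adjacent segments whose means differ by less than `min_gap` are merged.
#' Segment means equal the mean of their member windows exactly.
#'
#' @param profile data.frame from [compute_log2_ratio()].
#' @param alpha split acceptance level.
#' @param min_windows minimum windows on each side of a split.
#' @param nperm permutations per proposed split.
#' @param perm_seed fixed seed for the permutation null.
#' @param min_gap minimum mean difference between retained neighbors.
#' @param gain_thresh,loss_thresh log2-ratio call thresholds.
#' @return data.frame of segments: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_log2`, `call`.
#' @export
segment_profile <- function(profile, alpha = 0.01, min_windows = 3L,
                            nperm = 100L, perm_seed = 13L, min_gap = 0.1,
                            gain_thresh = 0.3, loss_thresh = -0.3) {
  stopifnot("log2_ratio" %in% colnames(profile))
  segment_chrom <- function(d) {
    x <- d$log2_ratio
    split_rec <- function(lo, hi) {
      x_seg <- x[lo:hi]
      best <- max_split_t(x_seg, min_windows)
      if (!is.finite(best$stat) && best$stat < 0) return(c(lo))
      if (best$stat == 0) return(c(lo))
      perm <- vapply(seq_len(nperm), function(i) {
        max_split_t(sample(x_seg), min_windows)$stat
      }, numeric(1))
      p <- mean(perm >= best$stat)
      if (p >= alpha) return(c(lo))
      b <- lo + best$boundary - 1L
      c(split_rec(lo, b - 1L), split_rec(b, hi))
    }
    starts <- split_rec(1L, length(x))
    ends <- c(starts[-1L] - 1L, length(x))
    segs <- data.frame(lo = starts, hi = ends)
    # merge neighbors closer than min_gap
    repeat {
      if (nrow(segs) < 2L) break
      means <- vapply(seq_len(nrow(segs)),
                      function(i) mean(x[segs$lo[i]:segs$hi[i]]), numeric(1))
      gaps <- abs(diff(means))
      if (all(gaps >= min_gap)) break
      j <- which.min(gaps)
      segs$hi[j] <- segs$hi[j + 1L]
      segs <- segs[-(j + 1L), , drop = FALSE]
    }
    data.frame(
      chrom = d$chrom[1L],
      start = d$start[segs$lo],
      end = d$end[segs$hi],
      n_windows = segs$hi - segs$lo + 1L,
      mean_log2 = vapply(seq_len(nrow(segs)),
                         function(i) mean(x[segs$lo[i]:segs$hi[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  out <- with_seed(perm_seed, {
    parts <- lapply(split(profile, factor(profile$chrom, levels = unique(profile$chrom))),
                    segment_chrom)
    do.call(rbind, parts)
  })
  out$call <- ifelse(out$mean_log2 >= gain_thresh, "gain",
                     ifelse(out$mean_log2 <= loss_thresh, "loss", "neutral"))
  rownames(out) <- NULL
  out
}

#' Per-window calls from a segmentation
#'
#' @param profile data.frame from [compute_log2_ratio()].
#' @param segments data.frame from [segment_profile()].
#' @return character vector of `gain`/`loss`/`neutral`, one per window.
#' @export
segment_window_calls <- function(profile, segments) {
  mid <- (profile$start + profile$end) / 2
  vapply(seq_len(nrow(profile)), function(i) {
    j <- which(segments$chrom == profile$chrom[i] &
                 segments$start <= mid[i] & mid[i] <= segments$end)
    if (length(j) == 0L) return(NA_character_)
    segments$call[j[1L]]
  }, character(1))
}

#' Per-gene copy-number calls from segments
#'
#' A gene takes the call of the segment containing its midpoint; a gene
#' spanning a segment boundary takes the length-weighted mean of the
#' overlapping segment means, re-thresholded.
#'
#' @param segments data.frame from [segment_profile()].
#' @param genes named list of [gene_model()]s.
#' @param gain_thresh,loss_thresh log2-ratio call thresholds
#'   (`gain_thresh > 0 > loss_thresh`).
#' @return data.frame with `gene_id`, `chrom`, `mean_log2`, `call`.
#' @export
call_gene_copy_number <- function(segments, genes, gain_thresh = 0.3,
                                  loss_thresh = -0.3) {
  stopifnot(gain_thresh > 0, loss_thresh < 0)
  spans <- gene_span_table(genes)
  rows <- lapply(seq_len(nrow(spans)), function(i) {
    g <- spans[i, ]
    ov <- segments[segments$chrom == g$chrom &
                     segments$start <= g$end & g$start <= segments$end, , drop = FALSE]
    if (nrow(ov) == 0L) stop("gene ", g$gene_id, " outside all segments")
    if (nrow(ov) == 1L) {
      m <- ov$mean_log2[[1L]]
    } else {
      w <- pmin(ov$end, g$end) - pmax(ov$start, g$start) + 1
      m <- sum(w * ov$mean_log2) / sum(w)
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, mean_log2 = m,
               call = if (m >= gain_thresh) "gain"
                      else if (m <= loss_thresh) "loss" else "neutral",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level gain/loss frequency per locus
#'
#' @param calls data.frame with one row per sample x locus, columns
#'   `sample`, `locus`, `call`.
#' @return data.frame with `locus`, `n_gain`, `n_loss`, `n_total`,
#'   suitable for a cohort CNA frequency track.
#' @export
cohort_frequency <- function(calls) {
  stopifnot(all(c("sample", "locus", "call") %in% colnames(calls)))
  loci <- unique(calls$locus)
  out <- data.frame(
    locus = loci,
    n_gain = vapply(loci, function(l) {
      length(unique(calls$sample[calls$locus == l & calls$call == "gain"]))
    }, integer(1)),
    n_loss = vapply(loci, function(l) {
      length(unique(calls$sample[calls$locus == l & calls$call == "loss"]))
    }, integer(1)),
    n_total = length(unique(calls$sample)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
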