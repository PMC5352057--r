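mate_genes <- function(chrom, start, len, spans) {
  end <- start + len - 1L
  spans$gene_id[spans$chrom == chrom & spans$start <= end & start <= spans$end]
}

#' Classify one read pair against a gene annotation
#'
#' Applies the two fusion filter criteria in order of evidence strength:
#' `discordant_gene_pair` when the two mates overlap two distinct genes
#' (criterion 1); otherwise `intronic_breakpoint_support` when at least one
#' mate lies wholly within an intron of a gene in `supported_genes`, i.e. a
#' gene already linked by criterion-1 pairs (criterion 2); otherwise
#' `concordant` when both mates fall in a single gene; `unassigned`
#' otherwise. A mate overlapping two nested/overlapping genes counts for
#' both.
#'
#' @param pair one-row data.frame (layout of [read_sam_lite()]).
#' @param genes named list of [gene_model()]s.
#' @param supported_genes gene ids with criterion-1 support (cohort-level
#'   knowledge; empty by default).
#' @param chrom_lengths optional named lengths; mates on unknown
#'   chromosomes raise an error when supplied.
#' @return one of `"discordant_gene_pair"`,
#'   `"intronic_breakpoint_support"`, `"concordant"`, `"unassigned"`.
#' @export
classify_read_pair <- function(pair, genes, supported_genes = character(0),
                               chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(c(pair$chrom1, pair$chrom2), names(chrom_lengths))
    if (length(unknown)) stop("mate on unknown chromosome: ", unknown[[1L]])
  }
  spans <- gene_span_table(genes)
  g1 <- mate_genes(pair$chrom1, pair$start1, pair$len1, spans)
  g2 <- mate_genes(pair$chrom2, pair$start2, pair$len2, spans)
  if (length(g1) && length(g2) && any(outer(g1, g2, `!=`))) {
    return("discordant_gene_pair")
  }
  intronic <- function(chrom, start, len) {
    end <- start + len - 1L
    any(vapply(supported_genes, function(gid) {
      g <- genes[[gid]]
      !is.null(g) && g$chrom == chrom && interval_in_intron(g, start, end)
    }, logical(1)))
  }
  if (length(supported_genes) &&
      (intronic(pair$chrom1, pair$start1, pair$len1) ||
       intronic(pair$chrom2, pair$start2, pair$len2))) {
    return("intronic_breakpoint_support")
  }
  if (length(intersect(g1, g2)) > 0L) return("concordant")
  "unassigned"
}

#' Classify every pair of an alignment set
#'
#' Vectorized wrapper around the [classify_read_pair()] rules.
#'
#' @inheritParams classify_read_pair
#' @param pairs data.frame of read pairs.
#' @return character vector of labels, one per pair.
#' @export
classify_pairs <- function(pairs, genes, supported_genes = character(0),
                           chrom_lengths = NULL) {
  n <- nrow(pairs)
  if (n == 0L) return(character(0))
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(c(pairs$chrom1, pairs$chrom2)), names(chrom_lengths))
    if (length(unknown)) stop("mate on unknown chromosome: ", unknown[[1L]])
  }
  spans <- gene_span_table(genes)
  hits <- function(chrom, start, len) {
    end <- start + len - 1L
    m <- matrix(FALSE, n, nrow(spans))
    for (j in seq_len(nrow(spans))) {
      m[, j] <- chrom == spans$chrom[j] & start <= spans$end[j] &
        spans$start[j] <= end
    }
    m
  }
  h1 <- hits(pairs$chrom1, pairs$start1, pairs$len1)
  h2 <- hits(pairs$chrom2, pairs$start2, pairs$len2)
  # criterion 1: some gene hit by mate 1 differs from some gene hit by
  # mate 2 (false only when both mates hit exactly the same single gene)
  n1 <- rowSums(h1); n2 <- rowSums(h2)
  shared <- rowSums(h1 & h2)
  discordant <- n1 > 0L & n2 > 0L & !(n1 == 1L & n2 == 1L & shared == 1L)
  intronic <- rep(FALSE, n)
  for (gid in supported_genes) {
    g <- genes[[gid]]
    if (is.null(g)) next
    introns <- gene_introns(g)
    for (k in seq_len(nrow(introns))) {
      within <- function(chrom, start, len) {
        chrom == g$chrom & start >= introns[k, "start"] &
          start + len - 1L <= introns[k, "end"]
      }
      intronic <- intronic |
        within(pairs$chrom1, pairs$start1, pairs$len1) |
        within(pairs$chrom2, pairs$start2, pairs$len2)
    }
  }
  concordant <- shared > 0L
  out <- rep("unassigned", n)
  out[concordant] <- "concordant"
  out[intronic] <- "intronic_breakpoint_support"
  out[discordant] <- "discordant_gene_pair"
  out
}

#' Per-nucleotide coverage over a region
#'
#' Depth at position i is the number of aligned bases covering i, summed
#' over both mates of every pair.
#'
#' @param pairs data.frame of read pairs.
#' @param chrom chromosome of the region.
#' @param start,end 1-based inclusive region bounds.
#' @return a `coverage_track`: list with `chrom`, `start` and integer
#'   `depth` of length `end - start + 1`.
#' @export
build_coverage <- function(pairs, chrom, start, end) {
  n <- end - start + 1L
  stopifnot(n >= 1L)
  delta <- integer(n + 1L)
  add <- function(s, len) {
    e <- s + len - 1L
    s2 <- pmax(s, start); e2 <- pmin(e, end)
    ok <- s2 <= e2
    if (any(ok)) {
      i <- (s2 - start + 1L)[ok]
      j <- (e2 - start + 2L)[ok]
      delta <<- delta + tabulate(i, n + 1L) - tabulate(j, n + 1L)
    }
  }
  m1 <- pairs$chrom1 == chrom
  if (any(m1)) add(pairs$start1[m1], pairs$len1[m1])
  m2 <- pairs$chrom2 == chrom
  if (any(m2)) add(pairs$start2[m2], pairs$len2[m2])
  structure(list(chrom = chrom, start = as.integer(start),
                 depth = cumsum(delta[-(n + 1L)])),
            class = "coverage_track")
}

changepoint_stat <- function(depth) {
  # |mean(left) - mean(right)| for every split boundary b (split before b)
  n <- length(depth)
  cs <- cumsum(as.numeric(depth))
  b <- seq(2L, n)
  left <- cs[b - 1L] / (b - 1L)
  right <- (cs[n] - cs[b - 1L]) / (n - b + 1L)
  list(boundary = b, stat = abs(left - right), signed = left - right)
}

#' Infer a coverage breakpoint within a gene
#'
#' Two-stage single-changepoint estimate. Stage one scans candidate split
#' positions — the gene's introns, each widened by `flank` bases into the
#' neighboring exons — for the boundary maximizing the absolute difference
#' between the mean coverage left and right of the split (a global
#' single-changepoint statistic). Stage two refines the boundary to the
#' largest per-base discontinuity in the same direction within
#' `refine_radius` bp, which pins the breakpoint to the exact base when
#' junction-anchored reads stack there. Ties go to the leftmost position.
#' The returned position is the first base of the right-hand segment; for
#' a coverage drop that is the first base of the low side, for a rise the
#' first elevated base.
#'
#' @param track a `coverage_track` from [build_coverage()] spanning the
#'   gene (plus any flank).
#' @param gene a [gene_model()].
#' @param flank candidate widening into exons, bp.
#' @param min_delta minimum local mean-coverage difference (computed in
#'   `local_window`-bp windows flanking the split) for a changepoint to be
#'   reported; `NULL` uses `max(1, 5 * median(low-side depth))` — the step
#'   must rise five times above the residual background coverage on the low
#'   side of the split, with an absolute floor of one read.
#' @param local_window window size (bp) for the local step-height check.
#' @param refine_radius half-width (bp) of the stage-two refinement around
#'   the global optimum.
#' @return list with `position` (NA when no changepoint clears
#'   `min_delta`), `direction` (`"drop"` or `"rise"`), and `delta`.
#' @export
infer_breakpoint <- function(track, gene, flank = 100L, min_delta = NULL,
                             local_window = 200L, refine_radius = 350L) {
  stopifnot(inherits(track, "coverage_track"), track$chrom == gene$chrom)
  n <- length(track$depth)
  introns <- gene_introns(gene)
  if (nrow(introns) == 0L) {
    return(list(position = NA_integer_, direction = NA_character_, delta = 0))
  }
  cp <- changepoint_stat(track$depth)
  pos <- track$start + cp$boundary - 1L
  candidate <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(introns))) {
    candidate <- candidate |
      (pos >= introns[i, "start"] - flank & pos <= introns[i, "end"] + flank + 1L)
  }
  if (!any(candidate)) {
    return(list(position = NA_integer_, direction = NA_character_, delta = 0))
  }
  stat <- ifelse(candidate, cp$stat, -Inf)
  best <- which.max(stat)  # which.max takes the leftmost maximum
  split_at <- cp$boundary[best]
  drop_side <- cp$signed[best] > 0

  # gate on the step height at the global optimum, measured locally so a
  # sharp step is not diluted by the track length the way the global split
  # statistic is
  if (is.null(min_delta)) {
    low <- if (drop_side) track$depth[split_at:n] else
      track$depth[seq_len(split_at - 1L)]
    min_delta <- max(1, 5 * stats::median(low))
  }
  w <- min(local_window, split_at - 1L, n - split_at + 1L)
  local_delta <- abs(mean(track$depth[(split_at - w):(split_at - 1L)]) -
                       mean(track$depth[split_at:(split_at + w - 1L)]))
  if (local_delta < min_delta) {
    return(list(position = NA_integer_, direction = NA_character_,
                delta = local_delta))
  }

  # stage two: refine to the coverage edge — the base where depth falls to
  # (or rises from) a sustained zero run — near the global optimum; on a
  # supporting-read track the fused segment's coverage vanishes beyond the
  # junction, so this edge is base-exact
  d <- track$depth
  zero_run <- function(i) {
    # length of the all-zero run starting at i (bounded by gap_len)
    j <- i
    while (j <= n && j - i < gap_len && d[j] == 0L) j <- j + 1L
    j - i
  }
  gap_len <- 101L
  # the zero side of the step is unbounded (supporting coverage stays at
  # zero past the junction); the radius only limits the covered side
  lo <- if (drop_side) max(2L, split_at - refine_radius) else 2L
  hi <- if (drop_side) n else min(n, split_at + refine_radius)
  refined <- NA_integer_
  if (drop_side) {
    # rightmost covered base followed by >= gap_len zeros
    for (i in seq(hi, lo, by = -1L)) {
      if (d[i - 1L] > 0L && zero_run(i) == min(gap_len, n - i + 1L)) {
        refined <- i
        break
      }
    }
  } else {
    # leftmost covered base preceded by >= gap_len zeros
    for (i in seq(lo, hi)) {
      run <- min(gap_len, i - 1L)
      if (d[i] > 0L && all(d[(i - run):(i - 1L)] == 0L)) {
        refined <- i
        break
      }
    }
  }
  if (!is.na(refined) && (refined + track$start - 1L) %in% pos[candidate]) {
    split_at <- refined
    best <- which(cp$boundary == refined)
  }
  list(position = as.integer(track$start + split_at - 1L),
       direction = if (drop_side) "drop" else "rise",
       delta = local_delta)
}

#' Call fusion candidates from paired-end alignments
#'
#' Implements the coverage-based fusion discovery procedure: (1) tally
#' criterion-1 discordant pairs per unordered gene pair and keep pairs with
#' at least `min_support`; (2) collect criterion-2 intronic-support pairs
#' for the implicated genes; (3) build per-gene coverage from the
#' supporting mates only and infer each partner's breakpoint with
#' [infer_breakpoint()]; (4) orient the candidate (donor = the gene whose
#' supporting coverage drops at its breakpoint, acceptor = the gene where
#' it rises) and call the reading frame. Candidates are sorted by
#' discordant support, descending. No candidate is emitted without
#' criterion-1 pairs.
#'
#' @param pairs data.frame of read pairs.
#' @param genes named list of [gene_model()]s.
#' @param min_support minimum number of discordant pairs.
#' @param flank breakpoint-candidate widening, bp (see
#'   [infer_breakpoint()]).
#' @param min_delta passed to [infer_breakpoint()].
#' @param chrom_lengths optional named chromosome lengths for validation.
#' @return data.frame of candidates: `gene5`, `gene3`, `chrom5`,
#'   `breakpoint5`, `chrom3`, `breakpoint3`, `n_discordant_pairs`,
#'   `n_junction_reads`, `frame_status`, `intrachromosomal`.
#' @export
call_fusions <- function(pairs, genes, min_support = 2L, flank = 100L,
                         min_delta = NULL, chrom_lengths = NULL) {
  stopifnot(min_support >= 1L)
  empty <- data.frame(gene5 = character(0), gene3 = character(0),
                      chrom5 = character(0), breakpoint5 = integer(0),
                      chrom3 = character(0), breakpoint3 = integer(0),
                      n_discordant_pairs = integer(0),
                      n_junction_reads = integer(0),
                      frame_status = character(0),
                      intrachromosomal = logical(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  spans <- gene_span_table(genes)
  g1 <- lapply(seq_len(nrow(pairs)),
               function(i) mate_genes(pairs$chrom1[i], pairs$start1[i], pairs$len1[i], spans))
  g2 <- lapply(seq_len(nrow(pairs)),
               function(i) mate_genes(pairs$chrom2[i], pairs$start2[i], pairs$len2[i], spans))
  # criterion 1: mates overlapping two distinct genes
  pair_keys <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- g1[[i]]; b <- g2[[i]]
    if (!length(a) || !length(b)) return(character(0))
    combos <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    combos <- combos[combos$a != combos$b, , drop = FALSE]
    unique(apply(combos, 1L, function(r) paste(sort(r), collapse = "\r")))
  })
  tallies <- table(unlist(pair_keys))
  supported_keys <- names(tallies)[tallies >= min_support]
  if (length(supported_keys) == 0L) return(empty)

  out <- list()
  for (key in supported_keys) {
    partner <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    ga <- genes[[partner[1L]]]; gb <- genes[[partner[2L]]]
    crit1 <- vapply(pair_keys, function(k) key %in% k, logical(1))
    labels <- classify_pairs(pairs[!crit1, , drop = FALSE], genes,
                             supported_genes = partner,
                             chrom_lengths = chrom_lengths)
    crit2 <- rep(FALSE, nrow(pairs))
    crit2[!crit1] <- labels == "intronic_breakpoint_support"
    support <- pairs[crit1 | crit2, , drop = FALSE]

    # fusion points come from the coverage of the identified (supporting)
    # pairs; the full profile only motivates the intron candidates
    bp <- lapply(list(ga, gb), function(g) {
      track <- build_coverage(support, g$chrom,
                              max(1L, gene_start(g) - flank),
                              gene_end(g) + flank)
      infer_breakpoint(track, g, flank = flank, min_delta = min_delta)
    })
    if (anyNA(c(bp[[1L]]$position, bp[[2L]]$position))) next
    dirs <- c(bp[[1L]]$direction, bp[[2L]]$direction)
    if (identical(dirs, c("drop", "rise"))) {
      donor_i <- 1L
    } else if (identical(dirs, c("rise", "drop"))) {
      donor_i <- 2L
    } else {
      # ambiguous orientation: take the larger coverage change as the donor
      donor_i <- if (bp[[1L]]$delta >= bp[[2L]]$delta) 1L else 2L
      message("call_fusions: ambiguous donor/acceptor orientation for ",
              partner[1L], "-", partner[2L])
    }
    acceptor_i <- 3L - donor_i
    donor <- list(ga, gb)[[donor_i]]; acceptor <- list(ga, gb)[[acceptor_i]]
    # donor: first base of the low side is one past the last fused base
    bp5 <- bp[[donor_i]]$position - 1L
    bp3 <- bp[[acceptor_i]]$position
    n_junction <- sum((support$chrom1 == donor$chrom &
                         support$start1 + support$len1 - 1L == bp5) |
                        (support$chrom2 == donor$chrom &
                           support$start2 + support$len2 - 1L == bp5))
    cand <- data.frame(
      gene5 = donor$gene_id, gene3 = acceptor$gene_id,
      chrom5 = donor$chrom, breakpoint5 = bp5,
      chrom3 = acceptor$chrom, breakpoint3 = bp3,
      n_discordant_pairs = as.integer(sum(crit1)),
      n_junction_reads = as.integer(n_junction),
      frame_status = NA_character_,
      intrachromosomal = donor$chrom == acceptor$chrom,
      stringsAsFactors = FALSE)
    cand$frame_status <- classify_frame(cand, genes)
    out[[length(out) + 1L]] <- cand
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$n_discordant_pairs, res$gene5), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reading-frame status of a fusion candidate
#'
#' The fusion is in frame when the donor's coding length up to the 5'
#' breakpoint is congruent (mod 3) with the codon phase of the acceptor
#' exon at the 3' breakpoint; `noncoding` when either partner lacks a CDS.
#'
#' @param candidate one-row data.frame with `gene5`, `gene3`,
#'   `breakpoint5`, `breakpoint3`.
#' @param genes named list of [gene_model()]s.
#' @return `"in_frame"`, `"out_of_frame"` or `"noncoding"`.
#' @export
classify_frame <- function(candidate, genes) {
  donor <- genes[[candidate$gene5]]; acceptor <- genes[[candidate$gene3]]
  if (is.null(donor) || is.null(acceptor)) stop("unknown fusion gene")
  if (candidate$breakpoint5 < gene_start(donor) ||
      candidate$breakpoint5 > gene_end(donor)) {
    stop("breakpoint5 outside gene ", donor$gene_id)
  }
  if (candidate$breakpoint3 < gene_start(acceptor) ||
      candidate$breakpoint3 > gene_end(acceptor)) {
    stop("breakpoint3 outside gene ", acceptor$gene_id)
  }
  if (!donor$is_coding || !acceptor$is_coding) return("noncoding")
  donor_cds <- cds_length_upto(donor, candidate$breakpoint5)
  bp3 <- candidate$breakpoint3
  exonic <- any(acceptor$exons[, "start"] <= bp3 & bp3 <= acceptor$exons[, "end"])
  if (!exonic) {
    # intronic acceptor breakpoint: splicing resumes at the next exon
    downstream <- if (acceptor$strand == "+") {
      which(acceptor$exons[, "start"] > bp3)
    } else {
      which(acceptor$exons[, "end"] < bp3)
    }
    if (length(downstream) == 0L) return("out_of_frame")
    nxt <- downstream[which.min(abs(acceptor$exons[downstream, "start"] - bp3))]
    bp3 <- if (acceptor$strand == "+") acceptor$exons[nxt, "start"] else
      acceptor$exons[nxt, "end"]
  }
  acceptor_phase <- exon_phase_at(acceptor, bp3)
  if (donor_cds %% 3L == acceptor_phase) "in_frame" else "out_of_frame"
}

#' Reconstruct the junction sequence of a fusion candidate
#'
#' Concatenates the last `k` transcribed donor bases before the junction
#' and the first `k` acceptor bases after it, in transcript orientation
#' (minus-strand sides are reverse-complemented).
#'
#' @param candidate one-row candidate data.frame (see [call_fusions()]).
#' @param genome named character vector of chromosome sequences.
#' @param genes named list of [gene_model()]s.
#' @param k bases taken from each side.
#' @return character scalar of length `2k`.
#' @export
reconstruct_junction <- function(candidate, genome, genes, k = 20L) {
  donor <- genes[[candidate$gene5]]; acceptor <- genes[[candidate$gene3]]
  side <- function(gene, bp, is_donor) {
    seq_chrom <- genome[[gene$chrom]]
    if (is.null(seq_chrom)) stop("chromosome ", gene$chrom, " absent from genome")
    towards_5 <- (is_donor && gene$strand == "+") || (!is_donor && gene$strand == "-")
    if (towards_5) { s <- bp - k + 1L; e <- bp } else { s <- bp; e <- bp + k - 1L }
    if (s < 1L || e > nchar(seq_chrom)) stop("k larger than available sequence")
    out <- substr(seq_chrom, s, e)
    if (gene$strand == "-") reverse_complement(out) else out
  }
  paste0(side(donor, candidate$breakpoint5, TRUE),
         side(acceptor, candidate$breakpoint3, FALSE))
}
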