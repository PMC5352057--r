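#' Collapse a substitution onto the six pyrimidine-strand classes
#'
#' Purine reference bases are complemented together with their alternate
#' base, so G>A becomes C>T, A>G becomes T>C, and so on.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return character vector of classes among
#'   `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @export
substitution_class <- function(ref, alt) {
  ok <- ref %in% BASES & alt %in% BASES
  if (!all(ok)) stop("non-ACGT base in substitution")
  if (any(ref == alt)) stop("ref equals alt")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, COMPLEMENT[ref], ref)
  a <- ifelse(purine, COMPLEMENT[alt], alt)
  paste0(r, ">", a)
}

#' Trinucleotide context of SNVs on the pyrimidine strand
#'
#' Reads both flanking bases from the reference; when the reference base is
#' a purine the flanks are complemented and swapped so every context is
#' reported on the pyrimidine strand. Variants at chromosome boundaries or
#' with an ambiguous (non-ACGT) base in their trinucleotide are excluded
#' with a logged count.
#'
#' @param genome named character vector of chromosome sequences.
#' @param variants data.frame of variants (`chrom`, `pos`, `ref`, `alt`);
#'   non-SNV rows are ignored.
#' @return data.frame with `class`, `five_prime`, `three_prime`, one row
#'   per usable SNV; attribute `n_excluded` counts the exclusions.
#' @export
trinucleotide_context <- function(genome, variants) {
  snv <- variants[variants$ref %in% BASES & variants$alt %in% BASES, , drop = FALSE]
  unknown <- setdiff(unique(snv$chrom), names(genome))
  if (length(unknown)) stop("unknown chromosome ", unknown[[1L]])
  n <- nrow(snv)
  left <- character(n); mid <- character(n); right <- character(n)
  boundary <- logical(n)
  for (ch in unique(snv$chrom)) {
    i <- which(snv$chrom == ch)
    chrom_seq <- genome[[ch]]
    pos <- snv$pos[i]
    boundary[i] <- pos <= 1L | pos >= nchar(chrom_seq)
    ok <- i[!boundary[i]]
    if (length(ok)) {
      p <- snv$pos[ok]
      left[ok] <- substring(chrom_seq, p - 1L, p - 1L)
      mid[ok] <- substring(chrom_seq, p, p)
      right[ok] <- substring(chrom_seq, p + 1L, p + 1L)
    }
  }
  usable <- !boundary & left %in% BASES & mid %in% BASES & right %in% BASES
  if (any(usable & mid != snv$ref)) {
    bad <- which(usable & mid != snv$ref)[1L]
    stop("reference mismatch at ", snv$chrom[bad], ":", snv$pos[bad])
  }
  n_excluded <- sum(!usable)
  purine <- snv$ref %in% c("A", "G")
  five <- ifelse(purine, COMPLEMENT[right], left)
  three <- ifelse(purine, COMPLEMENT[left], right)
  out <- data.frame(
    class = if (any(usable)) substitution_class(snv$ref[usable], snv$alt[usable])
            else character(0),
    five_prime = five[usable], three_prime = three[usable],
    stringsAsFactors = FALSE)
  if (n_excluded > 0L) {
    message("trinucleotide_context: excluded ", n_excluded,
            " variant(s) at boundaries or ambiguous contexts")
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Build the mutation spectrum of one sample
#'
#' Aggregates a sample's variants into the 6-class substitution spectrum
#' and the 96-channel trinucleotide-context matrix (class x 5' base x 3'
#' base, the 5' base indexing rows of each per-class 4x4 grid), and
#' computes the mutation burden: `(n_SNVs + n_indels) / capture_mb`.
#' Indels count toward the burden but not the context matrix.
#'
#' @param variants one sample's variants (`chrom`, `pos`, `ref`, `alt`,
#'   `kind`).
#' @param genome named character vector of chromosome sequences.
#' @param capture_mb size of the sequenced target territory in Mb.
#' @param hyper_thresh burden (mut/Mb) above which the sample is marked
#'   hypermutated.
#' @return a `spectrum_matrix`: list with `sample_id`, `six_class` (named
#'   counts), `context96` (6 x 4 x 4 array), `n_snvs`, `n_indels`,
#'   `n_excluded`, `mut_per_mb`, `hypermutated`.
#' @export
build_spectrum <- function(variants, genome, capture_mb, hyper_thresh = 10) {
  if (capture_mb <= 0) stop("capture_mb must be positive")
  sample_id <- unique(variants$sample) %||% "sample"
  if (length(sample_id) > 1L) stop("variants from more than one sample")
  if (length(sample_id) == 0L) sample_id <- "sample"
  is_snv <- variants$kind == "SNV"
  ctx <- trinucleotide_context(genome, variants[is_snv, , drop = FALSE])
  context96 <- array(0L, dim = c(6L, 4L, 4L),
                     dimnames = list(SUB_CLASSES, BASES, BASES))
  if (nrow(ctx)) {
    t3 <- table(factor(ctx$class, SUB_CLASSES),
                factor(ctx$five_prime, BASES),
                factor(ctx$three_prime, BASES))
    context96[] <- as.integer(t3)
  }
  six_class <- apply(context96, 1L, sum)
  n_snvs <- sum(is_snv)
  n_indels <- sum(!is_snv)
  structure(list(
    sample_id = sample_id,
    six_class = six_class,
    context96 = context96,
    n_snvs = as.integer(n_snvs),
    n_indels = as.integer(n_indels),
    n_excluded = attr(ctx, "n_excluded"),
    mut_per_mb = (n_snvs + n_indels) / capture_mb,
    snv_per_mb = n_snvs / capture_mb,
    hypermutated = (n_snvs + n_indels) / capture_mb > hyper_thresh
  ), class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %s: %d SNVs + %d indels, %.2f mut/Mb%s\n",
              x$sample_id, x$n_snvs, x$n_indels, x$mut_per_mb,
              if (x$hypermutated) " (hypermutated)" else ""))
  print(x$six_class)
  invisible(x)
}

#' NpCpG C>T prominence of a spectrum
#'
#' Scores the fraction of C>T events whose 3' base is G (the NpCpG
#' deamination signature of 5-methyl-cytosine) and flags the sample when
#' the score exceeds `prominence_thresh`. Under a uniform context
#' distribution the score expectation is 0.25; the default threshold sits
#' between that and the enriched regime.
#'
#' @param spectrum a `spectrum_matrix` from [build_spectrum()].
#' @param prominence_thresh score above which the sample is flagged.
#' @param min_snvs minimum SNVs for a determinate answer.
#' @return list with `score`, `flagged` (NA when indeterminate),
#'   `n_ct` (number of C>T events).
#' @export
npcpg_prominence <- function(spectrum, prominence_thresh = 0.4, min_snvs = 10L) {
  if (spectrum$n_snvs < min_snvs) {
    return(list(score = NA_real_, flagged = NA, n_ct = NA_integer_))
  }
  ct <- spectrum$context96["C>T", , ]
  n_ct <- sum(ct)
  if (n_ct == 0L) return(list(score = 0, flagged = FALSE, n_ct = 0L))
  score <- sum(ct[, "G"]) / n_ct
  list(score = score, flagged = score > prominence_thresh, n_ct = as.integer(n_ct))
}

#' Recurrently mutated genes across a cohort
#'
#' Tallies, per gene, the number of distinct samples carrying at least one
#' mutation, keeping genes hit in `min_cases` or more samples; when
#' position/allele (or `protein_change`) columns are present, recurrence of
#' the identical change across samples is reported separately (the shared
#' hotspot pattern).
#'
#' @param variants cohort variant data.frame with `sample` and `gene`
#'   columns (rows with `NA` gene are ignored).
#' @param min_cases minimum number of distinct mutated samples.
#' @return list with `genes` (data.frame `gene`, `n_cases`, sorted by
#'   count then name) and `identical_changes` (data.frame of shared
#'   identical variants with `n_cases >= min_cases`).
#' @export
recurrent_genes <- function(variants, min_cases = 3L) {
  stopifnot(min_cases >= 1L)
  v <- variants[!is.na(variants$gene), , drop = FALSE]
  if (nrow(v) == 0L) {
    return(list(
      genes = data.frame(gene = character(0), n_cases = integer(0)),
      identical_changes = data.frame(gene = character(0), n_cases = integer(0))))
  }
  tally <- stats::aggregate(sample ~ gene, data = v,
                            FUN = function(s) length(unique(s)))
  names(tally) <- c("gene", "n_cases")
  genes <- tally[tally$n_cases >= min_cases, , drop = FALSE]
  genes <- genes[order(-genes$n_cases, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL

  id_cols <- intersect(c("gene", "chrom", "pos", "ref", "alt"), colnames(v))
  key <- do.call(paste, c(v[id_cols], sep = ":"))
  site_tally <- stats::aggregate(v$sample, by = list(key = key),
                                 FUN = function(s) length(unique(s)))
  names(site_tally) <- c("key", "n_cases")
  shared <- site_tally[site_tally$n_cases >= min_cases, , drop = FALSE]
  identical_changes <- if (nrow(shared)) {
    info <- v[match(shared$key, key), id_cols, drop = FALSE]
    if ("protein_change" %in% colnames(v)) {
      info$protein_change <- v$protein_change[match(shared$key, key)]
    }
    info$n_cases <- shared$n_cases
    rownames(info) <- NULL
    info
  } else {
    out <- v[0L, id_cols, drop = FALSE]
    out$n_cases <- integer(0)
    out
  }
  list(genes = genes, identical_changes = identical_changes)
}
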