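#' Describe a gene to be placed on the synthetic genome
#'
#' Exon/intron lengths are given in transcription order; genomic exon
#' intervals are derived from `start` (the genomic start of the gene span,
#' regardless of strand). Codon phases of coding genes are assigned
#' natively: exon i carries phase = (cumulative exonic length before exon i)
#' mod 3.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param start 1-based genomic start of the gene span.
#' @param exon_lengths integer vector of exon lengths, transcription order.
#' @param intron_lengths integer vector (one fewer than exons).
#' @param strand `"+"` or `"-"`.
#' @param coding logical.
#' @return a `gene_spec` list consumed by [make_genome()].
#' @export
gene_spec <- function(gene_id, chrom, start, exon_lengths,
                      intron_lengths = integer(0), strand = "+", coding = TRUE) {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L,
            all(exon_lengths >= 1L), all(intron_lengths >= 1L), start >= 1L)
  structure(list(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 strand = strand, coding = isTRUE(coding)),
            class = "gene_spec")
}

spec_to_model <- function(spec) {
  n <- length(spec$exon_lengths)
  # lay exon/intron lengths left-to-right on the genome; for '-' genes the
  # transcription order runs right-to-left, so reverse the lengths first
  ex_len <- if (spec$strand == "+") spec$exon_lengths else rev(spec$exon_lengths)
  in_len <- if (spec$strand == "+") spec$intron_lengths else rev(spec$intron_lengths)
  starts <- integer(n); ends <- integer(n)
  pos <- spec$start
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + ex_len[i] - 1L
    if (i < n) pos <- ends[i] + in_len[i] + 1L
  }
  ord <- if (spec$strand == "+") seq_len(n) else rev(seq_len(n))
  exons <- cbind(starts, ends)[ord, , drop = FALSE]
  phase <- if (spec$coding) {
    as.integer(cumsum(c(0L, spec$exon_lengths[-n])) %% 3L)
  } else NULL
  gene_model(spec$gene_id, spec$chrom, spec$strand, exons,
             phase = phase, is_coding = spec$coding)
}

#' Default gene layout of the synthetic genome
#'
#' A scaled-down chordoma-like universe: the fusion partner pair (donor
#' `SAMD5L`, acceptor `SASH1L`) sits on one chromosome with gene starts
#' 77,200 bp apart — a 1:10 scaling of the 772 kb separation of the real
#' 6q24 partners — plus a brachyury analog (`TBXTL`) and background genes,
#' three of which (`MUC4L`, `NBPF1L`, `NPIPB15L`) are reserved for
#' recurrent-mutation injection.
#'
#' @param fusion_chrom chromosome carrying the fusion partners.
#' @param separation_bp distance between the partner genes' starts.
#' @return named list of `gene_spec`s.
#' @export
default_gene_specs <- function(fusion_chrom = "chr3", separation_bp = 77200L) {
  specs <- list(
    gene_spec("SAMD5L", fusion_chrom, 200001L,
              exon_lengths = c(402L, 300L, 450L), intron_lengths = c(3000L, 2000L)),
    gene_spec("SASH1L", fusion_chrom, 200001L + as.integer(separation_bp),
              exon_lengths = c(201L, 300L, 600L), intron_lengths = c(2500L, 1800L)),
    gene_spec("TBXTL", "chr5", 500001L,
              exon_lengths = c(300L, 399L, 501L), intron_lengths = c(1500L, 1200L)),
    gene_spec("MUC4L", "chr1", 300001L,
              exon_lengths = c(600L, 900L), intron_lengths = 2000L),
    gene_spec("NBPF1L", "chr1", 900001L,
              exon_lengths = c(450L, 600L), intron_lengths = 1800L),
    gene_spec("NPIPB15L", "chr2", 400001L,
              exon_lengths = c(501L, 750L), intron_lengths = 2200L),
    gene_spec("GENEA", "chr2", 1200001L,
              exon_lengths = c(300L, 300L), intron_lengths = 1000L),
    gene_spec("GENEB", "chr4", 700001L,
              exon_lengths = c(450L, 450L), intron_lengths = 1500L)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "gene_id")
  specs
}

#' Generate a deterministic synthetic genome with gene annotations
#'
#' Draws uniform random ACGT sequence for `n_chrom` chromosomes and places
#' the requested genes. The default universe is 5 chromosomes of 2 Mb;
#' real-genome scale is a parameter change, not a code change.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param gene_specs named list of [gene_spec()]s.
#' @param chrom_names chromosome names (default `chr1`..`chrN`).
#' @param seed integer seed; the same seed yields byte-identical output.
#' @return list with `genome` (named character vector), `genes` (named list
#'   of [gene_model()]s), `chrom_lengths`, and `arms` (a data.frame giving
#'   each chromosome's p/q arm intervals, split at the midpoint).
#' @export
make_genome <- function(n_chrom = 5L, chrom_length = 2000000L,
                        gene_specs = default_gene_specs(),
                        chrom_names = paste0("chr", seq_len(n_chrom)),
                        seed = 1L) {
  stopifnot(n_chrom >= 1L, chrom_length >= 1L, length(chrom_names) == n_chrom)
  chroms <- chrom_names
  for (sp in gene_specs) {
    if (!sp$chrom %in% chroms) stop("gene ", sp$gene_id, " on unknown chromosome ", sp$chrom)
  }
  models <- lapply(gene_specs, spec_to_model)
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  spans <- gene_span_table(models)
  if (any(spans$end > chrom_length)) {
    bad <- spans$gene_id[spans$end > chrom_length][1L]
    stop("gene ", bad, " extends past chromosome end")
  }
  by_chrom <- split(spans, spans$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("overlapping gene specs on ", d$chrom[[1L]])
    }
  }
  genome <- with_seed(seed, {
    vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  mid <- chrom_length %/% 2L
  arms <- data.frame(
    chrom = rep(chroms, each = 2L),
    arm = rep(c("p", "q"), n_chrom),
    start = rep(c(1L, mid + 1L), n_chrom),
    end = rep(c(mid, chrom_length), n_chrom),
    stringsAsFactors = FALSE
  )
  list(genome = genome, genes = models,
       chrom_lengths = setNames(rep(as.integer(chrom_length), n_chrom), chroms),
       arms = arms)
}

#' Default fusion event of the synthetic cohort
#'
#' The genomic donor breakpoint lies in the donor's first intron (the fused
#' transcript retains exon 1 plus the initial stretch of intron 1, so read
#' pairs with one mate wholly inside that intron exist); the acceptor
#' breakpoint is the first base of the acceptor's second exon. With the
#' default gene layout the donor contributes 402 CDS bases (a multiple of
#' three) and the acceptor's exon 2 has phase 0, so the fusion is in frame.
#'
#' @param genes named list of [gene_model()]s containing `SAMD5L`/`SASH1L`.
#' @param expression_level fraction of simulated fragments arising from the
#'   fusion transcript (0 disables the event).
#' @return list with `gene5`, `gene3`, `bp5`, `bp3`, `expression_level`.
#' @export
default_fusion_spec <- function(genes, expression_level = 0.3) {
  donor <- genes[["SAMD5L"]]; acceptor <- genes[["SASH1L"]]
  intron1 <- gene_introns(donor)[1L, ]
  bp5 <- as.integer(intron1[["start"]] + 1499L)
  stopifnot(bp5 <= intron1[["end"]])
  bp3 <- as.integer(sort(acceptor$exons[, "start"])[2L])
  list(gene5 = donor$gene_id, gene3 = acceptor$gene_id,
       bp5 = bp5, bp3 = bp3, expression_level = expression_level)
}
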