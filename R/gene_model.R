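#' Construct a gene model
#'
#' A gene model records a gene's location, strand, ordered exon structure and
#' (for coding genes) the codon phase of each exon. Exons are stored in
#' transcription order: ascending genomic start for `+` genes, descending for
#' `-` genes. Phase is the offset within a codon of an exon's first
#' transcribed base (0, 1 or 2), i.e. the cumulative CDS length of the
#' preceding exons modulo 3.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of 1-based inclusive
#'   `(start, end)` genomic intervals, one row per exon, in transcription
#'   order.
#' @param phase integer vector (one value in 0:2 per exon) for coding genes,
#'   or `NULL` for noncoding genes.
#' @param is_coding logical; must agree with `phase` being supplied.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, phase = NULL,
                       is_coding = !is.null(phase)) {
  stopifnot(length(gene_id) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] < exons[, "start"])) stop("exon end < start")
  if (any(exons[, "start"] < 1L)) stop("exon coordinates must be >= 1")
  genomic_order <- order(exons[, "start"])
  sorted <- exons[genomic_order, , drop = FALSE]
  if (nrow(sorted) > 1L &&
      any(sorted[-1L, "start"] <= sorted[-nrow(sorted), "end"])) {
    stop("exons overlap in gene ", gene_id)
  }
  expected <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  if (!identical(genomic_order, as.integer(expected))) {
    stop("exons of ", gene_id, " are not in transcription order for strand ", strand)
  }
  if (is_coding) {
    if (is.null(phase) || length(phase) != nrow(exons) || !all(phase %in% 0:2)) {
      stop("coding gene ", gene_id, " needs one phase value in 0:2 per exon")
    }
    phase <- as.integer(phase)
  } else {
    if (!is.null(phase)) stop("phase must be NULL for noncoding gene ", gene_id)
  }
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons, phase = phase,
         is_coding = isTRUE(is_coding)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), %s\n",
              x$gene_id, x$chrom, gene_start(x), gene_end(x), x$strand,
              nrow(x$exons), if (x$is_coding) "coding" else "noncoding"))
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param gene a [gene_model()].
#' @return integer position.
#' @export
gene_start <- function(gene) min(gene$exons[, "start"])

#' @rdname gene_start
#' @export
gene_end <- function(gene) max(gene$exons[, "end"])

#' Intron intervals of a gene model, in genomic order
#'
#' @param gene a [gene_model()].
#' @return integer matrix with columns `start`, `end` (possibly 0 rows).
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons[order(gene$exons[, "start"]), , drop = FALSE]
  if (nrow(ex) < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-nrow(ex), "end"] + 1L, end = ex[-1L, "start"] - 1L)
}

#' Does an interval lie wholly within an intron of a gene?
#'
#' @param gene a [gene_model()].
#' @param start,end 1-based inclusive interval.
#' @return logical scalar.
#' @export
interval_in_intron <- function(gene, start, end) {
  introns <- gene_introns(gene)
  any(introns[, "start"] <= start & end <= introns[, "end"])
}

#' Coding sequence length of the donor side of a fusion
#'
#' Sums the CDS bases of `gene` that are transcribed before (and including)
#' genomic position `bp`, walking exons in transcription order. Intronic
#' bases never contribute; for a `-` strand gene "up to `bp`" means positions
#' with genomic coordinate `>= bp`.
#'
#' @param gene a coding [gene_model()].
#' @param bp 1-based genomic breakpoint position (inclusive).
#' @return integer number of CDS bases.
#' @export
cds_length_upto <- function(gene, bp) {
  if (!gene$is_coding) stop("gene ", gene$gene_id, " is noncoding")
  if (bp < gene_start(gene) || bp > gene_end(gene)) {
    stop("breakpoint ", bp, " outside gene ", gene$gene_id)
  }
  total <- 0L
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons[i, "start"]; e <- gene$exons[i, "end"]
    if (gene$strand == "+") {
      if (s > bp) break
      total <- total + (min(e, bp) - s + 1L)
    } else {
      if (e < bp) break
      total <- total + (e - max(s, bp) + 1L)
    }
  }
  as.integer(total)
}

#' Codon phase of the exon containing a genomic position
#'
#' @param gene a coding [gene_model()].
#' @param pos 1-based genomic position; must fall inside an exon.
#' @return phase in 0:2.
#' @export
exon_phase_at <- function(gene, pos) {
  if (!gene$is_coding) stop("gene ", gene$gene_id, " is noncoding")
  hit <- which(gene$exons[, "start"] <= pos & pos <= gene$exons[, "end"])
  if (length(hit) == 0L) stop("position ", pos, " not exonic in ", gene$gene_id)
  gene$phase[hit[1L]]
}

#' Tabulate gene spans for interval lookup
#'
#' @param genes list of [gene_model()] objects.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_span_table <- function(genes) {
  data.frame(
    gene_id = vapply(genes, function(g) g$gene_id, character(1)),
    chrom = vapply(genes, function(g) g$chrom, character(1)),
    start = vapply(genes, gene_start, numeric(1)),
    end = vapply(genes, gene_end, numeric(1)),
    stringsAsFactors = FALSE
  )
}
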