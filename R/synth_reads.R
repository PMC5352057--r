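#' Simulate paired-end alignments with an optional injected fusion
#'
#' Background fragments are drawn uniformly over each gene's spliced
#' transcript (exons only, so introns carry essentially no background
#' coverage, as in RNA-seq) and yield concordant pairs; a mate crossing an
#' exon-exon junction is clipped to its longer exonic side. When a fusion
#' is injected, a fraction `expression_level` of all fragments is drawn
#' instead from the fused transcript — the donor's genomic span up to
#' `bp5` (a retained-intron junction when `bp5` is intronic) joined to the
#' unspliced acceptor side from `bp3`. Mapping those mates back to the
#' genome yields (a) concordant pairs on either side of the junction —
#' some with a mate wholly inside the donor's breakpoint intron, the
#' second filter criterion's signal — (b) discordant pairs with mates on
#' opposite sides, and (c) junction-spanning reads, represented as split
#' alignments clipped exactly at the breakpoints.
#'
#' Reads default to 2 x 101 bp with fragment size 250 +/- 30 bp. Both
#' fusion partners must be `+`-strand genes.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes named list of [gene_model()]s.
#' @param fusion `NULL`, or a list with `gene5`, `gene3`, `bp5`, `bp3`,
#'   `expression_level` (see [default_fusion_spec()]).
#' @param n_pairs total number of fragments to simulate.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment-size distribution (bp).
#' @param seed integer seed; output is fully deterministic given the seed.
#' @return list with `pairs` (SAM-lite data.frame as from
#'   [read_sam_lite()]), `truth` (per-class fragment counts) and
#'   `junction_read_sequences` (bases of each junction-straddling read, in
#'   transcript orientation).
#' @export
simulate_fusion_read_pairs <- function(genome, genes, fusion = NULL,
                                       n_pairs = 200L, read_length = 101L,
                                       insert_mean = 250, insert_sd = 30,
                                       seed = 1L) {
  stopifnot(n_pairs >= 0L, read_length >= 1L, insert_mean >= 2 * read_length)
  tx_lengths <- vapply(genes, function(g) {
    sum(g$exons[, "end"] - g$exons[, "start"] + 1L)
  }, numeric(1))
  if (any(tx_lengths < insert_mean)) {
    stop("insert size exceeds the spliced transcript length of gene ",
         names(genes)[which(tx_lengths < insert_mean)[1L]])
  }
  n_fus <- 0L
  if (!is.null(fusion) && fusion$expression_level > 0) {
    donor <- genes[[fusion$gene5]]; acceptor <- genes[[fusion$gene3]]
    if (donor$strand != "+" || acceptor$strand != "+") {
      stop("fusion simulation supports '+'-strand partner genes only")
    }
    n_fus <- round(fusion$expression_level * n_pairs)
  }
  n_bg <- n_pairs - n_fus

  with_seed(seed, {
    nrec <- n_bg + n_fus
    rec <- list(pair_id = character(nrec),
                chrom1 = character(nrec), start1 = integer(nrec),
                strand1 = character(nrec), len1 = integer(nrec),
                chrom2 = character(nrec), start2 = integer(nrec),
                strand2 = character(nrec), len2 = integer(nrec))
    truth <- c(background_concordant = 0L, fusion_donor_concordant = 0L,
               fusion_acceptor_concordant = 0L, fusion_discordant = 0L,
               junction_split = 0L)
    junction_seqs <- character(0)
    frag_sizes <- function(n) {
      pmax(2L * read_length + 10L, round(stats::rnorm(n, insert_mean, insert_sd)))
    }

    if (n_bg > 0L) {
      # map a transcript-space interval of a spliced gene back to the
      # genome; an interval crossing an exon boundary is clipped to its
      # longer exonic side
      exon_maps <- lapply(genes, function(g) {
        ex <- g$exons[order(g$exons[, "start"]), , drop = FALSE]
        len <- ex[, "end"] - ex[, "start"] + 1L
        cbind(gstart = ex[, "start"], gend = ex[, "end"],
              tstart = cumsum(c(1L, len[-length(len)])),
              tend = cumsum(len))
      })
      map_tx <- function(m, t1, t2) {
        ov <- pmin(m[, "tend"], t2) - pmax(m[, "tstart"], t1) + 1L
        i <- which.max(ov)
        s1 <- max(m[i, "tstart"], t1)
        list(start = m[i, "gstart"] + (s1 - m[i, "tstart"]),
             len = ov[i])
      }
      gene_idx <- rep_len(seq_along(genes), n_bg)
      fs <- frag_sizes(n_bg)
      for (k in seq_len(n_bg)) {
        g <- genes[[gene_idx[k]]]
        m <- exon_maps[[gene_idx[k]]]
        tx_len <- m[nrow(m), "tend"]
        f <- min(fs[k], tx_len)
        u <- sample.int(tx_len - f + 1L, 1L)
        a <- map_tx(m, u, min(u + read_length - 1L, tx_len))
        b <- map_tx(m, max(u + f - read_length, 1L), u + f - 1L)
        rec$pair_id[k] <- sprintf("bg%05d", k)
        rec$chrom1[k] <- g$chrom; rec$start1[k] <- a$start
        rec$strand1[k] <- "+"; rec$len1[k] <- a$len
        rec$chrom2[k] <- g$chrom; rec$start2[k] <- b$start
        rec$strand2[k] <- "-"; rec$len2[k] <- b$len
        truth[["background_concordant"]] <- truth[["background_concordant"]] + 1L
      }
    }

    if (n_fus > 0L) {
      d_start <- gene_start(donor)
      junction_T <- fusion$bp5 - d_start + 1L  # last donor base, transcript coords
      acc_len <- gene_end(acceptor) - fusion$bp3 + 1L
      t_len <- junction_T + acc_len
      to_genomic <- function(t) {
        ifelse(t <= junction_T, d_start + t - 1L, fusion$bp3 + (t - junction_T) - 1L)
      }
      fs <- pmin(frag_sizes(n_fus), t_len)
      for (k in seq_len(n_fus)) {
        f <- fs[k]
        u <- sample.int(t_len - f + 1L, 1L)
        m1 <- c(u, u + read_length - 1L)
        m2 <- c(u + f - read_length, u + f - 1L)
        mate <- function(t1, t2, mate_strand) {
          if (t2 <= junction_T) {
            list(chrom = donor$chrom, start = to_genomic(t1),
                 len = t2 - t1 + 1L, side = "donor", strand = mate_strand)
          } else if (t1 > junction_T) {
            list(chrom = acceptor$chrom, start = to_genomic(t1),
                 len = t2 - t1 + 1L, side = "acceptor", strand = mate_strand)
          } else {
            # junction-straddling read: keep the longer breakpoint-anchored
            # side as the alignment (donor anchors end exactly at bp5,
            # acceptor anchors start exactly at bp3)
            d_anchor <- junction_T - t1 + 1L
            a_anchor <- t2 - junction_T
            if (d_anchor >= a_anchor) {
              list(chrom = donor$chrom, start = to_genomic(t1), len = d_anchor,
                   side = "donor_clip", strand = mate_strand)
            } else {
              list(chrom = acceptor$chrom, start = fusion$bp3, len = a_anchor,
                   side = "acceptor_clip", strand = mate_strand)
            }
          }
        }
        a <- mate(m1[1L], m1[2L], "+")
        b <- mate(m2[1L], m2[2L], "-")
        split_read <- grepl("clip", a$side) || grepl("clip", b$side)
        if (split_read) {
          sm <- if (grepl("clip", a$side)) m1 else m2
          tpos <- sm[1L]:sm[2L]
          gpos <- to_genomic(tpos)
          chs <- ifelse(tpos <= junction_T, donor$chrom, acceptor$chrom)
          junction_seqs <- c(junction_seqs, paste(
            vapply(seq_along(gpos),
                   function(i) substr(genome[[chs[i]]], gpos[i], gpos[i]),
                   character(1)),
            collapse = ""))
          truth[["junction_split"]] <- truth[["junction_split"]] + 1L
        }
        side_of <- function(m) sub("_clip", "", m$side)
        cls <- if (side_of(a) != side_of(b)) {
          "fusion_discordant"
        } else if (side_of(a) == "donor") "fusion_donor_concordant" else "fusion_acceptor_concordant"
        truth[[cls]] <- truth[[cls]] + 1L
        i <- n_bg + k
        rec$pair_id[i] <- sprintf("fus%05d", k)
        rec$chrom1[i] <- a$chrom; rec$start1[i] <- a$start
        rec$strand1[i] <- a$strand; rec$len1[i] <- a$len
        rec$chrom2[i] <- b$chrom; rec$start2[i] <- b$start
        rec$strand2[i] <- b$strand; rec$len2[i] <- b$len
      }
    }

    pairs <- as.data.frame(rec, stringsAsFactors = FALSE)
    list(pairs = pairs, truth = truth, junction_read_sequences = junction_seqs)
  })
}
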