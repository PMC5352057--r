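SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Default 6-class substitution signature of the synthetic cohort
#'
#' Dominated by C>T, T>C and C>A transitions/transversions, the pattern
#' observed in skull base chordoma exomes.
#'
#' @return named numeric weights summing to 1.
#' @export
default_signature_mix <- function() {
  c("C>A" = 0.25, "C>G" = 0.05, "C>T" = 0.35,
    "T>A" = 0.05, "T>C" = 0.25, "T>G" = 0.05)
}

#' Index substitution-eligible sites of a genome
#'
#' Precomputes, per chromosome, the interior positions of each reference
#' base and of CpG dinucleotides (both strands), so repeated variant
#' simulations on one genome avoid rescanning the sequence.
#'
#' @param genome named character vector of chromosome sequences.
#' @return a `site_index` list used by [simulate_variants()].
#' @export
build_site_index <- function(genome) {
  idx <- lapply(names(genome), function(ch) {
    r <- charToRaw(genome[[ch]])
    n <- length(r)
    interior <- function(p) p[p > 1L & p < n]
    pos <- lapply(BASES, function(b) interior(which(r == charToRaw(b))))
    names(pos) <- BASES
    cg_c <- pos$C[r[pos$C + 1L] == charToRaw("G")]   # C of a CpG, plus strand
    cg_g <- pos$G[r[pos$G - 1L] == charToRaw("C")]   # G of a CpG, minus strand
    c(pos, list(cpg_C = cg_c, cpg_G = cg_g))
  })
  names(idx) <- names(genome)
  structure(list(per_chrom = idx,
                 chrom_lengths = vapply(genome, nchar, numeric(1))),
            class = "site_index")
}

sample_sites <- function(site_index, base, n) {
  counts <- vapply(site_index$per_chrom, function(p) length(p[[base]]), numeric(1))
  total <- sum(counts)
  if (total == 0L) stop("no eligible '", base, "' site in genome")
  ch <- sample(names(counts), n, replace = TRUE, prob = counts / total)
  pos <- integer(n)
  for (c1 in unique(ch)) {
    i <- ch == c1
    p <- site_index$per_chrom[[c1]][[base]]
    pos[i] <- p[sample.int(length(p), sum(i), replace = TRUE)]
  }
  data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate somatic variants for one sample
#'
#' SNV counts follow a Poisson law with expectation `mut_rate` mutations
#' per megabase of genome; classes are drawn from `signature_mix`
#' (pyrimidine-strand convention; the reference strand is chosen at random,
#' so G>A sites realize C>T events and so on). When `npcpg_enriched`, a
#' fraction `npcpg_fraction` of C>T events is placed at NpCpG sites (the C
#' of a CpG dinucleotide on either strand). Indels make up
#' `indel_fraction` of the total burden.
#'
#' @param genome named character vector of chromosome sequences.
#' @param mut_rate expected mutations (substitutions plus indels) per Mb.
#' @param signature_mix named weights over the six substitution classes;
#'   must sum to 1 within 1e-9.
#' @param npcpg_enriched logical.
#' @param npcpg_fraction fraction of C>T events forced onto NpCpG sites
#'   when enriched.
#' @param indel_fraction fraction of the burden simulated as indels.
#' @param sample_id sample label.
#' @param site_index optional precomputed [build_site_index()] result.
#' @param seed integer seed.
#' @return data.frame of variants (`sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `kind`).
#' @export
simulate_variants <- function(genome, mut_rate, signature_mix = default_signature_mix(),
                              npcpg_enriched = FALSE, npcpg_fraction = 0.4,
                              indel_fraction = 0.05, sample_id = "S1",
                              site_index = NULL, seed = 1L) {
  if (mut_rate < 0) stop("mut_rate must be >= 0")
  if (abs(sum(signature_mix) - 1) > 1e-9) stop("signature weights must sum to 1")
  if (!setequal(names(signature_mix), SUB_CLASSES)) {
    stop("signature_mix must be named by the six substitution classes")
  }
  if (is.null(site_index)) site_index <- build_site_index(genome)
  genome_mb <- sum(site_index$chrom_lengths) / 1e6
  empty <- data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
  with_seed(seed, {
    n_total <- stats::rpois(1L, mut_rate * genome_mb)
    if (n_total == 0L) return(empty)
    n_indel <- stats::rbinom(1L, n_total, indel_fraction)
    n_snv <- n_total - n_indel
    parts <- list()
    if (n_snv > 0L) {
      cls <- sample(SUB_CLASSES, n_snv, replace = TRUE,
                    prob = signature_mix[SUB_CLASSES])
      forced <- cls == "C>T" & npcpg_enriched &
        stats::runif(n_snv) < npcpg_fraction
      ref_pyr <- substr(cls, 1L, 1L)
      alt_pyr <- substr(cls, 3L, 3L)
      on_pyr <- stats::runif(n_snv) < 0.5
      base_key <- ifelse(forced, ifelse(on_pyr, "cpg_C", "cpg_G"),
                         ifelse(on_pyr, ref_pyr, COMPLEMENT[ref_pyr]))
      chrom <- character(n_snv); pos <- integer(n_snv)
      for (key in unique(base_key)) {
        i <- base_key == key
        site <- sample_sites(site_index, key, sum(i))
        chrom[i] <- site$chrom; pos[i] <- site$pos
      }
      parts$snv <- data.frame(
        sample = sample_id, chrom = chrom, pos = pos,
        ref = ifelse(on_pyr, ref_pyr, COMPLEMENT[ref_pyr]),
        alt = ifelse(on_pyr, alt_pyr, COMPLEMENT[alt_pyr]),
        kind = "SNV", stringsAsFactors = FALSE)
    }
    if (n_indel > 0L) {
      ch <- sample(names(genome), n_indel, replace = TRUE)
      pos <- vapply(ch, function(c1) {
        sample(seq(2L, site_index$chrom_lengths[[c1]] - 5L), 1L)
      }, numeric(1))
      anchor <- vapply(seq_len(n_indel),
                       function(k) substr(genome[[ch[k]]], pos[k], pos[k]),
                       character(1))
      is_ins <- stats::runif(n_indel) < 0.5
      ext <- sample(1:3, n_indel, replace = TRUE)
      ref <- anchor; alt <- anchor
      for (k in seq_len(n_indel)) {
        if (is_ins[k]) {
          alt[k] <- paste0(anchor[k], paste(sample(BASES, ext[k], replace = TRUE),
                                            collapse = ""))
        } else {
          ref[k] <- substr(genome[[ch[k]]], pos[k], pos[k] + ext[k])
        }
      }
      parts$indel <- data.frame(
        sample = sample_id, chrom = ch, pos = as.integer(pos), ref = ref,
        alt = alt, kind = ifelse(is_ins, "insertion", "deletion"),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Annotate variants with the gene whose span contains them
#'
#' @param variants variant data.frame.
#' @param genes named list of [gene_model()]s.
#' @return `variants` with a `gene` column (`NA` when intergenic).
#' @export
annotate_variant_genes <- function(variants, genes) {
  spans <- gene_span_table(genes)
  gene <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(spans))) {
    hit <- variants$chrom == spans$chrom[i] &
      variants$pos >= spans$start[i] & variants$pos <= spans$end[i]
    gene[hit] <- spans$gene_id[i]
  }
  variants$gene <- gene
  variants
}

#' Simulate the somatic variant tables of a whole cohort
#'
#' Draws per-sample variants, annotates genes, and injects ground-truth
#' recurrence: for each entry of `recurrent_spec`, one exonic SNV in the
#' named gene per listed sample (distinct positions), and for
#' `shared_site_spec` one identical SNV (same position, alleles and protein
#' change) across its listed samples, emulating a hotspot shared point
#' mutation.
#'
#' @param genome,genes synthetic genome and annotation from [make_genome()].
#' @param sample_ids character vector of tumor sample names.
#' @param mut_rate expected mutations per Mb per sample.
#' @param signature_mix shared 6-class signature.
#' @param npcpg_enriched_samples samples simulated with NpCpG C>T
#'   enrichment.
#' @param recurrent_spec named list: gene id -> sample ids carrying an
#'   (arbitrary-position) exonic mutation.
#' @param shared_site_spec list with `gene` and `samples` for the
#'   identical-change recurrence, or `NULL`.
#' @param seed integer seed.
#' @return data.frame of annotated variants across all samples.
#' @export
simulate_cohort_variants <- function(genome, genes, sample_ids,
                                     mut_rate = 2.1,
                                     signature_mix = default_signature_mix(),
                                     npcpg_enriched_samples = character(0),
                                     recurrent_spec = list(),
                                     shared_site_spec = NULL, seed = 1L) {
  site_index <- build_site_index(genome)
  per_sample <- lapply(seq_along(sample_ids), function(i) {
    simulate_variants(genome, mut_rate, signature_mix,
                      npcpg_enriched = sample_ids[i] %in% npcpg_enriched_samples,
                      sample_id = sample_ids[i], site_index = site_index,
                      seed = child_seed(seed, i))
  })
  variants <- annotate_variant_genes(do.call(rbind, per_sample), genes)
  variants$protein_change <- NA_character_

  exonic_snv <- function(gene, pos_seed) {
    with_seed(pos_seed, {
      ex <- gene$exons[sample.int(nrow(gene$exons), 1L), ]
      pos <- sample(seq(ex[["start"]], ex[["end"]]), 1L)
      ref <- substr(genome[[gene$chrom]], pos, pos)
      alt <- sample(setdiff(BASES, ref), 1L)
      list(pos = pos, ref = ref, alt = alt)
    })
  }
  inject <- function(variants, gene_id, samp, v, protein_change = NA_character_) {
    g <- genes[[gene_id]]
    rbind(variants, data.frame(
      sample = samp, chrom = g$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      kind = "SNV", gene = gene_id, protein_change = protein_change,
      stringsAsFactors = FALSE))
  }
  stream <- 1000L
  for (gene_id in names(recurrent_spec)) {
    for (samp in recurrent_spec[[gene_id]]) {
      stream <- stream + 1L
      v <- exonic_snv(genes[[gene_id]], child_seed(seed, stream))
      variants <- inject(variants, gene_id, samp, v)
    }
  }
  if (!is.null(shared_site_spec)) {
    g <- genes[[shared_site_spec$gene]]
    v <- exonic_snv(g, child_seed(seed, 9999L))
    aa <- (v$pos - gene_start(g)) %/% 3L + 1L
    label <- sprintf("p.%s%d%s", v$ref, aa, v$alt)
    for (samp in shared_site_spec$samples) {
      variants <- inject(variants, shared_site_spec$gene, samp, v, label)
    }
  }
  variants <- variants[order(variants$sample, variants$chrom, variants$pos), ]
  rownames(variants) <- NULL
  variants
}
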