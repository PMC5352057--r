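#' Union-of-exons gene lengths
#'
#' @param genes named list of [gene_model()]s.
#' @return named integer vector of summed exon lengths (bp).
#' @export
gene_lengths_from_models <- function(genes) {
  vapply(genes, function(g) sum(g$exons[, "end"] - g$exons[, "start"] + 1L),
         integer(1))
}

#' Convert segments to BED text (0-based half-open)
#'
#' @param segments data.frame from [segment_profile()].
#' @return character vector of BED lines.
#' @export
segments_to_bed <- function(segments) {
  sprintf("%s\t%d\t%d\t%s\t%.4f", segments$chrom,
          segments$start - 1L, segments$end,
          segments$call, segments$mean_log2)
}

run_stage <- function(name, input_hint, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed (", input_hint, "): ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the cohort characterization pipeline from a declarative config
#'
#' Stages (`fusion`, `copy_number`, `spectrum`, `expression`, `genotype`,
#' `clinical`) are independently optional; each consumes the file formats
#' of the IO layer, runs its module, and writes its tables under `outdir`.
#' A `manifest.json` lists every file written with its MD5 checksum plus
#' the excluded-record counts, and `report.json` aggregates the per-stage
#' results. Outputs are deterministic: two runs with the same config are
#' byte-identical.
#'
#' @param config a named list, or path to a YAML file, with elements
#'   `stages` (character vector), `inputs` (named file paths: `sam`,
#'   `genes`, `fasta`, `variants`, `depth_windows`, `counts`,
#'   `gene_lengths`, `groups`, `genotypes`, `clinical`) and optional
#'   `params` (`min_support`, `flank`, `capture_mb`, `hyper_thresh`,
#'   `prominence_thresh`, `min_cases`, `alpha`, `gain_thresh`,
#'   `loss_thresh`, `compare` = list(gene, group_a, group_b)).
#' @param outdir output directory (created if absent).
#' @return the report, invisibly; files under `outdir` as a side effect.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% character(0)
  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  written <- character(0)
  logs <- list()
  need <- function(key) {
    path <- inputs[[key]]
    if (is.null(path) || !file.exists(path)) {
      stop("missing input '", key, "'", if (!is.null(path)) paste0(": ", path))
    }
    path
  }
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    written <<- c(written, path)
    path
  }

  if ("fusion" %in% stages) {
    run_stage("fusion", inputs$sam %||% "sam", {
      pairs <- read_sam_lite(need("sam"))
      genes <- read_gene_table(need("genes"))
      logs$fusion_dropped_records <- attr(pairs, "n_dropped")
      fusions <- call_fusions(pairs, genes,
                              min_support = params$min_support %||% 2L,
                              flank = params$flank %||% 100L)
      emit("fusions.tsv", function(p) write_headed_tsv(fusions, p))
      if (!is.null(inputs$fasta) && nrow(fusions) > 0L) {
        genome <- read_fasta(need("fasta"))
        jx <- vapply(seq_len(nrow(fusions)), function(i) {
          reconstruct_junction(fusions[i, , drop = FALSE], genome, genes,
                               k = params$junction_k %||% 20L)
        }, character(1))
        names(jx) <- paste0(fusions$gene5, "-", fusions$gene3)
        emit("junctions.fa", function(p) write_fasta(jx, p))
      }
      report$fusion <- fusions
    })
  }

  if ("copy_number" %in% stages) {
    run_stage("copy_number", inputs$depth_windows %||% "depth_windows", {
      d <- read_headed_tsv(need("depth_windows"),
                           c("chrom", "start", "end", "normal", "tumor"))
      for (col in c("start", "end", "normal", "tumor")) d[[col]] <- as.numeric(d[[col]])
      profile <- compute_log2_ratio(d[c("chrom", "start", "end")],
                                    d$tumor, d$normal)
      segments <- segment_profile(profile,
                                  alpha = params$alpha %||% 0.01,
                                  gain_thresh = params$gain_thresh %||% 0.3,
                                  loss_thresh = params$loss_thresh %||% -0.3)
      emit("segments.tsv", function(p) write_headed_tsv(segments, p))
      emit("segments.bed", function(p) writeLines(segments_to_bed(segments), p))
      profile$call <- segment_window_calls(profile, segments)
      emit("window_calls.tsv", function(p) write_headed_tsv(profile, p))
      report$copy_number <- segments
    })
  }

  if ("spectrum" %in% stages) {
    run_stage("spectrum", inputs$variants %||% "variants", {
      genome <- read_fasta(need("fasta"))
      variants <- read_variant_table(need("variants"))
      capture_mb <- params$capture_mb %||% stop("params$capture_mb is required")
      per_sample <- lapply(split(variants, variants$sample), function(v) {
        sp <- build_spectrum(v, genome, capture_mb,
                             hyper_thresh = params$hyper_thresh %||% 10)
        pr <- npcpg_prominence(sp, prominence_thresh = params$prominence_thresh %||% 0.4)
        list(spectrum = sp, prominence = pr)
      })
      summary <- do.call(rbind, lapply(per_sample, function(s) {
        data.frame(sample = s$spectrum$sample_id,
                   n_snvs = s$spectrum$n_snvs, n_indels = s$spectrum$n_indels,
                   mut_per_mb = s$spectrum$mut_per_mb,
                   hypermutated = s$spectrum$hypermutated,
                   npcpg_score = s$prominence$score %||% NA_real_,
                   npcpg_flagged = s$prominence$flagged %||% NA,
                   stringsAsFactors = FALSE)
      }))
      rownames(summary) <- NULL
      context_long <- do.call(rbind, lapply(per_sample, function(s) {
        a <- s$spectrum$context96
        grid <- expand.grid(class = SUB_CLASSES, five_prime = BASES,
                            three_prime = BASES, stringsAsFactors = FALSE)
        grid$count <- as.integer(a[cbind(grid$class, grid$five_prime, grid$three_prime)])
        grid <- grid[order(grid$class, grid$five_prime, grid$three_prime), ]
        cbind(sample = s$spectrum$sample_id, grid)
      }))
      rownames(context_long) <- NULL
      if (!is.null(variants$gene)) {
        rec <- recurrent_genes(variants, min_cases = params$min_cases %||% 3L)
        emit("recurrent_genes.tsv", function(p) write_headed_tsv(rec$genes, p))
        report$recurrent <- rec
      }
      emit("spectrum_summary.tsv", function(p) write_headed_tsv(summary, p))
      emit("context96.tsv", function(p) write_headed_tsv(context_long, p))
      report$spectrum <- summary
    })
  }

  if ("expression" %in% stages) {
    run_stage("expression", inputs$counts %||% "counts", {
      counts <- read_tsv_matrix(need("counts"))
      gl <- read_headed_tsv(need("gene_lengths"), c("gene", "length"))
      lengths <- setNames(as.numeric(gl$length), gl$gene)[rownames(counts)]
      groups_df <- read_headed_tsv(need("groups"), c("sample", "group"))
      groups <- setNames(groups_df$group, groups_df$sample)[colnames(counts)]
      mat <- rpkm_matrix(counts, lengths)
      emit("rpkm.tsv", function(p) write_tsv_matrix(round(mat, 4L), p))
      cmp <- params$compare
      if (!is.null(cmp)) {
        res <- compare_groups(mat, cmp$gene, groups, cmp$group_a, cmp$group_b)
        report$expression <- res
        emit("expression_comparison.json", function(p) {
          jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
        })
      } else {
        report$expression <- list(rpkm_computed = TRUE)
      }
    })
  }

  if ("genotype" %in% stages) {
    run_stage("genotype", inputs$genotypes %||% "genotypes", {
      individuals <- read_genotype_table(need("genotypes"))
      counts <- genotype_counts(individuals)
      assoc <- genotype_association_report(counts,
                                           monte_carlo = params$monte_carlo %||% 0L)
      assoc$counts <- as.data.frame(counts)
      report$genotype <- assoc
      emit("genotype_association.json", function(p) {
        jsonlite::write_json(assoc, p, auto_unbox = TRUE, digits = NA)
      })
    })
  }

  if ("clinical" %in% stages) {
    run_stage("clinical", inputs$clinical %||% "clinical", {
      records <- read_clinical_table(need("clinical"))
      summary <- summarize_clinical(records)
      summary$counts <- lapply(summary$counts, as.list)
      report$clinical <- summary
      emit("clinical_summary.json", function(p) {
        jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
      })
    })
  }

  manifest <- list(
    stages = as.list(stages),
    files = as.list(tools::md5sum(sort(written))),
    excluded_counts = logs
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
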