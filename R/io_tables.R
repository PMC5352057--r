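#' Read or write a TSV with a '#'-prefixed header line
#'
#' The minimal tabular format shared by every table the pipeline emits:
#' the first line is `#` followed by tab-separated column names, and all
#' fields are read as character (callers coerce).
#'
#' @param path file path.
#' @param required column names that must be present.
#' @return `read_headed_tsv` returns a data.frame of character columns;
#'   `write_headed_tsv` returns `path` invisibly.
#' @export
read_headed_tsv <- function(path, required = character(0)) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- lines[[1L]]
  if (!startsWith(header, "#")) stop("missing '#' header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(text = body, sep = "\t", col.names = cols,
                             stringsAsFactors = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
  }
  missing <- setdiff(required, cols)
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path)
  }
  out
}

#' @rdname read_headed_tsv
#' @param df data.frame to write.
#' @export
write_headed_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
  if (nrow(df) > 0L) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Read a somatic variant table
#'
#' A VCF-like TSV with columns `sample`, `chrom`, `pos`, `ref`, `alt` and
#' optional annotation columns `gene` and `protein_change`. The variant
#' kind (SNV / insertion / deletion) is derived from the allele lengths.
#'
#' @param path TSV file with a `#`-prefixed header line.
#' @param chrom_lengths optional named vector; when given, positions are
#'   validated against it.
#' @return data.frame of variants with a derived `kind` column.
#' @export
read_variant_table <- function(path, chrom_lengths = NULL) {
  df <- read_headed_tsv(path, c("sample", "chrom", "pos", "ref", "alt"))
  df$pos <- as.integer(df$pos)
  if (anyNA(df$pos) || any(df$pos < 1L)) stop("variant position < 1 in ", path)
  if (any(df$ref == df$alt)) stop("ref equals alt in ", path)
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  if (any(snv & !(df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")))) {
    stop("non-ACGT SNV allele in ", path)
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
    if (length(unknown)) stop("unknown chromosome ", paste(unknown, collapse = ", "))
    if (any(df$pos > chrom_lengths[df$chrom])) stop("variant beyond chromosome end")
  }
  df$kind <- variant_kind(df$ref, df$alt)
  df
}

#' Write a somatic variant table
#'
#' @param variants data.frame with at least `sample`, `chrom`, `pos`,
#'   `ref`, `alt`; the derived `kind` column is not written.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  keep <- intersect(c("sample", "chrom", "pos", "ref", "alt", "gene", "protein_change"),
                    colnames(variants))
  write_headed_tsv(variants[, keep, drop = FALSE], path)
}

#' Read gene models from a GTF-like exon table
#'
#' One row per exon: `gene_id`, `chrom`, `strand`, `exon_rank` (1-based in
#' transcription order), `start`, `end`, `phase` (0-2 or `.` for noncoding)
#' and `is_coding`.
#'
#' @param path TSV file with a `#`-prefixed header line.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_table <- function(path) {
  df <- read_headed_tsv(path, c("gene_id", "chrom", "strand", "exon_rank",
                                "start", "end", "phase", "is_coding"))
  df$exon_rank <- as.integer(df$exon_rank)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 1L)) stop("exon coordinate < 1 in ", path)
  genes <- lapply(split(df, df$gene_id), function(d) {
    d <- d[order(d$exon_rank), , drop = FALSE]
    coding <- identical(unique(d$is_coding), "TRUE")
    gene_model(
      gene_id = d$gene_id[[1L]], chrom = d$chrom[[1L]], strand = d$strand[[1L]],
      exons = cbind(d$start, d$end),
      phase = if (coding) as.integer(d$phase) else NULL,
      is_coding = coding
    )
  })
  genes[order(names(genes))]
}

#' Write gene models as a GTF-like exon table
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      exon_rank = seq_len(nrow(g$exons)),
      start = g$exons[, "start"], end = g$exons[, "end"],
      phase = if (g$is_coding) as.character(g$phase) else ".",
      is_coding = as.character(g$is_coding),
      stringsAsFactors = FALSE
    )
  })
  write_headed_tsv(do.call(rbind, rows), path)
}

#' Read a gene-by-sample numeric matrix
#'
#' @param path TSV whose `#`-prefixed header holds `gene` plus sample names.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- read_headed_tsv(path, "gene")
  m <- as.matrix(df[, setdiff(colnames(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  m
}

#' Write a gene-by-sample numeric matrix
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_headed_tsv(df, path)
}

#' Read a clinical cohort table
#'
#' Columns mirror a surgical chordoma series: `patient_no`, `age`,
#' `gender` (M/F), `subtype`, `location`, `extent` (GTR/STR), `status`
#' (Primary/Recurrence), `radiation` (Y/N/ND) and `survival`.
#'
#' @param path TSV file with a `#`-prefixed header line.
#' @return data.frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  df <- read_headed_tsv(path, c("patient_no", "age", "gender", "subtype",
                                "location", "extent", "status", "radiation",
                                "survival"))
  df$patient_no <- as.integer(df$patient_no)
  df$age <- as.numeric(df$age)
  bad_extent <- setdiff(unique(df$extent), c("GTR", "STR"))
  if (length(bad_extent)) stop("unknown resection extent: ", paste(bad_extent, collapse = ", "))
  df
}

#' @rdname read_clinical_table
#' @param records data.frame of clinical records.
#' @export
write_clinical_table <- function(records, path) {
  write_headed_tsv(records, path)
}

#' Read a per-individual genotype table
#'
#' @param path TSV with columns `sample_id`, `group`, `genotype`
#'   (e.g. `G/G`, `G/A`, `A/A`).
#' @return data.frame of individuals.
#' @export
read_genotype_table <- function(path) {
  read_headed_tsv(path, c("sample_id", "group", "genotype"))
}

#' @rdname read_genotype_table
#' @param individuals data.frame of individuals.
#' @export
write_genotype_table <- function(individuals, path) {
  write_headed_tsv(individuals, path)
}
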