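#' Path to the bundled clinical table of the skull base chordoma series
#'
#' Ten surgical patients with age, gender, histologic subtype, tumor
#' location, extent of resection (GTR/STR), primary/recurrence status,
#' postoperative radiation and survival status.
#'
#' @return file path to the TSV.
#' @export
clinical_cohort_path <- function() {
  system.file("extdata", "clinical_cohort.tsv", package = "chordomics",
              mustWork = TRUE)
}

#' Summarize a clinical cohort table
#'
#' Mean age (one decimal), age range, and counts of every level of the
#' categorical columns. Records lacking an age are excluded from the age
#' statistics with a warning.
#'
#' @param records data.frame from [read_clinical_table()].
#' @return list with `n`, `mean_age`, `age_range`, and per-column level
#'   counts under `counts`.
#' @export
summarize_clinical <- function(records) {
  if (nrow(records) == 0L) stop("no clinical records")
  ages <- records$age
  if (anyNA(ages)) {
    warning("excluding ", sum(is.na(ages)), " record(s) with missing age")
    ages <- ages[!is.na(ages)]
  }
  counts <- lapply(c("gender", "subtype", "extent", "status", "radiation"),
                   function(col) table(records[[col]]))
  names(counts) <- c("gender", "subtype", "extent", "status", "radiation")
  list(n = nrow(records),
       mean_age = round(mean(ages), 1L),
       age_range = range(ages),
       counts = counts)
}
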