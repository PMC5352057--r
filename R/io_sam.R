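#' Read paired-end alignments from SAM text ("SAM-lite")
#'
#' Consumes the standard SAM columns QNAME, FLAG, RNAME, POS plus the
#' aligned length (taken from SEQ when present, otherwise from the summed
#' `M`/`=`/`X` operations of the CIGAR), which is all the fusion filter
#' needs; SAM text exported from real BAM files therefore also parses.
#' Records are paired by QNAME, using FLAG bit 0x40 (first of pair) to
#' orient mates when set. Records whose QNAME occurs a number of times
#' other than two are dropped with a logged count.
#'
#' @param path SAM text file; `@`-prefixed header lines are skipped.
#' @return data.frame of read pairs with columns `pair_id`, `chrom1`,
#'   `start1`, `strand1`, `len1`, `chrom2`, `start2`, `strand2`, `len2`,
#'   plus an attribute `n_dropped` with the unpaired-record count.
#' @export
read_sam_lite <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "@") & nzchar(lines)
  body <- lines[keep]
  line_no <- which(keep)
  empty <- data.frame(
    pair_id = character(0),
    chrom1 = character(0), start1 = integer(0), strand1 = character(0), len1 = integer(0),
    chrom2 = character(0), start2 = integer(0), strand2 = character(0), len2 = integer(0),
    stringsAsFactors = FALSE
  )
  if (length(body) == 0L) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 4L)) {
    stop("SAM record with fewer than 4 columns at line ", line_no[which(nfield < 4L)[1L]])
  }
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag_raw <- vapply(fields, `[[`, character(1), 2L)
  flag <- suppressWarnings(as.integer(flag_raw))
  if (anyNA(flag)) {
    bad <- which(is.na(flag))[1L]
    stop("malformed FLAG '", flag_raw[bad], "' at line ", line_no[bad])
  }
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- which(is.na(pos) | pos < 1L)[1L]
    stop("malformed POS at line ", line_no[bad])
  }
  alen <- integer(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    seq_field <- if (length(f) >= 10L) f[[10L]] else "*"
    if (seq_field != "*") {
      alen[i] <- nchar(seq_field)
    } else {
      cigar <- if (length(f) >= 6L) f[[6L]] else "*"
      m <- gregexpr("(\\d+)[M=X]", cigar)[[1L]]
      if (m[1L] == -1L) stop("cannot determine aligned length at line ", line_no[i])
      ops <- regmatches(cigar, gregexpr("(\\d+)[M=X]", cigar))[[1L]]
      alen[i] <- sum(as.integer(sub("[M=X]$", "", ops)))
    }
  }
  if (any(alen < 1L)) stop("aligned length < 1 at line ", line_no[which(alen < 1L)[1L]])
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  first_of_pair <- bitwAnd(flag, 64L) > 0L

  tab <- table(qname)
  paired <- names(tab)[tab == 2L]
  n_dropped <- as.integer(sum(tab[tab != 2L]))
  if (n_dropped > 0L) {
    message("read_sam_lite: dropped ", n_dropped, " record(s) without exactly one mate")
  }
  if (length(paired) == 0L) {
    attr(empty, "n_dropped") <- n_dropped
    return(empty)
  }
  idx <- split(seq_along(qname), qname)[paired]
  rows <- lapply(idx, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    # orient by the first-of-pair flag when it distinguishes the mates
    if (!first_of_pair[i] && first_of_pair[j]) { tmp <- i; i <- j; j <- tmp }
    list(qname[i], rname[i], pos[i], strand[i], alen[i],
         rname[j], pos[j], strand[j], alen[j])
  })
  out <- data.frame(
    pair_id = vapply(rows, `[[`, character(1), 1L),
    chrom1 = vapply(rows, `[[`, character(1), 2L),
    start1 = vapply(rows, function(r) as.integer(r[[3L]]), integer(1)),
    strand1 = vapply(rows, `[[`, character(1), 4L),
    len1 = vapply(rows, function(r) as.integer(r[[5L]]), integer(1)),
    chrom2 = vapply(rows, `[[`, character(1), 6L),
    start2 = vapply(rows, function(r) as.integer(r[[7L]]), integer(1)),
    strand2 = vapply(rows, `[[`, character(1), 8L),
    len2 = vapply(rows, function(r) as.integer(r[[9L]]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write paired-end alignments as SAM text
#'
#' Inverse of [read_sam_lite()]: each pair becomes two records with FLAG
#' bits for paired (0x1), first/second of pair (0x40/0x80) and reverse
#' strand (0x10). CIGAR is `<len>M` and SEQ/QUAL are `*`.
#'
#' @param pairs data.frame in the layout returned by [read_sam_lite()].
#' @param path output file.
#' @param chrom_lengths optional named lengths for `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam_lite <- function(pairs, path, chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  }
  if (nrow(pairs) > 0L) {
    flag1 <- 1L + 64L + ifelse(pairs$strand1 == "-", 16L, 0L)
    flag2 <- 1L + 128L + ifelse(pairs$strand2 == "-", 16L, 0L)
    rec <- function(flag, chrom, pos, len) {
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
              pairs$pair_id, flag, chrom, as.integer(pos), as.integer(len))
    }
    lines <- character(2L * nrow(pairs))
    lines[c(TRUE, FALSE)] <- rec(flag1, pairs$chrom1, pairs$start1, pairs$len1)
    lines[c(FALSE, TRUE)] <- rec(flag2, pairs$chrom2, pairs$start2, pairs$len2)
    writeLines(lines, con)
  }
  invisible(path)
}
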