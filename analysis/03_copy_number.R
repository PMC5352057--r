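#!/usr/bin/env Rscript

# Exome copy-number profiling: log2 tumor/reference ratios on the
# simulated depth windows, binary segmentation, per-window calls and the
# pseudo-normal comparison.

suppressPackageStartupMessages(library(chordomics))

cohort <- "results/cohort"
out <- "results/copy_number"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- read_headed_tsv(file.path(cohort, "depth_windows.tsv"),
                     c("chrom", "start", "end", "normal", "tumor"))
for (col in c("start", "end", "normal", "tumor")) d[[col]] <- as.numeric(d[[col]])

profile <- compute_log2_ratio(d[c("chrom", "start", "end")], d$tumor, d$normal)
segments <- segment_profile(profile)
write_headed_tsv(segments, file.path(out, "segments.tsv"))
writeLines(segments_to_bed(segments), file.path(out, "segments.bed"))

profile$call <- segment_window_calls(profile, segments)
write_headed_tsv(profile, file.path(out, "window_calls.tsv"))

by_call <- table(profile$call)
message("windows: ", paste(names(by_call), by_call, sep = "=", collapse = ", "))
arm_key <- paste0(d$chrom, d$arm)
for (call in c("gain", "loss")) {
  frac <- tapply(profile$call == call, arm_key, mean)
  message(call, " arms: ", paste(sort(names(frac)[frac > 0.5]), collapse = ", "))
}

# cohort-level frequency over simulated samples sharing the lesion pattern
lens <- default_cna_chrom_lengths()
cna <- default_cna_spec()
calls_all <- do.call(rbind, lapply(1:8, function(s) {
  ds <- simulate_depth_profiles(cna, lens, n_windows = 1000L,
                                seed = child_seed(20160L, 700L + s))
  p <- compute_log2_ratio(ds[c("chrom", "start", "end")], ds$tumor, ds$normal)
  data.frame(sample = paste0("T", s),
             locus = paste(ds$chrom, ds$arm, sep = "_"),
             call = segment_window_calls(p, segment_profile(p)),
             stringsAsFactors = FALSE)
}))
freq <- cohort_frequency(calls_all)
write_headed_tsv(freq, file.path(out, "cohort_frequency.tsv"))
top <- freq[order(-(freq$n_gain + freq$n_loss)), ]
message("most altered loci across 8 samples:")
print(utils::head(top, 8))
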