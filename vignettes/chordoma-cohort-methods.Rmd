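---
title: "Methods: profiling a skull base chordoma cohort with chordomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling a skull base chordoma cohort with chordomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chordomics)
```

## Scope

Skull base chordoma is a rare, locally destructive bone tumor arising from
notochordal remnants. A cohort-level molecular characterization of this
disease rests on a handful of computational stages: discovery of expressed
gene fusions from paired-end RNA alignments, exome copy-number profiling
against matched or pseudo-normal references, somatic mutation spectrum
analysis, RPKM expression comparison across tumor groups, and a
case-control association test for the brachyury (*T* gene) rs2305089 risk
genotype. `chordomics` implements each stage as a tested, reusable module
and pairs them with a deterministic synthetic-cohort generator, so every
claim the pipeline makes can be checked against injected ground truth
without access to patient sequence data.

This vignette documents the models and procedures, the parameters that
matter, the design decisions taken where the methods were genuinely open,
and what the synthetic validation does and does not demonstrate.

## Fusion discovery from paired-end alignments

A read pair supports a fusion under two criteria, applied in order:

1. **Discordant gene pair** — the two mates overlap two distinct annotated
   genes. Candidate gene pairs must collect at least `min_support` such
   pairs (default 2; a single discordant pair is indistinguishable from a
   chimeric library artifact).
2. **Intronic breakpoint support** — at least one mate lies wholly within
   an intron of a gene already implicated by criterion 1. This captures
   fragments from the fused transcript's retained intronic sequence around
   the genomic breakpoint.

Mates overlapping two nested or overlapping genes count for both genes.

**Breakpoint inference** works on the per-nucleotide coverage of the
*supporting* mates, built over each implicated gene plus a flank. The
estimator has two stages:

- *Stage 1 (localization):* over candidate split positions — intron
  intervals widened by `flank` (default 100 bp) into neighboring exons —
  choose the boundary maximizing the absolute difference between the mean
  coverage left and right of the split. Ties go to the leftmost position.
  A pure global mean-difference argmax systematically drifts into the
  read-length ramp that flanks any finite-read step (the marginal gain of
  excluding a ramp base depends on the track-length ratio of the two
  sides), so stage 1 is treated as approximate localization only.
- *Stage 2 (refinement):* supporting coverage vanishes beyond the real
  junction, so the base-exact boundary is the coverage edge — the last
  covered base followed by a sustained (>= one read length) zero run for
  the donor-side drop, or the first covered base after such a run for the
  acceptor-side rise. The covered side of the search is limited to
  `refine_radius` (default 350 bp, about one fragment length) around the
  stage-1 optimum; the zero side is unbounded because the step's silent
  side extends indefinitely. Junction-spanning reads — represented as
  split alignments clipped exactly at the breakpoints, as an aligner
  reports them — stack their ends on the true junction base and make the
  refinement exact.

A changepoint is only reported when its **local step height** (mean
difference in 200-bp windows flanking the split) exceeds `min_delta`,
which defaults to five times the median residual coverage on the low side
of the split, floored at one read. The step height is measured locally
because the global split statistic dilutes a sharp step by the length of
the track.

The donor/acceptor orientation of a candidate follows the direction of
the coverage change (donor genes drop at their breakpoint, acceptors
rise); the reading frame is called in-frame when the donor's CDS length
up to the 5' breakpoint is congruent modulo 3 with the codon phase of the
acceptor exon at the 3' breakpoint (intronic acceptor breakpoints defer
to the next downstream exon, as splicing would). Junction sequences are
reconstructed as *k* donor bases plus *k* acceptor bases in transcript
orientation, reverse-complemented on minus-strand sides.

No candidate is ever emitted from coverage alone: criterion-1 pairs are a
precondition.

## Copy-number profiling

Windowed tumor-versus-reference profiles emulate aCGH from exome depth:

- **Windows** hold a fixed count of reference reads (default 1000), so
  window width adapts to capture density; boundaries never cross
  chromosomes.
- **Pseudo-normal reference**: when no matched normal exists, the
  per-window median of library-size-normalized counts across the
  available normals, rescaled to the mean library size. With a single
  normal this reduces exactly to that normal.
- **Log2 ratio**: counts are converted to counts-per-million within each
  profile, floored by an offset (default 0.5) and log2-ratioed; the CPM
  scale makes the ratio exactly invariant to joint library-size changes.
  Profiles are median-centered, which assumes a majority-neutral genome —
  an assumption documented rather than enforced, and the reason the
  synthetic copy-number universe spreads its altered arms over a minority
  of 22 arms.
- **Segmentation** is a simplified circular-binary-segmentation variant:
  within each chromosome the split maximizing the pooled two-sample *t*
  statistic is accepted when its permutation p-value (within-segment
  shuffles, `nperm = 100`, fixed seed 13) falls below `alpha = 0.01`,
  then recursion continues on both sides; adjacent segments with mean
  difference below `min_gap = 0.1` are merged. Segment means equal the
  mean of their member windows exactly, and noiseless steps are split at
  the exact boundary (a zero-variance split yields an infinite statistic
  that no permutation can match).
- **Calls** use conventional log2 thresholds, gain >= +0.3 and loss <=
  -0.3. A gene takes the call of the segment containing its midpoint;
  genes spanning a boundary take the length-weighted mean of the
  overlapping segment means.

## Mutation spectra

Substitutions are collapsed onto the six pyrimidine-strand classes
(C>A, C>G, C>T, T>A, T>C, T>G); purine-reference events complement both
alleles and swap the flanks, so every trinucleotide context is reported
on the pyrimidine strand (5' base indexing the rows of each per-class
4 x 4 grid). Variants at chromosome boundaries or with ambiguous bases in
their trinucleotide are excluded with a logged count; a reference
mismatch is an error, never an exclusion. The context matrix marginals
equal the six-class totals by construction, and the whole spectrum is
invariant under a strand flip of the genome (a property the tests check
by rebuilding spectra on the reverse-complemented reference).

Burden is `(n_SNVs + n_indels) / capture_mb` — indels count toward burden
but not toward the context matrix — with an SNV-only rate reported
alongside, since published "mutations per Mb" figures are sometimes one
and sometimes the other. Samples above `hyper_thresh = 10` mut/Mb are
marked hypermutated (the conventional exome cutoff; no specific value is
established for chordoma).

**NpCpG C>T prominence** scores the fraction of C>T events whose 3'
neighbor is G — the deamination signature of 5-methyl-cytosine at CpG
dinucleotides. Under a uniform context distribution the score expectation
is 0.25; under the generator's enrichment model (40% of C>T events placed
at CpG sites, the remainder at random C sites) it is 0.55. The default
flag threshold of 0.4 is the midpoint of those two regimes, chosen so
that both false positives and false negatives sit more than 2.5 standard
errors away once a sample carries on the order of 50-70 C>T events. At a
2 mut/Mb exome burden a sample contributes only ~7 C>T events and the
per-sample flag is frankly underpowered — the validation studies
therefore use genome-scale mutation counts (rate 20/Mb over the 10 Mb
synthetic genome, about 70 C>T per sample), and per-sample flags on
exome-scale burdens should be read as suggestive only. Samples with fewer
than `min_snvs = 10` SNVs return an indeterminate (NA) flag rather than a
guess.

**Recurrence** keeps genes mutated in at least `min_cases` distinct
samples (default 3 — the figure-legend phrase "at least in more than
three cases" is self-contradictory, and the published gene list contains
three-case genes, fixing the reading at >= 3). Identical-change
recurrence (same gene, position and alleles across samples — the shared
hotspot pattern) is tallied separately.

## Expression

RPKM is the classical `1e9 * count / (library_size * gene_length)`, with
gene length the union of exon intervals (not transcript-specific — a
documented simplification). Group comparisons use the Wilcoxon rank-sum
test on log2(RPKM + 1): exact enumeration when both groups have at most
10 untied samples, otherwise the midrank normal approximation without
continuity correction (identical groups give p = 1; fully degenerate
input returns p = 1 directly). A rank test is the defensible choice at
the 4-8 samples per group this design provides, and it makes the
comparison invariant under any monotone transform. The fusion-positive
versus fusion-negative check reports group means and fold change, and
attaches the rank test only when both partitions have at least two
samples — with a single negative sample (the cohort's actual 4-versus-1
split) the report is explicitly flagged descriptive-only.

## Genotype association

The rs2305089 case-control table is tested with plain Pearson chi-squared:
`sum((O - E)^2 / E)` with margin-derived expectations,
`df = (r - 1)(c - 1)`, upper-tail p, no continuity correction (Yates
applies to 2 x 2 tables only). Zero-margin rows or columns are dropped
with a warning. Because a small case group leaves expected counts near 1,
the function warns below an expectation of 5 and can attach a fixed-seed
Monte-Carlo p-value from margin-conditioned tables (`stats::r2dtable`);
the headline number remains the asymptotic one, which truncates to the
two-significant-figure value the association is known by. The Monte-Carlo
p (~0.005) and the asymptotic p (~0.0039) differ by more than simulation
error — exactly the small-expected-count caveat the warning announces —
but agree on the scale of the association.

Two distinct frequencies are computed and deliberately never conflated:
the **carrier frequency** (fraction of individuals with at least one risk
allele; 7/8 = 87.5% in cases, 39/75 = 52% in controls) and the **allele
frequency** ((het + 2 hom)/2n; 11/16 = 68.75% in cases). Published
discussions sometimes quote the carrier figure as an "allele frequency";
the package reports both under their correct names.

## The synthetic cohort

The generator is the test bed for every stage, and its defaults *are* the
study conditions:

- **Genome**: 5 chromosomes x 2 Mb of uniform random sequence, 8 genes.
  The fusion partner genes sit 77,200 bp apart — a 1:10 scaling of the
  772 kb separating the real 6q24 partners. Real-genome scale is a
  parameter change.
- **Reads**: 2 x 101 bp pairs, fragment size 250 +/- 30 bp. Background
  fragments are drawn from spliced transcripts (introns carry essentially
  no background, as in RNA-seq); fusion-positive samples draw a fraction
  `expression_level` (default 0.4 of the fragments over the annotated
  gene set) from the fused transcript, reflecting a strongly expressed
  fusion. The genomic donor breakpoint lies in the donor's first intron —
  a retained-intron junction, so criterion-2 intronic mates exist — and
  the acceptor breakpoint is the first base of its second exon. Exon
  lengths make the donor's CDS contribution a multiple of three against a
  phase-0 acceptor exon: the injected fusion is in frame.
- **Depth**: negative-binomial counts (dispersion 0.05; Poisson
  undershoots exome depth variance) around 1.5x / 0.5x / 1.0x of the mean
  for gained / lost / neutral arms, over an 11-chromosome universe whose
  8 altered arms mirror the recurrent chordoma lesions (1p loss,
  whole-chromosome 10/13-like losses, chromosome-7-like gain, 17q-like
  gain) while leaving the genome majority-neutral.
- **Variants**: Poisson burden at 2.1 mut/Mb by default, 5% indels, a
  6-class signature dominated by C>T, T>C and C>A, and per-sample NpCpG
  C>T enrichment for a designated subset (four of eight exome samples,
  as observed).
- **Genotypes**: multinomial draws per group; the observed case-control
  table (1/3/4 vs 36/32/7) ships as a constant.
- Every simulator output is fully determined by its seed; derived seeds
  stay below 2^31.

**What passing tests show — and what they do not.** The synthetic data
have uniform base composition, no sequencing errors or quality scores, no
alignment ambiguity, no GC or mappability bias, no tumor purity or
subclonality, and breakpoints placed where the generative model says they
are. Recovery results (fusion recovery and base-exact breakpoints, >= 95%
arm-sign recovery, NpCpG flag concordance) therefore validate the
*inference machinery* against its own generative assumptions; they do not
certify performance on real sequencing data, where alignment artifacts
and coverage biases dominate the error budget.

## Problem sizes and numerical choices

The validation studies run at: 100 fusion replicates of 400 pairs (plus
10 deep replicates of 1200 pairs for base-exact breakpoints), 100
copy-number replicates of 1000 windows, 500 spectrum replicates of ~200
variants on the 10 Mb genome, and 100,000 Monte-Carlo tables for the
association p-value — sizes at which the binomial error of each estimated
proportion is comfortably below the margins being asserted. Permutation
segmentation uses a fixed seed (13) so profiles segment identically on
every run; all other randomness flows from user-supplied seeds through a
deterministic child-seed stream.

Degenerate inputs are handled explicitly rather than incidentally: flat
coverage tracks return a no-breakpoint result distinct from errors;
zero-variance segments split only on exact steps; empty variant tables
yield all-zero spectra with burden 0; empty genotype groups and
zero-margin tables are errors and warnings respectively.

## Known limitations

- The fusion caller models intrachromosomal, same-strand fusions (the
  configuration observed in this disease); interchromosomal events are
  carried in the data model but not simulated.
- Median-centered copy-number profiles mis-calibrate on majority-altered
  genomes; no purity or ploidy correction is attempted.
- RPKM is the only expression normalization offered, matching the
  original analysis; no dispersion modeling or differential-expression
  machinery is included.
- Survival analysis is out of scope (the underlying cohort reported no
  significant survival differences and published no data to implement
  against).
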