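---
title: "Quality-control methods for CUT&RUN data with cnrqc"
author: "cnrqc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-control methods for CUT&RUN data with cnrqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cnrqc collects the quality-control evidence a CUT&RUN (or ChIP-seq/ATAC-seq)
analyst needs before trusting a dataset: is the library enriched (FRiP), do
replicates agree (peak overlap, binned correlations), does the fragment
structure look like a real library (strand cross-correlation), and which
called regions are background artifacts (IgG-dominated signal clusters,
phantom-peak regions)? This vignette explains each computation, its
assumptions, the tunable parameters, and the design decisions taken where
the choices were genuinely open.

## Coordinate system and peak formats

All user-facing coordinates are 0-based half-open (the BED convention), the
native system of every supported peak format. BAM positions (1-based) are
converted on read. Three peak dialects are parsed into one uniform record
schema: ENCODE narrowPeak (10 columns, with a summit offset), broadPeak
(9 columns, no summit, `summit_offset = -1`), and SEACR bed (6 columns).
SEACR emits no p- or q-values; both are stored as -1, the narrowPeak
missing-value convention, and the q-value filter passes such records through
with a warning rather than silently discarding an entire caller's output.
The q-value filter keeps records with `q_value >= min_q` on the -log10
scale (larger means more significant); the pipeline default `min_q = 2`
(q <= 0.01) is a conventional reporting threshold and only affects the
`peak_count_after_qfilter` column, not the consensus set.

Merging treats intervals that touch end-to-start as one region, so consensus
regions never contain zero-gap splits. Strand is preserved on parse but
ignored by all overlap operations, since peak calls are unstranded in
practice. Interval algebra is delegated to GenomicRanges/IRanges; the test
suite checks it against an independent per-base sweep oracle.

## Consensus peaks and overlap summaries

The consensus set is the merged union of all samples' peaks; a sample is a
member of a region when at least one of its peaks overlaps it by >= 1 bp.
One base of overlap is the simplest deterministic rule and matches how
overlapping peak sets are usually summarized; a reciprocal-fraction
requirement can be imposed via the `min_overlap` parameter. Peaks are
overlapped at their raw coordinates — resizing to fixed width first is
available but not the default, because width standardization belongs to the
signal heatmap, not to the question "did both replicates call this region".
From the membership matrix the package derives upset-style combination
counts (any number of sets), venn counts (capped at three sets, beyond which
venn diagrams are not well defined), pairwise Jaccard indices, and a
binary-heatmap row order (patterns sorted by descending frequency, ties by
pattern string, original coordinate order within a pattern).

## Read counting and FRiP

All BAM-derived metrics share one filtering policy: primary, mapped
alignments with MAPQ >= 20, duplicates excluded. These are conventional QC
filters, configurable per run (`mapq_min`, `dedup`). FRiP is the fraction
of those reads whose aligned span overlaps any peak by >= 1 bp. The
counting unit is reads, not fragments: paired mates count individually in
both numerator and denominator, which keeps the metric literally "fraction
of reads" and makes it insensitive to single/paired library differences in
the denominator definition. FRiP is undefined (an error, reported as NA
with a reason in the CSV) when a sample has no mapped reads.

Genome-wide replicate concordance uses read counts in 10 kb bins (assigned
by the read's 5' position; half-open bins). Pearson correlation is computed
on log1p counts by default because raw bin counts are heavy-tailed and a
handful of deep bins would otherwise dominate; `transform = "raw"` is
available. Bins where both samples are zero are retained — dropping them
would inflate correlations on sparse genomes.

## RPM signal matrices

Signal over consensus regions is computed on fixed-width windows
(default 2,000 bp, 50 bins of 40 bp, centered on each consensus region) as
mean per-base fragment coverage per bin, scaled to reads per million
(1e6 / mapped reads). Paired templates contribute their full mate-to-mate
span; single-end reads are extended from their 5' end to the fragment
length estimated by the SCC module for that sample. Windows that run off a
chromosome end are zero-filled with a warning. bigWig tracks are accepted
as a pre-computed alternative and used as-is (tagged `raw` unless declared
normalized). The 2,000 bp / 50 bin default shows a nucleosome-scale signal
shape around typical TF and histone-mark peaks; both are configurable.

## Strand cross-correlation

For each region the 5' ends of plus- and minus-strand reads are tallied
per base (plus reads at their leftmost aligned base, minus reads at their
rightmost). The SCC curve is the Pearson correlation between the plus
profile and the minus profile slid toward it by k = 0..`max_shift` bp.
Numerical conventions:

* a shift of k superimposes 5' ends that span k + 1 bases, so the curve is
  indexed in fragment-length units as length = shift + 1 throughout: a
  library with every fragment exactly 180 bp puts its maximum at reported
  length 180, and the phantom peak of a read duplicated on both strands
  over the same span sits at the read length;
* slices with zero variance yield correlation 0 (not NaN), keeping averages
  defined over sparse regions;
* curves are computed per region and then averaged (uniformly by default,
  optionally weighted by read count), not on genome-wide concatenated
  vectors — the per-region curves are what the artifact filter needs;
* `max_shift` defaults to min(region width - 1, 500) bp because CUT&RUN
  libraries are size-selected below ~500 bp.

The fragment length is the argmax of the averaged curve after excluding the
window read length ± `exclusion_halfwidth` (default 10 bp), which removes
the phantom peak; ties break toward the larger shift so a flat curve
degenerates predictably. The per-dataset scalar reported as `scc_score` is
the averaged curve's correlation at the estimated fragment length. Regions
whose own correlation at the read length exceeds `artifact_threshold`
(default 0.9) are flagged as likely mapping artifacts; the per-region table
also carries the correlation at the fragment length, backing the standard
fragment-vs-read-length scatter.

On the synthetic fixtures used in the tests (uniform placement inside
400 bp peaks), the windowed per-region estimate carries a small upward skew
of ~2–7 bp relative to the true mean fragment length: the cross-fragment
term of the correlation is not perfectly symmetric when start positions are
confined to the peak body. The test tolerance (±10 bp) reflects that
property of windowed SCC, not measurement noise alone.

## Clustering and IgG artifact flagging

Each consensus region is described by the concatenation of all samples'
bin vectors and clustered with k-means (k = 6 by default, Euclidean
distance on RPM values, Lloyd's algorithm, 10 random restarts keeping the
lowest within-cluster sum of squares, fixed seed). If Lloyd abandons a
restart on an empty cluster the run falls back to Hartigan–Wong under the
same seed. Row scaling is off by default — absolute RPM differences between
samples are exactly what the IgG comparison needs — with optional per-row
max scaling for shape-based clustering. Clusters are relabeled by
descending mean signal, so cluster 1 is always the strongest-signal
cluster and labels are stable under sample column permutation; rows are
ordered by cluster, then descending region mean, giving a deterministic
heatmap layout.

A cluster is flagged as IgG-dominated when its mean RPM over IgG control
samples is at least `flag_ratio` (default 1.0) times its mean over target
samples and the IgG mean is non-zero. The ratio 1.0 encodes "the control
shows as much signal as the experiment"; it is deliberately explicit and
configurable because no universal cutoff exists. Regions of flagged
clusters are removed from `consensus_filtered.bed`. IgG samples are
declared via an `is_igg` config column or recognized by "igg" in the
sample id. With small k forced onto richer structure, or very shallow
fixtures, more than one cluster can exceed the ratio; the per-cluster
means are always written so the call can be audited.

## The synthetic-data generator

Every test runs on synthetic data with exact ground truth. The generator
emulates the statistical structure the QC metrics assume: fragments of
truncated-normal length (default mean 180 bp, sd 30 bp, floor of twice the
50 bp read length — nucleosomal CUT&RUN scale) are placed inside true peaks
with probability `frip_target` (peak choice weighted by per-peak
enrichment, position uniform within the peak, over-long fragments centered)
and uniformly on the background otherwise. Each fragment emits a
plus-strand read at its left end and, when paired, a minus-strand mate at
its right end; reads are written as SAM and converted to a coordinate-
sorted, indexed BAM with correct flags, TLEN and MAPQ 60. Duplicates are
emitted as flagged copies at a configurable rate. The recorded truth
(realized FRiP, per-peak counts, fragment lengths) uses the same per-read
counting rules as the metrics, so generator truth and computed FRiP agree
exactly — the master cross-module consistency check.

The archetype bundle adds cluster structure: two target replicates and one
IgG control over three region classes — `shared` (both replicates),
`sample1_only` (first replicate only) and `igg_high` (all samples, strongest
in IgG, the background/artifact archetype). Because the IgG sample
concentrates its in-peak mass on few regions, the igg_high block has the
highest mean RPM, lands in cluster 1 after relabeling, and is flagged by
the ratio rule, reproducing the expected analysis outcome end to end.

What the generator does **not** emulate: sequence content and base
qualities, mappability structure, GC bias, chimeric or clipped alignments,
spike-in genomes, and peak-shape heterogeneity beyond per-peak enrichment
multipliers. Passing tests therefore demonstrate correctness of the
computations and their conventions on well-formed alignments, not
robustness to every pathology of real sequencing data.

## Problem sizes and determinism

The test and acceptance workloads are sized for a laptop-class machine:
mini-genomes of 0.1–1 Mb, 2,000–125,000 fragments per sample, 36–200
regions, 20-seed replication for the fragment-length recovery property.
The full pipeline is deterministic given (inputs, parameters, seed): the
k-means seed is part of the configuration, all simulation seeds are
explicit, and repeated runs — cold or through the content-addressed result
cache (MD5 of operation, input file signatures and parameters) — produce
byte-identical CSV outputs.

## Known limitations

* Fragment-length estimation needs bidirectional coverage inside the
  analysis windows; single-end libraries with strongly skewed strand
  composition in small regions yield noisy estimates (reported per sample,
  never silently reused across samples).
* The E. coli spike-in fraction is exposed only as an optional second-BAM
  read-count ratio, not modeled.
* Statistical significance of peak overlap (permutation testing) is out of
  scope; the exported membership tables are designed to feed such tools.
* Euler/venn *areas* are not computed, only the combination counts a
  plotting layer needs.
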