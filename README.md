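# cnrqc — quality control for CUT&RUN and related enrichment assays

CUT&RUN, ChIP-seq and ATAC-seq experiments stand or fall on questions that
no single number answers: is the library enriched at all, do replicates
agree, does the fragment structure look like a real nuclease-released
library, and which of the called peaks are background artifacts rather than
specific binding? `cnrqc` computes the standard evidence for each of these
questions from coordinate-sorted BAM files and peak calls (ENCODE
narrowPeak, broadPeak, or SEACR bed), and writes a per-sample CSV report
plus plot-ready tables. It is aimed at analysts validating fresh vs frozen
material, antibody lots, or replicate batches before committing to
downstream analysis.

## What it computes

* **FRiP** — fraction of reads in peaks,
  `FRiP = |{reads overlapping any peak by ≥ 1 bp}| / |mapped reads|`,
  under one shared filtering policy (primary, mapped, MAPQ ≥ 20,
  duplicates removed). ENCODE's working guideline is FRiP > 0.1.
* **Consensus peak overlap** — merged union regions with a boolean
  membership matrix (region × sample), upset/venn combination counts,
  pairwise Jaccard, and a binary-heatmap row ordering.
* **Replicate concordance** — Pearson correlation of (log1p) read counts
  in 10 kb genomic bins.
* **RPM signal matrices** — reads-per-million fragment coverage
  (`1e6 / mapped reads` scaling) in 50 bins over 2 kb windows centered on
  consensus regions, clustered with k-means (k = 6 by default, relabeled
  so cluster 1 carries the strongest signal). Clusters whose mean IgG
  control signal reaches the target mean are flagged as artifacts and
  removed from a filtered consensus BED.
* **Strand cross-correlation (SCC)** — per-region correlation between
  plus- and minus-strand 5′-end profiles at progressive strand shifts.
  The averaged curve's maximum (excluding the phantom window at the read
  length) estimates the mean fragment length; regions with correlation
  > 0.9 at the read length are flagged as likely mapping artifacts.

A fully synthetic fixture generator (mini-genome, ground-truth peaks,
pre-aligned reads with controlled fragment length, enrichment, duplication
and IgG-like background) makes every metric testable without downloads.

## Worked example

Generate a three-sample synthetic bundle (two target replicates plus an
IgG control over shared / replicate-specific / IgG-dominated region
classes) and run the full pipeline:

```r
library(cnrqc)
dir <- file.path(tempdir(), "cnrqc_demo")
bundle <- make_cluster_archetypes(dir, n_regions_per_archetype = 12,
                                  n_fragments = 30000, seed = 1)
res <- run_qc(bundle$config, out_dir = file.path(dir, "qc"), quiet = TRUE)
print(res)
#> qc_run: 3 samples, 36 consensus regions, 3 flagged cluster(s)
#>   sample_id mapped_reads peak_count      frip fragment_length_estimate
#> 1      rep1        60000         36 0.7369833                      183
#> 2      rep2        60000         24 0.7269333                      188
#> 3       igg        60000         12 0.5225000                      193
#>   scc_score
#> 1 0.6218276
#> 2 0.4841843
#> 3 0.2697387
```

Each replicate maps 60,000 reads (30,000 paired fragments); rep1 calls all
36 regions, rep2 the 24 shared + IgG-dominated ones, the IgG control only
its 12 background regions. FRiP is high by construction, and the SCC
fragment-length estimates (183–193 bp) recover the generator's 180 bp
library within the expected windowed-SCC tolerance. The per-cluster IgG
table shows why three of the six k-means clusters were flagged:

```r
print(res$cluster_flags)
#>   cluster n_regions  mean_igg mean_target flagged
#> 1       1         5 2240.5817   1317.0467    TRUE
#> 2       2         2 2319.5417   1275.2063    TRUE
#> 3       3         5 2172.7383   1298.6525    TRUE
#> 4       4         8  349.3396   1316.5854   FALSE
#> 5       5         4  350.1958   1306.3427   FALSE
#> 6       6        12  354.3639   648.7559   FALSE
```

Clusters 1–3 are the 12 IgG-dominated regions (k = 6 splits the block):
IgG mean RPM exceeds the target mean, so their regions are dropped from
`consensus_filtered.bed`. Clusters 4–5 are the shared regions and cluster 6
the rep1-only regions, all with ~6× more target than IgG signal. The
output directory holds `qc_report.csv` plus the consensus BEDs,
overlap/correlation/SCC/cluster tables and the long-format signal matrix.

The same workflow is scriptable from a shell:

```sh
Rscript exec/cnr-qc.R fixtures --out fx --seed 1
Rscript exec/cnr-qc.R run --config fx/config.csv --out fx/qc
```

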