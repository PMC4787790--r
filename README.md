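# enhancerstrata

An R package for stratifying transcription-factor-bound enhancers by their
chromatin state — in particular by the presence of the histone variant
H2A.Z — and for asking what distinguishes the strata: local nucleosome
organization, chromatin accessibility, CpG methylation, nascent enhancer
transcription (eRNA) and the expression response of nearby genes.

It is aimed at regulatory-genomics analysts who have summit-anchored
binding sites (narrowPeak/BED), normalized signal tracks (bedGraph or
fixedStep wiggle) for histone marks and accessibility, per-CpG bisulfite
methylation calls, and a gene table with expression-response categories.
The package also ships a fully parameterized synthetic-data generator with
a ground-truth manifest, so every analysis step can be validated by
recovery tests before it ever touches real data.

## What it computes

- **Chromatin-state grouping.** TSS-distal, non-promoter sites (summits
  more than 3 kb from every TSS and outside H3K4me3-enriched regions, which
  flag unannotated promoters) are clustered by Euclidean K-means (k = 4,
  k-means++ seeding, best of 10 restarts) on a sites × (marks × bins)
  matrix of asinh-transformed, block-standardized signal in ±2 kb windows.
  Clusters are labeled by a rule on their H2A.Z / H3K27ac / H3K4me1 means:
  `active_w_H2AZ`, `active_wo_H2AZ`, `weak`, `inactive`.
- **Shape clustering with mirror alignment.** Per-site profiles in 300 bp
  windows are z-normalized (so the shape is compared independently of
  signal level) and clustered under the correlation distance
  `d(x, c) = min(1 − ρ(x, c), 1 − ρ(x̄, c))`, where `x̄` is the mirror
  image of the profile: patterns that are mirror images of each other are
  oriented in the same direction instead of producing artificial symmetry.
  Over-clustering (k = 40) is followed by agglomerative merging of
  centroids above 0.85 correlation. Each cluster centroid is categorized
  as *centered*, *side* or *ambiguous* from its peak geometry, and the
  categories are validated by summit-to-nearest-nucleosome distance
  histograms.
- **CpG methylation stratification.** Per-CpG percent-methylation records
  in 600 bp windows around summits, with each CpG assigned to its nearest
  summit; the headline statistic is the un/low-methylated fraction
  (strictly < 25% methylation), stratified by group and by basal
  ("prebound") occupancy status.
- **Gene association and enrichment.** GREAT-style basal-plus-extension
  regulatory domains (5 kb / 1 kb basal, ≤ 1 Mb extension), site-to-gene
  assignment by summit, relative enrichment of each group on gene
  categories against a per-chromosome uniform randomization, exclusive
  target sets (genes hit by both groups are discarded), strand-specific
  eRNA meta-profiles across stimulation timepoints, and Mann–Whitney
  rank tests (exact branch for small tie-free samples).

## Worked example

```r
library(enhancerstrata)

cfg <- simulation_config(seed = 42, n_sites = 400, n_genes = 150,
                         chrom_sizes = c(simA = 4e6, simB = 2e6))
sim <- simulate_all(cfg, marks = c("ERalpha", "H2AZ", "H3K27ac", "H3K4me1"))

sites <- filter_distal_nonpromoter(sim$sites, sim$genes,
                                   sim$features$h3k4me3_peaks)
mat <- build_matrix(sites, sim$tracks)
asg <- kmeans_group(mat, k = 4, seed = 1)
asg <- label_groups(asg, cluster_mark_means(
  asg, sites, sim$tracks[c("H2AZ", "H3K27ac", "H3K4me1")]))
sites <- apply_groups(sites, asg)
table(mcols(sites)$group)
#>  active_w_H2AZ active_wo_H2AZ           weak       inactive     unassigned
#>             82            209             60             49              0
```

The simulation carries a ground-truth manifest, so recovery can be scored
directly:

```r
truth <- sim$truth[match(mcols(sites)$site_id, sim$truth$site_id), ]
adjusted_rand_index(as.character(mcols(sites)$group), truth$group)
#> [1] 1
```

All 40 decoy promoter-contaminant sites were removed by the filter and all
400 true distal sites kept, and the four groups were recovered exactly.
Methylation stratification then reproduces the generator's Beta-mixture
structure — the H2A.Z stratum is predominantly un/low-methylated (< 25%),
the stratum without H2A.Z much less so:

```r
rep <- stratified_methylation_report(
  sim$cpgs, split_prebound(sites, sim$features$basal_peaks))
rep[rep$prebound == "all" & grepl("active", rep$group),
    c("group", "n_cpg", "frac_unlow")]
#>             group n_cpg frac_unlow
#> 1: active_wo_H2AZ  3856  0.4605809
#> 2:  active_w_H2AZ  2627  0.8340312
```

A single command-line entry point over the same stages (simulate →
classify → shapes → methylation → enrich → report) is installed at
`inst/exec/enhancer-strata`:

```sh
enhancer-strata all --config run.yaml --seed 7 --outdir results/
```

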