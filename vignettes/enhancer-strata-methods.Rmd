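---
title: "Methods: stratifying TF-bound enhancers by chromatin state and shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying TF-bound enhancers by chromatin state and shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which parameters matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and where the design was genuinely open.

## The analysis in one paragraph

Hormone-inducible transcription factors such as ERα bind mostly at distal
enhancers. These enhancers are not a homogeneous population: a subset
carries the histone variant H2A.Z, and that subset differs systematically
in accessibility, DNA methylation, nascent enhancer transcription (eRNA)
and the response of nearby genes. The pipeline makes that stratification
reproducible: it filters summit-anchored binding sites down to TSS-distal,
non-promoter candidates, groups them into four chromatin states by K-means
on multi-mark signal, clusters the *shape* of the local nucleosome signal
independently of its level (with mirror-image alignment), stratifies
per-CpG methylation around summits, and links groups to genes through
GREAT-style regulatory domains.

## Site filtering

Distal means more than `distal_bp` = 3000 bp (strictly greater) from every
TSS. Additionally, any site whose interval intersects an H3K4me3-enriched
region is removed: regions co-enriched for H2A.Z and H3K4me3 behave like
promoters regardless of annotation distance, so distal lists are
contaminated by unannotated promoters unless this mark is used as an
explicit filter. The H3K4me3 regions are consumed as a called-peak
`FeatureSet`; the pipeline deliberately does not call peaks itself. The
filter is order-preserving and idempotent.

## Chromatin-state grouping

The profile matrix holds one row per site and one block of `n_bins` = 100
bins per mark over ±`half_window` = 2000 bp. Values are asinh-transformed
— near-identity below 1, logarithmic above, which compresses the dynamic
range the way density-clustering tools do without a pseudo-count — and
each mark block is standardized to zero mean and unit variance *as a
block*, so marks contribute comparably while the spatial structure inside
a block is preserved. Grouping is plain Euclidean K-means with k-means++
seeding and 10 restarts (best inertia kept), k = 4 by default and
overridable; 4 matches the observed structure of this kind of data (two
active states split by H2A.Z, a weak state marked mainly by H3K4me1, and
an inactive remainder).

Numeric clusters are turned into semantic labels by a scale-free rule on
the cluster-mean table: among clusters with above-median H3K27ac, the one
with the highest H2A.Z mean is `active_w_H2AZ`, the rest `active_wo_H2AZ`;
of the remaining clusters, those with H3K4me1 above the median of the
remaining clusters are `weak`, the rest `inactive`. The weak rule uses the
median of the *remaining* clusters: with k = 4 and two clusters already
labeled active, a strict comparison against the median over all k would be
degenerate whenever the weak cluster's H3K4me1 equals that median.
Exact ties across all three marks abort with a request for manual labels.

Replicate tracks may be combined (averaged) only when their genome-wide
Pearson correlation at a common bin size reaches 0.9, the conventional
QC gate for this assay type.

The simulated tracks carry a single (stimulated-state) condition per mark.
With real data, whether to cluster on one condition or on the
concatenation of basal and stimulated matrices is the caller's choice:
`build_matrix()` takes an arbitrary named track list, so concatenating
conditions is just passing both tracks.

## Shape clustering

The question here is whether a chromatin feature changes the local
*geometry* of nucleosome-borne signal around summits, so magnitude must be
removed first: each profile in a 300 bp window (30 × 10 bp bins) is
z-normalized with the population standard deviation, making a profile and
any positive multiple of it identical. Profiles whose mean signal falls
below `min_signal` (default: the 25th percentile of per-profile means) are
set aside and reported as low-signal, never silently dropped — a
z-normalized noise floor is pure noise and would otherwise seed junk
clusters.

Distance is `1 − ρ` on the normalized profiles; with `flip = TRUE`
(default) the distance is the minimum over the profile and its mirror
image, and the minimizing orientation is recorded per member. Without this,
a left-shifted and a right-shifted nucleosome produce two "different"
clusters whose average is spuriously symmetric. The algorithm over-clusters
with k-means++ seeding at `k_init` = 40, iterates assignment/centroid
updates to convergence (centroid = re-normalized mean of oriented members),
and then agglomeratively merges centroid pairs whose flip-aware correlation
exceeds `merge_threshold` = 0.85, most-similar pair first.
Over-cluster-and-merge is robust to the initial k and mirrors
clustered-aggregation practice.

Two numerical safeguards matter in the noisy regime. Profiles are smoothed
with a `smooth_bins` = 5 (50 bp) moving average before normalization:
counting noise at the 10 bp bin scale is below the nucleosome scale and
carries no shape information. The *centroid* is smoothed with the same
window at every update; without this, a cluster can lock onto the
bin-level noise of its own members (members are recruited because their
noise matches the centroid, which then reinforces that noise). Five
restarts of the partitioning phase are run and the solution with the
highest mean member-to-centroid correlation kept.

A mirror-reversal property holds by construction: reversing every input
profile yields the identical partition with every centroid reversed
(ρ(x̄, c̄) = ρ(x, c)), so each member's orientation *relative to the
original centroid direction* toggles while the stored flags, which are
defined relative to the cluster's own centroid, are unchanged. Tests
assert the partition identity and centroid reversal, which together are
the orientation-soundness guarantee.

Cluster categories are computed from centroid geometry. Local maxima with
topographic prominence at least `prominence_frac` = 0.25 of the centroid
range qualify; prominence uses the lower of the two bases so that a peak
truncated by the window edge keeps its full prominence. A cluster is
*centered* if the global qualifying maximum lies within `center_tol_bp` =
60 bp of the window midpoint, *side* if beyond, and *ambiguous* when there
is no qualifying maximum or when a comparable (≥ 0.8×) maximum sits on the
opposite flank — so a symmetric two-peak centroid is ambiguous rather than
arbitrarily side. The 60 bp tolerance is roughly half a nucleosome footprint
on each side of the summit; both thresholds are exposed in the
configuration. As an independent check on the categories,
`summit_nucleosome_distances()` smooths the nucleosome track (30 bp moving
average), finds the local maximum nearest each summit within ±1 kb, and
histograms the distances in 10 bp bins normalized to sum 1; centered
clusters concentrate near zero, side clusters away from it.

## CpG methylation

Methylation records are consumed in the common bisulfite coverage-style
6-column dialect (chrom, start, end, percent, coverage, strand); merging
the two strands of a CpG pair is left to the caller and documented as
such. CpGs with coverage ≥ `min_coverage` (default 1 — no filter, since
no coverage threshold is part of the method definition) within 600 bp
windows around summits are stratified by group and prebound status. A CpG
falling in two overlapping windows is counted once, for the nearest summit
(ties to the lower coordinate), so stratified counts partition the data.
The headline fraction counts values *strictly* below 25%: 24.9 is un/low,
25.0 is not. Deciles of the full distribution are reported alongside.

## Gene association and statistics

Regulatory domains follow the basal-plus-extension convention: a
strand-aware basal region (5 kb upstream, 1 kb downstream of the TSS)
extended in both directions up to 1 Mb from the TSS but stopping at the
nearest neighbouring gene's basal region, clipped to the chromosome. All
three parameters are configuration-exposed. A site belongs to every domain
containing its summit. Relative enrichment of a site group on a gene
category compares the observed fraction of summits in that category's
domains with its mean over `n_shuffles` ≥ 100 per-chromosome uniform
random placements (site counts per chromosome preserved); the empirical
two-sided p-value comes from the same shuffle distribution with a +1/n
continuity correction. Placement is uniform rather than
mappability-masked; an exclusion set can be supplied where that matters.
For eRNA analyses, *intergenic* means the summit is outside every gene
interval extended by 1 kb, which avoids contamination by mRNA
transcription. Exclusive targets of two groups discard genes whose domains
contain summits of both. Mann–Whitney tests use exact enumeration when
`|a|·|b| ≤ 400` with no ties and the tie-corrected normal approximation
otherwise; pairwise p-values are reported raw, without multiplicity
correction, matching how such figure-level comparisons are conventionally
annotated.

## The synthetic-data generator

The generator's defaults define the study conditions under which the
recovery tests run: 2000 sites on a 30 Mb two-chromosome genome, group
proportions 20/55/15/10 over
`active_w_H2AZ` / `active_wo_H2AZ` / `weak` / `inactive`, plus 10% decoy
promoter-contaminant sites with high H3K4me3. Summits are at least 5 kb
apart and 4 kb from chromosome ends, so the ±2 kb analysis windows of
neighbouring sites never overlap; gene TSSs are kept at least 4 kb from
every summit so that no true site is lost to the distal filter by
construction.

Expected signal per mark is `background + amplitude(group, mark) ×
(broad_w · envelope + fine_w · template(shape))`: a Gaussian envelope
(σ = 700 bp) carries the domain-level enrichment that the 2 kb
classification window measures, and a fine component (σ = 40 bp bumps,
side/bimodal offsets ±100 bp) carries the nucleosome-scale structure that
the 300 bp shape window measures. Chromatin-state marks (H2A.Z, H3K27ac)
are broad-dominant, nucleosome-positioning signals (H3K4me1, MNase)
fine-dominant, and point-source signals (TF, DNase, H3K4me3) always
centered — a flat-shape site therefore still exposes its group through the
envelope. Counting noise is negative binomial per bin (dispersion 0.2,
variance μ + 0.2μ²) drawn at a sequencing-depth factor of 20 and scaled
back; Poisson and noise-free modes exist for variance-controlled tests.
Note the dispersion imposes a coefficient-of-variation floor of
√0.2 ≈ 45% per bin regardless of depth, which is what makes the 50 bp
smoothing in shape clustering necessary.

Methylation is a two-component Beta mixture per CpG (low: Beta(1, 30);
high: Beta(8, 4), on the percent scale ×100) whose low-component weight
depends on group and prebound status: 0.85 at prebound sites of any group,
and 0.80 / 0.20 / 0.25 / 0.20 at not-prebound sites of the four groups.
With the default 40% prebound probability these marginals put 82% and 46%
of CpG mass below 25% for the two active groups — the contrast the
methylation stratification is meant to recover. CpG density is highest in
the central 600 bp of H2A.Z-group sites. Strand-specific eRNA signal is a
divergent pair of bumps (plus strand at +150 bp, minus at −150 bp) whose
amplitude is multiplied by per-group induction factors at 0/10/40 min —
(1, 2, 4) for the H2A.Z group and flat (1, 1, 1) elsewhere, so induction
is specific to that stratum. E2-up genes are spawned 10–60 kb from a
randomly chosen active site with a larger mean log2 change when the site
carries H2A.Z (1.5 vs 1.0, i.e. a configured shift of 0.5); E2-down,
unchanged and not-expressed genes are placed away from summits, so a gene
more than 1 Mb from every site is never E2-up.

**What the generator does not emulate — and hence what passing tests do
not show about real data.** There is no read-level structure (fragment
sizes, duplicates, GC bias, mappability), no inter-site signal
correlation, no condition-to-condition dynamics within a mark, and CpG
methylation is independent across CpGs given the site. Most importantly,
the genome is compressed: 2000 sites on 30 Mb puts site spacing (~14 kb)
far below regulatory-domain width (~100 kb), whereas in a mammalian genome
sites are sparser than genes. Domain-based statistics are therefore
structurally attenuated here: most domains contain summits of several
groups, so exclusive-target sets are small and relative enrichments sit
close to 1 even though the machinery (null calibration, common-target
discarding, configured-shift recovery) is fully exercised and tested.
Genome-scale enrichment magnitudes cannot be reproduced at desk scale and
the reports should not be read as such.

## Problem sizes used by the tests

Unit tests run on 150-site simulations (3 Mb genome); the end-to-end
recovery checks use the full default conditions (2000 sites + 200 decoys,
30 Mb) for grouping, filtering, methylation and eRNA, a 1500-site
centered/side/bimodal mixture for shape recovery, and 200 replicate
600-site draws for the composition-homogeneity null calibration. These
sizes keep the whole suite under a couple of minutes on one CPU while
leaving the statistical checks well-powered.

## Known limitations

Orientation flags are meaningful only relative to each cluster's centroid
direction; there is no absolute left/right convention. The K-means label
rule assumes k ≥ 4 distinct states are present; with degenerate input
(all-identical cluster means) it refuses rather than guessing. The
enrichment null is uniform per chromosome, not mappability- or GC-matched.
The Mann–Whitney exact branch is limited to small tie-free samples by
design; large-sample p-values rely on the tie-corrected normal
approximation. The wiggle reader supports fixedStep only (variableStep
records are not part of any consumed interface).
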