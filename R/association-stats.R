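# Site-gene association and enrichment statistics
# -----------------------------------------------
# GREAT-style basal-plus-extension regulatory domains, summit-to-domain
# gene assignment, relative enrichment of site groups on gene categories
# versus a per-chromosome uniform randomization, meta-profiles (including
# strand-specific ones), and Mann-Whitney comparisons.

#' Build GREAT-style regulatory domains
#'
#' Each gene gets a strand-aware basal region (`basal_up` upstream,
#' `basal_down` downstream of the TSS) extended in both directions up to
#' `max_ext` from the TSS but stopping at the nearest neighbouring gene's
#' basal region, clipped to the chromosome. Defaults are the
#' basal-plus-extension convention (5 kb / 1 kb / 1 Mb).
#'
#' @param genes Gene models ([gene_models()]).
#' @param basal_up,basal_down Basal region extents in bp.
#' @param max_ext Maximum extension from the TSS in bp.
#' @param chrom_sizes Named chromosome lengths.
#' @return A `GRanges` of domains with `gene_id` and the gene's
#'   `expression_category`.
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000,
                                     basal_down = 1000, max_ext = 1e6,
                                     chrom_sizes) {
  chrom <- as.character(GenomicRanges::seqnames(genes))
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- mcols(genes)$tss
  b_start <- ifelse(strand == "+", tss - basal_up, tss - basal_down + 1)
  b_end <- ifelse(strand == "+", tss + basal_down, tss + basal_up + 1)
  b_start <- pmax(b_start, 0)
  b_end <- pmin(b_end, chrom_sizes[chrom])
  d_start <- numeric(length(genes)); d_end <- numeric(length(genes))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ord <- idx[order(tss[idx])]
    bs <- b_start[ord]; be <- b_end[ord]; ts <- tss[ord]
    n <- length(ord)
    # nearest basal boundary of any *other* gene on each side
    prev_end <- c(0, vapply(seq_len(n)[-1], function(i) max(be[1:(i - 1)]), 0))
    next_start <- c(vapply(seq_len(n - 1), function(i)
      min(bs[(i + 1):n]), 0), chrom_sizes[[ch]])
    left <- pmin(bs, pmax(ts - max_ext, prev_end))
    right <- pmax(be, pmin(ts + max_ext, next_start))
    d_start[ord] <- pmax(pmin(left, bs), 0)
    d_end[ord] <- pmin(pmax(right, be), chrom_sizes[[ch]])
  }
  dom <- gr_from_bed0(chrom, d_start, d_end)
  mcols(dom)$gene_id <- mcols(genes)$gene_id
  mcols(dom)$expression_category <- mcols(genes)$expression_category
  dom
}

#' Map sites to genes by regulatory domain
#'
#' A site maps to every gene whose domain contains its summit.
#'
#' @param sites Anchor sites.
#' @param domains Regulatory domains ([build_regulatory_domains()]).
#' @return `data.table` with one row per (site, gene) hit: `site_id`,
#'   `gene_id`.
#' @export
assign_sites_to_genes <- function(sites, domains) {
  s <- site_summits(sites)
  q <- gr_from_bed0(as.character(GenomicRanges::seqnames(sites)), s, s + 1)
  hits <- GenomicRanges::findOverlaps(q, domains)
  data.table(site_id = mcols(sites)$site_id[queryHits(hits)],
             gene_id = mcols(domains)$gene_id[subjectHits(hits)])
}

#' Genes exclusively targeted by one of two site groups
#'
#' Genes whose domains contain summits of both groups ("common targets")
#' are discarded.
#'
#' @param assignment Site-gene map from [assign_sites_to_genes()].
#' @param sites Anchor sites with `group` set.
#' @param group_a,group_b Group labels to compare.
#' @return List with character vectors `a_only` and `b_only` of gene ids.
#' @export
exclusive_targets <- function(assignment, sites, group_a, group_b) {
  grp <- setNames(as.character(mcols(sites)$group), mcols(sites)$site_id)
  ga <- unique(assignment$gene_id[grp[assignment$site_id] == group_a])
  gb <- unique(assignment$gene_id[grp[assignment$site_id] == group_b])
  list(a_only = setdiff(ga, gb), b_only = setdiff(gb, ga))
}

#' Relative enrichment of a site group on gene categories
#'
#' The observed fraction of the group's summits falling in domains of each
#' expression category is compared with its expectation under `n_shuffles`
#' per-chromosome uniform random summit placements (site counts per
#' chromosome preserved). Reports observed and expected fractions, their
#' ratio, and an empirical two-sided p-value from the shuffle distribution.
#'
#' @param sites Anchor sites (the group of interest).
#' @param domains Regulatory domains with `expression_category`.
#' @param chrom_sizes Named chromosome lengths.
#' @param n_shuffles Number of randomizations (default 1000, minimum 100).
#' @param seed RNG seed.
#' @param exclude Optional feature set of regions random summits must avoid
#'   (e.g. unmappable regions); `NULL` for plain uniform placement.
#' @return An object of class `enrichment_result`: `data.table` with
#'   `category`, `observed_fraction`, `expected_fraction`,
#'   `relative_enrichment`, `p_value`, plus `n_shuffles` and `seed`
#'   attributes.
#' @export
relative_enrichment <- function(sites, domains, chrom_sizes,
                                n_shuffles = 1000, seed = 1, exclude = NULL) {
  stopifnot(n_shuffles >= 100, length(sites) >= 1)
  categories <- levels(mcols(domains)$expression_category)
  chroms <- as.character(GenomicRanges::seqnames(sites))
  n_per <- table(chroms)
  frac_by_cat <- function(chrom, pos) {
    q <- gr_from_bed0(chrom, pos, pos + 1)
    hits <- GenomicRanges::findOverlaps(q, domains)
    cat_hit <- lapply(categories, function(cc) {
      sel <- mcols(domains)$expression_category[subjectHits(hits)] == cc
      length(unique(queryHits(hits)[sel]))
    })
    unlist(cat_hit) / length(q)
  }
  observed <- frac_by_cat(chroms, site_summits(sites))
  shuffled <- matrix(NA_real_, n_shuffles, length(categories))
  withr::with_seed(seed, {
    for (b in seq_len(n_shuffles)) {
      pos <- unlist(lapply(names(n_per), function(ch) {
        p <- floor(runif(n_per[[ch]], 0, chrom_sizes[[ch]]))
        if (!is.null(exclude) && length(exclude)) {
          for (k in 1:10) {
            bad <- IRanges::overlapsAny(gr_from_bed0(ch, p, p + 1), exclude)
            if (!any(bad)) break
            p[bad] <- floor(runif(sum(bad), 0, chrom_sizes[[ch]]))
          }
        }
        p
      }), use.names = FALSE)
      shuffled[b, ] <- frac_by_cat(rep(names(n_per), n_per), pos)
    }
  })
  expected <- colMeans(shuffled)
  enr <- ifelse(expected > 0, observed / expected, NA_real_)
  if (any(expected == 0))
    warning("category with zero expected fraction across all shuffles; NA enrichment")
  p <- vapply(seq_along(categories), function(j) {
    lo <- mean(shuffled[, j] <= observed[j])
    hi <- mean(shuffled[, j] >= observed[j])
    min(1, 2 * min(lo, hi) + 1 / n_shuffles)
  }, 0)
  out <- data.table(category = categories, observed_fraction = observed,
                    expected_fraction = expected,
                    relative_enrichment = enr, p_value = p,
                    shuffle_sd = apply(shuffled, 2, sd))
  attr(out, "n_shuffles") <- n_shuffles
  attr(out, "seed") <- seed
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Average signal profile over sites
#'
#' Mean of [extract_profiles()] over the given sites. In strand-specific
#' mode, supply `tracks = list(plus = ..., minus = ...)` and two curves on
#' the shared genomic axis are returned; sites are treated as unoriented
#' (genomic left/right preserved), as appropriate for enhancers.
#'
#' @param tracks A single [signal_track()] or a named list
#'   `list(plus =, minus =)`.
#' @param sites Anchor sites (non-empty).
#' @param half_window Half-window in bp.
#' @param n_bins Number of bins.
#' @return `data.frame` with `offset` (bp of bin centers) and `mean_signal`
#'   (columns `plus`/`minus` in strand-specific mode).
#' @export
meta_profile <- function(tracks, sites, half_window = 2000, n_bins = 100) {
  if (!length(sites)) stop("meta_profile undefined for an empty site list")
  offset <- -half_window + (seq_len(n_bins) - 0.5) * (2 * half_window / n_bins)
  if (inherits(tracks, "signal_track")) {
    prof <- colMeans(extract_profiles(tracks, sites, half_window, n_bins))
    return(data.frame(offset = offset, mean_signal = prof))
  }
  stopifnot(all(c("plus", "minus") %in% names(tracks)))
  data.frame(offset = offset,
             plus = colMeans(extract_profiles(tracks$plus, sites,
                                              half_window, n_bins)),
             minus = colMeans(extract_profiles(tracks$minus, sites,
                                               half_window, n_bins)))
}

#' Flag sites as intergenic
#'
#' A summit is intergenic when it does not fall inside any gene interval
#' extended by `slop` bp on both sides (used to avoid mRNA contamination in
#' nascent-transcription analyses).
#'
#' @param sites Anchor sites.
#' @param genes Gene models.
#' @param slop Gene-interval extension in bp (default 1000).
#' @return Sites with the `intergenic` column set.
#' @export
flag_intergenic <- function(sites, genes, slop = 1000) {
  s <- site_summits(sites)
  q <- gr_from_bed0(as.character(GenomicRanges::seqnames(sites)), s, s + 1)
  ext <- suppressWarnings(GenomicRanges::resize(
    genes, GenomicRanges::width(genes) + 2 * slop, fix = "center"))
  ext <- GenomicRanges::trim(ext)
  mcols(sites)$intergenic <- !IRanges::overlapsAny(q, ext)
  sites
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U statistic with exact enumeration when `|a| * |b| <= 400` and there are
#' no ties, and the tie-corrected normal approximation otherwise. Two
#' identical constant samples give p = 1.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1)
    return(list(U = length(a) * length(b) / 2, p = 1))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  ht <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = exact, correct = !exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Compare expression changes of exclusive target genes of two groups
#'
#' Genes associated with both groups are discarded ([exclusive_targets()]);
#' the expression-change distributions of the remaining two gene sets are
#' compared by a two-sided Mann-Whitney test.
#'
#' @param genes Gene models.
#' @param assignment Site-gene map from [assign_sites_to_genes()].
#' @param sites Anchor sites with `group` set.
#' @param group_a,group_b Groups to compare.
#' @param categories Gene categories considered E2-regulated (default
#'   `c("E2_up", "E2_down")`).
#' @return List with `changes_a`, `changes_b`, `U`, `p`.
#' @export
expression_change_compare <- function(genes, assignment, sites, group_a,
                                      group_b,
                                      categories = c("E2_up", "E2_down")) {
  ex <- exclusive_targets(assignment, sites, group_a, group_b)
  gm <- data.table(gene_id = mcols(genes)$gene_id,
                   category = as.character(mcols(genes)$expression_category),
                   change = mcols(genes)$expression_change)
  pick <- function(ids) gm$change[gm$gene_id %in% ids &
                                    gm$category %in% categories]
  ca <- pick(ex$a_only); cb <- pick(ex$b_only)
  if (length(ca) < 3 || length(cb) < 3)
    warning("fewer than 3 exclusive target genes in a group; p-value unstable")
  mw <- mann_whitney(ca, cb)
  list(changes_a = ca, changes_b = cb, U = mw$U, p = mw$p)
}
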