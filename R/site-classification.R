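# Chromatin-state grouping
# ------------------------
# Replicate QC, promoter-contamination filtering, multi-mark profile-matrix
# construction and K-means grouping of sites into the four chromatin-state
# strata (active with H2A.Z, active without, weak, inactive), followed by a
# rule-based semantic labeling of the numeric clusters.

#' Genome-wide Pearson correlation between two replicate tracks
#'
#' Both tracks are rebinned to a common `bin_size` and correlated over all
#' genome bins. Replicates are conventionally combined (averaged) only when
#' r exceeds 0.9.
#'
#' @param track_a,track_b [signal_track()] objects on the same chromosomes.
#' @param bin_size Common bin size in bp (default: the coarser of the two).
#' @return Pearson r.
#' @export
replicate_correlation <- function(track_a, track_b, bin_size = NULL) {
  if (!setequal(names(track_a$values), names(track_b$values)))
    stop("tracks cover different chromosomes")
  if (is.null(bin_size)) bin_size <- max(track_a$bin_size, track_b$bin_size)
  if (track_a$bin_size != bin_size) track_a <- rebin_track(track_a, bin_size)
  if (track_b$bin_size != bin_size) track_b <- rebin_track(track_b, bin_size)
  a <- unlist(track_a$values[names(track_a$values)], use.names = FALSE)
  b <- unlist(track_b$values[names(track_a$values)], use.names = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance track: correlation undefined")
  cor(a, b)
}

#' Average two replicate tracks after a correlation gate
#'
#' @inheritParams replicate_correlation
#' @param min_r Minimum Pearson r required to combine (default 0.9).
#' @return A [signal_track()] holding the mean of the two replicates.
#' @export
combine_replicates <- function(track_a, track_b, min_r = 0.9) {
  r <- replicate_correlation(track_a, track_b)
  if (r < min_r)
    stop(sprintf("replicate correlation %.3f below threshold %.2f", r, min_r))
  if (track_b$bin_size != track_a$bin_size)
    track_b <- rebin_track(track_b, track_a$bin_size)
  vals <- lapply(names(track_a$values), function(chrom)
    (track_a$values[[chrom]] + track_b$values[[chrom]]) / 2)
  names(vals) <- names(track_a$values)
  signal_track(vals, track_a$bin_size, track_a$chrom_sizes, track_a$label)
}

#' Keep TSS-distal, non-promoter sites
#'
#' Retains sites whose summit is more than `distal_bp` from every TSS and
#' whose interval does not intersect any H3K4me3-enriched region (called
#' peaks supplied as a feature set; peak calling itself is out of scope).
#' Order is preserved and the operation is idempotent.
#'
#' @param sites Anchor sites.
#' @param tss_list Numeric TSS positions named by chromosome (a list), or a
#'   gene `GRanges` from [gene_models()] whose `tss` column is used.
#' @param h3k4me3_regions Feature set of H3K4me3-enriched regions (may be
#'   empty).
#' @param distal_bp Distal threshold in bp; summits at distance
#'   `> distal_bp` are kept (default 3000).
#' @return The filtered sites.
#' @export
filter_distal_nonpromoter <- function(sites, tss_list, h3k4me3_regions = NULL,
                                      distal_bp = 3000) {
  stopifnot(distal_bp > 0)
  if (inherits(tss_list, "GRanges"))
    tss_list <- split(mcols(tss_list)$tss,
                      as.character(GenomicRanges::seqnames(tss_list)))
  if (!length(tss_list) || !sum(lengths(tss_list)))
    stop("empty TSS list")
  chroms <- as.character(GenomicRanges::seqnames(sites))
  summits <- site_summits(sites)
  dist <- rep(Inf, length(sites))
  for (chrom in names(tss_list)) {
    tss <- sort(as.numeric(tss_list[[chrom]]))
    idx <- which(chroms == chrom)
    if (!length(idx) || !length(tss)) next
    i <- findInterval(summits[idx], tss)
    lo <- ifelse(i >= 1, summits[idx] - tss[pmax(i, 1)], Inf)
    hi <- ifelse(i < length(tss), tss[pmin(i + 1, length(tss))] - summits[idx],
                 Inf)
    dist[idx] <- pmin(lo, hi)
  }
  keep <- dist > distal_bp
  if (!is.null(h3k4me3_regions) && length(h3k4me3_regions))
    keep <- keep & !IRanges::overlapsAny(sites, h3k4me3_regions)
  sites[keep]
}

#' Build a sites-by-(marks x bins) profile matrix
#'
#' Per-site per-mark profiles are extracted around summits, transformed
#' element-wise, concatenated, and each mark block is standardized to zero
#' mean and unit variance over the whole block.
#'
#' @param sites Anchor sites.
#' @param tracks Named list of [signal_track()] objects (the marks).
#' @param half_window Half-window in bp (default 2000).
#' @param n_bins Bins per mark (default 100).
#' @param transform `"asinh"` (default), `"log1p"` or `"none"`; asinh
#'   compresses the dynamic range the way density-clustering tools do.
#' @return An object of class `profile_matrix` with fields `values`
#'   (matrix), `site_ids`, `marks`, `half_window`, `n_bins`.
#' @export
build_matrix <- function(sites, tracks, half_window = 2000, n_bins = 100,
                         transform = c("asinh", "log1p", "none")) {
  transform <- match.arg(transform)
  stopifnot(length(tracks) >= 1, length(sites) >= 1)
  f <- switch(transform, asinh = asinh, log1p = log1p, none = identity)
  blocks <- lapply(tracks, function(track) {
    m <- f(extract_profiles(track, sites, half_window, n_bins))
    mu <- mean(m); s <- sd(as.vector(m))
    if (s > 0) (m - mu) / s else m * 0
  })
  values <- do.call(cbind, blocks)
  structure(list(values = values, site_ids = mcols(sites)$site_id,
                 marks = names(tracks), half_window = half_window,
                 n_bins = n_bins, transform = transform),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d sites x %d marks x %d bins (%s)\n",
              nrow(x$values), length(x$marks), x$n_bins, x$transform))
  invisible(x)
}

# k-means++ seeding (squared Euclidean); stats::kmeans lacks it
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

#' Group sites by Euclidean K-means on the profile matrix
#'
#' K-means++ initialization, `n_restarts` independent restarts, the
#' best-inertia solution returned. Deterministic under a fixed seed.
#'
#' @param matrix A [build_matrix()] result.
#' @param k Number of clusters (default 4).
#' @param seed RNG seed.
#' @param n_restarts Number of restarts (default 10).
#' @return An object of class `group_assignment`: `cluster` (integer per
#'   site, named by site id), `groups` (factor, `"unassigned"` until
#'   [label_groups()] is applied), `centers`, `inertia`, `k`, `seed`.
#' @export
kmeans_group <- function(matrix, k = 4, seed = 1, n_restarts = 10) {
  x <- matrix$values
  stopifnot(k >= 2, n_restarts >= 1)
  if (k > nrow(x)) stop("k exceeds the number of sites")
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- suppressWarnings(
        kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 100,
               algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  structure(list(cluster = setNames(best$cluster, matrix$site_ids),
                 groups = setNames(factor(rep("unassigned", nrow(x)),
                                          levels = GROUP_LEVELS),
                                   matrix$site_ids),
                 centers = best$centers, inertia = best$tot.withinss,
                 k = k, seed = seed, cluster_means = NULL),
            class = "group_assignment")
}

#' Per-cluster mean mark signal
#'
#' @param assignment A [kmeans_group()] result.
#' @param sites Anchor sites (same order as the matrix).
#' @param tracks Named list of tracks over which to summarise (typically
#'   H2A.Z, H3K27ac, H3K4me1).
#' @param half_window,n_bins Window used for the summary profile.
#' @return `data.frame` of k rows by marks, mean signal per cluster.
#' @export
cluster_mark_means <- function(assignment, sites, tracks, half_window = 300,
                               n_bins = 30) {
  cl <- assignment$cluster
  out <- sapply(tracks, function(track) {
    prof <- extract_profiles(track, sites, half_window, n_bins)
    tapply(rowMeans(prof), cl, mean)
  })
  as.data.frame(out)
}

#' Attach semantic chromatin-state labels to numeric clusters
#'
#' Rule over the cluster-mean table (columns `H2AZ`, `H3K27ac`, `H3K4me1`):
#' among clusters with above-median H3K27ac (median across the k cluster
#' means -- scale-free, so it works under any normalization), the one with
#' the highest H2A.Z mean is `active_w_H2AZ` and the others
#' `active_wo_H2AZ`; of the remaining clusters, those with H3K4me1 above the
#' median of the remaining clusters are `weak`; the rest `inactive`. Ties
#' are broken by H3K27ac then H3K4me1 mean; an exact tie on all criteria
#' stops with a request for manual labels.
#'
#' @param assignment A [kmeans_group()] result.
#' @param mark_means Cluster-mean table from [cluster_mark_means()].
#' @return The assignment with `groups` filled in and `cluster_means`
#'   recorded (with a `label` column).
#' @export
label_groups <- function(assignment, mark_means) {
  need <- c("H2AZ", "H3K27ac", "H3K4me1")
  if (!all(need %in% colnames(mark_means)))
    stop("mark_means must contain columns ", paste(need, collapse = ", "))
  mm <- mark_means[as.character(seq_len(assignment$k)), ]
  key <- paste(mm$H2AZ, mm$H3K27ac, mm$H3K4me1)
  if (anyDuplicated(key))
    stop("clusters exactly tied on all labeling criteria; assign labels manually")
  labels <- rep("inactive", assignment$k)
  acet <- mm$H3K27ac > median(mm$H3K27ac)
  if (any(acet)) {
    cand <- which(acet)
    ord <- order(-mm$H2AZ[cand], -mm$H3K27ac[cand], -mm$H3K4me1[cand])
    labels[cand] <- "active_wo_H2AZ"
    labels[cand[ord[1]]] <- "active_w_H2AZ"
  }
  rest <- which(labels == "inactive")
  if (length(rest) > 1)
    labels[rest[mm$H3K4me1[rest] > median(mm$H3K4me1[rest])]] <- "weak"
  assignment$groups <- setNames(
    factor(labels[assignment$cluster], levels = GROUP_LEVELS),
    names(assignment$cluster))
  mm$label <- labels
  assignment$cluster_means <- mm
  assignment
}

#' Apply a group assignment back onto the site object
#'
#' @param sites Anchor sites.
#' @param assignment A labeled [kmeans_group()] result.
#' @return Sites with the `group` column filled for assigned site ids.
#' @export
apply_groups <- function(sites, assignment) {
  idx <- match(mcols(sites)$site_id, names(assignment$groups))
  hit <- !is.na(idx)
  g <- as.character(mcols(sites)$group)
  g[hit] <- as.character(assignment$groups[idx[hit]])
  mcols(sites)$group <- factor(g, levels = GROUP_LEVELS)
  sites
}

#' Flag sites occupied in the basal (pre-stimulation) condition
#'
#' @param sites Anchor sites.
#' @param basal_peaks Feature set of basal-condition peaks (may be empty).
#' @param slop Symmetric summit extension in bp (default 0).
#' @return Sites with the `prebound` column set: `TRUE` where the summit
#'   (+/- slop) intersects a basal peak.
#' @export
split_prebound <- function(sites, basal_peaks, slop = 0) {
  stopifnot(slop >= 0)
  if (is.null(basal_peaks) || !length(basal_peaks)) {
    mcols(sites)$prebound <- rep(FALSE, length(sites))
    return(sites)
  }
  s <- site_summits(sites)
  q <- gr_from_bed0(as.character(GenomicRanges::seqnames(sites)),
                    pmax(s - slop, 0), s + slop + 1)
  mcols(sites)$prebound <- IRanges::overlapsAny(q, basal_peaks)
  sites
}

#' Adjusted Rand index between two labelings
#'
#' Used by the recovery tests and the pipeline summary to compare inferred
#' groups with the simulation manifest.
#'
#' @param a,b Two equal-length label vectors.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
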