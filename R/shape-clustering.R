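# Shape-based clustering with mirror alignment
# --------------------------------------------
# Clusters per-site signal profiles by local shape, independently of signal
# level: profiles are z-normalized, compared under a correlation distance
# that optionally considers the mirror image of each profile (so that
# patterns which are mirror images of each other are oriented in the same
# direction instead of producing artificial symmetry), over-clustered by a
# seeded k-means-style loop, and then agglomeratively merged. Clusters are
# finally categorized as centered / side / ambiguous from their centroid
# geometry, and validated against summit-to-nearest-nucleosome distances.

#' Magnitude-free profile normalization
#'
#' Returns `(profile - mean) / sd` using the population sd, so that a
#' profile and any positive multiple of it normalize identically. Profiles
#' whose mean signal is below `min_signal`, or with zero variance, are
#' low-signal and return `NULL`.
#'
#' @param profile Numeric vector (length >= 8).
#' @param min_signal Minimum mean signal.
#' @return Zero-mean unit-variance vector, or `NULL` for low signal.
#' @export
normalize_shape <- function(profile, min_signal = 0) {
  if (any(!is.finite(profile))) stop("non-finite values in profile")
  stopifnot(length(profile) >= 8)
  if (mean(profile) - min_signal < -1e-12) return(NULL)
  s <- sqrt(mean((profile - mean(profile))^2))
  if (s == 0) return(NULL)
  (profile - mean(profile)) / s
}

# row-wise population z-scoring; returns NA rows for low-signal profiles
normalize_shape_rows <- function(m, min_signal) {
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  low <- mu < min_signal | s == 0
  out <- (m - mu) / ifelse(s == 0, 1, s)
  out[low, ] <- NA_real_
  list(values = out, low = low)
}

# correlation of z-scored (population) rows x with z-scored centroids c:
# corr = <x, c> / n
zcorr <- function(x, centroids) {
  tcrossprod(x, centroids) / ncol(x)
}

rev_rows <- function(m) m[, ncol(m):1, drop = FALSE]

# centered moving average along rows, window shrunk at the edges so the
# output length matches the input (mirror-symmetric, so flipping commutes)
smooth_rows <- function(m, w) {
  n <- ncol(m)
  half <- (w - 1) %/% 2
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(m))
}

new_shape_cluster <- function(centroid, member_ids, orientation,
                              category = "unset") {
  structure(list(centroid = centroid, member_ids = member_ids,
                 orientation = orientation, size = length(member_ids),
                 category = category),
            class = "shape_cluster")
}

#' Cluster signal profiles by shape with optional mirror-flip alignment
#'
#' Algorithm: (1) z-normalize each profile, set aside low-signal profiles;
#' (2) k-means-style clustering under the distance `1 - corr(x, c)`, where
#' with `flip = TRUE` the distance is the minimum over the profile and its
#' mirror image and the minimizing orientation is recorded; centroids are
#' the re-normalized means of oriented members; (3) iterate to convergence;
#' (4) agglomeratively merge cluster pairs whose (flip-aware) centroid
#' correlation exceeds `merge_threshold`; (5) sort clusters by size.
#' Deterministic under a fixed seed.
#'
#' @param profiles A `profile_matrix` (single mark) or plain numeric matrix
#'   with site ids as row names.
#' @param k_init Initial number of clusters before merging (default 40).
#' @param flip Allow mirror-image alignment (default `TRUE`).
#' @param merge_threshold Centroid correlation above which clusters merge
#'   (default 0.85).
#' @param seed RNG seed.
#' @param min_signal Low-signal cutoff on per-profile means; the default
#'   `NULL` uses the 25th percentile of the per-profile means. Discarded
#'   profiles are reported in `discarded_low_signal`, never silently
#'   dropped.
#' @param smooth_bins Moving-average width (in bins) applied to profiles
#'   before normalization; the default 5 bins (50 bp at 10 bp
#'   resolution) suppresses bin-level counting noise below the
#'   nucleosome scale. Use 1 to disable.
#' @param n_restarts Independent k-means++ restarts of the partitioning
#'   phase; the solution with the highest mean member-to-centroid
#'   correlation is kept (default 5).
#' @param max_iter Assignment/update iteration cap.
#' @return An object of class `shape_clustering`: `clusters` (list of
#'   shape clusters sorted by size, each with `centroid`, `member_ids`,
#'   `orientation` -- `"as_is"`/`"flipped"` -- `size`, `category`),
#'   `discarded_low_signal`, and `params`.
#' @export
cluster_shapes <- function(profiles, k_init = 40, flip = TRUE,
                           merge_threshold = 0.85, seed = 1,
                           min_signal = NULL, smooth_bins = 5,
                           n_restarts = 5, max_iter = 50) {
  stopifnot(k_init >= 2, merge_threshold > 0, merge_threshold < 1)
  m <- if (inherits(profiles, "profile_matrix")) profiles$values else profiles
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("profile_%05d", seq_len(nrow(m)))
  if (is.null(min_signal))
    min_signal <- unname(quantile(rowMeans(m), 0.25))
  if (smooth_bins > 1) m <- smooth_rows(m, smooth_bins)
  nz <- normalize_shape_rows(m, min_signal)
  keep <- which(!nz$low)
  if (!length(keep)) stop("all profiles are low-signal")
  x <- nz$values[keep, , drop = FALSE]
  xr <- rev_rows(x)
  n <- nrow(x)
  k <- min(k_init, n)
  assign_step <- function(centroids) {
    cf <- zcorr(x, centroids)
    if (flip) {
      cr <- zcorr(xr, centroids)
      flipped <- cr > cf
      cbest <- pmax(cf, cr)
    } else {
      flipped <- matrix(FALSE, n, nrow(centroids))
      cbest <- cf
    }
    assign <- max.col(cbest, ties.method = "first")
    list(assign = assign,
         orient = flipped[cbind(seq_len(n), assign)],
         fit = mean(cbest[cbind(seq_len(n), assign)]))
  }
  run_once <- function() {
    centroids <- x[kmeanspp_corr_init(x, xr, k, flip), , drop = FALSE]
    assign_prev <- rep(0L, n)
    st <- NULL
    for (iter in seq_len(max_iter)) {
      st <- assign_step(centroids)
      if (identical(st$assign, assign_prev)) break
      assign_prev <- st$assign
      newc <- matrix(NA_real_, nrow(centroids), ncol(x))
      for (j in seq_len(nrow(centroids))) {
        mem <- which(st$assign == j)
        if (!length(mem)) next
        orm <- x[mem, , drop = FALSE]
        fl <- st$orient[mem]
        orm[fl, ] <- xr[mem[fl], , drop = FALSE]
        cen <- colMeans(orm)
        # smoothing the centroid keeps clusters from locking onto
        # bin-level noise modes of their own members
        if (smooth_bins > 1) cen <- smooth_rows(rbind(cen), smooth_bins)[1, ]
        s <- sqrt(mean((cen - mean(cen))^2))
        newc[j, ] <- if (s > 0) (cen - mean(cen)) / s else centroids[j, ]
      }
      ok <- !is.na(newc[, 1])
      centroids <- newc[ok, , drop = FALSE]
      if (nrow(centroids) < 2) break
    }
    list(centroids = centroids, fit = assign_step(centroids)$fit)
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      sol <- run_once()
      if (is.null(best) || sol$fit > best$fit) best <- sol
    }
  })
  centroids <- best$centroids
  st <- assign_step(centroids)
  assign <- st$assign
  orient <- st$orient

  # agglomerative merge of near-duplicate centroids (flip-aware)
  repeat {
    kk <- nrow(centroids)
    if (kk < 2) break
    cc <- tcrossprod(centroids) / ncol(centroids)  # centroids are z-scored
    ccr <- if (flip) tcrossprod(centroids, rev_rows(centroids)) /
      ncol(centroids) else cc
    sim <- pmax(cc, if (flip) ccr else cc)
    diag(sim) <- -Inf
    best <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    if (sim[best[1], best[2]] <= merge_threshold) break
    a <- min(best); b <- max(best)
    flip_b <- flip && ccr[a, b] > cc[a, b]
    mem_b <- which(assign == b)
    if (flip_b) orient[mem_b] <- !orient[mem_b]
    assign[mem_b] <- a
    mem <- which(assign == a)
    orm <- x[mem, , drop = FALSE]
    orm[orient[mem], ] <- xr[mem[orient[mem]], , drop = FALSE]
    cen <- colMeans(orm)
    s <- sqrt(mean((cen - mean(cen))^2))
    if (s > 0) centroids[a, ] <- (cen - mean(cen)) / s
    keep_cl <- setdiff(seq_len(kk), b)
    centroids <- centroids[keep_cl, , drop = FALSE]
    assign <- match(assign, keep_cl)
  }

  sizes <- tabulate(assign, nbins = nrow(centroids))
  ord <- order(-sizes)
  clusters <- lapply(ord[sizes[ord] > 0], function(j) {
    mem <- which(assign == j)
    new_shape_cluster(centroid = centroids[j, ],
                      member_ids = ids[keep][mem],
                      orientation = ifelse(orient[mem], "flipped", "as_is"))
  })
  structure(list(clusters = clusters,
                 discarded_low_signal = ids[nz$low],
                 params = list(k_init = k_init,
                               merge_threshold = merge_threshold,
                               flip_enabled = flip, seed = seed,
                               min_signal = min_signal,
                               smooth_bins = smooth_bins)),
            class = "shape_clustering")
}

# k-means++-style seeding under the flip-aware correlation distance
kmeanspp_corr_init <- function(x, xr, k, flip) {
  n <- nrow(x)
  chosen <- sample.int(n, 1)
  dist_to <- function(i) {
    d <- 1 - zcorr(x, x[i, , drop = FALSE])[, 1]
    if (flip) d <- pmin(d, 1 - zcorr(xr, x[i, , drop = FALSE])[, 1])
    d
  }
  d <- dist_to(chosen)
  while (length(chosen) < k) {
    p <- pmax(d, 0)
    i <- if (sum(p) > 0) sample.int(n, 1, prob = p) else sample.int(n, 1)
    chosen <- c(chosen, i)
    d <- pmin(d, dist_to(i))
  }
  chosen
}

#' @export
print.shape_clustering <- function(x, ...) {
  cat(sprintf("shape_clustering: %d cluster(s), %d profile(s), %d low-signal\n",
              length(x$clusters), sum(vapply(x$clusters, `[[`, 0L, "size")),
              length(x$discarded_low_signal)))
  invisible(x)
}

# interior local maxima with prominence: for each peak, walk left and right
# to the nearest strictly higher point (or the end), take the minimum along
# each walk; prominence = height - the lower of the two bases, so a peak
# truncated by the window edge keeps its full prominence
find_peaks <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3) return(data.frame(position = integer(), height = numeric()))
  is_pk <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  rows <- lapply(is_pk, function(i) {
    h <- v[i]
    left <- if (i == 1) h else {
      higher <- which(v[1:(i - 1)] > h)
      min(v[(if (length(higher)) max(higher) else 1):(i - 1)])
    }
    right <- if (i == n) h else {
      higher <- which(v[(i + 1):n] > h)
      lo <- i + 1
      hi <- if (length(higher)) i + min(higher) else n
      min(v[lo:hi])
    }
    data.frame(position = i, height = h, prominence = h - min(left, right))
  })
  out <- do.call(rbind, c(rows, list(data.frame(position = integer(),
                                                height = numeric(),
                                                prominence = numeric()))))
  out[out$prominence >= min_prominence, , drop = FALSE]
}

#' Categorize a cluster centroid as centered, side or ambiguous
#'
#' Local maxima of the centroid with prominence at least
#' `prominence_frac * (max - min)` qualify. The cluster is `centered` when
#' the global qualifying maximum lies within `center_tol_bp` of the window
#' midpoint and no qualifying maximum on the opposite flank exceeds 0.8x
#' its height; `side` when the global maximum lies beyond the tolerance
#' and is not balanced by a comparable (>= 0.8x) maximum on the opposite
#' flank; `ambiguous` otherwise (no qualifying maximum, or balanced
#' multi-modality such as a symmetric bimodal pattern).
#'
#' @param cluster A shape cluster (or bare centroid vector).
#' @param window_bp Total bp extent of the centroid window (default 300).
#' @param center_tol_bp Centering tolerance in bp (default 60).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   centroid range (default 0.25).
#' @return One of `"centered"`, `"side"`, `"ambiguous"`.
#' @export
classify_cluster <- function(cluster, window_bp = 300, center_tol_bp = 60,
                             prominence_frac = 0.25) {
  cen <- if (inherits(cluster, "shape_cluster")) cluster$centroid else cluster
  nb <- length(cen)
  rng <- max(cen) - min(cen)
  if (rng == 0) return("ambiguous")
  pk <- find_peaks(cen, min_prominence = prominence_frac * rng)
  if (!nrow(pk)) return("ambiguous")
  pos_bp <- (pk$position - 0.5) * window_bp / nb - window_bp / 2  # bp offset from midpoint
  h <- pk$height
  gi <- which.max(h)
  gpos <- pos_bp[gi]
  opp <- which(sign(pos_bp) == -sign(gpos) & abs(pos_bp) > center_tol_bp)
  balanced <- length(opp) && any(h[opp] >= 0.8 * h[gi])
  if (abs(gpos) > center_tol_bp) return(if (balanced) "ambiguous" else "side")
  if (balanced) return("ambiguous")
  "centered"
}

#' Categorize every cluster in a clustering result
#'
#' @param result A [cluster_shapes()] result.
#' @inheritParams classify_cluster
#' @return The result with each cluster's `category` filled in.
#' @export
classify_clusters <- function(result, window_bp = 300, center_tol_bp = 60,
                              prominence_frac = 0.25) {
  result$clusters <- lapply(result$clusters, function(cl) {
    cl$category <- classify_cluster(cl, window_bp, center_tol_bp,
                                    prominence_frac)
    cl
  })
  result
}

#' Distance from site summits to the nearest nucleosome summit
#'
#' The nucleosome signal is smoothed by a moving average and local maxima
#' within `search_bp` of each site summit are located; the nearest maximum
#' defines the distance. Sites with no local maximum in the window are `NA`
#' and excluded from the histogram, which is normalized to sum 1 over 10 bp
#' bins of the absolute distance.
#'
#' @param sites Anchor sites.
#' @param nucleosome_track Nucleosome-resolution [signal_track()] (MNase or
#'   a nucleosome-borne histone mark).
#' @param search_bp Search half-window in bp (default 1000).
#' @param smooth_bp Moving-average width in bp (default 30).
#' @param hist_bin_bp Histogram bin width (default 10).
#' @return List with `distance` (signed bp, named by site id),
#'   `abs_distance`, and `histogram` (`data.frame` of bin starts and
#'   normalized frequencies).
#' @export
summit_nucleosome_distances <- function(sites, nucleosome_track,
                                        search_bp = 1000, smooth_bp = 30,
                                        hist_bin_bp = 10) {
  bs <- nucleosome_track$bin_size
  w <- max(1L, round(smooth_bp / bs))
  kern <- rep(1 / w, w)
  smoothed <- lapply(nucleosome_track$values, function(v)
    as.numeric(stats::filter(v, kern, sides = 2)))
  chroms <- as.character(GenomicRanges::seqnames(sites))
  summits <- site_summits(sites)
  dist <- rep(NA_real_, length(sites))
  for (i in seq_along(sites)) {
    v <- smoothed[[chroms[i]]]
    c_bin <- floor(summits[i] / bs)
    lo <- max(0, c_bin - ceiling(search_bp / bs))
    hi <- min(length(v) - 1, c_bin + ceiling(search_bp / bs))
    seg <- v[(lo + 1):(hi + 1)]
    seg[is.na(seg)] <- -Inf
    if (length(seg) < 3) next
    is_max <- seg[2:(length(seg) - 1)] > seg[1:(length(seg) - 2)] &
      seg[2:(length(seg) - 1)] >= seg[3:length(seg)]
    peaks <- which(is_max) + 1
    if (!length(peaks)) next
    peak_bp <- (lo + peaks - 1 + 0.5) * bs
    d <- peak_bp - (summits[i] + 0.5)
    dist[i] <- d[which.min(abs(d))]
  }
  names(dist) <- mcols(sites)$site_id
  ad <- abs(dist[!is.na(dist)])
  if (length(ad)) {
    breaks <- seq(0, ceiling(max(ad) / hist_bin_bp) * hist_bin_bp + hist_bin_bp,
                  by = hist_bin_bp)
    hh <- hist(ad, breaks = breaks, plot = FALSE)
    histogram <- data.frame(bin_start = head(breaks, -1),
                            frequency = hh$counts / sum(hh$counts))
  } else {
    histogram <- data.frame(bin_start = numeric(), frequency = numeric())
  }
  list(distance = dist, abs_distance = abs(dist), histogram = histogram)
}

#' Group composition of each shape cluster
#'
#' Per-cluster fractions of each chromatin-state group plus a chi-squared
#' homogeneity test of composition across clusters (the statistic is ~0
#' when composition is identical across clusters).
#'
#' @param result A [cluster_shapes()] result.
#' @param groups Group labels: a labeled [kmeans_group()] result, or a
#'   named vector/factor keyed by site id.
#' @return List with `fractions` (clusters x groups), `counts`,
#'   `chisq_statistic`, `df`, `p_value`.
#' @export
cluster_composition <- function(result, groups) {
  if (inherits(groups, "group_assignment")) groups <- groups$groups
  labs <- lapply(result$clusters, function(cl) {
    g <- groups[cl$member_ids]
    if (anyNA(g)) stop("member ids missing from group assignment")
    as.character(g)
  })
  all_groups <- sort(unique(unlist(labs)))
  counts <- t(vapply(labs, function(g)
    table(factor(g, levels = all_groups)), numeric(length(all_groups))))
  rownames(counts) <- sprintf("cluster_%02d", seq_len(nrow(counts)))
  fractions <- counts / rowSums(counts)
  use <- counts[, colSums(counts) > 0, drop = FALSE]
  if (nrow(use) > 1 && ncol(use) > 1) {
    ct <- suppressWarnings(chisq.test(use))
    stat <- unname(ct$statistic); df <- unname(ct$parameter)
    p <- unname(ct$p.value)
  } else {
    stat <- 0; df <- 0; p <- 1
  }
  list(fractions = fractions, counts = counts, chisq_statistic = stat,
       df = df, p_value = p)
}
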