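# Shared fixtures: everything is built in code at test time.

# one-chromosome track from a plain numeric vector
tiny_track <- function(values, bin_size = 10, chrom = "chr1", label = "t") {
  sizes <- stats::setNames(length(values) * bin_size, chrom)
  signal_track(stats::setNames(list(values), chrom), bin_size, sizes, label)
}

# scaled-down simulation for fast unit tests
test_config <- function(...) {
  defaults <- list(n_sites = 150L, n_genes = 80L,
                   chrom_sizes = c(simA = 2e6, simB = 1e6))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# brute-force Mann-Whitney: enumerate all C(m+n, m) labelings of the pooled
# sample, U = number of (a, b) pairs with a > b (+ half the ties), two-sided
# p = fraction of labelings with U at least as extreme as observed
mw_enumerate <- function(a, b) {
  pool <- c(a, b)
  m <- length(a)
  u_stat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  combos <- utils::combn(length(pool), m)
  u_all <- apply(combos, 2, function(idx)
    u_stat(pool[idx], pool[-idx]))
  mu <- m * (length(b)) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

# z-scored archetype templates on the standard 300 bp / 30 bin shape grid,
# processed like cluster centroids (same moving-average smoothing)
archetype_matrix <- function(shapes = c("centered", "side_left",
                                        "side_right", "bimodal"),
                             n_bins = 30, window_bp = 300, smooth_bins = 5) {
  x <- -window_bp / 2 + (seq_len(n_bins) - 0.5) * window_bp / n_bins
  sapply(shapes, function(s) {
    v <- shape_template(s, x)
    if (smooth_bins > 1)
      v <- enhancerstrata:::smooth_rows(rbind(v), smooth_bins)[1, ]
    v
  })
}

# flip-aware correlation of a centroid with a template
flip_cor <- function(centroid, template) {
  max(stats::cor(centroid, template), stats::cor(rev(centroid), template))
}

# fraction of clustered profiles sitting in a cluster whose centroid matches
# their true archetype at the given correlation
shape_recovery_fraction <- function(result, truth, min_cor = 0.8) {
  arch <- archetype_matrix(smooth_bins = result$params$smooth_bins)
  ok <- 0; tot <- 0
  for (cl in result$clusters) {
    ts <- truth$shape[match(cl$member_ids, truth$site_id)]
    for (s in unique(ts)) {
      if (!s %in% colnames(arch)) next
      hit <- flip_cor(cl$centroid, arch[, s]) > min_cor
      ok <- ok + sum(ts == s) * hit
      tot <- tot + sum(ts == s)
    }
  }
  ok / tot
}
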