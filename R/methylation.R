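# CpG methylation around site summits
# -----------------------------------
# Per-CpG percent-methylation records (bisulfite coverage-style TSV) are
# collected in fixed windows around summits and stratified by chromatin-
# state group and prebound status; the headline statistic is the fraction
# of CpGs that are un/low-methylated, defined as strictly below 25%.

#' Read / write bisulfite coverage-style CpG records
#'
#' Six tab-separated columns: chrom, start (0-based C of the CpG), end,
#' percent methylation in `[0, 100]`, coverage (>= 1), strand. Merging of
#' the two strands of a CpG pair is the caller's responsibility.
#'
#' @param path File path.
#' @return `data.table` with `chrom`, `position`, `percent_meth`,
#'   `coverage`, `strand`.
#' @export
read_cpgs <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "percent_meth",
                            "coverage", "strand"))
  bad <- which(dt$percent_meth < 0 | dt$percent_meth > 100)
  if (length(bad))
    stop(sprintf("record %d in %s: percent methylation outside [0, 100]",
                 bad[1], path))
  bad <- which(dt$coverage < 1)
  if (length(bad))
    stop(sprintf("record %d in %s: coverage below 1", bad[1], path))
  data.table(chrom = dt$chrom, position = dt$start,
             percent_meth = dt$percent_meth,
             coverage = as.integer(dt$coverage), strand = dt$strand)
}

#' @rdname read_cpgs
#' @param cpgs CpG record table.
#' @export
write_cpgs <- function(cpgs, path) {
  fwrite(data.table(cpgs$chrom, cpgs$position, cpgs$position + 1,
                    cpgs$percent_meth, cpgs$coverage, cpgs$strand),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Scan a genome for CpG dinucleotide positions
#'
#' @param fasta Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @return Named list (per chromosome) of 0-based positions of the C of
#'   each `CG` dinucleotide on the plus strand.
#' @export
scan_cpg_positions <- function(fasta) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
  else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub(" .*", "", names(seqs))
  lapply(as.list(seqs), function(s) {
    hits <- Biostrings::matchPattern("CG", s)
    IRanges::start(hits) - 1
  })
}

#' Smoothed average CpG-density profile around summits
#'
#' Per-position mean CpG occurrence across sites (one column per bp offset
#' in `[-half_window, half_window)`), smoothed by a moving average.
#'
#' @param cpg_positions Per-chromosome list of 0-based CpG positions (from
#'   [scan_cpg_positions()] or a CpG record table's positions), or a CpG
#'   record `data.table`.
#' @param sites Anchor sites.
#' @param half_window Half-window in bp (default 1000).
#' @param smooth_bp Moving-average width in bp (default 50).
#' @return `data.frame` with `offset` (bp from summit) and `density`
#'   (smoothed mean occurrence per bp).
#' @export
cpg_density_profile <- function(cpg_positions, sites, half_window = 1000,
                                smooth_bp = 50) {
  if (is.data.frame(cpg_positions))
    cpg_positions <- split(cpg_positions$position, cpg_positions$chrom)
  stopifnot(length(sites) >= 1)
  chroms <- as.character(GenomicRanges::seqnames(sites))
  summits <- site_summits(sites)
  counts <- numeric(2 * half_window)
  for (chrom in unique(chroms)) {
    pos <- sort(as.numeric(cpg_positions[[chrom]]))
    idx <- which(chroms == chrom)
    if (!length(pos)) next
    for (i in idx) {
      lo <- summits[i] - half_window
      sel <- pos[pos >= lo & pos < summits[i] + half_window]
      off <- sel - lo + 1
      counts[off] <- counts[off] + 1
    }
  }
  dens <- counts / length(sites)
  w <- max(1L, round(smooth_bp))
  sm <- as.numeric(stats::filter(dens, rep(1 / w, w), sides = 2))
  # shrink the moving average at the edges instead of returning NA
  na <- which(is.na(sm))
  for (i in na) {
    lo <- max(1, i - w %/% 2); hi <- min(length(dens), i + w %/% 2)
    sm[i] <- mean(dens[lo:hi])
  }
  data.frame(offset = seq(-half_window, half_window - 1), density = sm)
}

#' CpGs in fixed windows around summits
#'
#' Collects CpGs with coverage at least `min_coverage` whose position lies
#' in `[summit - half_window, summit + half_window)`. When windows overlap,
#' each CpG is assigned to the nearest summit only (ties to the lower
#' coordinate), so stratified counts partition the CpGs.
#'
#' @param cpgs CpG record table ([read_cpgs()] / [simulate_methylome()]).
#' @param sites Anchor sites.
#' @param half_window Half-window in bp (default 300, i.e. the 600 bp
#'   windows used for methylation stratification).
#' @param min_coverage Minimum read coverage (default 1; no coverage filter).
#' @return `data.table` with `site_id`, `offset` (bp from summit, signed)
#'   and `percent_meth`.
#' @export
methylation_at_sites <- function(cpgs, sites, half_window = 300,
                                 min_coverage = 1) {
  cp <- cpgs[cpgs$coverage >= min_coverage, ]
  chroms <- as.character(GenomicRanges::seqnames(sites))
  summits <- site_summits(sites)
  ids <- mcols(sites)$site_id
  out <- vector("list", length(unique(chroms)))
  ci <- 0
  for (chrom in unique(chroms)) {
    ci <- ci + 1
    idx <- which(chroms == chrom)
    ord <- idx[order(summits[idx])]
    s <- summits[ord]
    sel <- cp[cp$chrom == chrom, ]
    if (!nrow(sel) || !length(s)) next
    p <- sel$position
    i <- findInterval(p, s)
    lo_i <- pmax(i, 1); hi_i <- pmin(i + 1, length(s))
    d_lo <- abs(p - s[lo_i]); d_hi <- abs(s[hi_i] - p)
    # nearest summit; tie -> lower coordinate
    nearest <- ifelse(d_lo <= d_hi | i == length(s), lo_i, hi_i)
    nearest[i == 0] <- 1
    off <- p - s[nearest]
    inw <- off >= -half_window & off < half_window
    if (!any(inw)) next
    out[[ci]] <- data.table(site_id = ids[ord][nearest[inw]],
                            offset = off[inw],
                            percent_meth = sel$percent_meth[inw])
  }
  res <- data.table::rbindlist(out)
  if (!nrow(res))
    return(data.table(site_id = character(), offset = numeric(),
                      percent_meth = numeric()))
  res
}

#' Fraction of un/low-methylated values
#'
#' A value is un/low-methylated when strictly below the threshold (default
#' 25%): 24.9 counts, 25.0 does not.
#'
#' @param values Percent-methylation values.
#' @param threshold Strict upper bound (default 25).
#' @return Fraction in `[0, 1]`.
#' @export
unlow_fraction <- function(values, threshold = 25) {
  if (!length(values)) stop("unlow_fraction undefined for an empty list")
  mean(values < threshold)
}

#' Stratified methylation report around sites
#'
#' For each group x prebound stratum (prebound `"yes"`, `"no"` and `"all"`,
#' the latter ignoring the prebound flag) reports the number of CpGs in the
#' windows, the un/low-methylated fraction, and the deciles of the percent-
#' methylation distribution. Strata with zero CpGs are reported as `NA`.
#'
#' @param cpgs CpG record table.
#' @param sites Anchor sites with `group` (and optionally `prebound`) set.
#' @param half_window Half-window in bp (default 300).
#' @param threshold Un/low threshold in percent (default 25, strict).
#' @param min_coverage Minimum coverage (default 1).
#' @return `data.table` with `group`, `prebound`, `n_cpg`, `frac_unlow`
#'   and decile columns `q10` ... `q90`.
#' @export
stratified_methylation_report <- function(cpgs, sites, half_window = 300,
                                          threshold = 25, min_coverage = 1) {
  win <- methylation_at_sites(cpgs, sites, half_window, min_coverage)
  meta <- data.table(site_id = mcols(sites)$site_id,
                     group = as.character(mcols(sites)$group),
                     prebound = mcols(sites)$prebound)
  win <- merge(win, meta, by = "site_id")
  strata <- list()
  qn <- paste0("q", seq(10, 90, 10))
  one <- function(vals, group, prebound) {
    if (!length(vals)) {
      row <- as.list(rep(NA_real_, 2 + length(qn)))
      names(row) <- c("n_cpg", "frac_unlow", qn)
      row$n_cpg <- 0
    } else {
      qq <- quantile(vals, probs = seq(0.1, 0.9, 0.1), names = FALSE)
      row <- c(list(n_cpg = length(vals),
                    frac_unlow = unlow_fraction(vals, threshold)),
               setNames(as.list(qq), qn))
    }
    c(list(group = group, prebound = prebound), row)
  }
  groups <- unique(c(as.character(mcols(sites)$group)))
  for (g in c(groups, "all")) {
    gsel <- if (g == "all") rep(TRUE, nrow(win)) else win$group == g
    strata <- c(strata, list(one(win$percent_meth[gsel], g, "all")))
    for (pb in c(TRUE, FALSE)) {
      sel <- gsel & !is.na(win$prebound) & win$prebound == pb
      strata <- c(strata,
                  list(one(win$percent_meth[sel], g,
                           if (pb) "yes" else "no")))
    }
  }
  data.table::rbindlist(strata)
}
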