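# Coordinate conventions
# ----------------------
# Every file format handled here is BED-style: 0-based, half-open [start, end).
# GRanges objects constructed from such records are 1-based closed, as
# throughout Bioconductor; the conversion happens in exactly one place
# (`gr_from_bed0()` / `bed0_from_gr()`) so that no other code needs to think
# about it. Summits are carried as 0-based absolute bp in metadata columns.

gr_from_bed0 <- function(chrom, start0, end0, strand = "*") {
  if (!length(chrom)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                         strand = strand)
}

bed0_from_gr <- function(gr) {
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Construct summit-anchored binding sites
#'
#' Builds the central site container used by the whole pipeline: a [GRanges]
#' with metadata columns `site_id`, `summit` (0-based absolute bp), `group`
#' (factor over the four chromatin-state strata plus `"unassigned"`),
#' `prebound` and `intergenic` (logical, `NA` when unknown).
#'
#' @param chrom Character vector of chromosome names.
#' @param start0,end0 0-based half-open interval bounds (BED convention).
#' @param summit 0-based summit positions; defaults to the interval midpoint
#'   (floor). Must satisfy `start0 <= summit < end0`.
#' @param site_id Unique identifiers; autogenerated when `NULL`.
#' @param group Group labels, recycled; default `"unassigned"`.
#' @param prebound,intergenic Optional logical flags.
#' @param strand Strand (`"*"` by default; enhancer sites are unstranded).
#' @return A `GRanges` of anchor sites.
#' @export
anchor_sites <- function(chrom, start0, end0, summit = NULL, site_id = NULL,
                         group = "unassigned", prebound = NA,
                         intergenic = NA, strand = "*") {
  n <- length(chrom)
  stopifnot(length(start0) == n, length(end0) == n)
  if (any(start0 < 0) || any(end0 <= start0))
    stop("invalid interval: need 0 <= start < end")
  if (is.null(summit)) summit <- floor((start0 + end0) / 2)
  bad <- which(summit < start0 | summit >= end0)
  if (length(bad))
    stop("summit outside interval for site(s) ", paste(head(bad, 5), collapse = ", "))
  if (is.null(site_id)) site_id <- sprintf("site_%05d", seq_len(n))
  gr <- gr_from_bed0(chrom, start0, end0, strand = strand)
  mcols(gr)$site_id <- as.character(site_id)
  mcols(gr)$summit <- as.numeric(summit)
  mcols(gr)$group <- factor(rep_len(group, n), levels = GROUP_LEVELS)
  mcols(gr)$prebound <- rep_len(as.logical(prebound), n)
  mcols(gr)$intergenic <- rep_len(as.logical(intergenic), n)
  gr
}

#' Summit positions of anchor sites
#'
#' @param sites Anchor sites from [anchor_sites()] or [read_sites()].
#' @return Numeric vector of 0-based summit coordinates.
#' @export
site_summits <- function(sites) mcols(sites)$summit

#' Read summit-anchored sites from BED or narrowPeak
#'
#' narrowPeak column 10 holds the summit offset from the interval start;
#' an offset of -1 (summit not called) falls back to the interval midpoint,
#' as does any plain BED input.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/column count), `"bed"` or
#'   `"narrowPeak"`.
#' @return A `GRanges` of anchor sites (see [anchor_sites()]).
#' @export
read_sites <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty site file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto")
    format <- if (all(nf == 10)) "narrowPeak" else "bed"
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, found %d",
                 bad[1], path, need, nf[bad[1]]))
  get_col <- function(i) vapply(fields, `[[`, "", i)
  chrom <- get_col(1)
  start0 <- suppressWarnings(as.numeric(get_col(2)))
  end0 <- suppressWarnings(as.numeric(get_col(3)))
  badnum <- which(!is.finite(start0) | !is.finite(end0) | start0 < 0 | end0 <= start0)
  if (length(badnum))
    stop(sprintf("malformed line %d in %s: bad interval coordinates", badnum[1], path))
  name <- if (all(nf >= 4)) get_col(4) else sprintf("site_%05d", seq_along(chrom))
  summit <- floor((start0 + end0) / 2)
  if (format == "narrowPeak") {
    off <- suppressWarnings(as.numeric(get_col(10)))
    badoff <- which(!is.finite(off))
    if (length(badoff))
      stop(sprintf("malformed line %d in %s: bad summit offset", badoff[1], path))
    use <- off >= 0
    summit[use] <- start0[use] + off[use]
    out <- which(summit < start0 | summit >= end0)
    if (length(out))
      stop(sprintf("line %d in %s: summit offset outside interval", out[1], path))
  }
  anchor_sites(chrom, start0, end0, summit = summit, site_id = name)
}

#' Write anchor sites as narrowPeak or BED6
#'
#' narrowPeak output round-trips summits exactly; BED6 carries the group
#' label in the name field (`id|group`), the convention used for the
#' classification reports.
#'
#' @param sites Anchor sites.
#' @param path Output file.
#' @param format `"narrowPeak"` or `"bed"`.
#' @export
write_sites <- function(sites, path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  bed <- bed0_from_gr(sites)
  if (format == "narrowPeak") {
    dt <- data.table(bed$chrom, bed$start, bed$end, mcols(sites)$site_id,
                     0L, ".", 0, -1, -1,
                     as.integer(mcols(sites)$summit - bed$start))
  } else {
    dt <- data.table(bed$chrom, bed$start, bed$end,
                     paste0(mcols(sites)$site_id, "|",
                            as.character(mcols(sites)$group)),
                     0L, ".")
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path File with `chrom<TAB>length` records.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "size"))
  setNames(as.numeric(dt$size), dt$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Named numeric vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  fwrite(data.table(names(chrom_sizes), as.numeric(chrom_sizes)), path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- SignalTrack ------------------------------------------------------------

#' Binned genome-wide signal track
#'
#' A light container for one normalized mark/condition signal: one numeric
#' vector per chromosome at a fixed bin size. Bin `i` covers
#' `[(i-1)*bin_size, i*bin_size)` in 0-based coordinates; the last bin may
#' extend past the chromosome end so that `length * bin_size` covers it.
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param label Mark+condition tag.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_sizes, label = "") {
  stopifnot(bin_size >= 1, is.list(values), !is.null(names(values)))
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (any(!is.finite(v))) stop("non-finite signal on ", chrom)
    if (any(v < 0)) stop("negative signal on ", chrom)
    need <- ceiling(chrom_sizes[[chrom]] / bin_size)
    if (length(v) != need)
      stop(sprintf("%s: %d bins do not cover %d bp at bin_size %d",
                   chrom, length(v), chrom_sizes[[chrom]], bin_size))
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes, label = label),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track '%s': %d chromosome(s), bin_size %d bp\n",
              x$label, length(x$values), x$bin_size))
  invisible(x)
}

empty_track_values <- function(chrom_sizes, bin_size) {
  lapply(chrom_sizes, function(n) numeric(ceiling(n / bin_size)))
}

# distribute interval records [start0, end) with values into fixed bins;
# each bin gets integral(value)/bin_size so uncovered bp count as zero
bin_records <- function(v, start0, end, value, bs) {
  aligned <- start0 %% bs == 0 & (end - start0) == bs
  if (any(aligned)) {
    idx <- start0[aligned] / bs + 1
    agg <- rowsum(value[aligned], idx)
    ii <- as.numeric(rownames(agg))
    v[ii] <- v[ii] + agg[, 1]
  }
  rest <- which(!aligned)
  for (r in rest) {
    b0 <- floor(start0[r] / bs)
    b1 <- ceiling(end[r] / bs) - 1
    for (b in b0:b1) {
      ov <- min(end[r], (b + 1) * bs) - max(start0[r], b * bs)
      v[b + 1] <- v[b + 1] + value[r] * ov / bs
    }
  }
  v
}

#' Read a signal track from bedGraph or fixedStep wiggle
#'
#' Records are binned to `bin_size`; the value of a bin is the
#' coverage-weighted mean of overlapping records with uncovered bp counting
#' as zero. Wiggle's 1-based starts are converted to the internal 0-based
#' convention on read.
#'
#' @param path File path (an empty file yields an all-zero track).
#' @param format `"bedGraph"` or `"fixedStep_wig"`.
#' @param bin_size Bin width in bp (default 10).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param label Track tag; defaults to the file name.
#' @return A [signal_track()].
#' @export
read_track <- function(path, format = c("bedGraph", "fixedStep_wig"),
                       bin_size = 10, chrom_sizes, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  vals <- empty_track_values(chrom_sizes, bin_size)
  if (format == "bedGraph") {
    if (file.size(path) == 0)
      return(signal_track(vals, bin_size, chrom_sizes, label))
    dt <- tryCatch(fread(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "value")),
                   error = function(e) stop("malformed bedGraph ", path, ": ",
                                            conditionMessage(e)))
    if (!nrow(dt))
      return(signal_track(vals, bin_size, chrom_sizes, label))
    recs <- dt
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
    decl <- startsWith(lines, "fixedStep")
    if (!length(lines))
      return(signal_track(vals, bin_size, chrom_sizes, label))
    if (!decl[1]) stop("malformed line 1 in ", path, ": expected fixedStep declaration")
    blocks <- cumsum(decl)
    recs_list <- lapply(split(seq_along(lines), blocks), function(ii) {
      hdr <- lines[ii[1]]
      get_attr <- function(key, default = NA) {
        m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
        if (!length(m)) return(default)
        sub(paste0(key, "="), "", m)
      }
      chrom <- get_attr("chrom")
      start1 <- as.numeric(get_attr("start"))
      step <- as.numeric(get_attr("step"))
      span <- as.numeric(get_attr("span", default = step))
      if (is.na(chrom) || !is.finite(start1) || !is.finite(step))
        stop("malformed fixedStep declaration in ", path, ": ", hdr)
      value <- as.numeric(lines[ii[-1]])
      if (anyNA(value))
        stop("malformed value line ", ii[-1][which(is.na(value))[1]], " in ", path)
      n <- length(value)
      if (!n) return(NULL)
      s0 <- (start1 - 1) + (seq_len(n) - 1) * step
      data.table(chrom = chrom, start = s0, end = s0 + span, value = value)
    })
    recs <- data.table::rbindlist(recs_list)
    if (!nrow(recs))
      return(signal_track(vals, bin_size, chrom_sizes, label))
  }
  if (any(recs$value < 0)) {
    bad <- which(recs$value < 0)[1]
    stop(sprintf("negative value in record %d of %s", bad, path))
  }
  unknown <- setdiff(unique(recs$chrom), names(chrom_sizes))
  if (length(unknown)) stop("unknown chromosome(s) in ", path, ": ",
                            paste(unknown, collapse = ", "))
  over <- which(recs$end > chrom_sizes[recs$chrom])
  if (length(over))
    stop(sprintf("record %d in %s extends beyond chromosome end", over[1], path))
  for (chrom in unique(recs$chrom)) {
    sel <- recs$chrom == chrom
    vals[[chrom]] <- bin_records(vals[[chrom]], recs$start[sel],
                                 recs$end[sel], recs$value[sel], bin_size)
  }
  signal_track(vals, bin_size, chrom_sizes, label)
}

#' Write a signal track as bedGraph
#'
#' One record per non-zero bin; values printed with enough digits to
#' round-trip at the pipeline's working precision.
#'
#' @param track A [signal_track()].
#' @param path Output file.
#' @export
write_track <- function(track, path) {
  bs <- track$bin_size
  parts <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.table(chrom = chrom, start = (nz - 1) * bs,
               end = pmin(nz * bs, track$chrom_sizes[[chrom]]),
               value = signif(v[nz], 8))
  })
  dt <- data.table::rbindlist(parts)
  if (is.null(dt) || !nrow(dt)) {
    file.create(path)
  } else {
    fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  }
  invisible(path)
}

# integral of the track on one chromosome over arbitrary bp interval edges;
# positions outside the chromosome contribute zero
track_integral_fun <- function(v, bs) {
  C <- c(0, cumsum(v)) * bs
  m <- length(v)
  function(x) {
    x <- pmin(pmax(x, 0), m * bs)
    i <- pmin(floor(x / bs), m - 1)
    C[i + 1] + v[i + 1] * (x - i * bs)
  }
}

#' Extract a summit-centered signal profile
#'
#' Returns the mean signal in `n_bins` equal bins spanning
#' `[summit - half_window, summit + half_window)`. Positions outside the
#' chromosome are zero-padded. With `orient = TRUE` the vector is reversed
#' for minus-strand sites; enhancer sites are unstranded so orientation is
#' off by default.
#'
#' @param track A [signal_track()].
#' @param site A single anchor site (`GRanges` of length 1).
#' @param half_window Half-window in bp; `2 * half_window` must be divisible
#'   by `n_bins`.
#' @param n_bins Number of profile bins.
#' @param orient Reverse the profile for minus-strand sites?
#' @return Numeric vector of length `n_bins`.
#' @export
extract_profile <- function(track, site, half_window, n_bins, orient = FALSE) {
  stopifnot(length(site) == 1)
  extract_profiles(track, site, half_window, n_bins, orient)[1, ]
}

#' Extract profiles for many sites at once
#'
#' @inheritParams extract_profile
#' @param sites Anchor sites (`GRanges`).
#' @return Matrix of `length(sites)` rows by `n_bins` columns, with row
#'   names taken from the `site_id` column.
#' @export
extract_profiles <- function(track, sites, half_window, n_bins,
                             orient = FALSE) {
  if ((2 * half_window) %% n_bins != 0)
    stop("2 * half_window must be divisible by n_bins")
  w <- 2 * half_window / n_bins
  chroms <- as.character(GenomicRanges::seqnames(sites))
  summits <- site_summits(sites)
  strands <- as.character(GenomicRanges::strand(sites))
  out <- matrix(0, length(sites), n_bins)
  for (chrom in unique(chroms)) {
    if (is.null(track$values[[chrom]]))
      stop("track has no chromosome ", chrom)
    Fint <- track_integral_fun(track$values[[chrom]], track$bin_size)
    idx <- which(chroms == chrom)
    for (i in idx) {
      edges <- summits[i] - half_window + (0:n_bins) * w
      out[i, ] <- diff(Fint(edges)) / w
    }
  }
  if (orient) {
    flip <- strands == "-"
    out[flip, ] <- out[flip, n_bins:1, drop = FALSE]
  }
  rownames(out) <- mcols(sites)$site_id
  out
}

#' Rebin a track to a coarser bin size
#'
#' @param track A [signal_track()].
#' @param bin_size New bin width in bp.
#' @return A [signal_track()] at the new resolution (coverage-weighted
#'   means).
#' @export
rebin_track <- function(track, bin_size) {
  vals <- lapply(names(track$values), function(chrom) {
    Fint <- track_integral_fun(track$values[[chrom]], track$bin_size)
    n <- ceiling(track$chrom_sizes[[chrom]] / bin_size)
    edges <- (0:n) * bin_size
    diff(Fint(edges)) / bin_size
  })
  names(vals) <- names(track$values)
  signal_track(vals, bin_size, track$chrom_sizes, track$label)
}

# ---- FeatureSet -------------------------------------------------------------

#' Build a named feature-interval set
#'
#' @param chrom,start0,end0 BED-style interval columns (0-based half-open).
#' @param name Set label.
#' @return A sorted `GRanges` with a `feature_set` name attribute.
#' @export
feature_set <- function(chrom, start0, end0, name = "features") {
  gr <- sort(gr_from_bed0(chrom, start0, end0))
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Read a BED3+ file as a feature set
#'
#' @param path BED file.
#' @param name Set label; defaults to the file name.
#' @export
read_features <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  dt <- fread(path, header = FALSE, select = 1:3,
              col.names = c("chrom", "start", "end"))
  feature_set(dt$chrom, dt$start, dt$end, name)
}

#' @rdname feature_set
#' @param features A feature set.
#' @param path Output BED3 file.
#' @export
write_features <- function(features, path) {
  fwrite(bed0_from_gr(features), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Fraction of sites whose summit (+/- slop) hits a feature
#'
#' Intersection is half-open on both sides, so a summit interval abutting a
#' feature does not count.
#'
#' @param sites Anchor sites.
#' @param features Feature set (`GRanges`).
#' @param slop Symmetric extension of the summit in bp.
#' @return Proportion in `[0, 1]`.
#' @export
overlap_proportion <- function(sites, features, slop = 0) {
  if (!length(sites)) stop("overlap proportion undefined for empty site list")
  stopifnot(slop >= 0)
  s <- site_summits(sites)
  q <- gr_from_bed0(as.character(GenomicRanges::seqnames(sites)),
                    pmax(s - slop, 0), s + slop + 1)
  mean(IRanges::overlapsAny(q, features))
}

# genes --------------------------------------------------------------------

#' Construct gene models
#'
#' @param chrom,start0,end0 Gene body interval (0-based half-open).
#' @param strand `"+"` or `"-"`; the TSS is `start0` on plus and `end0 - 1`
#'   on minus strand.
#' @param gene_id Identifiers.
#' @param expression_category One of `r toString(EXPR_LEVELS)`.
#' @param expression_change log2 fold change upon stimulation.
#' @return A `GRanges` with gene metadata columns, including the derived
#'   0-based `tss`.
#' @export
gene_models <- function(chrom, start0, end0, strand, gene_id = NULL,
                        expression_category = "not_expressed",
                        expression_change = 0) {
  n <- length(chrom)
  if (is.null(gene_id)) gene_id <- sprintf("gene_%05d", seq_len(n))
  gr <- gr_from_bed0(chrom, start0, end0, strand = strand)
  mcols(gr)$gene_id <- as.character(gene_id)
  mcols(gr)$tss <- ifelse(strand == "+", start0, end0 - 1)
  mcols(gr)$expression_category <- factor(rep_len(expression_category, n),
                                          levels = EXPR_LEVELS)
  mcols(gr)$expression_change <- rep_len(as.numeric(expression_change), n)
  gr
}

#' Read/write gene tables (BED6+2)
#'
#' Columns: chrom, start, end, gene_id, score, strand, expression_category,
#' expression_change.
#'
#' @param path File path.
#' @export
read_genes <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "gene_id", "score",
                            "strand", "expression_category",
                            "expression_change"))
  gene_models(dt$chrom, dt$start, dt$end, dt$strand, dt$gene_id,
              dt$expression_category, dt$expression_change)
}

#' @rdname read_genes
#' @param genes Gene models.
#' @export
write_genes <- function(genes, path) {
  bed <- bed0_from_gr(genes)
  fwrite(data.table(bed$chrom, bed$start, bed$end, mcols(genes)$gene_id, 0L,
                    as.character(GenomicRanges::strand(genes)),
                    as.character(mcols(genes)$expression_category),
                    mcols(genes)$expression_change),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
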