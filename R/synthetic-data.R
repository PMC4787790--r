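# Ground-truth simulator
# ----------------------
# Generates sites, signal tracks, a methylome, genes and auxiliary feature
# sets with the statistical structure the downstream analysis assumes:
# four chromatin-state groups with mark-amplitude structure, local profile
# shape archetypes (centered / side / bimodal / flat), group-dependent CpG
# methylation Beta mixtures, strand-specific divergent eRNA signal with
# time-dependent induction, and genes whose E2-response category is tied to
# nearby sites. A ground-truth manifest accompanies every simulation so that
# recovery tests never have to peek at internal state.

SIM_MARKS <- c("ERalpha", "H2AZ", "H3K4me1", "H3K27ac", "H3K4me3", "DNase",
               "MNase")
SIM_TIMEPOINTS <- c(0, 10, 40)

default_mark_amplitudes <- function() {
  amps <- rbind(
    active_w_H2AZ  = c(ERalpha = 7.0, H2AZ = 6.0, H3K4me1 = 5.0,
                       H3K27ac = 6.0, H3K4me3 = 0.3, DNase = 6.0, MNase = 4.0),
    active_wo_H2AZ = c(ERalpha = 5.0, H2AZ = 0.4, H3K4me1 = 5.0,
                       H3K27ac = 5.0, H3K4me3 = 0.3, DNase = 3.0, MNase = 4.0),
    weak           = c(ERalpha = 2.5, H2AZ = 0.3, H3K4me1 = 4.0,
                       H3K27ac = 0.6, H3K4me3 = 0.2, DNase = 1.5, MNase = 3.0),
    inactive       = c(ERalpha = 1.0, H2AZ = 0.2, H3K4me1 = 0.3,
                       H3K27ac = 0.2, H3K4me3 = 0.2, DNase = 0.8, MNase = 2.5),
    decoy          = c(ERalpha = 2.0, H2AZ = 3.0, H3K4me1 = 2.0,
                       H3K27ac = 2.0, H3K4me3 = 6.0, DNase = 3.0, MNase = 3.0))
  amps
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults that
#' define the study conditions exercised by the recovery tests: 2000 sites in
#' four groups at 20/55/15/10%, a shape mixture dominated by centered
#' profiles, negative-binomial counting noise, Beta-mixture methylation with
#' 82% / 46% sub-25% mass for the two active groups, and eRNA induction
#' factors (1, 2, 4) at 0/10/40 min for the H2A.Z group only.
#'
#' @param seed Integer seed; the generator derives fixed substreams from it.
#' @param n_sites Number of true (non-decoy) sites.
#' @param group_proportions Four proportions over the chromatin-state groups,
#'   summing to 1.
#' @param shape_mixture Five proportions over
#'   centered/side_left/side_right/bimodal/flat, summing to 1.
#' @param mark_amplitudes Numeric matrix, groups (plus `"decoy"`) by marks.
#' @param noise_model `"negbin"`, `"poisson"` or `"none"`.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param count_scale Sequencing-depth factor: counts are drawn at
#'   `count_scale * mu` and divided back, so larger values mean less noise.
#' @param background Baseline signal level of every track.
#' @param sigma_bp Width (sd, bp) of the fine-structure bumps.
#' @param offset_bp Displacement of side/bimodal bumps from the summit.
#' @param broad_sigma_bp Width of the broad enrichment envelope.
#' @param decoy_fraction Fraction of extra promoter-contaminant sites with
#'   high H3K4me3 added on top of `n_sites`.
#' @param prebound_prob Per-group probability of basal (pre-stimulation)
#'   occupancy.
#' @param meth_low_weight Named per-group low-methylation mixture weights for
#'   not-prebound sites; prebound sites use `meth_low_weight_prebound`.
#' @param meth_low_weight_prebound Low-component weight at prebound sites.
#' @param meth_beta_low,meth_beta_high Beta shape parameter pairs of the
#'   low/high mixture components (on the 0-1 scale; values reported as %).
#' @param cpg_rate_core Named per-group expected CpG count in the central
#'   600 bp window.
#' @param cpg_rate_flank Expected CpG count per flank (600-2000 bp).
#' @param coverage_mean Mean extra bisulfite coverage (coverage is
#'   `1 + Poisson(coverage_mean)`).
#' @param erna_amplitude Named per-group eRNA bump amplitude at baseline.
#' @param induction Matrix groups x 3 of multiplicative eRNA factors at 0,
#'   10 and 40 min.
#' @param gene_shift_mu Mean log2 expression change of E2-up genes linked to
#'   each active group (the configured group shift is their difference).
#' @param n_genes Number of genes.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param site_halfwidth Half-width of the site interval around the summit.
#' @param min_gap Minimum distance between neighbouring summits.
#' @param edge_margin Minimum distance of a summit from a chromosome end.
#' @param ... Unused; any unrecognised key raises an error.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_sites = 2000L,
                              group_proportions = c(0.20, 0.55, 0.15, 0.10),
                              shape_mixture = c(centered = 0.45,
                                                side_left = 0.15,
                                                side_right = 0.15,
                                                bimodal = 0.20,
                                                flat = 0.05),
                              mark_amplitudes = default_mark_amplitudes(),
                              noise_model = c("negbin", "poisson", "none"),
                              dispersion = 0.2,
                              count_scale = 20,
                              background = 0.2,
                              sigma_bp = 40,
                              offset_bp = 100,
                              broad_sigma_bp = 700,
                              decoy_fraction = 0.1,
                              prebound_prob = c(active_w_H2AZ = 0.4,
                                                active_wo_H2AZ = 0.4,
                                                weak = 0.4, inactive = 0.4),
                              meth_low_weight = c(active_w_H2AZ = 0.80,
                                                  active_wo_H2AZ = 0.20,
                                                  weak = 0.25,
                                                  inactive = 0.20),
                              meth_low_weight_prebound = 0.85,
                              meth_beta_low = c(1, 30),
                              meth_beta_high = c(8, 4),
                              cpg_rate_core = c(active_w_H2AZ = 30,
                                                active_wo_H2AZ = 18,
                                                weak = 15, inactive = 12),
                              cpg_rate_flank = 10,
                              coverage_mean = 20,
                              erna_amplitude = c(active_w_H2AZ = 2,
                                                 active_wo_H2AZ = 2,
                                                 weak = 0.5, inactive = 0.2),
                              induction = rbind(active_w_H2AZ = c(1, 2, 4),
                                                active_wo_H2AZ = c(1, 1, 1),
                                                weak = c(1, 1, 1),
                                                inactive = c(1, 1, 1)),
                              gene_shift_mu = c(active_w_H2AZ = 1.5,
                                                active_wo_H2AZ = 1.0),
                              n_genes = 400L,
                              chrom_sizes = c(simA = 2e7, simB = 1e7),
                              site_halfwidth = 200,
                              min_gap = 5000,
                              edge_margin = 4000,
                              ...) {
  noise_model <- match.arg(noise_model)
  extra <- names(list(...))
  if (length(extra)) stop("unknown configuration key(s): ",
                          paste(extra, collapse = ", "))
  cfg <- as.list(environment())
  cfg$extra <- NULL
  if (abs(sum(cfg$group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1")
  if (abs(sum(cfg$shape_mixture) - 1) > 1e-9)
    stop("shape_mixture must sum to 1")
  if (any(cfg$mark_amplitudes < 0)) stop("amplitudes must be >= 0")
  stopifnot(cfg$n_sites >= 1)
  class(cfg) <- "simulation_config"
  cfg
}

# fixed substream seeds so each stage is reproducible independently
sim_seed <- function(config, stage) {
  (as.integer(config$seed) + 1009L * match(stage, c("sites", "tracks",
                                                    "methylome", "genes",
                                                    "features"))) %% .Machine$integer.max
}

#' Fine-structure shape templates
#'
#' Unit-height archetype profiles evaluated at bp offsets from the summit:
#' a single Gaussian bump at the summit (`centered`), displaced by
#' `-offset_bp`/`+offset_bp` (`side_left`/`side_right`), two bumps at
#' `+/-offset_bp` (`bimodal`), or zero (`flat`).
#'
#' @param shape One of `r toString(SHAPE_LEVELS)`.
#' @param x Numeric vector of bp offsets.
#' @param sigma_bp Bump sd in bp.
#' @param offset_bp Side/bimodal displacement in bp.
#' @export
shape_template <- function(shape, x, sigma_bp = 40, offset_bp = 100) {
  g <- function(mu) exp(-(x - mu)^2 / (2 * sigma_bp^2))
  switch(shape,
         centered = g(0),
         side_left = g(-offset_bp),
         side_right = g(offset_bp),
         bimodal = g(-offset_bp) + g(offset_bp),
         flat = rep(0, length(x)),
         stop("unknown shape: ", shape))
}

place_positions <- function(n, lo, hi, gap) {
  span <- hi - lo - (n - 1) * gap
  if (span <= 0)
    stop("chromosome too small to place ", n, " sites with spacing ", gap)
  lo + sort(runif(n, 0, span)) + (seq_len(n) - 1) * gap
}

#' Simulate summit-anchored sites with ground truth
#'
#' Sites are placed per chromosome (proportionally to length) at least
#' `min_gap` apart and `edge_margin` from the ends; each true site draws a
#' group from `group_proportions`, a shape archetype from `shape_mixture`
#' and a prebound flag; an extra `decoy_fraction` of promoter-contaminant
#' sites is added. Deterministic under a fixed config seed.
#'
#' @param config A [simulation_config()].
#' @return `list(sites = GRanges, truth = data.table)` where `truth` holds
#'   one row per site: `site_id`, `chrom`, `summit`, `group` (including
#'   `"decoy"`), `shape`, `prebound`, `decoy`.
#' @export
simulate_sites <- function(config) {
  withr::with_seed(sim_seed(config, "sites"), {
    n_decoy <- round(config$decoy_fraction * config$n_sites)
    n_total <- config$n_sites + n_decoy
    sizes <- config$chrom_sizes
    n_per <- floor(n_total * sizes / sum(sizes))
    n_per[1] <- n_per[1] + (n_total - sum(n_per))
    pos <- lapply(names(sizes), function(chrom) {
      round(place_positions(n_per[[chrom]], config$edge_margin,
                            sizes[[chrom]] - config$edge_margin,
                            config$min_gap))
    })
    chrom <- rep(names(sizes), lengths(pos))
    summit <- unlist(pos, use.names = FALSE)
    n <- length(summit)
    is_decoy <- seq_len(n) %in% sample.int(n, n_decoy)
    group <- rep("decoy", n)
    group[!is_decoy] <- sample(GROUP_LEVELS[1:4], sum(!is_decoy),
                               replace = TRUE, prob = config$group_proportions)
    shape <- rep("centered", n)
    shape[!is_decoy] <- sample(names(config$shape_mixture), sum(!is_decoy),
                               replace = TRUE, prob = config$shape_mixture)
    prebound <- rep(FALSE, n)
    pg <- config$prebound_prob[group[!is_decoy]]
    prebound[!is_decoy] <- runif(sum(!is_decoy)) < pg
    hw <- config$site_halfwidth
    sites <- anchor_sites(chrom, summit - hw, summit + hw, summit = summit,
                          site_id = sprintf("site_%05d", seq_len(n)))
    truth <- data.table(site_id = mcols(sites)$site_id, chrom = chrom,
                        summit = summit, group = group, shape = shape,
                        prebound = prebound, decoy = is_decoy)
    list(sites = sites, truth = truth)
  })
}

noise_draw <- function(mu, config) {
  k <- config$count_scale
  switch(config$noise_model,
         none = mu,
         poisson = rpois(length(mu), mu * k) / k,
         negbin = rnbinom(length(mu), mu = mu * k,
                          size = 1 / config$dispersion) / k)
}

# Per-mark profile composition: chromatin-state marks are broad-dominant
# (domain-level enrichment over ~kb, what the 2 kb classification window
# measures), nucleosome-positioning signals are fine-dominant (nucleosome-
# scale structure, what the 300 bp shape window measures). Point-source
# signals (TF, DNase cut density, promoter H3K4me3) are always centered.
MARK_PROFILE <- list(
  ERalpha = list(fine = "centered", fine_w = 1.0, broad_w = 0.3, sigma = 30),
  H2AZ    = list(fine = "shape",    fine_w = 0.4, broad_w = 1.0),
  H3K4me1 = list(fine = "shape",    fine_w = 1.5, broad_w = 1.0),
  H3K27ac = list(fine = "shape",    fine_w = 0.4, broad_w = 1.0),
  H3K4me3 = list(fine = "centered", fine_w = 0.8, broad_w = 1.0, sigma = 80),
  DNase   = list(fine = "centered", fine_w = 0.8, broad_w = 0.5, sigma = 60),
  MNase   = list(fine = "shape",    fine_w = 1.5, broad_w = 1.0))

# expected (noise-free) signal added by one site to one mark, at bp offsets x
site_mark_signal <- function(mark, group, shape, x, config) {
  amp <- config$mark_amplitudes[group, mark]
  prof <- MARK_PROFILE[[mark]]
  broad <- exp(-x^2 / (2 * config$broad_sigma_bp^2))
  fine_shape <- if (prof$fine == "shape") shape else prof$fine
  sigma <- if (is.null(prof$sigma)) config$sigma_bp else prof$sigma
  fine <- shape_template(fine_shape, x, sigma, config$offset_bp)
  amp * (prof$broad_w * broad + prof$fine_w * fine)
}

#' Simulate signal tracks for all marks
#'
#' Expected signal per bin is `background + amplitude(group, mark) *
#' (0.5 * broad envelope + fine shape template)`; counting noise is then
#' drawn per bin from the configured noise model at depth `count_scale` and
#' scaled back. Marks: ERalpha, H2AZ, H3K4me1, H3K27ac, H3K4me3 (elevated
#' only at decoy promoter-contaminant sites), DNase, MNase, and
#' strand-specific eRNA tracks `eRNA_plus_t{0,10,40}` / `eRNA_minus_t*`
#' with divergent bumps (plus right of the summit, minus left) scaled by the
#' per-group induction factors.
#'
#' @param sites,truth Output of [simulate_sites()].
#' @param config A [simulation_config()].
#' @param marks Subset of track labels to generate (default: all).
#' @param bin_size Track resolution in bp.
#' @return Named list of [signal_track()] objects.
#' @export
simulate_tracks <- function(sites, truth, config, marks = NULL,
                            bin_size = 10) {
  all_marks <- c(SIM_MARKS,
                 paste0("eRNA_plus_t", SIM_TIMEPOINTS),
                 paste0("eRNA_minus_t", SIM_TIMEPOINTS))
  if (is.null(marks)) marks <- all_marks
  unknown <- setdiff(marks, all_marks)
  if (length(unknown)) stop("unknown mark(s): ", paste(unknown, collapse = ", "))
  withr::with_seed(sim_seed(config, "tracks"), {
    sizes <- config$chrom_sizes
    reach <- 2500  # bp beyond which site contributions are negligible
    out <- list()
    for (mark in marks) {
      vals <- lapply(sizes, function(L)
        rep(config$background, ceiling(L / bin_size)))
      is_erna <- grepl("^eRNA_", mark)
      tp_idx <- if (is_erna)
        match(as.numeric(sub(".*_t", "", mark)), SIM_TIMEPOINTS)
      erna_sign <- if (grepl("plus", mark)) 1 else -1
      for (i in seq_len(nrow(truth))) {
        chrom <- truth$chrom[i]
        m <- length(vals[[chrom]])
        b0 <- max(0, floor((truth$summit[i] - reach) / bin_size))
        b1 <- min(m - 1, floor((truth$summit[i] + reach) / bin_size))
        bins <- b0:b1
        x <- (bins + 0.5) * bin_size - truth$summit[i]
        grp <- truth$group[i]
        if (is_erna) {
          if (grp == "decoy") next
          amp <- config$erna_amplitude[grp] * config$induction[grp, tp_idx]
          add <- amp * exp(-(x - erna_sign * 150)^2 / (2 * 60^2))
        } else {
          add <- site_mark_signal(mark, grp, truth$shape[i], x, config)
        }
        vals[[chrom]][bins + 1] <- vals[[chrom]][bins + 1] + add
      }
      vals <- lapply(vals, function(v) noise_draw(v, config))
      out[[mark]] <- signal_track(vals, bin_size, sizes, label = mark)
    }
    out
  })
}

#' Simulate a per-CpG methylome around the sites
#'
#' CpG positions are placed with group-dependent density in the central
#' 600 bp window (highest for the H2A.Z group) and a common lower density in
#' the 600-2000 bp flanks. Percent methylation is drawn from a two-component
#' Beta mixture whose low-methylation weight depends on group and prebound
#' status; coverage is `1 + Poisson(coverage_mean)`.
#'
#' @inheritParams simulate_tracks
#' @return `data.table` with `chrom`, `position` (0-based bp),
#'   `percent_meth` in `[0, 100]`, `coverage`, `strand`.
#' @export
simulate_methylome <- function(sites, truth, config) {
  withr::with_seed(sim_seed(config, "methylome"), {
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      grp <- truth$group[i]
      rate_core <- if (grp == "decoy") 20 else config$cpg_rate_core[[grp]]
      n_core <- rpois(1, rate_core)
      n_flank <- rpois(1, config$cpg_rate_flank)
      if (n_core + n_flank == 0) next
      off_core <- round(runif(n_core, -300, 300))
      off_flank <- round(runif(n_flank, 600, 2000)) *
        sample(c(-1, 1), n_flank, replace = TRUE)
      offs <- c(off_core, off_flank)
      pos <- truth$summit[i] + offs
      pos <- pos[pos >= 0 & pos < config$chrom_sizes[[truth$chrom[i]]]]
      n <- length(pos)
      if (!n) next
      w_low <- if (grp == "decoy") 0.8
      else if (truth$prebound[i]) config$meth_low_weight_prebound
      else config$meth_low_weight[[grp]]
      low <- runif(n) < w_low
      pm <- numeric(n)
      pm[low] <- rbeta(sum(low), config$meth_beta_low[1],
                       config$meth_beta_low[2]) * 100
      pm[!low] <- rbeta(sum(!low), config$meth_beta_high[1],
                        config$meth_beta_high[2]) * 100
      rows[[i]] <- data.table(chrom = truth$chrom[i], position = pos,
                              percent_meth = pm,
                              coverage = 1L + rpois(n, config$coverage_mean))
    }
    cpgs <- data.table::rbindlist(rows)
    if (!nrow(cpgs))
      return(data.table(chrom = character(), position = numeric(),
                        percent_meth = numeric(), coverage = integer(),
                        strand = character()))
    cpgs[, strand := "+"]
    setorder(cpgs, chrom, position)
    cpgs
  })
}

#' Simulate genes with E2-response categories tied to nearby sites
#'
#' E2-up genes are spawned near sites of the two active groups, with a
#' larger mean log2 expression change when the responsible site carries
#' H2A.Z (`gene_shift_mu`); E2-down, unchanged and not-expressed genes are
#' placed away from summits. By construction a gene further than 1 Mb from
#' every site is never E2-up.
#'
#' @inheritParams simulate_tracks
#' @return `list(genes = GRanges, gene_truth = data.table)`; `gene_truth`
#'   holds `gene_id`, `category` and the responsible `site_id` (`NA` for
#'   unlinked genes).
#' @export
simulate_genes <- function(sites, truth, config) {
  stopifnot(config$n_genes >= 4)
  withr::with_seed(sim_seed(config, "genes"), {
    n <- config$n_genes
    n_up <- round(0.30 * n); n_down <- round(0.10 * n)
    n_unch <- round(0.35 * n); n_off <- n - n_up - n_down - n_unch
    category <- c(rep("E2_up", n_up), rep("E2_down", n_down),
                  rep("expressed_unchanged", n_unch),
                  rep("not_expressed", n_off))
    active <- truth[truth$group %in% c("active_w_H2AZ", "active_wo_H2AZ"), ]
    summits_by_chrom <- split(truth$summit, truth$chrom)
    keep_clear <- function(chrom, tss) {
      s <- summits_by_chrom[[chrom]]
      lim <- config$chrom_sizes[[chrom]] - 2000
      tss <- min(max(tss, 2000), lim)
      for (k in 1:200) {
        if (!length(s) || min(abs(s - tss)) >= 4000) break
        tss <- tss + 5000
        if (tss > lim) tss <- round(runif(1, 2000, lim))
      }
      tss
    }
    chrom <- character(n); tss <- numeric(n); resp <- rep(NA_character_, n)
    for (j in seq_len(n)) {
      if (category[j] == "E2_up" && nrow(active)) {
        i <- sample.int(nrow(active), 1)
        chrom[j] <- active$chrom[i]
        tss[j] <- active$summit[i] +
          sample(c(-1, 1), 1) * round(runif(1, 10000, 60000))
        resp[j] <- active$site_id[i]
      } else {
        chrom[j] <- sample(names(config$chrom_sizes), 1,
                           prob = config$chrom_sizes)
        tss[j] <- round(runif(1, 2000, config$chrom_sizes[[chrom[j]]] - 2000))
      }
      tss[j] <- keep_clear(chrom[j], tss[j])
    }
    shift <- setNames(rep(0, nrow(truth) + 1), c(truth$site_id, "none"))
    act_groups <- intersect(truth$group, names(config$gene_shift_mu))
    for (g in act_groups)
      shift[truth$site_id[truth$group == g]] <- config$gene_shift_mu[[g]]
    change <- numeric(n)
    up_resp <- resp[category == "E2_up"]
    up_resp[is.na(up_resp)] <- "none"
    change[category == "E2_up"] <- rnorm(n_up, mean = shift[up_resp], sd = 0.5)
    change[category == "E2_down"] <- rnorm(n_down, mean = -1, sd = 0.5)
    change[category == "expressed_unchanged"] <- rnorm(n_unch, 0, 0.15)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- round(runif(n, 2000, 30000))
    start0 <- ifelse(strand == "+", tss, pmax(tss + 1 - len, 0))
    end0 <- ifelse(strand == "+",
                   pmin(tss + len, config$chrom_sizes[chrom]), tss + 1)
    genes <- gene_models(chrom, start0, end0, strand,
                         gene_id = sprintf("gene_%04d", seq_len(n)),
                         expression_category = category,
                         expression_change = change)
    gene_truth <- data.table(gene_id = mcols(genes)$gene_id,
                             category = category, site_id = resp)
    list(genes = genes, gene_truth = gene_truth)
  })
}

#' Run the full simulation
#'
#' Chains [simulate_sites()], [simulate_tracks()], [simulate_methylome()]
#' and [simulate_genes()], and derives the auxiliary feature sets the
#' analysis consumes: H3K4me3-enriched regions (around decoy sites),
#' basal-condition peaks (around prebound sites) and pioneer-factor sites.
#'
#' @param config A [simulation_config()].
#' @param marks Track labels to simulate (default all).
#' @return List with `sites`, `truth`, `tracks`, `cpgs`, `genes`,
#'   `gene_truth`, `features` (named list of feature sets) and `config`.
#' @export
simulate_all <- function(config = simulation_config(), marks = NULL) {
  ss <- simulate_sites(config)
  tracks <- simulate_tracks(ss$sites, ss$truth, config, marks = marks)
  cpgs <- simulate_methylome(ss$sites, ss$truth, config)
  gg <- simulate_genes(ss$sites, ss$truth, config)
  tr <- ss$truth
  features <- withr::with_seed(sim_seed(config, "features"), {
    dec <- tr[tr$decoy == TRUE, ]
    h3k4me3 <- feature_set(dec$chrom, pmax(dec$summit - 500, 0),
                           dec$summit + 500, "h3k4me3_peaks")
    pre <- tr[tr$prebound == TRUE, ]
    basal <- feature_set(pre$chrom, pmax(pre$summit - 150, 0),
                         pre$summit + 150, "basal_peaks")
    p_pioneer <- c(active_w_H2AZ = 0.7, active_wo_H2AZ = 0.7, weak = 0.4,
                   inactive = 0.2, decoy = 0.3)[tr$group]
    pio <- tr[runif(nrow(tr)) < p_pioneer, ]
    n_bg <- 200
    bg_chrom <- sample(names(config$chrom_sizes), n_bg, replace = TRUE,
                       prob = config$chrom_sizes)
    bg_pos <- round(runif(n_bg, 1000,
                          config$chrom_sizes[bg_chrom] - 1000))
    pioneer <- feature_set(c(pio$chrom, bg_chrom),
                           pmax(c(pio$summit, bg_pos) - 200, 0),
                           c(pio$summit, bg_pos) + 200, "pioneer_sites")
    list(h3k4me3_peaks = h3k4me3, basal_peaks = basal, pioneer = pioneer)
  })
  list(sites = ss$sites, truth = tr, tracks = tracks, cpgs = cpgs,
       genes = gg$genes, gene_truth = gg$gene_truth, features = features,
       config = config)
}

#' Write a simulation to disk in standard formats
#'
#' Sites as narrowPeak, tracks as bedGraph, CpGs as bisulfite coverage-style
#' TSV, genes as BED6+2, feature sets as BED3, chrom sizes, the ground-truth
#' manifest as TSV, and the configuration as YAML.
#'
#' @param sim Output of [simulate_all()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(file.path(outdir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "features"), showWarnings = FALSE)
  write_sites(sim$sites, file.path(outdir, "sites.narrowPeak"))
  for (mark in names(sim$tracks))
    write_track(sim$tracks[[mark]],
                file.path(outdir, "tracks", paste0(mark, ".bedGraph")))
  write_cpgs(sim$cpgs, file.path(outdir, "cpgs.tsv"))
  write_genes(sim$genes, file.path(outdir, "genes.tsv"))
  for (nm in names(sim$features))
    write_features(sim$features[[nm]],
                   file.path(outdir, "features", paste0(nm, ".bed")))
  write_chrom_sizes(sim$config$chrom_sizes, file.path(outdir, "chrom.sizes"))
  fwrite(sim$truth, file.path(outdir, "manifest.tsv"), sep = "\t")
  fwrite(sim$gene_truth, file.path(outdir, "gene_manifest.tsv"), sep = "\t")
  cfg <- sim$config
  cfg$mark_amplitudes <- as.data.frame(cfg$mark_amplitudes)
  cfg$induction <- as.data.frame(cfg$induction)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  invisible(outdir)
}
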