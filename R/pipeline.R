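# Pipeline orchestration
# ----------------------
# Chains the analysis stages behind one entry point with a flat YAML config,
# per-stage output directories, run logs carrying every effective parameter,
# and deterministic per-stage seed substreams derived from one top-level
# seed. The `enhancer-strata` script under `inst/exec/` is a thin
# command-line wrapper over `run_subcommand()`.

PIPELINE_STAGES <- c("simulate", "classify", "shapes", "methylation",
                     "enrich", "report")

default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "enhancerstrata_run",
    simulate = list(n_sites = 2000L, decoy_fraction = 0.1, n_genes = 400L,
                    noise_model = "negbin"),
    classify = list(half_window = 2000, n_bins = 100, transform = "asinh",
                    k = 4L, n_restarts = 10L, distal_bp = 3000,
                    marks = c("ERalpha", "H2AZ", "H3K27ac", "H3K4me1")),
    shapes = list(mark = "H3K4me1", half_window = 150, n_bins = 30,
                  k_init = 40L, merge_threshold = 0.85, flip = TRUE,
                  center_tol_bp = 60, prominence_frac = 0.25),
    methylation = list(half_window = 300, threshold = 25, min_coverage = 1L),
    enrich = list(basal_up = 5000, basal_down = 1000, max_ext = 1e6,
                  n_shuffles = 200L, erna_half_window = 1000,
                  erna_n_bins = 50))
}

usage_error <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Load and validate a pipeline configuration
#'
#' Flat YAML with one section per stage; unknown keys are rejected; values
#' override the built-in defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults, or a list.
#' @param seed,outdir Optional overrides (e.g. from the command line).
#' @return Validated config list.
#' @export
pipeline_config <- function(path = NULL, seed = NULL, outdir = NULL) {
  cfg <- default_pipeline_config()
  user <- if (is.null(path)) list()
  else if (is.list(path)) path
  else if (!file.exists(path)) usage_error("missing config file: ", path)
  else yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    usage_error("invalid config key(s): ", paste(bad, collapse = ", "))
  for (section in intersect(names(user), PIPELINE_STAGES)) {
    allowed <- names(cfg[[section]])
    if (section == "simulate")  # any generator knob may be overridden
      allowed <- union(allowed, names(formals(simulation_config)))
    bad <- setdiff(names(user[[section]]), allowed)
    if (length(bad))
      usage_error("invalid config key(s) in [", section, "]: ",
                  paste(bad, collapse = ", "))
  }
  cfg <- modifyList(cfg, user)
  if (is.list(cfg$simulate$chrom_sizes))  # YAML maps arrive as lists
    cfg$simulate$chrom_sizes <- unlist(cfg$simulate$chrom_sizes)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  cfg
}

stage_seed <- function(cfg, stage) {
  (as.integer(cfg$seed) + 7919L * match(stage, PIPELINE_STAGES)) %%
    .Machine$integer.max
}

stage_dir <- function(cfg, stage, force = FALSE) {
  d <- file.path(cfg$outdir, stage)
  if (dir.exists(d) && force) unlink(d, recursive = TRUE)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_stage_log <- function(cfg, stage, dir, params) {
  lines <- c(sprintf("stage: %s", stage),
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("enhancerstrata"))),
             sprintf("seed: %d", cfg$seed),
             sprintf("stage_seed: %d", stage_seed(cfg, stage)),
             "parameters:",
             vapply(names(params), function(k)
               sprintf("  %s: %s", k,
                       paste(format(params[[k]]), collapse = ",")),
               ""))
  writeLines(lines, file.path(dir, "log.txt"))
}

write_summary <- function(dir, values) {
  dt <- data.table(
    k = names(values),
    value = vapply(values, function(v)
      paste(format(v, digits = 10), collapse = ","), ""))
  data.table::setnames(dt, "k", "key")
  fwrite(dt, file.path(dir, "summary.tsv"), sep = "\t")
}

read_groups_bed <- function(path) {
  dt <- fread(path, header = FALSE, select = 1:4,
              col.names = c("chrom", "start", "end", "name"))
  parts <- data.table::tstrsplit(dt$name, "|", fixed = TRUE)
  data.table(site_id = parts[[1]], group = parts[[2]])
}

load_sim <- function(cfg) {
  d <- file.path(cfg$outdir, "simulate")
  if (!dir.exists(d)) usage_error("missing simulate outputs under ", d,
                                  "; run the simulate stage first")
  chrom_sizes <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  list(dir = d, chrom_sizes = chrom_sizes,
       sites = read_sites(file.path(d, "sites.narrowPeak")),
       genes = read_genes(file.path(d, "genes.tsv")),
       manifest = if (file.exists(file.path(d, "manifest.tsv")))
         fread(file.path(d, "manifest.tsv")))
}

load_track <- function(cfg, mark, chrom_sizes) {
  p <- file.path(cfg$outdir, "simulate", "tracks", paste0(mark, ".bedGraph"))
  if (!file.exists(p)) usage_error("missing track file: ", p)
  read_track(p, "bedGraph", bin_size = 10, chrom_sizes = chrom_sizes,
             label = mark)
}

stage_simulate <- function(cfg, force = FALSE) {
  dir <- stage_dir(cfg, "simulate", force)
  sc <- do.call(simulation_config,
                c(list(seed = stage_seed(cfg, "simulate")), cfg$simulate))
  sim <- simulate_all(sc)
  write_simulation(sim, dir)
  write_stage_log(cfg, "simulate", dir, cfg$simulate)
  write_summary(dir, list(n_sites = length(sim$sites),
                          n_decoys = sum(sim$truth$decoy),
                          n_genes = length(sim$genes),
                          n_cpgs = nrow(sim$cpgs)))
  invisible(dir)
}

stage_classify <- function(cfg, force = FALSE) {
  dir <- stage_dir(cfg, "classify", force)
  p <- cfg$classify
  sim <- load_sim(cfg)
  k4me3 <- read_features(file.path(sim$dir, "features", "h3k4me3_peaks.bed"))
  basal <- read_features(file.path(sim$dir, "features", "basal_peaks.bed"))
  kept <- filter_distal_nonpromoter(sim$sites, sim$genes, k4me3, p$distal_bp)
  tracks <- lapply(setNames(p$marks, p$marks), load_track, cfg = cfg,
                   chrom_sizes = sim$chrom_sizes)
  mat <- build_matrix(kept, tracks, p$half_window, p$n_bins, p$transform)
  asg <- kmeans_group(mat, k = p$k, seed = stage_seed(cfg, "classify"),
                      n_restarts = p$n_restarts)
  mm <- cluster_mark_means(asg, kept, tracks[c("H2AZ", "H3K27ac", "H3K4me1")])
  asg <- label_groups(asg, mm)
  kept <- apply_groups(kept, asg)
  kept <- split_prebound(kept, basal)
  write_sites(kept, file.path(dir, "groups.bed"), format = "bed")
  fwrite(data.table(cluster = seq_len(p$k), asg$cluster_means),
         file.path(dir, "cluster_means.tsv"), sep = "\t")
  fwrite(data.table(site_id = mcols(kept)$site_id,
                    group = as.character(mcols(kept)$group),
                    prebound = mcols(kept)$prebound),
         file.path(dir, "site_groups.tsv"), sep = "\t")
  summary <- list(n_input = length(sim$sites), n_kept = length(kept),
                  inertia = asg$inertia)
  if (!is.null(sim$manifest)) {
    m <- sim$manifest[match(mcols(kept)$site_id, sim$manifest$site_id), ]
    summary$ari <- adjusted_rand_index(as.character(mcols(kept)$group),
                                       m$group)
    summary$frac_active_w_H2AZ <-
      mean(mcols(kept)$group == "active_w_H2AZ")
  }
  write_stage_log(cfg, "classify", dir, p)
  write_summary(dir, summary)
  invisible(dir)
}

classified_sites <- function(cfg) {
  d <- file.path(cfg$outdir, "classify")
  if (!dir.exists(d)) usage_error("missing classify outputs under ", d)
  sim <- load_sim(cfg)
  sg <- fread(file.path(d, "site_groups.tsv"))
  sites <- sim$sites[match(sg$site_id, mcols(sim$sites)$site_id)]
  mcols(sites)$group <- factor(sg$group, levels = GROUP_LEVELS)
  mcols(sites)$prebound <- sg$prebound
  list(sites = sites, sim = sim)
}

stage_shapes <- function(cfg, force = FALSE) {
  dir <- stage_dir(cfg, "shapes", force)
  p <- cfg$shapes
  cs <- classified_sites(cfg)
  active <- cs$sites[mcols(cs$sites)$group %in%
                       c("active_w_H2AZ", "active_wo_H2AZ")]
  track <- load_track(cfg, p$mark, cs$sim$chrom_sizes)
  prof <- extract_profiles(track, active, p$half_window, p$n_bins)
  res <- cluster_shapes(prof, k_init = p$k_init, flip = p$flip,
                        merge_threshold = p$merge_threshold,
                        seed = stage_seed(cfg, "shapes"))
  res <- classify_clusters(res, window_bp = 2 * p$half_window,
                           center_tol_bp = p$center_tol_bp,
                           prominence_frac = p$prominence_frac)
  cen <- t(vapply(res$clusters, `[[`, numeric(p$n_bins), "centroid"))
  fwrite(data.table(cluster = seq_len(nrow(cen)),
                    category = vapply(res$clusters, `[[`, "", "category"),
                    size = vapply(res$clusters, `[[`, 0L, "size"), cen),
         file.path(dir, "centroids.tsv"), sep = "\t")
  mem <- data.table::rbindlist(lapply(seq_along(res$clusters), function(j)
    data.table(site_id = res$clusters[[j]]$member_ids, cluster = j,
               orientation = res$clusters[[j]]$orientation)))
  fwrite(mem, file.path(dir, "membership.tsv"), sep = "\t")
  grp <- setNames(as.character(mcols(cs$sites)$group),
                  mcols(cs$sites)$site_id)
  comp <- cluster_composition(res, grp)
  fwrite(data.table(cluster = rownames(comp$fractions), comp$fractions),
         file.path(dir, "composition.tsv"), sep = "\t")
  dist <- summit_nucleosome_distances(active, track)
  fwrite(dist$histogram, file.path(dir, "summit_distance_histogram.tsv"),
         sep = "\t")
  write_stage_log(cfg, "shapes", dir, p)
  write_summary(dir, list(
    n_profiles = length(active), n_clusters = length(res$clusters),
    n_low_signal = length(res$discarded_low_signal),
    composition_chisq_p = comp$p_value,
    frac_centered = mean(vapply(res$clusters, `[[`, "",
                                "category") == "centered")))
  invisible(dir)
}

stage_methylation <- function(cfg, force = FALSE) {
  dir <- stage_dir(cfg, "methylation", force)
  p <- cfg$methylation
  cs <- classified_sites(cfg)
  cpgs <- read_cpgs(file.path(cs$sim$dir, "cpgs.tsv"))
  rep <- stratified_methylation_report(cpgs, cs$sites, p$half_window,
                                       p$threshold, p$min_coverage)
  fwrite(rep, file.path(dir, "methylation_report.tsv"), sep = "\t")
  dens <- cpg_density_profile(cpgs, cs$sites)
  fwrite(dens, file.path(dir, "cpg_density.tsv"), sep = "\t")
  pick <- function(g) rep$frac_unlow[rep$group == g & rep$prebound == "all"]
  write_stage_log(cfg, "methylation", dir, p)
  write_summary(dir, list(n_cpgs = nrow(cpgs),
                          frac_unlow_w_H2AZ = pick("active_w_H2AZ"),
                          frac_unlow_wo_H2AZ = pick("active_wo_H2AZ")))
  invisible(dir)
}

stage_enrich <- function(cfg, force = FALSE) {
  dir <- stage_dir(cfg, "enrich", force)
  p <- cfg$enrich
  cs <- classified_sites(cfg)
  domains <- build_regulatory_domains(cs$sim$genes, p$basal_up, p$basal_down,
                                      p$max_ext, cs$sim$chrom_sizes)
  enr_rows <- list()
  for (g in GROUP_LEVELS[1:4]) {
    gs <- cs$sites[mcols(cs$sites)$group == g]
    if (!length(gs)) next
    enr <- relative_enrichment(gs, domains, cs$sim$chrom_sizes,
                               n_shuffles = p$n_shuffles,
                               seed = stage_seed(cfg, "enrich"))
    enr_rows[[g]] <- data.table(group = g, enr)
  }
  fwrite(data.table::rbindlist(enr_rows), file.path(dir, "enrichment.tsv"),
         sep = "\t")
  asg <- assign_sites_to_genes(cs$sites, domains)
  cmp <- expression_change_compare(cs$sim$genes, asg, cs$sites,
                                   "active_w_H2AZ", "active_wo_H2AZ")
  sites_ig <- flag_intergenic(cs$sites, cs$sim$genes)
  act_ig <- sites_ig[mcols(sites_ig)$intergenic &
                       mcols(sites_ig)$group == "active_w_H2AZ"]
  prof_rows <- list()
  for (tp in SIM_TIMEPOINTS) {
    tr <- list(plus = load_track(cfg, paste0("eRNA_plus_t", tp),
                                 cs$sim$chrom_sizes),
               minus = load_track(cfg, paste0("eRNA_minus_t", tp),
                                  cs$sim$chrom_sizes))
    mp <- meta_profile(tr, act_ig, p$erna_half_window, p$erna_n_bins)
    prof_rows[[as.character(tp)]] <- data.table(timepoint = tp, mp)
  }
  fwrite(data.table::rbindlist(prof_rows),
         file.path(dir, "erna_meta_profiles.tsv"), sep = "\t")
  write_stage_log(cfg, "enrich", dir, p)
  write_summary(dir, list(
    n_domains = length(domains),
    expression_shift_p = cmp$p,
    n_exclusive_w = length(cmp$changes_a),
    n_exclusive_wo = length(cmp$changes_b)))
  invisible(dir)
}

stage_report <- function(cfg, force = FALSE) {
  dir <- stage_dir(cfg, "report", force)
  rows <- list()
  for (stage in setdiff(PIPELINE_STAGES, "report")) {
    f <- file.path(cfg$outdir, stage, "summary.tsv")
    if (!file.exists(f)) next
    dt <- fread(f, colClasses = "character")
    rows[[stage]] <- data.table(stage = stage, dt)
  }
  if (!length(rows)) usage_error("no stage summaries found under ",
                                 cfg$outdir)
  fwrite(data.table::rbindlist(rows), file.path(dir, "report.tsv"),
         sep = "\t")
  plots <- file.path(dir, "plots")
  dir.create(plots, showWarnings = FALSE)
  ep <- file.path(cfg$outdir, "enrich", "erna_meta_profiles.tsv")
  if (file.exists(ep)) {
    dt <- fread(ep)
    grDevices::pdf(file.path(plots, "erna_meta_profiles.pdf"), 7, 5)
    plot(NULL, xlim = range(dt$offset), ylim = range(c(dt$plus, dt$minus)),
         xlab = "bp from summit", ylab = "mean signal",
         main = "Strand-specific eRNA meta-profiles")
    cols <- c("grey40", "orange", "blue")
    for (i in seq_along(SIM_TIMEPOINTS)) {
      sel <- dt$timepoint == SIM_TIMEPOINTS[i]
      lines(dt$offset[sel], dt$plus[sel], col = cols[i])
      lines(dt$offset[sel], dt$minus[sel], col = cols[i], lty = 2)
    }
    legend("topleft", legend = paste0(SIM_TIMEPOINTS, " min"), col = cols,
           lty = 1, bty = "n")
    grDevices::dev.off()
  }
  cp <- file.path(cfg$outdir, "shapes", "centroids.tsv")
  if (file.exists(cp)) {
    dt <- fread(cp)
    cen <- as.matrix(dt[, -(1:3)])
    grDevices::pdf(file.path(plots, "shape_centroids.pdf"), 7, 5)
    matplot(t(cen), type = "l", lty = 1, xlab = "bin",
            ylab = "z-scored signal", main = "Shape-cluster centroids")
    grDevices::dev.off()
  }
  write_stage_log(cfg, "report", dir, list())
  write_summary(dir, list(n_stages = length(rows)))
  invisible(dir)
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (generate synthetic inputs), `classify`
#' (filtering + K-means grouping), `shapes` (shape clustering),
#' `methylation` (stratified CpG report), `enrich` (domains, enrichment,
#' expression comparison, eRNA meta-profiles), `report` (aggregate
#' summaries + plots), or `all` to chain them. Each stage writes its
#' artifacts, a `summary.tsv` and a `log.txt` (version, seed, every
#' effective parameter) into `<outdir>/<stage>/`; no stage mutates another
#' stage's outputs.
#'
#' @param name Subcommand name.
#' @param config Config file path or list (see [pipeline_config()]).
#' @param seed,outdir Optional overrides.
#' @param force Overwrite the invoked stage's directory.
#' @return The stage output directory (or `outdir` for `all`), invisibly.
#' @export
run_subcommand <- function(name, config = NULL, seed = NULL, outdir = NULL,
                           force = FALSE) {
  if (!name %in% c(PIPELINE_STAGES, "all"))
    usage_error("unknown subcommand: ", name)
  cfg <- pipeline_config(config, seed = seed, outdir = outdir)
  stages <- if (name == "all") PIPELINE_STAGES else name
  for (stage in stages) {
    fn <- switch(stage, simulate = stage_simulate, classify = stage_classify,
                 shapes = stage_shapes, methylation = stage_methylation,
                 enrich = stage_enrich, report = stage_report)
    fn(cfg, force = force)
  }
  invisible(if (name == "all") cfg$outdir else file.path(cfg$outdir, name))
}
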