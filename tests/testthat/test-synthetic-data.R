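test_that("site simulation is deterministic and honors group proportions", {
  cfg <- test_config(seed = 3)
  a <- simulate_sites(cfg)
  b <- simulate_sites(cfg)
  expect_identical(a$truth, b$truth)
  expect_equal(site_summits(a$sites), site_summits(b$sites))

  pure <- simulate_sites(test_config(seed = 3,
                                     group_proportions = c(1, 0, 0, 0),
                                     decoy_fraction = 0))
  expect_true(all(pure$truth$group == "active_w_H2AZ"))

  big <- simulate_sites(simulation_config(
    seed = 9, n_sites = 2000, group_proportions = c(0.2, 0.55, 0.15, 0.1),
    decoy_fraction = 0))
  frac <- prop.table(table(big$truth$group))
  expect_lt(abs(frac[["active_w_H2AZ"]] - 0.20), 0.02)
  expect_lt(abs(frac[["active_wo_H2AZ"]] - 0.55), 0.02)
  expect_lt(abs(frac[["weak"]] - 0.15), 0.02)
})

test_that("spacing constraints are enforced or rejected", {
  tight <- test_config(seed = 1, n_sites = 5000)
  expect_error(simulate_sites(tight), "too small")
  ok <- simulate_sites(test_config(seed = 1))
  for (ch in unique(ok$truth$chrom)) {
    s <- sort(ok$truth$summit[ok$truth$chrom == ch])
    expect_gte(min(diff(s)), 5000)
  }
})

test_that("noise-free tracks reproduce the analytic templates", {
  cfg <- test_config(seed = 2, noise_model = "none", decoy_fraction = 0,
                     group_proportions = c(1, 0, 0, 0),
                     shape_mixture = c(centered = 1, side_left = 0,
                                       side_right = 0, bimodal = 0,
                                       flat = 0))
  ss <- simulate_sites(cfg)
  tracks <- simulate_tracks(ss$sites, ss$truth, cfg, marks = "H3K4me1")
  prof <- extract_profile(tracks$H3K4me1, ss$sites[1], 125, 25)
  expect_equal(which.max(prof), 13)  # center bin holds the summit

  # zero amplitude leaves pure background near inactive sites
  amps <- default_mark_amplitudes()
  amps["inactive", ] <- 0
  cfg0 <- test_config(seed = 2, noise_model = "none",
                      mark_amplitudes = amps, decoy_fraction = 0,
                      group_proportions = c(0, 0, 0, 1))
  ss0 <- simulate_sites(cfg0)
  tr0 <- simulate_tracks(ss0$sites, ss0$truth, cfg0, marks = "H2AZ")
  expect_true(all(abs(unlist(tr0$H2AZ$values) - cfg0$background) < 1e-12))
})

test_that("averaging noisy profiles converges to the analytic mean", {
  base <- list(seed = 5, group_proportions = c(1, 0, 0, 0),
               decoy_fraction = 0,
               shape_mixture = c(centered = 1, side_left = 0, side_right = 0,
                                 bimodal = 0, flat = 0))
  mean_dev <- function(n) {
    cfg <- do.call(simulation_config,
                   c(base, list(n_sites = n,
                                chrom_sizes = c(simA = n * 6000 + 2e4))))
    ss <- simulate_sites(cfg)
    tracks <- simulate_tracks(ss$sites, ss$truth, cfg, marks = "ERalpha")
    cfg0 <- do.call(simulation_config,
                    c(base, list(n_sites = n, noise_model = "none",
                                 chrom_sizes = c(simA = n * 6000 + 2e4))))
    tracks0 <- simulate_tracks(ss$sites, ss$truth, cfg0, marks = "ERalpha")
    noisy <- colMeans(extract_profiles(tracks$ERalpha, ss$sites, 150, 30))
    exact <- colMeans(extract_profiles(tracks0$ERalpha, ss$sites, 150, 30))
    max(abs(noisy - exact))
  }
  d_small <- mean_dev(60)
  d_big <- mean_dev(540)  # 9x the sites: expect ~3x smaller deviation
  expect_lt(d_big, d_small / 1.5)
})

test_that("methylome mixtures, density and determinism behave as configured", {
  # all-low mixture: Beta(1, 20) puts ~99.7% of its mass below 25%
  cfg <- test_config(seed = 4, meth_low_weight = c(active_w_H2AZ = 1,
                                                   active_wo_H2AZ = 1,
                                                   weak = 1, inactive = 1),
                     meth_low_weight_prebound = 1,
                     meth_beta_low = c(1, 20), decoy_fraction = 0)
  ss <- simulate_sites(cfg)
  cpgs <- simulate_methylome(ss$sites, ss$truth, cfg)
  expect_gt(mean(cpgs$percent_meth < 25), 0.97)
  expect_true(all(cpgs$coverage >= 1))

  again <- simulate_methylome(ss$sites, ss$truth, cfg)
  expect_identical(cpgs, again)

  none <- test_config(seed = 4, cpg_rate_core = c(active_w_H2AZ = 0,
                                                  active_wo_H2AZ = 0,
                                                  weak = 0, inactive = 0),
                      cpg_rate_flank = 0, decoy_fraction = 0)
  empty <- simulate_methylome(ss$sites, ss$truth, none)
  expect_equal(nrow(empty), 0)
})

test_that("gene categories are tied to sites as configured", {
  cfg <- test_config(seed = 6, n_genes = 300)
  ss <- simulate_sites(cfg)
  gg <- simulate_genes(ss$sites, ss$truth, cfg)
  cats <- as.character(mcols(gg$genes)$expression_category)

  # every E2-up gene has a responsible site within the linking range
  up <- which(cats == "E2_up")
  tss <- mcols(gg$genes)$tss
  gch <- as.character(seqnames(gg$genes))
  for (j in up) {
    s <- ss$truth$summit[ss$truth$chrom == gch[j]]
    expect_lt(min(abs(s - tss[j])), 1e6)
  }
  # and no gene sits closer than the distal threshold to any summit
  for (j in seq_along(tss)) {
    s <- ss$truth$summit[ss$truth$chrom == gch[j]]
    expect_gt(min(abs(s - tss[j])), 3000)
  }

  # configured 0.5 shift between the two active groups is recovered
  # (averaged over replicate gene draws to beat sampling noise)
  truth_grp <- setNames(ss$truth$group, ss$truth$site_id)
  shifts <- vapply(1:8, function(k) {
    cfg_k <- test_config(seed = 600 + k, n_genes = 300)
    gg_k <- simulate_genes(ss$sites, ss$truth, cfg_k)
    cats_k <- as.character(mcols(gg_k$genes)$expression_category)
    ch_k <- mcols(gg_k$genes)$expression_change
    resp_k <- gg_k$gene_truth$site_id
    mean(ch_k[cats_k == "E2_up" &
                truth_grp[resp_k] == "active_w_H2AZ"]) -
      mean(ch_k[cats_k == "E2_up" &
                  truth_grp[resp_k] == "active_wo_H2AZ"])
  }, 0)
  expect_lt(abs(mean(shifts) - 0.5), 0.1)

  # null case: equal induction means -> no detectable shift
  cfg0 <- test_config(seed = 6, n_genes = 300,
                      gene_shift_mu = c(active_w_H2AZ = 1,
                                        active_wo_H2AZ = 1))
  gg0 <- simulate_genes(ss$sites, ss$truth, cfg0)
  cats0 <- as.character(mcols(gg0$genes)$expression_category)
  ch0 <- mcols(gg0$genes)$expression_change
  resp0 <- gg0$gene_truth$site_id
  a <- ch0[cats0 == "E2_up" & truth_grp[resp0] == "active_w_H2AZ"]
  b <- ch0[cats0 == "E2_up" & truth_grp[resp0] == "active_wo_H2AZ"]
  expect_gt(mann_whitney(a, b)$p, 0.001)
})

test_that("a simulation writes and reloads through the standard formats", {
  cfg <- test_config(seed = 8, n_sites = 30, n_genes = 20,
                     chrom_sizes = c(simA = 4e5, simB = 2e5))
  sim <- simulate_all(cfg, marks = c("H2AZ", "H3K4me1"))
  out <- file.path(tempdir(), "simout")
  write_simulation(sim, out)
  sites <- read_sites(file.path(out, "sites.narrowPeak"))
  expect_equal(site_summits(sites), site_summits(sim$sites))
  tr <- read_track(file.path(out, "tracks", "H2AZ.bedGraph"), "bedGraph",
                   bin_size = 10, chrom_sizes = cfg$chrom_sizes)
  expect_equal(tr$values$simA, sim$tracks$H2AZ$values$simA, tolerance = 1e-5)
  genes <- read_genes(file.path(out, "genes.tsv"))
  expect_equal(mcols(genes)$tss, mcols(sim$genes)$tss)
  cpgs <- read_cpgs(file.path(out, "cpgs.tsv"))
  expect_equal(nrow(cpgs), nrow(sim$cpgs))
  manifest <- data.table::fread(file.path(out, "manifest.tsv"))
  expect_equal(manifest$site_id, sim$truth$site_id)
  unlink(out, recursive = TRUE)
})
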