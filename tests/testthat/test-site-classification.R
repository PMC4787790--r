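test_that("replicate correlation matches hand-computed Pearson r", {
  a <- tiny_track(c(1, 2, 3, 4))
  expect_equal(replicate_correlation(a, a), 1.0)
  a2 <- tiny_track(c(2, 4, 6, 8))
  expect_equal(replicate_correlation(a, a2), 1.0)  # scale invariance
  b <- tiny_track(c(2, 1, 4, 3))
  expect_equal(replicate_correlation(a, b), 0.6)
  flat <- tiny_track(rep(2, 4))
  expect_error(replicate_correlation(a, flat), "zero-variance")
  expect_error(combine_replicates(a, b), "below threshold")
  comb <- combine_replicates(a, a2, min_r = 0.9)
  expect_equal(comb$values$chr1, c(1.5, 3, 4.5, 6))
})

test_that("distal non-promoter filter applies the >3 kb and H3K4me3 rules", {
  tss <- list(chr1 = c(50000))
  sites <- anchor_sites(rep("chr1", 3),
                        c(53001 - 150, 51000 - 150, 60000 - 150),
                        c(53001 + 150, 51000 + 150, 60000 + 150),
                        summit = c(53001, 51000, 60000))
  no_k4 <- feature_set(character(), numeric(), numeric())
  kept <- filter_distal_nonpromoter(sites, tss, no_k4)
  # 3001 bp away is distal (>3 kb), 1000 bp is proximal
  expect_equal(site_summits(kept), c(53001, 60000))

  k4 <- feature_set("chr1", 59900, 60100)
  kept2 <- filter_distal_nonpromoter(sites, tss, k4)
  expect_equal(site_summits(kept2), 53001)

  # subset + idempotence
  expect_identical(site_summits(filter_distal_nonpromoter(kept2, tss, k4)),
                   site_summits(kept2))
  expect_error(filter_distal_nonpromoter(sites, list(), no_k4), "empty TSS")
})

test_that("profile matrix standardizes per mark block", {
  sites <- anchor_sites(c("chr1", "chr1"), c(400, 400), c(600, 600))
  const <- tiny_track(rep(5, 120))
  m <- build_matrix(sites, list(M = const), half_window = 200, n_bins = 10)
  expect_true(all(m$values == 0))  # constant block -> all zeros
  expect_equal(m$values[1, ], m$values[2, ])  # identical sites

  # asinh is near-identity for small values
  set.seed(1)
  small <- tiny_track(runif(120, 0, 0.1))
  m1 <- build_matrix(sites, list(M = small), 200, 10, transform = "none")
  m2 <- build_matrix(sites, list(M = small), 200, 10, transform = "asinh")
  raw1 <- extract_profiles(small, sites, 200, 10)
  expect_lt(max(abs(asinh(raw1) - raw1) / raw1), 0.01)
  expect_equal(m1$values, m2$values, tolerance = 0.01)
})

test_that("kmeans grouping separates clouds and is stable", {
  set.seed(42)
  x <- rbind(matrix(rnorm(40 * 5, 0), ncol = 5),
             matrix(rnorm(30 * 5, 8), ncol = 5))
  pm <- structure(list(values = x,
                       site_ids = sprintf("s%03d", 1:70),
                       marks = "M", half_window = 100, n_bins = 5),
                  class = "profile_matrix")
  asg <- kmeans_group(pm, k = 2, seed = 1)
  expect_equal(length(unique(asg$cluster[1:40])), 1)
  expect_equal(length(unique(asg$cluster[41:70])), 1)
  expect_false(asg$cluster[1] == asg$cluster[70])

  # duplicated rows always co-assign
  pm2 <- pm
  pm2$values <- rbind(x, x[1:5, ])
  pm2$site_ids <- sprintf("s%03d", 1:75)
  asg2 <- kmeans_group(pm2, k = 2, seed = 1)
  expect_equal(unname(asg2$cluster[71:75]), unname(asg2$cluster[1:5]))

  # row permutation leaves the partition unchanged (up to relabeling)
  perm <- sample(70)
  pm3 <- pm
  pm3$values <- x[perm, ]
  pm3$site_ids <- pm$site_ids[perm]
  asg3 <- kmeans_group(pm3, k = 2, seed = 5)
  expect_equal(adjusted_rand_index(asg3$cluster[pm$site_ids], asg$cluster), 1)

  expect_error(kmeans_group(pm, k = 100), "exceeds")
})

test_that("semantic labels follow the mark-mean rule", {
  mm <- data.frame(H2AZ = c(5, 0, 0, 0), H3K27ac = c(5, 5, 0, 0),
                   H3K4me1 = c(5, 5, 5, 0))
  asg <- structure(list(cluster = setNames(1:4, paste0("s", 1:4)), k = 4,
                        groups = NULL, cluster_means = NULL),
                   class = "group_assignment")
  lab <- label_groups(asg, mm)
  expect_equal(lab$cluster_means$label,
               c("active_w_H2AZ", "active_wo_H2AZ", "weak", "inactive"))
  expect_equal(as.character(lab$groups),
               c("active_w_H2AZ", "active_wo_H2AZ", "weak", "inactive"))

  tied <- data.frame(H2AZ = rep(1, 4), H3K27ac = rep(1, 4),
                     H3K4me1 = rep(1, 4))
  expect_error(label_groups(asg, tied), "tied")
})

test_that("prebound splitting matches basal peak overlap", {
  sites <- anchor_sites(c("chr1", "chr1"), c(100, 500), c(200, 600))
  basal <- feature_set("chr1", 140, 160)
  out <- split_prebound(sites, basal)
  expect_equal(mcols(out)$prebound, c(TRUE, FALSE))
  none <- split_prebound(sites, feature_set(character(), numeric(),
                                            numeric()))
  expect_equal(mcols(none)$prebound, c(FALSE, FALSE))
})

test_that("group recovery holds on a reduced default simulation", {
  cfg <- test_config(seed = 12, n_sites = 300,
                     chrom_sizes = c(simA = 2.4e6, simB = 1.2e6))
  sim <- simulate_all(cfg, marks = c("ERalpha", "H2AZ", "H3K27ac",
                                     "H3K4me1"))
  kept <- filter_distal_nonpromoter(sim$sites, sim$genes,
                                    sim$features$h3k4me3_peaks)
  tr <- sim$truth[match(mcols(kept)$site_id, sim$truth$site_id), ]
  expect_equal(sum(tr$decoy), 0)
  mat <- build_matrix(kept, sim$tracks)
  asg <- kmeans_group(mat, seed = 2)
  mm <- cluster_mark_means(asg, kept,
                           sim$tracks[c("H2AZ", "H3K27ac", "H3K4me1")])
  asg <- label_groups(asg, mm)
  kept <- apply_groups(kept, asg)
  got <- as.character(mcols(kept)$group)
  expect_gt(adjusted_rand_index(got, tr$group), 0.9)

  # prebound flags recovered exactly from the truth-derived basal peaks
  kept <- split_prebound(kept, sim$features$basal_peaks)
  expect_equal(mcols(kept)$prebound, tr$prebound)
})
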