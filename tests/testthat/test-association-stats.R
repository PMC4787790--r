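test_that("regulatory domains follow the basal-plus-extension rule", {
  sizes <- c(chr1 = 1e7)
  lone <- gene_models("chr1", 5e6, 5.01e6, "+")
  dom <- build_regulatory_domains(lone, chrom_sizes = sizes)
  # basal [tss-5000, tss+1000) extended 1 Mb each way from the TSS
  expect_equal(start(dom) - 1, 5e6 - 1e6)
  expect_equal(end(dom), 5e6 + 1e6)

  # two + strand genes 8 kb apart stop at each other's basal boundary
  pair <- gene_models(c("chr1", "chr1"), c(1e6, 1e6 + 8000),
                      c(1e6 + 2000, 1e6 + 10000), c("+", "+"))
  dp <- build_regulatory_domains(pair, chrom_sizes = sizes)
  expect_equal(end(dp)[1], 1e6 + 3000)      # stops at gene 2 basal start
  expect_equal(start(dp)[2] - 1, 1e6 + 1000)  # stops at gene 1 basal end

  # gene at the chromosome start is clipped at 0
  first <- gene_models("chr1", 1000, 3000, "+")
  df <- build_regulatory_domains(first, chrom_sizes = sizes)
  expect_equal(start(df), 1)
})

test_that("site-gene assignment and exclusive targets", {
  sizes <- c(chr1 = 1e7)
  genes <- gene_models(c("chr1", "chr1"), c(2e6, 2.4e6),
                       c(2e6 + 1e4, 2.4e6 + 1e4), c("+", "+"),
                       gene_id = c("gA", "gB"))
  dom <- build_regulatory_domains(genes, chrom_sizes = sizes)
  sites <- anchor_sites(rep("chr1", 3), c(1.5e6, 2.2e6, 2.35e6) - 100,
                        c(1.5e6, 2.2e6, 2.35e6) + 100,
                        site_id = c("s1", "s2", "s3"),
                        group = c("active_w_H2AZ", "active_wo_H2AZ",
                                  "active_w_H2AZ"))
  asn <- assign_sites_to_genes(sites, dom)
  expect_equal(sort(unique(asn$gene_id[asn$site_id == "s1"])), "gA")
  # s2/s3 sit between the genes where both domains overlap
  expect_setequal(asn$gene_id[asn$site_id == "s2"], c("gA", "gB"))

  ex <- exclusive_targets(asn, sites, "active_w_H2AZ", "active_wo_H2AZ")
  # gA and gB are hit by both groups -> discarded from both sides except gA
  # which s1 (group A) reaches while s2 (group B) also reaches it: common
  expect_false("gA" %in% ex$a_only)
  expect_false("gA" %in% ex$b_only)
})

test_that("relative enrichment is calibrated under the null and detects
           concentration", {
  sizes <- c(chr1 = 1e6)
  # category domains tiling half the chromosome
  genes <- gene_models("chr1", 2.5e5 - 1000, 2.5e5 + 1000, "+",
                       expression_category = "E2_up")
  dom <- build_regulatory_domains(genes, basal_up = 1000, basal_down = 1000,
                                  max_ext = 2.49e5, chrom_sizes = sizes)
  expect_equal(end(dom) - (start(dom) - 1), 5e5, tolerance = 0.01)

  # all sites inside the domain half -> enrichment ~ 2
  withr::with_seed(8, {
    pos <- round(runif(10, 1e5, 4e5))
  })
  inside <- anchor_sites(rep("chr1", 10), pos - 50, pos + 50)
  enr <- suppressWarnings(
    relative_enrichment(inside, dom, sizes, n_shuffles = 300, seed = 4))
  row <- enr[enr$category == "E2_up", ]
  expect_equal(row$observed_fraction, 1)
  expect_equal(row$relative_enrichment, 2, tolerance = 0.1)
  expect_lt(row$p_value, 0.05)

  # uniformly placed sites -> enrichment ~ 1 within 3 shuffle SEs
  withr::with_seed(9, {
    upos <- round(runif(200, 0, 1e6 - 1))
  })
  unif <- anchor_sites(rep("chr1", 200), pmax(upos - 50, 0), upos + 50,
                       summit = upos)
  enr2 <- suppressWarnings(
    relative_enrichment(unif, dom, sizes, n_shuffles = 300, seed = 4))
  row2 <- enr2[enr2$category == "E2_up", ]
  se <- row2$shuffle_sd
  expect_lt(abs(row2$observed_fraction - row2$expected_fraction), 3 * se)
})

test_that("meta profiles average sites and keep strand separation", {
  const <- tiny_track(rep(4, 200))
  sites <- anchor_sites(c("chr1", "chr1"), c(500, 1200), c(700, 1400))
  mp <- meta_profile(const, sites, half_window = 100, n_bins = 10)
  expect_true(all(mp$mean_signal == 4))

  ramp <- tiny_track(as.numeric(1:200))
  p1 <- extract_profile(ramp, sites[1], 100, 10)
  p2 <- extract_profile(ramp, sites[2], 100, 10)
  mp2 <- meta_profile(ramp, sites, 100, 10)
  expect_equal(mp2$mean_signal, (p1 + p2) / 2)
  expect_error(meta_profile(const, sites[0], 100, 10), "empty")

  # meta_profile commutes with site subsetting
  mp_a <- meta_profile(ramp, sites[1], 100, 10)$mean_signal
  mp_b <- meta_profile(ramp, sites[2], 100, 10)$mean_signal
  expect_equal(mp2$mean_signal, (mp_a + mp_b) / 2)
})

test_that("divergent eRNA meta-profiles put plus right and minus left", {
  cfg <- test_config(seed = 14, group_proportions = c(1, 0, 0, 0),
                     decoy_fraction = 0)
  ss <- simulate_sites(cfg)
  tracks <- simulate_tracks(ss$sites, ss$truth, cfg,
                            marks = c("eRNA_plus_t40", "eRNA_minus_t40"))
  mp <- meta_profile(list(plus = tracks$eRNA_plus_t40,
                          minus = tracks$eRNA_minus_t40),
                     ss$sites, half_window = 1000, n_bins = 50)
  expect_gt(mp$offset[which.max(mp$plus)], 0)
  expect_lt(mp$offset[which.max(mp$minus)], 0)
})

test_that("Mann-Whitney agrees with enumeration and handles edge cases", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)
  expect_equal(mw_enumerate(c(1, 2), c(3, 4))$p, 1 / 3)

  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_gt(same$p, 0.99)
  expect_equal(mann_whitney(c(2, 2), c(2, 2))$p, 1)

  set.seed(3)
  a <- rnorm(50); b <- rnorm(50) + 1000
  expect_lt(mann_whitney(a, b)$p, 1e-6)

  # exact and normal-approximation branches agree closely at n = 20/20
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20, 0.3)
  exact <- wilcox.test(a, b, exact = TRUE)$p.value
  approx <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(exact - approx), 0.01)
  expect_equal(mann_whitney(a, b)$p, exact)  # m*n = 400, no ties -> exact
})

test_that("expression comparison discards common targets", {
  genes <- gene_models(rep("chr1", 4), c(1, 2, 3, 4) * 1e5,
                       c(1, 2, 3, 4) * 1e5 + 1e4, rep("+", 4),
                       gene_id = paste0("g", 1:4),
                       expression_category = "E2_up",
                       expression_change = c(2, 1.5, 0.5, 0.2))
  sites <- anchor_sites(rep("chr1", 3), c(95000, 195000, 98000),
                        c(95200, 195200, 98200),
                        site_id = c("sa", "sb", "sc"),
                        group = c("active_w_H2AZ", "active_wo_H2AZ",
                                  "active_wo_H2AZ"))
  asn <- data.table::data.table(
    site_id = c("sa", "sb", "sc", "sa", "sb"),
    gene_id = c("g1", "g2", "g1", "g3", "g4"))
  ex <- exclusive_targets(asn, sites, "active_w_H2AZ", "active_wo_H2AZ")
  expect_false("g1" %in% c(ex$a_only, ex$b_only))  # hit by both groups
  expect_setequal(ex$a_only, "g3")
  expect_setequal(ex$b_only, c("g2", "g4"))
  cmp <- suppressWarnings(
    expression_change_compare(genes, asn, sites, "active_w_H2AZ",
                              "active_wo_H2AZ"))
  expect_equal(sort(cmp$changes_b), c(0.2, 1.5))
})
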