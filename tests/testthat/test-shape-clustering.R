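test_that("shape normalization is magnitude-free and idempotent", {
  p <- c(0, 1, 0, 1, 2, 1, 0, 1)
  expect_equal(normalize_shape(p), normalize_shape(10 * p))
  expect_null(normalize_shape(rep(3, 8)))  # zero variance
  expect_null(normalize_shape(p, min_signal = 10))
  expect_equal(normalize_shape(c(0, 1, 0, 1, 0, 1, 0, 1)),
               rep(c(-1, 1), 4))  # population sd
  n1 <- normalize_shape(p)
  expect_equal(normalize_shape(n1), n1)
  expect_equal(mean(n1), 0)
  expect_equal(sqrt(mean(n1^2)), 1)
  expect_error(normalize_shape(c(p[-1], NA)), "non-finite")
})

test_that("mirror profiles collapse into one cluster only when flip is on", {
  x <- seq(-145, 145, by = 10)
  p <- shape_template("side_right", x) + 0.5
  m <- rbind(a = p, b = rev(p))
  res <- cluster_shapes(m, k_init = 2, flip = TRUE, min_signal = 0,
                        smooth_bins = 1, seed = 1)
  expect_equal(length(res$clusters), 1)
  expect_equal(sort(res$clusters[[1]]$member_ids), c("a", "b"))
  expect_equal(sort(res$clusters[[1]]$orientation), c("as_is", "flipped"))

  res2 <- cluster_shapes(m, k_init = 2, flip = FALSE, min_signal = 0,
                         smooth_bins = 1, seed = 1)
  expect_equal(length(res2$clusters), 2)

  all_low <- matrix(1, 3, 30)
  expect_error(cluster_shapes(all_low, min_signal = 0), "low-signal")
})

test_that("reversing every profile reverses centroids, same partition", {
  set.seed(11)
  x <- seq(-145, 145, by = 10)
  shapes <- sample(c("centered", "side_left", "side_right", "bimodal"), 80,
                   replace = TRUE)
  m <- t(sapply(shapes, function(s)
    shape_template(s, x) + 0.4 + rnorm(30, sd = 0.15)))
  rownames(m) <- sprintf("p%03d", seq_len(80))
  fwd <- cluster_shapes(m, k_init = 8, seed = 2, min_signal = 0)
  rev_in <- m[, 30:1]
  bwd <- cluster_shapes(rev_in, k_init = 8, seed = 2, min_signal = 0)
  expect_equal(length(fwd$clusters), length(bwd$clusters))
  for (j in seq_along(fwd$clusters)) {
    expect_setequal(fwd$clusters[[j]]$member_ids,
                    bwd$clusters[[j]]$member_ids)
    # mirrored input: the centroid is the mirror image of the original, and
    # each member's alignment relative to a fixed external direction flips
    expect_equal(bwd$clusters[[j]]$centroid,
                 rev(fwd$clusters[[j]]$centroid), tolerance = 1e-8)
  }
})

test_that("raising the merge threshold never yields fewer clusters", {
  set.seed(21)
  x <- seq(-145, 145, by = 10)
  shapes <- sample(c("centered", "side_left", "bimodal"), 60, replace = TRUE)
  m <- t(sapply(shapes, function(s)
    shape_template(s, x) + 0.4 + rnorm(30, sd = 0.3)))
  n_prev <- 0
  for (thr in c(0.5, 0.7, 0.9)) {
    res <- cluster_shapes(m, k_init = 10, merge_threshold = thr, seed = 3,
                          min_signal = 0)
    expect_gte(length(res$clusters), n_prev)
    n_prev <- length(res$clusters)
  }
})

test_that("centroid geometry maps to centered / side / ambiguous", {
  x <- seq(-145, 145, by = 10)
  expect_equal(classify_cluster(shape_template("centered", x)), "centered")
  expect_equal(classify_cluster(shape_template("side_left", x)), "side")
  expect_equal(classify_cluster(shape_template("side_right", x)), "side")
  expect_equal(classify_cluster(shape_template("bimodal", x)), "ambiguous")
  expect_equal(classify_cluster(rep(1, 30)), "ambiguous")  # flat
  bump120 <- exp(-(x - 120)^2 / (2 * 40^2))
  expect_equal(classify_cluster(bump120), "side")
})

test_that("summit-to-nucleosome distances locate smoothed maxima", {
  # bin_size 1 for exact positions; bump centered at summit + 10
  summit <- 500
  v <- exp(-((0:999 + 0.5) - (summit + 0.5 + 10))^2 / (2 * 30^2))
  tr <- tiny_track(v, bin_size = 1)
  site <- anchor_sites("chr1", summit - 50, summit + 50)
  d <- summit_nucleosome_distances(site, tr, search_bp = 300)
  expect_equal(unname(d$distance), 10)

  v2 <- exp(-((0:999) - (summit - 100))^2 / (2 * 25^2)) +
    exp(-((0:999) - (summit + 100))^2 / (2 * 25^2))
  d2 <- summit_nucleosome_distances(site, tiny_track(v2, bin_size = 1),
                                    search_bp = 300)
  expect_equal(unname(d2$abs_distance), 100, tolerance = 0.06)
  expect_equal(sum(d2$histogram$frequency), 1)

  flat <- summit_nucleosome_distances(site, tiny_track(rep(1, 1000),
                                                       bin_size = 1),
                                      search_bp = 300)
  expect_true(is.na(flat$distance))
  expect_equal(nrow(flat$histogram), 0)
})

test_that("cluster composition fractions and homogeneity statistic", {
  cl <- structure(list(clusters = list(
    structure(list(centroid = rnorm(10),
                   member_ids = sprintf("s%02d", 1:10),
                   orientation = rep("as_is", 10), size = 10,
                   category = "unset"), class = "shape_cluster")),
    discarded_low_signal = character(), params = list()),
    class = "shape_clustering")
  groups <- setNames(c(rep("active_w_H2AZ", 2), rep("active_wo_H2AZ", 8)),
                     sprintf("s%02d", 1:10))
  comp <- cluster_composition(cl, groups)
  expect_equal(unname(comp$fractions[1, "active_w_H2AZ"]), 0.2)

  # identical composition across two clusters -> statistic ~ 0
  cl2 <- cl
  cl2$clusters <- c(cl$clusters, cl$clusters)
  cl2$clusters[[2]]$member_ids <- sprintf("s%02d", 11:20)
  groups2 <- c(groups, setNames(c(rep("active_w_H2AZ", 2),
                                  rep("active_wo_H2AZ", 8)),
                                sprintf("s%02d", 11:20)))
  comp2 <- cluster_composition(cl2, groups2)
  expect_lt(comp2$chisq_statistic, 1e-10)
  expect_error(cluster_composition(cl, groups[1:5]), "missing")
})
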