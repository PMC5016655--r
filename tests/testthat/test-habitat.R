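test_that("Ward clustering recovers separated blobs exactly", {
  set.seed(12)
  X <- rbind(matrix(rnorm(20, 0, 1), ncol = 2),
             matrix(rnorm(20, 10, 1), ncol = 2))
  truth <- rep(1:2, each = 10)
  cl <- ward_cluster(X, k = 2, standardize = FALSE)
  expect_equal(length(unique(cl$assignment[truth == 1])), 1)
  expect_equal(length(unique(cl$assignment[truth == 2])), 1)
  # merge heights are nondecreasing (ultrametric dendrogram)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
})

test_that("Ward 2-partition matches the exhaustive optimum on small n", {
  set.seed(7)
  X <- matrix(rnorm(16, rep(c(0, 4), each = 8), 1.2), ncol = 2)
  cl <- ward_cluster(X, k = 2, standardize = FALSE)
  best <- Inf
  n <- nrow(X)
  for (code in 1:(2^(n - 1) - 1)) {     # all nontrivial 2-partitions
    lab <- as.integer(intToBits(code))[1:n]
    if (length(unique(lab)) == 2)
      best <- min(best, wss2(X, lab))
  }
  expect_equal(wss2(X, cl$assignment), best, tolerance = 1e-9)
})

test_that("Ward edge cases: singletons, duplicates, constant columns", {
  set.seed(2)
  X <- matrix(rnorm(12), ncol = 2)
  cl_n <- ward_cluster(X, k = nrow(X))
  expect_equal(length(unique(cl_n$assignment)), nrow(X))
  # duplicated rows merge first at height zero
  X2 <- rbind(X, X[1, ])
  cl_d <- ward_cluster(X2, k = 2, standardize = FALSE)
  expect_equal(cl_d$hclust$height[1], 0)
  expect_warning(ward_cluster(cbind(X, 1), k = 2), "constant")
  expect_error(ward_cluster(X, k = 1), "k")
})

test_that("standardized selection ratios behave like Manly's B", {
  expect_equal(unname(selection_ratio(c(1, 1))), c(0.5, 0.5))
  expect_equal(unname(selection_ratio(c(2, 1, 1))), c(0.5, 0.25, 0.25))
  # two-habitat complement as in the gazelle wadi/plain contrast
  B <- selection_ratio(c(wadi = 0.29, plain = 0.71))
  expect_equal(unname(B["plain"]), 0.71)
  expect_equal(sum(B), 1)
  # invariance to rescaling use or availability
  u <- c(3, 2, 7)
  expect_equal(selection_ratio(u * 100), selection_ratio(u))
  a <- c(0.2, 0.3, 0.5)
  expect_equal(selection_ratio(u, a * 2), selection_ratio(u, a))
  expect_error(selection_ratio(c(0, 0)), "all-zero")
})

test_that("key-resource flags use an inclusive 0.5 threshold", {
  expect_true(key_resource_flags(0.54))
  expect_true(key_resource_flags(0.50))
  expect_false(key_resource_flags(0.49))
  expect_equal(key_resource_flags(c(0.61, 0.14, 0.25)),
               c(TRUE, FALSE, FALSE))
})

test_that("Shannon-Wiener diversity of selection ratios", {
  expect_equal(shannon_diversity(c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(shannon_diversity(c(1, 0, 0)), 0)
  expect_equal(shannon_diversity(rep(1 / 5, 5)), log(5))
  expect_equal(shannon_diversity(rep(1 / 4, 4), base = 2), 2)
  expect_error(shannon_diversity(c(0.5, 0.4)), "sum to 1")
  # maximal iff uniform
  expect_lt(shannon_diversity(c(0.7, 0.2, 0.1)), log(3))
})

test_that("partition index reports fold-ratio and signed difference", {
  pi1 <- partition_index(2, 1)
  expect_equal(pi1$ratio, 2)
  expect_equal(pi1$difference, 1)
  pi2 <- partition_index(1, 1)
  expect_equal(pi2$ratio, 1)
  expect_equal(pi2$difference, 0)
  pi3 <- partition_index(0, 3)
  expect_equal(pi3$difference, -3)
  expect_true(pi3$ratio_defined)
  expect_gt(pi3$ratio, 1e6)           # epsilon-guarded
  pi4 <- partition_index(0, 0)
  expect_false(pi4$ratio_defined)
  expect_equal(pi4$difference, 0)
})

test_that("rank-sum test: exact enumeration, ties, and approximation", {
  out <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(out$p_value, 1 / 3)
  # identical samples: all midranks tie, p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2))$p_value, 1)
  # midranks can give half-integer statistics
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(2, 3))$statistic %% 1, 0.5)
  # agreement with the exact distribution in stats (no ties)
  set.seed(5)
  x <- rnorm(5); y <- rnorm(6)
  ref <- wilcox.test(x, y, exact = TRUE)
  out2 <- wilcoxon_rank_sum(x, y)
  expect_equal(out2$statistic, unname(ref$statistic))
  expect_equal(out2$p_value, ref$p.value, tolerance = 1e-12)
  # normal approximation close to enumeration at n = 20
  set.seed(9)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  exact <- wilcoxon_rank_sum(x, y, exact_max = 20)
  approx <- wilcoxon_rank_sum(x, y)             # default: approximation
  expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("habitat partition summary integrates ratios and diversity", {
  assignment <- c(T1 = "A", T2 = "A", T3 = "B", T4 = "B", T5 = "B")
  density <- rbind(
    data.frame(transect_id = names(assignment), species = "oryx",
               density = c(4, 4, 1, 1, 1)),
    data.frame(transect_id = names(assignment), species = "gazelle",
               density = c(1, 1, 2, 2, 2)))
  part <- habitat_partition(assignment, density)
  tab <- part$habitats
  expect_equal(tab$availability, c(0.4, 0.6))
  # oryx: use/availability = (4/.4, 1/.6) -> B = (.857, .143)
  expect_equal(tab$B_oryx, c(10, 5 / 3) / (10 + 5 / 3), tolerance = 1e-9)
  expect_true(tab$key_oryx[1])
  expect_equal(sum(tab$B_gazelle), 1)
  expect_equal(tab$density_difference, c(3, -1))
  expect_equal(unname(part$diversity["oryx"]),
               shannon_diversity(tab$B_oryx), tolerance = 1e-12)
})

test_that("wadi/plain covariate contrasts flag the built-in gradients", {
  ds <- simulate_survey(seed = 77)
  con <- habitat_contrasts(ds$covariates,
                           vars = c("rock_cover", "herb_cover"))
  expect_equal(nrow(con), 2)
  # generator contract: wadis less rocky, more herbaceous
  expect_lt(con$mean_wadi[1], con$mean_plain[1])
  expect_gt(con$mean_wadi[2], con$mean_plain[2])
  expect_true(all(con$p_value < 0.01))
})
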