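# Paired location tests, the site differential screen and the cross-site
# correlation / leverage diagnostics.

test_that("signed-rank p matches enumeration, psignrank and wilcox.test", {
  # all-positive differences, n = 5: p = 2/2^5
  expect_equal(paired_test(c(2, 3, 4, 5, 6), rep(1, 5))$p_value, 0.0625)

  set.seed(31)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    if (i %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # induce ties/zeros
    if (all(a == b)) next
    res <- suppressWarnings(paired_test(a, b))
    expect_equal(res$p_value, enum_signed_rank_p(a, b), tolerance = 1e-12)
    d <- a - b
    if (!any(d == 0) && !anyDuplicated(rank(abs(d)))) {
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("signed-rank test is exchangeable and scale-invariant", {
  set.seed(17)
  for (i in 1:15) {
    a <- rnorm(9); b <- rnorm(9)
    r1 <- paired_test(a, b)
    r2 <- paired_test(b, a)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_equal(r1$direction,
                 switch(r2$direction, higher_in_a = "higher_in_b",
                        higher_in_b = "higher_in_a", "none"))
    r3 <- paired_test(b + 3.7 * (a - b), b)   # scales all differences by 3.7
    expect_equal(r3$p_value, r1$p_value, tolerance = 1e-12)
  }
})

test_that("large-n normal approximation tracks the exact test", {
  set.seed(5)
  a <- rnorm(30, 0.4); b <- rnorm(30)
  approx <- paired_test(a, b)                       # n > exact_max default
  exact <- paired_test(a, b, exact_max = 30L)
  expect_false(isTRUE(all.equal(approx$statistic, NULL)))
  expect_lt(abs(approx$p_value - exact$p_value), 0.01)
})

test_that("degenerate paired inputs are flagged, not raised", {
  expect_warning(res <- paired_test(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")

  res2 <- suppressWarnings(paired_test(c(1, 2, 5), c(1, 2, 3)))  # one nonzero diff
  expect_true(res2$untestable)
  expect_true(is.na(res2$p_value))
  expect_equal(res2$n_zero_dropped, 2L)

  # paired t on the same data agrees with stats::t.test
  a <- c(1.2, 2.5, 3.1, 4.9); b <- c(1.0, 2.0, 3.5, 4.0)
  expect_equal(paired_test(a, b, method = "paired_t")$p_value,
               t.test(a, b, paired = TRUE)$p.value)
})

test_that("the site screen pairs by subject and flags planted effects", {
  md <- tiny_metadata(8L)
  tab <- random_gene_table(md, n_genes = 1L, seed = 2)
  scr <- differential_screen(tab, md)
  expect_equal(nrow(scr), 1L)
  expect_equal(attr(scr, "groups"), c(a = "mucosa", b = "feces"))

  # plant a strong mucosa shift on one feature of a 20-pair cohort
  md20 <- tiny_metadata(20L)
  tab20 <- random_gene_table(md20, n_genes = 50L, seed = 3)
  v <- tab20$values
  v["gene001", md20$site == "mucosa"] <- v["gene001", md20$site == "mucosa"] * 50
  v <- sweep(v, 2, colSums(v), "/")
  scr20 <- differential_screen(abundance_table(v, normalized = TRUE), md20)
  top <- scr20$feature[which.min(scr20$p_value)]
  expect_equal(top, "gene001")
  expect_equal(scr20$direction[scr20$feature == "gene001"], "higher_in_a")

  # all-zero features are skipped and reported
  v2 <- tab20$values; v2["gene002", ] <- 0
  expect_message(scr2 <- differential_screen(abundance_table(v2), md20), "skipped")
  expect_false("gene002" %in% scr2$feature)
  expect_equal(attr(scr2, "skipped"), "gene002")
})

test_that("BH adjustment flag controls the significance call", {
  md <- tiny_metadata(10L)
  tab <- random_gene_table(md, n_genes = 60L, seed = 7)
  raw <- differential_screen(tab, md, p_adjust = "none")
  bh <- differential_screen(tab, md, p_adjust = "BH")
  expect_equal(bh$p_adjusted, p.adjust(raw$p_value, "BH"))
  expect_lte(sum(bh$significant), sum(raw$significant))
})

test_that("cross-site mean correlation matches direct Pearson computation", {
  md <- tiny_metadata(3L)
  m <- matrix(0, nrow = 3, ncol = 6, dimnames = list(c("A", "B", "C"), md$sample_id))
  m[, md$site == "mucosa"] <- c(0.2, 0.3, 0.5)
  m[, md$site == "feces"] <- c(0.5, 0.3, 0.2)
  res <- group_mean_correlation(abundance_table(m), md, features = c("A", "B", "C"))
  expect_equal(res$r, -0.9285714, tolerance = 1e-3)
  expect_equal(res$r_squared, 0.8622, tolerance = 1e-3)

  # identical mean vectors -> perfect correlation
  m2 <- m; m2[, md$site == "feces"] <- c(0.2, 0.3, 0.5)
  expect_equal(group_mean_correlation(abundance_table(m2), md,
                                      features = c("A", "B", "C"))$r_squared, 1)

  expect_error(group_mean_correlation(abundance_table(m), md,
                                      features = c("A", "B", "C"), exclude = "A"),
               "at least 3")
})

test_that("leave-one-out screen equals brute-force recomputation", {
  md <- tiny_metadata(6L)
  tab <- random_gene_table(md, n_genes = 50L, seed = 19)
  loo <- leave_one_out_screen(tab, md, features = features(tab))
  mu_a <- rowMeans(tab$values[, md$site == "mucosa"])
  mu_b <- rowMeans(tab$values[, md$site == "feces"])
  base <- hand_r_squared(mu_a, mu_b)
  expect_equal(attr(loo, "r_squared_all"), base, tolerance = 1e-10)
  for (f in features(tab)) {
    keep <- setdiff(features(tab), f)
    expect_equal(loo$delta_r_squared[loo$feature == f],
                 hand_r_squared(mu_a[keep], mu_b[keep]) - base, tolerance = 1e-10)
  }
})

test_that("a planted high-leverage discriminator ranks first and exact lines have no leverage", {
  md <- tiny_metadata(6L)
  # features on an exact line across sites, plus one giant outlier feature
  base <- seq(0.01, 0.05, length.out = 9)
  m <- matrix(0, nrow = 10, ncol = 12,
              dimnames = list(c(sprintf("f%02d", 1:9), "burk"), md$sample_id))
  m[1:9, md$site == "mucosa"] <- base
  m[1:9, md$site == "feces"] <- 2 * base
  m["burk", md$site == "mucosa"] <- 0.6
  m["burk", md$site == "feces"] <- 0.001
  tab <- abundance_table(m)
  loo <- leave_one_out_screen(tab, md, features = rownames(m))
  expect_equal(loo$feature[1], "burk")
  expect_gt(loo$delta_r_squared[1], 0.5)

  # excluding the discriminator strengthens the correlation
  with_b <- group_mean_correlation(tab, md, features = rownames(m))
  without_b <- group_mean_correlation(tab, md, features = rownames(m), exclude = "burk")
  expect_gt(without_b$r_squared, with_b$r_squared)
  expect_equal(without_b$excluded_feature, "burk")

  # exact line only: all deltas vanish
  loo2 <- leave_one_out_screen(abundance_table(m[1:9, ]), md, features = sprintf("f%02d", 1:9))
  expect_lt(max(abs(loo2$delta_r_squared)), 1e-9)
})

test_that("outlier sensitivity drops the largest-difference pair", {
  # significance hinges on the extreme pair: n = 6 all-positive differences
  # give p = 2/2^6 < 0.05, n = 5 after the drop give p = 2/2^5 > 0.05
  b <- c(1, 1, 1, 1, 1, 1)
  a <- b + c(5, 0.1, 0.2, 0.3, 0.4, 0.15)
  res <- outlier_sensitivity(a, b)
  expect_equal(res$dropped_index, 1L)
  expect_lt(res$p_full, 0.05)
  expect_gt(res$p_reduced, 0.05)
  expect_true(res$flag_changed)
  expect_equal(res$p_reduced,
               suppressWarnings(paired_test(a[-1], b[-1]))$p_value)

  # homogeneous strong effect survives the drop
  a2 <- 2:9; b2 <- (2:9) - 1.5
  res2 <- outlier_sensitivity(a2, b2)
  expect_false(res2$flag_changed)
  expect_lt(res2$p_reduced, 0.05)
  expect_error(outlier_sensitivity(1:2, 2:3), "at least 3")
})
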