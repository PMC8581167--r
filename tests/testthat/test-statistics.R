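test_that("KS comparison of a sample with itself is null", {
  set.seed(3)
  d <- runif(100, 0, 500)
  res <- ks_radial_compare(d, d, "SOX17")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_error(ks_radial_compare(d, d[1:5]), "group B")
  expect_error(ks_radial_compare(d[1:5], d), "group A")
})

test_that("KS detects a shifted expression ring", {
  set.seed(5)
  a <- sample_positive_distances(radial_model("ring", 325, 50), 200)
  b <- sample_positive_distances(radial_model("ring", 425, 50), 200)
  res <- ks_radial_compare(a, b)
  expect_true(res$significant)
  expect_gt(res$statistic, 0.2)
})

test_that("Kruskal-Wallis H matches the hand rank formula on a toy", {
  df <- data.frame(v = 1:9, g = rep(c("a", "b", "c"), each = 3))
  kd <- kruskal_dunn(df, "v", "g")
  # ranks 1..9, mean ranks 2/5/8: H = 12/(9*10)*3*(4+25+64) - 3*10 = 7.2
  expect_equal(glance(kd)$statistic, 7.2, tolerance = 1e-10)
  expect_error(kruskal_dunn(data.frame(v = 1:4, g = rep(c("a", "b"), 2)),
                            "v", "g"), "3 groups")
})

test_that("Dunn's post hoc singles out the shifted group", {
  set.seed(11)
  df <- data.frame(
    v = c(rnorm(10, 0, 1), rnorm(10, 0, 1), rnorm(10, 10, 1)),
    g = rep(c("a", "b", "c"), each = 10))
  kd <- kruskal_dunn(df, "v", "g")
  pw <- tidy(kd)
  involves_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(max(pw$p_value[involves_c]) < min(pw$p_value[!involves_c]))
  expect_true(all(pw$p_value >= 0 & pw$p_value <= 1))
})

test_that("the pooled t statistic matches its closed form", {
  df <- data.frame(v = c(1, 2, 3, 2, 3, 4, 2, 3, 4),
                   line = c(rep("t", 3), rep("o", 6)))
  res <- outlier_mean_expression(df, "t", "v", "line", alpha = 0.05)
  # Student pooled: means 2 vs 3, sp^2 = (2*1 + 5*0.8)/7 = 6/7,
  # t = -1 / sqrt(6/7 * (1/3 + 1/6)) = -sqrt(7/3)
  expect_equal(res$statistic, -sqrt(7 / 3), tolerance = 1e-10)

  same <- data.frame(v = rep(c(1, 2, 3), 4),
                     line = rep(c("t", "o", "o", "o"), each = 3))
  expect_false(outlier_mean_expression(same, "t", "v", "line")$significant)
  zv <- data.frame(v = rep(5, 13), line = c(rep("t", 3), rep("o", 10)))
  expect_error(outlier_mean_expression(zv, "t", "v", "line"),
               "zero variance")
})

test_that("radial outlier calling is a KS test against the control", {
  set.seed(13)
  ctl <- sample_positive_distances(radial_model("ring", 425, 40), 300)
  expanded <- c(sample_positive_distances(radial_model("ring", 425, 40), 150),
                runif(150, 0, 400))  # domain extends to the colony centre
  res <- outlier_radial(expanded, ctl, "SOX17")
  expect_true(res$significant)
  self <- outlier_radial(ctl, ctl, "SOX17")
  expect_false(self$significant)
})

test_that("Spearman correlations reduce to ranks", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y_mono <- x^3
  df <- data.frame(a = x, b = y_mono, c = -x)
  r <- marker_correlations(df, c("a", "b", "c"))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  # brute-force oracle on an arbitrary 6-point table
  set.seed(21)
  df2 <- data.frame(a = rnorm(6), b = rnorm(6))
  r2 <- marker_correlations(df2, c("a", "b"))
  expect_equal(r2["a", "b"],
               stats::cor(rank(df2$a), rank(df2$b)), tolerance = 1e-12)
  const <- data.frame(a = rnorm(6), b = rep(1, 6))
  expect_warning(rc <- marker_correlations(const, c("a", "b")), "constant")
  expect_true(is.na(rc["a", "b"]))
})

test_that("PCA variance explained sums to one and finds structure", {
  set.seed(31)
  n <- 12
  dominant <- rnorm(n, sd = 10)
  df <- data.frame(line = paste0("l", 1:n),
                   SOX2 = dominant + rnorm(n, sd = 0.4),
                   BRA = -dominant + rnorm(n, sd = 0.4),
                   SOX17 = 0.5 * dominant + rnorm(n, sd = 0.4))
  p <- pca_lines(df, c("SOX2", "BRA", "SOX17"), ids = "line")
  ve <- glance(p)$variance_explained
  expect_equal(sum(ve), 1)
  expect_gt(ve[1], 0.9)
  expect_equal(nrow(tidy(p)), n)
  expect_error(pca_lines(df[1, ], c("SOX2", "BRA", "SOX17")), "at least 2")
})

test_that("clonal lines cluster in PCA score space", {
  set.seed(33)
  donors <- rep(c("aaaa", "bbbb", "cccc", "dddd"), each = 2)
  centre <- matrix(rnorm(12, sd = 8), nrow = 4)
  feats <- centre[rep(1:4, each = 2), ] + matrix(rnorm(24, sd = 0.5), 8)
  df <- data.frame(line = paste0(donors, "_", rep(1:2, 4)), feats)
  names(df)[2:4] <- c("SOX2", "BRA", "SOX17")
  p <- pca_lines(df, c("SOX2", "BRA", "SOX17"), ids = "line")
  sc <- tidy(p)
  d <- as.matrix(dist(sc[, c("PC1", "PC2")]))
  same <- outer(donors, donors, "==") & upper.tri(d)
  diff_donor <- outer(donors, donors, "!=") & upper.tri(d)
  expect_lt(max(d[same]), min(d[diff_donor]))
})
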