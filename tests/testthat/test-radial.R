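test_that("nucleus distance is the planar Euclidean distance", {
  expect_equal(nucleus_distance(3, 4, 0, 0), 5)
  expect_equal(nucleus_distance(10, 20, 10, 20), 0)
  expect_equal(nucleus_distance(125, 40, 100, 40), 25)
})

test_that("bin assignment uses half-open 25 um intervals", {
  b <- assign_bin(c(0, 24.999, 25, 499.9))
  expect_equal(as.integer(b), c(1L, 1L, 2L, 20L))
  expect_error(assign_bin(-1), ">= 0")
})

test_that("bin assignment matches a brute-force interval search exactly", {
  set.seed(101)
  d <- runif(10000, 0, 600)
  got <- suppressMessages(assign_bin(d))
  # independent oracle: explicit search over the 20 interval definitions
  edges_lo <- (0:19) * 25
  edges_hi <- (1:20) * 25
  oracle <- vapply(d, function(x) {
    hit <- which(x >= edges_lo & x < edges_hi)
    if (!length(hit)) 20L else as.integer(hit)  # clip beyond the last edge
  }, integer(1))
  expect_identical(as.integer(got), oracle)
  expect_equal(attr(got, "n_clipped"), sum(d >= 500))
})

test_that("DAPI normalization is a guarded ratio", {
  expect_equal(normalize_nucleus(200, 100), 2)
  expect_equal(normalize_nucleus(0, 100), 0)
  expect_equal(normalize_nucleus(400, 200), normalize_nucleus(200, 100))
  expect_error(normalize_nucleus(1, 0), "DAPI")
})

test_that("background estimation recovers a known mixture", {
  set.seed(7)
  ratios <- c(rnorm(600, 0.1, 0.03), rnorm(400, 1.0, 0.2))
  m <- estimate_background(ratios, "M")
  expect_s3_class(m, "positivity_model")
  expect_equal(m$method, "mixture")
  expect_lt(abs(m$background - 0.1), 0.05)
  expect_gte(m$threshold, m$background)
})

test_that("degenerate ratio distributions fall back with a warning", {
  expect_warning(m <- estimate_background(rep(0.1, 100)), "degenerate")
  expect_equal(m$method, "quantile")
  expect_error(estimate_background(rnorm(10)), "50")
})

test_that("background subtraction floors at zero", {
  m <- structure(list(marker = "M", background = 0.2, threshold = 0.3,
                      method = "mixture"), class = "positivity_model")
  expect_equal(subtract_background(c(0.1, 0.2, 0.5), m), c(0, 0, 0.3))
})

test_that("an all-negative marker yields near-zero percent positive", {
  set.seed(15)
  ratios <- rnorm(1000, 0.1, 0.03)  # background population only
  m <- estimate_background(ratios, "M")
  expect_lt(percent_positive(ratios, m), 2)
  # with a model fitted on a well that does contain positives, a
  # positive-free colony also scores ~0
  set.seed(16)
  with_pos <- c(rnorm(700, 0.1, 0.03), rnorm(300, 1, 0.2))
  m2 <- estimate_background(with_pos, "M")
  expect_lt(percent_positive(rnorm(500, 0.1, 0.03), m2), 2)
})

test_that("colony profiles average subtracted ratios per occupied bin", {
  m <- structure(list(marker = "M", background = 0, threshold = 0.5,
                      method = "mixture"), class = "positivity_model")
  d <- c(10, 30, 40, 480)
  p <- colony_profile(d, rep(1, 4), m)
  expect_equal(as.integer(p$bin), c(1L, 2L, 20L))
  expect_equal(p$value, c(1, 1, 1))
  expect_equal(p$n, c(1L, 2L, 1L))
  expect_error(colony_profile(numeric(0), numeric(0), m), "no nuclei")
})

test_that("a simulated outer ring peaks in the expected bin", {
  ring <- radial_model("ring", center_um = 425, width_um = 40)
  set.seed(77)
  d <- sample_positive_distances(ring, 2000)
  m <- structure(list(marker = "M", background = 0.1, threshold = 0.15,
                      method = "mixture"), class = "positivity_model")
  prof <- colony_profile(d, model_ratio(ring, d), m)
  expect_true(prof$bin[which.max(prof$value)] %in% c(17L, 18L))
})

test_that("well normalization scales the well maximum to exactly 1", {
  prof <- tibble::tibble(
    well = "A1", colony = c(1, 1, 2, 2), marker = "M",
    bin = c(1, 2, 1, 2), value = c(1, 4, 2, 3), n = 5)
  out <- well_normalize(prof)
  expect_equal(max(out$value), 1)
  expect_equal(out$value, c(0.25, 1, 0.5, 0.75))
  # idempotence
  expect_equal(well_normalize(out)$value, out$value)
  # identical colonies stay identical
  two <- tibble::tibble(well = "W", colony = c(1, 2), marker = "M",
                        bin = 1, value = c(2, 2), n = 3)
  expect_equal(unique(well_normalize(two)$value), 1)
  zero <- tibble::tibble(well = "W", colony = 1, marker = "M",
                         bin = 1:2, value = c(0, 0), n = 3)
  expect_warning(z <- well_normalize(zero), "left unscaled")
  expect_equal(z$value, c(0, 0))
})

test_that("aggregation is hierarchical with SD over the averaged units", {
  base <- tibble::tibble(
    line = "L", experiment = "E", marker = "M", bin = 1,
    well = c("w1", "w1", "w2"), colony = c(1, 2, 1),
    value = c(0.2, 0.4, 0.6))
  by_exp <- aggregate_profiles(base, "experiment")
  # hierarchical: mean(mean(0.2, 0.4), 0.6) = 0.45, not pooled 0.4
  expect_equal(by_exp$value, 0.45)
  expect_equal(by_exp$sd, stats::sd(c(0.3, 0.6)))

  ident <- tibble::tibble(line = "L", experiment = "E",
                          well = rep(c("a", "b"), each = 2),
                          colony = 1, marker = "M", bin = c(1, 2, 1, 2),
                          value = c(0.1, 0.9, 0.1, 0.9))
  agg <- aggregate_profiles(ident, "experiment")
  expect_equal(agg$sd, c(0, 0))
  expect_equal(agg$value, c(0.1, 0.9))

  anti <- tibble::tibble(line = "L", experiment = "E",
                         well = rep(c("a", "b"), each = 2),
                         colony = 1, marker = "M", bin = c(1, 2, 1, 2),
                         value = c(0, 1, 1, 0))
  agg2 <- aggregate_profiles(anti, "experiment")
  expect_equal(agg2$value, c(0.5, 0.5))
  expect_equal(agg2$sd, rep(sqrt(0.5), 2), tolerance = 1e-10)
})

test_that("percent positive is the positive fraction times 100", {
  m <- structure(list(marker = "M", background = 0, threshold = 0.5,
                      method = "mixture"), class = "positivity_model")
  expect_equal(percent_positive(c(rep(1, 30), rep(0.1, 70)), m), 30)
  expect_equal(percent_positive(rep(0.1, 50), m), 0)
})

test_that("bin geometry tiles the nominal colony radius exactly", {
  edges <- (0:20) * 25
  expect_equal(length(edges) - 1, 20)
  expect_equal(max(edges), 500)
  expect_equal(max(edges), 1000 / 2)
})
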