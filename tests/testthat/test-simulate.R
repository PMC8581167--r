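test_that("ground-truth intensities follow the stated radial model", {
  ring <- radial_model("ring", center_um = 300, width_um = 60,
                       amplitude = 0.9, baseline = 0.1,
                       positive_fraction = 0.9)
  cfg <- small_config(nuclei = 120, noise_sd = 0,
                      marker_models = list(M = ring))
  sim <- generate_well(cfg, seed = 3)
  tr <- sim$truth$nuclei
  closed_form <- 0.1 + 0.9 * exp(-(tr$dist_um - 300)^2 / (2 * 60^2))
  expect_equal(tr$ratio_M[tr$positive_M], closed_form[tr$positive_M])
  expect_equal(tr$ratio_M[!tr$positive_M],
               rep(0.1, sum(!tr$positive_M)))
})

test_that("noiseless images re-measured at true positions recover the model", {
  cfg <- small_config(nuclei = 100, noise_sd = 0, dapi_cv = 0)
  sim <- generate_well(cfg, seed = 9)
  tr <- sim$truth$nuclei
  ps <- sim$image$pixel_size_um
  px <- round(tr$x_um / ps + 0.5)
  py <- round(tr$y_um / ps + 0.5)
  dapi <- sim$image$channels$DAPI[cbind(px, py)]
  sox2 <- sim$image$channels$SOX2[cbind(px, py)]
  expect_gt(min(dapi), 0)
  # marker = DAPI * ratio pixelwise, both blurred identically, so the
  # centre-pixel ratio matches the configured ratio up to neighbour spill
  expect_lt(max(abs(sox2 / dapi - tr$ratio_SOX2)), 0.02)
})

test_that("truncation flags mark exactly the discs crossing the border", {
  cfg <- small_config(n_colonies = 4, nuclei = 60, fraction_truncated = 0.5)
  sim <- generate_well(cfg, seed = 21)
  tc <- sim$truth$colonies
  d <- dim(sim$image$channels$DAPI) * cfg$pixel_size_um
  border <- pmin(tc$x_um, d[1] - tc$x_um, tc$y_um, d[2] - tc$y_um)
  expect_equal(tc$truncated, border < 500)
  expect_equal(sum(tc$truncated), 2)

  none <- generate_well(small_config(n_colonies = 2, nuclei = 40), seed = 2)
  expect_false(any(none$truth$colonies$truncated))
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- small_config(nuclei = 80)
  a <- generate_well(cfg, seed = 7)
  b <- generate_well(cfg, seed = 7)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
})

test_that("infeasible nucleus packing errors and names the parameter", {
  cfg <- sim_config(colony_diameter_um = 100, n_colonies_per_well = 1,
                    nuclei_per_colony = 60, min_spacing_um = 30)
  expect_error(generate_well(cfg, seed = 1), "nuclei_per_colony")
})

test_that("replicate wells of one line share ground-truth expectations", {
  lay <- plate_layout(c("A1", "A2", "A3"), lines = "uoxz_4",
                      replicate = 1:3)
  cfg <- small_config(nuclei = 50, plate_layout = lay)
  plate <- generate_plate(cfg, seed = 4)
  expect_identical(plate$truth$A1$expected_profiles,
                   plate$truth$A2$expected_profiles)
  expect_identical(plate$truth$A1$expected_profiles,
                   plate$truth$A3$expected_profiles)
  expect_false(identical(plate$truth$A1$nuclei, plate$truth$A2$nuclei))
})

test_that("a 100 um donor ring shift moves the expected peak by 4 bins", {
  ring <- radial_model("ring", center_um = 287.5, width_um = 40)
  lay <- plate_layout(c("A1", "B1"), lines = c("lineA", "lineB"))
  cfg <- small_config(nuclei = 50, plate_layout = lay,
                      marker_models = list(M = ring),
                      donor_effects = list(
                        lineB = list(center_shift_um = 100)))
  plate <- generate_plate(cfg, seed = 8)
  peak <- function(w) {
    ep <- plate$truth[[w]]$expected_profiles
    ep$bin[which.max(ep$expected)]
  }
  expect_equal(peak("B1") - peak("A1"), 4)
})

test_that("plate generation validates its layout", {
  expect_error(generate_plate(small_config()), "empty")
  bad <- tibble::tibble(well = c("A1", "A1"), line = "x", donor = "x",
                        experiment = "e", replicate = 1L)
  cfg <- small_config(nuclei = 20, plate_layout = bad)
  expect_error(generate_plate(cfg), "duplicate")
  expect_error(plate_layout(c("A1", "A1"), "x"), "duplicate")
})

test_that("variant tables honour the requested pass/fail structure", {
  v <- generate_variant_table(5, 3, 2, 1, seed = 11)
  expect_equal(nrow(v), 11)
  expect_equal(sum(v$truth_pass), 5)
  pass <- v[v$truth_pass, ]
  expect_true(all(pass$maf_1000g < 0.005 & pass$maf_exac < 0.005))
  expect_true(all(pass$n_hipsci_lines < 5))
  expect_true(all(pass$condel_class == "deleterious"))
  fail <- v[!v$truth_pass, ]
  expect_true(all(fail$maf_1000g >= 0.005 | fail$maf_exac >= 0.005 |
                    fail$n_hipsci_lines >= 5 |
                    fail$condel_class != "deleterious"))

  expect_equal(nrow(generate_variant_table(0, 0, 0, 0, seed = 1)), 0)
  expect_error(generate_variant_table(-1, 0, 0, 0), ">= 0")
})

test_that("radial model construction enforces its invariants", {
  expect_error(radial_model("ring", amplitude = -1), ">= 0")
  expect_error(radial_model("ring", positive_fraction = 1.2), "0, 1")
  expect_error(radial_model("ring", discontinuity_fraction = 1), "0, 1")
  expect_error(sim_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(sim_config(fraction_truncated = 1.5), "fraction_truncated")
  dome <- radial_model("center_dome", center_um = 99, width_um = 150)
  expect_equal(dome$center_um, 0)
  expect_equal(model_shape(dome, 0), 1)
})
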