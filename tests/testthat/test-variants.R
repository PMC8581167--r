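mk_variant <- function(gene = "GENE1", maf1 = 0.001, maf2 = 0.001,
                       n_lines = 1L, condel = "deleterious",
                       carriers = "aaaa_1") {
  tibble::tibble(gene = gene, substitution = "p.A100V", maf_1000g = maf1,
                 maf_exac = maf2, n_hipsci_lines = as.integer(n_lines),
                 condel_class = condel, duet_ddg = NA_real_,
                 carrier_lines = carriers, truth_pass = NA)
}

test_that("rarity filter applies strict boundaries", {
  expect_equal(nrow(filter_rare(mk_variant(maf1 = 0.004, maf2 = 0.004,
                                           n_lines = 4))), 1)
  # boundary cases are excluded: MAF exactly 0.005, exactly five lines
  expect_equal(nrow(filter_rare(mk_variant(maf1 = 0.005, maf2 = 0.001))), 0)
  expect_equal(nrow(filter_rare(mk_variant(maf2 = 0.005))), 0)
  expect_equal(nrow(filter_rare(mk_variant(n_lines = 5))), 0)
  expect_message(out <- filter_rare(mk_variant(maf1 = NA)), "missing MAF")
  expect_equal(nrow(out), 0)
  expect_error(filter_rare(mk_variant(maf1 = 1.2)), "malformed")
  expect_error(filter_rare(mk_variant(maf2 = -0.1)), "malformed")
})

test_that("deleteriousness filter keeps only Condel-deleterious calls", {
  expect_equal(nrow(filter_deleterious(mk_variant())), 1)
  expect_equal(nrow(filter_deleterious(mk_variant(condel = "neutral"))), 0)
  expect_warning(out <- filter_deleterious(mk_variant(condel = "missing")),
                 "missing Condel")
  expect_equal(nrow(out), 0)
})

test_that("filters commute and round-trip generator pass counts", {
  for (counts in list(c(5, 3, 2, 1), c(0, 4, 0, 2), c(7, 0, 0, 0),
                      c(0, 0, 0, 0), c(2, 2, 2, 2))) {
    v <- generate_variant_table(counts[1], counts[2], counts[3], counts[4],
                                seed = sum(counts) + 17)
    ab <- suppressWarnings(suppressMessages(
      filter_deleterious(filter_rare(v))))
    ba <- suppressWarnings(suppressMessages(
      filter_rare(filter_deleterious(v))))
    expect_equal(nrow(ab), counts[1])
    expect_identical(dplyr::arrange(ab, gene, substitution),
                     dplyr::arrange(ba, gene, substitution))
    expect_true(all(ab$truth_pass))
  }
})

test_that("the rarity filter removes exactly the MAF-failing class", {
  v <- generate_variant_table(5, 3, 2, 1, seed = 99)
  kept <- filter_rare(v)
  # rows failing only the MAF rule are gone; condel-failing rows remain
  expect_equal(nrow(kept), 5 + 2)
  expect_true(all(kept$n_hipsci_lines < 5))
})

test_that("lines are classified into the four phenotype categories", {
  passing <- dplyr::bind_rows(
    mk_variant(gene = "FGFR1", carriers = "bokz_5;bokz_6"),
    mk_variant(gene = "ITGB1", carriers = "ffdc_5;ffdc_11"),
    mk_variant(gene = "TBXT", carriers = "ffdc_5;ffdc_11"),
    mk_variant(gene = "GENE042", carriers = "uoxz_4"))
  cls <- classify_lines(passing)
  lookup <- setNames(cls$category, cls$line)
  expect_equal(lookup[["bokz_5"]], "germ_layer")
  expect_equal(lookup[["bokz_6"]], "germ_layer")
  expect_equal(lookup[["ffdc_5"]], "both")
  expect_equal(lookup[["ffdc_11"]], "both")
  expect_equal(lookup[["uoxz_4"]], "control")
  expect_message(
    classify_lines(passing, outlier_flags = c("uoxz_4", "zzzz_9")),
    "without qualifying")
})

test_that("summaries count distinct variants, lines and donors", {
  expect_equal(summarize_variants(mk_variant()[0, ]),
               tibble::tibble(n_variants = 0L, n_lines = 0L, n_donors = 0L))
  two <- dplyr::bind_rows(
    mk_variant(gene = "A", carriers = "aaaa_1"),
    mk_variant(gene = "B", carriers = "aaaa_1"))
  expect_equal(summarize_variants(two),
               tibble::tibble(n_variants = 2L, n_lines = 1L, n_donors = 1L))
  v <- generate_variant_table(6, 2, 2, 2, seed = 5)
  s <- summarize_variants(v)
  carriers <- unique(unlist(strsplit(v$carrier_lines, ";")))
  expect_equal(s$n_variants, nrow(v))
  expect_equal(s$n_lines, length(carriers))
  expect_equal(s$n_donors, length(unique(sub("_.*$", "", carriers))))
})
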