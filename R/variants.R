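# Rare/deleterious nsSNV selection and line classification. Condel and DUET
# scores are consumed as input annotations; this module only applies the
# selection rules and bookkeeping.

check_maf <- function(variants, col) {
  v <- variants[[col]]
  bad <- which(!is.na(v) & (v < 0 | v > 1))
  if (length(bad))
    abort(sprintf("malformed %s (outside [0, 1]) in record(s): %s", col,
                  paste(variants$gene[bad], variants$substitution[bad],
                        sep = " ", collapse = ", ")))
  invisible(variants)
}

#' Keep rare variants
#'
#' Retains variants with minor allele frequency strictly below 0.005 in
#' both population databases and carried by strictly fewer than five HipSci
#' lines. A missing MAF in either database is treated as failing the rarity
#' test (conservative); the number of records dropped for missingness is
#' reported.
#'
#' @param variants Tibble with columns `maf_1000g`, `maf_exac`,
#'   `n_hipsci_lines` (plus `gene`/`substitution` for error reporting).
#' @param maf_cutoff Strict MAF cutoff (default 0.005).
#' @param max_lines Variants in at least this many lines are dropped
#'   (default 5, i.e. "fewer than five" are kept).
#' @return Filtered tibble.
#' @examples
#' v <- generate_variant_table(2, 2, 0, 0, seed = 1)
#' nrow(filter_rare(v))  # 2
#' @export
filter_rare <- function(variants, maf_cutoff = 0.005, max_lines = 5) {
  check_maf(variants, "maf_1000g")
  check_maf(variants, "maf_exac")
  missing_maf <- is.na(variants$maf_1000g) | is.na(variants$maf_exac)
  if (any(missing_maf))
    inform(sprintf("%d variants dropped for missing MAF annotation.",
                   sum(missing_maf)))
  filter(variants,
         !is.na(maf_1000g) & maf_1000g < maf_cutoff,
         !is.na(maf_exac) & maf_exac < maf_cutoff,
         n_hipsci_lines < max_lines)
}

#' Keep variants predicted deleterious
#'
#' Retains variants whose Condel classification is `"deleterious"`.
#' Records with a missing classification are dropped with a warning.
#'
#' @param variants Tibble with a `condel_class` column.
#' @return Filtered tibble.
#' @export
filter_deleterious <- function(variants) {
  miss <- is.na(variants$condel_class) | variants$condel_class == "missing"
  if (any(miss))
    warn(sprintf("%d variants dropped for missing Condel class.", sum(miss)))
  filter(variants, !is.na(condel_class), condel_class == "deleterious")
}

#' Default adhesion / germ-layer gene sets
#'
#' Representative members of the two curated sets used to classify lines:
#' cell-adhesion genes (e.g. ITGB1, ITGA6, FHL2) and germ-layer
#' differentiation genes (e.g. SMAD2, FGFR1, TBXT). Extend or replace as
#' needed; sets may overlap.
#'
#' @return Named list of character vectors `cell_adhesion`, `germ_layer`.
#' @export
default_gene_sets <- function() {
  list(
    cell_adhesion = c("ITGB1", "ITGA6", "FHL2", "ITGAV", "VCL", "PXN",
                      "TLN1"),
    germ_layer = c("SMAD2", "FGFR1", "TBXT", "NODAL", "EOMES", "GATA6",
                   "WNT3")
  )
}

# Expand the ';'-separated carrier_lines column into (variant row, line).
expand_carriers <- function(variants) {
  if (!nrow(variants))
    return(tibble(row = integer(), line = character()))
  carriers <- strsplit(variants$carrier_lines, ";", fixed = TRUE)
  tibble(row = rep(seq_len(nrow(variants)), lengths(carriers)),
         line = unlist(carriers))
}

#' Classify cell lines by their qualifying variants
#'
#' Assigns each carrier line to one of four categories depending on which
#' curated gene sets its surviving (rare + deleterious) variants hit:
#' `"adhesion"`, `"germ_layer"`, `"both"`, or `"control"` (no qualifying
#' variant in either set). Lines supplied via `outlier_flags` (e.g. known
#' fibronectin-adhesion outliers) but lacking any qualifying set variant
#' are reported as inconsistencies.
#'
#' @param variants Variants that already passed [filter_rare()] and
#'   [filter_deleterious()].
#' @param gene_sets Named list with `cell_adhesion` and `germ_layer`
#'   members (see [default_gene_sets()]).
#' @param lines Line ids to classify; defaults to all carrier lines in
#'   `variants`.
#' @param outlier_flags Optional character vector of line ids flagged as
#'   phenotypic outliers from prior (non-genetic) assays.
#' @return Tibble `line`, `category`, `adhesion_genes`, `germ_layer_genes`.
#' @export
classify_lines <- function(variants, gene_sets = default_gene_sets(),
                           lines = NULL, outlier_flags = NULL) {
  carriers <- expand_carriers(variants)
  carriers$gene <- variants$gene[carriers$row]
  lines <- lines %||% sort(unique(carriers$line))
  per_line <- lapply(lines, function(ln) {
    genes <- carriers$gene[carriers$line == ln]
    adh <- intersect(genes, gene_sets$cell_adhesion)
    germ <- intersect(genes, gene_sets$germ_layer)
    tibble(
      line = ln,
      category = if (length(adh) && length(germ)) "both"
                 else if (length(adh)) "adhesion"
                 else if (length(germ)) "germ_layer"
                 else "control",
      adhesion_genes = paste(adh, collapse = ";"),
      germ_layer_genes = paste(germ, collapse = ";")
    )
  })
  out <- bind_rows(per_line)
  if (!is.null(outlier_flags)) {
    odd <- setdiff(intersect(outlier_flags, out$line),
                   out$line[out$category != "control"])
    odd <- union(odd, setdiff(outlier_flags, out$line))
    if (length(odd))
      inform(paste0("flagged outlier line(s) without qualifying set ",
                    "variants: ", paste(odd, collapse = ", ")))
  }
  out
}

#' Summarize a variant table
#'
#' @param variants Variant tibble with `gene`, `substitution`,
#'   `carrier_lines`.
#' @return One-row tibble `n_variants`, `n_lines`, `n_donors` (donor = the
#'   four-letter prefix of the line id, the HipSci clonal-line convention).
#' @examples
#' summarize_variants(generate_variant_table(5, 0, 0, 0, seed = 1))
#' @export
summarize_variants <- function(variants) {
  if (!nrow(variants))
    return(tibble(n_variants = 0L, n_lines = 0L, n_donors = 0L))
  carriers <- expand_carriers(variants)
  tibble(
    n_variants = nrow(distinct(variants, gene, substitution)),
    n_lines = length(unique(carriers$line)),
    n_donors = length(unique(sub("_.*$", "", carriers$line)))
  )
}
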