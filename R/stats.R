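# The statistical layer: Kolmogorov-Smirnov comparison of radial positions
# of marker-positive nuclei, Kruskal-Wallis with Dunn's post hoc across
# lines, pooled two-tailed t outlier calling (p < 0.001), KS-vs-control
# radial outlier calling (p < 0.01), Spearman correlations and PCA of
# line-level percent-positive features.

stats_row <- function(test, statistic, p_value, comparison, alpha) {
  tibble(test = test, statistic = unname(statistic),
         p_value = unname(p_value), comparison = comparison,
         alpha = alpha, significant = p_value < alpha)
}

#' Compare radial patterning of two samples (Kolmogorov-Smirnov)
#'
#' Two-sample KS test on the radial distances of marker-positive nuclei in
#' two groups (technical/biological replicates, or a line against a
#' control). The spatial distribution of positive cells captures the radial
#' patterning directly, nucleus by nucleus.
#'
#' @param d_a,d_b Radial distances (um) of marker-positive nuclei in each
#'   group; each needs at least 10 values.
#' @param marker Optional marker name for reporting.
#' @param alpha Significance level (default 0.01, the level used for
#'   radial-outlier calling).
#' @return One-row tibble: `test`, `statistic` (KS D), `p_value`,
#'   `comparison`, `alpha`, `significant`.
#' @examples
#' ks_radial_compare(runif(50, 0, 500), runif(50, 0, 500))
#' @export
ks_radial_compare <- function(d_a, d_b, marker = NA_character_,
                              alpha = 0.01) {
  if (length(d_a) < 10)
    abort("group A has fewer than 10 marker-positive nuclei.")
  if (length(d_b) < 10)
    abort("group B has fewer than 10 marker-positive nuclei.")
  ks <- suppressWarnings(ks.test(d_a, d_b))
  stats_row("ks", ks$statistic, ks$p.value,
            paste0("radial distribution", if (!is.na(marker))
              paste0(" of ", marker)), alpha)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Rank-based comparison of a value (typically colony percent-positive)
#' across three or more cell lines, followed by Dunn's pairwise z tests on
#' mean ranks with tie correction and multiplicity adjustment.
#'
#' @param data Data frame with one row per colony.
#' @param value Name of the value column (string).
#' @param group Name of the grouping column (string), e.g. the line id.
#' @param alpha Omnibus significance level (default 0.05).
#' @param p_adjust Multiplicity adjustment for Dunn's p values (any
#'   [stats::p.adjust()] method; default `"bonferroni"`, the convention of
#'   common graphing software).
#' @return Object of class `mp_kruskal_dunn`: list with `omnibus` (one-row
#'   tibble) and `pairwise` (tibble of Dunn's z and adjusted p per pair).
#'   [glance()] returns the omnibus row, [tidy()] the pairwise table.
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                  g = rep(c("a", "b", "c"), each = 3))
#' glance(kruskal_dunn(df, "v", "g"))
#' @export
kruskal_dunn <- function(data, value, group, alpha = 0.05,
                         p_adjust = "bonferroni") {
  x <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 3) abort("need at least 3 groups.")
  kw <- kruskal.test(x, g)

  # Dunn's test: z on mean ranks with tie correction
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n_g[[p[1]]] + 1 / n_g[[p[2]]]))
    (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  pairwise <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z,
    p_value = stats::p.adjust(p_raw, method = p_adjust)
  )
  structure(
    list(
      omnibus = stats_row("kruskal_wallis", kw$statistic, kw$p.value,
                          paste0(value, " across ", group), alpha),
      pairwise = pairwise
    ),
    class = "mp_kruskal_dunn"
  )
}

#' @export
glance.mp_kruskal_dunn <- function(x, ...) x$omnibus

#' @export
tidy.mp_kruskal_dunn <- function(x, ...) x$pairwise

#' @export
print.mp_kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, p = %.3g (alpha %.3g)\n",
              x$omnibus$statistic, x$omnibus$p_value, x$omnibus$alpha))
  print(x$pairwise)
  invisible(x)
}

#' Pooled-t outlier test for one line's mean expression
#'
#' Compares the colony values of one line against the colonies of all other
#' lines pooled together with a two-tailed Student's (pooled-variance)
#' t test; p < 0.001 flags the line as a phenotypic outlier.
#'
#' @param data Data frame with one row per colony.
#' @param target Line id to test.
#' @param value Name of the value column (string).
#' @param line Name of the line-id column (string).
#' @param alpha Significance level (default 0.001).
#' @param welch Use Welch's unequal-variance t instead of Student's.
#' @return One-row tibble as in [ks_radial_compare()].
#' @export
outlier_mean_expression <- function(data, target, value, line,
                                    alpha = 0.001, welch = FALSE) {
  x <- data[[value]][data[[line]] == target]
  y <- data[[value]][data[[line]] != target]
  if (length(x) < 3) abort("target line has fewer than 3 colonies.")
  if (length(y) < 4) abort("pooled lines have fewer than 4 colonies.")
  if (sd(x) == 0 && sd(y) == 0)
    abort("zero variance in both groups; t test undefined.")
  tt <- t.test(x, y, var.equal = !welch)
  stats_row("pooled_t", tt$statistic, tt$p.value,
            paste0(target, " vs pooled lines"), alpha)
}

#' KS radial-outlier test of a line against the control line
#'
#' @param d_target,d_control Radial distances (um) of marker-positive
#'   nuclei of the tested line and of the designated control line.
#' @inheritParams ks_radial_compare
#' @return One-row tibble; `significant` flags a radial outlier at
#'   p < `alpha` (default 0.01).
#' @export
outlier_radial <- function(d_target, d_control, marker = NA_character_,
                           alpha = 0.01) {
  ks_radial_compare(d_target, d_control, marker = marker, alpha = alpha)
}

#' Spearman correlations between marker expression levels
#'
#' @param data Data frame with one row per colony (or per line).
#' @param markers Character vector of column names to correlate.
#' @return Symmetric matrix of Spearman's rank correlation coefficients;
#'   constant columns yield `NA` with a warning.
#' @export
marker_correlations <- function(data, markers) {
  m <- as.matrix(data[, markers, drop = FALSE])
  if (nrow(m) < 5) abort("need at least 5 observations.")
  constant <- apply(m, 2, function(v) sd(v, na.rm = TRUE) == 0)
  if (any(constant))
    warn(paste0("constant columns give undefined correlations: ",
                paste(markers[constant], collapse = ", ")))
  suppressWarnings(cor(m, method = "spearman",
                       use = "pairwise.complete.obs"))
}

#' PCA of line-level marker features
#'
#' Centered, optionally column-standardized principal component analysis of
#' a lines-by-markers feature table (percent-positive per marker). Clonal
#' lines from the same donor should land close together in score space when
#' phenotype is genetically driven.
#'
#' @param data Data frame with one row per line.
#' @param features Character vector of feature column names.
#' @param ids Name of the line-id column (string), or `NULL` for rownames.
#' @param scale Standardize columns (default `TRUE`).
#' @return Object of class `mp_pca` wrapping [stats::prcomp()]; [tidy()]
#'   returns per-line scores, [glance()] per-component variance explained
#'   (summing to 1).
#' @export
pca_lines <- function(data, features, ids = NULL, scale = TRUE) {
  if (nrow(data) < 2) abort("need at least 2 observations for PCA.")
  m <- as.matrix(data[, features, drop = FALSE])
  fit <- prcomp(m, center = TRUE, scale. = scale)
  structure(
    list(fit = fit,
         ids = if (!is.null(ids)) as.character(data[[ids]])
               else as.character(seq_len(nrow(data)))),
    class = "mp_pca"
  )
}

#' @export
tidy.mp_pca <- function(x, ...) {
  scores <- as_tibble(x$fit$x)
  scores$line <- x$ids
  select(scores, line, dplyr::everything())
}

#' @export
glance.mp_pca <- function(x, ...) {
  v <- x$fit$sdev^2
  tibble(component = paste0("PC", seq_along(v)),
         variance_explained = v / sum(v))
}

#' @export
print.mp_pca <- function(x, ...) {
  ve <- glance(x)$variance_explained
  cat(sprintf("<mp_pca> %d lines, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$ids), length(ve), 100 * ve[1],
              if (length(ve) > 1) 100 * ve[2] else 0))
  invisible(x)
}
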