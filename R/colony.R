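# Colony identification and morphology-based quality control. The colony
# mask is the morphological closing of the union of nucleus masks; connected
# components are colonies. QC rejects edge-touching, mis-sized or non-round
# colonies, in that priority order.

#' Isoperimetric roundness
#'
#' `4 * pi * area / perimeter^2`, capped at 1: exactly 1 for a circle,
#' `pi / 4` for a square, about 0.75 for a half disc.
#'
#' @param area Area (any consistent unit).
#' @param perimeter Perimeter (same length unit).
#' @return Roundness in `(0, 1]`.
#' @examples
#' colony_roundness(pi * 100^2, 2 * pi * 100)  # 1
#' colony_roundness(1, 4)                      # square: pi/4
#' @export
colony_roundness <- function(area, perimeter) {
  if (any(area <= 0)) abort("`area` must be > 0.")
  if (any(perimeter <= 0)) abort("`perimeter` must be > 0.")
  pmin(4 * pi * area / perimeter^2, 1)
}

# Convex-hull geometry (area, perimeter) of each labelled object from its
# boundary contour. The outer boundary of a micropatterned colony is convex
# by construction (circular pattern), so the hull strips the scalloping the
# nucleus-union mask shows between peripheral nuclei: a rasterized disc
# measures isoperimetric roundness ~0.99 and recovers the disc area to
# ~0.1%, while a half disc stays at its analytic ~0.75.
hull_geometry <- function(labels) {
  ocs <- EBImage::ocontour(labels)
  out <- vapply(ocs, function(oc) {
    if (nrow(oc) < 3) return(c(perimeter = 4, area = 1))
    hp <- oc[grDevices::chull(oc), , drop = FALSE]
    d <- rbind(diff(hp), hp[1, , drop = FALSE] - hp[nrow(hp), , drop = FALSE])
    per <- sum(sqrt(rowSums(d^2)))
    area <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                      hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
    # single-pixel specks can have a collinear/empty hull; floor the
    # geometry so roundness stays defined (they fail the area gate anyway)
    c(perimeter = max(per, 4), area = max(area, 1))
  }, c(perimeter = 0, area = 0))
  list(perimeter_px = out["perimeter", ], area_px2 = out["area", ])
}

#' Group nuclei into colonies
#'
#' Forms the colony mask by morphologically closing the union of nucleus
#' masks with a disc of radius about the inter-nucleus spacing, fills holes
#' and labels connected components. Every nucleus is assigned to the colony
#' whose mask contains its centroid (or left unassigned, `NA`).
#'
#' @param nuclei Measured nucleus table from [measure_intensities()] (with
#'   `"labels"` attribute).
#' @param image The [well_image()] the nuclei came from.
#' @param closing_radius_um Radius of the closing structuring element (um);
#'   default 50 um: large enough to bridge the sparsest inter-nucleus gaps, far below the inter-colony spacing.
#' @return A list: `colonies` (tibble `colony`, `x_um`, `y_um`, `area_um2`,
#'   `perimeter_um`, `roundness`, `edge_dist_um`, `n_nuclei`), `nuclei`
#'   (input plus `colony` column), `colony_labels` (integer matrix).
#' @export
identify_colonies <- function(nuclei, image, closing_radius_um = 50) {
  stopifnot(inherits(image, "well_image"))
  ps <- image$pixel_size_um
  empty <- list(
    colonies = tibble(colony = integer(), x_um = double(), y_um = double(),
                      area_um2 = double(), perimeter_um = double(),
                      roundness = double(), edge_dist_um = double(),
                      n_nuclei = integer()),
    nuclei = mutate(nuclei, colony = integer(nrow(nuclei))),
    colony_labels = attr(nuclei, "labels")
  )
  if (!nrow(nuclei)) return(empty)
  labels <- attr(nuclei, "labels")
  if (is.null(labels)) abort("`nuclei` must carry the segmentation labels.")

  brush_d <- 2 * round(closing_radius_um / ps) + 1
  mask <- EBImage::closing(labels > 0, EBImage::makeBrush(brush_d, "disc"))
  mask <- EBImage::fillHull(mask)
  clab <- EBImage::bwlabel(mask)
  n_col <- max(clab)
  if (n_col == 0) return(empty)

  mom <- EBImage::computeFeatures.moment(clab)
  geo <- hull_geometry(clab)
  cl <- EBImage::imageData(clab)
  nx <- nrow(cl); ny <- ncol(cl)

  # distance from each colony mask to the nearest image border, in px
  edge_px <- vapply(seq_len(n_col), function(k) {
    idx <- which(cl == k)
    ix <- (idx - 1) %% nx + 1
    iy <- (idx - 1) %/% nx + 1
    min(ix - 1, nx - ix, iy - 1, ny - iy)
  }, numeric(1))

  colonies <- tibble(
    colony = seq_len(n_col),
    x_um = (mom[, "m.cx"] - 0.5) * ps,
    y_um = (mom[, "m.cy"] - 0.5) * ps,
    area_um2 = geo$area_px2 * ps^2,
    perimeter_um = geo$perimeter_px * ps,
    roundness = colony_roundness(geo$area_px2, geo$perimeter_px),
    edge_dist_um = edge_px * ps
  )

  px <- pmin(pmax(round(nuclei$x_um / ps + 0.5), 1), nx)
  py <- pmin(pmax(round(nuclei$y_um / ps + 0.5), 1), ny)
  assign <- cl[cbind(px, py)]
  nuclei$colony <- ifelse(assign == 0, NA_integer_, as.integer(assign))
  counts <- table(factor(nuclei$colony, levels = seq_len(n_col)))
  colonies$n_nuclei <- as.integer(counts)
  # erosion can pinch off islets containing no nucleus centroid; a
  # component without nuclei is not a colony
  colonies <- colonies[colonies$n_nuclei > 0, ]
  list(colonies = colonies, nuclei = nuclei, colony_labels = cl)
}

#' QC thresholds for colony filtering
#'
#' @param min_area_frac,max_area_frac Accepted colony area window as a
#'   fraction of the nominal disc area `pi * (colony_diameter_um / 2)^2`.
#' @param min_roundness Minimum isoperimetric roundness.
#' @param edge_margin_um Colonies whose mask comes within this distance of
#'   the image border are rejected as edge colonies.
#' @param colony_diameter_um Nominal colony diameter (um).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_area_frac = 0.7, max_area_frac = 1.3,
                          min_roundness = 0.8, edge_margin_um = 10,
                          colony_diameter_um = 1000) {
  if (min_area_frac <= 0 || min_area_frac >= max_area_frac)
    abort("need 0 < min_area_frac < max_area_frac.")
  if (min_roundness <= 0 || min_roundness > 1)
    abort("need 0 < min_roundness <= 1.")
  structure(list(min_area_frac = min_area_frac,
                 max_area_frac = max_area_frac,
                 min_roundness = min_roundness,
                 edge_margin_um = edge_margin_um,
                 colony_diameter_um = colony_diameter_um),
            class = "qc_thresholds")
}

#' Apply colony quality control
#'
#' Rejects colonies whose mask approaches the image border (reason
#' `"edge"`), whose area falls outside the configured window around the
#' nominal disc area (`"area"`), or whose roundness is below threshold
#' (`"roundness"`); the first failing rule in that order is recorded. All
#' other colonies are qualified.
#'
#' @param colonies Colony table from [identify_colonies()].
#' @param thresholds A [qc_thresholds()].
#' @return `colonies` with `qc_status` (`"qualified"`/`"rejected"`) and
#'   `rejection_reason` (`"none"`, `"edge"`, `"area"`, `"roundness"`).
#' @export
qc_filter <- function(colonies, thresholds = qc_thresholds()) {
  nominal <- pi * (thresholds$colony_diameter_um / 2)^2
  mutate(colonies,
    rejection_reason = case_when(
      edge_dist_um < thresholds$edge_margin_um ~ "edge",
      area_um2 < thresholds$min_area_frac * nominal |
        area_um2 > thresholds$max_area_frac * nominal ~ "area",
      roundness < thresholds$min_roundness ~ "roundness",
      TRUE ~ "none"
    ),
    qc_status = ifelse(rejection_reason == "none", "qualified", "rejected")
  )
}
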