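# Nucleus segmentation in the DAPI channel: Gaussian smoothing, Otsu
# threshold, distance-transform watershed to split touching nuclei, and a
# minimum-area filter. The label matrix travels with the nucleus table (as an
# attribute) so downstream intensity measurement and colony grouping reuse
# the same masks.

#' Segmentation parameters
#'
#' @param blur_sigma_px Gaussian smoothing sigma before thresholding (px).
#' @param expected_nucleus_radius_um Nominal nucleus radius; objects smaller
#'   than `min_area_frac` times the nominal nucleus area are discarded.
#' @param min_area_frac Minimum object area as a fraction of nominal area.
#' @param watershed_tolerance,watershed_ext Passed to [EBImage::watershed()].
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(blur_sigma_px = 1,
                           expected_nucleus_radius_um = 8,
                           min_area_frac = 0.25,
                           watershed_tolerance = 1,
                           watershed_ext = 1) {
  structure(list(blur_sigma_px = blur_sigma_px,
                 expected_nucleus_radius_um = expected_nucleus_radius_um,
                 min_area_frac = min_area_frac,
                 watershed_tolerance = watershed_tolerance,
                 watershed_ext = watershed_ext),
            class = "segment_params")
}

#' Detect nuclei in the DAPI channel
#'
#' Segments nuclei by Gaussian smoothing, Otsu thresholding and a
#' distance-transform watershed that splits touching DAPI blobs, then drops
#' objects below the minimum-area filter. Centroids are reported in um
#' (pixel centre convention: pixel `i` spans `[(i-1), i] * pixel_size_um`).
#'
#' @param image A [well_image()] whose channels include `"DAPI"`.
#' @param params A [segment_params()].
#' @return A tibble with one row per nucleus (`nucleus`, `x_um`, `y_um`,
#'   `area_px`) carrying the integer label matrix as attribute `"labels"`.
#'   An all-zero image yields an empty tibble.
#' @examples
#' sim <- generate_well(sim_config(n_colonies_per_well = 1,
#'                                 nuclei_per_colony = 40), seed = 1)
#' nrow(detect_nuclei(sim$image))
#' @export
detect_nuclei <- function(image, params = segment_params()) {
  stopifnot(inherits(image, "well_image"))
  dapi <- image$channels[["DAPI"]]
  if (is.null(dapi)) abort("DAPI channel missing from well image.")
  ps <- image$pixel_size_um
  empty <- tibble(nucleus = integer(), x_um = double(), y_um = double(),
                  area_px = integer())
  attr(empty, "labels") <- matrix(0L, nrow(dapi), ncol(dapi))
  if (max(dapi) <= 0) return(empty)

  norm <- dapi / max(dapi)
  sm <- EBImage::imageData(EBImage::gblur(norm, sigma = params$blur_sigma_px))
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sm))
  mask <- sm > thr
  if (!any(mask)) return(empty)
  labels <- EBImage::watershed(EBImage::distmap(mask),
                               tolerance = params$watershed_tolerance,
                               ext = params$watershed_ext)
  min_area <- params$min_area_frac *
    pi * (params$expected_nucleus_radius_um / ps)^2
  shape <- EBImage::computeFeatures.shape(labels)
  small <- which(shape[, "s.area"] < min_area)
  if (length(small))
    labels <- EBImage::rmObjects(labels, small, reenumerate = TRUE)
  if (max(labels) == 0) return(empty)

  mom <- EBImage::computeFeatures.moment(labels)
  shape <- EBImage::computeFeatures.shape(labels)
  out <- tibble(
    nucleus = seq_len(nrow(mom)),
    x_um = (mom[, "m.cx"] - 0.5) * ps,
    y_um = (mom[, "m.cy"] - 0.5) * ps,
    area_px = as.integer(shape[, "s.area"])
  )
  attr(out, "labels") <- EBImage::imageData(labels)
  out
}

#' Measure per-nucleus mean channel intensities
#'
#' Computes the arithmetic mean intensity over each nucleus mask in every
#' channel of the well image. Nuclei whose measured DAPI mean is not
#' positive are dropped (the downstream DAPI normalization would be
#' undefined) with a message reporting the count.
#'
#' @param image A [well_image()].
#' @param nuclei Output of [detect_nuclei()] (must carry the `"labels"`
#'   attribute).
#' @return `nuclei` with one intensity column per channel (named after the
#'   channel) and the `"labels"` attribute preserved.
#' @export
measure_intensities <- function(image, nuclei) {
  stopifnot(inherits(image, "well_image"))
  labels <- attr(nuclei, "labels")
  if (is.null(labels)) abort("`nuclei` must carry the segmentation labels.")
  if (!identical(dim(labels), dim(image$channels[[1]])))
    abort("nucleus masks do not match the image dimensions.")
  if (!nrow(nuclei)) {
    for (ch in names(image$channels)) nuclei[[ch]] <- double()
    return(nuclei)
  }
  out <- nuclei
  for (ch in names(image$channels)) {
    b <- EBImage::computeFeatures.basic(labels, image$channels[[ch]])
    out[[ch]] <- unname(b[out$nucleus, "b.mean"])
  }
  bad <- out$DAPI <= 0
  if (any(bad)) {
    inform(sprintf("dropping %d nuclei with non-positive DAPI mean.",
                   sum(bad)))
    out <- out[!bad, ]
  }
  attr(out, "labels") <- labels
  out
}
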