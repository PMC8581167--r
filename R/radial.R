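# Radial profiling: distance from the colony centroid, assignment into 20
# concentric 25-um rings, the normalization cascade (marker/DAPI ratio ->
# background subtraction -> per-bin colony mean -> within-well max scaling),
# hierarchical aggregation and percent-positive quantification.

#' Distance of a nucleus from its colony centroid
#'
#' `D = sqrt((x_i - x)^2 + (y_i - y)^2)`, all coordinates in um.
#'
#' @param x_i,y_i Nucleus centroid (um); vectorized.
#' @param x,y Colony centroid (um).
#' @return Distances in um.
#' @examples
#' nucleus_distance(3, 4, 0, 0)  # 5
#' @export
nucleus_distance <- function(x_i, y_i, x, y) {
  sqrt((x_i - x)^2 + (y_i - y)^2)
}

#' Assign radial distances to concentric bins
#'
#' Bin `B` covers the half-open annulus `[(B - 1) * bin_width, B * bin_width)`
#' so `B = floor(D / bin_width) + 1`. Distances at or beyond the outermost
#' edge (segmentation jitter can push a nucleus past the nominal colony
#' radius) are clipped into the last bin; the clip count is attached as
#' attribute `"n_clipped"` and reported via a message.
#'
#' @param d Radial distances in um (must be >= 0).
#' @param bin_width_um Ring spacing (um); default 25.
#' @param n_bins Number of rings; default 20 (tiling `[0, 500)` um for a
#'   1000-um-diameter colony).
#' @return Integer bins in `1..n_bins` with attribute `n_clipped`.
#' @examples
#' assign_bin(c(0, 24.9, 25, 499.9))  # 1 1 2 20
#' @export
assign_bin <- function(d, bin_width_um = 25, n_bins = 20) {
  if (any(d < 0)) abort("radial distances must be >= 0.")
  b <- floor(d / bin_width_um) + 1
  clipped <- b > n_bins
  if (any(clipped))
    inform(sprintf("%d nuclei beyond %g um clipped into bin %d.",
                   sum(clipped), n_bins * bin_width_um, n_bins))
  b[clipped] <- n_bins
  out <- as.integer(b)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' DAPI-normalize a marker intensity
#'
#' @param marker,dapi Mean nuclear intensities; `dapi` must be > 0.
#' @return `marker / dapi`.
#' @examples
#' normalize_nucleus(200, 100)  # 2
#' @export
normalize_nucleus <- function(marker, dapi) {
  if (any(dapi <= 0)) abort("DAPI intensity must be > 0 for normalization.")
  marker / dapi
}

#' Estimate marker background and positivity threshold
#'
#' Fits a two-component Gaussian mixture to the per-nucleus marker/DAPI
#' ratios of one well: the lower component is the non-expressing background
#' population. Background = lower-component mean; positivity threshold =
#' lower mean + 2 lower SD. If the mixture fit fails or degenerates, falls
#' back to the 5th percentile (background) and median (threshold) with a
#' warning.
#'
#' @param ratios Per-nucleus marker/DAPI ratios (>= 50 values).
#' @param marker Marker name carried along for reporting.
#' @return An object of class `positivity_model`: list with `marker`,
#'   `background`, `threshold`, `method`.
#' @export
estimate_background <- function(ratios, marker = NA_character_) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 50)
    abort("need at least 50 nuclei to estimate background.")
  # a (near-)constant sample has no mixture structure and can hang the EM
  fit <- if (sd(ratios) < 1e-8 * max(1, abs(mean(ratios)))) NULL else
    tryCatch(
      suppressWarnings(
        Mclust(ratios, G = 2, modelNames = c("V", "E"), verbose = FALSE)
      ),
      error = function(e) NULL
    )
  bg <- thr <- NULL
  method <- "mixture"
  if (!is.null(fit)) {
    mu <- fit$parameters$mean
    sig <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sig) == 1) sig <- rep(sig, length(mu))
    lo <- which.min(mu)
    if (is.finite(sig[lo]) && sig[lo] > 0 &&
        diff(range(mu)) > .Machine$double.eps^0.5) {
      bg <- unname(mu[lo])
      thr <- unname(mu[lo] + 2 * sig[lo])
    }
  }
  if (is.null(bg)) {
    warn("mixture fit degenerate; falling back to quantile background.")
    bg <- unname(quantile(ratios, 0.05))
    thr <- unname(median(ratios))
    method <- "quantile"
  }
  structure(list(marker = marker, background = bg, threshold = thr,
                 method = method),
            class = "positivity_model")
}

#' Subtract estimated background from ratios, flooring at zero
#'
#' @param ratios Marker/DAPI ratios.
#' @param model A [positivity_model][estimate_background()].
#' @return `max(ratios - background, 0)`.
#' @export
subtract_background <- function(ratios, model) {
  pmax(ratios - model$background, 0)
}

#' Is a nucleus marker-positive?
#'
#' A nucleus is positive when its background-subtracted ratio exceeds the
#' positivity threshold. Keeping the comparison on the subtracted scale
#' makes an all-background well score ~0% positive even when the mixture
#' fit splits a unimodal background population in two.
#'
#' @inheritParams subtract_background
#' @return Logical vector.
#' @export
is_positive <- function(ratios, model) {
  subtract_background(ratios, model) > model$threshold
}

#' Per-colony radial expression profile
#'
#' Mean background-subtracted marker/DAPI ratio per occupied bin for one
#' colony. Bins without nuclei are absent from the result (missing, not
#' zero).
#'
#' @param d Radial distances of the colony's nuclei (um).
#' @param ratios Their marker/DAPI ratios.
#' @param model A [positivity_model][estimate_background()] for background
#'   subtraction.
#' @param bin_width_um,n_bins Bin geometry.
#' @return Tibble with `bin`, `value`, `n`.
#' @export
colony_profile <- function(d, ratios, model, bin_width_um = 25, n_bins = 20) {
  if (!length(d)) abort("colony has no nuclei.")
  bins <- suppressMessages(assign_bin(d, bin_width_um, n_bins))
  sub <- subtract_background(ratios, model)
  tibble(bin = bins, value = sub) |>
    group_by(bin) |>
    summarise(value = mean(value), n = n(), .groups = "drop") |>
    arrange(bin)
}

#' Scale colony profiles to the within-well maximum
#'
#' Divides every bin value by the maximum bin value over all colonies of
#' that well (per marker), so the well maximum becomes exactly 1. All-zero
#' wells are left untouched with a warning.
#'
#' @param profiles Long profile table with at least `well`, `marker`,
#'   `value` columns (e.g. from [radial_profiles()]).
#' @return `profiles` with `value` rescaled per (well, marker).
#' @export
well_normalize <- function(profiles) {
  out <- profiles |>
    group_by(well, marker) |>
    mutate(.well_max = max(value, na.rm = TRUE)) |>
    ungroup()
  zero <- unique(out[out$.well_max <= 0, c("well", "marker")])
  if (nrow(zero))
    warn(sprintf("no expression above background for %s; left unscaled.",
                 paste0(zero$well, "/", zero$marker, collapse = ", ")))
  out$value <- ifelse(out$.well_max > 0, out$value / out$.well_max, out$value)
  out$.well_max <- NULL
  out
}

#' Hierarchical aggregation of radial profiles
#'
#' Averages colony-level profiles up the replicate hierarchy: colonies to
#' well (technical replicate), wells to experiment (biological replicate),
#' experiments to line. The SD at each level is taken over the units being
#' averaged; missing bins propagate as missing (a unit without nuclei in a
#' bin simply does not contribute to it).
#'
#' @param profiles Long colony-level profile table with columns `line`,
#'   `experiment`, `well`, `colony`, `marker`, `bin`, `value`.
#' @param level `"well"`, `"experiment"` or `"line"`.
#' @return Tibble with the grouping ids for the level, `marker`, `bin`,
#'   `value` (mean), `sd`, `n_units`.
#' @export
aggregate_profiles <- function(profiles,
                               level = c("well", "experiment", "line")) {
  level <- match.arg(level)
  agg <- function(df, keys) {
    df |>
      group_by(across(all_of(c(keys, "marker", "bin")))) |>
      summarise(sd = sd(value), value = mean(value), n_units = n(),
                .groups = "drop")
  }
  by_well <- agg(profiles, c("line", "experiment", "well"))
  if (level == "well") return(by_well)
  by_exp <- agg(by_well, c("line", "experiment"))
  if (level == "experiment") return(by_exp)
  agg(by_exp, "line")
}

#' Percent of marker-positive nuclei in a colony
#'
#' `100 * #positive / #nuclei`, with positivity per [is_positive()]. This
#' statistic controls for variation in the number of cells per colony.
#'
#' @inheritParams colony_profile
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive <- function(ratios, model) {
  if (!length(ratios)) abort("colony has no nuclei.")
  100 * mean(is_positive(ratios, model))
}
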