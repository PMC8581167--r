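#' Radial expression model for one marker
#'
#' Describes how a marker's expression depends on a nucleus's distance `D`
#' from the colony centre. Three shapes cover the germ-layer patterns seen on
#' 1000-um micropatterned colonies: a `center_dome` (SOX2-like ectoderm core),
#' a `ring` at a given radius (BRA-like mid-ring, SOX17-like outer ring), and
#' a spatially `uniform` model used for calibration experiments.
#'
#' For a marker-positive nucleus at distance `D` the expected
#' marker-to-DAPI intensity ratio is
#' `baseline + amplitude * exp(-(D - center_um)^2 / (2 * width_um^2))`
#' (`center_um = 0` for a dome; the Gaussian term is 1 everywhere for
#' `uniform`). Non-expressing nuclei emit `baseline` only, which defines the
#' background population the analysis pipeline must subtract.
#'
#' The probability that a nucleus at distance `D` is marker-positive is
#' `positive_fraction` multiplied by the same unit-height spatial shape
#' (constant for `uniform`). For `ring` models an angular sector covering
#' `discontinuity_fraction` of the circle is forced negative, emulating the
#' discontinuities commonly observed in the outer endoderm ring.
#'
#' @param kind `"center_dome"`, `"ring"` or `"uniform"`.
#' @param center_um Radial position of peak expression (um). Forced to 0 for
#'   `center_dome`; ignored for `uniform`.
#' @param width_um Gaussian spread of the expression domain (um).
#' @param amplitude Peak marker/DAPI ratio above baseline (>= 0).
#' @param baseline Marker/DAPI ratio of non-expressing nuclei (>= 0).
#' @param positive_fraction Peak probability that a nucleus is
#'   marker-positive, attained at the model's spatial peak.
#' @param discontinuity_fraction Angular fraction of the colony (in `[0, 1)`)
#'   where ring positivity is suppressed.
#' @return An object of class `radial_model`.
#' @examples
#' radial_model("ring", center_um = 425, width_um = 40)
#' @export
radial_model <- function(kind = c("ring", "center_dome", "uniform"),
                         center_um = 0, width_um = 50,
                         amplitude = 0.9, baseline = 0.1,
                         positive_fraction = 0.9,
                         discontinuity_fraction = 0) {
  kind <- match.arg(kind)
  if (kind == "center_dome") center_um <- 0
  if (width_um <= 0) abort("`width_um` must be > 0.")
  if (amplitude < 0 || baseline < 0) abort("intensity amplitudes must be >= 0.")
  if (positive_fraction < 0 || positive_fraction > 1)
    abort("`positive_fraction` must be in [0, 1].")
  if (discontinuity_fraction < 0 || discontinuity_fraction >= 1)
    abort("`discontinuity_fraction` must be in [0, 1).")
  structure(
    list(kind = kind, center_um = center_um, width_um = width_um,
         amplitude = amplitude, baseline = baseline,
         positive_fraction = positive_fraction,
         discontinuity_fraction = discontinuity_fraction),
    class = "radial_model"
  )
}

#' Unit-height spatial shape of a radial model
#'
#' @param model A [radial_model()].
#' @param d Radial distances in um.
#' @return Values in `[0, 1]`.
#' @keywords internal
#' @export
model_shape <- function(model, d) {
  switch(model$kind,
    uniform     = rep(1, length(d)),
    center_dome = exp(-d^2 / (2 * model$width_um^2)),
    ring        = exp(-(d - model$center_um)^2 / (2 * model$width_um^2))
  )
}

#' Expected marker/DAPI ratio of an expressing nucleus at distance d
#' @inheritParams model_shape
#' @return Expected ratio `baseline + amplitude * shape(d)`.
#' @export
model_ratio <- function(model, d) {
  model$baseline + model$amplitude * model_shape(model, d)
}

#' Probability that a nucleus at distance d is marker-positive
#' @inheritParams model_shape
#' @return Probabilities in `[0, 1]`.
#' @export
model_positive_fraction <- function(model, d) {
  model$positive_fraction * model_shape(model, d)
}

#' Default germ-layer marker models
#'
#' SOX2 as a central ectoderm dome, BRA as a mesoderm mid-ring and SOX17 as
#' an outer endoderm ring with angular discontinuities.
#' @return Named list of [radial_model()] objects.
#' @export
default_marker_models <- function() {
  list(
    SOX2  = radial_model("center_dome", width_um = 150,
                         amplitude = 0.9, baseline = 0.1,
                         positive_fraction = 0.9),
    BRA   = radial_model("ring", center_um = 300, width_um = 60,
                         amplitude = 0.9, baseline = 0.1,
                         positive_fraction = 0.85),
    SOX17 = radial_model("ring", center_um = 425, width_um = 40,
                         amplitude = 0.9, baseline = 0.1,
                         positive_fraction = 0.9,
                         discontinuity_fraction = 0.2)
  )
}

#' Simulation configuration
#'
#' Bundles the geometry, intensity model, noise and plate structure used by
#' [generate_well()] and [generate_plate()]. Defaults emulate the published
#' assay: 1000-um circular colonies on a 96-well micropatterned plate, read
#' with a 20x objective (2 um/pixel), with four to seven analysable colonies
#' per well.
#'
#' @param pixel_size_um Physical pixel size (um/pixel).
#' @param colony_diameter_um Nominal colony diameter (um).
#' @param n_colonies_per_well Colonies rendered per well.
#' @param fraction_truncated Proportion of colonies whose disc crosses the
#'   image border (emulates patterns printed at the well edge).
#' @param nuclei_per_colony Nuclei placed in each colony.
#' @param nucleus_radius_um Rendered nucleus radius (um).
#' @param min_spacing_um Minimum centre-to-centre distance between nuclei
#'   (rejection sampling).
#' @param marker_models Named list of [radial_model()]s, one per marker
#'   channel.
#' @param noise_sd Additive Gaussian pixel noise (intensity units).
#' @param dapi_mean,dapi_cv Mean and coefficient of variation of the
#'   per-nucleus DAPI intensity (gamma distributed, strictly positive).
#' @param donor_effects Named list: line id -> list with any of
#'   `center_shift_um`, `width_scale`, `amplitude_scale`,
#'   `positive_fraction_scale`, applied to every marker model for colonies
#'   of that line. Unlisted lines get no effect.
#' @param plate_layout Tibble with columns `well`, `line`, `donor`,
#'   `experiment`, `replicate` (see [plate_layout()]).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_colonies_per_well = 2, nuclei_per_colony = 100)
#' @export
sim_config <- function(pixel_size_um = 2,
                       colony_diameter_um = 1000,
                       n_colonies_per_well = 6,
                       fraction_truncated = 0,
                       nuclei_per_colony = 600,
                       nucleus_radius_um = 8,
                       min_spacing_um = 18,
                       marker_models = default_marker_models(),
                       noise_sd = 5,
                       dapi_mean = 1000,
                       dapi_cv = 0.2,
                       donor_effects = NULL,
                       plate_layout = NULL,
                       seed = 1L) {
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0.")
  if (colony_diameter_um <= 0) abort("`colony_diameter_um` must be > 0.")
  if (fraction_truncated < 0 || fraction_truncated > 1)
    abort("`fraction_truncated` must be in [0, 1].")
  if (nuclei_per_colony < 1) abort("`nuclei_per_colony` must be >= 1.")
  if (nucleus_radius_um <= 0) abort("`nucleus_radius_um` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!length(marker_models) || is.null(names(marker_models)) ||
      any(!nzchar(names(marker_models))))
    abort("`marker_models` must be a non-empty named list.")
  for (m in marker_models)
    if (!inherits(m, "radial_model"))
      abort("every element of `marker_models` must be a `radial_model`.")
  structure(
    list(pixel_size_um = pixel_size_um,
         colony_diameter_um = colony_diameter_um,
         n_colonies_per_well = n_colonies_per_well,
         fraction_truncated = fraction_truncated,
         nuclei_per_colony = nuclei_per_colony,
         nucleus_radius_um = nucleus_radius_um,
         min_spacing_um = min_spacing_um,
         marker_models = marker_models,
         noise_sd = noise_sd,
         dapi_mean = dapi_mean,
         dapi_cv = dapi_cv,
         donor_effects = donor_effects,
         plate_layout = plate_layout,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Build a plate-layout table
#'
#' @param wells Character vector of well ids (must be unique).
#' @param lines Cell line id per well (recycled if length 1).
#' @param experiment Experiment (biological replicate) id per well.
#' @param replicate Technical replicate index per well.
#' @param donor Donor id per well; defaults to the four-letter prefix of the
#'   line id (HipSci convention: clonal lines from one donor share it).
#' @return A tibble with columns `well`, `line`, `donor`, `experiment`,
#'   `replicate`.
#' @examples
#' plate_layout(c("A1", "A2", "A3"), lines = "uoxz_4", experiment = "exp1",
#'              replicate = 1:3)
#' @export
plate_layout <- function(wells, lines, experiment = "exp1", replicate = 1L,
                         donor = NULL) {
  if (!length(wells)) abort("`wells` must be non-empty.")
  if (anyDuplicated(wells)) abort("duplicate well ids in layout.")
  donor <- donor %||% sub("_.*$", "", lines)
  tibble(well = as.character(wells), line = as.character(lines),
         donor = as.character(donor), experiment = as.character(experiment),
         replicate = as.integer(replicate))
}

# Apply a line's donor effect to one marker model (no-op when absent).
apply_donor_effect <- function(model, effect) {
  if (is.null(effect)) return(model)
  m <- model
  m$center_um <- m$center_um + (effect$center_shift_um %||% 0)
  m$width_um <- m$width_um * (effect$width_scale %||% 1)
  m$amplitude <- m$amplitude * (effect$amplitude_scale %||% 1)
  m$positive_fraction <-
    min(1, m$positive_fraction * (effect$positive_fraction_scale %||% 1))
  m
}

# Marker models effective for a given line under config donor effects.
line_marker_models <- function(config, line) {
  effect <- if (!is.null(line) && !is.null(config$donor_effects))
    config$donor_effects[[line]] else NULL
  lapply(config$marker_models, apply_donor_effect, effect = effect)
}
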