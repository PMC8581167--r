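# End-to-end orchestration: segment -> colonies -> QC -> radial bins ->
# normalization cascade -> percent-positive -> statistics. Each stage is
# also usable on its own; run_pipeline() wires them together for a set of
# wells and a plate layout.

#' Process one well image through segmentation, QC and binning
#'
#' @param image A [well_image()].
#' @param seg_params A [segment_params()].
#' @param thresholds A [qc_thresholds()].
#' @param closing_radius_um Passed to [identify_colonies()].
#' @param bin_width_um,n_bins Radial bin geometry.
#' @return List with `nuclei` (per-nucleus table: centroid, channel means,
#'   colony, `dist_um`, `bin`) and `colonies` (geometry + QC status), both
#'   tagged with the well id; and `n_clipped`, the count of nuclei clipped
#'   into the outermost bin.
#' @export
process_well <- function(image, seg_params = segment_params(),
                         thresholds = qc_thresholds(),
                         closing_radius_um = 50,
                         bin_width_um = 25, n_bins = 20) {
  nuclei <- detect_nuclei(image, seg_params)
  nuclei <- measure_intensities(image, nuclei)
  cc <- identify_colonies(nuclei, image, closing_radius_um)
  colonies <- qc_filter(cc$colonies, thresholds)
  nuclei <- cc$nuclei
  nuclei <- left_join(nuclei,
                      select(colonies, colony, cx = x_um, cy = y_um,
                             qc_status),
                      by = "colony")
  nuclei$dist_um <- nucleus_distance(nuclei$x_um, nuclei$y_um,
                                     nuclei$cx, nuclei$cy)
  n_clipped <- 0L
  ok <- !is.na(nuclei$dist_um)
  nuclei$bin <- NA_integer_
  if (any(ok)) {
    b <- suppressMessages(assign_bin(nuclei$dist_um[ok], bin_width_um,
                                     n_bins))
    n_clipped <- attr(b, "n_clipped")
    nuclei$bin[ok] <- b
  }
  nuclei <- select(nuclei, -cx, -cy)
  nuclei$well <- image$well
  colonies$well <- image$well
  list(nuclei = nuclei, colonies = colonies, n_clipped = n_clipped)
}

#' Long table of per-nucleus marker/DAPI ratios
#'
#' @param nuclei Nucleus table from [process_well()] (or a bound set of
#'   them) with one intensity column per channel.
#' @param markers Marker channel names; default every channel column
#'   except DAPI.
#' @return Long tibble: `well`, `colony`, `nucleus`, `dist_um`, `bin`,
#'   `qc_status`, `marker`, `ratio`.
#' @export
nucleus_ratios <- function(nuclei, markers = NULL) {
  if (is.null(markers)) {
    fixed <- c("nucleus", "x_um", "y_um", "area_px", "colony", "dist_um",
               "bin", "well", "qc_status", "DAPI")
    markers <- setdiff(names(nuclei), fixed)
  }
  nuclei |>
    pivot_longer(all_of(markers), names_to = "marker",
                 values_to = "intensity") |>
    mutate(ratio = normalize_nucleus(intensity, DAPI)) |>
    select(well, colony, nucleus, dist_um, bin, qc_status, marker, ratio)
}

#' Fit per-well, per-marker positivity models
#'
#' @param ratios Long ratio table from [nucleus_ratios()].
#' @return Tibble `well`, `marker`, `background`, `threshold`, `method`.
#' @export
fit_positivity <- function(ratios) {
  ratios |>
    group_by(well, marker) |>
    summarise({
      m <- estimate_background(ratio, marker[[1]])
      tibble(background = m$background, threshold = m$threshold,
             method = m$method)
    }, .groups = "drop")
}

positivity_model_for <- function(positivity, w, mk) {
  row <- positivity[positivity$well == w & positivity$marker == mk, ]
  structure(list(marker = mk, background = row$background[[1]],
                 threshold = row$threshold[[1]], method = row$method[[1]]),
            class = "positivity_model")
}

#' Colony-level radial profiles for all qualified colonies
#'
#' Applies background subtraction and per-bin averaging for every qualified
#' colony, then scales to the within-well maximum via [well_normalize()].
#'
#' @param ratios Long ratio table from [nucleus_ratios()].
#' @param positivity Positivity-model table from [fit_positivity()].
#' @param normalize Apply within-well max scaling (default `TRUE`).
#' @return Long tibble `well`, `colony`, `marker`, `bin`, `value`, `n`.
#' @export
radial_profiles <- function(ratios, positivity, normalize = TRUE) {
  prof <- ratios |>
    filter(qc_status == "qualified", !is.na(bin)) |>
    left_join(select(positivity, well, marker, background),
              by = c("well", "marker")) |>
    mutate(sub = pmax(ratio - background, 0)) |>
    group_by(well, colony, marker, bin) |>
    summarise(value = mean(sub), n = n(), .groups = "drop")
  if (normalize) prof <- well_normalize(prof)
  prof
}

#' Percent-positive per qualified colony and marker
#'
#' @inheritParams radial_profiles
#' @return Tibble `well`, `colony`, `marker`, `percent_positive`,
#'   `n_nuclei`.
#' @export
percent_positive_table <- function(ratios, positivity) {
  ratios |>
    filter(qc_status == "qualified") |>
    left_join(select(positivity, well, marker, background, threshold),
              by = c("well", "marker")) |>
    group_by(well, colony, marker) |>
    summarise(percent_positive =
                100 * mean(pmax(ratio - background, 0) > threshold),
              n_nuclei = n(), .groups = "drop")
}

#' Run the full image-to-phenotype pipeline
#'
#' Executes segmentation, colony QC, radial profiling and the statistical
#' layer for a set of well images under a plate layout: Kruskal-Wallis with
#' Dunn's post hoc across lines per marker, the pooled-t outlier test per
#' line (p < 0.001), and the KS radial-outlier test against the control
#' line (p < 0.01) when one is designated.
#'
#' @param images Named list of [well_image()] objects (names = well ids),
#'   or an `mp_plate` from [generate_plate()].
#' @param layout Plate layout tibble (see [plate_layout()]); defaults to
#'   the plate's own layout for `mp_plate` input.
#' @param control_line Line id used for KS radial-outlier comparisons, or
#'   `NULL` to skip them.
#' @inheritParams process_well
#' @return Object of class `mp_run`: list of tibbles `nuclei`, `colonies`,
#'   `positivity`, `profiles` (colony level, well-normalized),
#'   `line_profiles` (aggregated with SD), `percent_positive`, `stats`,
#'   and `log` (QC tallies, clip counts).
#' @export
run_pipeline <- function(images, layout = NULL, control_line = NULL,
                         seg_params = segment_params(),
                         thresholds = qc_thresholds(),
                         closing_radius_um = 50,
                         bin_width_um = 25, n_bins = 20) {
  if (inherits(images, "mp_plate")) {
    layout <- layout %||% images$layout
    images <- images$images
  }
  if (is.null(layout)) abort("a plate layout is required.")
  missing_wells <- setdiff(names(images), layout$well)
  if (length(missing_wells))
    abort(paste0("well(s) not in layout: ",
                 paste(missing_wells, collapse = ", ")))

  per_well <- lapply(images, process_well, seg_params = seg_params,
                     thresholds = thresholds,
                     closing_radius_um = closing_radius_um,
                     bin_width_um = bin_width_um, n_bins = n_bins)
  nuclei <- bind_rows(lapply(per_well, function(x)
    `attr<-`(x$nuclei, "labels", NULL)))
  colonies <- bind_rows(lapply(per_well, `[[`, "colonies"))
  n_clipped <- sum(vapply(per_well, `[[`, integer(1), "n_clipped"))

  ratios <- nucleus_ratios(nuclei)
  positivity <- fit_positivity(filter(ratios, qc_status == "qualified"))
  profiles <- radial_profiles(ratios, positivity) |>
    left_join(layout, by = "well")
  line_profiles <- aggregate_profiles(
    select(profiles, line, experiment, well, colony, marker, bin, value),
    level = "line")
  pct <- percent_positive_table(ratios, positivity) |>
    left_join(layout, by = "well")

  stats_out <- list()
  lines <- unique(layout$line)
  for (mk in unique(pct$marker)) {
    df <- filter(pct, marker == mk)
    if (length(lines) >= 3 && all(table(df$line) >= 3)) {
      kd <- kruskal_dunn(df, "percent_positive", "line")
      stats_out[[length(stats_out) + 1L]] <-
        mutate(glance(kd), marker = mk, line = NA_character_)
    }
    for (ln in lines) {
      if (sum(df$line == ln) >= 3 && sum(df$line != ln) >= 10)
        stats_out[[length(stats_out) + 1L]] <-
          mutate(outlier_mean_expression(df, ln, "percent_positive",
                                         "line"),
                 marker = mk, line = ln)
    }
  }
  if (!is.null(control_line)) {
    if (!control_line %in% lines)
      abort(paste0("control line `", control_line, "` absent from layout."))
    pos <- ratios |>
      filter(qc_status == "qualified") |>
      left_join(select(positivity, well, marker, background, threshold),
                by = c("well", "marker")) |>
      filter(pmax(ratio - background, 0) > threshold) |>
      left_join(select(layout, well, line), by = "well")
    for (mk in unique(pos$marker)) {
      d_ctl <- pos$dist_um[pos$marker == mk & pos$line == control_line]
      for (ln in setdiff(lines, control_line)) {
        d_t <- pos$dist_um[pos$marker == mk & pos$line == ln]
        if (length(d_t) >= 10 && length(d_ctl) >= 10)
          stats_out[[length(stats_out) + 1L]] <-
            mutate(outlier_radial(d_t, d_ctl, mk),
                   marker = mk, line = ln)
      }
    }
  }

  log <- tibble(
    n_wells = length(images),
    n_nuclei = nrow(nuclei),
    n_unassigned_nuclei = sum(is.na(nuclei$colony)),
    n_colonies = nrow(colonies),
    n_qualified = sum(colonies$qc_status == "qualified"),
    n_rejected_edge = sum(colonies$rejection_reason == "edge"),
    n_rejected_area = sum(colonies$rejection_reason == "area"),
    n_rejected_roundness = sum(colonies$rejection_reason == "roundness"),
    n_clipped_bin = n_clipped
  )
  structure(
    list(nuclei = nuclei, colonies = colonies, positivity = positivity,
         profiles = profiles, line_profiles = line_profiles,
         percent_positive = pct,
         stats = if (length(stats_out)) bind_rows(stats_out) else tibble(),
         log = log),
    class = "mp_run"
  )
}

#' @export
print.mp_run <- function(x, ...) {
  cat(sprintf(paste0("<mp_run> %d wells, %d nuclei, %d colonies ",
                     "(%d qualified)\n"),
              x$log$n_wells, x$log$n_nuclei, x$log$n_colonies,
              x$log$n_qualified))
  invisible(x)
}

#' Write pipeline results as CSV tables
#'
#' @param run An `mp_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "mp_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("nuclei", "colonies", "positivity", "profiles",
              "line_profiles", "percent_positive", "stats", "log")
  paths <- vapply(tables, function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(run[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
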