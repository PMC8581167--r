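# Standard-format I/O: multi-channel 16-bit TIFF per well and a YAML plate
# layout. The layout file carries the channel -> marker map, the pixel
# scale and the intensity scale used for 16-bit quantization, so a write /
# read round trip is lossless at the stored bit depth.
#
# Layout schema (YAML):
#   pixel_size_um: 2
#   intensity_scale: 8192        # intensity units mapped to the 16-bit max
#   control_line: uoxz_4         # optional
#   channels: [DAPI, SOX2, BRA, SOX17]   # TIFF page order
#   wells:
#     A1: {line: uoxz_4, donor: uoxz, experiment: exp1, replicate: 1}

#' Write a well image as a multi-channel 16-bit TIFF
#'
#' Channels are stored as TIFF pages in the given order; intensities are
#' quantized as `value / intensity_scale` (clipped to `[0, 1]`) at 16 bits.
#'
#' @param image A [well_image()].
#' @param path Output file path.
#' @param channels Channel order to store; default the image's own order.
#' @param intensity_scale Intensity value mapped to the 16-bit maximum.
#' @return Invisibly, `path`.
#' @export
write_well_image <- function(image, path, channels = names(image$channels),
                             intensity_scale = 8192) {
  stopifnot(inherits(image, "well_image"))
  pages <- lapply(channels, function(ch) {
    m <- image$channels[[ch]]
    if (is.null(m)) abort(paste0("channel `", ch, "` not in image."))
    pmin(pmax(m / intensity_scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a well image from a multi-channel TIFF under a plate layout
#'
#' @param path TIFF file path.
#' @param layout A `plate_layout_file` from [read_plate_layout()] (or any
#'   list with `channels`, `pixel_size_um`, `intensity_scale`).
#' @param well Well id to attach; default the file name without extension.
#' @return A [well_image()] with intensities restored to their original
#'   scale.
#' @export
read_well_image <- function(path, layout, well = NULL) {
  if (!file.exists(path)) abort(paste0("no such image file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(layout$channels))
    abort(sprintf("image has %d channels but layout declares %d.",
                  length(pages), length(layout$channels)))
  channels <- setNames(
    lapply(pages, function(p) p * layout$intensity_scale),
    layout$channels)
  well_image(channels, layout$pixel_size_um,
             well %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Read a plate-layout configuration file
#'
#' Parses the YAML schema documented above and validates it: the channel
#' list must include DAPI, well entries must carry a line id, and the
#' control line (when declared) must be present in the wells.
#'
#' @param path YAML file path.
#' @return A list of class `plate_layout_file`: `wells` (tibble as from
#'   [plate_layout()]), `channels`, `pixel_size_um`, `intensity_scale`,
#'   `control_line`.
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("no such layout file: ", path))
  cfg <- yaml::read_yaml(path)
  channels <- unlist(cfg$channels)
  if (is.null(channels) || !"DAPI" %in% channels)
    abort("layout must declare a channel map including DAPI.")
  if (is.null(cfg$wells) || !length(cfg$wells))
    abort("layout declares no wells.")
  wells <- bind_rows(imap(cfg$wells, function(w, id) {
    if (is.null(w$line)) abort(paste0("well `", id, "` has no line id."))
    tibble(well = id, line = w$line,
           donor = w$donor %||% sub("_.*$", "", w$line),
           experiment = as.character(w$experiment %||% "exp1"),
           replicate = as.integer(w$replicate %||% 1L))
  }))
  if (anyDuplicated(wells$well)) abort("duplicate well ids in layout.")
  control <- cfg$control_line
  if (!is.null(control) && !control %in% wells$line)
    abort(paste0("control line `", control, "` not present in any well."))
  structure(
    list(wells = wells, channels = unname(channels),
         pixel_size_um = cfg$pixel_size_um %||% 2,
         intensity_scale = cfg$intensity_scale %||% 8192,
         control_line = control),
    class = "plate_layout_file"
  )
}

#' Write a plate-layout configuration file
#'
#' @param layout Wells tibble (as from [plate_layout()]).
#' @param path Output YAML path.
#' @param channels Channel names in TIFF page order (must include DAPI).
#' @param pixel_size_um,intensity_scale,control_line Scalar metadata.
#' @return Invisibly, `path`.
#' @export
write_plate_layout <- function(layout, path, channels,
                               pixel_size_um = 2, intensity_scale = 8192,
                               control_line = NULL) {
  wells <- setNames(
    lapply(seq_len(nrow(layout)), function(i)
      list(line = layout$line[[i]], donor = layout$donor[[i]],
           experiment = layout$experiment[[i]],
           replicate = layout$replicate[[i]])),
    layout$well)
  cfg <- list(pixel_size_um = pixel_size_um,
              intensity_scale = intensity_scale,
              channels = as.list(channels), wells = wells)
  if (!is.null(control_line)) cfg$control_line <- control_line
  yaml::write_yaml(cfg, path)
  invisible(path)
}
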