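# Synthetic well-image generator. Colonies are rendered as discs of nuclei
# whose marker intensities follow the configured radial_model()s; the imaging
# model is: per-nucleus DAPI ~ gamma, marker = DAPI * ratio (so the DAPI
# normalization is exactly invertible in the noiseless limit), nuclei drawn
# as discs with Gaussian-blurred edges, additive Gaussian pixel noise.

# Evaluate a function with a private RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for well i of a plate, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 104729 * as.double(i)) %% 2147483629)
}

#' Construct a well image container
#'
#' @param channels Named list of numeric matrices (same dimensions), one per
#'   channel; must include `"DAPI"`.
#' @param pixel_size_um Physical pixel size (um/pixel).
#' @param well Well identifier.
#' @return An object of class `well_image`.
#' @export
well_image <- function(channels, pixel_size_um, well = "A1") {
  if (!length(channels) || is.null(names(channels)))
    abort("`channels` must be a named list of matrices.")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) abort("all channels must share dimensions.")
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0.")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 well = as.character(well)),
            class = "well_image")
}

#' @export
print.well_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<well_image> well %s: %d x %d px (%.0f x %.0f um), channels: %s\n",
              x$well, d[1], d[2], d[1] * x$pixel_size_um,
              d[2] * x$pixel_size_um, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Place n points uniformly in a disc (centre cx,cy, radius R) with minimum
# spacing, kept inside [0, bx] x [0, by]. Truncated colonies may legitimately
# fit fewer points than requested; complete colonies must reach n.
place_nuclei <- function(n, cx, cy, radius, min_spacing, bx, by,
                         truncated = FALSE) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- max(5000L, 400L * n)
  min_sq <- min_spacing^2
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    d <- radius * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
    x <- cx + d * cos(th); y <- cy + d * sin(th)
    if (x < 0 || x > bx || y < 0 || y > by) next
    if (placed > 0L &&
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) < min_sq)
      next
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  if (placed < n && !truncated)
    abort(paste0("could not place `nuclei_per_colony` = ", n,
                 " nuclei at `min_spacing_um` = ", min_spacing,
                 " within the colony disc; reduce `nuclei_per_colony`."))
  list(x = xs[seq_len(placed)], y = ys[seq_len(placed)])
}

# Colony centres on a grid; truncated ones are pushed across the nearest
# image border so their disc crosses it.
colony_centres <- function(config) {
  n <- config$n_colonies_per_well
  R <- config$colony_diameter_um / 2
  pitch <- config$colony_diameter_um * 1.2
  gx <- ceiling(sqrt(n)); gy <- ceiling(n / gx)
  size_x <- gx * pitch; size_y <- gy * pitch
  idx <- seq_len(n) - 1L
  cx <- (idx %% gx + 0.5) * pitch
  cy <- (idx %/% gx + 0.5) * pitch
  n_trunc <- round(config$fraction_truncated * n)
  truncated <- rep(FALSE, n)
  if (n_trunc > 0) {
    truncated[sample.int(n, n_trunc)] <- TRUE
    for (k in which(truncated)) {
      db <- c(cx[k], size_x - cx[k], cy[k], size_y - cy[k])
      side <- which.min(db)
      off <- 0.55 * R  # centre closer to the border than R: disc crosses it
      if (side == 1) cx[k] <- off
      else if (side == 2) cx[k] <- size_x - off
      else if (side == 3) cy[k] <- off
      else cy[k] <- size_y - off
    }
  }
  list(cx = cx, cy = cy, truncated = truncated,
       size_x = size_x, size_y = size_y)
}

# Stamp value discs at nucleus positions into a zero canvas (um coords).
stamp_discs <- function(nx, ny, x_um, y_um, values, r_px, pixel_size) {
  m <- matrix(0, nx, ny)
  if (!length(x_um)) return(m)
  r_ceil <- ceiling(r_px)
  off <- expand.grid(dx = -r_ceil:r_ceil, dy = -r_ceil:r_ceil)
  off <- off[off$dx^2 + off$dy^2 <= r_px^2, ]
  px <- round(x_um / pixel_size + 0.5)
  py <- round(y_um / pixel_size + 0.5)
  for (i in seq_along(px)) {
    ix <- px[i] + off$dx; iy <- py[i] + off$dy
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    m[cbind(ix[ok], iy[ok])] <- values[i]
  }
  m
}

#' Expected per-bin radial expression profile implied by a model
#'
#' The ground-truth expectation of the background-subtracted, DAPI-normalized
#' expression in each concentric bin: positivity probability at the bin
#' midpoint times the above-baseline expression of positive nuclei, reduced
#' by the angular discontinuity fraction for ring models. Deterministic in
#' the configuration (no RNG), so replicate wells of one line share it.
#'
#' @param model A [radial_model()] (after any donor effect).
#' @param n_bins,bin_width_um Bin geometry; defaults 20 bins of 25 um.
#' @return Tibble with `bin`, `mid_um`, `expected`.
#' @export
expected_bin_profile <- function(model, n_bins = 20, bin_width_um = 25) {
  mid <- (seq_len(n_bins) - 0.5) * bin_width_um
  disc <- if (model$kind == "ring") model$discontinuity_fraction else 0
  expected <- model_positive_fraction(model, mid) * (1 - disc) *
    (model$amplitude * model_shape(model, mid))
  tibble(bin = seq_len(n_bins), mid_um = mid, expected = expected)
}

#' Simulate one multi-channel well image with ground truth
#'
#' Renders `n_colonies_per_well` circular colonies of the configured diameter
#' with nuclei placed uniformly at random (minimum-spacing rejection), a DAPI
#' channel and one channel per marker model. Marker positivity, radial
#' expression, angular ring discontinuities, donor effects (via the plate
#' layout) and additive Gaussian noise follow the [sim_config()].
#'
#' @param config A [sim_config()].
#' @param well_id Well identifier; when `config$plate_layout` is set it must
#'   appear there (its line determines donor effects).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `image` (a [well_image()]) and `truth`, a list of
#'   `nuclei` (per-nucleus true centroid, colony, distance, DAPI and
#'   per-marker ratio/positivity), `colonies` (true centres and truncation
#'   flags) and `expected_profiles` (per-marker [expected_bin_profile()]).
#' @examples
#' sim <- generate_well(sim_config(n_colonies_per_well = 1,
#'                                 nuclei_per_colony = 50), seed = 1)
#' sim$truth$colonies
#' @export
generate_well <- function(config, well_id = "A1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  line <- NULL
  if (!is.null(config$plate_layout)) {
    row <- config$plate_layout[config$plate_layout$well == well_id, ]
    if (!nrow(row)) abort(paste0("well `", well_id, "` not in plate layout."))
    line <- row$line[[1]]
  }
  models <- line_marker_models(config, line)
  ps <- config$pixel_size_um
  R <- config$colony_diameter_um / 2

  with_seed(seed, {
    geo <- colony_centres(config)
    nx <- ceiling(geo$size_x / ps); ny <- ceiling(geo$size_y / ps)

    nuc <- vector("list", length(geo$cx))
    for (k in seq_along(geo$cx)) {
      p <- place_nuclei(config$nuclei_per_colony, geo$cx[k], geo$cy[k], R,
                        config$min_spacing_um, geo$size_x, geo$size_y,
                        truncated = geo$truncated[k])
      if (!length(p$x)) next
      nuc[[k]] <- tibble(
        colony = k, x_um = p$x, y_um = p$y,
        dist_um = sqrt((p$x - geo$cx[k])^2 + (p$y - geo$cy[k])^2),
        angle = atan2(p$y - geo$cy[k], p$x - geo$cx[k]) %% (2 * pi)
      )
    }
    nuclei <- bind_rows(nuc)
    nuclei$nucleus <- seq_len(nrow(nuclei))
    cv <- config$dapi_cv
    nuclei$dapi <- if (cv > 0)
      rgamma(nrow(nuclei), shape = 1 / cv^2, rate = 1 / (cv^2 * config$dapi_mean))
    else rep(config$dapi_mean, nrow(nuclei))

    for (mk in names(models)) {
      mod <- models[[mk]]
      p_pos <- model_positive_fraction(mod, nuclei$dist_um)
      pos <- runif(nrow(nuclei)) < p_pos
      if (mod$kind == "ring" && mod$discontinuity_fraction > 0) {
        for (k in unique(nuclei$colony)) {
          th0 <- runif(1, 0, 2 * pi)
          in_gap <- nuclei$colony == k &
            ((nuclei$angle - th0) %% (2 * pi)) < 2 * pi * mod$discontinuity_fraction
          pos[in_gap] <- FALSE
        }
      }
      ratio <- ifelse(pos, model_ratio(mod, nuclei$dist_um), mod$baseline)
      nuclei[[paste0("ratio_", mk)]] <- ratio
      nuclei[[paste0("positive_", mk)]] <- pos
    }

    r_px <- config$nucleus_radius_um / ps
    channels <- c(list(DAPI = nuclei$dapi),
                  setNames(lapply(names(models), function(mk)
                    nuclei$dapi * nuclei[[paste0("ratio_", mk)]]),
                    names(models)))
    channels <- lapply(channels, function(v) {
      m <- stamp_discs(nx, ny, nuclei$x_um, nuclei$y_um, v, r_px, ps)
      m <- EBImage::imageData(EBImage::gblur(m, sigma = 1))
      if (config$noise_sd > 0)
        m <- pmax(m + rnorm(length(m), 0, config$noise_sd), 0)
      m
    })

    truth <- list(
      nuclei = nuclei[, c("nucleus", "colony", "x_um", "y_um", "dist_um",
                          "angle", "dapi",
                          paste0("ratio_", names(models)),
                          paste0("positive_", names(models)))],
      colonies = tibble(colony = seq_along(geo$cx), x_um = geo$cx,
                        y_um = geo$cy, truncated = geo$truncated),
      expected_profiles = bind_rows(lapply(names(models), function(mk)
        mutate(expected_bin_profile(models[[mk]],
                                    n_bins = round(R / 25)),
               marker = mk, .before = 1))),
      well = well_id, line = line
    )
    list(image = well_image(channels, ps, well_id), truth = truth)
  })
}

#' Simulate a plate of wells
#'
#' Generates one [generate_well()] result per row of `config$plate_layout`.
#' Wells of the same line share donor effects (hence identical ground-truth
#' expected profiles); replicate wells differ only by their derived RNG
#' stream.
#'
#' @param config A [sim_config()] with a non-empty `plate_layout`.
#' @param seed Top-level seed; each well gets a deterministic sub-seed.
#' @return An object of class `mp_plate`: list with `images` (named list of
#'   [well_image()]), `truth` (named list), `layout`, `config`.
#' @export
generate_plate <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$plate_layout
  if (is.null(layout) || !nrow(layout)) abort("plate layout is empty.")
  if (anyDuplicated(layout$well)) abort("duplicate well ids in layout.")
  images <- list(); truth <- list()
  for (i in seq_len(nrow(layout))) {
    w <- layout$well[[i]]
    sim <- generate_well(config, w, seed = derive_seed(seed, i))
    images[[w]] <- sim$image
    truth[[w]] <- sim$truth
  }
  structure(list(images = images, truth = truth, layout = layout,
                 config = config), class = "mp_plate")
}

#' Sample radial distances of marker-positive nuclei
#'
#' Draws the radial positions of marker-positive nuclei implied by a
#' [radial_model()] under uniform cell density: position density
#' proportional to `2 d / R^2` times the model's positivity shape
#' (rejection sampling). Used for statistical calibration at known truth
#' without rendering images.
#'
#' @param model A [radial_model()].
#' @param n Number of distances to draw.
#' @param radius_um Colony radius (um).
#' @return Numeric vector of length `n`.
#' @export
sample_positive_distances <- function(model, n, radius_um = 500) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- radius_um * sqrt(runif(2L * n))
    keep <- runif(2L * n) < model_shape(model, d)
    out <- c(out, d[keep])
  }
  out[seq_len(n)]
}

#' Generate an annotated variant table with known filter outcomes
#'
#' Builds a synthetic non-synonymous SNV table in which exactly `n_pass`
#' records satisfy all three selection rules (MAF < 0.005 in both the 1000
#' Genomes and ExAC columns, carried by fewer than five HipSci lines, Condel
#' class deleterious) and each failure class violates exactly one designated
#' rule, including boundary records (MAF exactly 0.005; exactly five lines)
#' that must be excluded under the strict inequalities.
#'
#' @param n_pass Records passing all filters.
#' @param n_fail_maf Records failing only the MAF rule.
#' @param n_fail_condel Records failing only the Condel rule.
#' @param n_fail_linecount Records failing only the HipSci line-count rule.
#' @param seed Integer seed.
#' @return Tibble with columns `gene`, `substitution`, `maf_1000g`,
#'   `maf_exac`, `n_hipsci_lines`, `condel_class`, `duet_ddg`,
#'   `carrier_lines` (`;`-separated line ids), `truth_pass`.
#' @examples
#' generate_variant_table(5, 3, 2, 1, seed = 1)
#' @export
generate_variant_table <- function(n_pass, n_fail_maf = 0, n_fail_condel = 0,
                                   n_fail_linecount = 0, seed = 1L) {
  counts <- c(n_pass, n_fail_maf, n_fail_condel, n_fail_linecount)
  if (any(counts < 0)) abort("all counts must be >= 0.")
  n <- sum(counts)
  empty <- tibble(gene = character(), substitution = character(),
                  maf_1000g = double(), maf_exac = double(),
                  n_hipsci_lines = integer(), condel_class = character(),
                  duet_ddg = double(), carrier_lines = character(),
                  truth_pass = logical())
  if (n == 0) return(empty)
  adhesion <- c("ITGB1", "ITGA6", "FHL2", "ITGAV", "VCL", "PXN", "TLN1")
  germ <- c("SMAD2", "FGFR1", "TBXT", "NODAL", "EOMES", "GATA6", "WNT3")
  with_seed(seed, {
    donors <- unique(replicate(40, paste(sample(letters, 4, TRUE),
                                         collapse = "")))
    gene_pool <- c(adhesion, germ, sprintf("GENE%03d", 1:60))
    aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
    rare_maf <- function(k) runif(k, 0, 0.0049)
    carriers <- function(k) {
      dn <- sample(donors, min(k, length(donors)), replace = FALSE)
      paste(paste0(dn, "_", sample(1:3, length(dn), TRUE)), collapse = ";")
    }
    make <- function(k, class) {
      if (k == 0) return(empty[0, ])
      maf1 <- rare_maf(k); maf2 <- rare_maf(k)
      nl <- sample(1:4, k, TRUE)
      condel <- rep("deleterious", k)
      if (class == "fail_maf") {
        which_db <- sample(1:2, k, TRUE)
        bad <- ifelse(seq_len(k) == 1, 0.005, runif(k, 0.005, 0.3))
        maf1 <- ifelse(which_db == 1, bad, maf1)
        maf2 <- ifelse(which_db == 2, bad, maf2)
      } else if (class == "fail_condel") {
        condel <- sample(c("neutral", "missing"), k, TRUE, prob = c(0.8, 0.2))
      } else if (class == "fail_linecount") {
        nl <- ifelse(seq_len(k) == 1, 5L, sample(5:40, k, TRUE))
      }
      tibble(
        gene = sample(gene_pool, k, TRUE),
        substitution = sprintf("p.%s%d%s", sample(aa, k, TRUE),
                               sample(30:900, k, TRUE), sample(aa, k, TRUE)),
        maf_1000g = maf1, maf_exac = maf2, n_hipsci_lines = as.integer(nl),
        condel_class = condel, duet_ddg = round(rnorm(k, -0.8, 0.6), 3),
        carrier_lines = vapply(nl, carriers, character(1)),
        truth_pass = class == "pass"
      )
    }
    out <- bind_rows(make(n_pass, "pass"), make(n_fail_maf, "fail_maf"),
                     make(n_fail_condel, "fail_condel"),
                     make(n_fail_linecount, "fail_linecount"))
    out[sample.int(nrow(out)), ]
  })
}
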