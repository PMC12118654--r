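## Multiplex image container, analysis settings (with instrument presets),
## and persistence of cell tables and label masks.

.SETTINGS_SCHEMA_VERSION <- 1L

.settings_fields <- c("foreground_threshold", "bg_filter_size_px",
                      "artifact_min_area_px", "ck_gaussian_size_px",
                      "ck_threshold", "compartment_min_area_px",
                      "marker_thresholds", "nucleus_detector", "zscore_reps",
                      "microns_per_pixel", "preset")

#' Construct a multiplex image
#'
#' A named set of co-registered single-channel rasters plus the physical
#' pixel size and patient/region provenance. All channels must share one
#' shape; intensities are kept in their native arbitrary units (thresholds in
#' the analysis settings are expressed in these units, so no rescaling is
#' ever applied).
#'
#' @param channels named list of numeric matrices (marker name -> raster).
#' @param microns_per_pixel physical pixel size, micrometers per pixel.
#' @param patient_id,region,image_id provenance tags; `region` is one of
#'   "border" or "center".
#' @return an object of class `multiplex_image`.
#' @export
multiplex_image <- function(channels, microns_per_pixel,
                            patient_id = NA_character_, region = "center",
                            image_id = NA_character_) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || anyDuplicated(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must have unique non-empty marker names")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share the same height and width")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be > 0")
  region <- match.arg(region, c("border", "center"))
  structure(list(channels = lapply(channels, function(m) {
    storage.mode(m) <- "double"; m
  }),
  height = unname(dims[1, 1]), width = unname(dims[2, 1]),
  microns_per_pixel = microns_per_pixel,
  patient_id = patient_id, region = region, image_id = image_id),
  class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  cat(sprintf("multiplex_image: %d x %d px, %.3g um/px, %d channels (%s)\n",
              x$height, x$width, x$microns_per_pixel, length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  patient %s, region %s, image %s\n",
              x$patient_id, x$region, x$image_id))
  invisible(x)
}

#' Load a multiplex image from a multi-page TIFF
#'
#' @param path TIFF file, one 2D page per channel.
#' @param channel_map named integer vector: marker name -> 0-based page index.
#' @param microns_per_pixel,patient_id,region,image_id see
#'   [multiplex_image()].
#' @return a `multiplex_image`; intensities are read as-is (no rescaling).
#' @export
load_multiplex_image <- function(path, channel_map, microns_per_pixel,
                                 patient_id = NA_character_,
                                 region = "center",
                                 image_id = basename(path)) {
  pages <- read_tiff_stack(path)
  if (is.null(names(channel_map))) stop("channel_map must be named by marker")
  bad <- channel_map < 0 | channel_map >= length(pages)
  if (any(bad))
    stop("channel-map mismatch: page index ", paste(channel_map[bad], collapse = ", "),
         " not present in ", length(pages), "-page file")
  channels <- lapply(channel_map, function(i) pages[[i + 1L]])
  names(channels) <- names(channel_map)
  multiplex_image(channels, microns_per_pixel, patient_id, region, image_id)
}

#' Analysis settings with instrument presets
#'
#' Bundles every tunable of the image pipeline. The `"mxif"` preset carries
#' the multiplexed-immunofluorescence defaults (foreground threshold 0.1,
#' 1000-px background filter, 5000-px artifact/compartment minimum areas,
#' 10-px Gaussian for the cytokeratin channel, CK threshold 1.0, and marker
#' gates CK 0.1 / CD3 0.3 / CD8 0.4 / CD20 0.7 / CD56 0.7 / CD68 1.0); the
#' `"mibi"` preset adapts them to ion-beam imaging (threshold 0 in all
#' channels, 250-px artifact minimum, CK threshold 0.5, marker gates 0, i.e.
#' any nonzero corrected signal). Any field can be overridden per call or per
#' image.
#'
#' @param preset "mxif" or "mibi".
#' @param ... named overrides of individual fields.
#' @return an object of class `analysis_settings`.
#' @export
analysis_settings <- function(preset = c("mxif", "mibi"), ...) {
  if (length(preset) == 1 && !preset %in% c("mxif", "mibi"))
    stop("unknown preset: ", preset)
  preset <- match.arg(preset)
  base <- if (preset == "mxif") {
    list(foreground_threshold = 0.1, bg_filter_size_px = 1000L,
         artifact_min_area_px = 5000L, ck_gaussian_size_px = 10L,
         ck_threshold = 1.0, compartment_min_area_px = 5000L,
         marker_thresholds = c(CK = 0.1, CD3 = 0.3, CD8 = 0.4,
                               CD20 = 0.7, CD56 = 0.7, CD68 = 1.0),
         nucleus_detector = "builtin", zscore_reps = 1000L,
         microns_per_pixel = 0.5, preset = "mxif")
  } else {
    list(foreground_threshold = 0, bg_filter_size_px = 1000L,
         artifact_min_area_px = 250L, ck_gaussian_size_px = 10L,
         ck_threshold = 0.5, compartment_min_area_px = 5000L,
         marker_thresholds = c(CK = 0, CD3 = 0, CD8 = 0,
                               CD20 = 0, CD56 = 0, CD68 = 0),
         nucleus_detector = "builtin", zscore_reps = 1000L,
         microns_per_pixel = 0.5, preset = "mibi")
  }
  over <- list(...)
  unknown <- setdiff(names(over), .settings_fields)
  if (length(unknown)) stop("unknown settings field(s): ",
                            paste(unknown, collapse = ", "))
  base[names(over)] <- over
  validate_settings(structure(base, class = "analysis_settings"))
}

validate_settings <- function(s) {
  stopifnot(inherits(s, "analysis_settings"))
  sizes <- c("bg_filter_size_px", "artifact_min_area_px",
             "ck_gaussian_size_px", "compartment_min_area_px")
  for (f in sizes) {
    if (!is.numeric(s[[f]]) || s[[f]] < 1 || s[[f]] != floor(s[[f]]))
      stop(f, " must be a positive integer")
  }
  if (s$foreground_threshold < 0 || s$ck_threshold < 0 ||
      any(s$marker_thresholds < 0))
    stop("thresholds must be >= 0")
  if (s$zscore_reps < 1) stop("zscore_reps must be >= 1")
  if (s$microns_per_pixel <= 0) stop("microns_per_pixel must be > 0")
  if (!s$nucleus_detector %in% c("plugin", "builtin"))
    stop("nucleus_detector must be 'plugin' or 'builtin'")
  s
}

#' @export
print.analysis_settings <- function(x, ...) {
  cat(sprintf("analysis_settings (preset %s): fg > %g, bg filter %d px,\n",
              x$preset, x$foreground_threshold, x$bg_filter_size_px))
  cat(sprintf("  artifact < %d px, CK gaussian %d px, CK > %g, compartment < %d px\n",
              x$artifact_min_area_px, x$ck_gaussian_size_px, x$ck_threshold,
              x$compartment_min_area_px))
  cat("  marker gates:",
      paste(sprintf("%s > %g", names(x$marker_thresholds), x$marker_thresholds),
            collapse = ", "), "\n")
  invisible(x)
}

#' Save / load analysis settings as versioned JSON
#'
#' `load_settings(save_settings(x))` is field-for-field identical to `x`.
#' Unknown keys or a schema-version mismatch are rejected so that stale
#' settings files cannot silently drive an analysis.
#'
#' @param settings an `analysis_settings` object.
#' @param path JSON file path.
#' @export
save_settings <- function(settings, path) {
  settings <- validate_settings(settings)
  payload <- unclass(settings)
  ## named vector -> JSON object (jsonlite drops names of atomic vectors)
  payload$marker_thresholds <- as.list(payload$marker_thresholds)
  payload$schema_version <- .SETTINGS_SCHEMA_VERSION
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_settings
#' @export
load_settings <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version) ||
      payload$schema_version != .SETTINGS_SCHEMA_VERSION)
    stop("settings schema-version mismatch (expected ",
         .SETTINGS_SCHEMA_VERSION, ")")
  payload$schema_version <- NULL
  unknown <- setdiff(names(payload), .settings_fields)
  if (length(unknown)) stop("unknown settings key(s): ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(.settings_fields, names(payload))
  if (length(missing)) stop("settings file missing field(s): ",
                            paste(missing, collapse = ", "))
  ints <- c("bg_filter_size_px", "artifact_min_area_px", "ck_gaussian_size_px",
            "compartment_min_area_px", "zscore_reps")
  for (f in ints) payload[[f]] <- as.integer(payload[[f]])
  payload$marker_thresholds <- unlist(payload$marker_thresholds)
  validate_settings(structure(payload[.settings_fields],
                              class = "analysis_settings"))
}

## full-precision numeric formatting so CSV round trips are exact
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, "")
  out
}

#' Export / import the per-cell table as CSV
#'
#' One row per segmented cell: identifiers, 0-based nucleus centroid
#' (row, col), nucleus and cell areas in px and um^2, per-marker mean
#' corrected intensity, per-marker positivity flag, the inclusive phenotype
#' list (semicolon-separated) and the compartment. Numeric values are written
#' at full precision so a re-import reproduces them exactly.
#'
#' @param cells cell table as produced by [build_cell_table()].
#' @param path CSV file path.
#' @export
export_cell_table <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  out <- cells
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname export_cell_table
#' @export
import_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  flag_cols <- grep("^flag_", names(df))
  for (j in flag_cols) df[[j]] <- as.logical(df[[j]])
  if ("phenotypes" %in% names(df) && nrow(df))
    df$phenotypes[is.na(df$phenotypes)] <- ""
  df
}

#' Export / import an integer label mask as TIFF
#'
#' Lossless unsigned-integer raster; 16-bit when the largest label fits,
#' 32-bit otherwise.
#'
#' @param labels integer matrix, 0 = background.
#' @param path output TIFF path.
#' @export
export_label_mask <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (any(labels < 0)) stop("labels must be nonnegative")
  write_tiff_stack(list(labels), path, format = "uint")
}

#' @rdname export_label_mask
#' @export
import_label_mask <- function(path) {
  m <- read_tiff_stack(path)[[1]]
  storage.mode(m) <- "integer"
  m
}
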