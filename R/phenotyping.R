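## Per-cell intensity measurement, threshold gating, inclusive phenotype
## annotation and compartment assignment (workflow step v).

#' Cell phenotype labels
#'
#' The six phenotypes quantified by the pipeline, keyed by their defining
#' marker: CK (tumor cells), CD4 (CD3+CD8- helper T cells), CD8 (CD3+CD8+
#' cytotoxic T cells), CD20 (B cells), CD56 (NK cells), CD68 (macrophages).
#' @export
tme_phenotypes <- function() c("CK", "CD4", "CD8", "CD20", "CD56", "CD68")

#' Mean background-corrected intensity per cell and marker
#'
#' Arithmetic mean of each corrected channel over each cell's full pixel
#' region (the whole Voronoi cell, not the nucleus only; switch with
#' `scope = "nucleus"` and a nucleus label map).
#'
#' @param labels integer cell label map from [voronoi_cells()].
#' @param image a `multiplex_image`.
#' @param settings an `analysis_settings`.
#' @param corrected optional precomputed [background_corrected_channels()].
#' @return numeric matrix, cells (rownames = cell id) x markers.
#' @export
measure_cell_intensities <- function(labels, image, settings, corrected = NULL) {
  stopifnot(is.matrix(labels), all(dim(labels) == c(image$height, image$width)))
  if (is.null(corrected)) corrected <- background_corrected_channels(image, settings)
  sel <- labels > 0L
  ids <- labels[sel]
  if (length(ids) == 0L) {
    out <- matrix(numeric(0), 0, length(corrected),
                  dimnames = list(NULL, names(corrected)))
    return(out)
  }
  counts <- rowsum(rep(1, length(ids)), ids)
  means <- vapply(corrected, function(ch) {
    as.vector(rowsum(ch[sel], ids) / counts)
  }, numeric(nrow(counts)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(NULL, names(corrected)))
  rownames(means) <- rownames(counts)
  means
}

#' Gate cells into marker flags
#'
#' A cell is positive for a marker when its mean corrected intensity is
#' strictly greater than the marker's threshold; a mean exactly at the
#' threshold is negative. Markers are gated independently, so double
#' positives are expected and retained.
#'
#' @param means cells x markers matrix from [measure_cell_intensities()].
#' @param thresholds named numeric vector covering every marker column.
#' @return logical matrix of the same shape.
#' @export
gate_markers <- function(means, thresholds) {
  stopifnot(is.matrix(means))
  missing <- setdiff(colnames(means), names(thresholds))
  if (length(missing))
    stop("missing marker threshold(s): ", paste(missing, collapse = ", "))
  flags <- sweep(means, 2L, thresholds[colnames(means)], `>`)
  storage.mode(flags) <- "logical"
  flags
}

#' Annotate inclusive phenotypes from marker flags
#'
#' Rules: tumor cells CK+; CD4 T cells CD3+CD8-; CD8 T cells CD3+CD8+;
#' B cells CD20+; NK cells CD56+; macrophages CD68+. Assignment is
#' inclusive — one cell may carry several phenotypes (e.g. CK+CD68+ counts as
#' both tumor cell and macrophage) — and a CD3-CD8+ cell is neither a CD4 nor
#' a CD8 T cell.
#'
#' @param flags logical cells x markers matrix with columns CK, CD3, CD8,
#'   CD20, CD56, CD68.
#' @return logical cells x phenotypes matrix (columns [tme_phenotypes()]).
#' @export
annotate_phenotypes <- function(flags) {
  need <- c("CK", "CD3", "CD8", "CD20", "CD56", "CD68")
  missing <- setdiff(need, colnames(flags))
  if (length(missing))
    stop("flags missing marker column(s): ", paste(missing, collapse = ", "))
  cbind(CK = flags[, "CK"],
        CD4 = flags[, "CD3"] & !flags[, "CD8"],
        CD8 = flags[, "CD3"] & flags[, "CD8"],
        CD20 = flags[, "CD20"],
        CD56 = flags[, "CD56"],
        CD68 = flags[, "CD68"])
}

#' Assign cells to compartments by nucleus centroid
#'
#' The compartment is read from the compartment mask at the rounded centroid
#' (floor(centroid + 0.5) per axis, 0-based). A centroid on non-tissue gives
#' compartment "none".
#'
#' @param centroids data frame with 0-based `row`/`col` columns.
#' @param compartments integer mask from [segment_compartments()].
#' @return character vector: "tumor", "stroma" or "none".
#' @export
assign_compartment <- function(centroids, compartments) {
  r <- floor(centroids$row + 0.5) + 1L
  c_ <- floor(centroids$col + 0.5) + 1L
  if (any(r < 1L | r > nrow(compartments) | c_ < 1L | c_ > ncol(compartments)))
    stop("centroid outside raster")
  v <- compartments[cbind(r, c_)]
  c("none", "stroma", "tumor")[v + 1L]
}

#' Assemble the per-cell record table
#'
#' Joins segmentation, intensity, gating, phenotype and compartment results
#' into one data frame (one row per cell) ready for [export_cell_table()]
#' and [quantify_image()].
#'
#' @param nuclei nucleus data frame from [detect_nuclei()].
#' @param cell_labels label map from [voronoi_cells()].
#' @param image a `multiplex_image`.
#' @param settings an `analysis_settings`.
#' @param compartments compartment mask.
#' @param corrected optional precomputed corrected channels.
#' @return data frame of cell records; cells whose Voronoi region is empty
#'   are dropped.
#' @export
build_cell_table <- function(nuclei, cell_labels, image, settings,
                             compartments, corrected = NULL) {
  if (is.null(corrected)) corrected <- background_corrected_channels(image, settings)
  means <- measure_cell_intensities(cell_labels, image, settings, corrected)
  keep <- nuclei$id %in% as.integer(rownames(means))
  nuc <- nuclei[keep, , drop = FALSE]
  if (nrow(nuc) == 0L) {
    return(.empty_cell_table(names(image$channels)))
  }
  means <- means[as.character(nuc$id), , drop = FALSE]
  gated <- intersect(colnames(means), names(settings$marker_thresholds))
  flags <- gate_markers(means[, gated, drop = FALSE],
                        settings$marker_thresholds)
  phen <- annotate_phenotypes(flags)
  comp <- assign_compartment(nuc, compartments)
  cell_area <- tabulate(cell_labels[cell_labels > 0L], nbins = max(nuclei$id))
  um2 <- image$microns_per_pixel^2
  df <- data.frame(
    image_id = image$image_id,
    cell_id = nuc$id,
    centroid_row = nuc$row,
    centroid_col = nuc$col,
    nucleus_area_px = nuc$area_px,
    nucleus_area_um2 = nuc$area_px * um2,
    cell_area_px = cell_area[nuc$id],
    cell_area_um2 = cell_area[nuc$id] * um2,
    stringsAsFactors = FALSE
  )
  colnames(means) <- paste0("mean_", colnames(means))
  colnames(flags) <- paste0("flag_", colnames(flags))
  pheno_cols <- phen
  colnames(pheno_cols) <- paste0("pheno_", colnames(phen))
  df <- cbind(df, as.data.frame(means), as.data.frame(flags),
              as.data.frame(pheno_cols))
  df$phenotypes <- apply(phen, 1L, function(f)
    paste(colnames(phen)[f], collapse = ";"))
  df$compartment <- comp
  rownames(df) <- NULL
  df
}

.empty_cell_table <- function(markers) {
  df <- data.frame(image_id = character(0), cell_id = integer(0),
                   centroid_row = numeric(0), centroid_col = numeric(0),
                   nucleus_area_px = integer(0), nucleus_area_um2 = numeric(0),
                   cell_area_px = integer(0), cell_area_um2 = numeric(0),
                   stringsAsFactors = FALSE)
  for (m in markers) df[[paste0("mean_", m)]] <- numeric(0)
  for (m in markers) df[[paste0("flag_", m)]] <- logical(0)
  for (p in tme_phenotypes()) df[[paste0("pheno_", p)]] <- logical(0)
  df$phenotypes <- character(0)
  df$compartment <- character(0)
  df
}
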