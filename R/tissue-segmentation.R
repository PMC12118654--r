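## Foreground detection and tumor/stroma compartment segmentation
## (workflow steps ii-iii). All thresholds are strict (">"): a value exactly
## at a threshold goes to the lower class.

#' Background-corrected channels of a multiplex image
#'
#' One shared correction pass (large-kernel mean subtraction with the
#' settings' background filter) feeds both foreground detection and
#' per-cell intensity measurement.
#'
#' @param image a `multiplex_image`.
#' @param settings an `analysis_settings`.
#' @return named list of corrected matrices.
#' @export
background_corrected_channels <- function(image, settings) {
  lapply(image$channels, background_correct,
         filter_size_px = settings$bg_filter_size_px)
}

#' Remove small isolated regions from a binary mask ("gap filling")
#'
#' Every connected component — of either polarity — whose area is strictly
#' below `min_area_px` is flipped to the enclosing polarity; the rule is
#' iterated to a fixpoint, so the result is idempotent. Components of exactly
#' `min_area_px` pixels are kept.
#'
#' @param mask logical matrix.
#' @param min_area_px strict area threshold in pixels.
#' @param connectivity 4 (default) or 8.
#' @return cleaned logical matrix.
#' @export
fill_small_regions <- function(mask, min_area_px, connectivity = 4) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (min_area_px <= 1) return(mask)
  for (iter in seq_len(100L)) {
    changed <- FALSE
    for (polarity in c(TRUE, FALSE)) {
      m <- if (polarity) mask else !mask
      lab <- cpp_label_components(m, connectivity)
      n <- attr(lab, "n")
      if (n == 0L) next
      sizes <- tabulate(lab[lab > 0L], nbins = n)
      small <- which(sizes < min_area_px)
      if (length(small)) {
        flip <- lab %in% small
        dim(flip) <- dim(mask)
        mask[flip] <- !polarity
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mask
}

#' Foreground (tissue) detection
#'
#' A pixel is foreground when any background-corrected channel exceeds the
#' foreground threshold (strictly); small isolated regions of either polarity
#' are then reassigned to their surroundings.
#'
#' @param image a `multiplex_image`.
#' @param settings an `analysis_settings` (uses `foreground_threshold`,
#'   `bg_filter_size_px`, `artifact_min_area_px`).
#' @param corrected optional precomputed output of
#'   [background_corrected_channels()].
#' @return logical matrix (TRUE = foreground).
#' @export
detect_foreground <- function(image, settings, corrected = NULL) {
  if (is.null(corrected)) corrected <- background_corrected_channels(image, settings)
  fg <- Reduce(`|`, lapply(corrected, function(ch) ch > settings$foreground_threshold))
  fill_small_regions(fg, settings$artifact_min_area_px)
}

#' Tumor/stroma compartment segmentation
#'
#' The cytokeratin channel is Gaussian-smoothed (`ck_gaussian_size_px` as
#' sigma), background-corrected, and thresholded at `ck_threshold`: values
#' strictly above go to tumor, the rest to stroma. Compartments are
#' restricted to the detected foreground, and tumor or stroma patches smaller
#' than `compartment_min_area_px` are reassigned to the other compartment.
#'
#' @param ck_channel cytokeratin raster (matrix).
#' @param settings an `analysis_settings`.
#' @param foreground logical foreground mask from [detect_foreground()].
#' @return integer matrix: 0 = non-tissue, 1 = stroma, 2 = tumor.
#' @export
segment_compartments <- function(ck_channel, settings, foreground) {
  stopifnot(is.matrix(ck_channel), all(dim(ck_channel) == dim(foreground)))
  sm <- gaussian_blur(ck_channel, settings$ck_gaussian_size_px)
  corr <- background_correct(sm, settings$bg_filter_size_px)
  tumor <- (corr > settings$ck_threshold) & foreground
  min_area <- settings$compartment_min_area_px
  for (iter in seq_len(100L)) {
    changed <- FALSE
    for (polarity in c(TRUE, FALSE)) {
      m <- if (polarity) tumor else (foreground & !tumor)
      other <- if (polarity) (foreground & !tumor) else tumor
      if (!any(other)) next   # nothing to reassign small patches to
      lab <- cpp_label_components(m, 4L)
      n <- attr(lab, "n")
      if (n == 0L) next
      sizes <- tabulate(lab[lab > 0L], nbins = n)
      small <- which(sizes < min_area)
      if (length(small)) {
        ## flip small tumor patches to stroma and vice versa, within tissue
        flip <- lab %in% small
        dim(flip) <- dim(tumor)
        tumor[flip] <- !polarity
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp <- matrix(0L, nrow(ck_channel), ncol(ck_channel))
  comp[foreground] <- 1L
  comp[tumor & foreground] <- 2L
  comp
}
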