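## Nucleus detection and seeded Voronoi cell tessellation (workflow step iv).
## Coordinates are 0-based (row, col) with pixel centers at integers.

.default_nucleus_params <- function() {
  list(smooth_sigma = 1.5,        # px; light denoising before thresholding
       threshold = 0.5,           # a.u. on the corrected nuclear channel
       bg_filter_size_px = 101L,  # local background scale for nuclei
       min_area_px = 6L,          # discard debris below this size
       min_distance_px = 5L,      # minimal separation of watershed peaks
       peak_min_height = 1.5,     # minimal distance-transform peak height (px)
       max_pixels = 4e6)          # raster size guard; larger inputs need tiling
}

#' Detect nuclei on the nuclear (DAPI) channel
#'
#' `method = "plugin"` delegates to an injected detector (e.g. a star-convex
#' polygon network) that must return either a data frame with 0-based
#' `row`/`col` centroids (and optionally `area_px`) or a list with `nuclei`
#' and `labels` elements satisfying the same contract. When no plugin is
#' supplied the call fails loudly — there is no silent substitution.
#'
#' `method = "builtin"` is a classical fallback: Gaussian smoothing,
#' background correction, thresholding, then a distance-transform split of
#' touching blobs (each blob is divided among its suppressed distance-peak
#' maxima) and a size filter. Nuclei are returned sorted by centroid
#' (row, col) so results are deterministic.
#'
#' @param nuclear_channel nonnegative matrix.
#' @param method "builtin" or "plugin".
#' @param params named list overriding the builtin parameters
#'   (smooth_sigma, threshold, bg_filter_size_px, min_area_px,
#'   min_distance_px, max_pixels).
#' @param detector plugin callable `(matrix) -> nuclei`.
#' @return list with `nuclei` (data.frame: id, row, col, area_px) and
#'   `labels` (integer matrix of nucleus pixel sets, 0 = background).
#' @export
detect_nuclei <- function(nuclear_channel, method = c("builtin", "plugin"),
                          params = list(), detector = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(nuclear_channel))
  p <- utils::modifyList(.default_nucleus_params(), params)
  if (length(nuclear_channel) > p$max_pixels)
    stop("raster exceeds the pixel budget (", p$max_pixels,
         "); tile the image and analyze tiles separately")
  if (method == "plugin") {
    if (is.null(detector))
      stop("nucleus detector plugin unavailable; pass `detector=` or use ",
           "method = 'builtin'")
    res <- detector(nuclear_channel)
    if (is.data.frame(res)) res <- list(nuclei = res, labels = NULL)
    if (!all(c("row", "col") %in% names(res$nuclei)))
      stop("plugin detector must return 0-based 'row'/'col' centroids")
    nuc <- res$nuclei
    ord <- order(nuc$row, nuc$col)
    nuc <- nuc[ord, , drop = FALSE]
    nuc$id <- seq_len(nrow(nuc))
    rownames(nuc) <- NULL
    return(list(nuclei = nuc, labels = res$labels))
  }
  sm <- gaussian_blur(nuclear_channel, p$smooth_sigma)
  corr <- background_correct(sm, p$bg_filter_size_px)
  mask <- corr > p$threshold
  lab <- cpp_label_components(mask, 4L)
  ncomp <- attr(lab, "n")
  out_labels <- matrix(0L, nrow(mask), ncol(mask))
  nuclei <- list()
  if (ncomp > 0L) {
    edt <- cpp_distance_transform(mask)
    ## regional maxima of the distance transform = watershed markers
    locmax <- edt >= cpp_max_filter(edt, as.integer(p$min_distance_px)) &
      edt >= p$peak_min_height & mask
    pix_by_comp <- split(which(lab > 0L), lab[lab > 0L])
    nr <- nrow(mask)
    next_id <- 0L
    for (pix in pix_by_comp) {
      if (length(pix) < p$min_area_px) next
      rows <- (pix - 1L) %% nr          # 0-based
      cols <- (pix - 1L) %/% nr
      d <- edt[pix]
      cand <- which(locmax[pix])
      if (length(cand) == 0L) cand <- which.max(d)
      ## greedy merge of maxima closer than the minimal separation
      ord <- cand[order(-d[cand], rows[cand], cols[cand])]
      peaks <- integer(0)
      for (k in ord) {
        if (length(peaks) == 0L) { peaks <- k; next }
        dd <- sqrt((rows[k] - rows[peaks])^2 + (cols[k] - cols[peaks])^2)
        if (all(dd >= p$min_distance_px)) peaks <- c(peaks, k)
      }
      if (length(peaks) <= 1L) {
        assign_id <- rep(1L, length(pix))
        npk <- 1L
      } else {
        d2 <- outer(rows, rows[peaks], `-`)^2 + outer(cols, cols[peaks], `-`)^2
        assign_id <- max.col(-d2, ties.method = "first")
        npk <- length(peaks)
      }
      for (q in seq_len(npk)) {
        sel <- assign_id == q
        if (sum(sel) < p$min_area_px) next
        next_id <- next_id + 1L
        out_labels[pix[sel]] <- next_id
        nuclei[[next_id]] <- c(mean(rows[sel]), mean(cols[sel]), sum(sel))
      }
    }
  }
  if (length(nuclei) == 0L) {
    return(list(nuclei = data.frame(id = integer(0), row = numeric(0),
                                    col = numeric(0), area_px = integer(0)),
                labels = out_labels))
  }
  m <- do.call(rbind, nuclei)
  nuc <- data.frame(id = seq_len(nrow(m)), row = m[, 1], col = m[, 2],
                    area_px = as.integer(m[, 3]))
  ord <- order(nuc$row, nuc$col)
  remap <- integer(nrow(nuc))
  remap[nuc$id[ord]] <- seq_len(nrow(nuc))
  relab <- out_labels
  relab[out_labels > 0L] <- remap[out_labels[out_labels > 0L]]
  nuc <- nuc[ord, , drop = FALSE]
  nuc$id <- seq_len(nrow(nuc))
  rownames(nuc) <- NULL
  list(nuclei = nuc, labels = relab)
}

#' Seeded Voronoi cell tessellation of the foreground
#'
#' Every foreground pixel is labeled with the index of its nearest seed
#' (nucleus centroid) by Euclidean distance; equidistant pixels go to the
#' lowest seed index; non-foreground pixels stay 0. Seeds landing on
#' non-foreground keep a (possibly empty) cell of the foreground pixels
#' nearest to them; the number of empty cells is attached as an attribute.
#'
#' @param seeds data frame with 0-based `row`/`col` centroid columns.
#' @param foreground logical matrix.
#' @return integer matrix of cell labels (seed indices), attribute
#'   `empty_cells` = number of seeds whose cell has no pixels.
#' @export
voronoi_cells <- function(seeds, foreground) {
  stopifnot(is.logical(foreground), is.matrix(foreground))
  if (is.null(seeds) || nrow(seeds) == 0L) {
    warning("no seeds supplied; returning an empty label map")
    out <- matrix(0L, nrow(foreground), ncol(foreground))
    attr(out, "empty_cells") <- 0L
    return(out)
  }
  if (any(seeds$row < 0 | seeds$row > nrow(foreground) - 1 |
          seeds$col < 0 | seeds$col > ncol(foreground) - 1))
    stop("seeds must lie inside the raster")
  lab <- cpp_voronoi_labels(seeds$row, seeds$col, foreground)
  present <- tabulate(lab[lab > 0L], nbins = nrow(seeds))
  attr(lab, "empty_cells") <- sum(present == 0L)
  lab
}
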