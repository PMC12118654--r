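## Spatial immune-contexture statistics (workflow step vi): compartment
## areas, phenotype counts and densities, mean nearest-neighbor distances,
## permutation z-scores, per-patient aggregation and the inflammation rule.

param_density <- function(phenotype, compartment, region)
  sprintf("density of %s in %s in %s", phenotype, compartment, region)
param_area <- function(compartment, region)
  sprintf("area of %s in %s", compartment, region)
param_distance <- function(source, target, region)
  sprintf("distance from %s to %s in %s", source, target, region)

#' The 50-parameter tumor-center shortlist
#'
#' The feature space of the prognostic classifier: per-compartment areas
#' (tumor, stroma; n = 2), densities of the six phenotypes in tumor and
#' stroma (n = 12), and whole-tissue nearest-neighbor distance z-scores for
#' all ordered phenotype pairs (n = 36), all from center-region images.
#' Cell counts are deliberately excluded (captured by density x area and
#' highly correlated with both).
#'
#' @param region region label used in the parameter names.
#' @return character vector of exactly 50 parameter names.
#' @export
center_shortlist <- function(region = "center") {
  ph <- tme_phenotypes()
  c(param_area("Tumor", region), param_area("Stroma", region),
    as.vector(t(outer(ph, c("Tumor", "Stroma"),
                      function(p, comp) param_density(p, comp, region)))),
    as.vector(t(outer(ph, ph, function(a, b) param_distance(a, b, region)))))
}

#' Mean nearest-neighbor distance between two phenotypes
#'
#' For every source point, the minimal non-zero Euclidean distance to a
#' target point (coincident centroids are excluded, which also handles
#' self-pairing when source and target are the same set); the mean over
#' source points is returned, scaled to micrometers. `NA` when no valid
#' non-zero pair exists.
#'
#' @param source_pts,target_pts matrices or data frames with `row`/`col`
#'   pixel coordinates.
#' @param microns_per_pixel scale factor to micrometers.
#' @return mean nearest-neighbor distance in micrometers, or `NA`.
#' @export
mean_nn_distance <- function(source_pts, target_pts, microns_per_pixel = 1) {
  s <- .as_pts(source_pts); t_ <- .as_pts(target_pts)
  if (nrow(s) < 1 || nrow(t_) < 1) return(NA_real_)
  cpp_nn_mean(s, t_) * microns_per_pixel
}

.as_pts <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$row, x$col)
  if (!is.matrix(x)) x <- matrix(x, ncol = 2)
  storage.mode(x) <- "double"
  x
}

#' Permutation z-score for a mean nearest-neighbor distance
#'
#' Builds the null by repeatedly drawing `source_n` cells uniformly without
#' replacement from all cell positions in the scope, and independently
#' `target_n` cells (for a self-distance the same draw is kept for both
#' phenotypes), recomputing the mean nearest-neighbor distance each time.
#' z = (observed - mean_rand) / sd_rand (sample sd, n-1). A null with zero
#' spread (e.g. the source phenotype comprises every cell in scope) is
#' flagged degenerate and yields `NA`.
#'
#' Negative z-scores indicate the two phenotypes are closer than expected by
#' chance (clustering); |z| > 2 is conventionally read as significant.
#'
#' @param observed observed mean NN distance (micrometers).
#' @param all_cells positions of every cell in the scope (matrix or data
#'   frame with `row`/`col`, pixel units).
#' @param source_n,target_n numbers of cells of the two phenotypes.
#' @param self TRUE for a self-distance (source phenotype == target).
#' @param reps permutation repetitions.
#' @param microns_per_pixel scale factor applied to the null distances.
#' @return list: `z`, `mu_rand`, `sd_rand`, `degenerate`.
#' @export
distance_zscore <- function(observed, all_cells, source_n, target_n,
                            self = FALSE, reps = 1000,
                            microns_per_pixel = 1) {
  pts <- .as_pts(all_cells)
  n <- nrow(pts)
  if (source_n < 1 || target_n < 1) stop("source_n and target_n must be >= 1")
  if (n < max(source_n, target_n))
    stop("scope must contain at least max(source_n, target_n) cells")
  null <- cpp_perm_null(pts, as.integer(source_n), as.integer(target_n),
                        isTRUE(self), as.integer(reps)) * microns_per_pixel
  null <- null[!is.na(null)]
  if (length(null) < 2) {
    return(list(z = NA_real_, mu_rand = NA_real_, sd_rand = NA_real_,
                degenerate = TRUE))
  }
  mu <- mean(null)
  sdv <- stats::sd(null)
  ## identical repetitions differ only by floating-point summation order
  if (sdv <= 1e-10 * max(abs(mu), 1) || is.na(observed)) {
    return(list(z = NA_real_, mu_rand = mu, sd_rand = sdv, degenerate = TRUE))
  }
  list(z = (observed - mu) / sdv, mu_rand = mu, sd_rand = sdv,
       degenerate = FALSE)
}

#' Quantify one image: areas, counts, densities, distances
#'
#' Computes per-compartment areas (px and mm^2), per-phenotype counts and
#' densities (cells/mm^2) in the tumor and stroma compartments and in the
#' whole tissue, and — for the requested distance scopes — observed mean
#' nearest-neighbor distances with permutation z-scores for every ordered
#' phenotype pair. An empty compartment yields count 0 and a missing
#' density, never a division error.
#'
#' @param cells cell table from [build_cell_table()].
#' @param compartments compartment mask.
#' @param settings an `analysis_settings` (pixel size, z-score repetitions).
#' @param region region tag carried into the result.
#' @param distance_scopes compartments over which distances are computed;
#'   default whole tissue only ("all"), the scope the classifier uses.
#' @return object of class `region_quant`: list with `image_id`, `region`,
#'   `areas`, `counts`, `distances` data frames.
#' @export
quantify_image <- function(cells, compartments, settings,
                           region = "center", distance_scopes = "all") {
  mpp <- settings$microns_per_pixel
  px2mm2 <- (mpp / 1000)^2
  area_px <- c(Tumor = sum(compartments == 2L), Stroma = sum(compartments == 1L))
  areas <- data.frame(compartment = c("Tumor", "Stroma", "all"),
                      area_px = c(area_px, sum(area_px)),
                      area_mm2 = c(area_px, sum(area_px)) * px2mm2,
                      stringsAsFactors = FALSE)
  ph <- tme_phenotypes()
  comp_of <- function(scope) switch(scope, Tumor = "tumor", Stroma = "stroma",
                                    all = c("tumor", "stroma"))
  counts <- do.call(rbind, lapply(c("Tumor", "Stroma", "all"), function(sc) {
    in_scope <- cells$compartment %in% comp_of(sc)
    a <- areas$area_mm2[areas$compartment == sc]
    data.frame(phenotype = ph, compartment = sc,
               count = vapply(ph, function(p)
                 sum(cells[[paste0("pheno_", p)]] & in_scope), 0L),
               density = vapply(ph, function(p) {
                 k <- sum(cells[[paste0("pheno_", p)]] & in_scope)
                 if (a > 0) k / a else NA_real_
               }, 0), stringsAsFactors = FALSE, row.names = NULL)
  }))
  dist_rows <- list()
  for (sc in distance_scopes) {
    in_scope <- cells$compartment %in% comp_of(sc)
    scope_pts <- cbind(cells$centroid_row[in_scope], cells$centroid_col[in_scope])
    for (a in ph) {
      a_sel <- in_scope & cells[[paste0("pheno_", a)]]
      na_ <- sum(a_sel)
      for (b in ph) {
        b_sel <- in_scope & cells[[paste0("pheno_", b)]]
        nb <- sum(b_sel)
        row <- data.frame(source = a, target = b, compartment = sc,
                          n_source = na_, n_target = nb,
                          d_obs_um = NA_real_, mu_rand = NA_real_,
                          sd_rand = NA_real_, z = NA_real_,
                          stringsAsFactors = FALSE)
        if (na_ >= 1 && nb >= 1 && !(a == b && na_ < 2)) {
          obs <- mean_nn_distance(
            cbind(cells$centroid_row[a_sel], cells$centroid_col[a_sel]),
            cbind(cells$centroid_row[b_sel], cells$centroid_col[b_sel]), mpp)
          row$d_obs_um <- obs
          if (!is.na(obs) && nrow(scope_pts) >= max(na_, nb)) {
            zs <- distance_zscore(obs, scope_pts, na_, nb, self = (a == b),
                                  reps = settings$zscore_reps,
                                  microns_per_pixel = mpp)
            row$mu_rand <- zs$mu_rand
            row$sd_rand <- zs$sd_rand
            row$z <- zs$z
          }
        }
        dist_rows[[length(dist_rows) + 1L]] <- row
      }
    }
  }
  structure(list(image_id = if (nrow(cells)) cells$image_id[1] else NA_character_,
                 region = region, areas = areas, counts = counts,
                 distances = do.call(rbind, dist_rows)),
            class = "region_quant")
}

#' @export
print.region_quant <- function(x, ...) {
  cat(sprintf("region_quant for image %s (%s region)\n", x$image_id, x$region))
  cat(sprintf("  tissue %.3f mm2 (tumor %.3f, stroma %.3f)\n",
              x$areas$area_mm2[3], x$areas$area_mm2[1], x$areas$area_mm2[2]))
  tot <- x$counts[x$counts$compartment == "all", ]
  cat("  counts:", paste(sprintf("%s=%d", tot$phenotype, tot$count),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate image-level quantifications into a patient parameter table
#'
#' Counts and areas are pooled (summed) across a patient's images per scope,
#' so pooled density = pooled count / pooled area; distance z-scores are
#' averaged unweighted across the images where they are defined. Scopes with
#' no image stay missing.
#'
#' @param quants list of `region_quant` objects.
#' @param patient_ids character vector parallel to `quants`.
#' @param regions which regions to emit parameters for.
#' @return data frame: one row per patient, named contextual parameters as
#'   columns (see [center_shortlist()] for the naming scheme).
#' @export
aggregate_patients <- function(quants, patient_ids,
                               regions = c("border", "center")) {
  stopifnot(length(quants) == length(patient_ids))
  patients <- unique(patient_ids)
  ph <- tme_phenotypes()
  cols <- unlist(lapply(regions, function(rg) center_shortlist(rg)))
  out <- matrix(NA_real_, length(patients), length(cols),
                dimnames = list(patients, cols))
  for (pt in patients) {
    for (rg in regions) {
      qs <- quants[patient_ids == pt &
                     vapply(quants, function(q) q$region, "") == rg]
      if (length(qs) == 0L) next
      for (comp in c("Tumor", "Stroma")) {
        a_px <- sum(vapply(qs, function(q)
          q$areas$area_px[q$areas$compartment == comp], 0))
        a_mm2 <- sum(vapply(qs, function(q)
          q$areas$area_mm2[q$areas$compartment == comp], 0))
        out[pt, param_area(comp, rg)] <- a_mm2
        for (p in ph) {
          k <- sum(vapply(qs, function(q)
            q$counts$count[q$counts$phenotype == p &
                             q$counts$compartment == comp], 0))
          out[pt, param_density(p, comp, rg)] <-
            if (a_mm2 > 0) k / a_mm2 else NA_real_
        }
      }
      for (a in ph) for (b in ph) {
        zs <- vapply(qs, function(q) {
          d <- q$distances
          i <- d$source == a & d$target == b & d$compartment == "all"
          if (any(i)) d$z[i][1] else NA_real_
        }, 0)
        zs <- zs[!is.na(zs)]
        if (length(zs))
          out[pt, param_distance(a, b, rg)] <- mean(zs)
      }
    }
  }
  data.frame(patient_id = patients, out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Inflammation status from CD8 T-cell densities
#'
#' A tumor is called inflamed when the border CD8 T-cell density exceeds
#' 200 cells/mm^2 and the border-to-center density ratio is below 10 (a high
#' ratio flags immune exclusion from the center). A center density of 0
#' makes the ratio infinite, hence non-inflamed.
#'
#' @param border_cd8_density,center_cd8_density cells/mm^2.
#' @return "inflamed" or "non_inflamed".
#' @export
classify_inflammation <- function(border_cd8_density, center_cd8_density) {
  if (is.na(border_cd8_density)) stop("border density must be defined")
  ratio <- if (!is.na(center_cd8_density) && center_cd8_density > 0)
    border_cd8_density / center_cd8_density else Inf
  if (border_cd8_density > 200 && ratio < 10) "inflamed" else "non_inflamed"
}
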