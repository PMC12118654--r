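## Ground-truthed synthetic data: tissue images whose construction yields
## known nuclei, marker flags and tumor masks, point patterns for calibrating
## the distance z-score, and survival cohorts with planted prognostic
## effects. Every generator is deterministic given `seed`.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

.paint_disc <- function(img, r0, c0, radius, value, add = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- max(1L, floor(r0 + 1 - radius)):min(nr, ceiling(r0 + 1 + radius))
  cc <- max(1L, floor(c0 + 1 - radius)):min(nc, ceiling(c0 + 1 + radius))
  sub <- outer((rr - 1) - r0, (cc - 1) - c0,
               function(dr, dc) dr^2 + dc^2) <= radius^2
  if (add) img[rr, cc][sub] <- img[rr, cc][sub] + value
  else img[rr, cc][sub] <- value
  img
}

.disc_mask <- function(nr, nc, r0, c0, radius) {
  outer(seq_len(nr) - 1 - r0, seq_len(nc) - 1 - c0,
        function(dr, dc) dr^2 + dc^2) <= radius^2
}

#' Generate a ground-truthed synthetic multiplex tissue image
#'
#' Emulates the structure of a stained tissue scan: blob-like nuclei (discs,
#' slightly blurred, plus Gaussian noise) on a dark background inside a
#' circular tissue region, contiguous cytokeratin-high tumor islands in
#' CK-low stroma, and marker channels painted over positive nuclei at
#' intensities well separated from the gating thresholds, so that the
#' downstream pipeline's recall/precision can be asserted against the
#' construction. Nuclei are placed by dart throwing with a minimal
#' separation, so they never overlap.
#'
#' Default marker paint levels are 12x the immunofluorescence gating
#' thresholds: after background correction and averaging over a Voronoi
#' cell, a positive cell's mean stays comfortably above its gate and a
#' negative cell's stays below.
#'
#' @param height,width canvas size in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius,nucleus_radius_sd disc radius distribution (px).
#' @param tumor_islands,tumor_island_radius CK-high island count and radius.
#' @param markers named list per marker, each
#'   `list(fraction =, mode = "CSR"|"clustered", parents =, dispersion =)`.
#' @param marker_levels named paint intensities; default 12x the mxif gates.
#' @param microns_per_pixel pixel size (default 0.5 um/px, a typical 20x
#'   whole-slide scan).
#' @param patient_id,region,image_id provenance tags.
#' @param seed RNG seed (required for reproducibility).
#' @return list: `image` (a `multiplex_image`) and `truth` (nucleus centers,
#'   per-cell marker flag matrix, tissue and tumor masks).
#' @export
generate_tissue_image <- function(height = 256, width = 256, n_nuclei = 150,
                                  nucleus_radius = 4, nucleus_radius_sd = 0.5,
                                  tumor_islands = 2, tumor_island_radius = 40,
                                  markers = list(
                                    CD3 = list(fraction = 0.30, mode = "CSR"),
                                    CD8 = list(fraction = 0.15, mode = "CSR"),
                                    CD20 = list(fraction = 0.10, mode = "clustered",
                                                parents = 2, dispersion = 20),
                                    CD56 = list(fraction = 0.05, mode = "CSR"),
                                    CD68 = list(fraction = 0.10, mode = "CSR")),
                                  marker_levels = NULL,
                                  microns_per_pixel = 0.5,
                                  patient_id = "SYN01", region = "center",
                                  image_id = "syn-image", seed = 1) {
  .with_seed(seed, {
    if (is.null(marker_levels)) {
      gates <- c(CK = 0.1, CD3 = 0.3, CD8 = 0.4, CD20 = 0.7, CD56 = 0.7,
                 CD68 = 1.0)
      ## 12x the gate, painted over a slightly enlarged nucleus disc: after
      ## dilution over the Voronoi cell and background subtraction the mean
      ## of a positive cell stays well above its gate
      marker_levels <- gates * 12
    }
    ctr_r <- (height - 1) / 2; ctr_c <- (width - 1) / 2
    tissue_radius <- 0.44 * min(height, width)
    tissue <- .disc_mask(height, width, ctr_r, ctr_c, tissue_radius)

    ## --- nucleus placement: dart throwing with retry cap -----------------
    sep <- 2 * (nucleus_radius + 2 * nucleus_radius_sd) + 1
    centers <- matrix(NA_real_, n_nuclei, 2)
    radii <- pmax(1.5, stats::rnorm(n_nuclei, nucleus_radius, nucleus_radius_sd))
    placed <- 0L
    tries <- 0L
    max_tries <- 400L * n_nuclei
    while (placed < n_nuclei) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("packing failure: cannot place ", n_nuclei,
             " nuclei at radius ", nucleus_radius, " on this canvas")
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (tissue_radius - nucleus_radius - 2)
      cand <- c(ctr_r + rad * sin(ang), ctr_c + rad * cos(ang))
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
          (centers[seq_len(placed), 2] - cand[2])^2
        if (min(d2) < sep^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }

    ## --- tumor islands ----------------------------------------------------
    tumor <- matrix(FALSE, height, width)
    if (tumor_islands > 0) {
      for (k in seq_len(tumor_islands)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, tissue_radius - tumor_island_radius - 2)
        tumor <- tumor | .disc_mask(height, width, ctr_r + rad * sin(ang),
                                    ctr_c + rad * cos(ang), tumor_island_radius)
      }
      tumor <- tumor & tissue
    }

    ## --- marker assignment -------------------------------------------------
    in_tumor <- tumor[cbind(floor(centers[, 1] + 0.5) + 1L,
                            floor(centers[, 2] + 0.5) + 1L)]
    flags <- matrix(FALSE, n_nuclei, length(markers) + 1L,
                    dimnames = list(NULL, c("CK", names(markers))))
    flags[, "CK"] <- in_tumor
    for (m in names(markers)) {
      spec <- markers[[m]]
      k <- round(spec$fraction * n_nuclei)
      if (k == 0) next
      if (identical(spec$mode, "clustered")) {
        parents <- sample.int(n_nuclei, spec$parents)
        d2p <- sapply(parents, function(pi_)
          (centers[, 1] - centers[pi_, 1])^2 + (centers[, 2] - centers[pi_, 2])^2)
        pos <- order(apply(as.matrix(d2p), 1L, min))[seq_len(k)]
      } else {
        pos <- sample.int(n_nuclei, k)
      }
      flags[pos, m] <- TRUE
    }

    ## --- raster channels ---------------------------------------------------
    dapi <- matrix(0, height, width)
    dapi[tissue] <- 0.6                       # dim tissue autofluorescence
    for (i in seq_len(n_nuclei))
      dapi <- .paint_disc(dapi, centers[i, 1], centers[i, 2], radii[i], 3.0)
    dapi <- gaussian_blur(dapi, 0.8) +
      matrix(stats::rnorm(height * width, 0, 0.02), height, width)
    dapi[dapi < 0] <- 0

    ck <- matrix(0, height, width)
    ck[tumor] <- 3.0
    ck <- gaussian_blur(ck, 2)
    channels <- list(DAPI = dapi, CK = ck)
    for (m in names(markers)) {
      ch <- matrix(0, height, width)
      for (i in which(flags[, m]))
        ch <- .paint_disc(ch, centers[i, 1], centers[i, 2], radii[i] + 1,
                          marker_levels[[m]])
      channels[[m]] <- ch
    }
    img <- multiplex_image(channels, microns_per_pixel, patient_id, region,
                           image_id)
    list(image = img,
         truth = list(centers = data.frame(row = centers[, 1],
                                           col = centers[, 2]),
                      flags = flags, tissue_mask = tissue,
                      tumor_mask = tumor))
  })
}

#' Generate a labeled 2D point pattern
#'
#' CSR mode draws points uniformly in the window; clustered mode draws
#' offspring as Gaussian displacements around shared uniformly placed
#' parents (a Thomas-type process). Used to calibrate the distance z-score.
#'
#' @param n_a,n_b point counts for labels "A" and "B" (`n_b = 0` gives a
#'   single-type pattern).
#' @param mode "CSR" or "clustered" (applies to both labels).
#' @param window `c(height, width)` in pixels.
#' @param parents,dispersion clustered-mode parent count and offspring sd.
#' @param seed RNG seed.
#' @return data frame: `row`, `col`, `label`.
#' @export
generate_point_pattern <- function(n_a, n_b = 0, mode = c("CSR", "clustered"),
                                   window = c(100, 100), parents = 5,
                                   dispersion = 5, seed = 1) {
  mode <- match.arg(mode)
  if (n_a < 1) stop("n_a must be >= 1")
  if (any(window <= 0)) stop("empty window")
  .with_seed(seed, {
    draw <- function(n) {
      if (mode == "CSR") {
        cbind(stats::runif(n, 0, window[1]), stats::runif(n, 0, window[2]))
      } else {
        pr <- cbind(stats::runif(parents, 0, window[1]),
                    stats::runif(parents, 0, window[2]))
        pick <- sample.int(parents, n, replace = TRUE)
        pts <- pr[pick, , drop = FALSE] +
          matrix(stats::rnorm(2 * n, 0, dispersion), n, 2)
        pts[, 1] <- pmin(pmax(pts[, 1], 0), window[1])
        pts[, 2] <- pmin(pmax(pts[, 2], 0), window[2])
        pts
      }
    }
    a <- draw(n_a)
    out <- data.frame(row = a[, 1], col = a[, 2],
                      label = rep("A", n_a), stringsAsFactors = FALSE)
    if (n_b > 0) {
      b <- draw(n_b)
      out <- rbind(out, data.frame(row = b[, 1], col = b[, 2],
                                   label = rep("B", n_b),
                                   stringsAsFactors = FALSE))
    }
    out
  })
}

#' Generate a synthetic patient cohort with planted prognostic effects
#'
#' Parameter values are drawn per column: distance z-scores as standard
#' normals, areas and densities as log-normals, with block-correlated noise
#' (see `noise_correlation`). Survival follows a
#' proportional-hazards model on the standardized parameter values,
#' `h_i = baseline_hazard * exp(sum_j log(HR_j) * z_ij)`, with event times
#' exponential and censoring uniform over the follow-up window — the
#' standard construction that makes a planted effect directly interpretable
#' as a hazard ratio per standard deviation.
#'
#' Defaults mirror a node-negative triple-negative breast cancer discovery
#' cohort: 63 patients, the 50-parameter center shortlist, administrative
#' censoring uniform over a 10-15 year follow-up window, and a baseline
#' hazard of 0.08/year (roughly 50% observed deaths).
#'
#' @param n_patients cohort size (>= 12; the inner resampling loop draws 12).
#' @param parameters parameter (column) names.
#' @param planted named numeric vector of hazard ratios per unit z for a
#'   subset of parameters (all > 0); empty for a pure-noise cohort.
#' @param noise_correlation shared-factor loading of the non-planted
#'   ("noise") parameters: densities and areas load on one latent
#'   inflammation factor, distance z-scores on a factor per source
#'   phenotype. Real contexture parameters are strongly interrelated, and
#'   this block structure reproduces that.
#' @param missing_rate fraction of distance z-score entries set missing
#'   (in real cohorts a distance z-score is undefined whenever a phenotype
#'   is too sparse in an image; planted columns are kept complete so their
#'   effect size is exactly as stated).
#' @param baseline_hazard events per year for an average patient.
#' @param follow_up administrative censoring window (years), `c(min, max)`;
#'   censoring times are uniform over it.
#' @param seed RNG seed.
#' @return list: `parameters` (data frame with `patient_id` + columns),
#'   `survival` (patient_id, time, event), `planted`.
#' @export
generate_cohort <- function(n_patients = 63, parameters = center_shortlist(),
                            planted = c(), baseline_hazard = 0.08,
                            follow_up = c(10, 15), missing_rate = 0.1,
                            noise_correlation = 0.45, seed = 1) {
  if (n_patients < 12) stop("n_patients must be >= 12")
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% parameters))
      stop("planted effects must be named by parameters present in the table")
    if (any(planted <= 0)) stop("hazard multipliers must be > 0")
  }
  .with_seed(seed, {
    ## latent-factor noise: densities/areas share one "inflammation" factor,
    ## distance z-scores share a factor per source phenotype -- mirroring the
    ## strong block correlations of real contexture parameters. Planted
    ## columns stay independent so their effect size is exactly as stated.
    f_dens <- stats::rnorm(n_patients)
    f_src <- sapply(tme_phenotypes(), function(p) stats::rnorm(n_patients))
    X <- sapply(parameters, function(pname) {
      eps <- stats::rnorm(n_patients)
      z <- if (pname %in% names(planted) || noise_correlation <= 0) eps
      else if (startsWith(pname, "distance")) {
        src <- strsplit(sub("distance from ", "", pname), " to ")[[1]][1]
        if (src %in% colnames(f_src))
          sqrt(noise_correlation) * f_src[, src] +
            sqrt(1 - noise_correlation) * eps
        else eps
      } else {
        sqrt(noise_correlation) * f_dens + sqrt(1 - noise_correlation) * eps
      }
      if (startsWith(pname, "distance")) z
      else if (startsWith(pname, "area")) exp(log(5) + 0.5 * z)
      else exp(log(100) + 1 * z)
    })
    colnames(X) <- parameters
    ## hazard acts on standardized values; log scale for the log-normal
    ## columns (areas, densities), where prognostic effects are log-linear
    Z <- sapply(parameters, function(pname) {
      v <- X[, pname]
      if (!startsWith(pname, "distance")) v <- log(v)
      as.vector(scale(v))
    })
    lp <- rep(0, n_patients)
    for (pname in names(planted))
      lp <- lp + log(planted[[pname]]) * Z[, pname]
    t_event <- stats::rexp(n_patients, rate = baseline_hazard * exp(lp))
    if (length(follow_up) == 1L) follow_up <- c(follow_up, follow_up)
    t_cens <- stats::runif(n_patients, follow_up[1], follow_up[2])
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (all(event == 0))
      warning("all survival times censored; consider regenerating with a ",
              "different seed or higher baseline hazard")
    if (missing_rate > 0) {
      for (pname in setdiff(parameters, names(planted))) {
        if (!startsWith(pname, "distance")) next
        drop <- stats::runif(n_patients) < missing_rate
        X[drop, pname] <- NA_real_
      }
    }
    ids <- sprintf("P%03d", seq_len(n_patients))
    params <- data.frame(patient_id = ids, X, check.names = FALSE,
                         stringsAsFactors = FALSE)
    list(parameters = params,
         survival = data.frame(patient_id = ids, time = time, event = event,
                               stringsAsFactors = FALSE),
         planted = planted)
  })
}
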