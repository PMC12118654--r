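## Orchestration: the full per-image workflow (steps ii-vi), cohort batch
## processing from a manifest, and the driver that reproduces the published
## per-patient analysis when the supplementary tables are available locally.

#' Run the full analysis workflow on one image
#'
#' Executes foreground detection, compartment segmentation, nucleus
#' detection, Voronoi cell tessellation, intensity measurement, gating,
#' phenotype annotation, compartment assignment and spatial quantification,
#' in order. All intermediates are returned; a structured provenance record
#' (settings used, seed, package version) is attached.
#'
#' @param image a `multiplex_image` containing at least a DAPI channel.
#' @param settings an `analysis_settings`.
#' @param detector optional plugin nucleus detector (see [detect_nuclei()]).
#' @param nucleus_params builtin detector overrides.
#' @param distance_scopes compartments for distance statistics.
#' @param seed RNG seed for the permutation z-scores.
#' @return list of class `image_result`: foreground, compartments,
#'   nuclei, cell_labels, cells, quant.
#' @export
run_image <- function(image, settings, detector = NULL,
                      nucleus_params = list(), distance_scopes = "all",
                      seed = 1) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!"DAPI" %in% names(image$channels))
    stop("image ", image$image_id, ": missing DAPI channel")
  if (!"CK" %in% names(image$channels))
    stop("image ", image$image_id, ": missing CK channel")
  corrected <- background_corrected_channels(image, settings)
  fg <- detect_foreground(image, settings, corrected)
  comp <- segment_compartments(image$channels$CK, settings, fg)
  det <- detect_nuclei(image$channels$DAPI,
                       method = settings$nucleus_detector,
                       params = nucleus_params, detector = detector)
  labels <- if (nrow(det$nuclei)) voronoi_cells(det$nuclei, fg)
  else matrix(0L, image$height, image$width)
  cells <- build_cell_table(det$nuclei, labels, image, settings, comp,
                            corrected)
  quant <- .with_seed(seed,
                      quantify_image(cells, comp, settings,
                                     region = image$region,
                                     distance_scopes = distance_scopes))
  structure(list(foreground = fg, compartments = comp, nuclei = det$nuclei,
                 cell_labels = labels, cells = cells, quant = quant,
                 provenance = list(settings = unclass(settings), seed = seed,
                                   image_id = image$image_id,
                                   package_version =
                                     as.character(utils::packageVersion("tmequant")))),
            class = "image_result")
}

#' Read a cohort manifest
#'
#' CSV with columns `patient_id`, `path`, `region` and optionally
#' `settings_override` (per-image settings JSON applied on top of the cohort
#' settings).
#'
#' @param path manifest CSV.
#' @return data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "path", "region")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  bad <- !m$region %in% c("border", "center")
  if (any(bad)) stop("manifest regions must be 'border' or 'center'")
  m
}

#' Run the workflow over a cohort of images
#'
#' Processes every manifest row with [run_image()], aggregates image
#' quantifications into a per-patient parameter table, and joins survival
#' records. Failed images are collected in a failure report instead of being
#' dropped silently; the result is invariant to manifest row order.
#'
#' @param manifest data frame as from [read_manifest()], or rows of
#'   `(patient_id, image, region)` where `image` is a `multiplex_image` in a
#'   list-column — or a plain list of `multiplex_image`s with patient/region
#'   tags taken from the images themselves.
#' @param settings cohort-level `analysis_settings`.
#' @param survival optional data frame (patient_id, time, event) joined to
#'   the parameter table.
#' @param channel_map named page map used when loading image files.
#' @param seed base RNG seed; each image uses a sub-seed derived from it.
#' @param ... passed to [run_image()].
#' @return list of class `cohort_result`: `parameters` (patient x parameter
#'   data frame, survival joined when given), `quants`, `failures`.
#' @export
run_cohort <- function(manifest, settings, survival = NULL,
                       channel_map = NULL, seed = 1, ...) {
  images <- list(); pids <- character(0); regions <- character(0)
  if (is.data.frame(manifest)) {
    ord <- order(manifest$patient_id, manifest$path)
    manifest <- manifest[ord, , drop = FALSE]
    for (i in seq_len(nrow(manifest))) {
      images[[i]] <- manifest$path[i]
      pids[i] <- manifest$patient_id[i]
      regions[i] <- manifest$region[i]
    }
  } else {
    ord <- order(vapply(manifest, function(im) paste(im$patient_id, im$image_id), ""))
    manifest <- manifest[ord]
    images <- manifest
    pids <- vapply(manifest, function(im) im$patient_id, "")
    regions <- vapply(manifest, function(im) im$region, "")
  }
  quants <- list(); qpids <- character(0)
  failures <- list()
  for (i in seq_along(images)) {
    res <- tryCatch({
      img <- images[[i]]
      if (is.character(img)) {
        if (is.null(channel_map)) stop("channel_map required for file input")
        img <- load_multiplex_image(img, channel_map,
                                    settings$microns_per_pixel,
                                    patient_id = pids[i], region = regions[i])
      }
      run_image(img, settings, seed = seed + i, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(patient_id = pids[i], index = i,
                   error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      quants[[length(quants) + 1L]] <- res$quant
      qpids[length(qpids) + 1L] <- pids[i]
    }
  }
  params <- if (length(quants))
    aggregate_patients(quants, qpids, regions = unique(regions)) else NULL
  if (!is.null(params) && !is.null(survival))
    params <- merge(params, survival, by = "patient_id", all.x = TRUE,
                    sort = TRUE)
  structure(list(parameters = params, quants = quants,
                 failures = if (length(failures)) do.call(rbind, failures)
                 else NULL),
            class = "cohort_result")
}

#' Reproduce the published per-patient cohort analysis
#'
#' Runs the complete ranking + final-classifier + evaluation workflow on
#' externally supplied per-patient parameter and survival tables (the
#' processed supplementary data of the original study, converted to CSV).
#' Expects in `dir`: `discovery_parameters.csv` (patient_id + the
#' 50-parameter center shortlist), `discovery_survival.csv` (patient_id,
#' time, event), and optionally `validation_parameters.csv` /
#' `validation_survival.csv`. Errors when the tables are absent — they are
#' an optional external input, not shipped with the package.
#'
#' @param dir directory holding the CSV tables.
#' @param outer_reps,inner_reps,n_top,seed workflow controls.
#' @return list: ranking, model, discovery evaluation, and (when validation
#'   tables are present) validation evaluation and sensitivity/specificity.
#' @export
reproduce_cohort_analysis <- function(dir, outer_reps = 1000,
                                      inner_reps = 1000, n_top = 10,
                                      seed = 1) {
  fp <- function(f) file.path(dir, f)
  if (!file.exists(fp("discovery_parameters.csv")) ||
      !file.exists(fp("discovery_survival.csv")))
    stop("supplementary per-patient tables not found under ", dir,
         "; place discovery_parameters.csv and discovery_survival.csv there")
  par_d <- utils::read.csv(fp("discovery_parameters.csv"), check.names = FALSE)
  sur_d <- utils::read.csv(fp("discovery_survival.csv"))
  sur_d <- sur_d[match(par_d$patient_id, sur_d$patient_id), ]
  rk <- rank_parameters(par_d, sur_d$time, sur_d$event,
                        outer_reps = outer_reps, inner_reps = inner_reps,
                        seed = seed)
  top <- names(sort(rk$hits, decreasing = TRUE))[seq_len(n_top)]
  model <- build_final_classifier(par_d, sur_d$time, sur_d$event, top,
                                  reps = inner_reps, seed = seed + 1)
  out <- list(ranking = rk, model = model,
              discovery = evaluate_classifier(model, par_d, sur_d$time,
                                              sur_d$event))
  if (file.exists(fp("validation_parameters.csv")) &&
      file.exists(fp("validation_survival.csv"))) {
    par_v <- utils::read.csv(fp("validation_parameters.csv"),
                             check.names = FALSE)
    sur_v <- utils::read.csv(fp("validation_survival.csv"))
    sur_v <- sur_v[match(par_v$patient_id, sur_v$patient_id), ]
    out$validation <- evaluate_classifier(model, par_v, sur_v$time,
                                          sur_v$event)
    out$validation_sens_spec <-
      sensitivity_specificity(model, par_v, sur_v$time, sur_v$event)
  }
  out
}
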