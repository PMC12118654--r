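# Image/settings/table persistence: round trips and the instrument presets.

test_that("TIFF stacks round-trip bit-identically, float and integer", {
  set.seed(1)
  pages <- list(matrix(runif(64 * 48), 64, 48),
                matrix(rexp(64 * 48), 64, 48))
  ## float32 storage: quantize to float precision before comparing
  path <- tempfile(fileext = ".tiff")
  write_tiff_stack(pages, path, format = "float")
  back <- read_tiff_stack(path)
  expect_length(back, 2)
  for (k in 1:2) {
    f32 <- readBin(writeBin(as.vector(t(pages[[k]])), raw(), size = 4L),
                   "double", n = 64 * 48, size = 4L)
    expect_identical(as.vector(t(back[[k]])), f32)
  }

  lab <- matrix(0L, 8, 8); lab[2:3, 2:4] <- 1L; lab[6:7, 6:8] <- 2L
  p2 <- tempfile(fileext = ".tiff")
  export_label_mask(lab, p2)
  expect_identical(import_label_mask(p2), lab)

  zero <- matrix(0L, 5, 7)
  p3 <- tempfile(fileext = ".tiff")
  export_label_mask(zero, p3)
  expect_identical(import_label_mask(p3), zero)
})

test_that("label masks switch to 32-bit when labels exceed 16-bit range", {
  big <- matrix(c(0L, 70000L, 1L, 65535L), 2, 2)
  path <- tempfile(fileext = ".tiff")
  export_label_mask(big, path)
  expect_identical(import_label_mask(path), big)
  expect_error(export_label_mask(matrix(-1L, 2, 2), tempfile()), "nonnegative")
})

test_that("tifffile (Python) reads our TIFF and we read its output", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(2)
  m <- matrix(runif(32 * 20), 32, 20)
  ours <- tempfile(fileext = ".tiff")
  theirs <- tempfile(fileext = ".tiff")
  write_tiff_stack(list(m), ours, format = "float")
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread(%s)\n",
    "assert a.shape == (32, 20), a.shape\n",
    "tifffile.imwrite(%s, a.astype(np.float32))\n",
    "np.save(%s, a)\n"),
    shQuote(ours), shQuote(theirs), shQuote(paste0(theirs, ".npy")))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(theirs), paste("tifffile unavailable:", paste(res, collapse = " ")))
  back <- read_tiff_stack(theirs)[[1]]
  f32 <- readBin(writeBin(as.vector(t(m)), raw(), size = 4L),
                 "double", n = length(m), size = 4L)
  expect_equal(as.vector(t(back)), f32)
})

test_that("multiplex images load from multi-page TIFF with a channel map", {
  set.seed(3)
  chans <- list(DAPI = matrix(runif(64 * 64), 64, 64),
                CK = matrix(runif(64 * 64), 64, 64))
  path <- tempfile(fileext = ".tiff")
  write_tiff_stack(chans, path, format = "float")
  img <- load_multiplex_image(path, c(DAPI = 0L, CK = 1L),
                              microns_per_pixel = 0.5, region = "border")
  expect_s3_class(img, "multiplex_image")
  expect_named(img$channels, c("DAPI", "CK"))
  expect_equal(img$height, 64)
  ## loading never rescales: sums survive the round trip (float32 precision)
  expect_equal(sum(img$channels$DAPI), sum(chans$DAPI), tolerance = 1e-6)
  expect_error(load_multiplex_image(path, c(DAPI = 0L, CK = 9L), 0.5),
               "channel-map mismatch")
})

test_that("multiplex_image validates geometry and metadata", {
  a <- matrix(0, 4, 4)
  expect_error(multiplex_image(list(DAPI = a, CK = matrix(0, 5, 4)), 0.5),
               "same height")
  expect_error(multiplex_image(list(a, a), 0.5), "marker names")
  expect_error(multiplex_image(list(DAPI = a), 0), "microns_per_pixel")
})

test_that("settings presets carry the published parameter dialects", {
  s <- analysis_settings("mxif")
  expect_equal(s$foreground_threshold, 0.1)
  expect_equal(s$bg_filter_size_px, 1000L)
  expect_equal(s$artifact_min_area_px, 5000L)
  expect_equal(s$ck_gaussian_size_px, 10L)
  expect_equal(s$ck_threshold, 1.0)
  expect_equal(s$marker_thresholds,
               c(CK = 0.1, CD3 = 0.3, CD8 = 0.4, CD20 = 0.7, CD56 = 0.7,
                 CD68 = 1.0))
  m <- analysis_settings("mibi")
  expect_equal(m$foreground_threshold, 0)
  expect_equal(m$artifact_min_area_px, 250L)
  expect_equal(m$ck_threshold, 0.5)
  expect_true(all(m$marker_thresholds == 0))
  expect_error(analysis_settings("vectra"), "unknown preset")
})

test_that("settings save/load is a field-for-field round trip", {
  s <- analysis_settings("mxif", foreground_threshold = 0.25,
                         zscore_reps = 123L, microns_per_pixel = 0.325)
  path <- tempfile(fileext = ".json")
  save_settings(s, path)
  expect_equal(load_settings(path), s)
  ## schema violations are rejected
  bad <- jsonlite::read_json(path)
  bad$schema_version <- 99
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_settings(path), "schema-version")
  bad$schema_version <- 1
  bad$unknown_knob <- 5
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_settings(path), "unknown settings key")
})

test_that("cell tables round-trip exactly through CSV", {
  g <- generate_tissue_image(n_nuclei = 20, height = 96, width = 96,
                             tumor_islands = 1, tumor_island_radius = 25,
                             seed = 4)
  s <- small_settings()
  res <- run_image(g$image, s, seed = 1)
  expect_gt(nrow(res$cells), 0)
  path <- tempfile(fileext = ".csv")
  export_cell_table(res$cells, path)
  back <- import_cell_table(path)
  expect_equal(nrow(back), nrow(res$cells))
  for (cn in names(res$cells)) {
    expect_equal(back[[cn]], res$cells[[cn]], info = cn)
  }
  ## empty table -> header-only CSV
  p0 <- tempfile(fileext = ".csv")
  export_cell_table(res$cells[0, ], p0)
  expect_equal(nrow(import_cell_table(p0)), 0)
  expect_equal(length(readLines(p0)), 1L)
})
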