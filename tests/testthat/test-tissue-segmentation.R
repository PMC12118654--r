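# Background correction, foreground detection and compartment segmentation.

test_that("background correction equals the brute-force windowed mean oracle", {
  expect_equal(background_correct(matrix(7, 9, 9), 5), matrix(0, 9, 9))
  ## spec'd instance: single bright pixel, window covering the whole raster
  m <- matrix(0, 8, 8); m[4, 4] <- 64
  bc <- background_correct(m, 8)
  expect_equal(bc[4, 4], 64 - 1)
  set.seed(11)
  for (k in 1:8) {
    nr <- sample(3:16, 1); nc <- sample(3:16, 1)
    size <- sample(1:9, 1)
    x <- matrix(rnorm(nr * nc), nr, nc)
    expect_equal(background_correct(x, size), x - brute_uniform_mean(x, size),
                 tolerance = 1e-10)
  }
  ## linear ramp: interior of the corrected image is ~0
  ramp <- matrix(rep(1:16, each = 16), 16, 16)
  bc2 <- background_correct(ramp, 3)
  expect_equal(bc2[2:15, 2:15], matrix(0, 14, 14))
  expect_error(background_correct(ramp, 0), "filter size")
})

test_that("gap filling flips small regions of either polarity, strictly", {
  base <- matrix(TRUE, 30, 30)
  base[1:5, 25:30] <- FALSE          # large background corner (>= threshold)
  hole <- base
  hole[15:16, 15:19] <- FALSE        # 10-px hole
  filled <- fill_small_regions(hole, 50)
  expect_true(all(filled[15:16, 15:19]))
  ## a component of exactly min_area_px survives (strict "<")
  keep <- matrix(FALSE, 20, 20)
  keep[3:6, 3:7] <- TRUE             # 20 px island
  expect_identical(fill_small_regions(keep, 20), keep)
  expect_false(any(fill_small_regions(keep, 21)))
  ## idempotence and identity on clean masks
  expect_identical(fill_small_regions(filled, 50), filled)
  expect_identical(fill_small_regions(base, 10), base)
})

test_that("foreground is strict-threshold on corrected channels", {
  s <- small_settings()
  flat <- multiplex_image(list(DAPI = matrix(2, 40, 40),
                               CK = matrix(5, 40, 40)), 0.5)
  expect_false(any(detect_foreground(flat, s)))  # corrected == 0, not > 0.1
  ## corrected value exactly at the threshold stays background
  one <- matrix(0, 40, 40)
  img <- multiplex_image(list(DAPI = one), 0.5)
  corr <- list(DAPI = matrix(s$foreground_threshold, 40, 40))
  expect_false(any(detect_foreground(img, s, corrected = corr)))
  corr2 <- list(DAPI = matrix(s$foreground_threshold + 1e-9, 40, 40))
  expect_true(all(detect_foreground(img, s, corrected = corr2)))
})

test_that("foreground recovers the synthetic tissue blob (IoU > 0.9)", {
  g <- generate_tissue_image(seed = 21)
  s <- analysis_settings("mxif", compartment_min_area_px = 1000L,
                         zscore_reps = 50L)
  fg <- detect_foreground(g$image, s)
  tm <- g$truth$tissue_mask
  expect_gt(sum(fg & tm) / sum(fg | tm), 0.9)
})

test_that("compartments: CK-negative tissue is stroma; partition holds", {
  s <- small_settings()
  set.seed(22)
  fg <- matrix(FALSE, 50, 50); fg[5:45, 5:45] <- TRUE
  comp <- segment_compartments(matrix(0, 50, 50), s, fg)
  expect_true(all(comp[fg] == 1L))
  expect_true(all(comp[!fg] == 0L))
  expect_equal(sum(comp == 0) + sum(comp == 1) + sum(comp == 2), 2500)
})

test_that("a CK-high region below the minimum area is reassigned to stroma", {
  s <- small_settings(compartment_min_area_px = 5000L, bg_filter_size_px = 200L)
  fg <- matrix(TRUE, 100, 100)
  ck <- matrix(0, 100, 100)
  ck[30:65, 30:65] <- 10               # ~1300 px after blur/threshold, < 5000
  comp <- segment_compartments(ck, s, fg)
  expect_equal(sum(comp == 2L), 0)
  expect_true(all(comp == 1L))
  ## with a permissive minimum the same region is tumor
  s2 <- small_settings(compartment_min_area_px = 100L, bg_filter_size_px = 200L)
  comp2 <- segment_compartments(ck, s2, fg)
  expect_gt(sum(comp2 == 2L), 900)
})

test_that("synthetic tumor island is recovered (IoU > 0.85)", {
  g <- generate_tissue_image(tumor_islands = 1, tumor_island_radius = 80,
                             n_nuclei = 100, seed = 23)
  s <- analysis_settings("mxif", compartment_min_area_px = 1000L,
                         zscore_reps = 50L)
  fg <- detect_foreground(g$image, s)
  comp <- segment_compartments(g$image$channels$CK, s, fg)
  tum <- comp == 2L
  expect_gt(sum(tum & g$truth$tumor_mask) / sum(tum | g$truth$tumor_mask), 0.85)
})

test_that("raising the CK threshold never increases tumor area", {
  g <- generate_tissue_image(seed = 24)
  s0 <- analysis_settings("mxif", compartment_min_area_px = 500L,
                          zscore_reps = 50L)
  fg <- detect_foreground(g$image, s0)
  areas <- vapply(c(0.5, 1, 1.5, 2.5), function(thr) {
    s <- analysis_settings("mxif", ck_threshold = thr,
                           compartment_min_area_px = 500L, zscore_reps = 50L)
    sum(segment_compartments(g$image$channels$CK, s, fg) == 2L)
  }, 0)
  expect_true(all(diff(areas) <= 0))
})
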