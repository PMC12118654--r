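# Densities, nearest-neighbor distances, permutation z-scores, aggregation
# and the inflammation rule.

test_that("mean NN distance: closed-form cases and the all-pairs oracle", {
  expect_equal(mean_nn_distance(cbind(0, 0), cbind(3, 4), 1), 5)   # 3-4-5
  expect_equal(mean_nn_distance(cbind(c(0, 1), c(0, 0)),
                                cbind(c(0, 1), c(0, 0)), 1), 1)    # self
  expect_equal(mean_nn_distance(cbind(0, 0), cbind(3, 4), 2), 10)  # um scaling
  set.seed(51)
  for (k in 1:5) {
    a <- cbind(runif(30, 0, 50), runif(30, 0, 50))
    b <- cbind(runif(20, 0, 50), runif(20, 0, 50))
    expect_equal(mean_nn_distance(a, b, 1), brute_nn_mean(a, b))
    expect_equal(mean_nn_distance(b, a, 1), brute_nn_mean(b, a))
  }
  ## direction matters: A->B need not equal B->A
  a <- cbind(c(0, 100), c(0, 0)); b <- cbind(c(0, 1, 2), c(1, 1, 1))
  expect_false(isTRUE(all.equal(mean_nn_distance(a, b, 1),
                                mean_nn_distance(b, a, 1))))
  ## all-coincident points: no valid non-zero pair -> missing
  expect_true(is.na(mean_nn_distance(cbind(1, 1), cbind(1, 1), 1)))
})

test_that("distance z-score is deterministic by seed and flags degeneracy", {
  set.seed(52)
  pts <- cbind(runif(60, 0, 100), runif(60, 0, 100))
  obs <- mean_nn_distance(pts[1:15, ], pts[16:40, ], 1)
  set.seed(7); z1 <- distance_zscore(obs, pts, 15, 25, reps = 300)
  set.seed(7); z2 <- distance_zscore(obs, pts, 15, 25, reps = 300)
  expect_identical(z1, z2)
  expect_false(z1$degenerate)
  ## source phenotype == every cell in scope -> all repetitions identical
  zd <- distance_zscore(mean_nn_distance(pts, pts, 1), pts, 60, 60,
                        self = TRUE, reps = 50)
  expect_true(zd$degenerate)
  expect_true(is.na(zd$z))
  expect_error(distance_zscore(1, pts, 0, 5), "must be >= 1")
  expect_error(distance_zscore(1, pts, 61, 5), "at least")
})

test_that("quantify_image computes areas, counts and densities per scope", {
  ## hand-built cell table: 10 CD8 cells in stroma; compartments 2 mm2 stroma
  s <- small_settings(microns_per_pixel = 10)   # 1 px = 100 um2
  comp <- matrix(1L, 200, 100)                  # 20000 px = 2 mm2 stroma
  cells <- data.frame(image_id = "t", cell_id = 1:10,
                      centroid_row = seq(5, 95, 10), centroid_col = 50,
                      compartment = "stroma")
  for (p in tme_phenotypes()) cells[[paste0("pheno_", p)]] <- p == "CD8"
  q <- quantify_image(cells, comp, s, region = "center",
                      distance_scopes = character(0))
  expect_equal(q$areas$area_mm2[q$areas$compartment == "Stroma"], 2)
  cd8 <- q$counts[q$counts$phenotype == "CD8", ]
  expect_equal(cd8$count[cd8$compartment == "Stroma"], 10L)
  expect_equal(cd8$density[cd8$compartment == "Stroma"], 5)
  ## empty compartment: count 0, density missing, no division error
  expect_equal(cd8$count[cd8$compartment == "Tumor"], 0L)
  expect_true(is.na(cd8$density[cd8$compartment == "Tumor"]))
  ## compartment counts sum to the whole-tissue count per phenotype
  for (p in tme_phenotypes()) {
    pc <- q$counts[q$counts$phenotype == p, ]
    expect_equal(pc$count[pc$compartment == "all"],
                 pc$count[pc$compartment == "Tumor"] +
                   pc$count[pc$compartment == "Stroma"])
  }
})

test_that("patient aggregation pools counts/areas and averages z-scores", {
  mkq <- function(count, area_mm2, z, region = "center") {
    areas <- data.frame(compartment = c("Tumor", "Stroma", "all"),
                        area_px = c(0, area_mm2 * 1e4, area_mm2 * 1e4),
                        area_mm2 = c(0, area_mm2, area_mm2))
    counts <- do.call(rbind, lapply(c("Tumor", "Stroma", "all"), function(sc)
      data.frame(phenotype = tme_phenotypes(), compartment = sc,
                 count = ifelse(tme_phenotypes() == "CD8" & sc != "Tumor",
                                count, 0L),
                 density = NA_real_)))
    dists <- expand.grid(source = tme_phenotypes(), target = tme_phenotypes(),
                         stringsAsFactors = FALSE)
    dists$compartment <- "all"
    dists$z <- ifelse(dists$source == "CD8" & dists$target == "CD8", z,
                      NA_real_)
    structure(list(image_id = "x", region = region, areas = areas,
                   counts = counts, distances = dists),
              class = "region_quant")
  }
  ## two images: 2 cells / 1 mm2 and 0 cells / 1 mm2 -> pooled 1 cell/mm2
  tab <- aggregate_patients(list(mkq(2L, 1, 1.5), mkq(0L, 1, NA)),
                            c("P1", "P1"), regions = "center")
  expect_equal(tab[["density of CD8 in Stroma in center"]], 1)
  ## defined z + degenerate z -> the defined value
  expect_equal(tab[["distance from CD8 to CD8 in center"]], 1.5)
  ## pooled density differs from mean-of-densities under unequal areas
  tab2 <- aggregate_patients(list(mkq(4L, 1, NA), mkq(0L, 3, NA)),
                             c("P1", "P1"), regions = "center")
  expect_equal(tab2[["density of CD8 in Stroma in center"]], 1)  # not (4+0)/2
  ## a region with no images yields no columns (missing stays missing)
  expect_null(tab[["density of CD8 in Stroma in border"]])
})

test_that("center shortlist has exactly 50 uniquely named parameters", {
  sl <- center_shortlist()
  expect_length(sl, 50L)
  expect_equal(anyDuplicated(sl), 0L)
  expect_equal(sum(startsWith(sl, "area")), 2L)
  expect_equal(sum(startsWith(sl, "density")), 12L)
  expect_equal(sum(startsWith(sl, "distance")), 36L)
  expect_true("distance from CK to CK in center" %in% sl)
  expect_true("density of CD8 in Tumor in center" %in% sl)
})

test_that("inflammation rule: density and border/center ratio criteria", {
  expect_equal(classify_inflammation(250, 50), "inflamed")      # ratio 5
  expect_equal(classify_inflammation(150, 100), "non_inflamed") # density fails
  expect_equal(classify_inflammation(500, 10), "non_inflamed")  # ratio 50
  expect_equal(classify_inflammation(201, 21), "inflamed")
  expect_equal(classify_inflammation(300, 0), "non_inflamed")   # infinite ratio
  expect_error(classify_inflammation(NA, 10), "border density")
})
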