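# Shared fixtures: settings scaled to small test rasters, and a tiny
# survival data set used across the survival tests.

small_settings <- function(...) {
  analysis_settings("mxif", bg_filter_size_px = 64L, artifact_min_area_px = 50L,
                    ck_gaussian_size_px = 2L, compartment_min_area_px = 100L,
                    zscore_reps = 200L, ...)
}

# brute-force sliding-window mean with replicate padding (oracle for the
# uniform filter / background correction)
brute_uniform_mean <- function(x, size) {
  lo <- (size - 1) %/% 2
  hi <- size - 1 - lo
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- pmin(pmax((i - lo):(i + hi), 1), nr)
    ci <- pmin(pmax((j - lo):(j + hi), 1), nc)
    out[i, j] <- mean(x[ri, ci])
  }
  out
}

# brute-force nearest-seed labels (oracle for voronoi_cells)
brute_voronoi <- function(seeds, fg) {
  out <- matrix(0L, nrow(fg), ncol(fg))
  for (i in seq_len(nrow(fg))) for (j in seq_len(ncol(fg))) {
    if (!fg[i, j]) next
    d2 <- (i - 1 - seeds$row)^2 + (j - 1 - seeds$col)^2
    out[i, j] <- which.min(d2)   # which.min takes the first (lowest index) tie
  }
  out
}

# brute-force mean nearest-neighbor distance (oracle for mean_nn_distance)
brute_nn_mean <- function(src, tgt) {
  mins <- apply(src, 1, function(p) {
    d <- sqrt((p[1] - tgt[, 1])^2 + (p[2] - tgt[, 2])^2)
    d <- d[d > 0]
    if (length(d)) min(d) else NA_real_
  })
  mean(mins, na.rm = TRUE)
}

# six-subject survival fixture with hand-computed product-limit estimates
km_fixture <- function() {
  list(time = c(1, 2, 3, 4, 5, 6), event = c(1L, 0L, 1L, 1L, 0L, 1L),
       # S(1)=5/6; t=2 censored; S(3)=5/6*3/4; S(4)=...*2/3; t=5 censored;
       # S(6)=...*0/1
       surv = c(5 / 6, 5 / 6, 5 / 8, 5 / 12, 5 / 12, 0))
}
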