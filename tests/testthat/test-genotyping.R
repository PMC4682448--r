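test_that("inter-lane correlation matches its definition and locates shifts", {
  set.seed(6)
  b1 <- stats::runif(50, 0, 100)
  bj <- stats::runif(50, 0, 100)
  for (k in c(-9, 0, 4)) {
    expect_equal(interlane_correlation(b1, bj, k), oracle_xcorr(b1, bj, k))
  }
  expect_equal(interlane_correlation(b1, rep(0, 50), 3), 0)
  # identical profiles peak at k = 0; a shifted copy peaks at the shift
  prof <- 100 * exp(-((1:80) - 30)^2 / 6)
  ks <- -15:15
  self <- vapply(ks, function(k) interlane_correlation(prof, prof, k),
                 numeric(1))
  expect_equal(ks[which.max(self)], 0)
  for (s in c(-7, 5)) {
    moved <- 100 * exp(-((1:80) - 30 - s)^2 / 6)
    cc <- vapply(ks, function(k) interlane_correlation(prof, moved, k),
                 numeric(1))
    expect_equal(ks[which.max(cc)], -s)
  }
})

test_that("lane alignment recovers whole-lane offsets and anchors offsets at 0", {
  g <- generate_gel(gel_spec(lane_offset_max = 5, band_jitter_sd = 0,
                             noise_sd = 2, seed = 17))
  f <- extract_gel_features(g$image)
  al <- align_lanes(f$profiles, f$bands, ref_spec(60, 8))
  expect_equal(nrow(al), 12)
  expect_true(all(al$reference_found))
  # global shift compensates the generated per-lane offset (relative to
  # the anchor lane's own offset), within a pixel
  rel <- g$truth$lane_offsets[1] - g$truth$lane_offsets
  expect_true(all(abs(al$global_shift + al$local_shift - rel) <= 1))
  off <- band_offsets(f$bands, al)
  # reference anchoring: every lane has exactly one band at offset 0
  zero_per_lane <- tapply(off$offset == 0, off$lane_index, sum)
  expect_true(all(zero_per_lane == 1))
  # same species across lanes stays within a tight offset window
  spread <- tapply(off$offset[off$offset > 30],
                   round(off$offset[off$offset > 30] / 50),
                   function(v) diff(range(v)))
  expect_true(all(spread <= 4))
})

test_that("alignment requires the reference band and reports missing lanes", {
  g <- generate_gel(gel_spec(seed = 23))
  f <- extract_gel_features(g$image)
  # remove the reference band from lane 3's call table
  f$bands[[3]] <- f$bands[[3]][f$bands[[3]]$position > 100, ]
  expect_message(al <- align_lanes(f$profiles, f$bands, ref_spec(60, 8)),
                 "excluded")
  expect_false(al$reference_found[3])
  expect_true(all(al$reference_found[-3]))
  # with fewer than two lanes holding the reference, genotyping aborts
  few <- lapply(f$bands, function(b) b[b$position > 100, ])
  expect_error(align_lanes(f$profiles, few, ref_spec(60, 8)),
               "fewer than 2 lanes")
})

test_that("1-D DBSCAN equals the brute-force oracle across sweeps", {
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(1:30, 1)
    x <- round(stats::runif(n, 0, 60), 1)
    eps <- sample(c(1, 2, 4, 8), 1)
    minpts <- sample(2:5, 1)
    expect_identical(dbscan_1d(x, eps, minpts), oracle_dbscan(x, eps, minpts))
  }
})

test_that("DBSCAN basics: clusters, noise, degenerate variance floor", {
  off <- data.frame(lane_index = rep(1:10, 2),
                    position = 0,
                    offset = c(rep(0, 10), 40 + rep(c(-1, 0, 1), length.out = 10)))
  m <- cluster_bands(off, n_lanes = 10, eps = 3, minpts = 2)
  expect_equal(nrow(m$clusters), 2)
  expect_equal(m$clusters$mean[1], 0)
  expect_equal(m$clusters$mean[2], 40, tolerance = 0.05)
  expect_true(m$clusters$is_reference[1])
  expect_false(m$clusters$is_reference[2])
  expect_true(all(diff(m$clusters$mean) > 0))
  # a repeated single offset: one cluster with floored variance
  one <- data.frame(lane_index = 1:6, position = 0, offset = rep(0, 6))
  m1 <- cluster_bands(one, n_lanes = 6, eps = 2, minpts = 2)
  expect_equal(m1$clusters$variance, 0.25)
  # an isolated offset is noise, not a cluster
  iso <- data.frame(lane_index = c(1:6, 7), position = 0,
                    offset = c(rep(0, 6), 50))
  mi <- cluster_bands(iso, n_lanes = 12, eps = 2, minpts = 2)
  expect_equal(nrow(mi$clusters), 1)
  expect_equal(mi$noise, 50)
  # no cluster containing 0 is an error
  bad <- data.frame(lane_index = 1:6, position = 0, offset = rep(30, 6))
  expect_error(cluster_bands(bad, n_lanes = 6, eps = 2, minpts = 2),
               "reference cluster")
})

test_that("Gaussian classification picks the maximum-likelihood cluster", {
  m <- structure(list(clusters = data.frame(
    cluster_id = c(1L, 2L, 3L), mean = c(0, 30, 60),
    variance = c(1, 1, 16), count = c(10L, 10L, 10L),
    is_reference = c(TRUE, FALSE, FALSE)),
    epsilon = 2, minpts = 2L, noise = numeric(0), provenance = character(0)),
    class = "cluster_model")
  expect_equal(classify_band(c(0, 30, 60), m), c(1L, 2L, 3L))
  # equidistant between two equal-variance clusters: the smaller mean wins
  m2 <- m
  m2$clusters <- m$clusters[1:2, ]
  expect_equal(classify_band(15, m2, max_z = Inf), 1L)
  # far from everything: novel
  expect_true(is.na(classify_band(150, m)))
  # mixed variances: agree with a brute-force density evaluation
  for (o in seq(30, 60, by = 1.5)) {
    dens <- stats::dnorm(o, m$clusters$mean, sqrt(m$clusters$variance))
    want <- m$clusters$cluster_id[which.max(dens)]
    expect_equal(classify_band(o, m, max_z = Inf), want)
  }
})

test_that("genotype calls group lanes by banding pattern", {
  g <- generate_gel(gel_spec(seed = 41))
  f <- extract_gel_features(g$image)
  r <- genotype_gels(f, ref_spec(60, 8))
  calls <- r$genotypes[[1]]$calls
  expect_equal(length(unique(calls$group_id)), 3)
  expect_equal(calls$group_id, g$truth$genotype_groups)
  # identical patterns <=> identical groups
  expect_equal(length(unique(calls$pattern)), length(unique(calls$group_id)))
  # a lane with only the reference band has an all-zero pattern
  off <- band_offsets(f$bands, r$alignments[[1]])
  only_ref <- off[off$offset == 0 & off$lane_index == 1, ]
  fake_off <- rbind(only_ref, off[off$lane_index != 1, ])
  cg <- call_genotypes(fake_off, r$model, r$alignments[[1]])
  expect_equal(cg$calls$pattern[1], "000")
})

test_that("lane order permutation only relabels groups", {
  g <- generate_gel(gel_spec(seed = 43))
  f <- extract_gel_features(g$image)
  r <- genotype_gels(f, ref_spec(60, 8))
  base <- r$genotypes[[1]]$calls$pattern
  perm <- c(5:12, 1:4)
  f2 <- list(profiles = f$profiles[perm], bands = f$bands[perm])
  r2 <- genotype_gels(list(c(f2, list(lanes = NULL))), ref_spec(60, 8))
  expect_equal(r2$genotypes[[1]]$calls$pattern, base[perm])
})

test_that("cluster models survive a JSON round-trip and reuse", {
  g <- generate_gel(gel_spec(band_jitter_sd = 1, seed = 45))
  f <- extract_gel_features(g$image)
  r <- genotype_gels(f, ref_spec(60, 8))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(r$model, path)
  m2 <- load_model(path)
  expect_equal(m2$clusters, r$model$clusters, tolerance = 1e-12)
  expect_equal(m2$epsilon, r$model$epsilon)
  offs <- seq(-2, 215, by = 3.7)
  expect_identical(classify_band(offs, m2), classify_band(offs, r$model))
  # truncated file: schema error
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 40), bad)
  expect_error(load_model(bad), "parse|schema")
})
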