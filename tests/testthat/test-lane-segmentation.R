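test_that("row and column profiles sum pixels along the stated axes", {
  img <- gel_image(matrix(1, 3, 4))
  expect_equal(row_profile(img), rep(4, 3))
  strip <- gel_image(matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE))
  expect_equal(column_profile(strip), c(5, 7, 9))
  # single bright row
  px <- matrix(0, 5, 10); px[3, ] <- 255
  expect_equal(row_profile(gel_image(px)), c(0, 0, 2550, 0, 0))
  # conservation over any strip tiling
  set.seed(1)
  rpx <- matrix(sample(0:255, 60 * 30, replace = TRUE), 60, 30)
  rimg <- gel_image(rpx)
  strips <- compute_strips(rimg)
  total <- Reduce(`+`, lapply(seq_len(nrow(strips)), function(i)
    column_profile(rimg, strips$row_start[i], strips$row_end[i])))
  expect_equal(total, colSums(rpx))
  expect_equal(sum(row_profile(rimg)), sum(rpx))
})

test_that("3-point smoothing averages neighbours with edge replication", {
  expect_equal(smooth_profile(rep(7, 5)), rep(7, 5))
  expect_equal(smooth_profile(c(0, 3, 0, 3, 0))[2:4], c(1, 2, 1))
  expect_equal(smooth_profile(c(0, 0, 9, 0, 0)), c(0, 3, 3, 3, 0))
  expect_error(smooth_profile(c(1, 2)), "at least 3")
})

test_that("strips tile the image and split between band regions", {
  # two bright bands at rows 10 and 50 -> cut at the midpoint row 30
  px <- matrix(0, 60, 40)
  px[9:11, ] <- 200; px[49:51, ] <- 200
  s <- compute_strips(gel_image(px))
  expect_equal(nrow(s), 2)
  expect_equal(s$row_end[1], 30)
  expect_equal(s$row_start[2], 31)
  # uniform image falls back to N equal strips tiling [1, H]
  u <- compute_strips(gel_image(matrix(5, 80, 20)), fallback_n = 4)
  expect_equal(nrow(u), 4)
  expect_equal(u$row_start[1], 1)
  expect_equal(u$row_end[4], 80)
  expect_true(all(u$row_start[-1] == u$row_end[-4] + 1))
  # tiling invariant on arbitrary images
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(sample(0:255, 50 * 20, replace = TRUE), 50, 20)
    st <- compute_strips(gel_image(m))
    expect_equal(st$row_start[1], 1)
    expect_equal(st$row_end[nrow(st)], 50)
    if (nrow(st) > 1) expect_true(all(st$row_start[-1] == st$row_end[-nrow(st)] + 1))
    expect_true(all(st$height >= 1))
  }
})

test_that("boundary detection finds prominent minima with spacing filter", {
  W <- 60
  prof <- rep(1000, W)
  prof[18:22] <- c(600, 300, 200, 300, 600)   # deep minimum at 20
  prof[38:42] <- c(600, 300, 200, 300, 600)   # deep minimum at 40
  b <- detect_boundaries(prof, min_lane_width = 5)
  expect_equal(b, c(1L, 20L, 40L, 60L))
  # strictly monotone profile: only the outer boundaries
  expect_equal(detect_boundaries(seq(1, 600, length.out = 50)), c(1L, 50L))
  expect_equal(detect_boundaries(rep(4, 30)), c(1L, 30L))
  # two nearby minima: only the deeper survives the spacing filter
  p2 <- rep(1000, 40)
  p2[20] <- 100
  p2[22] <- 300
  b2 <- detect_boundaries(p2, min_lane_width = 10)
  expect_true(20 %in% b2 && !(22 %in% b2))
})

test_that("boundary detection matches a brute-force minimum scan", {
  set.seed(7)
  for (rep in 1:30) {
    prof <- smooth_profile(stats::runif(60, 0, 1000))
    got <- detect_boundaries(prof, prominence_frac = 0.05,
                             min_lane_width = 4, noise_gate = 0,
                             max_floor_width = Inf)
    # oracle: every local minimum of the profile, prominence-filtered on the
    # inverted profile, greedily thinned by depth with the spacing rule
    y <- max(prof) - prof
    cand <- oracle_peaks(y)
    if (length(cand) > 0) {
      keep <- peak_depth <- vapply(cand, function(p) {
        h <- y[p]; i <- p - 1; lmin <- h
        while (i >= 1 && y[i] <= h) { lmin <- min(lmin, y[i]); i <- i - 1 }
        i <- p + 1; rmin <- h
        while (i <= length(y) && y[i] <= h) { rmin <- min(rmin, y[i]); i <- i + 1 }
        h - max(lmin, rmin)
      }, numeric(1))
      cand <- cand[keep >= 0.05 * (max(prof) - min(prof))]
    }
    acc <- c(1L, 60L)
    for (p in cand[order(-y[cand], cand)]) {
      if (all(abs(p - acc) >= 4)) acc <- c(acc, p)
    }
    expect_equal(got, sort(as.integer(acc)))
  }
})

test_that("stitching joins boundaries by shortest monotone displacement", {
  strips2 <- data.frame(row_start = c(1L, 11L), row_end = c(10L, 20L),
                        height = c(10L, 10L))
  # identical lists -> vertical boundaries
  st <- stitch_boundaries(list(c(1, 10, 30), c(1, 10, 30)), strips2,
                          max_drift = 5, support_frac = 0)
  for (b in st) expect_equal(length(unique(b$cols)), 1)
  # unique monotone matching (10 -> 12), (30 -> 29)
  st2 <- stitch_boundaries(list(c(10, 30), c(12, 29)), strips2,
                           max_drift = 5, support_frac = 0)
  expect_equal(vapply(st2, function(b) b$cols[2:3], numeric(2)),
               matrix(c(10, 12, 30, 29), 2))
  # unmatched boundary propagates vertically
  st3 <- stitch_boundaries(list(c(10, 30), c(11)), strips2,
                           max_drift = 5, support_frac = 0)
  expect_equal(vapply(st3, function(b) b$cols[2:3], numeric(2)),
               matrix(c(10, 11, 30, 30), 2))
})

test_that("monotone matching attains the brute-force optimum cost", {
  set.seed(5)
  for (rep in 1:40) {
    a <- sort(sample(1:60, sample(1:4, 1)))
    b <- sort(sample(1:60, sample(1:4, 1)))
    drift <- sample(3:12, 1)
    pairs <- gelcaller:::monotone_match(a, b, drift)
    cost <- drift * (length(a) + length(b) - 2 * nrow(pairs))
    if (nrow(pairs) > 0) cost <- cost + sum(abs(a[pairs[, 1]] - b[pairs[, 2]]))
    expect_equal(cost, oracle_match_cost(a, b, drift))
    if (nrow(pairs) > 1) {
      expect_true(all(diff(pairs[, 1]) > 0) && all(diff(pairs[, 2]) > 0))
    }
  }
})

test_that("lane extraction between vertical boundaries is the identity", {
  set.seed(2)
  px <- matrix(sample(0:255, 20 * 30, replace = TRUE), 20, 30)
  img <- gel_image(px)
  vb <- function(col) structure(list(rows = c(1, 20), cols = c(col, col)),
                                class = "lane_boundary")
  lanes <- segment_lanes(img, list(vb(1), vb(11)), min_lane_width = 5)
  expect_length(lanes, 1)
  expect_equal(lanes[[1]]$width, 10L)
  expect_equal(lanes[[1]]$pixels, px[, 1:10], ignore_attr = TRUE)
  # five boundaries -> four lanes indexed left to right
  lanes5 <- segment_lanes(img, lapply(c(1, 8, 15, 22, 29), vb),
                          min_lane_width = 5)
  expect_length(lanes5, 4)
  expect_equal(vapply(lanes5, `[[`, integer(1), "index"), 1:4)
})

test_that("converging boundaries resample to the median width", {
  # ramp image: pixel value = column index, boundaries narrow from 12 to 8
  px <- matrix(rep(1:30, 21), 21, 30, byrow = TRUE)
  img <- gel_image(px)
  left <- structure(list(rows = c(1, 21), cols = c(5, 7)),
                    class = "lane_boundary")
  right <- structure(list(rows = c(1, 21), cols = c(17, 15)),
                     class = "lane_boundary")
  lanes <- segment_lanes(img, list(left, right), min_lane_width = 5)
  expect_equal(lanes[[1]]$width, 10L)
  # oracle: nearest-neighbour resample of each row's run
  for (m in c(1, 11, 21)) {
    lcol <- approx(c(1, 21), c(5, 7), m)$y
    rcol <- approx(c(1, 21), c(17, 15), m)$y
    wm <- ceiling(rcol) - ceiling(lcol)
    src <- ceiling(lcol) + floor(((1:10) - 0.5) * wm / 10)
    expect_equal(lanes[[1]]$pixels[m, ], px[m, src])
  }
})

test_that("crossing boundaries are rejected", {
  img <- gel_image(matrix(0, 10, 20))
  b1 <- structure(list(rows = c(1, 10), cols = c(5, 15)),
                  class = "lane_boundary")
  b2 <- structure(list(rows = c(1, 10), cols = c(15, 5)),
                  class = "lane_boundary")
  expect_error(segment_lanes(img, list(b1, b2)), "cross")
})
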