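#' Cumulative row-intensity profile
#'
#' `r(m)`: the sum of pixel intensities across each image row.  Rows holding
#' bands show up as high-contrast excursions; the spacing of those regions
#' drives the dynamic strip heights of [compute_strips()].
#'
#' @param image a bands-bright [gel_image()].
#' @return Numeric vector of length `H` (one sum per row).
#' @export
row_profile <- function(image) {
  stopifnot(inherits(image, "gel_image"))
  rowSums(image$pixels)
}

#' Cumulative column-intensity profile of a horizontal strip
#'
#' `c_i(n)`: the sum of pixel intensities down each column, restricted to
#' the rows of one strip.  Within a strip, lanes are locally straight, so
#' lane boundaries appear as minima of this profile (bands-bright
#' convention).
#'
#' @param image a bands-bright [gel_image()].
#' @param row_start,row_end first and last row of the strip (1-based,
#'   inclusive).  Defaults cover the whole image.
#' @return Numeric vector of length `W`.
#' @export
column_profile <- function(image, row_start = 1L, row_end = nrow(image$pixels)) {
  stopifnot(inherits(image, "gel_image"))
  H <- nrow(image$pixels)
  if (row_start < 1 || row_end > H || row_start > row_end) {
    stop("strip rows must satisfy 1 <= row_start <= row_end <= H")
  }
  colSums(image$pixels[row_start:row_end, , drop = FALSE])
}

#' Three-point moving-average smoothing
#'
#' Each interior value is replaced by the mean of itself and its two
#' neighbours; the ends are handled by edge replication so the output has
#' the same length as the input.
#'
#' @param values numeric vector of length >= 3.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values) {
  n <- length(values)
  if (n < 3) stop("profile must have at least 3 values to smooth")
  padded <- c(values[1], values, values[n])
  (padded[1:n] + padded[2:(n + 1)] + padded[3:(n + 2)]) / 3
}

#' Partition an image into dynamic-height strips
#'
#' Strips are horizontal slices within which lanes are treated as straight.
#' Their heights follow the banding pattern: rows whose smoothed cumulative
#' intensity `r(m)` exceeds its `percentile`-th percentile form
#' high-contrast regions (merged across gaps of at most `merge_gap` rows),
#' and strip cuts are placed at the midpoints between consecutive region
#' centres.  With fewer than two regions (sparse or blank gels) the image
#' falls back to `fallback_n` equal strips.
#'
#' @param image a bands-bright [gel_image()].
#' @param percentile high-contrast threshold percentile of the smoothed row
#'   profile (default 75).
#' @param merge_gap merge high rows separated by at most this many rows.
#' @param min_strip_height strips shorter than this are merged into a
#'   neighbour.
#' @param fallback_n equal strip count used when banding is too sparse.
#' @return Data frame with columns `row_start`, `row_end` (1-based,
#'   inclusive) and `height`, tiling `[1, H]` exactly.
#' @export
compute_strips <- function(image, percentile = 75, merge_gap = 5,
                           min_strip_height = 8, fallback_n = 4) {
  stopifnot(inherits(image, "gel_image"))
  H <- nrow(image$pixels)
  centers <- integer(0)
  if (H >= 3) {
    r <- smooth_profile(row_profile(image))
    # local contrast: remove the slowly varying baseline (background level
    # and vertical exposure gradient) so only band-scale excursions count.
    # The window must comfortably exceed a band region's height, including
    # the spread added by per-lane mobility offsets.
    k <- max(31L, 2L * (H %/% 16L) + 1L)
    k <- min(k, if (H %% 2 == 0) H - 1L else H)
    d <- r - stats::runmed(r, k)
    thr <- stats::quantile(d, percentile / 100, names = FALSE)
    high <- which(d >= thr & d >= 0.25 * max(d) & d > 0)
    regions <- NULL
    if (length(high) > 0) {
      brk <- c(0, which(diff(high) > merge_gap), length(high))
      regions <- t(vapply(seq_len(length(brk) - 1), function(i) {
        run <- high[(brk[i] + 1):brk[i + 1]]
        c(min(run), max(run))
      }, numeric(2)))
      centers <- round(rowMeans(regions))
    }
  }
  if (length(centers) < 2) {
    cuts <- round(H * seq_len(max(1L, fallback_n) - 1L) / max(1L, fallback_n))
  } else {
    # cut in the middle of each low-contrast gap separating two regions,
    # so a strip boundary can never fall inside a band region
    cuts <- floor((regions[-nrow(regions), 2] + regions[-1, 1]) / 2)
  }
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < H]))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, H)
  # merge undersized strips into their shorter neighbour
  repeat {
    h <- ends - starts + 1L
    if (length(h) <= 1 || all(h >= min_strip_height)) break
    i <- which.min(h)
    j <- if (i == 1) 2L
         else if (i == length(h)) i - 1L
         else if (h[i - 1] <= h[i + 1]) i - 1L else i + 1L
    keep <- min(i, j)
    ends[keep] <- ends[max(i, j)]
    starts <- starts[-max(i, j)]
    ends <- ends[-max(i, j)]
  }
  data.frame(row_start = as.integer(starts), row_end = as.integer(ends),
             height = as.integer(ends - starts + 1L))
}

#' Detect lane boundaries in a smoothed column profile
#'
#' Under the bands-bright convention, lane boundaries are local minima of
#' the cumulative column-intensity profile.  Minima are kept when their
#' topographic depth (prominence of the inverted profile) is at least
#' `prominence_frac` of the profile's range and when they are at least
#' `min_lane_width` columns away from any deeper accepted minimum (ties
#' resolved leftmost-first).  The outer columns `1` and `W` are always
#' returned, so a flat profile yields only the outer pair.
#'
#' A robust noise gate guards against speckle and shot noise: the profile's
#' point-to-point noise level is estimated as `mad(diff(profile)) / sqrt(2)`
#' and minima whose depth is below `noise_gate` times it are ignored, so a
#' strip containing no bands (where every valley is a noise fluctuation)
#' degrades to the outer boundaries alone rather than to spurious lanes.
#'
#' @param profile smoothed column-intensity profile (numeric vector).
#' @param prominence_frac minimum depth as a fraction of `max - min`.
#' @param min_lane_width minimum spacing between boundaries, in columns.
#' A valley can only localize a boundary when it is narrow: a lane that
#' carries no band within the strip merges with its two flanking gaps into
#' one wide valley whose minimum says nothing about where the boundaries
#' are.  Valleys whose floor (columns within a quarter of the valley depth
#' of the minimum) is wider than `max_floor_width` are therefore skipped in
#' this strip -- the strips in which the lane does carry a band localize
#' those boundaries instead.
#'
#' @param noise_gate minimum depth in units of the estimated profile noise.
#' @param max_floor_width widest usable valley floor, in columns; `NULL`
#'   defaults to `3 * min_lane_width`.
#' @return Sorted integer vector of boundary columns including `1` and `W`.
#' @export
detect_boundaries <- function(profile, prominence_frac = 0.05,
                              min_lane_width = 5, noise_gate = 8,
                              max_floor_width = NULL) {
  W <- length(profile)
  if (W < 3) return(sort(unique(c(1L, W))))
  rng <- max(profile) - min(profile)
  if (rng <= 0) return(c(1L, as.integer(W)))
  if (is.null(max_floor_width)) max_floor_width <- 3 * min_lane_width
  noise <- stats::mad(diff(profile)) / sqrt(2)
  y <- max(profile) - profile            # minima of profile = maxima of y
  cand <- local_maxima(y)
  if (length(cand) > 0) {
    prom <- peak_prominence(y, cand)
    keep <- prom >= max(prominence_frac * rng, noise_gate * noise)
    cand <- cand[keep]
    prom <- prom[keep]
  }
  if (length(cand) > 0) {
    floor_w <- vapply(seq_along(cand), function(i) {
      lim <- profile[cand[i]] + 0.25 * prom[i]
      lo <- cand[i]
      while (lo > 1 && profile[lo - 1] <= lim) lo <- lo - 1
      hi <- cand[i]
      while (hi < W && profile[hi + 1] <= lim) hi <- hi + 1
      as.integer(hi - lo + 1L)
    }, integer(1))
    keep <- floor_w <= max_floor_width
    cand <- cand[keep]
    prom <- prom[keep]
  }
  accepted <- c(1L, as.integer(W))
  if (length(cand) > 0) {
    ord <- order(-y[cand], cand)         # deepest first, ties leftmost
    for (p in cand[ord]) {
      if (all(abs(p - accepted) >= min_lane_width)) {
        accepted <- c(accepted, as.integer(p))
      }
    }
  }
  sort(accepted)
}

# Min-cost monotone (order-preserving) assignment between two sorted column
# lists; matches with |a - b| > max_drift are forbidden.  Skipping an
# element costs `max_drift`, so a feasible match is always preferred over
# leaving both sides unmatched.  Backtracking prefers match, then skip-a,
# then skip-b, which resolves cost ties toward the leftmost match.
# Returns a two-column matrix of (index into a, index into b) pairs.
monotone_match <- function(a, b, max_drift) {
  na <- length(a); nb <- length(b)
  gap <- max_drift
  D <- matrix(Inf, na + 1, nb + 1)
  D[1, ] <- gap * (0:nb)
  D[, 1] <- gap * (0:na)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- abs(a[i] - b[j])
      m <- if (cost <= max_drift) D[i, j] + cost else Inf
      D[i + 1, j + 1] <- min(m, D[i, j + 1] + gap, D[i + 1, j] + gap)
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- na; j <- nb
  while (i > 0 && j > 0) {
    cost <- abs(a[i] - b[j])
    if (cost <= max_drift && D[i + 1, j + 1] == D[i, j] + cost) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (D[i + 1, j + 1] == D[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  pairs
}

#' Stitch per-strip boundaries into full-height lane boundaries
#'
#' Boundary columns found independently in each strip are joined across
#' adjacent strips by a shortest-path rule: a minimum-total-displacement
#' order-preserving assignment (dynamic programming, cost `|delta column|`).
#' A boundary whose nearest admissible partner is farther than `max_drift`
#' is propagated vertically (same column) instead, so every lane boundary
#' spans the full image height; boundaries first seen in a lower strip are
#' back-filled vertically through the strips above.  Each chain receives
#' one vertex at every strip's vertical midpoint and is extended to rows
#' `1` and `H` along its end segments.
#'
#' @param per_strip list of sorted boundary-column vectors, one per strip
#'   (as returned by [detect_boundaries()]).
#' @param strips strip table from [compute_strips()].
#' A lane that happens to carry no band within some strip is
#' indistinguishable, in that strip alone, from an inter-lane gap, so its
#' centre shows up as a one-strip phantom boundary.  Chains are therefore
#' kept only when they were actually detected (matched, not merely
#' propagated) in at least `support_frac` of the strips; genuine gaps are
#' flanked by bands in almost every strip and easily clear this bar.
#'
#' @param max_drift maximum matching displacement in columns; `NULL` (the
#'   default) uses 0.4 times the median boundary spacing of the strips
#'   (falling back to 5).
#' @param support_frac minimum fraction of strips in which a kept chain
#'   must have been detected (default 0.5).
#' @return List of `lane_boundary` objects, ordered left to right, each
#'   with fields `rows` and `cols` (piecewise-linear vertices).
#' @export
stitch_boundaries <- function(per_strip, strips, max_drift = NULL,
                              support_frac = 0.5) {
  stopifnot(length(per_strip) == nrow(strips), length(per_strip) >= 1)
  mids <- (strips$row_start + strips$row_end) / 2
  H <- strips$row_end[nrow(strips)]
  if (is.null(max_drift)) {
    spacing <- unlist(lapply(per_strip, function(b) {
      if (length(b) > 2) diff(b) else numeric(0)
    }))
    max_drift <- if (length(spacing) > 0) 0.4 * stats::median(spacing) else 5
  }
  n_strips <- length(per_strip)
  chains <- lapply(per_strip[[1]], function(col)
    list(cols = col, det = TRUE))
  for (s in seq_len(n_strips)[-1]) {
    cur <- vapply(chains, function(ch) ch$cols[length(ch$cols)], numeric(1))
    ord <- order(cur)
    chains <- chains[ord]
    cur <- cur[ord]
    b <- per_strip[[s]]
    pairs <- monotone_match(cur, b, max_drift)
    matched_a <- pairs[, 1]
    matched_b <- pairs[, 2]
    for (i in seq_along(chains)) {
      hit <- i %in% matched_a
      nxt <- if (hit) b[matched_b[match(i, matched_a)]] else cur[i]
      chains[[i]]$cols <- c(chains[[i]]$cols, nxt)
      chains[[i]]$det <- c(chains[[i]]$det, hit)
    }
    for (j in setdiff(seq_along(b), matched_b)) {
      chains[[length(chains) + 1]] <- list(cols = rep(b[j], s),  # back-fill
                                           det = c(rep(FALSE, s - 1), TRUE))
    }
  }
  # a wide valley (gap plus a band-free lane) can localize differently in
  # different strips, splitting one physical boundary into two nearby
  # complementary chains: merge chains that track within max_drift of each
  # other, preferring the detected column in each strip
  chains <- chains[order(vapply(chains, function(ch) mean(ch$cols),
                                numeric(1)))]
  i <- 1
  while (i < length(chains)) {
    a <- chains[[i]]; b2 <- chains[[i + 1]]
    if (mean(abs(a$cols - b2$cols)) <= max_drift) {
      cols <- ifelse(a$det & !b2$det, a$cols,
                     ifelse(b2$det & !a$det, b2$cols,
                            (a$cols + b2$cols) / 2))
      chains[[i]] <- list(cols = cols, det = a$det | b2$det)
      chains[[i + 1]] <- NULL
    } else {
      i <- i + 1
    }
  }
  support <- vapply(chains, function(ch) sum(ch$det), integer(1))
  chains <- chains[support >= ceiling(support_frac * n_strips)]
  chains <- chains[order(vapply(chains, function(ch) mean(ch$cols),
                                numeric(1)))]
  lapply(chains, function(ch) {
    cols <- ch$cols
    rows <- mids
    if (length(cols) >= 2) {
      top <- cols[1] + (1 - rows[1]) * (cols[2] - cols[1]) / (rows[2] - rows[1])
      k <- length(cols)
      bot <- cols[k] + (H - rows[k]) * (cols[k] - cols[k - 1]) /
        (rows[k] - rows[k - 1])
    } else {
      top <- cols[1]; bot <- cols[1]
    }
    W_hint <- max(unlist(per_strip))
    structure(list(rows = c(1, rows, H),
                   cols = clamp(c(top, cols, bot), 1, W_hint)),
              class = "lane_boundary")
  })
}

#' Interpolated boundary column at given rows
#'
#' @param boundary a `lane_boundary`.
#' @param rows row coordinates.
#' @return Numeric columns, linearly interpolated between vertices (end
#'   values held constant beyond the outermost vertices).
#' @export
boundary_col <- function(boundary, rows) {
  stats::approx(boundary$rows, boundary$cols, xout = rows, rule = 2,
                ties = "ordered")$y
}

#' Cut an image into rectified lanes between boundary polylines
#'
#' Each adjacent boundary pair delimits one lane.  Row by row, the pixel run
#' between the interpolated boundary columns (half-open on the right) is
#' resampled by nearest neighbour to the lane's median width, producing a
#' fixed-width rectified lane sub-image; this removes lane curvature while
#' preserving 8-bit intensities.  Lanes narrower than `min_lane_width` are
#' dropped with a message.
#'
#' @param image a bands-bright [gel_image()].
#' @param boundaries list of `lane_boundary` objects, left to right.
#' @param min_lane_width minimum median lane width in pixels.
#' @return List of `gel_lane` objects with fields `index`, `pixels`
#'   (`H x W_i` matrix), `width`, `left`, `right`.
#' @export
segment_lanes <- function(image, boundaries, min_lane_width = 5) {
  stopifnot(inherits(image, "gel_image"), length(boundaries) >= 2)
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  rows <- seq_len(H)
  cols <- vapply(boundaries, boundary_col, numeric(H), rows = rows)
  if (any(apply(cols, 1, diff) < 0)) {
    stop("internal error: lane boundaries cross")
  }
  lanes <- list()
  for (i in seq_len(length(boundaries) - 1)) {
    left <- cols[, i]; right <- cols[, i + 1]
    width_m <- pmax(ceiling(right) - ceiling(left), 0)
    W_i <- as.integer(round(stats::median(width_m)))
    if (W_i < min_lane_width) {
      message("dropping lane candidate ", i, " (width ", W_i, " px)")
      next
    }
    px <- matrix(0, H, W_i)
    for (m in rows) {
      wm <- width_m[m]
      if (wm < 1) next
      src <- ceiling(left[m]) + floor((seq_len(W_i) - 0.5) * wm / W_i)
      src <- clamp(src, 1, W)
      px[m, ] <- image$pixels[m, src]
    }
    lanes[[length(lanes) + 1]] <- structure(
      list(index = length(lanes) + 1L, pixels = px, width = W_i,
           left = boundaries[[i]], right = boundaries[[i + 1]]),
      class = "gel_lane")
  }
  lanes
}

#' @export
print.gel_lane <- function(x, ...) {
  cat(sprintf("<gel_lane %d: %d x %d>\n", x$index, nrow(x$pixels), x$width))
  invisible(x)
}

#' Segment a gel image into lanes
#'
#' The full lane-segmentation stage.  In `curved` mode the image is split
#' into dynamic-height strips ([compute_strips()]), boundaries are detected
#' per strip from the smoothed cumulative column profile
#' ([detect_boundaries()]) and stitched across strips
#' ([stitch_boundaries()]); this tracks lanes whose register drifts
#' laterally down the gel.  `straight` mode is the same pipeline with a
#' single strip spanning the image, i.e. vertical boundaries -- the right
#' choice when lanes carry too few bands to anchor the strip histograms.
#'
#' @param image a bands-bright [gel_image()].
#' @param mode `"curved"` or `"straight"`.
#' @param expected_lanes optional known lane count; sets
#'   `min_lane_width = W / (4 * expected_lanes)` unless the config gives an
#'   explicit value.
#' @param config a [gel_config()] list.
#' @return List with elements `lanes` (list of `gel_lane`), `boundaries`,
#'   `strips`.
#' @export
segment_gel <- function(image, mode = c("curved", "straight"),
                        expected_lanes = NULL, config = gel_config()) {
  stopifnot(inherits(image, "gel_image"))
  mode <- match.arg(mode)
  W <- ncol(image$pixels); H <- nrow(image$pixels)
  mlw <- config$boundary$min_lane_width
  if (is.null(mlw)) {
    mlw <- if (!is.null(expected_lanes)) W / (4 * expected_lanes) else 5
  }
  strips <- if (mode == "curved") {
    compute_strips(image,
                   percentile = config$strip$percentile,
                   merge_gap = config$strip$merge_gap,
                   min_strip_height = config$strip$min_height,
                   fallback_n = config$strip$fallback_n)
  } else {
    data.frame(row_start = 1L, row_end = H, height = H)
  }
  per_strip <- lapply(seq_len(nrow(strips)), function(i) {
    prof <- column_profile(image, strips$row_start[i], strips$row_end[i])
    detect_boundaries(smooth_profile(prof),
                      prominence_frac = config$boundary$prominence_frac,
                      min_lane_width = mlw)
  })
  boundaries <- stitch_boundaries(per_strip, strips,
                                  max_drift = config$stitch$max_drift)
  # no strip found any interior boundary: a blank or featureless image,
  # not a single wall-to-wall lane
  lanes <- if (all(lengths(per_strip) <= 2)) {
    list()
  } else {
    segment_lanes(image, boundaries, min_lane_width = mlw)
  }
  list(lanes = lanes, boundaries = boundaries, strips = strips)
}
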