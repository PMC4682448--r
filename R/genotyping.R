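#' Reference-band specification
#'
#' The reference band is an amplicon (or spike-in) guaranteed present in
#' every lane with near-constant mobility; it anchors inter-lane alignment
#' and defines offset zero for band registration.
#'
#' @param position expected row of the reference band in rectified lane
#'   coordinates (1-based).
#' @param window half-width, in pixels, of the search window used to locate
#'   the reference band per lane.
#' @return A `ref_spec` list.
#' @export
ref_spec <- function(position, window = 8) {
  stopifnot(position >= 1, window >= 1)
  structure(list(position = position, window = window), class = "ref_spec")
}

#' Inter-lane cross-correlation of band profiles
#'
#' `R(k) = sum_n b1(n + k) * bj(n)` over the truncated overlap -- the same
#' index-validity rule as the intra-lane form.  Its argmax over `k` gives
#' the vertical offset of lane `j` relative to the anchor lane.
#'
#' @param b1,bj equal-length band profiles.
#' @param k integer shift.
#' @return The correlation value.
#' @export
interlane_correlation <- function(b1, bj, k) {
  H <- length(b1)
  stopifnot(length(bj) == H, abs(k) < H)
  if (k >= 0) sum(b1[(1 + k):H] * bj[1:(H - k)])
  else        sum(b1[1:(H + k)] * bj[(1 - k):H])
}

#' Align lanes globally and locally to the reference band
#'
#' Each lane is first aligned to the anchor (leftmost) lane by maximizing
#' the inter-lane cross-correlation of whole band profiles over
#' `k in [-search_bound, search_bound]` (ties toward the smallest `|k|`,
#' then negative).  A local refinement then re-maximizes the correlation
#' restricted to the reference-band window, correcting residual offset near
#' the reference.  Finally the lane's own reference band is identified as
#' the detected band closest to the expected position (after both shifts)
#' within the window; lanes where no such band exists are flagged
#' `reference_found = FALSE` and excluded from clustering downstream.
#'
#' @param profiles list of band profiles (equal length), leftmost first.
#' @param bands list of band tables (from [detect_bands()]) parallel to
#'   `profiles`.
#' @param ref a [ref_spec()].
#' @param search_bound global search bound; default `floor(H / 8)`.
#' @return Data frame with columns `lane_index`, `global_shift`,
#'   `local_shift`, `reference_found`, `reference_position` (lane
#'   coordinates).
#' @export
align_lanes <- function(profiles, bands, ref, search_bound = NULL) {
  stopifnot(length(profiles) >= 2, length(bands) == length(profiles),
            inherits(ref, "ref_spec"))
  H <- length(profiles[[1]])
  if (is.null(search_bound)) search_bound <- max(1L, H %/% 8L)
  b1 <- profiles[[1]]
  e <- ref$position
  win <- ref$window
  wlo <- max(1, e - win); whi <- min(H, e + win)
  res <- lapply(seq_along(profiles), function(j) {
    bj <- profiles[[j]]
    if (j == 1) {
      g <- 0L; l <- 0L
    } else {
      cc <- xcorr_range(b1, bj, search_bound)
      ord <- order(abs(cc$k), cc$k)
      g <- cc$k[ord][which.max(cc$R[ord])]
      # local refinement within the reference window
      score <- vapply((-win):win, function(k2) {
        n <- wlo:whi
        src <- n - g - k2
        ok <- src >= 1 & src <= H
        sum(b1[n[ok]] * bj[src[ok]])
      }, numeric(1))
      ks <- (-win):win
      ord2 <- order(abs(ks), ks)
      l <- ks[ord2][which.max(score[ord2])]
    }
    total <- g + l
    pos <- bands[[j]]$position
    d <- abs(pos + total - e)
    found <- length(pos) > 0 && min(d) <= win
    rp <- if (found) pos[which.min(d)] else NA_integer_
    data.frame(lane_index = j, global_shift = as.integer(g),
               local_shift = as.integer(l), reference_found = found,
               reference_position = as.integer(rp))
  })
  out <- do.call(rbind, res)
  if (sum(out$reference_found) < 2) {
    stop("genotyping aborted: fewer than 2 lanes contain the reference band",
         " near row ", e)
  }
  if (any(!out$reference_found)) {
    message("lanes without a reference band excluded from clustering: ",
            paste(out$lane_index[!out$reference_found], collapse = ", "))
  }
  out
}

#' Band mobilities relative to the reference band
#'
#' Every band's offset is its migration distance minus the lane's own
#' reference-band position, so each included lane has exactly one band at
#' offset 0 and offsets are comparable across lanes and gels regardless of
#' residual alignment error.
#'
#' @param bands list of band tables parallel to the lanes.
#' @param alignments output of [align_lanes()].
#' @return Data frame with columns `lane_index`, `position`, `offset`.
#' @export
band_offsets <- function(bands, alignments) {
  keep <- which(alignments$reference_found)
  out <- lapply(keep, function(j) {
    p <- bands[[j]]$position
    data.frame(lane_index = j, position = p,
               offset = p - alignments$reference_position[alignments$lane_index == j])
  })
  do.call(rbind, c(out, list(data.frame(lane_index = integer(0),
                                        position = integer(0),
                                        offset = numeric(0)))))
}

#' DBSCAN neighbourhood radius from reference-band spread
#'
#' The clustering radius epsilon is the range (max minus min) of the
#' per-lane reference-band positions measured after the global shift but
#' before local refinement -- i.e. the residual mobility scatter of a band
#' known to be identical in every lane -- floored at `floor_px` so a
#' single tightly-run gel cannot collapse the radius to zero.
#'
#' @param alignments output of [align_lanes()].
#' @param floor_px lower bound on epsilon in pixels (default 2).
#' @return Epsilon in pixels.
#' @export
estimate_eps <- function(alignments, floor_px = 2) {
  a <- alignments[alignments$reference_found, ]
  rp <- a$reference_position + a$global_shift
  max(floor_px, max(rp) - min(rp))
}

#' Density-based clustering of 1-D points (DBSCAN)
#'
#' Core points have at least `minpts` points (themselves included) within
#' `eps`; clusters are the connected components of core points under the
#' `eps` adjacency; border (non-core) points join the cluster of their
#' nearest core point within `eps` (ties toward the core with the smaller
#' coordinate); remaining points are noise.  The border rule makes the
#' result independent of input order.  Cluster labels are assigned in order
#' of increasing cluster minimum, so labels increase left to right.
#'
#' @param x numeric vector.
#' @param eps neighbourhood radius.
#' @param minpts minimum neighbourhood size for a core point.
#' @return Integer labels parallel to `x`; 0 marks noise.
#' @export
dbscan_1d <- function(x, eps, minpts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  ord <- order(x)
  xs <- x[ord]
  # neighbourhood counts via a two-pointer sweep over the sorted values;
  # the predicate is the plain difference xs[j] - xs[i] <= eps so boundary
  # cases resolve exactly as a pairwise distance comparison would
  lo <- hi <- integer(n)
  p <- 1L
  for (i in seq_len(n)) {
    while (xs[i] - xs[p] > eps) p <- p + 1L
    lo[i] <- p
  }
  p <- n
  for (i in rev(seq_len(n))) {
    while (xs[p] - xs[i] > eps) p <- p - 1L
    hi[i] <- p
  }
  cnt <- hi - lo + 1L
  core <- cnt >= minpts
  labels_s <- integer(n)
  if (any(core)) {
    ci <- which(core)
    gaps <- which(diff(xs[ci]) > eps)
    comp <- cumsum(c(1L, as.integer(seq_along(ci)[-1] %in% (gaps + 1L))))
    labels_s[ci] <- comp
    # border points: nearest core within eps, ties toward the smaller value
    bi <- which(!core)
    for (b in bi) {
      d <- abs(xs[ci] - xs[b])
      ok <- which(d <= eps)
      if (length(ok) > 0) {
        best <- ok[order(d[ok], xs[ci][ok])][1]
        labels_s[b] <- labels_s[ci[best]]
      }
    }
  }
  labels <- integer(n)
  labels[ord] <- labels_s
  labels
}

#' Cluster band offsets across lanes into band species
#'
#' Runs 1-D DBSCAN over all reference-relative band offsets.  By default
#' epsilon is the reference-band mobility range ([estimate_eps()]) and
#' `minpts` is the integer closest to 10% of the number of lanes, floored
#' at 2 (DBSCAN cannot form a cluster from fewer than two points).  Each
#' cluster's mean and variance are fitted from its member offsets (the
#' variance floored at `var_floor` so a degenerate cluster still defines a
#' usable Gaussian), and the cluster containing offset 0 is flagged as the
#' reference cluster.
#'
#' @param offsets data frame from [band_offsets()].
#' @param n_lanes number of lanes contributing offsets.
#' @param eps neighbourhood radius; `NULL` requires `alignments`.
#' @param minpts minimum cluster size; `NULL` for the 10% rule.
#' @param alignments optional [align_lanes()] output used to estimate
#'   epsilon.
#' @param eps_floor,var_floor numerical floors (pixels, pixels squared).
#' @param provenance optional character vector naming the source images.
#' @return A `cluster_model`: list with `clusters` (data frame
#'   `cluster_id`, `mean`, `variance`, `count`, `is_reference`), `epsilon`,
#'   `minpts`, `noise` (unclustered offsets), `provenance`.
#' @export
cluster_bands <- function(offsets, n_lanes, eps = NULL, minpts = NULL,
                          alignments = NULL, eps_floor = 2, var_floor = 0.25,
                          provenance = character(0)) {
  stopifnot(nrow(offsets) >= 1, n_lanes >= 2)
  if (is.null(eps)) {
    if (is.null(alignments)) stop("provide either eps or alignments")
    eps <- estimate_eps(alignments, eps_floor)
  }
  eps <- max(eps, eps_floor)
  if (is.null(minpts)) minpts <- max(2L, as.integer(floor(0.1 * n_lanes + 0.5)))
  labels <- dbscan_1d(offsets$offset, eps, minpts)
  ids <- sort(unique(labels[labels > 0]))
  clusters <- do.call(rbind, lapply(ids, function(id) {
    v <- offsets$offset[labels == id]
    data.frame(cluster_id = id, mean = mean(v),
               variance = max(var_floor, if (length(v) > 1) stats::var(v) else 0),
               count = length(v))
  }))
  if (is.null(clusters) || !any(vapply(ids, function(id)
    any(abs(offsets$offset[labels == id]) < 1e-9), logical(1)))) {
    stop("reference cluster not recovered: no cluster contains offset 0")
  }
  clusters$is_reference <- vapply(clusters$cluster_id, function(id)
    any(abs(offsets$offset[labels == id]) < 1e-9), logical(1))
  structure(list(clusters = clusters, epsilon = eps,
                 minpts = as.integer(minpts),
                 noise = offsets$offset[labels == 0],
                 provenance = provenance),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: %d clusters, eps = %.2f px, minPts = %d>\n",
              nrow(x$clusters), x$epsilon, x$minpts))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Maximum-likelihood assignment of band offsets to clusters
#'
#' Each offset is assigned to the cluster maximizing the Gaussian density
#' `N(offset; mean, variance)` (exact likelihood ties go to the cluster
#' with the smaller mean), so gel-to-gel systematic error is absorbed by
#' the fitted cluster parameters.
#'
#' A band far from every cluster is declared novel (`NA`) rather than
#' forced into the model.  The gate is expressed as `max_z` nominal
#' standard deviations but is applied through the cluster's Student-t
#' predictive distribution: with only `n` member offsets the fitted
#' variance is itself uncertain, so the rejection threshold is the
#' t quantile with `n - 1` degrees of freedom at the tail probability of a
#' `max_z`-sigma normal gate, on the predictive scale
#' `s * sqrt(1 + 1/n)`.  For large clusters this converges to the plain
#' `max_z`-sigma rule; for small ones it avoids rejecting genuine bands
#' merely because the variance was estimated from a handful of lanes.
#' `max_z = Inf` disables the gate entirely (every band is assigned to its
#' maximum-likelihood cluster).
#'
#' @param offset numeric vector of offsets.
#' @param model a `cluster_model`.
#' @param max_z novelty gate in nominal standard deviations (default 3).
#' @return Integer cluster ids parallel to `offset`, `NA` for novel bands.
#' @export
classify_band <- function(offset, model, max_z = 3) {
  stopifnot(inherits(model, "cluster_model"))
  cl <- model$clusters
  if (nrow(cl) == 0) stop("empty cluster model")
  ord <- order(cl$mean)
  mu <- cl$mean[ord]; sd_ <- sqrt(cl$variance[ord]); id <- cl$cluster_id[ord]
  n <- cl$count[ord]
  crit <- if (is.finite(max_z)) {
    alpha <- 2 * stats::pnorm(max_z, lower.tail = FALSE)
    stats::qt(1 - alpha / 2, df = pmax(1, n - 1))
  } else rep(Inf, length(n))
  pred_sd <- sd_ * sqrt(1 + 1 / n)
  vapply(offset, function(o) {
    dens <- stats::dnorm(o, mu, sd_)
    best <- which(dens == max(dens))[1]   # means sorted: tie -> smaller mean
    if (abs(o - mu[best]) / pred_sd[best] > crit[best]) NA_integer_
    else id[best]
  }, integer(1))
}

#' Call per-lane genotypes from classified bands
#'
#' A lane's genotype is its presence/absence pattern over the non-reference
#' band clusters: `presence[c] = 1` when at least one of the lane's bands
#' classifies to cluster `c`.  Novel (unassigned) bands are reported
#' separately and do not enter the pattern.  Lanes sharing an identical
#' pattern share a genotype group; group ids are assigned in order of first
#' appearance, leftmost lane first.  Lanes that lacked the reference band
#' get an all-missing call.
#'
#' @param offsets data frame from [band_offsets()].
#' @param model a `cluster_model`.
#' @param alignments output of [align_lanes()] (defines the full lane set).
#' @param max_z novelty gate passed to [classify_band()].
#' @return List with `calls` (data frame `lane_index`, `group_id`,
#'   `pattern`), `presence` (lanes x clusters 0/1 matrix, `NA` rows for
#'   excluded lanes) and `novel` (list of novel band positions per lane).
#' @export
call_genotypes <- function(offsets, model, alignments, max_z = 3) {
  stopifnot(inherits(model, "cluster_model"))
  cl <- model$clusters[order(model$clusters$mean), ]
  non_ref <- cl$cluster_id[!cl$is_reference]
  lanes <- alignments$lane_index
  presence <- matrix(NA_integer_, length(lanes), length(non_ref),
                     dimnames = list(NULL, paste0("cluster_", non_ref)))
  novel <- vector("list", length(lanes))
  cls_all <- classify_band(offsets$offset, model, max_z = max_z)
  for (i in seq_along(lanes)) {
    j <- lanes[i]
    if (!alignments$reference_found[alignments$lane_index == j]) next
    sel <- offsets$lane_index == j
    cls <- cls_all[sel]
    presence[i, ] <- as.integer(non_ref %in% cls[!is.na(cls)])
    novel[[i]] <- offsets$position[sel][is.na(cls)]
  }
  pattern <- apply(presence, 1, function(p) {
    if (anyNA(p)) NA_character_ else paste(p, collapse = "")
  })
  ok <- !is.na(pattern)
  group <- rep(NA_integer_, length(lanes))
  group[ok] <- match(pattern[ok], unique(pattern[ok]))
  list(calls = data.frame(lane_index = lanes, group_id = group,
                          pattern = pattern),
       presence = presence, novel = novel)
}

#' Save / load a cluster model as JSON
#'
#' The band-cluster model is fitted once per group of related gels and
#' reused to classify bands from further gels, so it round-trips through a
#' small versioned JSON schema.
#'
#' @param model a `cluster_model`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `cluster_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  obj <- list(schema = "gelcaller-cluster-model/1",
              epsilon = model$epsilon, minpts = model$minpts,
              clusters = model$clusters, noise = model$noise,
              provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e)))
  if (!identical(obj$schema, "gelcaller-cluster-model/1") ||
      is.null(obj$clusters) ||
      !all(c("cluster_id", "mean", "variance", "count", "is_reference")
           %in% names(obj$clusters))) {
    stop("model schema mismatch in ", path,
         " (expected gelcaller-cluster-model/1)")
  }
  cl <- as.data.frame(obj$clusters)
  cl$cluster_id <- as.integer(cl$cluster_id)
  cl$count <- as.integer(cl$count)
  structure(list(clusters = cl, epsilon = obj$epsilon,
                 minpts = as.integer(obj$minpts),
                 noise = as.numeric(obj$noise %||% numeric(0)),
                 provenance = as.character(obj$provenance %||% character(0))),
            class = "cluster_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
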