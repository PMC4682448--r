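# Raw truncated-overlap cross-correlation of two equal-length signals for
# every integer shift in [-bound, bound]:
#   R(k) = sum_h ref[h + k] * v[h]  over all h with both indices valid.
# Returns a named list with `k` and `R`.
xcorr_range <- function(ref, v, bound) {
  H <- length(ref)
  bound <- min(bound, H - 1L)
  ks <- (-bound):bound
  R <- vapply(ks, function(k) {
    if (k >= 0) sum(ref[(1 + k):H] * v[1:(H - k)])
    else        sum(ref[1:(H + k)] * v[(1 - k):H])
  }, numeric(1))
  list(k = ks, R = R)
}

# argmax of R over k; ties broken toward the smallest |k|, then negative k.
xcorr_argmax <- function(ref, v, bound) {
  cc <- xcorr_range(ref, v, bound)
  ord <- order(abs(cc$k), cc$k)
  k_sorted <- cc$k[ord]
  R_sorted <- cc$R[ord]
  k_sorted[which.max(R_sorted)]
}

#' Intra-lane column cross-correlation
#'
#' The raw inner product between a lane's reference column and its `n`-th
#' column, with the reference shifted by `k` rows:
#' `R(k) = sum_h p[h + k, ref] * p[h, n]`, summed over the truncated
#' overlap (terms with either index outside `[1, H]` are dropped, for
#' positive and negative `k` alike).  The shift maximizing `R` estimates
#' how far the band in column `n` is displaced relative to the reference
#' column -- the basis of smiling/frowning correction.
#'
#' @param lane a `gel_lane` or a plain intensity matrix.
#' @param n column index (1-based).
#' @param k integer shift, `-H < k < H`.
#' @param reference_col reference column index (default 1).
#' @return The correlation value (a single number).
#' @export
column_cross_correlation <- function(lane, n, k, reference_col = 1L) {
  px <- if (inherits(lane, "gel_lane")) lane$pixels else lane
  H <- nrow(px)
  stopifnot(n >= 1, n <= ncol(px), abs(k) < H)
  h <- seq_len(H)
  ok <- h + k >= 1 & h + k <= H
  sum(px[h[ok] + k, reference_col] * px[h[ok], n])
}

#' Straighten distorted bands within a lane
#'
#' Smiling, frowning or slanted bands are straightened column by column:
#' for each column `n`, the shift `k*(n)` maximizing the cross-correlation
#' against the reference column (searched over
#' `k in [-search_bound, search_bound]`, ties toward the smallest `|k|`,
#' then negative) is found, and the column is displaced so its band content
#' lines up with the reference column's rows.  Vacated pixels are
#' zero-filled (never wrapped, which would fabricate bands at the opposite
#' end).  Columns with an all-zero correlation keep shift 0.
#'
#' @param lane a `gel_lane` (or plain matrix, which is wrapped).
#' @param search_bound maximum `|k|` searched; default `floor(H / 8)`.
#' @param reference `"auto"` picks the first column carrying real band
#'   signal -- the first whose variance reaches a quarter of the maximum
#'   column variance -- so that an empty or noise-only margin column (lane
#'   crops extend to the gap centres) cannot anchor the alignment;
#'   `"first"` forces column 1.
#' @param normalized use the normalized cross-correlation (each shift's
#'   inner product divided by the overlap norms) instead of the raw
#'   product.  Raw is the default and the fidelity choice; normalized mode
#'   removes the bias toward small `|k|` that the shrinking overlap
#'   induces.
#' @return List with `lane` (rectified, same dimensions), `offsets`
#'   (integer `k*` per column; 0 at the reference column),
#'   `reference_col`, and `search_bound`.
#' @export
straighten_lane <- function(lane, search_bound = NULL,
                            reference = c("auto", "first"),
                            normalized = FALSE) {
  reference <- match.arg(reference)
  wrapped <- inherits(lane, "gel_lane")
  px <- if (wrapped) lane$pixels else lane
  H <- nrow(px); W <- ncol(px)
  if (is.null(search_bound)) search_bound <- max(1L, H %/% 8L)
  ref_col <- 1L
  if (reference == "auto") {
    v <- apply(px, 2, stats::var)
    strong <- which(v >= 0.25 * max(v) & v > 0)
    if (length(strong) > 0) ref_col <- strong[1]
  }
  ref <- px[, ref_col]
  offsets <- integer(W)
  out <- matrix(0, H, W)
  for (n in seq_len(W)) {
    cc <- xcorr_range(ref, px[, n], search_bound)
    if (normalized) {
      norms <- vapply(cc$k, function(k) {
        if (k >= 0) sqrt(sum(ref[(1 + k):H]^2) * sum(px[1:(H - k), n]^2))
        else        sqrt(sum(ref[1:(H + k)]^2) * sum(px[(1 - k):H, n]^2))
      }, numeric(1))
      cc$R <- ifelse(norms > 0, cc$R / norms, 0)
    }
    if (all(cc$R == 0)) {
      k_star <- 0L
    } else {
      ord <- order(abs(cc$k), cc$k)
      k_star <- cc$k[ord][which.max(cc$R[ord])]
    }
    offsets[n] <- k_star
    src <- seq_len(H) - k_star
    ok <- src >= 1 & src <= H
    out[which(ok), n] <- px[src[ok], n]
  }
  rect <- if (wrapped) {
    lane$pixels <- out
    lane
  } else {
    out
  }
  list(lane = rect, offsets = offsets, reference_col = ref_col,
       search_bound = as.integer(search_bound))
}

#' Summed band-intensity profile of a lane
#'
#' `b(n)`: the lane's pixel intensities summed across the lane width at
#' every migration position, after rectification.  Bands appear as peaks
#' of this profile.
#'
#' @param lane a `gel_lane` or plain matrix (rows = migration axis).
#' @return Numeric vector of length `H` with a `lane_index` attribute when
#'   available.
#' @export
band_profile <- function(lane) {
  px <- if (inherits(lane, "gel_lane")) lane$pixels else lane
  b <- rowSums(px)
  if (inherits(lane, "gel_lane")) attr(b, "lane_index") <- lane$index
  b
}

#' Call bands from a lane intensity profile
#'
#' Candidate band positions are the local maxima of `b`, found where the
#' first derivative `G(n) = b(n+1) - b(n)` changes sign from positive to
#' negative.  Every sign change counts and no minimum separation is
#' imposed, so doublet bands separated by a shallow valley are preserved.
#' Candidates at or below the `percentile`-th percentile of the profile's
#' own values are discarded as background; an optional absolute
#' `min_intensity` gate additionally removes candidates that do not stand
#' above the background noise floor (the pipeline sets it to
#' `median(b) + gate_k * mad(b)`).
#'
#' @param profile numeric band profile (length >= 3).
#' @param percentile background percentile threshold (default 15).
#' @param min_intensity optional absolute intensity floor; `NULL` disables
#'   it.
#' @return Data frame with columns `position` (1-based row), `intensity`,
#'   `prominence`, sorted by position.  Zero rows for a flat profile.
#' @export
detect_bands <- function(profile, percentile = 15, min_intensity = NULL) {
  if (length(profile) < 3) stop("profile must have at least 3 values")
  pos <- local_maxima(profile)
  thr <- stats::quantile(profile, percentile / 100, names = FALSE)
  pos <- pos[profile[pos] > thr]
  if (!is.null(min_intensity)) pos <- pos[profile[pos] >= min_intensity]
  if (length(pos) == 0) {
    return(data.frame(position = integer(0), intensity = numeric(0),
                      prominence = numeric(0)))
  }
  data.frame(position = as.integer(pos),
             intensity = profile[pos],
             prominence = peak_prominence(profile, pos))
}

#' Robust background gate for band calling
#'
#' A band must stand above the lane's background noise floor.  The gate is
#' `median(b) + k * mad(b)`, a standard robust detection limit: the median
#' tracks the background level (bands occupy a small fraction of rows) and
#' the MAD its fluctuation, so percentile-passing noise wiggles are
#' rejected while true bands, orders of magnitude above, always pass.
#'
#' @param profile numeric band profile.
#' @param k gate strength in robust standard deviations (default 5).
#' @return A single intensity threshold.
#' @export
band_gate <- function(profile, k = 5) {
  stats::median(profile) + k * stats::mad(profile)
}
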