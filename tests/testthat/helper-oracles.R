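# Independent brute-force oracles used to check the package's fast paths.

# Literal scan for profile peaks: p is a peak when the next value is
# strictly lower and, walking left across any plateau of equal values, the
# value just before the plateau is strictly lower.
oracle_peaks <- function(b) {
  out <- integer(0)
  n <- length(b)
  for (p in seq_len(n - 1)[-1]) {
    if (b[p + 1] >= b[p]) next
    q <- p
    while (q > 1 && b[q - 1] == b[p]) q <- q - 1
    if (q > 1 && b[q - 1] < b[p]) out <- c(out, p)
  }
  out
}

oracle_detect_bands <- function(b, percentile = 15) {
  thr <- stats::quantile(b, percentile / 100, names = FALSE)
  p <- oracle_peaks(b)
  p[b[p] > thr]
}

# O(n^2) DBSCAN: explicit distance matrix, depth-first connected components
# over core points, border points assigned to the nearest core within eps
# (ties toward the smaller coordinate).  Labels renumbered by cluster
# minimum so they are comparable with dbscan_1d().
oracle_dbscan <- function(x, eps, minpts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  D <- abs(outer(x, x, "-"))
  adj <- D <= eps
  core <- rowSums(adj) >= minpts
  lab <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] > 0) next
    cl <- cl + 1L
    stack <- i
    while (length(stack) > 0) {
      v <- stack[[1]]; stack <- stack[-1]
      if (lab[v] > 0) next
      lab[v] <- cl
      nb <- which(adj[v, ] & core & lab == 0)
      stack <- c(stack, nb)
    }
  }
  for (i in which(!core)) {
    cands <- which(core & adj[i, ])
    if (length(cands) > 0) {
      best <- cands[order(D[i, cands], x[cands])][1]
      lab[i] <- lab[best]
    }
  }
  # renumber by increasing cluster minimum
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) > 0) {
    mins <- vapply(ids, function(id) min(x[lab == id]), numeric(1))
    remap <- integer(max(ids))
    remap[ids[order(mins)]] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

# Exhaustive search over monotone matchings between sorted lists a and b,
# minimizing sum of matched |a_i - b_j| plus `gap` per unmatched element;
# matches farther than max_drift are forbidden.  Returns the minimum cost.
oracle_match_cost <- function(a, b, max_drift) {
  gap <- max_drift
  rec <- function(i, j) {
    if (i > length(a)) return(gap * (length(b) - j + 1))
    if (j > length(b)) return(gap * (length(a) - i + 1))
    best <- min(rec(i + 1, j) + gap, rec(i, j + 1) + gap)
    d <- abs(a[i] - b[j])
    if (d <= max_drift) best <- min(best, rec(i + 1, j + 1) + d)
    best
  }
  rec(1, 1)
}

# Direct double-loop cross-correlation with explicit index validity.
oracle_xcorr <- function(ref, v, k) {
  H <- length(ref)
  s <- 0
  for (h in seq_len(H)) {
    if (h + k >= 1 && h + k <= H) s <- s + ref[h + k] * v[h]
  }
  s
}

# Row centroid of each column's intensity (for straightening checks).
column_centroids <- function(m) {
  apply(m, 2, function(col) {
    if (sum(col) == 0) NA_real_ else sum(seq_along(col) * col) / sum(col)
  })
}
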