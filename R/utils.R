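clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Positions of strict local maxima of a numeric vector, plateau-aware:
# a run of equal values counts once, at its last index, and only when the
# signal strictly rises somewhere before the run and strictly falls right
# after it.  Endpoints are never maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  g <- diff(x)
  s <- sign(g)
  carried <- s
  for (i in seq_along(carried)[-1]) {
    if (carried[i] == 0) carried[i] <- carried[i - 1]
  }
  idx <- which(s == -1)
  idx <- idx[idx >= 2]
  idx[carried[idx - 1] == 1]
}

# Topographic prominence of peaks at `peaks` in `x`: height above the higher
# of the two valley floors reached before meeting strictly taller terrain
# (or the record edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- h
    i <- p + 1L
    while (i <= length(x) && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}
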