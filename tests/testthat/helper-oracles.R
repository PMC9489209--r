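# Independent oracles used by the tests. These reimplement the checked
# quantities by direct enumeration / brute force and must stay separate
# from the package's own code paths.

# Brute-force non-overlapping MSD: enumerate the segment endpoints of
# the anchored grid explicitly and average the squared displacements of
# the segments whose both endpoints were observed.
oracleMSD <- function(frames, x, y, lagSteps) {
  f0 <- frames[1L]
  fmax <- frames[length(frames)]
  vapply(lagSteps, function(n) {
    ends <- seq(f0, fmax, by = n)
    vals <- numeric()
    for (k in seq_len(length(ends) - 1L)) {
      a <- which(frames == ends[k])
      b <- which(frames == ends[k + 1L])
      if (length(a) == 1L && length(b) == 1L)
        vals <- c(vals, (x[b] - x[a])^2 + (y[b] - y[a])^2)
    }
    if (length(vals)) mean(vals) else NA_real_
  }, 0)
}

oracleMSDCounts <- function(frames, x, y, lagSteps) {
  f0 <- frames[1L]
  fmax <- frames[length(frames)]
  vapply(lagSteps, function(n) {
    ends <- seq(f0, fmax, by = n)
    cnt <- 0L
    for (k in seq_len(length(ends) - 1L))
      if (any(frames == ends[k]) && any(frames == ends[k + 1L]))
        cnt <- cnt + 1L
    cnt
  }, 0L)
}

# Exact two-sided rank-sum p by enumeration of all C(n, na) labelings
# of the pooled sample (midranks for ties), doubling the smaller tail.
oracleRankSumP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  uObs <- uOf(seq_len(na))
  us <- utils::combn(length(pooled), na, uOf)
  min(1, 2 * min(mean(us <= uObs + 1e-12), mean(us >= uObs - 1e-12)))
}

# Cramer-Rao-style localization bound (px) for a Gaussian spot of width
# s px, N signal photons, on a background with per-pixel variance bgVar
# (Thompson-type formula, pixel size a = 1 px).
oracleLocalizationBound <- function(sPx, nPhotons, bgVar) {
  sqrt((sPx^2 + 1 / 12) / nPhotons +
         8 * pi * sPx^4 * bgVar / nPhotons^2)
}
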