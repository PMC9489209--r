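# Fractional Gaussian noise synthesis.
#
# Exact simulation via circulant embedding (Davies-Harte): the n x n
# Toeplitz covariance of fGn is embedded in a 2n x 2n circulant matrix
# whose eigenvalues come from one FFT of its first row; two independent
# exact samples fall out of the real and imaginary parts of one complex
# FFT, which conveniently gives the x and y axes of a 2D trajectory.
# When the embedding is not non-negative definite (possible for H > 1/2
# at some lengths) a dense Cholesky factorization is used for short
# series instead.

#' Autocovariance of fractional Gaussian noise
#'
#' gamma(k) = sigma2/2 * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}), the
#' autocovariance at integer lag k of increments of fractional Brownian
#' motion with Hurst exponent H and per-step variance sigma2.
#'
#' @param k integer lag(s), >= 0
#' @param hurst Hurst exponent in (0, 1)
#' @param sigma2 variance of one increment
#' @return numeric vector of autocovariances
#' @export
fgnAutocovariance <- function(k, hurst, sigma2 = 1) {
  H2 <- 2 * hurst
  sigma2 / 2 * (abs(k + 1)^H2 + abs(k - 1)^H2 - 2 * abs(k)^H2)
}

# Eigenvalues of the circulant embedding for n-step fGn; NULL when the
# embedding fails (negative eigenvalues beyond round-off).
.dhEigenvalues <- function(n, hurst, sigma2) {
  g <- fgnAutocovariance(0:n, hurst, sigma2)
  row1 <- c(g[seq_len(n)], g[n + 1L], rev(g[seq(2L, n)]))
  ev <- Re(stats::fft(row1))
  if (min(ev) < -1e-8 * max(abs(ev))) return(NULL)
  pmax(ev, 0)
}

.cholFactor <- function(n, hurst, sigma2) {
  if (n > 4096L)
    stop("circulant embedding failed and series too long for Cholesky fallback (n = ", n, ")")
  g <- fgnAutocovariance(0:(n - 1L), hurst, sigma2)
  chol(stats::toeplitz(g))
}

# Prepared generator state, reused across trajectories of one population.
.fgnPlan <- function(n, hurst, sigma2) {
  stopifnot(n >= 1L)
  ev <- .dhEigenvalues(n, hurst, sigma2)
  if (!is.null(ev)) list(method = "davies-harte", n = n, ev = ev)
  else list(method = "cholesky", n = n, L = .cholFactor(n, hurst, sigma2))
}

# One pair of independent fGn sample paths (x and y increments), each of
# length n, drawn from the current RNG stream.
.fgnPair <- function(plan) {
  n <- plan$n
  if (plan$method == "davies-harte") {
    m <- length(plan$ev)  # m = 2n
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    f <- stats::fft(sqrt(plan$ev) * z)
    list(x = Re(f)[seq_len(n)] / sqrt(m), y = Im(f)[seq_len(n)] / sqrt(m))
  } else {
    list(x = drop(crossprod(plan$L, stats::rnorm(n))),
         y = drop(crossprod(plan$L, stats::rnorm(n))))
  }
}

# Reflecting boundary on a disc of radius R centred at the origin.
# Increments of the free path are replayed on the reflected path; any
# position outside the disc is folded back across the boundary circle
# (|r| -> 2R - |r|, same direction). Vectorized fast path: most
# trajectories never touch the boundary.
.reflectDisc <- function(x, y, radius) {
  r2 <- x * x + y * y
  bad <- which(r2 > radius * radius)
  if (!length(bad)) return(list(x = x, y = y))
  n <- length(x)
  px <- x; py <- y
  for (k in bad[1L]:n) {
    if (k > 1L) {
      px[k] <- px[k - 1L] + (x[k] - x[k - 1L])
      py[k] <- py[k - 1L] + (y[k] - y[k - 1L])
    }
    rk <- sqrt(px[k]^2 + py[k]^2)
    if (rk > radius) {
      f <- (2 * radius - rk) / rk
      px[k] <- px[k] * f
      py[k] <- py[k] * f
    }
  }
  list(x = px, y = py)
}
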