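# Time-averaged MSD with non-overlapping intervals, power-law fitting,
# and summary statistics.

# Non-overlapping MSD of one trajectory given frame indices and positions.
# The segmentation is anchored at the first observed frame: for lag n
# steps the segment endpoints are frames f0, f0+n, f0+2n, ...; a segment
# contributes only when both endpoints were observed (gaps reduce the
# interval count, nothing is interpolated). With segmentation = "offset"
# the n possible grid offsets are pooled (sensitivity variant).
.msdOneTrajectory <- function(frames, x, y, lagSteps, segmentation) {
  f0 <- frames[1L]
  fmax <- frames[length(frames)]
  pos <- match(f0:fmax, frames)  # NA where a frame is missing
  nFrames <- fmax - f0 + 1L
  msd <- numeric(length(lagSteps))
  cnt <- integer(length(lagSteps))
  offsets <- function(n) if (segmentation == "offset") 0:(n - 1L) else 0L
  for (j in seq_along(lagSteps)) {
    n <- lagSteps[j]
    ss <- 0; k <- 0L
    for (off in offsets(n)) {
      grid <- seq(1L + off, nFrames, by = n)
      if (length(grid) < 2L) next
      ia <- pos[grid[-length(grid)]]
      ib <- pos[grid[-1L]]
      ok <- !is.na(ia) & !is.na(ib)
      if (!any(ok)) next
      dx <- x[ib[ok]] - x[ia[ok]]
      dy <- y[ib[ok]] - y[ia[ok]]
      ss <- ss + sum(dx * dx + dy * dy)
      k <- k + sum(ok)
    }
    msd[j] <- if (k > 0L) ss / k else NA_real_
    cnt[j] <- k
  }
  list(msd = msd, n = cnt)
}

#' Per-trajectory time-averaged MSD
#'
#' Computes, for every trajectory in the set, the time-averaged mean
#' squared displacement at lags \code{frameInterval * (1, 2, ...)} up to
#' \code{maxLag} seconds, using non-overlapping time intervals anchored
#' at the first observed frame. Lags with no complete interval are
#' omitted from that trajectory's curve.
#'
#' @param x a [TrajectorySet-class]
#' @param maxLag largest lag in seconds (default 10)
#' @param segmentation "anchored" (default; strict non-overlapping grid
#'   starting at the first frame) or "offset" (pool all grid offsets;
#'   sensitivity variant)
#' @param lags optional subset of lag times (seconds, multiples of the
#'   frame interval) to evaluate instead of the full grid up to
#'   \code{maxLag}; useful when only a summary lag is needed
#' @return a named list of [MSDCurve-class], one per cell
#' @examples
#' d <- data.frame(cell_id = "c", condition = "demo", frame = 0:4,
#'                 t_s = 0:4, x_um = c(0, 1, 1, 2, 2), y_um = c(0, 0, 1, 1, 2))
#' ts <- trajectorySet(d, frameInterval = 1)
#' msdValues(trajectoryMSD(ts, maxLag = 4)[["c"]])  # 1, 2, 5, 8
#' @export
trajectoryMSD <- function(x, maxLag = 10,
                          segmentation = c("anchored", "offset"),
                          lags = NULL) {
  stopifnot(is(x, "TrajectorySet"))
  segmentation <- match.arg(segmentation)
  dt <- x@frameInterval
  if (maxLag < dt)
    stop("'maxLag' (", maxLag, " s) is smaller than the frame interval (", dt, " s)")
  lagSteps <- if (is.null(lags)) seq_len(floor(maxLag / dt + 1e-9))
              else sort(unique(as.integer(round(lags / dt))))
  if (any(lagSteps < 1L)) stop("'lags' must be positive multiples of the frame interval")
  d <- x@data
  cells <- split(d, d$cell_id)
  out <- lapply(cells, function(cd) {
    if (nrow(cd) < 2L)
      stop("trajectory '", cd$cell_id[1L], "' has fewer than 2 positions")
    r <- .msdOneTrajectory(cd$frame, cd$x_um, cd$y_um, lagSteps, segmentation)
    keep <- r$n > 0L
    methods::new("MSDCurve", lags = lagSteps[keep] * dt, msd = r$msd[keep],
                 nIntervals = as.numeric(r$n[keep]),
                 nTrajectories = rep(1, sum(keep)), level = "trajectory",
                 frameInterval = dt, cellId = cd$cell_id[1L],
                 condition = cd$condition[1L])
  })
  out[order(names(out))]
}

#' Population-averaged MSD
#'
#' Unweighted mean across trajectories at each lag: each cell counts
#' once, regardless of how many intervals contributed to its own
#' time-averaged value. Lags present in only some curves are averaged
#' over the curves that have them.
#'
#' @param curves list of trajectory-level [MSDCurve-class] objects
#'   sharing one frame interval
#' @param condition condition label for the averaged curve (default: the
#'   common label of the inputs, or "")
#' @return a population-level [MSDCurve-class]
#' @export
populationMSD <- function(curves, condition = NULL) {
  if (is(curves, "MSDCurve")) curves <- list(curves)
  if (!length(curves)) stop("no MSD curves supplied")
  stopifnot(all(vapply(curves, is, TRUE, "MSDCurve")))
  dts <- vapply(curves, function(cv) cv@frameInterval, 0)
  if (diff(range(dts)) > 1e-12)
    stop("curves do not share a frame interval")
  dt <- dts[1L]
  steps <- lapply(curves, function(cv) as.integer(round(cv@lags / dt)))
  allSteps <- sort(unique(unlist(steps)))
  sums <- numeric(length(allSteps))
  ns <- numeric(length(allSteps))
  ints <- numeric(length(allSteps))
  for (i in seq_along(curves)) {
    idx <- match(steps[[i]], allSteps)
    sums[idx] <- sums[idx] + curves[[i]]@msd
    ints[idx] <- ints[idx] + curves[[i]]@nIntervals
    ns[idx] <- ns[idx] + 1
  }
  if (is.null(condition)) {
    conds <- unique(vapply(curves, function(cv) cv@condition, ""))
    condition <- if (length(conds) == 1L) conds else ""
  }
  methods::new("MSDCurve", lags = allSteps * dt, msd = sums / ns,
               nIntervals = ints, nTrajectories = ns, level = "population",
               frameInterval = dt, cellId = "", condition = condition)
}

#' Fit the anomalous-diffusion power law MSD ~ D * t^alpha
#'
#' Ordinary least squares of log(MSD) on log(lag) over the lags inside
#' the fit window (both endpoints inclusive). alpha is the slope and
#' D = exp(intercept). Non-positive MSD values inside the window are
#' excluded with a warning.
#'
#' @param curve an [MSDCurve-class]
#' @param window c(t_min, t_max) in seconds; default c(0.1, 10), i.e.
#'   from the first lag of a 100 ms acquisition through the 10 s
#'   summary lag
#' @param method "ols" (default, log-log least squares) or "nls"
#'   (nonlinear least squares on the natural scale, started from the OLS
#'   solution; reported in the same object)
#' @return a [PowerLawFit-class]
#' @examples
#' cv <- methods::new("MSDCurve", lags = c(1, 2, 4), msd = c(1, 2, 8),
#'                    nIntervals = c(4, 2, 1), nTrajectories = rep(1, 3),
#'                    level = "trajectory", frameInterval = 1,
#'                    cellId = "c", condition = "")
#' fitPowerLaw(cv, window = c(1, 4))  # alpha ~ 1.50, D ~ 0.89
#' @export
fitPowerLaw <- function(curve, window = c(0.1, 10), method = c("ols", "nls")) {
  stopifnot(is(curve, "MSDCurve"), length(window) == 2L, window[1] < window[2])
  method <- match.arg(method)
  tol <- 1e-9
  sel <- curve@lags >= window[1] - tol & curve@lags <= window[2] + tol
  lag <- curve@lags[sel]
  msd <- curve@msd[sel]
  if (any(msd <= 0)) {
    warning(sum(msd <= 0), " lag(s) with MSD <= 0 excluded from the fit")
    lag <- lag[msd > 0]
    msd <- msd[msd > 0]
  }
  if (length(lag) < 3L)
    stop("fewer than 3 usable lags in the fit window [",
         window[1], ", ", window[2], "] s")
  fit <- stats::lm(log(msd) ~ log(lag))
  co <- stats::coef(fit)
  alpha <- unname(co[2L])
  D <- exp(unname(co[1L]))
  if (method == "nls") {
    # scaleOffset makes the convergence test well defined for
    # zero-residual (exact power-law) inputs
    nf <- try(stats::nls(msd ~ A * lag^a, start = list(A = D, a = alpha),
                         control = stats::nls.control(scaleOffset = 1)),
              silent = TRUE)
    if (!inherits(nf, "try-error")) {
      cf <- stats::coef(nf)
      D <- unname(cf["A"]); alpha <- unname(cf["a"])
    } else warning("nls did not converge; returning the log-log OLS fit")
  }
  # summary.lm warns on numerically perfect fits (exact power laws)
  sm <- suppressWarnings(summary(fit))
  methods::new("PowerLawFit", amplitude = D, alpha = alpha,
               fitWindow = as.numeric(window),
               rSquared = max(0, min(1, sm$r.squared)),
               stderrAlpha = unname(sm$coefficients[2L, 2L]),
               nPoints = length(lag))
}

#' MSD at a given lag
#'
#' Returns the exact grid value when \code{lag} is a stored lag of the
#' curve; otherwise interpolates linearly in log-log space between the
#' flanking lags (exact on power laws).
#'
#' @param curve an [MSDCurve-class]
#' @param lag lag time in seconds (default 10, the summary lag)
#' @return MSD in um^2
#' @export
msdAtLag <- function(curve, lag = 10) {
  stopifnot(is(curve, "MSDCurve"))
  lags <- curve@lags
  if (!length(lags)) stop("empty MSD curve")
  tol <- 1e-9 * max(1, lag)
  hit <- which(abs(lags - lag) <= tol)
  if (length(hit)) return(curve@msd[hit[1L]])
  if (lag < min(lags) - tol || lag > max(lags) + tol)
    stop("lag ", lag, " s outside the curve range [", min(lags), ", ",
         max(lags), "] s")
  hi <- which(lags > lag)[1L]
  lo <- hi - 1L
  if (curve@msd[lo] <= 0 || curve@msd[hi] <= 0)
    stop("cannot log-interpolate across non-positive MSD values")
  w <- (log(lag) - log(lags[lo])) / (log(lags[hi]) - log(lags[lo]))
  exp((1 - w) * log(curve@msd[lo]) + w * log(curve@msd[hi]))
}

#' Fold change of MSD between two curves at a lag
#'
#' @param curveNum,curveDen numerator and denominator [MSDCurve-class]
#' @param lag lag in seconds (default 10)
#' @return \code{msdAtLag(curveNum, lag) / msdAtLag(curveDen, lag)}
#' @export
foldChange <- function(curveNum, curveDen, lag = 10) {
  den <- msdAtLag(curveDen, lag)
  if (den == 0) stop("denominator MSD at lag ", lag, " s is zero")
  msdAtLag(curveNum, lag) / den
}

#' Per-cell MSD at a lag
#'
#' Convenience extractor: evaluates [msdAtLag()] on every
#' trajectory-level curve, returning the per-cell summary values used by
#' box plots and rank-sum comparisons.
#'
#' @param curves named list of trajectory-level [MSDCurve-class]
#' @param lag lag in seconds
#' @return data.frame(cell_id, condition, msd)
#' @export
perCellMSD <- function(curves, lag = 10) {
  vals <- vapply(curves, function(cv) {
    tryCatch(msdAtLag(cv, lag), error = function(e) NA_real_)
  }, 0)
  data.frame(cell_id = vapply(curves, function(cv) cv@cellId, ""),
             condition = vapply(curves, function(cv) cv@condition, ""),
             msd = unname(vals), row.names = NULL, stringsAsFactors = FALSE)
}
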