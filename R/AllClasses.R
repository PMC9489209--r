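# S4 containers for the chromatin-mobility pipeline.
#
# All positions are micrometres; pixel units appear only at the image
# boundary (FrameStack). Frames are 0-based so that t_s = frame *
# frameInterval starts at 0 for the first acquired frame.

.REQUIRED_TRAJ_COLS <- c("cell_id", "condition", "frame", "t_s", "x_um", "y_um")

#' Parameterization of the synthetic trajectory generator
#'
#' Holds every knob of the fractional-Brownian-motion (fBm) generator:
#' the Hurst exponent H (anomalous exponent alpha = 2H), the generalized
#' diffusion amplitude of the 2D ensemble law MSD(t) = amplitude * t^alpha
#' (units um^2/s^alpha), movie geometry, measurement-noise sigma, drift,
#' nuclear confinement radius and the mixture of conditions to simulate.
#'
#' @slot presetName label of the preset this config derives from ("" if none)
#' @slot hurst Hurst exponent, in (0, 1); alpha = 2 * hurst
#' @slot amplitude 2D generalized diffusion coefficient, um^2/s^alpha
#' @slot nFrames number of frames per trajectory (>= 2)
#' @slot frameInterval frame spacing Delta-t in seconds
#' @slot localizationSigma measurement (localization) noise sigma in um;
#'   applied by [addLocalizationNoise()] and emulated by rendered movies,
#'   never baked into the motion itself
#' @slot driftVelocity constant field drift, um/frame, length-2 vector
#' @slot confinementRadius reflecting-disc radius in um (0 = unconfined)
#' @slot nCells number of cells simulated by [simulatePopulation()]
#' @slot mixtureFractions named numeric, condition -> fraction (sums to 1)
#' @slot seed integer seed; identical config + seed gives bitwise-identical
#'   output
#' @export
setClass("SimulationConfig", representation(
  presetName = "character",
  hurst = "numeric",
  amplitude = "numeric",
  nFrames = "integer",
  frameInterval = "numeric",
  localizationSigma = "numeric",
  driftVelocity = "numeric",
  confinementRadius = "numeric",
  nCells = "integer",
  mixtureFractions = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@hurst) || object@hurst <= 0 || object@hurst >= 1)
    msg <- c(msg, "'hurst' must be a single finite value in (0, 1)")
  if (!num1(object@amplitude) || object@amplitude <= 0)
    msg <- c(msg, "'amplitude' must be a single finite value > 0")
  if (!num1(object@nFrames) || object@nFrames < 2L)
    msg <- c(msg, "'nFrames' must be >= 2")
  if (!num1(object@frameInterval) || object@frameInterval <= 0)
    msg <- c(msg, "'frameInterval' must be > 0")
  if (!num1(object@localizationSigma) || object@localizationSigma < 0)
    msg <- c(msg, "'localizationSigma' must be >= 0")
  if (length(object@driftVelocity) != 2L || !all(is.finite(object@driftVelocity)))
    msg <- c(msg, "'driftVelocity' must be a finite length-2 vector (um/frame)")
  if (!num1(object@confinementRadius) || object@confinementRadius < 0)
    msg <- c(msg, "'confinementRadius' must be >= 0")
  if (!num1(object@nCells) || object@nCells < 1L)
    msg <- c(msg, "'nCells' must be >= 1")
  mf <- object@mixtureFractions
  if (length(mf) == 0L || is.null(names(mf)) || any(!nzchar(names(mf))))
    msg <- c(msg, "'mixtureFractions' must be a non-empty named numeric vector")
  else if (any(!is.finite(mf)) || any(mf < 0) || abs(sum(mf) - 1) > 1e-9)
    msg <- c(msg, "'mixtureFractions' must be non-negative and sum to 1 (tol 1e-9)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Set of locus trajectories
#'
#' Wraps a long-format table of time-ordered 2D positions, one locus per
#' cell, each labeled with an experimental condition. This is the unit of
#' all downstream statistics. Columns: \code{cell_id}, \code{condition},
#' \code{frame} (0-based integer), \code{t_s} (seconds), \code{x_um},
#' \code{y_um}, and optionally \code{snr}. Frame gaps are allowed and are
#' never interpolated.
#'
#' @slot data the trajectory table (data.frame)
#' @slot frameInterval acquisition frame interval in seconds
#' @slot qc data.frame of per-cell QC annotations (cell_id, reason)
#' @slot metadata free-form list (seed, preset, provenance, ...)
#' @export
setClass("TrajectorySet", representation(
  data = "data.frame",
  frameInterval = "numeric",
  qc = "data.frame",
  metadata = "list"
))

setValidity("TrajectorySet", function(object) {
  d <- object@data
  msg <- character()
  miss <- setdiff(.REQUIRED_TRAJ_COLS, names(d))
  if (length(miss))
    return(paste("missing trajectory columns:", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    if (!all(is.finite(d$x_um)) || !all(is.finite(d$y_um)))
      msg <- c(msg, "positions must be finite")
    bad <- vapply(split(d$t_s, d$cell_id), function(t) any(diff(t) <= 0), TRUE)
    if (any(bad))
      msg <- c(msg, paste0("times not strictly increasing for cell(s): ",
                           paste(names(bad)[bad], collapse = ", ")))
  }
  if (!(length(object@frameInterval) == 1L && is.finite(object@frameInterval) &&
        object@frameInterval > 0))
    msg <- c(msg, "'frameInterval' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Rendered (or acquired) multi-frame image stack
#'
#' @slot pixels 3D intensity array, dim = c(nrow, ncol, nframes),
#'   non-negative counts
#' @slot pixelSize pixel size in um (default 0.108)
#' @slot frameInterval frame interval in seconds
#' @slot groundTruth optional TrajectorySet of the true positions used for
#'   rendering (NULL for real data)
#' @slot metadata list (seed, preset, rendering parameters, clip warnings)
#' @export
setClass("FrameStack", representation(
  pixels = "array",
  pixelSize = "numeric",
  frameInterval = "numeric",
  groundTruth = "ANY",
  metadata = "list"
))

setValidity("FrameStack", function(object) {
  msg <- character()
  if (length(dim(object@pixels)) != 3L)
    msg <- c(msg, "'pixels' must be a 3D array (row, col, frame)")
  if (any(object@pixels < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (!(length(object@pixelSize) == 1L && object@pixelSize > 0))
    msg <- c(msg, "'pixelSize' must be > 0")
  if (!is.null(object@groundTruth) && !is(object@groundTruth, "TrajectorySet"))
    msg <- c(msg, "'groundTruth' must be NULL or a TrajectorySet")
  if (length(msg)) msg else TRUE
})

#' Mean squared displacement curve
#'
#' Lag times (s) versus MSD (um^2), with the number of non-overlapping
#' intervals contributing to each lag. Exists at two levels: per
#' trajectory (time-averaged MSD of one cell) and population (unweighted
#' mean across cells at each lag). MSD at lag 0 is identically 0 by
#' definition and is not stored.
#'
#' @slot lags lag times in seconds, strictly increasing multiples of the
#'   frame interval
#' @slot msd mean squared displacement, um^2
#' @slot nIntervals displacement segments per lag (trajectory level) or
#'   summed over cells (population level)
#' @slot nTrajectories trajectories contributing per lag (population level;
#'   1 at trajectory level)
#' @slot level "trajectory" or "population"
#' @slot frameInterval seconds
#' @slot cellId cell identifier ("" at population level)
#' @slot condition condition label ("" if mixed/unknown)
#' @export
setClass("MSDCurve", representation(
  lags = "numeric",
  msd = "numeric",
  nIntervals = "numeric",
  nTrajectories = "numeric",
  level = "character",
  frameInterval = "numeric",
  cellId = "character",
  condition = "character"
))

setValidity("MSDCurve", function(object) {
  msg <- character()
  n <- length(object@lags)
  if (length(object@msd) != n || length(object@nIntervals) != n ||
      length(object@nTrajectories) != n)
    msg <- c(msg, "lags, msd, nIntervals, nTrajectories must have equal length")
  if (n && any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (any(object@msd < 0))
    msg <- c(msg, "msd must be >= 0")
  if (!object@level %in% c("trajectory", "population"))
    msg <- c(msg, "level must be 'trajectory' or 'population'")
  if (length(msg)) msg else TRUE
})

#' Anomalous-diffusion power-law fit MSD ~ D * t^alpha
#'
#' @slot amplitude fitted D, um^2/s^alpha (exp of the log-log intercept)
#' @slot alpha fitted anomalous exponent (log-log slope)
#' @slot fitWindow c(t_min, t_max) in seconds; only lags inside were used
#' @slot rSquared coefficient of determination of the log-log regression
#' @slot stderrAlpha standard error of the slope
#' @slot nPoints number of lags used
#' @export
setClass("PowerLawFit", representation(
  amplitude = "numeric",
  alpha = "numeric",
  fitWindow = "numeric",
  rSquared = "numeric",
  stderrAlpha = "numeric",
  nPoints = "integer"
))

setValidity("PowerLawFit", function(object) {
  msg <- character()
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (length(object@fitWindow) != 2L) msg <- c(msg, "fitWindow must have length 2")
  if (!is.na(object@rSquared) && (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Global (field-wide) drift series
#'
#' Cumulative 2D displacement per frame, anchored at 0 for the first
#' frame. Frames whose increment could not be estimated from >= 2 loci
#' are flagged (their increment is 0).
#'
#' @slot frames 0-based frame indices covering every frame present in the
#'   trajectory set
#' @slot displacement cumulative offset, um; matrix length(frames) x 2
#' @slot flagged logical, TRUE where < 2 loci contributed
#' @export
setClass("DriftSeries", representation(
  frames = "integer",
  displacement = "matrix",
  flagged = "logical"
))

setValidity("DriftSeries", function(object) {
  msg <- character()
  if (nrow(object@displacement) != length(object@frames) ||
      ncol(object@displacement) != 2L)
    msg <- c(msg, "'displacement' must be length(frames) x 2")
  if (length(object@flagged) != length(object@frames))
    msg <- c(msg, "'flagged' must match frames")
  if (any(!is.finite(object@displacement)))
    msg <- c(msg, "displacement must be finite")
  if (length(msg)) msg else TRUE
})

#' Spot detection and linking parameters
#'
#' @slot detectionThreshold detection threshold in units of the robust SD
#'   of the band-passed image background
#' @slot psfSigmaPx PSF Gaussian sigma in pixels
#' @slot maxLinkDisplacement maximum link displacement, um per frame
#' @slot maxGapFrames maximum number of missing frames bridged by gap
#'   closing
#' @slot minTrackLength minimum trajectory length (frames) kept by QC
#' @slot minMeanSnr minimum mean signal-to-noise ratio kept by QC
#' @export
setClass("TrackingParams", representation(
  detectionThreshold = "numeric",
  psfSigmaPx = "numeric",
  maxLinkDisplacement = "numeric",
  maxGapFrames = "integer",
  minTrackLength = "integer",
  minMeanSnr = "numeric"
))

setValidity("TrackingParams", function(object) {
  msg <- character()
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos(object@detectionThreshold)) msg <- c(msg, "detectionThreshold must be > 0")
  if (!pos(object@psfSigmaPx)) msg <- c(msg, "psfSigmaPx must be > 0")
  if (!pos(object@maxLinkDisplacement)) msg <- c(msg, "maxLinkDisplacement must be > 0")
  if (object@maxGapFrames < 0L) msg <- c(msg, "maxGapFrames must be >= 0")
  if (object@minTrackLength < 1L) msg <- c(msg, "minTrackLength must be >= 1")
  if (!pos(object@minMeanSnr)) msg <- c(msg, "minMeanSnr must be > 0")
  if (length(msg)) msg else TRUE
})

#' Two-group rank-based comparison
#'
#' Result of a two-sided Wilcoxon rank-sum (Mann-Whitney U) test with the
#' significance coding n.s. (p >= 0.05), * (p < 0.05), ** (p < 0.001),
#' *** (p < 0.0001).
#'
#' @slot groupLabels character(2)
#' @slot nPerGroup integer(2)
#' @slot statisticName "wilcoxon_rank_sum" (alias "mann_whitney_u")
#' @slot statisticValue Mann-Whitney U of the first group
#' @slot pValue two-sided p-value
#' @slot significanceCode one of "n.s.", "*", "**", "***"
#' @slot degenerate TRUE when both groups are identical constants
#' @export
setClass("PopulationComparison", representation(
  groupLabels = "character",
  nPerGroup = "integer",
  statisticName = "character",
  statisticValue = "numeric",
  pValue = "numeric",
  significanceCode = "character",
  degenerate = "logical"
))

setValidity("PopulationComparison", function(object) {
  msg <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must be in [0, 1]")
  expected <- .significanceCode(object@pValue)
  if (object@significanceCode != expected)
    msg <- c(msg, sprintf("significanceCode '%s' inconsistent with p = %g (expected '%s')",
                          object@significanceCode, object@pValue, expected))
  if (length(msg)) msg else TRUE
})

#' Box-plot summary of a sample
#'
#' Quartiles by linear interpolation between order statistics; outliers
#' are values beyond 1.5 IQR from the quartiles; whiskers span the full
#' range of the non-outlier values.
#'
#' @slot median,q1,q3 quartiles
#' @slot whiskerLow,whiskerHigh min/max of non-outlier values
#' @slot outliers values beyond the 1.5 IQR fences
#' @export
setClass("BoxSummary", representation(
  median = "numeric",
  q1 = "numeric",
  q3 = "numeric",
  whiskerLow = "numeric",
  whiskerHigh = "numeric",
  outliers = "numeric"
))

setValidity("BoxSummary", function(object) {
  if (!(object@q1 <= object@median && object@median <= object@q3))
    return("q1 <= median <= q3 violated")
  TRUE
})

#' End-to-end pipeline report
#'
#' Bundle produced by [runPipeline()]: corrected trajectories, per-condition
#' population MSD curves and power-law fits, per-cell MSD at the summary
#' lag with box summaries, pairwise rank-sum comparisons and fold changes,
#' plus the configuration, its hash and a stage log.
#'
#' @export
setClass("MobilityReport", representation(
  trajectories = "ANY",
  curves = "list",
  fits = "list",
  msdSummary = "data.frame",
  boxSummaries = "list",
  comparisons = "list",
  foldChanges = "list",
  config = "list",
  configHash = "character",
  log = "character"
))
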