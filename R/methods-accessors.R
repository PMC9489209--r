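# Accessors and show methods.

#' @describeIn TrajectorySet unique cell identifiers
#' @param x object
#' @export
setMethod("cellIds", "TrajectorySet", function(x) unique(x@data$cell_id))

#' @describeIn TrajectorySet per-cell condition labels (named by cell)
#' @export
setMethod("conditions", "TrajectorySet", function(x) {
  d <- x@data[!duplicated(x@data$cell_id), c("cell_id", "condition")]
  stats::setNames(d$condition, d$cell_id)
})

#' @describeIn TrajectorySet acquisition frame interval (s)
#' @export
setMethod("frameInterval", "TrajectorySet", function(x) x@frameInterval)

#' @describeIn TrajectorySet number of trajectories
#' @export
setMethod("nCells", "TrajectorySet", function(x) length(unique(x@data$cell_id)))

#' @describeIn TrajectorySet the long-format trajectory table
#' @export
setMethod("trajectoryData", "TrajectorySet", function(x) x@data)

#' @describeIn TrajectorySet QC annotations (cell_id, reason)
#' @export
setMethod("qcFlags", "TrajectorySet", function(x) x@qc)

#' @export
#' @describeIn TrajectorySet coerce to the underlying data.frame
setMethod("as.data.frame", "TrajectorySet", function(x, ...) x@data)

setMethod("show", "TrajectorySet", function(object) {
  d <- object@data
  nc <- length(unique(d$cell_id))
  cat("TrajectorySet with", nc, "trajectories,", nrow(d), "positions\n")
  cat("  frame interval:", object@frameInterval, "s\n")
  if (nrow(d)) {
    tab <- table(d$condition[!duplicated(d$cell_id)])
    cat("  conditions:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    cat("  frames:", min(d$frame), "..", max(d$frame), "\n")
  }
  if (nrow(object@qc))
    cat("  QC-rejected:", nrow(object@qc), "cell(s)\n")
})

#' @describeIn MSDCurve lag times (s)
#' @param x object
#' @export
setMethod("lagTimes", "MSDCurve", function(x) x@lags)

#' @describeIn MSDCurve MSD values (um^2)
#' @export
setMethod("msdValues", "MSDCurve", function(x) x@msd)

#' @describeIn MSDCurve non-overlapping intervals per lag
#' @export
setMethod("intervalCounts", "MSDCurve", function(x) x@nIntervals)

#' @describeIn MSDCurve "trajectory" or "population"
#' @export
setMethod("curveLevel", "MSDCurve", function(x) x@level)

#' @export
#' @describeIn MSDCurve coerce to data.frame (lag_s, msd_um2, n_intervals,
#'   n_trajectories)
setMethod("as.data.frame", "MSDCurve", function(x, ...) {
  data.frame(lag_s = x@lags, msd_um2 = x@msd, n_intervals = x@nIntervals,
             n_trajectories = x@nTrajectories, level = x@level,
             condition = x@condition, stringsAsFactors = FALSE)
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve (%s level%s): %d lags, %g..%g s\n", object@level,
              if (nzchar(object@condition)) paste0(", ", object@condition) else "",
              length(object@lags), min(object@lags), max(object@lags)))
  if (length(object@lags))
    cat(sprintf("  MSD range %.4g..%.4g um^2\n", min(object@msd), max(object@msd)))
})

#' @describeIn PowerLawFit fitted anomalous exponent alpha
#' @param x object
#' @export
setMethod("alphaExponent", "PowerLawFit", function(x) x@alpha)

#' @describeIn PowerLawFit fitted amplitude D (um^2/s^alpha)
#' @export
setMethod("amplitude", "PowerLawFit", function(x) x@amplitude)

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: MSD ~ D t^alpha over [%g, %g] s (%d lags)\n",
              object@fitWindow[1], object@fitWindow[2], object@nPoints))
  cat(sprintf("  alpha = %.4f (se %.4f), D = %.5g um^2/s^alpha, R^2 = %.4f\n",
              object@alpha, object@stderrAlpha, object@amplitude,
              object@rSquared))
})

#' @describeIn PopulationComparison two-sided p-value
#' @param x object
#' @export
setMethod("pValue", "PopulationComparison", function(x) x@pValue)

#' @describeIn PopulationComparison significance code at the 0.05 / 0.001 /
#'   0.0001 thresholds
#' @export
setMethod("significanceCode", "PopulationComparison", function(x) x@significanceCode)

setMethod("show", "PopulationComparison", function(object) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d)\n", object@statisticName,
              object@groupLabels[1], object@nPerGroup[1],
              object@groupLabels[2], object@nPerGroup[2]))
  cat(sprintf("  U = %g, p = %.4g  %s%s\n", object@statisticValue,
              object@pValue, object@significanceCode,
              if (object@degenerate) "  [degenerate: identical constant groups]" else ""))
})

setMethod("show", "BoxSummary", function(object) {
  cat(sprintf("BoxSummary: median %.4g [q1 %.4g, q3 %.4g], whiskers %.4g..%.4g, %d outlier(s)\n",
              object@median, object@q1, object@q3, object@whiskerLow,
              object@whiskerHigh, length(object@outliers)))
})

#' @describeIn FrameStack pixel size (um)
#' @param x object
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixelSize)

#' @describeIn FrameStack ground-truth trajectories used for rendering
#' @export
setMethod("groundTruth", "FrameStack", function(x) x@groundTruth)

#' @describeIn FrameStack acquisition frame interval (s)
#' @export
setMethod("frameInterval", "FrameStack", function(x) x@frameInterval)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FrameStack: %d frames of %d x %d px (%.3f um/px, %g s/frame)\n",
              d[3], d[1], d[2], object@pixelSize, object@frameInterval))
  if (!is.null(object@groundTruth))
    cat("  carries ground truth for", nCells(object@groundTruth), "spot(s)\n")
})

setMethod("show", "DriftSeries", function(object) {
  n <- length(object@frames)
  tot <- sqrt(sum(object@displacement[n, ]^2))
  cat(sprintf("DriftSeries over frames %d..%d; net displacement %.4g um; %d flagged frame(s)\n",
              object@frames[1], object@frames[n], tot, sum(object@flagged)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig",
      if (nzchar(object@presetName)) sprintf("[preset %s]", object@presetName) else "",
      "\n")
  cat(sprintf("  H = %g (alpha = %g), A = %.5g um^2/s^alpha\n",
              object@hurst, 2 * object@hurst, object@amplitude))
  cat(sprintf("  %d frames @ %g s; sigma_loc = %g um; confinement R = %g um\n",
              object@nFrames, object@frameInterval, object@localizationSigma,
              object@confinementRadius))
  cat(sprintf("  %d cells; mixture: %s; seed %d\n", object@nCells,
              paste(sprintf("%s=%.3g", names(object@mixtureFractions),
                            object@mixtureFractions), collapse = ", "),
              object@seed))
})

setMethod("show", "MobilityReport", function(object) {
  cat("MobilityReport (config", substr(object@configHash, 1, 8), ")\n")
  for (cond in names(object@fits)) {
    f <- object@fits[[cond]]
    m10 <- object@msdSummary$msd10[object@msdSummary$condition == cond]
    cat(sprintf("  %s: n=%d, alpha=%.3f, D=%.4g, MSD@10s=%.4g um^2 (population)\n",
                cond, sum(object@msdSummary$condition == cond),
                f@alpha, f@amplitude,
                msdAtLag(object@curves[[cond]], 10)))
  }
  for (cmp in object@comparisons) methods::show(cmp)
  invisible(NULL)
})
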