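# End-to-end orchestration: track -> drift-correct -> qc -> msd -> fit
# -> population statistics, with a provenance log.

#' Default pipeline configuration
#'
#' One versioned list of every pipeline default: acquisition geometry
#' (108 nm pixels, 100 ms frames, 1800-frame movies), tracking
#' parameters, MSD settings (10 s maximum lag, fit window 0.1--10 s,
#' anchored non-overlapping segmentation, 10 s summary lag) and the
#' significance thresholds 0.05 / 0.001 / 0.0001. CLI flags and function
#' arguments override entries; nothing is hard-coded in the stages.
#'
#' @param ... replacements for top-level entries
#' @return a named list
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    acquisition = list(pixel_size_um = 0.108, frame_interval_s = 0.1,
                       movie_length_frames = 1800L),
    tracking = list(detection_threshold = 5, psf_sigma_px = 1.2,
                    max_link_displacement_um = 0.5, max_gap_frames = 2L,
                    min_track_length = 100L, min_mean_snr = 2),
    msd = list(max_lag_s = 10, fit_window_s = c(0.1, 10),
               segmentation = "anchored", summary_lag_s = 10),
    stats = list(alpha_levels = c(0.05, 0.001, 0.0001)),
    seed = 1L,
    log_level = "info")
  repl <- list(...)
  for (nm in names(repl)) {
    if (is.list(cfg[[nm]]) && is.list(repl[[nm]]))
      cfg[[nm]][names(repl[[nm]])] <- repl[[nm]]
    else cfg[[nm]] <- repl[[nm]]
  }
  cfg
}

# md5 of a canonical text rendering of a config list
.configHash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))], control = "all"),
               collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

.trackingParamsFrom <- function(cfg) {
  t <- cfg$tracking
  trackingParams(detectionThreshold = t$detection_threshold,
                 psfSigmaPx = t$psf_sigma_px,
                 maxLinkDisplacement = t$max_link_displacement_um,
                 maxGapFrames = t$max_gap_frames,
                 minTrackLength = t$min_track_length,
                 minMeanSnr = t$min_mean_snr)
}

#' Run the full mobility analysis
#'
#' Orchestrates the chain on any supported input: a preset name or
#' [SimulationConfig-class] (simulated population), a
#' [FrameStack-class] (tracked first), a [TrajectorySet-class], or a
#' path to a trajectory TSV / TIFF movie. Stages: track (movies only)
#' -> global drift estimation and correction -> QC filter -> per-cell
#' MSD -> per-condition population MSD and power-law fit -> per-cell
#' MSD at the summary lag with box summaries -> pairwise rank-sum
#' comparisons and fold changes (both the MSD ratio at the summary lag
#' and the fitted-amplitude ratio). Any stage failure aborts with the
#' stage name. The report carries the configuration, its hash and a
#' stage log with counts.
#'
#' @param input see above
#' @param config a [pipelineConfig()] list
#' @return a [MobilityReport-class]
#' @examples
#' \donttest{
#' rep <- runPipeline(presetConfig("brownian-control", nCells = 50L))
#' alphaExponent(rep@fits[["brownian-control"]])
#' }
#' @export
runPipeline <- function(input, config = pipelineConfig()) {
  log <- character()
  note <- function(...) {
    line <- sprintf(...)
    if (identical(config$log_level, "info")) message(line)
    log <<- c(log, line)
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ts <- stage("input", {
    if (is(input, "SimulationConfig")) {
      note("simulate: preset '%s', %d cells, seed %d",
           input@presetName, input@nCells, input@seed)
      simulatePopulation(input)
    } else if (is.character(input) && input %in% presetNames()) {
      cfg <- presetConfig(input, seed = config$seed)
      note("simulate: preset '%s', %d cells, seed %d", input,
           cfg@nCells, cfg@seed)
      simulatePopulation(cfg)
    } else if (is(input, "FrameStack")) {
      note("track: %d frames", dim(input@pixels)[3L])
      trackMovie(input, .trackingParamsFrom(config))
    } else if (is(input, "TrajectorySet")) {
      input
    } else if (is.character(input) && file.exists(input)) {
      if (grepl("\\.tiff?$", input, ignore.case = TRUE))
        trackMovie(readMovie(input), .trackingParamsFrom(config))
      else readTrajectories(input)
    } else stop("unsupported input")
  })
  note("input: %d trajectories", nCells(ts))

  ts <- stage("drift-correct", {
    if (nCells(ts) >= 2L) {
      drift <- estimateGlobalDrift(ts)
      n <- length(drift@frames)
      note("drift-correct: net field displacement %.4g um, %d flagged frame(s)",
           sqrt(sum(drift@displacement[n, ]^2)), sum(drift@flagged))
      correctDrift(ts, drift)
    } else {
      note("drift-correct: skipped (single trajectory)")
      ts
    }
  })

  ts <- stage("qc", {
    qc <- qcFilter(ts, .trackingParamsFrom(config))
    note("qc: kept %d, rejected %d trajectory(ies)",
         nCells(qc$kept), if (nrow(qc$rejected@data)) nCells(qc$rejected) else 0L)
    if (!nCells(qc$kept)) stop("no trajectories pass QC")
    qc$kept
  })

  conds <- sort(unique(ts@data$condition))
  curvesByCell <- stage("msd", {
    seg <- if (identical(config$msd$segmentation, "offset")) "offset" else "anchored"
    trajectoryMSD(ts, maxLag = config$msd$max_lag_s, segmentation = seg)
  })
  note("msd: %d per-cell curves, max lag %g s", length(curvesByCell),
       config$msd$max_lag_s)

  cellCond <- conditions(ts)
  popCurves <- list(); fits <- list()
  stage("fit", for (cond in conds) {
    sub <- curvesByCell[names(cellCond)[cellCond == cond]]
    popCurves[[cond]] <- populationMSD(sub, condition = cond)
    fits[[cond]] <- fitPowerLaw(popCurves[[cond]],
                                window = config$msd$fit_window_s)
    note("fit [%s]: alpha = %.3f, D = %.4g um^2/s^alpha (R^2 %.3f)", cond,
         fits[[cond]]@alpha, fits[[cond]]@amplitude, fits[[cond]]@rSquared)
  })

  sumLag <- config$msd$summary_lag_s
  msdSummary <- stage("stats", {
    s <- perCellMSD(curvesByCell, lag = sumLag)
    names(s)[names(s) == "msd"] <- "msd10"
    s
  })
  boxes <- lapply(split(msdSummary$msd10, msdSummary$condition),
                  function(v) boxSummary(v[is.finite(v)]))
  comparisons <- list(); folds <- list()
  if (length(conds) > 1L) {
    prs <- utils::combn(conds, 2L, simplify = FALSE)
    for (pr in prs) {
      va <- msdSummary$msd10[msdSummary$condition == pr[1L]]
      vb <- msdSummary$msd10[msdSummary$condition == pr[2L]]
      key <- paste(pr, collapse = " vs ")
      comparisons[[key]] <- rankSumTest(va[is.finite(va)], vb[is.finite(vb)],
                                        labels = pr)
      folds[[key]] <- list(
        msd_ratio = foldChange(popCurves[[pr[1L]]], popCurves[[pr[2L]]],
                               lag = sumLag),
        amplitude_ratio = fits[[pr[1L]]]@amplitude / fits[[pr[2L]]]@amplitude)
      note("compare [%s]: p = %.3g %s", key, comparisons[[key]]@pValue,
           comparisons[[key]]@significanceCode)
    }
  }

  methods::new("MobilityReport", trajectories = ts, curves = popCurves,
               fits = fits, msdSummary = msdSummary, boxSummaries = boxes,
               comparisons = comparisons, foldChanges = folds,
               config = config, configHash = .configHash(config), log = log)
}

#' Serialize a report summary as JSON
#'
#' Deterministic summary (no timestamps): per-condition population MSD
#' at the summary lag, power-law fits, box summaries, comparisons, fold
#' changes, the configuration and its hash. Re-running the pipeline with
#' the same config and seed reproduces the same bytes.
#'
#' @param report a [MobilityReport-class]
#' @param path optional output file
#' @return the JSON string, invisibly when \code{path} is given
#' @export
summaryJSON <- function(report, path = NULL) {
  box2list <- function(b) list(median = b@median, q1 = b@q1, q3 = b@q3,
                               whisker_low = b@whiskerLow,
                               whisker_high = b@whiskerHigh,
                               outliers = b@outliers)
  cmp2list <- function(cm) list(groups = cm@groupLabels,
                                n = cm@nPerGroup,
                                statistic = cm@statisticName,
                                U = cm@statisticValue, p_value = cm@pValue,
                                significance = cm@significanceCode)
  fit2list <- function(f) list(alpha = f@alpha, amplitude = f@amplitude,
                               fit_window_s = f@fitWindow,
                               r_squared = f@rSquared,
                               stderr_alpha = f@stderrAlpha,
                               n_points = f@nPoints)
  sumLag <- report@config$msd$summary_lag_s
  out <- list(
    config_hash = report@configHash,
    config = report@config,
    n_cells = stats::setNames(
      as.list(as.integer(table(report@msdSummary$condition))),
      names(table(report@msdSummary$condition))),
    msd_at_summary_lag = lapply(report@curves, msdAtLag, lag = sumLag),
    fits = lapply(report@fits, fit2list),
    box_summaries = lapply(report@boxSummaries, box2list),
    comparisons = lapply(report@comparisons, cmp2list),
    fold_changes = report@foldChanges,
    log = report@log)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
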