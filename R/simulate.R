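# Synthetic locus-trajectory generator: confined fractional Brownian
# motion, measurement-noise overlay, drift injection, condition mixtures.

# Preset amplitudes (um^2/s^alpha) solved so that the simulated
# population observable -- the time-averaged, non-overlapping MSD at a
# 10 s lag under the preset's 0.9 um reflecting confinement -- equals the
# per-condition reference value (0.049 / 0.064 / 0.088 um^2). The
# closed-form A = MSD10 / 10^alpha is corrected for the small confinement
# bias by Monte-Carlo fixed-point calibration (see calibrateAmplitude and
# the methods vignette). brownian-control is a noise-free, unconfined
# estimator control with the same 10 s MSD as the undamaged preset.
.PRESETS <- list(
  "undamaged-baseline" = list(hurst = 0.30, amplitude = 0.0123593, msd10 = 0.049,
                              localizationSigma = 0.03, confinementRadius = 0.9),
  "repaired-red"       = list(hurst = 0.30, amplitude = 0.0162356, msd10 = 0.064,
                              localizationSigma = 0.03, confinementRadius = 0.9),
  "damaged-white"      = list(hurst = 0.35, amplitude = 0.0181304, msd10 = 0.088,
                              localizationSigma = 0.03, confinementRadius = 0.9),
  "brownian-control"   = list(hurst = 0.50, amplitude = 0.0049, msd10 = 0.049,
                              localizationSigma = 0, confinementRadius = 0)
)

#' Names of the built-in simulation presets
#' @return character vector of valid preset names
#' @export
presetNames <- function() names(.PRESETS)

#' Construct a simulation configuration
#'
#' @param hurst Hurst exponent H in (0, 1); the ensemble MSD scales as
#'   t^alpha with alpha = 2H
#' @param amplitude 2D generalized diffusion coefficient A of
#'   MSD(t) = A * t^alpha, um^2/s^alpha
#' @param nFrames frames per trajectory
#' @param frameInterval seconds between frames (default 0.1 s)
#' @param localizationSigma measurement noise sigma (um) used by
#'   [addLocalizationNoise()] and movie rendering; not applied to the
#'   motion itself
#' @param driftVelocity constant stage drift, um/frame (length 2)
#' @param confinementRadius reflecting-disc radius (um); 0 disables
#' @param nCells population size for [simulatePopulation()]
#' @param mixtureFractions named fractions of conditions; names may be
#'   preset names (their motion parameters are used) or free labels
#'   (this config's own hurst/amplitude are used)
#' @param seed integer seed; per-cell RNG streams are derived from it
#' @param presetName optional preset label carried in metadata
#' @return a validated [SimulationConfig-class] object
#' @export
simulationConfig <- function(hurst, amplitude, nFrames = 1800L,
                             frameInterval = 0.1, localizationSigma = 0.03,
                             driftVelocity = c(0, 0), confinementRadius = 0.9,
                             nCells = 500L, mixtureFractions = NULL,
                             seed = 1L, presetName = "") {
  if (is.null(mixtureFractions)) {
    lab <- if (nzchar(presetName)) presetName else "condition_1"
    mixtureFractions <- stats::setNames(1, lab)
  }
  methods::new("SimulationConfig",
    presetName = presetName, hurst = as.numeric(hurst),
    amplitude = as.numeric(amplitude), nFrames = as.integer(nFrames),
    frameInterval = as.numeric(frameInterval),
    localizationSigma = as.numeric(localizationSigma),
    driftVelocity = as.numeric(driftVelocity),
    confinementRadius = as.numeric(confinementRadius),
    nCells = as.integer(nCells), mixtureFractions = mixtureFractions,
    seed = as.integer(seed))
}

#' Built-in simulation presets
#'
#' Returns a fully populated configuration for one of the study
#' conditions: \code{"undamaged-baseline"} (subdiffusive, alpha = 0.6,
#' population MSD at 10 s of 0.049 um^2), \code{"repaired-red"}
#' (0.064 um^2, alpha = 0.6), \code{"damaged-white"} (0.088 um^2 with the
#' documented assumption alpha = 0.7), and \code{"brownian-control"}
#' (H = 0.5, noise-free, unconfined; an estimator control). All presets
#' use 1800 frames at 0.1 s intervals (3 min movies).
#'
#' @param name preset name, see [presetNames()]
#' @param nCells,seed overrides passed to [simulationConfig()]
#' @return a [SimulationConfig-class]
#' @examples
#' presetConfig("brownian-control")@hurst  # 0.5
#' @export
presetConfig <- function(name, nCells = 500L, seed = 1L) {
  if (length(name) != 1L || !name %in% names(.PRESETS))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(.PRESETS), collapse = ", "))
  p <- .PRESETS[[name]]
  simulationConfig(hurst = p$hurst, amplitude = p$amplitude,
                   localizationSigma = p$localizationSigma,
                   confinementRadius = p$confinementRadius,
                   nCells = nCells, seed = seed, presetName = name,
                   mixtureFractions = stats::setNames(1, name))
}

#' Construct a TrajectorySet
#'
#' @param data data.frame with columns cell_id, condition, frame, t_s,
#'   x_um, y_um (optionally snr)
#' @param frameInterval seconds
#' @param qc optional data.frame(cell_id, reason) of QC annotations
#' @param metadata optional list
#' @return a validated [TrajectorySet-class]
#' @export
trajectorySet <- function(data, frameInterval, qc = NULL, metadata = list()) {
  if (is.null(qc))
    qc <- data.frame(cell_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  data$cell_id <- as.character(data$cell_id)
  data$condition <- as.character(data$condition)
  data$frame <- as.integer(data$frame)
  methods::new("TrajectorySet", data = data,
               frameInterval = as.numeric(frameInterval),
               qc = qc, metadata = metadata)
}

## ---- reproducible per-cell RNG streams -------------------------------

# L'Ecuyer-CMRG stream seeds 1..n derived from one top-level seed.
# Stream i is obtained by advancing nextRNGStream i times, so a
# population is reproducible and each cell's stream is independent of
# the order in which cells are simulated.
.streamSeeds <- function(seed, n) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

.withStream <- function(streamSeed, expr) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  assign(".Random.seed", streamSeed, envir = globalenv())
  expr
}

## ---- trajectory synthesis --------------------------------------------

# One motion path (um) from the current RNG stream. Order of effects:
# fGn increments -> cumulative sum -> reflecting confinement -> drift.
.simMotionPath <- function(plan, config) {
  inc <- .fgnPair(plan)
  x <- c(0, cumsum(inc$x))
  y <- c(0, cumsum(inc$y))
  if (config@confinementRadius > 0) {
    p <- .reflectDisc(x, y, config@confinementRadius)
    x <- p$x; y <- p$y
  }
  v <- config@driftVelocity
  if (any(v != 0)) {
    k <- 0:(config@nFrames - 1L)
    x <- x + v[1L] * k
    y <- y + v[2L] * k
  }
  list(x = x, y = y)
}

.motionPlan <- function(config) {
  sigma2 <- (config@amplitude / 2) * config@frameInterval^(2 * config@hurst)
  .fgnPlan(config@nFrames - 1L, config@hurst, sigma2)
}

#' Simulate one locus trajectory
#'
#' Draws a 2D trajectory whose per-axis increments are exact fractional
#' Gaussian noise with the configured Hurst exponent, scaled so the
#' unconfined ensemble 2D MSD is \code{amplitude * t^(2*hurst)} (each
#' axis carries amplitude/2). A reflecting disc boundary is applied when
#' \code{confinementRadius > 0}, then constant drift. The returned
#' positions are the motion ground truth; measurement noise is a
#' separate overlay, see [addLocalizationNoise()].
#'
#' @param config a [SimulationConfig-class]
#' @param cellId identifier for the simulated cell
#' @param streamIndex which derived RNG stream to use (cell i of a
#'   population uses stream i)
#' @return a [TrajectorySet-class] with one trajectory
#' @export
simulateTrajectory <- function(config, cellId = "cell_1", streamIndex = 1L) {
  methods::validObject(config)
  plan <- .motionPlan(config)
  streamSeed <- .streamSeeds(config@seed, streamIndex)[[streamIndex]]
  path <- .withStream(streamSeed, .simMotionPath(plan, config))
  cond <- if (nzchar(config@presetName)) config@presetName
          else names(config@mixtureFractions)[1L]
  k <- 0:(config@nFrames - 1L)
  d <- data.frame(cell_id = cellId, condition = cond, frame = k,
                  t_s = k * config@frameInterval,
                  x_um = path$x, y_um = path$y,
                  stringsAsFactors = FALSE)
  trajectorySet(d, config@frameInterval,
                metadata = list(config = .configAsList(config)))
}

# Stratified largest-remainder allocation of nCells over conditions
# (sorted by name): label counts are exact and deterministic.
.mixtureCounts <- function(fractions, nCells) {
  fr <- fractions[order(names(fractions))]
  raw <- fr * nCells
  base <- floor(raw)
  left <- nCells - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fr))
}

#' Simulate a population of cells
#'
#' Simulates \code{nCells} trajectories. Condition labels are assigned by
#' stratified allocation over \code{mixtureFractions} (exact counts,
#' largest-remainder rounding, conditions in sorted-name order assigned in
#' cell-index blocks). A fraction named after a preset uses that preset's
#' motion parameters (hurst, amplitude); other names use the config's own.
#' Cell i is drawn from RNG stream i derived from the config seed, so the
#' population is bitwise reproducible.
#'
#' @param config a [SimulationConfig-class]
#' @return a [TrajectorySet-class] with \code{nCells} trajectories
#' @export
simulatePopulation <- function(config) {
  methods::validObject(config)
  counts <- .mixtureCounts(config@mixtureFractions, config@nCells)
  conds <- rep(names(counts), counts)
  n <- config@nCells
  seeds <- .streamSeeds(config@seed, n)
  width <- max(4L, nchar(as.character(n)))
  ids <- sprintf(paste0("cell_%0", width, "d"), seq_len(n))

  plans <- list()
  confFor <- function(cond) {
    if (cond %in% names(.PRESETS) && cond != config@presetName) {
      p <- .PRESETS[[cond]]
      cfg <- config
      cfg@hurst <- p$hurst
      cfg@amplitude <- p$amplitude
      cfg
    } else config
  }
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    cond <- conds[i]
    cfg <- confFor(cond)
    key <- cond
    if (is.null(plans[[key]])) plans[[key]] <- .motionPlan(cfg)
    path <- .withStream(seeds[[i]], .simMotionPath(plans[[key]], cfg))
    k <- 0:(cfg@nFrames - 1L)
    parts[[i]] <- data.frame(cell_id = ids[i], condition = cond, frame = k,
                             t_s = k * cfg@frameInterval,
                             x_um = path$x, y_um = path$y,
                             stringsAsFactors = FALSE)
  }
  trajectorySet(do.call(rbind, parts), config@frameInterval,
                metadata = list(config = .configAsList(config)))
}

#' Inject global drift into trajectories
#'
#' Translates every position by the cumulative drift at its frame. The
#' injected drift is recorded in the metadata (as a [DriftSeries-class])
#' so that correction can be verified against ground truth.
#'
#' @param x a [TrajectorySet-class]
#' @param driftVelocity either a length-2 constant velocity (um/frame) or
#'   a matrix with one row per frame (0-based frames of the set's frame
#'   range) of per-frame velocities
#' @return the shifted [TrajectorySet-class]
#' @export
applyDrift <- function(x, driftVelocity) {
  stopifnot(is(x, "TrajectorySet"))
  d <- x@data
  if (!nrow(d)) return(x)
  fmin <- min(d$frame); fmax <- max(d$frame)
  frames <- fmin:fmax
  if (is.matrix(driftVelocity)) {
    if (nrow(driftVelocity) != length(frames) || ncol(driftVelocity) != 2L)
      stop("per-frame drift must be a length(frames) x 2 matrix")
    v <- driftVelocity
  } else {
    if (length(driftVelocity) != 2L || any(!is.finite(driftVelocity)))
      stop("'driftVelocity' must be a finite 2-vector or per-frame matrix")
    v <- matrix(driftVelocity, nrow = length(frames), ncol = 2L, byrow = TRUE)
  }
  # cumulative displacement; zero at the first frame of the range
  cum <- apply(v, 2L, cumsum)
  cum <- sweep(cum, 2L, cum[1L, ])
  idx <- match(d$frame, frames)
  d$x_um <- d$x_um + cum[idx, 1L]
  d$y_um <- d$y_um + cum[idx, 2L]
  out <- x
  out@data <- d
  out@metadata$injectedDrift <- methods::new("DriftSeries",
    frames = as.integer(frames), displacement = cum,
    flagged = logical(length(frames)))
  out
}

#' Overlay localization (measurement) noise
#'
#' Adds i.i.d. Gaussian noise of standard deviation \code{sigma} to every
#' coordinate, emulating the localization error of a spot tracker. For a
#' stationary emitter this raises the 2D MSD by 4 sigma^2 at every lag.
#' Uses the current RNG state; call \code{set.seed()} for reproducibility.
#'
#' @param x a [TrajectorySet-class]
#' @param sigma noise sigma in um
#' @return the noisy [TrajectorySet-class]
#' @export
addLocalizationNoise <- function(x, sigma) {
  stopifnot(is(x, "TrajectorySet"), is.finite(sigma), sigma >= 0)
  if (sigma == 0) return(x)
  n <- nrow(x@data)
  x@data$x_um <- x@data$x_um + stats::rnorm(n, 0, sigma)
  x@data$y_um <- x@data$y_um + stats::rnorm(n, 0, sigma)
  x@metadata$localizationSigma <- sigma
  x
}

#' Calibrate a preset amplitude against the confined MSD observable
#'
#' Solves the generalized diffusion amplitude A such that the population
#' time-averaged MSD at \code{lag} seconds, computed with non-overlapping
#' intervals on trajectories confined to \code{confinementRadius}, equals
#' \code{msdTarget}. Starts from the unconfined closed form
#' A = msdTarget / lag^alpha and applies Monte-Carlo fixed-point
#' corrections. Used once to freeze the shipped preset amplitudes.
#'
#' @param msdTarget target MSD at \code{lag}, um^2
#' @param hurst Hurst exponent
#' @param lag calibration lag in seconds (default 10)
#' @param confinementRadius um
#' @param nFrames,frameInterval movie geometry
#' @param nTrajectories Monte-Carlo sample size per iteration
#' @param iterations fixed-point iterations
#' @param seed RNG seed
#' @return the calibrated amplitude (um^2/s^alpha)
#' @export
calibrateAmplitude <- function(msdTarget, hurst, lag = 10,
                               confinementRadius = 0.9, nFrames = 1800L,
                               frameInterval = 0.1, nTrajectories = 5000L,
                               iterations = 2L, seed = 1L) {
  alpha <- 2 * hurst
  A <- msdTarget / lag^alpha
  lagSteps <- as.integer(round(lag / frameInterval))
  for (it in seq_len(iterations)) {
    cfg <- simulationConfig(hurst = hurst, amplitude = A, nFrames = nFrames,
                            frameInterval = frameInterval,
                            localizationSigma = 0,
                            confinementRadius = confinementRadius,
                            nCells = as.integer(nTrajectories),
                            seed = as.integer(seed + it))
    plan <- .motionPlan(cfg)
    seeds <- .streamSeeds(cfg@seed, nTrajectories)
    v <- vapply(seq_len(nTrajectories), function(i) {
      p <- .withStream(seeds[[i]], .simMotionPath(plan, cfg))
      idx <- seq(1L, nFrames, by = lagSteps)
      mean(diff(p$x[idx])^2 + diff(p$y[idx])^2)
    }, 0)
    A <- A * msdTarget / mean(v)
  }
  A
}

# plain-list view of a config (serializable, hashable)
.configAsList <- function(config) {
  list(presetName = config@presetName, hurst = config@hurst,
       amplitude = config@amplitude, nFrames = config@nFrames,
       frameInterval = config@frameInterval,
       localizationSigma = config@localizationSigma,
       driftVelocity = config@driftVelocity,
       confinementRadius = config@confinementRadius,
       nCells = config@nCells,
       mixtureFractions = as.list(config@mixtureFractions),
       seed = config@seed)
}
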