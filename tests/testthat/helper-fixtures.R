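# Shared, memoised simulation fixtures. Everything is generated in code
# at test time under fixed seeds; expensive populations are computed
# once and reused across test files.

fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = fixtureEnv, inherits = FALSE))
    assign(name, expr, envir = fixtureEnv)
  get(name, envir = fixtureEnv, inherits = FALSE)
}

# Per-cell MSD values at one lag for n cells of a preset, simulated in
# chunks of 1000 cells (chunk c uses seed baseSeed + c) to bound memory.
msd10Pool <- function(preset, n, baseSeed, lag = 10) {
  key <- sprintf("pool_%s_%d_%d_%g", preset, n, baseSeed, lag)
  fixture(key, {
    chunks <- split(seq_len(n), ceiling(seq_len(n) / 1000))
    out <- numeric(0)
    for (ci in seq_along(chunks)) {
      cfg <- presetConfig(preset, nCells = length(chunks[[ci]]),
                          seed = baseSeed + ci)
      pop <- simulatePopulation(cfg)
      curves <- trajectoryMSD(pop, maxLag = lag, lags = lag)
      out <- c(out, perCellMSD(curves, lag = lag)$msd)
    }
    out
  })
}

# 1000 undamaged-baseline trajectories with full 0.1..10 s MSD curves.
baselineCurves1000 <- function() {
  fixture("baselineCurves1000", {
    pop <- simulatePopulation(presetConfig("undamaged-baseline",
                                           nCells = 1000L, seed = 101L))
    trajectoryMSD(pop, maxLag = 10)
  })
}

# A stationary "trajectory" (spot fixed at a position) as a TrajectorySet.
stationarySet <- function(nFrames = 500L, x = 1, y = 2, dt = 0.1,
                          cellId = "still") {
  k <- 0:(nFrames - 1L)
  trajectorySet(data.frame(cell_id = cellId, condition = "static",
                           frame = k, t_s = k * dt, x_um = x, y_um = y,
                           stringsAsFactors = FALSE), dt)
}

# Random short gappy trajectory for oracle-equivalence checks.
randomGappyTrajectory <- function(id) {
  nAll <- sample(8:25, 1)
  frames <- sort(sample(0:40, nAll))
  data.frame(cell_id = id, condition = "rnd", frame = frames,
             t_s = frames * 0.5,
             x_um = cumsum(rnorm(nAll)), y_um = cumsum(rnorm(nAll)),
             stringsAsFactors = FALSE)
}
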