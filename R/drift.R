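# Global (stage/field) drift estimation and removal.

#' Estimate global drift across a trajectory set
#'
#' For every frame pair (k, k+1) in the frame range of the set, the
#' drift increment is the component-wise median of the displacements of
#' all loci observed in both frames -- robust to single anomalously
#' mobile loci. Increments from frame pairs with fewer than 2
#' contributing loci are set to 0 and flagged. The cumulative series is
#' anchored at 0 at the first frame.
#'
#' @param x a [TrajectorySet-class]
#' @return a [DriftSeries-class]
#' @export
estimateGlobalDrift <- function(x) {
  stopifnot(is(x, "TrajectorySet"))
  d <- x@data
  if (!nrow(d)) stop("empty trajectory set")
  frames <- min(d$frame):max(d$frame)
  nf <- length(frames)
  single <- length(unique(d$cell_id)) < 2L
  if (single)
    warning("single-trajectory input: global drift cannot be separated ",
            "from locus motion; returning zero drift")
  inc <- matrix(0, nf, 2L)
  flagged <- logical(nf)
  if (!single && nf > 1L) {
    # per-cell positions on the common frame grid (NA where absent)
    cells <- split(d[c("frame", "x_um", "y_um")], d$cell_id)
    X <- vapply(cells, function(cd) {
      v <- rep(NA_real_, nf); v[match(cd$frame, frames)] <- cd$x_um; v
    }, numeric(nf))
    Y <- vapply(cells, function(cd) {
      v <- rep(NA_real_, nf); v[match(cd$frame, frames)] <- cd$y_um; v
    }, numeric(nf))
    dX <- X[-1L, , drop = FALSE] - X[-nf, , drop = FALSE]
    dY <- Y[-1L, , drop = FALSE] - Y[-nf, , drop = FALSE]
    for (k in seq_len(nf - 1L)) {
      ok <- !is.na(dX[k, ])
      if (sum(ok) >= 2L) {
        inc[k + 1L, 1L] <- stats::median(dX[k, ok])
        inc[k + 1L, 2L] <- stats::median(dY[k, ok])
      } else flagged[k + 1L] <- TRUE
    }
  }
  disp <- apply(inc, 2L, cumsum)
  if (nf == 1L) disp <- matrix(disp, 1L, 2L)
  methods::new("DriftSeries", frames = as.integer(frames),
               displacement = disp, flagged = flagged)
}

#' Remove global drift from trajectories
#'
#' Subtracts the cumulative drift displacement at each position's frame.
#' Labels, QC flags and time stamps are untouched. Note the operation is
#' linear, not idempotent: correcting twice subtracts the series twice.
#'
#' @param x a [TrajectorySet-class]
#' @param drift a [DriftSeries-class] defined on every frame used by
#'   \code{x}
#' @return the corrected [TrajectorySet-class]
#' @export
correctDrift <- function(x, drift) {
  stopifnot(is(x, "TrajectorySet"), is(drift, "DriftSeries"))
  d <- x@data
  idx <- match(d$frame, drift@frames)
  if (anyNA(idx)) {
    missing <- sort(unique(d$frame[is.na(idx)]))
    stop("drift series does not cover frame(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  }
  d$x_um <- d$x_um - drift@displacement[idx, 1L]
  d$y_um <- d$y_um - drift@displacement[idx, 2L]
  out <- x
  out@data <- d
  out@metadata$driftCorrected <- TRUE
  out
}
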