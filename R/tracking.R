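# Spot detection, sub-pixel localization, frame-to-frame linking and
# trajectory quality control.
#
# Coordinates: pixel indices are 0-based and positions refer to pixel
# centres; conversion to um multiplies by the pixel size. The SNR of a
# detection is (peak - annulus mean) / annulus SD on the raw image.

#' Construct tracking parameters
#'
#' Defaults: detection at 5 SD of the band-passed background, PSF sigma
#' 1.2 px (approximately 0.13 um at 108 nm pixels), maximum link step
#' 0.5 um/frame (generous against sub-diffusive steps), gap closing over
#' up to 2 missing frames, minimum track length 100 frames (the 10 s fit
#' window at 100 ms sampling), minimum mean SNR 2.
#'
#' @param detectionThreshold threshold in robust-SD units of the
#'   band-passed image
#' @param psfSigmaPx PSF sigma in pixels
#' @param maxLinkDisplacement um per frame
#' @param maxGapFrames frames
#' @param minTrackLength frames
#' @param minMeanSnr dimensionless
#' @return a [TrackingParams-class]
#' @export
trackingParams <- function(detectionThreshold = 5, psfSigmaPx = 1.2,
                           maxLinkDisplacement = 0.5, maxGapFrames = 2L,
                           minTrackLength = 100L, minMeanSnr = 2) {
  methods::new("TrackingParams",
    detectionThreshold = as.numeric(detectionThreshold),
    psfSigmaPx = as.numeric(psfSigmaPx),
    maxLinkDisplacement = as.numeric(maxLinkDisplacement),
    maxGapFrames = as.integer(maxGapFrames),
    minTrackLength = as.integer(minTrackLength),
    minMeanSnr = as.numeric(minMeanSnr))
}

# annulus statistics (mean, sd) around a pixel on the raw image,
# radii (rIn, rOut] in pixels
.annulusStats <- function(img, row, col, rIn, rOut) {
  nr <- nrow(img); nc <- ncol(img)
  rs <- max(1L, row - rOut):min(nr, row + rOut)
  cs <- max(1L, col - rOut):min(nc, col + rOut)
  dr <- outer(rs - row, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - col)
  dist2 <- dr * dr + dc * dc
  sel <- dist2 > rIn * rIn & dist2 <= rOut * rOut
  v <- img[rs, cs][sel]
  if (length(v) < 4L) v <- as.vector(img[rs, cs])
  c(mean = mean(v), sd = max(stats::sd(v), 1e-12))
}

#' Detect spots in one frame
#'
#' Band-passes the image with a difference of Gaussians (sigma and
#' 2 sigma of the PSF width), finds local maxima with non-maximum
#' suppression within 3 PSF sigma, and keeps maxima whose band-passed
#' response exceeds \code{detectionThreshold} robust SDs of the
#' band-passed background. An empty or constant image yields zero
#' detections.
#'
#' @param image 2D numeric matrix (rows = y, cols = x)
#' @param params a [TrackingParams-class]
#' @return data.frame with 0-based pixel coordinates \code{x_px},
#'   \code{y_px} (integer candidate positions), \code{peak},
#'   \code{bgMean}, \code{bgSd}, \code{snr}, \code{response}
#' @export
detectSpots <- function(image, params = trackingParams()) {
  stopifnot(is.matrix(image))
  empty <- data.frame(x_px = numeric(), y_px = numeric(), peak = numeric(),
                      bgMean = numeric(), bgSd = numeric(), snr = numeric(),
                      response = numeric())
  if (!nrow(image) || diff(range(image)) == 0) return(empty)
  s <- params@psfSigmaPx
  dog <- EBImage::gblur(image, sigma = s) - EBImage::gblur(image, sigma = 2 * s)
  noiseSd <- stats::mad(dog)
  if (noiseSd == 0) noiseSd <- stats::sd(as.vector(dog))
  if (noiseSd == 0) return(empty)
  thr <- stats::median(dog) + params@detectionThreshold * noiseSd

  # local maxima within a (2r+1)^2 window, r = ceiling(3 sigma)
  r <- max(1L, as.integer(ceiling(3 * s)))
  localMax <- .maxFilter(dog, r)
  cand <- which(dog >= localMax - 1e-12 & dog > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  # suppress plateau duplicates: keep highest response per neighborhood
  ord <- order(dog[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      close <- abs(cand[later, 1L] - cand[i, 1L]) <= r &
               abs(cand[later, 2L] - cand[i, 2L]) <= r
      keep[later][close] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  rIn <- ceiling(3 * s); rOut <- ceiling(5 * s) + 1L
  res <- lapply(seq_len(nrow(cand)), function(i) {
    row <- cand[i, 1L]; col <- cand[i, 2L]
    ann <- .annulusStats(image, row, col, rIn, rOut)
    peak <- image[row, col]
    data.frame(x_px = col - 1L, y_px = row - 1L, peak = peak,
               bgMean = ann["mean"], bgSd = ann["sd"],
               snr = (peak - ann["mean"]) / ann["sd"],
               response = dog[row, col])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  # canonical order: by position, so downstream linking is invariant to
  # the order in which maxima were found
  out[order(out$x_px, out$y_px), , drop = FALSE]
}

# grayscale dilation (running max) with a square window of radius r
.maxFilter <- function(m, r) {
  pad <- matrix(-Inf, nrow(m) + 2L * r, ncol(m) + 2L * r)
  pad[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m))] <- m
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (dr in -r:r) for (dc in -r:r) {
    out <- pmax(out, pad[(r + 1L + dr):(r + nrow(m) + dr),
                         (r + 1L + dc):(r + ncol(m) + dc)])
  }
  out
}

#' Refine a detection to sub-pixel precision
#'
#' Least-squares fit of a pixel-integrated 2D Gaussian (free position,
#' width, amplitude and offset) in a window of half-width
#' \code{ceiling(3 sigma)} around the candidate pixel. If the fit fails
#' or wanders outside the window, the intensity-weighted centroid of the
#' background-subtracted window is used instead and the detection is
#' flagged. The SNR is recomputed from the fitted peak and the annular
#' background.
#'
#' @param image 2D numeric matrix
#' @param spot one-row data.frame from [detectSpots()]
#' @param params a [TrackingParams-class]
#' @return the spot with refined \code{x_px}, \code{y_px} (0-based,
#'   sub-pixel), updated \code{peak}/\code{snr}, and a \code{fallback}
#'   flag
#' @export
localizeSubpixel <- function(image, spot, params = trackingParams()) {
  s0 <- params@psfSigmaPx
  w <- as.integer(ceiling(3 * s0))
  row0 <- as.integer(spot$y_px) + 1L
  col0 <- as.integer(spot$x_px) + 1L
  rs <- max(1L, row0 - w):min(nrow(image), row0 + w)
  cs <- max(1L, col0 - w):min(ncol(image), col0 + w)
  win <- image[rs, cs, drop = FALSE]
  xs <- cs - 1L   # 0-based pixel coordinates of the window
  ys <- rs - 1L

  bgsub <- pmax(win - min(win), 0)
  tot <- sum(bgsub)
  cx0 <- if (tot > 0) sum(outer(rep(1, length(ys)), xs) * bgsub) / tot else spot$x_px
  cy0 <- if (tot > 0) sum(outer(ys, rep(1, length(xs))) * bgsub) / tot else spot$y_px

  model <- function(p) {
    gx <- stats::pnorm((xs + 0.5 - p[1L]) / exp(p[3L])) -
          stats::pnorm((xs - 0.5 - p[1L]) / exp(p[3L]))
    gy <- stats::pnorm((ys + 0.5 - p[2L]) / exp(p[3L])) -
          stats::pnorm((ys - 0.5 - p[2L]) / exp(p[3L]))
    exp(p[4L]) * outer(gy, gx) + p[5L]
  }
  amp0 <- max(max(win) - stats::median(win), 1e-6)
  peakFrac <- (stats::pnorm(0.5 / s0) - stats::pnorm(-0.5 / s0))^2
  p0 <- c(cx0, cy0, log(s0), log(amp0 / peakFrac), stats::median(win))
  sse <- function(p) sum((model(p) - win)^2)
  fit <- try({
    f1 <- stats::optim(p0, sse, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
    # quasi-Newton polish: the simplex stalls near symmetric optima
    stats::optim(f1$par, sse, method = "BFGS",
                 control = list(maxit = 50, reltol = 1e-14))
  }, silent = TRUE)
  fallback <- inherits(fit, "try-error") ||
    fit$par[1L] < min(xs) - 0.5 || fit$par[1L] > max(xs) + 0.5 ||
    fit$par[2L] < min(ys) - 0.5 || fit$par[2L] > max(ys) + 0.5 ||
    !all(is.finite(fit$par))
  if (!fallback) {
    x <- fit$par[1L]; y <- fit$par[2L]
    sFit <- exp(fit$par[3L])
    peakFit <- exp(fit$par[4L]) *
      (stats::pnorm(0.5 / sFit) - stats::pnorm(-0.5 / sFit))^2 + fit$par[5L]
  } else {
    x <- cx0; y <- cy0
    peakFit <- max(win)
  }
  ann <- .annulusStats(image, as.integer(round(y)) + 1L,
                       as.integer(round(x)) + 1L,
                       ceiling(3 * s0), ceiling(5 * s0) + 1L)
  spot$x_px <- x
  spot$y_px <- y
  spot$peak <- peakFit
  spot$bgMean <- unname(ann["mean"])
  spot$bgSd <- unname(ann["sd"])
  spot$snr <- (peakFit - ann["mean"]) / ann["sd"]
  spot$fallback <- fallback
  spot
}

#' Link detections into trajectories
#'
#' Greedy nearest-neighbour linking: candidate links between open track
#' ends and the detections of each frame are accepted in order of
#' increasing Euclidean displacement, rejecting any link longer than
#' \code{maxLinkDisplacement} um per elapsed frame. Tracks missing from
#' up to \code{maxGapFrames} consecutive frames may be bridged (the gap
#' frames stay absent -- never interpolated). Equal-cost ties are broken
#' by lowest track index, then lowest detection index, with detections
#' in canonical (x, y) order within each frame so the result does not
#' depend on detection order. Unlinked detections start new tracks.
#'
#' @param detections data.frame with columns \code{frame} (0-based
#'   integer), \code{x_um}, \code{y_um} and optionally \code{snr}
#' @param params a [TrackingParams-class]
#' @param frameInterval seconds per frame
#' @return a [TrajectorySet-class]; cell ids \code{track_0001, ...} in
#'   order of first appearance
#' @export
linkSpots <- function(detections, params = trackingParams(),
                      frameInterval = 0.1) {
  need <- c("frame", "x_um", "y_um")
  stopifnot(all(need %in% names(detections)))
  det <- detections[order(detections$frame, detections$x_um,
                          detections$y_um), , drop = FALSE]
  if (!"snr" %in% names(det)) det$snr <- NA_real_
  tracks <- list()     # each: list(rows = integer row idx of det, last = frame)
  open <- integer()    # indices into tracks that may still be extended
  frames <- sort(unique(det$frame))
  rowsByFrame <- split(seq_len(nrow(det)), det$frame)
  for (f in frames) {
    rows <- rowsByFrame[[as.character(f)]]
    # drop tracks whose gap is already too large
    if (length(open)) {
      gaps <- f - vapply(open, function(ti) tracks[[ti]]$last, 0)
      open <- open[gaps <= params@maxGapFrames + 1L]
    }
    assignedDet <- rep(FALSE, length(rows))
    if (length(open)) {
      # candidate links (track, detection, cost)
      cand <- NULL
      lastPos <- t(vapply(open, function(ti) {
        r <- tracks[[ti]]$rows
        c(det$x_um[r[length(r)]], det$y_um[r[length(r)]],
          tracks[[ti]]$last)
      }, numeric(3)))
      for (oi in seq_along(open)) {
        dfr <- f - lastPos[oi, 3L]
        dx <- det$x_um[rows] - lastPos[oi, 1L]
        dy <- det$y_um[rows] - lastPos[oi, 2L]
        dist <- sqrt(dx * dx + dy * dy)
        ok <- dist <= params@maxLinkDisplacement * dfr
        if (any(ok))
          cand <- rbind(cand, cbind(oi = oi, di = which(ok),
                                    cost = dist[ok]))
      }
      if (!is.null(cand)) {
        cand <- cand[order(cand[, "cost"], cand[, "oi"], cand[, "di"]), ,
                     drop = FALSE]
        usedTrack <- rep(FALSE, length(open))
        for (ci in seq_len(nrow(cand))) {
          oi <- cand[ci, "oi"]; di <- cand[ci, "di"]
          if (usedTrack[oi] || assignedDet[di]) next
          ti <- open[oi]
          tracks[[ti]]$rows <- c(tracks[[ti]]$rows, rows[di])
          tracks[[ti]]$last <- f
          usedTrack[oi] <- TRUE
          assignedDet[di] <- TRUE
        }
      }
    }
    for (di in which(!assignedDet)) {
      tracks[[length(tracks) + 1L]] <- list(rows = rows[di], last = f)
      open <- c(open, length(tracks))
    }
  }
  width <- max(4L, nchar(length(tracks)))
  parts <- lapply(seq_along(tracks), function(ti) {
    r <- tracks[[ti]]$rows
    data.frame(cell_id = sprintf(paste0("track_%0", width, "d"), ti),
               condition = "tracked",
               frame = det$frame[r],
               t_s = det$frame[r] * frameInterval,
               x_um = det$x_um[r], y_um = det$y_um[r],
               snr = det$snr[r], stringsAsFactors = FALSE)
  })
  trajectorySet(do.call(rbind, parts), frameInterval)
}

#' Quality-control filter for trajectories
#'
#' Keeps trajectories with \code{length >= minTrackLength} frames and
#' (when an \code{snr} column is present) \code{mean(snr) >= minMeanSnr};
#' both thresholds are inclusive. Rejected trajectories are returned
#' separately with their reasons, so the filtering is auditable.
#'
#' @param x a [TrajectorySet-class]
#' @param params a [TrackingParams-class]
#' @return list with elements \code{kept} and \code{rejected} (both
#'   [TrajectorySet-class]; the rejected set carries a qc table of
#'   reasons, "length" and/or "snr")
#' @export
qcFilter <- function(x, params = trackingParams()) {
  stopifnot(is(x, "TrajectorySet"))
  d <- x@data
  cells <- split(d, d$cell_id)
  reasons <- lapply(cells, function(cd) {
    why <- character()
    if (nrow(cd) < params@minTrackLength) why <- c(why, "length")
    if ("snr" %in% names(cd) && !all(is.na(cd$snr)) &&
        mean(cd$snr, na.rm = TRUE) < params@minMeanSnr)
      why <- c(why, "snr")
    why
  })
  bad <- names(reasons)[lengths(reasons) > 0L]
  keep <- !(d$cell_id %in% bad)
  qcTab <- data.frame(
    cell_id = bad,
    reason = vapply(reasons[bad], paste, "", collapse = "+"),
    stringsAsFactors = FALSE)
  list(
    kept = trajectorySet(d[keep, , drop = FALSE], x@frameInterval,
                         metadata = x@metadata),
    rejected = trajectorySet(d[!keep, , drop = FALSE], x@frameInterval,
                             qc = qcTab, metadata = x@metadata))
}

#' Track a movie end to end
#'
#' Runs [detectSpots()] and [localizeSubpixel()] on every frame, converts
#' pixel positions to um via the stack's pixel size, and links detections
#' with [linkSpots()]. QC filtering is left to [qcFilter()] so rejected
#' tracks remain inspectable.
#'
#' @param stack a [FrameStack-class]
#' @param params a [TrackingParams-class]
#' @return a [TrajectorySet-class] of tracked loci (positions in um,
#'   image coordinate frame, with per-detection \code{snr})
#' @export
trackMovie <- function(stack, params = trackingParams()) {
  stopifnot(is(stack, "FrameStack"))
  nf <- dim(stack@pixels)[3L]
  detList <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- stack@pixels[, , f]
    det <- detectSpots(img, params)
    if (nrow(det)) {
      det <- do.call(rbind, lapply(seq_len(nrow(det)), function(i)
        localizeSubpixel(img, det[i, , drop = FALSE], params)))
      det$frame <- f - 1L
      det$x_um <- det$x_px * stack@pixelSize
      det$y_um <- det$y_px * stack@pixelSize
    }
    detList[[f]] <- det
  }
  det <- do.call(rbind, detList[vapply(detList, nrow, 0L) > 0L])
  if (is.null(det) || !nrow(det))
    return(trajectorySet(
      data.frame(cell_id = character(), condition = character(),
                 frame = integer(), t_s = numeric(), x_um = numeric(),
                 y_um = numeric(), snr = numeric(),
                 stringsAsFactors = FALSE),
      stack@frameInterval))
  linkSpots(det[, c("frame", "x_um", "y_um", "snr")], params,
            stack@frameInterval)
}
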