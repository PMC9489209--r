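# Rendering ground-truth trajectories into synthetic image stacks.

#' Render trajectories into a fluorescence movie
#'
#' Each locus is drawn per frame as a pixel-integrated 2D Gaussian of
#' width \code{psfSigma} centred at its ground-truth position, on top of
#' a uniform background, with optional shot noise. Trajectories are
#' placed at \code{origins} within the field (default: an evenly spaced
#' grid with a margin); the ground truth, expressed in image coordinates
#' (um, origin at the centre of pixel (0, 0)), is retained in the stack.
#' Positions falling outside the image are clipped to the border with a
#' warning and flagged in the ground-truth QC table.
#'
#' @param x a [TrajectorySet-class]
#' @param psfSigma PSF Gaussian sigma in um (default 0.13, a typical
#'   diffraction-limited width for GFP imaging at high NA)
#' @param backgroundMean mean background level, counts/pixel
#' @param spotPeak peak amplitude above background (counts) of a
#'   perfectly centred spot; for Poisson background the detection SNR is
#'   approximately \code{spotPeak / sqrt(backgroundMean)}
#' @param noiseModel "poisson" (shot noise on signal + background),
#'   "gaussian" (Gaussian approximation with variance equal to the mean,
#'   rounded to integer counts), or "none" (noise-free, float values)
#' @param imageShape c(rows, cols) in pixels
#' @param pixelSize um per pixel (default 0.108)
#' @param origins optional nCells x 2 matrix of cell placements (um, image
#'   coordinates)
#' @return a [FrameStack-class] with ground truth attached
#' @export
renderMovie <- function(x, psfSigma = 0.13, backgroundMean = 100,
                        spotPeak = 50, noiseModel = c("poisson", "gaussian", "none"),
                        imageShape = c(64L, 64L), pixelSize = 0.108,
                        origins = NULL) {
  stopifnot(is(x, "TrajectorySet"), psfSigma > 0, backgroundMean >= 0,
            spotPeak >= 0, length(imageShape) == 2L)
  noiseModel <- match.arg(noiseModel)
  d <- x@data
  ids <- unique(d$cell_id)
  ncell <- length(ids)
  nr <- as.integer(imageShape[1L]); ncol_ <- as.integer(imageShape[2L])
  if (is.null(origins)) origins <- .defaultOrigins(ncell, nr, ncol_, pixelSize)
  if (nrow(origins) != ncell) stop("'origins' must have one row per cell")

  # absolute ground-truth positions in image coordinates
  idx <- match(d$cell_id, ids)
  d$x_um <- d$x_um + origins[idx, 1L]
  d$y_um <- d$y_um + origins[idx, 2L]

  s <- psfSigma / pixelSize            # PSF sigma in pixels
  # peak fraction of total flux landing in the centre pixel of a centred spot
  peakFrac <- (stats::pnorm(0.5 / s) - stats::pnorm(-0.5 / s))^2
  flux <- spotPeak / peakFrac
  w <- ceiling(5 * s)

  frames <- sort(unique(d$frame))
  stack <- array(backgroundMean, dim = c(nr, ncol_, length(frames)))
  clipped <- logical(nrow(d))
  byFrame <- split(seq_len(nrow(d)), d$frame)
  for (fi in seq_along(frames)) {
    img <- stack[, , fi]
    for (ri in byFrame[[as.character(frames[fi])]]) {
      cx <- d$x_um[ri] / pixelSize     # 0-based pixel coordinates
      cy <- d$y_um[ri] / pixelSize
      if (cx < 0 || cx > ncol_ - 1L || cy < 0 || cy > nr - 1L) {
        clipped[ri] <- TRUE
        cx <- min(max(cx, 0), ncol_ - 1L)
        cy <- min(max(cy, 0), nr - 1L)
      }
      xs <- max(0L, floor(cx) - w):min(ncol_ - 1L, floor(cx) + w)
      ys <- max(0L, floor(cy) - w):min(nr - 1L, floor(cy) + w)
      gx <- stats::pnorm((xs + 0.5 - cx) / s) - stats::pnorm((xs - 0.5 - cx) / s)
      gy <- stats::pnorm((ys + 0.5 - cy) / s) - stats::pnorm((ys - 0.5 - cy) / s)
      img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + flux * outer(gy, gx)
    }
    stack[, , fi] <- img
  }
  if (any(clipped))
    warning(sum(clipped), " ground-truth position(s) outside the image were clipped")

  if (noiseModel == "poisson") {
    stack[] <- stats::rpois(length(stack), lambda = stack)
  } else if (noiseModel == "gaussian") {
    stack[] <- pmax(0, round(stack + stats::rnorm(length(stack), 0, sqrt(stack))))
  }

  qc <- x@qc
  if (any(clipped)) {
    cl <- unique(d$cell_id[clipped])
    qc <- rbind(qc, data.frame(cell_id = cl, reason = "clipped",
                               stringsAsFactors = FALSE))
  }
  gt <- trajectorySet(d, x@frameInterval, qc = qc, metadata = x@metadata)
  methods::new("FrameStack", pixels = stack, pixelSize = pixelSize,
               frameInterval = x@frameInterval, groundTruth = gt,
               metadata = list(psfSigma = psfSigma,
                               backgroundMean = backgroundMean,
                               spotPeak = spotPeak, noiseModel = noiseModel))
}

# grid placement with a margin of 1/(2*sqrt(ncell)) of the field
.defaultOrigins <- function(ncell, nr, ncol_, pixelSize) {
  k <- ceiling(sqrt(ncell))
  fx <- (seq_len(k) - 0.5) / k * (ncol_ - 1L) * pixelSize
  fy <- (seq_len(k) - 0.5) / k * (nr - 1L) * pixelSize
  g <- expand.grid(x = fx, y = fy)
  as.matrix(g[seq_len(ncell), , drop = FALSE])
}
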