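# Readers and writers: trajectory tables (TSV), MSD curves (TSV),
# movies (multi-frame TIFF + JSON metadata sidecar), fits and
# comparisons (JSON). The trajectory interchange format is a plain
# delimited table with '#'-prefixed header comments -- diff-able and
# language-neutral.

.TRAJ_NUM_COLS <- c("t_s", "x_um", "y_um", "snr")

#' Write trajectories as delimited text
#'
#' Tab-separated with header \code{cell_id condition frame t_s x_um y_um}
#' (plus \code{snr} when present). Numeric columns are written with 17
#' significant digits so positions round-trip at full double precision.
#' Key-value pairs in \code{comments} become \code{# key: value} lines
#' before the header.
#'
#' @param x a [TrajectorySet-class]
#' @param path output file
#' @param comments named character vector of metadata comments
#' @return \code{path}, invisibly
#' @export
writeTrajectories <- function(x, path, comments = character()) {
  stopifnot(is(x, "TrajectorySet"))
  d <- x@data
  cols <- c("cell_id", "condition", "frame", "t_s", "x_um", "y_um")
  if ("snr" %in% names(d)) cols <- c(cols, "snr")
  d <- d[, cols, drop = FALSE]
  for (cc in intersect(.TRAJ_NUM_COLS, cols)) d[[cc]] <- sprintf("%.17g", d[[cc]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_s: %.17g", x@frameInterval), con)
  if (length(comments))
    writeLines(sprintf("# %s: %s", names(comments), comments), con)
  writeLines(paste(cols, collapse = "\t"), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read trajectories from delimited text or a MAT adapter
#'
#' TSV: parses the interchange format written by [writeTrajectories()]
#' (or any delimited table with the same columns). Rows with missing or
#' non-finite values are rejected with their line numbers; a
#' non-monotone time column raises an error naming the offending cell.
#' An empty file yields an empty set with a warning.
#'
#' MAT: the study trajectories deposited alongside the original imaging
#' data are MATLAB files whose internal schema cannot be assumed;
#' \code{format = "mat"} is therefore an adapter interface. Supply
#' \code{matReader}, a function(path) returning a data.frame in the
#' interchange schema with positions already in um (conversion factor
#' is the adapter's responsibility -- it is never guessed).
#'
#' @param path input file
#' @param format "tsv" (default) or "mat"
#' @param frameInterval seconds; for TSV, defaults to the value recorded
#'   in the file header, else the smallest positive time step
#' @param matReader adapter function for MAT input
#' @return a [TrajectorySet-class]
#' @export
readTrajectories <- function(path, format = c("tsv", "mat"),
                             frameInterval = NULL, matReader = NULL) {
  format <- match.arg(format)
  if (format == "mat") {
    if (is.null(matReader))
      stop("MAT import needs an adapter: pass matReader = function(path) ",
           "returning a data.frame(cell_id, condition, frame, t_s, x_um, ",
           "y_um) with positions converted to um (state the conversion ",
           "explicitly; units are never guessed)")
    d <- matReader(path)
    if (is.null(frameInterval))
      frameInterval <- min(diff(sort(unique(d$t_s))))
    return(trajectorySet(d, frameInterval))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  isComment <- startsWith(lines, "#")
  hdr <- lines[isComment]
  fiLine <- grep("^# frame_interval_s:", hdr, value = TRUE)
  if (is.null(frameInterval) && length(fiLine))
    frameInterval <- as.numeric(sub("^# frame_interval_s:\\s*", "", fiLine[1L]))
  body <- lines[!isComment]
  if (!length(body) || all(!nzchar(body))) {
    warning("empty trajectory file: ", path)
    return(trajectorySet(
      data.frame(cell_id = character(), condition = character(),
                 frame = integer(), t_s = numeric(), x_um = numeric(),
                 y_um = numeric(), stringsAsFactors = FALSE),
      if (is.null(frameInterval)) 0.1 else frameInterval))
  }
  d <- utils::read.table(text = body, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_id", "condition", "frame", "t_s", "x_um", "y_um"),
                  names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  numOk <- is.finite(d$t_s) & is.finite(d$x_um) & is.finite(d$y_um) &
    is.finite(d$frame)
  if (any(!numOk)) {
    # line numbers in the original file: comments + header line offset
    offset <- sum(isComment) + 1L
    warning("rejected ", sum(!numOk), " malformed row(s) at line(s): ",
            paste(utils::head(which(!numOk) + offset, 10L), collapse = ", "))
    d <- d[numOk, , drop = FALSE]
  }
  if (is.null(frameInterval)) {
    steps <- diff(sort(unique(d$t_s)))
    frameInterval <- if (length(steps)) min(steps[steps > 0]) else 0.1
  }
  trajectorySet(d, frameInterval)
}

#' Write a movie as multi-frame TIFF with a JSON sidecar
#'
#' Pixel data are written as 16-bit integers (counts 0..65535), which
#' round-trips losslessly; non-integer stacks are refused. Metadata
#' (pixel size, frame interval, and any stack metadata such as seed or
#' preset) go to \code{<path>.json}.
#'
#' @param stack a [FrameStack-class]
#' @param path output TIFF path
#' @return \code{path}, invisibly
#' @export
writeMovie <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  px <- stack@pixels
  if (max(abs(px - round(px))) > 1e-9)
    stop("movie pixels must be integer counts for lossless 16-bit TIFF ",
         "output; render with a counting noise model or round explicitly")
  if (max(px) > 65535) stop("pixel counts exceed the 16-bit range")
  frames <- lapply(seq_len(dim(px)[3L]), function(f) px[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  meta <- c(list(pixel_size_um = stack@pixelSize,
                 frame_interval_s = stack@frameInterval),
            stack@metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF movie
#'
#' @param path TIFF path; the \code{<path>.json} sidecar written by
#'   [writeMovie()] is used for pixel size and frame interval when
#'   present
#' @param pixelSize,frameInterval overrides when no sidecar exists
#' @return a [FrameStack-class] (no ground truth)
#' @export
readMovie <- function(path, pixelSize = 0.108, frameInterval = 0.1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$pixel_size_um)) pixelSize <- meta$pixel_size_um
    if (!is.null(meta$frame_interval_s)) frameInterval <- meta$frame_interval_s
  }
  px <- array(0, dim = c(dim(frames[[1L]])[1:2], length(frames)))
  for (f in seq_along(frames)) px[, , f] <- round(frames[[f]] * 65535)
  methods::new("FrameStack", pixels = px, pixelSize = pixelSize,
               frameInterval = frameInterval, groundTruth = NULL,
               metadata = list(source = path))
}

#' Write MSD curves as delimited text
#'
#' Columns: lag_s, msd_um2, n_intervals, n_trajectories, level,
#' condition; one block per curve.
#'
#' @param curves an [MSDCurve-class] or list thereof
#' @param path output file
#' @param comments named character vector of metadata comments
#' @return \code{path}, invisibly
#' @export
writeMSDCurves <- function(curves, path, comments = character()) {
  if (is(curves, "MSDCurve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, as.data.frame))
  for (cc in c("lag_s", "msd_um2")) tab[[cc]] <- sprintf("%.17g", tab[[cc]])
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(sprintf("# %s: %s", names(comments), comments), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMSDCurves
#' @export
readMSDCurves <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  d <- utils::read.table(text = body, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  split_on <- paste(d$level, d$condition, sep = "\r")
  lapply(split(d, split_on), function(b) {
    methods::new("MSDCurve", lags = b$lag_s, msd = b$msd_um2,
                 nIntervals = b$n_intervals,
                 nTrajectories = b$n_trajectories, level = b$level[1L],
                 frameInterval = min(diff(c(0, b$lag_s))),
                 cellId = "", condition = as.character(b$condition[1L]))
  })
}
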