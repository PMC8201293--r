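## ROI statistics on cycle-indexed fluorescence frames. Frames are numeric
## matrices (rows = y, columns = x) or h x w x 3 arrays, in grayscale units
## on the [0, 2^bitDepth - 1] scale.

#' Logical pixel mask of an ROI
#'
#' @param roi a [RoiSpec-class].
#' @param width,height frame dimensions in pixels.
#' @return A `height x width` logical matrix; `TRUE` inside the ROI. For a
#'   polygon ROI, a pixel belongs if its center `(col - 0.5, row - 0.5)`
#'   (0-based coordinates) lies inside the polygon.
#' @examples
#' sum(roiMask(roiSpec(1, 1, 2, 3), 6, 5))  # 6 pixels
#' @export
roiMask <- function(roi, width, height) {
  validObject(roi)
  if (roi@x + roi@width > width || roi@y + roi@height > height)
    stop(sprintf("ROI [%d, %d) x [%d, %d) exceeds the %d x %d frame",
                 roi@x, roi@x + roi@width, roi@y, roi@y + roi@height,
                 width, height))
  mask <- matrix(FALSE, nrow = height, ncol = width)
  rows <- (roi@y + 1L):(roi@y + roi@height)
  cols <- (roi@x + 1L):(roi@x + roi@width)
  mask[rows, cols] <- TRUE
  if (nrow(roi@vertices) > 0L) {
    centers <- expand.grid(row = rows, col = cols)
    inside <- pracma::inpolygon(centers$col - 0.5, centers$row - 0.5,
                                roi@vertices[, 1], roi@vertices[, 2],
                                boundary = TRUE)
    mask[rows, cols] <- matrix(inside, nrow = length(rows))
  }
  mask
}

#' Convert a frame to grayscale
#'
#' A 3-channel frame is combined either with the BT.601 luma weights
#' (0.299, 0.587, 0.114; the default) or by taking the green channel alone,
#' where fluorescein emission (~520 nm) falls. A single-channel frame
#' passes through unchanged. No re-quantization is applied: the result
#' keeps full floating precision.
#'
#' @param frame numeric matrix or height x width x 3 array.
#' @param channel `"luma"` or `"green"`.
#' @param weights luma weights, summing to 1.
#' @return A numeric matrix.
#' @examples
#' a <- array(c(0, 200, 0), dim = c(1, 1, 3))
#' toGrayscale(a)            # 0.587 * 200 = 117.4
#' toGrayscale(a, "green")   # 200
#' @export
toGrayscale <- function(frame, channel = c("luma", "green"),
                        weights = c(0.299, 0.587, 0.114)) {
  channel <- match.arg(channel)
  d <- dim(frame)
  if (length(d) == 2L) return(frame)
  if (!(length(d) == 3L && d[3] %in% c(1L, 3L)))
    stop("unsupported frame format: expected 1 or 3 channels")
  ch <- function(i) {  # keep matrix shape even for 1 x 1 frames
    x <- frame[, , i]
    dim(x) <- d[1:2]
    x
  }
  if (d[3] == 1L) return(ch(1L))
  if (channel == "green") return(ch(2L))
  weights[1] * ch(1L) + weights[2] * ch(2L) + weights[3] * ch(3L)
}

#' Mean intensity of the ROI pixels of one frame
#'
#' The arithmetic mean over all ROI pixels, in full floating precision;
#' this is the per-cycle relative fluorescence readout.
#'
#' @param frame numeric grayscale matrix.
#' @param roi a [RoiSpec-class] within the frame.
#' @return Mean intensity (grayscale units).
#' @examples
#' roiMean(matrix(c(10, 20), 1), roiSpec(0, 0, 2, 1))  # 15
#' @export
roiMean <- function(frame, roi) {
  mask <- roiMask(roi, width = ncol(frame), height = nrow(frame))
  mean(frame[mask])
}

#' Load a cycle-indexed image stack from a directory
#'
#' Files are matched by a regular expression whose first capture group is
#' the cycle number (default: `cycle_01.png` style names, PNG or TIFF).
#' Frames are ordered by parsed cycle number; a missing cycle in the
#' sequence or frames of differing dimensions are errors.
#'
#' @param dir directory containing one image per cycle.
#' @param pattern regex with one capture group for the cycle number.
#' @param bitDepth bit depth used to scale PNG values back to grayscale
#'   units (TIFF files are read at native integer values).
#' @return An [ImageStack-class].
#' @examples
#' st <- renderImageStack(simulateCurve(amplificationModel(), seed = 1),
#'                        chipLayout(), cameraModel(noiseSd = 0))
#' d <- tempfile(); writeImageStack(st, d)
#' loadImageStack(d)
#' @export
loadImageStack <- function(dir, pattern = "^cycle_(\\d+)\\.(png|tiff?)$",
                           bitDepth = 8L) {
  files <- list.files(dir, full.names = FALSE)
  m <- regmatches(files, regexec(pattern, files, ignore.case = TRUE))
  hit <- lengths(m) >= 2L
  if (!any(hit))
    stop("no files in '", dir, "' match the cycle pattern")
  files <- files[hit]
  cyc <- as.integer(vapply(m[hit], `[`, character(1), 2L))
  o <- order(cyc)
  files <- files[o]; cyc <- cyc[o]
  if (anyDuplicated(cyc))
    stop("duplicate cycle indices: ",
         paste(unique(cyc[duplicated(cyc)]), collapse = ", "))
  full <- seq(min(cyc), max(cyc))
  gaps <- setdiff(full, cyc)
  if (length(gaps))
    stop("missing cycle(s): ", paste(gaps, collapse = ", "))
  vmax <- 2^bitDepth - 1
  frames <- lapply(file.path(dir, files), function(path) {
    img <- tryCatch({
      if (grepl("\\.png$", path, ignore.case = TRUE))
        png::readPNG(path) * vmax
      else tiff::readTIFF(path, as.is = TRUE)
    }, error = function(e) stop("cannot read '", path, "': ",
                                conditionMessage(e), call. = FALSE))
    if (length(dim(img)) == 3L && dim(img)[3] == 4L)
      img <- img[, , 1:3]  # drop alpha
    img
  })
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("frames have differing dimensions")
  new("ImageStack", frames = frames, cycles = cyc,
      bitDepth = as.integer(bitDepth), source = dir)
}

#' @rdname quantifyStack
setMethod("quantifyStack", "ImageStack", function(x, roi,
                                                  channel = c("luma", "green")) {
  channel <- match.arg(channel)
  vals <- vapply(x@frames,
                 function(f) roiMean(toGrayscale(f, channel), roi),
                 numeric(1))
  amplificationCurve(vals, state = "raw")
})
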