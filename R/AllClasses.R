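#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats plogis rnorm runif uniroot
#' @importFrom utils read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Region of interest
## ---------------------------------------------------------------------------

#' Region of interest within a camera frame
#'
#' Describes the pixel region covering the reaction chamber whose mean
#' grayscale value is read out as the per-cycle relative fluorescence.
#' Coordinates are 0-based, x to the right and y down, and the rectangle is
#' half-open: pixels with column index in `[x, x + width)` and row index in
#' `[y, y + height)` belong to the ROI. An optional polygon (vertex list in
#' the same pixel coordinate system) restricts the region further; pixels
#' whose centers fall inside the polygon are used.
#'
#' @slot x,y integer, top-left corner (0-based pixels).
#' @slot width,height integer, extent in pixels (at least 1).
#' @slot vertices numeric matrix with columns x, y; zero rows for a plain
#'   rectangle.
#' @exportClass RoiSpec
setClass("RoiSpec",
  representation(x = "integer", y = "integer",
                 width = "integer", height = "integer",
                 vertices = "matrix"),
  prototype(x = 0L, y = 0L, width = 1L, height = 1L,
            vertices = matrix(numeric(0), 0L, 2L)))

setValidity("RoiSpec", function(object) {
  msg <- character(0)
  if (length(object@x) != 1L || length(object@y) != 1L ||
      length(object@width) != 1L || length(object@height) != 1L)
    msg <- c(msg, "x, y, width, height must be scalars")
  else {
    if (object@width < 1L || object@height < 1L)
      msg <- c(msg, "width and height must be >= 1")
    if (object@x < 0L || object@y < 0L)
      msg <- c(msg, "x and y must be >= 0")
  }
  if (nrow(object@vertices) > 0L && ncol(object@vertices) != 2L)
    msg <- c(msg, "vertices must have two columns (x, y)")
  if (nrow(object@vertices) > 0L && nrow(object@vertices) < 3L)
    msg <- c(msg, "a polygon needs at least 3 vertices")
  if (length(msg)) msg else TRUE
})

#' Construct a region of interest
#'
#' @param x,y 0-based pixel coordinates of the top-left corner.
#' @param width,height extent in pixels.
#' @param vertices optional two-column matrix of polygon vertices (x, y) in
#'   pixel coordinates; when given, only pixels whose centers fall inside the
#'   polygon are part of the ROI.
#' @return A [RoiSpec-class] object.
#' @examples
#' roiSpec(10, 10, 40, 40)
#' @export
roiSpec <- function(x, y, width, height, vertices = NULL) {
  if (is.null(vertices)) vertices <- matrix(numeric(0), 0L, 2L)
  new("RoiSpec", x = as.integer(x), y = as.integer(y),
      width = as.integer(width), height = as.integer(height),
      vertices = vertices)
}

## ---------------------------------------------------------------------------
## Synthetic-data parameter objects
## ---------------------------------------------------------------------------

#' Parametric amplification-curve model
#'
#' Four-parameter logistic model of a qPCR amplification curve in linear
#' intensity (grayscale units on the 0-255 camera scale):
#' \deqn{I(c) = b + g\,P\,\sigma(k (c - c_0))}
#' with baseline \eqn{b}, camera/set gain \eqn{g}, plateau gain \eqn{P},
#' steepness \eqn{k} and center \eqn{c_0}. The center is not a free
#' parameter: it is placed so that the noiseless baseline-normalized curve
#' crosses the reference level `ctFraction * gain * plateauGain` exactly at
#' `trueCq`, which makes the ground-truth Cq of every simulated curve exact
#' by construction (see [sigmoidCenter()]).
#'
#' @slot baselineIntensity numeric, pre-amplification intensity (grayscale
#'   units).
#' @slot plateauGain numeric, intensity rise from baseline to plateau at unit
#'   gain (grayscale units), > 0.
#' @slot trueCq numeric, ground-truth threshold cycle in cycles, in
#'   \[1, 40\].
#' @slot slope numeric, logistic steepness per cycle, > 0.
#' @slot efficiency numeric, amplification fold-change per cycle, in (1, 2].
#' @slot ctFraction numeric, fraction of the normalized plateau that defines
#'   the ground-truth Cq level, in (0, 1).
#' @exportClass AmplificationModel
setClass("AmplificationModel",
  representation(baselineIntensity = "numeric", plateauGain = "numeric",
                 trueCq = "numeric", slope = "numeric",
                 efficiency = "numeric", ctFraction = "numeric"))

setValidity("AmplificationModel", function(object) {
  msg <- character(0)
  if (object@plateauGain <= 0) msg <- c(msg, "plateauGain must be > 0")
  if (object@slope <= 0) msg <- c(msg, "slope must be > 0")
  if (object@trueCq < 1 || object@trueCq > 40)
    msg <- c(msg, "trueCq must lie in [1, 40]")
  if (object@efficiency <= 1 || object@efficiency > 2)
    msg <- c(msg, "efficiency must lie in (1, 2]")
  if (object@ctFraction <= 0 || object@ctFraction >= 1)
    msg <- c(msg, "ctFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param baselineIntensity,plateauGain,trueCq,slope,efficiency,ctFraction
#'   see the class slots.
#' @return An [AmplificationModel-class] object.
#' @examples
#' amplificationModel(trueCq = 25)
#' @rdname AmplificationModel-class
#' @export
amplificationModel <- function(baselineIntensity = 30, plateauGain = 74,
                               trueCq = 20, slope = 0.6, efficiency = 2,
                               ctFraction = 0.1) {
  new("AmplificationModel", baselineIntensity = baselineIntensity,
      plateauGain = plateauGain, trueCq = trueCq, slope = slope,
      efficiency = efficiency, ctFraction = ctFraction)
}

#' Camera acquisition model
#'
#' @slot gain numeric multiplier applied to the fluorescence signal (> 0);
#'   per-set gain differences are what the inter-set calibration corrects.
#' @slot noiseSd numeric, zero-mean Gaussian noise standard deviation in
#'   grayscale units (per pixel when rendering frames, per readout when
#'   simulating curves directly), >= 0.
#' @slot bitDepth integer, bits per pixel (rendered values are clipped to
#'   `[0, 2^bitDepth - 1]`).
#' @slot seed integer seed for the random stream.
#' @exportClass CameraModel
setClass("CameraModel",
  representation(gain = "numeric", noiseSd = "numeric",
                 bitDepth = "integer", seed = "integer"))

setValidity("CameraModel", function(object) {
  msg <- character(0)
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@bitDepth < 1L) msg <- c(msg, "bitDepth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param gain,noiseSd,bitDepth,seed see the class slots.
#' @return A [CameraModel-class] object.
#' @examples
#' cameraModel(noiseSd = 0.3, seed = 7)
#' @rdname CameraModel-class
#' @export
cameraModel <- function(gain = 1, noiseSd = 0.3, bitDepth = 8L, seed = 1L) {
  new("CameraModel", gain = gain, noiseSd = noiseSd,
      bitDepth = as.integer(bitDepth), seed = as.integer(seed))
}

#' Chip frame geometry for rendered image stacks
#'
#' @slot frameWidth,frameHeight integer frame size in pixels.
#' @slot roi the [RoiSpec-class] of the reaction chamber; must lie strictly
#'   inside the frame.
#' @slot backgroundLevel numeric, grayscale level outside the chamber.
#' @exportClass ChipLayout
setClass("ChipLayout",
  representation(frameWidth = "integer", frameHeight = "integer",
                 roi = "RoiSpec", backgroundLevel = "numeric"))

setValidity("ChipLayout", function(object) {
  msg <- character(0)
  r <- object@roi
  if (r@x + r@width > object@frameWidth ||
      r@y + r@height > object@frameHeight)
    msg <- c(msg, "ROI must lie inside the frame")
  if (object@backgroundLevel < 0)
    msg <- c(msg, "backgroundLevel must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param frameWidth,frameHeight,roi,backgroundLevel see the class slots.
#' @return A [ChipLayout-class] object.
#' @examples
#' chipLayout(64L, 48L, roiSpec(12, 8, 40, 32))
#' @rdname ChipLayout-class
#' @export
chipLayout <- function(frameWidth = 64L, frameHeight = 48L,
                       roi = roiSpec(12L, 8L, 40L, 32L),
                       backgroundLevel = 5) {
  new("ChipLayout", frameWidth = as.integer(frameWidth),
      frameHeight = as.integer(frameHeight), roi = roi,
      backgroundLevel = backgroundLevel)
}

#' Design of a multi-set dilution-series experiment
#'
#' Defaults mirror a two-instrument-set study: 2 sets differing by an
#' endpoint-intensity gain gap of 1.8, a 10-fold dilution series at three
#' concentrations, four replicate experiments per set and 40 thermal cycles.
#'
#' @slot nSets integer number of instrument sets.
#' @slot nExperimentsPerSet integer replicate experiments per set.
#' @slot concentrations numeric relative template concentrations, strictly
#'   decreasing.
#' @slot nCycles integer number of PCR cycles (>= 12 so that the 10-cycle
#'   baseline window leaves at least two cycles of signal).
#' @slot setGains numeric per-set gain multipliers, one per set.
#' @slot cqJitterSd numeric sd (cycles) of the Gaussian replicate jitter
#'   applied to the true Cq.
#' @slot gainJitterSd numeric relative sd of the Gaussian replicate jitter
#'   applied to the gain.
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(nSets = "integer", nExperimentsPerSet = "integer",
                 concentrations = "numeric", nCycles = "integer",
                 setGains = "numeric", cqJitterSd = "numeric",
                 gainJitterSd = "numeric"))

setValidity("ExperimentDesign", function(object) {
  msg <- character(0)
  if (object@nCycles < 12L)
    msg <- c(msg, "nCycles must be >= 12 (10 baseline cycles + signal)")
  if (length(object@concentrations) < 1L ||
      any(diff(object@concentrations) >= 0))
    msg <- c(msg, "concentrations must be strictly decreasing")
  if (any(object@concentrations <= 0))
    msg <- c(msg, "concentrations must be > 0")
  if (length(object@setGains) != object@nSets)
    msg <- c(msg, "setGains must have one entry per set")
  if (any(object@setGains <= 0)) msg <- c(msg, "setGains must be > 0")
  if (object@cqJitterSd < 0 || object@gainJitterSd < 0)
    msg <- c(msg, "jitter sds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param nSets,nExperimentsPerSet,concentrations,nCycles,setGains see the
#'   class slots.
#' @param cqJitterSd,gainJitterSd replicate jitter magnitudes (cycles /
#'   relative gain).
#' @return An [ExperimentDesign-class] object.
#' @examples
#' experimentDesign()
#' @rdname ExperimentDesign-class
#' @export
experimentDesign <- function(nSets = 2L, nExperimentsPerSet = 4L,
                             concentrations = c(1, 0.1, 0.01),
                             nCycles = 40L, setGains = c(1, 1 / 1.8),
                             cqJitterSd = 0.2, gainJitterSd = 0.02) {
  new("ExperimentDesign", nSets = as.integer(nSets),
      nExperimentsPerSet = as.integer(nExperimentsPerSet),
      concentrations = concentrations, nCycles = as.integer(nCycles),
      setGains = setGains, cqJitterSd = cqJitterSd,
      gainJitterSd = gainJitterSd)
}

## ---------------------------------------------------------------------------
## Amplification curves and curve grids
## ---------------------------------------------------------------------------

.CURVE_STATES <- c("raw", "normalized", "log")

#' A single amplification curve
#'
#' Per-cycle relative fluorescence intensities for one PCR run, together with
#' its processing state. The state advances only forward:
#' `raw -> normalized -> log`. In the `log` state, cycles whose normalized
#' intensity was not positive carry `NA` (undefined; below any threshold).
#'
#' @slot intensities numeric per-cycle values (grayscale units, or log units
#'   in the `log` state, where `NA` marks undefined values).
#' @slot cycles integer 1-based cycle indices, contiguous from 1.
#' @slot state one of `"raw"`, `"normalized"`, `"log"`.
#' @slot setId,experimentId,concentration run metadata (may be `NA`).
#' @exportClass AmplificationCurve
setClass("AmplificationCurve",
  representation(intensities = "numeric", cycles = "integer",
                 state = "character", setId = "character",
                 experimentId = "integer", concentration = "numeric"))

setValidity("AmplificationCurve", function(object) {
  msg <- character(0)
  n <- length(object@intensities)
  if (n < 1L) msg <- c(msg, "curve must contain at least one cycle")
  if (length(object@cycles) != n)
    msg <- c(msg, "cycles and intensities must have equal length")
  else if (!identical(object@cycles, seq_len(n)))
    msg <- c(msg, "cycles must be contiguous starting at 1")
  if (!(object@state %in% .CURVE_STATES))
    msg <- c(msg, sprintf("state must be one of %s",
                          paste(.CURVE_STATES, collapse = ", ")))
  if (object@state != "log" && anyNA(object@intensities))
    msg <- c(msg, "NA intensities are only allowed in the log state")
  if (length(msg)) msg else TRUE
})

#' Construct an amplification curve
#'
#' @param intensities numeric per-cycle values.
#' @param state processing state, `"raw"` by default.
#' @param setId,experimentId,concentration optional run metadata.
#' @return An [AmplificationCurve-class] object.
#' @examples
#' amplificationCurve(c(rep(10, 10), 20, 60, 80))
#' @export
amplificationCurve <- function(intensities, state = "raw",
                               setId = NA_character_,
                               experimentId = NA_integer_,
                               concentration = NA_real_) {
  new("AmplificationCurve", intensities = as.numeric(intensities),
      cycles = seq_along(intensities), state = state,
      setId = as.character(setId), experimentId = as.integer(experimentId),
      concentration = as.numeric(concentration))
}

setMethod("show", "AmplificationCurve", function(object) {
  cat(sprintf("AmplificationCurve: %d cycles, state '%s'\n",
              length(object@intensities), object@state))
  meta <- c(set = object@setId,
            experiment = as.character(object@experimentId),
            concentration = as.character(object@concentration))
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = " = ", collapse = ", "), "\n")
  cat("  range:", paste(signif(range(object@intensities, na.rm = TRUE), 5),
                        collapse = " .. "), "\n")
})

#' Grid of amplification curves for a multi-set experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assays are
#' cycles-by-runs matrices. The `"raw"` assay holds the as-measured
#' intensities; [baselineNormalize()] adds `"normalized"` and
#' [logTransform()] adds `"log"` (with `NA` for non-positive normalized
#' values). `colData` carries `set_id`, `experiment_id` and `concentration`
#' for every run, plus `true_cq` and `gain` when the grid was simulated.
#'
#' @exportClass PCRGrid
setClass("PCRGrid", contains = "SummarizedExperiment")

setValidity("PCRGrid", function(object) {
  msg <- character(0)
  need <- c("set_id", "experiment_id", "concentration")
  missing <- setdiff(need, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, sprintf("colData must contain %s",
                          paste(missing, collapse = ", ")))
  if (!("raw" %in% assayNames(object)))
    msg <- c(msg, "a 'raw' assay is required")
  if (length(msg)) msg else TRUE
})

#' Construct a curve grid
#'
#' @param raw numeric matrix of raw intensities, cycles in rows and runs in
#'   columns.
#' @param colData data.frame or DataFrame with one row per run and at least
#'   columns `set_id`, `experiment_id`, `concentration`.
#' @param metadata optional list stored in the object metadata.
#' @return A [PCRGrid-class] object.
#' @examples
#' m <- matrix(rep(1:15, 2), ncol = 2)
#' PCRGrid(m, data.frame(set_id = c("A", "B"), experiment_id = 1L,
#'                       concentration = 1))
#' @export
PCRGrid <- function(raw, colData, metadata = list()) {
  raw <- as.matrix(raw)
  cd <- DataFrame(colData)
  if (is.null(colnames(raw)))
    colnames(raw) <- sprintf("%s_e%d_c%s", cd$set_id, cd$experiment_id,
                             as.character(cd$concentration))
  rownames(raw) <- sprintf("cycle_%02d", seq_len(nrow(raw)))
  se <- SummarizedExperiment(assays = list(raw = raw), colData = cd,
                             rowData = DataFrame(cycle = seq_len(nrow(raw))),
                             metadata = metadata)
  new("PCRGrid", se)
}

setMethod("show", "PCRGrid", function(object) {
  cd <- colData(object)
  cat(sprintf("PCRGrid: %d cycles x %d runs (%d set(s), %d concentration(s))\n",
              nrow(object), ncol(object),
              length(unique(cd$set_id)),
              length(unique(cd$concentration))))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (!is.null(cd$true_cq)) cat("  ground truth: true_cq, gain\n")
})

## ---------------------------------------------------------------------------
## Image stacks
## ---------------------------------------------------------------------------

#' A cycle-indexed stack of fluorescence frames
#'
#' One image per PCR cycle. Frames are numeric matrices (grayscale) or
#' height x width x 3 arrays (RGB), in grayscale units on the
#' `[0, 2^bitDepth - 1]` scale; values may be fractional until quantized at
#' write time.
#'
#' @slot frames list of frames, one per cycle, all the same dimensions.
#' @slot cycles integer 1-based cycle indices, contiguous.
#' @slot bitDepth integer bits per channel.
#' @slot source character, origin (directory path or "simulated").
#' @exportClass ImageStack
setClass("ImageStack",
  representation(frames = "list", cycles = "integer",
                 bitDepth = "integer", source = "character"))

setValidity("ImageStack", function(object) {
  msg <- character(0)
  n <- length(object@frames)
  if (n < 1L) msg <- c(msg, "stack must contain at least one frame")
  if (length(object@cycles) != n)
    msg <- c(msg, "cycles must match the number of frames")
  else if (any(diff(object@cycles) != 1L))
    msg <- c(msg, "cycle indices must be contiguous")
  dims <- lapply(object@frames, function(f) dim(f)[1:2])
  if (n > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "all frames must share the same dimensions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("ImageStack: %d frames of %d x %d px (%s), %d-bit, cycles %d..%d\n",
              length(object@frames), d[1], d[2],
              if (length(d) == 3L) "RGB" else "grayscale",
              object@bitDepth, min(object@cycles), max(object@cycles)))
  cat("  source:", object@source, "\n")
})

## ---------------------------------------------------------------------------
## Ct vectors, search results, calibration factors
## ---------------------------------------------------------------------------

#' Threshold cycles of one experiment, indexed by concentration
#'
#' @slot values numeric Ct values (cycles) named by concentration label;
#'   `NA` marks an undetermined Ct (curve never crossed the threshold).
#' @slot setId,experimentId identifiers of the run.
#' @exportClass CtVector
setClass("CtVector",
  representation(values = "numeric", setId = "character",
                 experimentId = "integer"))

setValidity("CtVector", function(object) {
  msg <- character(0)
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "values must carry unique concentration labels as names")
  if (length(msg)) msg else TRUE
})

#' Construct a Ct vector
#'
#' @param values numeric Ct values named by concentration label (`NA` =
#'   undetermined).
#' @param setId,experimentId optional identifiers.
#' @return A [CtVector-class] object.
#' @examples
#' ctVector(c(`1` = 20.1, `0.1` = 23.4, `0.01` = 26.8), "A", 1L)
#' @export
ctVector <- function(values, setId = NA_character_,
                     experimentId = NA_integer_) {
  new("CtVector", values = values, setId = as.character(setId),
      experimentId = as.integer(experimentId))
}

setMethod("show", "CtVector", function(object) {
  cat(sprintf("CtVector (set %s, experiment %s):\n", object@setId,
              object@experimentId))
  print(object@values)
})

#' Result of a threshold grid search
#'
#' @slot objective data.frame with columns `t` (log threshold), `distance`
#'   (cycles; `NA` where undefined) and `n_excluded` (undetermined Ct pairs
#'   dropped at that threshold).
#' @slot tOpt minimizing threshold (log units; smallest in case of ties).
#' @slot dOpt minimum distance (cycles).
#' @slot scope `"experiment"`, `"set"` or `"all"`, with identifiers appended
#'   where applicable.
#' @slot norm the aggregation used: `"rms"`, `"euclidean"` or `"sum"`.
#' @exportClass ThresholdSearchResult
setClass("ThresholdSearchResult",
  representation(objective = "data.frame", tOpt = "numeric",
                 dOpt = "numeric", scope = "character", norm = "character"))

setValidity("ThresholdSearchResult", function(object) {
  msg <- character(0)
  ok <- is.finite(object@objective$distance)
  if (any(ok) && abs(object@dOpt - min(object@objective$distance[ok])) >
      1e-12 * max(1, object@dOpt))
    msg <- c(msg, "dOpt must equal the minimum of the objective")
  if (object@dOpt < 0) msg <- c(msg, "dOpt must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ThresholdSearchResult", function(object) {
  cat(sprintf("ThresholdSearchResult (scope %s, %s norm)\n",
              object@scope, object@norm))
  cat(sprintf("  grid: %d thresholds in [%.4g, %.4g]\n",
              nrow(object@objective), min(object@objective$t),
              max(object@objective$t)))
  cat(sprintf("  t_opt = %.4g, d_opt = %.4g cycles\n",
              object@tOpt, object@dOpt))
  excl <- object@objective$n_excluded[match(object@tOpt, object@objective$t)]
  if (isTRUE(excl > 0))
    cat(sprintf("  %d undetermined Ct pair(s) excluded at t_opt\n", excl))
})

#' Inter-set intensity calibration factor
#'
#' @slot referenceSet,targetSet set identifiers; the target set's normalized
#'   intensities are multiplied by `ratio` to match the reference set's
#'   endpoint brightness.
#' @slot ratio positive multiplier (reference endpoint mean / target endpoint
#'   mean, after optional rounding).
#' @slot window integer vector of length 2, first and last cycle (1-based,
#'   inclusive) of the endpoint window.
#' @slot componentMeans named numeric, the per-set endpoint means the ratio
#'   was computed from.
#' @slot rounding `"full"` or `"1dp"`.
#' @exportClass CalibrationFactor
setClass("CalibrationFactor",
  representation(referenceSet = "character", targetSet = "character",
                 ratio = "numeric", window = "integer",
                 componentMeans = "numeric", rounding = "character"))

setValidity("CalibrationFactor", function(object) {
  msg <- character(0)
  if (object@ratio <= 0) msg <- c(msg, "ratio must be > 0")
  if (length(object@window) != 2L || object@window[1] > object@window[2] ||
      object@window[1] < 1L)
    msg <- c(msg, "window must be c(start, end) with 1 <= start <= end")
  if (!(object@rounding %in% c("full", "1dp")))
    msg <- c(msg, "rounding must be 'full' or '1dp'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationFactor", function(object) {
  cat(sprintf("CalibrationFactor: set %s x %.4g -> set %s scale\n",
              object@targetSet, object@ratio, object@referenceSet))
  cat(sprintf("  endpoint means (cycles %d-%d): %s\n", object@window[1],
              object@window[2],
              paste(names(object@componentMeans),
                    signif(object@componentMeans, 4),
                    sep = " = ", collapse = ", ")))
  cat("  rounding:", object@rounding, "\n")
})
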