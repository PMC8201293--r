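#' Accessors for amplification curves
#'
#' `intensities()` returns the per-cycle values, `cycleIndex()` the 1-based
#' cycle numbers and `curveState()` the processing state
#' (`"raw"`, `"normalized"` or `"log"`).
#'
#' @param x an [AmplificationCurve-class].
#' @return A numeric vector, integer vector, or character scalar.
#' @examples
#' cv <- amplificationCurve(1:15)
#' intensities(cv)
#' curveState(cv)
#' @name curve-accessors
NULL

#' @rdname curve-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname curve-accessors
#' @export
setGeneric("cycleIndex", function(x) standardGeneric("cycleIndex"))

#' @rdname curve-accessors
#' @export
setGeneric("curveState", function(x) standardGeneric("curveState"))

setMethod("intensities", "AmplificationCurve", function(x) x@intensities)
setMethod("cycleIndex", "AmplificationCurve", function(x) x@cycles)
setMethod("curveState", "AmplificationCurve", function(x) x@state)

#' Subtract the pre-amplification baseline from raw curves
#'
#' Every intensity is reduced by the mean of the first `nBaseline` cycles,
#' so the curve starts at zero and the fluorescence offset contributed by
#' the master mix and the optics before amplification is removed. The mean
#' of the first `nBaseline` normalized values is zero to machine precision.
#'
#' @param x an [AmplificationCurve-class] in state `"raw"`, or a
#'   [PCRGrid-class] with a `"raw"` assay.
#' @param nBaseline number of leading baseline cycles (default 10); the
#'   curve must be strictly longer than this.
#' @return The same class of object, in state `"normalized"` (for a grid: a
#'   `"normalized"` assay is added).
#' @examples
#' cv <- amplificationCurve(c(rep(3, 10), 13))
#' intensities(baselineNormalize(cv))
#' @export
setGeneric("baselineNormalize",
           function(x, nBaseline = 10L) standardGeneric("baselineNormalize"))

#' Log-transform normalized curves
#'
#' Positive normalized intensities are mapped to their logarithm; values
#' that are zero or negative (possible before amplification, where the
#' baseline-subtracted signal fluctuates around zero) are undefined and
#' stored as `NA`, which every threshold treats as "below threshold". This
#' way early-cycle noise can never create a spurious threshold crossing.
#'
#' @param x an [AmplificationCurve-class] in state `"normalized"`, or a
#'   [PCRGrid-class] with a `"normalized"` assay.
#' @param base logarithm base; natural log by default (10 and 2 are the
#'   usual alternatives).
#' @return The same class of object in state `"log"` (for a grid: a `"log"`
#'   assay is added and the base recorded in `metadata(x)$logBase`).
#' @examples
#' cv <- amplificationCurve(c(rep(0, 10), exp(2)), state = "normalized")
#' intensities(logTransform(cv))
#' @export
setGeneric("logTransform",
           function(x, base = exp(1)) standardGeneric("logTransform"))

#' Call the fractional threshold cycle of a log curve
#'
#' Returns the first fractional cycle at which the log-intensity curve
#' crosses the threshold from below, by linear interpolation in log units
#' between the two bracketing cycles. If the first defined log value already
#' exceeds the threshold (or the crossing value is preceded by an undefined
#' cycle, so there is nothing to interpolate against), the integer cycle
#' index is returned. A curve that never reaches the threshold is
#' undetermined and yields `NA`.
#'
#' @param x an [AmplificationCurve-class] in state `"log"`, or a
#'   [PCRGrid-class] with a `"log"` assay.
#' @param threshold log threshold (same log base as the curve). For a single
#'   curve a vector of thresholds is accepted.
#' @return For a curve: numeric Ct(s) in cycles, `NA` = undetermined. For a
#'   grid: a named numeric vector with one Ct per run.
#' @examples
#' lc <- amplificationCurve(c(rep(NA, 19), 1, 3), state = "log")
#' computeCt(lc, 2)  # 20.5
#' @export
setGeneric("computeCt",
           function(x, threshold) standardGeneric("computeCt"))

#' Mean late-cycle (endpoint) intensity
#'
#' Averages the normalized intensities over an endpoint window (default
#' cycles 35-40, 1-based and inclusive) across all in-scope curves; used to
#' measure each instrument set's plateau brightness for inter-set
#' calibration.
#'
#' @param x an [AmplificationCurve-class] in state `"normalized"`, or a
#'   [PCRGrid-class] with a `"normalized"` assay.
#' @param window integer length-2 vector, first and last cycle of the
#'   window.
#' @param ... for a grid: `set`, the set id whose curves enter the mean
#'   (required when the grid has more than one set).
#' @return Mean intensity in grayscale units.
#' @examples
#' cv <- amplificationCurve(seq_len(40), state = "normalized")
#' endpointMean(cv)  # mean of 35..40
#' @export
setGeneric("endpointMean",
           function(x, window = c(35L, 40L), ...) standardGeneric("endpointMean"))

#' Apply an inter-set calibration factor
#'
#' Multiplies the target set's normalized intensities by the calibration
#' ratio, so both sets share the reference set's intensity scale before the
#' log transform and the threshold search. Applied to a grid, any existing
#' `"log"` assay is dropped (it must be recomputed from the rescaled
#' curves).
#'
#' @param x an [AmplificationCurve-class] in state `"normalized"`, or a
#'   [PCRGrid-class] with a `"normalized"` assay.
#' @param factor a [CalibrationFactor-class].
#' @return The rescaled object.
#' @examples
#' fac <- calibrationFactor(74.2, 41.2, rounding = "1dp")
#' cv <- amplificationCurve(c(10, 20), state = "normalized")
#' intensities(applyCalibration(cv, fac))
#' @export
setGeneric("applyCalibration",
           function(x, factor) standardGeneric("applyCalibration"))

#' Extract an amplification curve from an image stack
#'
#' Converts each frame to grayscale and averages the pixels inside the ROI,
#' producing one relative-fluorescence value per cycle.
#'
#' @param x an [ImageStack-class].
#' @param roi a [RoiSpec-class] lying inside the frames.
#' @param channel `"luma"` (BT.601 weighted grayscale, default) or
#'   `"green"` (green channel only; fluorescein emission falls in the
#'   camera's green band).
#' @return An [AmplificationCurve-class] in state `"raw"`.
#' @examples
#' st <- renderImageStack(amplificationCurve(c(rep(10, 12), 50, 90)),
#'                        chipLayout(), cameraModel(noiseSd = 0))
#' quantifyStack(st, roiSpec(12, 8, 40, 32))
#' @export
setGeneric("quantifyStack",
           function(x, roi, channel = c("luma", "green"))
             standardGeneric("quantifyStack"))

#' Ground truth of a simulated grid
#'
#' @param x a [PCRGrid-class] produced by [generateExperimentGrid()].
#' @return A `DataFrame` with `set_id`, `experiment_id`, `concentration`,
#'   `true_cq` (cycles, including replicate jitter) and `gain` (effective
#'   multiplier) per run.
#' @examples
#' g <- generateExperimentGrid(experimentDesign(), seed = 1)
#' groundTruth(g)
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

setMethod("groundTruth", "PCRGrid", function(x) {
  cd <- colData(x)
  if (is.null(cd$true_cq))
    stop("grid carries no ground truth (not simulated)")
  cd[, c("set_id", "experiment_id", "concentration", "true_cq", "gain")]
})
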