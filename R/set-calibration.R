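## Inter-set intensity calibration: the two instrument sets reach different
## endpoint brightness (different optics/gain), so the dimmer set's
## normalized curves are multiplied by the ratio of endpoint means (cycles
## 35-40) before the log transform and the threshold re-optimization.

#' @rdname endpointMean
setMethod("endpointMean", "AmplificationCurve",
          function(x, window = c(35L, 40L), ...) {
  if (curveState(x) != "normalized")
    stop("endpointMean expects normalized intensities")
  .checkWindow(window, length(intensities(x)))
  mean(intensities(x)[window[1]:window[2]])
})

#' @rdname endpointMean
setMethod("endpointMean", "PCRGrid",
          function(x, window = c(35L, 40L), set = NULL) {
  if (!("normalized" %in% assayNames(x)))
    stop("grid has no 'normalized' assay; run baselineNormalize() first")
  .checkWindow(window, nrow(x))
  keep <- rep(TRUE, ncol(x))
  if (!is.null(set)) keep <- colData(x)$set_id == set
  else if (length(unique(colData(x)$set_id)) > 1L)
    stop("grid has several sets; give `set`")
  if (!any(keep)) stop("no curves for set ", set)
  mean(assay(x, "normalized")[window[1]:window[2], keep, drop = FALSE])
})

.checkWindow <- function(window, nCycles) {
  if (length(window) != 2L || window[1] < 1L || window[1] > window[2])
    stop("window must be c(start, end) with 1 <= start <= end")
  if (window[2] > nCycles)
    stop(sprintf("window end %d exceeds curve length %d", window[2], nCycles))
}

#' Calibration factor from two endpoint means
#'
#' The ratio of the reference set's endpoint mean to the target set's. With
#' `rounding = "1dp"` the ratio is rounded to one decimal, matching
#' calibration at a printed precision; the default keeps full precision.
#'
#' @param meanRef,meanTarget per-set endpoint mean intensities (grayscale
#'   units), both > 0.
#' @param rounding `"full"` (default) or `"1dp"`.
#' @param referenceSet,targetSet set identifiers recorded on the factor.
#' @param window endpoint window recorded on the factor.
#' @return A [CalibrationFactor-class].
#' @examples
#' calibrationFactor(74.2, 41.2, rounding = "1dp")  # ratio 1.8
#' @export
calibrationFactor <- function(meanRef, meanTarget,
                              rounding = c("full", "1dp"),
                              referenceSet = "A", targetSet = "B",
                              window = c(35L, 40L)) {
  rounding <- match.arg(rounding)
  if (meanRef <= 0 || meanTarget <= 0)
    stop("endpoint means must be > 0 (did the set amplify?)")
  ratio <- meanRef / meanTarget
  if (rounding == "1dp") ratio <- round(ratio, 1)
  new("CalibrationFactor", referenceSet = referenceSet,
      targetSet = targetSet, ratio = ratio, window = as.integer(window),
      componentMeans = stats::setNames(c(meanRef, meanTarget),
                                       c(referenceSet, targetSet)),
      rounding = rounding)
}

#' Calibration factor between two sets of a grid
#'
#' Computes both sets' endpoint means and forms the ratio. By default the
#' brighter set is the reference (its scale is kept; the dimmer set is
#' brought up to it).
#'
#' @param x a [PCRGrid-class] with a `"normalized"` assay, containing
#'   exactly two sets unless both ids are given.
#' @param referenceSet,targetSet set ids; default: reference = higher
#'   endpoint mean.
#' @inheritParams calibrationFactor
#' @param window endpoint window (1-based inclusive cycles).
#' @return A [CalibrationFactor-class].
#' @examples
#' g <- baselineNormalize(generateExperimentGrid(experimentDesign(), seed = 1))
#' setCalibrationFactor(g)
#' @export
setCalibrationFactor <- function(x, referenceSet = NULL, targetSet = NULL,
                                 window = c(35L, 40L),
                                 rounding = c("full", "1dp")) {
  rounding <- match.arg(rounding)
  sets <- unique(colData(x)$set_id)
  if (is.null(referenceSet) || is.null(targetSet)) {
    if (length(sets) != 2L)
      stop("grid must contain exactly two sets, or give both set ids")
    means <- vapply(sets, function(s) endpointMean(x, window, set = s),
                    numeric(1))
    referenceSet <- sets[which.max(means)]
    targetSet <- setdiff(sets, referenceSet)
  }
  calibrationFactor(endpointMean(x, window, set = referenceSet),
                    endpointMean(x, window, set = targetSet),
                    rounding = rounding, referenceSet = referenceSet,
                    targetSet = targetSet, window = window)
}

#' @rdname applyCalibration
setMethod("applyCalibration", "AmplificationCurve", function(x, factor) {
  if (curveState(x) != "normalized")
    stop("applyCalibration expects normalized intensities")
  initialize(x, intensities = intensities(x) * factor@ratio)
})

#' @rdname applyCalibration
setMethod("applyCalibration", "PCRGrid", function(x, factor) {
  if (!("normalized" %in% assayNames(x)))
    stop("grid has no 'normalized' assay; run baselineNormalize() first")
  validObject(factor)
  norm <- assay(x, "normalized")
  target <- colData(x)$set_id == factor@targetSet
  if (!any(target))
    stop("grid has no curves for target set ", factor@targetSet)
  norm[, target] <- norm[, target] * factor@ratio
  assay(x, "normalized") <- norm
  ## the log assay (if any) is stale now
  if ("log" %in% assayNames(x))
    assays(x) <- assays(x)[setdiff(assayNames(x), "log")]
  metadata(x)$calibration <- factor
  x
})

#' Calibration report
#'
#' @param factor a [CalibrationFactor-class].
#' @return A one-row data.frame: reference and target set, their endpoint
#'   means, window, rounding policy and ratio.
#' @examples
#' calibrationReport(calibrationFactor(74.2, 41.2, rounding = "1dp"))
#' @export
calibrationReport <- function(factor) {
  data.frame(reference_set = factor@referenceSet,
             target_set = factor@targetSet,
             mean_reference = unname(factor@componentMeans[factor@referenceSet]),
             mean_target = unname(factor@componentMeans[factor@targetSet]),
             window_start = factor@window[1], window_end = factor@window[2],
             rounding = factor@rounding, ratio = factor@ratio)
}

#' Accessors for calibration factors and search results
#'
#' @param x a [CalibrationFactor-class] or [ThresholdSearchResult-class].
#' @return `calibrationRatio()`: the multiplier; `tOpt()` / `dOpt()`: the
#'   optimal threshold (log units) and minimal distance (cycles);
#'   `objectiveTable()`: the full objective data.frame.
#' @name result-accessors
#' @export
calibrationRatio <- function(x) x@ratio

#' @rdname result-accessors
#' @export
tOpt <- function(x) x@tOpt

#' @rdname result-accessors
#' @export
dOpt <- function(x) x@dOpt

#' @rdname result-accessors
#' @export
objectiveTable <- function(x) x@objective
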