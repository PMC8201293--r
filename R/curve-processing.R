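## Baseline normalization, log transform and fractional Ct calling.

#' @rdname baselineNormalize
setMethod("baselineNormalize", "AmplificationCurve",
          function(x, nBaseline = 10L) {
  if (curveState(x) != "raw")
    stop("baselineNormalize expects a curve in state 'raw'")
  v <- intensities(x)
  if (length(v) <= nBaseline)
    stop(sprintf("curve has %d cycles; need more than the %d baseline cycles",
                 length(v), nBaseline))
  initialize(x, intensities = v - mean(v[seq_len(nBaseline)]),
             state = "normalized")
})

#' @rdname baselineNormalize
setMethod("baselineNormalize", "PCRGrid", function(x, nBaseline = 10L) {
  raw <- assay(x, "raw")
  if (nrow(raw) <= nBaseline)
    stop(sprintf("grid has %d cycles; need more than the %d baseline cycles",
                 nrow(raw), nBaseline))
  base <- colMeans(raw[seq_len(nBaseline), , drop = FALSE])
  assay(x, "normalized") <- sweep(raw, 2L, base, "-")
  metadata(x)$nBaseline <- as.integer(nBaseline)
  x
})

#' @rdname logTransform
setMethod("logTransform", "AmplificationCurve", function(x, base = exp(1)) {
  if (curveState(x) != "normalized")
    stop("logTransform expects a curve in state 'normalized'")
  initialize(x, intensities = .logOrNA(intensities(x), base), state = "log")
})

#' @rdname logTransform
setMethod("logTransform", "PCRGrid", function(x, base = exp(1)) {
  if (!("normalized" %in% assayNames(x)))
    stop("grid has no 'normalized' assay; run baselineNormalize() first")
  norm <- assay(x, "normalized")
  lg <- norm
  lg[] <- .logOrNA(as.vector(norm), base)
  assay(x, "log") <- lg
  metadata(x)$logBase <- base
  x
})

.logOrNA <- function(v, base) {
  out <- rep(NA_real_, length(v))
  pos <- !is.na(v) & v > 0
  out[pos] <- log(v[pos], base = base)
  out
}

## Fractional Ct of one log-curve at one threshold. NA values are
## undefined (below any threshold): a crossing needs a defined value >= t
## whose predecessor is either defined and < t (interpolate) or the start
## of the defined data / undefined (return the integer cycle).
.ctOne <- function(v, cycles, t) {
  above <- which(!is.na(v) & v >= t)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L || is.na(v[i - 1L])) return(as.numeric(cycles[i]))
  cycles[i - 1L] + (t - v[i - 1L]) / (v[i] - v[i - 1L])
}

#' @rdname computeCt
setMethod("computeCt", "AmplificationCurve", function(x, threshold) {
  if (curveState(x) != "log")
    stop("computeCt expects a curve in state 'log'")
  v <- intensities(x)
  if (!length(v)) stop("empty curve")
  vapply(threshold, function(t) .ctOne(v, cycleIndex(x), t), numeric(1))
})

#' @rdname computeCt
setMethod("computeCt", "PCRGrid", function(x, threshold) {
  lg <- .logAssay(x)
  stopifnot(length(threshold) == 1L)
  cycles <- seq_len(nrow(lg))
  vapply(seq_len(ncol(lg)),
         function(j) .ctOne(lg[, j], cycles, threshold),
         numeric(1)) |> stats::setNames(colnames(lg))
})

.logAssay <- function(x) {
  if (!("log" %in% assayNames(x)))
    stop("grid has no 'log' assay; run logTransform() first")
  assay(x, "log")
}

#' Ct table of a grid at a fixed threshold
#'
#' @param x a [PCRGrid-class] with a `"log"` assay.
#' @param threshold log threshold.
#' @return A data.frame with `set_id`, `experiment_id`, `concentration` and
#'   `ct` (NA = undetermined).
#' @examples
#' g <- logTransform(baselineNormalize(
#'   generateExperimentGrid(experimentDesign(), seed = 1)))
#' head(ctTable(g, 1.5))
#' @export
ctTable <- function(x, threshold) {
  cd <- colData(x)
  data.frame(set_id = cd$set_id, experiment_id = cd$experiment_id,
             concentration = cd$concentration,
             ct = unname(computeCt(x, threshold)))
}

#' Ct vectors of a grid at a fixed threshold
#'
#' Groups the Ct table by (set, experiment) into one [CtVector-class] per
#' experiment, the unit of comparison against the reference instrument.
#'
#' @inheritParams ctTable
#' @return A named list of [CtVector-class] objects (`"A.1"`, `"A.2"`, ...).
#' @examples
#' g <- logTransform(baselineNormalize(
#'   generateExperimentGrid(experimentDesign(), seed = 1)))
#' ctVectors(g, 1.5)[["A.1"]]
#' @export
ctVectors <- function(x, threshold) {
  tab <- ctTable(x, threshold)
  keys <- paste(tab$set_id, tab$experiment_id, sep = ".")
  lapply(split(tab, factor(keys, levels = unique(keys))), function(d) {
    ctVector(stats::setNames(d$ct, as.character(d$concentration)),
             setId = d$set_id[1], experimentId = d$experiment_id[1])
  })
}
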