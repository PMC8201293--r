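## Threshold calibration against a reference instrument: the distance
## between the reference Ct vector C and the system's Ct vector C^(s,e,t)
## is minimized over a grid of log thresholds t, per experiment, per set,
## or globally over all sets and experiments.

#' Distance between a reference and an estimated Ct vector
#'
#' Pairs the two vectors by concentration label and returns the Euclidean
#' norm of the differences, by default divided by the square root of the
#' number of compared pairs (root-mean-square per Ct measurement), so the
#' result is in cycles and directly comparable to a per-measurement
#' standard deviation. Pairs where either Ct is undetermined (`NA`) are
#' excluded; the number of exclusions is reported in the `"nExcluded"`
#' attribute.
#'
#' @param reference,estimated [CtVector-class] objects or named numeric
#'   vectors (names = concentration labels). Both must cover the same
#'   labels.
#' @param norm `"rms"` (default) or `"euclidean"` (raw norm).
#' @return Distance in cycles, with attribute `nExcluded`.
#' @examples
#' ctDistance(c(`1` = 20, `0.1` = 23, `0.01` = 26),
#'            c(`1` = 20.5, `0.1` = 23, `0.01` = 26))  # sqrt(0.25/3)
#' @export
ctDistance <- function(reference, estimated, norm = c("rms", "euclidean")) {
  norm <- match.arg(norm)
  ref <- .ctValues(reference); est <- .ctValues(estimated)
  if (!setequal(names(ref), names(est)))
    stop("reference and estimated vectors cover different concentrations")
  est <- est[names(ref)]
  ok <- !is.na(ref) & !is.na(est)
  if (!any(ok))
    stop("no comparable Ct pairs: all values undetermined")
  ss <- sum((ref[ok] - est[ok])^2)
  d <- if (norm == "rms") sqrt(ss / sum(ok)) else sqrt(ss)
  structure(d, nExcluded = sum(!ok))
}

.ctValues <- function(x) {
  if (is(x, "CtVector")) return(x@values)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a CtVector or a named numeric vector")
}

#' Evenly spaced threshold grid
#'
#' @param tMin,tMax grid bounds in log units, `tMin < tMax`.
#' @param step grid spacing in log units, > 0 (default 0.01).
#' @return Numeric vector of thresholds.
#' @examples
#' thresholdGrid(0, 4, 0.5)
#' @export
thresholdGrid <- function(tMin, tMax, step = 0.01) {
  stopifnot(tMin < tMax, step > 0)
  seq(tMin, tMax, by = step)
}

#' Default threshold grid of a log-transformed grid
#'
#' Spans the range of defined log values across all curves, at the given
#' step.
#'
#' @param x a [PCRGrid-class] with a `"log"` assay.
#' @param step grid spacing in log units.
#' @return Numeric vector of thresholds.
#' @export
defaultThresholdGrid <- function(x, step = 0.01) {
  lg <- .logAssay(x)
  r <- range(lg, na.rm = TRUE)
  thresholdGrid(r[1], r[2], step)
}

## Resolve a reference specification to a named vector per (set, exp).
## A single named vector applies to every experiment (the usual case: one
## reference instrument measured the same dilution series).
.refFor <- function(reference, set, experiment) {
  if (is.data.frame(reference)) {
    d <- reference[reference$set_id == set &
                     reference$experiment_id == experiment, ]
    if (!nrow(d)) stop(sprintf("no reference Ct for set %s experiment %s",
                               set, experiment))
    return(stats::setNames(d$ct, as.character(d$concentration)))
  }
  .ctValues(reference)
}

#' Objective curve and optimal threshold for a scope
#'
#' For every threshold on the grid, calls Ct for every in-scope curve,
#' pairs it with the reference Ct of its concentration, and aggregates the
#' paired differences into a distance: by default the pooled RMS over all
#' in-scope Ct pairs (`"rms"`), alternatively the raw Euclidean norm over
#' all pairs (`"euclidean"`) or the sum over experiments of per-experiment
#' Euclidean norms (`"sum"`). The minimizing threshold is returned, ties
#' broken toward the smallest threshold.
#'
#' Undetermined Ct values are excluded pairwise (their count is reported
#' per threshold); with `naAction = "strict"` any undetermined in-scope Ct
#' makes the objective undefined at that threshold. Thresholds where no
#' pair is comparable are undefined and never minimizers; if every
#' threshold is undefined the search fails with an error.
#'
#' @param x a [PCRGrid-class] with a `"log"` assay.
#' @param reference named numeric vector of reference Ct values (names =
#'   concentration labels), a [CtVector-class], or a data.frame with
#'   columns `set_id`, `experiment_id`, `concentration`, `ct` for
#'   per-experiment references.
#' @param thresholds numeric grid of log thresholds (default:
#'   [defaultThresholdGrid()] at step 0.01).
#' @param scope `"all"` (default), `"set"` or `"experiment"`.
#' @param set,experiment identifiers selecting the scope instance (needed
#'   for `"set"` / `"experiment"`).
#' @param norm `"rms"`, `"euclidean"` or `"sum"`.
#' @param naAction `"exclude"` (pairwise, default) or `"strict"`.
#' @return A [ThresholdSearchResult-class].
#' @examples
#' g <- logTransform(baselineNormalize(generateExperimentGrid(
#'   experimentDesign(setGains = c(1, 1), cqJitterSd = 0, gainJitterSd = 0),
#'   camera = cameraModel(noiseSd = 0), seed = 1)))
#' objectiveCurve(g, referenceCt(experimentDesign()))
#' @export
objectiveCurve <- function(x, reference, thresholds = NULL,
                           scope = c("all", "set", "experiment"),
                           set = NULL, experiment = NULL,
                           norm = c("rms", "euclidean", "sum"),
                           naAction = c("exclude", "strict")) {
  scope <- match.arg(scope)
  norm <- match.arg(norm)
  naAction <- match.arg(naAction)
  if (is.null(thresholds)) thresholds <- defaultThresholdGrid(x)
  stopifnot(length(thresholds) >= 1L)
  thresholds <- sort(thresholds)

  cd <- colData(x)
  keep <- rep(TRUE, ncol(x))
  if (scope %in% c("set", "experiment")) {
    if (is.null(set)) stop("scope '", scope, "' needs a set id")
    keep <- keep & cd$set_id == set
  }
  if (scope == "experiment") {
    if (is.null(experiment)) stop("scope 'experiment' needs an experiment id")
    keep <- keep & cd$experiment_id == experiment
  }
  if (!any(keep)) stop("no curves in scope")
  lg <- .logAssay(x)[, keep, drop = FALSE]
  cdk <- cd[keep, , drop = FALSE]

  ## reference Ct per in-scope curve
  ref <- vapply(seq_len(ncol(lg)), function(j) {
    r <- .refFor(reference, cdk$set_id[j], cdk$experiment_id[j])
    lab <- as.character(cdk$concentration[j])
    if (!(lab %in% names(r)))
      stop("no reference Ct for concentration ", lab)
    unname(r[lab])
  }, numeric(1))

  cycles <- seq_len(nrow(lg))
  ## Ct matrix: thresholds x curves
  cts <- vapply(seq_len(ncol(lg)), function(j) {
    v <- lg[, j]
    vapply(thresholds, function(t) .ctOne(v, cycles, t), numeric(1))
  }, numeric(length(thresholds)))
  cts <- matrix(cts, nrow = length(thresholds))

  diffs <- cts - rep(ref, each = length(thresholds))
  expKey <- paste(cdk$set_id, cdk$experiment_id, sep = ".")
  obj <- vapply(seq_along(thresholds), function(k) {
    d <- diffs[k, ]
    ok <- !is.na(d)
    nExcl <- sum(!ok)
    if (!any(ok) || (naAction == "strict" && nExcl > 0L))
      return(c(NA_real_, nExcl))
    val <- switch(norm,
      rms = sqrt(sum(d[ok]^2) / sum(ok)),
      euclidean = sqrt(sum(d[ok]^2)),
      sum = sum(vapply(split(d[ok], expKey[ok]),
                       function(z) sqrt(sum(z^2)), numeric(1))))
    c(val, nExcl)
  }, numeric(2))

  objective <- data.frame(t = thresholds, distance = obj[1, ],
                          n_excluded = as.integer(obj[2, ]))
  if (all(is.na(objective$distance)))
    stop("threshold search failed: objective undefined on the whole grid")
  iOpt <- which.min(objective$distance)  # first minimum = smallest t
  scopeLabel <- switch(scope,
    all = "all",
    set = paste0("set ", set),
    experiment = paste0("set ", set, ", experiment ", experiment))
  new("ThresholdSearchResult", objective = objective,
      tOpt = objective$t[iOpt], dOpt = objective$distance[iOpt],
      scope = scopeLabel, norm = norm)
}

#' Per-experiment optimal thresholds and distances
#'
#' One grid search per (set, experiment): the per-experiment analogue of a
#' results table listing each experiment's optimal threshold and residual
#' Ct distance.
#'
#' @inheritParams objectiveCurve
#' @return A data.frame with `set_id`, `experiment_id`, `t_opt`, `d_opt`.
#' @export
perExperimentTable <- function(x, reference, thresholds = NULL,
                               norm = c("rms", "euclidean", "sum"),
                               naAction = c("exclude", "strict")) {
  norm <- match.arg(norm); naAction <- match.arg(naAction)
  if (is.null(thresholds)) thresholds <- defaultThresholdGrid(x)
  cd <- colData(x)
  cells <- unique(data.frame(set_id = cd$set_id,
                             experiment_id = cd$experiment_id))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    r <- objectiveCurve(x, reference, thresholds, scope = "experiment",
                        set = cells$set_id[i],
                        experiment = cells$experiment_id[i],
                        norm = norm, naAction = naAction)
    data.frame(set_id = cells$set_id[i],
               experiment_id = cells$experiment_id[i],
               t_opt = r@tOpt, d_opt = r@dOpt)
  })
  do.call(rbind, res)
}

#' Per-set (and overall) optimal thresholds and distances
#'
#' One grid search per set over all of its experiments, plus an optional
#' final row minimizing the pooled objective over both sets together.
#'
#' @inheritParams objectiveCurve
#' @param includeOverall append the all-sets row (default TRUE).
#' @return A data.frame with `set_id` (the overall row is labelled
#'   `"all"`), `t_opt`, `d_opt`.
#' @export
perSetTable <- function(x, reference, thresholds = NULL,
                        norm = c("rms", "euclidean", "sum"),
                        naAction = c("exclude", "strict"),
                        includeOverall = TRUE) {
  norm <- match.arg(norm); naAction <- match.arg(naAction)
  if (is.null(thresholds)) thresholds <- defaultThresholdGrid(x)
  sets <- unique(colData(x)$set_id)
  rows <- lapply(sets, function(s) {
    r <- objectiveCurve(x, reference, thresholds, scope = "set", set = s,
                        norm = norm, naAction = naAction)
    data.frame(set_id = s, t_opt = r@tOpt, d_opt = r@dOpt)
  })
  out <- do.call(rbind, rows)
  if (includeOverall) {
    r <- objectiveCurve(x, reference, thresholds, scope = "all",
                        norm = norm, naAction = naAction)
    out <- rbind(out, data.frame(set_id = "all", t_opt = r@tOpt,
                                 d_opt = r@dOpt))
  }
  out
}

#' Plot an objective curve
#'
#' Distance versus log threshold, with the minimizer marked.
#'
#' @param result a [ThresholdSearchResult-class].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `result`.
#' @export
plotObjective <- function(result, ...) {
  obj <- result@objective
  graphics::plot(obj$t, obj$distance, type = "l",
                 xlab = "log threshold", ylab = "distance (cycles)",
                 main = sprintf("Ct distance vs threshold (%s)",
                                result@scope), ...)
  graphics::abline(v = result@tOpt, lty = 2, col = "grey40")
  graphics::points(result@tOpt, result@dOpt, pch = 19, col = "red3")
  invisible(result)
}
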