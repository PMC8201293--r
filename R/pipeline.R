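## End-to-end orchestration: ingest or simulate -> quantify -> normalize ->
## log -> threshold optimization -> inter-set calibration -> re-log ->
## re-optimization -> summary.

#' Run the full camera-qPCR analysis pipeline
#'
#' Stages: (1) obtain raw curves, either by simulating from a design
#' (`input = "simulate"`), by reading a long-format curve CSV
#' (`"curves"`), or by quantifying per-run image-stack directories
#' (`"images"`); (2) baseline-normalize and log-transform; (3) grid-search
#' the global log threshold against the reference Ct vector
#' (pre-calibration); (4) compute the inter-set endpoint calibration factor
#' on the normalized curves, rescale the dim set, re-log, and re-optimize
#' (post-calibration); (5) summarize distances and the concentration-error
#' bounds they imply.
#'
#' @param input `"simulate"`, `"curves"` or `"images"`.
#' @param design,model,camera simulation parameters
#'   ([ExperimentDesign-class], [AmplificationModel-class],
#'   [CameraModel-class]); used in `"simulate"` mode.
#' @param curvesFile long-format curve CSV (see [readCurves()]); `"curves"`
#'   mode.
#' @param imageDirs named list of per-run image-stack directories
#'   (`"images"` mode); names are ignored, run metadata comes from
#'   `imageMeta`.
#' @param imageMeta data.frame with `set_id`, `experiment_id`,
#'   `concentration`, one row per entry of `imageDirs`.
#' @param roi [RoiSpec-class] for image quantification.
#' @param channel grayscale conversion for image mode (`"luma"` or
#'   `"green"`).
#' @param reference reference Ct values (named vector or data.frame; see
#'   [objectiveCurve()]). In `"simulate"` mode defaults to the design's
#'   jitter-free ground truth ([referenceCt()]).
#' @param nBaseline baseline cycles (default 10).
#' @param logBase log base (default natural).
#' @param thresholds threshold grid; default spans the defined
#'   pre-calibration log values at step 0.01 (the same grid, extended to
#'   cover the post-calibration span, is reused after calibration).
#' @param norm distance aggregation (`"rms"`, `"euclidean"`, `"sum"`).
#' @param naAction undetermined-Ct handling (`"exclude"` or `"strict"`).
#' @param calWindow endpoint calibration window (1-based inclusive).
#' @param calRounding `"full"` or `"1dp"`.
#' @param referenceSet reference set id for calibration; default: brighter
#'   set.
#' @param efficiency amplification efficiency for the error bounds.
#' @param seed integer seed for the simulate mode.
#' @param outDir if non-NULL, artifacts (curves, Ct tables, objectives,
#'   calibration report, summary JSON) are written here via
#'   [writeSummary()].
#' @return A list of class `"qpcrPipelineResult"`: `grid` (post-calibration
#'   [PCRGrid-class]), `reference`, `pre` and `post`
#'   ([ThresholdSearchResult-class]), `calibration`
#'   ([CalibrationFactor-class]), `summary` (named list), `config`.
#' @examples
#' res <- runPipeline(seed = 7)
#' res$summary$post_calibration$d_opt <= res$summary$pre_calibration$d_opt
#' @export
runPipeline <- function(input = c("simulate", "curves", "images"),
                        design = experimentDesign(),
                        model = amplificationModel(),
                        camera = cameraModel(),
                        curvesFile = NULL, imageDirs = NULL,
                        imageMeta = NULL, roi = NULL,
                        channel = c("luma", "green"),
                        reference = NULL, nBaseline = 10L,
                        logBase = exp(1), thresholds = NULL,
                        norm = c("rms", "euclidean", "sum"),
                        naAction = c("exclude", "strict"),
                        calWindow = c(35L, 40L),
                        calRounding = c("full", "1dp"),
                        referenceSet = NULL, efficiency = 2,
                        seed = camera@seed, outDir = NULL) {
  input <- match.arg(input)
  norm <- match.arg(norm)
  naAction <- match.arg(naAction)
  calRounding <- match.arg(calRounding)
  channel <- match.arg(channel)

  grid <- switch(input,
    simulate = generateExperimentGrid(design, model, camera, seed = seed),
    curves = {
      if (is.null(curvesFile)) stop("ingest stage: curvesFile is required")
      readCurves(curvesFile)
    },
    images = {
      if (is.null(imageDirs) || is.null(imageMeta) || is.null(roi))
        stop("ingest stage: imageDirs, imageMeta and roi are required")
      if (length(imageDirs) != nrow(imageMeta))
        stop("ingest stage: one metadata row per image directory required")
      curves <- lapply(imageDirs, function(d)
        intensities(quantifyStack(loadImageStack(d), roi, channel)))
      PCRGrid(do.call(cbind, curves), imageMeta)
    })

  if (is.null(reference)) {
    if (input != "simulate")
      stop("optimization stage: a reference is required outside simulate mode")
    reference <- referenceCt(design, model)
  }

  grid <- baselineNormalize(grid, nBaseline = nBaseline)
  grid <- logTransform(grid, base = logBase)
  if (is.null(thresholds)) thresholds <- defaultThresholdGrid(grid)
  pre <- objectiveCurve(grid, reference, thresholds, scope = "all",
                        norm = norm, naAction = naAction)

  fac <- setCalibrationFactor(grid, referenceSet = referenceSet,
                              targetSet = NULL, window = calWindow,
                              rounding = calRounding)
  grid <- applyCalibration(grid, fac)
  grid <- logTransform(grid, base = logBase)
  ## calibration raises the dim set's plateau: extend the grid to cover it
  postRange <- range(assay(grid, "log"), na.rm = TRUE)
  step <- if (length(thresholds) > 1L) min(diff(sort(thresholds))) else 0.01
  postThresholds <- sort(unique(c(
    thresholds,
    thresholdGrid(min(thresholds[1], postRange[1]),
                  max(thresholds[length(thresholds)], postRange[2]) + step,
                  step))))
  post <- objectiveCurve(grid, reference, postThresholds, scope = "all",
                         norm = norm, naAction = naAction)

  config <- list(input = input, nBaseline = as.integer(nBaseline),
                 logBase = logBase, norm = norm, naAction = naAction,
                 calWindow = as.integer(calWindow),
                 calRounding = calRounding, efficiency = efficiency,
                 seed = as.integer(seed),
                 gridStep = step,
                 gridRange = range(thresholds))
  summary <- list(
    seed = as.integer(seed),
    config_hash = .configHash(config),
    n_runs = ncol(grid),
    pre_calibration = .scopeSummary(pre, efficiency),
    calibration = as.list(calibrationReport(fac)),
    post_calibration = .scopeSummary(post, efficiency))

  res <- structure(list(grid = grid, reference = reference, pre = pre,
                        post = post, calibration = fac, summary = summary,
                        config = config),
                   class = "qpcrPipelineResult")
  if (!is.null(outDir)) writeSummary(res, outDir)
  res
}

.scopeSummary <- function(result, efficiency) {
  list(scope = result@scope, norm = result@norm,
       t_opt = tOpt(result), d_opt = dOpt(result),
       error_bound_fraction = foldErrorFromCtError(dOpt(result), efficiency),
       error_bound_percent = percentErrorBound(dOpt(result), efficiency))
}

## stable hash of the configuration list (no digest dependency: serialize
## to a canonical text form and run md5 over a temp file)
.configHash <- function(config) {
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v, digits = 17),
                                                collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' @export
print.qpcrPipelineResult <- function(x, ...) {
  s <- x$summary
  cat("camera-qPCR pipeline result\n")
  cat(sprintf("  runs: %d, seed: %d, config: %s\n", s$n_runs, s$seed,
              substr(s$config_hash, 1, 8)))
  cat(sprintf("  pre-calibration:  t_opt = %.4g, d_opt = %.4g cycles (%.0f%% bound)\n",
              s$pre_calibration$t_opt, s$pre_calibration$d_opt,
              s$pre_calibration$error_bound_percent))
  cat(sprintf("  calibration:      set %s x %.4g (endpoint means %.4g / %.4g)\n",
              s$calibration$target_set, s$calibration$ratio,
              s$calibration$mean_reference, s$calibration$mean_target))
  cat(sprintf("  post-calibration: t_opt = %.4g, d_opt = %.4g cycles (%.0f%% bound)\n",
              s$post_calibration$t_opt, s$post_calibration$d_opt,
              s$post_calibration$error_bound_percent))
  invisible(x)
}

#' Write all pipeline artifacts
#'
#' Writes `curves.csv` (raw curves), `ct_pre.csv` / `ct_post.csv` (Ct
#' tables at the respective optimal thresholds), `objective_pre.csv` /
#' `objective_post.csv`, `calibration.csv` and `summary.json` (pretty,
#' deterministic: no timestamps) into `dir`.
#'
#' @param result a `"qpcrPipelineResult"` from [runPipeline()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSummary <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    curves = writeCurves(result$grid, file.path(dir, "curves.csv")),
    objective_pre = writeObjective(result$pre,
                                   file.path(dir, "objective_pre.csv")),
    objective_post = writeObjective(result$post,
                                    file.path(dir, "objective_post.csv")),
    ct_post = writeCtTable(ctTable(result$grid, tOpt(result$post)),
                           file.path(dir, "ct_post.csv")),
    calibration = .writeTable(calibrationReport(result$calibration),
                              file.path(dir, "calibration.csv"),
                              c("mean_reference", "mean_target", "ratio")),
    summary = {
      p <- file.path(dir, "summary.json")
      jsonlite::write_json(result$summary, p, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      p
    })
  invisible(paths)
}
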