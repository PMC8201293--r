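## Synthetic amplification curves and image stacks with known ground truth.
## The generator defines the benchmark conditions for every recovery test:
## two instrument sets with a 1.8x endpoint gain gap, a 10-fold dilution
## series at three concentrations, four replicates per set, 40 cycles.

#' Logistic center that pins the ground-truth Cq
#'
#' The simulated curve is `b + g P sigma(k (c - c0))`. Its baseline-
#' normalized form is `g P (sigma(c) - m)` with `m` the mean of the logistic
#' over the first `nBaseline` cycles, so the cycle at which it crosses the
#' reference level `ctFraction * g P` does not depend on the gain. This
#' function solves for the center `c0` such that the crossing happens
#' exactly at `trueCq`, making the recorded ground truth self-consistent
#' with threshold-based Ct calling.
#'
#' @param trueCq target threshold cycle (cycles).
#' @param slope logistic steepness per cycle.
#' @param ctFraction fraction of the normalized plateau defining the Cq
#'   level (default 0.1).
#' @param nBaseline baseline window length used by the normalization
#'   (default 10).
#' @return The logistic center `c0` (cycles).
#' @examples
#' sigmoidCenter(25, 0.6)
#' @export
sigmoidCenter <- function(trueCq, slope, ctFraction = 0.1, nBaseline = 10L) {
  stopifnot(slope > 0, ctFraction > 0, ctFraction < 1)
  h <- function(c0) {
    m <- mean(plogis(slope * (seq_len(nBaseline) - c0)))
    plogis(slope * (trueCq - c0)) - m - ctFraction
  }
  ## with no baseline correction the root would sit at
  ## trueCq + log((1 - f)/f)/slope; bracket generously around it
  upper <- trueCq + log((1 - ctFraction) / ctFraction) / slope + 20
  uniroot(h, lower = trueCq, upper = upper, tol = 1e-12)$root
}

#' Reference log level of a simulated curve's ground-truth Cq
#'
#' The noiseless baseline-normalized curve crosses
#' `ctFraction * gain * plateauGain` exactly at the model's `trueCq`; this
#' helper returns that level (or its log), the threshold at which
#' [computeCt()] recovers the ground truth.
#'
#' @param model an [AmplificationModel-class].
#' @param gain total gain applied to the curve.
#' @param log if `TRUE` (default) return the level in natural-log units.
#' @return The reference level (log or linear grayscale units).
#' @examples
#' ctReferenceLevel(amplificationModel())
#' @export
ctReferenceLevel <- function(model, gain = 1, log = TRUE) {
  level <- model@ctFraction * gain * model@plateauGain
  if (log) base::log(level) else level
}

#' Simulate one amplification curve
#'
#' Generates `baseline + gain * plateauGain * logistic(c)` plus optional
#' Gaussian readout noise, with the logistic center placed so the noiseless
#' normalized curve crosses `ctFraction * gain * plateauGain` exactly at the
#' model's `trueCq` (see [sigmoidCenter()]). Deterministic given `seed`.
#'
#' @param model an [AmplificationModel-class].
#' @param gain signal multiplier (camera x set gain), default 1.
#' @param nCycles number of cycles, default 40.
#' @param noiseSd sd of additive zero-mean Gaussian noise per cycle
#'   (grayscale units), default 0.
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @param setId,experimentId,concentration optional metadata stored on the
#'   curve.
#' @return An [AmplificationCurve-class] in state `"raw"`.
#' @examples
#' simulateCurve(amplificationModel(trueCq = 25), noiseSd = 0.3, seed = 1)
#' @export
simulateCurve <- function(model, gain = 1, nCycles = 40L, noiseSd = 0,
                          seed = NULL, setId = NA_character_,
                          experimentId = NA_integer_,
                          concentration = NA_real_) {
  validObject(model)
  stopifnot(gain > 0, nCycles >= 1L, noiseSd >= 0)
  c0 <- sigmoidCenter(model@trueCq, model@slope, model@ctFraction)
  cycles <- seq_len(nCycles)
  vals <- model@baselineIntensity +
    gain * model@plateauGain * plogis(model@slope * (cycles - c0))
  if (noiseSd > 0) {
    noise <- if (is.null(seed)) rnorm(nCycles, 0, noiseSd) else
      withr::with_seed(seed, rnorm(nCycles, 0, noiseSd))
    vals <- vals + noise
  }
  amplificationCurve(vals, state = "raw", setId = setId,
                     experimentId = experimentId,
                     concentration = concentration)
}

#' Cq shift implied by a dilution
#'
#' Under amplification efficiency `E` (fold-change per cycle), diluting the
#' template by `dilutionFactor` delays the threshold crossing by
#' `log(dilutionFactor) / log(E)` cycles: at perfect doubling, one cycle per
#' two-fold dilution.
#'
#' @param baseCq threshold cycle of the undiluted sample (cycles).
#' @param dilutionFactor fold dilution, >= 1.
#' @param efficiency amplification fold-change per cycle, > 1 (default 2).
#' @return The diluted sample's Cq in cycles.
#' @examples
#' shiftForDilution(20, 10)  # 23.32 at perfect doubling
#' @export
shiftForDilution <- function(baseCq, dilutionFactor, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  if (any(dilutionFactor < 1)) stop("dilutionFactor must be >= 1")
  baseCq + log(dilutionFactor) / log(efficiency)
}

#' Reference Ct vector implied by a design and base model
#'
#' The jitter-free ground-truth Cq per concentration: what an ideal
#' reference instrument would report for the dilution series. Used as the
#' reference vector `C` in synthetic threshold-calibration studies.
#'
#' @param design an [ExperimentDesign-class].
#' @param model the base [AmplificationModel-class]; its `trueCq` is the Cq
#'   of the highest concentration.
#' @return Named numeric vector of Cq values, names = concentration labels.
#' @examples
#' referenceCt(experimentDesign(), amplificationModel())
#' @export
referenceCt <- function(design, model = amplificationModel()) {
  conc <- design@concentrations
  cq <- shiftForDilution(model@trueCq, conc[1] / conc, model@efficiency)
  names(cq) <- as.character(conc)
  cq
}

#' Generate a full multi-set experiment grid
#'
#' Simulates one curve per (set, experiment, concentration) cell of the
#' design. Each curve's true Cq is the dilution-shifted base Cq plus
#' Gaussian replicate jitter (`design@cqJitterSd` cycles), and its gain is
#' `camera@gain * setGain * (1 + jitter)` with relative sd
#' `design@gainJitterSd`. Per-cycle readout noise uses `camera@noiseSd`.
#' The realized Cq and gain of every curve are recorded in `colData` as
#' ground truth.
#'
#' @param design an [ExperimentDesign-class].
#' @param model base [AmplificationModel-class] (Cq of the top
#'   concentration).
#' @param camera a [CameraModel-class]; its `noiseSd` acts on the ROI-mean
#'   scale here.
#' @param seed integer seed; defaults to the camera seed.
#' @return A [PCRGrid-class] with a `"raw"` assay and ground-truth columns
#'   `true_cq` and `gain` in `colData`.
#' @examples
#' g <- generateExperimentGrid(experimentDesign(), seed = 42)
#' dim(g)  # 40 cycles x 24 runs
#' @export
generateExperimentGrid <- function(design, model = amplificationModel(),
                                   camera = cameraModel(),
                                   seed = camera@seed) {
  validObject(design); validObject(model); validObject(camera)
  sets <- LETTERS[seq_len(design@nSets)]
  cells <- expand.grid(concentration = design@concentrations,
                       experiment_id = seq_len(design@nExperimentsPerSet),
                       set_id = sets, stringsAsFactors = FALSE)
  cells <- cells[, c("set_id", "experiment_id", "concentration")]
  baseCq <- shiftForDilution(model@trueCq,
                             design@concentrations[1] / cells$concentration,
                             model@efficiency)
  withr::with_seed(as.integer(seed), {
    trueCq <- baseCq + rnorm(nrow(cells), 0, design@cqJitterSd)
    gain <- camera@gain *
      design@setGains[match(cells$set_id, sets)] *
      (1 + rnorm(nrow(cells), 0, design@gainJitterSd))
    raw <- vapply(seq_len(nrow(cells)), function(i) {
      m <- amplificationModel(model@baselineIntensity, model@plateauGain,
                              trueCq[i], model@slope, model@efficiency,
                              model@ctFraction)
      noise <- if (camera@noiseSd > 0)
        rnorm(design@nCycles, 0, camera@noiseSd) else 0
      intensities(simulateCurve(m, gain = gain[i],
                                nCycles = design@nCycles,
                                noiseSd = 0)) + noise
    }, numeric(design@nCycles))
  })
  cd <- DataFrame(cells, true_cq = trueCq, gain = gain)
  PCRGrid(raw, cd, metadata = list(
    seed = as.integer(seed),
    base_model = model, design = design, camera = camera))
}

#' Render an amplification curve as a cycle-indexed image stack
#'
#' Draws one frame per cycle: pixels inside the ROI at the curve's intensity
#' for that cycle, the rest of the frame at the layout's background level,
#' plus optional per-pixel Gaussian noise from the camera model. Values are
#' clipped to the representable range `[0, 2^bitDepth - 1]` (with a warning
#' when clipping occurs). Reading the stack back with [quantifyStack()]
#' recovers the curve exactly when the noise is zero.
#'
#' @param curve an [AmplificationCurve-class] in state `"raw"`.
#' @param layout a [ChipLayout-class].
#' @param camera a [CameraModel-class] (per-pixel `noiseSd`, `bitDepth`,
#'   `seed`).
#' @param channels `"gray"` (default) or `"rgb"` (signal in the green
#'   channel, red and blue dark).
#' @return An [ImageStack-class].
#' @examples
#' st <- renderImageStack(simulateCurve(amplificationModel(), seed = 1),
#'                        chipLayout(), cameraModel(noiseSd = 0))
#' @export
renderImageStack <- function(curve, layout, camera,
                             channels = c("gray", "rgb")) {
  channels <- match.arg(channels)
  if (curveState(curve) != "raw")
    stop("renderImageStack expects a raw curve")
  validObject(layout); validObject(camera)
  h <- layout@frameHeight; w <- layout@frameWidth
  mask <- roiMask(layout@roi, width = w, height = h)
  vmax <- 2^camera@bitDepth - 1
  clipped <- FALSE
  vals <- intensities(curve)
  frames <- withr::with_seed(camera@seed, lapply(vals, function(v) {
    f <- matrix(layout@backgroundLevel, nrow = h, ncol = w)
    f[mask] <- v
    if (camera@noiseSd > 0)
      f <- f + matrix(rnorm(h * w, 0, camera@noiseSd), h, w)
    if (any(f < 0 | f > vmax)) clipped <<- TRUE
    f <- pmin(pmax(f, 0), vmax)
    if (channels == "rgb") {
      a <- array(0, dim = c(h, w, 3L)); a[, , 2L] <- f; a
    } else f
  }))
  if (clipped)
    warning("pixel intensities outside [0, ", vmax, "] were clipped")
  new("ImageStack", frames = frames, cycles = cycleIndex(curve),
      bitDepth = camera@bitDepth, source = "simulated")
}

#' Write an image stack as zero-padded per-cycle files
#'
#' Files are named `cycle_01.png` ... `cycle_NN.png` (or `.tif`) in one
#' directory per run. PNG output is 8-bit; TIFF supports 8 or 16 bits.
#' Pixel values are quantized to the stack's bit depth at write time.
#'
#' @param stack an [ImageStack-class].
#' @param dir output directory (created if absent).
#' @param format `"png"` (default) or `"tiff"`.
#' @return Invisibly, the written file paths.
#' @examples
#' st <- renderImageStack(simulateCurve(amplificationModel(), seed = 1),
#'                        chipLayout(), cameraModel(noiseSd = 0))
#' d <- tempfile(); writeImageStack(st, d)
#' @export
writeImageStack <- function(stack, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vmax <- 2^stack@bitDepth - 1
  ext <- if (format == "png") "png" else "tif"
  width <- max(2L, nchar(as.character(max(stack@cycles))))
  paths <- vapply(seq_along(stack@frames), function(i) {
    path <- file.path(dir, sprintf("cycle_%0*d.%s", width,
                                   stack@cycles[i], ext))
    scaled <- stack@frames[[i]] / vmax
    if (format == "png") png::writePNG(scaled, path)
    else tiff::writeTIFF(scaled, path,
                         bits.per.sample = if (stack@bitDepth > 8) 16L else 8L)
    path
  }, character(1))
  invisible(paths)
}
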