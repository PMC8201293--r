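# Shared fixtures and independent oracles, built in code at test time.

# Continuous-curve bisection oracle: the cycle at which the closed-form
# noiseless normalized log curve reaches threshold `t`. Independent of the
# package's per-cycle interpolation Ct caller.
oracleCq <- function(model, gain = 1, threshold = NULL, nBaseline = 10L) {
  if (is.null(threshold)) threshold <- ctReferenceLevel(model, gain)
  c0 <- sigmoidCenter(model@trueCq, model@slope, model@ctFraction, nBaseline)
  m <- mean(plogis(model@slope * (seq_len(nBaseline) - c0)))
  f <- function(c) {
    log(gain * model@plateauGain *
          (plogis(model@slope * (c - c0)) - m)) - threshold
  }
  # lower bracket: the cycle where the normalized curve sits at half the
  # threshold level (f is increasing where defined, and log(1/2) < 0 there)
  sigLo <- m + 0.5 * exp(threshold) / (gain * model@plateauGain)
  lo <- c0 + qlogis(sigLo) / model@slope
  uniroot(f, lower = lo, upper = c0 + 30, tol = 1e-10)$root
}

# Brute-force Ct scan written independently of the package internals:
# first cycle whose defined log value reaches t, interpolated when the
# previous cycle is defined and below t.
bruteCt <- function(v, t) {
  for (i in seq_along(v)) {
    if (!is.na(v[i]) && v[i] >= t) {
      if (i > 1 && !is.na(v[i - 1]) && v[i - 1] < t)
        return((i - 1) + (t - v[i - 1]) / (v[i] - v[i - 1]))
      return(i)
    }
  }
  NA_real_
}

# Brute-force pooled-RMS objective over a threshold grid, plain loops.
bruteObjective <- function(logMat, refs, thresholds) {
  vapply(thresholds, function(t) {
    diffs <- c()
    for (j in seq_len(ncol(logMat))) {
      ct <- bruteCt(logMat[, j], t)
      if (!is.na(ct)) diffs <- c(diffs, ct - refs[j])
    }
    if (!length(diffs)) return(NA_real_)
    sqrt(sum(diffs^2) / length(diffs))
  }, numeric(1))
}

# A small noiseless, jitter-free two-set grid used across tests.
cleanGrid <- function(setGains = c(1, 1 / 1.8), nExperiments = 2L,
                      seed = 1L) {
  generateExperimentGrid(
    experimentDesign(nExperimentsPerSet = nExperiments,
                     setGains = setGains,
                     cqJitterSd = 0, gainJitterSd = 0),
    camera = cameraModel(noiseSd = 0), seed = seed)
}
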