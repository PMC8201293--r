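## From Ct discrepancies to concentration errors: under amplification
## efficiency E, a Ct difference of dCt corresponds to an E^dCt-fold
## difference in initial template concentration (two-fold per cycle at
## perfect doubling).

#' Relative concentration error implied by a Ct discrepancy
#'
#' A threshold-cycle error of `deltaCt` cycles corresponds to a relative
#' error of `efficiency^deltaCt - 1` in the estimated initial
#' concentration: e.g. 0.8 cycles at perfect doubling gives
#' 2^0.8 - 1 = 0.74, i.e. the concentration is predicted within 74%.
#'
#' @param deltaCt Ct discrepancy magnitude in cycles, >= 0.
#' @param efficiency amplification fold-change per cycle, > 1 (default 2,
#'   perfect doubling).
#' @return Relative error as a fraction (dimensionless, >= 0).
#' @seealso [percentErrorBound()] for the integer-percent form.
#' @examples
#' foldErrorFromCtError(0.8)   # 0.741
#' foldErrorFromCtError(0.4)   # 0.320
#' @export
foldErrorFromCtError <- function(deltaCt, efficiency = 2) {
  if (any(deltaCt < 0))
    stop("deltaCt must be >= 0 (pass the magnitude of the discrepancy)")
  if (efficiency <= 1) stop("efficiency must be > 1")
  efficiency^deltaCt - 1
}

#' Concentration error bound as an integer percent
#'
#' @inheritParams foldErrorFromCtError
#' @return `foldErrorFromCtError()` expressed in percent and rounded to the
#'   nearest integer.
#' @examples
#' percentErrorBound(0.8)  # 74
#' percentErrorBound(0.4)  # 32
#' @export
percentErrorBound <- function(deltaCt, efficiency = 2) {
  round(100 * foldErrorFromCtError(deltaCt, efficiency))
}

#' Relative initial concentration of two samples from their Ct values
#'
#' The fold ratio of sample a's initial concentration to sample b's:
#' `efficiency^(ctB - ctA)`. One cycle of Ct difference is a two-fold
#' concentration difference at perfect doubling; the earlier Ct marks the
#' more concentrated sample. Undetermined Ct (`NA`) propagates.
#'
#' @param ctA,ctB threshold cycles of the two samples.
#' @param efficiency amplification fold-change per cycle, > 1 (default 2).
#' @return Fold ratio (a relative to b); `NA` if either Ct is undetermined.
#' @examples
#' relativeConcentration(20, 21)       # 2: one cycle earlier = 2x template
#' relativeConcentration(20, 23.3219)  # ~10
#' @export
relativeConcentration <- function(ctA, ctB, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  ifelse(is.na(ctA) | is.na(ctB), NA_real_, efficiency^(ctB - ctA))
}
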