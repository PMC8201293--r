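## Plain-text interchange. Numeric columns are written with %.17g so that
## reading a written file reproduces the doubles bit-for-bit; undetermined
## Ct values are serialized as the sentinel string "undetermined", never as
## a number.

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

.writeTable <- function(df, path, numCols) {
  for (nm in intersect(numCols, names(df))) df[[nm]] <- .fmtNum(df[[nm]])
  write.csv(df, path, row.names = FALSE, na = "undetermined")
  invisible(path)
}

#' Write and read long-format curve tables
#'
#' Long CSV with columns `set_id`, `experiment_id`, `concentration`,
#' `cycle`, `intensity` holding the raw intensities of every run.
#' `readCurves()` rebuilds the [PCRGrid-class]; the written and re-read
#' intensities are bit-identical.
#'
#' @param x a [PCRGrid-class].
#' @param path CSV file path.
#' @return `writeCurves()`: the path, invisibly. `readCurves()`: a
#'   [PCRGrid-class] with a `"raw"` assay.
#' @examples
#' g <- generateExperimentGrid(experimentDesign(), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeCurves(g, f)
#' readCurves(f)
#' @export
writeCurves <- function(x, path) {
  raw <- assay(x, "raw")
  cd <- colData(x)
  df <- data.frame(
    set_id = rep(cd$set_id, each = nrow(raw)),
    experiment_id = rep(cd$experiment_id, each = nrow(raw)),
    concentration = rep(cd$concentration, each = nrow(raw)),
    cycle = rep(seq_len(nrow(raw)), ncol(raw)),
    intensity = as.vector(raw))
  .writeTable(df, path, c("concentration", "intensity"))
}

#' @rdname writeCurves
#' @export
readCurves <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "experiment_id", "concentration", "cycle", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("curve CSV lacks column(s): ", paste(missing, collapse = ", "))
  key <- paste(df$set_id, df$experiment_id, df$concentration, sep = "\r")
  runs <- split(df, factor(key, levels = unique(key)))
  nCyc <- unique(vapply(runs, nrow, integer(1)))
  if (length(nCyc) != 1L)
    stop("runs have differing cycle counts")
  raw <- vapply(runs, function(d) d$intensity[order(d$cycle)],
                numeric(nCyc))
  dimnames(raw) <- NULL
  cd <- do.call(rbind, lapply(runs, function(d)
    data.frame(set_id = as.character(d$set_id[1]),
               experiment_id = as.integer(d$experiment_id[1]),
               concentration = as.numeric(d$concentration[1]))))
  rownames(cd) <- NULL
  PCRGrid(raw, cd)
}

#' Write the ground-truth table of a simulated grid
#'
#' CSV with columns `set_id`, `experiment_id`, `concentration`, `true_cq`,
#' `gain`.
#'
#' @param x a simulated [PCRGrid-class].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writeGroundTruth <- function(x, path) {
  .writeTable(as.data.frame(groundTruth(x)), path,
              c("concentration", "true_cq", "gain"))
}

#' Read reference Ct values from CSV
#'
#' Accepts either a two-column table (`concentration`, `ct`) giving one
#' reference vector for all experiments, or a four-column table (`set_id`,
#' `experiment_id`, `concentration`, `ct`) for per-experiment references.
#'
#' @param path CSV file path.
#' @return A named numeric vector (two-column form) or the data.frame
#'   (four-column form), both directly usable as the `reference` argument
#'   of [objectiveCurve()].
#' @export
readReferenceCt <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration", "ct") %in% names(df)))
    stop("reference CSV needs columns concentration, ct")
  df$ct <- suppressWarnings(
    ifelse(df$ct == "undetermined", NA_real_, as.numeric(df$ct)))
  if (all(c("set_id", "experiment_id") %in% names(df))) return(df)
  stats::setNames(df$ct, as.character(df$concentration))
}

#' Write a Ct table
#'
#' @param tab data.frame from [ctTable()].
#' @param path CSV file path.
#' @return The path, invisibly. Undetermined Ct values are written as the
#'   string `"undetermined"`.
#' @export
writeCtTable <- function(tab, path) {
  .writeTable(tab, path, c("concentration", "ct"))
}

#' Write an objective curve
#'
#' CSV with columns `t`, `distance`, `n_excluded` plus the scope and norm
#' as a comment-free leading columns.
#'
#' @param result a [ThresholdSearchResult-class].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
writeObjective <- function(result, path) {
  df <- cbind(scope = result@scope, norm = result@norm,
              objectiveTable(result))
  .writeTable(df, path, c("t", "distance"))
}
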