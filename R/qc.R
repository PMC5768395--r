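# Reliability filters applied before any statistics: CpG units quantified in
# fewer than 30% of samples are unreliable, as are samples missing more than
# 30% of their data points. Comparisons are strict ("less than" / "more
# than"), so exact-boundary units and samples are retained.

#' Discard unreliable CpG units
#'
#' Removes CpG units with non-missing data in strictly fewer than
#' `min_fraction` of samples. Unit order is preserved.
#'
#' @param x a [MethylationExperiment-class].
#' @param min_fraction minimum fraction of samples with data (default 0.30).
#' @return list with `experiment` (filtered) and `discarded` (unit ids).
#' @export
filterUnits <- function(x, min_fraction = 0.30) {
  stopifnot(is(x, "MethylationExperiment"))
  if (nrow(x) == 0) .msErr("data", "no CpG units in the experiment")
  observed <- rowMeans(!is.na(methValues(x)))
  keep <- observed >= min_fraction
  if (!any(keep))
    .msErr("empty_result",
           "all %d CpG units observed in < %.0f%% of samples were discarded",
           nrow(x), 100 * min_fraction)
  list(experiment = x[keep, ], discarded = rownames(x)[!keep])
}

#' Discard unreliable samples
#'
#' Removes samples missing strictly more than `max_missing` of their CpG-unit
#' values. Computed on the units present in `x`, so run [filterUnits()] first
#' (see [applyQc()] for the fixed order).
#'
#' @param x a [MethylationExperiment-class].
#' @param max_missing maximum tolerated missing fraction (default 0.30).
#' @return list with `experiment` (filtered) and `discarded` (sample ids).
#' @export
filterSamples <- function(x, max_missing = 0.30) {
  stopifnot(is(x, "MethylationExperiment"))
  if (ncol(x) == 0) .msErr("data", "no samples in the experiment")
  missing <- colMeans(is.na(methValues(x)))
  keep <- missing <= max_missing
  if (!any(keep))
    .msErr("empty_result", "all %d samples missing > %.0f%% of data points",
           ncol(x), 100 * max_missing)
  list(experiment = x[, keep], discarded = colnames(x)[!keep])
}

#' Apply both reliability filters in fixed order
#'
#' Unit filter first, then the sample filter computed on the surviving units.
#' The order is fixed because it changes results; it is recorded in pipeline
#' manifests.
#'
#' @inheritParams filterUnits
#' @inheritParams filterSamples
#' @return list with `experiment`, `discarded_units`, `discarded_samples`.
#' @export
applyQc <- function(x, min_fraction = 0.30, max_missing = 0.30) {
  u <- filterUnits(x, min_fraction)
  s <- filterSamples(u$experiment, max_missing)
  list(experiment = s$experiment,
       discarded_units = u$discarded,
       discarded_samples = s$discarded)
}
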