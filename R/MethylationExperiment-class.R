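#' MethylationExperiment: per-CpG-unit methylation with sample and site annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay `"methylation"` of per-CpG-unit methylation proportions (rows = CpG
#' units, columns = samples; values in \[0, 1\] or `NA` for missing).
#' `colData` carries the sample metadata (`class`, `stage`, `pair_id`);
#' `rowData` maps each CpG unit to its CTCF-binding site (`site_id`,
#' `chrom`, `start`, `end`, `direction`). Coordinates follow the BED
#' convention (0-based, half-open).
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msgs <- character()
  if (!"methylation" %in% assayNames(object))
    return("assay 'methylation' is missing")
  a <- assay(object, "methylation")
  if (any(a < 0 | a > 1, na.rm = TRUE))
    msgs <- c(msgs, "methylation values must lie in [0, 1]")
  cd <- colData(object)
  for (col in c("class", "stage"))
    if (!col %in% names(cd)) msgs <- c(msgs, sprintf("colData lacks '%s'", col))
  if ("class" %in% names(cd) && !all(cd$class %in% c("normal", "tumor")))
    msgs <- c(msgs, "sample class must be 'normal' or 'tumor'")
  if (all(c("class", "stage") %in% names(cd))) {
    if (!all(cd$stage %in% .stageLevels))
      msgs <- c(msgs, sprintf("stage must be one of %s",
                              paste(.stageLevels, collapse = ", ")))
    if (any(cd$class == "normal" & cd$stage != "none"))
      msgs <- c(msgs, "normal samples must have stage 'none'")
  }
  if ("pair_id" %in% names(cd)) {
    pid <- cd$pair_id[!is.na(cd$pair_id)]
    cls <- cd$class[!is.na(cd$pair_id)]
    bad <- vapply(split(cls, pid),
                  function(z) sum(z == "normal") > 1L || sum(z == "tumor") > 1L,
                  logical(1))
    if (any(bad))
      msgs <- c(msgs, "a pair_id may link at most one normal and one tumor sample")
  }
  rd <- rowData(object)
  if (!"site_id" %in% names(rd)) msgs <- c(msgs, "rowData lacks 'site_id'")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate CpG unit ids")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicate sample ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param values numeric matrix of methylation proportions, samples in rows and
#'   CpG units in columns (the on-disk layout), or units x samples with
#'   `samplesInRows = FALSE`.
#' @param meta data.frame of sample metadata with columns `sample_id`, `class`
#'   (`"normal"`/`"tumor"`), `stage` (`"adenoma"`, `"I"`, `"II"`, `"III"`,
#'   `"none"`) and optional `pair_id`.
#' @param annotation list with elements `sites` (data.frame: `site_id`,
#'   `chrom`, `start`, `end`, `direction`) and `units` (data.frame: `unit_id`,
#'   `site_id`), as returned by [readSiteAnnotation()].
#' @param samplesInRows logical; layout of `values`.
#' @return a [MethylationExperiment-class] object.
#' @export
MethylationExperiment <- function(values, meta, annotation, samplesInRows = TRUE) {
  if (samplesInRows) values <- t(values)
  units <- rownames(values)
  samples <- colnames(values)
  if (is.null(units) || is.null(samples))
    .msErr("format", "methylation matrix must carry unit and sample names")
  if (!all(samples %in% meta$sample_id))
    .msErr("consistency", "samples missing from metadata: %s",
           paste(setdiff(samples, meta$sample_id), collapse = ", "))
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  umap <- annotation$units
  if (!all(units %in% umap$unit_id))
    .msErr("consistency", "CpG units missing from annotation: %s",
           paste(utils::head(setdiff(units, umap$unit_id), 5), collapse = ", "))
  umap <- umap[match(units, umap$unit_id), , drop = FALSE]
  sites <- annotation$sites
  rd <- S4Vectors::DataFrame(
    site_id = umap$site_id,
    sites[match(umap$site_id, sites$site_id),
          setdiff(names(sites), "site_id"), drop = FALSE],
    row.names = units)
  cd <- S4Vectors::DataFrame(meta[setdiff(names(meta), "sample_id")],
                             row.names = samples)
  if (is.null(cd$pair_id)) cd$pair_id <- NA_character_
  se <- SummarizedExperiment(assays = list(methylation = values),
                             rowData = rd, colData = cd)
  new("MethylationExperiment", se)
}

#' @describeIn MethylationExperiment-class methylation assay (units x samples)
#' @param x a `MethylationExperiment`
#' @export
methValues <- function(x) assay(x, "methylation")

#' @describeIn MethylationExperiment-class sample class labels (normal/tumor)
#' @export
sampleClass <- function(x) setNames(as.character(colData(x)$class), colnames(x))

#' @describeIn MethylationExperiment-class sample stage labels
#' @export
sampleStage <- function(x) setNames(as.character(colData(x)$stage), colnames(x))

#' @describeIn MethylationExperiment-class matched-pair ids (NA when unpaired)
#' @export
pairIds <- function(x) setNames(as.character(colData(x)$pair_id), colnames(x))

#' @describeIn MethylationExperiment-class CpG-unit to site map (named vector)
#' @export
unitSites <- function(x) setNames(as.character(rowData(x)$site_id), rownames(x))

#' @describeIn MethylationExperiment-class site annotation table (one row per site)
#' @export
siteInfo <- function(x) {
  rd <- as.data.frame(rowData(x))
  out <- unique(rd[setdiff(names(rd), grep("^unit", names(rd), value = TRUE))])
  out <- out[!duplicated(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "MethylationExperiment", function(object) {
  cls <- table(factor(colData(object)$class, c("normal", "tumor")))
  cat(sprintf("MethylationExperiment: %d CpG units (%d sites) x %d samples (%d normal, %d tumor)\n",
              nrow(object), length(unique(rowData(object)$site_id)),
              ncol(object), cls["normal"], cls["tumor"]))
  cat(sprintf("missing: %.1f%% of entries\n",
              100 * mean(is.na(assay(object, "methylation")))))
  invisible(NULL)
})
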