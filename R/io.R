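# Tabular IO: methylation matrix, sample metadata, site annotation.
# Delimiter is sniffed from the header line unless given. Missing methylation
# is an empty cell or "NA" on disk; written back as empty. A "%" suffix is
# accepted and divided by 100.

.sniffSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

.readTable <- function(path, sep = NULL) {
  if (!file.exists(path)) .msErr("io", "file not found: %s", path)
  sep <- .sniffSep(path, sep)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    quote = "\"", comment.char = "", stringsAsFactors = FALSE)
}

#' Read / write a methylation matrix
#'
#' On-disk layout: header row of CpG-unit ids, first column sample ids, one row
#' per sample; values are methylation proportions in \[0, 1\] (a `%` suffix is
#' accepted and rescaled); empty cells or `NA` are missing.
#'
#' @param path file path (TSV or CSV; delimiter sniffed unless `sep` given).
#' @param sep optional field delimiter.
#' @return numeric matrix, samples in rows, CpG units in columns.
#' @export
readMethylationMatrix <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  sample_ids <- df[[1]]
  unit_ids <- names(df)[-1]
  if (anyDuplicated(sample_ids))
    .msErr("format", "duplicate sample ids: %s",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(unit_ids))
    .msErr("format", "duplicate CpG unit ids: %s",
           paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "))
  m <- matrix(NA_real_, length(sample_ids), length(unit_ids),
              dimnames = list(sample_ids, unit_ids))
  for (j in seq_along(unit_ids)) {
    raw <- trimws(df[[j + 1]])
    blank <- raw == "" | toupper(raw) == "NA"
    pct <- grepl("%$", raw)
    raw[pct] <- sub("%$", "", raw[pct])
    val <- suppressWarnings(as.numeric(raw))
    val[pct] <- val[pct] / 100
    bad <- !blank & is.na(val)
    if (any(bad))
      .msErr("format", "non-numeric value '%s' at sample '%s', unit '%s'",
             df[[j + 1]][which(bad)[1]], sample_ids[which(bad)[1]], unit_ids[j])
    out <- val[!blank & (val < 0 | val > 1)]
    if (length(out))
      .msErr("range", "methylation %g outside [0, 1] at sample '%s', unit '%s'",
             out[1], sample_ids[which(!blank & (val < 0 | val > 1))[1]],
             unit_ids[j])
    val[blank] <- NA_real_
    m[, j] <- val
  }
  m
}

#' @rdname readMethylationMatrix
#' @param x numeric matrix (samples x units) or a
#'   [MethylationExperiment-class].
#' @export
writeMethylationMatrix <- function(x, path, sep = "\t") {
  if (is(x, "MethylationExperiment")) x <- t(methValues(x))
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write sample metadata
#'
#' Required columns: `sample_id`, `class` (normal/tumor), `stage`
#' (adenoma/I/II/III/none; empty treated as none); optional `pair_id`.
#' A normal sample with a stage is rejected; a tumor sample with stage `none`
#' is accepted with a warning. Each pair_id may link at most one normal and
#' one tumor.
#'
#' @param path file path.
#' @param sep optional field delimiter.
#' @return data.frame with columns sample_id, class, stage, pair_id.
#' @export
readSampleMeta <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  need <- c("sample_id", "class", "stage")
  if (!all(need %in% names(df)))
    .msErr("format", "metadata must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    .msErr("format", "duplicate sample ids in metadata")
  if (!all(df$class %in% c("normal", "tumor")))
    .msErr("format", "unknown class label(s): %s",
           paste(unique(setdiff(df$class, c("normal", "tumor"))), collapse = ", "))
  df$stage[is.na(df$stage) | trimws(df$stage) == ""] <- "none"
  if (!all(df$stage %in% .stageLevels))
    .msErr("format", "unknown stage label(s): %s",
           paste(unique(setdiff(df$stage, .stageLevels)), collapse = ", "))
  if (any(df$class == "normal" & df$stage != "none"))
    .msErr("consistency", "normal sample(s) carry a tumor stage: %s",
           paste(df$sample_id[df$class == "normal" & df$stage != "none"],
                 collapse = ", "))
  if (any(df$class == "tumor" & df$stage == "none"))
    warning("tumor sample(s) without a stage: ",
            paste(df$sample_id[df$class == "tumor" & df$stage == "none"],
                  collapse = ", "))
  if (!"pair_id" %in% names(df)) df$pair_id <- NA_character_
  df$pair_id[trimws(df$pair_id) == ""] <- NA_character_
  pid <- df$pair_id[!is.na(df$pair_id)]
  cls <- df$class[!is.na(df$pair_id)]
  bad <- vapply(split(cls, pid),
                function(z) sum(z == "normal") > 1 || sum(z == "tumor") > 1,
                logical(1))
  if (any(bad))
    .msErr("consistency", "pair_id(s) link more than one sample per class: %s",
           paste(names(bad)[bad], collapse = ", "))
  df[c("sample_id", "class", "stage", "pair_id")]
}

#' @rdname readSampleMeta
#' @param meta data.frame as returned by [readSampleMeta()].
#' @export
writeSampleMeta <- function(meta, path, sep = "\t") {
  utils::write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write site annotation
#'
#' The site table is BED-derived: columns `chrom`, `start`, `end`, `site_id`,
#' `direction` (hyper/hypo/auto), coordinates 0-based half-open. The unit map
#' has columns `unit_id`, `site_id`; every unit maps to exactly one site.
#'
#' @param sites_path path to the site table.
#' @param units_path path to the unit->site map.
#' @param sep optional field delimiter.
#' @return list with data.frames `sites` and `units`.
#' @export
readSiteAnnotation <- function(sites_path, units_path, sep = NULL) {
  sites <- .readTable(sites_path, sep)
  need <- c("chrom", "start", "end", "site_id", "direction")
  if (!all(need %in% names(sites)))
    .msErr("format", "site table must have columns %s", paste(need, collapse = ", "))
  sites$start <- as.integer(sites$start)
  sites$end <- as.integer(sites$end)
  if (any(is.na(sites$start) | is.na(sites$end)))
    .msErr("format", "non-integer coordinates in site table")
  if (any(sites$start >= sites$end))
    .msErr("format", "start >= end for site(s): %s",
           paste(sites$site_id[sites$start >= sites$end], collapse = ", "))
  if (anyDuplicated(sites$site_id)) .msErr("format", "duplicate site ids")
  if (!all(sites$direction %in% c("hyper", "hypo", "auto", "null")))
    .msErr("format", "direction must be hyper, hypo, null or auto")
  units <- .readTable(units_path, sep)
  if (!all(c("unit_id", "site_id") %in% names(units)))
    .msErr("format", "unit map must have columns unit_id, site_id")
  if (anyDuplicated(units$unit_id))
    .msErr("format", "unit(s) mapped to more than one site: %s",
           paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", "))
  if (!all(units$site_id %in% sites$site_id))
    .msErr("consistency", "unit map references unknown site(s): %s",
           paste(unique(setdiff(units$site_id, sites$site_id)), collapse = ", "))
  list(sites = sites[c("site_id", "chrom", "start", "end", "direction")],
       units = units[c("unit_id", "site_id")])
}

#' @rdname readSiteAnnotation
#' @param annotation list with `sites` and `units` data.frames.
#' @export
writeSiteAnnotation <- function(annotation, sites_path, units_path, sep = "\t") {
  sites <- annotation$sites[c("chrom", "start", "end", "site_id", "direction")]
  utils::write.table(sites, sites_path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(annotation$units, units_path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(sites_path)
}
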