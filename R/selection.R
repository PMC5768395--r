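# Marker selection: per-site representative CpG unit (highest oriented AUC),
# AUC ranking / top-k shortlisting, and the cell-line occupancy-methylation
# discovery screen.

#' Representative CpG unit per site
#'
#' For each site, the CpG unit with the maximal oriented AUC (tumor vs normal)
#' represents the site. Ties break by lexicographic unit id. Units with fewer
#' than two observed values in either class are skipped; a site whose units
#' are all unusable is dropped with a warning.
#'
#' @param x a QC-filtered [MethylationExperiment-class] (unit level).
#' @return named character vector, site_id -> unit_id, with the winning AUC in
#'   attribute `"auc"`.
#' @export
selectRepresentativeUnit <- function(x) {
  stopifnot(is(x, "MethylationExperiment"))
  vals <- methValues(x)
  cls <- sampleClass(x)
  sites <- unitSites(x)
  decl <- as.character(rowData(x)$direction)
  decl[!decl %in% c("hyper", "hypo")] <- "auto"
  out <- auc_out <- character(0)
  aucs <- numeric(0)
  for (s in unique(sites)) {
    units <- sort(names(sites)[sites == s])  # lexicographic tie-break order
    a <- vapply(units, function(u) {
      pos <- vals[u, cls == "tumor"]; neg <- vals[u, cls == "normal"]
      pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
      if (length(pos) < 2 || length(neg) < 2) return(NA_real_)
      st <- aucStats(pos, neg, decl[match(u, rownames(vals))])
      st$auc
    }, numeric(1))
    if (all(is.na(a))) {
      warning("site ", s, " has no usable CpG units; dropped")
      next
    }
    best <- units[which.max(a)]  # first maximum = lexicographically smallest
    out[s] <- best
    aucs[s] <- max(a, na.rm = TRUE)
  }
  structure(out, auc = aucs)
}

#' Collapse to one representative value per site
#'
#' Subsets the experiment to the representative units and renames rows to the
#' site ids, yielding the site-level matrix used by ranking, panel evaluation
#' and clustering.
#'
#' @param x a [MethylationExperiment-class] (unit level).
#' @param rep_map site -> unit map from [selectRepresentativeUnit()]; computed
#'   if missing.
#' @return a site-level [MethylationExperiment-class].
#' @export
siteLevelExperiment <- function(x, rep_map = NULL) {
  if (is.null(rep_map)) rep_map <- selectRepresentativeUnit(x)
  y <- x[unname(rep_map), ]
  rownames(y) <- names(rep_map)
  rowData(y)$representative_unit <- unname(rep_map)
  y
}

#' Rank markers and shortlist the top k
#'
#' Markers sort by AUC descending; ties break by sensitivity at 95%
#' specificity (when present), then by marker id, so the order is total and
#' reproducible.
#'
#' @param roc_results data.frame from [rocAnalysis()] (the `"total"` stratum
#'   is used if several are present).
#' @param k how many markers to keep (default: all).
#' @return the ranked (and truncated) data.frame.
#' @export
rankMarkers <- function(roc_results, k = NULL) {
  d <- roc_results
  if ("stratum" %in% names(d)) d <- d[d$stratum == "total", , drop = FALSE]
  if (is.null(k)) k <- nrow(d)
  if (k > nrow(d)) .msErr("config", "k exceeds the number of markers")
  sens <- if ("sens_95" %in% names(d)) d$sens_95 else rep(0, nrow(d))
  d <- d[order(-d$auc, -sens, d$marker), , drop = FALSE]
  utils::head(d, k)
}

#' Discover candidate sites from cell-line occupancy and methylation
#'
#' Two-step screen. Step 1 keeps sites whose occupancy is present in at least
#' one immortal line and absent from every normal line. Step 2 keeps sites
#' where methylation in unoccupied lines exceeds methylation in occupied lines
#' by a one-sided rank-sum test at `alpha` (exact by default, appropriate for
#' the few lines per group); Spearman correlation of methylation against
#' occupancy is available instead. Sites with fewer than 4 lines, or without
#' both occupied and unoccupied lines, are skipped with a warning.
#'
#' @param occupancy an `OccupancyStudy` from [simulateCellLines()] or a long
#'   data.frame with columns site_id, cell_line, class (immortal/normal),
#'   occupied (0/1), methylation.
#' @param alpha significance level (default 0.05).
#' @param test association test for step 2.
#' @param adjust p-value adjustment across step-2 tests (default none;
#'   `"BH"` available).
#' @return data.frame: site_id, immortal_specific, n_occupied, n_unoccupied,
#'   p_value, selected.
#' @export
discoverCandidates <- function(occupancy, alpha = 0.05,
                               test = c("wilcoxon", "spearman"),
                               adjust = c("none", "BH")) {
  test <- match.arg(test); adjust <- match.arg(adjust)
  tab <- if (inherits(occupancy, "OccupancyStudy")) occupancy$table else occupancy
  need <- c("site_id", "cell_line", "class", "occupied", "methylation")
  if (!all(need %in% names(tab)))
    .msErr("format", "occupancy table must have columns %s",
           paste(need, collapse = ", "))
  res <- lapply(split(tab, tab$site_id), function(d) {
    spec <- any(d$occupied == 1 & d$class == "immortal") &&
      !any(d$occupied == 1 & d$class == "normal")
    occ <- d$methylation[d$occupied == 1]
    unocc <- d$methylation[d$occupied == 0]
    p <- NA_real_
    if (spec) {
      if (nrow(d) < 4 || !length(occ) || !length(unocc)) {
        warning("site ", d$site_id[1],
                " lacks enough lines in both occupancy groups; skipped")
        spec <- FALSE
      } else if (test == "wilcoxon") {
        p <- stats::wilcox.test(unocc, occ, alternative = "greater",
                                exact = TRUE)$p.value
      } else {
        p <- stats::cor.test(d$methylation, d$occupied, method = "spearman",
                             alternative = "less", exact = FALSE)$p.value
      }
    }
    data.frame(site_id = d$site_id[1], immortal_specific = spec,
               n_occupied = length(occ), n_unoccupied = length(unocc),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  tested <- out$immortal_specific & !is.na(out$p_value)
  padj <- out$p_value
  padj[tested] <- stats::p.adjust(out$p_value[tested], method = adjust)
  out$selected <- tested & padj < alpha
  out
}
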