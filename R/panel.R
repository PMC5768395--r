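# m-of-k marker panel: per-marker positivity thresholds at a fixed
# specificity, per-sample vote counting, and the stage-stratified sweep over
# all vote thresholds m = 1..k.

#' Panel specification
#'
#' @param thresholds data.frame with columns `marker`, `direction`
#'   (hyper/hypo), `threshold` (raw methylation cutpoint); a hyper marker is
#'   positive when its value >= threshold, a hypo marker when <= threshold.
#' @param vote_m markers required positive to call a sample tumor-positive
#'   (default 2, the 2-of-5 rule).
#' @return object of class `PanelSpec`.
#' @export
panelSpec <- function(thresholds, vote_m = 2) {
  need <- c("marker", "direction", "threshold")
  if (!all(need %in% names(thresholds)))
    .msErr("format", "thresholds must have columns %s", paste(need, collapse = ", "))
  k <- nrow(thresholds)
  if (vote_m < 1 || vote_m > k)
    .msErr("config", "vote_m must lie in 1..%d", k)
  if (!all(thresholds$direction %in% c("hyper", "hypo")))
    .msErr("config", "thresholds direction must be hyper or hypo")
  structure(list(thresholds = thresholds, vote_m = as.integer(vote_m),
                 markers = thresholds$marker, k = k),
            class = "PanelSpec")
}

#' Derive per-marker positivity thresholds
#'
#' Each marker's cutpoint is the sensitivity-at-specificity threshold from
#' [sensitivityAtSpecificity()] at `spec_level` on the full data (no
#' bootstrap needed).
#'
#' @param x a site-level [MethylationExperiment-class].
#' @param markers marker ids (rows of `x`); default all.
#' @param spec_level required per-marker specificity (default 0.95).
#' @param vote_m vote threshold stored in the returned spec.
#' @return a [panelSpec()].
#' @export
deriveThresholds <- function(x, markers = rownames(x), spec_level = 0.95,
                             vote_m = 2) {
  stopifnot(is(x, "MethylationExperiment"))
  vals <- methValues(x)
  cls <- sampleClass(x)
  decl <- as.character(rowData(x)$direction)[match(markers, rownames(x))]
  decl[!decl %in% c("hyper", "hypo")] <- "auto"
  rows <- lapply(seq_along(markers), function(i) {
    mk <- markers[i]
    ss <- sensitivityAtSpecificity(vals[mk, cls == "tumor"],
                                   vals[mk, cls == "normal"],
                                   decl[i], spec_level, n_boot = 0)
    data.frame(marker = mk, direction = ss$direction,
               threshold = ss$threshold, specificity = ss$specificity,
               stringsAsFactors = FALSE)
  })
  panelSpec(do.call(rbind, rows), vote_m = vote_m)
}

#' Count positive markers and call the panel per sample
#'
#' A missing marker value never counts as positive (conservative toward
#' specificity); samples missing all panel markers get an `NA` call, are
#' excluded from downstream denominators, and trigger a warning.
#'
#' @param x a site-level [MethylationExperiment-class].
#' @param spec a [panelSpec()].
#' @return data.frame: sample_id, class, stage, n_positive, n_observed, call
#'   (logical, `NA` when no marker observed).
#' @export
callPanel <- function(x, spec) {
  stopifnot(is(x, "MethylationExperiment"), inherits(spec, "PanelSpec"))
  if (!all(spec$markers %in% rownames(x)))
    .msErr("consistency", "panel markers absent from the experiment: %s",
           paste(setdiff(spec$markers, rownames(x)), collapse = ", "))
  vals <- methValues(x)[spec$markers, , drop = FALSE]
  posmat <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (i in seq_len(nrow(vals))) {
    th <- spec$thresholds$threshold[i]
    posmat[i, ] <- if (spec$thresholds$direction[i] == "hypo")
      vals[i, ] <= th else vals[i, ] >= th
  }
  posmat[is.na(posmat)] <- FALSE
  n_obs <- colSums(!is.na(vals))
  n_pos <- colSums(posmat)
  call <- n_pos >= spec$vote_m
  call[n_obs == 0] <- NA
  if (any(n_obs == 0))
    warning("sample(s) with no observed panel marker excluded: ",
            paste(colnames(vals)[n_obs == 0], collapse = ", "))
  data.frame(sample_id = colnames(vals), class = sampleClass(x),
             stage = sampleStage(x), n_positive = n_pos, n_observed = n_obs,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Sweep the vote threshold m = 1..k
#'
#' For each m, stage-stratified sensitivity (fraction of stage tumors with at
#' least m positive markers), pooled total sensitivity, and specificity
#' (fraction of normals with fewer than m positive markers). Counts behind
#' every proportion are retained; empty strata report `NA`, not zero.
#'
#' @inheritParams callPanel
#' @return object of class `PanelResult`: list with `sweep` (data.frame, one
#'   row per m), `counts` (long data.frame of numerators/denominators),
#'   `calls` (per-sample votes at `spec$vote_m`) and `spec`.
#' @export
sweepPanel <- function(x, spec) {
  calls <- callPanel(x, spec)
  d <- calls[calls$n_observed > 0, ]  # samples with an undefined call drop out
  stages_present <- .stages[.stages %in% d$stage[d$class == "tumor"]]
  sweep <- counts <- list()
  for (m in seq_len(spec$k)) {
    pos <- d$n_positive >= m
    row <- list(m = m)
    for (s in stages_present) {
      idx <- d$class == "tumor" & d$stage == s
      row[[paste0("sens_", s)]] <- if (any(idx)) mean(pos[idx]) else NA_real_
      counts[[length(counts) + 1L]] <- data.frame(
        m = m, stratum = s, numerator = sum(pos[idx]), denominator = sum(idx))
    }
    idxT <- d$class == "tumor"
    row$sens_total <- if (any(idxT)) mean(pos[idxT]) else NA_real_
    counts[[length(counts) + 1L]] <- data.frame(
      m = m, stratum = "total", numerator = sum(pos[idxT]),
      denominator = sum(idxT))
    idxN <- d$class == "normal"
    row$specificity <- if (any(idxN)) mean(!pos[idxN]) else NA_real_
    counts[[length(counts) + 1L]] <- data.frame(
      m = m, stratum = "specificity", numerator = sum(!pos[idxN]),
      denominator = sum(idxN))
    sweep[[m]] <- as.data.frame(row)
  }
  structure(list(sweep = do.call(rbind, sweep),
                 counts = do.call(rbind, counts),
                 calls = calls, spec = spec),
            class = "PanelResult")
}

#' @export
print.PanelResult <- function(x, ...) {
  cat(sprintf("m-of-%d marker panel (vote threshold %d):\n",
              x$spec$k, x$spec$vote_m))
  s <- x$sweep
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", 100 * v))
  for (cn in setdiff(names(s), "m")) s[[cn]] <- pct(s[[cn]])
  print(s, row.names = FALSE)
  invisible(x)
}
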