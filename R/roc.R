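# Single-marker discrimination statistics: marker orientation, Mann-Whitney
# AUC with DeLong variance and z-test, and bootstrap sensitivity at fixed
# specificity. All computations use methylation proportions; multiply by 100
# only at the reporting layer.

.orientValues <- function(v, direction) if (direction == "hypo") -v else v

# Mann-Whitney AUC with ties credited 1/2, via midranks.
.aucRank <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Orient a marker
#'
#' Decides whether larger values are more tumor-like (`hyper`) or smaller
#' values are (`hypo`). With `declared = "auto"` the orientation giving
#' AUC >= 0.5 is chosen; an exact tie breaks to `hyper` (with a message).
#'
#' @param values_pos,values_neg marker values in the positive (tumor) and
#'   negative (normal) class; `NA`s are dropped.
#' @param declared `"hyper"`, `"hypo"` or `"auto"`.
#' @return `"hyper"` or `"hypo"`.
#' @export
orientMarker <- function(values_pos, values_neg, declared = "auto") {
  values_pos <- values_pos[!is.na(values_pos)]
  values_neg <- values_neg[!is.na(values_neg)]
  if (!length(values_pos) || !length(values_neg))
    .msErr("data", "a class is empty after removing missing values")
  if (declared %in% c("hyper", "hypo")) return(declared)
  a <- .aucRank(values_pos, values_neg)
  if (a == 0.5) message("orientation tie (AUC = 0.5); defaulting to 'hyper'")
  if (a >= 0.5) "hyper" else "hypo"
}

#' AUC with significance
#'
#' AUC is the Mann-Whitney U statistic divided by n_pos * n_neg, ties credited
#' 1/2, computed on oriented values. The standard error comes from the DeLong
#' covariance estimator (placement values) and the p-value from a two-sided
#' z-test of AUC = 0.5; the Hanley-McNeil standard error is available via
#' `method`.
#'
#' @inheritParams orientMarker
#' @param direction `"hyper"`, `"hypo"` or `"auto"` (see [orientMarker()]).
#' @param method standard-error estimator.
#' @return list with `auc`, `se`, `p_value`, `direction`, `n_pos`, `n_neg`.
#' @export
aucStats <- function(values_pos, values_neg, direction = "auto",
                     method = c("delong", "hanley")) {
  method <- match.arg(method)
  values_pos <- values_pos[!is.na(values_pos)]
  values_neg <- values_neg[!is.na(values_neg)]
  direction <- orientMarker(values_pos, values_neg, direction)
  pos <- .orientValues(values_pos, direction)
  neg <- .orientValues(values_neg, direction)
  m <- length(pos); n <- length(neg)
  if (m < 2 || n < 2) .msErr("data", "need at least 2 values per class")
  auc <- .aucRank(pos, neg)
  if (method == "delong") {
    # placement values from midranks: V10_i = P(pos_i > neg) + P(=)/2
    r_all <- rank(c(pos, neg))
    v10 <- (r_all[seq_len(m)] - rank(pos)) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  } else {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n - 1) * (q2 - auc^2)) / (m * n))
  }
  if (se == 0) {
    if (auc == 0.5) {
      warning("all values tied; AUC 0.5 with p = 1")
      p <- 1
    } else p <- 0  # perfect separation: degenerate DeLong variance
  } else p <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
  list(auc = auc, se = se, p_value = p, direction = direction,
       n_pos = m, n_neg = n)
}

# Exhaustive threshold scan on oriented values. Candidate cutpoints are the
# midpoints between adjacent distinct observed values plus sentinels beyond
# the extremes; a sample is called positive when its oriented value >= t.
# Among cutpoints with empirical specificity >= level, pick maximal
# sensitivity, then maximal specificity, then the smallest cutpoint.
.scanThreshold <- function(pos, neg, level) {
  v <- sort(unique(c(pos, neg)))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  sp <- sort(pos); sn <- sort(neg)
  spec <- findInterval(thr, sn) / length(neg)                   # neg < t
  sens <- (length(pos) - findInterval(thr, sp)) / length(pos)   # pos >= t
  ok <- spec >= level
  if (!any(ok)) .msErr("data", "specificity level %g unreachable", level)
  best <- which(ok)[order(-sens[ok], -spec[ok], thr[ok])][1]
  list(threshold = thr[best], sensitivity = sens[best], specificity = spec[best])
}

#' Sensitivity at fixed specificity with bootstrap CI
#'
#' The decision threshold is the cutpoint on the oriented values maximizing
#' sensitivity subject to empirical specificity >= `spec_level` on the full
#' data; the point estimate is the sensitivity there. The confidence interval
#' is the percentile interval of sensitivities across `n_boot` stratified
#' bootstrap replicates (positive and negative classes resampled
#' independently, the threshold re-derived within each replicate).
#'
#' @inheritParams aucStats
#' @param spec_level required specificity, in (0, 1).
#' @param n_boot bootstrap replicates (default 1000); 0 skips the CI.
#' @param conf CI level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return list with `point`, `ci_lo`, `ci_hi`, `threshold` (on the raw
#'   methylation scale), `rule` (`">="` for hyper, `"<="` for hypo),
#'   `specificity` (achieved on the full data), `direction`, `spec_level`,
#'   `n_pos`, `n_neg`.
#' @export
sensitivityAtSpecificity <- function(values_pos, values_neg, direction = "auto",
                                     spec_level = 0.95, n_boot = 1000,
                                     conf = 0.95, seed = NULL) {
  if (spec_level <= 0 || spec_level >= 1)
    .msErr("config", "spec_level must lie in (0, 1)")
  values_pos <- values_pos[!is.na(values_pos)]
  values_neg <- values_neg[!is.na(values_neg)]
  direction <- orientMarker(values_pos, values_neg, direction)
  pos <- .orientValues(values_pos, direction)
  neg <- .orientValues(values_neg, direction)
  if (length(neg) < 5)
    .msErr("data", "need at least 5 negative-class values to fix specificity")
  full <- .scanThreshold(pos, neg, spec_level)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    sens_b <- withSeed(seed, {
      m <- length(pos); n <- length(neg)
      vapply(seq_len(n_boot), function(b) {
        .scanThreshold(pos[sample.int(m, m, replace = TRUE)],
                       neg[sample.int(n, n, replace = TRUE)],
                       spec_level)$sensitivity
      }, numeric(1))
    })
    alpha <- 1 - conf
    ci <- unname(stats::quantile(sens_b, c(alpha / 2, 1 - alpha / 2)))
  }
  list(point = full$sensitivity, ci_lo = ci[1], ci_hi = ci[2],
       threshold = if (direction == "hypo") -full$threshold else full$threshold,
       rule = if (direction == "hypo") "<=" else ">=",
       specificity = full$specificity, direction = direction,
       spec_level = spec_level, n_pos = length(pos), n_neg = length(neg))
}

#' Per-marker ROC table
#'
#' Computes orientation, AUC (with DeLong p-value) and bootstrap sensitivity
#' at each requested specificity level for every marker (row) of a
#' site-level [MethylationExperiment-class], optionally stratified by tumor
#' stage (negatives are always all normals).
#'
#' @param x a [MethylationExperiment-class] (typically site-level, see
#'   [siteLevelExperiment()]).
#' @param spec_levels specificity levels (default 0.90 and 0.95).
#' @param n_boot,conf,seed bootstrap settings, see
#'   [sensitivityAtSpecificity()].
#' @param by_stage if TRUE, add one stratum per tumor stage plus `"total"`.
#' @return data.frame with one row per marker x stratum: `marker`, `stratum`,
#'   `direction`, `auc`, `auc_se`, `p_value`, `n_pos`, `n_neg`, and per level
#'   L columns `sens_L`, `sens_L_lo`, `sens_L_hi`, `threshold_L`.
#' @export
rocAnalysis <- function(x, spec_levels = c(0.90, 0.95), n_boot = 1000,
                        conf = 0.95, seed = 1, by_stage = FALSE) {
  stopifnot(is(x, "MethylationExperiment"))
  vals <- methValues(x)
  cls <- sampleClass(x)
  stg <- sampleStage(x)
  decl <- as.character(rowData(x)$direction)
  decl[!decl %in% c("hyper", "hypo")] <- "auto"
  strata <- if (by_stage) c(.stages[.stages %in% stg], "total") else "total"
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(vals))) {
      for (s in strata) {
        posIdx <- cls == "tumor" & (s == "total" | stg == s)
        pos <- vals[i, posIdx]; neg <- vals[i, cls == "normal"]
        st <- aucStats(pos, neg, decl[i])
        row <- data.frame(marker = rownames(vals)[i], stratum = s,
                          direction = st$direction, auc = st$auc,
                          auc_se = st$se, p_value = st$p_value,
                          n_pos = st$n_pos, n_neg = st$n_neg,
                          stringsAsFactors = FALSE)
        for (lev in spec_levels) {
          ss <- sensitivityAtSpecificity(pos, neg, st$direction, lev,
                                         n_boot = n_boot, conf = conf)
          tag <- sprintf("%g", 100 * lev)
          row[[paste0("sens_", tag)]] <- ss$point
          row[[paste0("sens_", tag, "_lo")]] <- ss$ci_lo
          row[[paste0("sens_", tag, "_hi")]] <- ss$ci_hi
          row[[paste0("threshold_", tag)]] <- ss$threshold
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Format a sensitivity with CI as a percentage string
#'
#' Reporting-layer helper: `"97.37 [82.46,100.00]"`.
#'
#' @param point,lo,hi proportions in \[0, 1\].
#' @return character vector.
#' @export
formatSensCI <- function(point, lo, hi)
  sprintf("%.2f [%.2f,%.2f]", 100 * point, 100 * lo, 100 * hi)
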