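# Semiquantitative MS-HRM triage: bin each sample's melt statistic against the
# 0/1/10/100% dilution standard curve, then call tumor-specific sites from
# matched normal/tumor pairs.

#' Dilution standard curve
#'
#' @param statistics melt-shift scalars measured for the standards, strictly
#'   monotone in ratio (decreasing curves are flipped internally).
#' @param ratios methylated-DNA ratios of the standards (default 0, 1, 10,
#'   100%).
#' @return object of class `StandardCurve` (data.frame: ratio, melt_statistic).
#' @export
standardCurve <- function(statistics, ratios = c(0, 0.01, 0.10, 1.00)) {
  if (length(statistics) != length(ratios))
    .msErr("calibration", "one statistic per standard ratio required")
  o <- order(ratios)
  ratios <- ratios[o]; statistics <- statistics[o]
  d <- diff(statistics)
  if (all(d < 0)) statistics <- -statistics
  else if (!all(d > 0))
    .msErr("calibration", "standard curve is not strictly monotone in ratio")
  structure(data.frame(ratio = ratios, melt_statistic = statistics),
            class = c("StandardCurve", "data.frame"))
}

#' Bin observations against the standard curve
#'
#' Each observation is assigned the interval between the two consecutive
#' standards bracketing its melt statistic: bin 0 = \[0--1%), bin 1 =
#' \[1--10%), bin 2 = \[10--100%\]. Intervals are left-closed (a statistic
#' exactly at the 1% standard falls in bin 1); values below the 0% standard
#' clamp to bin 0 and above the 100% standard to bin 2.
#'
#' @param observations data.frame with columns `sample_id`, `site_id`,
#'   `melt_statistic` (e.g. from [simulateHrmObservations()]).
#' @param curve a [standardCurve()] or a data.frame coercible to one.
#' @return the observations with an integer `bin` column added.
#' @export
assignBins <- function(observations, curve) {
  if (!inherits(curve, "StandardCurve"))
    curve <- standardCurve(curve$melt_statistic, curve$ratio)
  s <- curve$melt_statistic
  stat <- observations$melt_statistic
  if (any(!is.finite(stat))) .msErr("data", "non-finite melt statistic")
  observations$bin <- (stat >= s[2]) + (stat >= s[3])
  observations
}

#' Call tumor-specific sites from matched pairs
#'
#' For every matched normal/tumor pair the direction is the sign of
#' (tumor bin - normal bin); ties count in the denominator of informative
#' pairs (a tied pair is evidence against specificity). A site passes when one
#' direction occurs in at least `min_fraction` of its pairs.
#'
#' @param calls binned observations from [assignBins()].
#' @param meta sample metadata data.frame (sample_id, class, pair_id).
#' @param min_fraction required fraction of same-direction pairs (default
#'   0.60, just below the 64% floor observed for sites kept in the reference
#'   screen).
#' @return data.frame: site_id, n_pairs, n_up (T>N), n_down (T<N),
#'   fraction_specific, direction ("T>N"/"T<N"/NA), pass.
#' @export
callSiteSpecificity <- function(calls, meta, min_fraction = 0.60) {
  need <- c("sample_id", "site_id", "bin")
  if (!all(need %in% names(calls)))
    .msErr("format", "calls must have columns %s", paste(need, collapse = ", "))
  m <- meta[!is.na(meta$pair_id), c("sample_id", "class", "pair_id")]
  calls <- merge(calls, m, by = "sample_id")
  out <- lapply(split(calls, calls$site_id), function(d) {
    w <- stats::reshape(d[c("pair_id", "class", "bin")], idvar = "pair_id",
                        timevar = "class", direction = "wide")
    bt <- w[["bin.tumor"]]; bn <- w[["bin.normal"]]
    ok <- !is.na(bt) & !is.na(bn)
    n <- sum(ok)
    if (n == 0) {
      warning("site ", d$site_id[1], " has no informative matched pairs; skipped")
      return(NULL)
    }
    n_up <- sum(bt[ok] > bn[ok])
    n_down <- sum(bt[ok] < bn[ok])
    frac <- max(n_up, n_down) / n
    direction <- if (n_up > n_down) "T>N" else if (n_down > n_up) "T<N" else NA
    data.frame(site_id = d$site_id[1], n_pairs = n, n_up = n_up,
               n_down = n_down, fraction_specific = frac,
               direction = direction,
               pass = !is.na(direction) && frac >= min_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
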