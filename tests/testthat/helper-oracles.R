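# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (loops, exhaustive enumeration, nested quadrature) so
# they cannot share a code path with the implementation.

# AUC by exhaustive concordant-pair counting (ties credited 1/2).
bruteAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Sensitivity at fixed specificity by exhaustive scan over all midpoint
# cutpoints (oriented values, positive iff value >= t), specificity >= level.
bruteSensAtSpec <- function(pos, neg, level) {
  v <- sort(unique(c(pos, neg)))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  best <- -1
  for (t in cand) {
    spec <- sum(neg < t) / length(neg)
    if (spec >= level) {
      sens <- sum(pos >= t) / length(pos)
      if (sens > best) best <- sens
    }
  }
  best
}

# P(T > N) for independent Betas by brute-force nested numerical integration
# (inner CDF integrated numerically, never via pbeta).
bruteBetaAUC <- function(an, bn, at, bt) {
  inner <- function(x) vapply(x, function(xx)
    stats::integrate(function(y) stats::dbeta(y, an, bn), 0, xx,
                     rel.tol = 1e-10)$value, numeric(1))
  stats::integrate(function(x) stats::dbeta(x, at, bt) * inner(x), 0, 1,
                   rel.tol = 1e-8)$value
}

# Small MethylationExperiment from a samples x units matrix.
toyME <- function(values, class, stage = NULL, pair_id = NULL,
                  unit_site = NULL, site_direction = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("u%02d", seq_len(ncol(values)))
  if (is.null(stage)) stage <- ifelse(class == "tumor", "II", "none")
  if (is.null(pair_id)) pair_id <- rep(NA_character_, nrow(values))
  meta <- data.frame(sample_id = rownames(values), class = class,
                     stage = stage, pair_id = pair_id,
                     stringsAsFactors = FALSE)
  if (is.null(unit_site)) unit_site <- colnames(values)
  sid <- unique(unit_site)
  if (is.null(site_direction)) site_direction <- rep("auto", length(sid))
  ann <- list(sites = data.frame(site_id = sid, chrom = "chr1",
                                 start = seq_along(sid) * 100L,
                                 end = seq_along(sid) * 100L + 30L,
                                 direction = site_direction,
                                 stringsAsFactors = FALSE),
              units = data.frame(unit_id = colnames(values),
                                 site_id = unit_site,
                                 stringsAsFactors = FALSE))
  MethylationExperiment(values, meta, ann)
}
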