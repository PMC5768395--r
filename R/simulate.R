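# Synthetic-data generator: Beta-distributed per-site methylation with
# class-specific parameters, CpG-unit jitter, MCAR missingness, matched pairs,
# HRM melt statistics, and cell-line occupancy/methylation tables.

#' Default per-site Beta parameters
#'
#' Deterministic (seed-free) construction of class-specific Beta shape pairs.
#' Hypermethylated sites: normal tissue centred at 2% methylation
#' (concentration 10), tumor means spread over 15--50% (concentration 8), so
#' single-site analytic AUCs span roughly 0.92--0.998. Hypomethylated sites
#' mirror this; null sites use the normal distribution for both classes.
#'
#' @param n_sites,n_hyper,n_hypo site counts (hyper + hypo <= total).
#' @return list with `normal` and `tumor` (n_sites x 2 matrices of shape
#'   parameters) and `direction` (character: hyper/hypo/null).
#' @export
defaultSiteParams <- function(n_sites, n_hyper, n_hypo) {
  stopifnot(n_hyper + n_hypo <= n_sites)
  shp <- function(m, c) c(m * c, (1 - m) * c)
  lowM <- 0.02; lowC <- 10; highC <- 8
  normal <- tumor <- matrix(NA_real_, n_sites, 2,
                            dimnames = list(NULL, c("alpha", "beta")))
  direction <- rep("null", n_sites)
  if (n_hyper > 0) {
    tm <- if (n_hyper == 1) 0.5 else seq(0.15, 0.50, length.out = n_hyper)
    for (i in seq_len(n_hyper)) {
      normal[i, ] <- shp(lowM, lowC)
      tumor[i, ] <- shp(tm[i], highC)
      direction[i] <- "hyper"
    }
  }
  if (n_hypo > 0) {
    nm <- if (n_hypo == 1) 0.5 else seq(0.15, 0.50, length.out = n_hypo)
    for (j in seq_len(n_hypo)) {
      i <- n_hyper + j
      normal[i, ] <- shp(nm[j], highC)
      tumor[i, ] <- shp(lowM, lowC)
      direction[i] <- "hypo"
    }
  }
  nulls <- which(direction == "null")
  for (i in nulls) normal[i, ] <- tumor[i, ] <- shp(lowM, lowC)
  list(normal = normal, tumor = tumor, direction = direction)
}

#' Simulation configuration
#'
#' Defaults emulate the reference study design: 84 normal tissues, 295 tumors
#' (108 adenoma, 39 stage I, 101 stage II, 47 stage III), 23 informative
#' CTCF-binding sites (16 hypermethylated, 7 hypomethylated in tumors), 3--6
#' CpG units per site, 5% missing data, every normal matched to a tumor.
#'
#' @param n_normal number of normal samples.
#' @param n_tumor_by_stage named integer vector over stages adenoma/I/II/III.
#' @param n_sites,n_hyper,n_hypo site counts; sites beyond hyper+hypo are null.
#' @param units_per_site length-2 range (min, max) of CpG units per site.
#' @param beta_params_normal,beta_params_tumor optional n_sites x 2 matrices of
#'   Beta shape parameters; defaults from [defaultSiteParams()].
#' @param unit_jitter_sd sd of the fixed per-unit offset on the logit scale.
#' @param unit_noise_sd sd of per-observation logit noise around the site value.
#' @param missing_rate MCAR missingness probability, in \[0, 1).
#' @param pairing_fraction fraction of tumors given a matched normal (capped by
#'   the number of normals available).
#' @param stage_shift optional named per-stage logit shift of tumor values
#'   (default 0 for all stages).
#' @param seed integer seed; identical seeds give identical studies.
#' @return object of class `simConfig`.
#' @export
simConfig <- function(n_normal = 84,
                      n_tumor_by_stage = c(adenoma = 108, I = 39, II = 101, III = 47),
                      n_sites = 23, n_hyper = 16, n_hypo = 7,
                      units_per_site = c(3, 6),
                      beta_params_normal = NULL, beta_params_tumor = NULL,
                      unit_jitter_sd = 0.2, unit_noise_sd = 0.1,
                      missing_rate = 0.05, pairing_fraction = 1,
                      stage_shift = NULL, seed = 1) {
  # tolerate list-valued fields from YAML configs
  n_tumor_by_stage <- unlist(n_tumor_by_stage)
  units_per_site <- as.numeric(unlist(units_per_site))
  if (!is.null(stage_shift)) stage_shift <- unlist(stage_shift)
  if (!.isCount(n_normal) || n_normal < 1)
    .msErr("config", "n_normal must be a positive count")
  if (!all(.stages %in% names(n_tumor_by_stage)))
    .msErr("config", "n_tumor_by_stage must name stages %s",
           paste(.stages, collapse = ", "))
  if (any(n_tumor_by_stage < 0) || sum(n_tumor_by_stage) < 1)
    .msErr("config", "tumor counts must be non-negative with at least one tumor")
  if (!.isCount(n_sites) || n_sites < 1)
    .msErr("config", "n_sites must be a positive count")
  if (n_hyper + n_hypo > n_sites)
    .msErr("config", "n_hyper + n_hypo must not exceed n_sites")
  if (length(units_per_site) != 2 || units_per_site[1] > units_per_site[2] ||
      units_per_site[1] < 1)
    .msErr("config", "units_per_site must be an increasing positive range")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    .msErr("config", "missing_rate must lie in [0, 1)")
  if (pairing_fraction < 0 || pairing_fraction > 1)
    .msErr("config", "pairing_fraction must lie in [0, 1]")
  if (is.null(beta_params_normal) || is.null(beta_params_tumor)) {
    def <- defaultSiteParams(n_sites, n_hyper, n_hypo)
    if (is.null(beta_params_normal)) beta_params_normal <- def$normal
    if (is.null(beta_params_tumor)) beta_params_tumor <- def$tumor
  }
  beta_params_normal <- as.matrix(beta_params_normal)
  beta_params_tumor <- as.matrix(beta_params_tumor)
  if (nrow(beta_params_normal) != n_sites || nrow(beta_params_tumor) != n_sites)
    .msErr("config", "beta parameter matrices must have one row per site")
  if (any(beta_params_normal <= 0) || any(beta_params_tumor <= 0))
    .msErr("config", "all Beta shape parameters must be > 0")
  if (is.null(stage_shift)) stage_shift <- setNames(numeric(4), .stages)
  structure(list(n_normal = n_normal,
                 n_tumor_by_stage = n_tumor_by_stage[.stages],
                 n_sites = n_sites, n_hyper = n_hyper, n_hypo = n_hypo,
                 units_per_site = units_per_site,
                 beta_params_normal = beta_params_normal,
                 beta_params_tumor = beta_params_tumor,
                 unit_jitter_sd = unit_jitter_sd, unit_noise_sd = unit_noise_sd,
                 missing_rate = missing_rate,
                 pairing_fraction = pairing_fraction,
                 stage_shift = stage_shift, seed = as.integer(seed)),
            class = "simConfig")
}

#' Analytic AUC between two Beta distributions
#'
#' P(X_tumor > X_normal) for independent Beta variables, by numerical
#' integration of the tumor density against the normal CDF. For
#' hypomethylated markers the oriented AUC P(X_tumor < X_normal) is returned.
#'
#' @param normal,tumor length-2 shape vectors (alpha, beta).
#' @param direction `"hyper"` or `"hypo"` orientation.
#' @return scalar AUC in \[0, 1\].
#' @export
analyticAUC <- function(normal, tumor, direction = "hyper") {
  f <- if (direction == "hypo") {
    function(x) stats::dbeta(x, tumor[1], tumor[2]) *
      (1 - stats::pbeta(x, normal[1], normal[2]))
  } else {
    function(x) stats::dbeta(x, tumor[1], tumor[2]) *
      stats::pbeta(x, normal[1], normal[2])
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

#' Simulate a methylation biomarker study
#'
#' Draws per-sample, per-site methylation from class- and site-specific Beta
#' distributions; CpG units of a site share the sample's site value plus a
#' fixed per-unit logit offset and small per-observation logit noise; entries
#' are masked missing completely at random.
#'
#' @param config a [simConfig()].
#' @return object of class `SimulatedStudy`: list with `experiment`
#'   (a [MethylationExperiment-class]), `truth` (data.frame: site_id,
#'   direction, analytic_auc), `site_values` (latent samples x sites matrix)
#'   and `config`.
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  withSeed(config$seed, {
    nN <- config$n_normal
    nT <- sum(config$n_tumor_by_stage)
    sample_id <- c(sprintf("normal_%03d", seq_len(nN)),
                   sprintf("tumor_%03d", seq_len(nT)))
    class <- rep(c("normal", "tumor"), c(nN, nT))
    stage <- c(rep("none", nN), rep(.stages, config$n_tumor_by_stage))
    n_pairs <- min(nN, round(config$pairing_fraction * nT), nT)
    pair_id <- rep(NA_character_, nN + nT)
    if (n_pairs > 0) {
      paired_t <- sample(seq_len(nT), n_pairs)
      pair_id[seq_len(n_pairs)] <- sprintf("pair_%03d", seq_len(n_pairs))
      pair_id[nN + paired_t] <- sprintf("pair_%03d", seq_len(n_pairs))
    }
    meta <- data.frame(sample_id = sample_id, class = class, stage = stage,
                       pair_id = pair_id, stringsAsFactors = FALSE)

    K <- config$n_sites
    site_id <- sprintf("site_%03d", seq_len(K))
    direction <- defaultSiteParams(K, config$n_hyper, config$n_hypo)$direction
    nunits <- sample(seq(config$units_per_site[1], config$units_per_site[2]),
                     K, replace = TRUE)

    # latent site-level methylation per sample
    site_values <- matrix(NA_real_, nN + nT, K,
                          dimnames = list(sample_id, site_id))
    shift <- c(none = 0, config$stage_shift)[stage]
    for (k in seq_len(K)) {
      pn <- config$beta_params_normal[k, ]
      pt <- config$beta_params_tumor[k, ]
      v <- numeric(nN + nT)
      isN <- class == "normal"
      v[isN] <- stats::rbeta(sum(isN), pn[1], pn[2])
      v[!isN] <- stats::rbeta(sum(!isN), pt[1], pt[2])
      if (any(shift != 0))
        v[!isN] <- stats::plogis(stats::qlogis(.clamp01(v[!isN])) + shift[!isN])
      site_values[, k] <- v
    }

    unit_id <- unlist(lapply(seq_len(K), function(k)
      sprintf("%s.u%d", site_id[k], seq_len(nunits[k]))))
    unit_site <- rep(site_id, nunits)
    offsets <- stats::rnorm(length(unit_id), 0, config$unit_jitter_sd)
    values <- matrix(NA_real_, nN + nT, length(unit_id),
                     dimnames = list(sample_id, unit_id))
    for (u in seq_along(unit_id)) {
      base <- stats::qlogis(.clamp01(site_values[, unit_site[u]]))
      eps <- stats::rnorm(nN + nT, 0, config$unit_noise_sd)
      values[, u] <- stats::plogis(base + offsets[u] + eps)
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(values)) < config$missing_rate,
                     nrow(values))
      values[mask] <- NA_real_
    }

    sites <- data.frame(site_id = site_id, chrom = paste0("chr", (seq_len(K) %% 22) + 1),
                        start = 1000L * seq_len(K),
                        end = 1000L * seq_len(K) + 30L,
                        direction = direction, stringsAsFactors = FALSE)
    annotation <- list(sites = sites,
                       units = data.frame(unit_id = unit_id, site_id = unit_site,
                                          stringsAsFactors = FALSE))
    truth <- data.frame(site_id = site_id, direction = direction,
                        analytic_auc = vapply(seq_len(K), function(k)
                          if (direction[k] == "null") 0.5 else
                            analyticAUC(config$beta_params_normal[k, ],
                                        config$beta_params_tumor[k, ],
                                        direction[k]),
                          numeric(1)),
                        stringsAsFactors = FALSE)
    structure(list(experiment = MethylationExperiment(values, meta, annotation),
                   truth = truth, site_values = site_values, config = config),
              class = "SimulatedStudy")
  })
}

#' HRM melt-shift statistic
#'
#' Strictly increasing map from methylation proportion to a melt-shift scalar,
#' anchored so fully unmethylated material scores 0. Purely a reporting scale;
#' binning only uses its monotonicity.
#'
#' @param m methylation proportion(s) in \[0, 1\].
#' @return numeric melt statistic(s).
#' @export
hrmMeltStatistic <- function(m) 25 * log10(1 + 999 * m)

#' Simulate MS-HRM observations and dilution standards
#'
#' Each sample x site receives a melt-shift statistic: the monotone
#' [hrmMeltStatistic()] of the sample's latent site methylation plus Gaussian
#' noise. Standards at methylated-DNA ratios 0, 1, 10 and 100% are emitted
#' noiseless alongside.
#'
#' @param study a [simulateStudy()] result.
#' @param noise_sd Gaussian noise sd on the melt statistic (>= 0).
#' @param seed integer seed.
#' @return list with `observations` (data.frame: sample_id, site_id,
#'   melt_statistic) and `standards` (data.frame: ratio, melt_statistic).
#' @export
simulateHrmObservations <- function(study, noise_sd = 1, seed = 1) {
  stopifnot(inherits(study, "SimulatedStudy"))
  if (noise_sd < 0) .msErr("config", "noise_sd must be >= 0")
  sv <- study$site_values
  obs <- data.frame(sample_id = rep(rownames(sv), ncol(sv)),
                    site_id = rep(colnames(sv), each = nrow(sv)),
                    melt_statistic = as.vector(hrmMeltStatistic(sv)),
                    stringsAsFactors = FALSE)
  if (noise_sd > 0)
    obs$melt_statistic <- obs$melt_statistic +
      withSeed(seed, stats::rnorm(nrow(obs), 0, noise_sd))
  ratios <- c(0, 0.01, 0.10, 1.00)
  list(observations = obs,
       standards = data.frame(ratio = ratios,
                              melt_statistic = hrmMeltStatistic(ratios)))
}

#' Simulate a cell-line occupancy/methylation table
#'
#' Emulates the discovery input: binary CTCF occupancy and site methylation
#' across immortal and normal cell lines. All sites are occupied only in
#' immortal lines (the class-specificity prefilter's surviving pool); at true
#' candidate sites methylation is low where occupied and high where
#' unoccupied, at null sites methylation is independent of occupancy.
#'
#' @param n_sites total sites; default mirrors the 1236-site pool.
#' @param n_immortal,n_normal_lines cell-line layout (defaults 6 and 7).
#' @param n_true_candidates number of planted candidates (default 121).
#' @param seed integer seed.
#' @return object of class `OccupancyStudy`: list with `table` (long
#'   data.frame: site_id, cell_line, class, occupied, methylation) and `truth`
#'   (data.frame: site_id, is_candidate).
#' @export
simulateCellLines <- function(n_sites = 1236, n_immortal = 6, n_normal_lines = 7,
                              n_true_candidates = 121, seed = 1) {
  if (n_true_candidates > n_sites)
    .msErr("config", "n_true_candidates must not exceed n_sites")
  withSeed(seed, {
    lines <- c(sprintf("immortal_%d", seq_len(n_immortal)),
               sprintf("normalline_%d", seq_len(n_normal_lines)))
    cls <- rep(c("immortal", "normal"), c(n_immortal, n_normal_lines))
    nL <- length(lines)
    site_id <- sprintf("cand_%04d", seq_len(n_sites))
    is_cand <- seq_len(n_sites) <= n_true_candidates
    rows <- vector("list", n_sites)
    for (k in seq_len(n_sites)) {
      occ <- integer(nL)
      n_occ <- sample(2:n_immortal, 1)
      occ[sample(seq_len(n_immortal), n_occ)] <- 1L
      meth <- if (is_cand[k]) {
        ifelse(occ == 1L, stats::rbeta(nL, 0.5, 9.5), stats::rbeta(nL, 4.8, 3.2))
      } else stats::rbeta(nL, 2, 8)
      rows[[k]] <- data.frame(site_id = site_id[k], cell_line = lines,
                              class = cls, occupied = occ, methylation = meth,
                              stringsAsFactors = FALSE)
    }
    structure(list(table = do.call(rbind, rows),
                   truth = data.frame(site_id = site_id, is_candidate = is_cand,
                                      stringsAsFactors = FALSE)),
              class = "OccupancyStudy")
  })
}
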