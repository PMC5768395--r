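# End-to-end orchestration: simulate (or load) -> QC -> HRM triage ->
# representative-unit selection -> ROC per stratum -> ranking -> panel sweep
# -> clustering, with a manifest of every parameter and discard decision.

.defaultPipelineConfig <- function() list(
  seed = 1,
  simulate = list(),
  qc = list(min_unit_fraction = 0.30, max_sample_missing = 0.30),
  hrm = list(enabled = TRUE, noise_sd = 1, min_fraction = 0.60),
  roc = list(spec_levels = c(0.90, 0.95), n_boot = 1000, by_stage = TRUE),
  select = list(k = 5),
  panel = list(vote_m = 2, spec_level = 0.95),
  cluster = list(distance = "bray", pseudocount = 0.005)
)

.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(user[[nm]]) && is.list(defaults[[nm]]))
      .mergeConfig(defaults[[nm]], user[[nm]]) else user[[nm]]
  }
  defaults
}

#' Run the full screening pipeline
#'
#' Stages: simulate (or load TSV inputs) -> CpG-unit/sample QC -> optional
#' MS-HRM matched-pair triage -> representative-unit selection -> per-marker
#' ROC with bootstrap sensitivity at fixed specificity (stage-stratified) ->
#' AUC ranking / top-k shortlist -> m-of-k panel sweep -> two-way clustering.
#' Identical config and seed give an identical report.
#'
#' @param config a nested list or the path of a YAML file. Blocks and
#'   defaults: `seed`; `simulate` (arguments of [simConfig()]) or `input`
#'   (paths `matrix`, `meta`, `sites`, `units`); `qc`
#'   (`min_unit_fraction`, `max_sample_missing`); `hrm` (`enabled`,
#'   `noise_sd`, `min_fraction`, or paths `observations` + `standards`);
#'   `roc` (`spec_levels`, `n_boot`, `by_stage`); `select` (`k`); `panel`
#'   (`vote_m`, `spec_level`); `cluster` (`distance`, `pseudocount`).
#' @return object of class `screenReport`: list with `experiment` (site
#'   level), `qc`, `hrm`, `representative_units`, `roc_table`, `ranking`,
#'   `panel` (a `PanelResult`), `cluster` (a `ClusterResult`), `truth` (when
#'   simulated) and `manifest`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  manifest <- list(seed = cfg$seed)
  study <- NULL

  if (!is.null(cfg$input)) {
    vals <- readMethylationMatrix(cfg$input$matrix)
    meta <- readSampleMeta(cfg$input$meta)
    ann <- readSiteAnnotation(cfg$input$sites, cfg$input$units)
    me <- MethylationExperiment(vals, meta, ann)
    manifest$data <- c(source = "files", cfg$input)
  } else {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sc <- do.call(simConfig, sim_args)
    study <- simulateStudy(sc)
    me <- study$experiment
    manifest$data <- list(source = "simulated",
                          n_normal = sc$n_normal,
                          n_tumor = sum(sc$n_tumor_by_stage),
                          n_sites = sc$n_sites, seed = sc$seed)
  }

  qc <- applyQc(me, cfg$qc$min_unit_fraction, cfg$qc$max_sample_missing)
  me <- qc$experiment
  manifest$qc <- list(min_unit_fraction = cfg$qc$min_unit_fraction,
                      max_sample_missing = cfg$qc$max_sample_missing,
                      discarded_units = qc$discarded_units,
                      discarded_samples = qc$discarded_samples)

  hrm <- NULL
  if (isTRUE(cfg$hrm$enabled)) {
    if (!is.null(cfg$hrm$observations)) {
      obs <- .readTable(cfg$hrm$observations)
      obs$melt_statistic <- as.numeric(obs$melt_statistic)
      stdtab <- .readTable(cfg$hrm$standards)
      curve <- standardCurve(as.numeric(stdtab$melt_statistic),
                             as.numeric(stdtab$ratio))
    } else if (!is.null(study)) {
      h <- simulateHrmObservations(study, noise_sd = cfg$hrm$noise_sd,
                                   seed = cfg$seed + 1L)
      obs <- h$observations
      curve <- standardCurve(h$standards$melt_statistic, h$standards$ratio)
    } else {
      obs <- NULL
      manifest$hrm <- list(skipped = "no observations available for file input")
    }
    if (!is.null(obs)) {
      meta_df <- data.frame(sample_id = colnames(me),
                            class = sampleClass(me), pair_id = pairIds(me),
                            stringsAsFactors = FALSE)
      calls <- assignBins(obs, curve)
      hrm <- callSiteSpecificity(calls, meta_df, cfg$hrm$min_fraction)
      passing <- hrm$site_id[hrm$pass]
      if (!length(passing))
        .msErr("empty_result", "HRM triage rejected every site")
      me <- me[unitSites(me) %in% passing, ]
      manifest$hrm <- list(min_fraction = cfg$hrm$min_fraction,
                           n_sites_tested = nrow(hrm),
                           n_sites_passing = length(passing))
    }
  } else manifest$hrm <- list(skipped = "hrm block disabled")

  rep_map <- selectRepresentativeUnit(me)
  site_me <- siteLevelExperiment(me, rep_map)
  manifest$representative_units <- as.list(rep_map)

  roc_table <- rocAnalysis(site_me, spec_levels = cfg$roc$spec_levels,
                           n_boot = cfg$roc$n_boot, seed = cfg$seed + 2L,
                           by_stage = isTRUE(cfg$roc$by_stage))
  k <- min(cfg$select$k, length(rep_map))
  ranking <- rankMarkers(roc_table, k)
  manifest$select <- list(k = k, shortlist = ranking$marker)

  pspec <- deriveThresholds(site_me, ranking$marker,
                            spec_level = cfg$panel$spec_level,
                            vote_m = min(cfg$panel$vote_m, k))
  panel <- sweepPanel(site_me, pspec)
  manifest$panel <- list(spec_level = cfg$panel$spec_level,
                         vote_m = pspec$vote_m,
                         thresholds = pspec$thresholds)

  cluster <- clusterTwoWay(site_me, distance = cfg$cluster$distance,
                           pseudocount = cfg$cluster$pseudocount)
  manifest$cluster <- list(distance = cfg$cluster$distance,
                           linkage = cluster$linkage,
                           pseudocount = cfg$cluster$pseudocount,
                           misassigned = cluster$misassigned)

  structure(list(experiment = site_me, qc = qc[c("discarded_units",
                                                 "discarded_samples")],
                 hrm = hrm, representative_units = rep_map,
                 roc_table = roc_table, ranking = ranking, panel = panel,
                 cluster = cluster,
                 truth = if (!is.null(study)) study$truth else NULL,
                 manifest = manifest),
            class = "screenReport")
}

#' @export
print.screenReport <- function(x, ...) {
  cat("methylscreen pipeline report\n")
  cat(sprintf("  site-level matrix: %d markers x %d samples\n",
              nrow(x$experiment), ncol(x$experiment)))
  if (!is.null(x$hrm))
    cat(sprintf("  HRM triage: %d/%d sites passed\n",
                sum(x$hrm$pass), nrow(x$hrm)))
  cat(sprintf("  shortlist (top %d by AUC): %s\n", nrow(x$ranking),
              paste(x$ranking$marker, collapse = ", ")))
  cat("  panel sweep:\n")
  print(x$panel)
  cat(sprintf("  clustering misassignments: %d\n", x$cluster$misassigned))
  invisible(x)
}
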