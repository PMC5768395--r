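# panel of 3 hand-set markers: m1/m2 hyper (positive >= threshold), m3 hypo
handSpec <- function(vote_m = 2) {
  panelSpec(data.frame(marker = c("m1", "m2", "m3"),
                       direction = c("hyper", "hyper", "hypo"),
                       threshold = c(0.5, 0.5, 0.2),
                       stringsAsFactors = FALSE), vote_m = vote_m)
}

panelME <- function(vals, class, stage = NULL)
  toyME(vals, class = class, stage = stage,
        site_direction = c("hyper", "hyper", "hypo")[seq_len(ncol(vals))])

test_that("votes are counted against oriented thresholds and the m rule applied", {
  vals <- rbind(a = c(0.1, 0.1, 0.9),  # 0 positive markers
                b = c(0.6, 0.1, 0.9),  # 1
                c = c(0.6, 0.7, 0.9),  # 2
                d = c(0.6, 0.7, 0.1))  # 3 (m3 positive because value <= 0.2)
  colnames(vals) <- c("m1", "m2", "m3")
  me <- panelME(vals, class = c("normal", "normal", "tumor", "tumor"))
  calls <- callPanel(me, handSpec(vote_m = 2))
  expect_identical(calls$n_positive, c(0, 1, 2, 3))
  expect_identical(calls$call, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(callPanel(me, handSpec(vote_m = 1))$call,
                   c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(callPanel(me, handSpec(vote_m = 3))$call,
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_error(handSpec(vote_m = 4), class = "methylscreen_config_error")
})

test_that("missing marker values never count positive; all-missing samples drop out", {
  vals <- rbind(a = c(0.6, NA, 0.1),   # 2 positive of 2 observed
                b = c(NA, NA, NA),     # undefined call
                c = c(0.6, 0.7, 0.9))
  colnames(vals) <- c("m1", "m2", "m3")
  me <- panelME(vals, class = c("tumor", "tumor", "normal"))
  expect_warning(calls <- callPanel(me, handSpec(2)), "no observed panel marker")
  expect_identical(calls$n_positive[1], 2)
  expect_true(is.na(calls$call[2]))
  # under m = k a tumor missing one marker call cannot be positive
  suppressWarnings(c3 <- callPanel(me, handSpec(3)))
  expect_false(c3$call[1])
  # the all-missing tumor is absent from sweep denominators (1 tumor remains)
  suppressWarnings(sw <- sweepPanel(me, handSpec(2)))
  expect_true(all(sw$counts$denominator[sw$counts$stratum == "total"] == 1))
})

test_that("derived thresholds respect the specificity floor by counting", {
  set.seed(41)
  vals <- cbind(mk = c(rbeta(84, 1, 9), rbeta(100, 5, 3)))
  rownames(vals) <- sprintf("s%03d", seq_len(nrow(vals)))
  me <- toyME(vals, class = rep(c("normal", "tumor"), c(84, 100)),
              site_direction = "hyper")
  spec <- deriveThresholds(me, "mk", spec_level = 0.95, vote_m = 1)
  th <- spec$thresholds$threshold
  n_fp <- sum(vals[1:84, 1] >= th)
  expect_lte(n_fp, floor(0.05 * 84))  # at most 4 of 84 normals positive
  expect_gte(spec$thresholds$specificity, 0.95)
  # hypo marker: positivity below the cutpoint
  valsh <- cbind(mk = c(rbeta(84, 5, 3), rbeta(100, 1, 9)))
  rownames(valsh) <- sprintf("s%03d", seq_len(nrow(valsh)))
  meh <- toyME(valsh, class = rep(c("normal", "tumor"), c(84, 100)),
               site_direction = "hypo")
  spech <- deriveThresholds(meh, "mk", spec_level = 0.95, vote_m = 1)
  expect_identical(spech$thresholds$direction, "hypo")
  expect_lte(sum(valsh[1:84, 1] <= spech$thresholds$threshold), 4)
})

test_that("the m-sweep is monotone and its proportions equal the recorded counts", {
  st <- simulateStudy(simConfig(seed = 44, n_normal = 30,
                                n_tumor_by_stage = c(adenoma = 10, I = 8, II = 8, III = 6),
                                n_sites = 5, n_hyper = 3, n_hypo = 2,
                                missing_rate = 0.1))
  sl <- siteLevelExperiment(applyQc(st$experiment)$experiment)
  pr <- sweepPanel(sl, deriveThresholds(sl, spec_level = 0.95, vote_m = 2))
  sw <- pr$sweep
  for (cn in grep("^sens", names(sw), value = TRUE))
    expect_true(all(diff(sw[[cn]]) <= 1e-12))
  expect_true(all(diff(sw$specificity) >= -1e-12))
  # every proportion is exactly its numerator/denominator
  for (i in seq_len(nrow(pr$counts))) {
    cc <- pr$counts[i, ]
    col <- switch(cc$stratum, total = "sens_total",
                  specificity = "specificity", paste0("sens_", cc$stratum))
    expect_equal(sw[[col]][sw$m == cc$m], cc$numerator / cc$denominator)
  }
  # pooled sensitivity is the count-weighted stage average
  for (m in sw$m) {
    cm <- pr$counts[pr$counts$m == m & !pr$counts$stratum %in% c("total", "specificity"), ]
    expect_equal(sw$sens_total[sw$m == m], sum(cm$numerator) / sum(cm$denominator))
  }
})
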