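test_that("simulation is deterministic under a fixed seed", {
  a <- simulateStudy(simConfig(seed = 42))
  b <- simulateStudy(simConfig(seed = 42))
  expect_identical(methValues(a$experiment), methValues(b$experiment))
  expect_identical(a$truth, b$truth)
  expect_identical(a$site_values, b$site_values)
  c <- simulateStudy(simConfig(seed = 43))
  expect_false(identical(methValues(a$experiment), methValues(c$experiment)))
})

test_that("simulated values are proportions and missingness matches the rate", {
  st <- simulateStudy(simConfig(seed = 11, missing_rate = 0.08))
  v <- methValues(st$experiment)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  n <- length(v)
  se <- sqrt(0.08 * 0.92 / n)
  expect_lt(abs(mean(is.na(v)) - 0.08), 3 * se)
})

test_that("analytic AUC matches nested numerical integration and the null case", {
  expect_equal(analyticAUC(c(2, 5), c(2, 5)), 0.5, tolerance = 1e-9)
  expect_equal(analyticAUC(normal = c(2, 50), tumor = c(50, 2)),
               bruteBetaAUC(2, 50, 50, 2), tolerance = 1e-6)
  # hypo orientation is the complement case
  expect_equal(analyticAUC(normal = c(50, 2), tumor = c(2, 50), "hypo"),
               1 - bruteBetaAUC(50, 2, 2, 50), tolerance = 1e-6)
  st <- simulateStudy(simConfig(seed = 3, n_sites = 10, n_hyper = 4, n_hypo = 3))
  expect_true(all(st$truth$analytic_auc >= 0 & st$truth$analytic_auc <= 1))
  expect_true(all(st$truth$analytic_auc[st$truth$direction == "null"] == 0.5))
})

test_that("planted directions show up as class mean differences", {
  st <- simulateStudy(simConfig(seed = 5))
  v <- methValues(st$experiment)
  cls <- sampleClass(st$experiment)
  sites <- unitSites(st$experiment)
  for (k in st$truth$site_id[st$truth$direction == "hyper"]) {
    sub <- v[sites == k, , drop = FALSE]
    expect_gt(mean(sub[, cls == "tumor"], na.rm = TRUE),
              mean(sub[, cls == "normal"], na.rm = TRUE))
  }
  for (k in st$truth$site_id[st$truth$direction == "hypo"]) {
    sub <- v[sites == k, , drop = FALSE]
    expect_lt(mean(sub[, cls == "tumor"], na.rm = TRUE),
              mean(sub[, cls == "normal"], na.rm = TRUE))
  }
})

test_that("HRM observations anchor at the standards and are monotone", {
  st <- simulateStudy(simConfig(seed = 9, n_sites = 4, n_hyper = 2, n_hypo = 1,
                                n_normal = 10,
                                n_tumor_by_stage = c(adenoma = 3, I = 3, II = 2, III = 2)))
  h <- simulateHrmObservations(st, noise_sd = 0, seed = 1)
  expect_identical(h$standards$ratio, c(0, 0.01, 0.10, 1.00))
  expect_identical(h$standards$melt_statistic[1], hrmMeltStatistic(0))
  # noiseless statistic is the exact monotone map of the latent methylation
  obs <- h$observations
  m <- st$site_values[cbind(obs$sample_id, obs$site_id)]
  expect_equal(obs$melt_statistic, hrmMeltStatistic(m))
  o <- order(m)
  expect_true(all(diff(obs$melt_statistic[o]) >= 0))
  expect_identical(hrmMeltStatistic(0), 0)
  # same seed reproduces noisy observations
  h1 <- simulateHrmObservations(st, noise_sd = 1, seed = 4)
  h2 <- simulateHrmObservations(st, noise_sd = 1, seed = 4)
  expect_identical(h1$observations, h2$observations)
})

test_that("cell-line simulation has the 6+7 layout and immortal-only occupancy", {
  occ <- simulateCellLines(n_sites = 50, n_true_candidates = 10, seed = 2)
  tab <- occ$table
  lines <- unique(tab[c("cell_line", "class")])
  expect_identical(sum(lines$class == "immortal"), 6L)
  expect_identical(sum(lines$class == "normal"), 7L)
  expect_true(all(tab$occupied[tab$class == "normal"] == 0))
  agg <- tapply(tab$occupied, tab$site_id, sum)
  expect_true(all(agg >= 2))
  expect_identical(simulateCellLines(n_sites = 20, n_true_candidates = 5, seed = 8)$table,
                   simulateCellLines(n_sites = 20, n_true_candidates = 5, seed = 8)$table)
  expect_error(simulateCellLines(n_sites = 5, n_true_candidates = 9),
               class = "methylscreen_config_error")
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_normal = 0), class = "methylscreen_config_error")
  expect_error(simConfig(missing_rate = 1), class = "methylscreen_config_error")
  expect_error(simConfig(n_sites = 5, n_hyper = 4, n_hypo = 2),
               class = "methylscreen_config_error")
  bad <- defaultSiteParams(23, 16, 7)$normal; bad[1, 1] <- -1
  expect_error(simConfig(beta_params_normal = bad),
               class = "methylscreen_config_error")
  st <- simulateStudy(simConfig(seed = 1, n_sites = 3, n_hyper = 1, n_hypo = 1,
                                n_normal = 5,
                                n_tumor_by_stage = c(adenoma = 2, I = 1, II = 1, III = 1)))
  expect_error(simulateHrmObservations(st, noise_sd = -1),
               class = "methylscreen_config_error")
})
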