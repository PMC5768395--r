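test_that("orientation follows the class separation and ties break to hyper", {
  expect_identical(orientMarker(c(0.8, 0.9), c(0.1, 0.2)), "hyper")
  expect_identical(orientMarker(c(0.1, 0.2), c(0.8, 0.9)), "hypo")
  expect_message(d <- orientMarker(c(0.4, 0.6), c(0.4, 0.6)), "tie")
  expect_identical(d, "hyper")
  expect_identical(orientMarker(c(0.8, 0.9), c(0.1, 0.2), declared = "hypo"), "hypo")
  expect_error(orientMarker(numeric(0), c(0.1)), class = "methylscreen_data_error")
})

test_that("AUC handles separation and fully tied data", {
  st <- aucStats(c(0.9, 0.8), c(0.1, 0.2))
  expect_identical(st$auc, 1)
  expect_identical(st$p_value, 0)
  expect_warning(st0 <- aucStats(c(0.5, 0.5), c(0.5, 0.5)), "tied")
  expect_identical(st0$auc, 0.5)
  expect_identical(st0$p_value, 1)
})

test_that("rank-based AUC equals exhaustive pair counting, with ties", {
  set.seed(101)
  for (r in 1:60) {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    pool <- if (r %% 2) round(runif(40), 1) else runif(40)  # coarse grid forces ties
    pos <- sample(pool, m, replace = TRUE)
    neg <- sample(pool, n, replace = TRUE)
    a <- aucStats(pos, neg, direction = "hyper")$auc
    expect_equal(a, bruteAUC(pos, neg), tolerance = 0)
  }
})

test_that("DeLong AUC standard error and p-value agree with pROC", {
  set.seed(7)
  pos <- rbeta(40, 4, 4); neg <- rbeta(50, 2, 8)
  st <- aucStats(pos, neg, direction = "hyper")
  r <- pROC::roc(controls = neg, cases = pos, direction = "<", quiet = TRUE)
  expect_equal(st$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  expect_equal(st$se^2, as.numeric(pROC::var(r)), tolerance = 1e-10)
})

test_that("orientation invariance: negating a hypo marker changes nothing", {
  set.seed(8)
  pos <- rbeta(30, 2, 10); neg <- rbeta(25, 8, 4)  # tumor-low marker
  a1 <- aucStats(pos, neg, "hypo")
  a2 <- aucStats(-pos, -neg, "hyper")
  expect_equal(a1$auc, a2$auc)
  expect_equal(a1$p_value, a2$p_value)
  s1 <- sensitivityAtSpecificity(pos, neg, "hypo", 0.90, n_boot = 200, seed = 5)
  s2 <- sensitivityAtSpecificity(-pos, -neg, "hyper", 0.90, n_boot = 200, seed = 5)
  expect_equal(s1$point, s2$point)
  expect_equal(c(s1$ci_lo, s1$ci_hi), c(s2$ci_lo, s2$ci_hi))
  expect_equal(s1$threshold, -s2$threshold)
  expect_identical(s1$rule, "<=")
})

test_that("sensitivity point estimate equals the exhaustive midpoint scan", {
  set.seed(33)
  for (r in 1:40) {
    m <- sample(5:10, 1); n <- sample(5:10, 1)
    pool <- round(runif(30), if (r %% 2) 1 else 3)
    pos <- sample(pool, m, replace = TRUE)
    neg <- sample(pool, n, replace = TRUE)
    for (lev in c(0.80, 0.90, 0.95)) {
      got <- sensitivityAtSpecificity(pos, neg, "hyper", lev, n_boot = 0)
      expect_equal(got$point, bruteSensAtSpec(pos, neg, lev), tolerance = 0)
      expect_gte(got$specificity, lev)
    }
  }
})

test_that("perfect separation gives sensitivity 100% with a degenerate CI", {
  s <- sensitivityAtSpecificity(c(0.8, 0.9, 0.85, 0.95, 0.7),
                                c(0.1, 0.2, 0.15, 0.05, 0.12),
                                "hyper", 0.95, n_boot = 200, seed = 1)
  expect_identical(s$point, 1)
  expect_identical(c(s$ci_lo, s$ci_hi), c(1, 1))
  expect_match(formatSensCI(s$point, s$ci_lo, s$ci_hi),
               "^100.00 \\[100.00,100.00\\]$")
})

test_that("sensitivity at 95% specificity never exceeds that at 90%", {
  set.seed(12)
  for (r in 1:20) {
    pos <- rbeta(30, 4, 6); neg <- rbeta(30, 1, 9)
    s95 <- sensitivityAtSpecificity(pos, neg, "hyper", 0.95, n_boot = 0)$point
    s90 <- sensitivityAtSpecificity(pos, neg, "hyper", 0.90, n_boot = 0)$point
    expect_lte(s95, s90)
  }
})

test_that("bootstrap CIs are reproducible under a fixed seed", {
  set.seed(3)
  pos <- rbeta(40, 4, 6); neg <- rbeta(40, 1, 9)
  s1 <- sensitivityAtSpecificity(pos, neg, "hyper", 0.95, n_boot = 300, seed = 11)
  s2 <- sensitivityAtSpecificity(pos, neg, "hyper", 0.95, n_boot = 300, seed = 11)
  expect_identical(c(s1$ci_lo, s1$ci_hi), c(s2$ci_lo, s2$ci_hi))
  s3 <- sensitivityAtSpecificity(pos, neg, "hyper", 0.95, n_boot = 300, seed = 12)
  expect_identical(s1$point, s3$point)  # the point estimate ignores the seed
})

test_that("rocAnalysis produces stage strata with consistent negatives", {
  st <- simulateStudy(simConfig(seed = 14, n_normal = 20,
                                n_tumor_by_stage = c(adenoma = 8, I = 6, II = 6, III = 5),
                                n_sites = 4, n_hyper = 2, n_hypo = 1,
                                missing_rate = 0))
  sl <- siteLevelExperiment(applyQc(st$experiment)$experiment)
  tab <- rocAnalysis(sl, spec_levels = 0.95, n_boot = 20, seed = 2, by_stage = TRUE)
  expect_setequal(unique(tab$stratum), c("adenoma", "I", "II", "III", "total"))
  expect_true(all(tab$n_neg == 20))
  tot <- tab[tab$stratum == "total", ]
  expect_true(all(tot$n_pos == 25))
  expect_true(all(tab$auc >= 0.5 & tab$auc <= 1))
  expect_true(all(tab$sens_95_lo <= tab$sens_95 + 1e-12 &
                    tab$sens_95 <= tab$sens_95_hi + 1e-12))
})
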