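test_that("generation is deterministic given (n, config, seed)", {
  a <- generateCohort(25, seed = 123)
  b <- generateCohort(25, seed = 123)
  expect_identical(a, b)
  c <- generateCohort(25, seed = 124)
  expect_false(identical(a, c))
  expect_error(generateCohort(0), "n must be")
})

test_that("records satisfy the scoring-module invariants", {
  co <- generateCohort(400, seed = 21)
  pos <- co$total > 0
  expect_true(all(co$nprs %in% 0:10))
  expect_true(all(co$index[pos] >= co$total[pos] - 1e-9))
  expect_true(all(co$index[pos] <= 4 * co$total[pos] + 1e-9))
  S <- as.matrix(co[, c("s_low", "s_mod", "s_sev", "s_vsev")])
  expect_equal(rowSums(S), co$total)
  expect_identical(co$color_count, as.integer(rowSums(S > 0)))
  # the drawn stratum is the realised predominant level
  expect_identical(co$predominant[pos], co$group[pos])
  expect_true(all(is.na(co$predominant[!pos])))
  # typology decomposition stays within the painted surface
  expect_equal(co$neuro_cm2 + co$mech_cm2 + co$mixed_cm2, co$total)
})

test_that("the default configuration implies the published overall NPRS", {
  cfg <- cohortConfig()
  # weighted stratum means reproduce the full-cohort mean NPRS
  w <- cfg@groupProbs[2:5] / sum(cfg@groupProbs[2:5])
  expect_equal(sum(w * cfg@groupNprsMean), 6.4, tolerance = 0.01)
  # moment-matched lognormal reproduces the target surface moments exactly
  m <- exp(cfg@surfaceLogMean + cfg@surfaceLogSD^2 / 2)
  v <- (exp(cfg@surfaceLogSD^2) - 1) * m^2
  expect_equal(m, 668.2, tolerance = 1e-6)
  expect_equal(sqrt(v), 837.6, tolerance = 1e-6)
})

test_that("large-sample moments recover the configuration", {
  n <- 1e5
  cfg <- cohortConfig()
  co <- generateCohort(n, cfg, seed = 31)
  # group proportions within 3 binomial SEs
  p_pain <- mean(co$group == "none")
  expect_lt(abs(p_pain - cfg@groupProbs[1]),
            3 * sqrt(cfg@groupProbs[1] * (1 - cfg@groupProbs[1]) / n) + 1e-4)
  lv <- intensityLevels()
  for (k in 1:4) {
    p <- mean(co$group == lv[k])
    expect_lt(abs(p - cfg@groupProbs[k + 1]),
              3 * sqrt(cfg@groupProbs[k + 1] / n) + 2e-3)
  }
  # analytic lognormal mean within 3 percent
  expect_lt(abs(mean(co$total[co$group != "none"]) / 668.2 - 1), 0.03)
  # color-count distribution: multi-color rate within 1 percent
  target_multi <- sum(cfg@colorCountProbs[3:5])
  expect_lt(abs(colorUsageRates(co)$multi_rate - target_multi), 0.01)
  # typology proportions
  pct <- 100 * co$neuro_cm2[co$total > 0] / co$total[co$total > 0]
  expect_lt(abs(mean(pct) - 56.2), 1.5)
})

test_that("stratum NPRS means follow the truncated-normal targets", {
  co <- generateCohort(5e4, seed = 32)
  cfg <- cohortConfig()
  lv <- intensityLevels()
  # oracle: mean of the rounded truncated normal by direct integration
  oracleMean <- function(m, s) {
    k <- 0:10
    lo <- pnorm((pmax(k - 0.5, 0) - m) / s); hi <- pnorm((pmin(k + 0.5, 10) - m) / s)
    z <- pnorm((10 - m) / s) - pnorm((0 - m) / s)
    sum(k * (hi - lo)) / z
  }
  for (k in 1:4) {
    got <- mean(co$nprs[co$group == lv[k]])
    want <- oracleMean(cfg@groupNprsMean[k], cfg@groupNprsSD[k])
    n_k <- sum(co$group == lv[k])
    expect_lt(abs(got - want), 3 * cfg@groupNprsSD[k] / sqrt(n_k) + 0.02,
              label = paste("stratum", lv[k]))
  }
})

test_that("coupling calibration is monotone and hits its target", {
  cfg <- cohortConfig()
  rs <- vapply(c(-0.4, 0, 0.4, 0.8), function(cpl) {
    cfg@coupling <- cpl
    co <- generateCohort(8000, cfg, seed = 41)
    cor(co$nprs, co$index)
  }, 0)
  expect_true(all(diff(rs) > 0))

  cal <- calibrateCoupling(0, config = cfg, tol = 0.015, seed = 42, n = 6000)
  co <- generateCohort(6000, cal, seed = 42)
  expect_lt(abs(cor(co$nprs, co$index)), 0.015)
  expect_error(calibrateCoupling(0.99, config = cfg, tol = 0.01, seed = 43,
                                 n = 3000), "unreachable")

  # the stored default reproduces its target on a fresh seed within 2x tol
  co2 <- generateCohort(20000, cohortConfig(), seed = 77)
  expect_lt(abs(cor(co2$nprs, co2$index) - 0.14), 0.02)
})

test_that("synthesised drawings measure back to their record", {
  av <- coarseAvatar()            # 5 mm pixels keep the raster small
  co <- generateCohort(40, seed = 51)
  picks <- order(co$total)[c(10, 25, 38)]
  for (i in picks) {
    rec <- co[i, ]
    d <- generateDrawing(rec, av, seed = i)
    ss <- measureSurfaces(d, av)
    want <- as.numeric(rec[c("s_low", "s_mod", "s_sev", "s_vsev")])
    got <- unname(surfaces(ss))
    expect_true(all(abs(got - want) <= pmax(0.02 * want, pixelScale(av))),
                label = sprintf("record %d intensity surfaces", i))
    ty <- measureTypology(d, av)
    wantT <- as.numeric(rec[c("neuro_cm2", "mech_cm2", "mixed_cm2")])
    gotT <- c(ty@neuropathic, ty@mechanical, ty@mixed)
    expect_true(all(abs(gotT - wantT) <= pmax(0.02 * wantT, 2 * pixelScale(av))),
                label = sprintf("record %d typology surfaces", i))
    # resolved intensity layers stay disjoint
    res <- resolveIntensityLayers(d@intensityMasks)
    expect_lte(max(Reduce(`+`, lapply(res, function(m) m * 1L))), 1L)
  }
})

test_that("zero targets give empty layers and infeasible targets error", {
  av <- coarseAvatar()
  rec <- list(s_low = 0, s_mod = 0, s_sev = 0, s_vsev = 50,
              neuro_cm2 = 50, mech_cm2 = 0, mixed_cm2 = 0)
  d <- generateDrawing(rec, av, seed = 1)
  expect_identical(sum(d@intensityMasks$low), 0L)
  expect_identical(sum(d@typologyMasks$nociceptive), 0L)

  bad <- list(s_low = 0, s_mod = 0, s_sev = 0, s_vsev = 1e6,
              neuro_cm2 = 1e6, mech_cm2 = 0, mixed_cm2 = 0)
  expect_error(generateDrawing(bad, av, seed = 1), "infeasible")
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohortConfig(coupling = 1.2), "coupling")
  cfg <- cohortConfig()
  cfg@groupProbs <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  expect_error(generateCohort(10, cfg, seed = 1), "invalid generator config")
})
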