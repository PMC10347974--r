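test_that("Bliss and HSA expectations follow their closed forms", {
  expect_equal(blissExpected(0.5, 0.5), 0.25)
  expect_equal(blissExpected(1.0, 0.7), 0.7)
  expect_equal(blissExpected(0.0, 0.4), 0.0)
  expect_equal(hsaExpected(0.3, 0.7), 0.3)
  expect_equal(hsaExpected(0.4, 0.4), 0.4)
  expect_equal(hsaExpected(1.0, 0.2), 0.2)
  expect_error(blissExpected(-0.1, 0.5), ">= 0")
  expect_warning(b <- blissExpected(1.2, 0.5), "clamped")
  expect_equal(b, 0.5)
})

test_that("HSA expectation dominates Bliss on the unit square", {
  g <- expand.grid(va = seq(0, 1, 0.05), vb = seq(0, 1, 0.05))
  expect_true(all(hsaExpected(g$va, g$vb) >= blissExpected(g$va, g$vb)))
})

test_that("Loewe expectation reduces to monotherapy on the edges", {
  fa <- mkHillFit(1, 0.05, 0.4, 1.3)
  fb <- mkHillFit(1, 0.15, 1.2, 0.9)
  expect_equal(as.numeric(loeweExpected(fa, fb, 0.7, 0)),
               predict(fa, 0.7), tolerance = 1e-12)
  expect_equal(as.numeric(loeweExpected(fa, fb, 0, 2.1)),
               predict(fb, 2.1), tolerance = 1e-12)
  expect_equal(as.numeric(loeweExpected(fa, fa, 0, 0)), 1)
})

test_that("a drug combined with itself is additive under Loewe (sham)", {
  f <- mkHillFit(1, 0.1, 0.6, 1.7)
  for (doses in list(c(0.2, 0.4), c(1, 1), c(0.05, 2))) {
    v <- loeweExpected(f, f, doses[1], doses[2])
    expect_equal(as.numeric(v), predict(f, sum(doses)), tolerance = 1e-7)
  }
})

test_that("the symmetric two-drug case matches the closed form v = 1/3", {
  fa <- mkHillFit(1, 0, 1, 1)
  fb <- mkHillFit(1, 0, 2, 1)
  expect_equal(as.numeric(loeweExpected(fa, fb, 1, 2)), 1 / 3,
               tolerance = 1e-7)
})

test_that("unreachable effect levels fall back to HSA and are flagged", {
  fa <- mkHillFit(1, 0.6, 0.5, 1)   # floor at 0.6
  fb <- mkHillFit(1, 0.0, 0.5, 1)
  v <- loeweExpected(fa, fb, 50, 50)  # deep effect demanded
  expect_true(attr(v, "fallback")[1])
  expect_equal(as.numeric(v),
               min(predict(fa, 50), predict(fb, 50)), tolerance = 1e-9)
  flat <- new("HillFit", e0 = 1, einf = 1, converged = TRUE,
              identifiable = FALSE)
  expect_error(loeweExpected(flat, fb, 1, 1), "identifiable")
})

test_that("combination index reduces to 1 for a single agent at its own effect", {
  fa <- mkHillFit(1, 0, 0.8, 1.6)
  fb <- mkHillFit(1, 0, 2.0, 0.9)
  d <- 0.37
  fa_obs <- faFromViability(fa, predict(fa, d))
  ci <- chouTalalayCI(fa, fb, d, 0, cbind(fa_obs, fa_obs))
  expect_equal(as.numeric(ci), 1, tolerance = 1e-9)
})

test_that("combination index matches the non-exclusive formula and is monotone", {
  f <- mkHillFit(1, 0, 1, 1)  # median-effect Dm = 1, m = 1
  expect_equal(as.numeric(chouTalalayCI(f, f, 0.5, 0.5, 0.5)), 1.25,
               tolerance = 1e-12)
  # stronger observed effect at the same doses => smaller CI
  ci_lo <- chouTalalayCI(f, f, 0.5, 0.5, 0.5)
  ci_hi <- chouTalalayCI(f, f, 0.5, 0.5, 0.8)
  expect_lt(as.numeric(ci_hi), as.numeric(ci_lo))
  # out-of-range affected fractions are clamped and recorded
  ci <- chouTalalayCI(f, f, 0.5, 0.5, 1.2)
  expect_true(attr(ci, "clamped")[1])
})

test_that("score sums decompose and match a brute-force double loop", {
  fa <- mkHillFit(1, 0.1, 0.3, 1.4)
  fb <- mkHillFit(1, 0.2, 0.9, 1.1)
  set.seed(5)
  m <- simMatrix(fa, fb, noise = 0.05)
  expected <- matrix(runif(36, 0.2, 1), 6, 6)
  sc <- scoreMatrix(m, expected, model = "custom")
  expect_equal(sc$scoreSum, bruteScoreSum(m, expected), tolerance = 1e-9)
  expect_equal(sc$scoreSum, sc$scoreSynergy + sc$scoreAntagonism,
               tolerance = 1e-9)
  expect_gte(sc$scoreSynergy, 0)
  expect_lte(sc$scoreAntagonism, 0)
  expect_error(scoreMatrix(m, matrix(0.5, 3, 3)), "shape")
})

test_that("zero and uniform deviations give exact score sums", {
  fa <- mkHillFit(1, 0.1, 0.3, 1.4)
  fb <- mkHillFit(1, 0.2, 0.9, 1.1)
  m <- simMatrix(fa, fb, noise = 0)
  obs <- comboWells(m)
  expect_equal(scoreMatrix(m, obs)$scoreSum, 0)
  expect_equal(scoreMatrix(m, obs + 0.01)$scoreSum, 36, tolerance = 1e-9)
})

test_that("minimum viability scans the combination block only", {
  fa <- mkHillFit(1, 0.1, 0.3, 1.4)
  fb <- mkHillFit(1, 0.2, 0.9, 1.1)
  m <- simMatrix(fa, fb, noise = 0)
  expect_equal(minViability(m), min(comboWells(m)), tolerance = 1e-12)
  # uniform surface
  wells <- expand.grid(doseA = c(0, 1, 3, 9), doseB = c(0, 1, 3, 9),
                       replicate = 1)
  wells$viability <- 1
  m1 <- assembleMatrix(wells, dilutionFactor = 3)
  expect_equal(minViability(m1), 1)
  wells$viability[wells$doseA == 9 & wells$doseB == 9] <- 0.05
  m2 <- assembleMatrix(wells, dilutionFactor = 3)
  expect_equal(minViability(m2), 0.05)
})

test_that("per-model scoring of Bliss-true data is null for Bliss", {
  fa <- mkHillFit(1, 0.15, 0.3, 1.4)
  fb <- mkHillFit(1, 0.25, 0.9, 1.1)
  m <- simMatrix(fa, fb, block = "bliss", noise = 0)
  res <- scoreCombination(m, fa, fb)
  expect_setequal(res$model, c("loewe", "hsa", "bliss", "chou_talalay",
                               "min_viability"))
  expect_equal(res$scoreSum[res$model == "bliss"], 0, tolerance = 1e-9)
  # HSA score dominates Bliss well-wise, hence in sum
  expect_gte(res$scoreSum[res$model == "hsa"],
             res$scoreSum[res$model == "bliss"])
})
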