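test_that("dose ladders follow the serial dilution design", {
  expect_equal(buildDoseLadder(1, 3, 6),
               c(1, 0.3333333, 0.1111111, 0.03703704, 0.01234568,
                 0.004115226),
               tolerance = 1e-6)
  expect_equal(buildDoseLadder(5, 3, 1), 5)
  expect_equal(buildDoseLadder(1, 2, 3), c(1, 0.5, 0.25))
  expect_error(buildDoseLadder(1, 1, 6), "factor")
  expect_error(buildDoseLadder(1, 3, 0), "n")
  expect_error(buildDoseLadder(-1, 3, 6), "top")
})

test_that("the dilution factor is recovered exactly in log space", {
  for (f in c(2, 3, 10, 3.5)) {
    lad <- buildDoseLadder(runif(1, 0.5, 20), f, 6)
    expect_equal(inferDilutionFactor(lad), f, tolerance = 1e-12)
  }
})

test_that("DMSO normalization is linear and guarded", {
  ctrl <- c(9e5, 1.1e6)
  expect_equal(normalizeToControl(1e6, ctrl), 1.0)
  expect_equal(normalizeToControl(0, ctrl), 0.0)
  expect_equal(normalizeToControl(matrix(2e6, 2, 2), ctrl),
               matrix(2, 2, 2))
  # idempotence: re-normalizing an already-normalized grid against unit
  # controls is the identity
  g <- matrix(runif(9), 3, 3)
  expect_equal(normalizeToControl(g, c(1, 1)), g)
  expect_error(normalizeToControl(1, c(1e6)), "2 control wells")
  expect_error(normalizeToControl(1, c(0, 0)), "non-positive")
})

test_that("complete plates assemble into a replicate surface", {
  fa <- mkHillFit(1, 0.1, 0.3, 1.5)
  fb <- mkHillFit(1, 0.2, 0.8, 1.0)
  m <- simMatrix(fa, fb, nrep = 2)
  expect_s4_class(m, "DoseMatrix")
  expect_identical(dim(m@viability), c(7L, 7L, 2L))
  expect_equal(length(m@dosesA), 6L)
  expect_true(all(diff(m@dosesA) < 0))
  expect_equal(replicateMeans(m)[1, 1], 1, tolerance = 1e-9)
})

test_that("duplicate wells, swapped axes and excess missingness error", {
  wells <- expand.grid(doseA = c(0, 1, 3), doseB = c(0, 2, 4),
                       replicate = 1)
  wells$viability <- 1
  expect_error(assembleMatrix(rbind(wells, wells[1, ]),
                              dilutionFactor = NA), "duplicate")
  expect_error(
    assembleMatrix(wells, dosesA = c(4, 2), dosesB = c(3, 1),
                   dilutionFactor = NA),
    "swapped")
  big <- expand.grid(doseA = c(0, 1, 3, 9), doseB = c(0, 1, 3, 9),
                     replicate = 1)
  big$viability <- 1
  # drop 5 of 16 wells (every dose still represented on the edges)
  gone <- big$doseA > 0 & big$doseB > 0 &
    !(big$doseA == 9 & big$doseB %in% c(1, 3)) &
    !(big$doseA %in% c(1, 3) & big$doseB == 9)
  expect_error(
    assembleMatrix(big[!gone, ], dosesA = c(9, 3, 1), dosesB = c(9, 3, 1),
                   dilutionFactor = 3),
    "missing")
})

test_that("masked wells are skipped with well-count bookkeeping", {
  fa <- mkHillFit(1, 0.1, 0.3, 1.5)
  fb <- mkHillFit(1, 0.2, 0.8, 1.0)
  full <- simMatrix(fa, fb, nrep = 1)
  # drop one interior combination well (both its replicates)
  wells <- tidyViability(full)
  drop <- wells$dose_a_um > 0 & wells$dose_b_um > 0 &
    abs(wells$dose_a_um - max(wells$dose_a_um)) < 1e-12 &
    abs(wells$dose_b_um - max(wells$dose_b_um)) < 1e-12
  w2 <- data.frame(doseA = wells$dose_a_um[!drop],
                   doseB = wells$dose_b_um[!drop],
                   replicate = wells$replicate[!drop],
                   viability = wells$viability[!drop])
  masked <- assembleMatrix(w2, dosesA = full@dosesA, dosesB = full@dosesB,
                           dilutionFactor = 3)
  expect_identical(sum(is.na(masked@viability)), 1L)

  expected <- matrix(0.5, 6, 6)
  sc <- scoreMatrix(masked, expected, model = "custom")
  expect_identical(sc$nWells, 35L)
  expect_equal(sc$scoreSum, bruteScoreSum(masked, expected),
               tolerance = 1e-9)
  expect_error(assembleMatrix(w2, dosesA = full@dosesA,
                              dosesB = full@dosesB, dilutionFactor = 3,
                              missingPolicy = "fail"), "policy")
})

test_that("off-unity control wells trigger a warning", {
  wells <- expand.grid(doseA = c(0, 1, 3), doseB = c(0, 2, 4),
                       replicate = 1)
  wells$viability <- 1
  wells$viability[wells$doseA == 0 & wells$doseB == 0] <- 1.3
  expect_warning(assembleMatrix(wells, dilutionFactor = NA), "control")
})

test_that("plate maps round-trip through CSV and assemble per plate", {
  cfg <- synthConfig(nCombinations = 2, nCultures = 2, nSynergistic = 0,
                     interactionDelta = 0, noiseSd = 0.02, seed = 3)
  scr <- simulateScreen(cfg)
  path <- tempfile(fileext = ".csv")
  writePlateMap(plateMap(scr), path)
  pm <- readPlateMap(path)
  expect_equal(nrow(pm), nrow(plateMap(scr)))
  mats <- assembleScreen(pm, dilutionFactor = 3)
  expect_length(mats, 4L)
  expect_s4_class(mats[[1]], "DoseMatrix")
  expect_identical(dim(mats[[1]]@viability), c(7L, 7L, 2L))
})
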