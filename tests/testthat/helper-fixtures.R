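# shared fixtures: analytic Hill fits and matrices built from known truth

mkHillFit <- function(e0 = 1, einf = 0, ec50 = 1, h = 1,
                      drug = "drug", culture = "culture") {
  new("HillFit", drug = drug, culture = culture, e0 = e0, einf = einf,
      ec50 = ec50, h = h, rss = 0, nPoints = 0L,
      converged = TRUE, identifiable = TRUE, doseRange = c(ec50 / 100, ec50 * 100))
}

# build a DoseMatrix whose combination block follows a chosen reference
# truth (Bliss product or Loewe surface) with an optional injected excess
# and replicate noise
simMatrix <- function(fitA, fitB, block = c("bliss", "loewe"),
                      delta = 0, weight = NULL, noise = 0, nrep = 2L,
                      nLevels = 6L, factor = 3,
                      drugA = "A", drugB = "B", culture = "c1",
                      topA = NULL, topB = NULL, dropWells = NULL) {
  block <- match.arg(block)
  if (is.null(topA)) topA <- absoluteIC50(fitA)
  if (is.null(topB)) topB <- absoluteIC50(fitB)
  axA <- c(0, rev(buildDoseLadder(topA, factor, nLevels)))
  axB <- c(0, rev(buildDoseLadder(topB, factor, nLevels)))
  va <- predict(fitA, axA)
  vb <- predict(fitB, axB)
  vtrue <- if (block == "bliss") outer(va, vb) else
    matrix(loeweExpected(fitA, fitB, rep(axA, length(axB)),
                         rep(axB, each = length(axA))),
           nrow = length(axA))
  if (delta != 0) {
    w <- if (is.null(weight)) matrix(1, nLevels, nLevels) else weight
    vtrue[-1L, -1L] <- pmax(vtrue[-1L, -1L] - delta * w, 0)
  }
  g <- expand.grid(ia = seq_along(axA), ib = seq_along(axB),
                   replicate = seq_len(nrep))
  g$doseA <- axA[g$ia]; g$doseB <- axB[g$ib]
  g$viability <- pmax(vtrue[cbind(g$ia, g$ib)] +
                        stats::rnorm(nrow(g), 0, noise), 0)
  wells <- g[, c("doseA", "doseB", "replicate", "viability")]
  if (!is.null(dropWells))
    wells <- wells[-dropWells, , drop = FALSE]
  suppressWarnings(assembleMatrix(wells, culture = culture, drugA = drugA,
                                  drugB = drugB, dilutionFactor = factor))
}

# independent brute-force oracle for the summed score: explicit double
# loop over the nonzero-dose wells on replicate means
bruteScoreSum <- function(mat, expected) {
  nA <- length(mat@dosesA); nB <- length(mat@dosesB)
  total <- 0
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      reps <- mat@viability[i + 1L, j + 1L, ]
      if (all(is.na(reps))) next
      total <- total + (expected[i, j] - mean(reps, na.rm = TRUE)) * 100
    }
  }
  total
}
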