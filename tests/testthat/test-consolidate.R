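# small handmade panel: 20 combinations x 2 cultures; the last five
# combinations are clearly synergistic and tumoricidal
mkToyPanel <- function() {
  combos <- sprintf("c%02d", 1:20)
  cultures <- c("g1", "g2")
  metrics <- c("loewe", "hsa", "bliss", "min_viability")
  arr <- array(NA_real_, dim = c(20, 2, 4),
               dimnames = list(combos, cultures, metrics))
  set.seed(99)
  base <- c(rnorm(15, 0, 6), runif(5, 120, 150))
  for (m in c("loewe", "hsa", "bliss")) {
    arr[, 1, m] <- base + rnorm(20, 0, 2)
    arr[, 2, m] <- base + rnorm(20, 0, 2)
  }
  mv <- c(runif(15, 0.6, 0.9), runif(5, 0.03, 0.15))
  arr[, 1, "min_viability"] <- mv + runif(20, -0.02, 0.02)
  arr[, 2, "min_viability"] <- mv + runif(20, -0.02, 0.02)
  new("MetricPanel", combinations = combos, cultures = cultures,
      metrics = metrics, values = arr)
}

toySynergistic <- sprintf("c%02d", 16:20)

test_that("z-scaling standardizes each metric over all entries", {
  p <- zscale(mkToyPanel())
  z <- panelZ(p)
  for (k in seq_along(p@metrics)) {
    x <- z[, , k]
    expect_equal(mean(x, na.rm = TRUE), 0, tolerance = 1e-9)
    expect_equal(sd(as.vector(x), na.rm = TRUE), 1, tolerance = 1e-9)
  }
  # idempotence: an already-standardized metric is unchanged
  p2 <- initialize(p, values = z)
  expect_equal(panelZ(zscale(p2)), z, tolerance = 1e-12)
})

test_that("the two-point sample-SD case gives -/+ 0.7071", {
  arr <- array(c(0, 2), dim = c(2, 1, 1),
               dimnames = list(c("a", "b"), "g", "m"))
  p <- new("MetricPanel", combinations = c("a", "b"), cultures = "g",
           metrics = "m", values = arr)
  expect_equal(as.vector(panelZ(zscale(p))),
               c(-0.7071068, 0.7071068), tolerance = 1e-6)
})

test_that("zero-variance metrics error by name; missingness propagates", {
  p <- mkToyPanel()
  p@values[, , "hsa"] <- 3
  expect_error(zscale(p), "hsa")
  p <- mkToyPanel()
  p@values[2, 1, "loewe"] <- NA
  z <- panelZ(zscale(p))
  expect_true(is.na(z[2, 1, "loewe"]))
  expect_false(any(z[, , "loewe"] == 0 & is.na(p@values[, , "loewe"]),
                   na.rm = TRUE))
})

test_that("mixture clustering recovers well-separated blobs deterministically", {
  b <- makeBlobs(3, 30, sep = 6, seed = 2)
  g1 <- gmmCluster(b$features, seed = 9)
  g2 <- gmmCluster(b$features, seed = 9)
  expect_identical(g1@k, 3L)
  expect_identical(clusterLabels(g1), clusterLabels(g2))
  expect_gte(mclust::adjustedRandIndex(clusterLabels(g1), b$labels), 0.9)
  # recovered means close to generating centers
  perm <- apply(g1@characterization, 1, function(m)
    which.min(colSums((t(rowsum(b$features, b$labels) / 30) - m)^2)))
  expect_setequal(unname(perm), 1:3)
  expect_equal(sum(g1@weights), 1, tolerance = 1e-9)
})

test_that("degenerate clustering inputs collapse to one cluster", {
  feat <- matrix(1, 10, 3, dimnames = list(sprintf("c%d", 1:10), NULL))
  g <- gmmCluster(feat, seed = 1)
  expect_identical(g@k, 1L)
  expect_true(all(clusterLabels(g) == 1L))
  km <- kmeansValidate(feat, k = 1, seed = 1)
  expect_identical(km@k, 1L)
  expect_error(gmmCluster(matrix(rnorm(8), 4, 2), kRange = 1:9), "at least")
})

test_that("K-means validation recovers blobs and is seed-deterministic", {
  b <- makeBlobs(3, 30, sep = 6, seed = 2)
  k1 <- kmeansValidate(b$features, k = 3, seed = 5)
  k2 <- kmeansValidate(b$features, k = 3, seed = 5)
  expect_identical(clusterLabels(k1), clusterLabels(k2))
  expect_gte(mclust::adjustedRandIndex(clusterLabels(k1), b$labels), 0.9)
})

test_that("consistent-synergy selection finds the synergy+kill cluster", {
  p <- zscale(mkToyPanel())
  feat <- panelSummary(p)[, c("loewe", "hsa", "bliss", "min_viability")]
  g <- gmmCluster(feat, kRange = 1:5, seed = 3)
  sel <- selectConsistent(g, p, validation = NULL)
  expect_setequal(sel, toySynergistic)
  # selection is a subset of one GMM cluster
  lab <- clusterLabels(g)
  expect_length(unique(lab[sel]), 1L)

  # intersection with a validation clustering that splits c20 away
  vlab <- stats::setNames(c(rep(1L, 15), rep(2L, 4), 3L), p@combinations)
  sel2 <- selectConsistent(g, p, validation = vlab)
  expect_true(all(sel2 %in% sel))
})

test_that("selection is invariant to cluster relabeling and affine rescaling", {
  p <- zscale(mkToyPanel())
  feat <- panelSummary(p)[, c("loewe", "hsa", "bliss", "min_viability")]
  g <- gmmCluster(feat, kRange = 1:5, seed = 3)
  sel <- selectConsistent(g, p, validation = NULL)
  # permute label ids: the selection depends on characterization only
  gPerm <- g
  gPerm@labels <- stats::setNames((g@labels %% g@k) + 1L, names(g@labels))
  expect_setequal(selectConsistent(gPerm, p, validation = NULL), sel)
  # per-metric affine rescaling of raw values is absorbed by z-scaling
  raw <- mkToyPanel()
  scales <- c(3, 0.5, 10, 7); shifts <- c(-2, 5, 100, 0.1)
  for (k in 1:4) raw@values[, , k] <- raw@values[, , k] * scales[k] + shifts[k]
  p2 <- zscale(raw)
  expect_equal(panelZ(p2), panelZ(p), tolerance = 1e-9)
  g2 <- gmmCluster(panelSummary(p2)[, c("loewe", "hsa", "bliss",
                                        "min_viability")],
                   kRange = 1:5, seed = 3)
  expect_setequal(selectConsistent(g2, p2, validation = NULL), sel)
})

test_that("a panel without synergy yields an empty selection with warning", {
  combos <- sprintf("c%02d", 1:20)
  set.seed(1)
  arr <- array(rnorm(20 * 3 * 4), dim = c(20, 3, 4),
               dimnames = list(combos, c("g1", "g2", "g3"),
                               c("loewe", "hsa", "bliss", "min_viability")))
  p <- zscale(new("MetricPanel", combinations = combos,
                  cultures = c("g1", "g2", "g3"),
                  metrics = c("loewe", "hsa", "bliss", "min_viability"),
                  values = arr))
  g <- gmmCluster(panelSummary(p), kRange = 1:5, seed = 1)
  expect_warning(sel <- selectConsistent(g, p, validation = NULL),
                 "no cluster")
  expect_length(sel, 0L)
})

test_that("replicate concordance estimates correlation honestly", {
  expect_equal(replicateConcordance(1:10, 1:10)$estimate, 1)
  expect_error(replicateConcordance(1:2, 1:2), "3 complete pairs")
  set.seed(8)
  n <- 43; rho <- 0.8
  est <- replicate(500, {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    replicateConcordance(x, y)$estimate
  })
  expect_gt(mean(est), 0.75)
  expect_lt(mean(est), 0.85)
  nullR <- replicate(500, replicateConcordance(rnorm(n), rnorm(n))$estimate)
  # null sampling distribution of r at n = 43: P(|r| < 0.3) via the exact
  # t transform r = t / sqrt(t^2 + n - 2)
  tcrit <- 0.3 * sqrt(n - 2) / sqrt(1 - 0.3^2)
  pExact <- 2 * pt(tcrit, n - 2) - 1
  expect_lt(abs(mean(abs(nullR) < 0.3) - pExact), 0.03)
  sp <- replicateConcordance(1:10, (1:10)^3, method = "spearman")
  expect_equal(sp$estimate, 1)
})
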