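#' Build the combinations x cultures x metrics panel
#'
#' Reshapes a tidy score table (rbind-ed [scoreCombination()] output over
#' a whole screen) into the clustering substrate. For each reference model
#' both the signed sum (\code{scoreSum}) and the synergy-only partial sum
#' (\code{scoreSynergy}, suffix \code{"_syn"}) are carried as metrics;
#' \code{min_viability} carries the minimum-viability fraction. Missing
#' (combination, culture) scores propagate as \code{NA}, never as 0.
#'
#' @param results data.frame with columns \code{combination},
#'   \code{culture}, \code{model}, \code{scoreSum}, \code{scoreSynergy},
#'   \code{minViability}.
#' @return a [MetricPanel-class] (raw values only; run [zscale()] next).
#' @export
buildMetricPanel <- function(results) {
  stopifnot(all(c("combination", "culture", "model", "scoreSum",
                  "scoreSynergy", "minViability") %in% names(results)))
  combos <- unique(results$combination)
  cultures <- unique(results$culture)
  scoreModels <- setdiff(unique(results$model), "min_viability")
  metrics <- c(scoreModels, paste0(scoreModels, "_syn"), "min_viability")
  arr <- array(NA_real_,
               dim = c(length(combos), length(cultures), length(metrics)),
               dimnames = list(combination = combos, culture = cultures,
                               metric = metrics))
  ic <- match(results$combination, combos)
  il <- match(results$culture, cultures)
  for (m in scoreModels) {
    sel <- results$model == m
    arr[cbind(ic[sel], il[sel], match(m, metrics))] <- results$scoreSum[sel]
    arr[cbind(ic[sel], il[sel], match(paste0(m, "_syn"), metrics))] <-
      results$scoreSynergy[sel]
  }
  selv <- results$model == if ("min_viability" %in% results$model)
    "min_viability" else results$model[1L]
  arr[cbind(ic[selv], il[selv], match("min_viability", metrics))] <-
    results$minViability[selv]
  new("MetricPanel", combinations = combos, cultures = cultures,
      metrics = metrics, values = arr)
}

#' z-scale a metric panel
#'
#' Standardizes each metric to mean 0, sample SD 1 (\eqn{n-1} denominator)
#' over all non-missing combination x culture entries, so metrics with
#' heterogeneous numerical amplitudes (summed percentage points vs
#' viability fractions) become commensurable for clustering. Also fills
#' the per-combination summary: the median z over cultures per metric.
#'
#' @param panel a [MetricPanel-class] with raw values.
#' @return the panel with \code{zvalues} and \code{summary} filled.
#' @export
zscale <- function(panel) {
  stopifnot(is(panel, "MetricPanel"))
  z <- panel@values
  for (k in seq_along(panel@metrics)) {
    x <- panel@values[, , k]
    ok <- !is.na(x)
    if (sum(ok) < 2L)
      stop(sprintf("metric '%s' has fewer than 2 non-missing values",
                   panel@metrics[k]))
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0)
      stop(sprintf("metric '%s' has zero variance; cannot z-scale",
                   panel@metrics[k]))
    z[, , k] <- (x - mean(x[ok])) / s
  }
  summ <- apply(z, c(1L, 3L), function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })
  dimnames(summ) <- list(panel@combinations, panel@metrics)
  initialize(panel, zvalues = z, summary = summ)
}

# per-metric median imputation for clustering inputs; returns the matrix
# plus the number of imputed cells
imputeFeatures <- function(features) {
  nimp <- 0L
  for (j in seq_len(ncol(features))) {
    na <- is.na(features[, j])
    if (any(na)) {
      features[na, j] <- stats::median(features[, j], na.rm = TRUE)
      nimp <- nimp + sum(na)
    }
  }
  list(features = features, nImputed = nimp)
}

#' Gaussian-mixture model-based clustering with BIC selection
#'
#' Fits Gaussian mixtures by EM for every k in \code{kRange} over four
#' covariance families (diagonal and full, shared and per-cluster:
#' mclust's EEI, VVI, EEE, VVV) and keeps the model with the best BIC.
#' The \code{bic} reported follows the lower-is-better convention
#' \eqn{-2\log L + p \log n}. Missing features are imputed with the
#' per-metric median (count recorded). Deterministic given the seed.
#'
#' @param features numeric matrix, combinations x features (rownames =
#'   combination ids).
#' @param kRange candidate cluster counts (default 1..9), truncated to
#'   at most \code{nrow(features) - 1}.
#' @param nRestarts recorded for the K-means companion; the mixture EM uses
#'   mclust's deterministic model-based hierarchical initialization.
#' @param seed random seed (set before fitting, recorded in the result).
#' @return a [ClusterModel-class].
#' @importFrom mclust Mclust mclustBIC
#' @export
gmmCluster <- function(features, kRange = 1:9, nRestarts = 10L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < max(kRange) + 1L)
    stop("need at least max(kRange) + 1 combinations")
  imp <- imputeFeatures(features)
  features <- imp$features
  kRange <- intersect(kRange, seq_len(max(1L, n - 1L)))

  if (all(apply(features, 2L, function(x) diff(range(x)) == 0))) {
    # degenerate: all points identical
    return(new("ClusterModel", k = 1L,
               labels = stats::setNames(rep(1L, n), rownames(features)),
               means = matrix(features[1L, ], nrow = 1L,
                              dimnames = list(NULL, colnames(features))),
               family = "degenerate", weights = 1,
               bic = NA_real_, bicTable = matrix(NA_real_, 0, 0),
               seed = as.integer(seed),
               characterization = matrix(features[1L, ], nrow = 1L,
                                         dimnames = list(NULL, colnames(features))),
               method = "gmm"))
  }

  set.seed(seed)
  fams <- c("EEI", "VVI", "EEE", "VVV")
  fit <- mclust::Mclust(features, G = kRange, modelNames = fams,
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fitting failed for every (k, family)")
  # mclust maximizes 2*logLik - p*log(n); negate for lower-is-better BIC
  bicTab <- -fit$BIC
  class(bicTab) <- "matrix"
  labels <- as.integer(fit$classification)
  names(labels) <- rownames(features)
  mu <- t(fit$parameters$mean)
  colnames(mu) <- colnames(features)
  new("ClusterModel", k = as.integer(fit$G), labels = labels, means = mu,
      family = fit$modelName, weights = fit$parameters$pro,
      bic = -as.numeric(fit$bic), bicTable = bicTab,
      seed = as.integer(seed),
      characterization = characterizeClusters(labels, features),
      method = "gmm")
}

# per-cluster median of each feature
characterizeClusters <- function(labels, features) {
  k <- max(labels)
  out <- matrix(NA_real_, k, ncol(features),
                dimnames = list(seq_len(k), colnames(features)))
  for (g in seq_len(k))
    out[g, ] <- apply(features[labels == g, , drop = FALSE], 2L,
                      stats::median, na.rm = TRUE)
  out
}

#' K-means validation clustering
#'
#' The synergy-only validation analysis: K-means on the synergy-only
#' metric features (Loewe, HSA, Bliss, Chou-Talalay positive partial sums
#' plus minimum viability), with multiple random restarts. Deterministic
#' given the seed.
#'
#' @param features combinations x features matrix.
#' @param k cluster count.
#' @param nRestarts number of random starts (default 10).
#' @param seed random seed.
#' @return a [ClusterModel-class] with \code{method = "kmeans"}.
#' @export
kmeansValidate <- function(features, k, nRestarts = 10L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k + 1L) stop("need at least k + 1 combinations")
  features <- imputeFeatures(features)$features
  k <- as.integer(k)
  if (k == 1L || all(apply(features, 2L, function(x) diff(range(x)) == 0))) {
    labels <- stats::setNames(rep(1L, n), rownames(features))
    return(new("ClusterModel", k = 1L, labels = labels,
               means = matrix(colMeans(features), nrow = 1L,
                              dimnames = list(NULL, colnames(features))),
               family = "kmeans", weights = 1, bic = NA_real_,
               bicTable = matrix(NA_real_, 0, 0), seed = as.integer(seed),
               characterization = characterizeClusters(labels, features),
               method = "kmeans"))
  }
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = nRestarts)
  labels <- stats::setNames(as.integer(km$cluster), rownames(features))
  new("ClusterModel", k = k, labels = labels, means = km$centers,
      family = "kmeans", weights = as.numeric(km$size) / n,
      bic = NA_real_, bicTable = matrix(NA_real_, 0, 0),
      seed = as.integer(seed),
      characterization = characterizeClusters(labels, features),
      method = "kmeans")
}

# identify the "synergy with viability loss" cluster from a label vector
# and the z-summary matrix; returns member ids or character(0)
synergyCluster <- function(labels, summary, synergyMetrics, viabilityMetric,
                           margin) {
  synergyMetrics <- intersect(synergyMetrics, colnames(summary))
  if (!length(synergyMetrics)) stop("no synergy metrics found in the panel")
  k <- max(labels)
  synZ <- viabZ <- rep(NA_real_, k)
  for (g in seq_len(k)) {
    members <- names(labels)[labels == g]
    block <- summary[members, synergyMetrics, drop = FALSE]
    synZ[g] <- stats::median(block, na.rm = TRUE)
    viabZ[g] <- stats::median(summary[members, viabilityMetric],
                              na.rm = TRUE)
  }
  qualifies <- !is.na(synZ) & synZ > margin & !is.na(viabZ) & viabZ < 0
  if (!any(qualifies)) return(character(0))
  win <- which(qualifies)[which.max(synZ[qualifies])]
  names(labels)[labels == win]
}

#' Select consistently synergistic combinations
#'
#' Concretizes "consistent synergy in both analyses": in the mixture-model
#' clustering, the \emph{synergy with viability loss} cluster is the one
#' maximizing the median z over the signed synergy metrics (Loewe, HSA,
#' Bliss) subject to (i) a median minimum-viability z below 0 (stronger
#' kill than the panel average) and (ii) a median synergy z above
#' \code{margin} (so a structureless single-cluster fit never qualifies).
#' The analogous cluster is found in the K-means synergy-only validation
#' (metrics \code{*_syn} + minimum viability), and the returned set is the
#' intersection of the two member sets.
#'
#' @param model [ClusterModel-class] from [gmmCluster()].
#' @param panel a z-scaled [MetricPanel-class].
#' @param validation [ClusterModel-class] from [kmeansValidate()], or a
#'   named label vector; \code{NULL} skips the intersection (GMM only).
#' @param synergyMetrics metrics characterizing synergy in the primary
#'   analysis.
#' @param viabilityMetric the tumoricidal metric (z must be negative).
#' @param margin minimum median synergy z of a qualifying cluster
#'   (default 0.5).
#' @return character vector of selected combination ids (possibly empty,
#'   with a warning when no cluster qualifies).
#' @export
selectConsistent <- function(model, panel, validation = NULL,
                             synergyMetrics = c("loewe", "hsa", "bliss"),
                             viabilityMetric = "min_viability",
                             margin = 0.5) {
  summ <- panelSummary(panel)
  sel <- synergyCluster(clusterLabels(model), summ, synergyMetrics,
                        viabilityMetric, margin)
  if (!length(sel)) {
    warning("no cluster shows both elevated synergy and viability loss")
    return(character(0))
  }
  if (!is.null(validation)) {
    vlab <- if (is(validation, "ClusterModel")) clusterLabels(validation)
            else validation
    synOnly <- paste0(setdiff(synergyMetrics, viabilityMetric), "_syn")
    synOnly <- intersect(c(synOnly, "chou_talalay_syn"), colnames(summ))
    if (!length(synOnly)) synOnly <- synergyMetrics
    vsel <- synergyCluster(vlab, summ, synOnly, viabilityMetric, margin)
    if (!length(vsel)) {
      warning("no validation cluster shows both elevated synergy and viability loss")
      return(character(0))
    }
    sel <- intersect(sel, vsel)
  }
  sel
}

#' Replicate concordance
#'
#' Correlation between paired replicate score vectors with a two-sided
#' test (Pearson by default, Spearman as the rank-based alternative).
#'
#' @param x,y paired score vectors (n >= 3 complete pairs).
#' @param method "pearson" or "spearman".
#' @return list with \code{estimate}, \code{p.value}, \code{n},
#'   \code{method}.
#' @export
replicateConcordance <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(x, y, method = method, alternative = "two.sided",
                        exact = FALSE)
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(x), method = method)
}
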