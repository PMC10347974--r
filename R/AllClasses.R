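#' @import methods
NULL

#' Four-parameter Hill monotherapy fit
#'
#' Represents one fitted dose-response curve
#' \eqn{v(d) = e_\infty + (e_0 - e_\infty) / (1 + (d/EC_{50})^h)}
#' for a single drug on a single culture. Viability is expressed as a
#' fraction of the DMSO control, doses in micromolar.
#'
#' @slot drug drug identifier.
#' @slot culture culture identifier.
#' @slot e0 viability fraction at zero dose (dimensionless).
#' @slot einf asymptotic viability fraction at infinite dose.
#' @slot ec50 concentration at the half-transition point (uM); \code{NA}
#'   when the curve is unidentifiable (flat response).
#' @slot h Hill slope (> 0); \code{NA} when unidentifiable.
#' @slot rss residual sum of squares of the fit.
#' @slot nPoints number of (dose, viability) points used.
#' @slot converged whether the optimizer reported convergence.
#' @slot identifiable whether ec50/h are meaningful; \code{FALSE} for flat
#'   responses where no transition is observed.
#' @slot doseRange range of positive doses used in the fit (uM).
#'
#' @seealso [fitHill()], [absoluteIC50()]
#' @export
setClass("HillFit",
  representation(
    drug = "character", culture = "character",
    e0 = "numeric", einf = "numeric", ec50 = "numeric", h = "numeric",
    rss = "numeric", nPoints = "integer",
    converged = "logical", identifiable = "logical",
    doseRange = "numeric"
  ),
  prototype(
    drug = NA_character_, culture = NA_character_,
    e0 = 1, einf = 0, ec50 = NA_real_, h = NA_real_,
    rss = NA_real_, nPoints = 0L,
    converged = FALSE, identifiable = FALSE,
    doseRange = c(NA_real_, NA_real_)
  )
)

setValidity("HillFit", function(object) {
  msg <- character()
  if (length(object@e0) != 1L || length(object@einf) != 1L)
    msg <- c(msg, "'e0' and 'einf' must be scalars")
  if (object@identifiable) {
    if (!is.finite(object@ec50) || object@ec50 <= 0)
      msg <- c(msg, "identifiable fit requires ec50 > 0")
    if (!is.finite(object@h) || object@h <= 0)
      msg <- c(msg, "identifiable fit requires h > 0")
  }
  if (is.finite(object@e0) && is.finite(object@einf)) {
    if (object@einf < -1e-9 || object@einf > object@e0 + 1e-9 ||
        object@e0 > 1.2 + 1e-9)
      msg <- c(msg, "requires 0 <= einf <= e0 <= 1.2")
  }
  if (length(msg)) msg else TRUE
})

#' One combination experiment on one culture
#'
#' Stores the replicate viability surface of a two-drug checkerboard:
#' an \eqn{n \times n} titration of both agents plus explicit zero-dose
#' edges, so the surface is \eqn{(n+1) \times (n+1)} with index 1 on each
#' axis corresponding to dose 0. The (0, 0) well is the on-plate control
#' after DMSO normalization; the zero-dose row/column are the monotherapy
#' responses used by the reference models.
#'
#' @slot culture culture identifier.
#' @slot drugA,drugB drug identifiers for the two axes.
#' @slot dosesA,dosesB strictly decreasing positive dose ladders (uM).
#' @slot viability numeric array of dim \code{(nA+1, nB+1, nrep)};
#'   the first index on each axis is dose 0 and doses then ascend.
#'   Missing wells are \code{NA}.
#' @slot dilutionFactor the configured serial dilution factor.
#'
#' @seealso [assembleMatrix()], [buildDoseLadder()]
#' @export
setClass("DoseMatrix",
  representation(
    culture = "character", drugA = "character", drugB = "character",
    dosesA = "numeric", dosesB = "numeric",
    viability = "array", dilutionFactor = "numeric"
  )
)

setValidity("DoseMatrix", function(object) {
  msg <- character()
  for (ax in c("A", "B")) {
    d <- slot(object, paste0("doses", ax))
    if (length(d) < 1L || any(d <= 0))
      msg <- c(msg, sprintf("doses%s must be positive", ax))
    if (is.unsorted(rev(d), strictly = TRUE))
      msg <- c(msg, sprintf("doses%s must be strictly decreasing", ax))
    if (length(d) >= 2L && is.finite(object@dilutionFactor)) {
      ratio <- d[-length(d)] / d[-1L]
      if (any(abs(ratio - object@dilutionFactor) >
              1e-9 * object@dilutionFactor))
        msg <- c(msg, sprintf(
          "consecutive doses%s do not follow the dilution factor %g",
          ax, object@dilutionFactor))
    }
  }
  dm <- dim(object@viability)
  if (length(dm) != 3L || dm[1L] != length(object@dosesA) + 1L ||
      dm[2L] != length(object@dosesB) + 1L)
    msg <- c(msg, "viability must be (nA+1) x (nB+1) x nrep")
  if (any(object@viability < 0, na.rm = TRUE))
    msg <- c(msg, "viabilities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Combinations x cultures x metrics score panel
#'
#' The clustering substrate: raw per-(combination, culture) scores for each
#' synergy/viability metric, the z-scaled version (per metric, over all
#' non-missing combination x culture entries), and a per-combination summary
#' (median z over cultures).
#'
#' @slot combinations,cultures,metrics identifier vectors.
#' @slot values raw score array, dim (C, L, M).
#' @slot zvalues z-scaled array, same shape (empty until [zscale()] is run).
#' @slot summary C x M matrix of per-combination median z over cultures.
#'
#' @seealso [buildMetricPanel()], [zscale()]
#' @export
setClass("MetricPanel",
  representation(
    combinations = "character", cultures = "character", metrics = "character",
    values = "array", zvalues = "array", summary = "matrix"
  ),
  prototype(zvalues = array(numeric(0), dim = c(0, 0, 0)),
            summary = matrix(numeric(0), 0, 0))
)

setValidity("MetricPanel", function(object) {
  dm <- dim(object@values)
  if (length(dm) != 3L ||
      dm[1L] != length(object@combinations) ||
      dm[2L] != length(object@cultures) ||
      dm[3L] != length(object@metrics))
    return("values must have dim (combinations, cultures, metrics)")
  TRUE
})

#' Fitted clustering model for a metric panel
#'
#' Result of Gaussian-mixture model-based clustering (or of the K-means
#' validation run) on per-combination feature vectors. The \code{bic} slot
#' follows the lower-is-better convention (\eqn{-2\log L + p\log n}); note
#' this is the negative of the quantity some mixture software maximizes.
#'
#' @slot k number of clusters.
#' @slot labels integer cluster assignment per combination (1..k), named.
#' @slot means k x p matrix of component means.
#' @slot family covariance family of the selected model ("EEI", "VVI",
#'   "EEE", "VVV" for mixtures; "kmeans" for the validation run).
#' @slot weights mixing proportions (sum to 1).
#' @slot bic criterion value of the selected model (lower is better).
#' @slot bicTable criterion values for every (k, family) fitted.
#' @slot seed random seed recorded for reproducibility.
#' @slot characterization k x p matrix: per-cluster median of each feature.
#' @slot method "gmm" or "kmeans".
#'
#' @seealso [gmmCluster()], [kmeansValidate()], [selectConsistent()]
#' @export
setClass("ClusterModel",
  representation(
    k = "integer", labels = "integer", means = "matrix",
    family = "character", weights = "numeric",
    bic = "numeric", bicTable = "matrix", seed = "integer",
    characterization = "matrix", method = "character"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (any(object@labels < 1L | object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "mixing weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Fully simulated combination screen with known ground truth
#'
#' Everything the analysis pipeline consumes (a plate-map table of raw RLU
#' wells with DMSO controls, in the same dialect the grid-assembly functions
#' read) together with the generating truth: the per-drug, per-culture Hill
#' parameters, which combinations carry an injected interaction, and the
#' interaction magnitude. Regenerating with the same configuration (which
#' includes the seed) reproduces the screen bit-identically.
#'
#' @slot plateMap data.frame of raw wells (plate, well, culture, drug_a,
#'   dose_a_um, drug_b, dose_b_um, replicate, rlu, is_control).
#' @slot hillTruth data.frame of generating Hill parameters per
#'   (drug, culture), with the anchored top dose.
#' @slot combinations data.frame (combination, drugA, drugB, synergistic,
#'   delta): the ground-truth interaction labels.
#' @slot config the generating configuration (echoed).
#'
#' @seealso [simulateScreen()], [synthConfig()], [assembleScreen()]
#' @export
setClass("SynthScreen",
  representation(
    plateMap = "data.frame", hillTruth = "data.frame",
    combinations = "data.frame", config = "list"
  )
)

setMethod("show", "HillFit", function(object) {
  cat("HillFit:", object@drug, "on", object@culture, "\n")
  if (object@identifiable) {
    cat(sprintf("  e0=%.3f einf=%.3f ec50=%.4g uM h=%.2f (rss=%.3g, n=%d)\n",
                object@e0, object@einf, object@ec50, object@h,
                object@rss, object@nPoints))
  } else {
    cat(sprintf("  flat/unidentifiable response, level %.3f (n=%d)\n",
                object@e0, object@nPoints))
  }
})

setMethod("show", "DoseMatrix", function(object) {
  dm <- dim(object@viability)
  cat(sprintf("DoseMatrix: %s + %s on %s\n", object@drugA, object@drugB,
              object@culture))
  cat(sprintf("  %dx%d titration (+ zero-dose edges), %d replicate(s), top doses %.4g / %.4g uM\n",
              length(object@dosesA), length(object@dosesB), dm[3L],
              max(object@dosesA), max(object@dosesB)))
  nmiss <- sum(is.na(object@viability))
  if (nmiss) cat("  missing wells:", nmiss, "\n")
})

setMethod("show", "MetricPanel", function(object) {
  cat(sprintf("MetricPanel: %d combinations x %d cultures x %d metrics\n",
              length(object@combinations), length(object@cultures),
              length(object@metrics)))
  cat("  metrics:", paste(object@metrics, collapse = ", "), "\n")
  cat("  z-scaled:", if (length(object@zvalues)) "yes" else "no", "\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel (%s): k = %d, family = %s, criterion = %.2f\n",
              object@method, object@k, object@family, object@bic))
  print(table(cluster = object@labels))
})

setMethod("show", "SynthScreen", function(object) {
  cat(sprintf("SynthScreen: %d combinations x %d cultures (%d synergistic, delta = %g)\n",
              nrow(object@combinations), object@config$nCultures,
              sum(object@combinations$synergistic),
              object@config$interactionDelta))
  cat(sprintf("  %d plate-map wells, seed %d\n", nrow(object@plateMap),
              object@config$seed))
})
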