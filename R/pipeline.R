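#' Run the full short-term screen analysis
#'
#' From a plate map (or simulated screen) to the consistently synergistic
#' set: assembles and normalizes every combination matrix, fits the
#' monotherapy edges, scores all reference models, builds and z-scales the
#' metric panel, clusters the per-combination median-z features with a
#' Gaussian mixture (BIC-selected k), validates with K-means on the
#' synergy-only features at the same k, and intersects the two
#' synergy-with-viability-loss clusters.
#'
#' The mixture clustering features are the per-combination median z of
#' \code{loewe}, \code{hsa}, \code{bliss} and \code{min_viability}; the
#' K-means validation uses \code{loewe_syn}, \code{hsa_syn},
#' \code{bliss_syn}, \code{chou_talalay_syn} and \code{min_viability}.
#'
#' @param x plate-map data.frame, [SynthScreen-class], or a pre-assembled
#'   named list of [DoseMatrix-class].
#' @param kRange candidate cluster counts for the mixture.
#' @param nRestarts K-means restarts.
#' @param seed seed recorded into both clustering stages.
#' @param margin qualification margin of [selectConsistent()].
#' @return list: \code{matrices}, \code{results} (tidy score table),
#'   \code{panel} (z-scaled [MetricPanel-class]), \code{gmm},
#'   \code{kmeans} ([ClusterModel-class]), \code{selected} (combination
#'   ids).
#' @export
analyzeScreen <- function(x, kRange = 1:9, nRestarts = 10L, seed = 1L,
                          margin = 0.5) {
  mats <- if (is.list(x) && !is.data.frame(x) && !is(x, "SynthScreen")) x
          else assembleScreen(x)
  results <- do.call(rbind, lapply(mats, scoreCombination))
  rownames(results) <- NULL
  panel <- zscale(buildMetricPanel(results))
  summ <- panelSummary(panel)

  gmmFeat <- summ[, intersect(c("loewe", "hsa", "bliss", "min_viability"),
                              colnames(summ)), drop = FALSE]
  gmm <- gmmCluster(gmmFeat, kRange = kRange, nRestarts = nRestarts,
                    seed = seed)
  kmFeat <- summ[, intersect(c("loewe_syn", "hsa_syn", "bliss_syn",
                               "chou_talalay_syn", "min_viability"),
                             colnames(summ)), drop = FALSE]
  km <- kmeansValidate(kmFeat, k = gmm@k, nRestarts = nRestarts,
                       seed = seed)
  selected <- withCallingHandlers(
    selectConsistent(gmm, panel, km, margin = margin),
    warning = function(w) invokeRestart("muffleWarning"))
  list(matrices = mats, results = results, panel = panel,
       gmm = gmm, kmeans = km, selected = selected)
}

#' Sensitivity and specificity of a selection against ground truth
#'
#' @param selected character vector of selected combination ids.
#' @param truth ground-truth data.frame with columns \code{combination},
#'   \code{synergistic} (e.g. [groundTruth()] of a [SynthScreen-class]).
#' @return named numeric: sensitivity, specificity, truePositives,
#'   falsePositives.
#' @export
evaluateSelection <- function(selected, truth) {
  pos <- truth$combination[truth$synergistic]
  neg <- truth$combination[!truth$synergistic]
  tp <- length(intersect(selected, pos))
  fp <- length(intersect(selected, neg))
  c(sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
    specificity = if (length(neg)) 1 - fp / length(neg) else NA_real_,
    truePositives = tp, falsePositives = fp)
}

#' JSON model report of a clustering stage
#'
#' @param model a [ClusterModel-class].
#' @param path optional path to write JSON to.
#' @return the report list, invisibly when written.
#' @export
clusterReport <- function(model, path = NULL) {
  rep_ <- list(method = model@method, k = model@k, family = model@family,
               criterion = model@bic, seed = model@seed,
               sizes = as.vector(table(model@labels)),
               characterization = model@characterization,
               labels = as.list(model@labels))
  if (!is.null(path)) {
    jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep_))
  }
  rep_
}
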