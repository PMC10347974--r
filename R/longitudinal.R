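#' Score a long-term endpoint matrix
#'
#' Runs the same Loewe scoring engine on an endpoint (e.g. day-18,
#' repeated-exposure) viability matrix: Hill curves are fitted to the
#' endpoint monotherapy edges and the summed Loewe deviation is computed
#' exactly as in the short-term screen. When a monotherapy edge is
#' unfittable (flat endpoint response) the result falls back to HSA
#' scoring and is flagged via the \code{model} field.
#'
#' @param mat endpoint [DoseMatrix-class].
#' @param fitA,fitB optional endpoint-edge [HillFit-class] objects.
#' @param schedule optional schedule metadata (exposure windows, imaging
#'   days); carried through untouched.
#' @return object of class \code{"LongitudinalScore"}: a list with the
#'   score row (as in [scoreMatrix()]), the per-well deviation surface,
#'   and the schedule metadata.
#' @export
scoreLongitudinal <- function(mat, fitA = NULL, fitB = NULL,
                              schedule = NULL) {
  if (is.null(fitA)) fitA <- fitEdge(mat, "A")
  if (is.null(fitB)) fitB <- fitEdge(mat, "B")
  fitsOk <- !is.null(fitA) && !is.null(fitB) &&
    fitA@identifiable && fitB@identifiable
  obs <- comboWells(mat)
  axA <- rev(doseAxis(mat, "A"))
  axB <- rev(doseAxis(mat, "B"))
  if (fitsOk) {
    g <- expand.grid(da = axA, db = axB)
    v <- loeweExpected(fitA, fitB, g$da, g$db)
    expected <- matrix(v, nrow = length(axA))
    row <- scoreMatrix(mat, expected, model = "loewe",
                       nFallback = sum(attr(v, "fallback")))
  } else {
    ed <- edgeViabilities(mat)
    expected <- matrix(hsaExpected(pmin(rep(ed$va, times = ncol(obs)), 1),
                                   pmin(rep(ed$vb, each = nrow(obs)), 1)),
                       nrow = nrow(obs))
    row <- scoreMatrix(mat, expected, model = "hsa")
  }
  structure(list(score = row, deviations = (expected - obs) * 100,
                 schedule = schedule),
            class = "LongitudinalScore")
}

#' @export
print.LongitudinalScore <- function(x, ...) {
  cat(sprintf("LongitudinalScore: %s on %s (%s) scoreSum = %.1f pp over %d wells\n",
              x$score$combination, x$score$culture, x$score$model,
              x$score$scoreSum, x$score$nWells))
  invisible(x)
}

# randomization null for a summed deviation surface: random sign flips of
# the per-well deviations (exact under exchangeable symmetric noise)
nullScores <- function(deviations, nPermutations) {
  d <- deviations[!is.na(deviations)]
  s <- matrix(sample(c(-1, 1), nPermutations * length(d), replace = TRUE),
              nrow = nPermutations)
  as.vector(s %*% d)
}

#' Classify longitudinal synergy against a randomization null
#'
#' For each scored endpoint matrix a null distribution of the summed score
#' is built by randomizing the signs of the per-well deviations
#' (\code{nPermutations} draws, seeded); the per-culture null threshold is
#' the 95th percentile (configurable via \code{level}). A combination is
#' called longitudinally synergistic when its observed score exceeds the
#' null threshold in at least \code{minCultures} cultures.
#'
#' @param scores list of \code{"LongitudinalScore"} objects (one per
#'   combination x culture, from [scoreLongitudinal()]).
#' @param nPermutations number of null draws (>= 100 recommended; fewer
#'   triggers a warning).
#' @param seed random seed; the whole classification is deterministic
#'   given it.
#' @param level null quantile for the calling threshold (default 0.95).
#' @param minCultures minimum number of cultures that must exceed the
#'   threshold (default 1).
#' @return list with \code{cultures} (per-culture data.frame: combination,
#'   culture, scoreSum, nullThreshold, synergistic) and
#'   \code{combinations} (per-combination call).
#' @export
classifyLongitudinal <- function(scores, nPermutations = 1000L, seed = 1L,
                                 level = 0.95, minCultures = 1L) {
  if (inherits(scores, "LongitudinalScore")) scores <- list(scores)
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 100L)
    warning("fewer than 100 permutations gives an unstable null threshold")
  set.seed(seed)
  rows <- lapply(scores, function(s) {
    thr <- stats::quantile(nullScores(s$deviations, nPermutations), level,
                           names = FALSE)
    data.frame(combination = s$score$combination,
               culture = s$score$culture,
               model = s$score$model,
               scoreSum = s$score$scoreSum,
               nullThreshold = thr,
               synergistic = s$score$scoreSum > thr,
               stringsAsFactors = FALSE)
  })
  cultures <- do.call(rbind, rows)
  agg <- stats::aggregate(synergistic ~ combination, cultures,
                          function(z) sum(z) >= minCultures)
  maxScore <- stats::aggregate(scoreSum ~ combination, cultures, max)
  combos <- merge(agg, maxScore, by = "combination")
  names(combos)[names(combos) == "scoreSum"] <- "maxScoreSum"
  combos <- combos[order(-combos$maxScoreSum), , drop = FALSE]
  rownames(combos) <- NULL
  list(cultures = cultures, combinations = combos)
}
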