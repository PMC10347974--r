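#' Bliss independence expectation
#'
#' Under multiplicative survival the expected combined viability of two
#' independently acting drugs is the product of the monotherapy
#' viabilities.
#'
#' @param va,vb monotherapy viability fractions in [0, 1]; values above 1
#'   (wells outgrowing the control) are clamped to 1 with a warning.
#' @return expected viability \code{va * vb}.
#' @export
blissExpected <- function(va, vb) {
  if (any(va < 0, na.rm = TRUE) || any(vb < 0, na.rm = TRUE))
    stop("viabilities must be >= 0")
  if (any(va > 1, na.rm = TRUE) || any(vb > 1, na.rm = TRUE)) {
    warning("viabilities > 1 clamped to 1")
    va <- pmin(va, 1); vb <- pmin(vb, 1)
  }
  va * vb
}

#' Highest-single-agent expectation
#'
#' The expected combined viability is that of the more effective (lower
#' viability) single agent.
#'
#' @inheritParams blissExpected
#' @return \code{pmin(va, vb)}.
#' @export
hsaExpected <- function(va, vb) {
  if (any(va < 0, na.rm = TRUE) || any(vb < 0, na.rm = TRUE))
    stop("viabilities must be >= 0")
  if (any(va > 1, na.rm = TRUE) || any(vb > 1, na.rm = TRUE)) {
    warning("viabilities > 1 clamped to 1")
    va <- pmin(va, 1); vb <- pmin(vb, 1)
  }
  pmin(va, vb)
}

#' Loewe additivity expectation
#'
#' Dose-equivalence reference: the expected viability \eqn{v} of the
#' combination \eqn{(d_A, d_B)} solves
#' \deqn{d_A / A(v) + d_B / B(v) = 1,}
#' where \eqn{A(v)} and \eqn{B(v)} invert the two monotherapy Hill curves.
#' The root is bracketed on \eqn{(\max(e_{\infty,A}, e_{\infty,B}),\;
#' \min(e_{0,A}, e_{0,B}))} and solved numerically. When one curve cannot
#' reach the required effect level (its floor is too high, so the equation
#' has no solution), the expectation falls back to the HSA value for that
#' well and the well is flagged.
#'
#' A combination of a drug with itself (shared curve) reduces exactly to
#' the monotherapy viability at dose \eqn{d_A + d_B} (sham invariance);
#' single-agent wells reduce to the monotherapy curve.
#'
#' @param fitA,fitB identifiable [HillFit-class] objects.
#' @param doseA,doseB dose vectors (uM, >= 0), recycled to equal length.
#' @param tol root-finding tolerance on viability.
#' @return numeric vector of expected viabilities with attribute
#'   \code{"fallback"}: logical, \code{TRUE} where the HSA fallback was
#'   used.
#' @export
loeweExpected <- function(fitA, fitB, doseA, doseB, tol = 1e-9) {
  stopifnot(is(fitA, "HillFit"), is(fitB, "HillFit"))
  if (!fitA@identifiable || !fitB@identifiable)
    stop("Loewe expectation requires identifiable Hill fits")
  n <- max(length(doseA), length(doseB))
  doseA <- rep_len(doseA, n); doseB <- rep_len(doseB, n)
  if (any(doseA < 0) || any(doseB < 0)) stop("doses must be >= 0")

  lo <- max(fitA@einf, fitB@einf)
  hi <- min(fitA@e0, fitB@e0)
  degenerate <- (hi - lo) < 1e-4  # no shared effect range between curves
  eps <- 1e-9 * max(hi - lo, 1e-6)

  v <- numeric(n)
  fb <- logical(n)
  g <- function(x, da, db)
    da / invertHill(fitA, x) + db / invertHill(fitB, x) - 1
  for (i in seq_len(n)) {
    da <- doseA[i]; db <- doseB[i]
    if (da == 0 && db == 0) {
      v[i] <- (fitA@e0 + fitB@e0) / 2
    } else if (db == 0) {
      v[i] <- predict(fitA, da)
    } else if (da == 0) {
      v[i] <- predict(fitB, db)
    } else {
      lower <- lo + eps; upper <- hi - eps
      gl <- if (degenerate) NaN else g(lower, da, db)
      if (!is.finite(gl) || gl >= 0) {
        # required effect deeper than one curve's floor allows (or no
        # shared effect range): HSA fallback
        v[i] <- hsaExpected(min(predict(fitA, da), 1),
                            min(predict(fitB, db), 1))
        fb[i] <- TRUE
      } else if (g(upper, da, db) <= 0) {
        # g is increasing in v; a root above hi - eps equals hi to
        # within the bracket tolerance
        v[i] <- upper
      } else {
        v[i] <- stats::uniroot(g, c(lower, upper), da = da, db = db,
                               tol = tol)$root
      }
    }
  }
  attr(v, "fallback") <- fb
  v
}

# clamp the affected fraction before dose inversion (bounds CI blow-up)
clampFa <- function(fa, limits = c(0.005, 0.995)) {
  pmin(pmax(fa, limits[1L]), limits[2L])
}

#' Affected fraction on a fit's own effect scale
#'
#' Maps an observed viability to the median-effect scale of one curve:
#' \eqn{f_a = (e_0 - v) / (e_0 - e_\infty)}, clamped to [0.005, 0.995].
#'
#' @param fit an identifiable [HillFit-class].
#' @param v observed viability fraction(s).
#' @return affected fraction in (0, 1).
#' @export
faFromViability <- function(fit, v) {
  clampFa((fit@e0 - v) / (fit@e0 - fit@einf))
}

#' Chou-Talalay combination index (mutually non-exclusive)
#'
#' Median-effect representation of each curve is taken from its Hill fit
#' (\eqn{D_m = EC_{50}}, \eqn{m = h}); the dose of drug \eqn{x} alone that
#' produces affected fraction \eqn{f_a} is
#' \eqn{D_x = D_{m,x} (f_a/(1-f_a))^{1/m_x}} and
#' \deqn{CI = d_A/D_A + d_B/D_B + d_A d_B / (D_A D_B).}
#' CI < 1 indicates synergy, CI > 1 antagonism. The affected fraction is
#' clamped to [0.005, 0.995] before inversion; inputs outside (0, 1) are
#' recorded in the \code{"clamped"} attribute.
#'
#' @param fitA,fitB identifiable [HillFit-class] objects.
#' @param doseA,doseB combination doses (uM).
#' @param fa observed affected fraction: either one shared value per well,
#'   or a 2-column matrix giving the fraction on each drug's own effect
#'   scale (see [faFromViability()]).
#' @return CI values with attribute \code{"clamped"}.
#' @export
chouTalalayCI <- function(fitA, fitB, doseA, doseB, fa) {
  stopifnot(is(fitA, "HillFit"), is(fitB, "HillFit"))
  if (!fitA@identifiable || !fitB@identifiable)
    stop("combination index requires identifiable Hill fits")
  if (is.matrix(fa)) {
    faA <- fa[, 1L]; faB <- fa[, 2L]
  } else {
    faA <- faB <- fa
  }
  clamped <- faA <= 0 | faA >= 1 | faB <= 0 | faB >= 1
  faA <- clampFa(faA); faB <- clampFa(faB)
  DA <- fitA@ec50 * (faA / (1 - faA))^(1 / fitA@h)
  DB <- fitB@ec50 * (faB / (1 - faB))^(1 / fitB@h)
  ci <- doseA / DA + doseB / DB + (doseA * doseB) / (DA * DB)
  attr(ci, "clamped") <- clamped
  ci
}

#' Sum a deviation surface into a synergy score
#'
#' The screen's score is the \emph{sum of synergy and antagonism}: over the
#' nonzero-dose combination wells, the per-well deviation
#' \eqn{(expected - observed) \times 100} percentage points (positive =
#' observed viability below expectation = synergy) is summed over
#' non-missing wells. Synergy-only and antagonism-only partial sums are
#' reported alongside, and \code{scoreSum = scoreSynergy +
#' scoreAntagonism} by construction.
#'
#' @param mat a [DoseMatrix-class].
#' @param expected expected-viability matrix over the nonzero-dose block
#'   (doses ascending, same orientation as [comboWells()]). For the
#'   combination-index model pass the per-well quantity directly via
#'   \code{deviation}.
#' @param model model label recorded in the result.
#' @param deviation optional matrix of per-well scores in percentage points
#'   (overrides \code{expected}; used for (1 - CI) x 100).
#' @param nFallback count of flagged wells (e.g. Loewe HSA fallbacks).
#' @return one-row data.frame: combination, culture, model, scoreSum,
#'   scoreSynergy, scoreAntagonism, minViability, nWells, nFallback.
#' @export
scoreMatrix <- function(mat, expected = NULL, model = "custom",
                        deviation = NULL, nFallback = 0L) {
  obs <- comboWells(mat)
  if (is.null(deviation)) {
    if (is.null(expected)) stop("supply 'expected' or 'deviation'")
    if (!all(dim(expected) == dim(obs)))
      stop("expected surface shape does not match the combination block")
    deviation <- (expected - obs) * 100
  } else if (!all(dim(deviation) == dim(obs))) {
    stop("deviation surface shape does not match the combination block")
  }
  dev <- deviation[!is.na(deviation)]
  data.frame(
    combination = paste0(mat@drugA, "+", mat@drugB),
    culture = mat@culture, model = model,
    scoreSum = sum(dev),
    scoreSynergy = sum(dev[dev > 0]),
    scoreAntagonism = sum(dev[dev < 0]),
    minViability = minViability(mat),
    nWells = length(dev), nFallback = as.integer(nFallback),
    stringsAsFactors = FALSE)
}

#' Minimum viability of a combination matrix
#'
#' The tumoricidal-effect metric: the lowest replicate-mean viability over
#' the nonzero-dose combination wells (missing wells skipped).
#'
#' @param mat a [DoseMatrix-class].
#' @return viability fraction.
#' @export
minViability <- function(mat) {
  w <- comboWells(mat)
  if (all(is.na(w))) stop("all combination wells missing")
  min(w, na.rm = TRUE)
}

# monotherapy edge viabilities (replicate means) at the ascending nonzero
# doses of each axis
edgeViabilities <- function(mat) {
  m <- replicateMeans(mat)
  list(va = m[-1L, 1L], vb = m[1L, -1L])
}

#' Score one combination matrix under every reference model
#'
#' Computes the summed synergy/antagonism score of a dose matrix under
#' Loewe additivity, HSA, Bliss independence and the Chou-Talalay
#' combination index (per-well quantity \eqn{(1 - CI) \times 100}), plus
#' the minimum-viability metric. Bliss and HSA expectations use the
#' observed monotherapy edges; Loewe and Chou-Talalay use Hill fits of the
#' edges (fitted here when not supplied). When an edge is unfittable the
#' fit-based models are returned as \code{NA} rows.
#'
#' @param mat a [DoseMatrix-class].
#' @param fitA,fitB optional [HillFit-class] for the two drugs; fitted from
#'   the monotherapy edges (plus the zero-dose control wells) when omitted.
#' @param models subset of \code{c("loewe", "hsa", "bliss",
#'   "chou_talalay", "min_viability")}.
#' @return data.frame with one row per model (see [scoreMatrix()]).
#' @export
scoreCombination <- function(mat, fitA = NULL, fitB = NULL,
                             models = c("loewe", "hsa", "bliss",
                                        "chou_talalay", "min_viability")) {
  models <- match.arg(models, several.ok = TRUE)
  obs <- comboWells(mat)
  ed <- edgeViabilities(mat)
  axA <- rev(doseAxis(mat, "A"))  # ascending
  axB <- rev(doseAxis(mat, "B"))
  if (is.null(fitA)) fitA <- fitEdge(mat, "A")
  if (is.null(fitB)) fitB <- fitEdge(mat, "B")
  fitsOk <- !is.null(fitA) && !is.null(fitB) &&
    fitA@identifiable && fitB@identifiable

  out <- list()
  naRow <- function(model) {
    r <- scoreMatrix(mat, deviation = obs * NA, model = model)
    r$scoreSum <- r$scoreSynergy <- r$scoreAntagonism <- NA_real_
    r$nWells <- 0L
    r
  }
  for (model in models) {
    if (model == "bliss") {
      exp_ <- blissExpected(pmin(rep(ed$va, times = ncol(obs)), 1),
                            pmin(rep(ed$vb, each = nrow(obs)), 1))
      dim(exp_) <- dim(obs)
      out[[model]] <- scoreMatrix(mat, exp_, model)
    } else if (model == "hsa") {
      exp_ <- hsaExpected(pmin(rep(ed$va, times = ncol(obs)), 1),
                          pmin(rep(ed$vb, each = nrow(obs)), 1))
      dim(exp_) <- dim(obs)
      out[[model]] <- scoreMatrix(mat, exp_, model)
    } else if (model == "loewe") {
      if (!fitsOk) { out[[model]] <- naRow(model); next }
      g <- expand.grid(da = axA, db = axB)
      v <- loeweExpected(fitA, fitB, g$da, g$db)
      exp_ <- matrix(v, nrow = length(axA))
      out[[model]] <- scoreMatrix(mat, exp_, model,
                                  nFallback = sum(attr(v, "fallback")))
    } else if (model == "chou_talalay") {
      if (!fitsOk) { out[[model]] <- naRow(model); next }
      g <- expand.grid(da = axA, db = axB)
      vobs <- as.vector(obs)
      fa <- cbind(faFromViability(fitA, vobs), faFromViability(fitB, vobs))
      ci <- chouTalalayCI(fitA, fitB, g$da, g$db, fa)
      devn <- matrix((1 - ci) * 100, nrow = length(axA))
      out[[model]] <- scoreMatrix(mat, deviation = devn, model = model)
    } else if (model == "min_viability") {
      r <- scoreMatrix(mat, deviation = obs * 0, model = model)
      r$scoreSum <- r$scoreSynergy <- r$scoreAntagonism <- NA_real_
      out[[model]] <- r
    }
  }
  do.call(rbind, out)
}

#' Fit a Hill curve to one monotherapy edge of a dose matrix
#'
#' Uses the zero-dose-edge wells of the given axis (all replicates) plus
#' the (0, 0) control wells as the zero-dose anchor.
#'
#' @param mat a [DoseMatrix-class].
#' @param axis "A" or "B".
#' @param ... passed to [fitHill()].
#' @return a [HillFit-class], or \code{NULL} when the edge is entirely
#'   missing.
#' @export
fitEdge <- function(mat, axis = c("A", "B"), ...) {
  axis <- match.arg(axis)
  nrep <- dim(mat@viability)[3L]
  if (axis == "A") {
    v <- mat@viability[, 1L, , drop = TRUE]
  } else {
    v <- mat@viability[1L, , , drop = TRUE]
  }
  v <- matrix(v, ncol = nrep)          # (n+1) x nrep, dose 0 first
  dosesAsc <- c(0, rev(doseAxis(mat, axis)))
  d <- rep(dosesAsc, times = nrep)
  vv <- as.vector(v)
  ok <- !is.na(vv)
  if (sum(ok) < 5L) return(NULL)
  tryCatch(fitHill(d[ok], pmin(vv[ok], 1.5), drug = drugNames(mat)[
             if (axis == "A") 1L else 2L],
           culture = mat@culture, ...),
           error = function(e) NULL)
}
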