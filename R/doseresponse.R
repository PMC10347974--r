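#' Predicted viability under a four-parameter Hill curve
#'
#' @param d dose vector (uM, >= 0).
#' @param e0,einf,ec50,h Hill parameters.
#' @return viability fractions; \code{d = 0} returns \code{e0}.
#' @export
hillViability <- function(d, e0, einf, ec50, h) {
  einf + (e0 - einf) / (1 + (d / ec50)^h)
}

#' @rdname hillViability
#' @param object a [HillFit-class].
#' @param newdata dose vector.
#' @param ... ignored.
#' @importFrom stats predict
#' @export
setMethod("predict", "HillFit", function(object, newdata, ...) {
  if (!object@identifiable) return(rep(object@e0, length(newdata)))
  hillViability(newdata, object@e0, object@einf, object@ec50, object@h)
})

#' Inverse Hill curve
#'
#' Dose at which a fitted curve reaches viability \code{v}; \code{v} must
#' lie strictly between \code{einf} and \code{e0}.
#'
#' @param fit an identifiable [HillFit-class].
#' @param v target viability fraction(s).
#' @return dose(s) in uM.
#' @export
invertHill <- function(fit, v) {
  fit@ec50 * ((fit@e0 - v) / (v - fit@einf))^(1 / fit@h)
}

#' Fit a monotherapy dose-response curve
#'
#' Least-squares fit of \eqn{v(d) = e_\infty + (e_0-e_\infty)/(1+(d/EC_{50})^h)}
#' to replicate viability measurements. All points are fitted jointly (not
#' per-dose means) so the replicate error structure is preserved. The
#' optimizer is box-bounded (\code{e0} in [0.7, 1.2], \code{einf} in [0, 1],
#' \code{h} in [0.1, 10], \code{ec50} within [min dose/100, max dose x 100])
#' and is multi-started from three log-spaced ec50 values to avoid local
#' minima. A monotone non-increasing penalty keeps \code{einf <= e0}.
#'
#' Flat responses (range of per-dose mean viabilities < \code{flatRange})
#' are returned with \code{identifiable = FALSE} and \code{NA} ec50/slope
#' rather than a fabricated transition.
#'
#' @param doses dose vector (uM), one entry per observation; at least 4
#'   distinct positive doses are required. Zero doses (control anchors) are
#'   allowed and contribute to the fit of \code{e0}.
#' @param viabilities viability fractions in [0, 1.5], same length as
#'   \code{doses}, or a matrix with \code{length(unique(doses))} rows and one
#'   column per replicate (rows matching \code{sort(unique(doses))}).
#' @param drug,culture identifiers carried into the result.
#' @param flatRange flat-response detection threshold on the range of
#'   per-dose mean viabilities (default 0.1).
#' @return a [HillFit-class].
#' @examples
#' d <- rep(10 / 3^(0:7), each = 2)
#' v <- hillViability(d, 1, 0.1, 0.5, 1.2)
#' fitHill(d, v)
#' @export
fitHill <- function(doses, viabilities, drug = NA_character_,
                    culture = NA_character_, flatRange = 0.1) {
  if (is.matrix(viabilities)) {
    ud <- sort(unique(doses))
    if (nrow(viabilities) != length(ud))
      stop("viability matrix rows must match the distinct doses")
    doses <- rep(ud, times = ncol(viabilities))
    viabilities <- as.vector(viabilities)
  }
  keep <- !is.na(viabilities)
  doses <- doses[keep]; viabilities <- viabilities[keep]
  if (length(doses) != length(viabilities))
    stop("doses and viabilities must have equal length")
  if (any(doses < 0)) stop("doses must be >= 0")
  if (length(unique(doses[doses > 0])) < 4L)
    stop("at least 4 distinct positive doses are required")
  if (any(viabilities < 0 | viabilities > 1.5))
    stop("viabilities must lie in [0, 1.5]")

  perDose <- tapply(viabilities, doses, mean)
  dpos <- doses[doses > 0]
  drange <- range(dpos)
  n <- length(viabilities)

  if (diff(range(perDose)) < flatRange) {
    lev <- mean(viabilities)
    return(new("HillFit",
      drug = drug, culture = culture,
      e0 = min(max(lev, 0), 1.2), einf = min(max(lev, 0), 1.2),
      ec50 = NA_real_, h = NA_real_,
      rss = sum((viabilities - lev)^2), nPoints = n,
      converged = TRUE, identifiable = FALSE, doseRange = drange))
  }

  # parameters: e0, einf, log(ec50), log(h)
  obj <- function(p) {
    v <- hillViability(doses, p[1L], p[2L], exp(p[3L]), exp(p[4L]))
    sum((viabilities - v)^2) + 1e3 * max(0, p[2L] - p[1L])^2
  }
  lower <- c(0.7, 0, log(drange[1L] / 100), log(0.1))
  upper <- c(1.2, 1, log(drange[2L] * 100), log(10))
  e0s <- min(max(max(perDose), 0.7), 1.2)
  einfs <- min(max(min(perDose), 0), 1)
  starts <- exp(seq(log(drange[1L]), log(drange[2L]), length.out = 3L))

  best <- NULL
  for (s in starts) {
    p0 <- c(e0s, einfs, log(s), log(1))
    f <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best))
    stop("Hill fit failed for all starts")

  p <- best$par
  new("HillFit",
    drug = drug, culture = culture,
    e0 = p[1L], einf = min(p[2L], p[1L]), ec50 = exp(p[3L]), h = exp(p[4L]),
    rss = sum((viabilities -
               hillViability(doses, p[1L], p[2L], exp(p[3L]), exp(p[4L])))^2),
    nPoints = n, converged = best$convergence == 0L,
    identifiable = TRUE, doseRange = drange)
}

#' Absolute IC50 of a fitted curve
#'
#' The dose at which the fitted viability crosses 50\% of control
#' (\emph{absolute} IC50, not the relative EC50), solved in closed form:
#' \eqn{d = EC_{50}\,((e_0 - 0.5)/(0.5 - e_\infty))^{1/h}}. When the curve
#' floor \eqn{e_\infty \ge 0.5} the 50\% level is never reached and
#' \code{NA} is returned.
#'
#' @param fit a converged [HillFit-class].
#' @return the IC50 in uM, or \code{NA_real_} when not reached (flat or
#'   floored curves).
#' @examples
#' f <- new("HillFit", e0 = 1, einf = 0.4, ec50 = 1, h = 1,
#'          converged = TRUE, identifiable = TRUE)
#' absoluteIC50(f)  # 5
#' @export
absoluteIC50 <- function(fit) {
  stopifnot(is(fit, "HillFit"))
  if (!fit@converged) stop("fit did not converge")
  if (!fit@identifiable) return(NA_real_)
  if (fit@einf >= 0.5) return(NA_real_)
  if (fit@e0 <= 0.5) return(0)
  invertHill(fit, 0.5)
}

#' Per-(drug, culture) sensitivity call
#'
#' @param fit a [HillFit-class].
#' @param maxDose highest tested dose (uM).
#' @return one-row data.frame with the absolute IC50 (NA = not reached), an
#'   \code{extrapolated} flag (IC50 beyond the tested range) and the
#'   \code{sensitive} call (IC50 reached within the tested range).
#' @export
sensitivityCall <- function(fit, maxDose) {
  ic50 <- absoluteIC50(fit)
  extrap <- !is.na(ic50) && ic50 > maxDose
  data.frame(
    drug = fit@drug, culture = fit@culture,
    ic50_abs = ic50, reached = !is.na(ic50),
    extrapolated = extrap,
    sensitive = !is.na(ic50) && !extrap,
    stringsAsFactors = FALSE)
}

#' Monotherapy sensitivity filter
#'
#' A drug is retained when its absolute IC50 is reached within the tested
#' dose range in at least \code{minFraction} of cultures (default: all of
#' them). Combinations survive only when both partner drugs are retained.
#'
#' @param calls data.frame with columns \code{drug}, \code{culture},
#'   \code{sensitive} — one row per (drug, culture), e.g. rbind-ed output
#'   of [sensitivityCall()].
#' @param minFraction minimum fraction of cultures in which the drug must
#'   be sensitive (default 1).
#' @return character vector of retained drug ids.
#' @export
sensitivityFilter <- function(calls, minFraction = 1) {
  if (!NROW(calls)) stop("empty sensitivity table")
  stopifnot(all(c("drug", "culture", "sensitive") %in% names(calls)))
  if (anyDuplicated(calls[c("drug", "culture")]))
    stop("one call per (drug, culture) required")
  frac <- tapply(calls$sensitive, calls$drug, mean)
  names(frac)[frac >= minFraction - 1e-12]
}

#' @rdname sensitivityFilter
#' @param combinations data.frame with columns \code{drugA}, \code{drugB}.
#' @param retained character vector from \code{sensitivityFilter}.
#' @return \code{retainCombinations}: the subset of \code{combinations}
#'   whose both drugs are retained.
#' @export
retainCombinations <- function(combinations, retained) {
  combinations[combinations$drugA %in% retained &
               combinations$drugB %in% retained, , drop = FALSE]
}
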