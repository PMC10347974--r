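#' Serial dilution dose ladder
#'
#' The screening design titrates each drug from a top concentration
#' (anchored near the absolute IC50) downwards in constant-factor steps;
#' the default is six 3-fold dilution levels.
#'
#' @param top highest concentration (uM, > 0).
#' @param factor dilution factor (> 1).
#' @param n number of levels (>= 1).
#' @return descending dose vector, \code{dose[i] = top / factor^(i-1)}.
#' @examples
#' buildDoseLadder(1, 3, 6)
#' @export
buildDoseLadder <- function(top, factor = 3, n = 6L) {
  if (!is.numeric(top) || top <= 0) stop("'top' must be > 0")
  if (factor <= 1) stop("'factor' must be > 1")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  top / factor^(0:(n - 1L))
}

#' Infer the dilution factor of a ladder
#'
#' Geometric mean ratio of consecutive doses (exact in log space for a
#' constant-factor ladder).
#'
#' @param doses descending positive dose vector.
#' @return the inferred factor.
#' @export
inferDilutionFactor <- function(doses) {
  if (length(doses) < 2L) stop("need at least 2 doses")
  exp(mean(diff(log(rev(doses)))))
}

#' Normalize raw signal to DMSO controls
#'
#' Each well is divided by the mean of the designated vehicle-control wells
#' on the same plate. Values above 1 (wells outgrowing the control) are
#' kept as-is.
#'
#' @param raw numeric vector/matrix/array of raw RLU values.
#' @param controlWells raw RLU of at least two control wells.
#' @return viability fractions, same shape as \code{raw}.
#' @export
normalizeToControl <- function(raw, controlWells) {
  controlWells <- controlWells[!is.na(controlWells)]
  if (length(controlWells) < 2L)
    stop("at least 2 control wells are required")
  m <- mean(controlWells)
  if (!is.finite(m) || m <= 0) stop("non-positive control mean")
  raw / m
}

#' Assemble a combination dose matrix from normalized wells
#'
#' Builds the \code{(n+1) x (n+1) x nrep} replicate viability surface of a
#' two-drug checkerboard from long-format wells, with the zero-dose
#' monotherapy edges and (0, 0) control in place. Wells absent from the
#' input are recorded as \code{NA} under the default \code{"mask"} policy —
#' never imputed — and downstream score sums skip them with explicit
#' well-count bookkeeping.
#'
#' @param wells data.frame with columns \code{doseA}, \code{doseB},
#'   \code{replicate}, \code{viability} (fractions, DMSO-normalized).
#' @param culture,drugA,drugB identifiers.
#' @param dosesA,dosesB optional expected descending ladders; when given,
#'   the observed nonzero doses must match exactly (guards against swapped
#'   axes), otherwise ladders are inferred from the data.
#' @param dilutionFactor configured serial dilution factor (recorded and
#'   checked by the class validity; use \code{NA} to skip the check).
#' @param missingPolicy \code{"mask"} (default: record missing wells as NA)
#'   or \code{"fail"}.
#' @param maxMissing maximum tolerated fraction of missing wells (0.2).
#' @return a [DoseMatrix-class].
#' @export
assembleMatrix <- function(wells, culture = NA_character_,
                           drugA = NA_character_, drugB = NA_character_,
                           dosesA = NULL, dosesB = NULL,
                           dilutionFactor = 3,
                           missingPolicy = c("mask", "fail"),
                           maxMissing = 0.2) {
  missingPolicy <- match.arg(missingPolicy)
  dilutionFactor <- as.numeric(dilutionFactor)
  stopifnot(all(c("doseA", "doseB", "replicate", "viability") %in%
                names(wells)))
  if (anyDuplicated(wells[c("doseA", "doseB", "replicate")]))
    stop("duplicate well keys (doseA, doseB, replicate)")

  obsA <- sort(unique(wells$doseA[wells$doseA > 0]), decreasing = TRUE)
  obsB <- sort(unique(wells$doseB[wells$doseB > 0]), decreasing = TRUE)
  for (ax in list(list("A", dosesA, obsA), list("B", dosesB, obsB))) {
    if (!is.null(ax[[2L]])) {
      exp_ <- sort(ax[[2L]], decreasing = TRUE)
      if (length(exp_) != length(ax[[3L]]) ||
          any(abs(exp_ - ax[[3L]]) > 1e-9 * exp_))
        stop(sprintf("observed doses on axis %s do not match the expected ladder (swapped axes?)", ax[[1L]]))
    }
  }
  if (is.null(dosesA)) dosesA <- obsA
  if (is.null(dosesB)) dosesB <- obsB

  axA <- c(0, rev(sort(dosesA, decreasing = TRUE)))
  axB <- c(0, rev(sort(dosesB, decreasing = TRUE)))
  reps <- sort(unique(wells$replicate))
  arr <- array(NA_real_,
               dim = c(length(axA), length(axB), length(reps)),
               dimnames = list(doseA = signif(axA, 7),
                               doseB = signif(axB, 7),
                               replicate = reps))
  snap <- function(d, ax) {
    i <- vapply(d, function(x) which.min(abs(ax - x)), integer(1L))
    off <- abs(d - ax[i]) > 1e-6 * pmax(d, ax[i]) & (d > 0 | ax[i] > 0)
    if (any(off)) stop("wells with doses outside the design grid")
    i
  }
  ia <- snap(wells$doseA, axA)
  ib <- snap(wells$doseB, axB)
  ir <- match(wells$replicate, reps)
  arr[cbind(ia, ib, ir)] <- wells$viability

  missFrac <- mean(is.na(arr))
  if (missFrac > maxMissing)
    stop(sprintf("%.0f%% of wells missing (> %.0f%% allowed)",
                 100 * missFrac, 100 * maxMissing))
  if (missFrac > 0 && missingPolicy == "fail")
    stop("missing wells with policy 'fail'")

  ctrl <- mean(arr[1L, 1L, ], na.rm = TRUE)
  if (is.finite(ctrl) && (ctrl < 0.9 || ctrl > 1.1))
    warning(sprintf("control well mean %.3f outside [0.9, 1.1] after normalization", ctrl))

  new("DoseMatrix", culture = culture, drugA = drugA, drugB = drugB,
      dosesA = sort(dosesA, decreasing = TRUE),
      dosesB = sort(dosesB, decreasing = TRUE),
      viability = arr, dilutionFactor = dilutionFactor)
}

#' Read / write the plate-map well table
#'
#' The screen's interchange format: one row per dispensed well with columns
#' \code{plate, well, culture, drug_a, dose_a_um, drug_b, dose_b_um,
#' replicate, rlu, is_control}.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readPlateMap <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "well", "culture", "drug_a", "dose_a_um",
            "drug_b", "dose_b_um", "replicate", "rlu", "is_control")
  miss <- setdiff(need, names(pm))
  if (length(miss))
    stop("plate map lacks columns: ", paste(miss, collapse = ", "))
  pm$is_control <- as.logical(pm$is_control)
  pm
}

#' @rdname readPlateMap
#' @param pm plate-map data.frame.
#' @export
writePlateMap <- function(pm, path) {
  utils::write.csv(pm, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble every combination matrix of a screen
#'
#' Groups a plate map by plate, normalizes each plate's wells to its own
#' DMSO controls, and assembles one [DoseMatrix-class] per
#' (combination, culture).
#'
#' @param pm plate-map data.frame (see [readPlateMap()]) or a
#'   [SynthScreen-class].
#' @param dilutionFactor recorded dilution factor.
#' @param ... passed to [assembleMatrix()].
#' @return named list of [DoseMatrix-class], names
#'   \code{"<drugA>+<drugB>|<culture>"}.
#' @export
assembleScreen <- function(pm, dilutionFactor = 3, ...) {
  if (is(pm, "SynthScreen")) {
    dilutionFactor <- pm@config$dilutionFactor
    pm <- plateMap(pm)
  }
  out <- list()
  for (pl in unique(pm$plate)) {
    sub <- pm[pm$plate == pl, , drop = FALSE]
    ctrl <- sub$rlu[sub$is_control]
    wells <- sub[!sub$is_control, , drop = FALSE]
    viab <- normalizeToControl(wells$rlu, ctrl)
    w <- data.frame(doseA = wells$dose_a_um, doseB = wells$dose_b_um,
                    replicate = wells$replicate, viability = viab)
    mat <- suppressWarnings(assembleMatrix(
      w, culture = wells$culture[1L],
      drugA = wells$drug_a[1L], drugB = wells$drug_b[1L],
      dilutionFactor = dilutionFactor, ...))
    out[[paste0(mat@drugA, "+", mat@drugB, "|", mat@culture)]] <- mat
  }
  out
}

#' Tidy export of a dose matrix
#'
#' @param mat a [DoseMatrix-class].
#' @return data.frame with one row per (dose_a, dose_b, replicate).
#' @export
tidyViability <- function(mat) {
  axA <- doseAxis(mat, "A", full = TRUE)
  axB <- doseAxis(mat, "B", full = TRUE)
  dm <- dim(mat@viability)
  g <- expand.grid(ia = seq_len(dm[1L]), ib = seq_len(dm[2L]),
                   rep = seq_len(dm[3L]))
  data.frame(
    culture = mat@culture, drug_a = mat@drugA, drug_b = mat@drugB,
    dose_a_um = axA[g$ia], dose_b_um = axB[g$ib], replicate = g$rep,
    viability = mat@viability[as.matrix(g)],
    stringsAsFactors = FALSE)
}
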