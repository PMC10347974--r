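EVENT_CATEGORIES <- c("amplification", "deep_deletion", "gain", "loss",
                      "mutation", "none")

# half-up integer rounding (reporting convention for percentages)
roundHalfUp <- function(x) floor(x + 0.5)

#' Construct a patient x gene alteration table
#'
#' @param events data.frame with columns \code{patient}, \code{gene},
#'   \code{event}; every (patient, gene) pair at most once, categories in
#'   \code{amplification, deep_deletion, gain, loss, mutation, none}.
#'   Pairs absent from the table are treated as \code{"none"}.
#' @param driverRules named list: per gene, the categories that count as a
#'   driving event (e.g. homozygous loss for tumor suppressors,
#'   amplification/mutation for oncogenes).
#' @return list of class \code{"AlterationTable"}.
#' @export
alterationTable <- function(events, driverRules) {
  stopifnot(all(c("patient", "gene", "event") %in% names(events)))
  bad <- setdiff(unique(events$event), EVENT_CATEGORIES)
  if (length(bad))
    stop("unknown event categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(events[c("patient", "gene")]))
    stop("each (patient, gene) must appear at most once")
  badRule <- setdiff(unlist(driverRules), EVENT_CATEGORIES)
  if (length(badRule))
    stop("unknown categories in driver rules: ",
         paste(badRule, collapse = ", "))
  structure(list(events = events,
                 patients = unique(events$patient),
                 genes = unique(events$gene),
                 driverRules = driverRules),
            class = "AlterationTable")
}

#' Driver-event frequencies and per-patient driver status
#'
#' For each gene, the percentage of patients carrying a driving event
#' (per the gene's driver rules); a patient is driver-positive when any
#' gene carries a driving event. Percentages are rounded half-up to
#' integers for reporting.
#'
#' @param table an \code{"AlterationTable"}.
#' @return list: \code{geneFrequencies} (gene, nDriving, pct),
#'   \code{patientStatus} (patient, driverPositive),
#'   \code{driverPositivePct} and \code{driverNegativePct} (integer
#'   percentages of the cohort).
#' @export
eventFrequencies <- function(table) {
  stopifnot(inherits(table, "AlterationTable"))
  ev <- table$events
  if (!nrow(ev)) stop("empty alteration table")
  nPat <- length(table$patients)
  driving <- logical(nrow(ev))
  for (g in unique(ev$gene)) {
    rules <- table$driverRules[[g]]
    if (is.null(rules)) rules <- character(0)
    sel <- ev$gene == g
    driving[sel] <- ev$event[sel] %in% setdiff(rules, "none")
  }
  geneFreq <- do.call(rbind, lapply(table$genes, function(g) {
    n <- length(unique(ev$patient[ev$gene == g & driving]))
    data.frame(gene = g, nDriving = n,
               pct = roundHalfUp(100 * n / nPat),
               stringsAsFactors = FALSE)
  }))
  posPatients <- unique(ev$patient[driving])
  status <- data.frame(patient = table$patients,
                       driverPositive = table$patients %in% posPatients,
                       stringsAsFactors = FALSE)
  nPos <- sum(status$driverPositive)
  list(geneFrequencies = geneFreq, patientStatus = status,
       driverPositivePct = roundHalfUp(100 * nPos / nPat),
       driverNegativePct = roundHalfUp(100 * (nPat - nPos) / nPat))
}

#' Driver / non-driver composition of a combination panel
#'
#' @param nDriver number of combinations targeting driver-gene proteins.
#' @param nNonDriver number of combinations for non-drivers.
#' @return named integer percentages (half-up rounding) summing to
#'   100 +/- 1.
#' @examples
#' selectionComposition(61, 29)  # 68 / 32
#' @export
selectionComposition <- function(nDriver, nNonDriver) {
  if (nDriver < 0 || nNonDriver < 0) stop("counts must be >= 0")
  tot <- nDriver + nNonDriver
  if (tot == 0) stop("at least one count must be positive")
  c(driver = roundHalfUp(100 * nDriver / tot),
    nonDriver = roundHalfUp(100 * nNonDriver / tot))
}

#' Load the packaged combination panel table
#'
#' Reads the panel of screened drug combinations (drug names, annotated
#' targets and the external prediction synergy scores on a 0-520 scale)
#' shipped as a plain TSV. Rows whose score was not calculated keep the
#' sentinel as \code{NA} with \code{scoreCalculated = FALSE}.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return data.frame: number, drug_1, target_1, drug_2, target_2,
#'   prediction_score (integer, NA when not calculated), scoreCalculated.
#' @export
loadTable1 <- function(path = system.file("extdata",
                                          "table1_combinations.tsv",
                                          package = "synergyscreen")) {
  if (!nzchar(path) || !file.exists(path)) stop("fixture not found")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("number", "drug_1", "target_1", "drug_2", "target_2",
            "prediction_score")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("fixture lacks columns: ",
                         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    if (any(!nzchar(trimws(unlist(r[need])))))
      stop(sprintf("malformed row %d: empty field", i))
    s <- trimws(r$prediction_score)
    if (s != "Not calculated" && is.na(suppressWarnings(as.integer(s))))
      stop(sprintf("malformed row %d: score '%s'", i, s))
  }
  score <- suppressWarnings(as.integer(raw$prediction_score))
  calc <- trimws(raw$prediction_score) != "Not calculated"
  if (any(!is.na(score) & (score < 0 | score > 520)))
    stop("prediction scores must lie in [0, 520]")
  data.frame(number = as.integer(raw$number),
             drug_1 = raw$drug_1, target_1 = raw$target_1,
             drug_2 = raw$drug_2, target_2 = raw$target_2,
             prediction_score = score, scoreCalculated = calc,
             stringsAsFactors = FALSE)
}
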