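#' Configuration for a synthetic combination screen
#'
#' The generator emulates the screen's design: per-(drug, culture) Hill
#' monotherapy curves, 6-level 3-fold checkerboards whose top dose is
#' anchored at each drug's true absolute IC50 on that culture (insensitive
#' curves fall back to a fixed 10 uM top), multiplicative (Bliss-baseline)
#' combination responses with an injected interaction for a designated
#' synergistic subset, truncated Gaussian replicate noise, and raw RLU
#' emission with on-plate DMSO controls so the normalization path is
#' exercised end to end.
#'
#' @param nCombinations number of drug combinations (each with its own
#'   drug pair).
#' @param nCultures number of cultures.
#' @param nSynergistic how many combinations carry the injected
#'   interaction (must be <= nCombinations).
#' @param interactionDelta per-well Bliss-excess magnitude (viability
#'   fraction, in [0, 0.5]) at the weight peak.
#' @param interactionWeight \code{"bump"}: a unimodal weight peaking
#'   mid-grid (so the zero-dose edges stay honest monotherapies and the
#'   excess fades toward the grid rim), or \code{"flat"}: weight 1 on
#'   every combination well.
#' @param noiseSd Gaussian viability noise SD per replicate well
#'   (truncated at 0, clipped at 1.2).
#' @param nReplicates technical replicates per well.
#' @param dilutionFactor,nLevels dose ladder design (3-fold, 6 levels).
#' @param hillPriors ranges for the generating Hill parameters:
#'   list(e0, einf, h: uniform ranges; ec50: log-uniform range in uM).
#' @param fallbackTop top dose (uM) for curves whose absolute IC50 is not
#'   reached.
#' @param insensitiveDrugs drug ids forced to a high floor
#'   (einf in [0.6, 0.9], IC50 never reached) on every culture.
#' @param nControlWells DMSO control wells per plate.
#' @param controlRLU mean raw signal of a fully viable well.
#' @param seed integer seed; the screen is bit-reproducible given the
#'   config.
#' @return list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(nCombinations = 40L, nCultures = 10L,
                        nSynergistic = 10L,
                        interactionDelta = 0.15,
                        interactionWeight = c("bump", "flat"),
                        noiseSd = 0.05, nReplicates = 2L,
                        dilutionFactor = 3, nLevels = 6L,
                        hillPriors = list(e0 = c(0.95, 1.05),
                                          einf = c(0, 0.4),
                                          ec50 = c(0.01, 2),
                                          h = c(0.8, 2.5)),
                        fallbackTop = 10,
                        insensitiveDrugs = character(0),
                        nControlWells = 16L,
                        controlRLU = 1e6,
                        seed = 1L) {
  cfg <- list(nCombinations = as.integer(nCombinations),
              nCultures = as.integer(nCultures),
              nSynergistic = as.integer(nSynergistic),
              interactionDelta = interactionDelta,
              interactionWeight = match.arg(interactionWeight),
              noiseSd = noiseSd, nReplicates = as.integer(nReplicates),
              dilutionFactor = dilutionFactor, nLevels = as.integer(nLevels),
              hillPriors = hillPriors, fallbackTop = fallbackTop,
              insensitiveDrugs = insensitiveDrugs,
              nControlWells = as.integer(nControlWells),
              controlRLU = controlRLU, seed = as.integer(seed))
  if (cfg$nSynergistic > cfg$nCombinations)
    stop("nSynergistic must be <= nCombinations")
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0")
  if (cfg$interactionDelta < 0 || cfg$interactionDelta > 0.5)
    stop("interactionDelta must lie in [0, 0.5]")
  if (cfg$nControlWells < 2L) stop("need at least 2 control wells")
  class(cfg) <- "SynthConfig"
  cfg
}

# unimodal interaction weight over the n x n combination block, peak 1 at
# the grid center, fading toward the rim
interactionWeights <- function(n, kind) {
  if (kind == "flat") return(matrix(1, n, n))
  mid <- (n + 1) / 2
  w1 <- exp(-((seq_len(n) - mid)^2) / (2 * (n / 4)^2))
  outer(w1, w1)
}

#' Simulate a complete combination screen with known ground truth
#'
#' See [synthConfig()] for what is emulated. Monotherapy wells follow the
#' sampled Hill curves; combination wells are
#' \eqn{v_a v_b - \delta\, w(a, b)} for the synergistic subset (with
#' \eqn{w} the configured interaction weight) and \eqn{v_a v_b} otherwise;
#' truncated Gaussian noise is added per replicate and raw RLUs are
#' emitted with DMSO control wells per plate.
#'
#' @param config a \code{"SynthConfig"}.
#' @return a [SynthScreen-class].
#' @export
simulateScreen <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  nc <- config$nCombinations; nl <- config$nCultures
  pr <- config$hillPriors

  combos <- data.frame(
    combination = character(nc), drugA = character(nc),
    drugB = character(nc),
    synergistic = rep(c(TRUE, FALSE),
                      c(config$nSynergistic, nc - config$nSynergistic)),
    delta = rep(c(config$interactionDelta, 0),
                c(config$nSynergistic, nc - config$nSynergistic)),
    stringsAsFactors = FALSE)
  combos$drugA <- sprintf("D%02da", seq_len(nc))
  combos$drugB <- sprintf("D%02db", seq_len(nc))
  combos$combination <- paste0(combos$drugA, "+", combos$drugB)

  cultures <- sprintf("GSC%02d", seq_len(nl))
  drugs <- c(rbind(combos$drugA, combos$drugB))

  # generating Hill parameters per (drug, culture)
  truth <- expand.grid(drug = drugs, culture = cultures,
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  nt <- nrow(truth)
  truth$e0 <- stats::runif(nt, pr$e0[1L], pr$e0[2L])
  truth$einf <- stats::runif(nt, pr$einf[1L], pr$einf[2L])
  truth$ec50 <- exp(stats::runif(nt, log(pr$ec50[1L]), log(pr$ec50[2L])))
  truth$h <- stats::runif(nt, pr$h[1L], pr$h[2L])
  ins <- truth$drug %in% config$insensitiveDrugs
  if (any(ins)) truth$einf[ins] <- stats::runif(sum(ins), 0.6, 0.9)

  # top dose anchored at the true absolute IC50 (fallback when unreached)
  ic50 <- ifelse(truth$einf < 0.5 & truth$e0 > 0.5,
                 truth$ec50 * ((truth$e0 - 0.5) /
                               (0.5 - truth$einf))^(1 / truth$h),
                 NA_real_)
  truth$topDose <- ifelse(is.na(ic50), config$fallbackTop, ic50)

  n <- config$nLevels
  w <- interactionWeights(n, config$interactionWeight)
  nrep <- config$nReplicates
  key <- function(d, l) paste(d, l, sep = "|")
  truthIdx <- stats::setNames(seq_len(nt), key(truth$drug, truth$culture))

  pmList <- vector("list", nc * nl)
  nNegative <- 0L; nComboWells <- 0L
  ctrlIds <- sprintf("CTRL%02d", seq_len(config$nControlWells))
  for (ci in seq_len(nc)) {
    for (li in seq_len(nl)) {
      ta <- truth[truthIdx[[key(combos$drugA[ci], cultures[li])]], ]
      tb <- truth[truthIdx[[key(combos$drugB[ci], cultures[li])]], ]
      dosesA <- buildDoseLadder(ta$topDose, config$dilutionFactor, n)
      dosesB <- buildDoseLadder(tb$topDose, config$dilutionFactor, n)
      axA <- c(0, rev(dosesA)); axB <- c(0, rev(dosesB))
      va <- hillViability(axA, ta$e0, ta$einf, ta$ec50, ta$h)
      vb <- hillViability(axB, tb$e0, tb$einf, tb$ec50, tb$h)
      vtrue <- outer(va, vb)
      if (combos$delta[ci] > 0) {
        block <- vtrue[-1L, -1L] - combos$delta[ci] * w
        nNegative <- nNegative + sum(block < 0)
        vtrue[-1L, -1L] <- pmax(block, 0)
      }
      nComboWells <- nComboWells + n * n

      g <- expand.grid(ia = seq_len(n + 1L), ib = seq_len(n + 1L),
                       rep = seq_len(nrep))
      vobs <- vtrue[cbind(g$ia, g$ib)] +
        stats::rnorm(nrow(g), 0, config$noiseSd)
      vobs <- pmin(pmax(vobs, 0), 1.2)
      vctrl <- pmin(pmax(1 + stats::rnorm(config$nControlWells, 0,
                                          config$noiseSd), 0), 1.2)
      plate <- sprintf("P%02d_%s", ci, cultures[li])
      pmList[[(ci - 1L) * nl + li]] <- data.frame(
        plate = plate,
        well = c(sprintf("R%dC%dr%d", g$ia, g$ib, g$rep), ctrlIds),
        culture = cultures[li],
        drug_a = c(rep(combos$drugA[ci], nrow(g)),
                   rep("DMSO", config$nControlWells)),
        dose_a_um = c(axA[g$ia], rep(0, config$nControlWells)),
        drug_b = c(rep(combos$drugB[ci], nrow(g)),
                   rep("DMSO", config$nControlWells)),
        dose_b_um = c(axB[g$ib], rep(0, config$nControlWells)),
        replicate = c(g$rep, rep(0L, config$nControlWells)),
        rlu = config$controlRLU * c(vobs, vctrl),
        is_control = c(rep(FALSE, nrow(g)),
                       rep(TRUE, config$nControlWells)),
        stringsAsFactors = FALSE)
    }
  }
  if (nComboWells > 0 && nNegative / nComboWells > 0.1)
    warning(sprintf(
      "interaction delta drives %.0f%% of combination wells below 0 pre-truncation",
      100 * nNegative / nComboWells))

  new("SynthScreen", plateMap = do.call(rbind, pmList),
      hillTruth = truth, combinations = combos,
      config = unclass(config))
}

#' Isotropic Gaussian blobs with known labels
#'
#' Clustering test harness: \code{k} unit-SD isotropic Gaussian clusters
#' in \code{dim} dimensions whose centers are mutually at least
#' \code{sep} SDs apart (placed on a circle in the first two coordinates).
#'
#' @param k number of clusters (>= 1).
#' @param nPer points per cluster.
#' @param sep minimal pairwise center distance in SD multiples.
#' @param seed random seed.
#' @param dim feature dimension (>= 2).
#' @return list with \code{features} (matrix, rownames \code{"b1"}...)
#'   and \code{labels} (integer vector).
#' @export
makeBlobs <- function(k, nPer, sep = 5, seed = 1L, dim = 2L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  set.seed(seed)
  centers <- matrix(0, k, dim)
  if (k >= 2L && sep > 0) {
    r <- sep / (2 * sin(pi / k))
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    centers[, 1L] <- r * cos(ang)
    centers[, 2L] <- r * sin(ang)
  }
  labels <- rep(seq_len(k), each = nPer)
  features <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(length(labels) * dim), ncol = dim)
  rownames(features) <- sprintf("b%d", seq_along(labels))
  list(features = features, labels = labels)
}
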