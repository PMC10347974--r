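#' Accessors for screen objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugNames", function(x, ...) standardGeneric("drugNames"))

#' @rdname accessors
#' @export
setGeneric("cultureName", function(x, ...) standardGeneric("cultureName"))

#' @rdname accessors
#' @export
setGeneric("doseAxis", function(x, axis, ...) standardGeneric("doseAxis"))

#' @rdname accessors
#' @export
setGeneric("replicateMeans", function(x, ...) standardGeneric("replicateMeans"))

#' @rdname accessors
#' @export
setGeneric("comboWells", function(x, ...) standardGeneric("comboWells"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("panelValues", function(x, ...) standardGeneric("panelValues"))

#' @rdname accessors
#' @export
setGeneric("panelZ", function(x, ...) standardGeneric("panelZ"))

#' @rdname accessors
#' @export
setGeneric("panelSummary", function(x, ...) standardGeneric("panelSummary"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("plateMap", function(x, ...) standardGeneric("plateMap"))

#' @rdname accessors
#' @export
setMethod("drugNames", "DoseMatrix", function(x, ...) c(x@drugA, x@drugB))

#' @rdname accessors
#' @export
setMethod("cultureName", "DoseMatrix", function(x, ...) x@culture)

#' @rdname accessors
#' @param axis "A" or "B".
#' @param full if \code{TRUE}, return the ascending axis including the
#'   leading zero dose (the order of the viability array); otherwise the
#'   stored descending ladder.
#' @export
setMethod("doseAxis", "DoseMatrix", function(x, axis = c("A", "B"),
                                             full = FALSE, ...) {
  axis <- match.arg(axis)
  d <- slot(x, paste0("doses", axis))
  if (full) c(0, rev(d)) else d
})

#' @rdname accessors
#' @export
setMethod("replicateMeans", "DoseMatrix", function(x, ...) {
  apply(x@viability, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
})

#' @rdname accessors
#' @details \code{comboWells} returns the replicate-mean viability of the
#'   nonzero-dose block only (doses ascending on both axes).
#' @export
setMethod("comboWells", "DoseMatrix", function(x, ...) {
  m <- replicateMeans(x)
  m[-1L, -1L, drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterModel", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("panelValues", "MetricPanel", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("panelZ", "MetricPanel", function(x, ...) {
  if (!length(x@zvalues)) stop("panel has not been z-scaled; run zscale()")
  x@zvalues
})

#' @rdname accessors
#' @export
setMethod("panelSummary", "MetricPanel", function(x, ...) {
  if (!length(x@summary)) stop("panel has not been z-scaled; run zscale()")
  x@summary
})

#' @rdname accessors
#' @export
setMethod("groundTruth", "SynthScreen", function(x, ...) x@combinations)

#' @rdname accessors
#' @export
setMethod("plateMap", "SynthScreen", function(x, ...) x@plateMap)
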