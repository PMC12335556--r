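#' Accessors for qebss classes
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param object a qebss S4 object.
#' @return The requested component; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameCount", function(object) standardGeneric("frameCount"))

#' @rdname accessors
#' @export
setMethod("frameCount", "TrajectoryHandle", function(object) {
  dim(object@coords)[3]
})

#' @rdname accessors
#' @export
setGeneric("frameSpacing", function(object) standardGeneric("frameSpacing"))

#' @rdname accessors
#' @export
setMethod("frameSpacing", "TrajectoryHandle", function(object) {
  if (frameCount(object) < 2L) return(NA_real_)
  diff(object@times[1:2])
})

#' @rdname accessors
#' @export
setMethod("frameSpacing", "VectorSeries", function(object) {
  if (length(object@times) < 2L) return(NA_real_)
  diff(object@times[1:2])
})

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setMethod("frameTimes", "TrajectoryHandle", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("frameTimes", "VectorSeries", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setMethod("atomTable", "TrajectoryHandle", function(object) object@atoms)

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname accessors
#' @export
setMethod("coords", "TrajectoryHandle", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("residueId", function(object) standardGeneric("residueId"))

#' @rdname accessors
#' @export
setMethod("residueId", "VectorSeries", function(object) object@residueId)

#' @rdname accessors
#' @export
setMethod("residueId", "CorrelationFunction", function(object) {
  object@residueId
})

#' @rdname accessors
#' @export
setGeneric("residueIds", function(object) standardGeneric("residueIds"))

#' @rdname accessors
#' @export
setMethod("residueIds", "RelaxationProfile", function(object) {
  object@residueIds
})

#' @rdname accessors
#' @export
setGeneric("bondVectors", function(object) standardGeneric("bondVectors"))

#' @rdname accessors
#' @export
setMethod("bondVectors", "VectorSeries", function(object) object@vectors)

#' @rdname accessors
#' @export
setGeneric("acfLags", function(object) standardGeneric("acfLags"))

#' @rdname accessors
#' @export
setMethod("acfLags", "CorrelationFunction", function(object) object@lags)

#' @rdname accessors
#' @export
setGeneric("acfValues", function(object) standardGeneric("acfValues"))

#' @rdname accessors
#' @export
setMethod("acfValues", "CorrelationFunction", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("nContributing", function(object) standardGeneric("nContributing"))

#' @rdname accessors
#' @export
setMethod("nContributing", "CorrelationFunction", function(object) {
  object@nContributing
})

#' @rdname accessors
#' @export
setGeneric("taus", function(object) standardGeneric("taus"))

#' @rdname accessors
#' @export
setMethod("taus", "TimescaleGrid", function(object) object@taus)

#' @rdname accessors
#' @export
setMethod("taus", "TimescaleSpectrum", function(object) object@grid@taus)

#' @rdname accessors
#' @export
setGeneric("alphas", function(object) standardGeneric("alphas"))

#' @rdname accessors
#' @export
setMethod("alphas", "TimescaleSpectrum", function(object) object@alphas)

#' @rdname accessors
#' @export
setGeneric("fitResidual", function(object) standardGeneric("fitResidual"))

#' @rdname accessors
#' @export
setMethod("fitResidual", "TimescaleSpectrum", function(object) {
  object@fitResidual
})

#' @rdname accessors
#' @export
setGeneric("fieldMhz", function(object) standardGeneric("fieldMhz"))

#' @rdname accessors
#' @export
setMethod("fieldMhz", "RelaxationProfile", function(object) object@fieldMhz)

#' @rdname accessors
#' @export
setMethod("fieldMhz", "NMRParams", function(object) object@fieldMhz)

#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))

#' @rdname accessors
#' @export
setMethod("qValues", "SAXSProfile", function(object) object@q)

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setMethod("intensities", "SAXSProfile", function(object) object@intensity)

#' @rdname accessors
#' @export
setGeneric("selectedIds", function(object) standardGeneric("selectedIds"))

#' @rdname accessors
#' @export
setMethod("selectedIds", "SelectionResult", function(object) {
  object@selectedIds
})

#' @rdname accessors
#' @export
setGeneric("comparisonTable", function(object) {
  standardGeneric("comparisonTable")
})

#' @rdname accessors
#' @export
setMethod("comparisonTable", "SelectionResult", function(object) {
  object@ratios
})

#' @rdname accessors
#' @export
setGeneric("rmsdValues", function(object) standardGeneric("rmsdValues"))

#' @rdname accessors
#' @export
setMethod("rmsdValues", "SelectionResult", function(object) object@rmsd)

#' @rdname accessors
#' @export
setGeneric("bestPerObservable", function(object) {
  standardGeneric("bestPerObservable")
})

#' @rdname accessors
#' @export
setMethod("bestPerObservable", "SelectionResult", function(object) {
  object@bestPerObservable
})

#' Convert a RelaxationProfile to a data.frame
#'
#' @param x a [RelaxationProfile-class].
#' @param row.names,optional,... ignored, present for the generic.
#' @return data.frame with columns `residue`, `t1`, `t2`, `hetnoe` and the
#'   error columns.
#' @export
as.data.frame.RelaxationProfile <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(
    residue = x@residueIds,
    t1 = x@t1, t2 = x@t2, hetnoe = x@hetnoe,
    t1_err = x@t1Err, t2_err = x@t2Err, noe_err = x@noeErr
  )
}

#' @export
setMethod("as.data.frame", "RelaxationProfile", as.data.frame.RelaxationProfile)

#' Convert a SAXSProfile to a data.frame
#'
#' @param x a [SAXSProfile-class].
#' @param row.names,optional,... ignored.
#' @return data.frame with columns `q`, `intensity` and optionally `sigma`.
#' @export
as.data.frame.SAXSProfile <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  out <- data.frame(q = x@q, intensity = x@intensity)
  if (length(x@sigma)) out$sigma <- x@sigma
  out
}

#' @export
setMethod("as.data.frame", "SAXSProfile", as.data.frame.SAXSProfile)
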