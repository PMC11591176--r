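## Generics and accessors. Slot access from user code should go through these.

#' @rdname EcgRecord-class
#' @param object,x An object.
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname EcgRecord-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname EcgRecord-class
#' @export
setGeneric("efClass", function(x) standardGeneric("efClass"))
#' @rdname EcgRecord-class
#' @export
setGeneric("lvef", function(x) standardGeneric("lvef"))
#' @rdname EcgRecord-class
#' @export
setGeneric("isAF", function(x) standardGeneric("isAF"))
#' @rdname EcgRecord-class
#' @export
setGeneric("truthBeats", function(x) standardGeneric("truthBeats"))
#' @rdname EcgRecord-class
#' @export
setGeneric("waveTable", function(x) standardGeneric("waveTable"))
#' @rdname BeatTensor-class
#' @param x An object.
#' @export
setGeneric("tensorData", function(x) standardGeneric("tensorData"))
#' @rdname BeatTensor-class
#' @export
setGeneric("tensorLeads", function(x) standardGeneric("tensorLeads"))

#' @rdname EcgRecord-class
#' @export
setMethod("caseId", "EcgRecord", function(x) x@caseId)
#' @rdname EcgRecord-class
#' @export
setMethod("signalMatrix", "EcgRecord", function(x) x@signal)
#' @rdname EcgRecord-class
#' @export
setMethod("efClass", "EcgRecord", function(x) x@efClass)
#' @rdname EcgRecord-class
#' @export
setMethod("lvef", "EcgRecord", function(x) x@lvef)
#' @rdname EcgRecord-class
#' @export
setMethod("isAF", "EcgRecord", function(x) x@af)
#' @rdname EcgRecord-class
#' @export
setMethod("truthBeats", "EcgRecord", function(x) x@truth)
#' @rdname EcgRecord-class
#' @export
setMethod("waveTable", "EcgRecord", function(x) x@waveTable)

#' @rdname BeatTensor-class
#' @export
setMethod("tensorData", "BeatTensor", function(x) x@data)
#' @rdname BeatTensor-class
#' @export
setMethod("tensorLeads", "BeatTensor", function(x) x@leads)
#' @rdname StripTensor-class
#' @param x A `StripTensor`.
#' @export
setMethod("tensorData", "StripTensor", function(x) x@data)

#' @rdname EcgCohort-class
#' @param x An `EcgCohort`.
#' @export
setMethod("length", "EcgCohort", function(x) length(x@records))

#' @rdname EcgCohort-class
#' @param i Index.
#' @param ... Ignored.
#' @export
setMethod("[[", "EcgCohort", function(x, i, ...) x@records[[i]])

#' @rdname EcgCohort-class
#' @export
setGeneric("cohortRecords", function(x) standardGeneric("cohortRecords"))
#' @rdname EcgCohort-class
#' @export
setMethod("cohortRecords", "EcgCohort", function(x) x@records)

#' Cohort manifest
#'
#' Summarises a cohort as one row per case: id, LVEF, EF class, binary label
#' (reduced LVEF < 50) and AF status.
#'
#' @param x An [EcgCohort-class].
#' @return A data.frame with columns `case_id`, `lvef`, `ef_class`,
#'   `reduced`, `af`.
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))
#' @rdname cohortManifest
#' @export
setMethod("cohortManifest", "EcgCohort", function(x) {
  data.frame(
    case_id = vapply(x@records, caseId, character(1L)),
    lvef = vapply(x@records, lvef, numeric(1L)),
    ef_class = vapply(x@records, efClass, character(1L)),
    reduced = vapply(x@records, function(r) efClass(r) != "pEF", logical(1L)),
    af = vapply(x@records, isAF, logical(1L)),
    stringsAsFactors = FALSE)
})

## show methods -------------------------------------------------------------

setMethod("show", "EcgRecord", function(object) {
  cat(sprintf("EcgRecord '%s': 12 x 5000 @ %g Hz, LVEF %.1f%% (%s)%s, %d beats\n",
              object@caseId, object@samplingRate, object@lvef,
              object@efClass, if (object@af) ", AF" else "",
              nrow(object@truth)))
})

setMethod("show", "EcgCohort", function(object) {
  cls <- table(factor(vapply(object@records, efClass, character(1L)),
                      levels = .EF_CLASSES))
  cat(sprintf("EcgCohort: %d records (pEF %d, mrEF %d, rEF %d), seed %d\n",
              length(object@records), cls[["pEF"]], cls[["mrEF"]],
              cls[["rEF"]], object@config@seed))
})

setMethod("show", "BeatTensor", function(object) {
  cat(sprintf("BeatTensor [%s] %d x %d (%s, beat %d of %s)\n",
              object@kind, nrow(object@data), ncol(object@data),
              object@segment, object@beatIndex, object@recordId))
})

setMethod("show", "StripTensor", function(object) {
  cat(sprintf("StripTensor 12 x 1500 (offset %d, %s)\n",
              object@startOffset, object@recordId))
})

setMethod("show", "Standardiser", function(object) {
  cat(sprintf("Standardiser: mean %.6g mV, sd %.6g mV\n",
              object@mean, object@sd))
})

setMethod("show", "FoldPlan", function(object) {
  sizes <- vapply(object@subsets, length, integer(1L))
  cat(sprintf("FoldPlan: %d cases in subsets [%s]; subset 5 is the fixed test set\n",
              sum(sizes), paste(sizes, collapse = ", ")))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %d ch x %d -> %d conv blocks [%s] -> %d classes (%d weighted layers)\n",
              object@inChannels, object@inputLen, length(object@filters),
              paste(object@filters, collapse = ","), object@nClasses,
              nWeightedLayers(object)))
})

setMethod("show", "EcgClassifier", function(object) {
  np <- sum(vapply(object@params, length, integer(1L)))
  cat(sprintf("EcgClassifier: %d weighted layers, %d parameters%s\n",
              nWeightedLayers(object@config), np,
              if (isTRUE(object@state$trained)) " (trained)" else ""))
})
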