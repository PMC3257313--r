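#' @include parameter-set.R
NULL

#' Evaluate a rate law at a given state
#'
#' Dispatches over the rate-law families. Rates are in mM s^-1; states are
#' named concentration vectors in mM.
#'
#' @param law A [RateLaw-class] object.
#' @param state Named numeric vector of species concentrations (mM).
#' @param params A [ParameterSet-class] or named numeric vector.
#' @param ... Further arguments passed to methods.
#' @return A single numeric rate (mM s^-1).
#' @export
setGeneric("evaluateRate", function(law, state, params, ...)
  standardGeneric("evaluateRate"))

#' @rdname speciesTable
#' @export
setGeneric("speciesTable", function(object) standardGeneric("speciesTable"))

#' @rdname speciesTable
#' @export
setGeneric("speciesIds", function(object) standardGeneric("speciesIds"))

#' @rdname speciesTable
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname speciesTable
#' @export
setGeneric("reactionList", function(object) standardGeneric("reactionList"))

#' @rdname speciesTable
#' @export
setGeneric("modelParameters", function(object) standardGeneric("modelParameters"))

#' @rdname speciesTable
#' @export
setGeneric("modelParameters<-", function(object, value)
  standardGeneric("modelParameters<-"))

#' @rdname speciesTable
#' @export
setGeneric("modelLineage", function(object) standardGeneric("modelLineage"))

#' @rdname speciesTable
#' @export
setGeneric("clampedSpecies", function(object) standardGeneric("clampedSpecies"))
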