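#' Named, unit-tagged kinetic parameters
#'
#' A `ParameterSet` holds named positive reals with unit tags. Reserved names
#' used by the model library include `k1` (mass-action carboxylation rate
#' constant), `kE7` (transketolase equilibrium constant), `kM103` (Michaelis
#' constant of the E4P modifier term in the second transketolase reaction, mM),
#' `Vm11` and the translocator Michaelis constants, the starch-phosphorylase
#' constants (`StPase_VM`, `StPase_km`, `StPase_kiG1P`), the oxygenase
#' constants (`Vo`, `Ko`, `Kc`, `Kr`, `KI11`..`KI15`), `f_oxygenation`,
#' `delta_flux` and `adenylate_total`.
#'
#' All values must be strictly positive except `f_oxygenation`, which lies in
#' `[0, 0.5]`. Every dimensional parameter carries a unit tag; dimensionless
#' parameters are tagged `"1"`.
#'
#' @slot values Named numeric vector of parameter values.
#' @slot units Named character vector of unit tags, parallel to `values`.
#' @export
setClass("ParameterSet",
  representation(values = "numeric", units = "character"))

setValidity("ParameterSet", function(object) {
  msgs <- character()
  v <- object@values
  if (length(v) && is.null(names(v))) msgs <- c(msgs, "values must be named")
  if (anyDuplicated(names(v))) msgs <- c(msgs, "duplicated parameter names")
  if (!identical(sort(names(v)), sort(names(object@units))))
    msgs <- c(msgs, "units must cover exactly the named values")
  bad <- names(v)[!is.finite(v)]
  if (length(bad)) msgs <- c(msgs, paste("non-finite parameter:", bad[1L]))
  nonpos <- names(v)[v <= 0 & names(v) != "f_oxygenation"]
  if (length(nonpos))
    msgs <- c(msgs, paste("non-positive parameter:",
                          paste(nonpos, collapse = ", ")))
  if ("f_oxygenation" %in% names(v)) {
    f <- unname(v[["f_oxygenation"]])
    if (f < 0 || f > 0.5)
      msgs <- c(msgs, "f_oxygenation must lie in [0, 0.5]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ParameterSet
#'
#' @param values Named numeric vector (or named list) of parameter values.
#' @param units Named character vector of unit tags. Names missing from
#'   `units` default to `"1"` (dimensionless).
#' @return A [ParameterSet-class].
#' @examples
#' ps <- parameterSet(c(k = 2, Km = 0.5),
#'                    units = c(k = "s^-1", Km = "mM"))
#' paramValue(ps, "Km")
#' @export
parameterSet <- function(values = numeric(), units = character()) {
  values <- unlist(values)
  if (is.null(values)) values <- numeric()
  u <- rep("1", length(values))
  names(u) <- names(values)
  u[names(units)[names(units) %in% names(u)]] <-
    units[names(units) %in% names(u)]
  methods::new("ParameterSet", values = values, units = u)
}

#' @describeIn parameterSet Look up one parameter value by name.
#' @param ps A `ParameterSet`.
#' @param name Parameter name.
#' @param default Value returned when `name` is absent (default: error).
#' @export
paramValue <- function(ps, name, default = NULL) {
  v <- if (methods::is(ps, "ParameterSet")) ps@values else ps
  if (!name %in% names(v)) {
    if (is.null(default))
      stop("parameter '", name, "' not found", call. = FALSE)
    return(default)
  }
  unname(v[[name]])
}

#' @describeIn parameterSet Names of the contained parameters.
#' @export
paramNames <- function(ps) {
  if (methods::is(ps, "ParameterSet")) names(ps@values) else names(ps)
}

#' @describeIn parameterSet Merge/override values, keeping unit tags.
#' @param updates Named numeric vector of new or replacement values.
#' @param units2 Unit tags for parameters new in `updates`.
#' @export
updateParameters <- function(ps, updates, units2 = character()) {
  stopifnot(methods::is(ps, "ParameterSet"))
  v <- ps@values
  u <- ps@units
  for (nm in names(updates)) {
    v[[nm]] <- updates[[nm]]
    if (!nm %in% names(u))
      u[[nm]] <- if (nm %in% names(units2)) units2[[nm]] else "1"
  }
  methods::new("ParameterSet", values = v, units = u)
}

#' @export
setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet with", length(object@values), "parameters\n")
  if (length(object@values)) {
    df <- data.frame(value = object@values,
                     unit = object@units[names(object@values)])
    print(utils::head(df, 15L))
    if (length(object@values) > 15L)
      cat("  ... and", length(object@values) - 15L, "more\n")
  }
})

#' @export
setMethod("length", "ParameterSet", function(x) length(x@values))

# coerce ParameterSet or named numeric to a plain named numeric lookup
.paramVector <- function(params) {
  if (methods::is(params, "ParameterSet")) params@values else params
}
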