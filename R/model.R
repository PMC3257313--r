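#' @include rate-laws.R
NULL

#' A single reaction with stoichiometry and a rate law
#'
#' Stoichiometric coefficients are reactants-negative / products-positive and
#' may be non-integer: the lumped carboxylation-oxygenation reaction
#' `RuBP + CO2 -> A x PGA + B x PGCA` requires real-valued coefficients.
#'
#' @slot id Short identifier, unique within a model.
#' @slot name Free-text name.
#' @slot stoichiometry Named numeric: species id -> coefficient.
#' @slot modifiers Character vector of species ids entering the rate law but
#'   not the stoichiometry.
#' @slot rateLaw A [RateLaw-class].
#' @slot reversible Logical.
#' @export
setClass("Reaction",
  representation(id = "character", name = "character",
                 stoichiometry = "numeric", modifiers = "character",
                 rateLaw = "RateLaw", reversible = "logical"))

setValidity("Reaction", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "reaction id must be a single non-empty string")
  s <- object@stoichiometry
  if (!length(s) || is.null(names(s)) || !any(s != 0))
    msgs <- c(msgs, "at least one nonzero stoichiometric coefficient required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Reaction
#'
#' @param id Reaction identifier.
#' @param stoichiometry Named numeric vector (reactants negative, products
#'   positive).
#' @param rateLaw A [RateLaw-class].
#' @param modifiers Species ids entering the rate law only.
#' @param reversible Logical.
#' @param name Optional display name.
#' @return A [Reaction-class].
#' @export
reaction <- function(id, stoichiometry, rateLaw, modifiers = character(),
                     reversible = FALSE, name = id) {
  methods::new("Reaction", id = id, name = name,
               stoichiometry = stoichiometry, modifiers = modifiers,
               rateLaw = rateLaw, reversible = reversible)
}

#' @export
setMethod("show", "Reaction", function(object) {
  s <- object@stoichiometry
  lhs <- s[s < 0]; rhs <- s[s > 0]
  fmt <- function(x) paste(ifelse(abs(x) == 1, names(x),
                                  paste0(abs(x), " ", names(x))),
                           collapse = " + ")
  arrow <- if (object@reversible) "<->" else "->"
  cat(sprintf("Reaction %s: %s %s %s  [%s]\n", object@id, fmt(lhs), arrow,
              fmt(rhs), object@rateLaw@family))
})

#' A kinetic reaction-network model of the Calvin-Benson cycle
#'
#' The central container: species (with carbon/phosphate counts and clamp
#' flags), reactions, a [ParameterSet-class], an append-only lineage of
#' (base variant, applied patches), and free-form metadata (units, compartment
#' volume, diagnostic-reproduction flag).
#'
#' Concentrations are mM, time is s, rates are mM s^-1; fluxes quoted in
#' mmol s^-1 convert through the declared compartment volume (default 1 l),
#' recorded in `metadata$compartment_volume_l`.
#'
#' @slot species `data.frame` with columns `id`, `name`, `compartment`,
#'   `initial` (mM), `carbons`, `phosphates`, `clamped`.
#' @slot reactions Named list of [Reaction-class] objects.
#' @slot parameters A [ParameterSet-class].
#' @slot lineage List of records, each `list(base=, patches=list(...))`;
#'   append-only, serialized with the model.
#' @slot metadata List.
#' @export
setClass("CbcModel",
  representation(species = "data.frame", reactions = "list",
                 parameters = "ParameterSet", lineage = "list",
                 metadata = "list"))

setValidity("CbcModel", function(object) {
  msgs <- character()
  sp <- object@species
  need <- c("id", "name", "compartment", "initial", "carbons", "phosphates",
            "clamped")
  if (!all(need %in% names(sp)))
    msgs <- c(msgs, paste("species table must have columns:",
                          paste(need, collapse = ", ")))
  else if (anyDuplicated(sp$id))
    msgs <- c(msgs, "species ids must be unique")
  if (length(object@reactions)) {
    ids <- vapply(object@reactions, function(r) r@id, "")
    if (anyDuplicated(ids)) msgs <- c(msgs, "reaction ids must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CbcModel
#'
#' @param species A `data.frame` as documented in [CbcModel-class], or a list
#'   of rows built by [speciesSpec()].
#' @param reactions List of [Reaction-class] objects.
#' @param parameters A [ParameterSet-class].
#' @param lineage Initial lineage record list.
#' @param metadata Metadata list; `diagnostic_reproduction = TRUE` permits
#'   negative initial concentrations and disables negative clipping.
#' @return A [CbcModel-class].
#' @export
cbcModel <- function(species, reactions = list(),
                     parameters = parameterSet(), lineage = list(),
                     metadata = list()) {
  if (is.list(species) && !is.data.frame(species))
    species <- do.call(rbind, lapply(species, as.data.frame))
  species$id <- as.character(species$id)
  rownames(species) <- NULL
  if (!length(metadata$compartment_volume_l))
    metadata$compartment_volume_l <- 1
  if (!length(metadata$units))
    metadata$units <- list(concentration = "mM", time = "s",
                           rate = "mM s^-1")
  names(reactions) <- vapply(reactions, function(r) r@id, "")
  m <- methods::new("CbcModel", species = species, reactions = reactions,
                    parameters = parameters, lineage = lineage,
                    metadata = metadata)
  if (!isTRUE(metadata$diagnostic_reproduction) &&
      any(species$initial < 0, na.rm = TRUE))
    stop("negative initial concentrations require ",
         "metadata$diagnostic_reproduction = TRUE", call. = FALSE)
  m
}

#' One species row
#'
#' @param id,name,compartment Identifiers.
#' @param initial Initial concentration (mM).
#' @param carbons,phosphates Element counts per molecule (`NA` if unknown).
#' @param clamped Logical: concentration held constant during simulation.
#' @return One-row species `data.frame`.
#' @export
speciesSpec <- function(id, initial = 0, carbons = NA_real_,
                        phosphates = NA_real_, clamped = FALSE,
                        name = id, compartment = "stroma") {
  data.frame(id = id, name = name, compartment = compartment,
             initial = initial, carbons = carbons, phosphates = phosphates,
             clamped = clamped, stringsAsFactors = FALSE)
}

# ---- accessors -------------------------------------------------------------

#' Accessors for CbcModel
#'
#' @param object A [CbcModel-class].
#' @param value Replacement value.
#' @return `speciesTable`: the species `data.frame`; `speciesIds`,
#'   `reactionIds`: character vectors; `reactionList`: named list of
#'   [Reaction-class]; `modelParameters`: the [ParameterSet-class];
#'   `modelLineage`: the lineage list; `clampedSpecies`: ids of clamped
#'   species.
#' @name speciesTable
NULL

#' @rdname speciesTable
#' @export
setMethod("speciesTable", "CbcModel", function(object) object@species)

#' @rdname speciesTable
#' @export
setMethod("speciesIds", "CbcModel", function(object) object@species$id)

#' @rdname speciesTable
#' @export
setMethod("reactionIds", "CbcModel", function(object) names(object@reactions))

#' @rdname speciesTable
#' @export
setMethod("reactionList", "CbcModel", function(object) object@reactions)

#' @rdname speciesTable
#' @export
setMethod("modelParameters", "CbcModel", function(object) object@parameters)

#' @rdname speciesTable
#' @export
setMethod("modelParameters<-", "CbcModel", function(object, value) {
  object@parameters <- value
  methods::validObject(object)
  object
})

#' @rdname speciesTable
#' @export
setMethod("modelLineage", "CbcModel", function(object) object@lineage)

#' @rdname speciesTable
#' @export
setMethod("clampedSpecies", "CbcModel",
          function(object) object@species$id[object@species$clamped])

#' @export
setMethod("show", "CbcModel", function(object) {
  base <- if (length(object@lineage)) object@lineage[[1L]]$base else "ad hoc"
  np <- sum(lengths(lapply(object@lineage, `[[`, "patches")))
  cat("CbcModel (", base, "): ", nrow(object@species), " species, ",
      length(object@reactions), " reactions, ",
      length(object@parameters), " parameters",
      if (np) paste0(", ", np, " patches") else "", "\n", sep = "")
  cl <- clampedSpecies(object)
  if (length(cl)) cat("  clamped:", paste(cl, collapse = ", "), "\n")
})

# set initial concentrations by named vector
setInitial <- function(model, values) {
  i <- match(names(values), model@species$id)
  stopifnot(!anyNA(i))
  model@species$initial[i] <- unname(values)
  model
}

# ---- validation ------------------------------------------------------------

.diag <- function(severity, location, message)
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)

.noDiag <- function()
  data.frame(severity = character(), location = character(),
             message = character(), stringsAsFactors = FALSE)

#' Validate a model
#'
#' Checks all structural invariants (unique ids, resolvable symbols, nonzero
#' stoichiometries, positive parameters, non-negative initial concentrations
#' unless the model is flagged as a diagnostic reproduction) plus dimensional
#' and physiological-range heuristics. Returns diagnostics rather than
#' raising: an empty `data.frame` means the model is well-formed.
#'
#' @param model A [CbcModel-class].
#' @return `data.frame` with columns `severity` (`"error"`/`"warning"`),
#'   `location`, `message`; zero rows iff the model passes.
#' @export
validateModel <- function(model) {
  out <- .noDiag()
  sp <- model@species
  pv <- .paramVector(model@parameters)
  if (anyDuplicated(sp$id))
    out <- rbind(out, .diag("error", "species",
                            "duplicated species ids"))
  if (!isTRUE(model@metadata$diagnostic_reproduction) &&
      any(sp$initial < 0, na.rm = TRUE))
    out <- rbind(out, .diag("error",
                            paste0("species:",
                                   sp$id[which(sp$initial < 0)[1L]]),
                            "negative initial concentration"))
  for (r in model@reactions) {
    loc <- paste0("reaction:", r@id)
    if (!any(r@stoichiometry != 0))
      out <- rbind(out, .diag("error", loc, "all-zero stoichiometry"))
    missing <- setdiff(names(r@stoichiometry), sp$id)
    if (length(missing))
      out <- rbind(out, .diag("error", loc,
                              paste("undefined species:",
                                    paste(missing, collapse = ", "))))
    missingMod <- setdiff(r@modifiers, sp$id)
    if (length(missingMod))
      out <- rbind(out, .diag("error", loc,
                              paste("undefined modifier species:",
                                    paste(missingMod, collapse = ", "))))
    syms <- .rateLawSymbols(r@rateLaw)
    unresolved <- setdiff(syms, c(sp$id, names(pv)))
    if (length(unresolved))
      out <- rbind(out, .diag("error", loc,
                              paste("unresolved symbol(s):",
                                    paste(unresolved, collapse = ", "))))
    # dimensional heuristic: the product-form modifier combination mixes
    # saturation terms whose declared form is a sum
    if (identical(r@rateLaw@family, "transketolase") &&
        identical(r@rateLaw@variant, "multiplicative_modifiers") &&
        length(r@rateLaw@bindings$modifiers) > 1L)
      out <- rbind(out, .diag("warning", loc,
        "modifier saturation terms multiplied where the declared form adds them (dimensional inconsistency)"))
    # MM with a zero Michaelis constant divides by zero at S = 0
    if (identical(r@rateLaw@family, "michaelis_menten")) {
      km <- r@rateLaw@bindings$km
      kmv <- tryCatch(.resolve(km, stats::setNames(sp$initial, sp$id), pv),
                      error = function(e) NA_real_)
      if (isTRUE(kmv == 0))
        out <- rbind(out, .diag("error", loc, "zero Michaelis constant"))
    }
  }
  # physiological-range heuristics from the literature table
  if ("kM103" %in% names(pv) && pv[["kM103"]] < 0.06)
    out <- rbind(out, .diag("warning", "parameter:kM103",
      "kM103 below 0.06 mM: appendix-form transketolase is unstable below 0.06"))
  out
}

# ---- stoichiometry / elements ---------------------------------------------

#' Stoichiometry matrix
#'
#' @param model A [CbcModel-class].
#' @return Numeric matrix species x reactions with dimnames; attribute
#'   `clamped` is a logical vector flagging clamped species rows.
#' @export
stoichiometryMatrix <- function(model) {
  sp <- model@species$id
  rx <- reactionIds(model)
  N <- matrix(0, nrow = length(sp), ncol = length(rx),
              dimnames = list(sp, rx))
  for (r in model@reactions)
    N[names(r@stoichiometry), r@id] <- r@stoichiometry
  attr(N, "clamped") <- stats::setNames(model@species$clamped, sp)
  N
}

#' Per-reaction element balance
#'
#' Imbalance of an element per reaction event:
#' `sum(coefficient * element count)`. Non-integer stoichiometry gives
#' real-valued imbalances; the lumped carboxylation-oxygenation reaction with
#' the printed coefficients (A = 1.916, B = 0.084) is not exactly
#' carbon-closed and is reported as such, not hidden.
#'
#' @param model A [CbcModel-class].
#' @param element `"carbon"` or `"phosphate"`.
#' @return Named numeric vector of imbalances (atoms per reaction event);
#'   exact zeros mean balanced.
#' @export
elementBalance <- function(model, element = c("carbon", "phosphate")) {
  element <- match.arg(element)
  col <- if (element == "carbon") "carbons" else "phosphates"
  counts <- stats::setNames(model@species[[col]], model@species$id)
  vapply(model@reactions, function(r) {
    cnt <- counts[names(r@stoichiometry)]
    if (anyNA(cnt))
      stop("missing ", element, " count for species: ",
           paste(names(r@stoichiometry)[is.na(cnt)], collapse = ", "),
           call. = FALSE)
    sum(r@stoichiometry * cnt)
  }, 0)
}

#' Lumped carboxylation-oxygenation stoichiometry
#'
#' Instead of a separate oxygenase reaction, oxygenation can be folded into
#' the carboxylation reaction `RuBP + CO2 -> A x PGA + B x PGCA`. Each RuBP
#' turnover yields two three-carbon-equivalent products; with an oxygenation
#' flux fraction `f` of RuBP synthesis, `B = 2 f` of them are PGCA and
#' `A = 2 - 2 f` are PGA, so `A + B = 2` always. At the flux-balance value
#' `f = 0.042` (4.2 %) this gives `A = 1.916`, `B = 0.084`.
#'
#' @param f_oxygenation Oxygenation fraction in `[0, 0.5]`.
#' @param rule `"product_flux"` (default, `B = 2 f`) or `"per_event"`
#'   (`B = f`, reading `f` as the fraction of RuBP turnovers that oxygenate).
#' @return Named numeric `c(A =, B =)`: PGA and PGCA coefficients.
#' @examples
#' lumpedCarboxylationStoichiometry(0.042)  # A = 1.916, B = 0.084
#' @export
lumpedCarboxylationStoichiometry <- function(f_oxygenation,
                                             rule = c("product_flux",
                                                      "per_event")) {
  rule <- match.arg(rule)
  if (!is.finite(f_oxygenation) || f_oxygenation < 0 || f_oxygenation > 0.5)
    stop("f_oxygenation must lie in [0, 0.5]", call. = FALSE)
  B <- switch(rule, product_flux = 2 * f_oxygenation,
              per_event = f_oxygenation)
  c(A = 2 - B, B = B)
}

#' Carbon conversion factor between sink species
#'
#' The dimensionless factor `q = source_carbons / target_carbons` used to fold
#' a minor sink's flux into the PGA sink on a carbon basis (e.g. RuBP with 5
#' carbons into PGA with 3: q = 5/3, displayed 1.66). The value is carried at
#' full precision; the `display` attribute truncates to 2 decimals for
#' reporting.
#'
#' @param source_carbons,target_carbons Positive integer carbon counts.
#' @return Numeric factor with attribute `display`.
#' @export
carbonConversionFactor <- function(source_carbons, target_carbons) {
  if (source_carbons <= 0 || target_carbons <= 0)
    stop("carbon counts must be positive", call. = FALSE)
  q <- source_carbons / target_carbons
  attr(q, "display") <- sprintf("%.2f", floor(q * 100) / 100)
  q
}
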