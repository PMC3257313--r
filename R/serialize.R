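#' @include model.R
NULL

# Native structured-text model serialization (one YAML document per model).
# Numeric fields are written as %.17g strings and R data (bindings, lineage,
# metadata, kinetic-law math) as deparsed literals with 17-digit numerics, so
# write -> read -> write is bit-stable.

.dep <- function(x)
  paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames",
                               "showAttributes", "digits17"),
                width.cutoff = 500L), collapse = " ")

.undep <- function(s) eval(str2lang(s), envir = baseenv())

.numStr <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a model as structured text
#'
#' @param model A [CbcModel-class].
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The YAML text (invisibly when written to `path`).
#' @export
writeModelText <- function(model, path = NULL) {
  sp <- model@species
  doc <- list(
    calvinsim_model = list(
      format = 1L,
      metadata = .dep(model@metadata),
      species = lapply(seq_len(nrow(sp)), function(i) list(
        id = sp$id[i], name = sp$name[i], compartment = sp$compartment[i],
        initial = .numStr(sp$initial[i]),
        carbons = .numStr(sp$carbons[i]),
        phosphates = .numStr(sp$phosphates[i]),
        clamped = sp$clamped[i])),
      parameters = list(
        values = as.list(stats::setNames(.numStr(model@parameters@values),
                                         names(model@parameters@values))),
        units = as.list(model@parameters@units[
          names(model@parameters@values)])),
      reactions = lapply(model@reactions, function(r) list(
        id = r@id, name = r@name, reversible = r@reversible,
        modifiers = as.list(r@modifiers),
        stoichiometry = as.list(stats::setNames(.numStr(r@stoichiometry),
                                                names(r@stoichiometry))),
        rate_law = list(
          family = r@rateLaw@family,
          variant = r@rateLaw@variant,
          bindings = .dep(r@rateLaw@bindings),
          math = if (identical(r@rateLaw@family, "generic_expression"))
            .dep(r@rateLaw@math) else ""))),
      lineage = .dep(model@lineage)))
  txt <- yaml::as.yaml(doc, indent = 2)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a model from structured text
#'
#' @param text YAML text as written by [writeModelText()]; ignored when
#'   `path` is given.
#' @param path Optional file path to read.
#' @return A [CbcModel-class].
#' @export
readModelText <- function(text = NULL, path = NULL) {
  if (!is.null(path)) text <- paste(readLines(path), collapse = "\n")
  doc <- yaml::yaml.load(text)$calvinsim_model
  if (is.null(doc)) stop("not a CalvinSim model document", call. = FALSE)
  species <- do.call(rbind, lapply(doc$species, function(s)
    data.frame(id = s$id, name = s$name, compartment = s$compartment,
               initial = as.numeric(s$initial),
               carbons = as.numeric(s$carbons),
               phosphates = as.numeric(s$phosphates),
               clamped = isTRUE(s$clamped), stringsAsFactors = FALSE)))
  vals <- vapply(doc$parameters$values, function(x) as.numeric(x), 0)
  units <- vapply(doc$parameters$units, as.character, "")
  params <- parameterSet(vals, units)
  reactions <- lapply(doc$reactions, function(r) {
    law <- methods::new("RateLaw",
      family = r$rate_law$family,
      bindings = .undep(r$rate_law$bindings),
      variant = r$rate_law$variant,
      math = if (nzchar(r$rate_law$math)) str2lang(r$rate_law$math)
             else NULL)
    methods::new("Reaction", id = r$id, name = r$name,
                 stoichiometry = vapply(r$stoichiometry, as.numeric, 0),
                 modifiers = as.character(unlist(r$modifiers)),
                 rateLaw = law, reversible = isTRUE(r$reversible))
  })
  cbcModel(species, reactions, params,
           lineage = .undep(doc$lineage),
           metadata = .undep(doc$metadata))
}

#' Structural model comparison
#'
#' Lists the locations at which two models differ (species rows, reaction
#' definitions, parameter values/units, metadata, lineage). Used for the
#' patch-locality and round-trip guarantees.
#'
#' @param a,b [CbcModel-class] objects.
#' @param ignoreLineage Logical: compare everything but the lineage.
#' @return Character vector of differing locations; empty iff structurally
#'   equal.
#' @export
modelDiff <- function(a, b, ignoreLineage = FALSE) {
  out <- character()
  sa <- a@species
  sb <- b@species
  ids <- union(sa$id, sb$id)
  for (id in ids) {
    ra <- sa[sa$id == id, , drop = FALSE]
    rb <- sb[sb$id == id, , drop = FALSE]
    if (nrow(ra) != 1L || nrow(rb) != 1L || !isTRUE(all.equal(
          as.list(ra[1L, ]), as.list(rb[1L, ]), tolerance = 0)))
      out <- c(out, paste0("species:", id))
  }
  rids <- union(names(a@reactions), names(b@reactions))
  for (id in rids) {
    ra <- a@reactions[[id]]
    rb <- b@reactions[[id]]
    same <- !is.null(ra) && !is.null(rb) &&
      identical(ra@stoichiometry, rb@stoichiometry) &&
      identical(ra@modifiers, rb@modifiers) &&
      identical(ra@reversible, rb@reversible) &&
      identical(ra@rateLaw@family, rb@rateLaw@family) &&
      identical(ra@rateLaw@variant, rb@rateLaw@variant) &&
      identical(.dep(ra@rateLaw@bindings), .dep(rb@rateLaw@bindings)) &&
      identical(.dep(ra@rateLaw@math), .dep(rb@rateLaw@math))
    if (!same) out <- c(out, paste0("reaction:", id))
  }
  pn <- union(paramNames(a@parameters), paramNames(b@parameters))
  for (nm in pn) {
    va <- a@parameters@values[nm]
    vb <- b@parameters@values[nm]
    if (!identical(unname(va), unname(vb)) ||
        !identical(unname(a@parameters@units[nm]),
                   unname(b@parameters@units[nm])))
      out <- c(out, paste0("parameter:", nm))
  }
  if (!identical(.dep(a@metadata), .dep(b@metadata)))
    out <- c(out, "metadata")
  if (!ignoreLineage && !identical(.dep(a@lineage), .dep(b@lineage)))
    out <- c(out, "lineage")
  out
}
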