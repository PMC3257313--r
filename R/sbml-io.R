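#' @include serialize.R
NULL

# SBML Level 2 read/write on xml2. Kinetic-law math is interconverted with
# R expression trees through MathML; named rate-law families are emitted as
# explicit math plus an annotation tag from which the family (and its exact
# bindings) is recoverable on import. Only Level 2 (versions 1-4) is
# targeted; events, algebraic rules and constraints are rejected.

.SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.CSIM_NS <- "https://calvinsim.invalid/annotations"

# ---- rate law -> R expression ---------------------------------------------

.sym <- function(x) if (is.character(x)) as.name(x) else x

# build the explicit algebraic form of any rate-law family
.rateLawToExpr <- function(law) {
  b <- law@bindings
  S <- function(x) .sym(x)
  prodExpr <- function(terms) Reduce(function(a, z) call("*", a, z), terms)
  sumExpr <- function(terms) Reduce(function(a, z) call("+", a, z), terms)
  powProd <- function(sp) {
    terms <- lapply(seq_along(sp), function(i) {
      if (sp[[i]] == 1) S(names(sp)[i])
      else call("^", S(names(sp)[i]), sp[[i]])
    })
    prodExpr(terms)
  }
  switch(law@family,
    generic_expression = law@math,
    mass_action = {
      fwd <- call("*", S(b$k), powProd(b$substrates))
      if (!is.null(b$keq) && length(b$products))
        call("-", fwd, call("*", call("/", S(b$k), S(b$keq)),
                            powProd(b$products)))
      else fwd
    },
    michaelis_menten = {
      inh <- lapply(b$inhibitors, function(i)
        call("/", S(i$species), S(i$ki)))
      den <- call("+", S(b$substrate),
                  call("*", S(b$km),
                       if (length(inh)) sumExpr(c(list(1), inh)) else 1))
      call("/", call("*", S(b$vmax), S(b$substrate)), den)
    },
    reversible_mm = {
      sOv <- lapply(seq_along(b$substrates), function(i)
        call("/", S(b$substrates[[i]]), S(b$kmS[[i]])))
      pNum <- call("/", prodExpr(lapply(b$products, S)),
                   call("*", prodExpr(lapply(b$kmS, S)), S(b$keq)))
      num <- call("-", prodExpr(sOv), pNum)
      satS <- prodExpr(lapply(seq_along(b$substrates), function(i)
        call("+", 1, call("/", S(b$substrates[[i]]), S(b$kmS[[i]])))))
      satP <- prodExpr(lapply(seq_along(b$products), function(i)
        call("+", 1, call("/", S(b$products[[i]]), S(b$kmP[[i]])))))
      call("/", call("*", S(b$vmax), num),
           call("-", call("+", satS, satP), 1))
    },
    transketolase = {
      temp <- 1
      if (identical(b$form, "appendix") && length(b$modifiers)) {
        terms <- lapply(b$modifiers, function(m)
          call("/", S(m$species), S(m$km)))
        temp <- if (identical(law@variant, "additive_modifiers"))
          sumExpr(c(list(1), terms))
        else prodExpr(lapply(terms, function(tt) call("+", 1, tt)))
      }
      num <- call("*", call("*", S(b$vmax), S(b$ke)),
                  call("-", call("*", S(b$s1), S(b$s2)),
                       call("/", call("*", S(b$p1), S(b$p2)), S(b$ke))))
      den <- call("*", call("+", S(b$s1), call("*", S(b$km1), temp)),
                  call("+", S(b$s2), S(b$km2)))
      call("/", num, den)
    },
    translocator = {
      side <- function(s)
        call("+", call("+", call("/", S(s$OP), S(s$KmOP)),
                       call("/", S(s$PGA), S(s$KmPGA))),
             call("/", call("+", S(s$GAP), S(s$DHAP)), S(s$KmT3P)))
      Ts <- side(b$stromal)
      Tc <- side(b$cytosolic)
      num <- call("-",
                  call("*", Tc, call("/", S(b$stromal$PGA),
                                    S(b$stromal$KmPGA))),
                  call("*", Ts, call("/", S(b$cytosolic$PGA),
                                    S(b$cytosolic$KmPGA))))
      call("/", call("*", S(b$vm), num),
           call("+", call("+", Ts, Tc), call("*", Ts, Tc)))
    },
    oxygenase = {
      inh <- lapply(seq_len(5L), function(i)
        call("/", S(b$inhibitors$species[[i]]), S(b$inhibitors$ki[[i]])))
      num <- call("/", call("*", call("*", S(b$rubp), S(b$vo)), S(b$o2)),
                  call("+", S(b$o2),
                       call("*", S(b$ko),
                            call("+", 1, call("/", S(b$co2), S(b$kc))))))
      den <- call("+", S(b$rubp),
                  call("*", S(b$kr), sumExpr(c(list(1), inh))))
      call("/", num, den)
    },
    starch_phosphorylase = {
      sub <- if (identical(law@variant, "corrected")) S(b$starch)
             else S(b$phosphate)
      call("/", call("*", S(b$vm), sub),
           call("+", sub,
                call("*", S(b$km),
                     call("+", 1, call("/", S(b$g1p), S(b$kiG1P))))))
    },
    stop("no math lowering for family ", law@family))
}

# ---- R expression <-> MathML ----------------------------------------------

.mathmlOps <- c(`+` = "plus", `-` = "minus", `*` = "times", `/` = "divide",
                `^` = "power", min = "min", max = "max")

.exprToMathmlNode <- function(parent, e) {
  if (is.numeric(e)) {
    xml2::xml_add_child(parent, "cn", format(e, digits = 17))
  } else if (is.symbol(e)) {
    xml2::xml_add_child(parent, "ci", as.character(e))
  } else if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(.exprToMathmlNode(parent, e[[2L]]))
    if (!op %in% names(.mathmlOps))
      stop("operator not expressible in MathML subset: ", op,
           call. = FALSE)
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, .mathmlOps[[op]])
    for (arg in as.list(e)[-1L]) .exprToMathmlNode(ap, arg)
    ap
  } else stop("cannot serialize expression node of class ", class(e)[1L],
              call. = FALSE)
}

.mathmlToExpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L)
      stop("malformed MathML: expected a single root expression",
           call. = FALSE)
    return(.mathmlToExpr(kids[[1L]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    txt <- trimws(xml2::xml_text(node))
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      nums <- trimws(vapply(parts, xml2::xml_text, ""))
      nums <- nums[nzchar(nums)]
      return(as.numeric(nums[1L]) * 10^as.numeric(nums[2L]))
    }
    if (!is.na(type) && type == "rational") {
      parts <- xml2::xml_contents(node)
      nums <- trimws(vapply(parts, xml2::xml_text, ""))
      nums <- nums[nzchar(nums)]
      return(as.numeric(nums[1L]) / as.numeric(nums[2L]))
    }
    return(as.numeric(txt))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    args <- lapply(kids[-1L], .mathmlToExpr)
    rop <- names(.mathmlOps)[match(op, .mathmlOps)]
    if (is.na(rop)) {
      if (op == "root" && length(args) == 1L)
        return(call("^", args[[1L]], 0.5))
      stop("unsupported MathML operator: ", op, call. = FALSE)
    }
    if (op == "minus" && length(args) == 1L)
      return(call("-", args[[1L]]))
    if (length(args) == 1L && op %in% c("plus", "times"))
      return(args[[1L]])
    Reduce(function(a, z) call(rop, a, z), args)
  } else stop("unsupported MathML node: ", nm, call. = FALSE)
}

# light structural matcher: k * S1 * S2 ... -> mass action
.matchMassAction <- function(expr, paramNames) {
  syms <- character()
  walk <- function(e) {
    if (is.symbol(e)) {
      syms <<- c(syms, as.character(e))
      TRUE
    } else if (is.call(e) && identical(as.character(e[[1L]]), "*")) {
      all(vapply(as.list(e)[-1L], walk, TRUE))
    } else FALSE
  }
  if (!walk(expr)) return(NULL)
  k <- syms[syms %in% paramNames]
  sp <- syms[!syms %in% paramNames]
  if (length(k) != 1L || !length(sp)) return(NULL)
  massActionLaw(k, stats::setNames(rep(1, length(sp)), sp))
}

# ---- write ----------------------------------------------------------------

#' Write a model as SBML Level 2 Version 4
#'
#' Clamped species are emitted with `boundaryCondition="true"`; every
#' reaction's kinetic law carries the explicit MathML of its rate law plus an
#' annotation naming the family and its bindings (so the family is
#' recoverable on import); the model lineage is serialized as a model
#' annotation and survives a round trip.
#'
#' @param model A validated [CbcModel-class].
#' @param path Optional output file; when `NULL` the `xml_document` is
#'   returned.
#' @return The `xml2::xml_document` (invisibly when written to `path`).
#' @export
writeSBML <- function(model, path = NULL) {
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS,
                            "xmlns:calvinsim" = .CSIM_NS, level = "2",
                            version = "4")
  mnode <- xml2::xml_add_child(doc, "model", id = "calvinsim_model")
  ann <- xml2::xml_add_child(mnode, "annotation")
  lin <- xml2::xml_add_child(ann, "calvinsim:lineage")
  xml2::xml_set_text(lin, .dep(model@lineage))
  meta <- xml2::xml_add_child(ann, "calvinsim:metadata")
  xml2::xml_set_text(meta, .dep(model@metadata))
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (comp in unique(model@species$compartment))
    xml2::xml_add_child(lc, "compartment", id = comp,
                        size = format(model@metadata$compartment_volume_l,
                                      digits = 17))
  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model@species))) {
    sp <- model@species[i, ]
    node <- xml2::xml_add_child(ls, "species", id = sp$id, name = sp$name,
      compartment = sp$compartment,
      initialConcentration = format(sp$initial, digits = 17),
      boundaryCondition = if (sp$clamped) "true" else "false")
    if (!is.na(sp$carbons) || !is.na(sp$phosphates)) {
      a <- xml2::xml_add_child(node, "annotation")
      xml2::xml_add_child(a, "calvinsim:elements",
                          carbons = format(sp$carbons),
                          phosphates = format(sp$phosphates))
    }
  }
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  pv <- model@parameters@values
  pu <- model@parameters@units
  for (nm in names(pv)) {
    node <- xml2::xml_add_child(lp, "parameter", id = nm,
                                value = format(pv[[nm]], digits = 17))
    a <- xml2::xml_add_child(node, "annotation")
    xml2::xml_add_child(a, "calvinsim:unit", tag = pu[[nm]])
  }
  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  for (r in model@reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = r@id, name = r@name,
      reversible = if (r@reversible) "true" else "false")
    a <- xml2::xml_add_child(rn, "annotation")
    xml2::xml_add_child(a, "calvinsim:rateLaw",
                        family = r@rateLaw@family,
                        variant = r@rateLaw@variant,
                        bindings = .dep(r@rateLaw@bindings))
    s <- r@stoichiometry
    reac <- s[s < 0]
    prod <- s[s > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in seq_along(reac))
        xml2::xml_add_child(lre, "speciesReference",
                            species = names(reac)[j],
                            stoichiometry = format(abs(reac[[j]]),
                                                   digits = 17))
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in seq_along(prod))
        xml2::xml_add_child(lpr, "speciesReference",
                            species = names(prod)[j],
                            stoichiometry = format(prod[[j]], digits = 17))
    }
    if (length(r@modifiers)) {
      lm <- xml2::xml_add_child(rn, "listOfModifiers")
      for (mm in r@modifiers)
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = mm)
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .MATHML_NS)
    .exprToMathmlNode(math, .rateLawToExpr(r@rateLaw))
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

# ---- read -----------------------------------------------------------------

#' Read an SBML Level 2 model
#'
#' Boundary-condition (or constant) species become clamped; kinetic-law math
#' becomes a `generic_expression` rate law unless a family annotation (as
#' written by [writeSBML()]) or a structural mass-action match recovers a
#' named family. Local parameters are namespaced by reaction id. Unsupported
#' constructs (events, algebraic rules, constraints) are rejected; a missing
#' kinetic law on a reaction is an error.
#'
#' @param source File path, XML string, or `xml2::xml_document`.
#' @return `list(model = CbcModel, report = list)` where `report` is the
#'   import report (species mapped, clamped mapping, kinetic-law families
#'   recognized vs generic, unit notes, unresolved constructs).
#' @export
readSBML <- function(source) {
  doc <- if (inherits(source, "xml_document")) source
         else xml2::read_xml(source)
  root <- xml2::xml_ns_strip(xml2::xml_root(doc))
  if (xml2::xml_name(root) != "sbml")
    stop("not an SBML document", call. = FALSE)
  level <- xml2::xml_attr(root, "level")
  if (!identical(level, "2"))
    stop("only SBML Level 2 is supported (got level ", level, ")",
         call. = FALSE)
  mnode <- xml2::xml_find_first(root, "./model")
  if (inherits(mnode, "xml_missing"))
    stop("SBML document has no model element", call. = FALSE)
  unsupported <- c("listOfEvents", "listOfConstraints")
  bad <- unsupported[vapply(unsupported, function(n)
    !inherits(xml2::xml_find_first(mnode, paste0("./", n)), "xml_missing"),
    TRUE)]
  rules <- xml2::xml_find_all(mnode, "./listOfRules/algebraicRule")
  if (length(rules)) bad <- c(bad, "algebraicRule")
  if (length(bad))
    stop("unsupported SBML constructs: ", paste(bad, collapse = ", "),
         call. = FALSE)

  notes <- character()
  if (inherits(xml2::xml_find_first(mnode, "./listOfUnitDefinitions"),
               "xml_missing")) {
    notes <- c(notes,
      "no unit definitions: concentrations assumed mM, time assumed s")
    warning("SBML model declares no units; assuming mM and s",
            call. = FALSE)
  } else {
    notes <- c(notes, paste("unit definitions present; values taken as",
                            "mM and s without rescaling"))
  }

  comps <- xml2::xml_find_all(mnode, "./listOfCompartments/compartment")
  vol <- 1
  if (length(comps)) {
    v <- xml2::xml_attr(comps[[1L]], "size")
    if (!is.na(v)) vol <- as.numeric(v)
  }

  spNodes <- xml2::xml_find_all(mnode, "./listOfSpecies/species")
  if (!length(spNodes)) stop("SBML model has no species", call. = FALSE)
  species <- do.call(rbind, lapply(spNodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    conc <- xml2::xml_attr(n, "initialConcentration")
    if (is.na(conc)) {
      amt <- xml2::xml_attr(n, "initialAmount")
      conc <- if (!is.na(amt)) as.numeric(amt) / vol else 0
    }
    clamped <- identical(xml2::xml_attr(n, "boundaryCondition"), "true") ||
      identical(xml2::xml_attr(n, "constant"), "true")
    el <- xml2::xml_find_first(n, ".//*[local-name()='elements']")
    carbons <- phosphates <- NA_real_
    if (!inherits(el, "xml_missing")) {
      carbons <- suppressWarnings(as.numeric(xml2::xml_attr(el, "carbons")))
      phosphates <- suppressWarnings(
        as.numeric(xml2::xml_attr(el, "phosphates")))
    }
    nmAttr <- xml2::xml_attr(n, "name")
    speciesSpec(id, initial = as.numeric(conc), carbons = carbons,
                phosphates = phosphates, clamped = clamped,
                name = if (is.na(nmAttr)) id else nmAttr,
                compartment = xml2::xml_attr(n, "compartment"))
  }))

  pNodes <- xml2::xml_find_all(mnode, "./listOfParameters/parameter")
  pv <- numeric()
  pu <- character()
  for (n in pNodes) {
    id <- xml2::xml_attr(n, "id")
    pv[[id]] <- as.numeric(xml2::xml_attr(n, "value"))
    un <- xml2::xml_find_first(n, ".//*[local-name()='unit']")
    pu[[id]] <- if (!inherits(un, "xml_missing"))
      xml2::xml_attr(un, "tag") else "1"
  }

  rNodes <- xml2::xml_find_all(mnode, "./listOfReactions/reaction")
  famCount <- c(named = 0L, generic = 0L)
  reactions <- list()
  for (n in rNodes) {
    rid <- xml2::xml_attr(n, "id")
    refs <- function(xp, sign) {
      rr <- xml2::xml_find_all(n, xp)
      if (!length(rr)) return(numeric())
      st <- vapply(rr, function(x) {
        s <- xml2::xml_attr(x, "stoichiometry")
        if (is.na(s)) 1 else as.numeric(s)
      }, 0)
      stats::setNames(sign * st,
                      vapply(rr, function(x) xml2::xml_attr(x, "species"),
                             ""))
    }
    sreac <- refs("./listOfReactants/speciesReference", -1)
    sprod <- refs("./listOfProducts/speciesReference", 1)
    st <- c(sreac, sprod)
    dup <- names(st)[duplicated(names(st))]
    if (length(dup)) {
      agg <- tapply(st, names(st), sum)
      st <- stats::setNames(as.numeric(agg), names(agg))
    }
    mods <- vapply(
      xml2::xml_find_all(n, "./listOfModifiers/modifierSpeciesReference"),
      function(x) xml2::xml_attr(x, "species"), "")
    kl <- xml2::xml_find_first(n, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction ", rid, " has no kinetic law", call. = FALSE)
    # local parameters are namespaced by reaction id
    lpNodes <- xml2::xml_find_all(kl,
      "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
    localMap <- character()
    for (lpn in lpNodes) {
      lid <- xml2::xml_attr(lpn, "id")
      nsid <- paste0(rid, "_", lid)
      pv[[nsid]] <- as.numeric(xml2::xml_attr(lpn, "value"))
      pu[[nsid]] <- "1"
      localMap[[lid]] <- nsid
    }
    mathNode <- xml2::xml_find_first(kl, "./math")
    if (inherits(mathNode, "xml_missing"))
      stop("reaction ", rid, " kinetic law has no math", call. = FALSE)
    expr <- .mathmlToExpr(mathNode)
    if (length(localMap)) expr <- .renameSymbols(expr, localMap)
    famNode <- xml2::xml_find_first(n, ".//*[local-name()='rateLaw']")
    law <- NULL
    if (!inherits(famNode, "xml_missing")) {
      fam <- xml2::xml_attr(famNode, "family")
      law <- tryCatch(
        methods::new("RateLaw", family = fam,
                     bindings = .undep(xml2::xml_attr(famNode, "bindings")),
                     variant = xml2::xml_attr(famNode, "variant"),
                     math = if (identical(fam, "generic_expression")) expr
                            else NULL),
        error = function(e) NULL)
    }
    if (is.null(law))
      law <- .matchMassAction(expr, names(pv))
    if (is.null(law)) {
      law <- genericLaw(expr)
      famCount[["generic"]] <- famCount[["generic"]] + 1L
    } else famCount[["named"]] <- famCount[["named"]] + 1L
    nmAttr <- xml2::xml_attr(n, "name")
    reactions[[rid]] <- reaction(rid, st, law, modifiers = mods,
      reversible = identical(xml2::xml_attr(n, "reversible"), "true"),
      name = if (is.na(nmAttr)) rid else nmAttr)
  }

  linNode <- xml2::xml_find_first(mnode, "./annotation//*[local-name()='lineage']")
  lineage <- if (!inherits(linNode, "xml_missing"))
    tryCatch(.undep(xml2::xml_text(linNode)), error = function(e) list())
  else list()

  metaNode <- xml2::xml_find_first(mnode,
    "./annotation//*[local-name()='metadata']")
  metadata <- if (!inherits(metaNode, "xml_missing"))
    tryCatch(.undep(xml2::xml_text(metaNode)), error = function(e) NULL)
  else NULL
  if (is.null(metadata))
    metadata <- list(compartment_volume_l = vol, source = "sbml_import")
  model <- cbcModel(species, reactions, parameterSet(pv, pu),
                    lineage = lineage, metadata = metadata)
  report <- list(
    species_mapped = nrow(species),
    clamped = species$id[species$clamped],
    kinetic_laws = famCount,
    unit_notes = notes,
    unresolved = character())
  list(model = model, report = report)
}

# rename symbols in an expression per a named map old -> new
.renameSymbols <- function(e, map) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(map)) as.name(map[[nm]]) else e
  } else if (is.call(e)) {
    as.call(c(e[[1L]], lapply(as.list(e)[-1L], .renameSymbols, map = map)))
  } else e
}
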