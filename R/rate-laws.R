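#' @include AllGenerics.R
NULL

#' Rate-law families for Calvin-Benson cycle models
#'
#' A `RateLaw` is a tagged union over the kinetic families used, critiqued or
#' corrected in published Calvin-cycle models:
#'
#' * `mass_action` - `k * prod(substrates)`, optionally minus
#'   `k/Keq * prod(products)` when reversible.
#' * `michaelis_menten` - irreversible MM with competitive modifiers:
#'   `Vmax * S / (S + Km * (1 + sum(I_j / Ki_j)))`.
#' * `reversible_mm` - multi-substrate reversible MM (convenience form) that
#'   vanishes exactly at the declared equilibrium composition.
#' * `transketolase` - the two-substrate reversible form used for the two
#'   transketolase reactions (S7P + GAP = Ri5P + Xu5P and
#'   F6P + GAP = E4P + Xu5P), with the modifier saturation terms for E4P and
#'   Ri5P combined either additively (the dimensionally correct form) or
#'   multiplicatively (reproducing the documented defect), and with two
#'   denominator conventions (`appendix` / `supplement`) because the two
#'   published encodings are genuinely different models.
#' * `translocator` - the chloroplast phosphate-translocator PGA export law
#'   (`V_PGAout`), antisymmetric under exchange of stromal and cytosolic
#'   compositions.
#' * `oxygenase` - RuBisCO O2-fixation rate with competitive CO2 and five
#'   inhibitor terms.
#' * `starch_phosphorylase` - starch degradation; the `original` variant
#'   carries inorganic phosphate in the substrate position (the documented
#'   defect that drives starch negative), the `corrected` variant carries
#'   starch.
#' * `generic_expression` - an arbitrary arithmetic expression tree over
#'   species and parameter symbols (used for imported SBML kinetic laws).
#'
#' Bindings map the law's symbols either to parameter names (character,
#' looked up in the [ParameterSet-class] at evaluation time) or to numeric
#' literals.
#'
#' @slot family Character, one of the families above.
#' @slot bindings Named list of family-specific symbol bindings.
#' @slot variant Character; `transketolase`: `"additive_modifiers"` or
#'   `"multiplicative_modifiers"`; `starch_phosphorylase`: `"original"` or
#'   `"corrected"`; otherwise `""`.
#' @slot math A `language` object (only for `generic_expression`; otherwise
#'   the `NULL` call).
#' @export
setClass("RateLaw",
  representation(family = "character", bindings = "list",
                 variant = "character", math = "ANY"))

.rateLawFamilies <- c("mass_action", "michaelis_menten", "reversible_mm",
                      "transketolase", "translocator", "oxygenase",
                      "starch_phosphorylase", "generic_expression")

setValidity("RateLaw", function(object) {
  msgs <- character()
  if (length(object@family) != 1L || !object@family %in% .rateLawFamilies)
    msgs <- c(msgs, paste("unknown rate-law family:", object@family))
  if (identical(object@family, "generic_expression")) {
    if (!is.language(object@math))
      msgs <- c(msgs, "generic_expression requires a math expression")
    else {
      bad <- .checkExprOps(object@math)
      if (length(bad))
        msgs <- c(msgs, paste("disallowed operator in expression:",
                              paste(unique(bad), collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

# expression trees may contain only arithmetic, powers and min/max
.allowedOps <- c("+", "-", "*", "/", "^", "(", "min", "max")

.checkExprOps <- function(e) {
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    bad <- if (!op %in% .allowedOps) op else character()
    c(bad, unlist(lapply(as.list(e)[-1L], .checkExprOps)))
  } else character()
}

# collect the symbols of an expression tree
.exprSymbols <- function(e) {
  if (is.symbol(e)) as.character(e)
  else if (is.call(e)) unique(unlist(lapply(as.list(e)[-1L], .exprSymbols)))
  else character()
}

.newRateLaw <- function(family, bindings, variant = "", math = NULL) {
  methods::new("RateLaw", family = family, bindings = bindings,
               variant = variant, math = math)
}

#' @export
setMethod("show", "RateLaw", function(object) {
  v <- if (nzchar(object@variant)) paste0(" [", object@variant, "]") else ""
  cat("RateLaw: ", object@family, v, "\n", sep = "")
  if (identical(object@family, "generic_expression"))
    cat("  math: ", deparse1(object@math), "\n", sep = "")
})

#' Rate-law constructors
#'
#' Each constructor builds one member of the [RateLaw-class] union. Bindings
#' given as character strings are parameter names resolved in the model's
#' `ParameterSet` at evaluation time; numeric bindings are literals.
#'
#' @param k,keq,vmax,km,ke,km1,km2,kmE4P,kmRi5P,vm,vo,ko,kc,kr Rate-law
#'   constants (parameter name or numeric).
#' @param substrates,products Character vectors of species ids; for
#'   `massActionLaw` optionally named numeric vectors of kinetic orders.
#' @param substrate,starch,phosphate,g1p Species ids.
#' @param inhibitors List of `list(species=, ki=)` competitive inhibitors.
#' @param kmS,kmP Character/numeric vectors of Michaelis constants parallel
#'   to `substrates` / `products`.
#' @name rateLaws
NULL

#' @rdname rateLaws
#' @export
massActionLaw <- function(k, substrates, products = character(), keq = NULL) {
  if (is.null(names(substrates)) && is.character(substrates))
    substrates <- stats::setNames(rep(1, length(substrates)), substrates)
  if (is.null(names(products)) && is.character(products) && length(products))
    products <- stats::setNames(rep(1, length(products)), products)
  .newRateLaw("mass_action",
              list(k = k, substrates = substrates, products = products,
                   keq = keq))
}

#' @rdname rateLaws
#' @export
michaelisMentenLaw <- function(vmax, substrate, km, inhibitors = list()) {
  .newRateLaw("michaelis_menten",
              list(vmax = vmax, substrate = substrate, km = km,
                   inhibitors = inhibitors))
}

#' @rdname rateLaws
#' @export
reversibleMMLaw <- function(vmax, keq, substrates, kmS, products, kmP) {
  stopifnot(length(substrates) == length(kmS),
            length(products) == length(kmP))
  .newRateLaw("reversible_mm",
              list(vmax = vmax, keq = keq, substrates = substrates,
                   kmS = kmS, products = products, kmP = kmP))
}

#' @rdname rateLaws
#' @param s1,s2,p1,p2 Species ids of the two substrates and two products.
#' @param modifiers Named list with optional entries `E4P = list(species=, km=)`
#'   and `Ri5P = list(species=, km=)`.
#' @param variant `"additive_modifiers"` (correct) or
#'   `"multiplicative_modifiers"` (documented defect).
#' @param form `"appendix"` or `"supplement"` denominator convention.
#' @export
transketolaseLaw <- function(vmax, ke, s1, s2, p1, p2, km1, km2,
                             modifiers = list(),
                             variant = c("additive_modifiers",
                                         "multiplicative_modifiers"),
                             form = c("appendix", "supplement")) {
  variant <- match.arg(variant)
  form <- match.arg(form)
  .newRateLaw("transketolase",
              list(vmax = vmax, ke = ke, s1 = s1, s2 = s2, p1 = p1, p2 = p2,
                   km1 = km1, km2 = km2, modifiers = modifiers, form = form),
              variant = variant)
}

#' @rdname rateLaws
#' @param stromal,cytosolic Named lists with species ids `OP`, `PGA`, `GAP`,
#'   `DHAP` and Michaelis-constant bindings `KmOP`, `KmPGA`, `KmT3P` for each
#'   side of the envelope.
#' @export
translocatorLaw <- function(vm, stromal, cytosolic) {
  need <- c("OP", "PGA", "GAP", "DHAP", "KmOP", "KmPGA", "KmT3P")
  stopifnot(all(need %in% names(stromal)), all(need %in% names(cytosolic)))
  .newRateLaw("translocator",
              list(vm = vm, stromal = stromal, cytosolic = cytosolic))
}

#' @rdname rateLaws
#' @param rubp,o2,co2,pga,fbp,sbp,pi,nadph Species ids entering the oxygenase
#'   law.
#' @param ki Character/numeric vector of the five inhibition constants
#'   (order: PGA, FBP, SBP, Pi, NADPH).
#' @export
oxygenaseLaw <- function(vo, ko, kc, kr, rubp, o2, co2,
                         pga, fbp, sbp, pi, nadph,
                         ki = c("KI11", "KI12", "KI13", "KI14", "KI15")) {
  stopifnot(length(ki) == 5L)
  .newRateLaw("oxygenase",
              list(vo = vo, ko = ko, kc = kc, kr = kr, rubp = rubp, o2 = o2,
                   co2 = co2,
                   inhibitors = list(species = c(pga, fbp, sbp, pi, nadph),
                                     ki = ki)))
}

#' @rdname rateLaws
#' @export
starchPhosphorylaseLaw <- function(vm = "StPase_VM", km = "StPase_km",
                                   kiG1P = "StPase_kiG1P",
                                   starch = "starch", phosphate = "Pi",
                                   g1p = "G1P",
                                   variant = c("corrected", "original")) {
  variant <- match.arg(variant)
  .newRateLaw("starch_phosphorylase",
              list(vm = vm, km = km, kiG1P = kiG1P, starch = starch,
                   phosphate = phosphate, g1p = g1p),
              variant = variant)
}

#' @rdname rateLaws
#' @param expr An R expression (language object or character) over species and
#'   parameter symbols; only arithmetic operators, powers and `min`/`max` are
#'   allowed.
#' @export
genericLaw <- function(expr) {
  if (is.character(expr)) expr <- str2lang(expr)
  stopifnot(is.language(expr))
  .newRateLaw("generic_expression", list(), math = expr)
}

# ---- evaluation ------------------------------------------------------------

# resolve a binding: character -> state value, else parameter, else error;
# numeric -> literal
.resolve <- function(sym, state, pv) {
  if (is.numeric(sym)) return(unname(sym))
  if (sym %in% names(state)) return(unname(state[[sym]]))
  if (sym %in% names(pv)) return(unname(pv[[sym]]))
  stop("unresolved symbol '", sym, "' in rate law", call. = FALSE)
}

#' @describeIn evaluateRate Evaluate any rate-law family.
#' @param clipNegatives Logical; when `TRUE` (default) negative concentrations
#'   are clipped to zero before evaluation and counted (see
#'   [negativeClipCount()]). Diagnostic-reproduction mode passes `FALSE` so
#'   documented pathologies (e.g. negative starch) evolve as published.
#' @export
setMethod("evaluateRate", "RateLaw",
  function(law, state, params, clipNegatives = TRUE) {
    pv <- .paramVector(params)
    if (clipNegatives && any(state < 0)) {
      .negClip$count <- .negClip$count + sum(state < 0)
      state[state < 0] <- 0
    }
    b <- law@bindings
    r <- function(sym) .resolve(sym, state, pv)
    switch(law@family,
      mass_action = {
        k <- r(b$k)
        fwd <- k * prod(vapply(names(b$substrates), r, 0)^b$substrates)
        if (!is.null(b$keq) && length(b$products)) {
          rev <- (k / r(b$keq)) *
            prod(vapply(names(b$products), r, 0)^b$products)
          fwd - rev
        } else fwd
      },
      michaelis_menten = {
        S <- r(b$substrate)
        inh <- 0
        for (i in b$inhibitors) inh <- inh + r(i$species) / r(i$ki)
        r(b$vmax) * S / (S + r(b$km) * (1 + inh))
      },
      reversible_mm = {
        S <- vapply(b$substrates, r, 0)
        P <- vapply(b$products, r, 0)
        kS <- vapply(b$kmS, r, 0)
        kP <- vapply(b$kmP, r, 0)
        num <- prod(S / kS) - prod(P) / (prod(kS) * r(b$keq))
        den <- prod(1 + S / kS) + prod(1 + P / kP) - 1
        r(b$vmax) * num / den
      },
      transketolase = .tkRate(b, law@variant, r),
      translocator = .translocatorRate(b, r),
      oxygenase = {
        RuBP <- r(b$rubp); O2 <- r(b$o2); CO2 <- r(b$co2)
        inh <- sum(vapply(seq_len(5L), function(i)
          r(b$inhibitors$species[[i]]) / r(b$inhibitors$ki[[i]]), 0))
        num <- RuBP * r(b$vo) * O2 / (O2 + r(b$ko) * (1 + CO2 / r(b$kc)))
        num / (RuBP + r(b$kr) * (1 + inh))
      },
      starch_phosphorylase = {
        sub <- if (identical(law@variant, "corrected")) r(b$starch)
               else r(b$phosphate)
        r(b$vm) * sub / (sub + r(b$km) * (1 + r(b$g1p) / r(b$kiG1P)))
      },
      generic_expression = {
        syms <- .exprSymbols(law@math)
        env <- new.env(parent = baseenv())
        for (s in syms) assign(s, r(s), envir = env)
        eval(law@math, env)
      },
      stop("unknown rate-law family: ", law@family))
  })

.tkRate <- function(b, variant, r) {
  S1 <- r(b$s1); S2 <- r(b$s2); P1 <- r(b$p1); P2 <- r(b$p2)
  kE <- r(b$ke)
  # appendix encoding: the competitive E4P/Ri5P saturation term TEMP scales
  # the first substrate's Michaelis constant; the supplement encoding does
  # not carry the term at all (the two published encodings are different
  # models, and only the appendix one destabilizes at small kM103)
  temp <- 1
  if (identical(b$form, "appendix")) {
    terms <- lapply(b$modifiers, function(m) r(m$species) / r(m$km))
    if (length(terms)) {
      if (identical(variant, "additive_modifiers")) {
        temp <- 1 + sum(unlist(terms))
      } else {
        temp <- prod(1 + unlist(terms))
      }
    }
  }
  num <- r(b$vmax) * kE * (S1 * S2 - P1 * P2 / kE)
  den <- (S1 + r(b$km1) * temp) * (S2 + r(b$km2))
  num / den
}

.translocatorRate <- function(b, r) {
  side <- function(s)
    r(s$OP) / r(s$KmOP) + r(s$PGA) / r(s$KmPGA) +
      (r(s$GAP) + r(s$DHAP)) / r(s$KmT3P)
  Ts <- side(b$stromal)
  Tc <- side(b$cytosolic)
  subst <- Ts * Tc
  num <- Tc * (r(b$stromal$PGA) / r(b$stromal$KmPGA)) -
         Ts * (r(b$cytosolic$PGA) / r(b$cytosolic$KmPGA))
  r(b$vm) * num / (Ts + Tc + subst)
}

# counter for clipped negative concentrations (diagnostic visibility)
.negClip <- new.env(parent = emptyenv())
.negClip$count <- 0

#' Count of negative-concentration clips since last reset
#'
#' Rates are by default evaluated on concentrations clipped at zero; every
#' clip increments this counter so silent pathologies are visible.
#'
#' @param reset Logical; reset the counter to zero after reading.
#' @return Integer count.
#' @export
negativeClipCount <- function(reset = FALSE) {
  n <- .negClip$count
  if (reset) .negClip$count <- 0
  n
}

# symbols a rate law needs, for validation
.rateLawSymbols <- function(law) {
  b <- law@bindings
  chr <- function(x) if (is.character(x)) x else character()
  switch(law@family,
    mass_action = c(chr(b$k), names(b$substrates), names(b$products),
                    chr(b$keq)),
    michaelis_menten = c(chr(b$vmax), chr(b$substrate), chr(b$km),
                         unlist(lapply(b$inhibitors, function(i)
                           c(chr(i$species), chr(i$ki))))),
    reversible_mm = c(chr(b$vmax), chr(b$keq), chr(b$substrates),
                      chr(b$kmS), chr(b$products), chr(b$kmP)),
    transketolase = c(chr(b$vmax), chr(b$ke), chr(b$s1), chr(b$s2),
                      chr(b$p1), chr(b$p2), chr(b$km1), chr(b$km2),
                      unlist(lapply(b$modifiers, function(m)
                        c(chr(m$species), chr(m$km))))),
    translocator = c(chr(b$vm),
                     unlist(b$stromal[vapply(b$stromal, is.character, TRUE)]),
                     unlist(b$cytosolic[vapply(b$cytosolic, is.character,
                                               TRUE)])),
    oxygenase = c(chr(b$vo), chr(b$ko), chr(b$kc), chr(b$kr), chr(b$rubp),
                  chr(b$o2), chr(b$co2), chr(b$inhibitors$species),
                  chr(b$inhibitors$ki)),
    starch_phosphorylase = c(chr(b$vm), chr(b$km), chr(b$kiG1P),
                             chr(b$starch), chr(b$phosphate), chr(b$g1p)),
    generic_expression = .exprSymbols(law@math))
}
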