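#' @include model-library.R
NULL

# Named, reversible, lineage-recorded patches: every documented correction
# (starch fix, kE7, kM103, transketolase modifier mode, lumped vs split
# oxygenation, relay sink, PGA-sink kinetics) is a patch that records the
# prior values it replaces, so models are reconstructible from
# (base variant, lineage) alone.

.patchNames <- c("starch_fix", "set_kE7", "set_kM103", "tk_modifier_mode",
                 "lump_oxygenation", "split_oxygenation", "add_relay_sink",
                 "sink_impl", "flux_match")

#' Describe a patch
#'
#' @param name One of `starch_fix`, `set_kE7`, `set_kM103`,
#'   `tk_modifier_mode`, `lump_oxygenation`, `split_oxygenation`,
#'   `add_relay_sink`, `sink_impl`.
#' @param arguments Named list of patch arguments.
#' @param note Free-text provenance note.
#' @return A `PatchDescriptor` list.
#' @export
patchDescriptor <- function(name, arguments = list(), note = "") {
  if (!name %in% .patchNames)
    stop("unknown patch name: ", name, call. = FALSE)
  structure(list(name = name, arguments = arguments, note = note),
            class = "PatchDescriptor")
}

.appendPatch <- function(model, name, arguments, prior, note = "") {
  i <- length(model@lineage)
  if (i == 0L) {
    model@lineage <- list(list(base = NA_character_, patches = list()))
    i <- 1L
  }
  model@lineage[[i]]$patches <-
    c(model@lineage[[i]]$patches,
      list(list(name = name, arguments = arguments, prior = prior,
                note = note)))
  model
}

#' Apply a named correction patch
#'
#' Applies one [patchDescriptor()] to a model. Only the targeted
#' reaction(s)/parameter(s) change; the patch (with the prior values it
#' replaced) is appended to the lineage, making patches invertible and the
#' model reconstructible. A patch whose target is already in the requested
#' state returns the model unchanged (idempotence).
#'
#' Patch semantics:
#' * `starch_fix` - replace free phosphate by starch in the substrate
#'   position of every original-variant starch-phosphorylase law.
#' * `set_kE7` / `set_kM103` - set the named parameter
#'   (`arguments$value`).
#' * `tk_modifier_mode` - set the modifier-combination variant
#'   (`arguments$mode`) on every transketolase law.
#' * `lump_oxygenation` - encode photorespiration inside the carboxylation
#'   reaction as `RuBP + CO2 -> A PGA + B PGCA` (`arguments$f`, default the
#'   model's `f_oxygenation`), removing any split oxygenation reaction.
#' * `split_oxygenation` - the inverse encoding: carboxylation back to
#'   `2 PGA` at fraction `1 - 2 f` of the maximal rate plus an explicit
#'   O2-fixation reaction at fraction `2 f`, which leaves all steady-state
#'   fluxes unchanged.
#' * `add_relay_sink` - route PGA export through a cytosolic relay
#'   (`PGA -> PGA_cyt -> Sink`), the stabilization used when the
#'   translocator law alone cannot saturate.
#' * `sink_impl` - delegate to [configureSink()] (`arguments$kinetics`).
#'
#' @param model A [CbcModel-class].
#' @param patch A [patchDescriptor()].
#' @return The patched model.
#' @export
applyPatch <- function(model, patch) {
  stopifnot(inherits(patch, "PatchDescriptor"))
  a <- patch$arguments
  switch(patch$name,
    starch_fix = {
      hit <- FALSE
      prior <- list()
      for (id in names(model@reactions)) {
        r <- model@reactions[[id]]
        if (identical(r@rateLaw@family, "starch_phosphorylase") &&
            identical(r@rateLaw@variant, "original")) {
          r@rateLaw@variant <- "corrected"
          model@reactions[[id]] <- r
          prior[[id]] <- "original"
          hit <- TRUE
        }
      }
      if (!hit) return(model)
      .appendPatch(model, "starch_fix", list(), prior, patch$note)
    },
    set_kE7 = .setParamPatch(model, "kE7", a$value, patch),
    set_kM103 = .setParamPatch(model, "kM103", a$value, patch),
    tk_modifier_mode = {
      mode <- match.arg(a$mode, c("additive_modifiers",
                                  "multiplicative_modifiers"))
      prior <- list()
      hit <- FALSE
      for (id in names(model@reactions)) {
        r <- model@reactions[[id]]
        if (identical(r@rateLaw@family, "transketolase") &&
            !identical(r@rateLaw@variant, mode)) {
          prior[[id]] <- r@rateLaw@variant
          r@rateLaw@variant <- mode
          model@reactions[[id]] <- r
          hit <- TRUE
        }
      }
      if (!hit) return(model)
      .appendPatch(model, "tk_modifier_mode", list(mode = mode), prior,
                   patch$note)
    },
    lump_oxygenation = {
      if (!"PGCA" %in% speciesIds(model))
        stop("lump_oxygenation requires a PGCA species (D-type model)",
             call. = FALSE)
      f <- if (!is.null(a$f)) a$f else
        paramValue(model@parameters, "f_oxygenation")
      AB <- lumpedCarboxylationStoichiometry(f)
      carb <- model@reactions[["CC1_carb"]]
      if (is.null(carb))
        stop("patch targets reaction CC1_carb, absent from the model",
             call. = FALSE)
      alreadyLumped <- "PGCA" %in% names(carb@stoichiometry) &&
        !"CC1_oxy" %in% names(model@reactions)
      if (alreadyLumped &&
          isTRUE(all.equal(unname(carb@stoichiometry[["PGCA"]]),
                           unname(AB[["B"]]))))
        return(model)
      prior <- list(stoichiometry = carb@stoichiometry,
                    had_split = "CC1_oxy" %in% names(model@reactions))
      carb@stoichiometry <- c(RuBP = -1, CO2 = -1,
                              PGA = unname(AB[["A"]]),
                              PGCA = unname(AB[["B"]]))
      carb@rateLaw <- michaelisMentenLaw("V_CC1", "RuBP", "Km_CC1")
      carb@name <- "lumped carboxylation-oxygenation"
      model@reactions[["CC1_carb"]] <- carb
      model@reactions[["CC1_oxy"]] <- NULL
      .appendPatch(model, "lump_oxygenation", list(f = f), prior,
                   patch$note)
    },
    split_oxygenation = {
      carb <- model@reactions[["CC1_carb"]]
      if (is.null(carb) || !"PGCA" %in% names(carb@stoichiometry))
        stop("split_oxygenation requires a lumped carboxylation-oxygenation ",
             "reaction", call. = FALSE)
      B <- unname(carb@stoichiometry[["PGCA"]])
      f <- B / 2
      prior <- list(stoichiometry = carb@stoichiometry)
      vmax <- paramValue(model@parameters, "V_CC1")
      modelParameters(model) <- updateParameters(model@parameters,
        c(V_CC1_carbox = (1 - 2 * f) * vmax, V_CC1_oxy = 2 * f * vmax),
        c(V_CC1_carbox = "mM s^-1", V_CC1_oxy = "mM s^-1"))
      carb@stoichiometry <- c(RuBP = -1, CO2 = -1, PGA = 2)
      carb@rateLaw <- michaelisMentenLaw("V_CC1_carbox", "RuBP", "Km_CC1")
      carb@name <- "RuBisCO carboxylation"
      model@reactions[["CC1_carb"]] <- carb
      oxy <- reaction("CC1_oxy",
                      c(RuBP = -1, O2 = -1, PGA = 1, PGCA = 1),
                      michaelisMentenLaw("V_CC1_oxy", "RuBP", "Km_CC1"),
                      name = "RuBisCO oxygenation (O2 fixation)")
      model@reactions <- c(model@reactions, list(CC1_oxy = oxy))
      names(model@reactions)[length(model@reactions)] <- "CC1_oxy"
      .appendPatch(model, "split_oxygenation", list(f = f), prior,
                   patch$note)
    },
    add_relay_sink = {
      sr <- model@reactions[["SR_PGA"]]
      if (is.null(sr))
        stop("patch targets reaction SR_PGA, absent from the model",
             call. = FALSE)
      if ("SR_PGA_relay" %in% names(model@reactions)) return(model)
      prior <- list(stoichiometry = sr@stoichiometry)
      model@species <- rbind(model@species,
        speciesSpec("PGA_cyt", 0, carbons = 3, phosphates = 1))
      sr@stoichiometry <- c(PGA = -1, PGA_cyt = 1)
      model@reactions[["SR_PGA"]] <- sr
      vr <- if (!is.null(a$vmax)) a$vmax else
        paramValue(model@parameters, "V_sr_PGA",
                   default = paramValue(model@parameters, "J_nominal",
                                        default = 1))
      kr <- if (!is.null(a$km)) a$km else 0.5
      modelParameters(model) <- updateParameters(model@parameters,
        c(V_relay = vr, Km_relay = kr),
        c(V_relay = "mM s^-1", Km_relay = "mM"))
      relay <- reaction("SR_PGA_relay",
                        c(PGA_cyt = -1, Sink_PGA = 1, Pi = 1),
                        michaelisMentenLaw("V_relay", "PGA_cyt",
                                           "Km_relay"),
                        name = "cytosolic PGA relay sink")
      model@reactions <- c(model@reactions, list(SR_PGA_relay = relay))
      .appendPatch(model, "add_relay_sink", list(vmax = vr, km = kr),
                   prior, patch$note)
    },
    sink_impl = {
      configureSink(model,
                    species = if (!is.null(a$species)) a$species else "PGA",
                    kinetics = a$kinetics,
                    params = if (!is.null(a$parameters)) a$parameters
                             else list())
    },
    flux_match = {
      # replay of a recorded flux-matching adjustment
      pv <- .paramVector(model@parameters)
      knobs <- a$knobs
      upd <- stats::setNames(pv[knobs] * a$scale, knobs)
      prior <- as.list(pv[knobs])
      modelParameters(model) <- updateParameters(model@parameters, upd)
      .appendPatch(model, "flux_match", a, prior, patch$note)
    },
    stop("unknown patch name: ", patch$name, call. = FALSE))
}

.setParamPatch <- function(model, pname, value, patch) {
  if (is.null(value)) stop("patch requires arguments$value", call. = FALSE)
  prior <- paramValue(model@parameters, pname, default = NA_real_)
  if (isTRUE(all.equal(prior, value))) return(model)
  modelParameters(model) <- updateParameters(model@parameters,
    stats::setNames(value, pname))
  .appendPatch(model, patch$name, list(value = value),
               stats::setNames(list(prior), pname), patch$note)
}

#' Configure the export kinetics of a sink
#'
#' Replaces the export reaction of `species` (by default PGA) with the
#' requested kinetics family: `MA` mass action without modifiers, `MM`
#' Michaelis-Menten regulated by phosphate, GAP and DHAP (the
#' translocator-style regulation), or `MMcb` the simplest Michaelis-Menten
#' regulated by the species alone (the cyanobacterial simplification). The
#' model ends up with exactly one export reaction for the species.
#'
#' @param model A [CbcModel-class] with the species present.
#' @param species Species id (default `"PGA"`).
#' @param kinetics `"MA"`, `"MM"` or `"MMcb"`.
#' @param params Optional list with `vmax`, `km` or `k` numeric overrides.
#' @return The modified model.
#' @export
configureSink <- function(model, species = "PGA",
                          kinetics = c("MMcb", "MM", "MA"),
                          params = list()) {
  kinetics <- match.arg(kinetics)
  if (!species %in% speciesIds(model))
    stop("species not in model: ", species, call. = FALSE)
  srId <- paste0("SR_", species)
  if (paste0(srId, "_relay") %in% names(model@reactions))
    stop("conflicting existing sink: ", species,
         " already exports through a relay", call. = FALSE)
  old <- model@reactions[[srId]]
  prior <- if (is.null(old)) list() else
    list(family = old@rateLaw@family)
  pool <- paste0("Sink_", species)
  if (!pool %in% speciesIds(model))
    model@species <- rbind(model@species,
      speciesSpec(pool, 0,
                  carbons = if (species %in% names(.sinkCarbons))
                    .sinkCarbons[[species]] else NA_real_,
                  phosphates = 0, clamped = TRUE))
  vName <- paste0("V_sr_", species)
  kName <- paste0("k_sr_", species)
  pv <- .paramVector(model@parameters)
  vmax <- if (!is.null(params$vmax)) params$vmax
          else if (vName %in% names(pv)) pv[[vName]] else 0.5
  km <- if (!is.null(params$km)) params$km
        else if ("Km_sink" %in% names(pv)) pv[["Km_sink"]] else 0.5
  upd <- stats::setNames(c(vmax, km), c(vName, "Km_sink"))
  if (identical(kinetics, "MA")) {
    k <- if (!is.null(params$k)) params$k else vmax / km
    upd <- c(upd, stats::setNames(k, kName))
  }
  if (identical(kinetics, "MM"))
    upd <- c(upd, c(Ki_sr_Pi = 2, Ki_sr_GAP = 1, Ki_sr_DHAP = 1))
  uu <- ifelse(grepl("^V_", names(upd)), "mM s^-1",
               ifelse(grepl("^k_", names(upd)), "s^-1", "mM"))
  modelParameters(model) <- updateParameters(model@parameters, upd,
    stats::setNames(uu, names(upd)))
  newRx <- .sinkReaction(species, kinetics, NA_real_)
  model@reactions[[srId]] <- newRx
  .appendPatch(model, "sink_impl",
               list(kinetics = kinetics, species = species), prior,
               "sink kinetics configuration")
}

#' Rebuild a model from its base variant and lineage
#'
#' Library models are reconstructible from `(base variant, lineage)` alone:
#' the base variant is rebuilt with its recorded sink configuration and every
#' recorded patch is replayed in order. Structural equality with the original
#' is the lineage-completeness guarantee (see [modelDiff()]).
#'
#' @param model A [CbcModel-class] built by [buildModel()].
#' @return The reconstructed model.
#' @export
reconstructFromLineage <- function(model) {
  if (!length(model@lineage))
    stop("model has no lineage", call. = FALSE)
  rec <- model@lineage[[1L]]
  if (is.na(rec$base) || !rec$base %in% modelVariants())
    stop("lineage base is not a library variant: ", rec$base,
         call. = FALSE)
  cfg <- NULL
  if (!is.null(rec$sink_config)) {
    sc <- rec$sink_config
    cfg <- sinkConfig(
      sinks = lapply(names(sc$explicit), function(sp)
        .mkSink(sp, sc$kinetics[[sp]], sc$explicit[[sp]])),
      lumpedIntoPga = sc$lumped_into_pga)
  }
  m <- buildModel(rec$base, sinkCfg = cfg)
  for (p in rec$patches)
    m <- applyPatch(m, patchDescriptor(p$name, p$arguments, p$note))
  m
}
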