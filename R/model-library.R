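#' @include model.R
NULL

# Model library: the corrected Calvin-Benson + starch network for
# cyanobacteria, its variant lineage (zhu_A / zhu_S transketolase encodings;
# C1/C2 with photorespiration folded into the PGA sink; D1/D2 with the first
# photorespiratory step as O2 fixation), and named, reversible patches.
#
# Literature-only parameterizations (Hahn, Pettersson, the Zhu supplement)
# are import targets, not built-ins: the numeric defaults here are fixture
# values flagged "non-archival" in the lineage.

#' Flux-balance sink fractions of the RuBP synthesis flux
#'
#' Basic sink fluxes as fractions of the steady-state RuBP synthesis flux,
#' from the flux-balance reconstruction of the cyanobacterial network:
#' PGCA 4.2 %, F6P 2.4 %, Ri5P 0.7 %, DHAP 0.32 %, E4P 0.31 %. The PGA
#' entry is the basic (direct) PGA sink fraction before any folded
#' contributions.
#'
#' @return Named numeric vector of fractions.
#' @export
basicSinkFractions <- function() {
  c(PGA = 0.128, F6P = 0.024, PGCA = 0.042,
    R5P = 0.007, DHAP = 0.0032, E4P = 0.0031)
}

#' Carbon-ratio folding factors for minor sinks
#'
#' The printed q factors used when a minor sink's basic flux is folded into
#' the PGA sink: q(Ri5P) = 5/3, q(DHAP) = 1, q(E4P) = 4/3, and the printed
#' 1.66 for PGCA.
#' @keywords internal
.printedQ <- c(R5P = 5 / 3, DHAP = 1, E4P = 4 / 3, PGCA = 1.66)

#' Aggregate minor-sink fractions into the PGA sink
#'
#' Each folded species' basic flux fraction is multiplied by its
#' stoichiometric factor q and the products are summed; the sum is added to
#' the basic flux of the PGA sink. Under the default rule the q values are
#' the printed ones (PGCA uses the printed 1.66); under `carbon_ratio` they
#' are `carbons / 3` via [carbonConversionFactor()].
#'
#' @param fractions Named numeric vector: species id -> basic flux fraction.
#' @param qRule `"printed"` (default) or `"carbon_ratio"`.
#' @param carbons Named carbon counts, required under `carbon_ratio` for
#'   species outside the built-in table.
#' @return The added PGA-sink fraction `sum(q_i * f_i)`.
#' @examples
#' aggregateMinorSinks(c(R5P = 0.007, DHAP = 0.0032, E4P = 0.0031))
#' @export
aggregateMinorSinks <- function(fractions, qRule = c("printed",
                                                     "carbon_ratio"),
                                carbons = NULL) {
  qRule <- match.arg(qRule)
  if (!length(fractions)) return(0)
  stopifnot(all(fractions > 0))
  q <- vapply(names(fractions), function(sp) {
    if (qRule == "printed") {
      if (!sp %in% names(.printedQ))
        stop("no printed q factor for species: ", sp, call. = FALSE)
      .printedQ[[sp]]
    } else {
      cc <- if (!is.null(carbons) && sp %in% names(carbons)) carbons[[sp]]
            else c(R5P = 5, DHAP = 3, E4P = 4, PGCA = 2)[sp]
      if (is.na(cc))
        stop("no carbon count declared for species: ", sp, call. = FALSE)
      as.numeric(carbonConversionFactor(cc, 3))
    }
  }, 0)
  sum(q * fractions)
}

#' Sink configuration
#'
#' @param sinks List of `list(species =, kinetics = "MA"|"MM"|"MMcb",
#'   fraction =, parameters = list())` entries: explicit export reactions and
#'   their basic flux fractions (of the reference RuBP-synthesis flux).
#' @param lumpedIntoPga Named numeric vector of basic flux fractions for
#'   species folded into the PGA sink (mutually exclusive with an explicit
#'   sink for the same species).
#' @param qRule Folding rule passed to [aggregateMinorSinks()].
#' @return A `SinkConfig` list.
#' @export
sinkConfig <- function(sinks = list(), lumpedIntoPga = numeric(),
                       qRule = "printed") {
  explicit <- vapply(sinks, function(s) s$species, "")
  overlap <- intersect(explicit, names(lumpedIntoPga))
  if (length(overlap))
    stop("species both explicit and lumped: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  fr <- vapply(sinks, function(s) s$fraction, 0)
  if (any(fr <= 0 | fr >= 1))
    stop("basic flux fractions must lie in (0, 1)", call. = FALSE)
  structure(list(sinks = sinks, lumpedIntoPga = lumpedIntoPga,
                 qRule = qRule), class = "SinkConfig")
}

.mkSink <- function(species, kinetics, fraction) {
  list(species = species, kinetics = kinetics, fraction = fraction,
       parameters = list())
}

#' Registered model variants
#'
#' @return Character vector of variant names accepted by [buildModel()].
#' @export
modelVariants <- function()
  c("zhu_A", "zhu_S", "cyano_C1", "cyano_C2", "cyano_D1", "cyano_D2",
    "hahn")

# default sink configuration per variant
.defaultSinkConfig <- function(variant) {
  f <- basicSinkFractions()
  minor <- f[c("R5P", "DHAP", "E4P")]
  switch(variant,
    zhu_A = ,
    zhu_S = sinkConfig(list(.mkSink("PGA", "MM", 0.20),
                            .mkSink("F6P", "MMcb", f[["F6P"]]))),
    cyano_C1 = sinkConfig(
      list(.mkSink("PGA", "MMcb",
                   f[["PGA"]] +
                     aggregateMinorSinks(c(minor, PGCA = f[["PGCA"]]))),
           .mkSink("F6P", "MMcb", f[["F6P"]])),
      lumpedIntoPga = c(minor, PGCA = f[["PGCA"]])),
    cyano_C2 = sinkConfig(
      list(.mkSink("PGA", "MMcb",
                   f[["PGA"]] + aggregateMinorSinks(c(PGCA = f[["PGCA"]]))),
           .mkSink("F6P", "MMcb", f[["F6P"]]),
           .mkSink("DHAP", "MMcb", f[["DHAP"]]),
           .mkSink("E4P", "MMcb", f[["E4P"]]),
           .mkSink("R5P", "MMcb", f[["R5P"]])),
      lumpedIntoPga = c(PGCA = f[["PGCA"]])),
    cyano_D1 = sinkConfig(
      list(.mkSink("PGA", "MMcb", f[["PGA"]] + aggregateMinorSinks(minor)),
           .mkSink("F6P", "MMcb", f[["F6P"]]),
           .mkSink("PGCA", "MMcb", 2 * f[["PGCA"]])),
      lumpedIntoPga = minor),
    cyano_D2 = sinkConfig(
      list(.mkSink("PGA", "MMcb", f[["PGA"]]),
           .mkSink("F6P", "MMcb", f[["F6P"]]),
           .mkSink("DHAP", "MMcb", f[["DHAP"]]),
           .mkSink("E4P", "MMcb", f[["E4P"]]),
           .mkSink("R5P", "MMcb", f[["R5P"]]),
           .mkSink("PGCA", "MMcb", 2 * f[["PGCA"]]))),
    hahn = sinkConfig(list(.mkSink("PGA", "MA", 0.20))))
}

# fixture ("non-archival") kinetic defaults for the cyanobacterial network
.cyanoDefaultParams <- function() {
  v <- c(
    # irreversible Michaelis-Menten steps
    V_CC1 = 1.5, Km_CC1 = 0.05,
    V_CC6 = 2.0, Km_CC6 = 0.08,
    V_CC9 = 2.0, Km_CC9 = 0.08,
    V_SS3 = 0.1, Km_SS3 = 1,
    # reversible steps: Vm, Keq, substrate/product Kms
    V_CC2 = 8, keq_CC2 = 10, Km_CC2_PGA = 0.5, Km_CC2_ATP = 0.1,
    Km_CC2_BPGA = 0.1, Km_CC2_ADP = 0.1,
    V_CC3 = 8, keq_CC3 = 500, Km_CC3_BPGA = 0.1, Km_CC3_NADPH = 0.1,
    Km_CC3_GAP = 0.5, Km_CC3_NADP = 0.1, Km_CC3_Pi = 1,
    V_CC4 = 8, keq_CC4 = 22, Km_CC4_GAP = 0.4, Km_CC4_DHAP = 0.4,
    V_CC5 = 8, keq_CC5 = 7, Km_CC5_GAP = 0.3, Km_CC5_DHAP = 0.4,
    Km_CC5_FBP = 0.2,
    V_CC8 = 8, keq_CC8 = 7, Km_CC8_E4P = 0.2, Km_CC8_DHAP = 0.4,
    Km_CC8_SBP = 0.2,
    V_CC11 = 8, keq_CC11 = 3, Km_CC11_R5P = 0.2, Km_CC11_Ru5P = 0.2,
    V_CC12 = 8, keq_CC12 = 0.67, Km_CC12_X5P = 0.2, Km_CC12_Ru5P = 0.2,
    V_CC13 = 8, keq_CC13 = 7000, Km_CC13_Ru5P = 0.15, Km_CC13_ATP = 0.1,
    Km_CC13_RuBP = 0.5, Km_CC13_ADP = 0.1,
    V_SS1 = 4, keq_SS1 = 0.3, Km_SS1_F6P = 0.3, Km_SS1_G6P = 0.3,
    V_SS2 = 4, keq_SS2 = 0.058, Km_SS2_G6P = 0.3, Km_SS2_G1P = 0.3,
    # transketolase (v10: F6P + GAP = E4P + X5P; v7: S7P + GAP = R5P + X5P)
    V_tk10 = 80, Km_tk10_F6P = 8, Km_tk10_GAP = 0.3, Km_tk10_R5P = 1,
    V_tk7 = 80, Km_tk7_S7P = 8, Km_tk7_GAP = 0.3, Km_tk7_R5P = 1,
    kE7 = 0.076, kM103 = 0.46,
    # light-driven ATP supply
    V_L = 3.5, Km_L_ADP = 0.1,
    # lumped carboxylation-oxygenation and flux matching
    f_oxygenation = 0.042,
    adenylate_total = 0.5,
    # sink half-saturation and capacity headroom over the nominal flux
    Km_sink = 2, sink_capacity = 3, J_nominal = 0.9)
  u <- rep("1", length(v))
  names(u) <- names(v)
  u[grep("^V_", names(v))] <- "mM s^-1"
  u[grep("^Km_", names(v))] <- "mM"
  u[c("adenylate_total", "J_nominal")] <- c("mM", "mM s^-1")
  parameterSet(v, u)
}

.cyanoSpecies <- function(withPGCA) {
  sp <- rbind(
    speciesSpec("RuBP", 0.07, carbons = 5, phosphates = 2),
    speciesSpec("PGA", 0.55, carbons = 3, phosphates = 1),
    speciesSpec("BPGA", 0.14, carbons = 3, phosphates = 2),
    speciesSpec("GAP", 0.06, carbons = 3, phosphates = 1),
    speciesSpec("DHAP", 0.20, carbons = 3, phosphates = 1),
    speciesSpec("FBP", 0.02, carbons = 6, phosphates = 2),
    speciesSpec("F6P", 4.30, carbons = 6, phosphates = 1),
    speciesSpec("E4P", 0.04, carbons = 4, phosphates = 1),
    speciesSpec("X5P", 0.09, carbons = 5, phosphates = 1),
    speciesSpec("SBP", 0.013, carbons = 7, phosphates = 2),
    speciesSpec("S7P", 4.00, carbons = 7, phosphates = 1),
    speciesSpec("R5P", 0.025, carbons = 5, phosphates = 1),
    speciesSpec("Ru5P", 0.045, carbons = 5, phosphates = 1),
    speciesSpec("G6P", 1.29, carbons = 6, phosphates = 1),
    speciesSpec("G1P", 0.075, carbons = 6, phosphates = 1),
    speciesSpec("starch", 0.00, carbons = 6, phosphates = 0,
                clamped = TRUE),
    speciesSpec("CO2", 0.20, carbons = 1, phosphates = 0, clamped = TRUE),
    speciesSpec("O2", 0.25, carbons = 0, phosphates = 0, clamped = TRUE),
    speciesSpec("Pi", 1.00, carbons = 0, phosphates = 1, clamped = TRUE),
    speciesSpec("ATP", 0.27, carbons = 0, phosphates = 3),
    speciesSpec("ADP", 0.23, carbons = 0, phosphates = 2),
    speciesSpec("NADPH", 0.21, carbons = 0, phosphates = 0, clamped = TRUE),
    speciesSpec("NADP", 0.29, carbons = 0, phosphates = 0, clamped = TRUE))
  if (withPGCA)
    sp <- rbind(sp, speciesSpec("PGCA", 0.01, carbons = 2, phosphates = 1))
  sp
}

.revMM <- function(id, vmax, keq, subs, prods, pre) {
  kmS <- paste0("Km_", pre, "_", subs)
  kmP <- paste0("Km_", pre, "_", prods)
  reversibleMMLaw(vmax = vmax, keq = keq, substrates = subs, kmS = kmS,
                  products = prods, kmP = kmP)
}

.cyanoReactions <- function(tkForm, tkMode) {
  list(
    reaction("CC1_carb", c(RuBP = -1, CO2 = -1, PGA = 2),
             michaelisMentenLaw("V_CC1", "RuBP", "Km_CC1"),
             name = "RuBisCO carboxylation"),
    reaction("CC2_pgak", c(PGA = -1, ATP = -1, BPGA = 1, ADP = 1),
             .revMM("CC2", "V_CC2", "keq_CC2", c("PGA", "ATP"),
                    c("BPGA", "ADP"), "CC2"), reversible = TRUE,
             name = "PGA kinase"),
    reaction("CC3_gapdh", c(BPGA = -1, NADPH = -1, GAP = 1, NADP = 1,
                            Pi = 1),
             .revMM("CC3", "V_CC3", "keq_CC3", c("BPGA", "NADPH"),
                    c("GAP", "NADP", "Pi"), "CC3"), reversible = TRUE,
             name = "GAP dehydrogenase"),
    reaction("CC4_tpi", c(GAP = -1, DHAP = 1),
             .revMM("CC4", "V_CC4", "keq_CC4", "GAP", "DHAP", "CC4"),
             reversible = TRUE, name = "triose-phosphate isomerase"),
    reaction("CC5_ald", c(GAP = -1, DHAP = -1, FBP = 1),
             .revMM("CC5", "V_CC5", "keq_CC5", c("GAP", "DHAP"), "FBP",
                    "CC5"), reversible = TRUE, name = "FBP aldolase"),
    reaction("CC6_fbpase", c(FBP = -1, F6P = 1, Pi = 1),
             michaelisMentenLaw("V_CC6", "FBP", "Km_CC6"),
             name = "FBPase"),
    reaction("CC7_tk10", c(F6P = -1, GAP = -1, E4P = 1, X5P = 1),
             transketolaseLaw("V_tk10", "kE7", s1 = "F6P", s2 = "GAP",
                              p1 = "E4P", p2 = "X5P", km1 = "Km_tk10_F6P",
                              km2 = "Km_tk10_GAP",
                              modifiers = list(
                                list(species = "E4P", km = "kM103"),
                                list(species = "R5P", km = "Km_tk10_R5P")),
                              variant = tkMode, form = tkForm),
             modifiers = c("E4P", "R5P"), reversible = TRUE,
             name = "transketolase (F6P + GAP = E4P + X5P)"),
    reaction("CC8_ald", c(E4P = -1, DHAP = -1, SBP = 1),
             .revMM("CC8", "V_CC8", "keq_CC8", c("E4P", "DHAP"), "SBP",
                    "CC8"), reversible = TRUE, name = "SBP aldolase"),
    reaction("CC9_sbpase", c(SBP = -1, S7P = 1, Pi = 1),
             michaelisMentenLaw("V_CC9", "SBP", "Km_CC9"),
             name = "SBPase"),
    reaction("CC10_tk7", c(S7P = -1, GAP = -1, R5P = 1, X5P = 1),
             transketolaseLaw("V_tk7", "kE7", s1 = "S7P", s2 = "GAP",
                              p1 = "R5P", p2 = "X5P", km1 = "Km_tk7_S7P",
                              km2 = "Km_tk7_GAP",
                              modifiers = list(
                                list(species = "E4P", km = "kM103"),
                                list(species = "R5P", km = "Km_tk7_R5P")),
                              variant = tkMode, form = tkForm),
             modifiers = c("E4P", "R5P"), reversible = TRUE,
             name = "transketolase (S7P + GAP = R5P + X5P)"),
    reaction("CC11_rpi", c(R5P = -1, Ru5P = 1),
             .revMM("CC11", "V_CC11", "keq_CC11", "R5P", "Ru5P", "CC11"),
             reversible = TRUE, name = "R5P isomerase"),
    reaction("CC12_rpe", c(X5P = -1, Ru5P = 1),
             .revMM("CC12", "V_CC12", "keq_CC12", "X5P", "Ru5P", "CC12"),
             reversible = TRUE, name = "Ru5P epimerase"),
    reaction("CC13_prk", c(Ru5P = -1, ATP = -1, RuBP = 1, ADP = 1),
             .revMM("CC13", "V_CC13", "keq_CC13", c("Ru5P", "ATP"),
                    c("RuBP", "ADP"), "CC13"), reversible = TRUE,
             name = "phosphoribulokinase (RuBP synthesis)"),
    reaction("SS1_pgi", c(F6P = -1, G6P = 1),
             .revMM("SS1", "V_SS1", "keq_SS1", "F6P", "G6P", "SS1"),
             reversible = TRUE, name = "phosphoglucose isomerase"),
    reaction("SS2_pgm", c(G6P = -1, G1P = 1),
             .revMM("SS2", "V_SS2", "keq_SS2", "G6P", "G1P", "SS2"),
             reversible = TRUE, name = "phosphoglucomutase"),
    reaction("SS3_stsyn", c(G1P = -1, ATP = -1, starch = 1, ADP = 1,
                            Pi = 2),
             michaelisMentenLaw("V_SS3", "G1P", "Km_SS3"),
             name = "starch synthesis"),
    # photophosphorylation: the light-driven ATP supply whose capacity sets
    # the energy limitation of the cycle
    reaction("L_atpsyn", c(ADP = -1, Pi = -1, ATP = 1),
             michaelisMentenLaw("V_L", "ADP", "Km_L_ADP"),
             name = "photophosphorylation (ATP synthesis)"))
}

# sink pool species carbon counts
.sinkCarbons <- c(PGA = 3, F6P = 6, DHAP = 3, E4P = 4, R5P = 5, PGCA = 2,
                  GAP = 3)

.sinkReaction <- function(species, kinetics, fraction) {
  pool <- paste0("Sink_", species)
  st <- stats::setNames(c(-1, 1, 1), c(species, pool, "Pi"))
  vName <- paste0("V_sr_", species)
  kmName <- "Km_sink"
  law <- switch(kinetics,
    MA = massActionLaw(paste0("k_sr_", species),
                       stats::setNames(1, species)),
    MMcb = michaelisMentenLaw(vName, species, kmName),
    MM = michaelisMentenLaw(vName, species, kmName,
           inhibitors = list(list(species = "Pi", ki = "Ki_sr_Pi"),
                             list(species = "GAP", ki = "Ki_sr_GAP"),
                             list(species = "DHAP", ki = "Ki_sr_DHAP"))),
    stop("unknown sink kinetics: ", kinetics, call. = FALSE))
  mods <- if (identical(kinetics, "MM")) c("Pi", "GAP", "DHAP")
          else character()
  reaction(paste0("SR_", species), st, law, modifiers = mods,
           name = paste(species, "sink"))
}

#' Build a model variant
#'
#' Constructs one of the registered variants of the corrected Calvin-Benson +
#' starch network. All cyanobacterial variants have one compartment with
#' fixed CO2, O2, Pi and fixed cofactors, every hexose/pentose and GAP/DHAP
#' as separate species, and Michaelis-Menten kinetics throughout; they differ
#' in the transketolase encoding (`zhu_A` appendix form, `zhu_S` supplement
#' form), in whether photorespiration appears only as a folded PGCA
#' contribution to the PGA sink (C variants) or as O2 fixation producing PGCA
#' (D variants, lumped stoichiometry by default), and in whether the minor
#' DHAP/E4P/Ri5P sinks are folded into the PGA sink (C1/D1) or explicit
#' (C2/D2). The `hahn` variant is the same topology under pure mass-action
#' kinetics (the behavior class of the earliest models) with dynamic
#' adenylates and an external phosphate pool.
#'
#' @param variant One of [modelVariants()].
#' @param params Optional [ParameterSet-class] overriding the fixture
#'   defaults (which are flagged `non-archival` in the lineage).
#' @param sinkCfg Optional [sinkConfig()]; must be consistent with the
#'   variant (explicit minor sinks on C1/D1 are an error).
#' @return A validated [CbcModel-class].
#' @export
buildModel <- function(variant, params = NULL, sinkCfg = NULL) {
  variant <- match.arg(variant, modelVariants())
  if (identical(variant, "hahn")) return(.buildHahn(params, sinkCfg))
  cfg <- if (is.null(sinkCfg)) .defaultSinkConfig(variant) else sinkCfg
  foldedOnly <- variant %in% c("cyano_C1", "cyano_D1")
  explicit <- vapply(cfg$sinks, function(s) s$species, "")
  if (foldedOnly && length(intersect(explicit, c("DHAP", "E4P", "R5P"))))
    stop("variant ", variant,
         " folds the minor sinks into the PGA sink; explicit DHAP/E4P/R5P ",
         "sinks are inconsistent", call. = FALSE)
  isD <- variant %in% c("cyano_D1", "cyano_D2")
  tkForm <- if (identical(variant, "zhu_S")) "supplement" else "appendix"
  ps <- .cyanoDefaultParams()
  if (identical(variant, "zhu_S"))
    ps <- updateParameters(ps, c(kM103 = 0.015))
  if (!is.null(params)) {
    # user values override the sink defaults computed below, so re-apply last
    userParams <- params
    ps <- updateParameters(ps, params@values,
                           params@units[names(params@values)])
  } else userParams <- NULL

  species <- .cyanoSpecies(withPGCA = isD)
  rx <- .cyanoReactions(tkForm, tkMode = "additive_modifiers")
  if (isD) {
    AB <- lumpedCarboxylationStoichiometry(
      paramValue(ps, "f_oxygenation"))
    rx[[1L]] <- reaction("CC1_carb",
                         c(RuBP = -1, CO2 = -1,
                           PGA = unname(AB[["A"]]),
                           PGCA = unname(AB[["B"]])),
                         michaelisMentenLaw("V_CC1", "RuBP", "Km_CC1"),
                         name = "lumped carboxylation-oxygenation")
  }
  # sinks: Vmax = capacity headroom x fraction x nominal flux
  jn <- paramValue(ps, "J_nominal")
  capf <- paramValue(ps, "sink_capacity")
  for (s in cfg$sinks) {
    species <- rbind(species,
      speciesSpec(paste0("Sink_", s$species), 0,
                  carbons = .sinkCarbons[[s$species]], phosphates = 0,
                  clamped = TRUE))
    vmax <- capf * s$fraction * jn
    if (identical(s$kinetics, "MA")) {
      ps <- updateParameters(ps,
        stats::setNames(vmax / paramValue(ps, "Km_sink"),
                        paste0("k_sr_", s$species)),
        stats::setNames("s^-1", paste0("k_sr_", s$species)))
    } else {
      ps <- updateParameters(ps,
        stats::setNames(vmax, paste0("V_sr_", s$species)),
        stats::setNames("mM s^-1", paste0("V_sr_", s$species)))
      if (identical(s$kinetics, "MM"))
        ps <- updateParameters(ps,
          c(Ki_sr_Pi = 2, Ki_sr_GAP = 1, Ki_sr_DHAP = 1),
          c(Ki_sr_Pi = "mM", Ki_sr_GAP = "mM", Ki_sr_DHAP = "mM"))
    }
    rx <- c(rx, list(.sinkReaction(s$species, s$kinetics, s$fraction)))
  }
  if (!is.null(userParams))
    ps <- updateParameters(ps, userParams@values,
                           userParams@units[names(userParams@values)])
  lineage <- list(list(
    base = variant,
    patches = list(),
    sink_config = list(
      explicit = stats::setNames(
        vapply(cfg$sinks, function(s) s$fraction, 0),
        vapply(cfg$sinks, function(s) s$species, "")),
      kinetics = stats::setNames(
        vapply(cfg$sinks, function(s) s$kinetics, ""),
        vapply(cfg$sinks, function(s) s$species, "")),
      lumped_into_pga = cfg$lumpedIntoPga),
    parameter_provenance = "non-archival fixture defaults"))
  m <- cbcModel(species, rx, ps, lineage = lineage,
                metadata = list(variant = variant, tk_form = tkForm))
  diags <- validateModel(m)
  if (any(diags$severity == "error"))
    stop("variant ", variant, " failed validation: ",
         paste(diags$message, collapse = "; "), call. = FALSE)
  m
}

# mass-action variant with dynamic adenylates and external phosphate
# (the behavior class of the earliest Calvin-cycle models)
.buildHahn <- function(params = NULL, sinkCfg = NULL) {
  species <- rbind(
    speciesSpec("RuBP", 0.30, carbons = 5, phosphates = 2),
    speciesSpec("PGA", 2.00, carbons = 3, phosphates = 1),
    speciesSpec("GAP", 0.30, carbons = 3, phosphates = 1),
    speciesSpec("Ru5P", 0.05, carbons = 5, phosphates = 1),
    speciesSpec("ATP", 0.40, carbons = 0, phosphates = 3),
    speciesSpec("ADP", 0.40, carbons = 0, phosphates = 2),
    speciesSpec("Pi", 1.00, carbons = 0, phosphates = 1),
    speciesSpec("Pi_ext", 1.00, carbons = 0, phosphates = 1),
    speciesSpec("Sink_PGA", 0.00, carbons = 3, phosphates = 1,
                clamped = TRUE),
    speciesSpec("CO2", 0.20, carbons = 1, phosphates = 0, clamped = TRUE))
  ps <- parameterSet(
    c(k1 = 1.0, k_red = 1.2, k_regen = 1.2, k_prk = 2.0, k_atpsyn = 3.0,
      k_sr_PGA = 0.15, k_piimp = 0.5, adenylate_total = 0.8),
    units = c(k1 = "mM^-1 s^-1", k_red = "mM^-1 s^-1", k_regen = "s^-1",
              k_prk = "mM^-1 s^-1", k_atpsyn = "mM^-1 s^-1",
              k_sr_PGA = "s^-1", k_piimp = "s^-1",
              adenylate_total = "mM"))
  if (!is.null(params))
    ps <- updateParameters(ps, params@values,
                           params@units[names(params@values)])
  rx <- list(
    # RuBP + CO2 -> 2 PGA (k1: the carboxylation rate constant)
    reaction("CC1_carb", c(RuBP = -1, CO2 = -1, PGA = 2),
             massActionLaw("k1", c(RuBP = 1, CO2 = 1))),
    # PGA + ATP -> GAP + ADP + (phosphate retained on GAP)
    reaction("red", c(PGA = -1, ATP = -1, GAP = 1, ADP = 1, Pi = 1),
             massActionLaw("k_red", c(PGA = 1, ATP = 1))),
    # 5 GAP -> 3 Ru5P, phosphate surplus released
    reaction("regen", c(GAP = -1, Ru5P = 0.6, Pi = 0.4),
             massActionLaw("k_regen", c(GAP = 1))),
    reaction("prk", c(Ru5P = -1, ATP = -1, RuBP = 1, ADP = 1),
             massActionLaw("k_prk", c(Ru5P = 1, ATP = 1))),
    reaction("atpsyn", c(ADP = -1, Pi = -1, ATP = 1),
             massActionLaw("k_atpsyn", c(ADP = 1, Pi = 1))),
    # PGA export sequesters its phosphate in the sink pool; the stroma is
    # resupplied from the finite external pool, whose exhaustion suspends
    # the cycle unless Pi_ext is clamped
    reaction("SR_PGA", c(PGA = -1, Sink_PGA = 1),
             massActionLaw("k_sr_PGA", c(PGA = 1))),
    reaction("pi_import", c(Pi_ext = -1, Pi = 1),
             massActionLaw("k_piimp", c(Pi_ext = 1))))
  cbcModel(species, rx, ps,
           lineage = list(list(base = "hahn", patches = list(),
                               parameter_provenance =
                                 "non-archival fixture defaults")),
           metadata = list(variant = "hahn"))
}
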