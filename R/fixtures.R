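#' @include model.R
NULL

# Synthetic fixtures: small networks with known analytic behavior, so every
# operation and analysis runs with no downloads. Fixtures claim known
# answers, not biological realism.

#' Linear chain fixture
#'
#' `source -> X1 -> ... -> Xn -> sink`, all mass action, constant input flux
#' `J` (a clamped source species at concentration 1 with rate constant `J`).
#' Analytic steady state: `x_i* = J / k_i`.
#'
#' @param n Number of chain species (>= 1).
#' @param inputFlux Input flux J (mM s^-1).
#' @param rateConstants Numeric vector of consumption constants `k_i`
#'   (length `n`); when `NULL`, drawn uniformly from `[0.5, 2]` under `seed`.
#' @param seed Integer seed for the random draw.
#' @return A [CbcModel-class] with metadata `analytic_steady_state`.
#' @export
linearChainFixture <- function(n, inputFlux = 1, rateConstants = NULL,
                               seed = 1L) {
  stopifnot(n >= 1L, inputFlux > 0)
  if (is.null(rateConstants)) {
    set.seed(seed)
    rateConstants <- stats::runif(n, 0.5, 2)
  }
  stopifnot(length(rateConstants) == n, all(rateConstants > 0))
  ids <- paste0("X", seq_len(n))
  species <- rbind(
    speciesSpec("Src", initial = 1, carbons = 1, phosphates = 0,
                clamped = TRUE),
    do.call(rbind, lapply(ids, speciesSpec, initial = 0, carbons = 1,
                          phosphates = 0)),
    speciesSpec("Out", initial = 0, carbons = 1, phosphates = 0,
                clamped = TRUE))
  kNames <- paste0("k", seq_len(n))
  params <- parameterSet(
    stats::setNames(c(inputFlux, rateConstants), c("J", kNames)),
    units = stats::setNames(c("mM s^-1", rep("s^-1", n)),
                            c("J", kNames)))
  rx <- vector("list", n + 1L)
  rx[[1L]] <- reaction("input", c(Src = -1, X1 = 1),
                       massActionLaw("J", c(Src = 1)))
  for (i in seq_len(n)) {
    prod <- if (i < n) ids[i + 1L] else "Out"
    st <- stats::setNames(c(-1, 1), c(ids[i], prod))
    rx[[i + 1L]] <- reaction(paste0("step", i), st,
                             massActionLaw(kNames[i],
                                           stats::setNames(1, ids[i])))
  }
  m <- cbcModel(species, rx, params,
                lineage = list(list(base = "linear_chain",
                                    patches = list())),
                metadata = list(fixture = "linear_chain", seed = seed))
  m@metadata$analytic_steady_state <-
    stats::setNames(inputFlux / rateConstants, ids)
  m
}

#' Toy autocatalytic cycle fixture
#'
#' A miniature Calvin-cycle analogue: a carboxylation-like input consuming an
#' acceptor `A` that is regenerated from the product pool, an ATP-coupled
#' reduction with finite closed adenylate and phosphate pools, and a PGA-like
#' sink that exports carbon but retains phosphate:
#'
#' * `carb`: `A + C -> 2 P` (C is a clamped 1-carbon input)
#' * `red`: `P + ATP -> T + ADP`
#' * `regen`: `T -> 0.6 A + 0.8 Pi` (fractional stoichiometry, carbon-exact)
#' * `atpsyn`: `ADP + Pi -> ATP`
#' * `sink`: `P -> Sink_P + Pi` (the sink pool carries no phosphate)
#'
#' Carbon and phosphate are exactly conserved (S accumulates carbon; C is
#' clamped). A steady state exists for the default parameters; reducing the
#' free-phosphate pool forces the cycle-suspension (phosphate-exhaustion)
#' behavior class, and removing the sink forces unbounded accumulation of P.
#'
#' @param seed Integer seed (parameters are deterministic; the seed only
#'   perturbs initial concentrations by up to 1 % to vary test states).
#' @param phosphateScale Multiplier on the initial free-phosphate pool.
#' @param withSink Logical; `FALSE` removes the sink reaction.
#' @param clampPhosphate Logical; hold free phosphate constant (an external
#'   phosphate supply). With the sink removed this forces the unbounded
#'   accumulation of the PGA-like species.
#' @param clampSinkPool Logical; hold the sink pool `Sink_P` constant (the
#'   boundary-species convention of the published models).
#' @param closedSystem Logical; unclamp everything (including the carbon
#'   input), giving a fully closed system in which total carbon and
#'   phosphate are exactly conserved along trajectories.
#' @return A [CbcModel-class].
#' @export
toyCycleFixture <- function(seed = 1L, phosphateScale = 1,
                            withSink = TRUE, clampPhosphate = FALSE,
                            clampSinkPool = TRUE, closedSystem = FALSE) {
  if (closedSystem) {
    clampPhosphate <- FALSE
    clampSinkPool <- FALSE
  }
  set.seed(seed)
  jitter <- stats::runif(6, 0.99, 1.01)
  species <- rbind(
    speciesSpec("A", initial = 1.0 * jitter[1], carbons = 5, phosphates = 2),
    speciesSpec("P", initial = 1.0 * jitter[2], carbons = 3, phosphates = 1),
    speciesSpec("T", initial = 0.8 * jitter[3], carbons = 3, phosphates = 2),
    speciesSpec("ATP", initial = 0.5 * jitter[4], carbons = 0,
                phosphates = 3),
    speciesSpec("ADP", initial = 0.5 * jitter[5], carbons = 0,
                phosphates = 2),
    speciesSpec("Pi", initial = 1.0 * phosphateScale * jitter[6],
                carbons = 0, phosphates = 1, clamped = clampPhosphate),
    speciesSpec("Sink_P", initial = 0, carbons = 3, phosphates = 0,
                clamped = clampSinkPool),
    speciesSpec("C", initial = 1, carbons = 1, phosphates = 0,
                clamped = !closedSystem))
  params <- parameterSet(
    c(k_carb = 0.6, k_red = 1, k_regen = 1, k_atpsyn = 2, k_sink = 0.1),
    units = c(k_carb = "mM^-1 s^-1", k_red = "mM^-1 s^-1",
              k_regen = "s^-1", k_atpsyn = "mM^-1 s^-1", k_sink = "s^-1"))
  rx <- list(
    reaction("carb", c(A = -1, C = -1, P = 2),
             massActionLaw("k_carb", c(A = 1, C = 1))),
    reaction("red", c(P = -1, ATP = -1, T = 1, ADP = 1),
             massActionLaw("k_red", c(P = 1, ATP = 1))),
    reaction("regen", c(T = -1, A = 0.6, Pi = 0.8),
             massActionLaw("k_regen", c(T = 1))),
    reaction("atpsyn", c(ADP = -1, Pi = -1, ATP = 1),
             massActionLaw("k_atpsyn", c(ADP = 1, Pi = 1))))
  if (withSink)
    rx <- c(rx, list(reaction("sink", c(P = -1, Sink_P = 1, Pi = 1),
                              massActionLaw("k_sink", c(P = 1)))))
  cbcModel(species, rx, params,
           lineage = list(list(base = "toy_cycle", patches = list())),
           metadata = list(fixture = "toy_cycle", seed = seed))
}

#' Miniature Calvin fixture with a starch branch
#'
#' The [toyCycleFixture()] network extended by a starch branch:
#' `store`: `T <-> G` (reversible, so liberated starch carbon re-enters the
#' cycle), `stsyn`: `G + ATP -> St + ADP + 3 Pi`, and starch
#' degradation `stdeg`: `St + 2 Pi -> G` governed by the starch-phosphorylase
#' law. With `starchVariant = "original"` the degradation rate carries free
#' phosphate in the substrate position, so it stays positive at zero starch
#' and (in diagnostic-reproduction mode) drives starch to negative
#' concentrations - the documented defect class. The `corrected` variant
#' carries starch itself and vanishes at zero starch.
#'
#' @inheritParams toyCycleFixture
#' @param starchVariant `"corrected"` or `"original"`.
#' @param diagnostic Logical: flag the model as a diagnostic reproduction
#'   (negative concentrations representable, no clipping).
#' @return A [CbcModel-class].
#' @export
calvinMiniFixture <- function(seed = 1L, starchVariant = c("corrected",
                                                           "original"),
                              diagnostic = FALSE, phosphateScale = 1,
                              withSink = TRUE, clampPhosphate = FALSE) {
  starchVariant <- match.arg(starchVariant)
  m <- toyCycleFixture(seed = seed, phosphateScale = phosphateScale,
                       withSink = withSink,
                       clampPhosphate = clampPhosphate)
  species <- rbind(
    m@species,
    speciesSpec("G", initial = 0.2, carbons = 3, phosphates = 2),
    speciesSpec("St", initial = 0.2, carbons = 3, phosphates = 0))
  params <- updateParameters(m@parameters,
    c(k_store = 0.05, keq_store = 2, k_stsyn = 0.5,
      StPase_VM = 0.3, StPase_km = 0.4, StPase_kiG1P = 1),
    units2 = c(k_store = "s^-1", k_stsyn = "mM^-1 s^-1",
               StPase_VM = "mM s^-1", StPase_km = "mM",
               StPase_kiG1P = "mM"))
  rx <- c(m@reactions, list(
    reaction("store", c(T = -1, G = 1),
             massActionLaw("k_store", c(T = 1), products = c(G = 1),
                           keq = "keq_store"), reversible = TRUE),
    reaction("stsyn", c(G = -1, ATP = -1, St = 1, ADP = 1, Pi = 3),
             massActionLaw("k_stsyn", c(G = 1, ATP = 1))),
    reaction("stdeg", c(St = -1, Pi = -2, G = 1),
             starchPhosphorylaseLaw(starch = "St", phosphate = "Pi",
                                    g1p = "G", variant = starchVariant),
             modifiers = c("Pi", "G"))))
  cbcModel(species, rx, params,
           lineage = list(list(base = "calvin_mini",
                               patches = list(list(name = "starch_variant",
                                                   arguments = list(
                                                     variant = starchVariant),
                                                   note = "fixture option")))),
           metadata = list(fixture = "calvin_mini", seed = seed,
                           diagnostic_reproduction = diagnostic))
}

#' Physiological reference ranges from the Calvin-cycle literature
#'
#' Named ranges used by [validateModel()] warnings and the energy-charge
#' scan's plausibility flags: the reported steady-state PGA range, the
#' literature transketolase equilibrium-constant values, the transaldolase-
#' vs-transketolase Michaelis constant values for the second transketolase
#' reaction, and the proposed/measured transketolase maximal rates.
#'
#' @return `data.frame` with columns `name`, `low`, `high`, `unit`, `note`.
#' @export
physiologicalParameterTable <- function() {
  data.frame(
    name = c("PGA_steady_state", "kE7_literature", "kM103_values",
             "kM103_stability_bound", "transketolase_vmax"),
    low = c(2.15, 0.076, 0.015, 0.06, 0.1),
    high = c(11.7, 0.1, 0.46, NA, 0.36),
    unit = c("mM", "1", "mM", "mM", "mmol s^-1"),
    note = c("reported steady-state concentration range",
             "literature equilibrium-constant values (low/high)",
             "original Laisk value (low) vs transaldolase-derived (high)",
             "appendix-form transketolase unstable below this value",
             "proposed (low) and measured (high) maximal rates"),
    stringsAsFactors = FALSE)
}
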