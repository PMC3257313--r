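#' @include simulate.R fixtures.R
NULL

# The four diagnostic analyses: stability test (knockout from steady state),
# energy-charge scan, sink-output analysis (boundary pools switched to
# variable), sink-implementation comparison table, and the paired-model
# ratio series. All are deterministic pipelines regenerable from their
# recorded inputs.

#' A diagnostic analysis report
#'
#' @slot kind One of `stability`, `energy_scan`, `sink_output`,
#'   `sink_table`, `ratio_series`.
#' @slot inputs List recording model lineage, clamps and horizon.
#' @slot results Kind-specific tables/series.
#' @slot normalization Reference cell/series metadata when normalized.
#' @export
setClass("AnalysisReport",
  representation(kind = "character", inputs = "list", results = "list",
                 normalization = "list"))

#' @export
setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport <", object@kind, ">\n", sep = "")
  nm <- names(object@results)
  for (n in nm) {
    x <- object@results[[n]]
    if (is.data.frame(x))
      cat("  $", n, ": data.frame ", nrow(x), " x ", ncol(x), "\n",
          sep = "")
    else if (is.numeric(x) && length(x) <= 6)
      cat("  $", n, ": ", paste(signif(x, 5), collapse = ", "), "\n",
          sep = "")
    else cat("  $", n, ": ", class(x)[1L], "\n", sep = "")
  }
})

.report <- function(kind, inputs, results, normalization = list())
  methods::new("AnalysisReport", kind = kind, inputs = inputs,
               results = results, normalization = normalization)

# carbon-weighted (or molar) totals over species groups
.carbonOf <- function(model, state, ids, molar = FALSE) {
  cc <- stats::setNames(model@species$carbons, model@species$id)
  ids <- ids[ids %in% names(state)]
  if (!length(ids)) return(0)
  w <- if (molar) rep(1, length(ids)) else cc[ids]
  sum(state[ids] * w)
}

.sinkPoolIds <- function(model)
  grep("^Sink_", speciesIds(model), value = TRUE)

.starchIds <- function(model)
  intersect(c("starch", "St"), speciesIds(model))

#' Cycle-intermediate species of a model
#'
#' The Calvin-Benson pool: species carrying carbon that are neither clamped
#' boundary inputs, sink pools, starch, nor adenylates/cofactors.
#' @param model A [CbcModel-class].
#' @return Character vector of species ids.
#' @export
cyclePoolIds <- function(model) {
  sp <- model@species
  excl <- c(.sinkPoolIds(model), .starchIds(model),
            c("ATP", "ADP", "NADPH", "NADP", "Pi", "Pi_ext", "CO2", "O2"))
  sp$id[!sp$id %in% excl & !is.na(sp$carbons) & sp$carbons > 0 &
          !sp$clamped]
}

# unclamp a set of species (the "fixed -> variable concentration" switch)
.unclamp <- function(model, ids) {
  model@species$clamped[model@species$id %in% ids] <- FALSE
  model
}

#' Stability test: knock a species out of a steady state
#'
#' All state variables are set to their steady-state values except the
#' knockout species (by default RuBP), which is set to zero; the system is
#' then simulated for `duration` seconds (the classic test ran 80 s; the
#' extended protocol 80 minutes). The report carries the trajectory, a
#' suspension flag (RuBP-synthesis flux below 1 % of its steady value at the
#' end), and - when adenylates are dynamic - the ATP-collapse time (first
#' time the energy charge drops below 1 %).
#'
#' @param model A [CbcModel-class].
#' @param knockout Species id set to zero (default `"RuBP"`).
#' @param duration Simulated seconds (default 4800 = 80 min).
#' @param clamps Optional [clampSpec()] (e.g. fixing external phosphate,
#'   which prevents the suspension).
#' @param steady Optional precomputed [SteadyState-class]; computed if
#'   missing.
#' @param referenceFlux Reaction id measuring RuBP synthesis; default the
#'   first of `CC13_prk`/`prk` present.
#' @return An [AnalysisReport-class] of kind `stability`.
#' @export
stabilityTest <- function(model, knockout = "RuBP", duration = 4800,
                          clamps = NULL, steady = NULL,
                          referenceFlux = NULL) {
  stopifnot(knockout %in% speciesIds(model))
  if (is.null(steady)) steady <- findSteadyState(model, clamps)
  if (!steady@converged)
    stop("no steady state available for the stability test", call. = FALSE)
  if (is.null(referenceFlux))
    referenceFlux <- intersect(c("CC13_prk", "prk"),
                               reactionIds(model))[1L]
  if (is.na(referenceFlux))
    stop("no RuBP-synthesis reaction found; pass referenceFlux",
         call. = FALSE)
  st0 <- steady@state
  st0[[knockout]] <- 0
  m <- setInitial(model, st0)
  traj <- integrateModel(m, clamps, tEnd = duration,
                         times = c(0, seq(duration / 400, duration,
                                          length.out = 400)))
  endFlux <- traj@flux[nrow(traj@flux), referenceFlux]
  refFlux <- steady@fluxes[[referenceFlux]]
  suspended <- is.finite(refFlux) && refFlux > 0 &&
    endFlux < 0.01 * refFlux
  atpCollapse <- NA_real_
  dynAden <- all(c("ATP", "ADP") %in% colnames(traj@conc)) &&
    !all(c("ATP", "ADP") %in% traj@clamped)
  if (dynAden) {
    ec <- traj@conc[, "ATP"] /
      pmax(traj@conc[, "ATP"] + traj@conc[, "ADP"], 1e-12)
    hit <- which(ec < 0.01)
    if (length(hit)) atpCollapse <- traj@time[hit[1L]]
  }
  .report("stability",
          inputs = list(lineage = .lineageString(model),
                        knockout = knockout, duration = duration,
                        clamps = clamps,
                        thresholds = list(suspension = 0.01,
                                          atp_collapse = 0.01)),
          results = list(trajectory = traj, suspended = suspended,
                         atp_collapse_time = atpCollapse,
                         reference_flux = referenceFlux,
                         steady_reference_value = refFlux,
                         end_flux = endFlux))
}

#' Energy-charge scan
#'
#' For each value of the energy charge `ATP (ADP + ATP)^-1`, ATP and ADP are
#' clamped at `ec * total` and `(1 - ec) * total` and the steady state is
#' computed; non-convergence or divergence at a grid point is flagged and the
#' scan continues. Steady PGA values outside the reported physiological range
#' (2.15 - 11.7 mM) are flagged.
#'
#' @param model A [CbcModel-class] with ATP and ADP species.
#' @param ecValues Numeric vector of energy-charge fractions.
#' @param observables Species ids to report (default PGA, F6P, S7P when
#'   present).
#' @param adenylateTotal Total adenylate pool (mM); default the model's
#'   `adenylate_total` parameter, falling back to initial ATP + ADP.
#' @return An [AnalysisReport-class] of kind `energy_scan` whose
#'   `results$table` has one row per (ec, observable).
#' @export
energyChargeScan <- function(model, ecValues,
                             observables = NULL,
                             adenylateTotal = NULL) {
  stopifnot(all(c("ATP", "ADP") %in% speciesIds(model)))
  if (is.null(observables))
    observables <- intersect(c("PGA", "F6P", "S7P"), speciesIds(model))
  if (is.null(adenylateTotal)) {
    adenylateTotal <- paramValue(model@parameters, "adenylate_total",
                                 default = NA_real_)
    if (is.na(adenylateTotal)) {
      ini <- stats::setNames(model@species$initial, model@species$id)
      adenylateTotal <- ini[["ATP"]] + ini[["ADP"]]
    }
  }
  pga <- physiologicalParameterTable()
  pgaRange <- unlist(pga[pga$name == "PGA_steady_state", c("low", "high")])
  rows <- lapply(ecValues, function(ec) {
    cl <- clampSpec(energyCharge = ec, adenylateTotal = adenylateTotal)
    ss <- tryCatch(findSteadyState(model, cl),
                   error = function(e) e)
    if (inherits(ss, "error")) {
      data.frame(ec = ec, observable = observables, value = NA_real_,
                 converged = FALSE,
                 flag = paste("divergent:", conditionMessage(ss)),
                 stringsAsFactors = FALSE)
    } else {
      vals <- ss@state[observables]
      flag <- rep(if (ss@converged) "" else
                    "no steady state within cap", length(observables))
      if ("PGA" %in% observables) {
        v <- vals[["PGA"]]
        if (is.finite(v) && (v < pgaRange[1L] || v > pgaRange[2L]))
          flag[observables == "PGA"] <- paste(
            c(flag[observables == "PGA"][nzchar(flag[observables == "PGA"])],
              "outside physiological PGA range"), collapse = "; ")
      }
      data.frame(ec = ec, observable = observables, value = unname(vals),
                 converged = ss@converged, flag = flag,
                 stringsAsFactors = FALSE)
    }
  })
  .report("energy_scan",
          inputs = list(lineage = .lineageString(model),
                        ec_values = ecValues,
                        adenylate_total = adenylateTotal,
                        pga_range = pgaRange),
          results = list(table = do.call(rbind, rows)))
}

#' Sink-output analysis
#'
#' Switches the sink pools and starch from fixed (constant) to variable
#' concentration and simulates over a short horizon, reporting the
#' fold-multiplication of the accumulated sink pool relative to the initial
#' cycle metabolite pool, the starch excursion (min/max, same fold units),
#' and the mass-production rate (carbon exported per second, averaged over
#' the horizon).
#'
#' @param model A [CbcModel-class].
#' @param horizon Simulated seconds (default 10).
#' @param pool Species ids defining the initial metabolite pool; default
#'   [cyclePoolIds()].
#' @param molar Use molar instead of carbon-weighted sums.
#' @return An [AnalysisReport-class] of kind `sink_output`.
#' @export
sinkOutputAnalysis <- function(model, horizon = 10, pool = NULL,
                               molar = FALSE) {
  if (is.null(pool)) pool <- cyclePoolIds(model)
  sinks <- .sinkPoolIds(model)
  starch <- .starchIds(model)
  m <- .unclamp(model, c(sinks, starch))
  traj <- integrateModel(m, tEnd = horizon,
                         times = c(0, seq(horizon / 200, horizon,
                                          length.out = 200)))
  s0 <- traj@conc[1L, ]
  sT <- traj@conc[nrow(traj@conc), ]
  pool0 <- .carbonOf(m, s0, pool, molar)
  sinkAcc <- .carbonOf(m, sT, sinks, molar) - .carbonOf(m, s0, sinks, molar)
  starchSeries <- if (length(starch))
    rowSums(traj@conc[, starch, drop = FALSE] *
              rep(if (molar) 1 else m@species$carbons[
                match(starch, m@species$id)], each = nrow(traj@conc)))
  else rep(0, nrow(traj@conc))
  # mass production: the rate of sink accumulation (starch is reported
  # separately; a spuriously negative starch flux inflates this rate)
  massProd <- sinkAcc / horizon
  .report("sink_output",
          inputs = list(lineage = .lineageString(model), horizon = horizon,
                        pool = pool, molar = molar),
          results = list(
            trajectory = traj,
            initial_pool = pool0,
            sink_fold = 1 + sinkAcc / pool0,
            starch_fold_min = min(starchSeries) / pool0,
            starch_fold_max = max(starchSeries) / pool0,
            mass_production_rate = massProd))
}

#' Sink-implementation comparison table
#'
#' Builds the two transketolase encodings x three PGA-sink kinetics
#' (mass action, translocator-regulated MM, simplest MM) and accumulates the
#' key products over `horizon` seconds from the steady state of each
#' configuration: PGA sink, starch, Calvin-Benson pool and total mass
#' (carbon-weighted by default), each normalized so the reference cell
#' (`zhu_S` + `MM` by convention) equals 100.
#'
#' @param variants Character vector of the two model variants.
#' @param kinetics Character vector of sink kinetics families.
#' @param horizon Simulated seconds (default 10800 = 3 h).
#' @param reference `c(variant, kinetics)` of the reference cell.
#' @param molar Use molar sums instead of carbon-weighted.
#' @param params Optional [ParameterSet-class] overrides for every build.
#' @return An [AnalysisReport-class] of kind `sink_table`; `results$table`
#'   holds the normalized values, `results$raw` the raw ones. Non-convergent
#'   configurations are reported as missing (NA) cells.
#' @export
sinkComparisonTable <- function(variants = c("zhu_A", "zhu_S"),
                                kinetics = c("MA", "MM", "MMcb"),
                                horizon = 10800,
                                reference = c("zhu_S", "MM"),
                                molar = FALSE, params = NULL) {
  cfg <- expand.grid(variant = variants, kinetics = kinetics,
                     stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cfg)), function(i) {
    v <- cfg$variant[i]
    kin <- cfg$kinetics[i]
    m <- buildModel(v, params = params)
    m <- configureSink(m, "PGA", kinetics = kin)
    ss <- tryCatch(findSteadyState(m), error = function(e) e)
    if (inherits(ss, "error") || !ss@converged)
      return(data.frame(variant = v, kinetics = kin, pga_sink = NA_real_,
                        starch = NA_real_, cb_pool = NA_real_,
                        total_mass = NA_real_, stringsAsFactors = FALSE))
    m2 <- .unclamp(setInitial(m, ss@state),
                   c(.sinkPoolIds(m), .starchIds(m)))
    traj <- integrateModel(m2, tEnd = horizon,
                           times = c(0, horizon / 2, horizon))
    sT <- traj@conc[nrow(traj@conc), ]
    s0 <- traj@conc[1L, ]
    pga <- .carbonOf(m2, sT, "Sink_PGA", molar) -
      .carbonOf(m2, s0, "Sink_PGA", molar)
    starch <- .carbonOf(m2, sT, .starchIds(m2), molar) -
      .carbonOf(m2, s0, .starchIds(m2), molar)
    cb <- .carbonOf(m2, sT, cyclePoolIds(m2), molar)
    other <- setdiff(.sinkPoolIds(m2), "Sink_PGA")
    total <- pga + starch +
      (.carbonOf(m2, sT, other, molar) - .carbonOf(m2, s0, other, molar))
    data.frame(variant = v, kinetics = kin, pga_sink = pga,
               starch = starch, cb_pool = cb, total_mass = total,
               stringsAsFactors = FALSE)
  })
  raw <- do.call(rbind, rows)
  ref <- raw[raw$variant == reference[1L] & raw$kinetics == reference[2L], ]
  if (nrow(ref) != 1L || anyNA(ref[, -(1:2)]))
    stop("reference configuration missing or non-convergent", call. = FALSE)
  norm <- raw
  for (col in c("pga_sink", "starch", "cb_pool", "total_mass"))
    norm[[col]] <- 100 * raw[[col]] / ref[[col]]
  .report("sink_table",
          inputs = list(variants = variants, kinetics = kinetics,
                        horizon = horizon, molar = molar),
          results = list(table = norm, raw = raw),
          normalization = list(reference = reference, value = 100))
}

#' Paired-model ratio series
#'
#' Simulates two flux-matched model variants from the same initial
#' concentrations on a shared time grid and reports the ratio x/y for each
#' observable (`total_mass`, `sink_sum`, or species ids). Ratios are guarded
#' by a 1e-12 mM floor; floored points are flagged. Transient excursions in
#' a ratio can appear even when the separate series are featureless - the
#' motivation for running paired variants at matched reference flux.
#'
#' @param modelX,modelY [CbcModel-class] objects (flux-matched via
#'   [matchFlux()]).
#' @param observables Character vector: `"total_mass"`, `"sink_sum"` and/or
#'   species ids.
#' @param grid Time grid (s).
#' @param initial Optional named initial concentrations imposed on both
#'   models (defaults to `modelX`'s initials for the shared species).
#' @return An [AnalysisReport-class] of kind `ratio_series`.
#' @export
pairedModelRatio <- function(modelX, modelY,
                             observables = c("total_mass", "sink_sum"),
                             grid = c(0, 10^seq(-1, 4, length.out = 200)),
                             initial = NULL) {
  shared <- intersect(speciesIds(modelX), speciesIds(modelY))
  if (is.null(initial)) {
    ini <- stats::setNames(modelX@species$initial, modelX@species$id)
    initial <- ini[shared]
  }
  mX <- .unclamp(setInitial(modelX, initial[intersect(names(initial),
                                                      speciesIds(modelX))]),
                 c(.sinkPoolIds(modelX), .starchIds(modelX)))
  mY <- .unclamp(setInitial(modelY, initial[intersect(names(initial),
                                                      speciesIds(modelY))]),
                 c(.sinkPoolIds(modelY), .starchIds(modelY)))
  tX <- integrateModel(mX, tEnd = max(grid), times = grid)
  tY <- integrateModel(mY, tEnd = max(grid), times = grid)
  obsSeries <- function(m, traj, obs) {
    switch(obs,
      total_mass = vapply(seq_along(traj@time), function(i)
        .carbonOf(m, traj@conc[i, ], c(.sinkPoolIds(m), .starchIds(m))),
        0),
      sink_sum = vapply(seq_along(traj@time), function(i)
        .carbonOf(m, traj@conc[i, ], .sinkPoolIds(m)), 0),
      traj@conc[, obs])
  }
  floor <- 1e-12
  series <- lapply(observables, function(obs) {
    x <- obsSeries(mX, tX, obs)
    y <- obsSeries(mY, tY, obs)
    flagged <- y < floor
    data.frame(time = tX@time, observable = obs,
               ratio = x / pmax(y, floor),
               floored = flagged, stringsAsFactors = FALSE)
  })
  .report("ratio_series",
          inputs = list(lineage_x = .lineageString(modelX),
                        lineage_y = .lineageString(modelY),
                        grid = grid, floor = floor),
          results = list(table = do.call(rbind, series)))
}

#' Write an analysis report as delimited text
#'
#' Serializes the report's tabular results with a structured-text metadata
#' header.
#'
#' @param report An [AnalysisReport-class].
#' @param path Output file path.
#' @export
writeReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", report@kind), con)
  writeLines(paste0("# inputs: ", .dep(report@inputs)), con)
  if (length(report@normalization))
    writeLines(paste0("# normalization: ", .dep(report@normalization)),
               con)
  tab <- report@results$table
  if (is.null(tab)) {
    scalars <- Filter(function(x) is.numeric(x) && length(x) == 1L,
                      report@results)
    tab <- data.frame(metric = names(scalars),
                      value = unlist(scalars, use.names = FALSE))
  }
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
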