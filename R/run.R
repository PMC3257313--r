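#' @include patches.R analyses.R sbml-io.R
NULL

# Reproducible runs: a resolved configuration plus an output directory
# containing the config, the model lineage and every output table, so a run
# can be repeated bit-identically (up to integrator floating point).

.runCommands <- c("simulate", "steady-state", "stability-test",
                  "energy-scan", "sink-output", "sink-table",
                  "ratio-series", "patch", "export-sbml", "fixtures")

#' Build a run configuration
#'
#' @param command One of `simulate`, `steady-state`, `stability-test`,
#'   `energy-scan`, `sink-output`, `sink-table`, `ratio-series`, `patch`,
#'   `export-sbml`, `fixtures`.
#' @param model Variant name (see [modelVariants()]) or fixture name
#'   (`linear_chain`, `toy_cycle`, `calvin_mini`).
#' @param sbml Path to an SBML file (used instead of `model` when given).
#' @param patches List of [patchDescriptor()]s (or `list(name=, arguments=)`
#'   lists) applied in order.
#' @param clamps A [clampSpec()] or `NULL`.
#' @param analysis Named list of analysis parameters (`t_end`, `horizon`,
#'   `ec_values`, `knockout`, `model2`, `delta_flux`, `observables`,
#'   `rtol`, `atol`, ...).
#' @param out Output directory (created; must not be an existing non-empty
#'   run directory).
#' @param seed Integer seed for every stochastic element (fixture draws).
#' @return A `RunConfig` list.
#' @export
runConfig <- function(command, model = NULL, sbml = NULL, patches = list(),
                      clamps = NULL, analysis = list(), out = tempfile(),
                      seed = 1L) {
  command <- match.arg(command, .runCommands)
  if (is.null(model) && is.null(sbml) && command != "fixtures")
    stop("config needs a model variant or an SBML path", call. = FALSE)
  structure(list(command = command, model = model, sbml = sbml,
                 patches = patches, clamps = clamps, analysis = analysis,
                 out = out, seed = as.integer(seed)),
            class = "RunConfig")
}

.resolveModel <- function(config) {
  seed <- config$seed
  if (!is.null(config$sbml)) return(readSBML(config$sbml)$model)
  v <- config$model
  m <- switch(v,
    linear_chain = linearChainFixture(
      n = config$analysis$n %||% 3L,
      inputFlux = config$analysis$input_flux %||% 1,
      seed = seed),
    toy_cycle = toyCycleFixture(seed = seed),
    calvin_mini = calvinMiniFixture(seed = seed),
    buildModel(v))
  for (p in config$patches) {
    if (!inherits(p, "PatchDescriptor"))
      p <- patchDescriptor(p$name, p$arguments %||% list(),
                           p$note %||% "")
    m <- applyPatch(m, p)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a configured run
#'
#' Executes the configured command, writing into the output directory the
#' fully resolved configuration (`config.yaml`), the model lineage
#' (`lineage.txt`) and the command's outputs (trajectory/steady-state/report
#' tables, exported SBML or fixture serialization).
#'
#' @param config A [runConfig()].
#' @return The output directory path, invisibly.
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  out <- config$out
  set.seed(config$seed)
  a <- config$analysis
  m <- if (config$command %in% c("sink-table", "fixtures")) NULL
       else .resolveModel(config)

  writeLines(yaml::as.yaml(list(
    command = config$command, model = config$model, sbml = config$sbml,
    patches = .dep(config$patches), clamps = .dep(config$clamps),
    analysis = .dep(a), seed = config$seed)),
    file.path(out, "config.yaml"))
  if (!is.null(m))
    writeLines(.lineageString(m), file.path(out, "lineage.txt"))

  switch(config$command,
    simulate = {
      traj <- integrateModel(m, config$clamps,
                             tEnd = a$t_end %||% 100,
                             rtol = a$rtol %||% 1e-8,
                             atol = a$atol %||% 1e-12)
      writeTrajectory(m, traj, file.path(out, "trajectory.tsv"))
      .plotSafely(file.path(out, "trajectory.png"), function() {
        matplot(traj@time, traj@conc, type = "l", lty = 1,
                xlab = "time (s)", ylab = "concentration (mM)")
      })
    },
    `steady-state` = {
      ss <- findSteadyState(m, config$clamps,
                            epsilon = a$epsilon %||% 1e-6)
      df <- data.frame(species = names(ss@state), value = ss@state)
      utils::write.table(df, file.path(out, "steady_state.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      fl <- data.frame(reaction = names(ss@fluxes), flux = ss@fluxes)
      utils::write.table(fl, file.path(out, "fluxes.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      writeLines(c(paste("converged:", ss@converged),
                   paste("time_to_steady_state_s:",
                         format(ss@timeToSteadyState))),
                 file.path(out, "convergence.txt"))
    },
    `stability-test` = {
      rep <- stabilityTest(m, knockout = a$knockout %||% "RuBP",
                           duration = a$duration %||% 4800,
                           clamps = config$clamps)
      writeTrajectory(m, rep@results$trajectory,
                      file.path(out, "trajectory.tsv"))
      writeLines(c(paste("suspended:", rep@results$suspended),
                   paste("atp_collapse_time_s:",
                         format(rep@results$atp_collapse_time))),
                 file.path(out, "stability.txt"))
    },
    `energy-scan` = {
      rep <- energyChargeScan(m, ecValues = a$ec_values %||%
                                seq(0.1, 0.9, by = 0.2),
                              observables = a$observables)
      writeReport(rep, file.path(out, "energy_scan.tsv"))
      .plotSafely(file.path(out, "energy_scan.png"), function() {
        tab <- rep@results$table
        plot(tab$ec, tab$value, col = factor(tab$observable), pch = 19,
             xlab = "energy charge ATP/(ADP+ATP)",
             ylab = "steady concentration (mM)", log = "y")
        legend("topright", legend = levels(factor(tab$observable)),
               col = seq_along(levels(factor(tab$observable))), pch = 19)
      })
    },
    `sink-output` = {
      rep <- sinkOutputAnalysis(m, horizon = a$horizon %||% 10)
      writeReport(rep, file.path(out, "sink_output.tsv"))
    },
    `sink-table` = {
      rep <- sinkComparisonTable(horizon = a$horizon %||% 10800)
      writeReport(rep, file.path(out, "sink_table.tsv"))
      utils::write.table(rep@results$raw, file.path(out, "sink_table_raw.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    },
    `ratio-series` = {
      m2cfg <- config
      m2cfg$model <- a$model2
      m2cfg$patches <- a$patches2 %||% list()
      m2 <- .resolveModel(m2cfg)
      ref <- a$reference_flux %||% "CC13_prk"
      m2 <- matchFlux(m, m2, ref,
                      knobParameters = a$knobs %||% "V_CC1",
                      deltaFlux = a$delta_flux %||% 5e-6)
      rep <- pairedModelRatio(m, m2,
                              observables = a$observables %||%
                                c("total_mass", "sink_sum"))
      writeReport(rep, file.path(out, "ratio_series.tsv"))
      .plotSafely(file.path(out, "ratio_series.png"), function() {
        tab <- rep@results$table
        plot(tab$time, tab$ratio, col = factor(tab$observable), pch = 20,
             xlab = "time (s)", ylab = "ratio x/y")
        abline(h = 1, lty = 2)
      })
    },
    patch = {
      writeModelText(m, file.path(out, "model.yaml"))
    },
    `export-sbml` = {
      writeSBML(m, file.path(out, "model.xml"))
    },
    fixtures = {
      fx <- list(linear_chain = linearChainFixture(3, seed = config$seed),
                 toy_cycle = toyCycleFixture(seed = config$seed),
                 calvin_mini = calvinMiniFixture(seed = config$seed))
      for (nm in names(fx)) {
        writeModelText(fx[[nm]], file.path(out, paste0(nm, ".yaml")))
        writeSBML(fx[[nm]], file.path(out, paste0(nm, ".xml")))
      }
    })
  invisible(out)
}


# best-effort figure rendering; headless systems without a png device just
# skip the plot, never the run
.plotSafely <- function(path, drawFn) {
  tryCatch({
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    drawFn()
  }, error = function(e) invisible(NULL))
  invisible(NULL)
}
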