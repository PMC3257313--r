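test_that("stability test reproduces the depletion behavior class", {
  h <- buildModel("hahn")
  clamped <- clampSpec(fixed = "Pi_ext")
  steady <- findSteadyState(h, clamped)
  expect_true(steady@converged)

  # finite external phosphate: the pool depletes, ATP collapses, the
  # cycle suspends
  rep1 <- stabilityTest(h, knockout = "RuBP", duration = 4800,
                        steady = steady)
  expect_true(rep1@results$suspended)
  expect_true(is.finite(rep1@results$atp_collapse_time))
  expect_lt(rep1@results$atp_collapse_time, 1000)

  # fixing the external phosphate concentration prevents the suspension
  rep2 <- stabilityTest(h, knockout = "RuBP", duration = 4800,
                        clamps = clamped, steady = steady)
  expect_false(rep2@results$suspended)
})

test_that("knockout of an already-zero species equals a plain simulation", {
  m <- linearChainFixture(2, inputFlux = 1, rateConstants = c(1, 2))
  # append an isolated species with no production: steady state zero
  sp <- rbind(speciesTable(m),
              speciesSpec("Z", 0, carbons = 1, phosphates = 0))
  m2 <- cbcModel(sp, c(reactionList(m), list(
    reaction("zdecay", c(Z = -1),
             massActionLaw(1, c(Z = 1)))))
    , modelParameters(m), lineage = modelLineage(m))
  ss <- findSteadyState(m2)
  rep <- stabilityTest(m2, knockout = "Z", duration = 10,
                       steady = ss, referenceFlux = "step2")
  tr <- rep@results$trajectory
  plain <- integrateModel(CalvinSim:::setInitial(m2, ss@state), tEnd = 10,
                          times = tr@time)
  expect_equal(tr@conc, plain@conc, tolerance = 1e-8)
  expect_false(rep@results$suspended)
})

test_that("energy-charge scan recovers the analytic 1/ec dependence", {
  # fixture: constant input to PGA, single ATP-dependent consumer; with a
  # clamped energy charge the steady state is J/(k ec T) proportional 1/ec
  species <- rbind(
    speciesSpec("Src", 1, carbons = 3, phosphates = 0, clamped = TRUE),
    speciesSpec("PGA", 0.5, carbons = 3, phosphates = 1),
    speciesSpec("ATP", 0.5, carbons = 0, phosphates = 3),
    speciesSpec("ADP", 0.5, carbons = 0, phosphates = 2),
    speciesSpec("Out", 0, carbons = 3, phosphates = 1, clamped = TRUE))
  m <- cbcModel(species, list(
    reaction("in", c(Src = -1, PGA = 1), massActionLaw("J", c(Src = 1))),
    reaction("use", c(PGA = -1, ATP = -1, Out = 1, ADP = 1),
             massActionLaw("k", c(PGA = 1, ATP = 1))),
    reaction("regen", c(ADP = -1, ATP = 1),
             massActionLaw("kr", c(ADP = 1)))),
    parameterSet(c(J = 0.2, k = 1, kr = 5, adenylate_total = 1)))
  ecs <- c(0.2, 0.4, 0.8)
  rep <- energyChargeScan(m, ecValues = ecs, observables = "PGA")
  tab <- rep@results$table
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$value, 0.2 / (1 * ecs * 1), tolerance = 1e-6)

  # ec = 0 switches the consumer off: the grid point is flagged divergent
  # and the scan continues
  rep0 <- energyChargeScan(m, ecValues = c(0, 0.5), observables = "PGA")
  t0 <- rep0@results$table
  expect_false(t0$converged[t0$ec == 0])
  expect_match(t0$flag[t0$ec == 0], "no steady state|divergent")
  expect_equal(t0$value[t0$ec == 0.5], 0.4, tolerance = 1e-6)

  # scan rows = values x observables, with physiological-range flags
  c2 <- buildModel("cyano_C2")
  repC <- energyChargeScan(c2, ecValues = c(0.5, 0.55),
                           observables = c("PGA", "F6P"))
  expect_identical(nrow(repC@results$table), 4L)
})

test_that("sink-output analysis measures pool multiplication and starch excursion", {
  # closed fixture: no sinks, no starch movement -> fold exactly 1
  closed <- toyCycleFixture(1, withSink = FALSE)
  repC <- sinkOutputAnalysis(closed, horizon = 5)
  expect_equal(repC@results$sink_fold, 1)

  # the defective starch law drives the starch excursion negative; with an
  # external phosphate supply (as in the published setting) the spurious
  # degradation also inflates the sink-accumulation rate
  mo <- calvinMiniFixture(1, starchVariant = "original", diagnostic = TRUE,
                          clampPhosphate = TRUE)
  repO <- sinkOutputAnalysis(mo, horizon = 100)
  expect_lt(repO@results$starch_fold_min, 0)
  repF <- sinkOutputAnalysis(
    calvinMiniFixture(1, starchVariant = "corrected",
                      clampPhosphate = TRUE), horizon = 100)
  expect_gte(repF@results$starch_fold_min, 0)
  expect_gt(repO@results$mass_production_rate,
            repF@results$mass_production_rate)
})

test_that("sink comparison table normalizes to its reference cell", {
  rep <- sinkComparisonTable(horizon = 300)
  tab <- rep@results$table
  raw <- rep@results$raw
  expect_identical(nrow(tab), 6L)
  ref <- tab[tab$variant == "zhu_S" & tab$kinetics == "MM", ]
  expect_equal(unlist(ref[, c("pga_sink", "starch", "cb_pool",
                              "total_mass")]),
               c(pga_sink = 100, starch = 100, cb_pool = 100,
                 total_mass = 100))
  # normalization is scale-free: the normalized cells are 100 * raw/ref
  refRaw <- raw[raw$variant == "zhu_S" & raw$kinetics == "MM", ]
  for (col in c("pga_sink", "starch", "cb_pool", "total_mass"))
    expect_equal(tab[[col]], 100 * raw[[col]] / refRaw[[col]])
})

test_that("paired-model ratios flag excursions invisible in the raw series", {
  # identical models: the ratio is identically 1
  c1 <- buildModel("cyano_C1")
  same <- pairedModelRatio(c1, c1, observables = "total_mass",
                           grid = c(0, 1, 5, 20))
  expect_equal(same@results$table$ratio[-1], rep(1, 3), tolerance = 1e-9)

  # two phase-shifted relaxations sharing start and end points: each raw
  # series is monotone, yet their ratio leaves 1 and returns - a transient
  # excursion visible only in the ratio
  mkRelax <- function(J, k) {
    sp <- rbind(speciesSpec("Src", 1, carbons = 1, phosphates = 0,
                            clamped = TRUE),
                speciesSpec("X", 2, carbons = 1, phosphates = 0),
                speciesSpec("Sink_X", 0, carbons = 1, phosphates = 0,
                            clamped = TRUE))
    cbcModel(sp, list(
      reaction("in", c(Src = -1, X = 1), massActionLaw("J", c(Src = 1))),
      reaction("decay", c(X = -1, Sink_X = 1),
               massActionLaw("k", c(X = 1)))),
      parameterSet(c(J = J, k = k)))
  }
  fast <- mkRelax(0.5, 1)       # x* = 0.5
  slow <- mkRelax(0.15, 0.3)    # same x* = 0.5, slower relaxation
  grid <- c(0, seq(0.5, 40, 0.5))
  pr <- pairedModelRatio(fast, slow, observables = "X", grid = grid)
  ratio <- pr@results$table$ratio
  xf <- integrateModel(fast, tEnd = 40, times = grid)@conc[, "X"]
  expect_true(all(diff(xf) <= 1e-10))          # raw series monotone
  expect_equal(ratio[1], 1)                    # same initial state
  expect_equal(ratio[length(ratio)], 1, tolerance = 1e-3)  # same endpoint
  idx <- which.min(ratio)
  expect_gt(idx, 1)                            # interior excursion
  expect_lt(idx, length(ratio))
  expect_lt(min(ratio), 0.9)
  # floor guard flags points where the denominator underflows
  expect_true(all(!pr@results$table$floored))
})

test_that("analysis reports are deterministic and serializable", {
  m <- buildModel("cyano_C2")
  r1 <- sinkOutputAnalysis(m, horizon = 5)
  r2 <- sinkOutputAnalysis(m, horizon = 5)
  expect_identical(r1@results$sink_fold, r2@results$sink_fold)
  expect_identical(r1@results$trajectory@conc, r2@results$trajectory@conc)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeReport(r1, path)
  expect_true(file.exists(path))
  expect_gt(length(readLines(path)), 2L)
})
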