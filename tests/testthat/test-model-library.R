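test_that("variant construction follows the cyanobacterial blueprint", {
  d2 <- buildModel("cyano_D2")
  ids <- reactionIds(d2)
  expect_length(grep("^CC", ids), 13L)
  expect_length(grep("^SS", ids), 3L)
  expect_setequal(grep("^SR_", ids, value = TRUE),
                  paste0("SR_", c("PGA", "F6P", "DHAP", "E4P", "R5P",
                                  "PGCA")))
  # photorespiration enters through the lumped carboxylation products
  expect_true("PGCA" %in%
                names(reactionList(d2)[["CC1_carb"]]@stoichiometry))
  expect_true(all(c("CO2", "O2", "Pi") %in% clampedSpecies(d2)))

  # C1 folds the minor sinks: no explicit DHAP/E4P/R5P exports, raised PGA
  c1 <- buildModel("cyano_C1")
  expect_length(intersect(reactionIds(c1),
                          c("SR_DHAP", "SR_E4P", "SR_R5P")), 0L)
  folded <- modelLineage(c1)[[1]]$sink_config
  expect_equal(unname(folded$explicit[["PGA"]]),
               0.128 + aggregateMinorSinks(
                 c(R5P = 0.007, DHAP = 0.0032, E4P = 0.0031,
                   PGCA = 0.042)))
  expect_error(buildModel("cyano_C1",
    sinkCfg = sinkConfig(list(
      CalvinSim:::.mkSink("PGA", "MMcb", 0.2),
      CalvinSim:::.mkSink("DHAP", "MMcb", 0.0032)))),
    "folds the minor sinks")
  expect_error(buildModel("no_such_variant"))

  # C variants carry no PGCA species at all; D variants do
  expect_false("PGCA" %in% speciesIds(c1))
  expect_true("PGCA" %in% speciesIds(buildModel("cyano_D1")))

  # the two transketolase encodings differ and neither is canonical
  za <- buildModel("zhu_A")
  zs <- buildModel("zhu_S")
  expect_identical(za@metadata$tk_form, "appendix")
  expect_identical(zs@metadata$tk_form, "supplement")
  expect_equal(paramValue(modelParameters(za), "kM103"), 0.46)
  expect_equal(paramValue(modelParameters(zs), "kM103"), 0.015)
})

test_that("aggregateMinorSinks reproduces the flux-balance bookkeeping", {
  # raw minor-sink sum: 0.7 % + 0.32 % + 0.31 % = 1.33 % of RuBP synthesis
  expect_equal(sum(c(R5P = 0.007, DHAP = 0.0032, E4P = 0.0031)), 0.0133)
  # folded with printed q factors
  expect_equal(aggregateMinorSinks(c(PGCA = 0.042)), 0.042 * 1.66)
  expect_equal(aggregateMinorSinks(c(R5P = 0.007)), 0.007 * 5 / 3)
  expect_equal(aggregateMinorSinks(numeric()), 0)
  # carbon-ratio rule recomputes q from declared carbon counts
  expect_equal(aggregateMinorSinks(c(E4P = 0.0031), qRule = "carbon_ratio"),
               0.0031 * 4 / 3)
  expect_error(aggregateMinorSinks(c(XYZ = 0.01)), "no printed q")
})

test_that("patches are local, recorded and invertible by reconstruction", {
  d2 <- buildModel("cyano_D2")
  p <- applyPatch(d2, patchDescriptor("set_kE7", list(value = 10)))
  expect_equal(paramValue(modelParameters(p), "kE7"), 10)
  expect_setequal(modelDiff(d2, p, ignoreLineage = TRUE), "parameter:kE7")
  rec <- modelLineage(p)[[1]]$patches
  expect_equal(rec[[length(rec)]]$prior$kE7, 0.076)

  p2 <- applyPatch(p, patchDescriptor("set_kM103", list(value = 0.06)))
  expect_equal(paramValue(modelParameters(p2), "kM103"), 0.06)

  # reconstruction from (base, lineage) alone is structurally exact
  expect_length(modelDiff(p2, reconstructFromLineage(p2)), 0L)

  # starch_fix: applying twice equals applying once (and is a no-op on
  # models without a defective starch law)
  expect_identical(writeModelText(applyPatch(d2,
                                             patchDescriptor("starch_fix"))),
                   writeModelText(d2))
  cm <- calvinMiniFixture(1, starchVariant = "original")
  fixed <- applyPatch(cm, patchDescriptor("starch_fix"))
  expect_identical(reactionList(fixed)[["stdeg"]]@rateLaw@variant,
                   "corrected")
  expect_identical(writeModelText(applyPatch(fixed,
                                             patchDescriptor("starch_fix"))),
                   writeModelText(fixed))

  # modifier-mode patch flips every transketolase law
  mult <- applyPatch(d2, patchDescriptor("tk_modifier_mode",
    list(mode = "multiplicative_modifiers")))
  tkv <- vapply(reactionList(mult)[c("CC7_tk10", "CC10_tk7")],
                function(r) r@rateLaw@variant, "")
  expect_true(all(tkv == "multiplicative_modifiers"))
})

test_that("lumped and split oxygenation encodings have identical steady fluxes", {
  d2 <- buildModel("cyano_D2")
  sp <- applyPatch(d2, patchDescriptor("split_oxygenation"))
  expect_true("CC1_oxy" %in% reactionIds(sp))
  sl <- findSteadyState(d2)
  ss <- findSteadyState(sp)
  shared <- setdiff(intersect(names(sl@fluxes), names(ss@fluxes)),
                    "CC1_carb")
  expect_lt(max(abs(sl@fluxes[shared] - ss@fluxes[shared])), 1e-6)
  expect_lt(abs(ss@fluxes[["CC1_carb"]] + ss@fluxes[["CC1_oxy"]] -
                  sl@fluxes[["CC1_carb"]]), 1e-6)
  # and lumping again restores the original reaction
  back <- applyPatch(sp, patchDescriptor("lump_oxygenation"))
  expect_equal(reactionList(back)[["CC1_carb"]]@stoichiometry,
               reactionList(d2)[["CC1_carb"]]@stoichiometry)
  expect_false("CC1_oxy" %in% reactionIds(back))
})

test_that("configureSink installs exactly one export with the requested family", {
  d2 <- buildModel("cyano_D2")
  pv <- CalvinSim:::.paramVector(modelParameters(d2))

  ma <- configureSink(d2, "PGA", "MA")
  expect_identical(reactionList(ma)[["SR_PGA"]]@rateLaw@family,
                   "mass_action")
  # MA with k = Vmax/Km equals the MM rate in the first-order limit
  vmax <- pv[["V_sr_PGA"]]
  km <- pv[["Km_sink"]]
  mmLaw <- reactionList(d2)[["SR_PGA"]]@rateLaw
  maLaw <- reactionList(ma)[["SR_PGA"]]@rateLaw
  tiny <- c(PGA = km * 1e-4)
  expect_equal(evaluateRate(maLaw, tiny,
                            CalvinSim:::.paramVector(modelParameters(ma))),
               evaluateRate(mmLaw, tiny, pv), tolerance = 1e-3)

  # MMcb with a vanishing Km saturates at Vmax for any positive PGA
  sat <- configureSink(d2, "PGA", "MMcb", params = list(km = 1e-9))
  satLaw <- reactionList(sat)[["SR_PGA"]]@rateLaw
  expect_equal(evaluateRate(satLaw, c(PGA = 0.01),
                            CalvinSim:::.paramVector(modelParameters(sat))),
               vmax, tolerance = 1e-6)

  # the translocator-regulated MM slows down when triose phosphates rise
  mm <- configureSink(d2, "PGA", "MM")
  mmP <- CalvinSim:::.paramVector(modelParameters(mm))
  mmL <- reactionList(mm)[["SR_PGA"]]@rateLaw
  lo <- evaluateRate(mmL, c(PGA = 1, Pi = 1, GAP = 0.1, DHAP = 0.1), mmP)
  hi <- evaluateRate(mmL, c(PGA = 1, Pi = 1, GAP = 2, DHAP = 0.1), mmP)
  expect_lt(hi, lo)
})

test_that("relay sink stabilizes PGA export behind a cytosolic pool", {
  d2 <- buildModel("cyano_D2")
  r <- applyPatch(d2, patchDescriptor("add_relay_sink"))
  expect_true(all(c("SR_PGA", "SR_PGA_relay") %in% reactionIds(r)))
  expect_true("PGA_cyt" %in% speciesIds(r))
  expect_equal(reactionList(r)[["SR_PGA"]]@stoichiometry,
               c(PGA = -1, PGA_cyt = 1))
  # applying twice is a no-op
  expect_identical(writeModelText(applyPatch(r,
    patchDescriptor("add_relay_sink"))), writeModelText(r))
  # and the relayed model still reaches a steady state with matching
  # throughput of the two stages
  ss <- findSteadyState(r)
  expect_true(ss@converged)
  expect_equal(unname(ss@fluxes[["SR_PGA"]]),
               unname(ss@fluxes[["SR_PGA_relay"]]), tolerance = 1e-6)
})
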