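test_that("lumped carboxylation-oxygenation stoichiometry follows B = 2f", {
  ab <- lumpedCarboxylationStoichiometry(0.042)
  expect_equal(unname(ab[["A"]]), 1.916)
  expect_equal(unname(ab[["B"]]), 0.084)
  expect_equal(unname(lumpedCarboxylationStoichiometry(0)), c(2, 0))
  expect_equal(unname(lumpedCarboxylationStoichiometry(0.5)), c(1, 1))
  # A + B = 2 for every admissible fraction
  for (f in seq(0, 0.5, by = 0.025))
    expect_equal(sum(lumpedCarboxylationStoichiometry(f)), 2)
  expect_error(lumpedCarboxylationStoichiometry(0.6), "0, 0.5")
  expect_error(lumpedCarboxylationStoichiometry(-0.1), "0, 0.5")
  # alternative per-event reading stays selectable
  ab2 <- lumpedCarboxylationStoichiometry(0.042, rule = "per_event")
  expect_equal(unname(ab2[["B"]]), 0.042)
})

test_that("carbon conversion factor is exact with truncated display", {
  q <- carbonConversionFactor(5, 3)
  expect_equal(as.numeric(q), 5 / 3)
  expect_identical(attr(q, "display"), "1.66")
  expect_equal(as.numeric(carbonConversionFactor(3, 3)), 1)
  expect_equal(as.numeric(carbonConversionFactor(4, 3)), 4 / 3)
  expect_error(carbonConversionFactor(0, 3), "positive")
  expect_error(carbonConversionFactor(5, -1), "positive")
})

test_that("stoichiometry matrix lays out coefficients and clamp flags", {
  m <- relaxationFixture()
  N <- stoichiometryMatrix(m)
  expect_equal(unname(N[, "decay"]), c(-1, 1))
  expect_true(attr(N, "clamped")[["Sink_X"]])
  expect_false(attr(N, "clamped")[["X"]])

  d2 <- buildModel("cyano_D2")
  col <- stoichiometryMatrix(d2)[, "CC1_carb"]
  expect_equal(unname(col[c("RuBP", "CO2", "PGA", "PGCA")]),
               c(-1, -1, 1.916, 0.084))

  # carbon weights annihilate every balanced reaction of the closed fixture
  tc <- toyCycleFixture(1, closedSystem = TRUE)
  Nc <- stoichiometryMatrix(tc)
  cc <- setNames(speciesTable(tc)$carbons, speciesTable(tc)$id)
  expect_equal(unname(as.numeric(cc[rownames(Nc)] %*% Nc)),
               rep(0, ncol(Nc)))
})

test_that("element balance reports real-valued imbalances and errors on missing counts", {
  split <- applyPatch(buildModel("cyano_D2"),
                      patchDescriptor("split_oxygenation"))
  bal <- elementBalance(split, "carbon")
  expect_equal(unname(bal[["CC1_oxy"]]), 0)  # 5 = 3 + 2
  # the printed lump is not exactly carbon-closed: 3*1.916 + 2*0.084 - 6
  lump <- elementBalance(buildModel("cyano_D2"), "carbon")
  expect_equal(unname(lump[["CC1_carb"]]), -0.084)
  # balanced transfer reactions report exact zero
  tc <- toyCycleFixture(1)
  expect_equal(unname(elementBalance(tc, "carbon")[["regen"]]), 0)
  expect_equal(unname(elementBalance(tc, "phosphate")[["red"]]), 0)
  # missing counts name the species
  m <- relaxationFixture()
  m@species$carbons[1] <- NA
  expect_error(elementBalance(m, "carbon"), "X")
})

test_that("validateModel returns diagnostics instead of raising", {
  expect_identical(nrow(validateModel(relaxationFixture())), 0L)

  # unresolved parameter symbol is an error diagnostic
  m <- relaxationFixture()
  r <- reactionList(m)[["decay"]]
  r@rateLaw@bindings$k <- "KM8"
  m@reactions[["decay"]] <- r
  d <- validateModel(m)
  expect_identical(d$severity, "error")
  expect_match(d$message, "KM8")

  # product-form modifier combination draws a dimensional warning
  mult <- applyPatch(buildModel("cyano_C2"),
                     patchDescriptor("tk_modifier_mode",
                                     list(mode = "multiplicative_modifiers")))
  dm <- validateModel(mult)
  expect_true(any(dm$severity == "warning" &
                    grepl("multiplied", dm$message)))

  # kM103 below the stability bound is flagged
  low <- buildModel("zhu_A", params = parameterSet(c(kM103 = 0.015)))
  dl <- validateModel(low)
  expect_true(any(grepl("0.06", dl$message)))

  # negative initial concentrations need the diagnostic-reproduction flag
  expect_error(cbcModel(speciesSpec("X", initial = -1), list(
    reaction("r", c(X = -1), massActionLaw(1, c(X = 1)))),
    parameterSet()), "diagnostic_reproduction")
  expect_s4_class(cbcModel(speciesSpec("X", initial = -1), list(
    reaction("r", c(X = -1), massActionLaw(1, c(X = 1)))),
    parameterSet(), metadata = list(diagnostic_reproduction = TRUE)),
    "CbcModel")
})

test_that("parameter sets enforce positivity and unit coverage", {
  ps <- parameterSet(c(k = 2, Km = 0.5), units = c(k = "s^-1", Km = "mM"))
  expect_equal(paramValue(ps, "Km"), 0.5)
  expect_error(paramValue(ps, "missing"), "not found")
  expect_equal(paramValue(ps, "missing", default = 7), 7)
  expect_error(parameterSet(c(k = -1)), "non-positive")
  # f_oxygenation is the one parameter allowed at zero, within [0, 0.5]
  expect_silent(parameterSet(c(f_oxygenation = 0)))
  expect_error(parameterSet(c(f_oxygenation = 0.7)), "0, 0.5")
  ps2 <- updateParameters(ps, c(Km = 1, Vm = 3), units2 = c(Vm = "mM s^-1"))
  expect_equal(paramValue(ps2, "Km"), 1)
  expect_identical(unname(ps2@units[["Vm"]]), "mM s^-1")
})
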