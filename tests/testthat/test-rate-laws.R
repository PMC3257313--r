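pv <- c(k = 2, keq = 4, vmax = 1, km = 0.5, ki = 0.2)

test_that("mass action and Michaelis-Menten evaluate to textbook values", {
  ma <- massActionLaw("k", c(A = 1, B = 1))
  expect_equal(evaluateRate(ma, c(A = 3, B = 0.5), pv), 3)
  # reversible mass action vanishes at its equilibrium composition
  rev <- massActionLaw("k", c(A = 1), products = c(B = 1), keq = "keq")
  expect_equal(evaluateRate(rev, c(A = 1, B = 4), pv), 0)

  mm <- michaelisMentenLaw("vmax", "S", "km")
  expect_equal(evaluateRate(mm, c(S = 0.5), pv), 0.5)  # S = Km -> Vmax/2
  mmI <- michaelisMentenLaw("vmax", "S", "km",
                            inhibitors = list(list(species = "I",
                                                   ki = "ki")))
  # one competitive inhibitor at I = Ki doubles the effective Km
  expect_equal(evaluateRate(mmI, c(S = 0.5, I = 0.2), pv), 1 / 3)
})

test_that("reversible MM vanishes exactly at its equilibrium composition", {
  law <- reversibleMMLaw("vmax", "keq", substrates = c("A", "B"),
                         kmS = c(0.3, 0.4), products = "C", kmP = 0.2)
  # C/(A B) = keq = 4
  expect_equal(evaluateRate(law, c(A = 0.5, B = 0.5, C = 1), pv), 0)
  expect_gt(evaluateRate(law, c(A = 1, B = 1, C = 1), pv), 0)
  expect_lt(evaluateRate(law, c(A = 0.1, B = 0.1, C = 1), pv), 0)
})

tkParams <- c(vm = 5, kE7 = 0.076, km1 = 0.3, km2 = 0.3, kmE = 0.8,
              kmR = 0.9)
tk <- function(variant = "additive_modifiers", form = "appendix")
  transketolaseLaw("vm", "kE7", s1 = "S7P", s2 = "GAP", p1 = "R5P",
                   p2 = "X5P", km1 = "km1", km2 = "km2",
                   modifiers = list(list(species = "E4P", km = "kmE"),
                                    list(species = "R5P", km = "kmR")),
                   variant = variant, form = form)

test_that("transketolase obeys detailed balance and the documented variant gap", {
  st <- c(S7P = 0.4, GAP = 0.25, R5P = 0.1, X5P = 0.076 * 0.4 * 0.25 / 0.1,
          E4P = 0.05)
  expect_equal(evaluateRate(tk(), st, tkParams), 0)

  # the product-form modifier defect changes the rate by less than 1 %
  ref <- c(S7P = 0.5, GAP = 0.2, R5P = 0.05, X5P = 0.02, E4P = 0.05)
  va <- evaluateRate(tk("additive_modifiers"), ref, tkParams)
  vm <- evaluateRate(tk("multiplicative_modifiers"), ref, tkParams)
  expect_lt(abs(vm - va) / abs(va), 0.01)

  # sign flips with the equilibrium constant at unit mass-action ratio
  one <- c(S7P = 1, GAP = 1, R5P = 1, X5P = 1, E4P = 0)
  expect_lt(evaluateRate(tk(), one, tkParams), 0)       # kE7 = 0.076
  hi <- tkParams; hi[["kE7"]] <- 10
  expect_gt(evaluateRate(tk(), one, hi), 0)

  # supplement encoding carries no modifier saturation term
  withE <- c(S7P = 0.5, GAP = 0.2, R5P = 0.05, X5P = 0.02, E4P = 2)
  noE <- withE; noE[["E4P"]] <- 0
  expect_equal(evaluateRate(tk(form = "supplement"), withE, tkParams),
               evaluateRate(tk(form = "supplement"), noE, tkParams))
  expect_lt(evaluateRate(tk(form = "appendix"), withE, tkParams),
            evaluateRate(tk(form = "appendix"), noE, tkParams))
})

trLaw <- translocatorLaw("vm",
  stromal = list(OP = "OP", PGA = "PGA", GAP = "GAP", DHAP = "DHAP",
                 KmOP = "KmOP", KmPGA = "KmPGA", KmT3P = "KmT3P"),
  cytosolic = list(OP = "OPc", PGA = "PGAc", GAP = "GAPc", DHAP = "DHAPc",
                   KmOP = "KmOP", KmPGA = "KmPGA", KmT3P = "KmT3P"))
trP <- c(vm = 2, KmOP = 1, KmPGA = 0.5, KmT3P = 0.4)

test_that("translocator law is antisymmetric and linear in its maximal rate", {
  sameBoth <- c(OP = 1, PGA = 0.5, GAP = 0.2, DHAP = 0.3,
                OPc = 1, PGAc = 0.5, GAPc = 0.2, DHAPc = 0.3)
  expect_equal(evaluateRate(trLaw, sameBoth, trP), 0)

  set.seed(11)
  for (i in 1:25) {
    st <- setNames(runif(8, 0.01, 3),
                   c("OP", "PGA", "GAP", "DHAP", "OPc", "PGAc", "GAPc",
                     "DHAPc"))
    sw <- st[c("OPc", "PGAc", "GAPc", "DHAPc", "OP", "PGA", "GAP", "DHAP")]
    names(sw) <- names(st)
    expect_equal(evaluateRate(trLaw, sw, trP),
                 -evaluateRate(trLaw, st, trP))
    # linear in Vm11
    tr2 <- trP; tr2[["vm"]] <- 2 * trP[["vm"]]
    expect_equal(evaluateRate(trLaw, st, tr2),
                 2 * evaluateRate(trLaw, st, trP))
  }

  # antiport: export needs a cytosolic counter-substrate; with cytosolic
  # phosphate present and no cytosolic PGA the net rate is a strict export
  exportOnly <- c(OP = 1, PGA = 1, GAP = 0.2, DHAP = 0.3,
                  OPc = 1, PGAc = 0, GAPc = 0, DHAPc = 0)
  expect_gt(evaluateRate(trLaw, exportOnly, trP), 0)
  # a completely empty cytosol carries no exchange flux at all
  empty <- exportOnly
  empty[c("OPc", "PGAc", "GAPc", "DHAPc")] <- 0
  expect_equal(evaluateRate(trLaw, empty, trP), 0)
})

oxy <- oxygenaseLaw("Vo", "Ko", "Kc", "Kr", rubp = "RuBP", o2 = "O2",
                    co2 = "CO2", pga = "PGA", fbp = "FBP", sbp = "SBP",
                    pi = "Pi", nadph = "NADPH")
oxyP <- c(Vo = 2, Ko = 0.3, Kc = 0.2, Kr = 0.05, KI11 = 1, KI12 = 1,
          KI13 = 1, KI14 = 1, KI15 = 1)
oxySt <- function(...) {
  st <- c(RuBP = 0.5, O2 = 0.25, CO2 = 0.2, PGA = 0.5, FBP = 0.1,
          SBP = 0.1, Pi = 1, NADPH = 0.2)
  upd <- c(...)
  st[names(upd)] <- upd
  st
}

test_that("oxygenase rate respects its limits and monotonicities", {
  expect_equal(evaluateRate(oxy, oxySt(O2 = 0), oxyP), 0)
  expect_gt(evaluateRate(oxy, oxySt(O2 = 0.5), oxyP),
            evaluateRate(oxy, oxySt(O2 = 0.25), oxyP))
  expect_lt(evaluateRate(oxy, oxySt(CO2 = 2), oxyP),
            evaluateRate(oxy, oxySt(CO2 = 0.2), oxyP))
  expect_lt(evaluateRate(oxy, oxySt(PGA = 5), oxyP),
            evaluateRate(oxy, oxySt(), oxyP))
  # saturation limit: inhibitors off, RuBP large
  noInh <- oxySt(PGA = 0, FBP = 0, SBP = 0, Pi = 0, NADPH = 0,
                 RuBP = 1e9)
  lim <- with(as.list(c(oxyP, noInh)),
              Vo * O2 / (O2 + Ko * (1 + CO2 / Kc)))
  expect_equal(evaluateRate(oxy, noInh, oxyP), lim, tolerance = 1e-6)
})

test_that("starch phosphorylase variants differ exactly at zero starch", {
  stP <- c(StPase_VM = 0.3, StPase_km = 0.4, StPase_kiG1P = 1)
  cor <- starchPhosphorylaseLaw(starch = "St", phosphate = "Pi",
                                g1p = "G", variant = "corrected")
  org <- starchPhosphorylaseLaw(starch = "St", phosphate = "Pi",
                                g1p = "G", variant = "original")
  zero <- c(St = 0, Pi = 1, G = 0.2)
  expect_equal(evaluateRate(cor, zero, stP), 0)
  expect_gt(evaluateRate(org, zero, stP), 0)
  # half saturation of the corrected form
  half <- c(St = 0.4 * (1 + 0.2), Pi = 1, G = 0.2)
  expect_equal(evaluateRate(cor, half, stP), 0.15)
})

test_that("every family is positively homogeneous in its maximal-rate constant", {
  cases <- list(
    list(massActionLaw("k", c(A = 1, B = 1)), c(A = 0.7, B = 0.4), "k"),
    list(michaelisMentenLaw("vmax", "S", "km"), c(S = 0.9), "vmax"),
    list(reversibleMMLaw("vmax", "keq", "A", 0.3, "B", 0.2),
         c(A = 1, B = 0.4), "vmax"),
    list(tk(), c(S7P = 0.5, GAP = 0.2, R5P = 0.05, X5P = 0.02, E4P = 0.05),
         "vm"),
    list(oxy, oxySt(), "Vo"))
  base <- c(pv, tkParams, oxyP)
  for (cs in cases) {
    v1 <- evaluateRate(cs[[1]], cs[[2]], base)
    doubled <- base
    doubled[[cs[[3]]]] <- 2 * base[[cs[[3]]]]
    expect_equal(evaluateRate(cs[[1]], cs[[2]], doubled), 2 * v1)
  }
})

test_that("generic expressions agree with an independent tree-walking oracle", {
  set.seed(2024)
  syms <- c("A", "B", "Km", "V")
  for (i in 1:1000) {
    ex <- randomExpr(syms)
    st <- setNames(runif(2, 0.1, 2), c("A", "B"))
    pp <- setNames(runif(2, 0.1, 2), c("Km", "V"))
    got <- evaluateRate(genericLaw(ex), st, pp)
    want <- walkEval(ex, as.list(c(st, pp)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("expression trees outside the arithmetic subset are rejected", {
  expect_error(genericLaw(quote(sin(A))), "disallowed")
  expect_silent(genericLaw(quote(min(A, 2) + max(B, 0.1)^2)))
  expect_error(evaluateRate(genericLaw(quote(A + Qx)), c(A = 1), pv),
               "unresolved symbol")
})

test_that("negative concentrations are clipped and counted, except in diagnostic mode", {
  negativeClipCount(reset = TRUE)
  ma <- massActionLaw("k", c(A = 1))
  expect_equal(evaluateRate(ma, c(A = -2), pv), 0)
  expect_equal(negativeClipCount(), 1)
  # diagnostic-reproduction mode evaluates on the raw state
  expect_equal(evaluateRate(ma, c(A = -2), pv, clipNegatives = FALSE), -4)
  negativeClipCount(reset = TRUE)
})
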