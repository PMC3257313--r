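# Independent oracles: hand-coded rate functions and solvers that do not go
# through the package's evaluation or steady-state path.

# recursive tree-walking evaluator for arithmetic expressions, independent
# of evaluateRate()'s environment-based evaluation
walkEval <- function(e, env) {
  if (is.numeric(e)) return(e)
  if (is.symbol(e)) return(env[[as.character(e)]])
  op <- as.character(e[[1L]])
  args <- lapply(as.list(e)[-1L], walkEval, env = env)
  switch(op,
    "+" = if (length(args) == 1L) args[[1L]] else args[[1L]] + args[[2L]],
    "-" = if (length(args) == 1L) -args[[1L]] else args[[1L]] - args[[2L]],
    "*" = args[[1L]] * args[[2L]],
    "/" = args[[1L]] / args[[2L]],
    "^" = args[[1L]]^args[[2L]],
    "(" = args[[1L]],
    "min" = do.call(min, args),
    "max" = do.call(max, args),
    stop("walkEval: unknown op ", op))
}

# random arithmetic expression over the given symbols (positive leaves keep
# powers and divisions well-defined)
randomExpr <- function(symbols, depth = 3L) {
  if (depth >= 3L) {  # top level: always an operator call
    op <- sample(c("+", "-", "*", "/"), 1L)
    return(call(op, randomExpr(symbols, depth - 1L),
                randomExpr(symbols, depth - 1L)))
  }
  if (depth == 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.5) return(as.name(sample(symbols, 1L)))
    return(round(stats::runif(1, 0.1, 3), 3))
  }
  op <- sample(c("+", "-", "*", "/", "^", "min", "max"), 1L,
               prob = c(0.25, 0.15, 0.25, 0.15, 0.05, 0.075, 0.075))
  a <- randomExpr(symbols, depth - 1L)
  b <- if (identical(op, "^")) round(stats::runif(1, 0.2, 2), 2)
       else randomExpr(symbols, depth - 1L)
  call(op, a, b)
}

# hand-coded mass-action rates of the toy autocatalytic cycle (independent
# of the package's RateLaw machinery)
toyCycleRatesByHand <- function(x, k) {
  c(carb = k[["k_carb"]] * x[["A"]] * x[["C"]],
    red = k[["k_red"]] * x[["P"]] * x[["ATP"]],
    regen = k[["k_regen"]] * x[["T"]],
    atpsyn = k[["k_atpsyn"]] * x[["ADP"]] * x[["Pi"]],
    sink = k[["k_sink"]] * x[["P"]])
}

toyCycleStoichByHand <- function() {
  sp <- c("A", "P", "T", "ATP", "ADP", "Pi", "Sink_P")
  N <- matrix(0, length(sp), 5, dimnames = list(sp,
    c("carb", "red", "regen", "atpsyn", "sink")))
  N["A", "carb"] <- -1; N["P", "carb"] <- 2
  N["P", "red"] <- -1; N["ATP", "red"] <- -1
  N["T", "red"] <- 1; N["ADP", "red"] <- 1
  N["T", "regen"] <- -1; N["A", "regen"] <- 0.6; N["Pi", "regen"] <- 0.8
  N["ADP", "atpsyn"] <- -1; N["Pi", "atpsyn"] <- -1; N["ATP", "atpsyn"] <- 1
  N["P", "sink"] <- -1; N["Sink_P", "sink"] <- 1; N["Pi", "sink"] <- 1
  N
}

# brute-force steady-state search: minimize ||N v(x)||^2 plus conservation
# constraints, from many random starts; returns the best solution found
bruteForceToySteadyState <- function(model, nStarts = 100L, seed = 42L) {
  k <- setNames(modelParameters(model)@values,
                names(modelParameters(model)@values))
  x0 <- setNames(speciesTable(model)$initial, speciesTable(model)$id)
  N <- toyCycleStoichByHand()
  # conserved moieties of the toy cycle (S clamped, C clamped):
  # adenylates and total free phosphate
  aden0 <- x0[["ATP"]] + x0[["ADP"]]
  phos0 <- 2 * x0[["A"]] + x0[["P"]] + 2 * x0[["T"]] +
    3 * x0[["ATP"]] + 2 * x0[["ADP"]] + x0[["Pi"]]
  dyn <- c("A", "P", "T", "ATP", "ADP", "Pi")
  obj <- function(z) {
    x <- c(setNames(exp(z), dyn), Sink_P = 0, C = unname(x0[["C"]]))
    v <- toyCycleRatesByHand(x, k)
    r <- (N[dyn, ] %*% v)
    cons <- c(x[["ATP"]] + x[["ADP"]] - aden0,
              2 * x[["A"]] + x[["P"]] + 2 * x[["T"]] + 3 * x[["ATP"]] +
                2 * x[["ADP"]] + x[["Pi"]] - phos0)
    sum(r^2) + sum(cons^2)
  }
  residVec <- function(z) {
    x <- c(setNames(exp(z), dyn), Sink_P = 0, C = unname(x0[["C"]]))
    v <- toyCycleRatesByHand(x, k)
    r <- as.numeric(N[dyn, ] %*% v)
    c(r, x[["ATP"]] + x[["ADP"]] - aden0,
      2 * x[["A"]] + x[["P"]] + 2 * x[["T"]] + 3 * x[["ATP"]] +
        2 * x[["ADP"]] + x[["Pi"]] - phos0)
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nStarts)) {
    z0 <- log(pmax(x0[dyn] * stats::runif(6, 0.2, 5), 1e-3))
    fit <- try(stats::optim(z0, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-16)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # Gauss-Newton polish of the best start to full precision
  z <- best$par
  for (it in 1:40) {
    r <- residVec(z)
    if (max(abs(r)) < 1e-14) break
    J <- matrix(0, length(r), length(z))
    for (j in seq_along(z)) {
      zp <- z; zp[j] <- zp[j] + 1e-7
      J[, j] <- (residVec(zp) - r) / 1e-7
    }
    step <- try(qr.solve(J, -r), silent = TRUE)
    if (inherits(step, "try-error")) break
    z <- z + step
  }
  setNames(exp(z), dyn)
}

# two-compartment fixture exercising the phosphate-translocator law:
# source -> PGA (stroma), translocator PGA <-> PGA_c, PGA_c -> sink
translocatorFixture <- function(vm = 1) {
  species <- rbind(
    speciesSpec("Src", 1, carbons = 3, phosphates = 1, clamped = TRUE),
    speciesSpec("PGA", 0.5, carbons = 3, phosphates = 1),
    speciesSpec("GAP", 0.1, carbons = 3, phosphates = 1, clamped = TRUE),
    speciesSpec("DHAP", 0.1, carbons = 3, phosphates = 1, clamped = TRUE),
    speciesSpec("OP", 1, carbons = 0, phosphates = 1, clamped = TRUE),
    speciesSpec("PGA_c", 0.1, carbons = 3, phosphates = 1,
                compartment = "cytosol"),
    speciesSpec("GAP_c", 0.05, carbons = 3, phosphates = 1,
                compartment = "cytosol", clamped = TRUE),
    speciesSpec("DHAP_c", 0.05, carbons = 3, phosphates = 1,
                compartment = "cytosol", clamped = TRUE),
    speciesSpec("OP_c", 1.2, carbons = 0, phosphates = 1,
                compartment = "cytosol", clamped = TRUE),
    speciesSpec("Out", 0, carbons = 3, phosphates = 1,
                compartment = "cytosol", clamped = TRUE))
  params <- parameterSet(
    c(J = 0.2, Vm11 = vm, KmOP = 1, KmPGA = 0.5, KmT3P = 0.4,
      KmOPc = 1, KmPGAc = 0.5, KmT3Pc = 0.4, k_out = 0.5),
    units = c(J = "mM s^-1", Vm11 = "mM s^-1", KmOP = "mM", KmPGA = "mM",
              KmT3P = "mM", KmOPc = "mM", KmPGAc = "mM", KmT3Pc = "mM",
              k_out = "s^-1"))
  law <- translocatorLaw("Vm11",
    stromal = list(OP = "OP", PGA = "PGA", GAP = "GAP", DHAP = "DHAP",
                   KmOP = "KmOP", KmPGA = "KmPGA", KmT3P = "KmT3P"),
    cytosolic = list(OP = "OP_c", PGA = "PGA_c", GAP = "GAP_c",
                     DHAP = "DHAP_c", KmOP = "KmOPc", KmPGA = "KmPGAc",
                     KmT3P = "KmT3Pc"))
  cbcModel(species, list(
    reaction("input", c(Src = -1, PGA = 1), massActionLaw("J", c(Src = 1))),
    reaction("transloc", c(PGA = -1, PGA_c = 1), law,
             modifiers = c("GAP", "DHAP", "OP", "GAP_c", "DHAP_c", "OP_c"),
             reversible = TRUE),
    reaction("out", c(PGA_c = -1, Out = 1),
             massActionLaw("k_out", c(PGA_c = 1)))),
    params, metadata = list(fixture = "translocator"))
}

# one-species relaxation chain used for ratio-excursion checks
relaxationFixture <- function(k = 1, x0 = 2) {
  species <- rbind(speciesSpec("X", x0, carbons = 1, phosphates = 0),
                   speciesSpec("Sink_X", 0, carbons = 1, phosphates = 0,
                               clamped = TRUE))
  cbcModel(species,
           list(reaction("decay", c(X = -1, Sink_X = 1),
                         massActionLaw("k", c(X = 1)))),
           parameterSet(c(k = k), units = c(k = "s^-1")))
}
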