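#' @include model.R serialize.R
NULL

#' Clamping specification
#'
#' Species in `fixed` are held at their initial concentration (their time
#' derivative is forced to zero; their rows stay in the stoichiometry matrix
#' for flux accounting). When `energyCharge` is set, ATP and ADP are removed
#' from the dynamic state and held at `ec * adenylateTotal` and
#' `(1 - ec) * adenylateTotal` respectively, implementing the
#' `ATP * (ADP + ATP)^-1` clamp used by the energy-limitation scans.
#'
#' @param fixed Character vector of species ids to hold constant.
#' @param energyCharge Optional fraction in `[0, 1]`.
#' @param adenylateTotal Total adenylate pool (mM); required with
#'   `energyCharge`.
#' @param atp,adp Ids of the adenylate species.
#' @return A `ClampSpec` list.
#' @export
clampSpec <- function(fixed = character(), energyCharge = NULL,
                      adenylateTotal = NULL, atp = "ATP", adp = "ADP") {
  if (!is.null(energyCharge)) {
    stopifnot(energyCharge >= 0, energyCharge <= 1,
              !is.null(adenylateTotal), adenylateTotal > 0)
  }
  structure(list(fixed = fixed, energyCharge = energyCharge,
                 adenylateTotal = adenylateTotal, atp = atp, adp = adp),
            class = "ClampSpec")
}

# resolve clamps against a model: returns list(state0, clampedIds)
.applyClamps <- function(model, clamps) {
  sp <- model@species
  state0 <- stats::setNames(sp$initial, sp$id)
  clamped <- sp$id[sp$clamped]
  if (!is.null(clamps)) {
    missing <- setdiff(clamps$fixed, sp$id)
    if (length(missing))
      stop("clamped species not in model: ",
           paste(missing, collapse = ", "), call. = FALSE)
    clamped <- union(clamped, clamps$fixed)
    if (!is.null(clamps$energyCharge)) {
      if (!all(c(clamps$atp, clamps$adp) %in% sp$id))
        stop("energy-charge clamp requires ATP and ADP species",
             call. = FALSE)
      state0[[clamps$atp]] <- clamps$energyCharge * clamps$adenylateTotal
      state0[[clamps$adp]] <- (1 - clamps$energyCharge) *
        clamps$adenylateTotal
      clamped <- union(clamped, c(clamps$atp, clamps$adp))
    }
  }
  list(state0 = state0, clamped = clamped)
}

# per-reaction rate evaluator; clip unless diagnostic-reproduction model
.rateEvaluator <- function(model) {
  laws <- lapply(model@reactions, function(r) r@rateLaw)
  pv <- .paramVector(model@parameters)
  clip <- !isTRUE(model@metadata$diagnostic_reproduction)
  rids <- reactionIds(model)
  function(state) {
    v <- vapply(laws, evaluateRate, 0, state = state, params = pv,
                clipNegatives = clip)
    names(v) <- rids
    v
  }
}

#' A simulated trajectory
#'
#' @slot time Numeric grid (s).
#' @slot conc Matrix time x species (mM).
#' @slot flux Matrix time x reactions (mM s^-1).
#' @slot clamped Character vector of clamped species ids.
#' @slot diagnostics List (negative-concentration events, integrator status).
#' @export
setClass("CbcTrajectory",
  representation(time = "numeric", conc = "matrix", flux = "matrix",
                 clamped = "character", diagnostics = "list"))

#' @export
setMethod("show", "CbcTrajectory", function(object) {
  cat("CbcTrajectory:", length(object@time), "time points over",
      format(max(object@time)), "s;", ncol(object@conc), "species\n")
  if (length(object@diagnostics$negative_species))
    cat("  negative concentrations:",
        paste(object@diagnostics$negative_species, collapse = ", "), "\n")
})

#' Integrate a model's ODE system
#'
#' Solves `dX/dt = N v(X)` with clamped rows zeroed, using a stiff-capable
#' integrator (`deSolve::lsoda`, switching automatically between stiff and
#' non-stiff). Integration stops early if any species exceeds
#' `divergenceCap` (the expected outcome when the PGA sink is absent).
#'
#' @param model A validated [CbcModel-class].
#' @param clamps A [clampSpec()] or `NULL`.
#' @param tEnd End time (s).
#' @param times Optional explicit output grid; default 1000 points per decade
#'   (log-spaced) plus t = 0.
#' @param rtol,atol Integrator tolerances (default 1e-8 relative,
#'   1e-12 mM absolute).
#' @param divergenceCap Concentration (mM) treated as unbounded accumulation.
#' @return A [CbcTrajectory-class].
#' @export
integrateModel <- function(model, clamps = NULL, tEnd, times = NULL,
                           rtol = 1e-8, atol = 1e-12,
                           divergenceCap = 1e6) {
  ac <- .applyClamps(model, clamps)
  state0 <- ac$state0
  N <- stoichiometryMatrix(model)
  free <- !(rownames(N) %in% ac$clamped)
  rates <- .rateEvaluator(model)
  if (is.null(times)) times <- .logTimes(tEnd)
  rhs <- function(t, y, p) {
    v <- rates(y)
    dy <- as.numeric(N %*% v)
    dy[!free] <- 0
    list(dy)
  }
  root <- function(t, y, p) max(abs(y)) - divergenceCap
  sol <- deSolve::ode(y = state0, times = times, func = rhs, parms = NULL,
                      method = "lsodar", rtol = rtol, atol = atol,
                      rootfunc = root, maxsteps = 50000)
  tt <- sol[, 1L]
  conc <- sol[, -1L, drop = FALSE]
  flux <- t(apply(conc, 1L, rates))
  if (nrow(conc) == 1L) flux <- matrix(flux, nrow = 1L,
                                       dimnames = list(NULL,
                                                       reactionIds(model)))
  negs <- colnames(conc)[apply(conc, 2L, function(x) any(x < -10 * atol))]
  troot <- attr(sol, "troot")
  diverged <- (!is.null(troot) && length(troot) > 0L) ||
    any(abs(conc[nrow(conc), ]) >= divergenceCap * 0.999)
  divergedSpecies <- if (diverged)
    colnames(conc)[which.max(abs(conc[nrow(conc), ]))] else character()
  methods::new("CbcTrajectory", time = tt, conc = conc, flux = flux,
               clamped = ac$clamped,
               diagnostics = list(negative_species = negs,
                                  diverged = diverged,
                                  diverged_species = divergedSpecies,
                                  rtol = rtol, atol = atol))
}

# log-spaced grid, pointsPerDecade per decade of simulated time, plus t = 0
.logTimes <- function(tEnd, pointsPerDecade = 1000, tMin = NULL) {
  if (is.null(tMin)) tMin <- tEnd * 1e-5
  decades <- log10(tEnd / tMin)
  n <- max(2L, ceiling(decades * pointsPerDecade))
  n <- min(n, 20000L)
  c(0, 10^seq(log10(tMin), log10(tEnd), length.out = n))
}

#' Time to steady state of a trajectory
#'
#' The first grid time from which on the normalized derivative criterion
#' `max_i |dX_i/dt| / max(|X_i|, floor) < epsilon` holds at every subsequent
#' recorded point. The criterion is this toolkit's definition (published
#' equilibration times presuppose an unstated one), so scans over `epsilon`
#' are cheap: pass a vector to get the sensitivity band.
#'
#' @param model The model that produced the trajectory (for the rate laws).
#' @param trajectory A [CbcTrajectory-class].
#' @param epsilon Criterion threshold(s) (s^-1), default 1e-6.
#' @param floor Concentration floor (mM) in the normalization.
#' @return Named numeric vector (per epsilon) of first steady grid times;
#'   `NA` where never satisfied.
#' @export
timeToSteadyState <- function(model, trajectory, epsilon = 1e-6,
                              floor = 1e-9) {
  N <- stoichiometryMatrix(model)
  free <- !(rownames(N) %in% trajectory@clamped)
  rates <- .rateEvaluator(model)
  crit <- apply(trajectory@conc, 1L, function(y) {
    dy <- as.numeric(N %*% rates(y))[free]
    y <- y[free]
    max(abs(dy) / pmax(abs(y), floor))
  })
  tss <- vapply(epsilon, function(eps) {
    ok <- crit < eps
    # first index from which all subsequent points satisfy the criterion
    idx <- which(rev(cumprod(rev(ok))) == 1)
    if (length(idx)) trajectory@time[idx[1L]] else NA_real_
  }, 0, USE.NAMES = FALSE)
  stats::setNames(tss, paste0("eps_", format(epsilon)))
}

#' A converged (or not) steady state
#'
#' @slot state Named concentration vector (mM).
#' @slot fluxes Named per-reaction rates (mM s^-1), recomputable from `state`.
#' @slot converged Logical.
#' @slot timeToSteadyState Seconds (NA when not converged).
#' @slot criterion List recording the detection rule and tolerance.
#' @export
setClass("SteadyState",
  representation(state = "numeric", fluxes = "numeric",
                 converged = "logical", timeToSteadyState = "numeric",
                 criterion = "list"))

#' @export
setMethod("show", "SteadyState", function(object) {
  cat("SteadyState (", if (object@converged) "converged" else
      "NOT converged", "), t* = ", format(object@timeToSteadyState),
      " s\n", sep = "")
  print(utils::head(round(object@state, 6), 12L))
})

#' Find a steady state by integration plus Newton refinement
#'
#' Integrates until the normalized-derivative criterion holds (simulated-time
#' cap default 1e5 s), then refines by damped Newton iteration on
#' `N v(X)` restricted to unclamped species. Trajectories in which any
#' species exceeds `divergenceCap` abort with an "unbounded accumulation"
#' error naming the species.
#'
#' @inheritParams integrateModel
#' @param epsilon Steady-state criterion (s^-1).
#' @param floor Normalization floor (mM).
#' @param cap Simulated-time cap (s).
#' @param refine Logical: run the Newton refinement.
#' @return A [SteadyState-class].
#' @export
findSteadyState <- function(model, clamps = NULL, epsilon = 1e-6,
                            floor = 1e-9, cap = 1e5, rtol = 1e-8,
                            atol = 1e-12, divergenceCap = 1e6,
                            refine = TRUE) {
  ac <- .applyClamps(model, clamps)
  N <- stoichiometryMatrix(model)
  free <- !(rownames(N) %in% ac$clamped)
  rates <- .rateEvaluator(model)
  resid <- function(y) as.numeric(N %*% rates(y))[free]
  critVal <- function(y) max(abs(resid(y)) / pmax(abs(y[free]), floor))

  state <- ac$state0
  tss <- NA_real_
  converged <- FALSE
  if (!any(free)) {
    converged <- TRUE
    tss <- 0
  } else if (critVal(state) < epsilon) {
    converged <- TRUE
    tss <- 0
  } else {
    tEnd <- 1
    tNow <- 0
    consW <- .conservedBasis(model, clamps)
    model0 <- setInitial(model, state)
    while (tEnd <= cap) {
      traj <- integrateModel(model0, clamps, tEnd = tEnd,
                             times = .logTimes(tEnd, pointsPerDecade = 25,
                                               tMin = tEnd * 1e-3),
                             rtol = rtol, atol = atol,
                             divergenceCap = divergenceCap)
      if (isTRUE(traj@diagnostics$diverged))
        stop("unbounded accumulation: ",
             traj@diagnostics$diverged_species, call. = FALSE)
      state <- traj@conc[nrow(traj@conc), ]
      if (critVal(state) < epsilon) {
        t1 <- timeToSteadyState(model0, traj, epsilon = epsilon,
                                floor = floor)
        tss <- tNow + unname(t1[1L])
        converged <- TRUE
        break
      }
      tNow <- tNow + max(traj@time)
      # restart on the exact conserved manifold of the initial state
      state <- .projectConserved(state, ac$state0, consW)
      model0 <- setInitial(model0, pmax(state, 0))
      tEnd <- tEnd * 10
    }
  }
  if (converged && refine && any(free)) {
    refined <- .newtonRefine(state, free, resid)
    if (!is.null(refined) && critVal(refined) <= critVal(state))
      state <- refined
  }
  methods::new("SteadyState", state = state, fluxes = rates(state),
               converged = converged, timeToSteadyState = tss,
               criterion = list(rule = "max |dX/dt| / max(|X|, floor)",
                                epsilon = epsilon, floor = floor,
                                cap = cap))
}

# damped Newton with numerical Jacobian on the free residual; singular
# Jacobians (conserved moieties) fall back to a minimum-norm SVD step.
# Returns the best state reached, or NULL if no improvement was possible.
.newtonRefine <- function(state, free, resid, maxit = 50L, tol = 1e-13) {
  x <- state[free]
  fullState <- state
  f <- function(x) {
    fullState[free] <- x
    resid(fullState)
  }
  fx <- f(x)
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol) break
    J <- .numJacobian(f, x, fx)
    # truncated-SVD step: near-null directions (conserved moieties) are
    # excluded so the iteration cannot drift off the conserved manifold
    step <- .pinvSolve(J, -fx)
    if (is.null(step) || !all(is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    repeat {
      xNew <- x + lambda * step
      if (all(is.finite(xNew)) && all(xNew > -1e-12)) {
        fNew <- f(pmax(xNew, 0))
        if (max(abs(fNew)) < max(abs(fx))) {
          x <- pmax(xNew, 0)
          fx <- fNew
          improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (!improved) break
  }
  fullState[free] <- x
  fullState
}

# orthonormal basis (rows) of the conserved moieties over free species:
# left null space of the free-row stoichiometry matrix
.conservedBasis <- function(model, clamps = NULL) {
  N <- stoichiometryMatrix(model)
  ac <- .applyClamps(model, clamps)
  Nf <- N[!(rownames(N) %in% ac$clamped), , drop = FALSE]
  sv <- svd(Nf, nu = nrow(Nf))
  nd <- length(sv$d)
  zero <- which(sv$d < 1e-10 * max(sv$d, 1))
  extra <- if (nrow(Nf) > nd) seq(nd + 1L, nrow(Nf)) else integer()
  null <- sv$u[, c(zero, extra), drop = FALSE]
  if (!ncol(null)) return(NULL)
  rownames(null) <- rownames(Nf)
  t(null)
}

# shift a state along the conserved directions so its conserved totals
# equal those of the reference state x0
.projectConserved <- function(x, x0, W) {
  if (is.null(W)) return(x)
  sp <- colnames(W)
  d <- as.numeric(W %*% x0[sp] - W %*% x[sp])
  x[sp] <- x[sp] + as.numeric(t(W) %*% d)
  x
}

# minimum-norm least-squares solve via SVD (rank-deficient Jacobians)
.pinvSolve <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d)
  if (!any(keep)) return(NULL)
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

.numJacobian <- function(f, x, fx = f(x)) {
  n <- length(x)
  J <- matrix(0, length(fx), n)
  for (j in seq_len(n)) {
    h <- max(1e-7 * abs(x[j]), 1e-9)
    xp <- x
    xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - fx) / h
  }
  J
}

#' Match a reference steady-state flux between two model variants
#'
#' Scales the knob parameters of `modelB` (all by a common factor) until its
#' steady-state flux through `referenceFluxId` matches `modelA`'s within
#' `deltaFlux` (the paired cyanobacterial variants use 5e-6 and 3e-4). The
#' adjustment is appended to `modelB`'s lineage.
#'
#' @param modelA,modelB [CbcModel-class] objects sharing the reference flux.
#' @param referenceFluxId Reaction id (typically the RuBP-synthesis reaction).
#' @param knobParameters Character vector of parameter names in `modelB`.
#' @param deltaFlux Absolute flux-matching tolerance (mM s^-1).
#' @param clamps Optional shared [clampSpec()].
#' @param scaleRange Log10 search bounds for the common scale factor.
#' @return The adjusted `modelB`.
#' @export
matchFlux <- function(modelA, modelB, referenceFluxId, knobParameters,
                      deltaFlux = 5e-6, clamps = NULL,
                      scaleRange = c(-2, 2)) {
  stopifnot(referenceFluxId %in% reactionIds(modelA),
            referenceFluxId %in% reactionIds(modelB),
            all(knobParameters %in% paramNames(modelB@parameters)))
  target <- findSteadyState(modelA, clamps)@fluxes[[referenceFluxId]]
  # every evaluation starts cold from modelB's initial state, so the
  # matched flux is exactly reproducible when the returned model is solved
  fluxAt <- function(logScale) {
    s <- 10^logScale
    pv <- .paramVector(modelB@parameters)
    upd <- stats::setNames(pv[knobParameters] * s, knobParameters)
    m <- modelB
    modelParameters(m) <- updateParameters(modelB@parameters, upd)
    findSteadyState(m, clamps)@fluxes[[referenceFluxId]] - target
  }
  f0 <- fluxAt(0)
  if (abs(f0) <= deltaFlux) return(modelB)
  # grow a bracket outward from scale 1, then bisect on the log scale,
  # stopping on the flux tolerance itself
  half <- 0.05
  lo <- -half
  hi <- half
  flo <- fluxAt(lo)
  fhi <- fluxAt(hi)
  while (sign(flo) == sign(fhi) &&
         (lo > scaleRange[1L] || hi < scaleRange[2L])) {
    half <- half * 2
    lo <- max(-half, scaleRange[1L])
    hi <- min(half, scaleRange[2L])
    flo <- fluxAt(lo)
    fhi <- fluxAt(hi)
  }
  if (sign(flo) == sign(fhi))
    stop("no knob scale in 10^[", scaleRange[1L], ", ", scaleRange[2L],
         "] matches the reference flux", call. = FALSE)
  mid <- fmid <- NULL
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    fmid <- fluxAt(mid)
    if (abs(fmid) <= deltaFlux) break
    if (sign(fmid) == sign(flo)) {
      lo <- mid
      flo <- fmid
    } else {
      hi <- mid
      fhi <- fmid
    }
  }
  if (abs(fmid) > deltaFlux)
    stop("flux matching did not reach delta_flux = ", deltaFlux,
         call. = FALSE)
  s <- 10^mid
  pv <- .paramVector(modelB@parameters)
  upd <- stats::setNames(pv[knobParameters] * s, knobParameters)
  prior <- as.list(pv[knobParameters])
  modelParameters(modelB) <- updateParameters(modelB@parameters, upd)
  .appendPatch(modelB, "flux_match",
               list(reference = referenceFluxId, knobs = knobParameters,
                    scale = s, delta_flux = deltaFlux),
               prior, "steady-state flux matching")
}

#' Export a trajectory as a delimited text table
#'
#' Writes time, species concentrations and reaction fluxes with a metadata
#' header (`#`-prefixed) naming model lineage, clamps and tolerances.
#'
#' @param model The source model.
#' @param trajectory A [CbcTrajectory-class].
#' @param path Output file path.
#' @export
writeTrajectory <- function(model, trajectory, path) {
  hdr <- c(
    paste0("# lineage: ", .lineageString(model)),
    paste0("# clamped: ", paste(trajectory@clamped, collapse = ",")),
    paste0("# rtol: ", trajectory@diagnostics$rtol,
           " atol: ", trajectory@diagnostics$atol))
  df <- data.frame(time = trajectory@time,
                   trajectory@conc, trajectory@flux,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.lineageString <- function(model) {
  if (!length(model@lineage)) return("ad hoc")
  paste(vapply(model@lineage, function(rec) {
    p <- vapply(rec$patches, function(x) x$name, "")
    paste0(if (!is.na(rec$base)) rec$base else "",
           if (length(p)) paste0("+", paste(p, collapse = "+")) else "")
  }, ""), collapse = " | ")
}
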