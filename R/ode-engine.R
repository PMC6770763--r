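#' Create simulation settings
#'
#' Builds a \linkS4class{SimulationSettings}. Only \code{duration} is
#' required; the interval size defaults to duration/nIntervals. When the
#' stated (duration, intervalSize, nIntervals) triple is inconsistent by
#' more than 1\%, the interval count is re-derived as
#' round(duration/intervalSize) with a warning -- published settings blocks
#' occasionally carry a typo in one of the three redundant fields, and
#' duration and interval size are taken as authoritative.
#'
#' \code{maxInternalSteps} is a pass-through to the solver; values below
#' 1000 are accepted for fidelity with external settings blocks but trigger
#' a warning, because an LSODA-class integrator rarely completes a stiff
#' step with so small a budget.
#'
#' @param duration total time, s
#' @param nIntervals number of output intervals
#' @param intervalSize output interval, s
#' @param relativeTolerance,absoluteTolerance solver tolerances
#' @param maxInternalSteps max internal solver steps per output interval
#' @param integrateReducedModel accepted for fidelity; the engine always
#'   integrates the full state (no-op)
#' @return a \linkS4class{SimulationSettings}
#' @examples
#' simulationSettings(duration = 10, nIntervals = 100)
#' @export
simulationSettings <- function(duration, nIntervals = 200L,
                               intervalSize = duration / nIntervals,
                               relativeTolerance = 1e-6,
                               absoluteTolerance = 1e-12,
                               maxInternalSteps = 100000L,
                               integrateReducedModel = FALSE) {
  if (duration <= 0) stop("duration must be > 0")
  if (intervalSize <= 0) stop("intervalSize must be > 0")
  derived <- round(duration / intervalSize)
  if (abs(duration - intervalSize * nIntervals) / duration >= 0.01) {
    warning(sprintf(paste0("settings triple inconsistent (duration %g, ",
                           "interval size %g, intervals %d); deriving ",
                           "intervals = %d from duration/interval size"),
                    duration, intervalSize, as.integer(nIntervals), derived))
    nIntervals <- derived
  }
  if (maxInternalSteps < 1000)
    warning("maxInternalSteps < 1000 is unlikely to complete a stiff ",
            "integration; passed through unchanged")
  new("SimulationSettings", duration = duration, intervalSize = intervalSize,
      nIntervals = as.integer(nIntervals),
      relativeTolerance = relativeTolerance,
      absoluteTolerance = absoluteTolerance,
      maxInternalSteps = as.integer(maxInternalSteps),
      integrateReducedModel = integrateReducedModel)
}

#' Assemble the ODE right-hand side of a network model
#'
#' Each reaction contributes signed-stoichiometry multiples of its rate to
#' the derivative of every participating species:
#' d[X]/dt = sum over reactions of (products stoich - substrates stoich)
#' times the reaction rate. Compartment volumes are constant, so they
#' cancel from the concentration dynamics and the system is integrated
#' directly in concentration units.
#'
#' @param model a valid \linkS4class{NetworkModel}
#' @return a list with \code{rhs}, a function(t, state) returning the named
#'   derivative vector; \code{indexMap}, the named species -> state-index
#'   map; and \code{stoichiometry}, the species x reaction net
#'   stoichiometry matrix
#' @export
buildOdeSystem <- function(model) {
  viol <- validateNetwork(model)
  if (length(viol))
    stop("invalid model:\n  - ", paste(viol, collapse = "\n  - "))
  spIds <- names(model@species)
  idx <- setNames(seq_along(spIds), spIds)
  nr <- length(model@reactions)
  S <- matrix(0, nrow = length(spIds), ncol = nr,
              dimnames = list(spIds, names(model@reactions)))
  for (j in seq_len(nr)) {
    r <- model@reactions[[j]]
    for (id in names(r@substrates))
      S[id, j] <- S[id, j] - r@substrates[[id]]
    for (id in names(r@products))
      S[id, j] <- S[id, j] + r@products[[id]]
  }
  # boundary/constant species (e.g. SBML boundaryCondition) are held fixed
  fixed <- intersect(model@metadata$constantSpecies, spIds)
  if (length(fixed)) S[fixed, ] <- 0
  reactions <- model@reactions
  rhs <- function(t, state) {
    names(state) <- spIds
    rates <- vapply(reactions, evalReactionRate, 0, state = state)
    drop(S %*% rates)
  }
  list(rhs = rhs, indexMap = idx, stoichiometry = S)
}

#' Simulate a network model time course (LSODA)
#'
#' Integrates the model's ODE system with \code{\link[deSolve]{lsoda}},
#' which switches automatically between stiff (BDF) and non-stiff (Adams)
#' methods, honoring the settings' tolerances, and samples the solution at
#' the nIntervals + 1 equally spaced requested times (dense interpolated
#' output, not nearest internal step). The run is deterministic for fixed
#' inputs. Solver round-off can leave concentrations marginally negative;
#' values above -10 * absoluteTolerance are clipped to zero, anything more
#' negative is reported as is (and flagged by the trajectory invariants in
#' the test suite).
#'
#' @param model a valid \linkS4class{NetworkModel}
#' @param settings a \linkS4class{SimulationSettings}
#' @param overrides optional named numeric vector of initial-concentration
#'   overrides (how scenarios introduce doses and constitutively active
#'   species)
#' @param times optional explicit sample times (overrides the settings
#'   grid; must start at 0 and increase)
#' @return a \linkS4class{Trajectory}
#' @examples
#' m <- networkModel(
#'   compartments = list(compartment("cell")),
#'   species = list(
#'     speciesNode("A", compartment = "cell", initialConcentration = 1),
#'     speciesNode("sink", compartment = "cell", role = "sink")),
#'   reactions = list(
#'     reaction("deg", substrates = "A", products = "sink",
#'              law = massActionLaw(log(2)), category = "degradation")),
#'   outputSpecies = "A")
#' tr <- simulateNetwork(m, simulationSettings(duration = 1, nIntervals = 10))
#' speciesTrajectory(tr, "A")[11]  # ~0.5 after one half-life
#' @export
simulateNetwork <- function(model, settings, overrides = NULL,
                            times = NULL) {
  sys <- buildOdeSystem(model)
  y0 <- initialState(model, overrides = overrides)
  if (is.null(times))
    times <- seq(0, settings@duration, length.out = settings@nIntervals + 1L)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("sample times must strictly increase from 0")
  func <- function(t, y, parms) list(sys$rhs(t, y))
  out <- deSolve::lsoda(y = y0, times = times, func = func, parms = NULL,
                        rtol = settings@relativeTolerance,
                        atol = settings@absoluteTolerance,
                        maxsteps = settings@maxInternalSteps)
  if (nrow(out) < length(times)) {
    lastT <- out[nrow(out), 1]
    stop(sprintf(paste0("integration failed at t = %g s (of %g s requested); ",
                        "last successful state retained by the solver"),
                 lastT, max(times)))
  }
  vals <- t(unname(out[, -1, drop = FALSE]))
  rownames(vals) <- names(y0)
  clip <- vals < 0 & vals > -10 * settings@absoluteTolerance
  vals[clip] <- 0
  new("Trajectory", times = as.numeric(times), values = vals,
      speciesOrder = names(y0))
}

#' Extract one species' concentration series from a trajectory
#'
#' @param traj a \linkS4class{Trajectory}
#' @param speciesId species id
#' @return numeric vector of concentrations at \code{trajectoryTimes(traj)}
#' @export
speciesTrajectory <- function(traj, speciesId) {
  if (!speciesId %in% traj@speciesOrder)
    stop("species '", speciesId, "' is not in the trajectory")
  traj@values[speciesId, ]
}

#' @rdname speciesTrajectory
#' @export
trajectoryTimes <- function(traj) traj@times

#' Area under a species' concentration curve
#'
#' Trapezoidal integral of the sampled concentrations over the trajectory's
#' time grid (units: concentration x time), the summary used to compare
#' treatment arms.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param speciesId species id
#' @return non-negative numeric
#' @export
trajectoryAUC <- function(traj, speciesId) {
  y <- speciesTrajectory(traj, speciesId)
  x <- traj@times
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Detect the plateau time of a species' trajectory
#'
#' Returns the earliest sampled time after which the absolute slope of
#' every subsequent sampling interval is at most
#' \code{relSlopeThreshold} times the trajectory's maximum absolute slope.
#' A constant trajectory plateaus at t = 0; a trajectory that keeps rising
#' linearly never satisfies the rule and yields \code{NA} ("not reached") --
#' the signature of a constitutively driven, unsaturated readout.
#'
#' @param traj a \linkS4class{Trajectory} with at least 3 time points
#' @param speciesId species id
#' @param relSlopeThreshold relative slope threshold (default 0.01)
#' @return plateau time in s, or \code{NA_real_} when not reached
#' @export
findPlateau <- function(traj, speciesId, relSlopeThreshold = 0.01) {
  if (length(traj@times) < 3L)
    stop("plateau detection needs at least 3 time points")
  y <- speciesTrajectory(traj, speciesId)
  slopes <- abs(diff(y) / diff(traj@times))
  maxSlope <- max(slopes)
  if (maxSlope == 0) return(traj@times[1])
  below <- slopes <= relSlopeThreshold * maxSlope
  # earliest k such that every interval from k on is below threshold
  ok <- rev(cumprod(rev(below))) > 0
  if (!any(ok)) return(NA_real_)
  traj@times[which(ok)[1]]
}

#' Find a steady state of the network
#'
#' Damped-Newton search for a state with max |d[X]/dt| <= tolerance,
#' started from the initial state, with a long-horizon integration
#' fallback when Newton stalls. Failure to reach steady state is a
#' first-class outcome (returned, not thrown): densely connected signaling
#' networks with constitutive drives often have no reachable steady state
#' on any practical horizon.
#'
#' @param model a valid \linkS4class{NetworkModel}
#' @param maxTime horizon for the integration fallback, s
#' @param tolerance max absolute derivative at the accepted state
#' @param maxIterations Newton iteration budget
#' @return list with \code{state} (named numeric), \code{converged}
#'   (logical), \code{method} ("newton" or "integration"), and
#'   \code{maxDerivative}
#' @export
steadyState <- function(model, maxTime = 1e6, tolerance = 1e-9,
                        maxIterations = 50L) {
  sys <- buildOdeSystem(model)
  y <- initialState(model)
  n <- length(y)
  # sink species are accounting nodes that accumulate degraded mass; their
  # monotone growth must not preclude a steady state of the live network
  sinkIdx <- which(vapply(model@species, function(s) s@role == "sink", TRUE))
  f <- function(state) {
    d <- sys$rhs(0, state)
    if (length(sinkIdx)) d[sinkIdx] <- 0
    d
  }

  numJac <- function(state) {
    h <- pmax(abs(state), 1) * 1e-7
    J <- matrix(0, n, n)
    f0 <- f(state)
    for (j in seq_len(n)) {
      yp <- state; yp[j] <- yp[j] + h[j]
      J[, j] <- (f(yp) - f0) / h[j]
    }
    J
  }

  for (it in seq_len(maxIterations)) {
    fy <- f(y)
    if (max(abs(fy)) <= tolerance)
      return(list(state = y, converged = TRUE, method = "newton",
                  maxDerivative = max(abs(fy))))
    J <- numJac(y)
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    while (lambda >= 1 / 1024) {
      cand <- pmax(y + lambda * step, 0)
      if (max(abs(f(cand))) < max(abs(fy))) {
        y <- cand; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }

  # integration fallback: relax toward an attractor, then test
  traj <- tryCatch(
    simulateNetwork(model,
                    simulationSettings(duration = maxTime, nIntervals = 50L,
                                       absoluteTolerance = min(tolerance, 1e-9))),
    error = function(e) NULL)
  if (!is.null(traj)) {
    yEnd <- traj@values[, ncol(traj@values)]
    md <- max(abs(f(yEnd)))
    return(list(state = yEnd, converged = md <= tolerance,
                method = "integration", maxDerivative = md))
  }
  list(state = y, converged = FALSE, method = "newton",
       maxDerivative = max(abs(f(y))))
}

#' Export a trajectory as a tidy table
#'
#' @param traj a \linkS4class{Trajectory}
#' @param path optional file path; when given, a TSV (time column plus one
#'   column per species) is written and the data.frame returned invisibly
#' @return data.frame with column \code{time} and one column per species
#' @export
trajectoryToTable <- function(traj, path = NULL) {
  df <- data.frame(time = traj@times, t(traj@values),
                   check.names = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
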