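test_that("the ODE right-hand side matches hand-written derivatives", {
  sys <- buildOdeSystem(decayModel(k = 0.5))
  d <- sys$rhs(0, c(A = 2, sink = 0))
  expect_equal(unname(d[1]), -1)          # -k1 * A
  # a species taking part in no reaction has zero derivative
  m <- addSpecies(decayModel(), speciesNode("orphan", compartment = "cell",
                                            initialConcentration = 3))
  d2 <- buildOdeSystem(m)$rhs(0, c(A = 2, sink = 0, orphan = 3))
  expect_equal(unname(d2["orphan"]), 0)
})

test_that("the crizotinib intervention subsystem has the expected derivatives", {
  # ALK_Mutated consumed by a modifier-proportional law, drug by first-order
  # decay: d[ALK_Mutated]/dt = -Kcat c a / (Km + a), d[Crizotinib]/dt = -k1 c
  base <- networkModel(
    compartments = list(compartment("cytoplasm")),
    species = list(
      speciesNode("ALK_Mutated", compartment = "cytoplasm",
                  activationState = "active", initialConcentration = 1e-3),
      speciesNode("sink", compartment = "cytoplasm", role = "sink")),
    reactions = list(), outputSpecies = "ALK_Mutated")
  m <- applyCrizotinib(base, dose = 1.4e-3, Kcat = 2, Km = 0.5, kDeg = 0.1)
  sys <- buildOdeSystem(m)
  a <- 0.3; cz <- 0.7
  d <- sys$rhs(0, c(ALK_Mutated = a, sink = 0, Crizotinib = cz))
  expect_equal(unname(d["ALK_Mutated"]), -2 * cz * a / (0.5 + a))
  expect_equal(unname(d["Crizotinib"]), -0.1 * cz)
  expect_equal(unname(d["sink"]), 2 * cz * a / (0.5 + a) + 0.1 * cz)
})

test_that("exponential decay reproduces its closed form", {
  tr <- simulateNetwork(decayModel(k = log(2)),
                        fastSettings(1, nIntervals = 10))
  a <- speciesTrajectory(tr, "A")
  expect_equal(a[1], 1)                               # initial condition
  expect_equal(a[11], 0.5, tolerance = 1e-6)          # one half-life
  expect_equal(a, 2^(-trajectoryTimes(tr)), tolerance = 1e-6)
})

test_that("the first trajectory column equals the initial state", {
  for (m in fleetModels()) {
    tr <- simulateNetwork(m, fastSettings(10, nIntervals = 5))
    expect_equal(tr@values[, 1], initialState(m))
  }
})

test_that("LSODA agrees with a fixed-step RK4 oracle across the fleet", {
  for (nm in names(fleetModels())) {
    m <- fleetModels()[[nm]]
    dur <- if (grepl("cascade", nm)) 5e3 else 5
    tr <- simulateNetwork(m, fastSettings(dur, nIntervals = 10))
    lsodaEnd <- tr@values[, 11]
    rkEnd <- rk4Endpoint(m, dur, nSteps = 10000)
    scale <- pmax(abs(rkEnd), max(abs(rkEnd)) * 1e-8)
    expect_lt(max(abs(lsodaEnd - rkEnd) / scale), 1e-4)
  }
})

test_that("trapezoidal AUC matches rectangle, triangle and analytic decay", {
  constTraj <- new("Trajectory", times = seq(0, 10, 1),
                   values = matrix(2, 1, 11,
                                   dimnames = list("c", NULL)),
                   speciesOrder = "c")
  expect_equal(trajectoryAUC(constTraj, "c"), 20)
  ramp <- new("Trajectory", times = seq(0, 2, 0.5),
              values = matrix(seq(0, 4, 1), 1, 5,
                              dimnames = list("c", NULL)),
              speciesOrder = "c")
  expect_equal(trajectoryAUC(ramp, "c"), 4)
  tr <- simulateNetwork(decayModel(k = log(2)),
                        fastSettings(1, nIntervals = 100))
  expect_equal(trajectoryAUC(tr, "A"), (1 - 0.5) / log(2), tolerance = 1e-3)
  expect_error(trajectoryAUC(tr, "nope"), "not in the trajectory")
})

test_that("plateau detection distinguishes saturation from linear growth", {
  mkTraj <- function(times, vals)
    new("Trajectory", times = times,
        values = matrix(vals, 1, dimnames = list("c", NULL)),
        speciesOrder = "c")
  t <- seq(0, 10, 0.1)
  expect_equal(findPlateau(mkTraj(t, rep(3, length(t))), "c"), 0)
  expect_true(is.na(findPlateau(mkTraj(t, 2 * t), "c")))
  # c(t) = 1 - exp(-t): slope falls below 1% of max at t = ln(100) ~ 4.6
  pt <- findPlateau(mkTraj(t, 1 - exp(-t)), "c", relSlopeThreshold = 0.01)
  expect_gte(pt, log(100) - 0.2)
  expect_lte(pt, 10)
})

test_that("steady states: symmetry, exhaustion, and long-horizon agreement", {
  ss <- steadyState(reversibleABModel(k1 = 1, k2 = 1, a0 = 2))
  expect_true(ss$converged)
  expect_equal(unname(ss$state[c("A", "B")]), c(1, 1), tolerance = 1e-6)

  ss2 <- steadyState(decayModel(k = 0.3))
  expect_true(ss2$converged)
  expect_equal(unname(ss2$state["A"]), 0, tolerance = 1e-6)

  # constitutive source feeding a degraded readout: X* = k_syn / k_deg
  m <- addSpecies(synthesisModel(k = 0.2),
                  speciesNode("sink", compartment = "cell", role = "sink"))
  m <- addReaction(m, reaction("deg_X", substrates = "X", products = "sink",
                               law = massActionLaw(0.05),
                               category = "degradation"))
  ss3 <- steadyState(m, tolerance = 1e-8)
  tr <- simulateNetwork(m, fastSettings(10 * 100, nIntervals = 20))
  expect_true(ss3$converged)
  expect_equal(unname(ss3$state["X"]), 0.2 / 0.05, tolerance = 1e-4)
  expect_equal(unname(ss3$state["X"]),
               unname(tr@values["X", 21]), tolerance = 1e-3)
})

test_that("compartment volume cancels from concentration dynamics", {
  spec <- cascadeSpec(nLayers = 1, seed = 11)
  m1 <- generateCascadeNetwork(spec)
  m10 <- m1
  m10@compartments[["cytoplasm"]]@volume <- 10
  s <- fastSettings(5e3, nIntervals = 20)
  expect_equal(simulateNetwork(m10, s)@values, simulateNetwork(m1, s)@values)
})

test_that("inactive/active pairs conserve total mass along trajectories", {
  s <- fastSettings(5e3, nIntervals = 20,
                    relativeTolerance = 1e-9, absoluteTolerance = 1e-9)
  m <- generateCascadeNetwork(cascadeSpec(nLayers = 2, seed = 22))
  tr <- simulateNetwork(m, s)
  for (pair in list(c("K1_1", "K1_1_active"), c("K2_1", "K2_1_active"))) {
    tot <- colSums(tr@values[pair, ])
    expect_lt(max(abs(tot - tot[1])), 10 * s@absoluteTolerance)
  }
})

test_that("no fleet trajectory reports concentrations below -atol", {
  s <- fastSettings(5e3, nIntervals = 20)
  for (m in fleetModels()) {
    tr <- simulateNetwork(m, s)
    expect_gte(min(tr@values), -s@absoluteTolerance)
  }
})

test_that("halving the sampling interval leaves endpoints stable", {
  for (nm in c("chain", "cascade1")) {
    m <- fleetModels()[[nm]]
    dur <- if (nm == "chain") 5 else 5e3
    e1 <- simulateNetwork(m, fastSettings(dur, nIntervals = 20))@values[, 21]
    e2 <- simulateNetwork(m, fastSettings(dur, nIntervals = 40))@values[, 41]
    scale <- pmax(abs(e1), max(abs(e1)) * 1e-8)
    expect_lt(max(abs(e1 - e2) / scale), 1e-6)
  }
})

test_that("inconsistent settings triples are re-derived with a warning", {
  expect_warning(
    s <- simulationSettings(duration = 2e5, intervalSize = 4.656609941,
                            nIntervals = 4295),
    "inconsistent")
  expect_equal(s@nIntervals, 42950L)
  expect_warning(simulationSettings(duration = 1, nIntervals = 10,
                                    maxInternalSteps = 10),
                 "maxInternalSteps")
  # the full published pair of frames is exposed as presets
  expect_equal(presetSettings("short")@nIntervals, 429497L)
  expect_equal(presetSettings("long")@nIntervals, 42950L)
  expect_equal(presetSettings("long", nIntervals = 200)@duration, 2e5)
})

test_that("simulation of an invalid model is rejected with the violations", {
  m <- decayModel()
  m@outputSpecies <- "A"
  m@reactions[["deg_A"]]@substrates <- c(Z = 1)
  expect_error(simulateNetwork(m, fastSettings(1)), "unresolved")
})
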