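test_that("expression values seed inactive pools and zero their active forms", {
  m <- networkModel(
    compartments = list(compartment("cell")),
    species = list(
      speciesNode("A", compartment = "cell", activationState = "inactive",
                  initialConcentration = 9, counterpart = "A_active"),
      speciesNode("A_active", compartment = "cell",
                  activationState = "active", initialConcentration = 0),
      speciesNode("B", compartment = "cell", activationState = "inactive",
                  initialConcentration = 9, counterpart = "B_active"),
      speciesNode("B_active", compartment = "cell",
                  activationState = "active", initialConcentration = 0)),
    reactions = list())
  m2 <- applyExpressionInitials(m, c(A = 2, B = 4), scale = 0.5)
  expect_equal(getSpecies(m2, "A")@initialConcentration, 1)
  expect_equal(getSpecies(m2, "B")@initialConcentration, 2)
  expect_equal(getSpecies(m2, "A_active")@initialConcentration, 0)
  expect_equal(getSpecies(m2, "B_active")@initialConcentration, 0)
  # degenerate scale zeroes all mapped pools
  m3 <- applyExpressionInitials(m, c(A = 2, B = 4), scale = 0)
  expect_equal(getSpecies(m3, "A")@initialConcentration, 0)
  # empty mapping is the identity
  m4 <- applyExpressionInitials(m, c(A = 2), mapping = character())
  expect_identical(modelFingerprint(m4), modelFingerprint(m))
  # mapping to an active-state species is refused
  expect_error(
    applyExpressionInitials(m, c(A = 2), mapping = c(A = "A_active")),
    "inactive-state")
  expect_error(applyExpressionInitials(m, c(A = -1)), "non-negative")
})

test_that("a single decay constant is recovered from noiseless data", {
  times <- c(0.5, 1, 2, 4)
  obs <- data.frame(species = "A", time = times, value = exp(-0.7 * times))
  pr <- fitProblem(decayModel(k = 0.3),
                   data.frame(reaction = "deg_A", parameter = "k1",
                              lower = 0.01, upper = 10, guess = 0.3),
                   obs, fastSettings(4, nIntervals = 10))
  fit <- fitParameters(pr)
  expect_true(fit@converged)
  expect_equal(unname(fit@estimates), 0.7, tolerance = 1e-4)
  expect_lt(fit@rss, 1e-10)
})

test_that("observations generated at the guess give zero RSS immediately", {
  m <- chainModel(k1 = 0.7, k2 = 0.3)
  s <- fastSettings(5, nIntervals = 10)
  obs <- generateObservations(m, s, c("A", "B"),
                              times = c(1, 2, 4), noiseSdRel = 0)
  pr <- fitProblem(m, data.frame(
    reaction = c("step1", "step2"), parameter = "k1",
    lower = 0.01, upper = 10, guess = c(0.7, 0.3)), obs, s)
  fit <- fitParameters(pr)
  expect_lt(fit@rss, 1e-14)
  expect_equal(unname(fit@estimates), c(0.7, 0.3), tolerance = 1e-6)
})

test_that("noiseless two-parameter recovery is sharp on the chain model", {
  truth <- c(0.7, 0.3)
  m <- chainModel(k1 = truth[1], k2 = truth[2])
  s <- fastSettings(6, nIntervals = 12)
  obs <- generateObservations(m, s, c("A", "B"),
                              times = seq(0.5, 6, by = 0.5), noiseSdRel = 0)
  mStart <- chainModel(k1 = 2, k2 = 1)   # start well away from the truth
  pr <- fitProblem(mStart, data.frame(
    reaction = c("step1", "step2"), parameter = "k1",
    lower = 0.01, upper = 10, guess = c(2, 1)), obs, s)
  fit <- fitParameters(pr)
  expect_true(fit@converged)
  expect_lt(max(abs(fit@estimates - truth) / truth), 1e-3)
  # estimates respect the declared bounds
  expect_true(all(fit@estimates >= 0.01 & fit@estimates <= 10))
})

test_that("5%-noise recovery stays within 10% median error over 20 replicates", {
  truth <- c(0.7, 0.3)
  m <- chainModel(k1 = truth[1], k2 = truth[2])
  s <- fastSettings(6, nIntervals = 12)
  relErr <- vapply(1:20, function(rep) {
    obs <- generateObservations(m, s, c("A", "B"),
                                times = seq(0.5, 6, by = 0.5),
                                noiseSdRel = 0.05, seed = 1000 + rep)
    pr <- fitProblem(chainModel(k1 = 1, k2 = 1), data.frame(
      reaction = c("step1", "step2"), parameter = "k1",
      lower = 0.01, upper = 10, guess = c(1, 1)), obs, s)
    fit <- fitParameters(pr)
    max(abs(fit@estimates - truth) / truth)
  }, 0)
  expect_lt(median(relErr), 0.10)
})

test_that("fitting never worsens the loss and ignores observation order", {
  m <- chainModel(k1 = 0.7, k2 = 0.3)
  s <- fastSettings(6, nIntervals = 12)
  obs <- generateObservations(m, s, c("A", "B"),
                              times = seq(1, 6, by = 1),
                              noiseSdRel = 0.1, seed = 5)
  mk <- function(o) fitProblem(chainModel(k1 = 1.5, k2 = 0.1), data.frame(
    reaction = c("step1", "step2"), parameter = "k1",
    lower = 0.01, upper = 10, guess = c(1.5, 0.1)), o, s)
  fit <- fitParameters(mk(obs))
  rss0 <- sum(pdl1net:::fitResiduals(mk(obs), c(1.5, 0.1))^2)
  expect_lte(fit@rss, rss0)
  shuffled <- obs[rev(seq_len(nrow(obs))), ]
  fit2 <- fitParameters(mk(shuffled))
  expect_equal(fit@estimates, fit2@estimates, tolerance = 1e-10)
})

test_that("ill-posed problems are reported, not hidden", {
  m <- decayModel()
  expect_error(fitProblem(m, data.frame(reaction = "deg_A", parameter = "k1",
                                        lower = 1, upper = 0.5, guess = 0.7),
                          data.frame(species = "A", time = 1, value = 0.5),
                          fastSettings(1)),
               "bounds")
  expect_warning(
    fitProblem(m, data.frame(reaction = c("deg_A", "deg_A"),
                             parameter = c("k1", "k2"),
                             lower = 0, upper = 1, guess = 0.5),
               data.frame(species = "A", time = 1, value = 0.5),
               fastSettings(1)),
    "underdetermined")
})
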