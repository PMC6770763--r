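# independent re-statement of the participant closure used by the oracle
reactionParticipants2 <- function(r) {
  ids <- c(names(r@substrates), names(r@products), r@modifiers)
  if (is(r@law, "HMMLaw") && !is.na(r@law@enzyme)) ids <- c(ids, r@law@enzyme)
  if (is(r@law, "ModifiedHMMLaw")) ids <- c(ids, r@law@modifier)
  unique(ids)
}

test_that("simplifyNetwork prunes reactions with excluded participants", {
  m <- referenceCascade()
  # identity when every species is kept
  mAll <- simplifyNetwork(m, speciesIds(m))
  expect_setequal(reactionIds(mAll), reactionIds(m))
  expect_setequal(speciesIds(mAll), speciesIds(m))
  # excluding one intermediate of a chain removes both adjacent reactions
  chain <- chainModel()
  pr <- simplifyNetwork(chain, c("A", "B"))
  expect_setequal(reactionIds(pr), c("step1", "step2"))  # sink auto-kept
  chain2 <- chain
  chain2@outputSpecies <- "A"
  pr2 <- simplifyNetwork(chain2, "A")   # dropping B removes both reactions
  expect_length(reactionIds(pr2), 0L)
  expect_error(simplifyNetwork(chain, "Z"), "unknown species")
})

test_that("simplification never grows the model and keeps it valid", {
  m <- referenceCascade()
  keep <- c("NGF", "ALK", "ALK_active", "K1_1", "K1_1_active",
            "K2_1", "K2_1_active", "K3_1", "K3_1_active",
            "PDL1_gene", "PDL1_mRNA")
  sm <- simplifyNetwork(m, keep)
  expect_lte(nSpecies(sm), nSpecies(m))
  expect_lte(nReactions(sm), nReactions(m))
  expect_identical(validateNetwork(sm), character(0))
  # independent reachability oracle: the readout is still driven from ALK
  expect_true("PDL1_mRNA" %in% bfsReachable(sm, "ALK"))
  # retained reactions are exactly those whose participants survive
  keepAll <- union(keep, "sink")
  manual <- Filter(function(r) all(reactionParticipants2(r) %in% keepAll),
                   m@reactions)
  expect_setequal(reactionIds(sm), names(manual))
  expect_error(simplifyNetwork(m, setdiff(keep, "PDL1_mRNA")),
               "output species")
})

test_that("constitutive synthesis has unscaled k1-sensitivity equal to T", {
  # c(T) = k1 * T, so dc/dk1 = T exactly; central differences are exact
  # for a linear map
  T <- 10
  rep <- localSensitivities(synthesisModel(k = 0.5),
                            settings = fastSettings(T, nIntervals = 10))
  e <- rep@entries
  expect_equal(nrow(e), 1L)
  expect_equal(e$sensitivity[e$reaction == "syn_X"], T, tolerance = 1e-5)
  # scaled variant: c = k1 T has unit elasticity regardless of k1's value
  # (invariance of the scaled sensitivity under parameter rescaling)
  for (k in c(0.05, 0.5, 5)) {
    repS <- localSensitivities(synthesisModel(k = k),
                               settings = fastSettings(T, nIntervals = 10),
                               scaling = "scaled")
    expect_equal(repS@entries$sensitivity, 1, tolerance = 1e-5)
  }
})

test_that("parameters with no path to the readout have zero sensitivity", {
  m <- generateCascadeNetwork(cascadeSpec(nLayers = 1, seed = 11))
  # finite differences bottom out at the solver noise floor, so tighten
  # the integration when probing for exact zeros
  s <- fastSettings(5e3, nIntervals = 20, relativeTolerance = 1e-9)
  rep <- localSensitivities(m, settings = s)
  e <- rep@entries
  # the translation and protein-degradation branch is downstream of the
  # mRNA readout: no directed path back
  down <- e$reaction %in% c("PDL1_translation", "PDL1_protein_degradation")
  scale <- max(abs(e$sensitivity), na.rm = TRUE)
  expect_true(all(abs(e$sensitivity[down & !e$skipped]) < 1e-5 * scale))
  # but transcription parameters do matter
  expect_gt(abs(e$sensitivity[e$reaction == "PDL1_transcription" &
                                e$parameter == "Kcat"]), 0)
})

test_that("sensitivity signs agree with a brute-force perturbation oracle", {
  m <- generateCascadeNetwork(cascadeSpec(nLayers = 1, seed = 33))
  s <- fastSettings(5e3, nIntervals = 20, relativeTolerance = 1e-9)
  rep <- localSensitivities(m, settings = s)
  e <- rep@entries[!rep@entries$skipped, ]
  endpointOf <- function(model) {
    tr <- simulateNetwork(model, s)
    speciesTrajectory(tr, "PDL1_mRNA")[21]
  }
  c0 <- endpointOf(m)
  floor <- 1e-4 * max(abs(e$sensitivity))
  for (i in seq_len(nrow(e))) {
    if (abs(e$sensitivity[i]) < floor) next
    pert <- pdl1net:::setLawParameter(m, e$reaction[i], e$parameter[i],
                                      e$baseline[i] * 1.10)
    expect_equal(sign(endpointOf(pert) - c0), sign(e$sensitivity[i]),
                 info = paste(e$reaction[i], e$parameter[i]))
  }
})

test_that("finite-difference sensitivities converge under delta halving", {
  m <- generateCascadeNetwork(cascadeSpec(nLayers = 1, seed = 11))
  s <- fastSettings(5e3, nIntervals = 20, relativeTolerance = 1e-9)
  r1 <- localSensitivities(m, settings = s, delta = 1e-2)@entries
  r2 <- localSensitivities(m, settings = s, delta = 5e-3)@entries
  keep <- !r1$skipped & abs(r1$sensitivity) >
    1e-4 * max(abs(r1$sensitivity), na.rm = TRUE)
  relChange <- abs(r2$sensitivity[keep] - r1$sensitivity[keep]) /
    abs(r1$sensitivity[keep])
  expect_lt(max(relChange), 0.05)
})

test_that("parameter ranking sorts by magnitude with lexicographic ties", {
  entries <- data.frame(
    reaction = c("r2", "r1", "r3", "r1", "r1"),
    parameter = c("Km", "Kcat", "k1", "Km", "k1"),
    baseline = 1, sensitivity = c(1, -3, 2, 2, -2),
    failed = FALSE, skipped = FALSE)
  rep <- new("SensitivityReport", entries = entries, target = "X",
             scaling = "unscaled", readout = "endpoint", baselineValue = 1)
  r <- rankParameters(rep)
  expect_equal(abs(r$sensitivity), c(3, 2, 2, 2, 1))
  # |s| = 2 tie broken by (reaction, parameter): r1.Km, r1.k1, r3.k1
  expect_equal(paste(r$reaction, r$parameter)[2:4],
               c("r1 Km", "r1 k1", "r3 k1"))
  expect_equal(nrow(rankParameters(rep, topN = 2)), 2L)
})
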