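## small hand-built models used across the suite

## A ->(k1) sink : closed-form exponential decay
decayModel <- function(k = log(2), a0 = 1) {
  networkModel(
    compartments = list(compartment("cell")),
    species = list(
      speciesNode("A", compartment = "cell", initialConcentration = a0),
      speciesNode("sink", compartment = "cell", role = "sink")),
    reactions = list(
      reaction("deg_A", substrates = "A", products = "sink",
               law = massActionLaw(k), category = "degradation")),
    outputSpecies = "A")
}

## A <->(k1, k2) B : symmetric interconversion
reversibleABModel <- function(k1 = 1, k2 = 1, a0 = 2, b0 = 0) {
  networkModel(
    compartments = list(compartment("cell")),
    species = list(
      speciesNode("A", compartment = "cell", initialConcentration = a0),
      speciesNode("B", compartment = "cell", initialConcentration = b0)),
    reactions = list(
      reaction("ab", substrates = "A", products = "B",
               law = massActionLaw(k1, k2))),
    outputSpecies = "B")
}

## constitutive synthesis 0 ->(k1) X : c(t) = k1 * t
synthesisModel <- function(k = 0.5) {
  networkModel(
    compartments = list(compartment("cell")),
    species = list(
      speciesNode("X", compartment = "cell", initialConcentration = 0)),
    reactions = list(
      reaction("syn_X", products = "X", law = massActionLaw(k))),
    outputSpecies = "X")
}

## A ->(k1) B ->(k2) sink : two-step chain used for parameter recovery
chainModel <- function(k1 = 0.7, k2 = 0.3, a0 = 1) {
  networkModel(
    compartments = list(compartment("cell")),
    species = list(
      speciesNode("A", compartment = "cell", initialConcentration = a0),
      speciesNode("B", compartment = "cell", initialConcentration = 0),
      speciesNode("sink", compartment = "cell", role = "sink")),
    reactions = list(
      reaction("step1", substrates = "A", products = "B",
               law = massActionLaw(k1)),
      reaction("step2", substrates = "B", products = "sink",
               law = massActionLaw(k2), category = "degradation")),
    outputSpecies = "B")
}

## the small synthetic fleet used by the property suites: modest cascades
## plus the hand-built motifs, all cheap to integrate
fleetModels <- function() {
  list(
    decay = decayModel(),
    revAB = reversibleABModel(),
    chain = chainModel(),
    cascade1 = generateCascadeNetwork(cascadeSpec(nLayers = 1, seed = 11)),
    cascade2 = generateCascadeNetwork(
      cascadeSpec(nLayers = 2, speciesPerLayer = 2, seed = 22)))
}

## classical fixed-step RK4: the independent integrator oracle
rk4Endpoint <- function(model, duration, nSteps) {
  sys <- buildOdeSystem(model)
  y <- initialState(model)
  h <- duration / nSteps
  f <- sys$rhs
  for (i in seq_len(nSteps)) {
    t <- (i - 1) * h
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

## independent breadth-first reachability over the reaction graph:
## edge substrate/enzyme/modifier -> product
bfsReachable <- function(model, from) {
  edges <- list()
  for (r in model@reactions) {
    inputs <- unique(c(names(r@substrates), r@modifiers,
                       if (is(r@law, "HMMLaw") && !is.na(r@law@enzyme))
                         r@law@enzyme,
                       if (is(r@law, "ModifiedHMMLaw")) r@law@modifier))
    for (i in inputs) edges[[length(edges) + 1L]] <- c(i, names(r@products))
  }
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- character()
    for (e in edges)
      if (e[1] %in% frontier) nxt <- c(nxt, e[-1])
    frontier <- setdiff(unique(nxt), seen)
    seen <- union(seen, frontier)
  }
  seen
}

## serialize a model to a canonical string (purity / equality checks)
modelFingerprint <- function(model) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeNetwork(model, tmp)
  paste(readLines(tmp), collapse = "\n")
}

fastSettings <- function(duration, nIntervals = 50L, ...)
  simulationSettings(duration = duration, nIntervals = nIntervals, ...)
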