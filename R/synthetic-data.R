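## run expr with a private RNG stream, restoring the caller's stream
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification for a synthetic signaling cascade
#'
#' Describes a layered receptor -> kinase-cascade -> transcription network
#' of the shape the analysis assumes: ligand inputs (EGF and NGF analogs),
#' an ALK and an EGFR receptor node (each an inactive pool with an active
#' counterpart initialized to zero), \code{nLayers} layers of kinases with
#' \code{speciesPerLayer} kinases each, and a terminal transcription
#' reaction producing the PD-L1 mRNA readout (plus translation to protein
#' and first-order degradations into a single sink). The species count is
#' closed-form: 10 + 2 * nLayers * speciesPerLayer (2 ligands, 4 receptor
#' states, 2 states per kinase, gene + mRNA + protein, 1 sink).
#'
#' Kinetic parameters are drawn uniformly from \code{ranges} under
#' \code{seed}. \code{egfrWeight} scales the EGFR-driven input into the
#' first kinase layer relative to the ALK-driven input; the default keeps
#' the cascade ALK-dominated, the regime in which EGFR inhibition leaves
#' the readout essentially unchanged.
#'
#' @param nLayers number of kinase layers (>= 1)
#' @param speciesPerLayer kinases per layer (>= 1)
#' @param includeAlkBranch,includeEgfrBranch include the ligand -> receptor
#'   activation reactions (the receptor nodes themselves are always
#'   present)
#' The default ranges keep signal transduction sub-saturated: receptor
#' activation is slow relative to deactivation (a few percent of the
#' receptor pool active under ligand), and each kinase layer has a gain
#' near one, so the readout responds approximately linearly to the ALK
#' drive -- the regime in which constitutive mutant activation of the full
#' receptor pool raises the readout by orders of magnitude and its removal
#' by crizotinib suppresses it again.
#'
#' @param egfrWeight multiplier on the EGFR-driven first-layer Kcat
#' @param ranges named list of c(min, max) parameter ranges (see Details)
#' @param initialConcentrations named list: ligand, receptor, kinase, gene
#'   pools, mmol/mL
#' @param seed integer RNG seed
#' @return a list of class "CascadeSpec"
#' @export
cascadeSpec <- function(nLayers = 3L, speciesPerLayer = 1L,
                        includeAlkBranch = TRUE, includeEgfrBranch = TRUE,
                        egfrWeight = 5e-4,
                        ranges = list(
                          recKcat = c(1e-4, 3e-4),  # ligand-driven activation
                          recKm = c(5e-4, 2e-3),
                          recDeactK = c(5e-3, 2e-2),# receptor inactivation, 1/s
                          actKcat = c(1e-3, 4e-3),  # kinase activation
                          actKm = c(5e-4, 2e-3),
                          deactK = c(5e-4, 2e-3),   # active -> inactive, 1/s
                          basalK2 = c(1e-8, 1e-7),  # basal re-activation, 1/s
                          ligDegK = c(4e-5, 6e-5),  # ligand decay, 1/s
                          txKcat = c(5, 15),        # transcription
                          txKm = c(5e-6, 2e-5),
                          mrnaDegK = c(5e-8, 2e-7),
                          tlVmax = c(1e-6, 1e-5),   # translation (Vmax form)
                          tlKm = c(1e-6, 1e-5),
                          protDegK = c(1e-6, 1e-5)),
                        initialConcentrations = list(
                          ligand = 1e-3, receptor = 1e-3,
                          kinase = 1e-3, gene = 1e-5),
                        seed = 1L) {
  stopifnot(nLayers >= 1L, speciesPerLayer >= 1L, egfrWeight >= 0)
  structure(list(nLayers = as.integer(nLayers),
                 speciesPerLayer = as.integer(speciesPerLayer),
                 includeAlkBranch = includeAlkBranch,
                 includeEgfrBranch = includeEgfrBranch,
                 egfrWeight = egfrWeight, ranges = ranges,
                 initialConcentrations = initialConcentrations,
                 seed = as.integer(seed)),
            class = "CascadeSpec")
}

#' Closed-form species count of a cascade spec
#' @param spec a \code{\link{cascadeSpec}}
#' @return integer species count of the generated model
#' @export
cascadeSpeciesCount <- function(spec)
  10L + 2L * spec$nLayers * spec$speciesPerLayer

#' Generate a synthetic signaling cascade network
#'
#' Builds the \linkS4class{NetworkModel} described by a
#' \code{\link{cascadeSpec}}: a pure function of the spec (including its
#' seed), always passing \code{\link{validateNetwork}}, with a directed
#' path from each receptor to the PD-L1 mRNA readout. The ground-truth
#' parameter draw is recorded in the model's metadata
#' (\code{metadata$groundTruth}) so recovery studies can compare estimates
#' against it.
#'
#' @param spec a \code{\link{cascadeSpec}}
#' @return a \linkS4class{NetworkModel} with outputSpecies "PDL1_mRNA"
#' @examples
#' m <- generateCascadeNetwork(cascadeSpec(nLayers = 2, seed = 7))
#' validateNetwork(m)  # character(0)
#' @export
generateCascadeNetwork <- function(spec) {
  stopifnot(inherits(spec, "CascadeSpec"))
  withSeed(spec$seed, {
    draw <- function(range) runif(1, range[1], range[2])
    R <- spec$ranges
    ic <- spec$initialConcentrations
    truth <- list()
    note <- function(rid, param, value) {
      truth[[paste(rid, param, sep = ".")]] <<- value
      value
    }

    cp <- compartment("cytoplasm", "Neuroblastoma Cell Cytoplasm")
    sps <- list(
      speciesNode("EGF", compartment = "cytoplasm", role = "simple molecule",
                  initialConcentration = ic$ligand),
      speciesNode("NGF", compartment = "cytoplasm", role = "simple molecule",
                  initialConcentration = ic$ligand),
      speciesNode("ALK", compartment = "cytoplasm", role = "protein",
                  activationState = "inactive",
                  initialConcentration = ic$receptor,
                  counterpart = "ALK_active"),
      speciesNode("ALK_active", compartment = "cytoplasm", role = "protein",
                  activationState = "active", initialConcentration = 0),
      speciesNode("EGFR_free", compartment = "cytoplasm", role = "protein",
                  activationState = "inactive",
                  initialConcentration = ic$receptor,
                  counterpart = "EGFR_active"),
      speciesNode("EGFR_active", compartment = "cytoplasm", role = "protein",
                  activationState = "active", initialConcentration = 0),
      speciesNode("PDL1_gene", compartment = "cytoplasm", role = "gene",
                  initialConcentration = ic$gene),
      speciesNode("PDL1_mRNA", compartment = "cytoplasm", role = "mRNA",
                  initialConcentration = 0),
      speciesNode("PDL1_protein", compartment = "cytoplasm", role = "protein",
                  initialConcentration = 0),
      speciesNode("sink", name = "degraded", compartment = "cytoplasm",
                  role = "sink"))
    kinase <- function(l, i) sprintf("K%d_%d", l, i)
    for (l in seq_len(spec$nLayers))
      for (i in seq_len(spec$speciesPerLayer)) {
        id <- kinase(l, i)
        sps <- c(sps, list(
          speciesNode(id, compartment = "cytoplasm", role = "protein",
                      activationState = "inactive",
                      initialConcentration = ic$kinase,
                      counterpart = paste0(id, "_active")),
          speciesNode(paste0(id, "_active"), compartment = "cytoplasm",
                      role = "protein", activationState = "active",
                      initialConcentration = 0)))
      }

    rxs <- list()
    addRx <- function(...) rxs[[length(rxs) + 1L]] <<- reaction(...)

    if (spec$includeAlkBranch)
      addRx("ALK_activation", substrates = "ALK", products = "ALK_active",
            modifiers = "NGF",
            law = modifiedHmmLaw(note("ALK_activation", "Kcat", draw(R$recKcat)),
                                 note("ALK_activation", "Km", draw(R$recKm)),
                                 modifier = "NGF"),
            category = "post-translational modification")
    ## reversible deactivation: k1 forward (inactivation), k2 basal
    ## re-activation -- the one reversible mass-action pair in the fleet
    addRx("ALK_deactivation", substrates = "ALK_active", products = "ALK",
          law = massActionLaw(note("ALK_deactivation", "k1", draw(R$recDeactK)),
                              note("ALK_deactivation", "k2", draw(R$basalK2))),
          category = "post-translational modification")
    if (spec$includeEgfrBranch)
      addRx("EGFR_activation", substrates = "EGFR_free",
            products = "EGFR_active", modifiers = "EGF",
            law = modifiedHmmLaw(note("EGFR_activation", "Kcat", draw(R$recKcat)),
                                 note("EGFR_activation", "Km", draw(R$recKm)),
                                 modifier = "EGF"),
            category = "post-translational modification")
    addRx("EGFR_deactivation", substrates = "EGFR_active",
          products = "EGFR_free",
          law = massActionLaw(note("EGFR_deactivation", "k1", draw(R$recDeactK))),
          category = "post-translational modification")
    for (lig in c("EGF", "NGF"))
      addRx(paste0(lig, "_degradation"), substrates = lig, products = "sink",
            law = massActionLaw(note(paste0(lig, "_degradation"), "k1",
                                     draw(R$ligDegK))),
            category = "degradation")

    for (l in seq_len(spec$nLayers))
      for (i in seq_len(spec$speciesPerLayer)) {
        id <- kinase(l, i)
        if (l == 1L) {
          addRx(paste0(id, "_activation_by_ALK"), substrates = id,
                products = paste0(id, "_active"),
                law = hmmLaw(note(paste0(id, "_activation_by_ALK"), "Kcat",
                                  draw(R$actKcat)),
                             note(paste0(id, "_activation_by_ALK"), "Km",
                                  draw(R$actKm)),
                             enzyme = "ALK_active"),
                category = "post-translational modification")
          addRx(paste0(id, "_activation_by_EGFR"), substrates = id,
                products = paste0(id, "_active"),
                law = hmmLaw(note(paste0(id, "_activation_by_EGFR"), "Kcat",
                                  spec$egfrWeight * draw(R$actKcat)),
                             note(paste0(id, "_activation_by_EGFR"), "Km",
                                  draw(R$actKm)),
                             enzyme = "EGFR_active"),
                category = "post-translational modification")
        } else {
          up <- paste0(kinase(l - 1L, sample.int(spec$speciesPerLayer, 1L)),
                       "_active")
          addRx(paste0(id, "_activation"), substrates = id,
                products = paste0(id, "_active"),
                law = hmmLaw(note(paste0(id, "_activation"), "Kcat",
                                  draw(R$actKcat)),
                             note(paste0(id, "_activation"), "Km",
                                  draw(R$actKm)),
                             enzyme = up),
                category = "post-translational modification")
        }
        addRx(paste0(id, "_deactivation"), substrates = paste0(id, "_active"),
              products = id,
              law = massActionLaw(note(paste0(id, "_deactivation"), "k1",
                                       draw(R$deactK))),
              category = "post-translational modification")
      }

    terminal <- paste0(kinase(spec$nLayers, 1L), "_active")
    addRx("PDL1_transcription", substrates = "PDL1_gene",
          products = c(PDL1_gene = 1, PDL1_mRNA = 1),
          law = hmmLaw(note("PDL1_transcription", "Kcat", draw(R$txKcat)),
                       note("PDL1_transcription", "Km", draw(R$txKm)),
                       enzyme = terminal),
          category = "transcription")
    addRx("PDL1_mRNA_degradation", substrates = "PDL1_mRNA",
          products = "sink",
          law = massActionLaw(note("PDL1_mRNA_degradation", "k1",
                                   draw(R$mrnaDegK))),
          category = "degradation")
    addRx("PDL1_translation", substrates = "PDL1_mRNA",
          products = c(PDL1_mRNA = 1, PDL1_protein = 1),
          law = hmmLaw(note("PDL1_translation", "Kcat", draw(R$tlVmax)),
                       note("PDL1_translation", "Km", draw(R$tlKm))),
          category = "translation")
    addRx("PDL1_protein_degradation", substrates = "PDL1_protein",
          products = "sink",
          law = massActionLaw(note("PDL1_protein_degradation", "k1",
                                   draw(R$protDegK))),
          category = "degradation")

    networkModel(list(cp), sps, rxs, outputSpecies = "PDL1_mRNA",
                 metadata = list(generator = "generateCascadeNetwork",
                                 seed = spec$seed,
                                 groundTruth = truth,
                                 units = list(concentration = "mmol/mL",
                                              time = "s")))
  })
}

#' The frozen reference cascade
#'
#' The fixed synthetic network (spec defaults, seed 20190831) used
#' throughout the package's qualitative tests and documentation as the
#' stand-in for a full curated signaling network: ALK-dominated PD-L1
#' drive, so the constitutively active mutant raises the readout,
#' crizotinib suppresses it, and gefitinib leaves it essentially
#' unchanged.
#'
#' @return a \linkS4class{NetworkModel}
#' @export
referenceCascade <- function()
  generateCascadeNetwork(cascadeSpec(seed = 20190831L))

#' Generate noisy time-course observations from a model
#'
#' Simulates the model and perturbs the sampled concentrations with
#' multiplicative Gaussian noise: observed = true * (1 + N(0, noiseSdRel)).
#' Noiseless when \code{noiseSdRel = 0}; reproducible by seed. The exact
#' simulated value is kept in the \code{truth} column.
#'
#' @param model a valid \linkS4class{NetworkModel}
#' @param settings a \linkS4class{SimulationSettings}
#' @param observedSpecies character vector of species ids to observe
#' @param times observation times (default: the settings grid without 0)
#' @param noiseSdRel relative noise standard deviation (>= 0)
#' @param nReplicates replicates per (species, time)
#' @param seed integer RNG seed
#' @return data.frame with columns species, time, replicate, value, truth,
#'   weight
#' @export
generateObservations <- function(model, settings, observedSpecies,
                                 times = NULL, noiseSdRel = 0.05,
                                 nReplicates = 1L, seed = 1L) {
  if (noiseSdRel < 0) stop("noiseSdRel must be >= 0")
  tr <- simulateNetwork(model, settings, times =
                          if (is.null(times)) NULL else sort(unique(c(0, times))))
  if (is.null(times)) times <- tr@times[-1]
  grid <- expand.grid(replicate = seq_len(nReplicates), time = times,
                      species = observedSpecies,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- mapply(function(sp, t) tr@values[sp, match(t, tr@times)],
                  grid$species, grid$time)
  value <- withSeed(seed,
                    truth * (1 + rnorm(length(truth), 0, noiseSdRel)))
  data.frame(species = grid$species, time = grid$time,
             replicate = grid$replicate, value = as.numeric(value),
             truth = as.numeric(truth), weight = 1)
}

#' Generate a synthetic expression matrix with planted effects
#'
#' Emulates a two-factor microarray design -- culture (2D, 3D) crossed
#' with treatment (DMSO, crizotinib, alectinib), \code{nPerGroup} samples
#' per cell -- on the log2 scale: per-probe baselines drawn from
#' N(8, 2^2), additive Gaussian noise N(0, noiseSd^2) per measurement, and
#' planted log2 effects added to selected (probe, culture, treatment)
#' cells. Reproducible by seed.
#'
#' @param nProbes number of probes; the first is named \code{pdl1Probe}
#' @param nPerGroup samples per (culture, treatment) cell
#' @param effects data.frame with columns probe, culture, treatment,
#'   log2fc (the planted shift, negative = down-regulation)
#' @param noiseSd additive log2 noise sd
#' @param pdl1Probe id given to the first probe (the PD-L1 readout)
#' @param seed integer RNG seed
#' @return an \linkS4class{ExpressionMatrix} (log2 scale)
#' @export
generateExpressionMatrix <- function(nProbes = 200L, nPerGroup = 3L,
                                     effects = NULL, noiseSd = 0.1,
                                     pdl1Probe = "CD274", seed = 1L) {
  stopifnot(nProbes >= 1L, nPerGroup >= 1L, noiseSd >= 0)
  cultures <- c("2D", "3D")
  treatments <- c("DMSO", "crizotinib", "alectinib")
  design <- expand.grid(replicate = seq_len(nPerGroup),
                        treatment = treatments, culture = cultures,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  probes <- c(pdl1Probe,
              if (nProbes > 1L) sprintf("probe_%03d", seq_len(nProbes - 1L)))
  withSeed(seed, {
    baseline <- rnorm(nProbes, mean = 8, sd = 2)
    vals <- matrix(baseline, nrow = nProbes, ncol = nrow(design)) +
      matrix(rnorm(nProbes * nrow(design), 0, noiseSd), nrow = nProbes)
    rownames(vals) <- probes
    colnames(vals) <- sprintf("%s_%s_%d", design$culture, design$treatment,
                              design$replicate)
    if (!is.null(effects))
      for (k in seq_len(nrow(effects))) {
        cols <- design$culture == effects$culture[k] &
          design$treatment == effects$treatment[k]
        vals[effects$probe[k], cols] <-
          vals[effects$probe[k], cols] + effects$log2fc[k]
      }
    expressionMatrix(vals, culture = design$culture,
                     treatment = design$treatment, scale = "log2")
  })
}

#' Synthetic validation matrix with the planted ALK-inhibition effect
#'
#' Convenience wrapper around \code{\link{generateExpressionMatrix}}
#' planting the study conditions of the validation design on the PD-L1
#' probe: a 4.33-fold reduction (log2 effect -log2(4.33)) under crizotinib
#' in 3D culture, a 3.26-fold reduction in 2D culture, and a milder
#' alectinib down-regulation (2-fold in both cultures). The default probe
#' count (1000) keeps the per-column distributions dense enough that
#' quantile normalization does not discretize away a single probe's
#' planted effect (the emulated platform carries ~60K probes).
#'
#' @param seed integer RNG seed
#' @param nProbes,nPerGroup,noiseSd forwarded to the generator
#' @return an \linkS4class{ExpressionMatrix} (log2 scale)
#' @export
syntheticValidationMatrix <- function(seed = 1L, nProbes = 1000L,
                                      nPerGroup = 3L, noiseSd = 0.05) {
  effects <- data.frame(
    probe = "CD274",
    culture = c("3D", "2D", "3D", "2D"),
    treatment = c("crizotinib", "crizotinib", "alectinib", "alectinib"),
    log2fc = c(-log2(4.33), -log2(3.26), -1, -1))
  generateExpressionMatrix(nProbes = nProbes, nPerGroup = nPerGroup,
                           effects = effects, noiseSd = noiseSd,
                           seed = seed)
}
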