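#' @import methods
#' @importFrom stats setNames rnorm runif median approx
#' @importFrom utils head read.delim write.table packageVersion
NULL

SPECIES_ROLES <- c("gene", "mRNA", "protein", "simple molecule", "drug", "sink")
ACTIVATION_STATES <- c("inactive", "active", "not_applicable")
REACTION_CATEGORIES <- c("post-translational modification",
                         "activation/inhibition", "degradation",
                         "transcription", "translation")

#' Compartment of a reaction network
#'
#' A well-mixed volume (nominally mL) containing species. Every valid
#' network has at least one compartment; because compartment volumes are
#' constant in time they cancel from the concentration dynamics, but the
#' volume is carried for fidelity with SBML sources.
#'
#' @slot id short unique identifier
#' @slot name display name (e.g. "Neuroblastoma Cell Cytoplasm")
#' @slot volume positive volume, nominal mL
#' @exportClass Compartment
setClass("Compartment",
         representation(id = "character", name = "character",
                        volume = "numeric"),
         prototype(name = "", volume = 1),
         validity = function(object) {
           msg <- character()
           if (length(object@id) != 1L || !nzchar(object@id))
             msg <- c(msg, "'id' must be a single non-empty string")
           if (length(object@volume) != 1L || is.na(object@volume) ||
               object@volume <= 0)
             msg <- c(msg, "'volume' must be a single positive number")
           if (length(msg)) msg else TRUE
         })

#' Molecular species in a network
#'
#' Species carry a biological role (gene, mRNA, protein, simple molecule,
#' drug, or the degradation sink), an activation state, and an initial
#' concentration in nominal mmol/mL. An inactive species may reference its
#' activated form through \code{counterpart}; by convention the activated
#' form starts at concentration zero unless a scenario overrides it.
#'
#' @slot id unique identifier
#' @slot name display name
#' @slot compartment id of the containing \linkS4class{Compartment}
#' @slot role one of gene, mRNA, protein, simple molecule, drug, sink
#' @slot activationState one of inactive, active, not_applicable
#' @slot initialConcentration non-negative, nominal mmol/mL
#' @slot counterpart id of the active form of an inactive species
#'   (\code{NA_character_} when none)
#' @exportClass Species
setClass("Species",
         representation(id = "character", name = "character",
                        compartment = "character", role = "character",
                        activationState = "character",
                        initialConcentration = "numeric",
                        counterpart = "character"),
         prototype(name = "", role = "protein",
                   activationState = "not_applicable",
                   initialConcentration = 0, counterpart = NA_character_),
         validity = function(object) {
           msg <- character()
           if (length(object@id) != 1L || !nzchar(object@id))
             msg <- c(msg, "'id' must be a single non-empty string")
           if (!object@role %in% SPECIES_ROLES)
             msg <- c(msg, sprintf("unknown role '%s'", object@role))
           if (!object@activationState %in% ACTIVATION_STATES)
             msg <- c(msg, sprintf("unknown activation state '%s'",
                                   object@activationState))
           if (length(object@initialConcentration) != 1L ||
               is.na(object@initialConcentration) ||
               object@initialConcentration < 0)
             msg <- c(msg, "'initialConcentration' must be >= 0")
           if (length(msg)) msg else TRUE
         })

#' Kinetic rate laws
#'
#' \code{KineticLaw} is the virtual parent of the three law variants used
#' throughout the network: irreversible or reversible mass action
#' (\code{MassActionLaw}, constants k1 and optional k2), Henri-Michaelis-
#' Menten (\code{HMMLaw}, Kcat and Km with an optional enzyme species;
#' without an enzyme Kcat plays the role of Vmax), and the modified
#' Henri-Michaelis-Menten form whose rate is additionally proportional to a
#' modifier species' concentration (\code{ModifiedHMMLaw}) -- the form used
#' for drug-mediated inactivation. \code{OpaqueLaw} retains an imported
#' rate expression that did not match any of the three variants; it is
#' evaluated symbolically.
#'
#' @aliases MassActionLaw HMMLaw ModifiedHMMLaw OpaqueLaw
#' @exportClass KineticLaw
#' @exportClass MassActionLaw
#' @exportClass HMMLaw
#' @exportClass ModifiedHMMLaw
#' @exportClass OpaqueLaw
setClass("KineticLaw", representation("VIRTUAL"))

setClass("MassActionLaw", contains = "KineticLaw",
         representation(k1 = "numeric", k2 = "numeric"),
         prototype(k1 = 0, k2 = NA_real_),
         validity = function(object) {
           msg <- character()
           if (is.na(object@k1) || object@k1 < 0)
             msg <- c(msg, "k1 must be a non-negative number")
           if (!is.na(object@k2) && object@k2 < 0)
             msg <- c(msg, "k2 must be non-negative when present")
           if (length(msg)) msg else TRUE
         })

setClass("HMMLaw", contains = "KineticLaw",
         representation(Kcat = "numeric", Km = "numeric",
                        enzyme = "character"),
         prototype(Kcat = 0, Km = 1, enzyme = NA_character_),
         validity = function(object) {
           msg <- character()
           if (is.na(object@Kcat) || object@Kcat < 0)
             msg <- c(msg, "Kcat must be non-negative")
           if (is.na(object@Km) || object@Km <= 0)
             msg <- c(msg, "Km must be strictly positive")
           if (length(msg)) msg else TRUE
         })

setClass("ModifiedHMMLaw", contains = "KineticLaw",
         representation(Kcat = "numeric", Km = "numeric",
                        modifier = "character"),
         prototype(Kcat = 0, Km = 1, modifier = NA_character_),
         validity = function(object) {
           msg <- character()
           if (is.na(object@Kcat) || object@Kcat < 0)
             msg <- c(msg, "Kcat must be non-negative")
           if (is.na(object@Km) || object@Km <= 0)
             msg <- c(msg, "Km must be strictly positive")
           if (is.na(object@modifier) || !nzchar(object@modifier))
             msg <- c(msg, "modifier species id is required")
           if (length(msg)) msg else TRUE
         })

setClass("OpaqueLaw", contains = "KineticLaw",
         representation(expression = "character", parameters = "numeric"),
         prototype(expression = "0", parameters = numeric()))

#' Reaction with stoichiometry and a kinetic law
#'
#' Substrates and products are named numeric vectors (names: species ids,
#' values: positive integer stoichiometries, default 1). Modifiers take part
#' in the rate law without being consumed. Each reaction belongs to one of
#' the curation categories used when the network was assembled; PubMed
#' citations are annotation only and play no computational role.
#'
#' @slot id unique identifier
#' @slot substrates named numeric vector, species id -> stoichiometry
#' @slot products named numeric vector, species id -> stoichiometry
#' @slot modifiers character vector of species ids (not consumed)
#' @slot law a \linkS4class{KineticLaw}
#' @slot category curation category
#' @slot citations PubMed identifiers (annotation only)
#' @exportClass Reaction
setClass("Reaction",
         representation(id = "character", substrates = "numeric",
                        products = "numeric", modifiers = "character",
                        law = "KineticLaw", category = "character",
                        citations = "character"),
         prototype(substrates = numeric(), products = numeric(),
                   modifiers = character(),
                   category = "activation/inhibition",
                   citations = character()),
         validity = function(object) {
           msg <- character()
           if (length(object@id) != 1L || !nzchar(object@id))
             msg <- c(msg, "'id' must be a single non-empty string")
           if (length(object@substrates) && (is.null(names(object@substrates)) ||
               any(!nzchar(names(object@substrates)))))
             msg <- c(msg, "substrates must be named by species id")
           if (length(object@products) && (is.null(names(object@products)) ||
               any(!nzchar(names(object@products)))))
             msg <- c(msg, "products must be named by species id")
           if (any(c(object@substrates, object@products) <= 0))
             msg <- c(msg, "stoichiometries must be positive")
           if (!object@category %in% REACTION_CATEGORIES)
             msg <- c(msg, sprintf("unknown category '%s'", object@category))
           if (length(msg)) msg else TRUE
         })

#' In-memory reaction network model
#'
#' The central container: compartments, species and reactions, plus the
#' designated readout node (\code{outputSpecies}, the PD-L1 mRNA analog in
#' the reference networks). Structural invariants are checked by
#' \code{\link{validateNetwork}}, which reports violations rather than
#' throwing, so partially built or deliberately broken models can be
#' constructed and inspected.
#'
#' @slot compartments named list of \linkS4class{Compartment}
#' @slot species named list of \linkS4class{Species}
#' @slot reactions named list of \linkS4class{Reaction}
#' @slot outputSpecies id of the readout species
#' @slot metadata free-form provenance list
#' @exportClass NetworkModel
setClass("NetworkModel",
         representation(compartments = "list", species = "list",
                        reactions = "list", outputSpecies = "character",
                        metadata = "list"),
         prototype(compartments = list(), species = list(),
                   reactions = list(), outputSpecies = NA_character_,
                   metadata = list()))

#' Time-course simulation settings
#'
#' Mirrors the vocabulary of a COPASI deterministic time-course block:
#' duration (s), interval size (s), number of intervals, relative and
#' absolute tolerances, maximum internal solver steps, and the
#' mass-conservation reduction flag (accepted for fidelity, but the engine
#' always integrates the full state). When duration, interval size and
#' interval count disagree by more than 1\%, the count is re-derived from
#' duration/interval size with a warning.
#'
#' @slot duration total simulated time, s
#' @slot intervalSize output sampling interval, s
#' @slot nIntervals number of output intervals (samples = nIntervals + 1)
#' @slot relativeTolerance solver relative tolerance
#' @slot absoluteTolerance solver absolute tolerance
#' @slot maxInternalSteps maximum internal solver steps per output interval
#' @slot integrateReducedModel accepted, ignored (no-op)
#' @exportClass SimulationSettings
setClass("SimulationSettings",
         representation(duration = "numeric", intervalSize = "numeric",
                        nIntervals = "integer",
                        relativeTolerance = "numeric",
                        absoluteTolerance = "numeric",
                        maxInternalSteps = "integer",
                        integrateReducedModel = "logical"),
         prototype(relativeTolerance = 1e-6, absoluteTolerance = 1e-12,
                   maxInternalSteps = 100000L,
                   integrateReducedModel = FALSE),
         validity = function(object) {
           msg <- character()
           if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
           if (object@intervalSize <= 0)
             msg <- c(msg, "intervalSize must be > 0")
           if (object@nIntervals < 1L)
             msg <- c(msg, "nIntervals must be >= 1")
           if (object@relativeTolerance <= 0 || object@absoluteTolerance <= 0)
             msg <- c(msg, "tolerances must be > 0")
           if (object@maxInternalSteps < 1L)
             msg <- c(msg, "maxInternalSteps must be >= 1")
           if (length(msg)) msg else TRUE
         })

#' Simulated trajectory
#'
#' Concentrations (nominal mmol/mL) of every species at the sampled times.
#' The first column equals the model's initial state; values in
#' (-10 * absolute tolerance, 0) arising from solver round-off are clipped
#' to zero on construction.
#'
#' @slot times strictly increasing sample times starting at 0, s
#' @slot values species x time matrix of concentrations
#' @slot speciesOrder species ids in row order
#' @exportClass Trajectory
setClass("Trajectory",
         representation(times = "numeric", values = "matrix",
                        speciesOrder = "character"),
         validity = function(object) {
           msg <- character()
           if (length(object@times) < 1L || object@times[1] != 0 ||
               is.unsorted(object@times, strictly = TRUE))
             msg <- c(msg, "times must strictly increase from 0")
           if (ncol(object@values) != length(object@times))
             msg <- c(msg, "values must have one column per time point")
           if (nrow(object@values) != length(object@speciesOrder))
             msg <- c(msg, "values must have one row per species")
           if (length(msg)) msg else TRUE
         })

#' Experimental arm (scenario) specification
#'
#' Declarative description of one simulation arm over a base network:
#' whether the constitutively active ALK-F1174L mutant is present, ligand
#' stimulation doses, crizotinib/gefitinib doses (mM; 0 = untreated), and
#' optional initial-concentration overrides. \code{\link{buildScenarioModel}}
#' turns a Scenario into a concrete model by pure model surgery.
#'
#' @slot label unique arm label
#' @slot alkF1174L apply the activating ALK mutation?
#' @slot stimulations named numeric vector of ligand doses (e.g. EGF, NGF)
#' @slot crizotinibDose crizotinib initial concentration, mM
#' @slot gefitinibDose gefitinib initial concentration, mM
#' @slot overrides named numeric vector of species initial-concentration
#'   overrides
#' @exportClass Scenario
setClass("Scenario",
         representation(label = "character", alkF1174L = "logical",
                        stimulations = "numeric",
                        crizotinibDose = "numeric",
                        gefitinibDose = "numeric", overrides = "numeric"),
         prototype(label = "arm", alkF1174L = FALSE,
                   stimulations = numeric(), crizotinibDose = 0,
                   gefitinibDose = 0, overrides = numeric()),
         validity = function(object) {
           msg <- character()
           if (object@crizotinibDose < 0 || object@gefitinibDose < 0)
             msg <- c(msg, "drug doses must be >= 0")
           if (any(object@stimulations < 0))
             msg <- c(msg, "stimulation doses must be >= 0")
           if (length(msg)) msg else TRUE
         })

#' Comparison of simulated arms
#'
#' One row per arm: label, readout endpoint concentration and readout AUC,
#' plus the underlying trajectories (or the per-arm failure condition).
#' All arms are simulated with identical settings.
#'
#' @slot table data.frame with columns arm, endpoint, auc, status
#' @slot trajectories named list of \linkS4class{Trajectory} (or condition)
#' @slot settings the shared \linkS4class{SimulationSettings}
#' @exportClass ArmComparison
setClass("ArmComparison",
         representation(table = "data.frame", trajectories = "list",
                        settings = "SimulationSettings"))

#' Local sensitivity report
#'
#' One entry per (reaction, kinetic parameter) pair: the signed central
#' finite-difference sensitivity of the target readout. Positive values
#' mean a parameter increase raises the readout.
#'
#' @slot entries data.frame with columns reaction, parameter, baseline,
#'   sensitivity, failed
#' @slot target readout species id
#' @slot scaling "scaled" or "unscaled"
#' @slot readout "endpoint" or "auc"
#' @slot baselineValue readout value at the unperturbed parameters
#' @exportClass SensitivityReport
setClass("SensitivityReport",
         representation(entries = "data.frame", target = "character",
                        scaling = "character", readout = "character",
                        baselineValue = "numeric"))

#' Kinetic parameter fit result
#'
#' @slot estimates named numeric vector of fitted parameter values
#' @slot rss residual sum of squares at the estimate
#' @slot converged logical convergence flag
#' @slot iterations optimizer iteration count
#' @slot residuals per-observation weighted residuals at the estimate
#' @slot message optimizer termination message
#' @exportClass FitResult
setClass("FitResult",
         representation(estimates = "numeric", rss = "numeric",
                        converged = "logical", iterations = "integer",
                        residuals = "numeric", message = "character"))

#' SBML import report
#'
#' @slot nSpecies number of species in the source document
#' @slot nReactions number of reactions in the source document
#' @slot lawCounts named integer vector: laws mapped per variant
#' @slot unmapped reaction ids whose law fell back to an opaque expression
#' @slot warnings import warnings
#' @exportClass ImportReport
setClass("ImportReport",
         representation(nSpecies = "integer", nReactions = "integer",
                        lawCounts = "integer", unmapped = "character",
                        warnings = "character"))

#' Probe-by-sample expression matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds probe
#' intensities (linear or log2 scale, tracked by \code{exprScale}) and whose
#' column data carries the two-factor design used in the validation stage:
#' culture (2D or 3D) and treatment (DMSO, crizotinib or alectinib).
#'
#' @slot exprScale "linear" or "log2"
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
         contains = "SummarizedExperiment",
         representation(exprScale = "character"),
         prototype(exprScale = "linear"),
         validity = function(object) {
           msg <- character()
           cd <- SummarizedExperiment::colData(object)
           if (!all(c("culture", "treatment") %in% colnames(cd)))
             msg <- c(msg, "colData must have 'culture' and 'treatment'")
           else {
             if (anyNA(cd$culture) || anyNA(cd$treatment))
               msg <- c(msg, "no sample may have a missing group label")
           }
           if (!object@exprScale %in% c("linear", "log2"))
             msg <- c(msg, "exprScale must be 'linear' or 'log2'")
           else if (object@exprScale == "linear" &&
                    length(SummarizedExperiment::assays(object)) &&
                    any(SummarizedExperiment::assay(object) < 0, na.rm = TRUE))
             msg <- c(msg, "linear-scale values must be non-negative")
           if (length(msg)) msg else TRUE
         })
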