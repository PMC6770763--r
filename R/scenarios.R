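#' Preset time-course settings blocks
#'
#' Two conventional deterministic time-course blocks: a short frame
#' (duration 1e-5 s, interval size 2.328304971e-11 s) resolving the fast
#' receptor kinetics, and a long frame (duration 2e5 s, interval size
#' 4.656609941 s) resolving transcriptional accumulation. The interval
#' count is always derived as round(duration / interval size); at full
#' resolution that is 429,497 (short) and 42,950 (long) output points,
#' so \code{nIntervals} can be set lower to thin the output grid without
#' touching solver accuracy (output sampling is dense interpolation).
#' Both frames use relative tolerance 1e-6 and absolute tolerance 1e-12.
#'
#' @param timescale "short" or "long"
#' @param nIntervals optional output interval count; default is the full
#'   derived count
#' @return a \linkS4class{SimulationSettings}
#' @export
presetSettings <- function(timescale = c("short", "long"),
                           nIntervals = NULL) {
  timescale <- match.arg(timescale)
  duration <- if (timescale == "short") 1e-5 else 2e5
  intervalSize <- if (timescale == "short") 2.328304971e-11 else 4.656609941
  if (is.null(nIntervals)) {
    nIntervals <- round(duration / intervalSize)
    intervalSizeOut <- intervalSize
  } else {
    intervalSizeOut <- duration / nIntervals
  }
  simulationSettings(duration = duration, nIntervals = nIntervals,
                     intervalSize = intervalSizeOut,
                     relativeTolerance = 1e-6, absoluteTolerance = 1e-12)
}

#' Construct a Scenario
#'
#' @param label unique arm label
#' @param alkF1174L apply the constitutively active ALK mutant?
#' @param stimulations named numeric vector of ligand doses (species id ->
#'   initial concentration), e.g. \code{c(EGF = 1e-3, NGF = 1e-3)}
#' @param crizotinibDose crizotinib dose, mM (0 = untreated)
#' @param gefitinibDose gefitinib dose, mM (0 = untreated)
#' @param overrides named numeric vector of extra initial-concentration
#'   overrides
#' @return a \linkS4class{Scenario}
#' @export
scenario <- function(label, alkF1174L = FALSE, stimulations = numeric(),
                     crizotinibDose = 0, gefitinibDose = 0,
                     overrides = numeric()) {
  new("Scenario", label = label, alkF1174L = alkF1174L,
      stimulations = stimulations, crizotinibDose = crizotinibDose,
      gefitinibDose = gefitinibDose, overrides = overrides)
}

## default drug kinetics used when a model does not carry its own values.
## Chosen once for the reference cascade: crizotinib inactivates mutant ALK
## fast relative to the simulated horizon and decays slowly enough to keep
## ALK suppressed; gefitinib mirrors them on EGFR.
DRUG_DEFAULTS <- list(
  crizotinib = list(Kcat = 50, Km = 1e-3, kDeg = 1e-6),
  gefitinib  = list(Kcat = 50, Km = 1e-3, kDeg = 1e-6))

#' Introduce the constitutively active ALK mutant (model surgery)
#'
#' Returns a copy of the model containing an \code{ALK_Mutated} species:
#' a constitutively active ALK that starts at a nonzero concentration (the
#' activating F1174L substitution renders the receptor ligand-independent)
#' and drives every reaction that the ligand-activated ALK drives, via
#' duplicated reactions with the mutant substituted as enzyme/modifier.
#' The input model is never modified. Applying the surgery twice is
#' idempotent.
#'
#' @param model a \linkS4class{NetworkModel} containing an ALK node
#' @param alkId id of the inactive (wild-type) ALK species
#' @param activeAlkId id of the ligand-activated ALK species
#' @param mutantId id given to the mutant species
#' @param initialConcentration mutant initial concentration; default: the
#'   wild-type inactive pool's initial concentration (constitutive
#'   activation of the expressed receptor pool)
#' @return a new \linkS4class{NetworkModel}
#' @export
applyAlkMutation <- function(model, alkId = "ALK",
                             activeAlkId = "ALK_active",
                             mutantId = "ALK_Mutated",
                             initialConcentration = NULL) {
  if (!alkId %in% names(model@species))
    stop("model has no ALK node '", alkId, "'")
  if (mutantId %in% names(model@species)) return(model)  # idempotent
  if (!activeAlkId %in% names(model@species))
    stop("model has no active ALK species '", activeAlkId, "'")
  wt <- model@species[[alkId]]
  if (is.null(initialConcentration))
    initialConcentration <- wt@initialConcentration
  mut <- speciesNode(mutantId, name = "ALK F1174L (constitutively active)",
                     compartment = wt@compartment, role = "protein",
                     activationState = "active",
                     initialConcentration = initialConcentration)
  out <- addSpecies(model, mut)
  # the mutant drives the same downstream reactions as activated ALK
  for (r in model@reactions) {
    drives <- FALSE
    r2 <- r
    if (is(r@law, "HMMLaw") && identical(r@law@enzyme, activeAlkId)) {
      r2@law@enzyme <- mutantId
      drives <- TRUE
    }
    if (is(r@law, "ModifiedHMMLaw") && identical(r@law@modifier, activeAlkId)) {
      r2@law@modifier <- mutantId
      r2@modifiers <- unique(c(setdiff(r2@modifiers, activeAlkId), mutantId))
      drives <- TRUE
    }
    if (drives) {
      r2@id <- paste0(r@id, "_mut")
      if (activeAlkId %in% r2@modifiers)
        r2@modifiers <- unique(c(setdiff(r2@modifiers, activeAlkId), mutantId))
      out <- addReaction(out, r2)
    }
  }
  out@metadata$alkF1174L <- TRUE
  out
}

## shared drug-surgery core: adds drug species + ModifiedHMM target
## inactivation (target -> product, drug as modifier) + first-order drug
## degradation into the sink.
addInhibitor <- function(model, drugId, dose, targetId, productId,
                         Kcat, Km, kDeg, categoryProduct = NULL) {
  if (dose < 0) stop("dose must be >= 0")
  if (!targetId %in% names(model@species))
    stop("model has no target species '", targetId, "'")
  sinkIds <- names(Filter(function(s) s@role == "sink", model@species))
  if (!length(sinkIds)) stop("model has no sink species")
  tgt <- model@species[[targetId]]
  out <- addSpecies(model, speciesNode(
    drugId, compartment = tgt@compartment, role = "drug",
    initialConcentration = dose))
  if (!is.null(productId) && !productId %in% names(out@species))
    out <- addSpecies(out, speciesNode(
      productId, compartment = tgt@compartment, role = "protein",
      activationState = "inactive", initialConcentration = 0))
  prod <- if (is.null(productId)) sinkIds[1] else productId
  out <- addReaction(out, reaction(
    paste0(drugId, "_inactivates_", targetId),
    substrates = targetId, products = prod, modifiers = drugId,
    law = modifiedHmmLaw(Kcat = Kcat, Km = Km, modifier = drugId),
    category = "activation/inhibition"))
  out <- addReaction(out, reaction(
    paste0(drugId, "_degradation"),
    substrates = drugId, products = sinkIds[1],
    law = massActionLaw(kDeg), category = "degradation"))
  out
}

#' Apply crizotinib treatment (model surgery)
#'
#' Adds a crizotinib drug species at the dose as its initial concentration,
#' a modified Henri-Michaelis-Menten inactivation reaction consuming the
#' constitutively active mutant ALK with crizotinib as modifier, and a
#' first-order crizotinib degradation reaction. One new species and two
#' new reactions; the input model is unmodified.
#'
#' @param model a \linkS4class{NetworkModel} containing the target species
#' @param dose crizotinib dose, mM (initial concentration)
#' @param targetId the ALK species the drug inactivates (default
#'   \code{"ALK_Mutated"}; falls back to \code{"ALK_active"} when no mutant
#'   is present)
#' @param Kcat,Km,kDeg drug kinetics; defaults are the frozen reference-
#'   cascade values (values embedded in an imported model take precedence
#'   because surgery is only applied to models lacking the drug)
#' @return a new \linkS4class{NetworkModel}
#' @export
applyCrizotinib <- function(model, dose,
                            targetId = if ("ALK_Mutated" %in% names(model@species))
                              "ALK_Mutated" else "ALK_active",
                            Kcat = DRUG_DEFAULTS$crizotinib$Kcat,
                            Km = DRUG_DEFAULTS$crizotinib$Km,
                            kDeg = DRUG_DEFAULTS$crizotinib$kDeg) {
  addInhibitor(model, "Crizotinib", dose, targetId, productId = NULL,
               Kcat = Kcat, Km = Km, kDeg = kDeg)
}

#' Apply gefitinib treatment (model surgery)
#'
#' Adds a gefitinib drug species at the dose, a modified
#' Henri-Michaelis-Menten reaction converting free EGFR to an inhibited
#' EGFR species with gefitinib as modifier, and first-order gefitinib
#' degradation. Two new species (gefitinib, and the inhibited receptor if
#' absent) and two new reactions.
#'
#' @param model a \linkS4class{NetworkModel} containing free EGFR
#' @param dose gefitinib dose, mM
#' @param targetId the free EGFR species id
#' @param inhibitedId id for the inhibited receptor species
#' @param Kcat,Km,kDeg drug kinetics (see \code{\link{applyCrizotinib}})
#' @return a new \linkS4class{NetworkModel}
#' @export
applyGefitinib <- function(model, dose, targetId = "EGFR_free",
                           inhibitedId = "EGFR_inhibited",
                           Kcat = DRUG_DEFAULTS$gefitinib$Kcat,
                           Km = DRUG_DEFAULTS$gefitinib$Km,
                           kDeg = DRUG_DEFAULTS$gefitinib$kDeg) {
  addInhibitor(model, "Gefitinib", dose, targetId, productId = inhibitedId,
               Kcat = Kcat, Km = Km, kDeg = kDeg)
}

#' Realize a Scenario as a concrete model
#'
#' Applies, in order: initial-concentration overrides, ligand stimulations,
#' the ALK mutation, crizotinib, gefitinib. Pure: the base model is never
#' modified.
#'
#' @param base the base \linkS4class{NetworkModel}
#' @param sc a \linkS4class{Scenario}
#' @return a new \linkS4class{NetworkModel}
#' @export
buildScenarioModel <- function(base, sc) {
  m <- base
  if (length(sc@overrides)) m <- setInitialConcentrations(m, sc@overrides)
  if (length(sc@stimulations))
    m <- setInitialConcentrations(m, sc@stimulations)
  if (sc@alkF1174L) m <- applyAlkMutation(m)
  if (sc@crizotinibDose > 0) m <- applyCrizotinib(m, sc@crizotinibDose)
  if (sc@gefitinibDose > 0) m <- applyGefitinib(m, sc@gefitinibDose)
  m
}

#' Simulate and compare experimental arms
#'
#' Simulates every scenario over the shared base model with identical
#' settings and summarizes the readout species by endpoint concentration
#' and trapezoidal AUC. Arms are independent; a failing arm is reported in
#' the status column without aborting the others.
#'
#' @param base the shared base \linkS4class{NetworkModel}
#' @param scenarios list of \linkS4class{Scenario} with unique labels
#' @param settings shared \linkS4class{SimulationSettings}
#' @param readoutId readout species id (default: the base model's output
#'   species)
#' @return an \linkS4class{ArmComparison}
#' @examples
#' \donttest{
#' cascade <- referenceCascade()
#' arms <- list(
#'   scenario("control", alkF1174L = TRUE),
#'   scenario("crizotinib", alkF1174L = TRUE, crizotinibDose = 1.4e-3))
#' cmp <- runArms(cascade, arms,
#'                simulationSettings(duration = 2e5, nIntervals = 200))
#' armTable(cmp)
#' }
#' @export
runArms <- function(base, scenarios, settings,
                    readoutId = outputSpecies(base)) {
  labels <- vapply(scenarios, function(s) s@label, "")
  if (anyDuplicated(labels))
    stop("duplicated arm labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (is.na(readoutId)) stop("no readout species designated")
  rows <- vector("list", length(scenarios))
  trajs <- setNames(vector("list", length(scenarios)), labels)
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    res <- tryCatch({
      m <- buildScenarioModel(base, sc)
      tr <- simulateNetwork(m, settings)
      y <- speciesTrajectory(tr, readoutId)
      list(traj = tr, endpoint = y[length(y)],
           auc = trajectoryAUC(tr, readoutId), status = "ok")
    }, error = function(e) list(traj = e, endpoint = NA_real_,
                                auc = NA_real_,
                                status = conditionMessage(e)))
    trajs[[i]] <- res$traj
    rows[[i]] <- data.frame(arm = sc@label, endpoint = res$endpoint,
                            auc = res$auc, status = res$status,
                            stringsAsFactors = FALSE)
  }
  new("ArmComparison", table = do.call(rbind, rows), trajectories = trajs,
      settings = settings)
}

#' Accessors for ArmComparison
#'
#' @param x an \linkS4class{ArmComparison}
#' @param path optional TSV path for \code{armTable}
#' @return \code{armTable}: data.frame (arm, endpoint, auc, status);
#'   \code{armTrajectories}: named list of \linkS4class{Trajectory}
#' @export
armTable <- function(x, path = NULL) {
  if (!is.null(path)) {
    write.table(x@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(x@table))
  }
  x@table
}

#' @rdname armTable
#' @export
armTrajectories <- function(x) x@trajectories
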