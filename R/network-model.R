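#' Construct network building blocks
#'
#' Convenience constructors for \linkS4class{Compartment},
#' \linkS4class{Species}, \linkS4class{Reaction} and the three kinetic law
#' variants. Ids are used as cross-references throughout a
#' \linkS4class{NetworkModel}; no object holds a live pointer to another,
#' which keeps models serializable and model surgery pure.
#'
#' @param id unique identifier
#' @param name display name (defaults to id)
#' @param volume compartment volume, nominal mL
#' @return the corresponding S4 object
#' @examples
#' cyt <- compartment("cytoplasm", "Neuroblastoma Cell Cytoplasm")
#' alk <- speciesNode("ALK", compartment = "cytoplasm", role = "protein",
#'                    activationState = "inactive", initialConcentration = 1,
#'                    counterpart = "ALK_active")
#' @export
compartment <- function(id, name = id, volume = 1)
  new("Compartment", id = id, name = name, volume = volume)

#' @rdname compartment
#' @param compartment id of the containing compartment
#' @param role species role (gene, mRNA, protein, simple molecule, drug, sink)
#' @param activationState inactive, active, or not_applicable
#' @param initialConcentration non-negative initial concentration, mmol/mL
#' @param counterpart id of the activated form, if any
#' @export
speciesNode <- function(id, name = id, compartment = "cell",
                        role = "protein",
                        activationState = "not_applicable",
                        initialConcentration = 0,
                        counterpart = NA_character_)
  new("Species", id = id, name = name, compartment = compartment,
      role = role, activationState = activationState,
      initialConcentration = initialConcentration, counterpart = counterpart)

#' @rdname compartment
#' @param k1 forward mass-action rate constant (>= 0)
#' @param k2 optional reverse rate constant (NA = irreversible)
#' @export
massActionLaw <- function(k1, k2 = NA_real_)
  new("MassActionLaw", k1 = k1, k2 = k2)

#' @rdname compartment
#' @param Kcat catalytic constant (Vmax when no enzyme is referenced)
#' @param Km Michaelis constant (> 0)
#' @param enzyme optional enzyme species id
#' @export
hmmLaw <- function(Kcat, Km, enzyme = NA_character_)
  new("HMMLaw", Kcat = Kcat, Km = Km, enzyme = enzyme)

#' @rdname compartment
#' @param modifier modifier species id whose concentration scales the rate
#' @export
modifiedHmmLaw <- function(Kcat, Km, modifier)
  new("ModifiedHMMLaw", Kcat = Kcat, Km = Km, modifier = modifier)

#' @rdname compartment
#' @param substrates named numeric vector (species id -> stoichiometry), or
#'   character vector of ids (stoichiometry 1)
#' @param products as \code{substrates}
#' @param modifiers character vector of modifier species ids
#' @param law a \linkS4class{KineticLaw}
#' @param category reaction category
#' @param citations PubMed ids (annotation only)
#' @export
reaction <- function(id, substrates = character(), products = character(),
                     modifiers = character(), law, category = "activation/inhibition",
                     citations = character()) {
  asStoich <- function(x) {
    if (is.character(x)) setNames(rep(1, length(x)), x)
    else if (is.numeric(x)) x
    else stop("substrates/products must be character or named numeric")
  }
  new("Reaction", id = id, substrates = asStoich(substrates),
      products = asStoich(products), modifiers = modifiers, law = law,
      category = category, citations = citations)
}

#' Assemble a NetworkModel
#'
#' @param compartments list of \linkS4class{Compartment}
#' @param species list of \linkS4class{Species}
#' @param reactions list of \linkS4class{Reaction}
#' @param outputSpecies id of the readout node (e.g. the PD-L1 mRNA species)
#' @param metadata free-form provenance list
#' @return a \linkS4class{NetworkModel}
#' @seealso \code{\link{validateNetwork}}
#' @export
networkModel <- function(compartments, species, reactions,
                         outputSpecies = NA_character_, metadata = list()) {
  nameBy <- function(lst) setNames(lst, vapply(lst, function(x) x@id, ""))
  new("NetworkModel", compartments = nameBy(compartments),
      species = nameBy(species), reactions = nameBy(reactions),
      outputSpecies = outputSpecies, metadata = metadata)
}

#' Accessors for NetworkModel
#'
#' @param x a \linkS4class{NetworkModel}
#' @param value replacement value
#' @param ... passed on (\code{initialState} accepts \code{overrides}, a
#'   named numeric vector of initial-concentration overrides)
#' @name NetworkModel-accessors
#' @aliases nSpecies nReactions speciesIds reactionIds outputSpecies
#'   outputSpecies<- initialState
NULL

#' @rdname NetworkModel-accessors
#' @export
setMethod("nSpecies", "NetworkModel", function(x) length(x@species))

#' @rdname NetworkModel-accessors
#' @export
setMethod("nReactions", "NetworkModel", function(x) length(x@reactions))

#' @rdname NetworkModel-accessors
#' @export
setMethod("speciesIds", "NetworkModel", function(x) names(x@species))

#' @rdname NetworkModel-accessors
#' @export
setMethod("reactionIds", "NetworkModel", function(x) names(x@reactions))

#' @rdname NetworkModel-accessors
#' @export
setMethod("outputSpecies", "NetworkModel", function(x) x@outputSpecies)

#' @rdname NetworkModel-accessors
#' @export
setReplaceMethod("outputSpecies", "NetworkModel", function(x, value) {
  if (!value %in% names(x@species))
    stop("output species '", value, "' is not in the model")
  x@outputSpecies <- value
  x
})

#' @rdname NetworkModel-accessors
#' @export
setMethod("initialState", "NetworkModel", function(x, overrides = NULL) {
  y <- vapply(x@species, function(s) s@initialConcentration, 0)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(y))
    if (length(bad))
      stop("override for unknown species: ", paste(bad, collapse = ", "))
    y[names(overrides)] <- overrides
  }
  y
})

#' Look up a species or reaction by id
#'
#' @param model a \linkS4class{NetworkModel}
#' @param id species or reaction id
#' @return the \linkS4class{Species} / \linkS4class{Reaction}
#' @export
getSpecies <- function(model, id) {
  if (!id %in% names(model@species))
    stop("unknown species id '", id, "'")
  model@species[[id]]
}

#' @rdname getSpecies
#' @export
getReaction <- function(model, id) {
  if (!id %in% names(model@reactions))
    stop("unknown reaction id '", id, "'")
  model@reactions[[id]]
}

#' Add or replace model elements (pure: returns a modified copy)
#'
#' @param model a \linkS4class{NetworkModel}
#' @param x a \linkS4class{Species} or \linkS4class{Reaction}
#' @return a new \linkS4class{NetworkModel}
#' @export
addSpecies <- function(model, x) {
  stopifnot(is(x, "Species"))
  model@species[[x@id]] <- x
  model
}

#' @rdname addSpecies
#' @export
addReaction <- function(model, x) {
  stopifnot(is(x, "Reaction"))
  model@reactions[[x@id]] <- x
  model
}

#' Set initial concentrations (pure)
#'
#' @param model a \linkS4class{NetworkModel}
#' @param concs named numeric vector of species id -> initial concentration
#' @return a new \linkS4class{NetworkModel}
#' @export
setInitialConcentrations <- function(model, concs) {
  bad <- setdiff(names(concs), names(model@species))
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "))
  for (id in names(concs))
    model@species[[id]]@initialConcentration <- unname(concs[[id]])
  model
}

## all species ids taking part in a reaction (incl. enzyme/modifier of law)
reactionParticipants <- function(r) {
  ids <- c(names(r@substrates), names(r@products), r@modifiers)
  law <- r@law
  if (is(law, "HMMLaw") && !is.na(law@enzyme)) ids <- c(ids, law@enzyme)
  if (is(law, "ModifiedHMMLaw")) ids <- c(ids, law@modifier)
  unique(ids)
}

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel:", length(object@compartments), "compartment(s),",
      length(object@species), "species,",
      length(object@reactions), "reactions\n")
  if (!is.na(object@outputSpecies))
    cat("  readout:", object@outputSpecies, "\n")
  vars <- table(vapply(object@reactions, function(r) class(r@law), ""))
  if (length(vars))
    cat("  laws:", paste(names(vars), vars, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@speciesOrder), "species x",
      length(object@times), "time points, t in [0,",
      max(object@times), "] s\n")
})

setMethod("show", "SensitivityReport", function(object) {
  cat("SensitivityReport for", object@target, "(", object@scaling, ",",
      object@readout, "readout ):", nrow(object@entries), "entries\n")
  print(head(object@entries[order(-abs(object@entries$sensitivity)), ], 5))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", if (object@converged) "converged" else "NOT converged",
      "in", object@iterations, "iterations, RSS =",
      format(object@rss, digits = 6), "\n")
  print(object@estimates)
})

setMethod("show", "ArmComparison", function(object) {
  cat("ArmComparison (", nrow(object@table), "arms )\n")
  print(object@table)
})

setMethod("show", "ImportReport", function(object) {
  cat("ImportReport:", object@nSpecies, "species,", object@nReactions,
      "reactions\n  laws:",
      paste(names(object@lawCounts), object@lawCounts, sep = "=",
            collapse = ", "), "\n")
  if (length(object@unmapped))
    cat("  unmapped (opaque):", paste(object@unmapped, collapse = ", "), "\n")
  for (w in object@warnings) cat("  warning:", w, "\n")
})

#' @rdname exprScale
#' @param x an \linkS4class{ExpressionMatrix}
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@exprScale)
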