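NATIVE_SCHEMA <- "pdl1net-network/1"

lawToList <- function(law) {
  if (is(law, "MassActionLaw")) {
    out <- list(variant = "MassAction", k1 = law@k1)
    if (!is.na(law@k2)) out$k2 <- law@k2
    out
  } else if (is(law, "HMMLaw")) {
    out <- list(variant = "HMM", Kcat = law@Kcat, Km = law@Km)
    if (!is.na(law@enzyme)) out$enzyme <- law@enzyme
    out
  } else if (is(law, "ModifiedHMMLaw")) {
    list(variant = "ModifiedHMM", Kcat = law@Kcat, Km = law@Km,
         modifier = law@modifier)
  } else if (is(law, "OpaqueLaw")) {
    list(variant = "Opaque", expression = law@expression,
         parameters = as.list(law@parameters))
  } else stop("unknown law class ", class(law))
}

lawFromList <- function(x) {
  switch(x$variant,
         MassAction = massActionLaw(x$k1, if (is.null(x$k2)) NA_real_ else x$k2),
         HMM = hmmLaw(x$Kcat, x$Km,
                      if (is.null(x$enzyme)) NA_character_ else x$enzyme),
         ModifiedHMM = modifiedHmmLaw(x$Kcat, x$Km, x$modifier),
         Opaque = new("OpaqueLaw", expression = x$expression,
                      parameters = setNames(as.numeric(unlist(x$parameters)),
                                            names(x$parameters))),
         stop("unknown law variant '", x$variant, "'"))
}

#' Native network format (versioned YAML)
#'
#' Writes/reads a \linkS4class{NetworkModel} as a structured, versioned
#' YAML document listing compartments, species (id, role, state, initial
#' concentration, counterpart), and reactions (substrates, products,
#' modifiers, law variant with constants, category, citations). The
#' round-trip write-then-read is the identity up to element ordering;
#' opaque imported rate expressions survive as their expression text.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param path file path
#' @return \code{writeNetwork}: the path, invisibly; \code{readNetwork}:
#'   a \linkS4class{NetworkModel}
#' @export
writeNetwork <- function(model, path) {
  doc <- list(
    schema = NATIVE_SCHEMA,
    compartments = lapply(unname(model@compartments), function(cp)
      list(id = cp@id, name = cp@name, volume = cp@volume)),
    species = lapply(unname(model@species), function(s) {
      out <- list(id = s@id, name = s@name, compartment = s@compartment,
                  role = s@role, activation_state = s@activationState,
                  initial_concentration = s@initialConcentration)
      if (!is.na(s@counterpart)) out$counterpart <- s@counterpart
      out
    }),
    reactions = lapply(unname(model@reactions), function(r) {
      out <- list(id = r@id,
                  substrates = as.list(r@substrates),
                  products = as.list(r@products),
                  modifiers = as.list(r@modifiers),
                  law = lawToList(r@law), category = r@category)
      if (length(r@citations)) out$citations <- as.list(r@citations)
      out
    }),
    metadata = model@metadata)
  if (!is.na(model@outputSpecies)) doc$output_species <- model@outputSpecies
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, NATIVE_SCHEMA))
    stop("schema version mismatch: expected '", NATIVE_SCHEMA,
         "', found '", doc$schema %||% "<none>", "'")
  comps <- lapply(doc$compartments, function(x)
    compartment(x$id, x$name %||% x$id, x$volume %||% 1))
  sps <- lapply(doc$species, function(x)
    speciesNode(x$id, name = x$name %||% x$id,
                compartment = x$compartment,
                role = x$role %||% "protein",
                activationState = x$activation_state %||% "not_applicable",
                initialConcentration = x$initial_concentration %||% 0,
                counterpart = x$counterpart %||% NA_character_))
  rxs <- lapply(doc$reactions, function(x) {
    toStoich <- function(v)
      if (length(v)) setNames(as.numeric(unlist(v)), names(v)) else numeric()
    reaction(x$id, substrates = toStoich(x$substrates),
             products = toStoich(x$products),
             modifiers = as.character(unlist(x$modifiers)),
             law = lawFromList(x$law),
             category = x$category %||% "activation/inhibition",
             citations = as.character(unlist(x$citations)))
  })
  networkModel(comps, sps, rxs,
               outputSpecies = doc$output_species %||% NA_character_,
               metadata = doc$metadata %||% list())
}
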