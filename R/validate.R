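#' Validate the structural invariants of a network model
#'
#' Checks every cross-reference and domain rule a well-formed model must
#' satisfy and returns a character vector of violation descriptions, each
#' naming the offending element and the broken rule. An empty vector means
#' the model is valid. Validation reports; it never throws, so broken
#' models can be inspected.
#'
#' Checked rules:
#' \itemize{
#'   \item at least one compartment; positive volumes; unique ids
#'   \item species reference existing compartments; non-negative initial
#'     concentrations; counterpart references resolve
#'   \item an active-state species that is the counterpart of an inactive
#'     one starts at concentration zero (scenario overrides are applied at
#'     simulation time, not stored in the model)
#'   \item reactions reference existing species; a ModifiedHMM law's
#'     modifier appears in the reaction's modifier list; an HMM enzyme
#'     resolves
#'   \item degradation reactions have exactly one substrate and produce
#'     only sink-role species
#'   \item transcription reactions produce an mRNA-role species;
#'     translation reactions consume or are modified by an mRNA-role
#'     species and produce a protein-role species
#'   \item Km strictly positive, rate constants non-negative (law validity)
#'   \item the output species, when set, is a member of the species list
#' }
#'
#' @param model a \linkS4class{NetworkModel}
#' @return character vector of violations; \code{character(0)} if valid
#' @examples
#' m <- networkModel(
#'   compartments = list(compartment("cell")),
#'   species = list(
#'     speciesNode("A", compartment = "cell", initialConcentration = 1),
#'     speciesNode("sink", compartment = "cell", role = "sink")),
#'   reactions = list(
#'     reaction("deg_A", substrates = "A", products = "sink",
#'              law = massActionLaw(0.5), category = "degradation")),
#'   outputSpecies = "A")
#' validateNetwork(m)  # character(0)
#' @export
validateNetwork <- function(model) {
  v <- character()
  say <- function(...) sprintf(...)

  if (length(model@compartments) == 0L)
    v <- c(v, "model: at least one compartment is required")
  for (cp in model@compartments) {
    ok <- validObject(cp, test = TRUE)
    if (!isTRUE(ok))
      v <- c(v, say("compartment '%s': %s", cp@id,
                    paste(ok, collapse = "; ")))
  }

  spIds <- names(model@species)
  if (anyDuplicated(spIds))
    v <- c(v, say("model: duplicated species ids: %s",
                  paste(unique(spIds[duplicated(spIds)]), collapse = ", ")))
  if (anyDuplicated(names(model@reactions)))
    v <- c(v, "model: duplicated reaction ids")

  counterpartOf <- character()   # active id -> inactive id
  for (s in model@species) {
    ok <- validObject(s, test = TRUE)
    if (!isTRUE(ok))
      v <- c(v, say("species '%s': %s", s@id, paste(ok, collapse = "; ")))
    if (!s@compartment %in% names(model@compartments))
      v <- c(v, say("species '%s': unknown compartment '%s'",
                    s@id, s@compartment))
    if (!is.na(s@counterpart)) {
      if (!s@counterpart %in% spIds)
        v <- c(v, say("species '%s': counterpart '%s' does not resolve",
                      s@id, s@counterpart))
      else if (s@activationState == "inactive")
        counterpartOf[s@counterpart] <- s@id
    }
  }

  # active counterparts start at zero (overridden only via Scenario)
  for (actId in names(counterpartOf)) {
    act <- model@species[[actId]]
    if (act@activationState == "active" && act@initialConcentration != 0)
      v <- c(v, say(paste0("species '%s': activated counterpart of '%s' ",
                           "must have initial concentration 0 ",
                           "(zero-initialization rule)"),
                    actId, counterpartOf[[actId]]))
  }

  roleOf <- vapply(model@species, function(s) s@role, "")
  for (r in model@reactions) {
    ok <- validObject(r, test = TRUE)
    if (!isTRUE(ok))
      v <- c(v, say("reaction '%s': %s", r@id, paste(ok, collapse = "; ")))
    lawOk <- validObject(r@law, test = TRUE)
    if (!isTRUE(lawOk))
      v <- c(v, say("reaction '%s' law: %s", r@id,
                    paste(lawOk, collapse = "; ")))
    missing <- setdiff(reactionParticipants(r), spIds)
    if (length(missing))
      v <- c(v, say("reaction '%s': unresolved species reference(s): %s",
                    r@id, paste(missing, collapse = ", ")))
    if (is(r@law, "ModifiedHMMLaw") && !is.na(r@law@modifier) &&
        !r@law@modifier %in% r@modifiers)
      v <- c(v, say(paste0("reaction '%s': ModifiedHMM modifier '%s' is ",
                           "not in the reaction's modifier list"),
                    r@id, r@law@modifier))
    if (length(missing)) next  # role checks need resolvable references
    if (r@category == "degradation") {
      if (length(r@substrates) != 1L)
        v <- c(v, say("reaction '%s': degradation must have exactly one substrate",
                      r@id))
      prodRoles <- roleOf[names(r@products)]
      if (length(r@products) == 0L || any(prodRoles != "sink"))
        v <- c(v, say("reaction '%s': degradation must produce only the sink",
                      r@id))
    }
    if (r@category == "transcription" &&
        !any(roleOf[names(r@products)] == "mRNA"))
      v <- c(v, say("reaction '%s': transcription must produce an mRNA species",
                    r@id))
    if (r@category == "translation") {
      inputs <- c(names(r@substrates), r@modifiers)
      if (!any(roleOf[inputs] == "mRNA"))
        v <- c(v, say(paste0("reaction '%s': translation must consume or be ",
                             "modified by an mRNA species"), r@id))
      if (!any(roleOf[names(r@products)] == "protein"))
        v <- c(v, say("reaction '%s': translation must produce a protein species",
                      r@id))
    }
  }

  if (!is.na(model@outputSpecies) && !model@outputSpecies %in% spIds)
    v <- c(v, say("model: output species '%s' is not a member of species",
                  model@outputSpecies))
  v
}
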