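## enumerate (reaction, parameter, value) triples over a model's laws
enumerateParameters <- function(model) {
  out <- list()
  for (r in model@reactions) {
    law <- r@law
    if (is(law, "MassActionLaw")) {
      out[[length(out) + 1L]] <- list(reaction = r@id, parameter = "k1",
                                      value = law@k1)
      if (!is.na(law@k2))
        out[[length(out) + 1L]] <- list(reaction = r@id, parameter = "k2",
                                        value = law@k2)
    } else if (is(law, "HMMLaw") || is(law, "ModifiedHMMLaw")) {
      out[[length(out) + 1L]] <- list(reaction = r@id, parameter = "Kcat",
                                      value = law@Kcat)
      out[[length(out) + 1L]] <- list(reaction = r@id, parameter = "Km",
                                      value = law@Km)
    } else if (is(law, "OpaqueLaw")) {
      for (p in names(law@parameters))
        out[[length(out) + 1L]] <- list(reaction = r@id, parameter = p,
                                        value = law@parameters[[p]])
    }
  }
  out
}

## set one law parameter (pure)
setLawParameter <- function(model, reactionId, parameter, value) {
  r <- getReaction(model, reactionId)
  law <- r@law
  if (is(law, "OpaqueLaw")) {
    if (!parameter %in% names(law@parameters))
      stop("reaction '", reactionId, "' has no parameter '", parameter, "'")
    law@parameters[[parameter]] <- value
  } else {
    if (!parameter %in% slotNames(law))
      stop("reaction '", reactionId, "' has no parameter '", parameter, "'")
    slot(law, parameter) <- value
  }
  r@law <- law
  model@reactions[[reactionId]] <- r
  model
}

#' Restrict a network to a kept species set
#'
#' Retains only the reactions all of whose participants (substrates,
#' products, modifiers, and any enzyme/modifier referenced by the law) are
#' in the kept set, and drops species outside the set. Sink species are
#' always kept so degradation reactions survive. Used to build the reduced
#' network on which sensitivity analysis is run when the full network has
#' no reachable steady state.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param keep character vector of species ids to keep; must contain the
#'   output species
#' @return a new, smaller \linkS4class{NetworkModel} (never larger)
#' @export
simplifyNetwork <- function(model, keep) {
  bad <- setdiff(keep, names(model@species))
  if (length(bad))
    stop("keep list contains unknown species: ", paste(bad, collapse = ", "))
  if (!is.na(model@outputSpecies) && !model@outputSpecies %in% keep)
    stop("the output species '", model@outputSpecies,
         "' must be in the keep list")
  sinks <- names(Filter(function(s) s@role == "sink", model@species))
  keep <- union(keep, sinks)
  model@reactions <- Filter(
    function(r) all(reactionParticipants(r) %in% keep), model@reactions)
  model@species <- model@species[intersect(names(model@species), keep)]
  model
}

#' Local sensitivity analysis of a readout species
#'
#' Central finite-difference sensitivity of the readout (endpoint
#' concentration at the settings' duration, or AUC) with respect to every
#' kinetic parameter (k1, k2, Kcat, Km) of every reaction:
#' s = (c(p0(1+delta)) - c(p0(1-delta))) / (2 delta p0). The scaled
#' variant multiplies by p0 / c(p0), giving dimensionless elasticities.
#' Parameters whose baseline is 0 cannot be perturbed relatively and are
#' skipped. A simulation failure at a perturbed point flags that entry as
#' failed rather than reporting a silent zero. Positive values mean the
#' parameter induces the readout; negative values mean it represses it.
#'
#' @param model a valid \linkS4class{NetworkModel}
#' @param target readout species id (default: the model's output species)
#' @param settings a \linkS4class{SimulationSettings}
#' @param delta relative perturbation (default 0.01)
#' @param scaling "unscaled" (default) or "scaled"
#' @param readout "endpoint" (default) or "auc"
#' @return a \linkS4class{SensitivityReport}
#' @export
localSensitivities <- function(model, target = outputSpecies(model),
                               settings, delta = 0.01,
                               scaling = c("unscaled", "scaled"),
                               readout = c("endpoint", "auc")) {
  scaling <- match.arg(scaling)
  readout <- match.arg(readout)
  if (is.na(target)) stop("no target species designated")
  measure <- function(m) {
    tr <- simulateNetwork(m, settings)
    if (readout == "endpoint")
      speciesTrajectory(tr, target)[settings@nIntervals + 1L]
    else trajectoryAUC(tr, target)
  }
  c0 <- measure(model)
  if (!is.finite(c0))
    stop("baseline readout is not finite; cannot compute sensitivities")
  params <- enumerateParameters(model)
  rows <- lapply(params, function(p) {
    if (p$value <= 0)
      return(data.frame(reaction = p$reaction, parameter = p$parameter,
                        baseline = p$value, sensitivity = NA_real_,
                        failed = FALSE, skipped = TRUE))
    s <- tryCatch({
      cp <- measure(setLawParameter(model, p$reaction, p$parameter,
                                    p$value * (1 + delta)))
      cm <- measure(setLawParameter(model, p$reaction, p$parameter,
                                    p$value * (1 - delta)))
      val <- (cp - cm) / (2 * delta * p$value)
      if (scaling == "scaled") val <- val * p$value / c0
      list(val = val, failed = FALSE)
    }, error = function(e) list(val = NA_real_, failed = TRUE))
    data.frame(reaction = p$reaction, parameter = p$parameter,
               baseline = p$value, sensitivity = s$val, failed = s$failed,
               skipped = FALSE)
  })
  entries <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(entries))
    entries <- data.frame(reaction = character(), parameter = character(),
                          baseline = numeric(), sensitivity = numeric(),
                          failed = logical(), skipped = logical())
  new("SensitivityReport", entries = entries, target = target,
      scaling = scaling, readout = readout, baselineValue = c0)
}

#' Rank parameters by sensitivity magnitude
#'
#' Orders the report's entries by |sensitivity| descending; ties are broken
#' lexicographically by (reaction id, parameter name). Skipped and failed
#' entries are dropped.
#'
#' @param report a \linkS4class{SensitivityReport}
#' @param topN number of rows to return (default: all)
#' @return data.frame of the top entries
#' @export
rankParameters <- function(report, topN = Inf) {
  e <- report@entries
  e <- e[!e$failed & !e$skipped & is.finite(e$sensitivity), , drop = FALSE]
  ord <- order(-abs(e$sensitivity), e$reaction, e$parameter)
  e <- e[ord, , drop = FALSE]
  rownames(e) <- NULL
  head(e, topN)
}

#' Export a sensitivity report as a table
#'
#' @param report a \linkS4class{SensitivityReport}
#' @param path optional TSV path
#' @return data.frame (reaction, parameter, baseline, sensitivity, scaled)
#' @export
sensitivityToTable <- function(report, path = NULL) {
  df <- report@entries
  df$scaled <- report@scaling == "scaled"
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
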