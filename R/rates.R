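#' Kinetic rate laws: numeric evaluation
#'
#' The three rate laws used by the network engine. \code{massActionRate}
#' returns the net rate k1 * prod(substrates) - k2 * prod(products) (k2
#' treated as 0 when absent). \code{hmmRate} is the Henri-Michaelis-Menten
#' rate Kcat * E * S / (Km + S), bounded above by Kcat * E and monotone
#' non-decreasing in S; with no enzyme species the enzyme concentration
#' defaults to 1 so Kcat plays the role of Vmax. \code{modifiedHmmRate} is
#' the modifier-proportional variant Kcat * M * S / (Km + S) used for
#' drug-mediated inactivation: linear (homogeneous of degree 1) in the
#' modifier concentration M.
#'
#' @param k1 forward rate constant (>= 0)
#' @param substrateConcs non-negative substrate concentrations
#' @param k2 optional reverse rate constant (>= 0); NULL/NA = irreversible
#' @param productConcs non-negative product concentrations (reverse term)
#' @return the rate (concentration/time)
#' @examples
#' massActionRate(2, 3)                      # 6
#' hmmRate(Kcat = 4, Km = 2, S = 2)          # half saturation: 2
#' modifiedHmmRate(Kcat = 2, Km = 1, modifierConc = 3, S = 1)  # 3
#' @export
massActionRate <- function(k1, substrateConcs, k2 = NULL,
                           productConcs = numeric()) {
  if (k1 < 0 || (!is.null(k2) && !is.na(k2) && k2 < 0))
    stop("rate constants must be non-negative")
  if (any(substrateConcs < 0) || any(productConcs < 0))
    stop("concentrations must be non-negative")
  fwd <- k1 * prod(substrateConcs)
  rev <- if (is.null(k2) || is.na(k2)) 0 else k2 * prod(productConcs)
  fwd - rev
}

#' @rdname massActionRate
#' @param Kcat catalytic constant (>= 0)
#' @param Km Michaelis constant (> 0)
#' @param S substrate concentration (>= 0)
#' @param enzymeConc enzyme concentration (1 when no enzyme species)
#' @export
hmmRate <- function(Kcat, Km, S, enzymeConc = 1) {
  if (Km <= 0) stop("Km must be strictly positive")
  if (Kcat < 0) stop("Kcat must be non-negative")
  if (S < 0 || enzymeConc < 0)
    stop("concentrations must be non-negative")
  Kcat * enzymeConc * S / (Km + S)
}

#' @rdname massActionRate
#' @param modifierConc modifier concentration M (>= 0)
#' @export
modifiedHmmRate <- function(Kcat, Km, modifierConc, S) {
  if (Km <= 0) stop("Km must be strictly positive")
  if (Kcat < 0) stop("Kcat must be non-negative")
  if (S < 0 || modifierConc < 0)
    stop("concentrations must be non-negative")
  Kcat * modifierConc * S / (Km + S)
}

## Evaluate a reaction's rate at a named concentration state.
## HMM substrate concentration is the product of substrate concentrations
## (with unit stoichiometry this is the single substrate's concentration).
## Opaque laws are evaluated in an environment exposing species ids and
## law parameters by name.
evalReactionRate <- function(r, state) {
  law <- r@law
  sub <- if (length(r@substrates))
    prod(state[names(r@substrates)]^r@substrates) else 1
  if (is(law, "MassActionLaw")) {
    pr <- if (length(r@products))
      prod(state[names(r@products)]^r@products) else 1
    fwd <- law@k1 * sub
    rev <- if (is.na(law@k2)) 0 else law@k2 * pr
    return(fwd - rev)
  }
  if (is(law, "HMMLaw")) {
    e <- if (is.na(law@enzyme)) 1 else state[[law@enzyme]]
    return(law@Kcat * e * sub / (law@Km + sub))
  }
  if (is(law, "ModifiedHMMLaw")) {
    m <- state[[law@modifier]]
    return(law@Kcat * m * sub / (law@Km + sub))
  }
  if (is(law, "OpaqueLaw")) {
    env <- list2env(as.list(state))
    for (p in names(law@parameters)) assign(p, law@parameters[[p]], envir = env)
    return(eval(str2lang(law@expression), envir = env))
  }
  stop("unknown kinetic law class: ", class(law))
}
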