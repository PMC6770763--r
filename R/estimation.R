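#' Seed initial concentrations from relative expression data
#'
#' Maps relative expression values (for instance, RNA-seq abundances of a
#' tumor cohort) onto the initial concentrations of the corresponding
#' inactive species: species X receives scale * expression(gene(X)), and
#' its activated counterpart is reset to zero. Unmapped species are left
#' untouched. Mapping onto an active-state species is an error, because
#' expression measures the expressed (inactive) pool; activated fractions
#' are produced by the dynamics.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param expression named numeric vector of non-negative relative
#'   expression values, names = gene symbols
#' @param mapping named character vector gene -> species id; by default
#'   genes are matched to species ids directly
#' @param scale single positive (or zero) global scale factor
#' @return a new \linkS4class{NetworkModel}
#' @examples
#' \donttest{
#' m <- referenceCascade()
#' m2 <- applyExpressionInitials(m, c(ALK = 2, EGFR_free = 4), scale = 0.5)
#' getSpecies(m2, "ALK")@initialConcentration   # 1
#' }
#' @export
applyExpressionInitials <- function(model, expression,
                                    mapping = setNames(names(expression),
                                                       names(expression)),
                                    scale = 1) {
  if (any(expression < 0)) stop("expression values must be non-negative")
  if (scale < 0) stop("scale must be non-negative")
  for (gene in names(mapping)) {
    spId <- mapping[[gene]]
    if (!gene %in% names(expression)) next
    if (!spId %in% names(model@species))
      stop("mapping targets unknown species '", spId, "'")
    sp <- model@species[[spId]]
    if (sp@activationState == "active")
      stop("mapping may target inactive-state species only; '", spId,
           "' is active")
    model@species[[spId]]@initialConcentration <-
      scale * unname(expression[[gene]])
    if (!is.na(sp@counterpart) &&
        sp@counterpart %in% names(model@species))
      model@species[[sp@counterpart]]@initialConcentration <- 0
  }
  model
}

#' Define a kinetic parameter fitting problem
#'
#' @param model the \linkS4class{NetworkModel} whose parameters are fitted
#' @param freeParameters data.frame with columns reaction, parameter,
#'   lower, upper, guess (0 <= lower < upper, guess within bounds)
#' @param observations data.frame with columns species, time, value and
#'   optionally weight (default 1)
#' @param settings \linkS4class{SimulationSettings} supplying solver
#'   tolerances (observation times define the sample grid)
#' @return a list of class "FitProblem"
#' @export
fitProblem <- function(model, freeParameters, observations, settings) {
  need <- c("reaction", "parameter", "lower", "upper", "guess")
  if (!all(need %in% names(freeParameters)))
    stop("freeParameters needs columns: ", paste(need, collapse = ", "))
  with(freeParameters, {
    if (any(lower < 0) || any(lower >= upper))
      stop("bounds must satisfy 0 <= lower < upper")
    if (any(guess < lower | guess > upper))
      stop("initial guesses must lie within bounds")
  })
  if (!all(c("species", "time", "value") %in% names(observations)))
    stop("observations need columns species, time, value")
  if (is.null(observations$weight)) observations$weight <- 1
  bad <- setdiff(unique(observations$species), names(model@species))
  if (length(bad))
    stop("observations reference unknown species: ",
         paste(bad, collapse = ", "))
  if (nrow(observations) < nrow(freeParameters))
    warning("fewer observations than free parameters; ",
            "the fit is underdetermined")
  structure(list(model = model, freeParameters = freeParameters,
                 observations = observations, settings = settings),
            class = "FitProblem")
}

## simulate the problem's model at the observation times and return the
## weighted residual vector; Inf-residuals on simulation failure
fitResiduals <- function(problem, par) {
  fp <- problem$freeParameters
  m <- problem$model
  for (i in seq_len(nrow(fp)))
    m <- setLawParameter(m, fp$reaction[i], fp$parameter[i], par[i])
  obs <- problem$observations
  times <- sort(unique(c(0, obs$time)))
  tr <- tryCatch(simulateNetwork(m, problem$settings, times = times),
                 error = function(e) NULL)
  if (is.null(tr)) return(rep(1e6, nrow(obs)))
  sim <- mapply(function(sp, t) {
    tr@values[sp, match(t, tr@times)]
  }, obs$species, obs$time)
  sqrt(obs$weight) * (sim - obs$value)
}

#' Fit kinetic parameters by bounded least squares
#'
#' Minimizes the weighted residual sum of squares
#' sum w_i (simulated_i - observed_i)^2 over the free kinetic parameters,
#' within bounds, using the Levenberg-Marquardt algorithm
#' (\code{\link[minpack.lm]{nls.lm}}) with a numeric Jacobian. A simulation
#' failure inside the loss assigns that candidate a large finite loss
#' instead of crashing; non-convergence is reported in the result's flag,
#' never as an exception. The fit is deterministic given the initial guess
#' and invariant to observation order.
#'
#' @param problem a problem built by \code{\link{fitProblem}}
#' @param maxIterations optimizer iteration budget
#' @return a \linkS4class{FitResult}
#' @examples
#' \donttest{
#' m <- networkModel(
#'   compartments = list(compartment("cell")),
#'   species = list(
#'     speciesNode("A", compartment = "cell", initialConcentration = 1),
#'     speciesNode("sink", compartment = "cell", role = "sink")),
#'   reactions = list(
#'     reaction("deg", substrates = "A", products = "sink",
#'              law = massActionLaw(0.3), category = "degradation")),
#'   outputSpecies = "A")
#' obs <- data.frame(species = "A", time = c(0.5, 1, 2),
#'                   value = exp(-0.7 * c(0.5, 1, 2)))
#' pr <- fitProblem(m,
#'   data.frame(reaction = "deg", parameter = "k1",
#'              lower = 0.01, upper = 10, guess = 0.3),
#'   obs, simulationSettings(duration = 2, nIntervals = 20))
#' fitParameters(pr)@estimates  # ~0.7
#' }
#' @export
fitParameters <- function(problem, maxIterations = 100L) {
  stopifnot(inherits(problem, "FitProblem"))
  fp <- problem$freeParameters
  ## canonical observation order so the result is order-invariant
  obs <- problem$observations
  problem$observations <- obs[order(obs$species, obs$time), , drop = FALSE]
  parNames <- paste(fp$reaction, fp$parameter, sep = ".")
  guess <- setNames(fp$guess, parNames)
  res0 <- fitResiduals(problem, fp$guess)
  fit <- minpack.lm::nls.lm(
    par = guess, lower = fp$lower, upper = fp$upper,
    fn = function(p) fitResiduals(problem, p),
    control = minpack.lm::nls.lm.control(maxiter = maxIterations))
  est <- pmin(pmax(coef(fit), fp$lower), fp$upper)
  resid <- fitResiduals(problem, est)
  rss <- sum(resid^2)
  rss0 <- sum(res0^2)
  if (rss > rss0) {  # never report a worsening over the starting point
    est <- guess; resid <- res0; rss <- rss0
  }
  new("FitResult", estimates = setNames(est, parNames), rss = rss,
      converged = fit$info %in% 1:4,
      iterations = as.integer(fit$niter), residuals = as.numeric(resid),
      message = fit$message)
}
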