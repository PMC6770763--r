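## settings block using the external (COPASI-style) vocabulary
settingsFromConfig <- function(block) {
  if (is.null(block)) return(simulationSettings(duration = 2e5,
                                                nIntervals = 200L))
  dur <- block[["duration"]]
  if (is.null(dur)) stop("settings block needs 'duration'")
  nInt <- block[["intervals"]]
  isz <- block[["interval_size"]]
  if (is.null(nInt) && is.null(isz)) nInt <- 200L
  if (is.null(isz)) isz <- dur / nInt
  if (is.null(nInt)) nInt <- round(dur / isz)
  simulationSettings(
    duration = dur, nIntervals = nInt, intervalSize = isz,
    relativeTolerance = block[["relative_tolerance"]] %||% 1e-6,
    absoluteTolerance = block[["absolute_tolerance"]] %||% 1e-12,
    maxInternalSteps = block[["maximum_internal_steps"]] %||% 100000L,
    integrateReducedModel =
      isTRUE(as.logical(block[["integrate_reduced_model"]] %||% FALSE)))
}

loadConfigModel <- function(config) {
  if (!is.null(config$model)) {
    path <- config$model
    if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      readSBML(path)$model
    else readNetwork(path)
  } else referenceCascade()
}

scenarioFromConfig <- function(block) {
  scenario(block$label %||% "arm",
           alkF1174L = isTRUE(block$alk_f1174l),
           stimulations = if (length(block$stimulations))
             unlist(block$stimulations) else numeric(),
           crizotinibDose = block$crizotinib_dose %||% 0,
           gefitinibDose = block$gefitinib_dose %||% 0,
           overrides = if (length(block$overrides))
             unlist(block$overrides) else numeric())
}

writeManifest <- function(outDir, config, seed, outputs) {
  manifest <- list(
    package = "pdl1net",
    version = as.character(packageVersion("pdl1net")),
    seed = seed,
    config = config,
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run one pipeline stage from a configuration
#'
#' Thin driver tying the package's stages into a reproducible workflow.
#' \code{config} is a named list (typically parsed from a YAML file) with
#' \code{stage} (one of simulate, arms, sensitivity, fit,
#' validate-expression, synth), an optional \code{model} path (native YAML
#' or SBML; the frozen reference cascade when absent), an optional
#' \code{settings} block whose field names mirror a COPASI deterministic
#' time-course block (duration, interval_size, intervals,
#' relative_tolerance, absolute_tolerance, maximum_internal_steps,
#' integrate_reduced_model), and stage-specific blocks. Each stage writes
#' its TSV outputs into \code{outDir} together with \code{manifest.json}
#' (inputs, output checksums, settings, package version). Identical
#' config + seed produces identical primary outputs.
#'
#' @param config named list, or path to a YAML config file
#' @param outDir output directory (created if needed)
#' @param seed integer seed for stages with randomness
#' @return named list of written file paths, invisibly
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$stage))
    stop("config needs a 'stage' field (simulate, arms, sensitivity, ",
         "fit, validate-expression, synth)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  settings <- settingsFromConfig(config$settings)
  outputs <- character()
  put <- function(name) {
    p <- file.path(outDir, name)
    outputs <<- c(outputs, p)
    p
  }

  switch(config$stage,
    "simulate" = {
      model <- loadConfigModel(config)
      if (!is.null(config$scenario))
        model <- buildScenarioModel(model, scenarioFromConfig(config$scenario))
      tr <- simulateNetwork(model, settings)
      trajectoryToTable(tr, put("trajectory.tsv"))
    },
    "arms" = {
      model <- loadConfigModel(config)
      scs <- lapply(config$arms, scenarioFromConfig)
      cmp <- runArms(model, scs, settings)
      armTable(cmp, put("arms.tsv"))
    },
    "sensitivity" = {
      model <- loadConfigModel(config)
      if (!is.null(config$keep))
        model <- simplifyNetwork(model, unlist(config$keep))
      rep <- localSensitivities(model, settings = settings,
                                delta = config$delta %||% 0.01,
                                scaling = config$scaling %||% "unscaled")
      sensitivityToTable(rep, put("sensitivities.tsv"))
    },
    "fit" = {
      model <- loadConfigModel(config)
      obs <- read.delim(config$observations)
      fp <- do.call(rbind, lapply(config$free_parameters, as.data.frame))
      pr <- fitProblem(model, fp, obs, settings)
      fit <- fitParameters(pr)
      df <- data.frame(parameter = names(fit@estimates),
                       estimate = unname(fit@estimates),
                       rss = fit@rss, converged = fit@converged)
      write.table(df, put("estimates.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    "validate-expression" = {
      m <- if (!is.null(config$values))
        readExpressionMatrix(config$values, config$annotation,
                             scale = config$scale %||% "linear")
      else syntheticValidationMatrix(seed = seed)
      if (exprScale(m) == "linear") m <- log2Transform(m)
      m <- quantileNormalize(m)
      probe <- config$probe %||% "CD274"
      rows <- expand.grid(culture = c("2D", "3D"),
                          treatment = c("crizotinib", "alectinib"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      rows$fold_reduction <- mapply(function(cu, trt)
        foldChange(m, probe, culture = cu, treated = trt),
        rows$culture, rows$treatment)
      write.table(rows, put("fold_changes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    },
    "synth" = {
      spec <- cascadeSpec(seed = seed)
      model <- generateCascadeNetwork(spec)
      writeNetwork(model, put("network.yaml"))
      obs <- generateObservations(model, settings,
                                  observedSpecies = outputSpecies(model),
                                  noiseSdRel = config$noise %||% 0.05,
                                  seed = seed)
      write.table(obs, put("observations.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    stop("unknown stage '", config$stage, "'"))

  writeManifest(outDir, config, seed, outputs)
  invisible(c(outputs, file.path(outDir, "manifest.json")))
}
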