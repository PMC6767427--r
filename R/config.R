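## Run configuration: one YAML/JSON file drives every subcommand, so a
## prior-sensitivity sweep is just a loop over configs.

#' Named prior presets
#'
#' Presets bundling the default analysis priors: divergence-time prior
#' means of 0.005 ("cyrt-default"), 0.0005 ("gekko-default") or 0.05
#' ("diffuse-tau"); theta ~ Gamma(shape 4, mean 0.004); root multiplier ~
#' Gamma(shape 100, mean 1); and the three concentration hyperpriors
#' "alpha-default" Gamma(1.1, 56.1) (about half the prior mass on k = n),
#' "alpha-moderate" Gamma(1.5, 3.13) (prior mean of five events for
#' n = 8), "alpha-clustered" Gamma(0.5, 1.31) (about half the mass on
#' k = 1).
#'
#' @param name preset name.
#' @return a [divergencePriors()] object.
#' @examples
#' priorPreset("gekko-default")$tauMean  # 5e-04
#' @export
priorPreset <- function(name = c("cyrt-default", "gekko-default",
                                 "diffuse-tau", "alpha-default",
                                 "alpha-moderate", "alpha-clustered")) {
  name <- match.arg(name)
  tauMean <- switch(name, "gekko-default" = 0.0005, "diffuse-tau" = 0.05,
                    0.005)
  alpha <- switch(name,
                  "alpha-moderate" = concentrationPrior(1.5, 3.13),
                  "alpha-clustered" = concentrationPrior(0.5, 1.31),
                  concentrationPrior(1.1, 56.1))
  divergencePriors(tauMean = tauMean, thetaShape = 4, thetaMean = 0.004,
                   multShape = 100, multMean = 1, alpha = alpha)
}

configAllowedKeys <- list(
  top = c("comparisons", "priors", "polyallelicMode", "mcmc", "outputDir",
          "preset"),
  comparison = c("label", "path", "populations"),
  priors = c("tau", "theta", "rootMultiplier", "alpha"),
  mcmc = c("generations", "sampleInterval", "burnin", "chains", "seed"))

checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills unspecified priors with the
#' defaults of the selected preset (logging each filled default), rejects
#' unknown keys, and returns a validated `runConfig` list with elements
#' `comparisons`, `priors`, `polyallelicMode`, `mcmc` (an
#' [McmcSettings-class]) and `outputDir`.
#'
#' @param path configuration file path.
#' @return a list of class `runConfig`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  checkKeys(cfg, configAllowedKeys$top, "top level")
  if (is.null(cfg$comparisons) || !length(cfg$comparisons))
    stop("config must list at least one comparison")
  preset <- priorPreset(if (is.null(cfg$preset)) "cyrt-default" else cfg$preset)
  pr <- cfg$priors
  if (!is.null(pr)) checkKeys(pr, configAllowedKeys$priors, "priors")
  getNum <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0)
      stop("prior field ", what, " must be a single positive number")
    x
  }
  tauMean <- if (!is.null(pr$tau$mean)) getNum(pr$tau$mean, "tau$mean") else {
    message("prior tau mean not set; using preset default ", preset$tauMean)
    preset$tauMean
  }
  thetaShape <- if (!is.null(pr$theta$shape))
    getNum(pr$theta$shape, "theta$shape") else preset$thetaShape
  thetaMean <- if (!is.null(pr$theta$mean))
    getNum(pr$theta$mean, "theta$mean") else {
      message("theta prior not fully set; using Gamma(shape ", thetaShape,
              ", mean ", preset$thetaMean, ")")
      preset$thetaMean
    }
  multShape <- if (!is.null(pr$rootMultiplier$shape))
    getNum(pr$rootMultiplier$shape, "rootMultiplier$shape") else preset$multShape
  multMean <- if (!is.null(pr$rootMultiplier$mean))
    getNum(pr$rootMultiplier$mean, "rootMultiplier$mean") else preset$multMean
  alpha <- if (!is.null(pr$alpha$fixed)) {
    getNum(pr$alpha$fixed, "alpha$fixed")
  } else if (!is.null(pr$alpha$shape) || !is.null(pr$alpha$scale)) {
    concentrationPrior(getNum(pr$alpha$shape, "alpha$shape"),
                       getNum(pr$alpha$scale, "alpha$scale"))
  } else preset$alpha
  priors <- divergencePriors(tauMean = tauMean, thetaShape = thetaShape,
                             thetaMean = thetaMean, multShape = multShape,
                             multMean = multMean, alpha = alpha)
  comparisons <- lapply(cfg$comparisons, function(cmp) {
    checkKeys(cmp, configAllowedKeys$comparison, "comparison")
    if (is.null(cmp$label) || is.null(cmp$path) || is.null(cmp$populations))
      stop("each comparison needs label, path and populations")
    if (length(cmp$populations) != 2)
      stop("exactly two populations are required per comparison")
    assignment <- unlist(lapply(names(cmp$populations), function(p)
      structure(rep(p, length(cmp$populations[[p]])),
                names = unlist(cmp$populations[[p]]))))
    list(path = cmp$path,
         popMap = populationMap(cmp$label, names(cmp$populations), assignment))
  })
  mode <- if (is.null(cfg$polyallelicMode)) "remove" else cfg$polyallelicMode
  if (!mode %in% c("remove", "recode"))
    stop("polyallelicMode must be 'remove' or 'recode'")
  mc <- cfg$mcmc
  if (!is.null(mc)) checkKeys(mc, configAllowedKeys$mcmc, "mcmc")
  settings <- mcmcSettings(
    generations = if (is.null(mc$generations)) 150000 else mc$generations,
    interval = if (is.null(mc$sampleInterval)) 100 else mc$sampleInterval,
    burnin = if (is.null(mc$burnin)) 101 else mc$burnin,
    chains = if (is.null(mc$chains)) 10 else mc$chains,
    seed = if (is.null(mc$seed)) 1 else mc$seed)
  structure(list(comparisons = comparisons, priors = priors,
                 polyallelicMode = mode, mcmc = settings,
                 outputDir = if (is.null(cfg$outputDir)) "." else cfg$outputDir),
            class = "runConfig")
}

writeManifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "codivtimes",
    version = as.character(utils::packageVersion("codivtimes")),
    configHash = unname(tools::md5sum(attr(config, "sourcePath"))),
    seed = config$mcmc@seed,
    priors = config$priors[setdiff(names(config$priors), "alpha")],
    alpha = if (is.numeric(config$priors$alpha))
      list(fixed = config$priors$alpha) else
        list(shape = config$priors$alpha$shape,
             scale = config$priors$alpha$scale),
    polyallelicMode = config$polyallelicMode), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

readConfigured <- function(config) {
  lapply(config$comparisons, function(cmp)
    readComparison(cmp$path, cmp$popMap, config$polyallelicMode))
}

#' Command-line entry point
#'
#' Thin orchestration over the package functions, mirroring the analysis
#' workflow: `priors` (write prior P(k) and pairwise-sharing tables),
#' `analyze` (read data, run chains, write traces, diagnostics and a
#' model-choice summary), `simulate` (template-matched replicates plus a
#' truth table), `vet` (split one comparison's loci in half and analyse
#' the halves as separate comparisons), and `summarize` (recompute the
#' summary from written traces).  A run manifest (config hash, package
#' version, seed, priors) is written next to the outputs.
#'
#' @param args character vector, e.g.
#'   `c("analyze", "--config", "run.yml")`.
#' @return exit status, 0 on success (invisibly).
#' @export
commandSuite <- function(args) {
  status <- tryCatch({
    if (!length(args)) stop("usage: <priors|analyze|simulate|vet|summarize> ",
                            "--config <file> [--replicates N] [--template F] ",
                            "[--comparison LABEL]")
    cmd <- args[1]
    opt <- function(flag, default = NULL) {
      i <- which(args == flag)
      if (!length(i)) return(default)
      args[i[1] + 1]
    }
    cfgPath <- opt("--config")
    if (is.null(cfgPath)) stop("--config is required")
    config <- loadConfig(cfgPath)
    attr(config, "sourcePath") <- cfgPath
    outDir <- opt("--out", config$outputDir)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    n <- length(config$comparisons)
    switch(cmd,
      priors = {
        pk <- probNumEventsMarginal(n, seq_len(n), config$priors$alpha)
        utils::write.table(
          data.frame(k = seq_len(n), prior = pk),
          file.path(outDir, "prior_num_events.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(quantity = "pairwise_shared",
                     prior = probPairShared(config$priors$alpha)),
          file.path(outDir, "prior_pair_shared.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      },
      analyze = {
        data <- readConfigured(config)
        traces <- runChains(data, config$priors, config$mcmc,
                            outputDir = outDir)
        diag <- traceDiagnostics(traces)
        utils::write.table(diag, file.path(outDir, "diagnostics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sm <- summarizeTraces(traces)
        utils::write.table(
          data.frame(k = seq_along(sm$pk), posterior = sm$pk,
                     prior = sm$priorK, bayesFactor = sm$bayesFactors),
          file.path(outDir, "num_events.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(sm$tauSummary,
                           file.path(outDir, "divergence_times.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeDatasetSummary(data, file.path(outDir, "dataset_summary.tsv"))
      },
      simulate = {
        reps <- as.integer(opt("--replicates", "5"))
        tpl <- opt("--template")
        template <- if (!is.null(tpl)) readTemplateJson(tpl) else
          extractTemplate(readConfigured(config))
        sims <- lapply(seq_len(reps), function(i)
          simulateReplicate(template, config$priors,
                            seed = config$mcmc@seed + i))
        writeTruthTable(sims, file.path(outDir, "truth.tsv"))
        for (i in seq_len(reps))
          for (d in sims[[i]]$data)
            writeComparison(d, file.path(outDir, sprintf("rep%03d", i),
                                         d@label))
      },
      vet = {
        lab <- opt("--comparison")
        data <- readConfigured(config)
        labels <- vapply(data, function(d) d@label, "")
        pick <- if (is.null(lab)) 1L else match(lab, labels)
        if (is.na(pick)) stop("comparison not found: ", lab)
        halves <- vetSplit(data[[pick]], seed = config$mcmc@seed)
        traces <- runChains(halves, config$priors, config$mcmc,
                            outputDir = outDir)
        sm <- summarizeTraces(traces)
        co <- sm$coassignment[1, 2]
        prior <- probPairShared(config$priors$alpha)
        utils::write.table(
          data.frame(posteriorCoassignment = co, priorPairShared = prior),
          file.path(outDir, "vet_split.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      },
      summarize = {
        files <- list.files(outDir, pattern = "^chain[0-9]+\\.tsv$",
                            full.names = TRUE)
        if (!length(files)) stop("no chain traces found in ", outDir)
        chains <- lapply(files, utils::read.delim)
        traces <- structure(list(chains = chains,
                                 labels = sub("^event_", "",
                                              grep("^event_", names(chains[[1]]),
                                                   value = TRUE)),
                                 settings = config$mcmc,
                                 priors = config$priors),
                            class = "codivTraces")
        sm <- summarizeTraces(traces)
        utils::write.table(
          data.frame(k = seq_along(sm$pk), posterior = sm$pk,
                     prior = sm$priorK, bayesFactor = sm$bayesFactors),
          file.path(outDir, "num_events.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      },
      stop("unknown subcommand: ", cmd))
    writeManifest(config, file.path(outDir, "manifest.json"),
                  extra = list(command = cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
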