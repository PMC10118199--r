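# End-to-end experiment orchestration: generate topologies, establish
# networks, evolve noise under both modes, assemble tables, and serialize
# a fully reproducible bundle.

#' Experiment configuration
#'
#' Bundles the simulation parameters of both stages with the topology plan
#' and replication scheme. Seeds are derived hierarchically from `seed`
#' (root -> topology -> stage -> replicate) so adding topologies or
#' replicates never perturbs existing streams.
#'
#' @param nTopologies Number of founding topologies.
#' @param topologyModel `"ER"`, `"BA"` or `"WS"`.
#' @param density Directed edge density.
#' @param weightLow,weightHigh Weight range of the founding draw.
#' @param establishParams [SimulationParams-class] for the establishment
#'   stage.
#' @param noiseParams [SimulationParams-class] for the noise-evolution stage.
#' @param replicatesSelection,replicatesNeutral Replicates per topology and
#'   mode (study default 10 + 10).
#' @param seed Integer root seed.
#' @param outDir Optional output directory; when set, [runExperiment] writes
#'   TSV tables and a JSON manifest there.
#' @param keepRecords Retain the per-run [EvolutionRecord-class] objects in
#'   the returned bundle? Default TRUE.
#' @param maxTopologyAttempts How many candidate topologies may be consumed
#'   (established networks that oscillate as a whole population are discarded
#'   and logged) before giving up on reaching `nTopologies`.
#' @return A list of class `grnoise_config`.
#' @export
experimentConfig <- function(nTopologies = 2, topologyModel = "ER",
                             density = 0.05, weightLow = -3, weightHigh = 3,
                             establishParams = simulationParams(),
                             noiseParams = simulationParams(),
                             replicatesSelection = 10,
                             replicatesNeutral = 10,
                             seed = 1, outDir = NULL, keepRecords = TRUE,
                             maxTopologyAttempts = 5 * nTopologies) {
  stopifnot(
    nTopologies >= 1, replicatesSelection >= 1, replicatesNeutral >= 1,
    is(establishParams, "SimulationParams"), is(noiseParams, "SimulationParams")
  )
  structure(
    list(
      nTopologies = as.integer(nTopologies),
      topologyModel = topologyModel, density = density,
      weightLow = weightLow, weightHigh = weightHigh,
      establishParams = establishParams, noiseParams = noiseParams,
      replicatesSelection = as.integer(replicatesSelection),
      replicatesNeutral = as.integer(replicatesNeutral),
      seed = as.integer(seed), outDir = outDir,
      keepRecords = isTRUE(keepRecords),
      maxTopologyAttempts = as.integer(maxTopologyAttempts)
    ),
    class = "grnoise_config"
  )
}

#' Named experiment presets
#'
#' `"desk"` is a scaled-down configuration that runs on one CPU in minutes
#' (10 topologies, establishment N = 100 for 1000 generations, noise stage
#' N = 200 for 500 generations, 3 + 3 replicates); `"paper"` is the
#' full-scale study configuration (2000 topologies, N = 1000, 10000
#' generations, 10 + 10 replicates) and is not desk-runnable.
#'
#' @param name `"desk"` or `"paper"`.
#' @param seed Integer root seed.
#' @param ... Overrides forwarded to [experimentConfig].
#' @return A `grnoise_config`.
#' @export
experimentPreset <- function(name = c("desk", "paper"), seed = 1, ...) {
  name <- match.arg(name)
  base <- switch(name,
    desk = list(
      nTopologies = 10,
      establishParams = simulationParams(popSize = 100, generations = 1000),
      noiseParams = simulationParams(popSize = 200, generations = 500),
      replicatesSelection = 3, replicatesNeutral = 3
    ),
    paper = list(
      nTopologies = 2000,
      establishParams = simulationParams(),
      noiseParams = simulationParams(),
      replicatesSelection = 10, replicatesNeutral = 10
    )
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(experimentConfig, args)
}

#' Run a full experiment
#'
#' For each topology: generate (rejecting disconnected draws), establish
#' (topologies whose establishment aborts because the whole population
#' oscillates are discarded, logged in the manifest, and replaced by the next
#' candidate seed), evolve noise under selection and neutrality with the
#' configured replicate counts, and compute metrics and gene tables. Given
#' the same config and seed, outputs are identical run to run.
#'
#' @param config A `grnoise_config` from [experimentConfig] or
#'   [experimentPreset].
#' @return List with `geneTableSelection`, `geneTableNeutral` (pooled
#'   data.frames), `graphMetrics` (one row per network), `axes` (from
#'   [syntheticAxes] when >= 3 networks), `establishments`, `records` (when
#'   `keepRecords`), and `manifest` (seeds, parameters, discarded topology
#'   ids).
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "grnoise_config"))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(config$outDir)) stop("output directory is not writable")
  }
  establishments <- list()
  records <- list()
  metricsRows <- list()
  strengthsList <- list()
  masks <- list()
  topoSeeds <- integer(0)
  attemptOf <- integer(0)
  discarded <- integer(0)
  attempt <- 0L
  while (length(establishments) < config$nTopologies) {
    attempt <- attempt + 1L
    if (attempt > config$maxTopologyAttempts)
      stop("exceeded maxTopologyAttempts before reaching nTopologies")
    topoSeed <- deriveSeed(config$seed, "topology", attempt)
    graph <- generateTopology(config$topologyModel,
      nGenes = config$establishParams@nGenes,
      density = config$density, weightLow = config$weightLow,
      weightHigh = config$weightHigh, seed = topoSeed
    )
    est <- tryCatch(
      establishNetwork(graph, config$establishParams,
                       seed = deriveSeed(config$seed, "establish", attempt)),
      error = function(e) {
        if (grepl("every individual oscillates", conditionMessage(e))) NULL
        else stop(e)
      }
    )
    if (is.null(est)) {
      discarded <- c(discarded, attempt)
      next
    }
    id <- sprintf("net%03d", length(establishments) + 1L)
    establishments[[id]] <- est
    topoSeeds[id] <- topoSeed
    attemptOf[id] <- attempt
    strengthsList[[id]] <- nodeStrengths(graph)
    masks[[id]] <- est@intermediateMask
    metricsRows[[id]] <- cbind(network = id, graphMetrics(graph))
    records[[id]] <- list(selection = list(), neutral = list())
    for (mode in c("selection", "neutral")) {
      nrep <- if (mode == "selection") config$replicatesSelection else
        config$replicatesNeutral
      for (rep in seq_len(nrep)) {
        records[[id]][[mode]][[rep]] <- evolveNoise(
          est, config$noiseParams, mode = mode,
          seed = deriveSeed(config$seed, "evolve", attempt, mode, rep)
        )
      }
    }
  }
  selRecords <- lapply(records, `[[`, "selection")
  neuRecords <- lapply(records, `[[`, "neutral")
  geneSel <- buildGeneTable(selRecords, strengthsList, masks,
    pressureThreshold = config$noiseParams@pressureThreshold
  )
  geneNeu <- buildGeneTable(neuRecords, strengthsList, masks,
    pressureThreshold = config$noiseParams@pressureThreshold
  )
  metricsTable <- do.call(rbind, metricsRows)
  rownames(metricsTable) <- NULL
  axes <- if (nrow(metricsTable) >= 3L) {
    tryCatch(syntheticAxes(metricsTable), error = function(e) NULL)
  } else {
    NULL
  }
  manifest <- list(
    rootSeed = config$seed,
    topologyModel = config$topologyModel,
    density = config$density,
    weightRange = c(config$weightLow, config$weightHigh),
    nTopologies = config$nTopologies,
    replicates = list(
      selection = config$replicatesSelection,
      neutral = config$replicatesNeutral
    ),
    establishParams = .paramsAsList(config$establishParams),
    noiseParams = .paramsAsList(config$noiseParams),
    topologySeeds = as.list(topoSeeds),
    discardedTopologyAttempts = discarded,
    seedDerivation = lapply(names(establishments), function(id) {
      att <- attemptOf[[id]]
      list(
        network = id,
        topologyAttempt = att,
        topologySeed = topoSeeds[[id]],
        establishSeed = deriveSeed(config$seed, "establish", att),
        replicateSeeds = list(
          selection = vapply(
            seq_len(config$replicatesSelection),
            function(r) deriveSeed(config$seed, "evolve", att, "selection", r),
            integer(1)
          ),
          neutral = vapply(
            seq_len(config$replicatesNeutral),
            function(r) deriveSeed(config$seed, "evolve", att, "neutral", r),
            integer(1)
          )
        )
      )
    })
  )
  out <- list(
    geneTableSelection = geneSel, geneTableNeutral = geneNeu,
    graphMetrics = metricsTable, axes = axes,
    establishments = establishments,
    records = if (config$keepRecords) records else NULL,
    manifest = manifest
  )
  if (!is.null(config$outDir)) {
    writeGeneTable(geneSel, file.path(config$outDir,
                                      "gene_table_selection.tsv"))
    writeGeneTable(geneNeu, file.path(config$outDir,
                                      "gene_table_neutral.tsv"))
    write.table(metricsTable, file.path(config$outDir, "graph_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(axes)) {
      write.table(axes$scores, file.path(config$outDir, "synthetic_axes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(
        data.frame(metric = rownames(axes$loadings), axes$loadings),
        file.path(config$outDir, "axis_loadings.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

.paramsAsList <- function(p) {
  nm <- methods::slotNames(class(p))
  setNames(lapply(nm, function(s) slot(p, s)), nm)
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' The document mirrors the arguments of [experimentConfig]; the
#' `establishParams` and `noiseParams` entries are themselves argument lists
#' for [simulationParams].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `grnoise_config`.
#' @export
readExperimentConfig <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (nm in c("establishParams", "noiseParams")) {
    if (!is.null(doc[[nm]]))
      doc[[nm]] <- do.call(simulationParams, as.list(doc[[nm]]))
  }
  do.call(experimentConfig, doc)
}
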