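## End-to-end orchestration: simulate -> normalize -> domains -> differential
## -> genescape -> reader, with one master seed fanned out to per-stage seeds
## by stable hashing of stage names.

#' Build a pipeline configuration
#'
#' Defaults follow the analysis conventions: 250-bp differential windows,
#' 5-kb Z-score windows, domain cutoff 3 with 1-kb minimum length, 12 gene
#' clusters, cluster-level FDR 0.05, 50% minimum change, 5% spike-in.
#'
#' @param seed master seed.
#' @param conditions,features design of the synthetic experiment.
#' @param replicates ChIP replicates per design cell.
#' @param depth expected target reads per library.
#' @param bin simulation bin size (bp).
#' @param geneWindow resize window (bp) for gene-centric tracks.
#' @param diffWindow differential window width (bp).
#' @param zWindow Z-score window (bp).
#' @param domainCutoff,domainMinLen,domainMaxGap domain-calling parameters.
#' @param k gene cluster count.
#' @param fdr cluster-level FDR target.
#' @param minChange minimum proportional change for reported regions.
#' @param spikeFraction configured spike-in fraction.
#' @param noise negative-binomial dispersion of simulated counts.
#' @param jitterSd log-sd of per-library depth jitter.
#' @param inputMode input normalization mode (`"subtract"` or `"ratio"`).
#' @param normMode spike normalization mode (`"totalreads"` or `"tmm"`).
#' @param outdir optional output directory for result files.
#' @return a named list (class `k36land_config`) that round-trips through
#'   [writePipelineConfig()] / [readPipelineConfig()] losslessly.
#' @export
pipelineConfig <- function(seed = 1,
                           conditions = K36_CONDITIONS,
                           features = c("K36me1", "K36me2", "K36me3", "JASPer"),
                           replicates = 2L, depth = 2e6, bin = 50,
                           geneWindow = 500, diffWindow = 250, zWindow = 5000,
                           domainCutoff = 3, domainMinLen = 1000,
                           domainMaxGap = 100, k = 12, fdr = 0.05,
                           minChange = 0.5, spikeFraction = 0.05,
                           noise = 0.1, jitterSd = 0.2,
                           inputMode = "subtract", normMode = "totalreads",
                           outdir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- c("k36land_config", "list")
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (!"GST" %in% cfg$conditions)
    stop("configuration lacks the GST control condition")
  stopifnot(cfg$depth > 0, cfg$bin >= 1,
            cfg$geneWindow %% cfg$bin == 0, cfg$diffWindow %% cfg$bin == 0,
            cfg$fdr > 0, cfg$fdr < 1)
  invisible(cfg)
}

#' @rdname pipelineConfig
#' @param cfg a configuration list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  cfg <- do.call(pipelineConfig, raw)
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> normalize -> domains -> differential -> genescape ->
#' reader in order and returns a result bundle with a manifest sufficient to
#' reproduce every output. Identical configurations produce identical
#' results. Any stage failure aborts with the stage name; previously
#' completed stage results are preserved in the error condition's `partial`
#' field.
#'
#' @param config a configuration from [pipelineConfig()].
#' @param stages subset of stages to run (in canonical order).
#' @return list: `preset`, `experiment` manifest, `factors`, `tracks`
#'   (normalized, replicate-averaged, at `geneWindow` resolution), `domains`
#'   (per mark, control condition), `fractions`, `consensus`, `differential`
#'   (per condition x mark region tables), `zscores`, `gsm`, `clusters`,
#'   `compensation`, `readerFit`, `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate", "normalize", "domains",
                                   "differential", "genescape", "reader")) {
  validatePipelineConfig(config)
  res <- list(manifest = list(config = unclass(config)))
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(structure(class = c("k36land_stage_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = NULL, partial = res))))
  }
  marks <- intersect(c("K36me1", "K36me2", "K36me3"), config$features)

  if ("simulate" %in% stages) {
    res$preset <- runStage("simulate",
      buildGenomeModel(seed = stageSeed(config$seed, "genome")))
    res$experiment <- runStage("simulate",
      simulateExperiment(res$preset, defaultEffectTable(),
                         conditions = config$conditions,
                         features = config$features,
                         replicates = config$replicates,
                         depth = config$depth, bin = config$bin,
                         noise = config$noise,
                         spikeFraction = config$spikeFraction,
                         jitterSd = config$jitterSd,
                         seed = stageSeed(config$seed, "libraries")))
  }

  if ("normalize" %in% stages) {
    res <- runStage("normalize", c(res, normalizeStage(res, config)))
  }

  if ("domains" %in% stages) {
    res <- runStage("domains", c(res, domainsStage(res, config, marks)))
  }

  if ("differential" %in% stages) {
    res <- runStage("differential", c(res, differentialStage(res, config, marks)))
  }

  if ("genescape" %in% stages) {
    res <- runStage("genescape", c(res, genescapeStage(res, config, marks)))
  }

  if ("reader" %in% stages && "JASPer" %in% config$features) {
    res <- runStage("reader", c(res, readerStage(res, config)))
  }

  if (!is.null(config$outdir)) writeResultBundle(res, config$outdir)
  res
}

## spike scaling + replicate-averaged input-normalized tracks at two
## resolutions (native bin for domain calling, geneWindow for gene stages)
normalizeStage <- function(res, config) {
  libs <- res$experiment$libraries
  stats <- libraryStats(res$experiment)
  factors <- if (identical(config$normMode, "tmm"))
    spikeScaleTMM(spikeBinCounts(res$experiment,
                                 seed = stageSeed(config$seed, "spikebins")))
  else spikeScaleTotalReads(stats)
  man <- res$experiment$manifest$libraries
  scaledAvg <- function(feature, condition) {
    ids <- man$id[man$feature == feature & man$condition == condition]
    averageTracks(lapply(ids, function(id)
      scaleTrack(asCoverageTrack(libs[[id]]),
                 factors$factor[factors$library_id == id])))
  }
  normTracks <- list(); fineTracks <- list()
  for (cond in config$conditions) {
    inp <- scaledAvg("input", cond)
    inpG <- resizeToWindows(inp, config$geneWindow)
    for (feat in config$features) {
      chip <- scaledAvg(feat, cond)
      key <- paste(feat, cond, sep = ".")
      fineTracks[[key]] <- inputNormalize(chip, inp, mode = config$inputMode)
      normTracks[[key]] <- inputNormalize(
        resizeToWindows(chip, config$geneWindow), inpG,
        mode = config$inputMode)
    }
  }
  list(stats = stats, factors = factors, tracks = normTracks,
       fineTracks = fineTracks)
}

domainsStage <- function(res, config, marks) {
  domains <- list(); fractions <- numeric()
  allDoms <- list()
  for (mark in marks) {
    for (cond in config$conditions) {
      ds <- callBroadDomains(res$fineTracks[[paste(mark, cond, sep = ".")]],
                             cutoff = config$domainCutoff,
                             minLen = config$domainMinLen,
                             maxGap = config$domainMaxGap,
                             mark = mark, condition = cond)
      allDoms[[paste(mark, cond, sep = ".")]] <- ds
      if (cond == "GST") {
        domains[[mark]] <- ds
        fractions[mark] <- genomeFraction(ds, res$preset)
      }
    }
  }
  consensus <- reduce(bindGR(lapply(allDoms, function(d)
    granges(domainRanges(d)))))
  list(domains = domains, allDomains = allDoms, fractions = fractions,
       consensus = consensus)
}

differentialStage <- function(res, config, marks) {
  libs <- res$experiment$libraries
  man <- res$experiment$manifest$libraries
  diffRes <- list(); zs <- list()
  rnaiConds <- setdiff(config$conditions, "GST")
  for (mark in marks) {
    chipIds <- man$id[man$feature == mark]
    se <- countWindows(libs[chipIds], width = config$diffWindow)
    inputIds <- man$id[man$feature == "input"]
    ise <- countWindows(libs[inputIds], width = config$diffWindow)
    ## input columns matched to chip columns by condition
    cd <- SummarizedExperiment::colData(se)
    icond <- SummarizedExperiment::colData(ise)$condition
    iseM <- ise[, match(cd$condition, icond)]
    filt <- filterWindowsByInput(se, iseM, factors = res$factors, fold = 3)
    for (cond in rnaiConds) {
      tw <- testWindows(filt, factors = res$factors, condition = cond)
      diffRes[[paste(mark, cond, sep = ".")]] <-
        mergeAndFdr(tw, targetFdr = config$fdr, minChange = config$minChange)
      zs[[paste(mark, cond, sep = ".")]] <- zscoreTransform(
        res$fineTracks[[paste(mark, cond, sep = ".")]],
        res$fineTracks[[paste(mark, "GST", sep = ".")]],
        window = config$zWindow, consensus = res$consensus)
    }
  }
  list(differential = diffRes, zscores = zs)
}

genescapeStage <- function(res, config, marks) {
  preset <- res$preset
  gsm <- buildGeneSignalMatrix(res$tracks, presetGenes(preset),
                               domains = res$consensus,
                               exons = presetExons(preset),
                               pch = presetPCH(preset))
  ca <- clusterGenes(gsm, k = config$k,
                     seed = stageSeed(config$seed, "clustering"))
  ca <- assignSuperclusters(ca, gsm, pch = presetPCH(preset))
  list(gsm = gsm, clusters = ca)
}

readerStage <- function(res, config) {
  comp <- lapply(setdiff(config$conditions, "GST"), function(cond)
    compensationTable(res$gsm, cond))
  names(comp) <- setdiff(config$conditions, "GST")
  dat <- readerModelData(res$gsm, conditions = config$conditions)
  fit <- fitThresholdModel(dat, seed = stageSeed(config$seed, "readerfit"))
  list(compensation = comp, readerFit = fit)
}

writeResultBundle <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(res$factors))
    utils::write.table(res$factors, file.path(dir, "normfactors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(res$differential))
    utils::write.table(res$differential[[key]],
                       file.path(dir, paste0("diffregions_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$clusters))
    utils::write.table(clusterAssignment(res$clusters),
                       file.path(dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$readerFit))
    jsonlite::write_json(as.list(res$readerFit$params),
                         file.path(dir, "reader_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plot a metagene profile
#'
#' Simple base-graphics rendering of a [metageneProfile()] result with flank
#' and body segments demarcated.
#'
#' @param profile a list from [metageneProfile()].
#' @param ... passed to [plot()].
#' @export
plotMetagene <- function(profile, ...) {
  nf <- length(profile$profile) - profile$bodyBins
  nf <- nf / 2
  x <- seq_along(profile$profile)
  graphics::plot(x, profile$profile, type = "l", xaxt = "n",
                 xlab = "", ylab = "mean signal", ...)
  graphics::abline(v = c(nf + 0.5, nf + profile$bodyBins + 0.5), lty = 2)
  graphics::axis(1, at = c(1, nf, nf + profile$bodyBins / 2,
                           nf + profile$bodyBins,
                           2 * nf + profile$bodyBins),
                 labels = c("-1kb", "TSS", "body", "TTS", "+1kb"))
  invisible(profile)
}
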