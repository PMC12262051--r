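## Simulation of sequencing libraries from a GenomePreset + effect table.
##
## Count model: the expected per-bp coverage of a library is
##   lambda(x) = beta + excess(x) * effect(group(x), condition, feature)
## with input baseline beta = 1. Every library is sequenced to the same
## expected target depth D (counts are multinomial-like over bins:
## E[count_bin] = D * integral(lambda)_bin / integral(lambda)_genome), while
## the expected spike-in read count scales inversely with the library's
## enrichment integral:
##   E[spike] = jitter * D * f/(1-f) * (beta*G / integral(lambda))
## This models a cell-number spike-in: a more efficient IP yields a smaller
## spike share, and spike scaling (1e6 / spike reads) maps every library onto
## the common absolute scale gamma * lambda(x), so planted multiplicative
## effects are recovered exactly in expectation. Bin counts are drawn from a
## negative binomial (gamma-Poisson) with configurable dispersion.

#' Expected coverage profile for a (condition, feature) pair
#'
#' Returns the noiseless per-bp expected coverage (input baseline 1 plus
#' enrichment excess with planted effects applied) as an RleList, together
#' with its genome integral. This is the ground truth that simulated counts
#' fluctuate around; tests and oracles use it directly.
#'
#' @param preset a [GenomePreset-class].
#' @param effects an effect table (see [defaultEffectTable()]).
#' @param condition,feature condition and feature keys; unknown keys raise an
#'   error naming the offending key.
#' @return list with elements `rle` (SimpleRleList, per-bp expected coverage),
#'   `Z` (genome integral of the profile) and `G` (genome length).
#' @export
expectedProfile <- function(preset, effects, condition, feature) {
  if (!feature %in% names(preset@enrichment) && feature != "input")
    stop("unknown feature: '", feature, "'")
  enr <- preset@enrichment[[feature]]
  if (is.null(enr)) enr <- GRanges()
  eff <- if (length(enr)) effectFor(effects, enr$group, condition, feature)
         else effectFor(effects, character(), condition, feature)
  w <- if (length(enr)) enr$excess * eff else numeric()
  cov <- coverage(GRanges(seqnames(enr), ranges(enr),
                          seqinfo = Seqinfo(names(preset@seqlens),
                                            as.integer(preset@seqlens))),
                  weight = w)
  rle <- cov + 1
  G <- sum(preset@seqlens)
  Z <- G + if (length(enr)) sum(as.numeric(width(enr)) * w) else 0
  list(rle = rle, Z = Z, G = G)
}

#' Expected bin counts for a library (noise-free oracle)
#'
#' @inheritParams expectedProfile
#' @param depth expected target-genome mapped reads.
#' @param bin bin size in bp.
#' @param spikeFraction configured spike-in fraction (expected spike share of
#'   an unenriched library).
#' @return list: `mu` (named list of per-chromosome expected bin counts),
#'   `spikeMu` (expected spike reads), `Z`, `G`.
#' @export
expectedCounts <- function(preset, effects, condition, feature, depth,
                           bin = 50, spikeFraction = 0.05) {
  prof <- expectedProfile(preset, effects, condition, feature)
  mu <- list()
  for (chr in names(preset@seqlens)) {
    sl <- preset@seqlens[[chr]]
    st <- binStarts(sl, bin)
    v <- Views(prof$rle[[chr]], IRanges(st, width = binWidths(sl, bin)))
    mu[[chr]] <- as.numeric(viewMeans(v)) * binWidths(sl, bin) * depth / prof$Z
  }
  spikeMu <- depth * spikeFraction / (1 - spikeFraction) * prof$G / prof$Z
  list(mu = mu, spikeMu = spikeMu, Z = prof$Z, G = prof$G)
}

#' Simulate one ChIP (or input) library
#'
#' Draws binned fragment counts from a negative-binomial (gamma-Poisson)
#' model around the expected profile of the requested condition/feature, and
#' a Poisson spike-in read total (see the count model described above).
#'
#' @inheritParams expectedCounts
#' @param noise negative-binomial dispersion (0 gives Poisson counts).
#' @param replicate replicate tag stored in the metadata.
#' @param depthJitter multiplicative sequencing-depth factor applied to both
#'   target and spike expectations (drawn log-normally by
#'   [simulateExperiment()]).
#' @param seed integer seed; identical seed + parameters give identical output.
#' @return a [SimulatedLibrary-class].
#' @export
simulateLibraryCounts <- function(preset, effects, condition, feature,
                                  depth = 2e6, bin = 50, noise = 0.1,
                                  spikeFraction = 0.05, replicate = 1L,
                                  depthJitter = 1, seed = NULL) {
  stopifnot(depth >= 0, bin >= 1, noise >= 0)
  ec <- expectedCounts(preset, effects, condition, feature, depth, bin,
                       spikeFraction)
  withSeed(seed, {
    counts <- list()
    for (chr in names(ec$mu)) {
      mu <- ec$mu[[chr]] * depthJitter
      counts[[chr]] <- if (noise > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / noise)
      else stats::rpois(length(mu), mu)
    }
    spikeReads <- stats::rpois(1, ec$spikeMu * depthJitter)
    new("SimulatedLibrary", counts = counts, binSize = as.integer(bin),
        seqlens = preset@seqlens, spikeReads = as.numeric(spikeReads),
        info = list(id = paste(feature, condition, replicate, sep = "_"),
                    condition = condition, feature = feature,
                    replicate = replicate, depth = depth, noise = noise,
                    spikeFraction = spikeFraction, depthJitter = depthJitter,
                    seed = seed))
  })
}

setMethod("show", "SimulatedLibrary", function(object) {
  cat(sprintf("SimulatedLibrary %s: %.3g target reads in %d-bp bins, %.3g spike reads\n",
              object@info$id %||% "?",
              sum(vapply(object@counts, sum, numeric(1))),
              object@binSize, object@spikeReads))
})

#' @rdname SimulatedLibrary-class
#' @param x a SimulatedLibrary
#' @export
setMethod("binSize", "SimulatedLibrary", function(x) x@binSize)

#' @rdname SimulatedLibrary-class
#' @export
setMethod("libraryInfo", "SimulatedLibrary", function(x) x@info)

#' Spike-in mapped reads of a simulated library
#' @param lib a [SimulatedLibrary-class]
#' @export
spikeReads <- function(lib) lib@spikeReads

#' Binned fragment counts of a simulated library
#' @param lib a [SimulatedLibrary-class]
#' @export
libraryCounts <- function(lib) lib@counts

#' Convert a simulated library to a CoverageTrack
#'
#' Signal is fragment coverage per bp (bin count / bin width).
#'
#' @param lib a [SimulatedLibrary-class].
#' @return a [CoverageTrack-class].
#' @export
asCoverageTrack <- function(lib) {
  stopifnot(is(lib, "SimulatedLibrary"))
  sig <- list()
  for (chr in names(lib@counts)) {
    w <- binWidths(lib@seqlens[[chr]], lib@binSize)
    sig[[chr]] <- lib@counts[[chr]] / w
  }
  CoverageTrack(sig, lib@binSize, lib@seqlens, lib@info)
}

#' Simulate a full multi-condition experiment
#'
#' One ChIP library per (condition, feature, replicate) design cell plus one
#' input library per condition, each with a per-library seed derived from the
#' master seed and a log-normal sequencing-depth jitter. The manifest records
#' every seed and parameter for exact replay.
#'
#' @inheritParams simulateLibraryCounts
#' @param conditions character vector of conditions; must include the `"GST"`
#'   control (downstream normalization requires it).
#' @param features ChIP features to simulate (input is added automatically).
#' @param replicates ChIP replicates per design cell.
#' @param jitterSd standard deviation (log scale) of the per-library depth
#'   jitter.
#' @param seed master seed.
#' @return list with class `SimulatedExperiment`: `libraries` (named list of
#'   [SimulatedLibrary-class]) and `manifest` (master seed, parameters and a
#'   per-library table of seeds and jitters).
#' @export
simulateExperiment <- function(preset, effects = defaultEffectTable(),
                               conditions = K36_CONDITIONS,
                               features = c("K36me1", "K36me2", "K36me3",
                                            "JASPer"),
                               replicates = 2L, depth = 2e6, bin = 50,
                               noise = 0.1, spikeFraction = 0.05,
                               jitterSd = 0.2, seed = 1) {
  if (!"GST" %in% conditions)
    stop("design must include the GST control condition")
  cells <- expand.grid(feature = features, condition = conditions,
                       replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
  cells <- rbind(cells,
                 data.frame(feature = "input", condition = conditions,
                            replicate = 1L))
  cells$id <- paste(cells$feature, cells$condition, cells$replicate, sep = "_")
  cells$seed <- vapply(cells$id, function(id) stageSeed(seed, id), integer(1))
  cells$jitter <- vapply(cells$id, function(id)
    withSeed(stageSeed(seed, paste0(id, ":jitter")),
             stats::rlnorm(1, 0, jitterSd)), numeric(1))
  libs <- vector("list", nrow(cells))
  names(libs) <- cells$id
  for (i in seq_len(nrow(cells))) {
    libs[[i]] <- simulateLibraryCounts(
      preset, effects, cells$condition[i], cells$feature[i],
      depth = depth, bin = bin, noise = noise, spikeFraction = spikeFraction,
      replicate = cells$replicate[i], depthJitter = cells$jitter[i],
      seed = cells$seed[i])
  }
  manifest <- list(seed = seed, depth = depth, bin = bin, noise = noise,
                   spikeFraction = spikeFraction, jitterSd = jitterSd,
                   presetSeed = preset@params$seed,
                   libraries = cells[, c("id", "feature", "condition",
                                         "replicate", "seed", "jitter")])
  structure(list(libraries = libs, manifest = manifest),
            class = "SimulatedExperiment")
}

#' @export
print.SimulatedExperiment <- function(x, ...) {
  m <- x$manifest$libraries
  cat(sprintf("SimulatedExperiment: %d libraries (%d ChIP + %d input), master seed %d\n",
              nrow(m), sum(m$feature != "input"), sum(m$feature == "input"),
              x$manifest$seed))
  invisible(x)
}

#' Library statistics table (target and spike mapped reads)
#'
#' @param experiment a `SimulatedExperiment`.
#' @return data.frame with columns `library_id`, `target_reads`, `spike_reads`.
#' @export
libraryStats <- function(experiment) {
  libs <- experiment$libraries
  data.frame(
    library_id = names(libs),
    target_reads = vapply(libs, function(l)
      sum(vapply(l@counts, function(v) sum(as.numeric(v)), numeric(1))),
      numeric(1)),
    spike_reads = vapply(libs, spikeReads, numeric(1)),
    row.names = NULL)
}

#' Simulated spike-genome window counts for TMM normalization
#'
#' The exogenous genome is represented by a shared high/low-signal window
#' profile (log-normal across windows, synthetic); each library's expected
#' window counts scale with its spike-in read total, so trimmed-M factors
#' computed on high-signal windows agree with total-read factors up to noise.
#'
#' @param experiment a `SimulatedExperiment`.
#' @param nBins number of spike-genome windows.
#' @param noise negative-binomial dispersion.
#' @param seed seed for the shared profile and the counts.
#' @return integer matrix, windows x libraries.
#' @export
spikeBinCounts <- function(experiment, nBins = 2000, noise = 0.1, seed = 1) {
  libs <- experiment$libraries
  withSeed(stageSeed(seed, "spike-profile"), {
    w <- stats::rlnorm(nBins, meanlog = 0, sdlog = 1.2)
    w <- w / sum(w)
    mat <- vapply(libs, function(l)
      stats::rnbinom(nBins, mu = spikeReads(l) * w, size = 1 / max(noise, 1e-8)),
      numeric(nBins))
    storage.mode(mat) <- "integer"
    colnames(mat) <- names(libs)
    mat
  })
}
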