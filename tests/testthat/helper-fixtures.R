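## Shared fixtures and independent oracles. The full default pipeline run is
## expensive, so it is computed once per test session and memoized.

.fixtureCache <- new.env(parent = emptyenv())

## full default-scale pipeline result (~5 Mb genome, 54 libraries)
defaultPipelineFixture <- function(seed = 7) {
  key <- paste0("pipeline", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- suppressMessages(suppressWarnings(
      runPipeline(pipelineConfig(seed = seed))))
  .fixtureCache[[key]]
}

## reduced genome for simulation-heavy property tests (1 Mb, ~225 genes)
smallGenomeConfig <- function() {
  list(
    seqlens = c(chrA = 6e5, chrB = 4e5),
    pchFraction = 0.2,
    groups = data.frame(
      group        = c("C1",   "C3",  "C6",    "C7",    "C9",    "SC0"),
      supercluster = c("SC-I", "SC-I","SC-IIA","SC-IIB","SC-III","SC-0"),
      n            = c(50L,    40L,   30L,     15L,     30L,     60L),
      budget       = c(110e3,  90e3,  55e3,    30e3,    55e3,    70e3),
      stringsAsFactors = FALSE))
}

smallPreset <- function(seed = 3) {
  key <- paste0("smallpreset", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- buildGenomeModel(smallGenomeConfig(), seed = seed)
  .fixtureCache[[key]]
}

## one-chromosome toy track
toyTrack <- function(values, bin = 100, seqlen = length(values) * bin,
                     info = list()) {
  CoverageTrack(list(chr1 = values), binSize = bin, seqlens = c(chr1 = seqlen),
                info = info)
}

## independent O(n) scan oracle for broad-domain calling on one chromosome:
## above-cutoff bin runs, bp-gap merging, minimum-length filter
bruteDomains <- function(v, bin, seqlen, cutoff, minLen, maxGap) {
  above <- which(v >= cutoff)
  if (!length(above)) return(matrix(numeric(), ncol = 2))
  iv <- cbind((above - 1) * bin + 1, pmin(above * bin, seqlen))
  res <- list(); cs <- iv[1, 1]; ce <- iv[1, 2]
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] - ce - 1 <= maxGap) ce <- iv[r, 2]
    else { res[[length(res) + 1]] <- c(cs, ce); cs <- iv[r, 1]; ce <- iv[r, 2] }
  }
  res[[length(res) + 1]] <- c(cs, ce)
  m <- do.call(rbind, res)
  m[m[, 2] - m[, 1] + 1 >= minLen, , drop = FALSE]
}

## adjusted Rand index (independent implementation for clustering recovery)
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumij <- sum(comb2(tab))
  sumi <- sum(comb2(rowSums(tab)))
  sumj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- sumi * sumj / n2
  (sumij - exp_) / ((sumi + sumj) / 2 - exp_)
}

## build a GeneSignalMatrix directly from a fabricated signal matrix
toyGsm <- function(signal, feature, condition, pch = NULL) {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_len(nrow(signal)) * 1000, width = 500))
  genes$gene_id <- rownames(signal)
  tracksNA <- NULL
  cd <- S4Vectors::DataFrame(feature = feature, condition = condition,
                             row.names = colnames(signal))
  rr <- genes
  S4Vectors::mcols(rr)$pch <- if (is.null(pch)) rep(FALSE, nrow(signal)) else pch
  names(rr) <- genes$gene_id
  new("GeneSignalMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signal), rowRanges = rr, colData = cd))
}
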