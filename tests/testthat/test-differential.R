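## helper: wrap raw per-window counts as a count CoverageTrack "library"
countLib <- function(counts, bin = 250, id = "lib", condition = "A",
                     replicate = 1) {
  CoverageTrack(list(chr1 = counts), binSize = bin,
                seqlens = c(chr1 = length(counts) * bin),
                info = list(id = id, condition = condition, feature = "m",
                            replicate = replicate))
}

test_that("window counting sums bins and conserves library totals", {
  p <- smallPreset()
  lib <- simulateLibraryCounts(p, defaultEffectTable(), "GST", "K36me2",
                               depth = 3e4, seed = 12)
  se <- countWindows(list(lib), width = 250)
  expect_equal(sum(SummarizedExperiment::assay(se, "counts")),
               sum(unlist(libraryCounts(lib))))
  expect_equal(nrow(se), sum(ceiling(presetSeqlens(p) / 250)))
  ## hand-counted toy: bins (1,2,3,4,5,6) at 50 bp into 100-bp windows
  toy <- CoverageTrack(list(chr1 = c(1, 2, 3, 4, 5, 6)), 50L,
                       c(chr1 = 300), info = list(id = "t"))
  se2 <- countWindows(list(toy), width = 100)
  expect_equal(unname(SummarizedExperiment::assay(se2, "counts")[, 1]),
               c(3, 7, 11))
  ## empty library gives a zero column
  zero <- CoverageTrack(list(chr1 = rep(0, 6)), 50L, c(chr1 = 300),
                        info = list(id = "z"))
  se3 <- countWindows(list(toy, zero), width = 100)
  expect_true(all(SummarizedExperiment::assay(se3, "counts")[, 2] == 0))
  other <- CoverageTrack(list(chr2 = rep(0, 6)), 50L, c(chr2 = 300))
  expect_error(countWindows(list(toy, other)), "different genomes")
})

test_that("input filtering separates windows exactly at the fold threshold", {
  chip <- countLib(c(30, 29, 31, 0), id = "c")
  inp <- countLib(c(10, 10, 10, 10), id = "i")
  se <- countWindows(list(chip))
  ise <- countWindows(list(inp))
  kept <- filterWindowsByInput(se, ise, fold = 3)
  expect_equal(nrow(kept), 2)             # 30 and 31 pass, 29 and 0 fail
  all4 <- filterWindowsByInput(se, ise, fold = 0)
  expect_equal(nrow(all4), 4)             # fold 0 keeps everything
  expect_error(filterWindowsByInput(se, se, fold = 3), "lower the fold")
})

test_that("Z-score transform standardizes log-ratios over its universe", {
  ## three 5-kb windows with d = (-1, 0, 1) by construction (psi = 0.5)
  ctrl <- toyTrack(c(1.5, 1.5, 1.5), bin = 5000)
  rnai <- toyTrack(c(0.5, 1.5, 3.5), bin = 5000)
  z <- zscoreTransform(rnai, ctrl, window = 5000)
  expect_equal(z$d, c(-1, 0, 1))
  expect_equal(z$z, c(-1, 0, 1))          # sd of (-1,0,1) is exactly 1
  ## identical tracks: degenerate universe, all z zero with a warning
  expect_warning(z0 <- zscoreTransform(ctrl, ctrl, window = 5000),
                 "degenerate")
  expect_true(all(z0$z == 0))
  ## mean 0 / sd 1 invariant on a random pair, restricted to the universe
  set.seed(8)
  a <- toyTrack(rexp(200, 1), bin = 5000)
  b <- toyTrack(rexp(200, 1), bin = 5000)
  zz <- zscoreTransform(a, b, window = 5000)
  u <- !is.na(zz$z)
  expect_equal(mean(zz$z[u]), 0, tolerance = 1e-6)
  expect_equal(sd(zz$z[u]), 1, tolerance = 1e-6)
  ## consensus flag marks overlapping windows
  cons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4000))
  zc <- zscoreTransform(rnai, ctrl, window = 5000, consensus = cons)
  expect_equal(zc$consensus, c(TRUE, FALSE, FALSE))
})

test_that("planted depletion shows as negative z in SC-I but not PCH windows", {
  p <- smallPreset()
  eff <- defaultEffectTable()
  ex <- suppressMessages(simulateExperiment(
    p, eff, conditions = c("GST", "Set2"), features = "K36me3",
    replicates = 2, seed = 61))
  fac <- spikeScaleTotalReads(libraryStats(ex))
  man <- ex$manifest$libraries
  avg <- function(feat, cond) {
    ids <- man$id[man$feature == feat & man$condition == cond]
    averageTracks(lapply(ids, function(id)
      scaleTrack(asCoverageTrack(ex$libraries[[id]]),
                 fac$factor[fac$library_id == id])))
  }
  norm <- function(cond)
    inputNormalize(avg("K36me3", cond), avg("input", cond))
  z <- zscoreTransform(norm("Set2"), norm("GST"), window = 5000)
  win <- GenomicRanges::GRanges(z$chrom, IRanges::IRanges(z$start, z$end))
  genes <- presetGenes(p)
  sc1 <- GenomicRanges::countOverlaps(
    win, genes[genes$supercluster == "SC-I"]) > 0
  inPCH <- GenomicRanges::countOverlaps(win, presetPCH(p)) > 0 & !sc1
  ## depleted SC-I windows sit well below unaffected PCH windows on the z
  ## scale, and the absolute log-ratio of PCH windows is near zero (z itself
  ## is centred over a universe that contains the depleted windows)
  expect_lt(median(z$z[sc1], na.rm = TRUE),
            median(z$z[inPCH], na.rm = TRUE) - 1)
  expect_lt(abs(median(z$d[inPCH], na.rm = TRUE)), 0.3)
})

test_that("Simes combination matches the hand-computed oracle", {
  expect_equal(simesP(c(0.01, 0.04, 0.03)), 0.03)
  expect_equal(simesP(0.2), 0.2)
  expect_equal(simesP(c(0.5, 0.001)), 0.002)
})

test_that("window tests are calibrated under the null and powered", {
  ## null: label permutation of replicate libraries from one condition
  p <- smallPreset()
  eff <- defaultEffectTable()
  fracBelow <- sapply(1:5, function(s) {
    libs <- lapply(1:4, function(r)
      simulateLibraryCounts(p, eff, "GST", "K36me3", depth = 3e5,
                            replicate = r, seed = 700 + 10 * s + r))
    libs <- lapply(seq_along(libs), function(i) {
      l <- libs[[i]]
      l@info$id <- paste0("l", i)
      l@info$condition <- if (i <= 2) "GST" else "fake"
      l
    })
    se <- countWindows(libs, width = 250)
    inp <- simulateLibraryCounts(p, eff, "GST", "input", depth = 3e5,
                                 seed = 700 + 10 * s)
    inp@info$id <- "inp"
    ise0 <- countWindows(list(inp), width = 250)
    ise <- ise0[, rep(1, 4)]
    filt <- filterWindowsByInput(se, ise, fold = 3)
    tw <- suppressWarnings(testWindows(filt, condition = "fake",
                                       control = "GST"))
    mean(tw$PValue < 0.05)
  })
  expect_lt(mean(fracBelow), 0.05 + 2 * sd(fracBelow) / sqrt(5) + 0.02)
  ## power: planted 4x drop in 100 of 400 windows at ~50 counts/window
  set.seed(77)
  mkCounts <- function(mu) rnbinom(400, mu = mu, size = 1 / 0.05)
  muA <- rep(50, 400)
  muB <- muA; muB[1:100] <- muB[1:100] / 4
  libs <- list(
    countLib(mkCounts(muA), id = "a1", condition = "GST", replicate = 1),
    countLib(mkCounts(muA), id = "a2", condition = "GST", replicate = 2),
    countLib(mkCounts(muB), id = "b1", condition = "KD", replicate = 1),
    countLib(mkCounts(muB), id = "b2", condition = "KD", replicate = 2))
  se <- countWindows(libs, width = 250)
  tw <- testWindows(se, condition = "KD", control = "GST")
  expect_gt(mean(tw$PValue[1:100] < 0.01), 0.9)
  ## log2FC of an exact 2x change is close to -1
  set.seed(78)
  mu2 <- rep(400, 200)
  libs2 <- list(
    countLib(rpois(200, mu2), id = "a1", condition = "GST", replicate = 1),
    countLib(rpois(200, mu2), id = "a2", condition = "GST", replicate = 2),
    countLib(rpois(200, mu2 / 2), id = "b1", condition = "KD", replicate = 1),
    countLib(rpois(200, mu2 / 2), id = "b2", condition = "KD", replicate = 2))
  tw2 <- testWindows(countWindows(libs2, width = 250), condition = "KD")
  expect_equal(median(tw2$logFC), -1, tolerance = 0.05)
})

test_that("region merging caps spans, combines by Simes and controls FDR", {
  ## two significant windows 5 kb apart stay separate clusters
  w <- data.frame(chrom = "chr1", start = c(1, 5001), end = c(250, 5250),
                  logFC = c(-2, -2), PValue = c(0.001, 0.001))
  reg <- mergeAndFdr(w)
  expect_equal(nrow(reg), 2)
  ## chained adjacent windows respect the 3-kb cap
  n <- 24
  w2 <- data.frame(chrom = "chr1", start = seq(1, by = 250, length.out = n),
                   end = seq(250, by = 250, length.out = n),
                   logFC = -2, PValue = 0.001)
  reg2 <- mergeAndFdr(w2)
  expect_true(all(reg2$end - reg2$start + 1 <= 3000))
  expect_equal(sum(reg2$n_windows), n)
  ## directions match fold-change signs
  w3 <- data.frame(chrom = "chr1", start = c(1, 8001), end = c(250, 8250),
                   logFC = c(-2, 2), PValue = c(0.001, 0.001))
  reg3 <- mergeAndFdr(w3)
  expect_equal(reg3$direction, c("loss", "gain"))
  expect_true(all(reg3$significant))
  ## Simes p of a cluster matches the oracle
  w4 <- data.frame(chrom = "chr1", start = c(1, 251, 501),
                   end = c(250, 500, 750),
                   logFC = -2, PValue = c(0.01, 0.04, 0.03))
  reg4 <- mergeAndFdr(w4)
  expect_equal(nrow(reg4), 1)
  expect_equal(reg4$PValue, 0.03)
})

test_that("null pipelines call few clusters significant at FDR 0.05", {
  p <- smallPreset()
  eff <- defaultEffectTable()
  rates <- sapply(1:20, function(s) {
    libs <- lapply(1:4, function(r)
      simulateLibraryCounts(p, eff, "GST", "K36me3", depth = 2e5,
                            replicate = r, seed = 9000 + 20 * s + r))
    libs <- lapply(seq_along(libs), function(i) {
      l <- libs[[i]]
      l@info$id <- paste0("l", i)
      l@info$condition <- if (i <= 2) "GST" else "fake"
      l
    })
    se <- countWindows(libs, width = 250)
    inp <- simulateLibraryCounts(p, eff, "GST", "input", depth = 2e5,
                                 seed = 9000 + 20 * s)
    inp@info$id <- "inp"
    ise <- countWindows(list(inp), width = 250)[, rep(1, 4)]
    filt <- filterWindowsByInput(se, ise, fold = 3)
    ## edgeR's variance-offset notices are expected at this replicate depth
    tw <- suppressWarnings(testWindows(filt, condition = "fake",
                                       control = "GST"))
    reg <- mergeAndFdr(tw)
    if (nrow(reg) == 0) 0 else sum(reg$q <= 0.05) / nrow(reg)
  })
  expect_lte(mean(rates), 0.05)
})
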