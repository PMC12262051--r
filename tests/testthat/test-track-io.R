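test_that("bedGraph records import at the documented coordinate convention", {
  f <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t100\t5.0", f)
  tr <- readBedGraphTrack(f, binSize = 100, seqlens = c(chr1 = 100))
  expect_equal(trackSignal(tr)$chr1, 5.0)
  ## 0-based half-open on disk: [100, 200) lands entirely in bin 2 of 2
  writeLines("chr1\t100\t200\t4.0", f)
  tr2 <- readBedGraphTrack(f, binSize = 100, seqlens = c(chr1 = 200))
  expect_equal(trackSignal(tr2)$chr1, c(0, 4))
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), f)
  expect_error(readBedGraphTrack(f, 50, c(chr1 = 200)), "overlapping")
  writeLines("chrZ\t0\t100\t1", f)
  expect_error(readBedGraphTrack(f, 50, c(chr1 = 200)), "chrZ")
})

test_that("bedGraph round trip is lossless at bin resolution", {
  set.seed(4)
  tr <- CoverageTrack(list(chrA = rpois(40, 5), chrB = rpois(25, 2)),
                      binSize = 50,
                      seqlens = c(chrA = 2000, chrB = 1230))
  f <- tempfile(fileext = ".bedGraph")
  writeBedGraphTrack(tr, f)
  back <- readBedGraphTrack(f, 50, seqlens = trackSeqlens(tr))
  expect_equal(trackSignal(back), trackSignal(tr), tolerance = 1e-12)
})

test_that("GTF-lite gene models convert from 1-based closed coordinates", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t300\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "gA";'), f)
  gm <- readGtfGenes(f)
  ## the exon printed as (101, 200) covers half-open [100, 200): 100 bp
  expect_equal(GenomicRanges::start(gm$exons), 101)
  expect_equal(GenomicRanges::end(gm$exons), 200)
  expect_equal(GenomicRanges::width(gm$exons), 100)
  expect_equal(gm$genes$gene_id, "gA")
})

test_that("total-reads spike factors follow C / spike_reads", {
  st <- data.frame(library_id = c("a", "b"), spike_reads = c(1e6, 5e5))
  f <- spikeScaleTotalReads(st)
  expect_equal(f$factor, c(1, 2))
  expect_error(spikeScaleTotalReads(
    data.frame(library_id = "z", spike_reads = 0)), "spike")
})

test_that("TMM factors match direct expectations and are permutation invariant", {
  set.seed(11)
  base <- rpois(400, 60) + 10
  m <- cbind(lib1 = base, lib2 = base)
  f <- spikeScaleTMM(m, highSignalQuantile = 0)
  expect_equal(f$factor, c(1, 1), tolerance = 1e-9)
  ## a library scaled by exactly 2: every M-value is log2(2), so the trimmed
  ## mean is exact and the geometric-mean-1 factors have ratio 0.5
  m2 <- cbind(lib1 = base, lib2 = 2L * base)
  f2 <- spikeScaleTMM(m2, highSignalQuantile = 0)
  expect_equal(f2$factor[2] / f2$factor[1], 0.5, tolerance = 1e-6)
  expect_equal(exp(mean(log(f2$factor))), 1, tolerance = 1e-9)
  perm <- sample(nrow(m2))
  f3 <- spikeScaleTMM(m2[perm, ], highSignalQuantile = 0)
  expect_equal(f3$factor, f2$factor, tolerance = 1e-12)
  expect_error(spikeScaleTMM(m2[1:40, ], highSignalQuantile = 0.9),
               "high-signal")
})

test_that("TMM and total-reads factors agree without composition bias", {
  p <- smallPreset()
  ex <- suppressMessages(simulateExperiment(
    p, conditions = c("GST", "Set2"), features = "K36me3", seed = 21))
  tot <- spikeScaleTotalReads(libraryStats(ex))
  tmm <- spikeScaleTMM(spikeBinCounts(ex, seed = 21))
  ## compare shapes after normalizing both to geometric mean 1
  tg <- tot$factor / exp(mean(log(tot$factor)))
  expect_true(all(abs(tmm$factor / tg - 1) < 0.10))
})

test_that("input normalization modes follow their definitions", {
  chip <- toyTrack(c(4, 2, 8, 1, 0))
  inp <- toyTrack(c(2, 2, 2, 2, 2))
  same <- inputNormalize(chip, chip)
  expect_true(all(trackSignal(same)$chr1 == 0))
  sub <- inputNormalize(chip, inp)
  expect_equal(trackSignal(sub)$chr1, c(2, 0, 6, 0, 0))  # floored at 0
  rat <- inputNormalize(toyTrack(c(4, 4)), toyTrack(c(2, 2)),
                        mode = "ratio", psi = 1e-9)
  expect_equal(trackSignal(rat)$chr1, c(2, 2), tolerance = 1e-6)
  expect_error(inputNormalize(chip, toyTrack(c(1, 2), bin = 50, seqlen = 100)),
               "mismatch")
})

test_that("spike scaling removes planted depth jitter and recovers depletion", {
  p <- smallPreset()
  ## global x0.5 K36me3 depletion in the "Set2" condition
  eff <- defaultEffectTable()
  extra <- data.frame(group = c("C1", "C3", "C6", "C7"), condition = "Set2",
                      feature = "K36me3", effect = 0.5)
  eff2 <- rbind(eff[!(eff$condition == "Set2" & eff$feature == "K36me3"), ],
                extra)
  attributes(eff2)[c("conditions", "features")] <-
    attributes(eff)[c("conditions", "features")]
  ex <- suppressMessages(simulateExperiment(
    p, eff2, conditions = c("GST", "Set2"),
    features = c("K36me3"), replicates = 2, seed = 31))
  fac <- spikeScaleTotalReads(libraryStats(ex))
  sc <- function(id) scaleTrack(asCoverageTrack(ex$libraries[[id]]),
                                fac$factor[fac$library_id == id])
  man <- ex$manifest$libraries
  dom <- plantedDomains(p)$K36me3
  domMean <- function(tr) {
    rle <- k36land:::trackRle(tr)
    v <- unlist(lapply(unique(as.character(GenomicRanges::seqnames(dom))),
      function(chr) {
        sel <- as.character(GenomicRanges::seqnames(dom)) == chr
        k36land:::rleRangeMeans(rle[[chr]], IRanges::ranges(dom)[sel])
      }))
    mean(v)
  }
  gst <- mean(sapply(man$id[man$condition == "GST" & man$feature == "K36me3"],
                     function(id) domMean(sc(id))))
  set2 <- mean(sapply(man$id[man$condition == "Set2" & man$feature == "K36me3"],
                      function(id) domMean(sc(id))))
  bg <- mean(sapply(man$id[man$feature == "input"], function(id)
    trackMean(sc(id))))
  ## planted multiplier on the enrichment excess over the input baseline
  expect_equal((set2 - bg) / (gst - bg), 0.5, tolerance = 0.05)
  ## depth jitter removal: CV of scaled genome-wide input means < 5%
  exBig <- suppressMessages(simulateExperiment(
    p, conditions = c("GST", "Set2", "NSD", "Ash1", "DKD", "TKD"),
    features = "K36me3", replicates = 1, seed = 33))
  fb <- spikeScaleTotalReads(libraryStats(exBig))
  manB <- exBig$manifest$libraries
  inMeans <- sapply(manB$id[manB$feature == "input"], function(id)
    trackMean(scaleTrack(asCoverageTrack(exBig$libraries[[id]]),
                         fb$factor[fb$library_id == id])))
  jitters <- manB$jitter[manB$feature == "input"]
  expect_gt(sd(jitters) / mean(jitters), 0.05)  # jitter was actually planted
  expect_lt(sd(inMeans) / mean(inMeans), 0.05)  # and scaling removed it
})

test_that("fixture sets round-trip losslessly with a complete manifest", {
  p <- smallPreset()
  ex <- suppressMessages(simulateExperiment(
    p, conditions = "GST", features = "K36me2", replicates = 1, seed = 41))
  dir <- file.path(tempdir(), "fixtureset")
  writeFixtureSet(ex, dir, p)
  back <- readFixtureSet(dir)
  expect_setequal(names(back$tracks), names(ex$libraries))
  for (id in names(ex$libraries)) {
    orig <- lapply(k36land::libraryCounts(ex$libraries[[id]]), as.numeric)
    expect_equal(trackSignal(back$tracks[[id]]), orig, tolerance = 1e-9)
  }
  ## one spike count per library
  expect_equal(nrow(back$spikeStats), length(ex$libraries))
  expect_equal(back$spikeStats$spike_reads,
               unname(sapply(ex$libraries, spikeReads)))
  ## genome fractions recomputed from the written BED match the preset
  G <- sum(presetSeqlens(p))
  for (mark in names(plantedDomains(p))) {
    fromBed <- sum(GenomicRanges::width(back$domains[[mark]])) / G
    fromPreset <- sum(GenomicRanges::width(plantedDomains(p)[[mark]])) / G
    expect_equal(fromBed, fromPreset, tolerance = 1e-9)
  }
  ## manifest supports exact replay
  m <- back$manifest
  ex2 <- suppressMessages(simulateExperiment(
    p, conditions = "GST", features = "K36me2", replicates = 1,
    seed = m$seed, depth = m$depth, bin = m$bin, noise = m$noise,
    spikeFraction = m$spikeFraction, jitterSd = m$jitterSd))
  expect_identical(libraryCounts(ex2$libraries[[1]]),
                   libraryCounts(ex$libraries[[1]]))
})
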