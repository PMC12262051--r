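## Track and annotation I/O plus spike-in normalization.
##
## External formats follow their native conventions (bedGraph/BED 0-based
## half-open, GTF 1-based closed); rtracklayer performs the conversions and
## everything internal uses Bioconductor 1-based closed GRanges/IRanges
## arithmetic, where adjacent BED intervals [a,b),[b,c) import as
## non-overlapping ranges.

#' Read a bedGraph file into a CoverageTrack
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param binSize bin size of the returned track.
#' @param seqlens named chromosome lengths; if `NULL`, inferred from the
#'   rightmost record per chromosome. If given, records on chromosomes absent
#'   from `seqlens` raise an error listing them.
#' @param info library metadata list.
#' @return a [CoverageTrack-class]; bin values are coverage-weighted means of
#'   the records overlapping each bin (positions without records count as 0).
#' @export
readBedGraphTrack <- function(path, binSize, seqlens = NULL, info = list()) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(seqlens)) {
    seqlens <- tapply(end(gr), as.character(seqnames(gr)), max)
    seqlens <- stats::setNames(as.numeric(seqlens), names(seqlens))
  } else {
    unknown <- setdiff(unique(as.character(seqnames(gr))), names(seqlens))
    if (length(unknown))
      stop("unknown chromosome(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
  }
  if (!isDisjoint(granges(gr)))
    stop("overlapping bedGraph records in ", path, " (ambiguous signal)")
  sig <- list()
  for (chr in names(seqlens)) {
    sub <- gr[seqnames(gr) == chr]
    sl <- seqlens[[chr]]
    rle <- coverage(ranges(sub), weight = sub$score, width = as.integer(sl))
    st <- binStarts(sl, binSize)
    sig[[chr]] <- as.numeric(viewMeans(Views(rle,
      IRanges(st, width = binWidths(sl, binSize)))))
  }
  CoverageTrack(sig, binSize, seqlens, info)
}

#' Write a CoverageTrack as bedGraph
#'
#' Adjacent equal-valued bins are merged into single records; round trip
#' through [readBedGraphTrack()] at the same bin size is lossless.
#'
#' @param track a [CoverageTrack-class].
#' @param path output file.
#' @export
writeBedGraphTrack <- function(track, path) {
  grl <- list()
  for (chr in names(track@signal)) {
    sl <- track@seqlens[[chr]]
    bin <- track@binSize
    r <- rle(track@signal[[chr]])
    endBin <- cumsum(r$lengths)
    startBin <- c(1L, utils::head(endBin, -1) + 1L)
    gr <- GRanges(chr, IRanges((startBin - 1L) * bin + 1L,
                               pmin(endBin * bin, as.integer(sl))),
                  score = r$values)
    grl[[chr]] <- gr
  }
  rtracklayer::export(bindGR(grl), path, format = "bedGraph")
  invisible(path)
}

#' Read a BED annotation file
#'
#' @param path BED3/BED6 file (0-based half-open on disk).
#' @return GRanges (1-based closed, Bioconductor convention).
#' @export
readBedAnnotation <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write intervals as BED6
#'
#' @param gr GRanges; mcol `name` (or `gene_id`) becomes the name field, mcol
#'   `score` (numeric) is clamped to the integer 0-1000 BED score with the
#'   float value preserved in a sidecar column of `<path>.scores.tsv`.
#' @param path output file.
#' @export
writeBedAnnotation <- function(gr, path) {
  out <- granges(gr)
  nm <- if (!is.null(gr$name)) gr$name else gr$gene_id
  out$name <- if (is.null(nm)) sprintf("feature_%d", seq_along(gr)) else nm
  if (!is.null(gr$score)) {
    out$score <- pmax(0L, pmin(1000L, as.integer(round(gr$score))))
    utils::write.table(
      data.frame(name = out$name, score = gr$score),
      paste0(path, ".scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else out$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read gene models from a GTF-lite file
#'
#' Accepts any GTF/GFF2 with `gene` and `exon` rows carrying `gene_id`
#' attributes (1-based closed on disk, converted by rtracklayer).
#'
#' @param path GTF file.
#' @return list with `genes` (GRanges, mcol `gene_id`) and `exons` (GRanges,
#'   mcol `gene_id`).
#' @export
readGtfGenes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  g <- granges(genes); g$gene_id <- genes$gene_id
  e <- granges(exons); e$gene_id <- exons$gene_id
  list(genes = g, exons = e)
}

#' Read / write a spike-in library statistics table
#'
#' Tab-delimited with columns `library_id`, `target_reads`, `spike_reads`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readSpikeStats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("library_id", "target_reads", "spike_reads") %in% colnames(df)))
  df
}

#' @rdname readSpikeStats
#' @param stats data.frame as returned by [libraryStats()].
#' @export
writeSpikeStats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spike-in scale factors from total spike-mapped reads
#'
#' factor = C / spike_reads with C = 1e6; scaling a library's track by its
#' factor places all libraries on a common absolute (spike-calibrated) scale.
#'
#' @param stats data.frame with `library_id` and `spike_reads` (see
#'   [libraryStats()], [readSpikeStats()]).
#' @param C numerator constant (reads).
#' @return data.frame with `library_id`, `factor`, `mode`.
#' @examples
#' spikeScaleTotalReads(data.frame(library_id = "a", spike_reads = 5e5))$factor
#' @export
spikeScaleTotalReads <- function(stats, C = 1e6) {
  if (any(stats$spike_reads <= 0))
    stop("spike-in read count must be > 0 for spike scaling (library ",
         paste(stats$library_id[stats$spike_reads <= 0], collapse = ", "), ")")
  data.frame(library_id = stats$library_id,
             factor = C / stats$spike_reads,
             mode = "total-reads", row.names = NULL)
}

#' Spike-in scale factors by trimmed mean of M-values on high-signal bins
#'
#' Filters spike-genome windows to the high-signal fraction, computes TMM
#' factors (log-ratio trim 30%, abundance trim 5%) on the raw bin counts with
#' equal library sizes -- so M-values are direct between-library bin
#' log-ratios -- and returns multiplicative scale factors renormalized to
#' geometric mean 1.
#'
#' @param spikeCounts windows x libraries count matrix (see [spikeBinCounts()]).
#' @param highSignalQuantile retain windows with mean count at or above this
#'   quantile (default top 25%).
#' @param minBins minimum windows required after filtering.
#' @return data.frame with `library_id`, `factor`, `mode`.
#' @export
spikeScaleTMM <- function(spikeCounts, highSignalQuantile = 0.75,
                          minBins = 50) {
  stopifnot(is.matrix(spikeCounts), ncol(spikeCounts) >= 2)
  keep <- rowMeans(spikeCounts) >=
    stats::quantile(rowMeans(spikeCounts), highSignalQuantile)
  if (sum(keep) < minBins)
    stop("only ", sum(keep), " high-signal spike bins after filtering; ",
         "lower highSignalQuantile")
  m <- spikeCounts[keep, , drop = FALSE]
  nf <- edgeR::calcNormFactors(m, lib.size = rep(1e6, ncol(m)),
                               method = "TMM",
                               logratioTrim = 0.3, sumTrim = 0.05)
  s <- 1 / nf
  s <- s / exp(mean(log(s)))
  data.frame(library_id = colnames(spikeCounts) %||%
               paste0("lib", seq_along(s)),
             factor = s, mode = "trimmed-M", row.names = NULL)
}

#' Input-normalize a ChIP coverage track
#'
#' Default mode subtracts the scaled input from the scaled ChIP and floors at
#' zero; ratio mode returns `(chip + psi) / (input + psi)` on the scaled
#' tracks.
#'
#' @param chip,input [CoverageTrack-class] on the same genome and bin size.
#' @param chipFactor,inputFactor spike scale factors applied before combining.
#' @param mode `"subtract"` (default) or `"ratio"`.
#' @param psi pseudocount for ratio mode.
#' @return a [CoverageTrack-class] of input-normalized signal.
#' @export
inputNormalize <- function(chip, input, chipFactor = 1, inputFactor = 1,
                           mode = c("subtract", "ratio"), psi = PSEUDOCOUNT) {
  mode <- match.arg(mode)
  if (binSize(chip) != binSize(input))
    stop("bin-size mismatch: chip ", binSize(chip), " vs input ",
         binSize(input))
  stopifnot(identical(chip@seqlens, input@seqlens))
  sig <- list()
  for (chr in names(chip@signal)) {
    cv <- chip@signal[[chr]] * chipFactor
    iv <- input@signal[[chr]] * inputFactor
    sig[[chr]] <- if (mode == "subtract") pmax(cv - iv, 0)
                  else (cv + psi) / (iv + psi)
  }
  info <- chip@info
  info$normalized <- mode
  CoverageTrack(sig, binSize(chip), chip@seqlens, info)
}

#' Write a simulated experiment as a plain-text fixture set
#'
#' Emits one bedGraph of binned counts per library, BED annotations (genes,
#' exons, PCH blocks, planted group "state" intervals, planted per-mark
#' domains), the spike-in statistics TSV, a gene-metadata TSV and a JSON
#' manifest. Everything round-trips through [readFixtureSet()] losslessly at
#' bin resolution.
#'
#' @param experiment a `SimulatedExperiment`.
#' @param dir output directory (created if needed).
#' @param preset the [GenomePreset-class] the experiment was simulated from.
#' @return `dir`, invisibly.
#' @export
writeFixtureSet <- function(experiment, dir, preset) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create fixture directory ", dir)
  for (id in names(experiment$libraries))
    writeBedGraphTrack(countTrack(experiment$libraries[[id]]),
                       file.path(dir, paste0(id, ".bedGraph")))
  writeBedAnnotation(preset@genes, file.path(dir, "genes.bed"))
  writeBedAnnotation(preset@exons, file.path(dir, "exons.bed"))
  writeBedAnnotation(preset@pch, file.path(dir, "pch.bed"))
  states <- preset@genes
  if (length(states)) states$name <- states$group
  writeBedAnnotation(states, file.path(dir, "states.bed"))
  for (mark in names(preset@domains)) {
    d <- preset@domains[[mark]]
    if (length(d)) d$name <- d$group
    writeBedAnnotation(d, file.path(dir, paste0("domains_", mark, ".bed")))
  }
  writeSpikeStats(libraryStats(experiment), file.path(dir, "spike_counts.tsv"))
  if (length(preset@genes))
    utils::write.table(
      as.data.frame(mcols(preset@genes)),
      file.path(dir, "gene_groups.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  man <- experiment$manifest
  man$seqlens <- as.list(preset@seqlens)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

## track of raw bin counts (not per-bp coverage) for lossless fixture output
countTrack <- function(lib) {
  CoverageTrack(lapply(lib@counts, as.numeric), lib@binSize, lib@seqlens,
                lib@info)
}

#' Read a fixture set written by [writeFixtureSet()]
#'
#' @param dir fixture directory.
#' @return list: `tracks` (named list of count [CoverageTrack-class]s),
#'   `genes`, `exons`, `pch`, `domains` (per-mark GRanges), `spikeStats`,
#'   `manifest`.
#' @export
readFixtureSet <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  seqlens <- unlist(man$seqlens)
  bin <- man$bin
  ids <- man$libraries$id
  tracks <- lapply(ids, function(id)
    readBedGraphTrack(file.path(dir, paste0(id, ".bedGraph")), bin, seqlens,
                      info = as.list(man$libraries[man$libraries$id == id, ])))
  names(tracks) <- ids
  domFiles <- list.files(dir, pattern = "^domains_.*\\.bed$")
  domains <- lapply(domFiles, function(f) readBedAnnotation(file.path(dir, f)))
  names(domains) <- sub("^domains_(.*)\\.bed$", "\\1", domFiles)
  list(tracks = tracks,
       genes = readBedAnnotation(file.path(dir, "genes.bed")),
       exons = readBedAnnotation(file.path(dir, "exons.bed")),
       pch = readBedAnnotation(file.path(dir, "pch.bed")),
       domains = domains,
       spikeStats = readSpikeStats(file.path(dir, "spike_counts.tsv")),
       manifest = man)
}
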