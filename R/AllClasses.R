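#' @import methods
#' @importFrom BiocGenerics sort
#' @importFrom S4Vectors DataFrame Rle metadata metadata<-
#' @importFrom GenomicRanges GRanges granges coverage seqnames start end width
#'   strand mcols mcols<- findOverlaps countOverlaps reduce
#' @importFrom IRanges IRanges Views viewMeans ranges isDisjoint
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
NULL

#' CoverageTrack: binned genomic signal
#'
#' The universal currency between pipeline stages: one numeric vector of signal
#' per chromosome at a fixed bin size, plus library metadata. Values are in
#' arbitrary coverage units (fragments per bp before scaling; spike-calibrated
#' units after [spikeScaleTotalReads()] + [scaleTrack()]; enrichment over input
#' after [inputNormalize()]).
#'
#' @slot signal named list of numeric vectors, one per chromosome; element
#'   `i` covers base pairs `[(i-1)*binSize, i*binSize)` (the trailing bin may
#'   be shorter).
#' @slot binSize integer bin width in bp.
#' @slot seqlens named numeric vector of chromosome lengths in bp.
#' @slot info list of library metadata (id, condition, feature, replicate, units).
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(signal = "list", binSize = "integer",
                 seqlens = "numeric", info = "list"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (object@binSize < 1L) msg <- c(msg, "binSize must be >= 1")
  if (is.null(names(object@seqlens)) || is.null(names(object@signal)))
    msg <- c(msg, "signal and seqlens must be named by chromosome")
  if (!identical(sort(names(object@signal)), sort(names(object@seqlens))))
    msg <- c(msg, "signal and seqlens chromosome names differ")
  for (chr in names(object@signal)) {
    n.exp <- as.integer(ceiling(object@seqlens[[chr]] / object@binSize))
    v <- object@signal[[chr]]
    if (length(v) != n.exp)
      msg <- c(msg, sprintf("chromosome %s: %d bins, expected %d",
                            chr, length(v), n.exp))
    if (any(!is.finite(v)))
      msg <- c(msg, sprintf("chromosome %s: non-finite signal", chr))
  }
  if (length(msg)) msg else TRUE
})

#' GenomePreset: planted synthetic genome architecture
#'
#' Chromosome sizes, pericentric heterochromatin (PCH) blocks, gene models with
#' planted cluster-group and supercluster labels, exon structure, enhancer
#' intervals, per-feature enrichment geometry (excess coverage over the input
#' baseline) and the planted per-mark domain footprints with their target
#' genome fractions.
#'
#' @slot seqlens named numeric, chromosome lengths (bp).
#' @slot pch GRanges of pericentric heterochromatin blocks.
#' @slot genes GRanges with mcols `gene_id`, `group` (planted cluster label),
#'   `supercluster`, `pch` (logical).
#' @slot exons GRanges with mcol `gene_id` (disjoint within each gene).
#' @slot enhancers GRanges of intergenic K36me1 domains.
#' @slot enrichment named list (by feature) of GRanges with mcols `excess`
#'   (enrichment over input baseline, unitless) and `group` (effect key).
#' @slot domains named list (by mark) of GRanges: planted strong domains whose
#'   summed length defines the planted genome fraction.
#' @slot fractions named numeric, target genome fraction per mark.
#' @slot params list of generator parameters (for the manifest).
#' @exportClass GenomePreset
setClass("GenomePreset",
  representation(seqlens = "numeric", pch = "GRanges", genes = "GRanges",
                 exons = "GRanges", enhancers = "GRanges",
                 enrichment = "list", domains = "list",
                 fractions = "numeric", params = "list"))

setValidity("GenomePreset", function(object) {
  msg <- character()
  g <- object@genes
  if (length(g)) {
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicated gene ids")
    sl <- object@seqlens[as.character(seqnames(g))]
    if (any(start(g) < 1) || any(end(g) > sl))
      msg <- c(msg, "gene intervals exceed chromosome bounds")
    if (any(!g$supercluster %in% c("SC-I", "SC-IIA", "SC-IIB", "SC-III", "SC-0")))
      msg <- c(msg, "unknown supercluster label")
    ## SC-IIB genes lie inside PCH, SC-IIA outside
    iib <- g[g$supercluster == "SC-IIB"]
    if (length(iib) && !all(countOverlaps(iib, object@pch, type = "within") > 0))
      msg <- c(msg, "SC-IIB gene outside PCH")
    iia <- g[g$supercluster == "SC-IIA"]
    if (length(iia) && any(countOverlaps(iia, object@pch) > 0))
      msg <- c(msg, "SC-IIA gene overlapping PCH")
    ## exons within their gene, non-overlapping per gene
    ex <- object@exons
    if (length(ex)) {
      hit <- findOverlaps(ex, g, type = "within")
      ok <- tapply(g$gene_id[S4Vectors::subjectHits(hit)],
                   S4Vectors::queryHits(hit), function(z) any(z == TRUE))
      m <- match(ex$gene_id, g$gene_id)
      if (any(is.na(m))) msg <- c(msg, "exon with unknown gene_id")
      else {
        within.ok <- start(ex) >= start(g)[m] & end(ex) <= end(g)[m]
        if (!all(within.ok)) msg <- c(msg, "exon outside its gene")
        for (gid in unique(ex$gene_id[duplicated(ex$gene_id)])) {
          e <- ex[ex$gene_id == gid]
          if (length(reduce(e)) != length(e))
            { msg <- c(msg, "overlapping exons within a gene"); break }
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimulatedLibrary: one synthetic sequencing library
#'
#' Binned fragment counts for the target genome plus the spike-in mapped-read
#' total and library metadata, as produced by [simulateLibraryCounts()].
#'
#' @slot counts named list of integer vectors (per-chromosome binned counts).
#' @slot binSize integer bin width (bp).
#' @slot seqlens named numeric chromosome lengths.
#' @slot spikeReads numeric, spike-in genome mapped reads.
#' @slot info list: id, condition, feature, replicate, depth, seed.
#' @exportClass SimulatedLibrary
setClass("SimulatedLibrary",
  representation(counts = "list", binSize = "integer", seqlens = "numeric",
                 spikeReads = "numeric", info = "list"))

setValidity("SimulatedLibrary", function(object) {
  msg <- character()
  for (chr in names(object@counts)) {
    v <- object@counts[[chr]]
    if (any(v < 0) || any(v != round(v)))
      msg <- c(msg, sprintf("chromosome %s: counts must be non-negative integers", chr))
  }
  if (object@spikeReads < 0) msg <- c(msg, "spikeReads must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DomainSet: broad enriched domains for one mark
#'
#' Sorted, non-overlapping intervals with a mean-signal score, as returned by
#' [callBroadDomains()].
#'
#' @slot ranges GRanges with mcol `score` (mean in-domain signal).
#' @slot params list: cutoff, minLen, maxGap.
#' @slot mark character, source mark (e.g. "K36me2").
#' @slot condition character, source condition.
#' @exportClass DomainSet
setClass("DomainSet",
  representation(ranges = "GRanges", params = "list",
                 mark = "character", condition = "character"))

setValidity("DomainSet", function(object) {
  r <- object@ranges
  msg <- character()
  if (length(r) > 1) {
    if (length(reduce(r, min.gapwidth = 0L)) != length(r))
      msg <- c(msg, "domains must be non-overlapping")
  }
  if (length(r) && !is.null(object@params$minLen) &&
      any(width(r) < object@params$minLen))
    msg <- c(msg, "domain shorter than minLen")
  if (length(msg)) msg else TRUE
})

#' GeneSignalMatrix: genes x (feature, condition) mean gene-body signal
#'
#' A thin SummarizedExperiment subclass: one assay `"signal"` holding mean
#' spike-calibrated, input-normalized gene-body signal; `colData` carries
#' `feature` and `condition`; `rowData` carries gene metadata (length,
#' intron fraction, PCH flag and, for synthetic input, planted labels).
#'
#' @exportClass GeneSignalMatrix
setClass("GeneSignalMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("GeneSignalMatrix", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' required")
  else if (any(SummarizedExperiment::assay(object, "signal") < 0, na.rm = TRUE))
    msg <- c(msg, "signal must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("feature", "condition") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'feature' and 'condition'")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicated gene ids")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: gene clusters and superclusters
#'
#' @slot assignment data.frame with columns `gene_id`, `cluster` and (after
#'   [assignSuperclusters()]) `supercluster`.
#' @slot centers matrix of cluster centroids in raw signal units
#'   (clusters x columns of the clustered matrix).
#' @slot zcenters matrix of centroids in the standardized space used by k-means.
#' @slot k integer number of clusters.
#' @slot seed integer clustering seed.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(assignment = "data.frame", centers = "matrix",
                 zcenters = "matrix", k = "integer", seed = "integer",
                 superclusters = "character"))

#' HillFit: specific-binding-with-Hill-slope fit
#'
#' Parameters of F(c) = F0 + A * c^h / (Kd^h + c^h) fitted to a
#' concentration-response series.
#'
#' @slot estimate named numeric: Kd, h, A, F0.
#' @slot se named numeric standard errors (from the curvature at the optimum).
#' @slot converged logical.
#' @slot rss numeric residual sum of squares.
#' @slot data data.frame of the fitted points (concentration_M, response).
#' @exportClass HillFit
setClass("HillFit",
  representation(estimate = "numeric", se = "numeric", converged = "logical",
                 rss = "numeric", data = "data.frame"))

setValidity("HillFit", function(object) {
  e <- object@estimate
  msg <- character()
  if (!all(c("Kd", "h", "A", "F0") %in% names(e)))
    msg <- c(msg, "estimate must name Kd, h, A, F0")
  else {
    if (e[["Kd"]] <= 0) msg <- c(msg, "Kd must be > 0")
    if (e[["h"]] < 0.5 || e[["h"]] > 4) msg <- c(msg, "h must lie in [0.5, 4]")
  }
  if (!is.finite(object@rss)) msg <- c(msg, "residual sum must be finite")
  if (length(msg)) msg else TRUE
})
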