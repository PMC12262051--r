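## Broad-domain calling and domain-set summaries.

#' Call broad enriched domains on an input-normalized track
#'
#' Maximal runs of bins with signal at or above the cutoff are taken; runs
#' separated by at most `maxGap` bp are merged; merged runs shorter than
#' `minLen` are discarded. The score of each domain is its mean signal. The
#' defaults for the K36 methylation marks are cutoff 3 and minimum length
#' 1000 bp; 0.8 and 2.0 are the matching cutoffs for K27me3 and K9me2 broad
#' domains.
#'
#' @param track an input-normalized [CoverageTrack-class].
#' @param cutoff signal cutoff `c` (> 0).
#' @param minLen minimum domain length in bp (> 0).
#' @param maxGap maximum gap (bp) across which above-cutoff runs are merged.
#' @param mark,condition labels stored on the result.
#' @return a [DomainSet-class].
#' @export
callBroadDomains <- function(track, cutoff = 3, minLen = 1000, maxGap = 100,
                             mark = NA_character_, condition = NA_character_) {
  stopifnot(is(track, "CoverageTrack"), cutoff > 0, minLen > 0, maxGap >= 0)
  bin <- binSize(track)
  out <- list()
  for (chr in names(track@signal)) {
    v <- track@signal[[chr]]
    above <- v >= cutoff
    if (!any(above)) next
    r <- IRanges(above)                      # runs of TRUE, in bin units
    gr <- IRanges(start = (start(r) - 1L) * bin + 1L,
                  end = pmin(end(r) * bin, as.integer(track@seqlens[[chr]])))
    gr <- reduce(gr, min.gapwidth = maxGap + 1L)
    gr <- gr[width(gr) >= minLen]
    if (!length(gr)) next
    rle <- S4Vectors::Rle(v, binWidths(track@seqlens[[chr]], bin))
    res <- GRanges(chr, gr)
    res$score <- rleRangeMeans(rle, gr)
    out[[chr]] <- res
  }
  ranges <- if (length(out)) sort(bindGR(out)) else {
    empty <- GRanges(); empty$score <- numeric(); empty
  }
  new("DomainSet", ranges = ranges,
      params = list(cutoff = cutoff, minLen = minLen, maxGap = maxGap),
      mark = mark, condition = condition)
}

setMethod("show", "DomainSet", function(object) {
  cat(sprintf("DomainSet (%s, %s): %d domains, %.3g bp total\n",
              object@mark, object@condition, length(object@ranges),
              sum(width(object@ranges))))
  p <- object@params
  cat(sprintf("  params: cutoff=%.3g minLen=%d maxGap=%d\n",
              p$cutoff, as.integer(p$minLen), as.integer(p$maxGap)))
})

#' @rdname DomainSet-class
#' @export
setMethod("domainRanges", "DomainSet", function(x) x@ranges)

#' @rdname genomeFraction
#' @export
setMethod("genomeFraction", signature("DomainSet", "ANY"),
  function(domains, genome) {
    genomeFraction(domains@ranges, genome)
  })

#' @rdname genomeFraction
#' @export
setMethod("genomeFraction", signature("GRanges", "ANY"),
  function(domains, genome) {
    sl <- genomeSeqlens(genome)
    if (length(domains) == 0) return(0)
    if (any(end(domains) > sl[as.character(seqnames(domains))]))
      stop("domains exceed genome bounds")
    sum(as.numeric(width(reduce(domains)))) / sum(sl)
  })

#' Keep the strongest decile of domains
#'
#' Retains domains whose score is at or above the 90th percentile of all
#' scores; ties at the threshold are all retained.
#'
#' @param domains a [DomainSet-class] with at least 10 domains.
#' @return a filtered [DomainSet-class].
#' @export
topDecileFilter <- function(domains) {
  r <- domainRanges(domains)
  if (length(r) < 10)
    stop("top-decile filtering needs at least 10 domains (got ",
         length(r), ")")
  thr <- stats::quantile(r$score, 0.9, type = 7)
  domains@ranges <- r[r$score >= thr]
  domains
}

#' Annotate domains with genomic feature classes
#'
#' Each domain is assigned by its midpoint with precedence
#' promoter > TTS > exon > intron > intergenic. The promoter window is
#' `[TSS - 1000, TSS + 100)` and the TTS window `[TTS - 100, TTS + 1000)`,
#' strand-aware. Genes without exon records are treated as single-exon (with
#' a message). Whole-domain overlap annotation is available as an option.
#'
#' @param domains a [DomainSet-class] or GRanges.
#' @param genes GRanges of genes with mcol `gene_id` and strand.
#' @param exons GRanges of exons with mcol `gene_id` (may omit some genes).
#' @param promoterUp,promoterDown promoter window extent upstream/downstream
#'   of the TSS (bp).
#' @param ttsUp,ttsDown TTS window extent upstream/downstream of the TTS (bp).
#' @param method `"midpoint"` (default) or `"overlap"` (a domain is assigned
#'   the highest-precedence class it overlaps at all).
#' @return list: `annotation` (data.frame with `class` and `nearest_gene` per
#'   domain) and `proportions` (named proportions over the five classes,
#'   summing to 1).
#' @export
annotateFeatures <- function(domains, genes, exons = NULL,
                             promoterUp = 1000, promoterDown = 100,
                             ttsUp = 100, ttsDown = 1000,
                             method = c("midpoint", "overlap")) {
  method <- match.arg(method)
  r <- if (is(domains, "DomainSet")) domainRanges(domains) else domains
  classes <- c("promoter", "TTS", "exon", "intron", "intergenic")
  if (length(r) == 0)
    return(list(annotation = data.frame(class = character(),
                                        nearest_gene = character()),
                proportions = stats::setNames(rep(NA_real_, 5), classes)))
  if (is.null(exons) || length(exons) == 0) {
    exons <- granges(genes); exons$gene_id <- genes$gene_id
  } else {
    bare <- setdiff(genes$gene_id, exons$gene_id)
    if (length(bare)) {
      message(length(bare), " gene(s) without exon records treated as single-exon")
      add <- granges(genes[genes$gene_id %in% bare])
      add$gene_id <- genes$gene_id[genes$gene_id %in% bare]
      exons <- c(exons, add)
    }
  }
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, end(genes), start(genes))
  tts <- ifelse(minus, start(genes), end(genes))
  dirW <- function(anchor, up, down) {
    GRanges(seqnames(genes),
            IRanges(pmax(1, ifelse(minus, anchor - down + 1, anchor - up)),
                    ifelse(minus, anchor + up - 1, anchor + down - 1)))
  }
  prom <- dirW(tss, promoterUp, promoterDown)
  ttsW <- dirW(tts, ttsUp, ttsDown)
  query <- if (method == "midpoint")
    GRanges(seqnames(r), IRanges(floor((start(r) + end(r)) / 2), width = 1))
  else granges(r)
  cls <- rep("intergenic", length(query))
  hitAny <- function(win) countOverlaps(query, win, ignore.strand = TRUE) > 0
  cls[hitAny(granges(genes))] <- "intron"
  cls[hitAny(granges(exons))] <- "exon"
  cls[hitAny(ttsW)] <- "TTS"
  cls[hitAny(prom)] <- "promoter"
  nearest <- rep(NA_character_, length(query))
  if (length(genes)) {
    nh <- GenomicRanges::nearest(query, genes, ignore.strand = TRUE)
    nearest[!is.na(nh)] <- genes$gene_id[nh[!is.na(nh)]]
  }
  prop <- table(factor(cls, levels = classes)) / length(query)
  list(annotation = data.frame(class = cls, nearest_gene = nearest,
                               stringsAsFactors = FALSE),
       proportions = stats::setNames(as.numeric(prop), classes))
}

#' Binned mean-signal table for chromosome-scale maps
#'
#' Resizes the track to the requested bin (10 kb for overview maps, 2 kb for
#' differential maps) and emits a long-format table.
#'
#' @param track a [CoverageTrack-class].
#' @param bin output bin size in bp (multiple of the track bin size).
#' @return data.frame with `chrom`, `start` (1-based), `end`, `signal`.
#' @export
chromomapBins <- function(track, bin = 10000) {
  r <- resizeToWindows(track, bin)
  rows <- lapply(names(r@signal), function(chr) {
    st <- binStarts(r@seqlens[[chr]], bin)
    data.frame(chrom = chr, start = st,
               end = pmin(st + bin - 1, as.integer(r@seqlens[[chr]])),
               signal = r@signal[[chr]])
  })
  do.call(rbind, rows)
}
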