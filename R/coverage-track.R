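#' Construct a CoverageTrack
#'
#' @param signal named list of per-chromosome numeric vectors (binned signal).
#' @param binSize bin width in bp.
#' @param seqlens named numeric chromosome lengths in bp.
#' @param info list of library metadata (id, condition, feature, replicate, units).
#' @return a [CoverageTrack-class].
#' @examples
#' tr <- CoverageTrack(list(chr1 = c(1, 3, 5)), binSize = 100,
#'                     seqlens = c(chr1 = 300))
#' trackMean(tr)
#' @export
CoverageTrack <- function(signal, binSize, seqlens, info = list()) {
  new("CoverageTrack", signal = lapply(signal, as.numeric),
      binSize = as.integer(binSize), seqlens = seqlens, info = info)
}

#' @rdname CoverageTrack-class
#' @export
setMethod("binSize", "CoverageTrack", function(x) x@binSize)

#' @rdname CoverageTrack-class
#' @export
setMethod("trackSignal", "CoverageTrack", function(x) x@signal)

#' @rdname CoverageTrack-class
#' @export
setMethod("libraryInfo", "CoverageTrack", function(x) x@info)

#' @rdname CoverageTrack-class
#' @export
trackSeqlens <- function(x) x@seqlens

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack: %d chromosome(s), bin %d bp\n",
              length(object@signal), object@binSize))
  inf <- object@info
  if (length(inf))
    cat("  library:", paste(names(inf), unlist(lapply(inf, format)),
                            sep = "=", collapse = " "), "\n")
  tot <- sum(object@seqlens)
  cat(sprintf("  genome: %.3g bp; genome-wide mean signal: %.4g\n",
              tot, trackMean(object)))
})

#' Genome-wide mean signal of a track
#'
#' Length-weighted mean over all bins (trailing partial bins weighted by their
#' true width).
#'
#' @param track a [CoverageTrack-class].
#' @return numeric scalar.
#' @export
trackMean <- function(track) {
  stopifnot(is(track, "CoverageTrack"))
  tot <- 0; len <- 0
  for (chr in names(track@signal)) {
    w <- binWidths(track@seqlens[[chr]], track@binSize)
    tot <- tot + sum(track@signal[[chr]] * w)
    len <- len + sum(w)
  }
  tot / len
}

## widths of successive bins on a chromosome (last one may be partial)
binWidths <- function(seqlen, bin) {
  n <- as.integer(ceiling(seqlen / bin))
  w <- rep(as.numeric(bin), n)
  if (n > 0) w[n] <- seqlen - (n - 1) * bin
  w
}

## bin start coordinates (1-based) for a chromosome
binStarts <- function(seqlen, bin) {
  n <- as.integer(ceiling(seqlen / bin))
  seq.int(1L, by = bin, length.out = n)
}

#' Multiply every bin of a track by a scalar factor
#'
#' Used to apply spike-in normalization factors (see [spikeScaleTotalReads()]).
#'
#' @param track a [CoverageTrack-class].
#' @param factor positive scalar.
#' @return a scaled [CoverageTrack-class].
#' @export
scaleTrack <- function(track, factor) {
  stopifnot(is(track, "CoverageTrack"), is.finite(factor), factor > 0)
  track@signal <- lapply(track@signal, `*`, factor)
  track@info$scaled <- TRUE
  validObject(track)
  track
}

#' Resize a track to coarser fixed windows of mean signal
#'
#' Each output window holds the mean of its constituent bins; a trailing
#' partial window averages the bins that exist (weighted by their widths), so
#' the genome-wide length-weighted mean is conserved exactly.
#'
#' @param track a [CoverageTrack-class].
#' @param window target window size in bp; must be a positive integer multiple
#'   of `binSize(track)`.
#' @return a [CoverageTrack-class] at the new bin size.
#' @examples
#' tr <- CoverageTrack(list(chr1 = c(1, 3, 5, 7)), 100, c(chr1 = 400))
#' trackSignal(resizeToWindows(tr, 200))$chr1   # 2, 6
#' @export
resizeToWindows <- function(track, window) {
  stopifnot(is(track, "CoverageTrack"))
  bin <- track@binSize
  if (window < bin || window %% bin != 0)
    stop("window (", window, ") must be an integer multiple of the bin size (",
         bin, ")")
  if (window == bin) return(track)
  k <- window %/% bin
  out <- list()
  for (chr in names(track@signal)) {
    v <- track@signal[[chr]]
    w <- binWidths(track@seqlens[[chr]], bin)
    n.out <- ceiling(length(v) / k)
    grp <- rep(seq_len(n.out), each = k)[seq_along(v)]
    out[[chr]] <- as.numeric(tapply(v * w, grp, sum) / tapply(w, grp, sum))
  }
  CoverageTrack(out, window, track@seqlens, track@info)
}

#' Average several replicate tracks bin-by-bin
#'
#' @param tracks list of [CoverageTrack-class] on the same genome and bin size.
#' @return a [CoverageTrack-class] of bin-wise means.
#' @export
averageTracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]
  for (t in tracks[-1])
    stopifnot(binSize(t) == binSize(ref),
              identical(t@seqlens, ref@seqlens))
  sig <- ref@signal
  for (chr in names(sig)) {
    acc <- Reduce(`+`, lapply(tracks, function(t) t@signal[[chr]]))
    sig[[chr]] <- acc / length(tracks)
  }
  info <- ref@info
  info$replicate <- "avg"
  CoverageTrack(sig, binSize(ref), ref@seqlens, info)
}

## per-bp RleList view of a track (expands bins; trailing bin clipped to seqlen)
trackRle <- function(track) {
  out <- list()
  for (chr in names(track@signal)) {
    w <- binWidths(track@seqlens[[chr]], track@binSize)
    out[[chr]] <- S4Vectors::Rle(track@signal[[chr]], as.integer(w))
  }
  methods::as(out, "SimpleRleList")
}

## mean of a per-bp Rle over a set of IRanges on one chromosome
rleRangeMeans <- function(rle, ranges) {
  if (length(ranges) == 0) return(numeric())
  as.numeric(viewMeans(Views(rle, ranges)))
}
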