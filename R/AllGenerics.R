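#' @rdname CoverageTrack-class
#' @param x a CoverageTrack (or other object with bins)
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackSignal", function(x) standardGeneric("trackSignal"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("libraryInfo", function(x) standardGeneric("libraryInfo"))

#' Genome fraction covered by a domain set
#'
#' Sum of domain widths divided by total genome length.
#'
#' @param domains a [DomainSet-class] (or GRanges).
#' @param genome named numeric vector of chromosome lengths, or an object with
#'   seqlengths.
#' @return fraction in `[0, 1]`.
#' @export
setGeneric("genomeFraction", function(domains, genome) standardGeneric("genomeFraction"))

#' @rdname DomainSet-class
#' @param x a DomainSet
#' @export
setGeneric("domainRanges", function(x) standardGeneric("domainRanges"))
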