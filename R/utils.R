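## Pseudocount used wherever a log-ratio of scaled signals is taken.
PSEUDOCOUNT <- 0.5

#' Derive a reproducible child seed from a master seed and a stage name
#'
#' Stable string hash (polynomial, mod 2^31 - 1) combined with the master
#' seed, so a single pipeline seed fans out deterministically to per-stage and
#' per-library seeds.
#'
#' @param master integer master seed.
#' @param name character stage/library tag.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
stageSeed <- function(master, name) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (cp in utf8ToInt(as.character(name)))
    h <- (h * 131 + cp) %% m
  as.integer(h %% (m - 1) + 1)
}

## run code with a locally seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

## named numeric seqlengths from flexible genome arguments
genomeSeqlens <- function(genome) {
  if (is(genome, "GenomePreset")) return(genome@seqlens)
  if (is(genome, "CoverageTrack")) return(genome@seqlens)
  if (is.numeric(genome) && !is.null(names(genome))) return(genome)
  sl <- GenomeInfoDb::seqlengths(genome)
  if (any(is.na(sl))) stop("genome has undefined seqlengths")
  stats::setNames(as.numeric(sl), names(sl))
}

## concatenate a (possibly named) list of GRanges/IRanges; names on the list
## break S4 dispatch of c(), so strip them first
bindGR <- function(lst) {
  lst <- unname(lst)
  if (!length(lst)) return(GRanges())
  suppressWarnings(do.call("c", lst))
}
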