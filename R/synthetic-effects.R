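## Planted multiplicative effects of HMT depletion on enrichment excess.

K36_CONDITIONS <- c("GST", "Set2", "NSD", "Ash1", "DKD", "TKD")
K36_FEATURES <- c("K36me1", "K36me2", "K36me3", "JASPer", "MSL3", "input")

#' Default planted effect table
#'
#' Multiplicative effects of each RNAi condition on the enrichment excess of
#' each feature within each planted gene/domain group. GST (control) is the
#' implicit identity; only deviations from 1 are tabulated. The cluster-1 /
#' cluster-3 / cluster-6 entries plant the reader-compensation effect sizes
#' that the gene-centric stage is expected to recover as median proportional
#' changes (me3 -50%, me2 +100%, reader -20% at C1 under Set2; me3 -70%,
#' me2 +50%, reader -55% at C3; me2/me3 collapse with reader -60% at C6 under
#' NSD). PCH di-methylation and enhancer mono-methylation depend on NSD and
#' Ash1 respectively; DKD (Set2+NSD) and TKD (all three) compose accordingly,
#' with the C1 me2 gain suppressed under DKD.
#'
#' @return data.frame with columns `group`, `condition`, `feature`, `effect`
#'   and attributes `conditions`/`features` listing the valid levels.
#' @export
defaultEffectTable <- function() {
  rows <- rbind(
    ## group   condition feature    effect
    c("C1", "Set2", "K36me3", 0.5),  c("C1", "Set2", "K36me2", 2.0),
    c("C1", "Set2", "JASPer", 0.8),  c("C1", "Set2", "MSL3", 0.8),
    c("C1", "NSD",  "K36me3", 0.9),  c("C1", "NSD",  "K36me2", 0.85),
    c("C1", "NSD",  "JASPer", 0.95),
    c("C1", "DKD",  "K36me3", 0.3),  c("C1", "DKD",  "K36me2", 1.0),
    c("C1", "DKD",  "JASPer", 0.6),
    c("C1", "TKD",  "K36me3", 0.15), c("C1", "TKD",  "K36me2", 0.3),
    c("C1", "TKD",  "JASPer", 0.3),  c("C1", "TKD",  "MSL3", 0.3),

    c("C3", "Set2", "K36me3", 0.3),  c("C3", "Set2", "K36me2", 1.5),
    c("C3", "Set2", "JASPer", 0.45), c("C3", "Set2", "MSL3", 0.45),
    c("C3", "NSD",  "K36me3", 0.85), c("C3", "NSD",  "K36me2", 0.9),
    c("C3", "NSD",  "JASPer", 0.9),
    c("C3", "DKD",  "K36me3", 0.2),  c("C3", "DKD",  "K36me2", 0.8),
    c("C3", "DKD",  "JASPer", 0.35),
    c("C3", "TKD",  "K36me3", 0.15), c("C3", "TKD",  "K36me2", 0.3),
    c("C3", "TKD",  "JASPer", 0.3),

    c("C6", "Set2", "K36me3", 0.8),  c("C6", "Set2", "K36me2", 1.3),
    c("C6", "Set2", "JASPer", 1.15),
    c("C6", "NSD",  "K36me2", 0.3),  c("C6", "NSD",  "K36me3", 0.4),
    c("C6", "NSD",  "JASPer", 0.4),  c("C6", "NSD",  "MSL3", 0.4),
    c("C6", "DKD",  "K36me2", 0.25), c("C6", "DKD",  "K36me3", 0.3),
    c("C6", "DKD",  "JASPer", 0.35),
    c("C6", "TKD",  "K36me2", 0.2),  c("C6", "TKD",  "K36me3", 0.25),
    c("C6", "TKD",  "JASPer", 0.3),

    c("C7", "NSD",  "K36me2", 0.3),  c("C7", "NSD",  "K36me3", 0.4),
    c("C7", "NSD",  "JASPer", 0.45),
    c("C7", "DKD",  "K36me2", 0.25), c("C7", "DKD",  "K36me3", 0.35),
    c("C7", "DKD",  "JASPer", 0.4),
    c("C7", "TKD",  "K36me2", 0.2),  c("C7", "TKD",  "K36me3", 0.3),
    c("C7", "TKD",  "JASPer", 0.35),

    c("C9", "Ash1", "K36me1", 0.5),  c("C9", "Ash1", "JASPer", 0.95),
    c("C9", "TKD",  "K36me1", 0.45), c("C9", "TKD",  "JASPer", 0.7),

    c("PCH", "NSD", "K36me2", 0.3),  c("PCH", "DKD", "K36me2", 0.3),
    c("PCH", "TKD", "K36me2", 0.25),
    c("ENH", "Ash1", "K36me1", 0.5), c("ENH", "TKD", "K36me1", 0.5))
  tab <- data.frame(group = rows[, 1], condition = rows[, 2],
                    feature = rows[, 3], effect = as.numeric(rows[, 4]),
                    stringsAsFactors = FALSE)
  attr(tab, "conditions") <- K36_CONDITIONS
  attr(tab, "features") <- K36_FEATURES
  class(tab) <- c("EffectTable", "data.frame")
  validateEffectTable(tab)
  tab
}

validateEffectTable <- function(tab) {
  stopifnot(all(c("group", "condition", "feature", "effect") %in% colnames(tab)))
  if (any(tab$effect <= 0)) stop("all effects must be > 0")
  if (any(tab$condition == "GST" & tab$effect != 1))
    stop("control (GST) effects must be 1.0")
  invisible(tab)
}

#' Look up planted effects for a condition/feature across groups
#'
#' @param effects an effect table from [defaultEffectTable()] (or a
#'   compatible data.frame).
#' @param groups character vector of group labels.
#' @param condition,feature single condition / feature key.
#' @return numeric vector of multiplicative effects (1 where untabulated).
#' @export
effectFor <- function(effects, groups, condition, feature) {
  conds <- attr(effects, "conditions") %||% K36_CONDITIONS
  feats <- attr(effects, "features") %||% K36_FEATURES
  if (!condition %in% conds)
    stop("unknown condition: '", condition, "'")
  if (!feature %in% feats)
    stop("unknown feature: '", feature, "'")
  out <- rep(1, length(groups))
  sel <- effects$condition == condition & effects$feature == feature
  m <- match(groups, effects$group[sel])
  hit <- !is.na(m)
  out[hit] <- effects$effect[sel][m[hit]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
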