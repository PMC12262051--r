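## Reader (JASPer / MSL3) response to methylation change, and the saturating
## dual-mark model of reader retention:
##
##   R(g) = b + A * u^m / (K^m + u^m),   u = w2 * me2(g) + w3 * me3(g)
##
## with w3 fixed to 1 for identifiability. The Hill-form readout nests a hard
## threshold (large m) and proportional binding (m = 1), formalizing the
## hypothesis that readers are retained while the combined K36me2 + K36me3
## density stays above a critical level.

#' Per-gene reader vs mark response table
#'
#' Proportional changes of the reader and of K36me2/K36me3 for one RNAi
#' condition, joined per gene, with group medians per planted or inferred
#' cluster.
#'
#' @param gsm a [GeneSignalMatrix-class] containing reader, K36me2 and
#'   K36me3 columns for the condition and the control.
#' @param condition RNAi condition.
#' @param reader reader feature name (default `"JASPer"`; `"MSL3"` restricts
#'   to X-chromosome genes).
#' @param control control condition.
#' @param clusters optional named vector (gene id -> cluster label) for the
#'   medians; defaults to the `group` column of `rowData(gsm)` if present.
#' @return list: `table` (gene_id, cluster, dp_reader, dp_me2, dp_me3) and
#'   `medians` (per-cluster medians of the three changes).
#' @export
compensationTable <- function(gsm, condition, reader = "JASPer",
                              control = "GST", clusters = NULL) {
  cd <- SummarizedExperiment::colData(gsm)
  for (f in c(reader, "K36me2", "K36me3")) {
    if (!any(cd$feature == f & cd$condition == condition) ||
        !any(cd$feature == f & cd$condition == control))
      stop("missing column: feature '", f, "' for condition '", condition,
           "' or '", control, "'")
  }
  if (reader == "MSL3") {
    genes <- SummarizedExperiment::rowRanges(gsm)
    gsm <- gsm[as.character(seqnames(genes)) == "chrX", ]
  }
  pcR <- proportionalChange(gsm, reader, condition, control)
  pc2 <- proportionalChange(gsm, "K36me2", condition, control)
  pc3 <- proportionalChange(gsm, "K36me3", condition, control)
  ids <- Reduce(intersect, list(pcR$gene_id, pc2$gene_id, pc3$gene_id))
  tab <- data.frame(
    gene_id = ids,
    dp_reader = pcR$delta[match(ids, pcR$gene_id)],
    dp_me2 = pc2$delta[match(ids, pc2$gene_id)],
    dp_me3 = pc3$delta[match(ids, pc3$gene_id)])
  if (is.null(clusters)) {
    rd <- SummarizedExperiment::rowData(gsm)
    if (!is.null(rd$group))
      clusters <- stats::setNames(rd$group, rd$gene_id)
  }
  tab$cluster <- if (!is.null(clusters)) unname(clusters[tab$gene_id])
                 else NA_character_
  tab$cluster[is.na(tab$cluster)] <- "all"
  med <- do.call(rbind, lapply(split(tab, tab$cluster), function(g)
    data.frame(cluster = g$cluster[1], n = nrow(g),
               dp_reader = stats::median(g$dp_reader),
               dp_me2 = stats::median(g$dp_me2),
               dp_me3 = stats::median(g$dp_me3))))
  rownames(med) <- NULL
  list(table = tab[, c("gene_id", "cluster", "dp_reader", "dp_me2", "dp_me3")],
       medians = med)
}

#' Predict reader retention from mark densities
#'
#' Forward evaluation of the saturating dual-mark model; monotone
#' non-decreasing in both marks and bounded in `[b, b + A]`.
#'
#' @param params named numeric/list with `b`, `A`, `K`, `w2`, `m` (and
#'   optionally `w3`, default 1).
#' @param me2,me3 mark density vectors (same scale as the fitted data).
#' @return predicted reader signal.
#' @export
predictReaderRetention <- function(params, me2, me3) {
  p <- as.list(params)
  w3 <- p$w3 %||% 1
  u <- p$w2 * me2 + w3 * me3
  p$b + p$A * u^p$m / (p$K^p$m + u^p$m)
}

#' Fit the dual-mark reader-retention model
#'
#' Least-squares fit of `R = b + A u^m / (K^m + u^m)`, `u = w2 me2 + me3`,
#' across all (gene, condition) observations, by bounded
#' Levenberg-Marquardt with jittered restarts. `w2` is initialized from the
#' measured nucleosome affinity ratio Kd(me3)/Kd(me2) = 0.60/0.32, reflecting
#' the reader's slight preference for the di-methylated state. A random 20%
#' of genes is held out to report out-of-sample R-squared.
#'
#' @param data data.frame with columns `gene_id`, `reader`, `me2`, `me3`
#'   (signal levels, one row per gene x condition observation); see
#'   [readerModelData()].
#' @param init optional named list overriding initial values (`b`, `A`, `K`,
#'   `w2`, `m`).
#' @param holdout fraction of genes held out for validation.
#' @param seed seed for the holdout split and restart jitter.
#' @param maxRestarts bounded restarts before giving up.
#' @return list: `params` (named vector b, A, K, w2, w3 = 1, m), `se`,
#'   `r2_holdout`, `fitted` data.frame with predictions, `converged`.
#' @export
fitThresholdModel <- function(data, init = list(), holdout = 0.2, seed = 1,
                              maxRestarts = 5) {
  stopifnot(all(c("gene_id", "reader", "me2", "me3") %in% colnames(data)))
  data <- data[is.finite(data$reader) & is.finite(data$me2) &
               is.finite(data$me3), ]
  if (length(unique(data$gene_id)) < 100)
    stop("need >= 100 genes spanning a range of mark densities")
  if (all(data$me2 == 0 & data$me3 == 0))
    stop("degenerate input: all mark densities are zero")
  withSeed(seed, {
    ids <- unique(data$gene_id)
    hold <- sample(ids, round(holdout * length(ids)))
    train <- data[!data$gene_id %in% hold, ]
    test <- data[data$gene_id %in% hold, ]
    u0 <- 1.875 * train$me2 + train$me3
    start <- utils::modifyList(list(
      b = max(min(train$reader), 1e-6),
      A = max(diff(range(train$reader)), 1e-6),
      K = stats::median(u0[u0 > 0]),
      w2 = 0.60 / 0.32, m = 1), init)
    lower <- c(b = 0, A = 1e-9, K = 1e-9, w2 = 1e-9, m = 0.5)
    upper <- c(b = Inf, A = Inf, K = Inf, w2 = Inf, m = 4)
    fit <- NULL
    for (r in 0:maxRestarts) {
      st <- if (r == 0) start else
        lapply(start, function(v) v * stats::rlnorm(1, 0, 0.3))
      st$m <- min(max(st$m, 0.5), 4)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          reader ~ b + A * (w2 * me2 + me3)^m / (K^m + (w2 * me2 + me3)^m),
          data = train, start = st, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("reader-model fit failed to converge after ", maxRestarts,
           " restarts")
    cf <- stats::coef(fit)
    params <- c(b = unname(cf["b"]), A = unname(cf["A"]), K = unname(cf["K"]),
                w2 = unname(cf["w2"]), w3 = 1, m = unname(cf["m"]))
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 5))
    predTest <- predictReaderRetention(params, test$me2, test$me3)
    r2 <- if (nrow(test) > 1)
      1 - sum((test$reader - predTest)^2) /
          sum((test$reader - mean(test$reader))^2)
    else NA_real_
    list(params = params, se = se, r2_holdout = r2,
         fitted = data.frame(data,
                             pred = predictReaderRetention(params, data$me2,
                                                           data$me3)),
         converged = TRUE)
  })
}

#' Assemble (gene, condition) observations for the retention model
#'
#' @param gsm a [GeneSignalMatrix-class].
#' @param conditions conditions to include.
#' @param reader reader feature.
#' @return data.frame with `gene_id`, `condition`, `reader`, `me2`, `me3`.
#' @export
readerModelData <- function(gsm, conditions = K36_CONDITIONS,
                            reader = "JASPer") {
  cd <- SummarizedExperiment::colData(gsm)
  conditions <- intersect(conditions, unique(cd$condition))
  do.call(rbind, lapply(conditions, function(cond)
    data.frame(gene_id = rownames(gsm), condition = cond,
               reader = geneSignal(gsm, reader, cond),
               me2 = geneSignal(gsm, "K36me2", cond),
               me3 = geneSignal(gsm, "K36me3", cond), row.names = NULL)))
}
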