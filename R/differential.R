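## Window-based differential binding: Z-score maps on 5-kb windows and
## significant differential regions from 250-bp windows with Simes-combined
## cluster-level FDR.

#' Count libraries into fixed-width genomic windows
#'
#' Windows tile the genome without overlap (step = width). Counts are sums of
#' the libraries' bins; the library bin size must divide the window width.
#'
#' @param libraries list of [SimulatedLibrary-class] (or count
#'   [CoverageTrack-class]) objects sharing a genome.
#' @param width window width in bp (default 250).
#' @return a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with assay `"counts"`, `rowRanges` of windows and library metadata in
#'   `colData`.
#' @export
countWindows <- function(libraries, width = 250) {
  stopifnot(length(libraries) >= 1)
  asCounts <- function(l) {
    if (is(l, "SimulatedLibrary")) countTrack(l) else l
  }
  tr <- lapply(libraries, asCounts)
  ref <- tr[[1]]
  for (t in tr[-1])
    if (!identical(t@seqlens, ref@seqlens))
      stop("libraries are on different genomes")
  bin <- binSize(ref)
  if (width %% bin != 0)
    stop("window width must be a multiple of the library bin size")
  k <- width %/% bin
  winlist <- lapply(names(ref@seqlens), function(chr) {
    sl <- ref@seqlens[[chr]]
    st <- binStarts(sl, width)
    GRanges(chr, IRanges(st, width = pmin(width, sl - st + 1)))
  })
  windows <- bindGR(winlist)
  counts <- vapply(tr, function(t) {
    unlist(lapply(names(t@signal), function(chr) {
      v <- t@signal[[chr]]
      grp <- rep(seq_len(ceiling(length(v) / k)), each = k)[seq_along(v)]
      as.numeric(tapply(v, grp, sum))
    }), use.names = FALSE)
  }, numeric(length(windows)))
  colnames(counts) <- vapply(seq_along(tr), function(i)
    tr[[i]]@info$id %||% paste0("lib", i), character(1))
  cd <- DataFrame(
    condition = vapply(tr, function(t) t@info$condition %||% NA_character_,
                       character(1)),
    feature = vapply(tr, function(t) t@info$feature %||% NA_character_,
                     character(1)),
    replicate = vapply(tr, function(t) as.character(t@info$replicate %||% NA),
                       character(1)),
    row.names = colnames(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = windows, colData = cd)
}

#' Filter windows against matched input profiles
#'
#' Retains windows whose mean spike-scaled ChIP count is at least `fold`
#' times the mean spike-scaled input count.
#'
#' @param se window counts (ChIP libraries) from [countWindows()].
#' @param inputs window counts of the matched input libraries (same windows).
#' @param factors data.frame of spike scale factors for all libraries
#'   involved (`library_id`, `factor`), or `NULL` for unscaled counts.
#' @param fold enrichment fold required over input (default 3).
#' @return the filtered SummarizedExperiment.
#' @export
filterWindowsByInput <- function(se, inputs, factors = NULL, fold = 3) {
  stopifnot(nrow(se) == nrow(inputs))
  sf <- function(x) {
    if (is.null(factors)) rep(1, ncol(x))
    else {
      m <- match(colnames(x), factors$library_id)
      if (any(is.na(m))) stop("missing scale factor for ",
                              paste(colnames(x)[is.na(m)], collapse = ", "))
      factors$factor[m]
    }
  }
  chip <- sweep(SummarizedExperiment::assay(se, "counts"), 2, sf(se), `*`)
  inp <- sweep(SummarizedExperiment::assay(inputs, "counts"), 2, sf(inputs), `*`)
  keep <- rowMeans(chip) >= fold * rowMeans(inp)
  if (fold > 0) keep <- keep & rowMeans(chip) > 0
  if (fold > 0 && !any(keep))
    stop("no windows pass the input filter at fold = ", fold,
         "; lower the fold")
  se[keep, ]
}

#' Z-score transform of condition-vs-control signal in genomic windows
#'
#' Both tracks (spike-scaled, input-normalized) are averaged into windows
#' (default 5 kb); the per-window statistic is `d = log2((x + psi)/(y + psi))`
#' and `z` standardizes `d` over the universe of windows with nonzero control
#' coverage. Windows overlapping the consensus domain set (all regions
#' carrying at least one K36 mark in any condition) are flagged.
#'
#' @param rnai,control input-normalized [CoverageTrack-class]s.
#' @param window window size in bp.
#' @param consensus optional GRanges (or [DomainSet-class]) marking consensus
#'   peak regions.
#' @param psi pseudocount.
#' @return data.frame with `chrom`, `start`, `end`, `control_mean`, `d`, `z`
#'   (NA outside the standardization universe) and `consensus`.
#' @export
zscoreTransform <- function(rnai, control, window = 5000, consensus = NULL,
                            psi = PSEUDOCOUNT) {
  rw <- resizeToWindows(rnai, window)
  cw <- resizeToWindows(control, window)
  tab <- do.call(rbind, lapply(names(rw@signal), function(chr) {
    st <- binStarts(rw@seqlens[[chr]], window)
    data.frame(chrom = chr, start = st,
               end = pmin(st + window - 1, as.integer(rw@seqlens[[chr]])),
               x = rw@signal[[chr]], y = cw@signal[[chr]])
  }))
  tab$d <- log2((tab$x + psi) / (tab$y + psi))
  universe <- tab$y > 0
  d0 <- tab$d[universe]
  s <- stats::sd(d0)
  if (!length(d0) || is.na(s) || s == 0) {
    warning("degenerate Z-score universe (sd of log-ratios is 0); all z set to 0")
    tab$z <- ifelse(universe, 0, NA_real_)
  } else {
    tab$z <- NA_real_
    tab$z[universe] <- (d0 - mean(d0)) / s
  }
  cons <- if (is(consensus, "DomainSet")) domainRanges(consensus) else consensus
  tab$consensus <- if (is.null(cons)) NA else
    countOverlaps(GRanges(tab$chrom, IRanges(tab$start, tab$end)), cons) > 0
  tab$control_mean <- tab$y
  tab[, c("chrom", "start", "end", "control_mean", "d", "z", "consensus")]
}

#' Per-window differential test between a condition and the control
#'
#' Window counts are tested in the negative-binomial quasi-likelihood
#' framework (edgeR, robust QL fit) with spike-derived effective library
#' sizes, so log-fold changes are spike-calibrated. With single replicates
#' the QL machinery is not estimable and the test falls back to a Poisson-like
#' GLM with a common dispersion pooled across windows (with a warning).
#'
#' @param se filtered window counts (see [filterWindowsByInput()]).
#' @param factors spike scale-factor data.frame (`library_id`, `factor`);
#'   effective library size is proportional to `1/factor`.
#' @param condition condition to compare against the control.
#' @param control control condition label.
#' @param batch optional character/factor batch covariate (one per library).
#' @return data.frame (one row per window): `chrom`, `start`, `end`,
#'   `logFC`, `PValue`.
#' @export
testWindows <- function(se, factors = NULL, condition, control = "GST",
                        batch = NULL) {
  cd <- SummarizedExperiment::colData(se)
  sel <- cd$condition %in% c(condition, control)
  se <- se[, sel]
  cd <- cd[sel, , drop = FALSE]
  counts <- SummarizedExperiment::assay(se, "counts")
  grp <- factor(cd$condition, levels = c(control, condition))
  if (any(table(grp) < 1)) stop("both conditions must be present")
  libsize <- if (is.null(factors)) rep(1e6, ncol(counts)) else {
    m <- match(colnames(counts), factors$library_id)
    if (any(is.na(m))) stop("missing scale factor for ",
                            paste(colnames(counts)[is.na(m)], collapse = ", "))
    1e6 / factors$factor[m]
  }
  design <- if (is.null(batch)) stats::model.matrix(~grp) else
    stats::model.matrix(~factor(batch[sel]) + grp)
  y <- edgeR::DGEList(counts = round(counts), lib.size = libsize,
                      group = grp)
  singleRep <- any(table(grp) < 2)
  if (singleRep) {
    warning("single replicate: pooling dispersion across windows")
    y <- edgeR::estimateGLMCommonDisp(y, method = "deviance",
                                      robust = TRUE, subset = NULL)
    fit <- edgeR::glmFit(y, design)
    res <- edgeR::glmLRT(fit, coef = ncol(design))
  } else {
    y <- edgeR::estimateDisp(y, design)
    fit <- edgeR::glmQLFit(y, design, robust = TRUE)
    res <- edgeR::glmQLFTest(fit, coef = ncol(design))
  }
  win <- SummarizedExperiment::rowRanges(se)
  data.frame(chrom = as.character(seqnames(win)), start = start(win),
             end = end(win), logFC = res$table$logFC,
             PValue = res$table$PValue, row.names = NULL)
}

#' Simes combination of a vector of p-values
#'
#' `min_i (n * p_(i) / i)` over the sorted p-values.
#'
#' @param p numeric vector of p-values.
#' @return combined p-value.
#' @export
simesP <- function(p) {
  p <- sort(p)
  min(length(p) * p / seq_along(p))
}

#' Merge tested windows into differential regions with cluster-level FDR
#'
#' Windows with `PValue < seedP` seed clusters; neighbouring seed windows
#' within `gapTol` bp join the same cluster until its span would exceed
#' `maxSpan` bp. Each cluster's combined p-value is the Simes combination of
#' its member windows; Benjamini-Hochberg across clusters controls the
#' cluster-level FDR. Regions are reported as significant when `q <=
#' targetFdr` and the effect is at least a 50% loss or gain relative to
#' control (fold <= `1 - minChange` or >= `1 + minChange`).
#'
#' @param windows data.frame from [testWindows()] (sorted by coordinate).
#' @param maxSpan maximum region span in bp (default 3000).
#' @param targetFdr cluster-level FDR target.
#' @param seedP p-value below which windows enter clusters.
#' @param gapTol maximum gap (bp) between member windows.
#' @param minChange minimum proportional change for reporting (0.5 = 50%).
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `logFC` (mean over members), `PValue` (Simes), `q` (BH), `direction`
#'   (`"gain"`/`"loss"`), `significant`.
#' @export
mergeAndFdr <- function(windows, maxSpan = 3000, targetFdr = 0.05,
                        seedP = 0.1, gapTol = 500, minChange = 0.5) {
  w <- windows[windows$PValue < seedP, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), logFC = numeric(),
                      PValue = numeric(), q = numeric(),
                      direction = character(), significant = logical())
  if (nrow(w) == 0) return(empty)
  w <- w[order(w$chrom, w$start), ]
  cl <- integer(nrow(w)); cur <- 1L; cl[1] <- 1L
  spanStart <- w$start[1]
  for (i in seq_len(nrow(w))[-1]) {
    newClus <- w$chrom[i] != w$chrom[i - 1] ||
      w$start[i] - w$end[i - 1] - 1 > gapTol ||
      w$end[i] - spanStart + 1 > maxSpan
    if (newClus) { cur <- cur + 1L; spanStart <- w$start[i] }
    cl[i] <- cur
  }
  ## the Simes combination runs over every tested window inside the cluster
  ## span, not only the seeds, so window selection does not bias the
  ## combined p-value
  reg <- do.call(rbind, lapply(split(w, cl), function(g) {
    s0 <- min(g$start); e0 <- max(g$end)
    memb <- windows[windows$chrom == g$chrom[1] &
                    windows$start >= s0 & windows$end <= e0, , drop = FALSE]
    data.frame(chrom = g$chrom[1], start = s0, end = e0,
               n_windows = nrow(memb), logFC = mean(memb$logFC),
               PValue = simesP(memb$PValue))
  }))
  ## BH runs over the full tested universe: windows outside every cluster
  ## enter as singleton clusters, so cluster selection does not shrink the
  ## multiple-testing denominator
  inReg <- rep(FALSE, nrow(windows))
  for (j in seq_len(nrow(reg)))
    inReg <- inReg | (windows$chrom == reg$chrom[j] &
                      windows$start >= reg$start[j] &
                      windows$end <= reg$end[j])
  allP <- c(reg$PValue, windows$PValue[!inReg])
  reg$q <- stats::p.adjust(allP, method = "BH")[seq_len(nrow(reg))]
  reg$direction <- ifelse(reg$logFC >= 0, "gain", "loss")
  fold <- 2^reg$logFC
  reg$significant <- reg$q <= targetFdr &
    (fold <= 1 - minChange | fold >= 1 + minChange)
  rownames(reg) <- NULL
  reg[order(reg$chrom, reg$start), ]
}
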