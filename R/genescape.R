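## Gene-centric signal matrices, clustering into superclusters, metagene
## profiles, exon/intron bias and the proportional-change statistic.

#' Mean gene-body signal of a track
#'
#' Strand-aware mean of the (per-bp) signal over `[TSS, TTS]` for each gene
#' (the mean is orientation-invariant; strand matters for profile-shaped
#' summaries, see [metageneProfile()]).
#'
#' @param track a [CoverageTrack-class].
#' @param genes GRanges with mcol `gene_id`, within the track's genome.
#' @return named numeric vector of per-gene means.
#' @export
geneBodySignal <- function(track, genes) {
  if (any(width(genes) < 1)) stop("zero-length gene")
  sl <- track@seqlens
  if (any(end(genes) > sl[as.character(seqnames(genes))]))
    stop("gene outside genome bounds")
  rle <- trackRle(track)
  out <- numeric(length(genes))
  for (chr in unique(as.character(seqnames(genes)))) {
    idx <- which(as.character(seqnames(genes)) == chr)
    out[idx] <- rleRangeMeans(rle[[chr]], ranges(genes)[idx])
  }
  stats::setNames(out, genes$gene_id)
}

#' Mean signal in fixed windows around per-gene signal maxima
#'
#' Locates the maximum-signal bin within each gene body (leftmost bin on
#' ties) and returns the mean signal over a window of `2 * halfWidth` bp
#' centred on that bin (clipped at chromosome ends).
#'
#' @param track a [CoverageTrack-class].
#' @param genes GRanges with mcol `gene_id`.
#' @param halfWidth half-window in bp (default 1000, i.e. 2-kb windows).
#' @return named numeric vector.
#' @export
hmtPeakWindowSignal <- function(track, genes, halfWidth = 1000) {
  bin <- binSize(track)
  rle <- trackRle(track)
  out <- numeric(length(genes))
  for (i in seq_along(genes)) {
    chr <- as.character(seqnames(genes))[i]
    b0 <- (start(genes)[i] - 1) %/% bin + 1
    b1 <- (end(genes)[i] - 1) %/% bin + 1
    v <- track@signal[[chr]][b0:b1]
    peak <- b0 + which.max(v) - 1
    centre <- (peak - 1) * bin + bin %/% 2
    win <- IRanges(max(1, centre - halfWidth),
                   min(track@seqlens[[chr]], centre + halfWidth - 1))
    out[i] <- rleRangeMeans(rle[[chr]], win)
  }
  stats::setNames(out, genes$gene_id)
}

#' Assemble a gene x (feature, condition) signal matrix
#'
#' One column per normalized track; genes are restricted to those overlapping
#' at least one domain of the consensus set (all marks, any condition) when
#' `domains` is supplied. Gene metadata (length, intron fraction, PCH flag
#' and any planted labels) is carried in `rowData`.
#'
#' @param tracks named list of spike-scaled, input-normalized
#'   [CoverageTrack-class]s whose `info` carries `feature` and `condition`.
#' @param genes GRanges with mcol `gene_id` (unique ids).
#' @param domains optional GRanges / [DomainSet-class] / list thereof:
#'   the consensus peak set used to select genes.
#' @param exons optional exon GRanges (mcol `gene_id`) for intron fractions.
#' @param pch optional GRanges of heterochromatin blocks for the PCH flag.
#' @return a [GeneSignalMatrix-class].
#' @export
buildGeneSignalMatrix <- function(tracks, genes, domains = NULL, exons = NULL,
                                  pch = NULL) {
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!is.null(domains)) {
    if (is(domains, "DomainSet")) domains <- domainRanges(domains)
    if (is.list(domains))
      domains <- bindGR(lapply(domains, function(d)
        granges(if (is(d, "DomainSet")) domainRanges(d) else d)))
    genes <- genes[countOverlaps(genes, domains, ignore.strand = TRUE) > 0]
  }
  sig <- vapply(tracks, geneBodySignal, numeric(length(genes)), genes = genes)
  if (length(genes) == 1) sig <- matrix(sig, nrow = 1)
  rownames(sig) <- genes$gene_id
  cd <- DataFrame(
    feature = vapply(tracks, function(t) t@info$feature %||% NA_character_,
                     character(1)),
    condition = vapply(tracks, function(t) t@info$condition %||% NA_character_,
                       character(1)),
    row.names = names(tracks) %||% paste0("track", seq_along(tracks)))
  rd <- DataFrame(gene_id = genes$gene_id, length = width(genes))
  if (!is.null(exons)) {
    exBp <- tapply(width(exons), exons$gene_id, sum)
    m <- exBp[genes$gene_id]
    rd$intron_fraction <- pmax(0, 1 - ifelse(is.na(m), 1, m) / width(genes))
  }
  rd$pch <- if (!is.null(pch)) countOverlaps(genes, pch) > 0 else
    (genes$pch %||% rep(NA, length(genes)))
  for (extra in c("group", "supercluster"))
    if (!is.null(mcols(genes)[[extra]]))
      rd[[extra]] <- mcols(genes)[[extra]]
  rr <- granges(genes)
  mcols(rr) <- rd
  names(rr) <- genes$gene_id
  new("GeneSignalMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = pmax(sig, 0)), rowRanges = rr, colData = cd))
}

#' Pull one (feature, condition) column from a GeneSignalMatrix
#' @param gsm a [GeneSignalMatrix-class].
#' @param feature,condition column keys.
#' @return named numeric vector.
#' @export
geneSignal <- function(gsm, feature, condition) {
  cd <- SummarizedExperiment::colData(gsm)
  j <- which(cd$feature == feature & cd$condition == condition)
  if (length(j) == 0)
    stop("no column for feature '", feature, "', condition '", condition, "'")
  if (length(j) > 1) {
    out <- rowMeans(SummarizedExperiment::assay(gsm, "signal")[, j, drop = FALSE])
  } else out <- SummarizedExperiment::assay(gsm, "signal")[, j]
  stats::setNames(out, rownames(gsm))
}

#' k-means clustering of the gene signal matrix
#'
#' Columns (restricted to the requested features across all conditions) are
#' standardized and genes clustered with k-means (default k = 12, 20 random
#' restarts keeping the best inertia). Clusters are renumbered by descending
#' control-K36me3 centroid so cluster 1 is the most me3-rich. An empty
#' cluster triggers a restart with a derived sub-seed (with a message).
#'
#' @param gsm a [GeneSignalMatrix-class].
#' @param k number of clusters.
#' @param seed required clustering seed.
#' @param features features used for clustering (default the three K36
#'   methylation states).
#' @param control control condition for renumbering.
#' @return a [ClusterAssignment-class].
#' @export
clusterGenes <- function(gsm, k = 12, seed,
                         features = c("K36me1", "K36me2", "K36me3"),
                         control = "GST") {
  if (missing(seed)) stop("clustering seed is required")
  cd <- SummarizedExperiment::colData(gsm)
  j <- which(cd$feature %in% features)
  X <- SummarizedExperiment::assay(gsm, "signal")[, j, drop = FALSE]
  colnames(X) <- paste(cd$feature[j], cd$condition[j], sep = ".")
  if (nrow(X) < k) stop("fewer genes (", nrow(X), ") than clusters (", k, ")")
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  km <- NULL; s <- as.integer(seed)
  for (attempt in 1:5) {
    km <- withSeed(s, tryCatch(
      stats::kmeans(Z, centers = k, nstart = 20, iter.max = 100),
      error = function(e) NULL))
    if (!is.null(km) && length(unique(km$cluster)) == k) break
    message("empty cluster or failed k-means; restarting with sub-seed")
    s <- stageSeed(s, paste0("kmeans-restart", attempt))
  }
  if (is.null(km)) stop("k-means failed after restarts")
  ## renumber by descending control me3 centroid (raw units)
  rawC <- vapply(seq_len(k), function(cl)
    colMeans(X[km$cluster == cl, , drop = FALSE]), numeric(ncol(X)))
  rawC <- t(rawC)
  colnames(rawC) <- colnames(X)
  keyCol <- paste0("K36me3.", control)
  key <- if (keyCol %in% colnames(rawC)) rawC[, keyCol] else rawC[, 1]
  ord <- order(key, decreasing = TRUE)
  relab <- match(seq_len(k), ord)
  new("ClusterAssignment",
      assignment = data.frame(gene_id = rownames(X),
                              cluster = relab[km$cluster],
                              stringsAsFactors = FALSE),
      centers = rawC[ord, , drop = FALSE],
      zcenters = km$centers[ord, , drop = FALSE],
      k = as.integer(k), seed = as.integer(seed),
      superclusters = character(0))
}

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d genes in %d clusters (seed %d)\n",
              nrow(object@assignment), object@k, object@seed))
  if (length(object@superclusters)) {
    sc <- table(object@assignment$supercluster)
    cat("  superclusters:", paste(names(sc), sc, sep = "=", collapse = " "), "\n")
  }
})

#' @rdname ClusterAssignment-class
#' @param x a ClusterAssignment
#' @export
clusterAssignment <- function(x) x@assignment

#' @rdname ClusterAssignment-class
#' @export
clusterCenters <- function(x) x@centers

#' Map clusters to superclusters by centroid dominance rules
#'
#' A rule-based replacement for a manual merge of clusters: for each cluster
#' the dominant mark is the K36 state with the highest standardized control
#' centroid, and the canonical depletions are the centroid proportional
#' changes for the (K36me3, Set2), (K36me2, NSD) and (K36me1, Ash1) pairs.
#' SC-I requires dominant me3 and the Set2 me3 drop as strongest canonical
#' depletion; SC-II likewise for me2/NSD and SC-III for me1/Ash1. Clusters
#' whose control centroids sit below the 20th percentile of gene signals for
#' every mark become SC-IV (excluded downstream). Unmappable clusters are
#' assigned to the nearest mapped supercluster centroid (warning). SC-II
#' genes are split into IIA (euchromatic) and IIB (heterochromatic) purely by
#' overlap of the gene with H3K9me2/PCH domains.
#'
#' @param ca a [ClusterAssignment-class] from [clusterGenes()].
#' @param gsm the clustered [GeneSignalMatrix-class].
#' @param pch GRanges of heterochromatin (H3K9me2) domains, or `NULL` to use
#'   the `pch` flag in `rowData(gsm)`.
#' @param control control condition label.
#' @return the [ClusterAssignment-class] with a per-gene `supercluster`
#'   column (`SC-I`, `SC-IIA`, `SC-IIB`, `SC-III`, `SC-IV`) and per-cluster
#'   labels in the `superclusters` slot.
#' @export
assignSuperclusters <- function(ca, gsm, pch = NULL, control = "GST") {
  marks <- c("K36me1", "K36me2", "K36me3")
  canon <- c(K36me3 = "Set2", K36me2 = "NSD", K36me1 = "Ash1")
  ctrCols <- paste0(marks, ".", control)
  C <- ca@centers
  stopifnot(all(ctrCols %in% colnames(C)))
  ## gene-universe scale per control column
  gmean <- numeric(3); gsd <- numeric(3); q20 <- numeric(3)
  names(gmean) <- names(gsd) <- names(q20) <- marks
  for (m in marks) {
    v <- geneSignal(gsm, m, control)
    gmean[m] <- mean(v); gsd[m] <- stats::sd(v); q20[m] <- stats::quantile(v, 0.2)
  }
  k <- ca@k
  lab <- character(k)
  for (cl in seq_len(k)) {
    ctr <- C[cl, ctrCols]
    names(ctr) <- marks
    if (all(ctr < q20)) { lab[cl] <- "SC-IV"; next }
    zdom <- (ctr - gmean) / ifelse(gsd > 0, gsd, 1)
    dom <- marks[which.max(zdom)]
    depl <- vapply(marks, function(m) {
      col <- paste0(m, ".", canon[[m]])
      if (!col %in% colnames(C) || C[cl, paste0(m, ".", control)] <= 0)
        return(Inf)
      (C[cl, col] - C[cl, paste0(m, ".", control)]) /
        C[cl, paste0(m, ".", control)]
    }, numeric(1))
    strongest <- marks[which.min(depl)]
    lab[cl] <- if (dom == strongest)
      switch(dom, K36me3 = "SC-I", K36me2 = "SC-II", K36me1 = "SC-III")
    else NA_character_
  }
  if (any(is.na(lab))) {
    warning(sum(is.na(lab)), " cluster(s) unmappable by rules; ",
            "assigned to nearest supercluster centroid")
    mapped <- which(!is.na(lab) & lab != "SC-IV")
    for (cl in which(is.na(lab))) {
      d <- vapply(mapped, function(j)
        sum((ca@zcenters[cl, ] - ca@zcenters[j, ])^2), numeric(1))
      lab[cl] <- lab[mapped[which.min(d)]]
    }
  }
  asg <- ca@assignment
  asg$supercluster <- lab[asg$cluster]
  ## IIA / IIB split by gene-PCH overlap
  isII <- asg$supercluster == "SC-II"
  if (any(isII)) {
    genes <- SummarizedExperiment::rowRanges(gsm)
    inPCH <- if (!is.null(pch))
      countOverlaps(genes, pch, ignore.strand = TRUE) > 0
    else as.logical(SummarizedExperiment::rowData(gsm)$pch)
    inPCH <- inPCH[match(asg$gene_id, genes$gene_id)]
    asg$supercluster[isII] <- ifelse(inPCH[isII], "SC-IIB", "SC-IIA")
  }
  ca@assignment <- asg
  ca@superclusters <- lab
  ca
}

#' Metagene profile with scaled gene bodies and unscaled flanks
#'
#' For each gene of at least `minLen` bp, the 1-kb regions flanking the TSS
#' and TTS are sampled in fixed `flankBin`-bp bins (unscaled) and the gene
#' body is resampled to `bodyBins` equal-width chunks by exact mean-preserving
#' piecewise averaging of the per-bp step function; minus-strand genes are
#' reversed. The group profile is the per-bin mean over genes.
#'
#' @param track a [CoverageTrack-class].
#' @param genes GRanges with mcol `gene_id`.
#' @param bodyBins scaled body bins (default 500).
#' @param flank flank extent in bp (default 1000).
#' @param flankBin flank bin width in bp (default 50).
#' @param minLen minimum gene length (default 1500); shorter genes excluded.
#' @return list: `profile` (numeric, `2*flank/flankBin + bodyBins` bins,
#'   upstream flank / body / downstream flank), `n` genes used, `bodyBins`,
#'   `flankBin`.
#' @export
metageneProfile <- function(track, genes, bodyBins = 500, flank = 1000,
                            flankBin = 50, minLen = 1500) {
  genes <- genes[width(genes) >= minLen]
  if (length(genes) == 0) stop("no genes pass the minimum length filter")
  nf <- as.integer(flank / flankBin)
  rle <- trackRle(track)
  prof <- matrix(NA_real_, nrow = length(genes),
                 ncol = 2L * nf + as.integer(bodyBins))
  for (i in seq_along(genes)) {
    chr <- as.character(seqnames(genes))[i]
    sl <- track@seqlens[[chr]]
    gs <- start(genes)[i]; ge <- end(genes)[i]
    flankMeans <- function(from, to) {
      st <- seq(from, to, by = flankBin)
      w <- pmin(flankBin, to - st + 1)
      ok <- st >= 1 & st + w - 1 <= sl
      v <- rep(NA_real_, length(st))
      if (any(ok))
        v[ok] <- rleRangeMeans(rle[[chr]], IRanges(st[ok], width = w[ok]))
      v
    }
    up <- flankMeans(gs - flank, gs - 1)
    down <- flankMeans(ge + 1, ge + flank)
    xbp <- as.numeric(rle[[chr]][gs:ge])
    body <- resampleMeanPreserving(xbp, bodyBins)
    v <- c(up, body, down)
    if (as.character(strand(genes))[i] == "-") v <- rev(v)
    prof[i, ] <- v
  }
  list(profile = colMeans(prof, na.rm = TRUE), n = length(genes),
       bodyBins = bodyBins, flankBin = flankBin)
}

## exact mean-preserving resampling of a step function to n equal chunks
resampleMeanPreserving <- function(x, n) {
  L <- length(x)
  cum <- c(0, cumsum(x))
  b <- L * (0:n) / n
  cumAt <- function(p) {
    i <- pmin(floor(p), L)
    cum[i + 1] + (p - i) * x[pmin(i + 1, L)] * (p > i)
  }
  cb <- cumAt(b)
  diff(cb) / (L / n)
}

#' Per-gene exon/intron signal bias
#'
#' Ratio of mean exonic to mean intronic per-bp signal (each with pseudocount
#' `psi`); genes lacking introns are excluded (with a message).
#'
#' @param track a [CoverageTrack-class].
#' @param genes GRanges with mcol `gene_id`.
#' @param exons GRanges with mcol `gene_id`.
#' @param psi pseudocount.
#' @return data.frame: `gene_id`, `exon_mean`, `intron_mean`, `ratio`.
#' @export
exonIntronBias <- function(track, genes, exons, psi = PSEUDOCOUNT) {
  rle <- trackRle(track)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    chr <- as.character(seqnames(g))
    exR <- IRanges::reduce(IRanges::restrict(
      ranges(exons[exons$gene_id == g$gene_id]), start(g), end(g)))
    if (length(exR) == 0) return(NULL)
    inR <- IRanges::gaps(exR, start = start(g), end = end(g))
    if (length(inR) == 0) return(NULL)
    em <- sum(rleRangeMeans(rle[[chr]], exR) * width(exR)) / sum(width(exR))
    im <- sum(rleRangeMeans(rle[[chr]], inR) * width(inR)) / sum(width(inR))
    data.frame(gene_id = g$gene_id, exon_mean = em, intron_mean = im,
               ratio = (em + psi) / (im + psi))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) message(skipped, " intronless gene(s) excluded")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), exon_mean = numeric(),
                      intron_mean = numeric(), ratio = numeric())
  out
}

#' Proportional change in gene signal between a condition and control
#'
#' `(S_RNAi - S_control) / S_control` per gene; genes with non-positive
#' control signal are excluded (counted in a message).
#'
#' @param gsm a [GeneSignalMatrix-class].
#' @param feature feature whose change is measured.
#' @param condition RNAi condition.
#' @param control control condition.
#' @return data.frame: `gene_id`, `control`, `treated`, `delta`.
#' @export
proportionalChange <- function(gsm, feature, condition, control = "GST") {
  s0 <- geneSignal(gsm, feature, control)
  s1 <- geneSignal(gsm, feature, condition)
  keep <- s0 > 0
  if (any(!keep))
    message(sum(!keep), " gene(s) with zero control signal excluded")
  data.frame(gene_id = names(s0)[keep], control = s0[keep],
             treated = s1[keep], delta = (s1[keep] - s0[keep]) / s0[keep],
             row.names = NULL)
}

#' Group medians of proportional change with bootstrap confidence intervals
#'
#' @param pc data.frame from [proportionalChange()].
#' @param groups named grouping vector (names = gene ids) or vector aligned
#'   with `pc` rows.
#' @param B bootstrap replicates.
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return data.frame: `group`, `n`, `median`, `lower`, `upper`.
#' @export
summarizeProportionalChange <- function(pc, groups, B = 500, conf = 0.95,
                                        seed = 1) {
  g <- if (!is.null(names(groups))) groups[pc$gene_id] else groups
  withSeed(seed, {
    rows <- lapply(split(pc$delta, g), function(d) {
      boot <- vapply(seq_len(B), function(b)
        stats::median(sample(d, replace = TRUE)), numeric(1))
      a <- (1 - conf) / 2
      data.frame(n = length(d), median = stats::median(d),
                 lower = stats::quantile(boot, a),
                 upper = stats::quantile(boot, 1 - a))
    })
    out <- do.call(rbind, rows)
    out$group <- names(rows)
    rownames(out) <- NULL
    out[, c("group", "n", "median", "lower", "upper")]
  })
}
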