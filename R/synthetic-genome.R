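## Synthetic genome architecture.
##
## The generator emulates, at reduced scale, a fly-like genome partitioned into
## euchromatin and pericentric heterochromatin (PCH), with genes grouped into
## planted cluster groups that carry distinct K36 methylation signatures and
## known multiplicative responses to HMT depletion:
##
##   C1, C3 : K36me3-dominant euchromatic genes (supercluster I; Set2-dependent)
##   C6     : K36me2-dominant euchromatic genes (supercluster IIA; NSD-dependent)
##   C7     : K36me2-dominant PCH genes         (supercluster IIB; NSD-dependent)
##   C9     : K36me1-dominant genes             (supercluster III; Ash1-dependent)
##   SC0    : unmethylated baseline genes       (supercluster 0)
##
## plus non-genic K36me2 blocks inside PCH ("PCH") and intergenic K36me1
## enhancer domains ("ENH"). Group bp budgets are chosen so the planted strong
## domains occupy target genome fractions (~20% me2, ~20% me3, ~12% me1).

defaultGenomeConfig <- function() {
  list(
    seqlens = c(chr2L = 2.2e6, chr3L = 1.8e6, chrX = 1.0e6),
    pchFraction = 0.15,
    groups = data.frame(
      group        = c("C1",   "C3",   "C6",    "C7",    "C9",    "SC0"),
      supercluster = c("SC-I", "SC-I", "SC-IIA","SC-IIB","SC-III","SC-0"),
      n            = c(280L,   245L,   230L,    130L,    240L,    600L),
      budget       = c(540e3,  460e3,  440e3,   250e3,   460e3,   720e3),
      stringsAsFactors = FALSE),
    fractions = c(K36me1 = 0.12, K36me2 = 0.20, K36me3 = 0.20),
    lengthSdLog = 0.22,
    minGeneLen = 600,
    lattice = 50,                      # all planted breakpoints on this grid
    minGeneGap = 500,                  # intergenic spacing >= one gene window
    enhancerLen = 1400,
    exonBias = c(K36me3 = 2),          # exon:intron excess ratio
    strongExcess = 7,                  # called domains
    weakExcess = 0.3,                  # sub-cutoff enrichment
    readerExcess = c(C1 = 5, C3 = 5, C6 = 3.5, C7 = 2.5, C9 = 0.6),
    msl3Excess = 3                     # chrX genes only
  )
}

## place items of given widths inside [s, e] with random lattice-aligned gaps
## of at least minGap bp (so neighbouring items never share an analysis window)
placeInRegion <- function(s, e, widths, lattice = 50, minGap = 500) {
  n <- length(widths)
  if (n == 0) return(integer())
  free <- (e - s + 1) - sum(widths) - minGap * (n + 1)
  if (free < 0)
    stop("configuration error: requested intervals (", sum(widths),
         " bp plus spacing) do not fit in region of ", e - s + 1, " bp")
  g <- stats::rexp(n + 1)
  gaps <- minGap + floor(g / sum(g) * free / lattice) * lattice
  starts <- integer(n)
  pos <- s
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + widths[i]
  }
  starts
}

## split shuffled items across regions proportionally to free capacity, place
regionsPack <- function(regions, items, lattice = 50, minGap = 500) {
  ## regions: data.frame(chrom, start, end); items: data.frame(width, idx)
  if (nrow(items) == 0)
    return(cbind(items, chrom = character(0), start = integer(0)))
  cap <- regions$end - regions$start + 1
  if (sum(items$width) + minGap * (nrow(items) + nrow(regions)) > sum(cap))
    stop("configuration error: total gene footprint (", sum(items$width),
         " bp) exceeds available space (", sum(cap), " bp)")
  fill <- sum(items$width) / sum(cap)
  cum <- cumsum(items$width)
  bound <- cumsum(cap * fill)
  reg <- findInterval(cum - items$width / 2, c(0, bound[-length(bound)]))
  reg <- pmin(reg, nrow(regions))
  out <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    sel <- which(reg == r)
    if (!length(sel)) { out[[r]] <- NULL; next }
    st <- placeInRegion(regions$start[r], regions$end[r], items$width[sel],
                        lattice, minGap)
    out[[r]] <- data.frame(items[sel, , drop = FALSE],
                           chrom = regions$chrom[r], start = st)
  }
  do.call(rbind, out)
}

## draw lattice-aligned gene lengths summing exactly to a bp budget
drawLengths <- function(n, budget, sdlog, minLen, lattice = 50) {
  if (n == 0) return(integer())
  raw <- stats::rlnorm(n, meanlog = log(budget / n) - sdlog^2 / 2, sdlog = sdlog)
  len <- pmax(minLen, round(raw * budget / sum(raw) / lattice) * lattice)
  ## absorb rounding drift (a lattice multiple) in the longest gene
  drift <- budget - sum(len)
  len[which.max(len)] <- len[which.max(len)] + drift
  as.integer(len)
}

## cut a gene into alternating lattice-aligned exon/intron segments
cutExons <- function(start, len, lattice = 50) {
  if (len < 1000) return(IRanges(start, width = len))
  nE <- sample(2:5, 1)
  nseg <- 2L * nE - 1L
  w <- stats::rexp(nseg)
  w[seq(1, nseg, by = 2)] <- w[seq(1, nseg, by = 2)] * 1.5  # exon-heavier
  seg <- pmax(2 * lattice, floor(w / sum(w) * len / lattice) * lattice)
  seg[nseg] <- len - sum(seg[-nseg])
  if (seg[nseg] < 2 * lattice) return(IRanges(start, width = len))
  ends <- start - 1 + cumsum(seg)
  starts <- c(start, ends[-nseg] + 1)
  IRanges(starts[seq(1, nseg, by = 2)], ends[seq(1, nseg, by = 2)])
}

#' Build a synthetic genome preset
#'
#' Generates a reduced-scale genome (default ~5 Mb over three chromosomes,
#' ~1700 genes) whose architecture plants the signal structure the pipeline is
#' designed to recover: supercluster gene groups with distinct K36me1/2/3 and
#' reader enrichment, PCH blocks housing heterochromatic K36me2, intergenic
#' K36me1 enhancer domains, and per-mark strong-domain footprints that occupy
#' configurable target genome fractions.
#'
#' @param config named list overriding entries of the default configuration
#'   (chromosome sizes, PCH fraction, gene group table with bp budgets, target
#'   mark fractions, enrichment excess levels, exon bias).
#' @param seed integer seed; the same seed and config reproduce the preset
#'   exactly.
#' @return a [GenomePreset-class].
#' @examples
#' preset <- buildGenomeModel(seed = 1)
#' preset
#' @export
buildGenomeModel <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(defaultGenomeConfig(), config)
  if (any(cfg$fractions <= 0 | cfg$fractions >= 1))
    stop("configuration error: domain fractions must lie in (0, 1)")
  G <- sum(cfg$seqlens)
  grp <- cfg$groups
  if (sum(grp$budget) > G)
    stop("configuration error: total gene footprint exceeds genome length")

  withSeed(seed, {
    lat <- cfg$lattice %||% 50
    ## PCH block at the centromere-proximal end of each chromosome
    pchW <- round(cfg$seqlens * cfg$pchFraction / lat) * lat
    pch <- GRanges(names(cfg$seqlens), IRanges(1, width = pmax(1, pchW)))
    euReg <- data.frame(chrom = names(cfg$seqlens),
                        start = as.integer(pchW + 1),
                        end = as.integer(cfg$seqlens))
    pchReg <- data.frame(chrom = names(cfg$seqlens),
                         start = 1L, end = as.integer(pchW))

    ## gene lengths per group
    lens <- list(); labs <- list()
    for (i in seq_len(nrow(grp))) {
      lens[[i]] <- drawLengths(grp$n[i], grp$budget[i], cfg$lengthSdLog,
                               cfg$minGeneLen, lat)
      labs[[i]] <- rep(grp$group[i], grp$n[i])
    }
    geneTab <- data.frame(group = unlist(labs), width = unlist(lens),
                          stringsAsFactors = FALSE)
    geneTab$supercluster <- grp$supercluster[match(geneTab$group, grp$group)]

    ## PCH items: C7 genes + heterochromatic K36me2 filler blocks
    isPCHgene <- geneTab$supercluster == "SC-IIB"
    me2Genic <- sum(geneTab$width[geneTab$group %in% c("C6", "C7")])
    me2Fill <- round(cfg$fractions[["K36me2"]] * G) - me2Genic
    fillW <- if (me2Fill > 0) {
      nf <- max(1, round(me2Fill / 4000))
      w <- rep(floor(me2Fill / nf / lat) * lat, nf)
      w[1] <- w[1] + me2Fill - sum(w)
      w
    } else integer()
    pchItems <- rbind(
      if (any(isPCHgene)) data.frame(kind = "gene", key = which(isPCHgene),
                                     width = geneTab$width[isPCHgene]),
      if (length(fillW)) data.frame(kind = "pchme2", key = seq_along(fillW),
                                    width = fillW))
    if (is.null(pchItems))
      pchItems <- data.frame(kind = character(), key = integer(),
                             width = numeric())
    pchItems <- pchItems[sample(nrow(pchItems)), , drop = FALSE]
    gapMin <- cfg$minGeneGap %||% 500
    pchPlaced <- regionsPack(pchReg, pchItems, lat, gapMin)

    ## euchromatin items: remaining genes + K36me1 enhancer domains
    me1Genic <- sum(geneTab$width[geneTab$group == "C9"])
    me1Fill <- round(cfg$fractions[["K36me1"]] * G) - me1Genic
    enhW <- if (me1Fill > 0) {
      ne <- max(1, round(me1Fill / cfg$enhancerLen))
      w <- rep(floor(me1Fill / ne / lat) * lat, ne)
      w[1] <- w[1] + me1Fill - sum(w)
      w
    } else integer()
    euItems <- rbind(
      if (any(!isPCHgene)) data.frame(kind = "gene", key = which(!isPCHgene),
                                      width = geneTab$width[!isPCHgene]),
      if (length(enhW)) data.frame(kind = "enh", key = seq_along(enhW),
                                   width = enhW))
    if (is.null(euItems))
      euItems <- data.frame(kind = character(), key = integer(),
                            width = numeric())
    euItems <- euItems[sample(nrow(euItems)), , drop = FALSE]
    euPlaced <- regionsPack(euReg, euItems, lat, gapMin)

    placed <- rbind(pchPlaced, euPlaced)
    gsel <- placed[placed$kind == "gene", ]
    ord <- order(gsel$key)
    gsel <- gsel[ord, ]
    genes <- if (nrow(gsel)) {
      GRanges(gsel$chrom,
              IRanges(gsel$start, width = geneTab$width[gsel$key]),
              strand = sample(c("+", "-"), nrow(gsel), replace = TRUE))
    } else GRanges()
    if (length(genes)) {
      genes$gene_id <- sprintf("g%04d", seq_along(genes))
      genes$group <- geneTab$group[gsel$key]
      genes$supercluster <- geneTab$supercluster[gsel$key]
      genes$pch <- countOverlaps(genes, pch) > 0
    }
    esel <- placed[placed$kind == "enh", , drop = FALSE]
    enhancers <- if (nrow(esel))
      GRanges(esel$chrom, IRanges(esel$start, width = esel$width)) else GRanges()
    fsel <- placed[placed$kind == "pchme2", , drop = FALSE]
    pchMe2 <- if (nrow(fsel))
      GRanges(fsel$chrom, IRanges(fsel$start, width = fsel$width)) else GRanges()

    ## exon structure
    exons <- GRanges()
    if (length(genes)) {
      exList <- lapply(seq_along(genes), function(i)
        cutExons(start(genes)[i], width(genes)[i], lat))
      nEx <- lengths(exList)
      exons <- GRanges(rep(as.character(seqnames(genes)), nEx),
                       do.call("c", exList))
      exons$gene_id <- rep(genes$gene_id, nEx)
    }

    seqi <- Seqinfo(names(cfg$seqlens), as.integer(cfg$seqlens))
    fixSeqinfo <- function(gr) {
      GenomeInfoDb::seqlevels(gr) <- names(cfg$seqlens)
      GenomeInfoDb::seqinfo(gr) <- seqi
      sort(gr)
    }
    genes <- fixSeqinfo(genes); exons <- fixSeqinfo(exons)
    pch <- fixSeqinfo(pch); enhancers <- fixSeqinfo(enhancers)
    pchMe2 <- fixSeqinfo(pchMe2)

    enr <- buildEnrichment(genes, exons, enhancers, pchMe2, cfg)
    doms <- list(
      K36me1 = domainUnion(genes[genes$group == "C9"], enhancers, "C9", "ENH"),
      K36me2 = domainUnion(genes[genes$group %in% c("C6", "C7")], pchMe2,
                           NULL, "PCH"),
      K36me3 = domainUnion(genes[genes$group %in% c("C1", "C3")], GRanges(),
                           NULL, NULL))

    preset <- new("GenomePreset", seqlens = cfg$seqlens, pch = pch,
                  genes = genes, exons = exons, enhancers = enhancers,
                  enrichment = enr, domains = doms,
                  fractions = cfg$fractions,
                  params = list(config = cfg, seed = seed))
    validObject(preset)
    preset
  })
}

domainUnion <- function(genes, extra, geneLab, extraLab) {
  g <- granges(genes)
  if (length(g)) g$group <- if (is.null(geneLab)) genes$group else
    rep(geneLab, length(g))
  e <- granges(extra)
  if (length(e)) e$group <- rep(extraLab, length(e))
  sort(concatGR(list(g, e)))
}

## concatenate GRanges with `excess`/`group`-style mcols, tolerating empties
concatGR <- function(lst, mcolNames = "group") {
  lst <- lst[vapply(lst, length, integer(1)) > 0]
  if (!length(lst)) {
    out <- GRanges()
    for (nm in mcolNames) mcols(out)[[nm]] <-
      if (nm == "excess") numeric() else character()
    return(out)
  }
  bindGR(lst)
}

## enrichment geometry: per feature, intervals with excess-over-input values
buildEnrichment <- function(genes, exons, enhancers, pchMe2, cfg) {
  S <- cfg$strongExcess; W <- cfg$weakExcess
  bodies <- function(groups, excess) {
    g <- genes[genes$group %in% groups]
    gr <- granges(g)
    if (length(gr)) { gr$excess <- excess; gr$group <- g$group }
    gr
  }
  blocks <- function(gr, excess, label) {
    gr <- granges(gr)
    if (length(gr)) { gr$excess <- excess; gr$group <- label }
    gr
  }
  ## K36me3 with exon bias on strong genes: piecewise excess so the gene-body
  ## mean equals the nominal excess exactly
  me3Strong <- genes[genes$group %in% c("C1", "C3")]
  me3 <- GRanges()
  if (length(me3Strong)) {
    b <- if ("K36me3" %in% names(cfg$exonBias)) cfg$exonBias[["K36me3"]] else 1
    pieces <- lapply(seq_along(me3Strong), function(i) {
      g <- me3Strong[i]
      ex <- exons[exons$gene_id == g$gene_id]
      exR <- IRanges::restrict(ranges(ex), start(g), end(g))
      inR <- IRanges::gaps(exR, start = start(g), end = end(g))
      Le <- sum(width(exR)); Li <- sum(width(inR)); L <- width(g)
      k <- L / (b * Le + Li)
      chr <- as.character(seqnames(g))
      gr <- c(GRanges(rep(chr, length(exR)), exR),
              GRanges(rep(chr, length(inR)), inR))
      gr$excess <- S * k * c(rep(b, length(exR)), rep(1, length(inR)))
      gr$group <- rep(g$group, length(gr))
      gr
    })
    me3 <- bindGR(pieces)
  }
  me3 <- concatGR(list(me3, bodies(c("C6", "C7"), W)),
                  c("excess", "group"))

  list(
    K36me1 = concatGR(list(bodies("C9", S), blocks(enhancers, S, "ENH")),
                      c("excess", "group")),
    K36me2 = concatGR(list(bodies(c("C6", "C7"), S), bodies(c("C1", "C3"), W),
                           blocks(pchMe2, S, "PCH")),
                      c("excess", "group")),
    K36me3 = me3,
    JASPer = {
      re <- cfg$readerExcess
      concatGR(lapply(names(re), function(g) bodies(g, re[[g]])),
               c("excess", "group"))
    },
    MSL3 = {
      gX <- genes[genes$group != "SC0" &
                  as.character(seqnames(genes)) == "chrX"]
      gr <- granges(gX)
      if (length(gr)) { gr$excess <- cfg$msl3Excess; gr$group <- gX$group }
      concatGR(list(gr), c("excess", "group"))
    },
    input = GRanges())
}

setMethod("show", "GenomePreset", function(object) {
  cat(sprintf("GenomePreset: %d chromosomes, %.3g bp, %d genes\n",
              length(object@seqlens), sum(object@seqlens),
              length(object@genes)))
  if (length(object@genes)) {
    tab <- table(object@genes$group)
    cat("  gene groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  fr <- vapply(object@domains, function(d) sum(width(d)) / sum(object@seqlens),
               numeric(1))
  cat("  planted domain fractions:",
      paste(names(fr), sprintf("%.3f", fr), collapse = " "), "\n")
})

#' @rdname GenomePreset-class
#' @param preset a [GenomePreset-class]
#' @export
presetGenes <- function(preset) preset@genes

#' @rdname GenomePreset-class
#' @export
presetExons <- function(preset) preset@exons

#' @rdname GenomePreset-class
#' @export
presetPCH <- function(preset) preset@pch

#' @rdname GenomePreset-class
#' @export
presetSeqlens <- function(preset) preset@seqlens

#' Planted strong-domain intervals per mark
#' @rdname GenomePreset-class
#' @export
plantedDomains <- function(preset) preset@domains

#' Planted per-mark target genome fractions
#' @rdname GenomePreset-class
#' @export
targetFractions <- function(preset) preset@fractions
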