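## ChIP-target assignment and downstream statistics: peaks are assigned
## to genes whose TSS lies within 2 kb of a peak edge, targets are
## crossed with differential-expression status (UP / DOWN / NDE), and
## user-supplied genesets are tested for over-representation with the
## Fisher exact (hypergeometric) test plus Benjamini-Hochberg adjustment.

#' Assign ChIP peaks to target genes near their TSS
#'
#' A gene is a target iff any peak's nearest edge lies within
#' \code{windowBp} of its TSS point (inclusive; distance 0 when the peak
#' covers the TSS). A peak may support several genes.
#'
#' @param peaks GRanges of ChIP peaks.
#' @param tss named GRanges of single-bp TSS positions (names = genes),
#'   e.g. from \code{\link{readTssTable}}.
#' @param windowBp assignment window in bp (default 2000).
#' @return \link[S4Vectors]{DataFrame} of target genes with columns
#'   \code{gene}, \code{chrom}, \code{tss}, \code{minDistanceBp},
#'   \code{nPeaks} and a \code{peaks} GRangesList column of supporting
#'   peaks.
#' @export
assignTargets <- function(peaks, tss, windowBp = 2000L) {
  if (is.null(names(tss)) || anyDuplicated(names(tss)))
    stop("tss must be named with unique gene ids", call. = FALSE)
  win <- GenomicRanges::resize(GenomicRanges::granges(tss),
                               width = 2L * windowBp + 1L, fix = "center")
  ov <- GenomicRanges::findOverlaps(win, peaks, ignore.strand = TRUE)
  if (length(ov) == 0L) {
    out <- S4Vectors::DataFrame(gene = character(), chrom = character(),
                                tss = integer(), minDistanceBp = integer(),
                                nPeaks = integer())
    out$peaks <- GenomicRanges::GRangesList()
    return(out)
  }
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  tpos <- GenomicRanges::start(tss)[q]
  d <- pmax(0L, GenomicRanges::start(peaks)[s] - tpos,
            tpos - GenomicRanges::end(peaks)[s])
  keep <- d <= windowBp
  q <- q[keep]; s <- s[keep]; d <- d[keep]
  genes <- unique(q)
  out <- S4Vectors::DataFrame(
    gene = names(tss)[genes],
    chrom = as.character(GenomicRanges::seqnames(tss))[genes],
    tss = GenomicRanges::start(tss)[genes],
    minDistanceBp = vapply(genes, function(g) min(d[q == g]), 0L),
    nPeaks = vapply(genes, function(g) sum(q == g), 0L))
  out$peaks <- GenomicRanges::GRangesList(
    lapply(genes, function(g) peaks[s[q == g]]))
  out[order(out$gene), , drop = FALSE]
}

#' Classify differential-expression status
#'
#' UP iff \code{fdr < fdrMax} and linear fold change \code{> fcMin}
#' (i.e. \code{log2fc > log2(fcMin)}); DOWN iff \code{fdr < fdrMax} and
#' fold change \code{< 1/fcMin}; everything else NDE. Every gene gets
#' exactly one class.
#'
#' @param de data.frame with columns gene, log2fc, fdr.
#' @param fdrMax FDR threshold (default 0.05).
#' @param fcMin linear fold-change threshold, must exceed 1 (default 1.5).
#' @return named character vector gene -> \{UP, DOWN, NDE\}.
#' @examples
#' de <- data.frame(gene = c("a", "b"), log2fc = c(1, 0.5),
#'                  fdr = c(0.01, 0.01))
#' classifyDe(de)   # a = UP (2-fold), b = NDE (1.41-fold)
#' @export
classifyDe <- function(de, fdrMax = 0.05, fcMin = 1.5) {
  if (fcMin <= 1) stop("fcMin must be > 1", call. = FALSE)
  lfc <- log2(fcMin)
  status <- ifelse(de$fdr < fdrMax & de$log2fc > lfc, "UP",
                   ifelse(de$fdr < fdrMax & de$log2fc < -lfc, "DOWN", "NDE"))
  stats::setNames(status, de$gene)
}

#' Crosstab of target genes by differential-expression class
#'
#' @param targets character vector of target gene ids (or the output of
#'   \code{\link{assignTargets}}).
#' @param deStatus named vector from \code{\link{classifyDe}}. Targets
#'   absent from it are counted as NDE, with a warning.
#' @return list with \code{nTargets}, \code{counts} and \code{fractions}
#'   (both named UP / DOWN / NDE).
#' @export
crosstabTargets <- function(targets, deStatus) {
  if (methods::is(targets, "DataFrame")) targets <- targets$gene
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("zero target genes", call. = FALSE)
  cls <- deStatus[targets]
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " target gene(s) absent from the DE table; ",
            "counted as NDE")
    cls[is.na(cls)] <- "NDE"
  }
  counts <- vapply(c("UP", "DOWN", "NDE"), function(k) sum(cls == k), 0L)
  list(nTargets = length(targets), counts = counts,
       fractions = counts / length(targets))
}

#' Counts-per-million normalization
#'
#' Delegates to \code{\link[edgeR]{cpm}}: value = count / library size x
#' 1e6, where the library size is the column sum.
#'
#' @param counts non-negative integer matrix genes x samples.
#' @return CPM matrix of the same shape.
#' @export
cpmNormalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and >= 0", call. = FALSE)
  libs <- colSums(counts)
  if (any(libs <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libs <= 0], collapse = ", "), call. = FALSE)
  edgeR::cpm(counts, normalized.lib.sizes = FALSE, log = FALSE)
}

#' Expression filter on CPM and multi-mapping
#'
#' Keeps a gene iff it has CPM > 1 in more than (minimum group size - 1)
#' samples, and (when provided) its multi-mapping read fraction is below
#' 20\%.
#'
#' @param counts genes x samples count matrix.
#' @param groupSizes integer vector of per-condition sample counts; their
#'   sum must equal \code{ncol(counts)}.
#' @param multimapFraction optional named per-gene fraction of
#'   multi-mapping reads.
#' @param cpmMin CPM cutoff (default 1).
#' @param multimapMax multi-mapping cutoff (default 0.2).
#' @return character vector of kept gene ids.
#' @export
expressionFilter <- function(counts, groupSizes, multimapFraction = NULL,
                             cpmMin = 1, multimapMax = 0.2) {
  if (sum(groupSizes) != ncol(counts))
    stop("groupSizes must sum to the number of samples", call. = FALSE)
  cpm <- cpmNormalize(counts)
  nPass <- rowSums(cpm > cpmMin)
  keep <- nPass > (min(groupSizes) - 1L)
  if (!is.null(multimapFraction)) {
    mm <- multimapFraction[rownames(counts)]
    mm[is.na(mm)] <- 0
    keep <- keep & mm < multimapMax
  }
  rownames(counts)[keep]
}

## One-sided (over-representation) Fisher p from the hypergeometric tail:
## P(X >= overlap) with X ~ Hypergeom(setSize, universe - setSize, listSize).
.hyperTailP <- function(overlap, setSize, listSize, universe) {
  stats::phyper(overlap - 1L, setSize, universe - setSize, listSize,
                lower.tail = FALSE)
}

#' Fisher-exact geneset over-representation
#'
#' For each geneset, builds the 2x2 table of the query list against the
#' universe and computes the one-sided (enrichment) Fisher exact p-value
#' from the hypergeometric tail; p-values are Benjamini-Hochberg adjusted
#' across genesets. The odds ratio is the cross-product ratio; when a
#' margin is zero a 0.5 continuity correction is applied to the reported
#' odds ratio only (flagged in \code{orContinuity}).
#'
#' @param geneList character vector of query genes (must lie in the
#'   universe).
#' @param genesets named list of character vectors; each set is
#'   intersected with the universe.
#' @param universe character vector of all considered genes.
#' @param alternative \code{"greater"} (default, one-sided enrichment) or
#'   \code{"two.sided"} (delegated to \code{stats::fisher.test}).
#' @return data.frame with columns geneset, overlap, setOnly, listOnly,
#'   neither, oddsRatio, orContinuity, p, padj.
#' @export
fisherEnrichment <- function(geneList, genesets, universe,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  geneList <- unique(geneList)
  if (!all(geneList %in% universe))
    stop("gene list contains genes outside the universe", call. = FALSE)
  res <- lapply(names(genesets), function(nm) {
    set <- intersect(unique(genesets[[nm]]), universe)
    a <- length(intersect(geneList, set))
    b <- length(set) - a                      # set only
    c_ <- length(geneList) - a                # list only
    d <- length(universe) - a - b - c_
    p <- if (alternative == "greater")
      .hyperTailP(a, length(set), length(geneList), length(universe))
    else
      stats::fisher.test(matrix(c(a, b, c_, d), 2L), alternative = "two.sided")$p.value
    continuity <- any(c(a, b, c_, d) == 0L)
    orTab <- if (continuity) c(a, b, c_, d) + 0.5 else c(a, b, c_, d)
    data.frame(geneset = nm, overlap = a, setOnly = b, listOnly = c_,
               neither = d,
               oddsRatio = (orTab[1L] * orTab[4L]) / (orTab[2L] * orTab[3L]),
               orContinuity = continuity, p = min(p, 1))
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
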