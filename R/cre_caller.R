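## CRE identification around a target TSS: per-mark peak evidence across
## cell types is unioned, restricted to a +/- 20 kb window, gap-merged,
## classified by mark precedence (H3K4me3 promoter > H3K4me1 enhancer >
## accessible-only) and numbered 1..k along the gene strand so the
## promoter cluster takes the lowest numbers.

.MARK_H3K4ME3 <- "H3K4me3"
.MARK_H3K4ME1 <- "H3K4me1"
.MARK_DNASE <- "DNase"
.MARK_H3K27AC <- "H3K27ac"

## Sum of per-cell-type occupancy indicators, padded to a common extent
## per chromosome so Rle addition is well defined.
.sumCoverage <- function(grs) {
  grs <- lapply(grs, GenomicRanges::reduce)
  allLevels <- unique(unlist(lapply(grs, function(g)
    as.character(GenomeInfoDb::seqlevels(g)))))
  ends <- vapply(allLevels, function(sl) {
    e <- unlist(lapply(grs, function(g) {
      gg <- g[as.character(GenomicRanges::seqnames(g)) == sl]
      if (length(gg)) max(GenomicRanges::end(gg)) else 0L
    }))
    as.integer(max(e, 1L))
  }, 1L)
  covs <- lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- allLevels
    GenomicRanges::coverage(g, width = ends)
  })
  Reduce(`+`, covs)
}

## Normalize a per-mark peak input: either a GRanges (one aggregate
## sample) or a list of GRanges (one per cell type). Returns the ranges
## supported by >= minCellTypes cell types.
.supportedPeaks <- function(x, minCellTypes) {
  if (methods::is(x, "GRanges")) return(GenomicRanges::reduce(x))
  if (!is.list(x)) stop("peaks must be a GRanges or a list of GRanges",
                        call. = FALSE)
  if (length(x) == 0L) return(GenomicRanges::GRanges())
  tot <- .sumCoverage(x)
  sup <- IRanges::slice(tot, lower = minCellTypes, rangesOnly = TRUE)
  GenomicRanges::GRanges(sup)
}

#' Length-weighted mean signal over an interval
#'
#' Averages a \linkS4class{SignalTrack} over a query interval; bases not
#' covered by the track contribute 0.
#'
#' @param track \linkS4class{SignalTrack} (or GRanges with a \code{score}
#'   column).
#' @param interval single GRanges interval.
#' @return length-weighted mean signal (numeric scalar).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), score = 2)
#' st <- SignalTrack(gr, "H3K27ac")
#' aggregateSignal(st, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50)))
#' @export
aggregateSignal <- function(track, interval) {
  gr <- if (methods::is(track, "SignalTrack")) trackRegions(track) else track
  if (length(interval) != 1L)
    stop("interval must be a single range", call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(interval))
  if (length(gr) > 0L &&
      !chrom %in% as.character(GenomeInfoDb::seqlevels(gr)))
    stop("chromosome '", chrom, "' absent from the signal track",
         call. = FALSE)
  ov <- GenomicRanges::findOverlaps(interval, gr, ignore.strand = TRUE)
  if (length(ov) == 0L) return(0)
  hits <- gr[S4Vectors::subjectHits(ov)]
  inter <- IRanges::pintersect(
    IRanges::ranges(rep(interval, length(hits))), IRanges::ranges(hits))
  sum(IRanges::width(inter) * S4Vectors::mcols(hits)$score) /
    IRanges::width(interval)
}

#' Call cis-regulatory elements around a TSS
#'
#' Unions peak evidence per mark (optionally across cell types with a
#' minimum-support filter), restricts it to \code{[TSS - windowBp,
#' TSS + windowBp]}, merges elements closer than \code{mergeGapBp},
#' classifies each merged element (promoter if it overlaps any H3K4me3
#' peak; else enhancer if H3K4me1; else accessible-only) and numbers the
#' elements 1..k in 5'-to-3' order along the gene strand, so the element
#' at / immediately upstream of the TSS takes the lowest number among
#' promoter-class elements.
#'
#' @param peaks named list: mark -> GRanges of peaks, or mark -> list of
#'   per-cell-type GRanges. Recognized marks: \code{H3K4me3},
#'   \code{H3K4me1}, \code{DNase}, \code{H3K27ac} (case-insensitive).
#' @param tss single-position GRanges of the target TSS; its strand is
#'   the gene strand used for numbering.
#' @param windowBp half-width of the search window (default 20000, i.e.
#'   elements within 20 kb of the TSS).
#' @param minCellTypes minimum number of supporting cell types per mark
#'   (default 1).
#' @param mergeGapBp elements closer than this are merged (default 200).
#' @param tracks optional named list of \linkS4class{SignalTrack}s per
#'   mark, used to fill per-mark mean-signal summary columns.
#' @return GRanges of CREs in genomic order, metadata columns
#'   \code{number}, \code{creClass}, \code{name} ("CRE\{n\}:\{class\}"),
#'   \code{nCellTypesSupporting}, and \code{signal_<mark>} columns when
#'   \code{tracks} are given. Empty GRanges when nothing survives.
#' @export
callCres <- function(peaks, tss, windowBp = 20000L, minCellTypes = 1L,
                     mergeGapBp = 200L, tracks = NULL) {
  if (length(peaks) == 0L)
    stop("at least one mark's peaks must be supplied", call. = FALSE)
  if (length(tss) != 1L)
    stop("tss must be a single position", call. = FALSE)
  markNames <- names(peaks)
  canon <- c(.MARK_H3K4ME3, .MARK_H3K4ME1, .MARK_DNASE, .MARK_H3K27AC)
  m <- match(tolower(markNames), tolower(canon))
  markNames[!is.na(m)] <- canon[m[!is.na(m)]]
  names(peaks) <- markNames
  supported <- lapply(peaks, .supportedPeaks, minCellTypes = minCellTypes)

  tssPos <- GenomicRanges::start(tss)
  window <- GenomicRanges::GRanges(GenomicRanges::seqnames(tss),
    IRanges::IRanges(max(1L, tssPos - windowBp), tssPos + windowBp))
  inWindow <- lapply(supported, function(g)
    suppressWarnings(GenomicRanges::intersect(g, window,
                                              ignore.strand = TRUE)))
  pooled <- GenomicRanges::reduce(
    do.call(c, unname(lapply(inWindow, GenomicRanges::granges))),
    min.gapwidth = mergeGapBp)
  if (length(pooled) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      number = integer(), creClass = character(), name = character())
    return(out)
  }

  overlapsMark <- function(mark) {
    if (!mark %in% names(inWindow)) return(rep(FALSE, length(pooled)))
    IRanges::overlapsAny(pooled, inWindow[[mark]], ignore.strand = TRUE)
  }
  isProm <- overlapsMark(.MARK_H3K4ME3)
  isEnh <- !isProm & overlapsMark(.MARK_H3K4ME1)
  creClass <- ifelse(isProm, "promoter",
                     ifelse(isEnh, "enhancer", "accessible_only"))

  ## support count: max number of cell types backing any constituent peak
  nSupport <- rep(1L, length(pooled))
  perCt <- peaks[vapply(peaks, function(x) is.list(x) &&
                          !methods::is(x, "GRanges"), TRUE)]
  if (length(perCt) > 0L) {
    covs <- .sumCoverage(unlist(perCt, recursive = FALSE))
    nSupport <- vapply(seq_along(pooled), function(i) {
      v <- covs[[as.character(GenomicRanges::seqnames(pooled[i]))]]
      hi <- min(length(v), GenomicRanges::end(pooled[i]))
      lo <- min(GenomicRanges::start(pooled[i]), hi)
      as.integer(max(S4Vectors::window(v, lo, hi)))
    }, 1L)
  }

  geneStrand <- as.character(GenomicRanges::strand(tss))
  ord <- order(GenomicRanges::start(pooled),
               decreasing = identical(geneStrand, "-"))
  number <- integer(length(pooled))
  number[ord] <- seq_along(pooled)

  S4Vectors::mcols(pooled) <- S4Vectors::DataFrame(
    number = number, creClass = creClass,
    name = paste0("CRE", number, ":", creClass),
    nCellTypesSupporting = nSupport)
  if (!is.null(tracks)) {
    for (mark in names(tracks)) {
      S4Vectors::mcols(pooled)[[paste0("signal_", mark)]] <-
        vapply(seq_along(pooled), function(i)
          aggregateSignal(tracks[[mark]], pooled[i]), 0)
    }
  }
  pooled
}

#' Select the core promoter among called CREs
#'
#' Among promoter-class CREs that overlap the TSS or lie immediately
#' upstream of it (in the gene-strand sense), returns the one with the
#' highest aggregate DNase signal; ties are broken by smallest genomic
#' start. This mirrors picking the element immediately upstream of the
#' major TSS with the strongest chromatin accessibility.
#'
#' @param cres GRanges from \code{\link{callCres}}.
#' @param dnase \linkS4class{SignalTrack} of DNase accessibility.
#' @param tss single-position GRanges of the TSS.
#' @return single-range GRanges (the core promoter), or \code{NULL} with
#'   a warning when no promoter-class CRE qualifies.
#' @export
selectCorePromoter <- function(cres, dnase, tss) {
  prom <- cres[S4Vectors::mcols(cres)$creClass == "promoter"]
  if (length(prom) == 0L) {
    warning("no promoter-class CRE called; cannot select a core promoter")
    return(NULL)
  }
  tssPos <- GenomicRanges::start(tss)
  upstream <- if (identical(as.character(GenomicRanges::strand(tss)), "-"))
    GenomicRanges::start(prom) > tssPos
  else
    GenomicRanges::end(prom) < tssPos
  eligible <- upstream | IRanges::overlapsAny(prom,
    GenomicRanges::GRanges(GenomicRanges::seqnames(tss),
                           IRanges::IRanges(tssPos, tssPos)),
    ignore.strand = TRUE)
  cand <- prom[eligible]
  if (length(cand) == 0L) {
    warning("no promoter-class CRE overlaps or lies upstream of the TSS")
    return(NULL)
  }
  sig <- vapply(seq_along(cand), function(i) aggregateSignal(dnase, cand[i]), 0)
  cand[order(-sig, GenomicRanges::start(cand))][1L]
}

#' Binned coverage profile matrix around TSSs
#'
#' For each TSS, mean coverage in \code{nBins} equal bins across
#' \code{[TSS - flankBp, TSS + flankBp)}; profiles of minus-strand TSSs
#' are flipped so bin 1 is always the 5' end. When \code{2 * flankBp} is
#' not an exact multiple of \code{nBins} the window is truncated
#' deterministically to \code{nBins * floor(2 * flankBp / nBins)} bases.
#'
#' @param coverage \linkS4class{SignalTrack} of read coverage.
#' @param tss GRanges of TSS positions (names = region/gene labels).
#' @param flankBp half-width of the profiled window (default 2000).
#' @param nBins number of bins (default 100).
#' @return list with \code{matrix} (regions x bins) and \code{mean}
#'   (column means, the average profile).
#' @export
tssProfileMatrix <- function(coverage, tss, flankBp = 2000L, nBins = 100L) {
  if (length(tss) == 0L) stop("tss list is empty", call. = FALSE)
  binW <- (2L * flankBp) %/% nBins
  if (binW < 1L) stop("nBins too large for the flank width", call. = FALSE)
  gr <- trackRegions(coverage)
  covRle <- GenomicRanges::coverage(gr, weight = "score")
  mat <- matrix(0, nrow = length(tss), ncol = nBins)
  rownames(mat) <- if (!is.null(names(tss))) names(tss) else
    paste0("tss", seq_along(tss))
  for (i in seq_along(tss)) {
    chrom <- as.character(GenomicRanges::seqnames(tss[i]))
    t0 <- GenomicRanges::start(tss[i])
    from <- t0 - flankBp
    v <- numeric(nBins * binW)
    if (chrom %in% names(covRle)) {
      rle <- covRle[[chrom]]
      lo <- max(1L, from)
      hi <- min(length(rle), from + nBins * binW - 1L)
      if (hi >= lo)
        v[(lo - from + 1L):(hi - from + 1L)] <-
          as.numeric(IRanges::Views(rle, lo, hi)[[1L]])
    }
    prof <- colMeans(matrix(v, nrow = binW))
    if (identical(as.character(GenomicRanges::strand(tss[i])), "-"))
      prof <- base::rev(prof)
    mat[i, ] <- prof
  }
  list(matrix = mat, mean = colMeans(mat))
}
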