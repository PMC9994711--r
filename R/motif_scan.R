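## PWM machinery: log-odds construction, exact score-distribution
## thresholding by dynamic programming on a discretized score lattice,
## double-strand scanning, and per-TF binding-site counting (Bumscore).
##
## All scores are log2 odds ("bits"). To keep the scanner and the DP on
## the same footing, log-odds entries are rounded to the lattice (default
## step 1e-3 bits) at construction time: every window score is then an
## exact lattice sum and the DP tail probability at a reported hit score
## is exact for the scored matrix, not an approximation.

#' Build a log-odds PWM from a count matrix
#'
#' Entry (b, j) is
#' \deqn{\log_2 \frac{(n_{bj} + s\,\pi_b)/(N_j + s)}{\pi_b}}
#' where \eqn{n_{bj}} is the count, \eqn{N_j} the column sum, \eqn{s} the
#' pseudocount and \eqn{\pi} the background. Entries are rounded to the
#' p-value lattice (\code{step} bits) so that scanning and the exact
#' score-distribution DP agree bit-for-bit.
#'
#' @param pfm a \linkS4class{PFM}.
#' @param pseudocount positive pseudocount (default 0.5), spread over the
#'   bases proportionally to the background.
#' @param background length-4 base composition (A, C, G, T); default
#'   uniform. Normalized to sum to 1.
#' @param step score lattice step in bits (default 1e-3).
#' @return A \linkS4class{PWM}.
#' @examples
#' pfm <- PFM("M1", matrix(c(10, 0, 0, 0), 4, 5, dimnames = list(c("A", "C",
#'   "G", "T"), NULL)) + diag(0, 4, 5))
#' @export
buildPwm <- function(pfm, pseudocount = 0.5,
                     background = rep(0.25, 4), step = 1e-3) {
  if (pseudocount <= 0)
    stop("pseudocount must be > 0", call. = FALSE)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive values", call. = FALSE)
  background <- background / sum(background)
  counts <- motifCounts(pfm)
  csum <- colSums(counts)
  freq <- sweep(counts + pseudocount * background, 2L,
                csum + pseudocount, "/")
  mat <- log2(freq / background)
  mat <- round(mat / step) * step
  names(background) <- DNA_BASES4
  methods::new("PWM", id = motifId(pfm), tf = tfName(pfm), mat = mat,
               background = background, pseudocount = pseudocount)
}

## Exact background score distribution on the integer lattice.
## Returns integer lattice scores (units of `step` bits) and their
## background probabilities, by column-wise convolution.
.pwmScoreDist <- function(pwm, step = 1e-3) {
  imat <- round(motifMatrix(pwm) / step)
  bg <- motifBackground(pwm)
  L <- ncol(imat)
  lo <- sum(apply(imat, 2L, min))
  hi <- sum(apply(imat, 2L, max))
  probs <- 1
  offset <- 0  # lattice score of probs[1]
  for (j in seq_len(L)) {
    cmin <- min(imat[, j])
    cmax <- max(imat[, j])
    newlen <- length(probs) + (cmax - cmin)
    np <- numeric(newlen)
    for (b in 1:4) {
      sh <- imat[b, j] - cmin
      np[(1 + sh):(length(probs) + sh)] <-
        np[(1 + sh):(length(probs) + sh)] + bg[b] * probs
    }
    probs <- np
    offset <- offset + cmin
  }
  stopifnot(offset == lo, offset + length(probs) - 1L == hi)
  list(scores = seq.int(lo, hi), probs = probs, step = step)
}

#' Exact background p-value of a PWM score
#'
#' Tail probability \eqn{P_{bg}(S \ge s)} of the per-window score under
#' the PWM's 0-order background model, computed by exact dynamic
#' programming over the discretized score lattice.
#'
#' @param pwm a \linkS4class{PWM}.
#' @param score score(s) in bits.
#' @param step lattice step in bits; must match the PWM's construction
#'   step (default 1e-3).
#' @return numeric vector of tail probabilities.
#' @export
pwmTailProbability <- function(pwm, score, step = 1e-3) {
  d <- .pwmScoreDist(pwm, step)
  tail <- rev(cumsum(rev(d$probs)))
  ## half-step guard so lattice scores compare exactly
  idx <- findInterval(round(score / step) - 0.5, d$scores) + 1L
  out <- numeric(length(score))
  out[idx > length(tail)] <- 0
  out[idx < 1L] <- 1
  ok <- idx >= 1L & idx <= length(tail)
  out[ok] <- tail[idx[ok]]
  out
}

#' Score threshold at a background p-value
#'
#' The smallest score s (in bits, on the lattice) such that
#' \eqn{P_{bg}(S \ge s) \le p}. If even the maximal score has tail
#' probability above p, a threshold one step above the maximum is
#' returned (no window can qualify).
#'
#' @param pwm a \linkS4class{PWM}.
#' @param p background p-value in (0, 1].
#' @param step lattice step in bits (default 1e-3).
#' @return threshold score in bits.
#' @examples
#' pfm <- PFM("M1", matrix(5, 4, 4, dimnames = list(c("A","C","G","T"), NULL)))
#' scoreThreshold(buildPwm(pfm), p = 1)   # minimum achievable score
#' @export
scoreThreshold <- function(pwm, p, step = 1e-3) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]", call. = FALSE)
  d <- .pwmScoreDist(pwm, step)
  tail <- rev(cumsum(rev(d$probs)))
  ok <- which(tail <= p + 1e-15)
  if (length(ok) == 0L) return((d$scores[length(d$scores)] + 1L) * step)
  d$scores[ok[1L]] * step
}

## Encode an upper-case DNA string as integers 1..5 (A C G T, 5 = N/other).
.encodeSeq <- function(seq) {
  v <- utf8ToInt(toupper(as.character(seq)))
  code <- rep(5L, 128L)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[v]
}

## Per-window scores of `mat5` (5 x L, row 5 = N penalty) along an
## integer-encoded sequence. Returns numeric vector of length n - L + 1.
.windowScores <- function(codes, mat5) {
  L <- ncol(mat5)
  npos <- length(codes) - L + 1L
  if (npos < 1L) return(numeric())
  s <- numeric(npos)
  for (j in seq_len(L))
    s <- s + mat5[codes[j:(j + npos - 1L)], j]
  s
}

## 5-row scoring matrix: ACGT rows plus per-column minimum for N
## (worst-case scoring, so N never inflates a score).
.mat5 <- function(mat) rbind(mat, apply(mat, 2L, min))

## Reverse-complement scoring matrix: complement rows, reverse columns.
.revcompMat <- function(mat) {
  m <- mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
  rownames(m) <- DNA_BASES4
  m
}

## Raw hit finder on an encoded sequence: returns start (1-based, local),
## strand and score vectors. The fast path shared by scanSequence and
## computeBumscore.
.scanRaw <- function(codes, mat, threshold, step = 1e-3) {
  L <- ncol(mat)
  fwd <- .windowScores(codes, .mat5(mat))
  rev <- .windowScores(codes, .mat5(.revcompMat(mat)))
  eps <- step / 2
  hf <- which(fwd >= threshold - eps)
  hr <- which(rev >= threshold - eps)
  list(start = c(hf, hr),
       strand = rep(c("+", "-"), c(length(hf), length(hr))),
       score = c(fwd[hf], rev[hr]), width = L)
}

## Greedy best-first non-overlap resolution on raw hits (equal widths):
## keep the best-scoring hit (ties: leftmost, then + strand), drop
## anything within `width` bp of a kept start.
.resolveRaw <- function(h) {
  n <- length(h$start)
  if (n <= 1L) return(h)
  o <- order(-h$score, h$start, h$strand == "-")
  st <- h$start[o]
  keep <- logical(n)
  keptStarts <- integer(0)
  for (i in seq_len(n)) {
    if (!any(abs(keptStarts - st[i]) < h$width)) {
      keep[i] <- TRUE
      keptStarts <- c(keptStarts, st[i])
    }
  }
  sel <- o[keep]
  sel <- sel[order(h$start[sel])]
  list(start = h$start[sel], strand = h$strand[sel], score = h$score[sel],
       width = h$width)
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window on both strands is scored; windows scoring at or above
#' \code{\link{scoreThreshold}(pwm, p)} are reported as hits.
#' Reverse-strand hits are reported in forward coordinates. Windows
#' containing N are scored with the per-position minimum over the
#' alphabet, so at stringent p an N-containing window is never a hit.
#'
#' @param seq a single sequence (character or \link[Biostrings]{DNAString});
#'   length >= motif length.
#' @param pwm a \linkS4class{PWM}.
#' @param p background p-value cutoff (default 1e-4).
#' @param chrom chromosome name for the reported intervals.
#' @param offset 0-based offset added to hit coordinates (use when
#'   \code{seq} is a sub-sequence of a larger reference).
#' @param threshold optional precomputed score threshold (bits); overrides
#'   \code{p}.
#' @param step lattice step in bits (default 1e-3).
#' @return GRanges of hits with metadata columns \code{tf} and
#'   \code{score} (bits), strand +/-.
#' @export
scanSequence <- function(seq, pwm, p = 1e-4, chrom = "seq", offset = 0L,
                         threshold = NULL, step = 1e-3) {
  codes <- .encodeSeq(seq)
  L <- motifLength(pwm)
  if (length(codes) < L)
    stop("sequence shorter than motif length", call. = FALSE)
  if (is.null(threshold)) threshold <- scoreThreshold(pwm, p, step)
  h <- .scanRaw(codes, motifMatrix(pwm), threshold, step)
  starts <- h$start + offset
  if (length(starts) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$tf <- character()
    S4Vectors::mcols(gr)$score <- numeric()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = starts, width = L),
          strand = h$strand, tf = tfName(pwm), score = h$score)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

## Greedy non-overlap resolution among same-TF hits: keep the
## best-scoring hit, ties broken leftmost then "+" strand; drop anything
## overlapping a kept hit. Prevents palindromic double-counting.
.resolveOverlaps <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  strandOrd <- as.integer(GenomicRanges::strand(hits) == "-")
  o <- order(-S4Vectors::mcols(hits)$score, GenomicRanges::start(hits),
             strandOrd)
  hits <- hits[o]
  keep <- logical(length(hits))
  for (i in seq_along(hits)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    ov <- GenomicRanges::countOverlaps(hits[i], hits[keep],
                                       ignore.strand = TRUE)
    keep[i] <- ov == 0L
  }
  GenomicRanges::sort(hits[keep], ignore.strand = TRUE)
}

#' Count predicted binding sites per CRE: the Bumscore
#'
#' For each TF, each CRE sequence is scanned on both strands at the given
#' background p-value; overlapping same-TF hits are collapsed greedily,
#' keeping the best-scoring one (ties: leftmost, then + strand). The
#' Bumscore is the total count of retained hits across all CREs.
#'
#' @param pwms list of \linkS4class{PWM} (or \linkS4class{PFM}, which are
#'   converted with default \code{\link{buildPwm}} settings).
#' @param cres GRanges of CREs (as returned by \code{\link{callCres}}).
#' @param genome named \link[Biostrings]{DNAStringSet} (or single
#'   character string) holding the locus sequence.
#' @param p background p-value cutoff (default 1e-4).
#' @param step lattice step in bits (default 1e-3).
#' @return A \link[S4Vectors]{DataFrame} with columns \code{tf},
#'   \code{creCounts} (integer matrix, one column per CRE) and
#'   \code{bumscore}; one row per TF. Hit coordinates are attached as the
#'   \code{"hits"} metadata element (a GRangesList named by TF).
#' @export
computeBumscore <- function(pwms, cres, genome, p = 1e-4, step = 1e-3) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome))) names(genome) <- "seq"
  }
  pwms <- lapply(pwms, function(w)
    if (methods::is(w, "PFM")) buildPwm(w, step = step) else w)
  creNames <- if (!is.null(S4Vectors::mcols(cres)$name))
    S4Vectors::mcols(cres)$name else paste0("CRE", seq_along(cres))
  if (length(cres) > 0L) {
    chroms <- as.character(GenomicRanges::seqnames(cres))
    if (!all(chroms %in% names(genome)))
      stop("CRE chromosome absent from the genome sequence", call. = FALSE)
    if (any(GenomicRanges::start(cres) < 1L |
            GenomicRanges::end(cres) >
              BiocGenerics::width(genome)[match(chroms, names(genome))]))
      stop("CRE coordinates fall outside the genome sequence", call. = FALSE)
  }
  nTf <- length(pwms)
  counts <- matrix(0L, nrow = nTf, ncol = length(cres),
                   dimnames = list(NULL, creNames))
  tfs <- vapply(pwms, tfName, "")
  creCodes <- lapply(seq_along(cres), function(k)
    .encodeSeq(Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(cres[k]))]],
      GenomicRanges::start(cres[k]), GenomicRanges::end(cres[k]))))
  hitStart <- hitStrand <- hitScore <- hitTf <- hitChrom <- list()
  hitWidth <- integer(0)
  for (i in seq_len(nTf)) {
    pwm <- pwms[[i]]
    thr <- scoreThreshold(pwm, p, step)
    mat <- motifMatrix(pwm)
    for (k in seq_along(cres)) {
      if (length(creCodes[[k]]) < ncol(mat)) next
      h <- .resolveRaw(.scanRaw(creCodes[[k]], mat, thr, step))
      nh <- length(h$start)
      counts[i, k] <- nh
      if (nh > 0L) {
        j <- length(hitStart) + 1L
        hitStart[[j]] <- h$start + GenomicRanges::start(cres[k]) - 1L
        hitStrand[[j]] <- h$strand
        hitScore[[j]] <- h$score
        hitTf[[j]] <- rep(tfs[i], nh)
        hitChrom[[j]] <- rep(as.character(GenomicRanges::seqnames(cres[k])),
                             nh)
        hitWidth <- c(hitWidth, rep(ncol(mat), nh))
      }
    }
  }
  out <- S4Vectors::DataFrame(tf = tfs, bumscore = as.integer(rowSums(counts)))
  out$creCounts <- counts
  if (length(hitStart) > 0L) {
    hits <- GenomicRanges::GRanges(unlist(hitChrom),
      IRanges::IRanges(start = as.integer(unlist(hitStart)),
                       width = hitWidth),
      strand = unlist(hitStrand))
    S4Vectors::mcols(hits)$tf <- unlist(hitTf)
    S4Vectors::mcols(hits)$score <- unlist(hitScore)
  } else {
    hits <- GenomicRanges::GRanges()
    S4Vectors::mcols(hits)$tf <- character()
    S4Vectors::mcols(hits)$score <- numeric()
  }
  S4Vectors::metadata(out)$hits <-
    GenomicRanges::split(hits, factor(S4Vectors::mcols(hits)$tf,
                                      levels = tfs))
  out
}
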