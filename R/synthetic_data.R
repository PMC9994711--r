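## Synthetic study generator: a locus with planted cis-regulatory
## elements and a planted true-regulator motif among Dirichlet-sampled
## decoys, Gaussian-bump signal tracks per histone mark, an expression
## matrix with a planted TF-target correlation, a differential-expression
## table with exact UP/DOWN fractions, and ChIP peaks over a pseudo-gene
## roster. Every generator draws from its own RNG stream derived from the
## master seed, so changing e.g. the sample count never perturbs the
## locus sequence.

.SIM_CHROM <- "chrSim"
.GENE_CHROM <- "chrGenes"

## Independent per-generator sub-seeds from the master seed.
.streamSeeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  names(s) <- c("locus", "tracks", "expression", "de", "chip", "genesets",
                "spare1", "spare2")
  s
}

.withStream <- function(streamSeed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(streamSeed)
  expr
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Non-overlapping placement of n intervals of width w inside [lo, hi],
## keeping >= gap bp between intervals and away from `avoid` intervals.
.placeIntervals <- function(n, w, lo, hi, gap, avoid, maxTries = 2000L) {
  placed <- avoid
  out <- integer(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      st <- sample.int(hi - lo - w + 2L, 1L) + lo - 1L
      cand <- c(st - gap, st + w - 1L + gap)
      clash <- any(placed[, 1L] <= cand[2L] & placed[, 2L] >= cand[1L])
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop("infeasible CRE placement: window too crowded for the requested ",
           "number and width of elements", call. = FALSE)
    out <- c(out, st)
    placed <- rbind(placed, c(st, st + w - 1L))
  }
  out
}

#' Simulate the target locus with planted regulatory elements
#'
#' Generates an i.i.d.-uniform background sequence, places \code{nCres}
#' non-overlapping elements within 20 kb of a central TSS (the element
#' immediately upstream of the TSS is promoter-class, the rest
#' enhancers), plants \code{trueTfSitesPerCre} copies of the true
#' regulator's consensus (random strand) inside every element, and draws
#' \code{nTfDecoys} decoy motifs from a Dirichlet prior without planting
#' them. Identical seeds give byte-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{seq} (named \link[Biostrings]{DNAStringSet}),
#'   \code{tss} (named GRanges), \code{pfms} (named list of
#'   \linkS4class{PFM}; the true TF first, then decoys) and
#'   \code{groundTruth} (\linkS4class{GroundTruth}).
#' @examples
#' loc <- simulateLocus(simulationConfig(seed = 1, locusLength = 20000,
#'                                       nCres = 3))
#' loc$groundTruth
#' @export
simulateLocus <- function(config) {
  methods::validObject(config)
  seeds <- .streamSeeds(config@seed)
  .withStream(seeds["locus"], {
    L <- config@locusLength
    w <- config@creWidth
    bases <- sample(DNA_BASES4, L, replace = TRUE)

    tssPos <- L %/% 2L
    winLo <- max(1L, tssPos - 20000L)
    winHi <- min(L, tssPos + 20000L)
    promStart <- tssPos - w + 1L   # promoter element ends at the TSS
    if (promStart < winLo)
      stop("locus too small for the promoter element", call. = FALSE)
    ## enhancers go downstream of the TSS (the promoter cluster sits at
    ## the 5' end of the element series, as in the locus this emulates),
    ## so 5'-to-3' numbering always gives the promoter the lowest number
    avoid <- matrix(c(promStart, tssPos), 1L)
    enhStarts <- .placeIntervals(config@nCres - 1L, w, tssPos + 1L,
                                 min(winHi, L - w), gap = 500L,
                                 avoid = avoid)
    starts <- c(promStart, enhStarts)
    creClass <- c("promoter", rep("enhancer", config@nCres - 1L))
    cres <- GenomicRanges::GRanges(.SIM_CHROM,
      IRanges::IRanges(starts, width = w), creClass = creClass)
    ord <- order(GenomicRanges::start(cres))
    cres <- cres[ord]

    consensus <- paste(sample(DNA_BASES4, config@motifLength, replace = TRUE),
                       collapse = "")
    ml <- config@motifLength
    siteStarts <- integer(0)
    siteStrands <- character(0)
    for (k in seq_along(cres)) {
      creStart <- GenomicRanges::start(cres[k])
      slots <- floor(w / (2L * ml))
      if (slots < config@trueTfSitesPerCre)
        stop("creWidth too small for the requested sites per CRE",
             call. = FALSE)
      ## non-overlapping slots of width 2*mL, one site planted per slot
      chosen <- sort(sample.int(slots, config@trueTfSitesPerCre))
      off <- sample.int(ml, config@trueTfSitesPerCre, replace = TRUE) - 1L
      st <- creStart + (chosen - 1L) * 2L * ml + off
      strands <- sample(c("+", "-"), config@trueTfSitesPerCre, replace = TRUE)
      for (i in seq_along(st)) {
        ins <- if (strands[i] == "+") consensus else .revcomp(consensus)
        bases[st[i]:(st[i] + ml - 1L)] <- strsplit(ins, "")[[1L]]
      }
      siteStarts <- c(siteStarts, st)
      siteStrands <- c(siteStrands, strands)
    }
    sites <- GenomicRanges::GRanges(.SIM_CHROM,
      IRanges::IRanges(siteStarts, width = ml), strand = siteStrands)

    truePfm <- PFM("TF_TRUE", .consensusCounts(consensus))
    decoys <- lapply(seq_len(config@nTfDecoys), function(i) {
      counts <- replicate(ml, {
        g <- stats::rgamma(4L, shape = 1)
        v <- round(100 * g / sum(g))
        if (sum(v) == 0L) v[1L] <- 1L
        v
      })
      PFM(sprintf("TF_DECOY_%02d", i), counts)
    })
    pfms <- c(list(truePfm), decoys)
    names(pfms) <- vapply(pfms, motifId, "")

    tss <- GenomicRanges::GRanges(.SIM_CHROM,
      IRanges::IRanges(tssPos, tssPos), strand = "+")
    names(tss) <- "GENE_TARGET"
    genes <- c("GENE_TARGET", names(pfms))

    seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(seq) <- .SIM_CHROM
    gt <- methods::new("GroundTruth", trueTf = "TF_TRUE",
                       trueConsensus = consensus, plantedSites = sites,
                       cres = cres, tss = tss, targetGene = "GENE_TARGET",
                       genes = genes)
    list(seq = seq, tss = tss, pfms = pfms, groundTruth = gt)
  })
}

.consensusCounts <- function(consensus, major = 85, minor = 5) {
  b <- strsplit(consensus, "")[[1L]]
  counts <- matrix(minor, 4L, length(b), dimnames = list(DNA_BASES4, NULL))
  counts[cbind(match(b, DNA_BASES4), seq_along(b))] <- major
  counts
}

## Gaussian bump of a given height centred on an interval, evaluated on
## 1..L; sd is a quarter of the interval width.
.bump <- function(L, center, width, height) {
  x <- seq_len(L)
  height * exp(-((x - center)^2) / (2 * (width / 4)^2))
}

#' Simulate histone-mark and accessibility signal tracks
#'
#' Gaussian bumps of height \code{peakHeight} centred on the planted
#' elements: H3K4me3 only at the promoter element, H3K4me1 only at
#' enhancers, DNase at all elements (1.5x at the promoter), H3K27ac at
#' all elements; plus Gaussian noise (sd \code{trackNoiseSd}) clipped at
#' zero. Peak files are the bump supports (the element intervals) for the
#' elements each mark covers. With \code{nCellTypes > 1}, per-cell-type
#' H3K27ac tracks with log-normal height factors are emitted as well.
#'
#' @param locus output of \code{\link{simulateLocus}} (or a
#'   \linkS4class{GroundTruth}).
#' @param config the same \linkS4class{SimulationConfig}.
#' @return list with \code{tracks} (named list of
#'   \linkS4class{SignalTrack} per mark), \code{peaks} (named list of
#'   GRanges per mark) and, when \code{nCellTypes > 1},
#'   \code{celltypeTracks} (mark -> list of per-cell-type SignalTracks)
#'   and \code{heightFactors}.
#' @export
simulateTracks <- function(locus, config) {
  gt <- if (methods::is(locus, "GroundTruth")) locus else locus$groundTruth
  seeds <- .streamSeeds(config@seed)
  .withStream(seeds["tracks"], {
    L <- config@locusLength
    cres <- creRegions(gt)
    cls <- S4Vectors::mcols(cres)$creClass
    centers <- (GenomicRanges::start(cres) + GenomicRanges::end(cres)) / 2
    w <- config@creWidth
    h <- config@peakHeight

    bumpSum <- function(idx, mult = rep(1, length(idx))) {
      v <- numeric(L)
      for (j in seq_along(idx))
        v <- v + .bump(L, centers[idx[j]], w, h * mult[j])
      v
    }
    promIdx <- which(cls == "promoter")
    enhIdx <- which(cls == "enhancer")
    allIdx <- seq_along(cres)
    signal <- list(
      H3K4me3 = bumpSum(promIdx),
      H3K4me1 = bumpSum(enhIdx),
      DNase = bumpSum(allIdx, ifelse(allIdx %in% promIdx, 1.5, 1)),
      H3K27ac = bumpSum(allIdx))

    mkTrack <- function(v, mark, sample = "aggregate") {
      if (config@trackNoiseSd > 0)
        v <- pmax(v + stats::rnorm(L, 0, config@trackNoiseSd), 0)
      r <- S4Vectors::Rle(round(v, 6))
      gr <- GenomicRanges::GRanges(.SIM_CHROM,
        IRanges::IRanges(start = cumsum(c(1L, S4Vectors::runLength(r)))[
                           seq_along(S4Vectors::runLength(r))],
                         width = S4Vectors::runLength(r)),
        score = S4Vectors::runValue(r))
      SignalTrack(gr, mark, sample)
    }
    tracks <- mapply(mkTrack, signal, names(signal), SIMPLIFY = FALSE)
    peaks <- list(
      H3K4me3 = GenomicRanges::granges(cres[promIdx]),
      H3K4me1 = GenomicRanges::granges(cres[enhIdx]),
      DNase = GenomicRanges::granges(cres),
      H3K27ac = GenomicRanges::granges(cres))

    out <- list(tracks = tracks, peaks = peaks)
    if (config@nCellTypes > 1L) {
      hf <- matrix(exp(stats::rnorm(config@nCellTypes * length(cres), 0, 0.5)),
                   nrow = config@nCellTypes,
                   dimnames = list(paste0("CT", seq_len(config@nCellTypes)),
                                   NULL))
      ctTracks <- lapply(seq_len(config@nCellTypes), function(ct) {
        v <- numeric(L)
        for (j in allIdx) v <- v + .bump(L, centers[j], w, h * hf[ct, j])
        mkTrack(v, "H3K27ac", paste0("CT", ct))
      })
      names(ctTracks) <- rownames(hf)
      out$celltypeTracks <- list(H3K27ac = ctTracks)
      out$heightFactors <- hf
    }
    out
  })
}

#' Simulate the expression matrix with a planted correlation
#'
#' The target gene and the true TF are drawn from a bivariate normal
#' structure with population Pearson correlation
#' \code{targetTfCorrelation} on the log2 scale (latent log2-CPM = 6 +
#' latent, sd 1); decoy TFs are independent of the target. Values are
#' exponentiated to the CPM scale.
#'
#' @param locus output of \code{\link{simulateLocus}} (or a
#'   \linkS4class{GroundTruth}).
#' @param config the \linkS4class{SimulationConfig}.
#' @return genes x samples CPM matrix (rows: target, true TF, decoys).
#' @export
simulateExpression <- function(locus, config) {
  gt <- if (methods::is(locus, "GroundTruth")) locus else locus$groundTruth
  r <- config@targetTfCorrelation
  if (abs(r) >= 1)
    stop("targetTfCorrelation must lie strictly inside (-1, 1)",
         call. = FALSE)
  seeds <- .streamSeeds(config@seed)
  .withStream(seeds["expression"], {
    n <- config@nSamples
    genes <- simGenes(gt)
    z <- stats::rnorm(n)
    latent <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                     dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    latent[targetGene(gt), ] <- z
    latent[trueTf(gt), ] <- r * z + sqrt(1 - r^2) * latent[trueTf(gt), ]
    2^(6 + latent)
  })
}

#' Simulate a differential-expression table with exact planted fractions
#'
#' Exactly \code{round(n * deUpFraction)} genes receive
#' \code{log2fc > log2(1.5)} with \code{fdr < 0.05},
#' \code{round(n * deDownFraction)} the symmetric negative, and the rest
#' \code{fdr >= 0.05} (so no threshold rule can pick them up). When
#' \code{trueTfDe} is set and the true TF is in the roster it is planted
#' in the UP set.
#'
#' @param genes character vector of gene ids.
#' @param config the \linkS4class{SimulationConfig}.
#' @param trueTfId id to force into the UP set when \code{trueTfDe}
#'   (default \code{"TF_TRUE"}; ignored when absent from \code{genes}).
#' @return data.frame with columns gene, log2fc, fdr and a
#'   \code{"status"} attribute (the planted classes).
#' @export
simulateDeTable <- function(genes, config, trueTfId = "TF_TRUE") {
  seeds <- .streamSeeds(config@seed)
  .withStream(seeds["de"], {
    n <- length(genes)
    nUp <- round(n * config@deUpFraction)
    nDown <- round(n * config@deDownFraction)
    pool <- genes
    up <- character(0)
    if (config@trueTfDe && trueTfId %in% genes && nUp >= 1L) {
      up <- trueTfId
      pool <- setdiff(pool, trueTfId)
    }
    up <- c(up, sample(pool, nUp - length(up)))
    pool <- setdiff(pool, up)
    down <- if (nDown > 0L) sample(pool, nDown) else character(0)

    status <- stats::setNames(rep("NDE", n), genes)
    status[up] <- "UP"
    status[down] <- "DOWN"
    log2fc <- stats::runif(n, -0.5, 0.5)
    fdr <- stats::runif(n, 0.05, 1)
    names(log2fc) <- names(fdr) <- genes
    log2fc[up] <- stats::runif(length(up), log2(1.5) + 0.1, 3)
    log2fc[down] <- -stats::runif(length(down), log2(1.5) + 0.1, 3)
    fdr[c(up, down)] <- stats::runif(length(up) + length(down), 1e-6, 0.049)
    out <- data.frame(gene = genes, log2fc = unname(log2fc),
                      fdr = unname(fdr))
    attr(out, "status") <- status
    out
  })
}

#' Simulate ChIP peaks over a pseudo-gene roster
#'
#' Places the genes' TSSs 10 kb apart on a dedicated chromosome and
#' plants one ChIP peak within the assignment window of a
#' \code{boundFraction} of them (the target gene, when present, is always
#' bound - the planted regulator binds its target's promoter).
#'
#' @param genes character vector of gene ids.
#' @param config the \linkS4class{SimulationConfig}.
#' @param boundFraction fraction of genes with a peak near the TSS
#'   (default 0.3).
#' @param windowBp half-width within which planted peaks fall
#'   (default 2000).
#' @return list with \code{tss} (named GRanges), \code{peaks} (GRanges)
#'   and \code{bound} (character vector of bound genes).
#' @export
simulateChipPeaks <- function(genes, config, boundFraction = 0.3,
                              windowBp = 2000L) {
  seeds <- .streamSeeds(config@seed)
  .withStream(seeds["chip"], {
    n <- length(genes)
    tssPos <- 5000L + (seq_len(n) - 1L) * 10000L
    tss <- GenomicRanges::GRanges(.GENE_CHROM,
      IRanges::IRanges(tssPos, tssPos), strand = "+")
    names(tss) <- genes
    nBound <- max(1L, round(n * boundFraction))
    bound <- genes
    if (nBound < n) {
      pool <- genes
      bound <- character(0)
      if ("GENE_TARGET" %in% genes) {
        bound <- "GENE_TARGET"
        pool <- setdiff(pool, bound)
      }
      bound <- c(bound, sample(pool, nBound - length(bound)))
    }
    idx <- match(bound, genes)
    centerOff <- sample.int(2L * windowBp - 400L, length(idx), replace = TRUE) -
      (windowBp - 200L)
    peakW <- 201L
    starts <- tssPos[idx] + centerOff - (peakW - 1L) %/% 2L
    peaks <- GenomicRanges::GRanges(.GENE_CHROM,
      IRanges::IRanges(starts, width = peakW))
    list(tss = tss, peaks = peaks, bound = sort(bound))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator with streams derived from the one master seed and
#' (optionally) writes all inputs to a directory in the standard formats
#' (FASTA, BED, bedGraph, JASPAR text, TSV), plus a ground-truth TSV.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir optional output directory; created when missing.
#' @return list with elements \code{config}, \code{locus}, \code{tracks},
#'   \code{expression}, \code{de}, \code{deStatus}, \code{chip},
#'   \code{groundTruth} and, when \code{dir} is given, \code{files}
#'   (named vector of written paths).
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  locus <- simulateLocus(config)
  tracks <- simulateTracks(locus, config)
  expr <- simulateExpression(locus, config)
  gt <- locus$groundTruth
  de <- simulateDeTable(simGenes(gt), config)
  chip <- simulateChipPeaks(simGenes(gt), config)
  out <- list(config = config, locus = locus, tracks = tracks,
              expression = expr, de = de, deStatus = attr(de, "status"),
              chip = chip, groundTruth = gt)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      fasta = writeFastaSeqs(locus$seq, file.path(dir, "locus.fa")),
      tss = writeTssTable(locus$tss, file.path(dir, "tss.tsv")),
      pfms = writeJasparPfm(locus$pfms, file.path(dir, "motifs.jaspar")),
      expression = writeExpressionMatrix(expr, file.path(dir, "expression.tsv")),
      de = writeDeTable(de, file.path(dir, "de.tsv")),
      chipTss = writeTssTable(chip$tss, file.path(dir, "chip_tss.tsv")),
      chipPeaks = writeBed(chip$peaks, file.path(dir, "chip_peaks.bed")))
    for (mark in names(tracks$peaks))
      files[paste0("peaks_", mark)] <-
        writeBed(tracks$peaks[[mark]],
                 file.path(dir, paste0("peaks_", mark, ".bed")))
    for (mark in names(tracks$tracks))
      files[paste0("track_", mark)] <-
        writeBedGraph(tracks$tracks[[mark]],
                      file.path(dir, paste0("track_", mark, ".bedGraph")))
    gtdf <- data.frame(
      key = c("trueTf", "trueConsensus", "targetGene"),
      value = c(trueTf(gt), trueConsensus(gt), targetGene(gt)))
    utils::write.table(gtdf, file.path(dir, "ground_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["groundTruth"] <- file.path(dir, "ground_truth.tsv")
    out$files <- files
  }
  out
}
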