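#' @title Core classes
#'
#' @description S4 containers shared across the package: signal tracks,
#' motif count/weight matrices, the simulation configuration and the
#' planted ground truth.
#'
#' @name regprior-classes
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' SignalTrack: a sorted, non-overlapping genomic signal
#'
#' Wraps a \link[GenomicRanges]{GRanges} whose \code{score} metadata column
#' holds a finite, non-negative coverage/enrichment value per interval
#' (bedGraph semantics), together with the assay mark (e.g. \code{H3K4me1})
#' and a sample / cell-type label.
#'
#' @slot track GRanges with a numeric \code{score} column, sorted by
#'   (seqnames, start), non-overlapping within a chromosome.
#' @slot mark single character, the assay / histone-mark label.
#' @slot sample single character, the sample or cell-type label.
#'
#' @exportClass SignalTrack
setClass("SignalTrack",
  slots = c(track = "GRanges", mark = "character", sample = "character"))

setValidity("SignalTrack", function(object) {
  gr <- object@track
  msgs <- character()
  if (length(object@mark) != 1L) msgs <- c(msgs, "'mark' must be a single string")
  if (length(object@sample) != 1L) msgs <- c(msgs, "'sample' must be a single string")
  if (!"score" %in% names(S4Vectors::mcols(gr)))
    return("track must carry a 'score' metadata column")
  sc <- S4Vectors::mcols(gr)$score
  if (any(!is.finite(sc))) msgs <- c(msgs, "track scores must be finite")
  else if (any(sc < 0)) msgs <- c(msgs, "track scores must be >= 0")
  if (length(gr) > 1L) {
    if (is.unsorted(order(gr)))
      msgs <- c(msgs, "track intervals must be sorted by (chrom, start)")
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) > 0L)
      msgs <- c(msgs, "track intervals overlap; the signal is ill-defined")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignalTrack
#'
#' @param gr GRanges with a numeric \code{score} column.
#' @param mark assay label (e.g. \code{"H3K4me3"}).
#' @param sample sample / cell-type label.
#' @return A \linkS4class{SignalTrack}.
#' @export
SignalTrack <- function(gr, mark = "signal", sample = "sample") {
  gr <- GenomicRanges::sort(gr)
  methods::new("SignalTrack", track = gr, mark = mark, sample = sample)
}

#' PFM: position frequency matrix
#'
#' Raw per-position base counts for a transcription-factor binding motif,
#' rows fixed in A, C, G, T order.
#'
#' @slot id motif identifier.
#' @slot tf transcription-factor name.
#' @slot counts 4 x L non-negative count matrix, rownames A,C,G,T.
#' @exportClass PFM
setClass("PFM", slots = c(id = "character", tf = "character", counts = "matrix"))

setValidity("PFM", function(object) {
  m <- object@counts
  msgs <- character()
  if (!is.numeric(m) || nrow(m) != 4L)
    return("counts must be a numeric 4 x L matrix")
  if (!identical(rownames(m), DNA_BASES4))
    msgs <- c(msgs, "counts rownames must be A, C, G, T")
  if (ncol(m) < 4L) msgs <- c(msgs, "motif length must be >= 4")
  if (any(m < 0) || any(!is.finite(m))) msgs <- c(msgs, "counts must be finite and >= 0")
  else if (any(colSums(m) <= 0)) msgs <- c(msgs, "every column sum must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PFM
#'
#' @param id motif identifier.
#' @param tf TF name (defaults to \code{id}).
#' @param counts 4 x L count matrix; rownames are set to A,C,G,T.
#' @return A \linkS4class{PFM}.
#' @export
PFM <- function(id, counts, tf = id) {
  counts <- as.matrix(counts)
  rownames(counts) <- DNA_BASES4
  methods::new("PFM", id = id, tf = tf, counts = counts)
}

#' PWM: log-odds position weight matrix
#'
#' Log2-odds scoring matrix derived from a \linkS4class{PFM} against a
#' 0-order background, retaining the background and pseudocount it was
#' built with so every downstream p-value is reproducible.
#'
#' @slot id motif identifier.
#' @slot tf transcription-factor name.
#' @slot mat 4 x L numeric log2-odds matrix, rownames A,C,G,T.
#' @slot background length-4 probability vector (A,C,G,T), entries > 0.
#' @slot pseudocount positive real used in the log-odds construction.
#' @exportClass PWM
setClass("PWM",
  slots = c(id = "character", tf = "character", mat = "matrix",
            background = "numeric", pseudocount = "numeric"))

setValidity("PWM", function(object) {
  msgs <- character()
  if (!identical(rownames(object@mat), DNA_BASES4))
    msgs <- c(msgs, "mat rownames must be A, C, G, T")
  if (any(!is.finite(object@mat))) msgs <- c(msgs, "log-odds entries must be finite")
  bg <- object@background
  if (length(bg) != 4L || any(bg <= 0) || abs(sum(bg) - 1) > 1e-8)
    msgs <- c(msgs, "background must be 4 probabilities > 0 summing to 1")
  if (object@pseudocount <= 0) msgs <- c(msgs, "pseudocount must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic study
#'
#' Bundles every knob of the synthetic-data generator. The defaults are
#' the package's reference study conditions: a 50 kb locus carrying 7
#' regulatory elements of 600 bp, one true regulator with 2 planted sites
#' per element among 50 decoy motifs, 40 expression samples with a planted
#' regulator-target Pearson correlation of 0.7 on the log scale, and
#' 10\%/10\% up-/down-regulated genes in the differential-expression table.
#'
#' @slot seed master seed; all generator streams derive from it.
#' @slot locusLength locus size in bp.
#' @slot nCres number of planted cis-regulatory elements.
#' @slot creWidth width of each element in bp.
#' @slot nTfDecoys number of decoy TF motifs (never planted).
#' @slot trueTfSitesPerCre planted true-TF sites per element.
#' @slot motifLength motif length in bp.
#' @slot nSamples expression samples.
#' @slot targetTfCorrelation planted Pearson r between true TF and target
#'   on the log2 expression scale, in (-1, 1).
#' @slot trackNoiseSd standard deviation of the Gaussian track noise.
#' @slot peakHeight height of the Gaussian signal bumps.
#' @slot deUpFraction,deDownFraction fractions of genes planted as
#'   up-/down-regulated; their sum must be <= 1.
#' @slot trueTfDe logical; plant the true TF as differentially expressed.
#' @slot nCellTypes number of pseudo-cell-types for the per-cell-type
#'   tracks (1 = a single aggregate track per mark).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(seed = "integer", locusLength = "integer", nCres = "integer",
            creWidth = "integer", nTfDecoys = "integer",
            trueTfSitesPerCre = "integer", motifLength = "integer",
            nSamples = "integer", targetTfCorrelation = "numeric",
            trackNoiseSd = "numeric", peakHeight = "numeric",
            deUpFraction = "numeric", deDownFraction = "numeric",
            trueTfDe = "logical", nCellTypes = "integer"),
  prototype = list(seed = 1L, locusLength = 50000L, nCres = 7L,
                   creWidth = 600L, nTfDecoys = 50L, trueTfSitesPerCre = 2L,
                   motifLength = 8L, nSamples = 40L,
                   targetTfCorrelation = 0.7, trackNoiseSd = 0.2,
                   peakHeight = 5, deUpFraction = 0.1, deDownFraction = 0.1,
                   trueTfDe = TRUE, nCellTypes = 1L))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nCres * object@creWidth >= object@locusLength)
    msgs <- c(msgs, "nCres * creWidth must be < locusLength")
  if (abs(object@targetTfCorrelation) >= 1)
    msgs <- c(msgs, "targetTfCorrelation must lie strictly inside (-1, 1)")
  if (object@trackNoiseSd < 0) msgs <- c(msgs, "trackNoiseSd must be >= 0")
  if (object@deUpFraction < 0 || object@deDownFraction < 0 ||
      object@deUpFraction + object@deDownFraction > 1)
    msgs <- c(msgs, "deUpFraction + deDownFraction must lie in [0, 1]")
  if (object@motifLength < 4L) msgs <- c(msgs, "motifLength must be >= 4")
  if (object@nSamples < 3L) msgs <- c(msgs, "nSamples must be >= 3")
  if (object@nCellTypes < 1L) msgs <- c(msgs, "nCellTypes must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed master seed (integer).
#' @param locusLength,nCres,creWidth,nTfDecoys,trueTfSitesPerCre,motifLength
#'   locus-architecture parameters; see \linkS4class{SimulationConfig}.
#' @param nSamples,targetTfCorrelation expression parameters.
#' @param trackNoiseSd,peakHeight signal-track parameters.
#' @param deUpFraction,deDownFraction,trueTfDe differential-expression
#'   parameters.
#' @param nCellTypes number of pseudo-cell-types.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(seed = 1, locusLength = 50000, nCres = 7,
                             creWidth = 600, nTfDecoys = 50,
                             trueTfSitesPerCre = 2, motifLength = 8,
                             nSamples = 40, targetTfCorrelation = 0.7,
                             trackNoiseSd = 0.2, peakHeight = 5,
                             deUpFraction = 0.1, deDownFraction = 0.1,
                             trueTfDe = TRUE, nCellTypes = 1) {
  methods::new("SimulationConfig", seed = as.integer(seed),
    locusLength = as.integer(locusLength), nCres = as.integer(nCres),
    creWidth = as.integer(creWidth), nTfDecoys = as.integer(nTfDecoys),
    trueTfSitesPerCre = as.integer(trueTfSitesPerCre),
    motifLength = as.integer(motifLength), nSamples = as.integer(nSamples),
    targetTfCorrelation = as.numeric(targetTfCorrelation),
    trackNoiseSd = as.numeric(trackNoiseSd),
    peakHeight = as.numeric(peakHeight),
    deUpFraction = as.numeric(deUpFraction),
    deDownFraction = as.numeric(deDownFraction),
    trueTfDe = isTRUE(trueTfDe), nCellTypes = as.integer(nCellTypes))
}

#' GroundTruth: the planted signal of a synthetic study
#'
#' Records everything the generator planted, so downstream recovery can be
#' scored without re-deriving anything: the true regulator and its
#' consensus, the planted binding-site intervals, the regulatory elements
#' with their intended class, the TSS, and the gene roster.
#'
#' @slot trueTf identifier of the planted regulator.
#' @slot trueConsensus consensus sequence of the planted motif.
#' @slot plantedSites GRanges of planted site intervals (with strand).
#' @slot cres GRanges of planted elements, \code{creClass} metadata column
#'   in \{promoter, enhancer\}.
#' @slot tss single-position GRanges of the target TSS (gene strand).
#' @slot targetGene identifier of the target gene.
#' @slot genes character vector of all simulated gene identifiers.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(trueTf = "character", trueConsensus = "character",
            plantedSites = "GRanges", cres = "GRanges", tss = "GRanges",
            targetGene = "character", genes = "character"))

setValidity("GroundTruth", function(object) {
  if (length(object@plantedSites) == 0L) return(TRUE)
  hits <- GenomicRanges::countOverlaps(object@plantedSites, object@cres,
                                       type = "within")
  if (any(hits != 1L))
    return("every planted site must lie inside exactly one CRE interval")
  TRUE
})

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack <", object@mark, "/", object@sample, "> with ",
      length(object@track), " intervals\n", sep = "")
})

setMethod("show", "PFM", function(object) {
  cat("PFM ", object@id, " (", object@tf, "), length ",
      ncol(object@counts), "\n", sep = "")
})

setMethod("show", "PWM", function(object) {
  cat("PWM ", object@id, " (", object@tf, "), length ", ncol(object@mat),
      ", max score ", round(sum(apply(object@mat, 2, max)), 2), " bits\n",
      sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed ", object@seed, ", ", object@locusLength,
      " bp locus, ", object@nCres, " CREs (", object@creWidth, " bp), ",
      object@nTfDecoys, " decoy TFs, planted r = ",
      object@targetTfCorrelation, "\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: true TF ", object@trueTf, " (consensus ",
      object@trueConsensus, "), ", length(object@plantedSites),
      " planted sites in ", length(object@cres), " CREs\n", sep = "")
})
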