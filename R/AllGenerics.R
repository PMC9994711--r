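#' Accessors for regprior classes
#'
#' Slot access goes through these accessors rather than \code{@}.
#'
#' @param x a \linkS4class{SignalTrack}, \linkS4class{PFM},
#'   \linkS4class{PWM} or \linkS4class{GroundTruth}.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackRegions", function(x) standardGeneric("trackRegions"))
#' @rdname accessors
#' @export
setMethod("trackRegions", "SignalTrack", function(x) x@track)

#' @rdname accessors
#' @export
setGeneric("trackMark", function(x) standardGeneric("trackMark"))
#' @rdname accessors
#' @export
setMethod("trackMark", "SignalTrack", function(x) x@mark)

#' @rdname accessors
#' @export
setGeneric("trackSample", function(x) standardGeneric("trackSample"))
#' @rdname accessors
#' @export
setMethod("trackSample", "SignalTrack", function(x) x@sample)

#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @rdname accessors
#' @export
setMethod("motifId", "PFM", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("motifId", "PWM", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("tfName", function(x) standardGeneric("tfName"))
#' @rdname accessors
#' @export
setMethod("tfName", "PFM", function(x) x@tf)
#' @rdname accessors
#' @export
setMethod("tfName", "PWM", function(x) x@tf)

#' @rdname accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))
#' @rdname accessors
#' @export
setMethod("motifCounts", "PFM", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))
#' @rdname accessors
#' @export
setMethod("motifMatrix", "PWM", function(x) x@mat)

#' @rdname accessors
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))
#' @rdname accessors
#' @export
setMethod("motifBackground", "PWM", function(x) x@background)

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
#' @rdname accessors
#' @export
setMethod("motifLength", "PFM", function(x) ncol(x@counts))
#' @rdname accessors
#' @export
setMethod("motifLength", "PWM", function(x) ncol(x@mat))

#' @rdname accessors
#' @export
setGeneric("trueTf", function(x) standardGeneric("trueTf"))
#' @rdname accessors
#' @export
setMethod("trueTf", "GroundTruth", function(x) x@trueTf)

#' @rdname accessors
#' @export
setGeneric("trueConsensus", function(x) standardGeneric("trueConsensus"))
#' @rdname accessors
#' @export
setMethod("trueConsensus", "GroundTruth", function(x) x@trueConsensus)

#' @rdname accessors
#' @export
setGeneric("plantedSites", function(x) standardGeneric("plantedSites"))
#' @rdname accessors
#' @export
setMethod("plantedSites", "GroundTruth", function(x) x@plantedSites)

#' @rdname accessors
#' @export
setGeneric("creRegions", function(x) standardGeneric("creRegions"))
#' @rdname accessors
#' @export
setMethod("creRegions", "GroundTruth", function(x) x@cres)

#' @rdname accessors
#' @export
setGeneric("tssSite", function(x) standardGeneric("tssSite"))
#' @rdname accessors
#' @export
setMethod("tssSite", "GroundTruth", function(x) x@tss)

#' @rdname accessors
#' @export
setGeneric("targetGene", function(x) standardGeneric("targetGene"))
#' @rdname accessors
#' @export
setMethod("targetGene", "GroundTruth", function(x) x@targetGene)

#' @rdname accessors
#' @export
setGeneric("simGenes", function(x) standardGeneric("simGenes"))
#' @rdname accessors
#' @export
setMethod("simGenes", "GroundTruth", function(x) x@genes)
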