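# Accessor generics and methods. Slots are never touched directly by user
# code; these are the supported surface.

#' @name accessors
#' @title Accessors for TyProfiler classes
#' @description Read-only accessors for [GenomeModel], [CoverageTrack],
#'   [MetaProfile] and [PromoterBalance] objects.
#' @param x An object of the documented class.
#' @return The slot value (see the class documentation).
NULL

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)
#' @rdname accessors
#' @export
setMethod("chromLengths", "CoverageTrack", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setGeneric("elementCopies", function(x) standardGeneric("elementCopies"))
#' @rdname accessors
#' @export
setMethod("elementCopies", "GenomeModel", function(x) x@elements)

#' @rdname accessors
#' @export
setGeneric("fullCopies", function(x) standardGeneric("fullCopies"))
#' @rdname accessors
#' @export
setMethod("fullCopies", "GenomeModel", function(x)
  x@elements[S4Vectors::mcols(x@elements)$copy_class == "full"])

#' @rdname accessors
#' @export
setGeneric("soloCopies", function(x) standardGeneric("soloCopies"))
#' @rdname accessors
#' @export
setMethod("soloCopies", "GenomeModel", function(x)
  x@elements[S4Vectors::mcols(x@elements)$copy_class == "solo_ltr"])

#' @rdname accessors
#' @export
setGeneric("elementLength", function(x) standardGeneric("elementLength"))
#' @rdname accessors
#' @export
setMethod("elementLength", "GenomeModel", function(x) x@elementLen)
#' @rdname accessors
#' @export
setMethod("elementLength", "MetaProfile", function(x) x@elementLen)

#' @rdname accessors
#' @export
setGeneric("ltrLength", function(x) standardGeneric("ltrLength"))
#' @rdname accessors
#' @export
setMethod("ltrLength", "GenomeModel", function(x) x@ltrLen)

#' @rdname accessors
#' @export
setGeneric("tssOffset", function(x) standardGeneric("tssOffset"))
#' @rdname accessors
#' @export
setMethod("tssOffset", "GenomeModel", function(x) x@tssOffset)
#' @rdname accessors
#' @export
setMethod("tssOffset", "MetaProfile", function(x) x@tssOffset)

#' @rdname accessors
#' @export
setGeneric("internalTssOffset", function(x) standardGeneric("internalTssOffset"))
#' @rdname accessors
#' @export
setMethod("internalTssOffset", "GenomeModel", function(x) x@internalTssOffset)
#' @rdname accessors
#' @export
setMethod("internalTssOffset", "MetaProfile", function(x) x@internalTssOffset)

#' @rdname accessors
#' @export
setGeneric("tesOffset", function(x) standardGeneric("tesOffset"))
#' @rdname accessors
#' @export
setMethod("tesOffset", "GenomeModel", function(x) x@tesOffset)
#' @rdname accessors
#' @export
setMethod("tesOffset", "MetaProfile", function(x) x@tesOffset)

#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setMethod("genomeSequence", "GenomeModel", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("coverageRle", function(x) standardGeneric("coverageRle"))
#' @rdname accessors
#' @export
setMethod("coverageRle", "CoverageTrack", function(x) x@coverage)

#' @rdname accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))
#' @rdname accessors
#' @export
setMethod("sampleName", "CoverageTrack", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("sampleName", "MetaProfile", function(x) x@sample)

#' @rdname accessors
#' @export
setGeneric("totalFragments", function(x) standardGeneric("totalFragments"))
#' @rdname accessors
#' @export
setMethod("totalFragments", "CoverageTrack", function(x) x@totalFragments)

#' @rdname accessors
#' @export
setGeneric("trackScale", function(x) standardGeneric("trackScale"))
#' @rdname accessors
#' @export
setMethod("trackScale", "CoverageTrack", function(x) x@scale)
#' @rdname accessors
#' @export
setMethod("trackScale", "MetaProfile", function(x) x@scale)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "MetaProfile", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("nUnmasked", function(x) standardGeneric("nUnmasked"))
#' @rdname accessors
#' @export
setMethod("nUnmasked", "MetaProfile", function(x) x@nUnmasked)

#' @rdname accessors
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))
#' @rdname accessors
#' @export
setMethod("nElements", "MetaProfile", function(x) x@nElements)

#' @rdname accessors
#' @export
setGeneric("flankBp", function(x) standardGeneric("flankBp"))
#' @rdname accessors
#' @export
setMethod("flankBp", "MetaProfile", function(x) x@flankBp)

#' @rdname accessors
#' @export
setGeneric("marginBp", function(x) standardGeneric("marginBp"))
#' @rdname accessors
#' @export
setMethod("marginBp", "MetaProfile", function(x) x@marginBp)

#' @rdname accessors
#' @export
setGeneric("bodyBins", function(x) standardGeneric("bodyBins"))
#' @rdname accessors
#' @export
setMethod("bodyBins", "MetaProfile", function(x) x@bodyBins)

#' @rdname accessors
#' @export
setGeneric("balanceRatio", function(x) standardGeneric("balanceRatio"))
#' @rdname accessors
#' @export
setMethod("balanceRatio", "PromoterBalance", function(x) x@ratio)

#' @rdname accessors
#' @export
setGeneric("isUndefined", function(x) standardGeneric("isUndefined"))
#' @rdname accessors
#' @export
setMethod("isUndefined", "PromoterBalance", function(x) x@undefined)

#' @rdname accessors
#' @export
setGeneric("windowMeans", function(x) standardGeneric("windowMeans"))
#' @rdname accessors
#' @export
setMethod("windowMeans", "PromoterBalance", function(x)
  c(ty1 = x@ty1WindowMean, ty1i = x@ty1iWindowMean))
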