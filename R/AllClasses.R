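#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand width coverage
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols Rle runValue
NULL

#' GenomeModel: a toy genome carrying a repeated retrotransposon family
#'
#' Container for a simulated genome in which a family of full-length,
#' sequence-identical LTR retrotransposon copies (Ty1-like: a ~334 bp LTR at
#' each end, the Ty1 TSS at +238 inside the 5' LTR and the internal Ty1i TSS
#' at +1000) coexists with short solo-LTR ("delta") copies that share the LTR
#' sequence. Because all full copies are identical and the solo copies are
#' prefixes of the LTR, the mapping ambiguity of any fragment is fully
#' determined by element geometry; see [identityGroups()] and
#' [candidateLoci()].
#'
#' @slot chromLengths Named integer vector of chromosome lengths (bp).
#' @slot elements A [GenomicRanges::GRanges] of element copies with metadata
#'   columns `copy_id` (unique) and `copy_class` (`"full"` or `"solo_ltr"`).
#' @slot elementLen Length (bp) of the canonical full-length element.
#' @slot ltrLen Length (bp) of the LTR.
#' @slot tssOffset,internalTssOffset Element-relative offsets (bp from the
#'   element 5' end) of the Ty1 TSS (+238) and internal Ty1i TSS (+1000).
#' @slot tesOffset Offset (bp) of the TES from the element 3' end (default 0:
#'   TES = element end).
#' @slot sequence A [Biostrings::DNAStringSet] with one record per chromosome.
#'
#' @seealso [buildToyGenome()]
#' @export
setClass("GenomeModel",
  representation(
    chromLengths      = "integer",
    elements          = "GRanges",
    elementLen        = "integer",
    ltrLen            = "integer",
    tssOffset         = "integer",
    internalTssOffset = "integer",
    tesOffset         = "integer",
    sequence          = "DNAStringSet"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  cl <- object@chromLengths
  if (is.null(names(cl)) || anyDuplicated(names(cl)))
    msg <- c(msg, "chromLengths must be uniquely named")
  el <- object@elements
  mc <- S4Vectors::mcols(el)
  if (!all(c("copy_id", "copy_class") %in% colnames(mc)))
    return("elements must carry mcols 'copy_id' and 'copy_class'")
  if (anyDuplicated(mc$copy_id))
    msg <- c(msg, "copy_id values must be unique")
  if (!all(mc$copy_class %in% c("full", "solo_ltr")))
    msg <- c(msg, "copy_class must be 'full' or 'solo_ltr'")
  if (length(el)) {
    chr <- as.character(GenomicRanges::seqnames(el))
    if (!all(chr %in% names(cl)))
      msg <- c(msg, "all elements must lie on declared chromosomes")
    else {
      if (any(GenomicRanges::start(el) < 1L) ||
          any(GenomicRanges::end(el) > cl[chr]))
        msg <- c(msg, "element intervals must lie within their chromosomes")
    }
    if (length(el) > 1L) {
      ov <- GenomicRanges::findOverlaps(el, drop.self = TRUE)
      if (length(ov)) msg <- c(msg, "element copies must not overlap")
    }
    w <- GenomicRanges::width(el)
    full <- mc$copy_class == "full"
    if (any(w[full] != object@elementLen))
      msg <- c(msg, "all full copies must have length elementLen")
    if (any(w[!full] > object@ltrLen))
      msg <- c(msg, "solo-LTR copies must be no longer than ltrLen")
  }
  if (object@elementLen < 2L * object@ltrLen)
    msg <- c(msg, "elementLen must be >= 2 * ltrLen")
  if (object@tssOffset >= object@ltrLen)
    msg <- c(msg, "tssOffset must lie inside the 5' LTR (tssOffset < ltrLen)")
  if (!(object@tssOffset < object@internalTssOffset &&
        object@internalTssOffset < object@elementLen))
    msg <- c(msg, "need tssOffset < internalTssOffset < elementLen")
  if (object@tesOffset < 0L || object@tesOffset >= object@elementLen)
    msg <- c(msg, "tesOffset must be in [0, elementLen)")
  if (length(object@sequence)) {
    if (!identical(names(object@sequence), names(cl)) ||
        !identical(Biostrings::width(object@sequence), unname(cl)))
      msg <- c(msg, "sequence records must match chromLengths")
  }
  if (length(msg)) msg else TRUE
})

#' CoverageTrack: per-base-pair occupancy over a genome
#'
#' Dense per-bp occupancy stored as a run-length encoded list (one
#' [S4Vectors::Rle] per chromosome). A raw track produced by
#' [computeCoverage()] sums, over all bases, to the total length of the
#' assigned fragments; [normalizeToControl()] produces a `"ratio"` track.
#'
#' @slot coverage An [IRanges::RleList]-like object, one run-length vector per
#'   chromosome.
#' @slot chromLengths Named integer vector of chromosome lengths.
#' @slot sample Sample label.
#' @slot totalFragments Number of fragments contributing to the track.
#' @slot scale `"raw"`, `"per-million"` or `"ratio"`.
#' @export
setClass("CoverageTrack",
  representation(
    coverage       = "RleList",
    chromLengths   = "integer",
    sample         = "character",
    totalFragments = "numeric",
    scale          = "character"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (!identical(names(object@coverage), names(object@chromLengths)))
    msg <- c(msg, "coverage names must match chromLengths names")
  else if (!identical(unname(lengths(object@coverage)),
                      as.vector(object@chromLengths, "numeric")) &&
           !identical(as.integer(lengths(object@coverage)),
                      unname(object@chromLengths)))
    msg <- c(msg, "per-chromosome vector lengths must equal chromosome lengths")
  if (!object@scale %in% c("raw", "per-million", "ratio"))
    msg <- c(msg, "scale must be 'raw', 'per-million' or 'ratio'")
  if (length(object@totalFragments) != 1L ||
      (!is.na(object@totalFragments) && object@totalFragments < 0))
    msg <- c(msg, "totalFragments must be a single nonnegative number (or NA)")
  if (length(msg)) msg else TRUE
})

#' MetaProfile: element-anchored averaged occupancy
#'
#' Occupancy averaged over all full-length copies of the element family on a
#' fixed coordinate schema: per-bp upstream flank (`flankBp`), per-bp
#' TSS..TSS+`marginBp` strip, `bodyBins` length-scaled bins over
#' TSS+`marginBp`..TES-`marginBp`, per-bp TES-`marginBp`..TES strip, and
#' per-bp downstream flank. Positions falling off a chromosome end are
#' masked (NA) rather than zero-filled, and `nUnmasked` records how many
#' element copies contributed at each position.
#'
#' @slot values Numeric vector of length
#'   `2*flankBp + 2*marginBp + bodyBins`; NA where all copies were masked.
#' @slot nUnmasked Integer vector, same length: copies contributing per
#'   position.
#' @slot flankBp,marginBp,bodyBins Layout parameters (bp, bp, count).
#' @slot nElements Number of element copies averaged.
#' @slot elementLen,tssOffset,internalTssOffset,tesOffset Anchor metadata
#'   copied from the genome model.
#' @slot sample Sample label of the source track.
#' @slot scale Scale of the source track.
#' @export
setClass("MetaProfile",
  representation(
    values            = "numeric",
    nUnmasked         = "integer",
    flankBp           = "integer",
    marginBp          = "integer",
    bodyBins          = "integer",
    nElements         = "integer",
    elementLen        = "integer",
    tssOffset         = "integer",
    internalTssOffset = "integer",
    tesOffset         = "integer",
    sample            = "character",
    scale             = "character"
  )
)

setValidity("MetaProfile", function(object) {
  msg <- character()
  expect <- 2L * object@flankBp + 2L * object@marginBp + object@bodyBins
  if (length(object@values) != expect)
    msg <- c(msg, sprintf("values must have length %d (layout)", expect))
  if (length(object@nUnmasked) != length(object@values))
    msg <- c(msg, "nUnmasked must parallel values")
  if (object@nElements < 1L)
    msg <- c(msg, "nElements must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PromoterBalance: dual-promoter occupancy balance
#'
#' Mean occupancy in windows centred on the Ty1 TSS (+238) and the internal
#' Ty1i TSS (+1000) of a [MetaProfile], and their ratio (Ty1i / Ty1). When
#' the Ty1 window mean is zero the ratio is undefined and flagged rather
#' than returned as NaN.
#'
#' @slot ty1WindowMean,ty1iWindowMean Window means.
#' @slot ratio Ty1i / Ty1 window-mean ratio (NA when undefined).
#' @slot undefined TRUE when the Ty1 window mean is zero.
#' @slot halfwidth Window halfwidth (bp).
#' @export
setClass("PromoterBalance",
  representation(
    ty1WindowMean  = "numeric",
    ty1iWindowMean = "numeric",
    ratio          = "numeric",
    undefined      = "logical",
    halfwidth      = "integer"
  )
)

# show methods ----------------------------------------------------------------

setMethod("show", "GenomeModel", function(object) {
  el <- object@elements
  cls <- S4Vectors::mcols(el)$copy_class
  cat("GenomeModel with", length(object@chromLengths), "chromosome(s),",
      sum(cls == "full"), "full element copies and",
      sum(cls == "solo_ltr"), "solo-LTR copies\n")
  cat("  genome size:", sum(object@chromLengths), "bp;",
      "element:", object@elementLen, "bp; LTR:", object@ltrLen, "bp\n")
  cat("  TSS +", object@tssOffset, ", internal TSS +",
      object@internalTssOffset, ", TES offset ", object@tesOffset,
      "\n", sep = "")
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack '", object@sample, "' (", object@scale, ") over ",
      length(object@chromLengths), " chromosome(s), ",
      object@totalFragments, " fragments\n", sep = "")
})

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile over", object@nElements, "element(s):",
      object@flankBp, "bp flanks +", object@marginBp,
      "bp per-bp margins +", object@bodyBins, "body bins\n")
  cat("  sample '", object@sample, "' (", object@scale, "); ",
      sum(is.na(object@values)), " masked position(s)\n", sep = "")
})

setMethod("show", "PromoterBalance", function(object) {
  cat("PromoterBalance (halfwidth ", object@halfwidth, " bp): Ty1 = ",
      format(object@ty1WindowMean, digits = 4), ", Ty1i = ",
      format(object@ty1iWindowMean, digits = 4), ", ratio = ",
      if (object@undefined) "undefined (zero Ty1 window)"
      else format(object@ratio, digits = 4), "\n", sep = "")
})
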