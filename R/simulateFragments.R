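#' EnrichmentSpec: mixture model of ChIP enrichment over an element family
#'
#' Describes where ChIP fragment centers fall: a uniform background over the
#' whole genome with weight `backgroundWeight`, plus per-element enrichment
#' components, each a symmetric triangular window of halfwidth `spread`
#' around an element-relative `center` offset (e.g. the Ty1 TSS at +238 and
#' the Ty1i TSS at +1000). Components apply to every full-length copy.
#'
#' @slot components data.frame with columns `center` (bp from element
#'   start), `weight` (nonnegative) and `spread` (bp).
#' @slot backgroundWeight Nonnegative background weight.
#' @export
setClass("EnrichmentSpec",
  representation(components = "data.frame", backgroundWeight = "numeric"))

setValidity("EnrichmentSpec", function(object) {
  msg <- character()
  cmp <- object@components
  if (nrow(cmp) && !all(c("center", "weight", "spread") %in% colnames(cmp)))
    return("components needs columns center, weight, spread")
  if (nrow(cmp) && (any(cmp$weight < 0) || any(cmp$spread < 0)))
    msg <- c(msg, "component weights and spreads must be nonnegative")
  if (object@backgroundWeight < 0)
    msg <- c(msg, "backgroundWeight must be nonnegative")
  if (object@backgroundWeight + sum(cmp$weight) <= 0)
    msg <- c(msg, "total weight must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an EnrichmentSpec
#'
#' @param components Either a data.frame with columns `center`, `weight`,
#'   `spread`, or a list of length-3 numeric vectors
#'   `c(center, weight, spread)`. Empty (default) means background only.
#' @param backgroundWeight Nonnegative background weight (default 1).
#' @return An [EnrichmentSpec-class] object.
#' @examples
#' enrichmentSpec(list(c(238, 1, 100), c(1000, 1, 100)), backgroundWeight = 2)
#' @export
enrichmentSpec <- function(components = list(), backgroundWeight = 1) {
  if (is.data.frame(components)) {
    cmp <- components
  } else if (length(components)) {
    cmp <- as.data.frame(do.call(rbind, lapply(components, function(x) {
      if (length(x) != 3L) stop("each component is c(center, weight, spread)")
      as.numeric(x)
    })))
    colnames(cmp) <- c("center", "weight", "spread")
  } else {
    cmp <- data.frame(center = numeric(), weight = numeric(),
                      spread = numeric())
  }
  methods::new("EnrichmentSpec", components = cmp,
               backgroundWeight = as.numeric(backgroundWeight))
}

setMethod("show", "EnrichmentSpec", function(object) {
  cat("EnrichmentSpec:", nrow(object@components),
      "component(s), background weight", object@backgroundWeight, "\n")
  if (nrow(object@components)) print(object@components)
})

#' Simulate ChIP fragments with multimapping ambiguity
#'
#' Draws `nFragments` sequenced-fragment alignments from the mixture defined
#' by `spec`: with probability proportional to `backgroundWeight` a fragment
#' center is uniform over the genome; otherwise a component and a full
#' element copy are picked and the center falls at the component's
#' element-relative offset plus symmetric triangular noise of halfwidth
#' `spread`. Fragment lengths are uniform integers on `fragLenRange`
#' (ChIP fragments run from 200 to about 500 bp). Each fragment's
#' candidate-locus list is computed exactly from the genome's identity
#' structure via [candidateLoci()]; the true locus is always on the list.
#'
#' @param genome A [GenomeModel].
#' @param spec An [EnrichmentSpec-class]; zero-weight components are dropped
#'   before any random draw, so a spec with all component weights zero is
#'   equivalent to [simulateControl()].
#' @param nFragments Number of fragments to emit.
#' @param fragLenRange Integer length range, default `c(200, 500)`.
#' @param sample Sample label recorded on each fragment.
#' @param seed Integer seed; output is reproducible given the seed.
#' @return A data.frame (one row per fragment) with columns `fragment_id`,
#'   `sample`, `length`, `candidates` (semicolon-separated
#'   `chrom:start:strand` triples, 0-based starts), `n_candidates`, and the
#'   true locus in `true_chrom` / `true_start`.
#' @export
simulateFragments <- function(genome, spec, nFragments,
                              fragLenRange = c(200L, 500L),
                              sample = "IP", seed = 1L) {
  stopifnot(methods::is(genome, "GenomeModel"),
            methods::is(spec, "EnrichmentSpec"))
  n <- .checkCount(nFragments, "nFragments", min = 0L)
  fragLenRange <- as.integer(fragLenRange)
  if (length(fragLenRange) != 2L || fragLenRange[1] > fragLenRange[2] ||
      fragLenRange[1] < 1L)
    stop("fragLenRange must be an increasing positive range", call. = FALSE)
  cl <- chromLengths(genome)
  if (sum(cl) == 0L || length(cl) == 0L)
    stop("empty genome", call. = FALSE)
  if (any(fragLenRange[2] > cl))
    stop("fragments longer than the shortest chromosome", call. = FALSE)

  cmp <- spec@components
  cmp <- cmp[cmp$weight > 0, , drop = FALSE]      # canonicalize: drop null
  if (nrow(cmp) && (any(cmp$center < 0) ||
                    any(cmp$center >= elementLength(genome))))
    stop("component centers must lie within the element length", call. = FALSE)

  full <- fullCopies(genome)
  nFull <- length(full)
  fS0 <- GenomicRanges::start(full) - 1L
  fE0 <- GenomicRanges::end(full)
  fStr <- as.character(GenomicRanges::strand(full))
  fChrom <- as.character(GenomicRanges::seqnames(full))

  withSeed(seed, {
    compIdx <- if (nrow(cmp))
      sample.int(nrow(cmp) + 1L, n, replace = TRUE,
                 prob = c(spec@backgroundWeight, cmp$weight)) - 1L
    else rep.int(0L, n)
    lens <- .runifInt(n, fragLenRange[1], fragLenRange[2])

    chrom <- character(n)
    gstart <- integer(n)

    bg <- which(compIdx == 0L)
    if (length(bg)) {
      ci <- sample.int(length(cl), length(bg), replace = TRUE,
                       prob = cl / sum(cl))
      chrom[bg] <- names(cl)[ci]
      gstart[bg] <- as.integer(floor(stats::runif(length(bg)) *
                                     (cl[ci] - lens[bg] + 1L)))
    }
    for (j in seq_len(nrow(cmp))) {
      idx <- which(compIdx == j)
      if (!length(idx)) next
      copy <- .runifInt(length(idx), 1L, nFull)
      noise <- round((stats::runif(length(idx)) + stats::runif(length(idx))
                      - 1) * cmp$spread[j])
      center <- cmp$center[j] + noise
      relA <- as.integer(center - lens[idx] %/% 2L)
      gs <- ifelse(fStr[copy] == "+",
                   fS0[copy] + relA,
                   fE0[copy] - relA - lens[idx])
      gs <- pmax(0L, pmin(as.integer(gs), cl[fChrom[copy]] - lens[idx]))
      chrom[idx] <- fChrom[copy]
      gstart[idx] <- gs
    }

    cand <- candidateLoci(genome, chrom, gstart, lens)
    data.frame(
      fragment_id = sprintf("%s_%07d", sample, seq_len(n)),
      sample = rep.int(sample, n),
      length = lens,
      candidates = cand$candidates,
      n_candidates = cand$n,
      true_chrom = chrom,
      true_start = gstart,
      stringsAsFactors = FALSE)
  })
}

#' Simulate an untagged-control fragment set
#'
#' Background-only fragment simulation: identical to [simulateFragments()]
#' with an enrichment spec that has no (or only zero-weight) components.
#' Models the untagged control to which ChIP signal is normalized.
#'
#' @inheritParams simulateFragments
#' @return As [simulateFragments()].
#' @export
simulateControl <- function(genome, nFragments,
                            fragLenRange = c(200L, 500L),
                            sample = "control", seed = 1L) {
  simulateFragments(genome, enrichmentSpec(backgroundWeight = 1),
                    nFragments, fragLenRange = fragLenRange,
                    sample = sample, seed = seed)
}
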