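# Element-anchored occupancy profiles: per-bp flanks + per-bp TSS/TES margins
# + 100 length-scaled body bins, averaged over all full copies of the family.

# even integer partition of `total` bp into `bins` bins; the remainder is
# spread over the first bins (deterministic, order-independent)
.binSizes <- function(total, bins) {
  sizes <- rep.int(total %/% bins, bins)
  rem <- total %% bins
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

.layoutLength <- function(flankBp, marginBp, bodyBins)
  2L * flankBp + 2L * marginBp + bodyBins

#' Per-element occupancy profile
#'
#' Extracts one element copy's occupancy on the anchored layout: per-bp from
#' 2 kb upstream of the TSS through TSS+1 kb, 100 bins of (approximately)
#' equal width over the element body from TSS+1 kb to TES-1 kb, then per-bp
#' from TES-1 kb to 2 kb downstream of the TES. The TSS sits `tssOffset`
#' (+238) bp from the element start; the TES is the element end minus
#' `tesOffset`. Minus-strand copies are reversed so all profiles read 5'->3'
#' of the element. Positions beyond chromosome ends are masked (NA), never
#' zero-filled.
#'
#' @param track A [CoverageTrack].
#' @param element A `copy_id` string, or a length-1
#'   [GenomicRanges::GRanges] row from [elementCopies()].
#' @param genome The [GenomeModel] the track refers to.
#' @param flankBp,marginBp,bodyBins Layout parameters (defaults 2000, 1000,
#'   100).
#' @return A numeric vector of length `2*flankBp + 2*marginBp + bodyBins`
#'   (NA where masked), carrying a `"layout"` attribute with the anchor
#'   metadata consumed by [averageProfiles()].
#' @export
elementProfile <- function(track, element, genome,
                           flankBp = 2000L, marginBp = 1000L,
                           bodyBins = 100L) {
  stopifnot(methods::is(track, "CoverageTrack"),
            methods::is(genome, "GenomeModel"))
  flankBp <- .checkCount(flankBp, "flankBp", 0L)
  marginBp <- .checkCount(marginBp, "marginBp", 0L)
  bodyBins <- .checkCount(bodyBins, "bodyBins", 1L)
  if (is.character(element)) {
    el <- elementCopies(genome)
    element <- el[S4Vectors::mcols(el)$copy_id == element]
  }
  if (length(element) != 1L)
    stop("element must identify exactly one copy", call. = FALSE)

  chrom <- as.character(GenomicRanges::seqnames(element))
  s0 <- GenomicRanges::start(element) - 1L
  e0 <- GenomicRanges::end(element)
  st <- as.character(GenomicRanges::strand(element))
  elLen <- e0 - s0
  tss <- tssOffset(genome)
  tes <- elLen - tesOffset(genome)
  bodyLen <- (tes - marginBp) - (tss + marginBp)
  if (bodyLen < bodyBins)
    stop(sprintf(paste0("element body (%d bp) shorter than %d bins; ",
                        "reduce marginBp or bodyBins"), bodyLen, bodyBins),
         call. = FALSE)

  relLo <- tss - flankBp
  relHi <- tes + flankBp
  winLen <- relHi - relLo
  cl <- chromLengths(genome)[chrom]
  rle <- coverageRle(track)[[chrom]]

  v <- rep(NA_real_, winLen)
  if (st == "-") {
    gLo <- e0 - relHi            # 0-based inclusive
    gHi <- e0 - relLo            # 0-based exclusive
  } else {
    gLo <- s0 + relLo
    gHi <- s0 + relHi
  }
  cLo <- max(gLo, 0L)
  cHi <- min(gHi, cl)
  if (cHi > cLo) {
    vals <- as.numeric(S4Vectors::window(rle, cLo + 1L, cHi))
    v[(cLo - gLo + 1L):(cHi - gLo)] <- vals
  }
  if (st == "-") v <- rev(v)

  perbp5 <- v[seq_len(flankBp + marginBp)]
  bodyV <- v[(flankBp + marginBp + 1L):(flankBp + marginBp + bodyLen)]
  sizes <- .binSizes(bodyLen, bodyBins)
  binIdx <- rep.int(seq_len(bodyBins), sizes)
  binSum <- tapply(bodyV, binIdx, function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  perbp3 <- v[(flankBp + marginBp + bodyLen + 1L):winLen]

  out <- c(perbp5, as.numeric(binSum), perbp3)
  attr(out, "layout") <- list(
    flankBp = flankBp, marginBp = marginBp, bodyBins = bodyBins,
    elementLen = elLen, tssOffset = tss,
    internalTssOffset = internalTssOffset(genome),
    tesOffset = tesOffset(genome),
    sample = sampleName(track), scale = trackScale(track))
  out
}

#' Average per-element profiles into a MetaProfile
#'
#' Unweighted positionwise mean over element copies, computed per position
#' over the unmasked copies only (a copy masked at a position simply does
#' not contribute there). All profiles must share one layout.
#'
#' @param profiles A list of [elementProfile()] vectors.
#' @return A [MetaProfile].
#' @export
averageProfiles <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  lay <- attr(profiles[[1L]], "layout")
  if (is.null(lay)) stop("profiles must come from elementProfile()",
                         call. = FALSE)
  len <- length(profiles[[1L]])
  same <- vapply(profiles, function(p) {
    l <- attr(p, "layout")
    length(p) == len && !is.null(l) &&
      identical(l[c("flankBp", "marginBp", "bodyBins")],
                lay[c("flankBp", "marginBp", "bodyBins")])
  }, TRUE)
  if (!all(same)) stop("profile layouts differ", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, as.numeric))
  nOk <- colSums(!is.na(m))
  vals <- colSums(m, na.rm = TRUE) / nOk
  vals[nOk == 0L] <- NA_real_
  methods::new("MetaProfile",
               values = vals, nUnmasked = as.integer(nOk),
               flankBp = as.integer(lay$flankBp),
               marginBp = as.integer(lay$marginBp),
               bodyBins = as.integer(lay$bodyBins),
               nElements = length(profiles),
               elementLen = as.integer(lay$elementLen),
               tssOffset = as.integer(lay$tssOffset),
               internalTssOffset = as.integer(lay$internalTssOffset),
               tesOffset = as.integer(lay$tesOffset),
               sample = lay$sample, scale = lay$scale)
}

#' Metaelement occupancy profile over all full copies
#'
#' Convenience wrapper: extracts [elementProfile()] for every full-length
#' copy in the genome and averages them with [averageProfiles()] (all copies
#' weighted equally), the averaged-over-31-elements profile of the family.
#'
#' @inheritParams elementProfile
#' @return A [MetaProfile].
#' @export
metaProfile <- function(track, genome, flankBp = 2000L, marginBp = 1000L,
                        bodyBins = 100L) {
  full <- fullCopies(genome)
  if (!length(full)) stop("genome has no full-length copies", call. = FALSE)
  profiles <- lapply(seq_along(full), function(i)
    elementProfile(track, full[i], genome, flankBp = flankBp,
                   marginBp = marginBp, bodyBins = bodyBins))
  averageProfiles(profiles)
}

#' Map element coordinates to MetaProfile positions
#'
#' Element coordinates are bp from the element start (so the Ty1 TSS is
#' +238). Coordinates falling in the per-bp segments (upstream flank, the
#' TSS..TSS+margin strip, the TES-margin..TES strip, downstream flank) map
#' to a layout index; coordinates inside the binned body (or outside the
#' plotted window) return NA.
#'
#' @param profile A [MetaProfile].
#' @param coord Integer vector of element coordinates.
#' @return Integer vector of layout indices (NA where not per-bp).
#' @export
elementCoordToIndex <- function(profile, coord) {
  f <- flankBp(profile); m <- marginBp(profile); b <- bodyBins(profile)
  tss <- tssOffset(profile)
  tes <- elementLength(profile) - tesOffset(profile)
  idx <- rep(NA_integer_, length(coord))
  i5 <- coord >= (tss - f) & coord < (tss + m)
  idx[i5] <- coord[i5] - (tss - f) + 1L
  i3 <- coord >= (tes - m) & coord < (tes + f)
  idx[i3] <- f + m + b + (coord[i3] - (tes - m)) + 1L
  idx
}

#' Mean profile value over an element-coordinate window
#'
#' Mean of the (unmasked) per-bp profile values with element coordinates in
#' `[from, to]`; coordinates that fall in the binned body are skipped.
#'
#' @param profile A [MetaProfile].
#' @param from,to Window bounds in element coordinates (inclusive).
#' @return A single numeric value (NaN if the window has no usable
#'   positions).
#' @export
profileWindowMean <- function(profile, from, to) {
  idx <- elementCoordToIndex(profile, seq.int(from, to))
  idx <- idx[!is.na(idx)]
  mean(profileValues(profile)[idx], na.rm = TRUE)
}

#' Dual-promoter occupancy balance
#'
#' Mean occupancy in windows of `halfwidth` bp around the Ty1 TSS (+238) and
#' the internal Ty1i TSS (+1000), and their ratio Ty1i/Ty1 - the statistic
#' that quantifies a shift of Mediator (or any factor) from the element
#' promoter to the internal promoter. A zero Ty1-window mean yields an
#' explicit undefined-ratio flag, never a silent NaN.
#'
#' @param profile A [MetaProfile].
#' @param halfwidth Window halfwidth in bp (default 100).
#' @return A [PromoterBalance-class] object.
#' @export
promoterBalance <- function(profile, halfwidth = 100L) {
  stopifnot(methods::is(profile, "MetaProfile"))
  halfwidth <- .checkCount(halfwidth, "halfwidth", 0L)
  winMean <- function(center) {
    coords <- seq.int(center - halfwidth, center + halfwidth)
    idx <- elementCoordToIndex(profile, coords)
    if (anyNA(idx))
      stop("promoter window extends outside the per-bp layout segments",
           call. = FALSE)
    mean(profileValues(profile)[idx], na.rm = TRUE)
  }
  ty1 <- winMean(tssOffset(profile))
  ty1i <- winMean(internalTssOffset(profile))
  undef <- !is.finite(ty1) || ty1 == 0
  methods::new("PromoterBalance",
               ty1WindowMean = ty1, ty1iWindowMean = ty1i,
               ratio = if (undef) NA_real_ else ty1i / ty1,
               undefined = undef, halfwidth = halfwidth)
}

#' Locate occupancy peaks in the promoter-proximal profile
#'
#' Finds the `n` highest, mutually separated local maxima of the smoothed
#' profile over the contiguous per-bp stretch from `-flankBp` to `+marginBp`
#' around the TSS (where both the Ty1 and Ty1i TSSs live), then refines each
#' peak position as the background-subtracted intensity centroid of a
#' `halfwin` window around the coarse maximum. On ratio tracks the per-bp
#' noise is correlated on the scale of a fragment length, so a plain argmax
#' wanders over the peak plateau; the centroid of the (symmetric) peak is a
#' far more precise location estimator. Background is the median smoothed
#' value away from all coarse peaks.
#'
#' @param profile A [MetaProfile].
#' @param n Number of peaks to report (default 2).
#' @param smoothBp Running-mean window (odd bp, default 51).
#' @param minSep Minimum separation between reported peaks (bp, default
#'   300).
#' @param halfwin Centroid refinement half-window (bp, default 250).
#' @param refine Apply centroid refinement (default TRUE); `FALSE` reports
#'   the coarse smoothed maxima.
#' @return data.frame with columns `coord` (element coordinate, refined)
#'   and `height` (smoothed profile value at the coarse maximum), ordered
#'   by decreasing height.
#' @export
profilePeaks <- function(profile, n = 2L, smoothBp = 51L, minSep = 300L,
                         halfwin = 250L, refine = TRUE) {
  stopifnot(methods::is(profile, "MetaProfile"))
  f <- flankBp(profile); m <- marginBp(profile)
  v <- profileValues(profile)[seq_len(f + m)]
  coords <- seq.int(tssOffset(profile) - f, length.out = f + m)
  if (smoothBp > 1L) {
    k <- rep(1 / smoothBp, smoothBp)
    v <- as.numeric(stats::filter(v, k, sides = 2))
  }
  ok <- which(is.finite(v))
  ord <- ok[order(v[ok], decreasing = TRUE)]
  picked <- integer()
  for (i in ord) {
    if (length(picked) >= n) break
    if (all(abs(i - picked) >= minSep)) picked <- c(picked, i)
  }
  pos <- coords[picked]
  if (refine && length(picked)) {
    bgmask <- rep(TRUE, length(v))
    for (p in picked)
      bgmask[max(1L, p - 2L * halfwin):min(length(v), p + 2L * halfwin)] <-
        FALSE
    bg <- stats::median(v[bgmask & is.finite(v)])
    if (is.finite(bg)) {
      pos <- vapply(picked, function(p) {
        w <- max(1L, p - halfwin):min(length(v), p + halfwin)
        wt <- pmax(v[w] - bg, 0)
        wt[!is.finite(wt)] <- 0
        if (sum(wt) > 0) sum(wt * coords[w]) / sum(wt) else coords[p]
      }, 0)
    }
  }
  data.frame(coord = pos, height = v[picked])
}

#' Tabulate a MetaProfile for export or plotting
#'
#' @param profile A [MetaProfile].
#' @return data.frame with columns `segment` (`upstream_flank`,
#'   `tss_margin`, `body_bin`, `tes_margin`, `downstream_flank`),
#'   `element_coordinate` (bp from element start; bin midpoints for body
#'   bins), `value` and `n_unmasked`.
#' @export
profileTable <- function(profile) {
  stopifnot(methods::is(profile, "MetaProfile"))
  f <- flankBp(profile); m <- marginBp(profile); b <- bodyBins(profile)
  tss <- tssOffset(profile)
  tes <- elementLength(profile) - tesOffset(profile)
  bodyLen <- (tes - m) - (tss + m)
  sizes <- .binSizes(bodyLen, b)
  binEnd <- cumsum(sizes)
  binMid <- tss + m + floor((c(0L, binEnd[-b]) + binEnd) / 2)
  coords <- c(seq.int(tss - f, tss - 1L),
              seq.int(tss, tss + m - 1L),
              binMid,
              seq.int(tes - m, tes - 1L),
              seq.int(tes, tes + f - 1L))
  segment <- c(rep("upstream_flank", f), rep("tss_margin", m),
               rep("body_bin", b), rep("tes_margin", m),
               rep("downstream_flank", f))
  data.frame(segment = segment, element_coordinate = coords,
             value = profileValues(profile),
             n_unmasked = nUnmasked(profile))
}
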