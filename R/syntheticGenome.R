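#' Build a toy genome carrying a repeated LTR retrotransposon family
#'
#' Constructs a [GenomeModel] emulating the Ty1 genomic context: `nFull`
#' full-length element copies that are sequence-identical to one another
#' (including identical 5' and 3' LTRs), plus `nSolo` solo-LTR ("delta")
#' copies whose sequence is a prefix of the LTR. The reference yeast genome
#' carries 31 full-length Ty1 copies and 266 delta elements, 263 of them
#' shorter than 350 bp; the defaults mirror those counts with an LTR of
#' 334 bp, the Ty1 TSS at +238 (inside the 5' LTR) and the internal Ty1i TSS
#' at +1000.
#'
#' Background sequence is drawn uniformly at random and rejected (and
#' redrawn) if it contains an exact copy of any element k-mer of length
#' `minSharedKmer` (the minimum ChIP fragment length), so that the element
#' geometry is the complete truth about mapping ambiguity: a fragment is
#' multi-mapping if and only if its interval lies wholly inside an element
#' copy, as enumerated by [candidateLoci()]. Because the LTR recurs inside
#' every full copy, a window crossing a copy boundary could by chance
#' extend an LTR context by a few matching background bases; the single
#' background base flanking each copy is therefore forced to differ from
#' the element's continuation in every LTR context ("guard base"), making
#' the geometric candidate lists exact.
#'
#' Copies are placed uniformly over the chromosomes with a minimum gap of
#' `minGap` bp between copies (and from chromosome ends); placement failure
#' after bounded retries is an error naming the constraint.
#'
#' @param nFull Number of full-length copies (default 31).
#' @param nSolo Number of solo-LTR copies (default 266).
#' @param elementLen Full element length in bp (default 5918).
#' @param ltrLen LTR length in bp (default 334).
#' @param chromTemplate Named integer vector of chromosome lengths.
#' @param soloLenRange Range (bp) from which solo-LTR lengths are drawn
#'   uniformly; default `c(150, ltrLen)` echoes that most delta elements are
#'   shorter than a full LTR.
#' @param tssOffset,internalTssOffset,tesOffset Element-relative anchors
#'   (defaults +238, +1000, 0).
#' @param minGap Minimum gap (bp) between placed copies; default 500, one
#'   maximum fragment length.
#' @param seed Integer seed; the whole construction (placement, strands,
#'   sequence) is reproducible bit-for-bit given the seed.
#' @param checkKmers Run the background k-mer rejection check (default TRUE).
#' @param minSharedKmer k-mer length for the rejection check (default 200).
#' @param maxTries Placement retries per copy before failing (default 1000).
#'
#' @return A [GenomeModel].
#' @examples
#' gm <- buildToyGenome(nFull = 2, nSolo = 3, elementLen = 2000,
#'                      ltrLen = 334, chromTemplate = c(chrI = 60000),
#'                      seed = 1)
#' gm
#' @export
buildToyGenome <- function(nFull = 31L, nSolo = 266L,
                           elementLen = 5918L, ltrLen = 334L,
                           chromTemplate = c(chrI = 250000L, chrII = 250000L,
                                             chrIII = 250000L),
                           soloLenRange = c(150L, ltrLen),
                           tssOffset = 238L, internalTssOffset = 1000L,
                           tesOffset = 0L,
                           minGap = 500L, seed = 1L,
                           checkKmers = TRUE, minSharedKmer = 200L,
                           maxTries = 1000L) {
  nFull <- .checkCount(nFull, "nFull", min = 1L)
  nSolo <- .checkCount(nSolo, "nSolo", min = 0L)
  elementLen <- .checkCount(elementLen, "elementLen", min = 1L)
  ltrLen <- .checkCount(ltrLen, "ltrLen", min = 1L)
  if (elementLen <= 2L * ltrLen)
    stop("elementLen must exceed 2 * ltrLen", call. = FALSE)
  if (is.null(names(chromTemplate)) || any(chromTemplate < 1))
    stop("chromTemplate must be a named vector of positive lengths",
         call. = FALSE)
  if (any(grepl(":", names(chromTemplate), fixed = TRUE)))
    stop("chromosome names must not contain ':'", call. = FALSE)
  chromLengths <- stats::setNames(as.integer(chromTemplate),
                                  names(chromTemplate))
  soloLenRange <- as.integer(soloLenRange)
  if (length(soloLenRange) != 2L || soloLenRange[1] > soloLenRange[2] ||
      soloLenRange[2] > ltrLen || soloLenRange[1] < 1L)
    stop("soloLenRange must be an increasing range within [1, ltrLen]",
         call. = FALSE)
  minGap <- .checkCount(minGap, "minGap", min = 0L)

  withSeed(seed, {
    soloLens <- if (nSolo > 0L)
      .runifInt(nSolo, soloLenRange[1], soloLenRange[2]) else integer()

    ## placement: longest first, uniform over chromosomes, min gap enforced
    lens <- c(rep.int(elementLen, nFull), soloLens)
    classes <- c(rep.int("full", nFull), rep.int("solo_ltr", nSolo))
    ids <- c(sprintf("full_%02d", seq_len(nFull)),
             if (nSolo > 0L) sprintf("solo_%03d", seq_len(nSolo)))
    ord <- order(lens, decreasing = TRUE)

    placedChrom <- character(length(lens))
    placedStart <- integer(length(lens))  # 0-based
    occupied <- lapply(chromLengths, function(x) IRanges::IRanges())
    chromNames <- names(chromLengths)
    chromProb <- chromLengths / sum(chromLengths)

    for (i in ord) {
      len <- lens[i]
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        ci <- sample.int(length(chromNames), 1L, prob = chromProb)
        maxStart <- chromLengths[ci] - len - minGap
        if (maxStart < minGap) next
        s0 <- .runifInt(1L, minGap, maxStart)
        cand <- IRanges::IRanges(start = s0 + 1L - minGap,
                                 end = s0 + len + minGap)
        if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0L) {
          occupied[[ci]] <- c(occupied[[ci]],
                              IRanges::IRanges(s0 + 1L, s0 + len))
          placedChrom[i] <- chromNames[ci]
          placedStart[i] <- s0
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(paste0("failed to place element copy '%s' (%d bp) with ",
                            "a %d bp minimum gap after %d tries; enlarge ",
                            "chromTemplate or reduce copy number"),
                     ids[i], len, minGap, maxTries), call. = FALSE)
    }
    strands <- sample(c("+", "-"), length(lens), replace = TRUE)

    ## sequences: one canonical element whose two LTRs are identical; solos
    ## are prefixes of the LTR; background random, rejection-checked
    alphabet <- c("A", "C", "G", "T")
    elemChars <- sample(alphabet, elementLen, replace = TRUE)
    elemChars[(elementLen - ltrLen + 1L):elementLen] <- elemChars[1:ltrLen]
    elemSeq <- Biostrings::DNAString(paste(elemChars, collapse = ""))

    drawBackground <- function() {
      Biostrings::DNAStringSet(vapply(chromLengths, function(n)
        paste(sample(alphabet, n, replace = TRUE), collapse = ""), ""))
    }
    background <- drawBackground()
    if (isTRUE(checkKmers)) {
      k <- min(.checkCount(minSharedKmer, "minSharedKmer", 1L), elementLen)
      starts <- seq_len(elementLen - k + 1L)
      kmers <- Biostrings::DNAStringSet(elemSeq,
                                        start = starts, width = k)
      pd <- Biostrings::PDict(unique(kmers))
      for (redraw in 1:5) {
        hits <- sum(Biostrings::vcountPDict(pd, background))
        if (hits == 0L) break
        if (redraw == 5L)
          stop("background sequence kept colliding with element k-mers",
               call. = FALSE)
        background <- drawBackground()
      }
    }

    ## paste copies into the background (reverse-complement on '-')
    seqs <- as.list(background)
    for (i in seq_along(lens)) {
      copySeq <- if (classes[i] == "full") elemSeq
                 else Biostrings::subseq(elemSeq, 1L, lens[i])
      if (strands[i] == "-")
        copySeq <- Biostrings::reverseComplement(copySeq)
      seqs[[placedChrom[i]]] <- Biostrings::replaceAt(
        seqs[[placedChrom[i]]],
        IRanges::IRanges(placedStart[i] + 1L, placedStart[i] + lens[i]),
        copySeq)
    }

    ## boundary guard bases: the LTR repeat structure means a window
    ## crossing a copy boundary by j bp could still exactly match an
    ## element k-mer if the first flanking base happens to equal the
    ## element's continuation at the other LTR context (probability 1/4
    ## per boundary). Force each flanking base to differ from every such
    ## continuation so candidate lists derived from geometry stay exact.
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pick <- function(forbidden)
      setdiff(alphabet, forbidden)[1L]
    inAnyCopy <- function(ch, pos) {
      hit <- placedChrom == ch & pos >= placedStart + 1L &
        pos <= placedStart + lens
      any(hit)
    }
    for (i in seq_along(lens)) {
      w <- lens[i]
      # element-orientation continuations (1-based element coordinates)
      beforeForb <- elemChars[elementLen - ltrLen]        # precedes 3' LTR
      afterForb <- if (classes[i] == "full") elemChars[ltrLen + 1L]
        else c(elemChars[w + 1L],
               if (w < ltrLen) elemChars[elementLen - ltrLen + w + 1L])
      if (strands[i] == "+") {
        guards <- list(list(pos = placedStart[i], forb = beforeForb),
                       list(pos = placedStart[i] + w + 1L, forb = afterForb))
      } else {
        guards <- list(list(pos = placedStart[i] + w + 1L,
                            forb = unname(comp[beforeForb])),
                       list(pos = placedStart[i],
                            forb = unname(comp[afterForb])))
      }
      ch <- placedChrom[i]
      for (g in guards) {
        if (g$pos < 1L || g$pos > chromLengths[[ch]] ||
            inAnyCopy(ch, g$pos)) next
        cur <- as.character(Biostrings::subseq(seqs[[ch]], g$pos, g$pos))
        if (cur %in% g$forb)
          seqs[[ch]] <- Biostrings::replaceAt(
            seqs[[ch]], IRanges::IRanges(g$pos, g$pos),
            Biostrings::DNAString(pick(g$forb)))
      }
    }
    genomeSeq <- Biostrings::DNAStringSet(seqs)
    names(genomeSeq) <- names(chromLengths)

    el <- GenomicRanges::GRanges(
      seqnames = placedChrom,
      ranges = IRanges::IRanges(start = placedStart + 1L,
                                width = lens),
      strand = strands,
      copy_id = ids,
      copy_class = classes,
      seqlengths = chromLengths)
    el <- GenomicRanges::sort(el, ignore.strand = TRUE)

    methods::new("GenomeModel",
                 chromLengths = chromLengths,
                 elements = el,
                 elementLen = elementLen,
                 ltrLen = ltrLen,
                 tssOffset = as.integer(tssOffset),
                 internalTssOffset = as.integer(internalTssOffset),
                 tesOffset = as.integer(tesOffset),
                 sequence = genomeSeq)
  })
}

#' Sequence-identity structure of a genome model
#'
#' Returns the identity groups implied by the construction of a
#' [buildToyGenome()] genome: a `"element"` group spanning the entire length
#' of every full copy (all full copies are identical end-to-end) and a
#' `"ltr"` group covering the 5' LTR and 3' LTR of every full copy and the
#' whole of every solo-LTR copy (solos are prefixes of the LTR). The groups
#' nest rather than partition: the LTR intervals of full copies belong to
#' both, which is what makes LTR-resident fragments ambiguous among 5' LTRs,
#' 3' LTRs and solo copies while junction-straddling fragments remain shared
#' only among full copies.
#'
#' @param genome A [GenomeModel].
#' @return A data.frame with columns `group`, `copy_id`, `rel_start`,
#'   `rel_end` (element-relative, 0-based half-open) and `group_start` (the
#'   offset of `rel_start` in group coordinates).
#' @export
identityGroups <- function(genome) {
  stopifnot(methods::is(genome, "GenomeModel"))
  el <- elementCopies(genome)
  mc <- S4Vectors::mcols(el)
  L <- elementLength(genome)
  ltr <- ltrLength(genome)
  fullIds <- mc$copy_id[mc$copy_class == "full"]
  soloIds <- mc$copy_id[mc$copy_class == "solo_ltr"]
  soloW <- GenomicRanges::width(el)[mc$copy_class == "solo_ltr"]
  rbind(
    data.frame(group = "element", copy_id = fullIds,
               rel_start = 0L, rel_end = L, group_start = 0L),
    data.frame(group = "ltr", copy_id = fullIds,
               rel_start = 0L, rel_end = ltr, group_start = 0L),
    data.frame(group = "ltr", copy_id = fullIds,
               rel_start = L - ltr, rel_end = L, group_start = 0L),
    if (length(soloIds))
      data.frame(group = "ltr", copy_id = soloIds,
                 rel_start = 0L, rel_end = soloW, group_start = 0L)
  )
}

#' Enumerate the equally-good mapping loci of fragment intervals
#'
#' For each fragment interval, lists every genomic locus whose sequence is
#' identical to the fragment's true locus, as implied by the identity
#' structure of the genome model: an interval wholly inside a full copy maps
#' to the corresponding position of every full copy; if it additionally lies
#' wholly within an LTR it also maps to the other LTR of every full copy and
#' to every solo-LTR copy long enough to contain it; an interval crossing an
#' element/flank junction (or lying in background) is unique. This replaces
#' sequence search: the genome is built so that these lists are exact.
#'
#' @param genome A [GenomeModel].
#' @param chrom Character vector of chromosome names (recycled rules not
#'   applied; all three vectors must have equal length).
#' @param start Integer vector of 0-based fragment starts.
#' @param length Integer vector of fragment lengths (bp).
#' @return A list with `candidates` (character vector; per fragment the
#'   semicolon-separated, coordinate-sorted `chrom:start:strand` triples) and
#'   `n` (integer vector of candidate counts).
#' @export
candidateLoci <- function(genome, chrom, start, length) {
  stopifnot(methods::is(genome, "GenomeModel"))
  n <- base::length(chrom)
  stopifnot(base::length(start) == n, base::length(length) == n)
  start <- as.integer(start)
  fragLen <- as.integer(length)
  if (n == 0L)
    return(list(candidates = character(), n = integer()))
  if (any(fragLen <= 0L)) stop("fragment lengths must be positive")

  el <- elementCopies(genome)
  mc <- S4Vectors::mcols(el)
  L <- elementLength(genome)
  ltr <- ltrLength(genome)

  frags <- GenomicRanges::GRanges(chrom,
             IRanges::IRanges(start = start + 1L, width = fragLen),
             seqlengths = chromLengths(genome))
  ov <- GenomicRanges::findOverlaps(frags, el, type = "within",
                                    ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)

  ## default: unique at the true locus
  out <- paste0(chrom, ":", start, ":+")
  nCand <- rep.int(1L, n)
  if (base::length(qh) == 0L)
    return(list(candidates = out, n = nCand))

  elStrand <- as.character(GenomicRanges::strand(el))
  elS0 <- GenomicRanges::start(el) - 1L        # 0-based start
  elE0 <- GenomicRanges::end(el)               # 0-based exclusive end
  isFullCopy <- mc$copy_class == "full"

  hitStrand <- elStrand[sh]
  relA <- ifelse(hitStrand == "+",
                 start[qh] - elS0[sh],
                 elE0[sh] - (start[qh] + fragLen[qh]))
  hLen <- fragLen[qh]
  hFull <- isFullCopy[sh]

  in5 <- relA + hLen <= ltr                     # holds for every solo hit
  in3 <- hFull & relA >= (L - ltr)
  isLTR <- in5 | in3
  ltrA <- ifelse(in5, relA, relA - (L - ltr))

  ## full-copy lookup tables
  fi <- which(isFullCopy)
  nFull <- base::length(fi)
  fChrom <- as.character(GenomicRanges::seqnames(el))[fi]
  fS0 <- elS0[fi]; fE0 <- elE0[fi]; fStr <- elStrand[fi]

  ## solos, sorted by decreasing length so "long enough" solos are a prefix
  si <- which(!isFullCopy)
  sW <- GenomicRanges::width(el)[si]
  sOrd <- order(sW, decreasing = TRUE)
  si <- si[sOrd]; sW <- sW[sOrd]
  sChrom <- as.character(GenomicRanges::seqnames(el))[si]
  sS0 <- elS0[si]; sE0 <- elE0[si]; sStr <- elStrand[si]
  ## ascending copy for findInterval
  sWAsc <- rev(sW)

  expandFull <- function(hidx, pos) {
    # one candidate per full copy at canonical position `pos`
    m <- base::length(hidx)
    if (m == 0L || nFull == 0L)
      return(NULL)
    fragIdx <- rep(qh[hidx], each = nFull)
    p <- rep(pos, each = nFull)
    flen <- rep(fragLen[qh[hidx]], each = nFull)
    copy <- rep.int(seq_len(nFull), m)
    gs <- ifelse(fStr[copy] == "+",
                 fS0[copy] + p,
                 fE0[copy] - p - flen)
    data.frame(fragIdx = fragIdx, chrom = fChrom[copy], gstart = gs,
               strand = fStr[copy], stringsAsFactors = FALSE)
  }

  blocks <- list()
  intIdx <- which(!isLTR)                      # internal / junction, full only
  blocks[[1L]] <- expandFull(intIdx, relA[intIdx])
  ltrIdx <- which(isLTR)
  blocks[[2L]] <- expandFull(ltrIdx, ltrA[ltrIdx])
  blocks[[3L]] <- expandFull(ltrIdx, (L - ltr) + ltrA[ltrIdx])

  if (base::length(ltrIdx) && base::length(si)) {
    need <- ltrA[ltrIdx] + fragLen[qh[ltrIdx]]  # solo must be >= this long
    k <- base::length(si) - findInterval(need - 0.5, sWAsc)
    keep <- k > 0L
    if (any(keep)) {
      hidx <- ltrIdx[keep]; kk <- k[keep]
      fragIdx <- rep(qh[hidx], times = kk)
      p <- rep(ltrA[hidx], times = kk)
      flen <- rep(fragLen[qh[hidx]], times = kk)
      soloSel <- sequence(kk)
      gs <- ifelse(sStr[soloSel] == "+",
                   sS0[soloSel] + p,
                   sE0[soloSel] - p - flen)
      blocks[[4L]] <- data.frame(fragIdx = fragIdx, chrom = sChrom[soloSel],
                                 gstart = gs, strand = sStr[soloSel],
                                 stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, blocks[!vapply(blocks, is.null, TRUE)])
  tab <- tab[order(tab$fragIdx, tab$chrom, tab$gstart, tab$strand), ,
             drop = FALSE]
  strs <- paste0(tab$chrom, ":", tab$gstart, ":", tab$strand)
  grp <- factor(tab$fragIdx)
  collapsed <- vapply(split(strs, grp), paste0, "", collapse = ";")
  idx <- as.integer(levels(grp))
  out[idx] <- unname(collapsed)
  nCand[idx] <- as.integer(table(grp))
  list(candidates = out, n = nCand)
}
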