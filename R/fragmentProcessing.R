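#' Remove duplicate fragments
#'
#' Removes PCR/optical duplicates identified from paired-end information:
#' two fragments are duplicates iff they have identical length and identical
#' candidate-locus sets (order-insensitive). The first occurrence is kept
#' and output order is stable. Deduplication runs before multimapper
#' assignment: duplicates share identical mapping ambiguity, and
#' deduplicating on a post-assignment locus would stochastically retain
#' duplicates assigned to different copies. The alternative order is
#' available via `on = "assigned"` for fragments that already carry an
#' assignment.
#'
#' @param fragments Fragment data.frame as produced by
#'   [simulateFragments()] / [readFragments()].
#' @param on `"candidates"` (default) keys duplicates on
#'   (length, candidate set); `"assigned"` keys on the assigned locus.
#' @return The deduplicated fragment data.frame. Idempotent.
#' @export
dedupFragments <- function(fragments, on = c("candidates", "assigned")) {
  on <- match.arg(on)
  if (nrow(fragments) == 0L) return(fragments)
  if (on == "candidates") {
    sets <- strsplit(fragments$candidates, ";", fixed = TRUE)
    canon <- vapply(sets, function(x) paste(sort(x), collapse = ";"), "")
    key <- paste(fragments$length, canon, sep = "|")
  } else {
    need <- c("chrom", "start")
    if (!all(need %in% colnames(fragments)))
      stop("on = 'assigned' needs assigned fragments (chrom/start columns)",
           call. = FALSE)
    key <- paste(fragments$length, fragments$chrom, fragments$start,
                 sep = "|")
  }
  fragments[!duplicated(key), , drop = FALSE]
}

#' Randomly assign multi-mapping fragments
#'
#' Every fragment is assigned to one of its candidate loci, chosen uniformly
#' at random (candidates are equally good by construction); fragments with a
#' single candidate are assigned to it deterministically. The input is not
#' mutated; the seed makes assignment reproducible.
#'
#' @param fragments Deduplicated fragment data.frame.
#' @param seed Integer seed.
#' @return The fragment data.frame with columns `assigned` (1-based index
#'   into the candidate list) and the assigned locus in `chrom`, `start`
#'   (0-based), `strand`.
#' @export
assignMultimappers <- function(fragments, seed = 1L) {
  n <- nrow(fragments)
  if (n == 0L) {
    fragments$assigned <- integer()
    fragments$chrom <- character()
    fragments$start <- integer()
    fragments$strand <- character()
    return(fragments)
  }
  sets <- strsplit(fragments$candidates, ";", fixed = TRUE)
  nCand <- lengths(sets)
  bad <- which(nCand == 0L | !nzchar(fragments$candidates))
  if (length(bad))
    stop("fragment(s) with empty candidate list: ",
         paste(utils::head(fragments$fragment_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  idx <- withSeed(seed, {
    u <- stats::runif(n)
    pmin(1L + as.integer(floor(u * nCand)), nCand)
  })
  chosen <- vapply(seq_len(n), function(i) sets[[i]][idx[i]], "")
  parts <- matrix(unlist(strsplit(chosen, ":", fixed = TRUE),
                         use.names = FALSE), ncol = 3L, byrow = TRUE)
  out <- fragments
  out$assigned <- idx
  out$chrom <- parts[, 1L]
  out$start <- as.integer(parts[, 2L])
  out$strand <- parts[, 3L]
  out
}

#' Fragment-pileup coverage
#'
#' Each assigned fragment adds 1 to every base pair of its interval
#' (fragment-level pileup, not point counting: ChIP fragments of 200-500 bp
#' spread occupancy signal to either side of the bound position). The raw
#' track sums to the total assigned fragment length.
#'
#' @param fragments Assigned fragment data.frame (see
#'   [assignMultimappers()]).
#' @param genome A [GenomeModel] supplying chromosome lengths.
#' @param sample Sample label; defaults to the fragments' label.
#' @return A raw [CoverageTrack].
#' @export
computeCoverage <- function(fragments, genome, sample = NULL) {
  stopifnot(methods::is(genome, "GenomeModel"))
  if (!all(c("chrom", "start") %in% colnames(fragments)))
    stop("fragments must be assigned first (assignMultimappers)",
         call. = FALSE)
  cl <- chromLengths(genome)
  if (nrow(fragments)) {
    unknown <- !(fragments$chrom %in% names(cl))
    oob <- unknown | fragments$start < 0L |
      (fragments$start + fragments$length) >
        ifelse(unknown, 0L, cl[fragments$chrom])
    if (any(oob)) {
      i <- which(oob)[1L]
      stop(sprintf("fragment '%s' out of bounds on chromosome '%s'",
                   fragments$fragment_id[i], fragments$chrom[i]),
           call. = FALSE)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(fragments$chrom, levels = names(cl)),
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              width = fragments$length),
    seqlengths = cl)
  cov <- GenomicRanges::coverage(gr)
  if (is.null(sample))
    sample <- if (nrow(fragments)) fragments$sample[1L] else "unknown"
  methods::new("CoverageTrack", coverage = cov, chromLengths = cl,
               sample = sample, totalFragments = as.numeric(nrow(fragments)),
               scale = "raw")
}

#' Normalize a ChIP track to an untagged control
#'
#' Both tracks are scaled to coverage per million fragments, then the
#' per-bp ratio `(ip + pseudocount) / (control + pseudocount)` is taken,
#' mirroring normalization of ChIP-seq signal to an untagged control. A
#' subtraction mode (`mode = "subtract"`, depth-scaled IP minus control) is
#' available as an alternative.
#'
#' @param ip,control [CoverageTrack]s over the same chromosomes, each with
#'   `totalFragments > 0`.
#' @param pseudocount Additive pseudocount in per-million units (default
#'   0.5); must be positive if the control has any zero-coverage base.
#' @param mode `"ratio"` (default) or `"subtract"`.
#' @return A [CoverageTrack] with scale `"ratio"`.
#' @export
normalizeToControl <- function(ip, control, pseudocount = 0.5,
                               mode = c("ratio", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(methods::is(ip, "CoverageTrack"),
            methods::is(control, "CoverageTrack"))
  if (!identical(chromLengths(ip), chromLengths(control)))
    stop("ip and control tracks are over different chromosomes",
         call. = FALSE)
  if (totalFragments(ip) <= 0 || totalFragments(control) <= 0)
    stop("both tracks need totalFragments > 0", call. = FALSE)
  pseudocount <- .checkNumber(pseudocount, "pseudocount", 0)
  sfIp <- 1e6 / totalFragments(ip)
  sfCt <- 1e6 / totalFragments(control)
  covIp <- coverageRle(ip)
  covCt <- coverageRle(control)
  if (mode == "ratio" && pseudocount == 0) {
    anyZero <- any(vapply(names(covCt), function(ch)
      any(S4Vectors::runValue(covCt[[ch]]) == 0), TRUE))
    if (anyZero)
      stop(paste("control has zero coverage at some base pairs;",
                 "use a positive pseudocount"), call. = FALSE)
  }
  out <- lapply(names(covIp), function(ch) {
    a <- covIp[[ch]] * sfIp
    b <- covCt[[ch]] * sfCt
    if (mode == "ratio") (a + pseudocount) / (b + pseudocount) else a - b
  })
  names(out) <- names(covIp)
  methods::new("CoverageTrack",
               coverage = methods::as(out, "SimpleRleList"),
               chromLengths = chromLengths(ip),
               sample = paste0(sampleName(ip), "/", sampleName(control)),
               totalFragments = totalFragments(ip),
               scale = "ratio")
}
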