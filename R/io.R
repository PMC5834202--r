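# Readers/writers for the package's plain-text interchange formats: FASTA +
# BED6 for genomes, a fragment TSV dialect, bedGraph coverage, metaprofile
# TSV and colony-count TSV.

#' @importFrom rtracklayer export import BEDFile
#' @importFrom Biostrings writeXStringSet readDNAStringSet
#' @importFrom utils write.table read.delim
NULL

#' Write a genome model to FASTA and BED6
#'
#' One FASTA record per chromosome; element annotations as BED6 (0-based
#' half-open) with `name` = copy_id, `score` encoding the copy class (1 =
#' full, 2 = solo_ltr) and the strand column used.
#'
#' @param genome A [GenomeModel].
#' @param fastaPath,bedPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writeGenome <- function(genome, fastaPath, bedPath) {
  stopifnot(methods::is(genome, "GenomeModel"))
  Biostrings::writeXStringSet(genomeSequence(genome), filepath = fastaPath)
  el <- elementCopies(genome)
  mc <- S4Vectors::mcols(el)
  bed <- el
  S4Vectors::mcols(bed) <- S4Vectors::DataFrame(
    name = mc$copy_id,
    score = ifelse(mc$copy_class == "full", 1L, 2L))
  rtracklayer::export(bed, bedPath, format = "BED")
  invisible(c(fasta = fastaPath, bed = bedPath))
}

#' Read element annotations from BED6
#'
#' @param path BED6 file written by [writeGenome()] (score 1 = full copy,
#'   2 = solo-LTR copy).
#' @return A [GenomicRanges::GRanges] with mcols `copy_id` and `copy_class`.
#' @export
readElementsBED <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    copy_id = mc$name,
    copy_class = ifelse(mc$score == 1L, "full", "solo_ltr"))
  gr
}

#' Write / read fragment alignments as TSV
#'
#' Columns `fragment_id`, `sample`, `length`, `candidates`
#' (semicolon-separated `chrom:start:strand` triples, 0-based starts), plus
#' any extra columns present (e.g. `n_candidates`, the true locus, or the
#' assignment).
#'
#' @param fragments Fragment data.frame.
#' @param path TSV path.
#' @param includeTruth Keep the `true_chrom`/`true_start` columns (default
#'   TRUE).
#' @return `writeFragments()`: the path, invisibly. `readFragments()`: the
#'   fragment data.frame.
#' @export
writeFragments <- function(fragments, path, includeTruth = TRUE) {
  if (!includeTruth)
    fragments <- fragments[, setdiff(colnames(fragments),
                                     c("true_chrom", "true_start")),
                           drop = FALSE]
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragments
#' @export
readFragments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA)
  need <- c("fragment_id", "sample", "length", "candidates")
  if (!all(need %in% colnames(df)))
    stop("fragment TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"n_candidates" %in% colnames(df))
    df$n_candidates <- lengths(strsplit(df$candidates, ";", fixed = TRUE))
  df
}

#' Export assigned fragments as BED6
#'
#' One line per assigned fragment interval; name = fragment_id, score =
#' number of candidate loci, strand from the assigned candidate.
#'
#' @param fragments Assigned fragment data.frame.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
writeAssignedBED <- function(fragments, path) {
  if (!all(c("chrom", "start", "strand") %in% colnames(fragments)))
    stop("fragments must be assigned first", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(start = fragments$start + 1L,
                     width = fragments$length),
    strand = fragments$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = fragments$fragment_id, score = fragments$n_candidates)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read a coverage track as bedGraph
#'
#' Runs of equal value are merged into 0-based half-open intervals.
#' `readCoverageBedGraph()` reconstitutes the dense track against a genome
#' model (bases not covered by any interval get value 0).
#'
#' @param track A [CoverageTrack].
#' @param path bedGraph path.
#' @param genome A [GenomeModel] (for reading).
#' @param sample,scale Metadata to attach on read.
#' @return The path (write) or a [CoverageTrack] (read).
#' @export
writeCoverageBedGraph <- function(track, path) {
  stopifnot(methods::is(track, "CoverageTrack"))
  gr <- methods::as(coverageRle(track), "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeCoverageBedGraph
#' @param totalFragments Fragment count metadata to attach on read.
#' @export
readCoverageBedGraph <- function(path, genome, sample = "imported",
                                 scale = "raw", totalFragments = NA_real_) {
  stopifnot(methods::is(genome, "GenomeModel"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  cl <- chromLengths(genome)
  GenomeInfoDb::seqlevels(gr) <- names(cl)
  GenomeInfoDb::seqlengths(gr) <- cl
  cov <- GenomicRanges::coverage(gr, weight = "score")
  methods::new("CoverageTrack", coverage = cov, chromLengths = cl,
               sample = sample, totalFragments = totalFragments,
               scale = scale)
}

#' Write a MetaProfile as TSV
#'
#' The [profileTable()] layout: `segment`, `element_coordinate`, `value`,
#' `n_unmasked`.
#'
#' @param profile A [MetaProfile].
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
writeMetaProfile <- function(profile, path) {
  utils::write.table(profileTable(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read colony-count tables
#'
#' The dialect of [simulateMobilityCounts()]: columns `strain`, `bio_rep`,
#' `tech_rep`, `plate_type`, `volume_plated_ul`, `dilution_factor`,
#' `culture_volume_ul`, `colonies`.
#'
#' @param counts Colony-count data.frame.
#' @param path TSV path.
#' @return The path (write) or the data.frame (read).
#' @export
writeColonyCounts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeColonyCounts
#' @export
readColonyCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "bio_rep", "tech_rep", "plate_type",
            "volume_plated_ul", "dilution_factor", "colonies")
  if (!all(need %in% colnames(df)))
    stop("colony-count TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"culture_volume_ul" %in% colnames(df))
    df$culture_volume_ul <- 1000
  df
}
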