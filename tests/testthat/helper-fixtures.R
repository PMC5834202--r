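# Shared fixtures, built in code. Genomes are cached per session because
# construction (sequence draw + k-mer rejection check) dominates test time.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# 2 full copies + 3 full-length solo LTRs on one small chromosome; short
# element so candidate arithmetic is easy to reason about
tinyGenome <- function() cachedFixture("tiny", function()
  buildToyGenome(nFull = 2, nSolo = 3, elementLen = 1200, ltrLen = 334,
                 chromTemplate = c(chrT = 30000L),
                 soloLenRange = c(334L, 334L), seed = 7L))

# 2 identical full copies, no solos: the simplest multimapping genome
twinGenome <- function() cachedFixture("twin", function()
  buildToyGenome(nFull = 2, nSolo = 0, elementLen = 5000, ltrLen = 334,
                 chromTemplate = c(chrT = 40000L), seed = 3L))

# full-size elements for metaprofile layout tests (default 2kb/1kb/100 bins)
profileGenome <- function() cachedFixture("profile", function()
  buildToyGenome(nFull = 4, nSolo = 6, elementLen = 5918, ltrLen = 334,
                 chromTemplate = c(chrP = 90000L), seed = 21L))

# element-relative coordinates -> genomic 0-based start for a fragment of
# `len` bp beginning at rel offset `relA` of copy `copyId`
relToGenomic <- function(genome, copyId, relA, len) {
  el <- elementCopies(genome)
  el <- el[S4Vectors::mcols(el)$copy_id == copyId]
  if (as.character(GenomicRanges::strand(el)) == "+")
    GenomicRanges::start(el) - 1L + relA
  else
    GenomicRanges::end(el) - relA - len
}

# candidate string -> data.frame of triples
parseCandidates <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p)
    data.frame(chrom = p[1], start = as.integer(p[2]), strand = p[3])))
}

# minimal assigned-fragment table for direct coverage construction
madeFragments <- function(chrom, start, length, sample = "manual") {
  n <- base::length(start)
  data.frame(fragment_id = sprintf("m%03d", seq_len(n)),
             sample = sample, length = as.integer(length),
             candidates = paste0(chrom, ":", start, ":+"),
             n_candidates = 1L, chrom = chrom,
             start = as.integer(start), strand = "+",
             stringsAsFactors = FALSE)
}
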