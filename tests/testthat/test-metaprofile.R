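# profileGenome(): 4 full copies of 5918 bp on one 90 kb chromosome, so the
# default layout (2 kb flanks, 1 kb margins, 100 body bins) applies.

constantTrack <- function(gm, value = 1) {
  # one fragment spanning the whole chromosome per unit of value
  cl <- chromLengths(gm)
  frs <- do.call(rbind, lapply(names(cl), function(ch)
    madeFragments(ch, rep(0L, value), rep(cl[[ch]], value))))
  computeCoverage(frs, gm)
}

test_that("a constant track yields a constant profile on both strands", {
  gm <- profileGenome()
  tr <- constantTrack(gm)
  full <- fullCopies(gm)
  strands <- as.character(GenomicRanges::strand(full))
  for (i in seq_along(full)) {
    p <- elementProfile(tr, full[i], gm)
    expect_identical(length(p), 2L * 2000L + 2L * 1000L + 100L)
    expect_true(all(p[!is.na(p)] == 1))
  }
  mp <- metaProfile(tr, gm)
  expect_identical(nElements(mp), 4L)
  expect_true(all(profileValues(mp)[nUnmasked(mp) > 0] == 1))
})

test_that("a narrow bump at +238 peaks at the +238 profile position", {
  gm <- profileGenome()
  full <- fullCopies(gm)
  for (i in seq_along(full)) {   # covers both strands
    gs <- relToGenomic(gm, S4Vectors::mcols(full)$copy_id[i], 238L, 1L)
    tr <- computeCoverage(
      madeFragments(as.character(GenomicRanges::seqnames(full[i])), gs, 1L),
      gm)
    p <- elementProfile(tr, full[i], gm)
    # index arithmetic oracle: +238 is the first bp of the TSS..TSS+1kb
    # strip, i.e. layout position flank + 1
    expect_identical(which(p == max(p, na.rm = TRUE)), 2000L + 1L)
  }
})

test_that("minus-strand profiles equal plus-strand profiles of the same signal", {
  gm <- profileGenome()
  full <- fullCopies(gm)
  strands <- as.character(GenomicRanges::strand(full))
  expect_setequal(unique(strands), c("+", "-"))  # fixture has both strands
  ip <- which(strands == "+")[1]; im <- which(strands == "-")[1]
  mkBump <- function(i) {
    gs <- relToGenomic(gm, S4Vectors::mcols(full)$copy_id[i], 500L, 50L)
    tr <- computeCoverage(
      madeFragments(as.character(GenomicRanges::seqnames(full[i])), gs, 50L),
      gm)
    elementProfile(tr, full[i], gm)
  }
  expect_identical(mkBump(ip), mkBump(im))
})

test_that("profile averaging is positionwise, mask-aware, and idempotent on copies", {
  gm <- profileGenome()
  tr <- constantTrack(gm)
  full <- fullCopies(gm)
  p1 <- elementProfile(tr, full[1], gm)
  p2 <- p1 * 2
  attr(p2, "layout") <- attr(p1, "layout")
  mp <- averageProfiles(list(p1, p2))
  expect_true(all(abs(profileValues(mp) - 1.5) < 1e-12, na.rm = TRUE))
  # single profile returned unchanged
  one <- averageProfiles(list(p1))
  expect_equal(profileValues(one), as.numeric(p1))
  expect_identical(nElements(one), 1L)
  # masked position: mean over the remaining profiles
  p3 <- p1; p3[10] <- NA
  mp2 <- averageProfiles(list(p1, p3))
  expect_identical(profileValues(mp2)[10], p1[10])
  expect_identical(nUnmasked(mp2)[10], 1L)
  # k copies of the same profile average to that profile
  mpk <- averageProfiles(list(p1, p1, p1))
  expect_equal(profileValues(mpk), as.numeric(p1))
  bad <- p1[-1]
  attr(bad, "layout") <- attr(p1, "layout")
  expect_error(averageProfiles(list(p1, bad)), "layout")
})

test_that("body shorter than the bin count is rejected with advice", {
  gm <- tinyGenome()   # 1200 bp elements: no room for 1 kb margins
  tr <- computeCoverage(madeFragments("chrT", 0L, 100L), gm)
  expect_error(metaProfile(tr, gm), "reduce marginBp or bodyBins")
  # small margins make it work
  mp <- metaProfile(tr, gm, flankBp = 200L, marginBp = 100L, bodyBins = 50L)
  expect_identical(length(profileValues(mp)), 2L * 200L + 2L * 100L + 50L)
})

test_that("promoter balance matches window means and flags zero denominators", {
  gm <- profileGenome()
  mpConst <- metaProfile(constantTrack(gm), gm)
  pb <- promoterBalance(mpConst)
  expect_false(isUndefined(pb))
  expect_equal(balanceRatio(pb), 1.0)
  # scale the Ty1i window 3x by hand
  vals <- profileValues(mpConst)
  idx <- elementCoordToIndex(mpConst, seq(1000L - 100L, 1000L + 100L))
  vals[idx] <- 3
  mp3 <- methods::new("MetaProfile", values = vals,
                      nUnmasked = nUnmasked(mpConst),
                      flankBp = 2000L, marginBp = 1000L, bodyBins = 100L,
                      nElements = nElements(mpConst), elementLen = 5918L,
                      tssOffset = 238L, internalTssOffset = 1000L,
                      tesOffset = 0L, sample = "x", scale = "ratio")
  expect_equal(balanceRatio(promoterBalance(mp3)), 3.0)
  # zero Ty1 window -> undefined flag, not NaN
  vals0 <- profileValues(mpConst)
  vals0[elementCoordToIndex(mpConst, seq(138L, 338L))] <- 0
  mp0 <- methods::new("MetaProfile", values = vals0,
                      nUnmasked = nUnmasked(mpConst),
                      flankBp = 2000L, marginBp = 1000L, bodyBins = 100L,
                      nElements = nElements(mpConst), elementLen = 5918L,
                      tssOffset = 238L, internalTssOffset = 1000L,
                      tesOffset = 0L, sample = "x", scale = "ratio")
  pb0 <- promoterBalance(mp0)
  expect_true(isUndefined(pb0))
  expect_true(is.na(balanceRatio(pb0)))
})

test_that("coordinate mapping covers exactly the per-bp segments", {
  gm <- profileGenome()
  mp <- metaProfile(constantTrack(gm), gm)
  # first upstream-flank bp, TSS, last bp before body, TES strip, body NA
  expect_identical(elementCoordToIndex(mp, 238L - 2000L), 1L)
  expect_identical(elementCoordToIndex(mp, 238L), 2001L)
  expect_identical(elementCoordToIndex(mp, 1237L), 3000L)
  expect_true(is.na(elementCoordToIndex(mp, 1238L)))       # body
  expect_identical(elementCoordToIndex(mp, 4918L), 3101L)  # TES strip start
  expect_identical(elementCoordToIndex(mp, 5918L + 1999L), 6100L)
  expect_true(is.na(elementCoordToIndex(mp, 5918L + 2000L)))
})

test_that("the control metaprofile is flat (body CV < 0.1 at n = 100,000)", {
  gm <- cachedFixture("flatness", function()
    buildToyGenome(nFull = 8, nSolo = 12, elementLen = 5918,
                   chromTemplate = c(chrI = 120000L, chrII = 120000L),
                   seed = 42L))
  fr <- simulateControl(gm, 100000, seed = 55L)
  as <- assignMultimappers(dedupFragments(fr), seed = 56L)
  mp <- metaProfile(computeCoverage(as, gm), gm)
  body <- profileValues(mp)[(2000L + 1000L + 1L):(2000L + 1000L + 100L)]
  expect_lt(stats::sd(body) / mean(body), 0.1)
})
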