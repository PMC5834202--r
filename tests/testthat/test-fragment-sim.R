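test_that("fragment simulation emits the requested number of records", {
  gm <- tinyGenome()
  fr <- simulateFragments(gm, enrichmentSpec(), 1000, seed = 1L)
  expect_identical(nrow(fr), 1000L)
  expect_true(all(fr$length >= 200L & fr$length <= 500L))
  expect_identical(nrow(simulateControl(gm, 0, seed = 1L)), 0L)
})

test_that("an LTR-resident fragment lists every LTR copy (2x2 full + 3 solo = 7)", {
  gm <- tinyGenome()
  el <- elementCopies(gm)
  fullA <- S4Vectors::mcols(el)$copy_id[
    S4Vectors::mcols(el)$copy_class == "full"][1]
  gs <- relToGenomic(gm, fullA, 50L, 200L)   # rel [50, 250) inside 5' LTR
  cand <- candidateLoci(gm, "chrT", gs, 200L)
  expect_identical(cand$n, 7L)
  trip <- parseCandidates(cand$candidates)
  expect_identical(nrow(trip), 7L)
  expect_true(any(trip$start == gs))          # true locus on its own list
})

test_that("junction and background fragments are unique; interior fragments shared by full copies", {
  gm <- tinyGenome()
  el <- elementCopies(gm)
  mc <- S4Vectors::mcols(el)
  fullA <- mc$copy_id[mc$copy_class == "full"][1]
  # crossing the element/flank junction: unique
  gs <- relToGenomic(gm, fullA, -50L, 300L)
  expect_identical(candidateLoci(gm, "chrT", gs, 300L)$n, 1L)
  # wholly inside the internal (non-LTR) region: one locus per full copy
  gs <- relToGenomic(gm, fullA, 400L, 300L)
  expect_identical(candidateLoci(gm, "chrT", gs, 300L)$n, 2L)
  # straddling the 5'LTR/internal junction: still shared by both full copies
  gs <- relToGenomic(gm, fullA, 300L, 200L)
  expect_identical(candidateLoci(gm, "chrT", gs, 200L)$n, 2L)
})

test_that("with one full copy and no solos, only LTR fragments are ambiguous", {
  gm <- cachedFixture("single", function()
    buildToyGenome(nFull = 1, nSolo = 0, elementLen = 1200, ltrLen = 334,
                   chromTemplate = c(chrS = 15000L), seed = 11L))
  fr <- simulateFragments(gm, enrichmentSpec(), 3000, seed = 2L)
  expect_true(all(fr$n_candidates %in% c(1L, 2L)))
  # reconstruct which fragments sit wholly inside an LTR
  el <- elementCopies(gm)
  st <- as.character(GenomicRanges::strand(el))
  s0 <- GenomicRanges::start(el) - 1L; e0 <- GenomicRanges::end(el)
  relA <- if (st == "+") fr$true_start - s0 else
    e0 - (fr$true_start + fr$length)
  inLtr <- (relA >= 0 & relA + fr$length <= 334) |
    (relA >= 1200 - 334 & relA + fr$length <= 1200)
  expect_identical(fr$n_candidates == 2L, inLtr)
})

test_that("candidate lists are symmetric and contain the true locus", {
  gm <- tinyGenome()
  fr <- simulateFragments(gm,
    enrichmentSpec(list(c(100, 1, 80), c(700, 1, 80)), backgroundWeight = 1),
    400, seed = 13L)
  expect_true(all(mapply(function(s, chr, st) {
    any(parseCandidates(s)$start == st & parseCandidates(s)$chrom == chr)
  }, fr$candidates, fr$true_chrom, fr$true_start)))
  multi <- fr[fr$n_candidates > 1, ][1:20, ]
  for (i in seq_len(nrow(multi))) {
    set1 <- sort(strsplit(multi$candidates[i], ";")[[1]])
    trips <- parseCandidates(multi$candidates[i])
    for (j in seq_len(nrow(trips))) {
      c2 <- candidateLoci(gm, trips$chrom[j], trips$start[j],
                          multi$length[i])
      expect_identical(sort(strsplit(c2$candidates, ";")[[1]]), set1)
    }
  }
})

test_that("background-only fragment centers are uniform (chi-square gof)", {
  gm <- twinGenome()
  fr <- simulateControl(gm, 20000, seed = 17L)
  centers <- fr$true_start + fr$length / 2
  cl <- chromLengths(gm)[["chrT"]]
  keep <- centers >= 500 & centers <= cl - 500   # edge-free region
  br <- seq(500, cl - 500, length.out = 21)
  counts <- table(cut(centers[keep], br))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("control equals a zero-weight-component simulation; lengths match the uniform oracle", {
  gm <- tinyGenome()
  zw <- enrichmentSpec(list(c(238, 0, 100)), backgroundWeight = 1)
  a <- simulateFragments(gm, zw, 500, sample = "control", seed = 23L)
  b <- simulateControl(gm, 500, seed = 23L)
  expect_identical(a, b)
  big <- simulateControl(gm, 10000, seed = 29L)
  se <- sqrt((301^2 - 1) / 12) / sqrt(10000)
  expect_lt(abs(mean(big$length) - 350), 3 * se)
})

test_that("fragment simulation is deterministic given the seed", {
  gm <- tinyGenome()
  spec <- enrichmentSpec(list(c(238, 1, 100)), backgroundWeight = 1)
  expect_identical(simulateFragments(gm, spec, 800, seed = 31L),
                   simulateFragments(gm, spec, 800, seed = 31L))
  expect_false(identical(simulateFragments(gm, spec, 800, seed = 31L),
                         simulateFragments(gm, spec, 800, seed = 32L)))
})

test_that("invalid simulation inputs are rejected", {
  gm <- tinyGenome()
  expect_error(simulateFragments(gm, enrichmentSpec(), 10,
                                 fragLenRange = c(500, 200)),
               "increasing")
  expect_error(enrichmentSpec(list(c(238, -1, 100))), "nonnegative")
  expect_error(enrichmentSpec(backgroundWeight = 0), "positive")
  expect_error(simulateFragments(gm,
    enrichmentSpec(list(c(5000, 1, 10)), backgroundWeight = 1), 10),
    "element length")
})

test_that("mobility count simulation respects frequency edge cases", {
  z <- simulateMobilityCounts(mobilitySimConfig(c(a = 0, b = 0), seed = 2L))
  expect_true(all(z$colonies[z$plate_type == "selective"] == 0))
  o <- simulateMobilityCounts(
    mobilitySimConfig(c(a = 1), cfuPerCulture = 1e4, seed = 2L))
  sel <- o$colonies[o$plate_type == "selective"]
  # with p = 1 every cell is an event, and the default selective plating
  # (whole culture, undiluted) recovers the full Poisson(1e4) culture
  expect_true(all(sel > 0))
  expect_lt(abs(mean(sel) - 1e4), 3 * sqrt(1e4 / 12))
  expect_error(mobilitySimConfig(c(a = 1.5)), "0, 1")
  expect_identical(simulateMobilityCounts(
                     mobilitySimConfig(c(a = 1e-6), seed = 4L)),
                   simulateMobilityCounts(
                     mobilitySimConfig(c(a = 1e-6), seed = 4L)))
})
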