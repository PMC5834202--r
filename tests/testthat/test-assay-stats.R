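plateRow <- function(colonies, vol = 1, dil = 1000, cult = 1000,
                     type = "permissive")
  data.frame(colonies = colonies, volume_plated_ul = vol,
             dilution_factor = dil, culture_volume_ul = cult,
             plate_type = type)

test_that("whole-culture CFU back-calculation", {
  expect_equal(cfuInCulture(plateRow(200)), 2e8)
  expect_equal(cfuInCulture(plateRow(15, vol = 100, dil = 1)), 150)
  expect_equal(cfuInCulture(plateRow(7, vol = 1000, dil = 1)), 7)
  expect_error(cfuInCulture(plateRow(0)), "unmeasurable")
  # selective plates may legitimately have zero colonies
  expect_equal(cfuInCulture(plateRow(0, type = "selective")), 0)
})

test_that("per-culture frequency is selective CFU over permissive CFU", {
  mk <- function(colonies, type, vol = 1, dil = 1000)
    data.frame(strain = "s", bio_rep = 1, tech_rep = 1,
               plateRow(colonies, vol = vol, dil = dil, type = type))
  f <- mobilityFrequency(mk(200, "selective", vol = 1000, dil = 1),
                         mk(200, "permissive"))
  expect_equal(f$frequency, 200 / 2e8)
  expect_equal(mobilityFrequency(mk(0, "selective", vol = 1000, dil = 1),
                                 mk(200, "permissive"))$frequency, 0)
  # identical counts and geometry -> frequency 1
  expect_equal(mobilityFrequency(mk(50, "selective"),
                                 mk(50, "permissive"))$frequency, 1)
  b <- mk(10, "permissive"); b$tech_rep <- 2
  expect_error(mobilityFrequency(mk(1, "selective"), b), "same cultures")
})

strainCounts <- function(strain, selColonies, permColonies = 250,
                         nBio = 3, nTech = 4) {
  grid <- expand.grid(tech_rep = seq_len(nTech), bio_rep = seq_len(nBio),
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(strain = strain, grid[, c("bio_rep", "tech_rep")],
               plate_type = "permissive", volume_plated_ul = 1,
               dilution_factor = 1000, culture_volume_ul = 1000,
               colonies = permColonies),
    data.frame(strain = strain, grid[, c("bio_rep", "tech_rep")],
               plate_type = "selective", volume_plated_ul = 1000,
               dilution_factor = 1, culture_volume_ul = 1000,
               colonies = selColonies))
}

test_that("strain summary pools technical cultures and censors all-zero strains", {
  # biological means 1e-6, 2e-6, 3e-6 by construction: permissive CFU 2.5e8
  counts <- strainCounts("wt", selColonies = rep(c(250, 500, 750), each = 4))
  res <- summarizeMobility(counts)
  expect_equal(res$mean, 2e-6)
  expect_equal(res$dispersion, 1e-6)
  expect_identical(res$dispersion_type, "sd")
  expect_false(res$censored)
  expect_true(is.na(res$upper_limit))

  # all-zero selective: censored with upper limit 1 / total permissive CFU
  z <- summarizeMobility(strainCounts("null", selColonies = 0))
  expect_true(z$censored)
  expect_equal(z$upper_limit, 1 / (12 * 2.5e8))
  expect_equal(z$mean, 0)

  # exactly the stated fixture: total permissive CFU 1e9 -> limit 1e-9
  fx <- strainCounts("fix", selColonies = 0, permColonies = 250,
                     nBio = 2, nTech = 2)
  # 4 cultures x 2.5e8 = 1e9
  zfx <- summarizeMobility(fx)
  expect_equal(zfx$upper_limit, 1e-9, tolerance = 1e-12)

  # n_bio = 2 reports a range, not an s.d.
  two <- summarizeMobility(strainCounts("pair",
    selColonies = rep(c(250, 750), each = 4), nBio = 2))
  expect_identical(two$dispersion_type, "range")
  expect_equal(two$dispersion, 3e-6 - 1e-6)

  one <- strainCounts("solo", selColonies = 5, nBio = 1)
  expect_error(summarizeMobility(one), "2 biological replicates")
})

test_that("upper limits strictly decrease as assayed CFU increases", {
  lims <- vapply(c(100, 250, 1000), function(cp)
    summarizeMobility(strainCounts("s", 0, permColonies = cp))$upper_limit,
    0)
  expect_true(all(diff(lims) < 0))
})

test_that("fold changes respect censoring and invert cleanly", {
  a <- list(mean = 1e-5, censored = FALSE, upper_limit = NA_real_)
  b <- list(mean = 1e-7, censored = FALSE, upper_limit = NA_real_)
  cns <- list(mean = 0, censored = TRUE, upper_limit = 1e-8)
  expect_equal(foldChange(a, b)$fold, 100)
  expect_equal(foldChange(a, a)$fold, 1)
  fb <- foldChange(a, cns)
  expect_true(fb$lowerBound)
  expect_equal(fb$fold, 1000)
  expect_match(fb$label, "^> ")
  expect_true(foldChange(cns, cns)$undefined)
  expect_equal(foldChange(a, b)$fold * foldChange(b, a)$fold, 1)
})

test_that("densitometry levels are loading-corrected and WT-normalized", {
  expect_equal(relativeLevel(10, 2, 5, 2), 2)
  expect_equal(relativeLevel(5, 2, 5, 2), 1)
  expect_error(relativeLevel(10, 0, 5, 2), "positive")
  tab <- data.frame(sample = c("WT", "mut"), target_signal = c(5, 10),
                    loading_signal = c(2, 2))
  out <- densitometryTable(tab, reference = "WT")
  expect_equal(out$relative_level, c(1, 2))
})

test_that("RT-PCR fold arithmetic reproduces the worked example", {
  expect_equal(cycleOffsetFold(5, 2), 32)
  expect_equal(cycleOffsetFold(0), 1)
  expect_equal(cycleOffsetFold(6, 2), 64)
  expect_error(cycleOffsetFold(5, 1), "> 1")
  expect_error(cycleOffsetFold(-1), ">= 0")
  expect_equal(molarCorrection(200, 3000), 15)
  expect_equal(molarCorrection(100, 100), 1)
  expect_equal(molarCorrection(100, 1000), 10)
  expect_error(molarCorrection(0, 10), "positive")
  fe <- combinedAbundance(5, 2, 200, 3000)
  expect_equal(fe$combined_fold, 480)
  expect_equal(fe$percent_of_reference, 100 / 480)
  expect_equal(combinedAbundance(0, 2, 100, 100)$combined_fold, 1)
  expect_equal(combinedAbundance(1, 2, 100, 100)$percent_of_reference, 50)
  # multiplicative in cycle offsets at fixed lengths
  expect_equal(combinedAbundance(3 + 2, 2, 200, 3000)$combined_fold,
               combinedAbundance(3, 2, 200, 3000)$combined_fold *
                 cycleOffsetFold(2, 2))
})

test_that("censoring probability matches the Poisson zero-event oracle", {
  # cfu * p = 0.1 events per culture; 12 cultures -> P(censored) = exp(-1.2)
  cfg <- function(seed) mobilitySimConfig(c(s = 1e-8), cfuPerCulture = 1e7,
                                          permissiveVolumeUl = 10,
                                          seed = seed)
  cens <- vapply(1:200, function(s)
    summarizeMobility(simulateMobilityCounts(cfg(s)))$censored, TRUE)
  p0 <- exp(-12 * 1e7 * 1e-8)
  se <- sqrt(p0 * (1 - p0) / 200)
  expect_lt(abs(mean(cens) - p0), 3 * se)
})
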