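# Retromobility frequency arithmetic, censored upper limits, and
# semi-quantitative RT-PCR / densitometry fold estimation.

#' Colony-forming units in a culture from a plate count
#'
#' Back-calculates whole-culture CFU from a plating:
#' `CFU = colonies * dilution_factor * (culture_volume / volume_plated)`.
#' Vectorized over the rows of a colony-count table. A permissive plate with
#' zero colonies is an error: the culture density is unmeasurable.
#'
#' @param counts data.frame with columns `colonies`, `dilution_factor`,
#'   `volume_plated_ul`, `culture_volume_ul` and (optionally) `plate_type`.
#' @return Numeric vector of whole-culture CFU estimates.
#' @examples
#' cfuInCulture(data.frame(colonies = 200, dilution_factor = 1000,
#'                         volume_plated_ul = 1, culture_volume_ul = 1000))
#' # 2e8
#' @export
cfuInCulture <- function(counts) {
  need <- c("colonies", "dilution_factor", "volume_plated_ul",
            "culture_volume_ul")
  if (!all(need %in% colnames(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(counts$volume_plated_ul <= 0) || any(counts$dilution_factor < 1))
    stop("volume_plated_ul must be > 0 and dilution_factor >= 1",
         call. = FALSE)
  if (any(counts$colonies < 0))
    stop("colonies must be nonnegative", call. = FALSE)
  if ("plate_type" %in% colnames(counts) &&
      any(counts$plate_type == "permissive" & counts$colonies == 0))
    stop("zero colonies on a permissive plate: culture density unmeasurable",
         call. = FALSE)
  counts$colonies * counts$dilution_factor *
    (counts$culture_volume_ul / counts$volume_plated_ul)
}

#' Per-culture retromobility frequency
#'
#' Frequency = His+ CFU / total CFU in the same culture, each
#' back-calculated with [cfuInCulture()]. Rows are matched on
#' (`strain`, `bio_rep`, `tech_rep`). Zero selective colonies give frequency
#' 0 (censoring is decided at strain level by [summarizeMobility()]).
#'
#' @param selective,permissive data.frames of selective (His+) and
#'   permissive plate counts for the same cultures.
#' @return data.frame with columns `strain`, `bio_rep`, `tech_rep`,
#'   `frequency`, `selective_colonies`, `permissive_cfu`.
#' @export
mobilityFrequency <- function(selective, permissive) {
  keyS <- paste(selective$strain, selective$bio_rep, selective$tech_rep,
                sep = "|")
  keyP <- paste(permissive$strain, permissive$bio_rep, permissive$tech_rep,
                sep = "|")
  if (anyDuplicated(keyS) || anyDuplicated(keyP) ||
      !setequal(keyS, keyP) || length(keyS) != length(keyP))
    stop("selective and permissive tables must cover the same cultures",
         call. = FALSE)
  permissive <- permissive[match(keyS, keyP), , drop = FALSE]
  permCfu <- cfuInCulture(permissive)
  selCfu <- selective$colonies * selective$dilution_factor *
    (selective$culture_volume_ul / selective$volume_plated_ul)
  data.frame(strain = selective$strain, bio_rep = selective$bio_rep,
             tech_rep = selective$tech_rep,
             frequency = selCfu / permCfu,
             selective_colonies = selective$colonies,
             permissive_cfu = permCfu,
             stringsAsFactors = FALSE)
}

#' Summarize retromobility per strain, with zero-event censoring
#'
#' Computes per-culture frequencies, averages technical cultures within each
#' biological replicate, and reports the mean across biological replicates
#' with standard deviation (3+ replicates) or the range (exactly 2, where a
#' standard deviation is not meaningful). When no selective colonies were
#' observed in any culture of a strain, the result is censored and an upper
#' limit of `1 / (total permissive CFU over all cultures)` is reported in
#' place of a measured frequency.
#'
#' @param counts Colony-count table in the [simulateMobilityCounts()]
#'   dialect (long format with `plate_type`).
#' @param pooling `"bio-mean"` (default: technical cultures averaged within
#'   biological replicate, dispersion across biological replicates) or
#'   `"culture"` (mean and dispersion across all cultures).
#' @return data.frame, one row per strain: `strain`, `mean`, `dispersion`,
#'   `dispersion_type` (`"sd"`/`"range"`), `censored`, `upper_limit`,
#'   `n_bio`, `n_cultures`, plus a list-column `bio_means`.
#' @export
summarizeMobility <- function(counts, pooling = c("bio-mean", "culture")) {
  pooling <- match.arg(pooling)
  sel <- counts[counts$plate_type == "selective", , drop = FALSE]
  perm <- counts[counts$plate_type == "permissive", , drop = FALSE]
  if (!nrow(sel) || !nrow(perm))
    stop("counts must contain both selective and permissive plates",
         call. = FALSE)
  freq <- mobilityFrequency(sel, perm)

  res <- lapply(split(freq, freq$strain), function(d) {
    nBio <- length(unique(d$bio_rep))
    if (nBio < 2L)
      stop(sprintf("strain '%s': need >= 2 biological replicates",
                   d$strain[1L]), call. = FALSE)
    censored <- all(d$selective_colonies == 0)
    vals <- if (pooling == "bio-mean")
      as.numeric(tapply(d$frequency, d$bio_rep, mean)) else d$frequency
    mu <- mean(vals)
    if (length(vals) == 2L) {
      disp <- max(vals) - min(vals); dtype <- "range"
    } else {
      disp <- stats::sd(vals); dtype <- "sd"
    }
    data.frame(strain = d$strain[1L], mean = mu, dispersion = disp,
               dispersion_type = dtype, censored = censored,
               upper_limit = if (censored) 1 / sum(d$permissive_cfu)
                             else NA_real_,
               n_bio = nBio, n_cultures = nrow(d),
               bio_means = I(list(vals)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fold change between two strains' retromobility
#'
#' `a` over `b`. When `b` is censored (no events observed) the result is a
#' lower bound computed against `b`'s upper limit and reported as "> x".
#'
#' @param a,b One-row results from [summarizeMobility()] (or lists with
#'   `mean`, `censored`, `upper_limit`).
#' @return A list with `fold`, `lowerBound` (logical), `undefined`
#'   (logical, TRUE when both strains are censored) and a formatted
#'   `label`.
#' @examples
#' a <- list(mean = 1e-5, censored = FALSE, upper_limit = NA)
#' b <- list(mean = 0, censored = TRUE, upper_limit = 1e-8)
#' foldChange(a, b)$label  # "> 1000"
#' @export
foldChange <- function(a, b) {
  aCens <- isTRUE(as.logical(a$censored))
  bCens <- isTRUE(as.logical(b$censored))
  if (aCens && bCens)
    return(list(fold = NA_real_, lowerBound = FALSE, undefined = TRUE,
                label = "undefined (both censored)"))
  if (!aCens && a$mean <= 0)
    stop("numerator mean must be positive", call. = FALSE)
  if (aCens)
    stop("numerator strain is censored; compare in the other direction",
         call. = FALSE)
  if (bCens) {
    fold <- a$mean / b$upper_limit
    list(fold = fold, lowerBound = TRUE, undefined = FALSE,
         label = paste0("> ", format(fold, digits = 4)))
  } else {
    fold <- a$mean / b$mean
    list(fold = fold, lowerBound = FALSE, undefined = FALSE,
         label = format(fold, digits = 4))
  }
}

#' Blot band level relative to a loading control, normalized to a reference
#'
#' `(target / loading) / (reference_target / reference_loading)`: the
#' standard densitometry arithmetic for e.g. Ty1 RNA relative to PYK1 RNA
#' normalized to the wild-type level.
#'
#' @param targetSignal,loadingSignal Band intensities for the sample.
#' @param refTargetSignal,refLoadingSignal Band intensities for the
#'   reference (e.g. WT) sample.
#' @return Numeric relative level (vectorized).
#' @export
relativeLevel <- function(targetSignal, loadingSignal,
                          refTargetSignal, refLoadingSignal) {
  sig <- cbind(targetSignal, loadingSignal, refTargetSignal,
               refLoadingSignal)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("all band signals must be positive", call. = FALSE)
  (targetSignal / loadingSignal) / (refTargetSignal / refLoadingSignal)
}

#' Normalize a band-intensity table to a reference sample
#'
#' @param table data.frame with columns `sample`, `target_signal`,
#'   `loading_signal`.
#' @param reference Name of the reference sample (default "WT").
#' @return The table with a `relative_level` column added.
#' @export
densitometryTable <- function(table, reference = "WT") {
  i <- which(table$sample == reference)
  if (length(i) != 1L)
    stop(sprintf("reference sample '%s' must occur exactly once", reference),
         call. = FALSE)
  table$relative_level <- relativeLevel(
    table$target_signal, table$loading_signal,
    table$target_signal[i], table$loading_signal[i])
  table
}

#' Fold difference implied by a PCR cycle offset
#'
#' A template observed `deltaCycles` cycles earlier is
#' `efficiency^deltaCycles`-fold more abundant; with perfect doubling
#' (efficiency 2, the conservative assumption) 5 fewer cycles mean 32-fold.
#'
#' @param deltaCycles Nonnegative cycle offset(s).
#' @param efficiency Per-cycle amplification factor, must exceed 1
#'   (default 2).
#' @return Numeric fold(s).
#' @export
cycleOffsetFold <- function(deltaCycles, efficiency = 2) {
  if (any(efficiency <= 1))
    stop("efficiency must be > 1", call. = FALSE)
  if (any(deltaCycles < 0))
    stop("deltaCycles must be >= 0", call. = FALSE)
  efficiency^deltaCycles
}

#' Molar correction for unequal amplicon lengths
#'
#' Equal mass-signal for amplicons of different lengths implies a molar
#' excess of the short-amplicon species of `targetLen / refLen` (a ~200 bp
#' reference amplicon vs ~3 kb target amplicons gives 15).
#'
#' @param refAmpliconLen Reference amplicon length (bp).
#' @param targetAmpliconLen Target amplicon length (bp).
#' @return Numeric molar ratio(s).
#' @export
molarCorrection <- function(refAmpliconLen, targetAmpliconLen) {
  if (any(refAmpliconLen <= 0) || any(targetAmpliconLen <= 0))
    stop("amplicon lengths must be positive", call. = FALSE)
  targetAmpliconLen / refAmpliconLen
}

#' Combined semi-quantitative RT-PCR abundance estimate
#'
#' Combines the cycle-offset fold and the amplicon-length molar correction
#' into the overall fold by which the reference transcript exceeds the
#' target, and the target's abundance as a percentage of the reference:
#' `combined_fold = efficiency^deltaCycles * targetLen/refLen`;
#' `percent_of_reference = 100 / combined_fold`.
#'
#' @inheritParams cycleOffsetFold
#' @param refAmpliconLen,targetAmpliconLen Amplicon lengths (bp).
#' @return One-row data.frame with `cycle_fold`, `molar_correction`,
#'   `combined_fold`, `percent_of_reference`.
#' @examples
#' combinedAbundance(5, 2, 200, 3000)  # combined_fold 480, ~0.21%
#' @export
combinedAbundance <- function(deltaCycles, efficiency = 2,
                              refAmpliconLen, targetAmpliconLen) {
  cf <- cycleOffsetFold(deltaCycles, efficiency)
  mc <- molarCorrection(refAmpliconLen, targetAmpliconLen)
  data.frame(cycle_fold = cf, molar_correction = mc,
             combined_fold = cf * mc,
             percent_of_reference = 100 / (cf * mc))
}
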