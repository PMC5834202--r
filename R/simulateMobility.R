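#' Configuration for retromobility colony-count simulation
#'
#' Describes a His+ retromobility assay: for each strain, `nBiological`
#' overnight cultures each diluted in quadruplicate (`nTechnical`) and grown
#' to saturation, then plated on permissive (YPD; 1 uL of a 1:1000 dilution)
#' and selective (SC-HIS; undiluted) agar. `trueFrequency` is the fraction
#' of cells carrying a retromobility event.
#'
#' @param trueFrequency Named numeric vector of per-strain event
#'   frequencies in \[0, 1\] (names are strain labels).
#' @param cfuPerCulture Expected colony-forming units per saturated culture
#'   (default 2e8).
#' @param nBiological,nTechnical Biological replicates per strain (default
#'   3) and technical cultures per biological replicate (default 4).
#' @param cultureVolumeUl Culture volume in uL (default 1000).
#' @param permissiveVolumeUl,permissiveDilution Plated volume (uL) and
#'   dilution factor for the permissive plating (defaults 1 uL of a 1:1000
#'   dilution).
#' @param selectiveVolumeUl,selectiveDilution Plated volume (uL) and
#'   dilution factor for the selective plating (defaults 1000 uL undiluted).
#' @param seed Default integer seed used by [simulateMobilityCounts()].
#' @return A validated list of class `MobilitySimConfig`.
#' @export
mobilitySimConfig <- function(trueFrequency,
                              cfuPerCulture = 2e8,
                              nBiological = 3L, nTechnical = 4L,
                              cultureVolumeUl = 1000,
                              permissiveVolumeUl = 1,
                              permissiveDilution = 1000,
                              selectiveVolumeUl = 1000,
                              selectiveDilution = 1,
                              seed = 1L) {
  if (is.null(names(trueFrequency)))
    names(trueFrequency) <- sprintf("strain%02d", seq_along(trueFrequency))
  if (any(trueFrequency < 0) || any(trueFrequency > 1))
    stop("trueFrequency values must lie in [0, 1]", call. = FALSE)
  cfg <- list(
    trueFrequency = trueFrequency,
    cfuPerCulture = .checkNumber(cfuPerCulture, "cfuPerCulture", 0,
                                 strict = TRUE),
    nBiological = .checkCount(nBiological, "nBiological", 1L),
    nTechnical = .checkCount(nTechnical, "nTechnical", 1L),
    cultureVolumeUl = .checkNumber(cultureVolumeUl, "cultureVolumeUl", 0,
                                   strict = TRUE),
    permissiveVolumeUl = .checkNumber(permissiveVolumeUl,
                                      "permissiveVolumeUl", 0, strict = TRUE),
    permissiveDilution = .checkNumber(permissiveDilution,
                                      "permissiveDilution", 1),
    selectiveVolumeUl = .checkNumber(selectiveVolumeUl,
                                     "selectiveVolumeUl", 0, strict = TRUE),
    selectiveDilution = .checkNumber(selectiveDilution,
                                     "selectiveDilution", 1),
    seed = seed)
  class(cfg) <- "MobilitySimConfig"
  cfg
}

#' Simulate His+ retromobility colony counts
#'
#' For each strain x biological x technical culture: total CFU is Poisson
#' around `cfuPerCulture`; retromobility (His+) cells are binomial with
#' p = `trueFrequency`; each plate then receives a binomial subsample of
#' the relevant cells with sampling fraction
#' `volume_plated / (dilution_factor * culture_volume)`.
#'
#' @param config A [mobilitySimConfig()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data.frame in the colony-count table dialect: columns `strain`,
#'   `bio_rep`, `tech_rep`, `plate_type` (`"permissive"`/`"selective"`),
#'   `volume_plated_ul`, `dilution_factor`, `culture_volume_ul`, `colonies`.
#' @examples
#' cfg <- mobilitySimConfig(c(WT = 1e-6), seed = 7)
#' head(simulateMobilityCounts(cfg))
#' @export
simulateMobilityCounts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "MobilitySimConfig"))
  strains <- names(config$trueFrequency)
  grid <- expand.grid(tech_rep = seq_len(config$nTechnical),
                      bio_rep = seq_len(config$nBiological),
                      strain = strains,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("strain", "bio_rep", "tech_rep")]
  nc <- nrow(grid)
  p <- config$trueFrequency[grid$strain]
  fracPerm <- config$permissiveVolumeUl /
    (config$permissiveDilution * config$cultureVolumeUl)
  fracSel <- config$selectiveVolumeUl /
    (config$selectiveDilution * config$cultureVolumeUl)
  if (fracPerm > 1 || fracSel > 1)
    stop("plated volume exceeds the (diluted) culture volume", call. = FALSE)

  withSeed(seed, {
    total <- stats::rpois(nc, config$cfuPerCulture)
    events <- stats::rbinom(nc, total, p)
    permColonies <- stats::rbinom(nc, total, fracPerm)
    selColonies <- stats::rbinom(nc, events, fracSel)
    rbind(
      data.frame(grid, plate_type = "permissive",
                 volume_plated_ul = config$permissiveVolumeUl,
                 dilution_factor = config$permissiveDilution,
                 culture_volume_ul = config$cultureVolumeUl,
                 colonies = permColonies, stringsAsFactors = FALSE),
      data.frame(grid, plate_type = "selective",
                 volume_plated_ul = config$selectiveVolumeUl,
                 dilution_factor = config$selectiveDilution,
                 culture_volume_ul = config$cultureVolumeUl,
                 colonies = selColonies, stringsAsFactors = FALSE))
  })
}
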