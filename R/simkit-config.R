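#' Default SNP-dense region layout
#'
#' Five dense blocks with lengths 0.4, 0.8, 2.6, 1.9 and 1.5 Mb. C
#' (13.9-16.5 Mb) and D (16.9-18.8 Mb) are placed at the coordinates the
#' mapping localised; A, B and E have fixed published lengths but not
#' published positions, so their placements (3.0-3.4, 6.0-6.8,
#' 19.5-21.0 Mb) are configurable package defaults.
#'
#' @return data.frame with columns label, start, end (0-based bp).
#' @export
defaultDenseRegions <- function() {
  data.frame(
    label = c("A", "B", "C", "D", "E"),
    start = c(3.0e6, 6.0e6, 13.9e6, 16.9e6, 19.5e6),
    end   = c(3.4e6, 6.8e6, 16.5e6, 18.8e6, 21.0e6)
  )
}

#' Construct a simulation configuration
#'
#' Defaults describe the study design being emulated: a 23.5 Mb X
#' chromosome whose inter-line SNPs average 25/10 kb inside five dense
#' blocks and 4/10 kb elsewhere; ~80 Hi founder females x ~55 Lo founder
#' males intermating freely for 15 generations; one crossover per X
#' bivalent per female meiosis on average, with placement suppressed
#' 3.4-fold inside dense blocks; 788 assayed males split into extreme
#' activity pools of 45. The activity model (baseline 250 counts/day,
#' additive Hi-parentage effects of 945 and 405 counts/day in regions C and
#' D, sd 80) is calibrated so the extreme pools land in the low-hundreds vs
#' mid-thousands counts/day regime.
#'
#' @param chromLen chromosome length in bp.
#' @param denseRegions data.frame(label, start, end), 0-based bp.
#' @param denseSnpRate,sparseSnpRate SNPs per bp inside/outside dense blocks.
#' @param parentalHetFrac length-2 named numeric (hi, lo): probability a
#'   site segregates within the line and is masked.
#' @param nFounderHiFemales,nFounderLoMales founder counts.
#' @param generations generations of free intermating.
#' @param popSize individuals per intermediate generation.
#' @param meanCosPerMeiosis expected crossovers per X bivalent per female
#'   meiosis.
#' @param suppressionFactor crossover-placement weight penalty in dense
#'   regions (>= 1).
#' @param causalRegions dense-region labels with activity effects.
#' @param effectSizes named numeric, counts/day per unit Hi fraction.
#' @param baselineActivity,activitySd phenotype baseline and noise sd.
#' @param nAssayedMales males collected in the final generation.
#' @param poolSize flies per extreme pool.
#' @param dropoutProb,genotypeErrorProb genotyping noise probabilities,
#'   emulating marginal single-fly whole-genome coverage.
#' @param nFlies,nMeioses rate-normalisation constants (sequenced flies
#'   passing QC; effective single-recombination opportunities per X).
#' @param seed default RNG seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(generations = 2L, popSize = 50L,
#'                         nAssayedMales = 20L, poolSize = 5L)
#' cfg
#' @export
simulationConfig <- function(chromLen = 23.5e6,
                             denseRegions = defaultDenseRegions(),
                             denseSnpRate = 25 / 1e4,
                             sparseSnpRate = 4 / 1e4,
                             parentalHetFrac = c(hi = 0.079, lo = 0.058),
                             nFounderHiFemales = 80L,
                             nFounderLoMales = 55L,
                             generations = 15L,
                             popSize = 400L,
                             meanCosPerMeiosis = 1.0,
                             suppressionFactor = 3.4,
                             causalRegions = c("C", "D"),
                             effectSizes = c(C = 945, D = 405),
                             baselineActivity = 250,
                             activitySd = 80,
                             nAssayedMales = 788L,
                             poolSize = 45L,
                             dropoutProb = 0.15,
                             genotypeErrorProb = 0.02,
                             nFlies = 84L,
                             nMeioses = 5L,
                             seed = 1L) {
  dr <- as.data.frame(denseRegions)
  dr <- dr[order(dr$start), , drop = FALSE]
  rownames(dr) <- NULL
  new("SimulationConfig",
      chromLen = as.numeric(chromLen),
      denseRegions = dr,
      denseSnpRate = denseSnpRate,
      sparseSnpRate = sparseSnpRate,
      parentalHetFrac = parentalHetFrac,
      nFounderHiFemales = as.integer(nFounderHiFemales),
      nFounderLoMales = as.integer(nFounderLoMales),
      generations = as.integer(generations),
      popSize = as.integer(popSize),
      meanCosPerMeiosis = meanCosPerMeiosis,
      suppressionFactor = suppressionFactor,
      causalRegions = causalRegions,
      effectSizes = effectSizes,
      baselineActivity = baselineActivity,
      activitySd = activitySd,
      nAssayedMales = as.integer(nAssayedMales),
      poolSize = as.integer(poolSize),
      dropoutProb = dropoutProb,
      genotypeErrorProb = genotypeErrorProb,
      nFlies = as.integer(nFlies),
      nMeioses = as.integer(nMeioses),
      seed = as.integer(seed))
}

#' True region layout of a configuration as a RegionSet
#'
#' Tiles the chromosome with the configured dense blocks and the sparse
#' intervals between and around them.
#'
#' @param config a [SimulationConfig-class].
#' @return a [RegionSet-class].
#' @export
configRegions <- function(config) {
  dr <- config@denseRegions
  bounds <- c(0, as.vector(rbind(dr$start, dr$end)), config@chromLen)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  keep <- ends > starts
  cls <- rep(c("sparse", "dense"), length.out = length(starts))
  lab <- character(length(starts))
  lab[cls == "dense"] <- dr$label
  sp <- which(cls == "sparse" & keep)
  lab[sp] <- sprintf("sparse_%d", seq_along(sp))
  new("RegionSet",
      regions = data.frame(label = lab[keep], start = starts[keep],
                           end = ends[keep], class = cls[keep]),
      chromLen = config@chromLen)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [SimulationConfig-class].
#' @param path file path.
#' @return \code{readSimulationConfigYaml} returns a
#'   [SimulationConfig-class]; the writer returns \code{path} invisibly.
#' @export
writeSimulationConfigYaml <- function(config, path) {
  x <- list(
    chromLen = config@chromLen,
    denseRegions = lapply(seq_len(nrow(config@denseRegions)), function(i)
      as.list(config@denseRegions[i, ])),
    denseSnpRate = config@denseSnpRate,
    sparseSnpRate = config@sparseSnpRate,
    parentalHetFrac = as.list(config@parentalHetFrac),
    nFounderHiFemales = config@nFounderHiFemales,
    nFounderLoMales = config@nFounderLoMales,
    generations = config@generations,
    popSize = config@popSize,
    meanCosPerMeiosis = config@meanCosPerMeiosis,
    suppressionFactor = config@suppressionFactor,
    causalRegions = as.list(config@causalRegions),
    effectSizes = as.list(config@effectSizes),
    baselineActivity = config@baselineActivity,
    activitySd = config@activitySd,
    nAssayedMales = config@nAssayedMales,
    poolSize = config@poolSize,
    dropoutProb = config@dropoutProb,
    genotypeErrorProb = config@genotypeErrorProb,
    nFlies = config@nFlies,
    nMeioses = config@nMeioses,
    seed = config@seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeSimulationConfigYaml
#' @export
readSimulationConfigYaml <- function(path) {
  x <- yaml::read_yaml(path)
  dr <- do.call(rbind, lapply(x$denseRegions, as.data.frame))
  simulationConfig(
    chromLen = x$chromLen,
    denseRegions = dr,
    denseSnpRate = x$denseSnpRate,
    sparseSnpRate = x$sparseSnpRate,
    parentalHetFrac = unlist(x$parentalHetFrac),
    nFounderHiFemales = x$nFounderHiFemales,
    nFounderLoMales = x$nFounderLoMales,
    generations = x$generations,
    popSize = x$popSize,
    meanCosPerMeiosis = x$meanCosPerMeiosis,
    suppressionFactor = x$suppressionFactor,
    causalRegions = unlist(x$causalRegions),
    effectSizes = unlist(x$effectSizes),
    baselineActivity = x$baselineActivity,
    activitySd = x$activitySd,
    nAssayedMales = x$nAssayedMales,
    poolSize = x$poolSize,
    dropoutProb = x$dropoutProb,
    genotypeErrorProb = x$genotypeErrorProb,
    nFlies = x$nFlies,
    nMeioses = x$nMeioses,
    seed = x$seed)
}
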