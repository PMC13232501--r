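#' @import methods
#' @importFrom stats rpois rbinom rnorm runif quantile dbinom pbinom dhyper
#'   wilcox.test lm fisher.test setNames coef var
#' @importFrom utils read.delim write.table head tail
NULL

.ORIGIN_HI <- 1L
.ORIGIN_LO <- 2L
.ORIGIN_LEVELS <- c("Hi", "Lo")
.LABEL_LEVELS <- c("Hi", "Lo", "Unique", "Missing")

#' Simulation configuration for the free-intermating breeding design
#'
#' Holds every knob of the forward simulator: the chromosome, the SNP-density
#' landscape of the two parental lines, the breeding design (founders,
#' generations, population size), the female meiosis model (mean crossovers
#' per bivalent and the placement suppression inside SNP-dense blocks), the
#' activity phenotype model, and the genotyping noise model.
#'
#' @slot chromLen chromosome length in bp.
#' @slot denseRegions data.frame with columns \code{label}, \code{start},
#'   \code{end} (0-based half-open bp) giving the SNP-dense blocks.
#' @slot denseSnpRate,sparseSnpRate inter-line SNP rates (SNPs per bp) inside
#'   and outside the dense blocks.
#' @slot parentalHetFrac named numeric of length 2 (\code{hi}, \code{lo}):
#'   probability that a site is segregating (non-fixed) within each parental
#'   line and therefore masked from the informative set.
#' @slot nFounderHiFemales,nFounderLoMales founder counts.
#' @slot generations number of generations of free intermating.
#' @slot popSize individuals per intermediate generation.
#' @slot meanCosPerMeiosis expected crossovers per X bivalent per female
#'   meiosis.
#' @slot suppressionFactor relative crossover-placement weight penalty inside
#'   dense regions (weight 1 in sparse, 1/suppressionFactor in dense); >= 1.
#' @slot causalRegions labels of dense regions carrying additive activity
#'   effects.
#' @slot effectSizes named numeric, activity counts/day per unit Hi fraction
#'   for each causal region.
#' @slot baselineActivity,activitySd phenotype baseline and Gaussian noise sd
#'   (counts/day).
#' @slot nAssayedMales males collected in the final generation.
#' @slot poolSize flies per extreme phenotype pool.
#' @slot dropoutProb,genotypeErrorProb per-site per-fly probabilities of a
#'   missing call and of a flipped call.
#' @slot nFlies,nMeioses normalisation constants for per-meiosis rates: number
#'   of sequenced flies passing QC and the effective number of recombination
#'   opportunities per transmitted X (the design gives ~10 female-line
#'   transmissions of which half the chromatids carry each crossover).
#' @slot seed default RNG seed.
#' @export
setClass("SimulationConfig", representation(
  chromLen = "numeric",
  denseRegions = "data.frame",
  denseSnpRate = "numeric",
  sparseSnpRate = "numeric",
  parentalHetFrac = "numeric",
  nFounderHiFemales = "integer",
  nFounderLoMales = "integer",
  generations = "integer",
  popSize = "integer",
  meanCosPerMeiosis = "numeric",
  suppressionFactor = "numeric",
  causalRegions = "character",
  effectSizes = "numeric",
  baselineActivity = "numeric",
  activitySd = "numeric",
  nAssayedMales = "integer",
  poolSize = "integer",
  dropoutProb = "numeric",
  genotypeErrorProb = "numeric",
  nFlies = "integer",
  nMeioses = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  dr <- object@denseRegions
  if (length(object@chromLen) != 1L || object@chromLen <= 0)
    msg <- c(msg, "chromLen must be a single positive number")
  if (!all(c("label", "start", "end") %in% names(dr)))
    msg <- c(msg, "denseRegions needs columns label, start, end")
  else {
    if (nrow(dr) && any(dr$end <= dr$start))
      msg <- c(msg, "dense regions must have end > start")
    if (nrow(dr) && (any(dr$start < 0) || any(dr$end > object@chromLen)))
      msg <- c(msg, "dense regions must lie within [0, chromLen)")
    if (nrow(dr) > 1L) {
      o <- order(dr$start)
      if (any(diff(dr$start) < 0))
        msg <- c(msg, "dense regions must be sorted by start")
      if (any(utils::head(dr$end[o], -1L) > dr$start[o][-1L]))
        msg <- c(msg, "dense regions must be disjoint")
    }
  }
  probs <- c(object@parentalHetFrac, object@dropoutProb,
             object@genotypeErrorProb)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@denseSnpRate < 0 || object@sparseSnpRate < 0)
    msg <- c(msg, "SNP rates must be non-negative")
  if (object@denseSnpRate == 0 && object@sparseSnpRate == 0)
    msg <- c(msg, "at least one SNP rate must be positive")
  if (object@suppressionFactor < 1)
    msg <- c(msg, "suppressionFactor must be >= 1")
  if (object@meanCosPerMeiosis < 0)
    msg <- c(msg, "meanCosPerMeiosis must be >= 0")
  if (object@activitySd < 0)
    msg <- c(msg, "activitySd must be >= 0")
  if (!all(object@causalRegions %in% dr$label))
    msg <- c(msg, "causalRegions must name dense region labels")
  if (!all(object@causalRegions %in% names(object@effectSizes)))
    msg <- c(msg, "every causal region needs an effect size")
  counts <- c(object@nFounderHiFemales, object@nFounderLoMales,
              object@generations, object@nAssayedMales, object@poolSize,
              object@nFlies, object@nMeioses)
  if (any(counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Parental haplotypes of the two lines
#'
#' Positions and alleles at every site where the two parental X chromosomes
#' differ, together with per-line heterozygosity masks marking sites that are
#' not fixed within a line and are therefore excluded from painting.
#' Coordinates are 0-based bp internally.
#'
#' @slot positions strictly increasing 0-based bp positions.
#' @slot hiAllele,loAllele single-character allele per position.
#' @slot hetHi,hetLo logical masks: site segregates within the Hi (Lo) line.
#' @slot chromLen chromosome length in bp.
#' @export
setClass("ParentalHaplotypes", representation(
  positions = "numeric",
  hiAllele = "character",
  loAllele = "character",
  hetHi = "logical",
  hetLo = "logical",
  chromLen = "numeric"
))

setValidity("ParentalHaplotypes", function(object) {
  n <- length(object@positions)
  msg <- character(0)
  if (n && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@hiAllele) != n || length(object@loAllele) != n ||
      length(object@hetHi) != n || length(object@hetLo) != n)
    msg <- c(msg, "all per-site slots must have equal length")
  inf <- !object@hetHi & !object@hetLo
  if (n && any(object@hiAllele[inf] == object@loAllele[inf]))
    msg <- c(msg, "informative sites must carry different alleles per line")
  if (length(msg)) msg else TRUE
})

#' Informative SNP set for parental-origin assignment
#'
#' Sites homozygous within each parental line with different alleles between
#' lines, plus the QC statistics of the filtering (fraction of sites dropped
#' as segregating per line, per-line homozygosity percentages).
#'
#' @slot positions strictly increasing 0-based bp.
#' @slot hiAllele,loAllele allele codes per position (VCF GT index codes or
#'   nucleotides; the painter only compares for equality).
#' @slot qc named list: \code{hetFracHi}, \code{hetFracLo},
#'   \code{homPctHi}, \code{homPctLo}, \code{nInput}, \code{nRetained}.
#' @slot chromLen chromosome length in bp.
#' @export
setClass("InformativeSiteSet", representation(
  positions = "numeric",
  hiAllele = "character",
  loAllele = "character",
  qc = "list",
  chromLen = "numeric"
))

setValidity("InformativeSiteSet", function(object) {
  n <- length(object@positions)
  msg <- character(0)
  if (n && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@hiAllele) != n || length(object@loAllele) != n)
    msg <- c(msg, "allele slots must match positions")
  if (n && any(object@hiAllele == object@loAllele))
    msg <- c(msg, "informative sites must differ between lines")
  if (length(msg)) msg else TRUE
})

#' A painted (parental-origin assigned) recombinant X chromosome
#'
#' Per-site raw labels (Hi / Lo / Unique / Missing), the smoothed labels used
#' for tract building, and the resulting ordered parentage tracts tiling
#' [0, chromLen). Tracts are 0-based half-open.
#'
#' @slot flyId sample identifier.
#' @slot chromLen chromosome length in bp.
#' @slot positions informative-site positions evaluated for this fly.
#' @slot rawLabels factor with levels Hi, Lo, Unique, Missing.
#' @slot labels smoothed labels (same levels) actually used for tracts.
#' @slot tractStart,tractEnd,tractOrigin the tract tiling; origins are
#'   "Hi"/"Lo", or a single "Unknown" tract when no usable site exists.
#' @slot k the minimum-run smoothing parameter applied.
#' @export
setClass("PaintedChromosome", representation(
  flyId = "character",
  chromLen = "numeric",
  positions = "numeric",
  rawLabels = "factor",
  labels = "factor",
  tractStart = "numeric",
  tractEnd = "numeric",
  tractOrigin = "character",
  k = "integer"
))

setValidity("PaintedChromosome", function(object) {
  msg <- character(0)
  nt <- length(object@tractStart)
  if (length(object@tractEnd) != nt || length(object@tractOrigin) != nt)
    msg <- c(msg, "tract slots must have equal length")
  if (nt) {
    if (object@tractStart[1L] != 0 ||
        object@tractEnd[nt] != object@chromLen)
      msg <- c(msg, "tracts must tile [0, chromLen)")
    if (nt > 1L && any(object@tractStart[-1L] != object@tractEnd[-nt]))
      msg <- c(msg, "tracts must be gap- and overlap-free")
    if (nt > 1L &&
        any(object@tractOrigin[-1L] == object@tractOrigin[-nt]))
      msg <- c(msg, "adjacent tracts must differ in origin")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort of truth-tagged simulated male X chromosomes
#'
#' Container for the assayed males produced by [simulateGenerations()]. Each
#' chromosome is stored as interior breakpoints plus alternating tract
#' origins, with a log of the crossover events in the ancestry of its
#' material (position and generation).
#'
#' @slot chromosomes list; each element has \code{brk} (sorted interior
#'   breakpoints, bp), \code{org} (integer origins per tract, 1 = Hi,
#'   2 = Lo), \code{lin} (two-column matrix: crossover position, generation).
#' @slot config the [SimulationConfig-class] that produced the cohort.
#' @export
setClass("SimulatedCohort", representation(
  chromosomes = "list",
  config = "SimulationConfig"
))

#' Genotype calls for a cohort of flies plus parental samples
#'
#' Allele-index genotype calls over the parental SNP positions. Recombinant
#' males are hemizygous, so calls are haploid: "0" (Lo/reference allele),
#' "1" (Hi/alternate allele) or "." (missing). Parental samples are diploid
#' ("0/0", "1/1", "0/1", "./.").
#'
#' @slot positions 0-based bp positions.
#' @slot ref,alt reference (Lo) and alternate (Hi) alleles.
#' @slot flyGT character matrix, sites x flies, haploid codes.
#' @slot parentalGT character matrix, sites x parental samples, diploid codes.
#' @slot parentalRoles named character: "hi" or "lo" per parental sample.
#' @slot chromLen chromosome length in bp.
#' @export
setClass("GenotypeCalls", representation(
  positions = "numeric",
  ref = "character",
  alt = "character",
  flyGT = "matrix",
  parentalGT = "matrix",
  parentalRoles = "character",
  chromLen = "numeric"
))

setValidity("GenotypeCalls", function(object) {
  n <- length(object@positions)
  msg <- character(0)
  if (nrow(object@flyGT) != n)
    msg <- c(msg, "flyGT must have one row per position")
  if (nrow(object@parentalGT) != n && ncol(object@parentalGT) > 0L)
    msg <- c(msg, "parentalGT must have one row per position")
  if (!all(object@parentalRoles %in% c("hi", "lo")))
    msg <- c(msg, "parentalRoles must be 'hi' or 'lo'")
  if (length(msg)) msg else TRUE
})

#' Labelled chromosome segmentation into SNP-dense and SNP-sparse regions
#'
#' Disjoint, sorted, labelled intervals classifying the chromosome by
#' inter-parental SNP density. Dense blocks are labelled A, B, C, ... in
#' coordinate order; the sparse intervals between and around them complete
#' the tiling.
#'
#' @slot regions data.frame with columns \code{label}, \code{start},
#'   \code{end} (0-based half-open bp) and \code{class} ("dense"/"sparse").
#' @slot chromLen chromosome length in bp.
#' @export
setClass("RegionSet", representation(
  regions = "data.frame",
  chromLen = "numeric"
))

setValidity("RegionSet", function(object) {
  r <- object@regions
  msg <- character(0)
  if (!all(c("label", "start", "end", "class") %in% names(r)))
    msg <- c(msg, "regions needs columns label, start, end, class")
  else {
    if (nrow(r) > 1L && any(diff(r$start) <= 0))
      msg <- c(msg, "regions must be sorted")
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)]))
      msg <- c(msg, "regions must be disjoint")
    if (nrow(r) && !all(r$class %in% c("dense", "sparse")))
      msg <- c(msg, "class must be 'dense' or 'sparse'")
  }
  if (length(msg)) msg else TRUE
})
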