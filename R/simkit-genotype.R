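#' Genotype a simulated cohort at the parental SNP sites
#'
#' Each fly's call at each site is the allele of the covering truth tract,
#' replaced by missing with probability \code{dropoutProb} and flipped to
#' the opposite allele with probability \code{genotypeErrorProb} — the noise
#' regime of low-coverage single-fly whole-genome sequencing. Parental
#' samples (3 Hi, 2 Lo) are emitted as diploid calls, heterozygous at the
#' sites flagged as segregating within their line.
#'
#' Allele coding is arbitrary but fixed: the Lo allele is REF ("0") and the
#' Hi allele is ALT ("1").
#'
#' @param cohort a [SimulatedCohort-class].
#' @param parental a [ParentalHaplotypes-class] from [buildParentalSnps()].
#' @param config a [SimulationConfig-class]; defaults to the cohort's.
#' @param seed RNG seed.
#' @param flies indices (or names) of cohort flies to genotype; default all.
#' @return a [GenotypeCalls-class].
#' @export
genotypeCohort <- function(cohort, parental, config = cohort@config,
                           seed = config@seed, flies = NULL) {
  stopifnot(is(cohort, "SimulatedCohort"), is(parental, "ParentalHaplotypes"))
  pos <- parental@positions
  if (length(pos) && (min(pos) < 0 || max(pos) >= config@chromLen))
    stop("site outside chromosome")
  if (is.null(flies))
    flies <- seq_along(cohort@chromosomes)
  if (is.character(flies))
    flies <- match(flies, .flyIds(cohort))
  ids <- .flyIds(cohort)[flies]
  nS <- length(pos)
  nF <- length(flies)
  withSeed(seed, {
    gt <- matrix("0", nrow = nS, ncol = nF, dimnames = list(NULL, ids))
    for (j in seq_len(nF)) {
      chrom <- cohort@chromosomes[[flies[j]]]
      org <- chrom$org[findInterval(pos, chrom$brk) + 1L]
      gt[org == .ORIGIN_HI, j] <- "1"
    }
    if (config@genotypeErrorProb > 0) {
      flip <- matrix(runif(nS * nF) < config@genotypeErrorProb, nS, nF)
      gt[flip] <- ifelse(gt[flip] == "1", "0", "1")
    }
    if (config@dropoutProb > 0) {
      drop <- matrix(runif(nS * nF) < config@dropoutProb, nS, nF)
      gt[drop] <- "."
    }
    hiGT <- ifelse(parental@hetHi, "0/1", "1/1")
    loGT <- ifelse(parental@hetLo, "0/1", "0/0")
    parentalGT <- cbind(HiP1 = hiGT, HiP2 = hiGT, HiP3 = hiGT,
                        LoP1 = loGT, LoP2 = loGT)
    new("GenotypeCalls",
        positions = pos,
        ref = parental@loAllele,
        alt = parental@hiAllele,
        flyGT = gt,
        parentalGT = parentalGT,
        parentalRoles = c(HiP1 = "hi", HiP2 = "hi", HiP3 = "hi",
                          LoP1 = "lo", LoP2 = "lo"),
        chromLen = config@chromLen)
  })
}
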