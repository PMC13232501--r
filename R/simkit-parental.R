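.NUCS <- c("A", "C", "G", "T")

#' Simulate the divergent sites of the two parental X chromosomes
#'
#' Draws inter-line SNP positions as an inhomogeneous Poisson process with
#' rate \code{denseSnpRate} inside the configured dense blocks and
#' \code{sparseSnpRate} elsewhere, assigns distinct alleles per line, and
#' independently flags sites as segregating within each parental line
#' (the heterozygosity mask that QC later removes).
#'
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed (NULL advances the current stream).
#' @return a [ParentalHaplotypes-class].
#' @examples
#' ph <- buildParentalSnps(simulationConfig(), seed = 1)
#' ph
#' @export
buildParentalSnps <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (config@chromLen <= 0)
    stop("zero-length chromosome")
  withSeed(seed, {
    rs <- configRegions(config)@regions
    rate <- ifelse(rs$class == "dense", config@denseSnpRate,
                   config@sparseSnpRate)
    pos <- unlist(lapply(seq_len(nrow(rs)), function(i) {
      len <- rs$end[i] - rs$start[i]
      n <- rpois(1L, rate[i] * len)
      if (n == 0L) return(numeric(0))
      floor(runif(n, rs$start[i], rs$end[i]))
    }))
    pos <- sort(unique(pos))
    n <- length(pos)
    lo <- sample(.NUCS, n, replace = TRUE)
    # Hi allele drawn from the three nucleotides different from Lo's
    hi <- vapply(lo, function(a) sample(setdiff(.NUCS, a), 1L), character(1),
                 USE.NAMES = FALSE)
    hetHi <- runif(n) < config@parentalHetFrac[["hi"]]
    hetLo <- runif(n) < config@parentalHetFrac[["lo"]]
    new("ParentalHaplotypes", positions = pos, hiAllele = hi,
        loAllele = lo, hetHi = hetHi, hetLo = hetLo,
        chromLen = config@chromLen)
  })
}
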