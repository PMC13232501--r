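#' Simulate locomotor activity phenotypes
#'
#' Activity (counts/day) is the configured baseline plus, for each causal
#' dense region, its effect size times the fly's true Hi-parentage fraction
#' in that region, plus Gaussian noise, floored at zero.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param config a [SimulationConfig-class]; defaults to the cohort's.
#' @param seed RNG seed.
#' @return data.frame with columns flyId, activity.
#' @export
simulatePhenotypes <- function(cohort, config = cohort@config,
                               seed = config@seed) {
  stopifnot(is(cohort, "SimulatedCohort"))
  if (config@activitySd < 0)
    stop("activitySd must be non-negative")
  n <- length(cohort@chromosomes)
  dr <- config@denseRegions
  withSeed(seed, {
    activity <- rep(config@baselineActivity, n)
    for (lab in config@causalRegions) {
      row <- dr[dr$label == lab, ]
      frac <- vapply(cohort@chromosomes, .truthHiFrac, numeric(1),
                     a = row$start, b = row$end, chromLen = config@chromLen)
      activity <- activity + config@effectSizes[[lab]] * frac
    }
    activity <- activity + rnorm(n, 0, config@activitySd)
    data.frame(flyId = .flyIds(cohort), activity = pmax(0, activity))
  })
}

#' Assign extreme phenotype pools
#'
#' The \code{poolSize} lowest-activity flies form the low pool and the
#' \code{poolSize} highest form the high pool; everyone else is unassayed.
#' Ties are broken deterministically by fly id.
#'
#' @param phenotypes data.frame with columns flyId, activity.
#' @param poolSize flies per pool.
#' @return the input data.frame with an added factor column \code{pool}
#'   (levels low, high, unassayed).
#' @export
selectExtremePools <- function(phenotypes, poolSize) {
  stopifnot(all(c("flyId", "activity") %in% names(phenotypes)))
  n <- nrow(phenotypes)
  if (n < 2L * poolSize)
    stop("too few flies: need at least 2 * poolSize = ", 2L * poolSize)
  ord <- order(phenotypes$activity, phenotypes$flyId)
  pool <- rep("unassayed", n)
  pool[ord[seq_len(poolSize)]] <- "low"
  pool[ord[seq.int(n - poolSize + 1L, n)]] <- "high"
  phenotypes$pool <- factor(pool, levels = c("low", "high", "unassayed"))
  phenotypes
}
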