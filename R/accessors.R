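#' Site positions of an object
#'
#' @param x a [ParentalHaplotypes-class], [InformativeSiteSet-class],
#'   [PaintedChromosome-class] or [GenotypeCalls-class] object.
#' @return numeric vector of 0-based bp positions.
#' @name sitePositions
NULL

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "ParentalHaplotypes", function(x) x@positions)

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "InformativeSiteSet", function(x) x@positions)

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "PaintedChromosome", function(x) x@positions)

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "GenotypeCalls", function(x) x@positions)

#' Parentage tracts as genomic ranges
#'
#' Returns the parentage tract tiling of a painted chromosome, or the truth
#' tracts of a simulated cohort, as a [GenomicRanges::GRanges] (1-based
#' closed, seqname "X") with metadata columns \code{origin} and
#' \code{flyId}.
#'
#' @param x a [PaintedChromosome-class] or [SimulatedCohort-class].
#' @param ... for a cohort, \code{i}: indices of flies (default all).
#' @return a \code{GRanges}.
#' @name tracts
NULL

#' @rdname tracts
#' @export
setMethod("tracts", "PaintedChromosome", function(x, ...) {
  GenomicRanges::GRanges(
    seqnames = "X",
    ranges = IRanges::IRanges(start = x@tractStart + 1L, end = x@tractEnd),
    origin = x@tractOrigin,
    flyId = x@flyId
  )
})

#' @rdname tracts
#' @export
setMethod("tracts", "SimulatedCohort", function(x, i = seq_along(x@chromosomes), ...) {
  pieces <- lapply(i, function(j) {
    chrom <- x@chromosomes[[j]]
    b <- c(0, chrom$brk, x@config@chromLen)
    data.frame(start = utils::head(b, -1L), end = b[-1L],
               origin = .ORIGIN_LEVELS[chrom$org],
               flyId = .flyIds(x)[j])
  })
  df <- do.call(rbind, pieces)
  GenomicRanges::GRanges(
    seqnames = "X",
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    origin = df$origin, flyId = df$flyId
  )
})

.flyIds <- function(cohort) {
  ids <- names(cohort@chromosomes)
  if (is.null(ids))
    ids <- sprintf("fly%04d", seq_along(cohort@chromosomes))
  ids
}

#' QC statistics of informative-site selection
#'
#' @param x an [InformativeSiteSet-class].
#' @return named list with the fraction of candidate sites dropped as
#'   segregating within each line (\code{hetFracHi}, \code{hetFracLo}), the
#'   per-line homozygosity percentages, and input/retained site counts.
#' @name qcStats
NULL

#' @rdname qcStats
#' @export
setMethod("qcStats", "InformativeSiteSet", function(x) x@qc)

#' Region table of a RegionSet
#'
#' @param x a [RegionSet-class].
#' @return data.frame with columns label, start, end, class and lengthMb.
#' @name regionTable
NULL

#' @rdname regionTable
#' @export
setMethod("regionTable", "RegionSet", function(x) {
  r <- x@regions
  r$lengthMb <- (r$end - r$start) / 1e6
  r
})

#' Labels of the dense regions in coordinate order
#'
#' @param x a [RegionSet-class].
#' @return character vector of dense-region labels.
#' @name denseRegionLabels
NULL

#' @rdname denseRegionLabels
#' @export
setMethod("denseRegionLabels", "RegionSet", function(x)
  x@regions$label[x@regions$class == "dense"])

#' @export
setMethod("length", "SimulatedCohort", function(x) length(x@chromosomes))

#' @export
setMethod("length", "InformativeSiteSet", function(x) length(x@positions))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  chromosome: %.1f Mb, %d dense regions (%s)\n",
              object@chromLen / 1e6, nrow(object@denseRegions),
              paste(object@denseRegions$label, collapse = ", ")))
  cat(sprintf("  SNP rates: %.1f (dense) vs %.1f (sparse) per 10 kb\n",
              object@denseSnpRate * 1e4, object@sparseSnpRate * 1e4))
  cat(sprintf("  design: %d Hi females x %d Lo males, %d generations, popSize %d\n",
              object@nFounderHiFemales, object@nFounderLoMales,
              object@generations, object@popSize))
  cat(sprintf("  meiosis: %.2f CO/bivalent, dense suppression x%.2f\n",
              object@meanCosPerMeiosis, object@suppressionFactor))
  cat(sprintf("  phenotype: causal %s, baseline %.0f, sd %.0f\n",
              paste(object@causalRegions, collapse = "+"),
              object@baselineActivity, object@activitySd))
  cat(sprintf("  assay: %d males, pools of %d; dropout %.2f, error %.3f\n",
              object@nAssayedMales, object@poolSize, object@dropoutProb,
              object@genotypeErrorProb))
})

setMethod("show", "ParentalHaplotypes", function(object) {
  n <- length(object@positions)
  inf <- sum(!object@hetHi & !object@hetLo)
  cat(sprintf("ParentalHaplotypes: %d sites on %.1f Mb (%d informative)\n",
              n, object@chromLen / 1e6, inf))
})

setMethod("show", "InformativeSiteSet", function(object) {
  cat(sprintf("InformativeSiteSet: %d sites on %.1f Mb\n",
              length(object@positions), object@chromLen / 1e6))
  qc <- object@qc
  if (length(qc))
    cat(sprintf("  parental het fraction: Hi %.1f%%, Lo %.1f%% (homozygosity %.2f%% / %.2f%%)\n",
                100 * qc$hetFracHi, 100 * qc$hetFracLo,
                qc$homPctHi, qc$homPctLo))
})

setMethod("show", "PaintedChromosome", function(object) {
  cat(sprintf("PaintedChromosome %s: %d tracts over %.1f Mb (k = %d)\n",
              object@flyId, length(object@tractOrigin),
              object@chromLen / 1e6, object@k))
  tab <- table(object@rawLabels)
  cat("  site labels:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = " "), "\n")
})

setMethod("show", "SimulatedCohort", function(object) {
  nb <- vapply(object@chromosomes, function(ch) length(ch$brk), integer(1))
  cat(sprintf("SimulatedCohort: %d male X chromosomes, mean %.2f tract boundaries\n",
              length(object@chromosomes), mean(nb)))
})

setMethod("show", "GenotypeCalls", function(object) {
  cat(sprintf("GenotypeCalls: %d sites x %d flies (+%d parental samples)\n",
              length(object@positions), ncol(object@flyGT),
              ncol(object@parentalGT)))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet on %.1f Mb:\n", object@chromLen / 1e6))
  print(regionTable(object))
})
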