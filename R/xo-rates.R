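#' Segment a chromosome into SNP-dense and SNP-sparse regions
#'
#' Tiles the chromosome into windows, computes SNP density per window, and
#' calls maximal runs of windows at or above the threshold dense. Dense runs
#' separated by a gap shorter than \code{mergeGap} are merged. The
#' complement is sparse. Dense regions are labelled A, B, C, ... in
#' coordinate order.
#'
#' @param sites an [InformativeSiteSet-class] (or any object with
#'   \code{sitePositions}), or a numeric vector of positions if
#'   \code{chromLen} is given.
#' @param window window width in bp (>= 10 kb).
#' @param denseThreshold density threshold in SNPs per 10 kb.
#' @param mergeGap dense runs closer than this (bp) merge; default one
#'   window.
#' @param chromLen required when \code{sites} is a bare numeric vector.
#' @return a [RegionSet-class].
#' @export
segmentByDensity <- function(sites, window = 1e5, denseThreshold = 10,
                             mergeGap = window, chromLen = NULL) {
  if (is(sites, "InformativeSiteSet")) {
    pos <- sites@positions
    chromLen <- sites@chromLen
  } else {
    pos <- as.numeric(sites)
    stopifnot(!is.null(chromLen))
  }
  if (!length(pos))
    stop("empty site set")
  if (window < 1e4)
    stop("window must be >= 10 kb")
  nw <- ceiling(chromLen / window)
  wStart <- (seq_len(nw) - 1L) * window
  wEnd <- pmin(wStart + window, chromLen)
  counts <- tabulate(findInterval(pos, wStart), nbins = nw)
  dens <- counts / (wEnd - wStart) * 1e4   # SNPs per 10 kb
  dense <- dens >= denseThreshold
  if (!any(dense)) {
    return(new("RegionSet",
               regions = data.frame(label = "sparse_1", start = 0,
                                    end = chromLen, class = "sparse"),
               chromLen = chromLen))
  }
  r <- rle(dense)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  dRuns <- which(r$values)
  dStart <- wStart[starts[dRuns]]
  dEnd <- wEnd[ends[dRuns]]
  # merge dense runs separated by less than mergeGap
  if (length(dStart) > 1L) {
    keep <- c(TRUE, dStart[-1L] - dEnd[-length(dEnd)] >= mergeGap)
    grp <- cumsum(keep)
    dStart <- tapply(dStart, grp, min)
    dEnd <- tapply(dEnd, grp, max)
  }
  nD <- length(dStart)
  dr <- data.frame(label = LETTERS[seq_len(nD)], start = as.numeric(dStart),
                   end = as.numeric(dEnd))
  bounds <- c(0, as.vector(rbind(dr$start, dr$end)), chromLen)
  s <- bounds[-length(bounds)]
  e <- bounds[-1L]
  cls <- rep(c("sparse", "dense"), length.out = length(s))
  lab <- character(length(s))
  lab[cls == "dense"] <- dr$label
  keep <- e > s
  sp <- which(cls == "sparse" & keep)
  lab[sp] <- sprintf("sparse_%d", seq_along(sp))
  new("RegionSet",
      regions = data.frame(label = lab[keep], start = s[keep], end = e[keep],
                           class = cls[keep]),
      chromLen = chromLen)
}

# usable (Hi/Lo) site positions and origins of a painting
.usableSites <- function(painting) {
  u <- which(painting@labels %in% c("Hi", "Lo"))
  list(pos = painting@positions[u],
       org = as.character(painting@labels[u]))
}

#' Count crossovers of a painted chromosome within a region
#'
#' A crossover is an origin switch between consecutive usable informative
#' sites. Its breakpoint is only localised to the interval between the two
#' flanking sites; the crossover is assigned to the region containing the
#' interval midpoint.
#'
#' @param painting a [PaintedChromosome-class].
#' @param start,end region bounds, 0-based half-open bp.
#' @return integer crossover count.
#' @export
countCrossovers <- function(painting, start, end) {
  stopifnot(is(painting, "PaintedChromosome"))
  if (start < 0 || end > painting@chromLen || end <= start)
    stop("region outside chromosome")
  us <- .usableSites(painting)
  if (length(us$pos) < 2L)
    return(0L)
  sw <- which(us$org[-1L] != us$org[-length(us$org)])
  if (!length(sw))
    return(0L)
  mid <- (us$pos[sw] + us$pos[sw + 1L]) / 2
  sum(mid >= start & mid < end)
}

#' Infer a crossover within an unreadable sparse gap from its flanks
#'
#' Origin cannot be read inside a near-identical sparse region, but a
#' parentage difference between the facing edges of the two flanking dense
#' regions implies at least one crossover inside the gap. An even number of
#' gap crossovers is invisible, so this is a minimum. Returns NA when either
#' edge has no usable site (logged via attribute).
#'
#' @param painting a [PaintedChromosome-class].
#' @param left,right numeric length-2 vectors (start, end) of the flanking
#'   dense regions, left of and right of the gap.
#' @return integer 0/1, or NA when not evaluable.
#' @export
inferFlankingCrossover <- function(painting, left, right) {
  us <- .usableSites(painting)
  li <- which(us$pos >= left[1L] & us$pos < left[2L])
  ri <- which(us$pos >= right[1L] & us$pos < right[2L])
  if (!length(li) || !length(ri))
    return(NA_integer_)
  lOrg <- us$org[max(li)]
  rOrg <- us$org[min(ri)]
  as.integer(lOrg != rOrg)
}

#' Per-Mb per-meiosis recombination rate
#'
#' Normalises a crossover total by region length (Mb), the number of flies,
#' and the effective number of single-recombination opportunities per X.
#'
#' @param count total crossovers.
#' @param lengthMb region length in Mb.
#' @param nFlies number of flies (default 84).
#' @param nMeioses effective meioses per fly (default 5).
#' @return rate in crossovers per Mb per meiosis.
#' @examples
#' perMeiosisRate(10, 0.4)  # 0.059524
#' @export
perMeiosisRate <- function(count, lengthMb, nFlies = 84, nMeioses = 5) {
  if (lengthMb <= 0)
    stop("zero region length")
  if (nFlies <= 0 || nMeioses <= 0)
    stop("denominators must be positive")
  count / lengthMb / nFlies / nMeioses
}

#' Bootstrap percentile confidence interval for a region rate
#'
#' Resamples flies (the exchangeable unit) with replacement, recomputes the
#' per-Mb per-meiosis rate each time, and returns the percentile interval.
#'
#' @param perFlyCounts integer vector, one crossover count per fly (NA
#'   counts are dropped).
#' @param lengthMb region length in Mb.
#' @param nFlies,nMeioses normalisation constants passed to
#'   [perMeiosisRate()]; \code{nFlies} defaults to the number of counts.
#' @param B bootstrap resamples (default 10,000).
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return numeric c(lo, hi).
#' @export
bootstrapCI <- function(perFlyCounts, lengthMb,
                        nFlies = length(perFlyCounts), nMeioses = 5,
                        B = 10000L, conf = 0.95, seed = NULL) {
  counts <- perFlyCounts[!is.na(perFlyCounts)]
  n <- length(counts)
  if (n < 1L)
    stop("need at least one fly")
  if (B < 1L)
    stop("B must be >= 1")
  withSeed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    totals <- colSums(matrix(counts[idx], nrow = n))
    rates <- perMeiosisRate(totals, lengthMb, nFlies, nMeioses)
    alpha <- (1 - conf) / 2
    unname(quantile(rates, c(alpha, 1 - alpha)))
  })
}

#' Bootstrap CI for the sparse:dense rate ratio
#'
#' Jointly resamples flies and recomputes (sparse rate) / (pooled dense
#' rate). The default interval is the basic (reflected) bootstrap interval
#' constructed on the log scale, the standard construction for rate-ratio
#' estimands: raw percentile intervals on a ratio with a small denominator
#' count undercover. \code{method = "percentile"} gives the raw percentile
#' interval instead. Degenerate resamples (zero numerator or denominator)
#' are excluded from the log-scale quantiles; if the point estimate itself
#' is zero or infinite the percentile interval is returned.
#'
#' @param sparseCounts,denseCounts per-fly crossover counts for the sparse
#'   and the pooled dense regions (flies aligned; NA pairs dropped).
#' @param sparseLengthMb,denseLengthMb region lengths in Mb.
#' @param B bootstrap resamples.
#' @param conf confidence level.
#' @param method "logbasic" (default) or "percentile".
#' @param seed RNG seed.
#' @return list(ratio, ci = c(lo, hi), method).
#' @export
bootstrapRateRatio <- function(sparseCounts, denseCounts, sparseLengthMb,
                               denseLengthMb, B = 10000L, conf = 0.95,
                               method = c("logbasic", "percentile"),
                               seed = NULL) {
  method <- match.arg(method)
  ok <- !is.na(sparseCounts) & !is.na(denseCounts)
  s <- sparseCounts[ok]
  d <- denseCounts[ok]
  n <- length(s)
  if (n < 1L)
    stop("need at least one fly")
  ratio <- (sum(s) / sparseLengthMb) / (sum(d) / denseLengthMb)
  withSeed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    sTot <- colSums(matrix(s[idx], nrow = n))
    dTot <- colSums(matrix(d[idx], nrow = n))
    r <- (sTot / sparseLengthMb) / (dTot / denseLengthMb)
    alpha <- (1 - conf) / 2
    usable <- is.finite(r) & r > 0
    if (method == "logbasic" && is.finite(ratio) && ratio > 0 &&
        any(usable)) {
      q <- quantile(log(r[usable]), c(alpha, 1 - alpha), names = FALSE)
      ci <- exp(c(2 * log(ratio) - q[2L], 2 * log(ratio) - q[1L]))
    } else {
      method <- "percentile"
      ci <- unname(quantile(r, c(alpha, 1 - alpha), names = FALSE))
    }
    list(ratio = ratio, ci = ci, method = method)
  })
}

#' Exact conditional Poisson rate test for two regions
#'
#' Conditions on the total crossover count N = c1 + c2; under the null of
#' equal per-Mb rates, c1 ~ Binomial(N, L1 / (L1 + L2)). The two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one (the minimum-likelihood convention, as in
#' \code{stats::binom.test} / \code{stats::poisson.test}).
#'
#' @param c1,c2 crossover counts in the two regions.
#' @param l1,l2 region lengths in Mb.
#' @return object of class \code{htest} with the p-value, the conditional
#'   null probability, and the counts.
#' @examples
#' exactConditionalRateTest(23, 2.6, 10, 0.4)$p.value  # ~0.009
#' @export
exactConditionalRateTest <- function(c1, l1, c2, l2) {
  if (c1 < 0 || c2 < 0)
    stop("counts must be non-negative")
  if (l1 <= 0 || l2 <= 0)
    stop("lengths must be positive")
  N <- c1 + c2
  p0 <- l1 / (l1 + l2)
  if (N == 0) {
    warning("both counts zero; p = 1 by convention")
    pval <- 1
  } else {
    d <- dbinom(0:N, N, p0)
    # relative tolerance guards ties against floating-point noise
    pval <- min(1, sum(d[d <= d[c1 + 1L] * (1 + 1e-7)]))
  }
  structure(list(
    statistic = c(count1 = c1),
    parameter = c(N = N, p0 = p0),
    p.value = pval,
    estimate = c(`rate ratio (per Mb)` = (c1 / l1) / (c2 / l2)),
    alternative = "two.sided",
    method = "Exact conditional Poisson rate test (binomial, minimum-likelihood two-sided)",
    data.name = sprintf("%g COs over %g Mb vs %g COs over %g Mb",
                        c1, l1, c2, l2)),
    class = "htest")
}

#' Region-wise crossover rate table
#'
#' Counts crossovers per fly in every dense region, infers the minimum
#' crossover indicator for the narrowest sparse gap between consecutive
#' dense regions from its flanks, and reports per-Mb per-meiosis rates with
#' bootstrap CIs and exact conditional p-values of each dense region against
#' the sparse gap.
#'
#' @param paintings list of [PaintedChromosome-class].
#' @param regions a [RegionSet-class].
#' @param nFlies,nMeioses normalisation constants; \code{nFlies} defaults to
#'   the number of paintings.
#' @param B bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param gap optionally the label pair c(left, right) of dense regions
#'   flanking the sparse gap to use; default: the narrowest gap.
#' @return list with \code{table} (data.frame: region, class, count,
#'   lengthMb, rate, ciLo, ciHi, pVsSparse), \code{perFlyCounts} (matrix),
#'   \code{gap} (the gap definition), and \code{nEvaluable} for the gap.
#' @export
crossoverRateTable <- function(paintings, regions,
                               nFlies = length(paintings), nMeioses = 5,
                               B = 10000L, seed = NULL, gap = NULL) {
  r <- regions@regions
  dense <- r[r$class == "dense", , drop = FALSE]
  if (nrow(dense) < 2L)
    stop("need at least two dense regions to define a sparse gap")
  # narrowest sparse gap between consecutive dense regions
  gapLen <- dense$start[-1L] - dense$end[-nrow(dense)]
  if (is.null(gap)) {
    gi <- which.min(gapLen)
  } else {
    gi <- match(gap[1L], dense$label)
    if (is.na(gi) || gi >= nrow(dense) || dense$label[gi + 1L] != gap[2L])
      stop("gap must name two consecutive dense regions")
  }
  gapStart <- dense$end[gi]
  gapEnd <- dense$start[gi + 1L]
  gapLab <- sprintf("%s-%s gap", dense$label[gi], dense$label[gi + 1L])
  left <- c(dense$start[gi], dense$end[gi])
  right <- c(dense$start[gi + 1L], dense$end[gi + 1L])

  counts <- vapply(paintings, function(p)
    vapply(seq_len(nrow(dense)), function(j)
      countCrossovers(p, dense$start[j], dense$end[j]), integer(1)),
    integer(nrow(dense)))
  counts <- matrix(counts, nrow = nrow(dense))  # regions x flies
  gapInd <- vapply(paintings, inferFlankingCrossover, integer(1),
                   left = left, right = right)

  lens <- (dense$end - dense$start) / 1e6
  gapLenMb <- (gapEnd - gapStart) / 1e6
  gapCounts <- gapInd
  gapTotal <- sum(gapCounts, na.rm = TRUE)

  rows <- lapply(seq_len(nrow(dense)), function(j) {
    tot <- sum(counts[j, ])
    ci <- bootstrapCI(counts[j, ], lens[j], nFlies, nMeioses, B = B,
                      seed = seed)
    p <- exactConditionalRateTest(tot, lens[j], gapTotal, gapLenMb)$p.value
    data.frame(region = dense$label[j], class = "dense", count = tot,
               lengthMb = lens[j],
               rate = perMeiosisRate(tot, lens[j], nFlies, nMeioses),
               ciLo = ci[1L], ciHi = ci[2L], pVsSparse = p)
  })
  gapCi <- bootstrapCI(gapCounts, gapLenMb, nFlies, nMeioses, B = B,
                       seed = seed)
  rows[[length(rows) + 1L]] <-
    data.frame(region = gapLab, class = "sparse", count = gapTotal,
               lengthMb = gapLenMb,
               rate = perMeiosisRate(gapTotal, gapLenMb, nFlies, nMeioses),
               ciLo = gapCi[1L], ciHi = gapCi[2L], pVsSparse = NA_real_)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  dimnames(counts) <- list(dense$label,
                           vapply(paintings, function(p) p@flyId,
                                  character(1)))
  list(table = tab, perFlyCounts = counts, gapIndicator = gapInd,
       gap = list(label = gapLab, start = gapStart, end = gapEnd,
                  left = dense$label[gi], right = dense$label[gi + 1L]),
       nEvaluable = sum(!is.na(gapInd)))
}

#' Sparse:dense rate-ratio contrast
#'
#' The sparse-gap rate divided by the length-weighted pooled rate of the two
#' flanking dense regions: pooled counts over pooled lengths. Reported both
#' at full precision and at lengths rounded to one decimal Mb (the printed
#' precision of region lengths).
#'
#' @param sparseCount,sparseLengthMb sparse-gap crossover count and length.
#' @param denseCounts,denseLengthsMb vectors for the pooled dense regions.
#' @return list(ratio, ratioPrintedPrecision).
#' @export
rateRatioContrast <- function(sparseCount, sparseLengthMb, denseCounts,
                              denseLengthsMb) {
  full <- (sparseCount / sparseLengthMb) /
    (sum(denseCounts) / sum(denseLengthsMb))
  printed <- (sparseCount / round(sparseLengthMb, 1)) /
    (sum(denseCounts) / sum(round(denseLengthsMb, 1)))
  list(ratio = full, ratioPrintedPrecision = printed)
}

#' Estimate the dense-region crossover suppression factor from paintings
#'
#' Chromosome-wide contrast for simulation-based parameter recovery:
#' crossovers are counted per fly in every sparse and every dense region
#' (both are readable when informative sites exist throughout, as in
#' simulated data), and the suppression estimate is the sparse per-Mb rate
#' divided by the dense per-Mb rate, with a fly-resampling bootstrap CI via
#' [bootstrapRateRatio()].
#'
#' @param paintings list of [PaintedChromosome-class].
#' @param regions a [RegionSet-class].
#' @param B bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list(ratio, ci, sparseCount, denseCount, sparseLengthMb,
#'   denseLengthMb).
#' @export
estimateSuppressionRatio <- function(paintings, regions, B = 1000L,
                                     conf = 0.95, seed = NULL) {
  r <- regions@regions
  counts <- vapply(paintings, function(p)
    vapply(seq_len(nrow(r)), function(j)
      countCrossovers(p, r$start[j], r$end[j]), integer(1)),
    integer(nrow(r)))
  counts <- matrix(counts, nrow = nrow(r))
  sp <- r$class == "sparse"
  sTot <- colSums(counts[sp, , drop = FALSE])
  dTot <- colSums(counts[!sp, , drop = FALSE])
  Ls <- sum(r$end[sp] - r$start[sp]) / 1e6
  Ld <- sum(r$end[!sp] - r$start[!sp]) / 1e6
  rr <- bootstrapRateRatio(sTot, dTot, Ls, Ld, B = B, conf = conf,
                           seed = seed)
  c(rr, list(sparseCount = sum(sTot), denseCount = sum(dTot),
             sparseLengthMb = Ls, denseLengthMb = Ld))
}
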