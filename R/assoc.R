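# Two-sided Fisher exact p for a 2x2 table (a b / c d), minimum-likelihood
# convention: sum over all tables with the observed margins whose point
# hypergeometric probability does not exceed the observed one.
.fisher2x2 <- function(a, b, c, d) {
  m1 <- a + b          # row 1 total (allele 1)
  n1 <- a + c          # column 1 total (pool 1)
  N <- a + b + c + d
  if (m1 == 0L || m1 == N || n1 == 0L || n1 == N)
    return(1)          # monomorphic site or empty pool margin
  k <- max(0L, n1 - (N - m1)):min(m1, n1)
  dpr <- dhyper(k, m1, N - m1, n1)
  sum(dpr[dpr <= dhyper(a, m1, N - m1, n1) * (1 + 1e-7)])
}

#' Per-site Fisher exact association between allele and pool
#'
#' For each site, builds the 2x2 table of allele ("1" vs "0") by pool (high
#' vs low), dropping flies with a missing call at that site only, and
#' computes the two-sided Fisher exact p-value (minimum-likelihood
#' convention). Monomorphic sites get p = 1 and are flagged.
#'
#' @param genotypes character matrix of haploid calls ("0"/"1"/"."), sites
#'   x flies, or a [GenotypeCalls-class].
#' @param pools factor/character per fly with levels containing "high" and
#'   "low" (other flies are ignored).
#' @param positions site positions (0-based bp); taken from a
#'   [GenotypeCalls-class] input automatically.
#' @return data.frame: position, n1High, n0High, n1Low, n0Low, p,
#'   monomorphic, negLog10P.
#' @export
fisherSiteAssociation <- function(genotypes, pools, positions = NULL) {
  if (is(genotypes, "GenotypeCalls")) {
    positions <- genotypes@positions
    genotypes <- genotypes@flyGT
  }
  stopifnot(is.matrix(genotypes))
  if (is.null(positions))
    positions <- seq_len(nrow(genotypes))
  pools <- as.character(pools)
  hiCol <- which(pools == "high")
  loCol <- which(pools == "low")
  if (!length(hiCol) || !length(loCol))
    stop("both pools must be non-empty")
  gHi <- genotypes[, hiCol, drop = FALSE]
  gLo <- genotypes[, loCol, drop = FALSE]
  n1High <- rowSums(gHi == "1")
  n0High <- rowSums(gHi == "0")
  n1Low <- rowSums(gLo == "1")
  n0Low <- rowSums(gLo == "0")
  p <- vapply(seq_along(positions), function(i)
    .fisher2x2(n1High[i], n1Low[i], n0High[i], n0Low[i]), numeric(1))
  mono <- (n1High + n1Low == 0L) | (n0High + n0Low == 0L)
  data.frame(position = positions,
             n1High = n1High, n0High = n0High,
             n1Low = n1Low, n0Low = n0Low,
             p = p, monomorphic = mono,
             negLog10P = -log10(p))
}

#' Bonferroni correction threshold and flags
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @return list(threshold = alpha / m, flags = p < threshold, m).
#' @export
bonferroni <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m < 1L)
    stop("need at least one test")
  thr <- alpha / m
  list(threshold = thr, flags = p < thr, m = m)
}

#' Hi-parentage fraction of a painted chromosome within a region
#'
#' Length-weighted by default: Hi bp / (Hi + Lo bp) within the region.
#' \code{weight = "sites"} instead uses the fraction of usable informative
#' sites labelled Hi. Returns NA when the region has no determinable
#' parentage.
#'
#' @param painting a [PaintedChromosome-class].
#' @param start,end region bounds (0-based half-open bp).
#' @param weight "bp" (default) or "sites".
#' @return fraction in [0, 1], or NA.
#' @export
hiFraction <- function(painting, start, end, weight = c("bp", "sites")) {
  weight <- match.arg(weight)
  if (weight == "sites") {
    us <- .usableSites(painting)
    sel <- us$pos >= start & us$pos < end
    if (!any(sel))
      return(NA_real_)
    return(mean(us$org[sel] == "Hi"))
  }
  s <- pmax(painting@tractStart, start)
  e <- pmin(painting@tractEnd, end)
  w <- pmax(0, e - s)
  known <- painting@tractOrigin != "Unknown"
  denom <- sum(w[known])
  if (denom <= 0)
    return(NA_real_)
  sum(w[known & painting@tractOrigin == "Hi"]) / denom
}

#' Per-region Hi-parentage fractions for a cohort of paintings
#'
#' @param paintings list of [PaintedChromosome-class].
#' @param regions a [RegionSet-class]; dense regions are used.
#' @param weight passed to [hiFraction()].
#' @return numeric matrix flies x dense regions.
#' @export
hiFractionMatrix <- function(paintings, regions, weight = "bp") {
  dense <- regions@regions[regions@regions$class == "dense", , drop = FALSE]
  out <- vapply(paintings, function(p)
    vapply(seq_len(nrow(dense)), function(j)
      hiFraction(p, dense$start[j], dense$end[j], weight = weight),
      numeric(1)),
    numeric(nrow(dense)))
  out <- matrix(out, nrow = nrow(dense))
  t(structure(out, dimnames = list(
    dense$label, vapply(paintings, function(p) p@flyId, character(1)))))
}

# Exact two-sided rank-sum p by full enumeration of group assignments,
# using midranks (handles ties); two-sidedness by doubling the smaller
# tail, capped at 1.
.rankSumExact <- function(x, y) {
  v <- c(x, y)
  rk <- rank(v)
  n1 <- length(x)
  W <- sum(rk[seq_len(n1)])
  sums <- colSums(matrix(rk[utils::combn(length(v), n1)],
                         nrow = n1))
  pLo <- mean(sums <= W + 1e-9)
  pHi <- mean(sums >= W - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

#' Compare Hi-parentage fractions between pools per region
#'
#' Two-sided Wilcoxon rank-sum test of high- vs low-pool fractions in each
#' dense region, Bonferroni-corrected across regions. The exact permutation
#' distribution (midranks, tail doubling) is enumerated when the number of
#' group assignments is at most \code{maxExact}; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param fractions matrix flies x regions from [hiFractionMatrix()].
#' @param pools factor/character per fly ("high"/"low"/other).
#' @param maxExact enumeration budget for the exact path.
#' @return data.frame: region, nHigh, nLow, meanHigh, meanLow, p, pAdj.
#' @export
compareFractions <- function(fractions, pools, maxExact = 1e5) {
  pools <- as.character(pools)
  hi <- pools == "high"
  lo <- pools == "low"
  if (!any(hi) || !any(lo))
    stop("both pools must be non-empty")
  regions <- colnames(fractions)
  if (is.null(regions))
    regions <- as.character(seq_len(ncol(fractions)))
  rows <- lapply(seq_len(ncol(fractions)), function(j) {
    x <- fractions[hi, j]
    y <- fractions[lo, j]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (!length(x) || !length(y))
      return(data.frame(region = regions[j], nHigh = length(x),
                        nLow = length(y), meanHigh = NA_real_,
                        meanLow = NA_real_, p = NA_real_))
    if (length(unique(c(x, y))) == 1L) {
      p <- 1   # fully tied, no information
    } else if (choose(length(x) + length(y), length(x)) <= maxExact) {
      p <- .rankSumExact(x, y)
    } else {
      p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    }
    data.frame(region = regions[j], nHigh = length(x), nLow = length(y),
               meanHigh = mean(x), meanLow = mean(y), p = p)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- pmin(1, out$p * ncol(fractions))
  out
}

#' Expected mapping resolution of a free-intermating design
#'
#' With n effective single-recombination opportunities per transmitted
#' chromosome, uniformly placed crossovers partition the chromosome into
#' 2^n expected intervals: resolution = chromLenMb / 2^n.
#'
#' @param chromLenMb chromosome length in Mb.
#' @param n effective recombination opportunities (>= 0).
#' @return expected resolution in Mb.
#' @examples
#' expectedResolution(23.5, 5)  # 0.734375
#' @export
expectedResolution <- function(chromLenMb, n) {
  if (n < 0)
    stop("n must be non-negative")
  chromLenMb / 2^n
}

#' Least-squares fit of genetic map position against physical position
#'
#' Ordinary least squares of centimorgan map position on Mb molecular
#' position, with the coefficient of determination.
#'
#' @param cM genetic map positions (centimorgans).
#' @param Mb physical positions (Mb).
#' @return list(slope, intercept, r2, fit) where fit is the \code{lm}.
#' @export
cmMbFit <- function(cM, Mb) {
  stopifnot(length(cM) == length(Mb))
  if (length(cM) < 3L)
    stop("need at least 3 points")
  if (stats::var(Mb) == 0 || stats::var(cM) == 0)
    stop("zero variance in a coordinate")
  fit <- lm(cM ~ Mb)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r2 = summary(fit)$r.squared,
       fit = fit)
}
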