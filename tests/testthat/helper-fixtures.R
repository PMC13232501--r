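# Small design used where the full 15-generation study is not needed.
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(generations = 3L, popSize = 80L, nAssayedMales = 60L,
         poolSize = 10L, seed = 1L),
    list(...))
  do.call(simulationConfig, args)
}

# Compact two-block chromosome for fast pipeline tests.
tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(chromLen = 6e6,
         denseRegions = data.frame(label = c("A", "B"),
                                   start = c(1.0e6, 2.2e6),
                                   end = c(1.6e6, 3.2e6)),
         causalRegions = "B",
         effectSizes = c(B = 1200),
         generations = 4L, popSize = 60L, nAssayedMales = 40L,
         poolSize = 8L, seed = 1L),
    list(...))
  do.call(simulationConfig, args)
}

# An informative-site set with identical allele codes at every site.
makeSites <- function(positions, chromLen = max(positions) + 1e5,
                      hi = "1", lo = "0") {
  n <- length(positions)
  new("InformativeSiteSet", positions = as.numeric(positions),
      hiAllele = rep(hi, n), loAllele = rep(lo, n),
      qc = list(), chromLen = as.numeric(chromLen))
}

# Paint directly from a label character vector (no smoothing).
paintFromLabels <- function(labels, positions, chromLen, flyId = "f") {
  interpolateOrigins(factor(labels, levels = c("Hi", "Lo", "Unique",
                                               "Missing")),
                     positions, chromLen, flyId = flyId)
}

# Fraction of base pairs on which a painting agrees with the truth tracts.
paintedTruthAgreement <- function(painting, chrom, chromLen) {
  tb <- c(0, chrom$brk, chromLen)
  to <- c("Hi", "Lo")[chrom$org]
  pb <- c(painting@tractStart, chromLen)
  po <- painting@tractOrigin
  cuts <- sort(unique(c(tb, pb)))
  s <- head(cuts, -1L)
  w <- diff(cuts)
  truthAt <- to[findInterval(s, tb[-1L], left.open = FALSE) + 1L]
  paintAt <- po[findInterval(s, pb[-c(1L, length(pb))]) + 1L]
  sum(w[truthAt == paintAt]) / chromLen
}

# Independent full-enumeration oracle for the conditional binomial test:
# exact point probabilities from lchoose, summed over the minimum-likelihood
# rejection set.
binomEnumOracle <- function(x, N, p) {
  k <- 0:N
  logd <- lchoose(N, k) + k * log(p) + (N - k) * log1p(-p)
  d <- exp(logd)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

# Independent hypergeometric enumeration oracle for the 2x2 Fisher test.
fisherEnumOracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || b + d == 0) return(1)
  k <- max(0, n1 - m2):min(m1, n1)
  logd <- lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(m1 + m2, n1)
  dd <- exp(logd)
  obs <- exp(lchoose(m1, a) + lchoose(m2, c) - lchoose(m1 + m2, n1))
  sum(dd[dd <= obs * (1 + 1e-7)])
}
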