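test_that("parental SNP counts follow the inhomogeneous Poisson intensity", {
  # isolate region C by silencing the sparse background
  cfg <- simulationConfig(sparseSnpRate = 1e-9)
  cRow <- cfg@denseRegions[cfg@denseRegions$label == "C", ]
  expMean <- (cRow$end - cRow$start) * cfg@denseSnpRate  # 6500
  counts <- vapply(1:100, function(s) {
    ph <- buildParentalSnps(cfg, seed = s)
    pos <- sitePositions(ph)
    sum(pos >= cRow$start & pos < cRow$end)
  }, numeric(1))
  sd1 <- sqrt(expMean)
  expect_true(all(abs(counts - expMean) < 4 * sd1))
  expect_lt(abs(mean(counts) - expMean), 4 * sd1 / sqrt(length(counts)))
})

test_that("zero sparse rate yields no sites outside dense regions", {
  cfg <- simulationConfig(sparseSnpRate = 0)
  ph <- buildParentalSnps(cfg, seed = 3)
  pos <- sitePositions(ph)
  dr <- cfg@denseRegions
  inDense <- rowSums(vapply(seq_len(nrow(dr)), function(i)
    pos >= dr$start[i] & pos < dr$end[i], logical(length(pos)))) > 0
  expect_true(all(inDense))
})

test_that("default parents are near-isogenic at the configured magnitude", {
  cfg <- simulationConfig()
  ph <- buildParentalSnps(cfg, seed = 11)
  divergence <- length(sitePositions(ph)) / cfg@chromLen
  # rates imply ~0.104% divergence, i.e. >99.88% identity
  expect_gt(divergence, 0.0009)
  expect_lt(divergence, 0.0012)
  expect_gt(1 - divergence, 0.9988)
  het <- mean(ph@hetHi)
  expect_lt(abs(het - 0.079), 0.01)
})

test_that("crossover placement is uniform when suppression is off", {
  cfg <- simulationConfig(suppressionFactor = 1)
  prof <- crossoverWeightProfile(cfg)
  pos <- sampleCrossoverPositions(prof, 1e4, seed = 5)
  ks <- suppressWarnings(ks.test(pos / cfg@chromLen, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero-weight intervals receive no crossovers and all-zero errors", {
  prof <- data.frame(start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6),
                     weight = c(1, 0, 1))
  pos <- sampleCrossoverPositions(prof, 5000, seed = 6)
  expect_false(any(pos >= 1e6 & pos < 2e6))
  expect_equal(pos, sort(pos))
  prof$weight <- 0
  expect_error(sampleCrossoverPositions(prof, 10, seed = 1), "zero")
})

test_that("dense suppression produces the configured sparse:dense density ratio", {
  cfg <- simulationConfig()
  prof <- crossoverWeightProfile(cfg)
  pos <- sampleCrossoverPositions(prof, 1e5, seed = 7)
  rs <- regionTable(configRegions(cfg))
  hit <- vapply(seq_len(nrow(rs)), function(i)
    sum(pos >= rs$start[i] & pos < rs$end[i]), numeric(1))
  sp <- rs$class == "sparse"
  densSparse <- sum(hit[sp]) / sum(rs$lengthMb[sp])
  densDense <- sum(hit[!sp]) / sum(rs$lengthMb[!sp])
  expect_lt(abs(densSparse / densDense - 3.4), 0.15)
})

test_that("no generations or no crossovers give pure parental chromosomes", {
  cfg0 <- smallConfig(generations = 0L)
  co0 <- simulateGenerations(cfg0, seed = 2)
  expect_true(all(vapply(co0@chromosomes, function(ch)
    length(ch$brk) == 0L && ch$org == 2L, logical(1))))

  cfg1 <- smallConfig(meanCosPerMeiosis = 0)
  co1 <- simulateGenerations(cfg1, seed = 2)
  expect_true(all(vapply(co1@chromosomes, function(ch)
    length(unique(ch$org)) == 1L, logical(1))))
})

test_that("population extinction is rejected", {
  expect_error(simulateGenerations(smallConfig(popSize = 0L), seed = 1),
               "extinction")
})

test_that("simulation is reproducible bit-for-bit given (config, seed)", {
  cfg <- smallConfig()
  a <- simulateGenerations(cfg, seed = 42)
  b <- simulateGenerations(cfg, seed = 42)
  expect_identical(a@chromosomes, b@chromosomes)
  pa <- buildParentalSnps(cfg, seed = 9)
  pb <- buildParentalSnps(cfg, seed = 9)
  expect_identical(pa@positions, pb@positions)
  expect_identical(pa@hiAllele, pb@hiAllele)
})

test_that("lineage records about five crossover events over the design", {
  # ~10 female-line transmissions x 0.5 kept crossovers each
  cfg <- simulationConfig()
  means <- vapply(1:6, function(s) {
    co <- simulateGenerations(cfg, seed = 100 + s)
    nrow(truthCrossoverEvents(co)) / length(co)
  }, numeric(1))
  expect_gt(mean(means), 4)
  expect_lt(mean(means), 6)
})

test_that("truth tracts tile the chromosome with alternating origins", {
  cfg <- smallConfig()
  co <- simulateGenerations(cfg, seed = 13)
  for (ch in co@chromosomes[1:20]) {
    expect_equal(length(ch$org), length(ch$brk) + 1L)
    if (length(ch$brk)) {
      expect_true(all(diff(ch$brk) > 0))
      expect_true(all(ch$brk > 0 & ch$brk < cfg@chromLen))
      expect_true(all(ch$org[-1L] != ch$org[-length(ch$org)]))
    }
  }
})

test_that("phenotypes with no effects carry no pool signal", {
  cfg <- smallConfig(effectSizes = c(C = 0, D = 0))
  co <- simulateGenerations(cfg, seed = 21)
  fr <- vapply(co@chromosomes, crossoverBSA:::.truthHiFrac, numeric(1),
               a = 13.9e6, b = 16.5e6, chromLen = cfg@chromLen)
  pvals <- vapply(1:200, function(s) {
    ph <- selectExtremePools(simulatePhenotypes(co, cfg, seed = 1000 + s),
                             cfg@poolSize)
    hi <- fr[ph$pool == "high"]
    lo <- fr[ph$pool == "low"]
    suppressWarnings(wilcox.test(hi, lo, exact = FALSE)$p.value)
  }, numeric(1))
  # with no causal effect the pool comparison is a null test: its p-values
  # are roughly uniform, so the 5% rejection rate is honoured
  expect_gt(mean(pvals < 0.05), 0.002)
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.60)
})

test_that("noiseless phenotypes are monotone in causal Hi fraction", {
  cfg <- smallConfig(activitySd = 0, causalRegions = "C",
                     effectSizes = c(C = 1000))
  co <- simulateGenerations(cfg, seed = 22)
  ph <- simulatePhenotypes(co, cfg, seed = 1)
  fr <- vapply(co@chromosomes, crossoverBSA:::.truthHiFrac, numeric(1),
               a = 13.9e6, b = 16.5e6, chromLen = cfg@chromLen)
  expect_true(all(diff(ph$activity[order(fr)]) >= -1e-9))
  expect_equal(cor(fr, ph$activity), 1)
})

test_that("default calibration separates extreme pools by an order of magnitude", {
  cfg <- simulationConfig()
  co <- simulateGenerations(cfg, seed = 23)
  ph <- selectExtremePools(simulatePhenotypes(co, cfg, seed = 24),
                           cfg@poolSize)
  mLow <- mean(ph$activity[ph$pool == "low"])
  mHigh <- mean(ph$activity[ph$pool == "high"])
  expect_gt(mLow, 50);  expect_lt(mLow, 500)
  expect_gt(mHigh, 1000); expect_lt(mHigh, 2500)
})

test_that("genotyping noise model behaves as configured", {
  cfg <- smallConfig()
  co <- simulateGenerations(cfg, seed = 31)
  ph <- buildParentalSnps(cfg, seed = 32)
  flies <- 1:20

  clean <- genotypeCohort(co, ph, smallConfig(dropoutProb = 0,
                                              genotypeErrorProb = 0),
                          seed = 33, flies = flies)
  truthAllele <- vapply(flies, function(j) {
    ch <- co@chromosomes[[j]]
    org <- ch$org[findInterval(ph@positions, ch$brk) + 1L]
    ifelse(org == 1L, "1", "0")
  }, character(length(ph@positions)))
  expect_identical(unname(clean@flyGT), unname(truthAllele))

  gone <- genotypeCohort(co, ph, smallConfig(dropoutProb = 1),
                         seed = 33, flies = flies)
  expect_true(all(gone@flyGT == "."))

  err <- genotypeCohort(co, ph, smallConfig(dropoutProb = 0,
                                            genotypeErrorProb = 0.02),
                        seed = 34, flies = flies)
  mismatch <- mean(err@flyGT != truthAllele)
  n <- length(truthAllele)
  expect_lt(abs(mismatch - 0.02), 4 * sqrt(0.02 * 0.98 / n))
})

test_that("extreme pools are the order statistics of activity", {
  set.seed(5)
  ph <- data.frame(flyId = sprintf("f%03d", 1:788),
                   activity = runif(788, 0, 2000))
  pools <- selectExtremePools(ph, 45L)
  expect_equal(sum(pools$pool == "low"), 45L)
  expect_equal(sum(pools$pool == "high"), 45L)
  expect_length(intersect(pools$flyId[pools$pool == "low"],
                          pools$flyId[pools$pool == "high"]), 0L)
  o <- order(ph$activity)
  expect_setequal(pools$flyId[pools$pool == "low"], ph$flyId[o[1:45]])
  expect_setequal(pools$flyId[pools$pool == "high"], ph$flyId[o[744:788]])

  tied <- data.frame(flyId = sprintf("f%02d", 1:30), activity = 7)
  p1 <- selectExtremePools(tied, 5L)
  expect_equal(p1$flyId[p1$pool == "low"], sprintf("f%02d", 1:5))
  expect_equal(p1$flyId[p1$pool == "high"], sprintf("f%02d", 26:30))
  expect_error(selectExtremePools(tied[1:9, ], 5L), "too few")
})
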