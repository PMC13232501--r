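test_that("density segmentation finds dense blocks and degenerate cases", {
  # uniform low density: no dense region
  set.seed(1)
  lowPos <- sort(runif(400, 0, 1e6))
  rsLow <- segmentByDensity(lowPos, window = 1e5, denseThreshold = 10,
                            chromLen = 1e6)
  expect_equal(regionTable(rsLow)$class, "sparse")

  # one site: a single sparse region spanning the chromosome
  rs1 <- segmentByDensity(5e5, window = 1e5, chromLen = 1e6)
  expect_equal(regionTable(rs1)$start, 0)
  expect_equal(regionTable(rs1)$end, 1e6)
  expect_equal(regionTable(rs1)$class, "sparse")

  expect_error(segmentByDensity(numeric(0), chromLen = 1e6), "empty")
  expect_error(segmentByDensity(1:10, window = 5e3, chromLen = 1e6),
               "10 kb")
})

test_that("segmentation recovers the generator's dense regions within one window", {
  cfg <- simulationConfig()
  ph <- buildParentalSnps(cfg, seed = 91)
  co <- simulateGenerations(cfg, seed = 92)
  calls <- genotypeCohort(co, ph, cfg, seed = 93, flies = 1:2)
  sites <- selectInformativeSites(calls)
  rs <- segmentByDensity(sites, window = 1e5, denseThreshold = 10)
  found <- regionTable(rs)
  found <- found[found$class == "dense", ]
  truth <- cfg@denseRegions
  expect_equal(nrow(found), nrow(truth))
  expect_true(all(abs(found$start - truth$start) <= 1e5))
  expect_true(all(abs(found$end - truth$end) <= 1e5))
  expect_equal(found$label, truth$label)
})

test_that("crossover counting localises switches by flanking-interval midpoint", {
  pos <- c(0.5e6, 0.9e6, 1.1e6, 1.5e6)
  p <- paintFromLabels(c("Hi", "Hi", "Lo", "Lo"), pos, 2e6)
  expect_equal(countCrossovers(p, 0, 2e6), 1L)
  expect_equal(countCrossovers(p, 0, 1e6), 0L)   # midpoint 1.0 Mb: right
  expect_equal(countCrossovers(p, 1e6, 2e6), 1L)
  single <- paintFromLabels(rep("Hi", 4), pos, 2e6)
  expect_equal(countCrossovers(single, 0, 2e6), 0L)
  expect_error(countCrossovers(p, -1, 5e6), "outside")
})

test_that("flanking inference detects odd crossover counts in the gap", {
  pos <- c(1e5, 2e5, 8e5, 9e5)
  left <- c(0, 3e5)
  right <- c(7e5, 1e6)
  p10 <- paintFromLabels(c("Hi", "Hi", "Lo", "Lo"), pos, 1e6)
  expect_equal(inferFlankingCrossover(p10, left, right), 1L)
  p00 <- paintFromLabels(c("Hi", "Hi", "Hi", "Hi"), pos, 1e6)
  expect_equal(inferFlankingCrossover(p00, left, right), 0L)
  pNA <- paintFromLabels(c("Hi", "Hi", "Missing", "Missing"), pos, 1e6)
  expect_true(is.na(inferFlankingCrossover(pNA, left, right)))
})

test_that("flanking inference on simulation is a lower bound with parity equality", {
  cfg <- smallConfig(dropoutProb = 0, genotypeErrorProb = 0)
  ph <- buildParentalSnps(cfg, seed = 96)
  co <- simulateGenerations(cfg, seed = 97)
  calls <- genotypeCohort(co, ph, cfg, seed = 98, flies = 1:60)
  pts <- paintCohort(calls, selectInformativeSites(calls), k = 1L)
  dr <- cfg@denseRegions
  cRow <- dr[dr$label == "C", ]
  dRow <- dr[dr$label == "D", ]
  gapCounts <- vapply(co@chromosomes[1:60], function(ch)
    sum(ch$brk >= cRow$end & ch$brk < dRow$start), numeric(1))
  inferred <- vapply(pts, inferFlankingCrossover, integer(1),
                     left = c(cRow$start, cRow$end),
                     right = c(dRow$start, dRow$end))
  ok <- !is.na(inferred)
  expect_lte(sum(inferred[ok]), sum(gapCounts[ok]))
  # parity: inference equals the oddness of the true breakpoint count
  # between the two usable flanking sites it actually compared
  for (j in which(ok)) {
    us <- crossoverBSA:::.usableSites(pts[[j]])
    pL <- max(us$pos[us$pos >= cRow$start & us$pos < cRow$end])
    pR <- min(us$pos[us$pos >= dRow$start & us$pos < dRow$end])
    between <- sum(co@chromosomes[[j]]$brk > pL &
                     co@chromosomes[[j]]$brk <= pR)
    expect_equal(unname(inferred[j]), as.integer(between %% 2 == 1))
  }
})

test_that("per-meiosis rates reproduce the printed normalisation arithmetic", {
  expect_equal(perMeiosisRate(10, 0.4, 84, 5), 0.0595238, tolerance = 1e-5)
  expect_equal(perMeiosisRate(23, 2.6, 84, 5), 0.0210623, tolerance = 1e-5)
  expect_equal(perMeiosisRate(0, 1.7, 84, 5), 0)
  expect_error(perMeiosisRate(3, 0), "length")
  # rates scale inversely with each denominator
  expect_equal(perMeiosisRate(7, 1.3, 168, 5),
               perMeiosisRate(7, 1.3, 84, 5) / 2)
  expect_equal(perMeiosisRate(7, 1.3, 84, 10),
               perMeiosisRate(7, 1.3, 84, 5) / 2)
})

test_that("bootstrap CI is degenerate at zero and contains the point estimate", {
  expect_equal(bootstrapCI(rep(0L, 30), 0.4, B = 200, seed = 1), c(0, 0))
  expect_error(bootstrapCI(integer(0), 1), "at least one")
  expect_error(bootstrapCI(c(1L, 2L), 1, B = 0), "B must")
  set.seed(7)
  for (i in 1:100) {
    counts <- rpois(sample(10:80, 1), runif(1, 0.1, 2))
    L <- runif(1, 0.3, 3)
    est <- perMeiosisRate(sum(counts), L, length(counts), 5)
    ci <- bootstrapCI(counts, L, length(counts), 5, B = 400, seed = i)
    expect_lte(ci[1], est + 1e-12)
    expect_gte(ci[2], est - 1e-12)
  }
})

test_that("exact conditional test matches enumeration and poisson.test", {
  # oracle agreement on a grid, and the independent stats implementation
  set.seed(11)
  for (i in 1:200) {
    N <- sample(1:150, 1)
    c1 <- sample(0:N, 1)
    l1 <- runif(1, 0.2, 5)
    l2 <- runif(1, 0.2, 5)
    p <- exactConditionalRateTest(c1, l1, N - c1, l2)$p.value
    expect_equal(p, binomEnumOracle(c1, N, l1 / (l1 + l2)),
                 tolerance = 1e-12)
    expect_equal(p, stats::poisson.test(c(c1, N - c1),
                                        c(l1, l2))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("exact conditional test is symmetric and handles boundaries", {
  a <- exactConditionalRateTest(23, 2.6, 10, 0.4)$p.value
  b <- exactConditionalRateTest(10, 0.4, 23, 2.6)$p.value
  expect_equal(a, b, tolerance = 1e-12)
  # observed equals the conditional expectation
  expect_equal(exactConditionalRateTest(5, 1, 5, 1)$p.value, 1)
  expect_warning(p0 <- exactConditionalRateTest(0, 1, 0, 1)$p.value,
                 "both counts zero")
  expect_equal(p0, 1)
  expect_error(exactConditionalRateTest(-1, 1, 2, 1), "non-negative")
  expect_error(exactConditionalRateTest(1, 0, 2, 1), "positive")
})

test_that("rate table assembles counts, CIs and tests per region", {
  pos <- seq(5e4, 2.95e6, by = 5e4)
  labels <- ifelse(pos < 1.5e6, "Hi", "Lo")
  p1 <- paintFromLabels(labels, pos, 3e6, flyId = "a")
  p2 <- paintFromLabels(rep("Hi", length(pos)), pos, 3e6, flyId = "b")
  rs <- new("RegionSet",
            regions = data.frame(
              label = c("A", "gap", "B"),
              start = c(0, 1.2e6, 1.8e6),
              end = c(1.2e6, 1.8e6, 3e6),
              class = c("dense", "sparse", "dense")),
            chromLen = 3e6)
  rt <- crossoverRateTable(list(a = p1, b = p2), rs, nFlies = 2,
                           nMeioses = 5, B = 200, seed = 3)
  tab <- rt$table
  expect_equal(tab$count[tab$region == "A-B gap"], 1)
  expect_equal(tab$count[tab$region == "A"], 0)
  expect_equal(rt$nEvaluable, 2)
  expect_equal(tab$rate,
               tab$count / tab$lengthMb / 2 / 5)
  expect_true(all(tab$ciLo <= tab$rate + 1e-12 &
                    tab$rate <= tab$ciHi + 1e-12))
})

test_that("rate-ratio contrast reports full and printed precision", {
  rr <- rateRatioContrast(10, 0.4, c(23, 11), c(2.6, 1.9))
  expect_equal(rr$ratio, (10 / 0.4) / (34 / 4.5), tolerance = 1e-12)
  expect_equal(rr$ratioPrintedPrecision, rr$ratio, tolerance = 1e-12)
  rr2 <- rateRatioContrast(10, 0.44, c(23, 11), c(2.64, 1.92))
  expect_equal(rr2$ratioPrintedPrecision,
               (10 / 0.4) / (34 / (2.6 + 1.9)), tolerance = 1e-12)
})

test_that("log-basic ratio bootstrap falls back gracefully", {
  set.seed(4)
  s <- rpois(50, 0.5)
  d <- rpois(50, 1)
  rr <- bootstrapRateRatio(s, d, 1, 2, B = 500, seed = 5)
  expect_equal(rr$method, "logbasic")
  expect_lte(rr$ci[1], rr$ratio)
  expect_gte(rr$ci[2], rr$ratio)
  rr0 <- bootstrapRateRatio(rep(0L, 20), rpois(20, 1), 1, 2, B = 200,
                            seed = 6)
  expect_equal(rr0$ratio, 0)
  expect_equal(rr0$method, "percentile")
})
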