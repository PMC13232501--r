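test_that("informative sites require fixed, divergent parental genotypes", {
  gt <- cbind(Hi1 = c("A/A", "A/A", "A/A"),
              Lo1 = c("G/G", "G/G", "A/A"))
  roles <- c(Hi1 = "hi", Lo1 = "lo")
  s <- selectInformativeSites(gt, roles, positions = c(100, 200, 300),
                              chromLen = 1000)
  expect_equal(sitePositions(s), c(100, 200))

  # a heterozygous call in one Lo sample drops the site and is counted in QC
  gt2 <- cbind(Hi1 = c("A/A", "A/A"), Lo1 = c("G/G", "A/G"),
               Lo2 = c("G/G", "A/A"))
  roles2 <- c(Hi1 = "hi", Lo1 = "lo", Lo2 = "lo")
  s2 <- selectInformativeSites(gt2, roles2, positions = c(10, 20),
                               chromLen = 100)
  expect_equal(sitePositions(s2), 10)
  expect_equal(qcStats(s2)$hetFracLo, 0.5)
  expect_equal(qcStats(s2)$hetFracHi, 0)

  expect_error(selectInformativeSites(gt, c(Hi1 = "hi", Lo1 = "hi"),
                                      positions = c(1, 2, 3),
                                      chromLen = 10),
               "parental sample per line")
})

test_that("informative-site selection recovers the generator truth mask", {
  cfg <- smallConfig()
  ph <- buildParentalSnps(cfg, seed = 41)
  co <- simulateGenerations(cfg, seed = 42)
  calls <- genotypeCohort(co, ph, cfg, seed = 43, flies = 1:5)
  sites <- selectInformativeSites(calls)
  truthInf <- !ph@hetHi & !ph@hetLo
  expect_identical(sitePositions(sites), ph@positions[truthInf])
  expect_equal(qcStats(sites)$hetFracHi, mean(ph@hetHi))
  expect_equal(qcStats(sites)$hetFracLo, mean(ph@hetLo))
})

test_that("site origin labels follow the allele matching rules", {
  s <- makeSites(c(10, 20, 30, 40))
  expect_equal(as.character(assignSiteOrigins(c("1", "1", "1", "1"), s)),
               rep("Hi", 4))
  expect_equal(as.character(assignSiteOrigins(rep(".", 4), s)),
               rep("Missing", 4))
  mixed <- assignSiteOrigins(c("1", "0", "2", "."), s)
  expect_equal(as.character(mixed), c("Hi", "Lo", "Unique", "Missing"))
  expect_error(assignSiteOrigins(c(`999` = "1"), s), "absent")
})

test_that("error-free flies are labelled by their truth tract at every site", {
  cfg <- smallConfig(dropoutProb = 0, genotypeErrorProb = 0)
  ph <- buildParentalSnps(cfg, seed = 51)
  co <- simulateGenerations(cfg, seed = 52)
  calls <- genotypeCohort(co, ph, cfg, seed = 53, flies = 1:10)
  sites <- selectInformativeSites(calls)
  idx <- match(sitePositions(sites), calls@positions)
  for (j in 1:10) {
    lab <- assignSiteOrigins(calls@flyGT[idx, j], sites)
    ch <- co@chromosomes[[j]]
    truth <- c("Hi", "Lo")[ch$org[findInterval(sitePositions(sites),
                                               ch$brk) + 1L]]
    expect_identical(as.character(lab), truth)
  }
})

test_that("nearest-site interpolation assigns midpoints to the left label", {
  p <- paintFromLabels(c("Hi", "Lo"), c(1e5, 5e5), 1e6)
  originAt <- function(p, x)
    p@tractOrigin[findInterval(x, p@tractStart)]
  expect_equal(originAt(p, 250000), "Hi")
  expect_equal(originAt(p, 400000), "Lo")
  expect_equal(originAt(p, 300000), "Hi")   # exact midpoint: left
  expect_equal(originAt(p, 300001), "Lo")
  expect_equal(originAt(p, 0), "Hi")        # ends inherit inward
  expect_equal(originAt(p, 999999), "Lo")
})

test_that("painting with no usable label is wholly Unknown", {
  p <- paintFromLabels(c("Missing", "Unique"), c(100, 200), 1000)
  expect_equal(p@tractOrigin, "Unknown")
  expect_equal(p@tractStart, 0)
  expect_equal(p@tractEnd, 1000)
})

test_that("smoothing removes short discordant runs and k = 1 is the identity", {
  lab <- factor(c(rep("Hi", 10), "Lo", rep("Hi", 10)),
                levels = c("Hi", "Lo", "Unique", "Missing"))
  expect_identical(smoothSiteLabels(lab, 1L), lab)
  sm <- smoothSiteLabels(lab, 3L)
  expect_equal(as.character(sm), rep("Hi", 21))
  p <- interpolateOrigins(sm, seq(1000, 21000, by = 1000), 30000)
  expect_equal(p@tractOrigin, "Hi")
  # end runs are never reassigned
  lab2 <- factor(c("Lo", rep("Hi", 10)),
                 levels = c("Hi", "Lo", "Unique", "Missing"))
  expect_identical(smoothSiteLabels(lab2, 3L), lab2)
})

test_that("smoothing suppresses genotype-error tracts by over an order of magnitude", {
  cfg <- smallConfig(dropoutProb = 0, genotypeErrorProb = 0.02)
  ph <- buildParentalSnps(cfg, seed = 61)
  co <- simulateGenerations(cfg, seed = 62)
  calls <- genotypeCohort(co, ph, cfg, seed = 63, flies = 1:10)
  sites <- selectInformativeSites(calls)
  truthSwitches <- vapply(co@chromosomes[1:10], function(ch)
    length(ch$brk), numeric(1))
  spurious <- function(k) {
    pts <- paintCohort(calls, sites, k = k)
    painted <- vapply(pts, function(p)
      countCrossovers(p, 0, cfg@chromLen), integer(1))
    sum(pmax(painted - truthSwitches, 0))
  }
  s1 <- spurious(1L)
  s3 <- spurious(3L)
  expect_gt(s1, 0)
  expect_gte(s1 / max(s3, 1), 10)
})

test_that("painting is idempotent on its own implied calls", {
  cfg <- smallConfig()
  ph <- buildParentalSnps(cfg, seed = 71)
  co <- simulateGenerations(cfg, seed = 72)
  calls <- genotypeCohort(co, ph, cfg, seed = 73, flies = 1:5)
  sites <- selectInformativeSites(calls)
  idx <- match(sitePositions(sites), calls@positions)
  for (j in 1:5) {
    p1 <- paintChromosome(calls@flyGT[idx, j], sites, k = 5L)
    lab <- as.character(p1@labels)
    implied <- ifelse(lab == "Hi", "1", ifelse(lab == "Lo", "0", "."))
    p2 <- paintChromosome(implied, sites, k = 1L)
    expect_identical(p2@tractStart, p1@tractStart)
    expect_identical(p2@tractOrigin, p1@tractOrigin)
  }
})

test_that("adding Missing calls never changes the tracts", {
  pos <- c(1e5, 2e5, 3e5, 4e5, 5e5)
  s5 <- makeSites(pos, 6e5)
  p1 <- paintFromLabels(c("Hi", "Hi", "Lo", "Lo", "Hi"), pos, 6e5)
  pos2 <- sort(c(pos, 150000, 250000, 450000))
  lab2 <- rep("Missing", 8)
  lab2[match(pos, pos2)] <- c("Hi", "Hi", "Lo", "Lo", "Hi")
  p2 <- paintFromLabels(lab2, pos2, 6e5)
  expect_identical(p1@tractStart, p2@tractStart)
  expect_identical(p1@tractOrigin, p2@tractOrigin)
})

test_that("noise-free painting matches truth switches up to parity losses", {
  cfg <- smallConfig(dropoutProb = 0, genotypeErrorProb = 0)
  ph <- buildParentalSnps(cfg, seed = 81)
  co <- simulateGenerations(cfg, seed = 82)
  calls <- genotypeCohort(co, ph, cfg, seed = 83, flies = 1:50)
  sites <- selectInformativeSites(calls)
  pts <- paintCohort(calls, sites, k = 1L)
  pos <- sitePositions(sites)
  for (j in 1:50) {
    ch <- co@chromosomes[[j]]
    painted <- countCrossovers(pts[[j]], 0, cfg@chromLen)
    truth <- length(ch$brk)
    expect_lte(painted, truth)
    # equality whenever consecutive truth breakpoints are separated by a site
    gaps <- c(0, ch$brk, cfg@chromLen)
    sitesBetween <- vapply(seq_len(length(gaps) - 1L), function(i)
      sum(pos >= gaps[i] & pos < gaps[i + 1L]), numeric(1))
    if (all(sitesBetween >= 1L))
      expect_equal(painted, truth)
  }
})
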