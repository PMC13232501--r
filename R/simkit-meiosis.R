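.emptyLin <- function() matrix(numeric(0), ncol = 2L,
                               dimnames = list(NULL, c("pos", "gen")))

#' Crossover placement weight profile of a configuration
#'
#' Piecewise-constant placement weights: 1 in SNP-sparse intervals,
#' 1/suppressionFactor inside SNP-dense blocks, reflecting suppression of
#' crossover placement where the homologues are divergent.
#'
#' @param config a [SimulationConfig-class].
#' @param suppressionFactor override for the configured factor.
#' @return data.frame with columns start, end, weight.
#' @export
crossoverWeightProfile <- function(config,
                                   suppressionFactor = config@suppressionFactor) {
  rs <- configRegions(config)@regions
  data.frame(start = rs$start, end = rs$end,
             weight = ifelse(rs$class == "dense", 1 / suppressionFactor, 1))
}

#' Sample crossover positions under a density-bias profile
#'
#' Positions are i.i.d. with density proportional to the piecewise-constant
#' weight profile.
#'
#' @param profile data.frame(start, end, weight), disjoint sorted intervals.
#' @param n number of positions to draw.
#' @param seed RNG seed (NULL advances the current stream).
#' @return sorted numeric vector of n bp positions.
#' @export
sampleCrossoverPositions <- function(profile, n, seed = NULL) {
  stopifnot(all(c("start", "end", "weight") %in% names(profile)))
  if (any(profile$weight < 0))
    stop("weights must be non-negative")
  mass <- (profile$end - profile$start) * profile$weight
  total <- sum(mass)
  if (total <= 0)
    stop("all-zero weight profile")
  withSeed(seed, {
    u <- runif(n, 0, total)
    cum <- cumsum(mass)
    seg <- findInterval(u, cum) + 1L
    before <- c(0, cum)[seg]
    sort(profile$start[seg] + (u - before) / profile$weight[seg])
  })
}

# Female meiosis: produce one gamete from the two maternal X chromosomes.
# `kept` are the crossover positions carried by the transmitted chromatid;
# `startFrom` is the haplotype at the left telomere. Crossover events in
# the ancestry of the transmitted material are carried along in `lin`.
.gamete <- function(x1, x2, kept, startFrom, gen, chromLen) {
  if (!length(kept)) {
    return(if (startFrom == 1L) x1 else x2)
  }
  srcs <- rep(c(startFrom, 3L - startFrom), length.out = length(kept) + 1L)
  segStart <- c(0, kept)
  segEnd <- c(kept, chromLen)
  orgAll <- integer(0)
  brkAll <- numeric(0)
  linKeep <- vector("list", length(srcs) + 1L)
  for (i in seq_along(srcs)) {
    x <- if (srcs[i] == 1L) x1 else x2
    a <- segStart[i]
    b <- segEnd[i]
    ia <- findInterval(a, x$brk) + 1L
    ib <- findInterval(b, x$brk, left.open = TRUE) + 1L
    if (i > 1L)
      brkAll <- c(brkAll, a)
    if (ib > ia)
      brkAll <- c(brkAll, x$brk[ia:(ib - 1L)])
    orgAll <- c(orgAll, x$org[ia:ib])
    if (nrow(x$lin)) {
      sel <- x$lin[, 1L] >= a & x$lin[, 1L] < b
      if (any(sel))
        linKeep[[i]] <- x$lin[sel, , drop = FALSE]
    }
  }
  keep <- diff(orgAll) != 0L
  linKeep[[length(srcs) + 1L]] <-
    cbind(pos = kept, gen = rep(as.numeric(gen), length(kept)))
  list(brk = brkAll[keep],
       org = c(orgAll[1L], orgAll[-1L][keep]),
       lin = do.call(rbind, linKeep[!vapply(linKeep, is.null, logical(1))]))
}

#' Forward-simulate the free-intermating design
#'
#' Founds the population with pure Hi females and pure Lo males, then
#' intermates randomly for the configured number of discrete non-overlapping
#' generations. Only females recombine: the crossover count per X bivalent is
#' Poisson(\code{meanCosPerMeiosis}), each crossover lands on the transmitted
#' chromatid with probability 1/2, and positions follow the suppression
#' weight profile. Males transmit their single X intact to daughters. The
#' final generation yields the assayed males.
#'
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed.
#' @return a [SimulatedCohort-class] of \code{nAssayedMales} truth-tagged
#'   male X chromosomes.
#' @examples
#' cfg <- simulationConfig(generations = 3L, popSize = 60L,
#'                         nAssayedMales = 30L)
#' cohort <- simulateGenerations(cfg, seed = 1)
#' cohort
#' @export
simulateGenerations <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (config@generations > 0L && config@popSize < 2L)
    stop("population extinction: popSize must be >= 2 when generations > 0")
  if (config@nFounderHiFemales < 1L || config@nFounderLoMales < 1L)
    stop("population extinction: need founders of both sexes")
  withSeed(seed, {
    profile <- crossoverWeightProfile(config)
    hiX <- list(brk = numeric(0), org = .ORIGIN_HI, lin = .emptyLin())
    loX <- list(brk = numeric(0), org = .ORIGIN_LO, lin = .emptyLin())
    females <- rep(list(list(hiX, hiX)), config@nFounderHiFemales)
    maleXs <- rep(list(loX), config@nFounderLoMales)
    if (config@generations == 0L) {
      idx <- sample.int(length(maleXs), config@nAssayedMales, replace = TRUE)
      out <- maleXs[idx]
      names(out) <- sprintf("fly%04d", seq_along(out))
      return(new("SimulatedCohort", chromosomes = out, config = config))
    }
    for (g in seq_len(config@generations)) {
      last <- g == config@generations
      nOff <- if (last) config@nAssayedMales else config@popSize
      if (!length(females) || !length(maleXs))
        stop("population extinction: one sex died out at generation ", g)
      mothers <- sample.int(length(females), nOff, replace = TRUE)
      fathers <- sample.int(length(maleXs), nOff, replace = TRUE)
      isMale <- if (last) rep(TRUE, nOff) else runif(nOff) < 0.5
      keptN <- rbinom(nOff, rpois(nOff, config@meanCosPerMeiosis), 0.5)
      startF <- sample(c(1L, 2L), nOff, replace = TRUE)
      newFem <- vector("list", nOff)
      newMal <- vector("list", nOff)
      fi <- mi <- 0L
      for (i in seq_len(nOff)) {
        mom <- females[[mothers[i]]]
        kept <- if (keptN[i] > 0L)
          sampleCrossoverPositions(profile, keptN[i]) else numeric(0)
        gam <- .gamete(mom[[1L]], mom[[2L]], kept, startF[i], g,
                       config@chromLen)
        if (isMale[i]) {
          mi <- mi + 1L
          newMal[[mi]] <- gam
        } else {
          fi <- fi + 1L
          newFem[[fi]] <- list(gam, maleXs[[fathers[i]]])
        }
      }
      maleXs2 <- newMal[seq_len(mi)]
      if (last) {
        maleXs <- maleXs2
      } else {
        females <- newFem[seq_len(fi)]
        maleXs <- maleXs2
      }
    }
    names(maleXs) <- sprintf("fly%04d", seq_along(maleXs))
    new("SimulatedCohort", chromosomes = maleXs, config = config)
  })
}

#' Crossover-event history of each assayed chromosome
#'
#' @param cohort a [SimulatedCohort-class].
#' @return data.frame with columns flyId, pos, gen: every meiotic crossover
#'   event in the ancestry of the transmitted material of each male X.
#' @export
truthCrossoverEvents <- function(cohort) {
  ids <- .flyIds(cohort)
  pieces <- lapply(seq_along(cohort@chromosomes), function(i) {
    lin <- cohort@chromosomes[[i]]$lin
    if (!nrow(lin))
      return(NULL)
    data.frame(flyId = ids[i], pos = lin[, 1L], gen = lin[, 2L])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(flyId = character(0), pos = numeric(0),
                      gen = numeric(0))
  rownames(out) <- NULL
  out
}

# Hi-parentage fraction of a truth chromosome within [a, b)
.truthHiFrac <- function(chrom, a, b, chromLen) {
  bounds <- c(0, chrom$brk, chromLen)
  s <- pmax(utils::head(bounds, -1L), a)
  e <- pmin(bounds[-1L], b)
  w <- pmax(0, e - s)
  sum(w[chrom$org == .ORIGIN_HI]) / (b - a)
}

#' True per-region crossover counts of a cohort
#'
#' Counts truth tract boundaries (visible origin switches) per fly per
#' region; a boundary belongs to the region containing it.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param regions a [RegionSet-class] (default: the configured layout).
#' @return integer matrix, flies x regions.
#' @export
truthRegionCounts <- function(cohort, regions = configRegions(cohort@config)) {
  r <- regions@regions
  out <- matrix(0L, nrow = length(cohort@chromosomes), ncol = nrow(r),
                dimnames = list(.flyIds(cohort), r$label))
  for (i in seq_along(cohort@chromosomes)) {
    b <- cohort@chromosomes[[i]]$brk
    if (!length(b))
      next
    for (j in seq_len(nrow(r)))
      out[i, j] <- sum(b >= r$start[j] & b < r$end[j])
  }
  out
}
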