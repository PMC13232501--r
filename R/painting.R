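#' Select informative SNPs from parental genotype calls
#'
#' A site is informative when it is homozygous in every Hi parental sample,
#' homozygous in every Lo parental sample, and the two lines carry different
#' alleles. Sites segregating within a line (any heterozygous or discordant
#' call) are dropped and counted in the QC statistics; sites with any
#' missing parental call are likewise unusable.
#'
#' @param calls a [GenotypeCalls-class], or a character matrix of diploid
#'   GT codes ("0/0", "0/1", "1/1", "./.", phased "|" accepted) with one
#'   column per parental sample.
#' @param roles for a matrix input: named character vector ("hi"/"lo") per
#'   sample column.
#' @param positions,chromLen for a matrix input: site positions (0-based bp)
#'   and chromosome length.
#' @return an [InformativeSiteSet-class]; alleles are GT index codes
#'   ("0"/"1").
#' @export
selectInformativeSites <- function(calls, roles = NULL, positions = NULL,
                                   chromLen = NULL) {
  if (is(calls, "GenotypeCalls")) {
    roles <- calls@parentalRoles
    positions <- calls@positions
    chromLen <- calls@chromLen
    gt <- calls@parentalGT
  } else {
    gt <- calls
  }
  stopifnot(is.matrix(gt), !is.null(roles), !is.null(positions),
            !is.null(chromLen))
  hiCols <- which(roles == "hi")
  loCols <- which(roles == "lo")
  if (!length(hiCols) || !length(loCols))
    stop("need at least one parental sample per line")
  al <- .splitDiploid(gt)
  hom <- al$a1 == al$a2 & al$a1 != "."
  homHi <- rowSums(!hom[, hiCols, drop = FALSE]) == 0L
  homLo <- rowSums(!hom[, loCols, drop = FALSE]) == 0L
  # unanimity within each line
  hiAllele <- al$a1[, hiCols[1L]]
  loAllele <- al$a1[, loCols[1L]]
  unanHi <- rowSums(al$a1[, hiCols, drop = FALSE] != hiAllele) == 0L
  unanLo <- rowSums(al$a1[, loCols, drop = FALSE] != loAllele) == 0L
  fixedHi <- homHi & unanHi
  fixedLo <- homLo & unanLo
  keep <- fixedHi & fixedLo & hiAllele != loAllele
  if (!any(keep))
    stop("zero informative sites retained")
  qc <- list(hetFracHi = mean(!fixedHi),
             hetFracLo = mean(!fixedLo),
             homPctHi = 100 * mean(fixedHi),
             homPctLo = 100 * mean(fixedLo),
             nInput = nrow(gt),
             nRetained = sum(keep))
  new("InformativeSiteSet",
      positions = as.numeric(positions[keep]),
      hiAllele = hiAllele[keep],
      loAllele = loAllele[keep],
      qc = qc,
      chromLen = as.numeric(chromLen))
}

.splitDiploid <- function(gt) {
  ok <- grepl("^[A-Za-z0-9.]+[/|][A-Za-z0-9.]+$", gt) | gt == "."
  if (!all(ok))
    stop("malformed diploid genotype: ", gt[which(!ok)[1L]])
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  a1[gt == "."] <- "."
  a2[gt == "."] <- "."
  dim(a1) <- dim(a2) <- dim(gt)
  list(a1 = a1, a2 = a2)
}

#' Label each informative site of a hemizygous fly by parental origin
#'
#' "Hi"/"Lo" when the haploid call matches that line's allele, "Missing"
#' when there is no call ("."), "Unique" when the call matches neither
#' parental allele.
#'
#' @param calls character vector of haploid GT codes aligned to
#'   \code{sites}, or named by position.
#' @param sites an [InformativeSiteSet-class].
#' @return factor of length \code{length(sites)} with levels
#'   Hi, Lo, Unique, Missing.
#' @export
assignSiteOrigins <- function(calls, sites) {
  stopifnot(is(sites, "InformativeSiteSet"))
  if (!is.null(names(calls))) {
    idx <- match(as.numeric(names(calls)), sites@positions)
    if (anyNA(idx))
      stop("call at position absent from site set: ",
           names(calls)[which(is.na(idx))[1L]])
    full <- rep(".", length(sites@positions))
    full[idx] <- calls
    calls <- full
  }
  if (length(calls) != length(sites@positions))
    stop("calls must align with the informative sites")
  lab <- rep("Unique", length(calls))
  lab[calls == "."] <- "Missing"
  lab[calls == sites@hiAllele] <- "Hi"
  lab[calls == sites@loAllele] <- "Lo"
  factor(lab, levels = .LABEL_LEVELS)
}

#' Smooth site labels by removing short discordant runs
#'
#' Within the subsequence of usable (Hi/Lo) labels, any run of one origin
#' shorter than \code{k} sites that is flanked on both sides by the opposite
#' origin is reassigned to the flanking origin. All maximal short interior
#' runs are flipped together, runs are re-merged, and the pass repeats until
#' a fixed point; \code{k = 1} is the identity. Chromosome-end runs are
#' never reassigned. Unique/Missing labels are transparent and unchanged.
#'
#' @param labels factor from [assignSiteOrigins()].
#' @param k minimum run length (informative sites) for a tract to survive.
#' @return factor of smoothed labels.
#' @export
smoothSiteLabels <- function(labels, k) {
  stopifnot(k >= 1L)
  if (k == 1L)
    return(labels)
  u <- which(labels %in% c("Hi", "Lo"))
  if (length(u) < 3L)
    return(labels)
  v <- as.character(labels[u])
  r <- rle(v)
  repeat {
    nr <- length(r$lengths)
    if (nr < 3L)
      break
    short <- which(r$lengths < k)
    short <- short[short > 1L & short < nr]
    if (!length(short))
      break
    # flanking runs of an interior run always agree (labels are binary)
    r$values[short] <- r$values[short - 1L]
    r <- rle(inverse.rle(r))
  }
  labels[u] <- inverse.rle(r)
  labels
}

#' Interpolate parental origin across the whole chromosome
#'
#' Every base pair inherits the origin of the nearest usable (Hi/Lo)
#' labelled site by bp distance; exact midpoints go to the lower-coordinate
#' site. Unique and Missing sites are transparent; chromosome ends inherit
#' the nearest label inward. With no usable label the whole chromosome is
#' Unknown.
#'
#' @param labels factor from [assignSiteOrigins()] (optionally smoothed).
#' @param positions site positions aligned with \code{labels} (0-based bp).
#' @param chromLen chromosome length in bp.
#' @param flyId sample identifier stored in the result.
#' @param k smoothing parameter recorded in the result (bookkeeping only).
#' @param rawLabels optionally the pre-smoothing labels, for the record.
#' @return a [PaintedChromosome-class] whose tracts tile [0, chromLen).
#' @export
interpolateOrigins <- function(labels, positions, chromLen,
                               flyId = "fly", k = 1L, rawLabels = labels) {
  stopifnot(length(labels) == length(positions))
  u <- which(labels %in% c("Hi", "Lo"))
  if (!length(u)) {
    return(new("PaintedChromosome", flyId = flyId, chromLen = chromLen,
               positions = as.numeric(positions),
               rawLabels = factor(as.character(rawLabels), .LABEL_LEVELS),
               labels = factor(as.character(labels), .LABEL_LEVELS),
               tractStart = 0, tractEnd = chromLen,
               tractOrigin = "Unknown", k = as.integer(k)))
  }
  p <- positions[u]
  org <- as.character(labels[u])
  r <- rle(org)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  # boundary between run i and i+1: midpoint of the facing sites, ties left
  if (length(r$lengths) > 1L) {
    pl <- p[ends[-length(ends)]]
    pr <- p[starts[-1L]]
    bnd <- floor((pl + pr) / 2) + 1
  } else {
    bnd <- numeric(0)
  }
  new("PaintedChromosome", flyId = flyId, chromLen = chromLen,
      positions = as.numeric(positions),
      rawLabels = factor(as.character(rawLabels), .LABEL_LEVELS),
      labels = factor(as.character(labels), .LABEL_LEVELS),
      tractStart = c(0, bnd), tractEnd = c(bnd, chromLen),
      tractOrigin = r$values, k = as.integer(k))
}

#' Paint one fly's X chromosome
#'
#' Convenience wrapper: label sites, smooth, interpolate.
#'
#' @param calls haploid GT codes aligned to \code{sites}.
#' @param sites an [InformativeSiteSet-class].
#' @param k minimum informative-site run length kept by smoothing
#'   (default 5); 1 disables smoothing.
#' @param flyId sample identifier.
#' @return a [PaintedChromosome-class].
#' @export
paintChromosome <- function(calls, sites, k = 5L, flyId = "fly") {
  raw <- assignSiteOrigins(calls, sites)
  sm <- smoothSiteLabels(raw, k)
  interpolateOrigins(sm, sites@positions, sites@chromLen,
                     flyId = flyId, k = k, rawLabels = raw)
}

#' Paint every fly in a genotype call set
#'
#' @param calls a [GenotypeCalls-class].
#' @param sites an [InformativeSiteSet-class] (default: selected from the
#'   parental samples in \code{calls}).
#' @param k smoothing parameter, as in [paintChromosome()].
#' @return named list of [PaintedChromosome-class] objects.
#' @export
paintCohort <- function(calls, sites = selectInformativeSites(calls),
                        k = 5L) {
  idx <- match(sites@positions, calls@positions)
  if (anyNA(idx))
    stop("informative sites must be a subset of the call positions")
  out <- lapply(colnames(calls@flyGT), function(id)
    paintChromosome(calls@flyGT[idx, id], sites, k = k, flyId = id))
  names(out) <- colnames(calls@flyGT)
  out
}

#' Per-fly-by-site label matrix (the painting matrix)
#'
#' Rows are flies (ordered by decreasing activity when phenotypes are
#' given), columns are informative sites; entries are the raw site labels.
#'
#' @param paintings list of [PaintedChromosome-class].
#' @param phenotypes optional data.frame(flyId, activity) used to order rows.
#' @return character matrix.
#' @export
paintingMatrix <- function(paintings, phenotypes = NULL) {
  ids <- vapply(paintings, function(p) p@flyId, character(1))
  if (!is.null(phenotypes)) {
    ord <- order(-phenotypes$activity, phenotypes$flyId)
    ids <- intersect(phenotypes$flyId[ord], ids)
  }
  m <- do.call(rbind, lapply(ids, function(id)
    as.character(paintings[[id]]@rawLabels)))
  rownames(m) <- ids
  colnames(m) <- as.character(paintings[[ids[1L]]]@positions)
  m
}
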