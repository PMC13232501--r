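#' Write genotype calls as VCF 4.2
#'
#' One record per site (CHROM "X", POS 1-based), REF = Lo allele, ALT = Hi
#' allele, GT-only FORMAT. Parental samples come first with diploid
#' genotypes; recombinant males follow with haploid genotypes
#' ("0"/"1"/"."), matching a variant-calling run with sample ploidy 2 for
#' parents and 1 for hemizygous males.
#'
#' @param calls a [GenotypeCalls-class].
#' @param path output path.
#' @param contig contig name (default "X").
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(calls, path, contig = "X") {
  stopifnot(is(calls, "GenotypeCalls"))
  samples <- c(colnames(calls@parentalGT), colnames(calls@flyGT))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=crossoverBSA %s",
            as.character(utils::packageVersion("crossoverBSA"))),
    sprintf("##contig=<ID=%s,length=%d>", contig,
            as.integer(calls@chromLen)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gtCols <- cbind(calls@parentalGT, calls@flyGT)
  body <- paste(contig, format(calls@positions + 1, scientific = FALSE,
                               trim = TRUE),
                ".", calls@ref, calls@alt, ".", ".", ".", "GT",
                apply(gtCols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sample sheet naming parental and recombinant samples
#'
#' Two-column TSV (sample, role) with roles \code{parental_hi},
#' \code{parental_lo} or \code{recombinant}; VCF itself has no slot for
#' this metadata.
#'
#' @param calls a [GenotypeCalls-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(calls, path) {
  df <- data.frame(
    sample = c(colnames(calls@parentalGT), colnames(calls@flyGT)),
    role = c(ifelse(calls@parentalRoles == "hi", "parental_hi",
                    "parental_lo"),
             rep("recombinant", ncol(calls@flyGT))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype calls from VCF plus a sample sheet
#'
#' Reads a VCF 4.2 via \code{VariantAnnotation::readVcf} and classifies the
#' samples with the two-column sample sheet written by
#' [writeSampleSheet()]. Recombinant males must carry haploid GT codes
#' ("0", "1" or "."); a diploid call for a recombinant is an error, since
#' hemizygous males are genotyped at ploidy 1 while parental females are
#' genotyped at ploidy 2.
#'
#' @param path VCF path.
#' @param sampleSheet sample sheet path.
#' @return a [GenotypeCalls-class].
#' @export
readGenotypeVcf <- function(path, sampleSheet) {
  if (!file.exists(path))
    stop("VCF not found: ", path)
  if (!file.exists(sampleSheet))
    stop("sample sheet not found: ", sampleSheet)
  sheet <- utils::read.delim(sampleSheet, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "role") %in% names(sheet)))
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "custom")),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e)))
  gt <- VariantAnnotation::geno(vcf)$GT
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf)) - 1
  refA <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  altA <- vapply(seq_along(altList), function(i) {
    a <- as.character(altList[[i]])
    if (length(a)) a[1L] else "."
  }, character(1))
  chromLen <- {
    sl <- GenomeInfoDb::seqlengths(vcf)
    if (length(sl) && !is.na(sl[1L])) as.numeric(sl[1L])
    else max(pos) + 1
  }
  roleOf <- stats::setNames(sheet$role, sheet$sample)
  missing <- setdiff(colnames(gt), names(roleOf))
  if (length(missing))
    stop("samples absent from sample sheet: ",
         paste(missing, collapse = ", "))
  rec <- colnames(gt)[roleOf[colnames(gt)] == "recombinant"]
  par <- colnames(gt)[roleOf[colnames(gt)] %in%
                        c("parental_hi", "parental_lo")]
  flyGT <- gt[, rec, drop = FALSE]
  badPloidy <- matrix(grepl("[/|]", flyGT), nrow = nrow(flyGT))
  if (any(badPloidy)) {
    i <- which(badPloidy, arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0(
      "diploid genotype '%s' for recombinant sample '%s' at record %d: ",
      "recombinant males are hemizygous and must be called at ",
      "sample ploidy 1 (haploid GT), parental females at ploidy 2"),
      flyGT[i[1L], i[2L]], rec[i[2L]], i[1L]))
  }
  parentalGT <- gt[, par, drop = FALSE]
  roles <- ifelse(roleOf[par] == "parental_hi", "hi", "lo")
  names(roles) <- par
  dimnames(flyGT) <- list(NULL, rec)
  dimnames(parentalGT) <- list(NULL, par)
  new("GenotypeCalls", positions = as.numeric(pos), ref = refA, alt = altA,
      flyGT = flyGT, parentalGT = parentalGT, parentalRoles = roles,
      chromLen = chromLen)
}

#' Write parentage tracts as BED
#'
#' BED4+1 (0-based half-open): chrom, start, end, origin, fly_id.
#'
#' @param paintings list of [PaintedChromosome-class], or a
#'   [SimulatedCohort-class] (truth tracts).
#' @param path output path.
#' @param header optional comment lines prepended to the file.
#' @param contig contig name.
#' @return \code{path}, invisibly.
#' @export
writeTractsBed <- function(paintings, path, header = character(0),
                           contig = "X") {
  if (is(paintings, "SimulatedCohort")) {
    gr <- tracts(paintings)
    df <- data.frame(chrom = contig,
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     origin = gr$origin, fly_id = gr$flyId)
  } else {
    df <- do.call(rbind, lapply(paintings, function(p)
      data.frame(chrom = contig, start = p@tractStart, end = p@tractEnd,
                 origin = p@tractOrigin, fly_id = p@flyId)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(header, con)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write / read a region set as BED
#'
#' BED4+1: chrom, start, end, label, class. Reading uses
#' \code{rtracklayer::import} with an extra class column.
#'
#' @param regions a [RegionSet-class].
#' @param path file path.
#' @param contig contig name.
#' @param chromLen chromosome length for the reader (defaults to the last
#'   region end).
#' @return the writer returns \code{path} invisibly; the reader a
#'   [RegionSet-class].
#' @export
writeRegionsBed <- function(regions, path, contig = "X") {
  r <- regions@regions
  df <- data.frame(chrom = contig, start = r$start, end = r$end,
                   label = r$label, class = r$class)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionsBed
#' @export
readRegionsBed <- function(path, chromLen = NULL) {
  if (!file.exists(path))
    stop("region BED not found: ", path)
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(class = "character"))
  df <- data.frame(label = gr$name,
                   start = GenomicRanges::start(gr) - 1,
                   end = as.numeric(GenomicRanges::end(gr)),
                   class = gr$class)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(chromLen))
    chromLen <- max(df$end)
  new("RegionSet", regions = df, chromLen = as.numeric(chromLen))
}

#' Write / read the phenotype table
#'
#' TSV with columns fly_id, activity and pool.
#'
#' @param phenotypes data.frame(flyId, activity[, pool]).
#' @param path file path.
#' @return the writer returns \code{path} invisibly; the reader a
#'   data.frame(flyId, activity, pool).
#' @export
writePhenotypeTsv <- function(phenotypes, path) {
  df <- data.frame(fly_id = phenotypes$flyId,
                   activity = phenotypes$activity,
                   pool = if ("pool" %in% names(phenotypes))
                     as.character(phenotypes$pool) else "unassayed")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTsv
#' @export
readPhenotypeTsv <- function(path) {
  if (!file.exists(path))
    stop("phenotype table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fly_id", "activity") %in% names(df)))
  out <- data.frame(flyId = as.character(df$fly_id),
                    activity = df$activity)
  out$pool <- if ("pool" %in% names(df)) factor(
    df$pool, levels = c("low", "high", "unassayed")) else
      factor("unassayed", levels = c("low", "high", "unassayed"))
  out
}
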