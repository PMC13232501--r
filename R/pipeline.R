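#' Pipeline configuration
#'
#' Paths of the standard-format inputs and outputs plus the analysis
#' constants, validated up front. Built directly or from a YAML file.
#'
#' @param vcf,sampleSheet,phenotypes input paths (VCF 4.2, sample sheet
#'   TSV, phenotype TSV).
#' @param regions optional region BED; when NULL regions are derived from
#'   the informative sites with [segmentByDensity()].
#' @param outDir output directory (created if needed).
#' @param nFlies,nMeioses rate-normalisation constants (NULL nFlies: use
#'   the number of painted flies).
#' @param bootstrapB bootstrap resamples.
#' @param alpha family-wise error rate for Bonferroni.
#' @param smoothK painting smoothing parameter.
#' @param window,denseThreshold segmentation parameters (bp; SNPs/10 kb).
#' @param seed RNG seed for the bootstrap.
#' @return a validated list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(vcf, sampleSheet, phenotypes, regions = NULL,
                           outDir = ".", nFlies = NULL, nMeioses = 5,
                           bootstrapB = 10000L, alpha = 0.05, smoothK = 5L,
                           window = 1e5, denseThreshold = 10, seed = 1L) {
  cfg <- list(vcf = vcf, sampleSheet = sampleSheet, phenotypes = phenotypes,
              regions = regions, outDir = outDir, nFlies = nFlies,
              nMeioses = nMeioses, bootstrapB = as.integer(bootstrapB),
              alpha = alpha, smoothK = as.integer(smoothK),
              window = window, denseThreshold = denseThreshold,
              seed = as.integer(seed))
  for (nm in c("nMeioses", "bootstrapB", "alpha", "smoothK", "window",
               "denseThreshold"))
    if (cfg[[nm]] <= 0)
      stop("configuration error: ", nm, " must be positive")
  for (nm in c("vcf", "sampleSheet", "phenotypes"))
    if (!file.exists(cfg[[nm]]))
      stop("configuration error: missing ", nm, " file: ", cfg[[nm]])
  if (!is.null(cfg$regions) && !file.exists(cfg$regions))
    stop("configuration error: missing regions file: ", cfg$regions)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file with the same field names.
#' @export
readPipelineConfigYaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipelineConfig, x)
}

#' Simulate a study and write its standard-format inputs
#'
#' Runs the forward simulator end to end (parental SNPs, intermating,
#' phenotypes, pool selection, genotyping of the pooled flies) and writes
#' VCF, sample sheet, phenotype TSV, truth-tract BED, true region BED and
#' the config YAML into \code{dir}.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param genotypePoolsOnly genotype only the pooled flies (default TRUE;
#'   matches the study, where only pooled flies were sequenced).
#' @return list with the written paths and the in-memory objects
#'   (parental, cohort, phenotypeTable, calls).
#' @export
simulateStudy <- function(config, dir, seed = config@seed,
                          genotypePoolsOnly = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- withSeed(seed, sample.int(2^31 - 1L, 4L))
  parental <- buildParentalSnps(config, seed = seeds[1L])
  cohort <- simulateGenerations(config, seed = seeds[2L])
  pheno <- simulatePhenotypes(cohort, config, seed = seeds[3L])
  pheno <- selectExtremePools(pheno, config@poolSize)
  flies <- if (genotypePoolsOnly)
    pheno$flyId[pheno$pool != "unassayed"] else pheno$flyId
  calls <- genotypeCohort(cohort, parental, config, seed = seeds[4L],
                          flies = flies)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    sampleSheet = file.path(dir, "samples.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truthBed = file.path(dir, "truth_tracts.bed"),
    regionsBed = file.path(dir, "regions.bed"),
    configYaml = file.path(dir, "sim_config.yaml"))
  writeGenotypeVcf(calls, paths$vcf)
  writeSampleSheet(calls, paths$sampleSheet)
  writePhenotypeTsv(pheno, paths$phenotypes)
  writeTractsBed(cohort, paths$truthBed)
  writeRegionsBed(configRegions(config), paths$regionsBed)
  writeSimulationConfigYaml(config, paths$configYaml)
  c(paths, list(parental = parental, cohort = cohort,
                phenotypeTable = pheno, calls = calls))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Reads the VCF, sample sheet and phenotype table, selects informative
#' sites, paints every recombinant fly, segments (or loads) the region set,
#' estimates region-wise crossover rates with bootstrap CIs and exact
#' conditional tests, and computes pool association and per-region
#' Hi-fraction statistics. All outputs carry the seed and a configuration
#' hash in a header comment; identical config and inputs give byte-identical
#' outputs.
#'
#' @param config a \code{pipelineConfig}.
#' @return invisibly, a list with the result tables and output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  # hash the analysis-relevant fields only, so the same inputs and
  # parameters give identical output headers wherever they are written
  hash <- configHash(config[setdiff(names(config), "outDir")])
  hdr <- outputHeader(config$seed, hash,
                      sprintf("# smoothK=%d tieBreak=lower-coordinate sidedness=minimum-likelihood bootstrap=flies(B=%d)",
                              config$smoothK, config$bootstrapB))
  logLines <- c(hdr, sprintf("# window=%g denseThreshold=%g alpha=%g nMeioses=%g",
                             config$window, config$denseThreshold,
                             config$alpha, config$nMeioses))

  calls <- .stage("read_vcf",
                  readGenotypeVcf(config$vcf, config$sampleSheet))
  pheno <- .stage("read_phenotypes", readPhenotypeTsv(config$phenotypes))
  sites <- .stage("informative_sites", selectInformativeSites(calls))
  logLines <- c(logLines,
                sprintf("# informative sites: %d of %d (het dropped: Hi %.1f%%, Lo %.1f%%)",
                        qcStats(sites)$nRetained, qcStats(sites)$nInput,
                        100 * qcStats(sites)$hetFracHi,
                        100 * qcStats(sites)$hetFracLo))
  paintings <- .stage("painting", paintCohort(calls, sites,
                                              k = config$smoothK))
  regions <- .stage("regions", {
    if (is.null(config$regions))
      segmentByDensity(sites, window = config$window,
                       denseThreshold = config$denseThreshold)
    else
      readRegionsBed(config$regions, chromLen = sites@chromLen)
  })
  nFlies <- if (is.null(config$nFlies)) length(paintings) else config$nFlies
  rates <- .stage("rates",
                  crossoverRateTable(paintings, regions, nFlies = nFlies,
                                     nMeioses = config$nMeioses,
                                     B = config$bootstrapB,
                                     seed = config$seed))
  pools <- pheno$pool[match(names(paintings), pheno$flyId)]
  assocTab <- .stage("association", {
    idx <- match(sites@positions, calls@positions)
    fisherSiteAssociation(calls@flyGT[idx, , drop = FALSE], pools,
                          positions = sites@positions)
  })
  bf <- bonferroni(assocTab$p, config$alpha)
  assocTab$significant <- bf$flags
  fracTab <- .stage("fractions", {
    fr <- hiFractionMatrix(paintings, regions)
    compareFractions(fr, pools)
  })
  logLines <- c(logLines,
                sprintf("# Bonferroni threshold: %.3g over %d sites",
                        bf$threshold, bf$m),
                sprintf("# sparse gap: %s, evaluable flies %d of %d",
                        rates$gap$label, rates$nEvaluable, length(paintings)))

  paths <- list(
    tractsBed = file.path(config$outDir, "tracts.bed"),
    ratesTsv = file.path(config$outDir, "rates.tsv"),
    assocTsv = file.path(config$outDir, "association.tsv"),
    fracTsv = file.path(config$outDir, "fractions.tsv"),
    matrixTsv = file.path(config$outDir, "painting_matrix.tsv"),
    log = file.path(config$outDir, "pipeline.log"))
  .stage("write_outputs", {
    writeTractsBed(paintings, paths$tractsBed, header = hdr)
    writeTsvWithHeader(rates$table, paths$ratesTsv, hdr)
    writeTsvWithHeader(assocTab, paths$assocTsv, hdr)
    writeTsvWithHeader(fracTab, paths$fracTsv, hdr)
    m <- paintingMatrix(paintings, pheno[pheno$flyId %in% names(paintings), ])
    writeTsvWithHeader(data.frame(flyId = rownames(m), m,
                                  check.names = FALSE),
                       paths$matrixTsv, hdr)
    writeLines(logLines, paths$log)
  })
  invisible(list(calls = calls, sites = sites, paintings = paintings,
                 regions = regions, rates = rates, association = assocTab,
                 bonferroni = bf, fractions = fracTab, paths = paths))
}
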