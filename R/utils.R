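# Evaluate expr under a temporary RNG state seeded with `seed`; NULL seed
# uses (and advances) the current stream. Keeps every stochastic operation
# reproducible bit-for-bit given (config, seed).
withSeed <- function(seed, expr) {
  if (is.null(seed))
    return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had)
    old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Stable short hash of an R object (used to stamp outputs with the config).
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 keeps the serialisation stable across R sessions
  saveRDS(x, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}

# header comment lines stamped into every TSV/BED output
outputHeader <- function(seed, hash, extra = character(0)) {
  c(sprintf("# crossoverBSA %s",
            as.character(utils::packageVersion("crossoverBSA"))),
    sprintf("# seed=%s configHash=%s",
            ifelse(is.null(seed), "NA", as.character(seed)), hash),
    extra)
}

writeTsvWithHeader <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
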