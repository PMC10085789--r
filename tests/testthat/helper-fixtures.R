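# Shared fixtures, built in code at test time.

# A tiny factorial trial reused across tests (2 testers x 12 males).
toyTrial <- local({
  cache <- NULL
  function(seed = 11, nMales = 12, nMarkers = 300, ...) {
    key <- paste(seed, nMales, nMarkers)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    cfg <- simConfig(nMales = nMales, nMarkers = nMarkers, seed = seed, ...)
    parents <- simulateParents(cfg)
    tr <- simulateTrial(parents, cfg)
    value <- list(config = cfg, parents = parents, design = tr$design,
                  truth = tr$truth, crosses = crossingTable(tr$design))
    cache <<- list(key = key, value = value)
    value
  }
})

# Hand-writable VCF fixture: returns the path of a small VCF.
writeToyVCF <- function(rows, samples, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

vcfRow <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Balanced one-group dataset for REML oracle checks.
oneWayData <- function(nGroups, nReps, sdG, sdE, seed) {
  set.seed(seed)
  g <- rep(sprintf("g%03d", seq_len(nGroups)), each = nReps)
  u <- rnorm(nGroups, 0, sdG)
  data.frame(g = g, y = u[as.integer(factor(g))] + rnorm(length(g), 0, sdE))
}
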