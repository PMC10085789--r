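## Plain-text writers/readers: dosage TSV, minimal VCF, GRM TSV, YAML config.

#' Write and read genotype dosages as TSV
#'
#' The TSV carries the map columns (`chrom`, `pos`) as the first rows of a
#' transposed layout: markers in columns, individuals in rows, with a
#' header of marker ids; the map travels in a sidecar `<path>.map` file.
#' Round-trips are lossless for dosages.
#'
#' @param g a [GenotypeMatrix].
#' @param path output TSV path.
#' @export
writeDosageTSV <- function(g, path) {
  d <- dosages(g)
  out <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(markerMap(g), paste0(path, ".map"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDosageTSV
#' @export
readDosageTSV <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  map <- read.table(paste0(path, ".map"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  d <- as.matrix(x[, -1, drop = FALSE])
  rownames(d) <- x$id
  genotypeMatrix(d, map)
}

#' Write a minimal VCF from integer dosages
#'
#' Dosages must be integral (0/1/2): 0 -> 0/0, 1 -> 0/1, 2 -> 1/1.
#' REF/ALT default to A/T when the map carries none.
#'
#' @param g a [GenotypeMatrix].
#' @param path output path (`.vcf`).
#' @export
writeVCF <- function(g, path) {
  d <- dosages(g)
  if (anyNA(d) || any(abs(d - round(d)) > 1e-9))
    stop("writeVCF requires complete integer dosages")
  map <- markerMap(g)
  gtcode <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  ref <- if (!is.null(map$ref)) map$ref else rep("A", nrow(map))
  alt <- if (!is.null(map$alt)) map$alt else rep("T", nrow(map))
  id <- if (!is.null(map$id)) map$id else
    paste(map$chrom, map$pos, sep = "_")
  body <- vapply(seq_len(nrow(map)), function(j) {
    paste(c(map$chrom[j], map$pos[j], id[j], ref[j], alt[j], ".", "PASS",
            ".", "GT", gtcode[round(d[, j]) + 1]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a relationship matrix as TSV with an id header
#'
#' @param rm a [RelationshipMatrix].
#' @param path output path.
#' @export
writeGRM <- function(rm, path) {
  out <- data.frame(id = rownames(rm@values), rm@values,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a simulation configuration to YAML
#'
#' @param config a [SimConfig].
#' @param path output path.
#' @export
writeSimConfigYAML <- function(config, path) {
  sl <- slotNames(config)
  x <- lapply(sl, function(s) {
    v <- slot(config, s)
    if (length(v) > 1) as.list(v) else v
  })
  names(x) <- sl
  yaml::write_yaml(x, path)
  invisible(path)
}
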