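#' Create a GenotypeMatrix
#'
#' Markers are sorted by (chromosome, position); duplicated positions within
#' a chromosome are dropped (first kept) so that positions are strictly
#' increasing, as required by the class validity.
#'
#' @param dosages individuals x markers numeric matrix with id rownames.
#' @param map data.frame with columns `chrom`, `pos` (1-based) and optional
#'   `id`, `ref`, `alt`.
#' @return a [GenotypeMatrix].
#' @export
genotypeMatrix <- function(dosages, map) {
  stopifnot(is.matrix(dosages), nrow(map) == ncol(dosages))
  map$chrom <- as.character(map$chrom)
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  dup <- duplicated(paste(map$chrom, map$pos))
  if (any(dup)) {
    map <- map[!dup, , drop = FALSE]
    dosages <- dosages[, !dup, drop = FALSE]
  }
  rownames(map) <- NULL
  colnames(dosages) <- if (!is.null(map$id)) map$id else
    paste(map$chrom, map$pos, sep = "_")
  new("GenotypeMatrix", dosages = dosages, map = map)
}

#' Accessors for GenotypeMatrix
#'
#' @param x a [GenotypeMatrix].
#' @return `dosages()` the numeric matrix, `markerMap()` the marker map,
#'   `sampleIds()` the individual ids.
#' @name dosages
NULL

setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
setMethod("markerMap", "GenotypeMatrix", function(x) x@map)
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "individuals x", ncol(d), "markers on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
  nmiss <- sum(is.na(d))
  if (nmiss > 0) cat("  missing dosages:", nmiss, "\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix (", object@kind, "): ", nrow(object@values), " x ",
      ncol(object@values), ", mean diagonal ",
      round(mean(diag(object@values)), 3), "\n", sep = "")
})

#' Subset a GenotypeMatrix by individuals and/or markers
#'
#' @param x a [GenotypeMatrix]
#' @param i individual ids or indices
#' @param j marker indices
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosages
  m <- x@map
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) {
    d <- d[, j, drop = FALSE]
    m <- m[j, , drop = FALSE]
  }
  genotypeMatrix(d, m)
})
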