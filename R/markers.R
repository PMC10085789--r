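## Marker handling: VCF import with QC filters, positional thinning, F1
## genotype construction, the VanRaden additive GRM, and parental distances.

#' Read a VCF of inbred-parent genotypes with QC filters
#'
#' Biallelic SNP records are converted to alternate-allele dosages (GT field;
#' DS is used for records without GT). A marker is kept when its fraction of
#' missing calls is at most `allowedMissingFraction` and its minor allele
#' frequency (computed on non-missing calls) is strictly greater than
#' `minMaf`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param allowedMissingFraction maximum tolerated missing-call fraction
#'   (default 0.01).
#' @param minMaf minor-allele-frequency threshold, exclusive (default 0.02).
#' @return a [GenotypeMatrix].
#' @export
readVCF <- function(path, allowedMissingFraction = 0.01, minMaf = 0.02) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  snp <- nchar(vcfR::getREF(v)) == 1 & nchar(vcfR::getALT(v)) == 1
  keep <- bi & snp & !is.na(snp)
  v <- v[keep, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- .gtToDosage(gt)
  if (anyNA(dos) && "DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ds <- suppressWarnings(
      vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    dos[is.na(dos)] <- ds[is.na(dos)]
  }
  map <- data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                    id = vcfR::getID(v), ref = vcfR::getREF(v),
                    alt = vcfR::getALT(v), stringsAsFactors = FALSE)
  g <- genotypeMatrix(t(dos), map)
  filterGenotypes(g, allowedMissingFraction, minMaf)
}

.gtToDosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(gsub("\\|", "/", s), "/", fixed = FALSE)[[1]]
    if (any(al == ".") || length(al) != 2) return(NA_real_)
    sum(as.numeric(al))
  }, numeric(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Filter markers by missingness and minor allele frequency
#'
#' @param g a [GenotypeMatrix].
#' @param allowedMissingFraction maximum missing-call fraction (inclusive).
#' @param minMaf MAF threshold (exclusive: markers with MAF > minMaf kept).
#' @return the filtered [GenotypeMatrix].
#' @export
filterGenotypes <- function(g, allowedMissingFraction = 0.01, minMaf = 0.02) {
  d <- dosages(g)
  missFrac <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- missFrac <= allowedMissingFraction & !is.na(maf) & maf > minMaf
  if (!any(keep))
    stop("no markers survive the missingness/MAF filters (over-filtering)")
  g[, which(keep)]
}

#' Thin markers to at most one per window of physical distance
#'
#' Within each chromosome the first marker is always kept; a subsequent
#' marker is kept only when its position exceeds the last kept position by at
#' least `windowBp` (the scan runs in ascending position, so the first marker
#' in each window wins, matching vcftools `--thin` semantics).
#'
#' @param g a [GenotypeMatrix] with a position-sorted map.
#' @param windowBp window size in base pairs; 0 returns the input unchanged.
#' @return the thinned [GenotypeMatrix].
#' @export
thinByPosition <- function(g, windowBp) {
  if (windowBp <= 0) return(g)
  map <- markerMap(g)
  keep <- logical(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    if (is.unsorted(pos, strictly = TRUE)) stop("map not sorted by position")
    last <- -Inf
    for (k in seq_along(idx)) {
      if (pos[k] - last >= windowBp) {
        keep[idx[k]] <- TRUE
        last <- pos[k]
      }
    }
  }
  g[, which(keep)]
}

#' Construct F1 hybrid genotypes from inbred parents
#'
#' The expected F1 dosage at each locus is the mean of the two parental
#' dosages. For fully inbred parents this is the exact F1 genotype; residual
#' parental heterozygosity propagates as fractional expected dosages
#' (`hetPolicy = "expected"`, default) or the affected markers can be dropped
#' (`hetPolicy = "drop"`).
#'
#' @param parents a [GenotypeMatrix] containing all parents.
#' @param crosses data.frame with columns `female`, `male` (parent ids);
#'   hybrids are named `"<female>/<male>"` in row order of `crosses`.
#' @param hetPolicy `"expected"` or `"drop"`.
#' @return a [GenotypeMatrix] of hybrids.
#' @export
buildHybridGenotypes <- function(parents, crosses,
                                 hetPolicy = c("expected", "drop")) {
  hetPolicy <- match.arg(hetPolicy)
  d <- dosages(parents)
  ids <- c(crosses$female, crosses$male)
  unknown <- setdiff(unique(ids), rownames(d))
  if (length(unknown))
    stop("unknown parent id(s): ", paste(unknown, collapse = ", "))
  if (anyNA(d[unique(ids), , drop = FALSE]))
    stop("parental dosages contain missing values; impute or filter first")
  map <- markerMap(parents)
  if (hetPolicy == "drop") {
    het <- apply(d[unique(ids), , drop = FALSE], 2,
                 function(x) any(x > 1e-9 & x < 2 - 1e-9))
    d <- d[, !het, drop = FALSE]
    map <- map[!het, , drop = FALSE]
  }
  h <- (d[crosses$female, , drop = FALSE] +
        d[crosses$male, , drop = FALSE]) / 2
  rownames(h) <- paste(crosses$female, crosses$male, sep = "/")
  genotypeMatrix(h, map)
}

#' VanRaden additive genomic relationship matrix
#'
#' G = Z Z' / (2 sum p_k (1 - p_k)) where Z is the dosage matrix with each
#' column centered by twice the observed alternate-allele frequency p_k.
#' Monomorphic columns are centered to zero and contribute nothing to either
#' numerator or denominator. Missing dosages are column-mean imputed first.
#'
#' @param g a [GenotypeMatrix] with at least 2 polymorphic markers.
#' @return a [RelationshipMatrix] of kind `"additive_genomic"`.
#' @export
additiveGRM <- function(g) {
  d <- dosages(g)
  if (anyNA(d)) {
    cm <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- cm[idx[, 2]]
  }
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    stop("fewer than 2 polymorphic markers; GRM denominator degenerate")
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  Z <- sweep(d, 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(d), rownames(d))
  new("RelationshipMatrix", values = G, kind = "additive_genomic")
}

#' Identity relationship matrix over a set of ids
#'
#' @param ids character vector of ids.
#' @return a [RelationshipMatrix] of kind `"identity"`.
#' @export
identityRM <- function(ids) {
  v <- diag(length(ids))
  dimnames(v) <- list(ids, ids)
  new("RelationshipMatrix", values = v, kind = "identity")
}

#' Euclidean genetic distance between two individuals
#'
#' @param g a [GenotypeMatrix] without missing dosages for the two rows.
#' @param idA,idB individual ids.
#' @return nonnegative scalar Euclidean distance between dosage rows.
#' @export
geneticDistance <- function(g, idA, idB) {
  d <- dosages(g)
  miss <- setdiff(c(idA, idB), rownames(d))
  if (length(miss)) stop("unknown id(s): ", paste(miss, collapse = ", "))
  sqrt(sum((d[idA, ] - d[idB, ])^2))
}
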