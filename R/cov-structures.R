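## Covariance structures for random terms: identity, supplied matrix,
## Kronecker product. A structure knows its level ids, its dense matrix, its
## inverse and its log-determinant; Kronecker structures compute the latter
## two from their parts, never by materializing and inverting the product.

#' Construct covariance structures
#'
#' `identityCov()` is the i.i.d. structure; level ids may be left empty and
#' taken from the data at fit time. `suppliedCov()` wraps a relationship
#' matrix (e.g. a genomic relationship matrix); it is stabilized to positive
#' definiteness by adding `max(0, -lambda_min) + 1e-8` to the diagonal when
#' the minimum eigenvalue falls below 1e-8, so that it can always be inverted
#' and factorized. `kroneckerCov()` forms the Kronecker product of two
#' structures; the left factor's level varies slowest, and level ids are
#' `paste(left, right, sep = ":")`.
#'
#' @param ids character vector of level ids (identity only; may be empty).
#' @param m a [RelationshipMatrix] or a symmetric matrix with id dimnames.
#' @param left,right component [CovStruct]s.
#' @param maxDim guard against accidentally huge Kronecker products.
#' @return a [CovStruct].
#' @examples
#' kroneckerCov(identityCov(c("y1", "y2")), identityCov(c("a", "b", "c")))
#' @name covConstructors
NULL

#' @rdname covConstructors
#' @export
identityCov <- function(ids = character(0)) {
  new("IdentityCov", ids = as.character(ids))
}

#' @rdname covConstructors
#' @export
suppliedCov <- function(m) {
  if (is(m, "RelationshipMatrix")) m <- m@values
  if (!is.matrix(m)) stop("supplied covariance must be a matrix")
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev)
  jitter <- 0
  if (lmin < 1e-8) {
    jitter <- max(0, -lmin) + 1e-8
    diag(m) <- diag(m) + jitter
  }
  new("SuppliedCov", values = m, jitter = jitter)
}

#' @rdname covConstructors
#' @export
kroneckerCov <- function(left, right, maxDim = 1e7) {
  stopifnot(is(left, "CovStruct"), is(right, "CovStruct"))
  dl <- covDim(left); dr <- covDim(right)
  if (dl < 1 || dr < 1)
    stop("kronecker components must have known level ids")
  if (dl * dr > maxDim)
    stop("kronecker dimension ", dl * dr, " exceeds the cap of ", maxDim)
  new("KronCov", left = left, right = right)
}

#' Covariance-structure queries
#'
#' `covIds()`/`covDim()` give the level ids and dimension, `covMatrix()` the
#' dense matrix, `covInverse()` its inverse and `covLogDet()` its
#' log-determinant (both computed from the parts for Kronecker structures).
#'
#' @param x a [CovStruct].
#' @name covOps
NULL

setMethod("covIds", "IdentityCov", function(x) x@ids)
setMethod("covIds", "SuppliedCov", function(x) rownames(x@values))
setMethod("covIds", "KronCov", function(x) {
  as.vector(t(outer(covIds(x@left), covIds(x@right), paste, sep = ":")))
})

setMethod("covDim", "IdentityCov", function(x) length(x@ids))
setMethod("covDim", "SuppliedCov", function(x) nrow(x@values))
setMethod("covDim", "KronCov", function(x) covDim(x@left) * covDim(x@right))

setMethod("covMatrix", "IdentityCov", function(x) {
  d <- diag(length(x@ids))
  dimnames(d) <- list(x@ids, x@ids)
  d
})
setMethod("covMatrix", "SuppliedCov", function(x) x@values)
setMethod("covMatrix", "KronCov", function(x) {
  k <- kronecker(covMatrix(x@left), covMatrix(x@right))
  ids <- covIds(x)
  dimnames(k) <- list(ids, ids)
  k
})

setMethod("covInverse", "IdentityCov", function(x) {
  d <- diag(length(x@ids))
  dimnames(d) <- list(x@ids, x@ids)
  d
})
setMethod("covInverse", "SuppliedCov", function(x) {
  inv <- chol2inv(chol(x@values))
  dimnames(inv) <- dimnames(x@values)
  inv
})
setMethod("covInverse", "KronCov", function(x) {
  k <- kronecker(covInverse(x@left), covInverse(x@right))
  ids <- covIds(x)
  dimnames(k) <- list(ids, ids)
  k
})

setMethod("covLogDet", "IdentityCov", function(x) 0)
setMethod("covLogDet", "SuppliedCov", function(x) {
  2 * sum(log(diag(chol(x@values))))
})
setMethod("covLogDet", "KronCov", function(x) {
  covDim(x@right) * covLogDet(x@left) + covDim(x@left) * covLogDet(x@right)
})

## Replace an empty-id identity structure with one carrying the observed
## levels (used at fit time).
.withIds <- function(struct, ids) {
  if (is(struct, "IdentityCov") && covDim(struct) == 0)
    identityCov(ids)
  else struct
}
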