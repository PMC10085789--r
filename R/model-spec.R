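#' Build random terms and model specifications
#'
#' `randomTerm()` couples a grouping factor (or an interaction of factors,
#' first column varying slowest, matching the Kronecker ordering contract)
#' with a covariance structure. `modelSpec()` assembles the response, the
#' categorical fixed terms (an intercept is always present; treatment
#' contrasts with the first level as reference) and the random terms.
#'
#' @param name unique term label.
#' @param factors character vector of data column names.
#' @param struct a [CovStruct]; defaults to the identity with levels taken
#'   from the data.
#' @param response response column name.
#' @param fixed character vector of fixed-effect columns (may be empty).
#' @param random list of [RandomTerm].
#' @return a [RandomTerm] / [ModelSpec].
#' @examples
#' spec <- modelSpec("y", fixed = "rep",
#'                   random = list(randomTerm("genotype", "genotype")))
#' @export
randomTerm <- function(name, factors, struct = identityCov()) {
  new("RandomTerm", name = name, factors = factors, struct = struct)
}

#' @rdname randomTerm
#' @export
modelSpec <- function(response, fixed = character(0), random = list()) {
  new("ModelSpec", response = response, fixed = fixed, random = random)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: ", object@response, " ~ ",
      paste(c("1", object@fixed), collapse = " + "), sep = "")
  for (t in object@random)
    cat(" + (", paste(t@factors, collapse = ":"), " | ", t@name, ")",
        sep = "")
  cat("\n")
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit (REML):", object@spec@response, "on", object@nObs,
      "observations\n")
  cat("  logLik:", format(object@logLik, digits = 8),
      " AIC:", format(object@aic, digits = 8),
      " BIC:", format(object@bic, digits = 8), "\n")
  cat("  converged:", object@converged, "in", object@nIter, "iterations\n")
  vc <- object@varComp
  cat("  variance components:\n")
  for (nm in names(vc))
    cat(sprintf("    %-14s %g\n", nm, vc[[nm]]))
})

#' Serialize a model specification to/from YAML
#'
#' Covariance structures are written by kind; supplied matrices are
#' referenced by an id list only (the matrix itself travels separately).
#'
#' @param spec a [ModelSpec].
#' @param path file path.
#' @export
writeModelSpecYAML <- function(spec, path) {
  enc <- function(s) {
    if (is(s, "IdentityCov")) list(kind = "identity", ids = as.list(s@ids))
    else if (is(s, "SuppliedCov")) list(kind = "supplied",
                                        ids = as.list(rownames(s@values)))
    else list(kind = "kronecker", left = enc(s@left), right = enc(s@right))
  }
  x <- list(response = spec@response, fixed = as.list(spec@fixed),
            random = lapply(spec@random, function(t)
              list(name = t@name, factors = as.list(t@factors),
                   structure = enc(t@struct))))
  yaml::write_yaml(x, path)
  invisible(path)
}
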