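#' @import methods
#' @importFrom stats var sd cor rnorm runif rbinom rbeta setNames
#'   model.matrix as.formula
#' @importFrom utils read.table write.table head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypeMatrix: individuals-by-markers allele dosages with a marker map
#'
#' Dosages count copies of the alternate allele (0, 1, 2; fractional values
#' arise for F1 hybrids built from heterozygous parents; NA allowed before
#' imputation). The map holds one row per marker with chromosome and 1-based
#' position, strictly increasing within chromosome.
#'
#' @slot dosages numeric matrix, individuals in rows (rownames are ids),
#'   markers in columns.
#' @slot map data.frame with columns \code{chrom}, \code{pos} and optionally
#'   \code{id}, \code{ref}, \code{alt}; one row per dosage column.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", map = "data.frame"),
  validity = function(object) {
    d <- object@dosages
    msg <- character(0)
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
      msg <- c(msg, "dosage rownames must be unique individual ids")
    if (nrow(object@map) != ncol(d))
      msg <- c(msg, "map must have one row per marker column")
    if (!all(c("chrom", "pos") %in% names(object@map)))
      msg <- c(msg, "map needs 'chrom' and 'pos' columns")
    rng <- suppressWarnings(range(d, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 2 + 1e-9))
      msg <- c(msg, "dosages must lie in [0, 2]")
    if (nrow(object@map) > 0) {
      byc <- split(object@map$pos, object@map$chrom)
      if (!all(vapply(byc, function(p) all(diff(p) > 0), logical(1))))
        msg <- c(msg, "positions must be strictly increasing within chromosome")
    }
    if (length(msg)) msg else TRUE
  })

#' RelationshipMatrix: a symmetric relationship/covariance matrix over ids
#'
#' @slot values symmetric numeric matrix with matching dimnames.
#' @slot kind one of \code{"additive_genomic"} or \code{"identity"}.
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", kind = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character(0)
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
      msg <- c(msg, "dimnames must be set and identical")
    if (nrow(v) > 0 && max(abs(v - t(v))) > 1e-10)
      msg <- c(msg, "matrix must be symmetric within 1e-10")
    if (!object@kind %in% c("additive_genomic", "identity"))
      msg <- c(msg, "kind must be 'additive_genomic' or 'identity'")
    if (length(msg)) msg else TRUE
  })

#' Covariance structures for random model terms
#'
#' A \code{CovStruct} names the covariance of one random term: the identity
#' (\code{IdentityCov}), a supplied relationship matrix (\code{SuppliedCov},
#' stabilized to be positive definite at construction), or a Kronecker
#' product of two structures (\code{KronCov}; left factor varies slowest in
#' the level ordering).
#'
#' @name CovStruct
#' @aliases IdentityCov SuppliedCov KronCov
#' @export
setClass("CovStruct", representation("VIRTUAL"))

#' @rdname CovStruct
#' @slot ids level ids; may be empty, in which case levels are taken from the
#'   data at fit time.
#' @export
setClass("IdentityCov", contains = "CovStruct",
  representation(ids = "character"))

#' @rdname CovStruct
#' @slot values stabilized positive-definite matrix with id dimnames.
#' @slot jitter the diagonal ridge added by the PSD stabilization policy.
#' @export
setClass("SuppliedCov", contains = "CovStruct",
  representation(values = "matrix", jitter = "numeric"),
  validity = function(object) {
    v <- object@values
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
      return("supplied covariance needs matching id dimnames")
    if (max(abs(v - t(v))) > 1e-8) return("supplied covariance must be symmetric")
    TRUE
  })

#' @rdname CovStruct
#' @slot left,right component structures; level ids are
#'   \code{paste(left, right, sep = ":")} with the left factor slowest.
#' @export
setClass("KronCov", contains = "CovStruct",
  representation(left = "CovStruct", right = "CovStruct"))

#' A random model term: grouping factor(s) plus a covariance structure
#'
#' @slot name unique term label.
#' @slot factors column name(s) in the data; two or more columns denote an
#'   interaction whose levels are joined with ":" (first column slowest,
#'   matching the Kronecker ordering contract).
#' @slot struct a [CovStruct].
#' @export
setClass("RandomTerm",
  representation(name = "character", factors = "character",
                 struct = "CovStruct"))

#' Declarative mixed-model specification
#'
#' @slot response name of the numeric response column.
#' @slot fixed character vector of categorical fixed-effect columns (an
#'   intercept is always included; treatment contrasts, first level as
#'   reference).
#' @slot random list of [RandomTerm].
#' @export
setClass("ModelSpec",
  representation(response = "character", fixed = "character",
                 random = "list"),
  validity = function(object) {
    nm <- vapply(object@random, function(t) t@name, character(1))
    if (anyDuplicated(nm)) return("random term names must be unique")
    TRUE
  })

#' A fitted mixed model (REML)
#'
#' @slot varComp named variance components (each random term plus
#'   \code{residual}); components converged onto the lower boundary are
#'   reported as 0.
#' @slot varCompSE asymptotic standard errors from the inverse average
#'   information matrix (NA when a component is on the boundary).
#' @slot fixedEffects data.frame (term, level, estimate); term
#'   \code{"(Intercept)"} is the model intercept.
#' @slot blup named list: per random term, a named vector of BLUPs in the
#'   covariance structure's id order.
#' @slot pev named list: per random term, prediction error variances.
#' @slot logLik REML log-likelihood (constants included).
#' @slot aic,bic minus twice the log-likelihood penalized by the number of
#'   estimated variance components (BIC uses log of the number of
#'   observations used).
#' @slot converged,nIter,nObs,nDropped fit diagnostics.
#' @slot spec the [ModelSpec] that was fit.
#' @export
setClass("ModelFit",
  representation(varComp = "numeric", varCompSE = "numeric",
                 fixedEffects = "data.frame", blup = "list", pev = "list",
                 logLik = "numeric", aic = "numeric", bic = "numeric",
                 converged = "logical", nIter = "integer", nObs = "integer",
                 nDropped = "integer", spec = "ModelSpec"))

#' Configuration of the synthetic factorial hybrid trial
#'
#' Defaults emulate a two-tester by many-male sorghum factorial evaluated in
#' 2 years x 2 replications with small blocks nested in replications; see the
#' methods vignette for the rationale behind each default.
#'
#' @slot nMales,nTesters,nMarkers,nChromosomes counts.
#' @slot chromLengthBp chromosome length in base pairs.
#' @slot mafRange allele-frequency range in (0, 0.5] for simulated loci.
#' @slot nYears,nReps,nBlocksPerRep trial dimensions (nBlocksPerRep = 0 picks
#'   roughly 30 plots per block).
#' @slot varGcaMale,varSca,varGxe,varBlock,varError variance components of the
#'   generative model (male GCA, tester-by-male SCA, male-by-year interaction,
#'   block within replication within year, plot residual).
#' @slot testerEffects,yearEffects fixed shifts, one per tester / year.
#' @slot mu overall hybrid mean; \code{heterosisShift} is how far the parent
#'   per-se mean sits below \code{mu} (the dominance-like gap that generates
#'   mid-parent heterosis).
#' @slot nSubpops,fst Balding-Nichols population structure of the parents:
#'   parents belong to one of `nSubpops` subpopulations whose per-locus
#'   allele frequencies diverge from the ancestral frequency with
#'   differentiation `fst` (0 = panmictic panel).
#' @slot gcaMode "marker" draws male GCA as a linear combination of centered
#'   male dosages (so markers carry the signal); "exchangeable" draws i.i.d.
#'   normal GCAs.
#' @slot residualHet fraction of parent genotype cells set heterozygous
#'   (dosage 1) to exercise the F1-construction policy; 0 = fully inbred.
#' @slot seed integer master seed; all draws derive from named substreams.
#' @export
setClass("SimConfig",
  representation(nMales = "numeric", nTesters = "numeric",
    nMarkers = "numeric", nChromosomes = "numeric", chromLengthBp = "numeric",
    mafRange = "numeric", nSubpops = "numeric", fst = "numeric",
    nYears = "numeric", nReps = "numeric",
    nBlocksPerRep = "numeric", varGcaMale = "numeric", varSca = "numeric",
    varGxe = "numeric", varBlock = "numeric", varError = "numeric",
    testerEffects = "numeric", yearEffects = "numeric", mu = "numeric",
    heterosisShift = "numeric", gcaMode = "character",
    residualHet = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character(0)
    counts <- c(object@nMales, object@nTesters, object@nMarkers,
                object@nChromosomes, object@nYears, object@nReps)
    if (any(counts < 1)) msg <- c(msg, "counts must be >= 1")
    if (object@nTesters < 2) msg <- c(msg, "at least 2 testers are required")
    vs <- c(object@varGcaMale, object@varSca, object@varGxe, object@varBlock,
            object@varError)
    if (any(vs < 0)) msg <- c(msg, "variances must be >= 0")
    mr <- object@mafRange
    if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
      msg <- c(msg, "mafRange must lie within (0, 0.5]")
    if (length(object@testerEffects) != object@nTesters)
      msg <- c(msg, "testerEffects must have one entry per tester")
    if (length(object@yearEffects) != object@nYears)
      msg <- c(msg, "yearEffects must have one entry per year")
    if (object@residualHet < 0 || object@residualHet > 1)
      msg <- c(msg, "residualHet must be in [0, 1]")
    if (object@fst < 0 || object@fst >= 1)
      msg <- c(msg, "fst must be in [0, 1)")
    if (object@nSubpops < 1)
      msg <- c(msg, "nSubpops must be >= 1")
    if (!object@gcaMode %in% c("marker", "exchangeable"))
      msg <- c(msg, "gcaMode must be 'marker' or 'exchangeable'")
    if (length(msg)) msg else TRUE
  })

#' Generative truths of a simulated trial
#'
#' @slot gcaMale named per-male genetic value (centered).
#' @slot sca named per-hybrid tester-by-male deviation.
#' @slot hybridValue named per-hybrid total genetic value
#'   (mu + tester effect + male GCA + SCA, exactly).
#' @slot parentValue named per-parent per-se genetic value (used for the
#'   mid-parent heterosis truth).
#' @slot varianceComponents echo of the configured variances.
#' @export
setClass("SimTruth",
  representation(gcaMale = "numeric", sca = "numeric",
                 hybridValue = "numeric", parentValue = "numeric",
                 varianceComponents = "numeric"))

#' Cross-validation scheme for hybrid prediction
#'
#' @slot scenario "T2" (both parents of every validation hybrid phenotyped in
#'   training), "T1F" (whole male lines held out, only the female tester
#'   shared), or "maleGCA" (male lines masked, GCA predicted).
#' @slot fraction validation fraction of hybrids (T2) or males (T1F).
#' @slot count number of males masked under maleGCA.
#' @slot nIterations number of resampling iterations.
#' @slot seedStart first iteration seed; iteration i uses seedStart + i - 1.
#' @slot model "GCA" or "GCA+SCA".
#' @export
setClass("CVScheme",
  representation(scenario = "character", fraction = "numeric",
    count = "numeric", nIterations = "numeric", seedStart = "numeric",
    model = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@scenario %in% c("T2", "T1F", "maleGCA"))
      msg <- c(msg, "scenario must be T2, T1F or maleGCA")
    if (object@fraction <= 0 || object@fraction >= 1)
      msg <- c(msg, "fraction must be in (0, 1)")
    if (object@nIterations < 1) msg <- c(msg, "nIterations must be >= 1")
    if (!object@model %in% c("GCA", "GCA+SCA"))
      msg <- c(msg, "model must be 'GCA' or 'GCA+SCA'")
    if (length(msg)) msg else TRUE
  })

#' Per-iteration prediction accuracies for one scenario/trait/model
#'
#' @slot scenario,trait,model identifiers.
#' @slot reliability squared Pearson correlation between full-data GBLUP and
#'   full-data (identity) BLUP values; computed once per trait/model.
#' @slot iterations data.frame with one row per resampling iteration:
#'   seed, predictive ability r, prediction accuracy r/sqrt(reliability),
#'   validation size, and a note for skipped iterations.
#' @export
setClass("AccuracyReport",
  representation(scenario = "character", trait = "character",
    model = "character", reliability = "numeric", iterations = "data.frame"))
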