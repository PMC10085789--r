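## Synthetic tester-by-line factorial hybrid trial with known truths.
## The generative model mirrors the analysis models: a fixed tester shift and
## year shift, a male GCA effect (marker-determined by default), a
## tester-by-male SCA deviation, a male-by-year interaction, block effects
## nested in replication within year, and i.i.d. plot error. Parents are
## phenotyped in the same trial so mid-parent heterosis is computable; their
## per-se mean sits `heterosisShift` below the hybrid mean.

#' Build a simulation configuration
#'
#' Defaults describe a two-tester factorial over two years and two
#' replications with blocks of roughly 30 plots, the layout of a
#' CMS-based sorghum hybrid trial; variances default to a moderately
#' heritable yield-like trait with a small SCA share. See the methods
#' vignette for the reasoning behind every default.
#'
#' @param nMales number of male (restorer) lines (default 301).
#' @param nTesters number of female testers (default 2).
#' @param nMarkers,nChromosomes,chromLengthBp,mafRange marker architecture.
#' @param nSubpops,fst Balding-Nichols population structure among parents
#'   (defaults 5 subpopulations at fst 0.3, emulating a racially structured
#'   diversity panel; set `fst = 0` for a panmictic panel).
#' @param nYears,nReps,nBlocksPerRep trial dimensions; `nBlocksPerRep = 0`
#'   chooses blocks of about 30 plots.
#' @param varGcaMale,varSca,varGxe,varBlock,varError generative variances.
#' @param testerEffects,yearEffects fixed shifts (length nTesters / nYears).
#' @param mu overall hybrid mean; `heterosisShift` the hybrid-over-parent
#'   mean gap.
#' @param gcaMode `"marker"` (default) or `"exchangeable"`.
#' @param residualHet fraction of parental heterozygous calls (default 0).
#' @param seed master seed.
#' @return a [SimConfig].
#' @export
simConfig <- function(nMales = 301, nTesters = 2, nMarkers = 5000,
                      nChromosomes = 10, chromLengthBp = 6e7,
                      mafRange = c(0.05, 0.5), nSubpops = 5, fst = 0.3,
                      nYears = 2, nReps = 2,
                      nBlocksPerRep = 0, varGcaMale = 1, varSca = 0.15,
                      varGxe = 0.4, varBlock = 0.3, varError = 1,
                      testerEffects = NULL, yearEffects = NULL, mu = 10,
                      heterosisShift = 2.5, gcaMode = "marker",
                      residualHet = 0, seed = 1) {
  if (is.null(testerEffects)) testerEffects <- seq(0, by = 1,
                                                   length.out = nTesters)
  if (is.null(yearEffects)) yearEffects <- seq(0, by = 1,
                                               length.out = nYears)
  new("SimConfig", nMales = nMales, nTesters = nTesters,
      nMarkers = nMarkers, nChromosomes = nChromosomes,
      chromLengthBp = chromLengthBp, mafRange = mafRange,
      nSubpops = nSubpops, fst = fst, nYears = nYears,
      nReps = nReps, nBlocksPerRep = nBlocksPerRep,
      varGcaMale = varGcaMale, varSca = varSca, varGxe = varGxe,
      varBlock = varBlock, varError = varError,
      testerEffects = testerEffects, yearEffects = yearEffects, mu = mu,
      heterosisShift = heterosisShift, gcaMode = gcaMode,
      residualHet = residualHet, seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTesters, "testers x", object@nMales,
      "males,", object@nMarkers, "markers,", object@nYears, "years x",
      object@nReps, "reps; seed", object@seed, "\n")
})

## One master seed drives named substreams so that adding a draw category
## never perturbs the others.
.simSeed <- function(config, stream) {
  offs <- c(parents = 11, gca = 23, sca = 37, gxe = 47, blocks = 59,
            error = 71, parentError = 83, het = 97)
  ## double arithmetic is exact here and avoids 32-bit overflow
  as.integer((config@seed * 1009 + offs[[stream]]) %% 2147483647)
}

.maleIds <- function(config) sprintf("M%03d", seq_len(config@nMales))
.testerIds <- function(config) sprintf("T%d", seq_len(config@nTesters))
.yearIds <- function(config) sprintf("Y%d", seq_len(config@nYears))

#' Simulate fully inbred parent genotypes
#'
#' Parents (testers first, then males) are homozygous at every locus:
#' dosages are 0 or 2, drawn per locus with an alternate-allele frequency
#' sampled uniformly from `mafRange`. With `fst > 0`, parents belong to
#' `nSubpops` subpopulations (assigned round-robin; testers start in
#' subpopulations 1 and 2) whose per-locus frequencies are Balding-Nichols
#' draws around the ancestral frequency, giving the panel genuine genomic
#' relatedness structure. Marker positions are strictly increasing within
#' each chromosome. With `residualHet > 0` that fraction of calls is
#' flipped to dosage 1 to exercise downstream heterozygosity policies.
#'
#' @param config a [SimConfig].
#' @return a [GenotypeMatrix] with `nTesters + nMales` individuals.
#' @export
simulateParents <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nMarkers < 1) stop("nMarkers must be >= 1")
  set.seed(.simSeed(config, "parents"))
  nInd <- config@nTesters + config@nMales
  m <- config@nMarkers
  perChrom <- diff(floor(seq(0, m, length.out = config@nChromosomes + 1)))
  map <- do.call(rbind, lapply(seq_len(config@nChromosomes), function(ch) {
    k <- perChrom[ch]
    if (k == 0) return(NULL)
    data.frame(chrom = sprintf("chr%02d", ch),
               pos = sort(sample.int(config@chromLengthBp, k)))
  }))
  p <- runif(m, config@mafRange[1], config@mafRange[2])
  if (config@fst > 0 && config@nSubpops > 1) {
    subpop <- c(rep(seq_len(config@nSubpops), length.out = config@nTesters),
                rep(seq_len(config@nSubpops), length.out = config@nMales))
    fac <- (1 - config@fst) / config@fst
    d <- matrix(0, nInd, m)
    for (s in seq_len(config@nSubpops)) {
      rows <- which(subpop == s)
      if (!length(rows)) next
      ps <- rbeta(m, p * fac, (1 - p) * fac)
      d[rows, ] <- matrix(2 * rbinom(length(rows) * m, 1,
                                     rep(ps, each = length(rows))),
                          length(rows), m)
    }
  } else {
    d <- matrix(2 * rbinom(nInd * m, 1, rep(p, each = nInd)), nInd, m)
  }
  rownames(d) <- c(.testerIds(config), .maleIds(config))
  if (config@residualHet > 0) {
    set.seed(.simSeed(config, "het"))
    flip <- which(runif(length(d)) < config@residualHet)
    d[flip] <- 1
  }
  genotypeMatrix(d, map)
}

#' Simulate the factorial trial phenotypes with known truths
#'
#' All `nTesters x nMales` hybrids are formed. Male GCA values are either a
#' rescaled linear combination of centered male dosages (`gcaMode =
#' "marker"`, so genomic prediction has signal) or i.i.d. normal; either way
#' they are centered and scaled so their sample variance equals
#' `varGcaMale` exactly. SCA deviations are i.i.d. `N(0, varSca)`,
#' male-by-year interactions `N(0, varGxe)`, block effects `N(0, varBlock)`
#' and plot errors `N(0, varError)`. One phenotype row is emitted per
#' hybrid x year x replication (block assigned by random partition within
#' replication), plus parent rows (per-se genetic value + the same block and
#' error structure) so mid-parent heterosis is estimable.
#'
#' @param parents a [GenotypeMatrix] from [simulateParents()].
#' @param config the same [SimConfig].
#' @return list with `design` (plot-level data.frame: genotype, role,
#'   female, male, year, rep, block, Y) and `truth` (a [SimTruth]).
#' @export
simulateTrial <- function(parents, config) {
  stopifnot(is(config, "SimConfig"))
  totVar <- config@varGcaMale + config@varSca + config@varGxe +
    config@varBlock + config@varError
  if (totVar <= 0 && all(config@testerEffects == 0))
    stop("degenerate configuration: total variance is 0")
  testers <- .testerIds(config)
  males <- .maleIds(config)
  years <- .yearIds(config)
  reps <- sprintf("R%d", seq_len(config@nReps))
  crosses <- expand.grid(female = testers, male = males,
                         stringsAsFactors = FALSE)
  crosses <- crosses[order(crosses$female, crosses$male), ]
  hybrids <- paste(crosses$female, crosses$male, sep = "/")

  ## male GCA
  set.seed(.simSeed(config, "gca"))
  if (config@gcaMode == "marker") {
    Zm <- dosages(parents)[males, , drop = FALSE]
    alpha <- rnorm(ncol(Zm))
    g <- as.numeric(scale(Zm, center = TRUE, scale = FALSE) %*% alpha)
  } else {
    g <- rnorm(config@nMales)
  }
  g <- g - mean(g)
  sdg <- sd(g)
  gca <- if (config@varGcaMale > 0 && sdg > 0)
    g / sdg * sqrt(config@varGcaMale) else rep(0, config@nMales)
  names(gca) <- males

  ## SCA
  set.seed(.simSeed(config, "sca"))
  sca <- if (config@varSca > 0)
    rnorm(length(hybrids), 0, sqrt(config@varSca)) else
      rep(0, length(hybrids))
  names(sca) <- hybrids

  ## male x year
  set.seed(.simSeed(config, "gxe"))
  meIds <- as.vector(t(outer(years, males, paste, sep = ":")))
  me <- if (config@varGxe > 0)
    setNames(rnorm(length(meIds), 0, sqrt(config@varGxe)), meIds) else
      setNames(rep(0, length(meIds)), meIds)

  fEff <- setNames(config@testerEffects, testers)
  eEff <- setNames(config@yearEffects, years)
  hybridValue <- config@mu + fEff[crosses$female] + gca[crosses$male] + sca
  names(hybridValue) <- hybrids

  ## parent per-se values: same marker scale, mean heterosisShift below mu
  parentIds <- c(testers, males)
  pd <- dosages(parents)[parentIds, , drop = FALSE]
  if (config@gcaMode == "marker" && config@varGcaMale > 0 && sdg > 0) {
    sc <- as.numeric(scale(pd, center = TRUE, scale = FALSE) %*% alpha)
    sc <- (sc - mean(sc)) / sdg * sqrt(config@varGcaMale)
  } else {
    set.seed(.simSeed(config, "parentError") + 1L)
    sc <- rnorm(length(parentIds), 0, sqrt(max(config@varGcaMale, 0)))
    sc <- sc - mean(sc)
  }
  parentValue <- setNames(config@mu - config@heterosisShift + sc, parentIds)

  ## plot table: hybrids + parents, each year x rep
  units <- data.frame(
    genotype = c(hybrids, parentIds),
    role = c(rep("hybrid", length(hybrids)),
             rep("female_parent", length(testers)),
             rep("male_parent", length(males))),
    female = c(crosses$female, rep(NA_character_, length(parentIds))),
    male = c(crosses$male, rep(NA_character_, length(parentIds))),
    stringsAsFactors = FALSE)
  nUnits <- nrow(units)
  nBlocks <- config@nBlocksPerRep
  if (nBlocks == 0) nBlocks <- max(1, round(nUnits / 30))

  set.seed(.simSeed(config, "blocks"))
  rows <- vector("list", config@nYears * config@nReps)
  i <- 0
  for (yr in years) for (rp in reps) {
    i <- i + 1
    blk <- sample(rep(seq_len(nBlocks), length.out = nUnits))
    rows[[i]] <- data.frame(units,
      year = yr, rep = rp,
      block = paste(yr, rp, sprintf("B%02d", blk), sep = "_"),
      stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  blockIds <- unique(design$block)
  blockEff <- if (config@varBlock > 0)
    setNames(rnorm(length(blockIds), 0, sqrt(config@varBlock)), blockIds)
  else setNames(rep(0, length(blockIds)), blockIds)

  set.seed(.simSeed(config, "error"))
  err <- if (config@varError > 0)
    rnorm(nrow(design), 0, sqrt(config@varError)) else rep(0, nrow(design))

  isHyb <- design$role == "hybrid"
  gval <- numeric(nrow(design))
  gval[isHyb] <- hybridValue[design$genotype[isHyb]]
  gval[!isHyb] <- parentValue[design$genotype[!isHyb]]
  gxe <- numeric(nrow(design))
  gxe[isHyb] <- me[paste(design$year[isHyb], design$male[isHyb], sep = ":")]
  design$Y <- gval + eEff[design$year] + gxe + blockEff[design$block] + err
  rownames(design) <- NULL

  truth <- new("SimTruth", gcaMale = gca, sca = sca,
               hybridValue = hybridValue, parentValue = parentValue,
               varianceComponents = c(gca_male = config@varGcaMale,
                                      sca = config@varSca,
                                      gxe = config@varGxe,
                                      block = config@varBlock,
                                      error = config@varError))
  list(design = design, truth = truth)
}

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@gcaMale), "male GCAs,",
      length(object@hybridValue), "hybrid values,",
      length(object@parentValue), "parent values\n")
})

#' Crossing table of a simulated (or any) design
#'
#' @param design plot-level data.frame with hybrid rows.
#' @return data.frame (hybrid, female, male), one row per hybrid, sorted by
#'   hybrid id.
#' @export
crossingTable <- function(design) {
  h <- unique(design[design$role == "hybrid",
                     c("genotype", "female", "male")])
  names(h)[1] <- "hybrid"
  h <- h[order(h$hybrid), ]
  rownames(h) <- NULL
  h
}
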