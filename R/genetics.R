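## Derived quantitative-genetic statistics: plot QC for grain traits,
## within-year spatial adjustment, mid-parent and inbred-midparent
## heterosis, broad- and narrow-sense heritability, GCA/SCA variance
## decomposition, and hybrid genetic values.

#' Quality-control grain-yield plots
#'
#' Plots with harvest weight strictly below `minHarvestG` get their
#' grain-trait values (`traits`) set missing (poor stand); plots with grain
#' moisture strictly below `minMoisturePct` get the moisture replaced by the
#' same-year mean of moistures at or above the threshold (machine-error
#' imputation). Every modified cell is recorded in the attached QC log.
#'
#' @param d plot-level data.frame with `harvest_weight`, `moisture`, `year`.
#' @param minHarvestG harvest-weight threshold in grams (default 1000).
#' @param minMoisturePct moisture threshold in percent (default 10).
#' @param traits grain-trait columns to blank for low-weight plots (those of
#'   `c("GY", "GNP")` present, by default).
#' @return the QC'd data.frame; attribute `"qcLog"` is a data.frame of
#'   (row, column, old, new, reason).
#' @export
qcGrainPlots <- function(d, minHarvestG = 1000, minMoisturePct = 10,
                         traits = intersect(c("GY", "GNP"), names(d))) {
  stopifnot(all(c("harvest_weight", "moisture") %in% names(d)))
  log <- list()
  low <- which(!is.na(d$harvest_weight) & d$harvest_weight < minHarvestG)
  for (tr in traits) {
    ch <- low[!is.na(d[[tr]][low])]
    if (length(ch))
      log[[length(log) + 1]] <- data.frame(row = ch, column = tr,
        old = d[[tr]][ch], new = NA_real_, reason = "harvest_weight_low")
    d[[tr]][low] <- NA_real_
  }
  wet <- which(!is.na(d$moisture) & d$moisture < minMoisturePct)
  if (length(wet)) {
    yrMean <- tapply(
      d$moisture[!is.na(d$moisture) & d$moisture >= minMoisturePct],
      d$year[!is.na(d$moisture) & d$moisture >= minMoisturePct], mean)
    repl <- yrMean[as.character(d$year[wet])]
    if (anyNA(repl))
      stop("a year has no moisture readings at or above the threshold")
    log[[length(log) + 1]] <- data.frame(row = wet, column = "moisture",
      old = d$moisture[wet], new = as.numeric(repl),
      reason = "moisture_below_threshold")
    d$moisture[wet] <- as.numeric(repl)
  }
  attr(d, "qcLog") <- if (length(log)) do.call(rbind, log) else
    data.frame(row = integer(0), column = character(0), old = numeric(0),
               new = numeric(0), reason = character(0))
  d
}

#' Derive grain traits from harvest weight, moisture and TGW
#'
#' Grain number per plot is `GNP = harvest_weight / tgw * 1000` (TGW is the
#' thousand-grain weight in grams). Grain yield is the harvest weight
#' standardized to a fixed moisture basis and converted to t/ha:
#' `GY = harvest_weight * (100 - moisture) / (100 - standardMoisture)
#' / plotAreaM2 / 100`.
#'
#' @param d plot table with `harvest_weight` (g), `moisture` (%), `tgw` (g).
#' @param plotAreaM2 harvested plot area in square meters.
#' @param standardMoisture moisture basis in percent (default 14).
#' @return `d` with `GNP` and `GY` columns added.
#' @export
deriveGrainTraits <- function(d, plotAreaM2, standardMoisture = 14) {
  stopifnot(all(c("harvest_weight", "moisture", "tgw") %in% names(d)))
  if (any(!is.na(d$tgw) & d$tgw <= 0)) stop("tgw must be positive")
  d$GNP <- d$harvest_weight / d$tgw * 1000
  ## g/m2 -> t/ha is a factor of 1/100
  d$GY <- d$harvest_weight * (100 - d$moisture) /
    (100 - standardMoisture) / plotAreaM2 / 100
  d
}

#' Spatially adjust phenotypes within each year
#'
#' Per year, fits `trait ~ mu + replication (fixed) + genotype (random,
#' identity) + block-in-rep (random, identity) + error` and returns the
#' adjusted value `mu-hat + BLUP(genotype)`. Parents and hybrids enter the
#' same fit. With a single replication and a single block the model is
#' unidentifiable and raw genotype means are returned with a warning.
#'
#' @param d plot-level data.frame (columns genotype, year, rep, block and
#'   the trait).
#' @param trait trait column name.
#' @return data.frame (genotype, year, adjusted).
#' @export
adjustPhenotypesByYear <- function(d, trait = "Y") {
  out <- lapply(split(d, d$year), function(dy) {
    dy <- dy[!is.na(dy[[trait]]), , drop = FALSE]
    if (length(unique(dy$genotype)) < 2)
      stop("need at least 2 genotypes per year")
    if (length(unique(dy$rep)) < 2 && length(unique(dy$block)) < 2) {
      warning("single replication and block in year ", dy$year[1],
              ": falling back to raw genotype means")
      m <- tapply(dy[[trait]], dy$genotype, mean)
      return(data.frame(genotype = names(m), year = dy$year[1],
                        adjusted = as.numeric(m)))
    }
    spec <- modelSpec(trait, fixed = "rep",
                      random = list(randomTerm("genotype", "genotype"),
                                    randomTerm("block", "block")))
    fit <- remlFit(dy, spec)
    mu <- fit@fixedEffects$estimate[fit@fixedEffects$term == "(Intercept)"]
    bl <- blupTable(fit, "genotype")
    data.frame(genotype = bl$level, year = dy$year[1],
               adjusted = mu + bl$blup)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mid-parent heterosis per hybrid and year
#'
#' `MPH% = 100 * (F1 - MPV) / MPV` where F1 is the hybrid's adjusted value
#' and MPV the mean of its two parents' adjusted values in the same year.
#' Female testers may be represented phenotypically by isogenic maintainer
#' lines via `femaleAlias` (a named vector, female id -> phenotyped id).
#' Hybrids missing a parent value, or with MPV = 0, are reported with an NA
#' and a reason.
#'
#' @param adjusted data.frame (genotype, year, adjusted) from
#'   [adjustPhenotypesByYear()].
#' @param crosses data.frame (hybrid, female, male).
#' @param femaleAlias optional named character vector mapping female ids to
#'   the ids carrying their phenotypes.
#' @return data.frame (hybrid, female, male, year, f1, midparent,
#'   mph_percent, note).
#' @export
midParentHeterosis <- function(adjusted, crosses, femaleAlias = NULL) {
  fem <- crosses$female
  if (!is.null(femaleAlias)) {
    hit <- fem %in% names(femaleAlias)
    fem[hit] <- femaleAlias[fem[hit]]
  }
  out <- lapply(split(adjusted, adjusted$year), function(ay) {
    val <- setNames(ay$adjusted, ay$genotype)
    f1 <- val[crosses$hybrid]
    pv <- (val[fem] + val[crosses$male]) / 2
    mph <- 100 * (f1 - pv) / pv
    note <- rep("", nrow(crosses))
    note[is.na(f1)] <- "missing_hybrid_value"
    note[is.na(pv) & note == ""] <- "missing_parent_value"
    note[!is.na(pv) & pv == 0] <- "midparent_zero"
    mph[note != ""] <- NA_real_
    data.frame(hybrid = crosses$hybrid, female = crosses$female,
               male = crosses$male, year = ay$year[1],
               f1 = as.numeric(f1), midparent = as.numeric(pv),
               mph_percent = as.numeric(mph), note = note)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inbred-midparent heterosis (population level)
#'
#' `IMPH = mean(hybrid adjusted values) - mean(parent adjusted values)`,
#' per year; each parent line counts once (testers via their maintainer
#' alias), irrespective of how many crosses it enters.
#'
#' @param adjusted data.frame (genotype, year, adjusted).
#' @param roles data.frame (genotype, role) with roles `hybrid`,
#'   `female_parent`, `male_parent`.
#' @return data.frame (year, hybrid_mean, parent_mean, imph).
#' @export
inbredMidparentHeterosis <- function(adjusted, roles) {
  role <- setNames(roles$role, roles$genotype)[adjusted$genotype]
  out <- lapply(split(seq_len(nrow(adjusted)), adjusted$year), function(ix) {
    h <- adjusted$adjusted[ix][role[ix] == "hybrid"]
    p <- adjusted$adjusted[ix][role[ix] %in% c("female_parent",
                                               "male_parent")]
    if (!length(h) || !length(p)) stop("empty hybrid or parent group")
    data.frame(year = adjusted$year[ix][1], hybrid_mean = mean(h),
               parent_mean = mean(p), imph = mean(h) - mean(p))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Closed-form heritabilities from variance components
#'
#' Broad sense: `H2 = s2H / (s2H + s2HE/nE + s2e/(nE*nR))`. Narrow sense
#' uses the additive variance from the genomic refit in the numerator over
#' the unscaled identity-fit components: `h2 = s2Ha / (s2H + s2HE + s2e)`
#' (denominator exactly as conventionally printed for this design; a
#' plot-basis variant is deliberately not substituted).
#'
#' @param s2H,s2HE,s2e identity-fit hybrid, hybrid-by-year and error
#'   variances.
#' @param nE,nR numbers of years and replications.
#' @param s2Ha additive (genomic-fit) hybrid variance.
#' @return scalar heritability.
#' @export
broadSenseH2 <- function(s2H, s2HE, s2e, nE, nR) {
  s2H / (s2H + s2HE / nE + s2e / (nE * nR))
}

#' @rdname broadSenseH2
#' @export
narrowSenseH2 <- function(s2Ha, s2H, s2HE, s2e) {
  s2Ha / (s2H + s2HE + s2e)
}

#' Broad- and narrow-sense heritability of a trait
#'
#' Fits the hybrid phenotypic model (year fixed; hybrid, hybrid-by-year and
#' block-in-rep-in-year random, identity structures) for the broad-sense
#' estimate, then refits with the hybrid genomic relationship matrix
#' replacing the identity (and year-identity Kronecker GRM for the
#' interaction) for the additive variance and the narrow-sense estimate.
#'
#' @param d plot-level data.frame; only hybrid rows are used.
#' @param trait trait column.
#' @param grmHybrids optional [RelationshipMatrix] of the hybrids; when
#'   absent only H2 is computed.
#' @return list with `H2`, `h2` (NA without a GRM), `components` (named:
#'   identity fit s2H, s2HE, s2e; genomic s2Ha), `nE`, `nR`, and the two
#'   fits.
#' @export
heritabilities <- function(d, trait = "Y", grmHybrids = NULL) {
  dh <- d[d$role == "hybrid", , drop = FALSE]
  nE <- length(unique(dh$year))
  nR <- length(unique(dh$rep))
  if (nE < 2)
    warning("a single year: hybrid-by-year variance unidentifiable, ",
            "treated as 0")
  rterms <- function(structH, structHE) {
    list(randomTerm("hybrid", "genotype", structH),
         if (nE >= 2) randomTerm("hybridYear", c("year", "genotype"),
                                 structHE),
         randomTerm("block", "block"))
  }
  ids <- sort(unique(dh$genotype))
  specI <- modelSpec(trait, fixed = "year",
    random = Filter(Negate(is.null), rterms(identityCov(ids),
      kroneckerCov(identityCov(sort(unique(dh$year))), identityCov(ids)))))
  fitI <- remlFit(dh, specI)
  vc <- varComp(fitI)
  s2H <- vc[["hybrid"]]
  s2HE <- if ("hybridYear" %in% names(vc)) vc[["hybridYear"]] else 0
  s2e <- vc[["residual"]]
  H2 <- broadSenseH2(s2H, s2HE, s2e, nE, nR)

  h2 <- NA_real_
  s2Ha <- NA_real_
  fitG <- NULL
  if (!is.null(grmHybrids)) {
    sG <- suppliedCov(grmHybrids)
    specG <- modelSpec(trait, fixed = "year",
      random = Filter(Negate(is.null), rterms(sG,
        kroneckerCov(identityCov(sort(unique(dh$year))), sG))))
    fitG <- remlFit(dh, specG)
    s2Ha <- varComp(fitG)[["hybrid"]]
    h2 <- narrowSenseH2(s2Ha, s2H, s2HE, s2e)
  }
  list(trait = trait, H2 = H2, h2 = h2,
       components = c(s2H = s2H, s2HE = s2HE, s2e = s2e, s2Ha = s2Ha),
       nE = nE, nR = nR, fitIdentity = fitI, fitGenomic = fitG)
}

#' Combining-ability analysis of a tester-by-line factorial
#'
#' Fits the GCA model (tester and year fixed; male GCA, male-by-year and
#' block random) or the GCA+SCA model (adds the tester-by-male SCA and its
#' year interaction). With `structure = "genomic"` the male term uses the
#' male GRM, the interaction the year-identity Kronecker of it, and the SCA
#' terms the Kronecker of the female and male GRMs; `"identity"` fits the
#' identity-matrix BLUP twin of the same model.
#'
#' @param d plot-level data.frame; only hybrid rows are used.
#' @param grmMales,grmFemales [RelationshipMatrix]es (genomic structure
#'   only; `grmFemales` only for `includeSca = TRUE`).
#' @param trait trait column.
#' @param includeSca fit the SCA terms?
#' @param structure `"genomic"` or `"identity"`.
#' @return list with `fit` (a [ModelFit]) and `proportions`: each variance
#'   component's share of the summed components (residual included).
#' @export
combiningAbility <- function(d, grmMales = NULL, grmFemales = NULL,
                             trait = "Y", includeSca = FALSE,
                             structure = c("genomic", "identity")) {
  structure <- match.arg(structure)
  dh <- d[d$role == "hybrid", , drop = FALSE]
  if (length(unique(dh$female)) < 2) stop("need at least 2 testers")
  years <- sort(unique(dh$year))
  males <- sort(unique(dh$male))
  females <- sort(unique(dh$female))
  if (structure == "genomic") {
    if (is.null(grmMales)) stop("genomic structure needs grmMales")
    if (!all(males %in% rownames(grmMales@values)))
      stop("males missing from grmMales")
    sM <- suppliedCov(grmMales)
    sF <- if (!is.null(grmFemales)) suppliedCov(grmFemales) else NULL
    if (includeSca && (is.null(sF) || covDim(sF) < 2))
      stop("SCA terms need a female relationship matrix of dimension >= 2")
  } else {
    sM <- identityCov(males)
    sF <- identityCov(females)
  }
  yearsI <- identityCov(years)
  terms <- list(
    randomTerm("maleGCA", "male", sM),
    randomTerm("maleYear", c("year", "male"), kroneckerCov(yearsI, sM)),
    randomTerm("block", "block"))
  if (includeSca) {
    sFM <- kroneckerCov(sF, sM)
    terms <- append(terms, list(
      randomTerm("sca", c("female", "male"), sFM),
      randomTerm("scaYear", c("year", "female", "male"),
                 kroneckerCov(yearsI, sFM))), after = 2)
  }
  spec <- modelSpec(trait, fixed = c("female", "year"), random = terms)
  fit <- remlFit(dh, spec)
  vc <- varComp(fit)
  props <- vc / sum(vc)
  list(fit = fit, proportions = props, includeSca = includeSca,
       structure = structure)
}

#' Hybrid genetic values from a combining-ability fit
#'
#' `yhat_ij = mu-hat + f-hat_i + m-hat_j (+ s-hat_ij)`: the intercept plus
#' the tester fixed-effect contrast (0 for the reference tester), the male
#' GCA BLUP, and, for GCA+SCA fits, the SCA BLUP. Values are computable for
#' untested pairs: male GCAs propagate through the relationship matrix, and
#' an SCA level carrying no information beyond the structure has BLUP 0.
#'
#' @param ca result of [combiningAbility()].
#' @param crosses data.frame (hybrid, female, male); defaults to all
#'   (tester, male) pairs in the fit.
#' @return data.frame (hybrid, female, male, value).
#' @export
hybridGeneticValues <- function(ca, crosses = NULL) {
  fit <- ca$fit
  fe <- fit@fixedEffects
  mu <- fe$estimate[fe$term == "(Intercept)"]
  fEst <- setNames(fe$estimate[fe$term == "female"],
                   fe$level[fe$term == "female"])
  m <- setNames(fit@blup[["maleGCA"]], names(fit@blup[["maleGCA"]]))
  if (is.null(crosses)) {
    females <- sort(unique(c(names(fEst),
      fit@fixedEffects$level[fit@fixedEffects$term == "female"])))
    ## reference female level: present in data but absorbed in intercept
    allF <- if (ca$includeSca)
      sort(unique(sub(":.*$", "", names(fit@blup[["sca"]])))) else
        names(fEst)
    crosses <- expand.grid(female = allF, male = names(m),
                           stringsAsFactors = FALSE)
    crosses$hybrid <- paste(crosses$female, crosses$male, sep = "/")
  }
  if (!all(crosses$male %in% names(m)))
    stop("male id(s) absent from the male relationship structure: ",
         paste(setdiff(crosses$male, names(m)), collapse = ", "))
  fshift <- ifelse(crosses$female %in% names(fEst),
                   fEst[crosses$female], 0)
  val <- mu + fshift + m[crosses$male]
  if (ca$includeSca) {
    s <- fit@blup[["sca"]]
    key <- paste(crosses$female, crosses$male, sep = ":")
    if (!all(key %in% names(s)))
      stop("cross(es) absent from the SCA structure: ",
           paste(setdiff(key, names(s)), collapse = ", "))
    val <- val + s[key]
  }
  data.frame(hybrid = crosses$hybrid, female = crosses$female,
             male = crosses$male, value = as.numeric(val),
             stringsAsFactors = FALSE)
}
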