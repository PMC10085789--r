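## Cross-validation engines for the three prediction scenarios and the
## reliability-corrected prediction-accuracy statistic.

#' Define a cross-validation scheme
#'
#' @param scenario `"T2"` (20% of hybrids held out such that every
#'   validation hybrid's male stays phenotyped in training via the other
#'   tester), `"T1F"` (20% of males held out with all their hybrids, so only
#'   the female testers are shared), or `"maleGCA"` (a fixed number of males
#'   masked and their GCA predicted).
#' @param fraction validation fraction (hybrids for T2, males for T1F).
#' @param count males masked under maleGCA (default 60).
#' @param nIterations resampling iterations (default 100).
#' @param seedStart first iteration seed (default 123; iteration i uses
#'   seedStart + i - 1, i.e. 123..222 for the default 100 iterations).
#' @param model `"GCA"` or `"GCA+SCA"`.
#' @return a [CVScheme].
#' @export
cvScheme <- function(scenario = c("T2", "T1F", "maleGCA"), fraction = 0.2,
                     count = 60, nIterations = 100, seedStart = 123,
                     model = c("GCA", "GCA+SCA")) {
  new("CVScheme", scenario = match.arg(scenario), fraction = fraction,
      count = count, nIterations = nIterations, seedStart = seedStart,
      model = match.arg(model))
}

#' Construct one training/validation split
#'
#' Fold membership is a pure function of the iteration seed and the
#' lexicographically sorted hybrid table. Under T2, hybrids whose male has a
#' single cross are ineligible for validation (their exclusion is recorded
#' in the `"note"` attribute); eligible hybrids are scanned in shuffled
#' order and accepted while their male retains at least one training hybrid.
#'
#' @param crosses data.frame (hybrid, female, male).
#' @param scheme a [CVScheme].
#' @param iterationSeed integer seed for this iteration.
#' @return list with `training` and `validation` hybrid ids (for maleGCA,
#'   also `maskedMales`).
#' @export
makeFolds <- function(crosses, scheme, iterationSeed) {
  crosses <- crosses[order(crosses$hybrid), , drop = FALSE]
  hy <- crosses$hybrid
  set.seed(iterationSeed)
  note <- character(0)
  if (scheme@scenario == "T2") {
    perMale <- table(crosses$male)
    eligible <- which(perMale[crosses$male] >= 2)
    if (length(eligible) < length(hy))
      note <- paste0(sum(perMale < 2), " single-cross male(s) ineligible")
    target <- round(scheme@fraction * length(hy))
    remain <- perMale
    val <- integer(0)
    for (i in sample(eligible)) {
      if (length(val) >= target) break
      m <- crosses$male[i]
      if (remain[m] >= 2) {
        val <- c(val, i)
        remain[m] <- remain[m] - 1
      }
    }
    validation <- hy[sort(val)]
  } else if (scheme@scenario == "T1F") {
    males <- sort(unique(crosses$male))
    nv <- max(1, round(scheme@fraction * length(males)))
    vm <- sort(sample(males, nv))
    validation <- hy[crosses$male %in% vm]
  } else {
    males <- sort(unique(crosses$male))
    nv <- min(scheme@count, length(males) - 1)
    vm <- sort(sample(males, nv))
    out <- list(training = hy[!crosses$male %in% vm],
                validation = hy[crosses$male %in% vm], maskedMales = vm)
    attr(out, "note") <- note
    return(out)
  }
  out <- list(training = setdiff(hy, validation), validation = validation)
  attr(out, "note") <- note
  out
}

#' Run cross-validated genomic prediction for one scenario
#'
#' Reliability is computed once from the complete data as the squared
#' Pearson correlation between full-data GBLUP and full-data identity-model
#' BLUP values (hybrid genetic values for T2/T1F; male GCAs for maleGCA).
#' Per iteration, the genomic model is refit on training rows only,
#' validation values are predicted (relationship matrices propagate
#' information to unphenotyped males), and predictive ability is the
#' Pearson correlation between predictions and the validation individuals'
#' full-data BLUPs. Prediction accuracy is predictive ability divided by
#' the square root of reliability. Iterations whose fit does not converge
#' and ends on a variance boundary are skipped with a note.
#'
#' @param d plot-level data.frame (hybrid rows are used).
#' @param grmMales,grmFemales [RelationshipMatrix]es for the genomic model.
#' @param scheme a [CVScheme].
#' @param trait trait column.
#' @return an [AccuracyReport].
#' @export
runCV <- function(d, grmMales, grmFemales, scheme, trait = "Y") {
  dh <- d[d$role == "hybrid", , drop = FALSE]
  crosses <- crossingTable(dh)
  includeSca <- scheme@model == "GCA+SCA"

  caI <- combiningAbility(dh, trait = trait, includeSca = includeSca,
                          structure = "identity")
  caG <- combiningAbility(dh, grmMales = grmMales,
                          grmFemales = grmFemales, trait = trait,
                          includeSca = includeSca, structure = "genomic")
  if (scheme@scenario == "maleGCA") {
    males <- sort(unique(crosses$male))
    obsFull <- setNames(caI$fit@blup[["maleGCA"]][males], males)
    gbFull <- setNames(caG$fit@blup[["maleGCA"]][males], males)
    reliability <- cor(gbFull, obsFull)^2
  } else {
    hvI <- hybridGeneticValues(caI, crosses)
    hvG <- hybridGeneticValues(caG, crosses)
    obsFull <- setNames(hvI$value, hvI$hybrid)
    reliability <- cor(hvG$value, hvI$value)^2
  }
  if (!is.finite(reliability) || reliability <= 0)
    stop("reliability is zero; prediction accuracy undefined")

  rows <- vector("list", scheme@nIterations)
  for (i in seq_len(scheme@nIterations)) {
    seed <- scheme@seedStart + i - 1
    folds <- makeFolds(crosses, scheme, seed)
    dTrain <- dh[dh$genotype %in% folds$training, , drop = FALSE]
    note <- ""
    r <- NA_real_
    fitTry <- tryCatch(
      combiningAbility(dTrain, grmMales = grmMales,
                       grmFemales = grmFemales, trait = trait,
                       includeSca = includeSca, structure = "genomic"),
      error = function(e) e)
    if (inherits(fitTry, "error")) {
      note <- paste("fit_error:", conditionMessage(fitTry))
    } else if (!fitTry$fit@converged &&
               any(varComp(fitTry$fit)[names(varComp(fitTry$fit)) !=
                                       "residual"] == 0)) {
      note <- "not_converged_on_boundary"
    } else {
      if (scheme@scenario == "maleGCA") {
        pred <- fitTry$fit@blup[["maleGCA"]][folds$maskedMales]
        obs <- obsFull[folds$maskedMales]
      } else {
        vc <- crosses[crosses$hybrid %in% folds$validation, , drop = FALSE]
        pv <- hybridGeneticValues(fitTry, vc)
        pred <- pv$value
        obs <- obsFull[pv$hybrid]
      }
      if (sd(pred) == 0 || sd(obs) == 0) {
        note <- "zero_variance_in_predictions"
      } else {
        r <- cor(pred, obs)
      }
    }
    rows[[i]] <- data.frame(iteration = i, seed = seed, r = r,
      accuracy = r / sqrt(reliability),
      nValidation = length(folds$validation), note = note,
      stringsAsFactors = FALSE)
  }
  new("AccuracyReport", scenario = scheme@scenario, trait = trait,
      model = scheme@model, reliability = reliability,
      iterations = do.call(rbind, rows))
}

#' Summarize an accuracy report
#'
#' @param report an [AccuracyReport] (or a list of them).
#' @return data.frame (scenario, trait, model, reliability, n_valid,
#'   n_skipped, mean_r, sd_r, mean_accuracy, sd_accuracy).
#' @export
summarizeAccuracy <- function(report) {
  if (is.list(report))
    return(do.call(rbind, lapply(report, summarizeAccuracy)))
  it <- report@iterations
  ok <- !is.na(it$r)
  if (sum(ok) < 2) warning("fewer than 2 valid iterations; SD undefined")
  data.frame(scenario = report@scenario, trait = report@trait,
             model = report@model, reliability = report@reliability,
             n_valid = sum(ok), n_skipped = sum(!ok),
             mean_r = mean(it$r[ok]), sd_r = sd(it$r[ok]),
             mean_accuracy = mean(it$accuracy[ok]),
             sd_accuracy = sd(it$accuracy[ok]),
             stringsAsFactors = FALSE)
}

setMethod("show", "AccuracyReport", function(object) {
  s <- summarizeAccuracy(object)
  cat("AccuracyReport [", object@scenario, "/", object@trait, "/",
      object@model, "]: mean accuracy ",
      sprintf("%.3f (%.3f)", s$mean_accuracy, s$sd_accuracy),
      " over ", s$n_valid, " iterations (reliability ",
      sprintf("%.3f", object@reliability), ")\n", sep = "")
})
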