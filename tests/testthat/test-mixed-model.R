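test_that("REML matches lme4 on identity-structure models", {
  skip_if_not_installed("lme4")
  d <- oneWayData(30, 4, sqrt(2), 1, seed = 101)
  d$r <- rep(c("r1", "r2", "r3", "r4"), 30)
  spec <- modelSpec("y", fixed = "r",
                    random = list(randomTerm("g", "g")))
  fit <- remlFit(d, spec)
  lf <- lme4::lmer(y ~ r + (1 | g), d, REML = TRUE)
  expect_equal(unname(varComp(fit)[["g"]]),
               unname(as.numeric(lme4::VarCorr(lf)$g)), tolerance = 1e-6)
  expect_equal(varComp(fit)[["residual"]], sigma(lf)^2, tolerance = 1e-6)
  expect_equal(fit@logLik, as.numeric(logLik(lf)), tolerance = 1e-7)
  blups <- blupTable(fit, "g")
  ref <- lme4::ranef(lf)$g
  expect_equal(blups$blup, ref[blups$level, 1], tolerance = 1e-6)
})

test_that("balanced one-way REML equals ANOVA method-of-moments", {
  d <- oneWayData(40, 5, 1.5, 1, seed = 55)
  fit <- remlFit(d, modelSpec("y", random = list(randomTerm("g", "g"))))
  a <- anova(aov(y ~ g, d))
  msB <- a$`Mean Sq`[1]; msW <- a$`Mean Sq`[2]
  expect_equal(varComp(fit)[["residual"]], msW, tolerance = 1e-6)
  expect_equal(unname(varComp(fit)[["g"]]), (msB - msW) / 5,
               tolerance = 1e-6)
})

test_that("engine logLik equals the dense likelihood at the solution", {
  fx <- toyTrial()
  dh <- fx$design[fx$design$role == "hybrid", ]
  gm <- additiveGRM(fx$parents[sort(unique(dh$male)), ])
  years <- sort(unique(dh$year))
  spec <- modelSpec("Y", fixed = c("female", "year"), random = list(
    randomTerm("maleGCA", "male", suppliedCov(gm)),
    randomTerm("maleYear", c("year", "male"),
               kroneckerCov(identityCov(years), suppliedCov(gm))),
    randomTerm("block", "block")))
  fit <- remlFit(dh, spec)
  vc <- varComp(fit)
  vc[vc == 0] <- 1e-9
  expect_equal(fit@logLik, denseREMLLogLik(dh, spec, vc),
               tolerance = 1e-6)
})

test_that("BLUEs at zero random variance equal ordinary least squares", {
  fx <- toyTrial()
  dh <- fx$design[fx$design$role == "hybrid", ]
  spec <- modelSpec("Y", fixed = c("female", "year"),
                    random = list(randomTerm("maleGCA", "male")))
  fit <- remlFit(dh, spec, varCompFixed = c(maleGCA = 0, residual = 1))
  ols <- lm(Y ~ factor(female) + factor(year), dh)
  expect_equal(unname(fit@fixedEffects$estimate),
               unname(coef(ols)), tolerance = 1e-8)
  expect_true(all(blupTable(fit, "maleGCA")$blup == 0))
})

test_that("GBLUP equals marker-effect ridge regression on toys", {
  set.seed(61)
  n <- 25; m <- 40
  Zm <- matrix(rbinom(n * m, 2, 0.4), n,
               dimnames = list(sprintf("i%02d", 1:n), NULL))
  g <- genotypeMatrix(Zm, data.frame(chrom = "c1", pos = seq_len(m) * 101))
  G <- additiveGRM(g)
  p <- colMeans(Zm) / 2
  c0 <- 2 * sum(p * (1 - p))
  Zc <- sweep(Zm, 2, 2 * p)
  d <- data.frame(id = rownames(Zm),
                  y = rnorm(n, 0, 1) + Zc %*% rnorm(m, 0, 0.3))
  s2g <- 1.3; s2e <- 0.8
  fit <- remlFit(d, modelSpec("y", random = list(
    randomTerm("id", "id", suppliedCov(G)))),
    varCompFixed = c(id = s2g, residual = s2e))
  mu <- fit@fixedEffects$estimate[1]
  # ridge marker solutions with matched regularization
  lambda <- s2e * c0 / s2g
  a <- solve(crossprod(Zc) + diag(lambda, m), crossprod(Zc, d$y - mu))
  expect_equal(blupTable(fit, "id")$blup[match(rownames(Zm),
               blupTable(fit, "id")$level)], as.numeric(Zc %*% a),
               tolerance = 1e-6)
})

test_that("row permutation leaves all estimates unchanged", {
  fx <- toyTrial()
  dh <- fx$design[fx$design$role == "hybrid", ]
  spec <- modelSpec("Y", fixed = "female", random = list(
    randomTerm("maleGCA", "male"), randomTerm("block", "block")))
  f1 <- remlFit(dh, spec)
  set.seed(3)
  f2 <- remlFit(dh[sample(nrow(dh)), ], spec)
  expect_equal(varComp(f1), varComp(f2), tolerance = 1e-10)
  expect_equal(f1@fixedEffects$estimate, f2@fixedEffects$estimate,
               tolerance = 1e-10)
  expect_equal(f1@blup[["maleGCA"]], f2@blup[["maleGCA"]],
               tolerance = 1e-10)
})

test_that("identity BLUPs shrink toward zero and sum to about zero", {
  d <- oneWayData(25, 4, 1, 1.5, seed = 77)
  fit <- remlFit(d, modelSpec("y", random = list(randomTerm("g", "g"))))
  bl <- blupTable(fit, "g")
  rawDev <- tapply(d$y, d$g, mean) - mean(d$y)
  expect_true(all(abs(bl$blup) <= abs(rawDev[bl$level]) + 1e-10))
  expect_lt(abs(sum(bl$blup)), 1e-6)
})

test_that("perfectly correlated 2-level structure forces equal BLUPs", {
  set.seed(9)
  K <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  d <- data.frame(grp = rep(c("a", "b"), each = 10), y = rnorm(20, 5, 1))
  d$y[d$grp == "b"] <- d$y[d$grp == "b"] + 2
  fit <- remlFit(d, modelSpec("y", random = list(
    randomTerm("grp", "grp", suppliedCov(K)))),
    varCompFixed = c(grp = 1, residual = 1))
  bl <- blupTable(fit, "grp")
  expect_equal(bl$blup[1], bl$blup[2], tolerance = 1e-6)
})

test_that("kronecker structures obey the product definition", {
  I2 <- identityCov(c("u", "v")); I3 <- identityCov(c("x", "y", "z"))
  k <- kroneckerCov(I2, I3)
  expect_equal(unname(covMatrix(k)), diag(6))
  expect_equal(covIds(k), c("u:x", "u:y", "u:z", "v:x", "v:y", "v:z"))
  A <- matrix(c(2, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  B <- matrix(c(1, -.3, -.3, 2), 2,
              dimnames = list(c("p", "q"), c("p", "q")))
  kk <- kroneckerCov(suppliedCov(A), suppliedCov(B))
  M <- covMatrix(kk)
  for (i in 1:2) for (j in 1:2) for (k2 in 1:2) for (l in 1:2)
    expect_equal(M[(i - 1) * 2 + k2, (j - 1) * 2 + l],
                 covMatrix(suppliedCov(A))[i, j] *
                   covMatrix(suppliedCov(B))[k2, l])
  expect_equal(covLogDet(kk),
               as.numeric(determinant(M)$modulus), tolerance = 1e-10)
  expect_error(kroneckerCov(I2, I3, maxDim = 5), "cap")
})

test_that("aliased fixed designs are reported with column names", {
  d <- data.frame(y = rnorm(10), a = rep(c("x", "y"), 5),
                  b = rep(c("x", "y"), 5))
  expect_error(remlFit(d, modelSpec("y", fixed = c("a", "b"))),
               "aliased.*b", ignore.case = TRUE)
})

test_that("unknown structure levels and terms raise errors", {
  d <- data.frame(y = rnorm(8), g = rep(c("a", "b"), 4))
  K <- diag(2); dimnames(K) <- list(c("a", "zz"), c("a", "zz"))
  expect_error(remlFit(d, modelSpec("y", random = list(
    randomTerm("g", "g", suppliedCov(K))))), "absent")
  fit <- remlFit(d, modelSpec("y", random = list(randomTerm("g", "g"))))
  expect_error(blupTable(fit, "nope"), "unknown random term")
})

test_that("variance recovery and AIC model selection behave on truth", {
  # moderately sized end-to-end check: fit the SCA model to data simulated
  # with and without SCA variance
  aicGcaWins <- 0; scaShare <- numeric(0)
  for (seed in 1:3) {
    cfg <- simConfig(nMales = 60, nMarkers = 400, varSca = 0,
                     seed = 500 + seed)
    d <- simulateTrial(simulateParents(cfg), cfg)$design
    caS <- combiningAbility(d, trait = "Y", includeSca = TRUE,
                            structure = "identity")
    caG <- combiningAbility(d, trait = "Y", includeSca = FALSE,
                            structure = "identity")
    scaShare <- c(scaShare, caS$proportions[["sca"]])
    aicGcaWins <- aicGcaWins + (caG$fit@aic <= caS$fit@aic)
  }
  expect_gte(aicGcaWins, 2)
  expect_lt(mean(scaShare), 0.05)
})
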