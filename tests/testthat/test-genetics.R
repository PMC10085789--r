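test_that("grain-plot QC applies strict thresholds and logs changes", {
  d <- data.frame(year = c(1, 1, 1, 2), harvest_weight = c(999, 1000,
                  2500, 1500), moisture = c(12, 8, 14, 13),
                  GY = c(1, 2, 3, 4), GNP = c(10, 20, 30, 40))
  out <- qcGrainPlots(d)
  expect_true(is.na(out$GY[1]) && is.na(out$GNP[1]))   # 999 g -> missing
  expect_false(is.na(out$GY[2]))                        # 1000 g retained
  expect_equal(out$moisture[2], mean(c(12, 14)))        # 8 -> year mean 13
  log <- attr(out, "qcLog")
  expect_setequal(log$reason[log$row == 1],
                  rep("harvest_weight_low", 2))
  expect_equal(log$new[log$column == "moisture"], 13)
  # no violations: table unchanged, empty log
  clean <- d[3:4, ]
  out2 <- qcGrainPlots(clean)
  expect_equal(out2$GY, clean$GY)
  expect_equal(nrow(attr(out2, "qcLog")), 0)
})

test_that("grain trait derivation follows the closed forms", {
  d <- data.frame(harvest_weight = 2240, moisture = 14, tgw = 22.4)
  out <- deriveGrainTraits(d, plotAreaM2 = 9.29)
  expect_equal(out$GNP, 100000)
  # at standard moisture GY = weight / area / 100 (g/m2 -> t/ha)
  expect_equal(out$GY, 2240 / 9.29 / 100)
  d2 <- d; d2$tgw <- 44.8
  expect_equal(deriveGrainTraits(d2, 9.29)$GNP, 50000)
  expect_error(deriveGrainTraits(transform(d, tgw = 0), 9.29), "positive")
})

test_that("spatial adjustment reduces to genotype means when clean", {
  cfg <- simConfig(nMales = 6, nMarkers = 60, varGxe = 0, varBlock = 0,
                   varError = 0, yearEffects = c(0, 0), seed = 21)
  d <- simulateTrial(simulateParents(cfg), cfg)$design
  adj <- adjustPhenotypesByYear(d, "Y")
  means <- aggregate(Y ~ genotype + year, d, mean)
  m <- merge(adj, means, by.x = c("genotype", "year"),
             by.y = c("genotype", "year"))
  expect_equal(m$adjusted, m$Y, tolerance = 1e-4)
})

test_that("a constant shift of one replication is absorbed", {
  fx <- toyTrial()
  d <- fx$design[fx$design$year == "Y1", ]
  adj1 <- adjustPhenotypesByYear(d, "Y")
  d2 <- d
  d2$Y[d2$rep == "R2"] <- d2$Y[d2$rep == "R2"] + 50
  adj2 <- adjustPhenotypesByYear(d2, "Y")
  dev1 <- adj1$adjusted - mean(adj1$adjusted)
  dev2 <- adj2$adjusted - mean(adj2$adjusted)
  expect_equal(dev1, dev2, tolerance = 1e-4)
})

test_that("simulated block noise: adjustment beats raw means", {
  wins <- 0
  for (seed in 1:5) {
    cfg <- simConfig(nMales = 16, nMarkers = 80, varBlock = 4,
                     nBlocksPerRep = 6, varError = 0.5, varGxe = 0,
                     seed = 900 + seed)
    tr <- simulateTrial(simulateParents(cfg), cfg)
    d <- tr$design[tr$design$year == "Y1" & tr$design$role == "hybrid", ]
    adj <- adjustPhenotypesByYear(d, "Y")
    truth <- tr$truth@hybridValue[adj$genotype]
    rmseAdj <- sqrt(mean((scale(adj$adjusted, scale = FALSE) -
                            scale(truth, scale = FALSE))^2))
    raw <- tapply(d$Y, d$genotype, mean)[adj$genotype]
    rmseRaw <- sqrt(mean((scale(raw, scale = FALSE) -
                            scale(truth, scale = FALSE))^2))
    wins <- wins + (rmseAdj < rmseRaw)
  }
  expect_gte(wins, 4)
})

test_that("mid-parent heterosis follows its defining identity", {
  adjusted <- data.frame(genotype = c("F/M1", "F/M2", "Fp", "M1", "M2"),
                         year = "Y1",
                         adjusted = c(1.4, 72, 74, 1.0 * 2 - 74, 76))
  # hybrid F/M1: parents Fp (74) and M1 (2 - 74 = -72): MPV = 1.0
  crosses <- data.frame(hybrid = c("F/M1", "F/M2"), female = c("F", "F"),
                        male = c("M1", "M2"))
  mph <- midParentHeterosis(adjusted, crosses,
                            femaleAlias = c(F = "Fp"))
  expect_equal(mph$mph_percent[1], 100 * (1.4 - 1.0) / 1.0)  # 40%
  expect_equal(mph$mph_percent[2], -4.0)  # 72 vs parents 74 and 76
  # F1 equal to MPV gives exactly 0
  adjusted$adjusted[1] <- 1.0
  mph0 <- midParentHeterosis(adjusted, crosses, c(F = "Fp"))
  expect_equal(mph0$mph_percent[1], 0)
})

test_that("undefined and missing MPH cases are flagged, not dropped", {
  adjusted <- data.frame(genotype = c("H1", "A", "B"), year = "Y1",
                         adjusted = c(5, 2, -2))
  crosses <- data.frame(hybrid = c("H1", "H2"), female = c("A", "A"),
                        male = c("B", "C"))
  mph <- midParentHeterosis(adjusted, crosses)
  expect_equal(mph$note, c("midparent_zero", "missing_hybrid_value"))
  expect_true(all(is.na(mph$mph_percent)))
})

test_that("inbred-midparent heterosis is the difference of means", {
  adjusted <- data.frame(genotype = c("h1", "h2", "p1", "p2"),
                         year = "Y1", adjusted = c(9, 11, 7, 9))
  roles <- data.frame(genotype = c("h1", "h2", "p1", "p2"),
                      role = c("hybrid", "hybrid", "male_parent",
                               "female_parent"))
  im <- inbredMidparentHeterosis(adjusted, roles)
  expect_equal(im$imph, 2)
  roles2 <- roles; adjusted2 <- adjusted
  adjusted2$adjusted <- c(5, 5, 5, 5)
  expect_equal(inbredMidparentHeterosis(adjusted2, roles2)$imph, 0)
})

test_that("simulated dominance shift is recovered by IMPH", {
  cfg <- simConfig(nMales = 40, nMarkers = 300, heterosisShift = 2.5,
                   varError = 0.5, testerEffects = c(0, 0), seed = 31)
  tr <- simulateTrial(simulateParents(cfg), cfg)
  adj <- adjustPhenotypesByYear(tr$design, "Y")
  roles <- unique(tr$design[, c("genotype", "role")])
  im <- inbredMidparentHeterosis(adj, roles)
  expect_equal(mean(im$imph), 2.5, tolerance = 0.35)
})

test_that("closed-form heritabilities match hand substitution", {
  expect_equal(broadSenseH2(4, 2, 2, 2, 2), 8 / 11)
  expect_equal(broadSenseH2(4, 0, 0, 2, 2), 1)
  sets <- list(c(2, 4, 1, 3), c(0.5, 1, 0.2, 0.9), c(3, 3, 3, 3),
               c(1, 0, 0, 0.5), c(0.1, 2, 0.3, 0.4))
  for (s in sets)
    expect_equal(narrowSenseH2(s[1], s[2], s[3], s[4]),
                 s[1] / (s[2] + s[3] + s[4]))
})

test_that("MPH and heritability are scale equivariant, IMPH scales", {
  fx <- toyTrial()
  d <- fx$design
  d2 <- d; d2$Y <- d$Y * 3
  adj <- adjustPhenotypesByYear(d, "Y")
  adj2 <- adjustPhenotypesByYear(d2, "Y")
  expect_equal(adj2$adjusted, 3 * adj$adjusted, tolerance = 1e-6)
  mph <- midParentHeterosis(adj, fx$crosses)
  mph2 <- midParentHeterosis(adj2, fx$crosses)
  expect_equal(mph$mph_percent, mph2$mph_percent, tolerance = 1e-5)
  roles <- unique(d[, c("genotype", "role")])
  expect_equal(inbredMidparentHeterosis(adj2, roles)$imph,
               3 * inbredMidparentHeterosis(adj, roles)$imph,
               tolerance = 1e-5)
  h <- heritabilities(d, "Y")
  h2 <- heritabilities(d2, "Y")
  expect_equal(h$H2, h2$H2, tolerance = 1e-6)
})

test_that("hybrid genetic values reconstruct mu + f + m (+ s) exactly", {
  fx <- toyTrial()
  gm <- additiveGRM(fx$parents[sort(unique(fx$crosses$male)), ])
  gf <- additiveGRM(fx$parents[c("T1", "T2"), ])
  for (inc in c(FALSE, TRUE)) {
    ca <- combiningAbility(fx$design, gm, gf, "Y", includeSca = inc)
    hv <- hybridGeneticValues(ca, fx$crosses)
    fe <- fixedEffects(ca$fit)
    mu <- fe$estimate[fe$term == "(Intercept)"]
    fEst <- setNames(fe$estimate[fe$term == "female"],
                     fe$level[fe$term == "female"])
    m <- ca$fit@blup[["maleGCA"]]
    manual <- mu + ifelse(fx$crosses$female %in% names(fEst),
                          fEst[fx$crosses$female], 0) + m[fx$crosses$male]
    if (inc)
      manual <- manual + ca$fit@blup[["sca"]][
        paste(fx$crosses$female, fx$crosses$male, sep = ":")]
    expect_identical(hv$value, as.numeric(manual))
  }
})

test_that("without SCA, tester differences in genetic values are constant", {
  fx <- toyTrial()
  ca <- combiningAbility(fx$design, trait = "Y", includeSca = FALSE,
                         structure = "identity")
  hv <- hybridGeneticValues(ca, fx$crosses)
  byMale <- split(hv, hv$male)
  gaps <- vapply(byMale, function(x)
    x$value[x$female == "T2"] - x$value[x$female == "T1"], numeric(1))
  expect_lt(diff(range(gaps)), 1e-10)
  fe <- fixedEffects(ca$fit)
  expect_equal(unname(gaps[1]),
               fe$estimate[fe$term == "female" & fe$level == "T2"])
})

test_that("combining ability requires two testers and matched ids", {
  fx <- toyTrial()
  d1 <- fx$design[fx$design$female %in% "T1" | is.na(fx$design$female), ]
  expect_error(combiningAbility(d1, trait = "Y", structure = "identity"),
               "2 testers")
})
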