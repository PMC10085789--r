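test_that("VCF import converts genotypes and applies the QC filters", {
  samples <- c("A", "B", "C", "D")
  rows <- c(
    vcfRow("chr1", 100, "A", "T", c("0/0", "0/0", "0/0", "0/1")),  # MAF .125
    vcfRow("chr1", 200, "A", "T", c("./.", "./.", "0/1", "1/1")),  # 50% miss
    vcfRow("chr1", 300, "G", "C", c("0/0", "0/0", "0/0", "0/0")),  # MAF 0
    vcfRow("chr1", 400, "G", "C", c("0/1", "1/1", "0/1", "0/0")),  # MAF .5
    vcfRow("chr1", 500, "G", "GA", c("0/0", "0/1", "0/0", "0/0")), # indel
    vcfRow("chr2", 100, "T", "A", c("1/1", "1/1", "0/1", "1/1")))  # MAF .125
  path <- writeToyVCF(rows, samples)
  g <- readVCF(path, allowedMissingFraction = 0.01, minMaf = 0.02)
  expect_equal(sampleIds(g), samples)
  expect_equal(markerMap(g)$pos, c(100, 400, 100))
  # hand-computed alternate-allele dosages
  expect_equal(unname(dosages(g)[, 1]), c(0, 0, 0, 1))
  expect_equal(unname(dosages(g)[, 2]), c(1, 2, 1, 0))
  expect_equal(unname(dosages(g)[, 3]), c(2, 2, 1, 2))
})

test_that("MAF threshold is exclusive and missingness inclusive", {
  samples <- sprintf("s%02d", 1:50)
  gts1 <- c(rep("0/1", 2), rep("0/0", 48))         # MAF 0.02 exactly
  gts2 <- c(rep("0/1", 3), rep("0/0", 47))         # MAF 0.03
  gts3 <- c("./.", rep("0/1", 25), rep("0/0", 24)) # 2% missing
  path <- writeToyVCF(c(vcfRow("chr1", 10, "A", "T", gts1),
                        vcfRow("chr1", 20, "A", "T", gts2),
                        vcfRow("chr1", 30, "A", "T", gts3)), samples)
  g <- readVCF(path, allowedMissingFraction = 0.02, minMaf = 0.02)
  expect_equal(markerMap(g)$pos, c(20, 30))  # MAF == 0.02 dropped
  expect_error(readVCF(path, allowedMissingFraction = 0.01, minMaf = 0.49),
               "over-filtering")
})

test_that("positional thinning follows the ascending linear scan", {
  d <- matrix(rep(c(0, 2), 8), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  map <- data.frame(chrom = c(rep("chr1", 4), rep("chr2", 4)),
                    pos = c(100, 150, 210, 330, 5, 40, 104, 205))
  g <- genotypeMatrix(d[, 1:8], map)
  thinned <- thinByPosition(g, 100)
  expect_equal(markerMap(thinned)$pos[markerMap(thinned)$chrom == "chr1"],
               c(100, 210, 330))
  # 104 is only 99 bp past 5, so it falls inside the window; 205 reopens it
  expect_equal(markerMap(thinned)$pos[markerMap(thinned)$chrom == "chr2"],
               c(5, 205))
  # idempotence at the same window; no-op at window 0
  expect_identical(dosages(thinByPosition(thinned, 100)), dosages(thinned))
  expect_identical(dosages(thinByPosition(g, 0)), dosages(g))
})

test_that("one marker per chromosome is always kept", {
  d <- matrix(0, 1, 3, dimnames = list("x", NULL))
  g <- genotypeMatrix(d, data.frame(chrom = c("c1", "c2", "c3"),
                                    pos = c(5, 5, 5)))
  expect_equal(ncol(dosages(thinByPosition(g, 1e6))), 3)
})

test_that("F1 construction is the elementwise parental mean", {
  d <- rbind(F1 = c(0, 2, 0, 1), F2 = c(2, 2, 0, 0), M1 = c(2, 0, 0, 1),
             M2 = c(0, 2, 2, 2))
  g <- genotypeMatrix(d, data.frame(chrom = "c1", pos = 1:4 * 10))
  crosses <- data.frame(female = c("F1", "F1", "F2"),
                        male = c("M1", "M2", "M1"))
  h <- buildHybridGenotypes(g, crosses)
  expect_equal(sampleIds(h), c("F1/M1", "F1/M2", "F2/M1"))
  expect_equal(unname(dosages(h)),
               unname((d[crosses$female, ] + d[crosses$male, ]) / 2))
  # opposite homozygotes give 1; shared homozygote gives 2
  expect_equal(dosages(h)["F1/M1", 1], 1)
  expect_equal(dosages(h)["F2/M1", 1], 2)
  # heterozygous parent cells can be dropped instead of propagated
  h2 <- buildHybridGenotypes(g, crosses, hetPolicy = "drop")
  expect_equal(ncol(dosages(h2)), 3)
  expect_error(buildHybridGenotypes(g, data.frame(female = "F9",
                                                  male = "M1")), "unknown")
})

test_that("the additive GRM matches brute-force VanRaden arithmetic", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(3:8, 1); m <- sample(5:30, 1)
    d <- matrix(sample(0:2, n * m, replace = TRUE), n,
                dimnames = list(sprintf("i%d", 1:n), NULL))
    g <- genotypeMatrix(d, data.frame(chrom = "c1", pos = seq_len(m) * 7))
    p <- colMeans(dosages(g)) / 2
    if (sum(p > 0 & p < 1) < 2) next
    Z <- sweep(dosages(g), 2, 2 * p)
    Gref <- Z %*% t(Z) / (2 * sum(p[p > 0 & p < 1] * (1 - p[p > 0 & p < 1])))
    expect_equal(unname(additiveGRM(g)@values), unname(Gref),
                 tolerance = 1e-10)
  }
})

test_that("GRM of identical inbred individuals has G12 = G11", {
  d <- rbind(a = c(0, 2, 2, 0, 2), b = c(0, 2, 2, 0, 2),
             c = c(2, 0, 0, 2, 0))
  g <- genotypeMatrix(d, data.frame(chrom = "c1", pos = 1:5))
  G <- additiveGRM(g)@values
  expect_equal(G["a", "b"], G["a", "a"])
})

test_that("mean GRM diagonal of an inbred panel is near 2", {
  cfg <- simConfig(nMales = 150, nMarkers = 2000, seed = 8)
  g <- simulateParents(cfg)
  G <- additiveGRM(g)
  expect_equal(mean(diag(G@values)), 2, tolerance = 0.1)
})

test_that("GRM is invariant to marker and individual permutations", {
  fx <- toyTrial()
  g <- fx$parents
  G <- additiveGRM(g)@values
  set.seed(1)
  jperm <- sample(ncol(dosages(g)))
  Gp <- additiveGRM(g[, jperm])@values
  expect_equal(G, Gp, tolerance = 1e-12)
  iperm <- sample(sampleIds(g))
  Gi <- additiveGRM(g[iperm, ])@values
  expect_equal(Gi[sampleIds(g), sampleIds(g)], G, tolerance = 1e-12)
})

test_that("PSD stabilization yields an invertible structure", {
  G <- matrix(c(2, -2, -2, 2), 2, dimnames = list(c("T1", "T2"),
                                                  c("T1", "T2")))
  s <- suppliedCov(G)
  expect_gt(s@jitter, 0)
  ev <- eigen(covMatrix(s), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(covMatrix(s) %*% covInverse(s), diag(2),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("missing dosages are column-mean imputed before the GRM", {
  d <- rbind(a = c(0, 2, NA), b = c(2, 2, 0), c = c(0, 0, 2))
  g <- genotypeMatrix(d, data.frame(chrom = "c1", pos = 1:3))
  dImp <- d; dImp["a", 3] <- 1
  gImp <- genotypeMatrix(dImp, data.frame(chrom = "c1", pos = 1:3))
  expect_equal(additiveGRM(g)@values, additiveGRM(gImp)@values)
})

test_that("genetic distance is the Euclidean row distance", {
  d <- rbind(a = c(0, 0, 0), b = c(2, 2, 2), c = c(0, 0, 0))
  g <- genotypeMatrix(d, data.frame(chrom = "c1", pos = 1:3))
  expect_equal(geneticDistance(g, "a", "c"), 0)
  expect_equal(geneticDistance(g, "a", "b"), sqrt(12))
  set.seed(30)
  d2 <- matrix(runif(100, 0, 2), 2, dimnames = list(c("x", "y"), NULL))
  g2 <- genotypeMatrix(d2, data.frame(chrom = "c1", pos = 1:50))
  expect_equal(geneticDistance(g2, "x", "y"),
               sqrt(sum((d2[1, ] - d2[2, ])^2)))
  expect_error(geneticDistance(g, "a", "zz"), "unknown")
})

test_that("re-filtering already filtered data changes nothing", {
  fx <- toyTrial()
  g <- filterGenotypes(fx$parents, 0.01, 0.05)
  g2 <- filterGenotypes(g, 0.01, 0.05)
  expect_identical(dosages(g), dosages(g2))
})
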