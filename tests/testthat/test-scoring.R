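test_that("MAS is the sub-cutoff minimum of the mutant grid", {
  expect_equal(computeMAS(makeAM(c(12, 480, 600))), 12)
  expect_true(is.na(computeMAS(makeAM(c(500, 900, 12000)))))
  expect_equal(computeMAS(makeAM(499.9)), 499.9)  # strict at the cutoff
  expect_equal(computeMAS(makeAM(c(600, 700)), cutoff = 1000), 600)
})

test_that("HCS counts alleles with at least one sub-cutoff window", {
  m <- matrix(c(30, 900, 700, 2000, 499, 600), nrow = 2)
  expect_equal(computeHCS(makeAM(m)), 2L)
  expect_equal(sort(responsiveAlleles(makeAM(m))),
               c("HLA-A*01:01", "HLA-A*03:01"))
  expect_equal(computeHCS(makeAM(c(501, 800))), 0L)
})

test_that("WCS follows the Hardy-Weinberg coverage closed form", {
  one <- makeFreqs(allele = "HLA-A*02:01", locus = "A", frequency = 0.5)
  expect_equal(computeWCS(character(0), one), 0)
  expect_equal(computeWCS("HLA-A*02:01", one), 0.75)

  # full responsive mass at every locus -> clamped full coverage
  full <- makeFreqs(allele = c("HLA-A*01:01", "HLA-B*01:01", "HLA-C*01:01"),
                    locus = c("A", "B", "C"), frequency = c(1, 1, 1))
  expect_equal(computeWCS(alleleNames(full), full), 1)

  # two loci multiply: 1 - (1-.3)^2 (1-.2)^2
  two <- makeFreqs(allele = c("HLA-A*01:01", "HLA-B*01:01"),
                   locus = c("A", "B"), frequency = c(0.3, 0.2))
  expect_equal(computeWCS(alleleNames(two), two), 1 - 0.49 * 0.64)

  expect_error(computeWCS("HLA-C*05:01", two), "HLA-C\\*05:01")
})

test_that("WCS is monotone in the responsive set and stays in [0,1]", {
  set.seed(11)
  for (rep in 1:10) {
    ft <- randomFreqs()
    all <- alleleNames(ft)
    small <- sample(all, 4)
    big <- union(small, sample(all, 6))
    w1 <- computeWCS(small, ft); w2 <- computeWCS(big, ft)
    expect_gte(w2, w1)
    expect_true(w1 >= 0 && w2 <= 1)
  }
})

test_that("WCS agrees with genotype-simulation Monte Carlo", {
  set.seed(5)
  for (rep in 1:5) {
    ft <- randomFreqs(nPerLocus = 7, mass = runif(1, 0.6, 0.98))
    resp <- sample(alleleNames(ft), sample(3:10, 1))
    w <- computeWCS(resp, ft)
    mc <- wcsMonteCarlo(resp, ft, n = 2e4, seed = rep)
    se <- sqrt(max(w * (1 - w), 1e-4) / 2e4)
    expect_lt(abs(w - mc), 3 * se + 1e-9)
  }
})

test_that("AMS is the mutant/wild-type ratio at the MAS cell", {
  am <- makeAM(c(40, 300), wildtype = c(400, 350))
  expect_equal(computeAMS(am), 0.1)
  expect_equal(computeAMS(am, inverted = TRUE), 10)
  eq <- makeAM(100, wildtype = 100)
  expect_equal(computeAMS(eq), 1)
  nb <- makeAM(c(800, 900), wildtype = c(10, 10))
  expect_true(is.na(computeAMS(nb)))  # undefined when MAS undefined
})

test_that("PNS: extremes score 3 and 0, all values within [0,3]", {
  ft <- makeFreqs(allele = c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*01:01"),
                  locus = c("A", "A", "B"), frequency = c(0.3, 0.2, 0.4))
  best <- makeAM(matrix(c(10, 20, 30), 1,
                        dimnames = list(NULL, alleleNames(ft))),
                 wildtype = matrix(100, 1, 3), variant = "p.V1A")
  none <- makeAM(matrix(c(900, 800, 700), 1,
                        dimnames = list(NULL, alleleNames(ft))),
                 wildtype = matrix(100, 1, 3), variant = "p.V2A")
  sc <- scoreVariants(list(best, none), ft)
  expect_equal(sc$PNS[1], 3)
  expect_equal(sc$PNS[2], 0)
  expect_equal(as.character(sc$category), c("High", "Low"))
  expect_true(is.na(sc$MAS[2]))
  expect_equal(sc$HCS[2], 0L)
  expect_equal(sc$WCS[2], 0)

  # anchors travel with the result
  an <- attr(sc, "anchors")
  expect_equal(an$mas_min, -500)
  expect_equal(an$mas_max, -10)
  expect_equal(an$hcs_min, 0)

  # random sets stay within bounds
  set.seed(21)
  ft2 <- randomFreqs()
  mats <- lapply(1:15, function(i)
    makeAM(matrix(10^runif(2 * 21, 0, 4.7), 2,
                  dimnames = list(NULL, alleleNames(ft2))),
           variant = paste0("p.V", i, "A")))
  sc2 <- scoreVariants(mats, ft2, ams = FALSE)
  expect_true(all(sc2$PNS >= 0 & sc2$PNS <= 3))
  expect_equal(sc2$PNS, sc2$norm_MAS + sc2$norm_HCS + sc2$norm_WCS)
})

test_that("degenerate all-identical components collapse to 0 with a message", {
  ft <- makeFreqs(allele = "HLA-A*01:01", locus = "A", frequency = 0.2)
  m1 <- makeAM(matrix(100, 1, 1, dimnames = list(NULL, "HLA-A*01:01")),
               variant = "p.V1A")
  m2 <- makeAM(matrix(100, 1, 1, dimnames = list(NULL, "HLA-A*01:01")),
               variant = "p.V2A")
  expect_message(sc <- scoreVariants(list(m1, m2), ft, ams = FALSE),
                 "zero range")
  expect_equal(sc$norm_MAS, c(0, 0))
  expect_equal(sc$PNS, sc$norm_HCS + sc$norm_WCS)
  expect_error(scoreVariants(list(), ft), "no variants")
})

test_that("category bounds: 1 and 2 are Intermediate, beyond 2 is High", {
  expect_equal(as.character(categorizePNS(c(0, 0.4, 0.999, 1, 1.5, 2))),
               c("Low", "Low", "Low", rep("Intermediate", 3)))
  expect_equal(as.character(categorizePNS(c(2.01, 3))), c("High", "High"))
  expect_error(categorizePNS(3.2), "\\[0, 3\\]")
  expect_error(categorizePNS(-0.1), "\\[0, 3\\]")
})

test_that("adding a binder for a new allele never lowers HCS/WCS or PNS rank", {
  set.seed(31)
  ft <- randomFreqs()
  alleles <- alleleNames(ft)
  mats <- lapply(1:8, function(i)
    makeAM(matrix(10^runif(21, 2.2, 4.7), 1,
                  dimnames = list(NULL, alleles)),
           variant = paste0("p.V", i, "A")))
  sc <- scoreVariants(mats, ft, ams = FALSE)
  # give variant 4 a strong binder on an allele it did not yet cover
  target <- mats[[4]]
  free <- setdiff(alleles, responsiveAlleles(target))
  boosted <- mutantAffinities(target)
  boosted[1, free[1]] <- 25
  mats2 <- mats
  mats2[[4]] <- makeAM(boosted, variant = "p.V4A")
  sc2 <- scoreVariants(mats2, ft, ams = FALSE)
  expect_gte(sc2$HCS[4], sc$HCS[4])
  expect_gte(sc2$WCS[4], sc$WCS[4])
  rank1 <- rank(sc$PNS)[4]; rank2 <- rank(sc2$PNS)[4]
  expect_gte(rank2, rank1)
})

test_that("a shared latent driver induces strong inter-metric correlation", {
  cfg <- simConfig(seed = 17L, nVariants = 200L, effectSize = 2)
  ft <- simAlleleFrequencies(cfg)
  space <- enumerateMissenseSpace(tp53Cds())
  set.seed(17)
  vars <- space[sample.int(nrow(space), 200L), , drop = FALSE]
  mats <- simAffinityMatrices(cfg, vars, ft)
  sc <- scoreVariants(mats, ft, ams = FALSE)
  # no-binder variants enter at the bottom of all three metrics, the same
  # convention the normalisation uses
  masFilled <- ifelse(is.na(sc$MAS), 500, sc$MAS)
  rho1 <- cor(-masFilled, sc$HCS, method = "spearman")
  rho2 <- cor(-masFilled, sc$WCS, method = "spearman")
  rho3 <- cor(sc$HCS, sc$WCS, method = "spearman")
  expect_gt(rho1, 0.8)
  expect_gt(rho2, 0.8)
  expect_gt(rho3, 0.8)
})
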