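test_that("Z normalization identities hold and degenerate input warns", {
  sim <- simulateCohort(nIndividuals = 30, totalMb = 100, nChrom = 1,
                        snpSpacingBp = 50000, seed = 3)
  zs <- zscoreScan(sim$dosage)
  expect_equal(unname(colMeans(zs$z)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(zs$z, 2, sd)), c(1, 1, 1), tolerance = 1e-9)
  expect_true(all(zs$meanFraction >= 0 & zs$meanFraction <= 1))

  ## constant dosage everywhere: Z all zero with a warning
  d <- array(0, c(3, 5, 3)); d[, , 1] <- 2
  dt <- DosageTensor(d, rep("1", 5), (1:5) * 1000L, c("E", "N", "S"))
  expect_warning(z0 <- zscoreScan(dt), "constant ancestry")
  expect_true(all(z0$z == 0))
})

test_that("region calling matches a brute-force run enumeration", {
  set.seed(20)
  for (r in 1:8) {
    m <- 400
    z <- matrix(rnorm(m), m, 1)
    hot <- sample.int(m - 20, 2)
    for (h in hot) z[h:(h + 10), 1] <- 5 * sample(c(-1, 1), 1)
    zs <- structure(list(
      meanFraction = matrix(0.2, m, 1), mu = 0.2, sigma = 0.05,
      z = z, chrom = rep("1", m), pos = (1:m) * 10000L,
      ancestries = "NAF"), class = "ZScanResult")
    got <- callRegions(zs, threshold = 3)
    ## brute force: scan runs by hand
    hotIdx <- which(abs(z[, 1]) > 3)
    exp_regions <- split(hotIdx, cumsum(c(1, diff(hotIdx) != 1)))
    expect_equal(nrow(got), length(exp_regions))
    for (q in seq_along(exp_regions)) {
      run <- exp_regions[[q]]
      expect_equal(got$start[q], (run[1]) * 10000 - 1)
      expect_equal(got$end[q], run[length(run)] * 10000)
      lead <- run[which.max(abs(z[run, 1]))]
      expect_equal(got$leadZ[q], z[lead, 1])
    }
  }
})

test_that("a single locus above threshold is a one-SNP region", {
  z <- matrix(0, 50, 1); z[25, 1] <- 5.92
  zs <- structure(list(meanFraction = matrix(0.432, 50, 1), mu = 0.2,
                       sigma = 0.04, z = z, chrom = rep("2", 50),
                       pos = (1:50) * 1000L, ancestries = "NAF"),
                  class = "ZScanResult")
  got <- callRegions(zs)
  expect_equal(nrow(got), 1)
  expect_equal(got$nSnps, 1L)
  expect_equal(got$leadZ, 5.92)
  expect_equal(nrow(callRegions(zs, threshold = 6)), 0)
})

test_that("a seeded ancestry deviation is the top region in every seed", {
  hits <- 0
  nSeeds <- 20
  for (sd in seq_len(nSeeds)) {
    dev <- data.frame(chrom = "1", start = 3e7, end = 4e7,
                      ancestry = "NAF", target = 0.46)
    sim <- simulateCohort(nIndividuals = 200, totalMb = 250, nChrom = 3,
                          snpSpacingBp = 20000, deviant = dev,
                          withDosage = TRUE, seed = 100 + sd)
    zs <- zscoreScan(sim$dosage)
    regs <- callRegions(zs)
    naf <- regs[regs$ancestry == "NAF", ]
    top <- naf[which.max(abs(naf$leadZ)), ]
    if (nrow(top) == 1 && top$chrom == "1" &&
        top$leadPos > 3e7 && top$leadPos <= 4e7 && top$leadZ > 3)
      hits <- hits + 1
  }
  expect_equal(hits, nSeeds)
})

test_that("locus-level false-positive rate tracks the binomial benchmark", {
  ## on null cohorts the per-locus mean ancestry is Binomial(2n, p)/2n;
  ## the benchmark is the exact two-sided binomial tail at 3 empirical
  ## SDs. Exceedance clumping from mosaic autocorrelation inflates the
  ## across-seed variance, so the band is a factor of two around the
  ## benchmark, not a binomial CI.
  nSeeds <- 10
  tot <- 0; hot <- 0
  for (sd in seq_len(nSeeds)) {
    sim <- simulateCohort(nIndividuals = 200, totalMb = 250, nChrom = 3,
                          snpSpacingBp = 20000, seed = 300 + sd)
    zs <- zscoreScan(sim$dosage)
    tot <- tot + length(zs$z[, 2])
    hot <- hot + sum(abs(zs$z[, 2]) > 3)
  }
  rate <- hot / tot
  n2 <- 2 * 200
  mu <- 0.22; sigma <- sqrt(mu * (1 - mu) / n2)
  benchmark <- pbinom(floor(n2 * (mu - 3 * sigma)), n2, mu) +
    1 - pbinom(ceiling(n2 * (mu + 3 * sigma)) - 1, n2, mu)
  expect_gt(rate, benchmark / 2)
  expect_lt(rate, benchmark * 2)
  ## and the benchmark itself sits near the normal tail 2.7e-3
  expect_equal(benchmark, 2 * pnorm(-3), tolerance = 0.5)
})

test_that("region diversity flags autozygous regions and spares background", {
  set.seed(71)
  ## cohort with one region fully homozygous and covered by ROH in all
  n <- 40; m <- 500
  f <- runif(m, 0.2, 0.8)
  calls <- matrix(rbinom(n * m, 2, rep(f, each = n)), n, m)
  sel <- 201:250
  calls[, sel] <- 2L
  vt <- VariantTable(chrom = rep("1", m), pos = (1:m) * 20000L,
                     ref = rep("A", m), alt = rep("G", m),
                     samples = sprintf("s%02d", 1:n), calls = calls)
  roh <- data.frame(individual = sprintf("s%02d", 1:n), chrom = "1",
                    start = 200 * 20000, end = 250 * 20000,
                    lengthKb = 1000, nSnps = 50L,
                    category = "1-2", over1.6Mb = FALSE)
  regions <- data.frame(ancestry = "NAF", chrom = "1",
                        start = 200 * 20000, end = 250 * 20000,
                        nSnps = 50L, leadPos = 210 * 20000,
                        leadZ = 4, leadMeanPct = 40)
  dv <- regionDiversity(vt, roh, regions, mTests = 6)
  expect_equal(dv$perRegion$meanHet, 0)
  expect_equal(dv$perRegion$meanRohCarriers, n)
  expect_true(dv$perRegion$sigHet && dv$perRegion$sigRoh)
  expect_equal(dv$bonferroniThreshold, 0.05 / 6)
  expect_equal(signif(dv$bonferroniThreshold, 1), 8e-3)
})

test_that("a background-like region is not significant in most draws", {
  set.seed(72)
  notSig <- 0
  for (r in 1:40) {
    n <- 30; m <- 300
    f <- runif(m, 0.2, 0.8)
    calls <- matrix(rbinom(n * m, 2, rep(f, each = n)), n, m)
    vt <- VariantTable(chrom = rep("1", m), pos = (1:m) * 20000L,
                       ref = rep("A", m), alt = rep("G", m),
                       samples = sprintf("s%02d", 1:n), calls = calls)
    regions <- data.frame(ancestry = "NAF", chrom = "1",
                          start = 100 * 20000, end = 150 * 20000,
                          nSnps = 50L, leadPos = 120 * 20000,
                          leadZ = 3.5, leadMeanPct = 30)
    dv <- regionDiversity(vt, callRoh(vt), regions, mTests = 1)
    if (is.na(dv$perRegion$pHet) || dv$perRegion$pHet >= 0.05)
      notSig <- notSig + 1
  }
  expect_gte(notSig / 40, 0.85)
})
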