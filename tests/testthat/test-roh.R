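test_that("an all-heterozygous individual yields no segments", {
  m <- 300
  vt <- VariantTable(chrom = rep("1", m),
                     pos = seq(20000, by = 20000, length.out = m),
                     ref = rep("A", m), alt = rep("G", m),
                     samples = "s1",
                     calls = matrix(1L, 1, m))
  expect_equal(nrow(callRoh(vt)), 0)
})

test_that("caller equals the brute-force window enumeration exactly", {
  cfg <- rohConfig()
  for (sd in 1:10) {
    set.seed(sd)
    m <- 200
    pos <- sort(sample.int(6e6, m))
    ## genotypes with embedded homozygous stretches so segments do occur
    g <- rbinom(m, 2, 0.5)
    runStart <- sample.int(m - 80, 2)
    for (rs in runStart) g[rs:(rs + sample(40:80, 1))] <-
        sample(c(0L, 2L), 1)
    g[sample.int(m, 5)] <- NA
    vt <- VariantTable(chrom = rep("1", m), pos = pos,
                       ref = rep("A", m), alt = rep("G", m),
                       samples = "s1", calls = matrix(g, 1, m))
    got <- callRoh(vt, cfg)
    ref <- bruteRoh(g, pos, cfg)
    if (is.null(ref)) {
      expect_equal(nrow(got), 0, info = paste("seed", sd))
    } else {
      expect_equal(nrow(got), nrow(ref), info = paste("seed", sd))
      expect_equal(got$start, ref$start, info = paste("seed", sd))
      expect_equal(got$end, ref$end, info = paste("seed", sd))
      expect_equal(got$nSnps, ref$nSnps, info = paste("seed", sd))
    }
  }
})

test_that("an injected 2.5-Mb tract is recovered and 400 kb is rejected", {
  roh <- data.frame(individual = 1, chrom = "1", start = 1e7, end = 1.25e7)
  sim <- simulateCohort(nIndividuals = 5, totalMb = 120, nChrom = 2,
                        snpSpacingBp = 20000, rohIntervals = roh, seed = 7)
  segs <- callRoh(sim$variants)
  hit <- segs[segs$individual == "ind001" & segs$chrom == "1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(as.character(hit$category), "2-4")
  ## boundaries close to truth (hit-rate smearing allows a few SNPs)
  expect_lt(abs(hit$start - (1e7 - 1)), 3e5)
  expect_lt(abs(hit$end - 1.25e7), 3e5)
  expect_true(hit$start <= 1e7 + 2e4 && hit$end >= 1.25e7 - 2e4)

  roh2 <- data.frame(individual = 1, chrom = "1", start = 1e7,
                     end = 1.04e7)
  sim2 <- simulateCohort(nIndividuals = 5, totalMb = 120, nChrom = 2,
                         snpSpacingBp = 20000, rohIntervals = roh2,
                         seed = 8)
  expect_equal(nrow(callRoh(sim2$variants)), 0)
})

test_that("every emitted segment satisfies its own constraints", {
  roh <- data.frame(individual = c(1, 2), chrom = c("1", "2"),
                    start = c(5e6, 2e7), end = c(9e6, 2.2e7))
  sim <- simulateCohort(nIndividuals = 4, totalMb = 150, nChrom = 2,
                        snpSpacingBp = 20000, rohIntervals = roh,
                        seed = 41)
  cfg <- rohConfig()
  segs <- callRoh(sim$variants, cfg)
  expect_gt(nrow(segs), 0)
  expect_true(all(segs$lengthKb >= cfg$minRohKb))
  expect_true(all(segs$lengthKb / segs$nSnps <= cfg$minDensityKbPerSnp))
})

test_that("relaxing the heterozygote tolerance never shrinks total ROH", {
  roh <- data.frame(individual = 1, chrom = "1", start = 5e6, end = 8e6)
  sim <- simulateCohort(nIndividuals = 3, totalMb = 60, nChrom = 1,
                        snpSpacingBp = 20000, rohIntervals = roh,
                        seed = 51)
  tot <- function(maxHet) {
    s <- callRoh(sim$variants, rohConfig(maxHetPerWindow = maxHet))
    sum(s$lengthKb[s$individual == "ind001"])
  }
  expect_gte(tot(2), tot(1))
})

test_that("summaries aggregate lengths, categories and the 1.6-Mb split", {
  segs <- data.frame(individual = "s1", chrom = "1",
                     start = c(0, 5e6), end = c(8e5, 7.5e6),
                     lengthKb = c(800, 2500), nSnps = c(40, 125),
                     category = factor(c("0.5-1", "2-4"),
                                       levels = c("0.5-1", "1-2", "2-4",
                                                  "4-8", "8-16", ">16")),
                     over1.6Mb = c(FALSE, TRUE))
  samples <- data.frame(id = c("s1", "s2"), group = c("a", "b"))
  sm <- summarizeRoh(segs, samples)
  i1 <- sm$perIndividual[sm$perIndividual$id == "s1", ]
  expect_equal(i1$totalMb, 3.3)
  expect_equal(i1$count, 2L)
  expect_equal(i1$`cat0.5-1`, 0.8)
  expect_equal(i1$`cat2-4`, 2.5)
  expect_equal(i1$le1.6Mb, 0.8)
  expect_equal(i1$gt1.6Mb, 2.5)
  ## s2 has no segments and counts as zero
  expect_equal(sm$perIndividual$totalMb[2], 0)

  ## random lists against direct aggregation
  set.seed(6)
  n <- 50
  rs <- data.frame(individual = sample(c("s1", "s2"), n, TRUE),
                   chrom = "1", start = 0, end = 1,
                   lengthKb = runif(n, 500, 20000), nSnps = 10L)
  rs$category <- rohCategories <- cut(rs$lengthKb / 1000,
                                      c(0.5, 1, 2, 4, 8, 16, Inf),
                                      right = FALSE,
                                      labels = c("0.5-1", "1-2", "2-4",
                                                 "4-8", "8-16", ">16"))
  rs$over1.6Mb <- rs$lengthKb > 1600
  sm2 <- summarizeRoh(rs, samples)
  for (id in c("s1", "s2")) {
    expect_equal(sm2$perIndividual$totalMb[sm2$perIndividual$id == id],
                 sum(rs$lengthKb[rs$individual == id]) / 1000)
  }
})

test_that("a heavily autozygous group has a larger mean total ROH", {
  roh <- data.frame(individual = 1:3, chrom = "1",
                    start = c(5e6, 15e6, 25e6), end = c(9e6, 19e6, 29e6))
  sim <- simulateCohort(nIndividuals = 6, totalMb = 80, nChrom = 1,
                        snpSpacingBp = 20000, rohIntervals = roh,
                        seed = 61)
  vt <- sim$variants
  vt@samples$group <- rep(c("isolated", "open"), each = 3)
  sm <- summarizeRoh(callRoh(vt), sampleSheet(vt))
  g <- sm$perGroup
  expect_gt(g$totalMb[g$group == "isolated"],
            g$totalMb[g$group == "open"])
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4))$p, 1 / 3,
               tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(c(5, 5, 5), c(5, 5))$p, 1)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  ## agreement with the reference implementation on larger samples
  set.seed(2)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(wilcoxonRankSum(x, y)$p,
               wilcox.test(x, y, correct = FALSE)$p.value)
})
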