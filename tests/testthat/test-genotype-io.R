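test_that("VCF reading keeps biallelic SNVs and preserves missing calls", {
  f <- writeToyVcf(tempfile(fileext = ".vcf"))
  vt <- readVcfTable(f)
  expect_equal(nVariants(vt), 2)          # triallelic rs2 dropped
  expect_equal(vt@id, c("rs1", "rs3"))
  expect_equal(vt@chrom, c("1", "1"))     # chr prefix stripped
  expect_true(is.na(calls(vt)[1, 2]))     # ./. preserved
  expect_equal(calls(vt)[2, ], c(1L, 2L))
})

test_that("VCF write/read round-trip is the identity on calls", {
  vt <- randomVariantTable(5, 20, missRate = 0.1, seed = 3)
  f <- tempfile(fileext = ".vcf")
  writeVcfTable(vt, f)
  back <- readVcfTable(f)
  expect_identical(calls(back), calls(vt))
  expect_equal(back@pos, vt@pos)
  expect_equal(back@ref, vt@ref)
})

test_that("region filtering returns an empty table, not an error", {
  f <- writeToyVcf(tempfile(fileext = ".vcf"))
  vt <- readVcfTable(f, region = "1:1000-2000")
  expect_equal(nVariants(vt), 0)
  expect_equal(nSamples(vt), 2)
})

test_that("dosage wide dialect round-trips and rejects bad sums", {
  d <- array(0, c(3, 4, 3))
  d[, , 1] <- 1.2; d[, , 2] <- 0.7; d[, , 3] <- 0.1   # sums to 2.0
  dt <- DosageTensor(d, rep("1", 4), c(10L, 20L, 30L, 40L),
                     c("EUR", "NAF", "SSA"))
  f <- tempfile(); fl <- tempfile()
  writeDosage(dt, f, fl)
  back <- readDosage(f, fl, K = 3, ancestries = c("EUR", "NAF", "SSA"))
  expect_equal(back$nRejected, 0)
  expect_equal(dosages(back$tensor), dosages(dt), tolerance = 1e-12)

  ## corrupt one locus of one individual: (1.2, 0.7, 0.4) sums to 2.3
  tb <- read.table(f, sep = "\t")
  tb[2, 5] <- 0.4
  write.table(tb, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_warning(back2 <- readDosage(f, fl, K = 3), "sum-to-2")
  expect_equal(back2$nRejected, 1)
  expect_equal(nSamples(back2$tensor), 2)
})

test_that("dosage reader enforces K against the column count", {
  d <- array(2 / 3, c(2, 3, 3))
  dt <- DosageTensor(d, rep("1", 3), c(1L, 2L, 3L), paste0("A", 1:3))
  f <- tempfile(); fl <- tempfile()
  writeDosage(dt, f, fl)
  expect_error(readDosage(f, fl, K = 4), "dimension")
})

test_that("synthetic truth dosages survive the file round-trip", {
  sim <- simulateCohort(nIndividuals = 4, totalMb = 20, nChrom = 1,
                        snpSpacingBp = 1e6, seed = 11)
  f <- tempfile(); fl <- tempfile()
  writeDosage(sim$dosage, f, fl)
  back <- readDosage(f, fl, K = 3, ancestries = ancestries(sim$dosage))
  expect_equal(dosages(back$tensor), dosages(sim$dosage))
})

test_that("BED export uses 0-based half-open coordinates", {
  ## 1-based inclusive chr2:133,952,040-144,266,489 converts to
  ## (133952039, 144266489)
  f <- tempfile(fileext = ".bed")
  writeBedRegions(data.frame(chrom = "chr2", start = 133952039,
                             end = 144266489, name = "NAF_peak",
                             score = 5.92), f)
  line <- readLines(f)
  expect_equal(line, "chr2\t133952039\t144266489\tNAF_peak\t5.92")
  expect_error(writeBedRegions(data.frame(chrom = "1", start = 10,
                                          end = 10), tempfile()),
               "end > start")
})

test_that("BED round-trip is the identity and empty input gives empty file", {
  f <- tempfile(fileext = ".bed")
  writeBedRegions(data.frame(chrom = character(), start = numeric(),
                             end = numeric()), f)
  expect_equal(file.size(f), 0)
  expect_equal(nrow(readBedRegions(f)), 0)

  set.seed(5)
  reg <- data.frame(chrom = sample(as.character(1:5), 100, TRUE),
                    start = sample.int(1e8, 100))
  reg$end <- reg$start + sample.int(1e6, 100)
  reg$name <- sprintf("r%03d", 1:100)
  reg$score <- round(runif(100), 3)
  writeBedRegions(reg, f)
  back <- readBedRegions(f)
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
  expect_equal(back$name, reg$name)
  expect_equal(back$score, reg$score)
})

test_that("extractSites reports frequencies and flags absent targets", {
  vt <- VariantTable(chrom = rep("1", 2), pos = c(100L, 200L),
                     ref = c("A", "C"), alt = c("G", "T"),
                     samples = sprintf("s%d", 1:4),
                     calls = matrix(c(0L, 1L, 1L, 2L,
                                      0L, 0L, NA, 1L), 4, 2))
  res <- extractSites(vt, data.frame(chrom = c("1", "1"),
                                     pos = c(100, 999)))
  expect_equal(res$altFreq[1], 0.5)       # (0+1+1+2) / 8
  expect_true(res$detected[1])
  expect_false(res$detected[2])
  expect_true(is.na(res$altFreq[2]))
})

test_that("extractSites frequencies equal a brute-force allele count", {
  vt <- randomVariantTable(12, 40, missRate = 0.15, seed = 9)
  targets <- variantInfo(vt)[sample(40, 10), c("chrom", "pos")]
  res <- extractSites(vt, targets)
  for (t in seq_len(10)) {
    j <- which(vt@pos == targets$pos[t])
    g <- calls(vt)[, j]
    expect_equal(res$altFreq[t],
                 sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))))
  }
})

test_that("genetic map interpolation is linear and clamped", {
  gm <- GeneticMap(chrom = c("1", "1", "1"), bp = c(0, 1e6, 3e6),
                   cM = c(0, 1, 2))
  expect_equal(interpolateCM(gm, "1", 5e5), 0.5)
  expect_equal(interpolateCM(gm, "1", 2e6), 1.5)
  expect_equal(interpolateCM(gm, "1", 5e6), 2)   # beyond range: clamped
  expect_error(interpolateCM(gm, "2", 100), "does not cover")
})

test_that("ped/map and genotype TSV readers agree with the VCF path", {
  vt <- randomVariantTable(4, 6, seed = 21)
  ## write as ped/map
  mp <- tempfile(fileext = ".map"); pd <- tempfile(fileext = ".ped")
  vi <- variantInfo(vt)
  write.table(data.frame(vi$chrom, vi$id, 0, vi$pos), mp,
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  al <- matrix("0", 4, 12)
  for (j in 1:6) {
    a <- c("A", "G")
    g <- calls(vt)[, j]
    al[, 2 * j - 1] <- ifelse(g >= 1, a[2], a[1])
    al[, 2 * j] <- ifelse(g == 2, a[2], a[1])
  }
  write.table(cbind("f", sprintf("s%02d", 1:4), 0, 0, 0, 0, al), pd,
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  back <- readPedMap(pd, mp)
  ## alt allele is the minor one, so calls may be flipped (g -> 2 - g)
  for (j in 1:6) {
    g0 <- calls(vt)[, j]; g1 <- calls(back)[, j]
    expect_true(all(g1 == g0) || all(g1 == 2L - g0))
  }
})

test_that("variantRanges returns a GRanges mirroring the loci", {
  vt <- randomVariantTable(3, 8, seed = 2)
  gr <- variantRanges(vt)
  expect_s4_class(gr, "GRanges")
  expect_equal(length(gr), 8)
  expect_equal(GenomicRanges::start(gr), vt@pos)
})

test_that("validity catches malformed containers", {
  expect_error(VariantTable(chrom = c("1", "1"), pos = c(200L, 100L),
                            ref = c("A", "A"), alt = c("G", "G"),
                            samples = "s1",
                            calls = matrix(0L, 1, 2)),
               "strictly increasing")
  expect_error(DosageTensor(array(1, c(1, 1, 3)), "1", 1L,
                            c("a", "b", "c")),
               "dosage sums")
})
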