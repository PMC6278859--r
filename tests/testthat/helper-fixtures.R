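## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately naive (direct enumeration, double loops) and share no code
## with the implementation paths they check.

randomVariantTable <- function(nSamples = 10, nVariants = 50,
                               missRate = 0, seed = 1, nChrom = 1,
                               groups = NULL, spacing = 1000) {
  set.seed(seed)
  perChrom <- ceiling(nVariants / nChrom)
  chrom <- rep(as.character(seq_len(nChrom)), each = perChrom)[
    seq_len(nVariants)]
  pos <- unlist(lapply(seq_len(nChrom), function(c2) {
    k <- sum(chrom == as.character(c2))
    sort(sample.int(spacing * 100 * k, k))
  }))
  f <- runif(nVariants, 0.05, 0.95)
  calls <- matrix(rbinom(nSamples * nVariants, 2,
                         rep(f, each = nSamples)),
                  nSamples, nVariants)
  if (missRate > 0)
    calls[runif(length(calls)) < missRate] <- NA
  if (is.null(groups)) groups <- rep("g1", nSamples)
  VariantTable(chrom = chrom, pos = pos,
               ref = rep("A", nVariants), alt = rep("G", nVariants),
               samples = data.frame(id = sprintf("s%02d", seq_len(nSamples)),
                                    group = groups),
               calls = calls)
}

## exact HWE p by direct enumeration of the conditional distribution
## (log-factorial arithmetic, no recurrence)
bruteHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  lp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 0)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  pObs <- p[match(nAa, hets)]
  sum(p[p <= pObs * (1 + 1e-12)])
}

## brute-force ROH reference: direct window enumeration, no cumulative
## sums, single individual
bruteRoh <- function(g, pos, cfg = rohConfig()) {
  m <- length(pos)
  ws <- cfg$windowSnp
  W <- cfg$windowKb * 1000
  nAnchor <- m - ws + 1
  if (nAnchor < 1) return(NULL)
  winSnps <- vector("list", nAnchor)
  pass <- logical(nAnchor)
  for (a in seq_len(nAnchor)) {
    idx <- a:(a + ws - 1)
    idx <- idx[pos[idx] < pos[a] + W]
    winSnps[[a]] <- idx
    gw <- g[idx]
    pass[a] <- sum(gw == 1, na.rm = TRUE) <= cfg$maxHetPerWindow &&
      sum(is.na(gw)) <= cfg$maxMissingPerWindow
  }
  eligible <- logical(m)
  for (s in seq_len(m)) {
    inWin <- vapply(seq_len(nAnchor), function(a) s %in% winSnps[[a]],
                    TRUE)
    if (!any(inWin)) next
    eligible[s] <- mean(pass[inWin]) >= cfg$hitFraction
  }
  segs <- NULL
  s <- 1
  while (s <= m) {
    if (!eligible[s]) { s <- s + 1; next }
    e <- s
    while (e < m && eligible[e + 1] &&
           pos[e + 1] - pos[e] <= cfg$maxGapKb * 1000) e <- e + 1
    run <- s:e
    gRun <- g[run]
    hom <- which(!is.na(gRun) & gRun != 1)
    if (length(hom) > 0) {
      run <- run[min(hom):max(hom)]
      lenKb <- (pos[run[length(run)]] - (pos[run[1]] - 1)) / 1000
      if (lenKb >= cfg$minRohKb &&
          lenKb / length(run) <= cfg$minDensityKbPerSnp)
        segs <- rbind(segs, data.frame(start = pos[run[1]] - 1,
                                       end = pos[run[length(run)]],
                                       nSnps = length(run)))
    }
    s <- e + 1
  }
  segs
}

## mean pairwise Hamming distance, all pairs explicitly
brutePi <- function(haps) {
  n <- nrow(haps)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(haps[i, ] != haps[j, ])
    cnt <- cnt + 1
  }
  tot / cnt
}

## small admixed cohort with reference panels, memoized across tests
cachedCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCohort(nIndividuals = 100, totalMb = 600,
                               nChrom = 10, snpSpacingBp = 30000,
                               refPanelSize = 60, withDosage = FALSE,
                               seed = 42)
    cache
  }
})

writeToyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", sep = "\t"),
    paste("chr1", "200", "rs2", "C", "T,G", ".", "PASS", ".", "GT",
          "0/1", "1/1", sep = "\t"),
    paste("chr1", "300", "rs3", "G", "A", ".", "PASS", ".", "GT",
          "./.", "1/1", sep = "\t")), path)
  path
}
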