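## qc_filters: call-rate / MAF / HWE filtering, greedy windowed LD pruning
## and long-range-LD region exclusion, mirroring standard PLINK behaviour
## on unphased genotype dosages.

#' QC configuration
#'
#' Defaults follow common array-QC practice: 95% call rates, MAF 0.01,
#' HWE exact P 1e-6, pruning windows of 50 SNPs sliding by 10 with an r^2
#' ceiling of 0.5, and the four canonical hg19 long-range-LD regions
#' (chr5/6/8/11) excluded before pruning.
#'
#' @param sampleCallRateMin,variantCallRateMin minimum fraction of
#'   non-missing calls per sample / per variant.
#' @param mafMin minimum minor allele frequency.
#' @param hwePMin minimum HWE exact-test probability.
#' @param pruneWindow,pruneStep window size and step, in SNP counts.
#' @param pruneR2Max maximum pairwise genotype r^2 within a window.
#' @param excludedRegions data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open) of regions removed before pruning, or NULL.
#' @return A list of class `QCConfig`.
#' @export
qcConfig <- function(sampleCallRateMin = 0.95, variantCallRateMin = 0.95,
                     mafMin = 0.01, hwePMin = 1e-6,
                     pruneWindow = 50, pruneStep = 10, pruneR2Max = 0.5,
                     excludedRegions = longRangeLDRegions()) {
  stopifnot(sampleCallRateMin >= 0, sampleCallRateMin <= 1,
            variantCallRateMin >= 0, variantCallRateMin <= 1,
            mafMin >= 0, mafMin <= 1, pruneWindow > pruneStep,
            pruneStep > 0)
  structure(list(sampleCallRateMin = sampleCallRateMin,
                 variantCallRateMin = variantCallRateMin,
                 mafMin = mafMin, hwePMin = hwePMin,
                 pruneWindow = pruneWindow, pruneStep = pruneStep,
                 pruneR2Max = pruneR2Max,
                 excludedRegions = excludedRegions),
            class = "QCConfig")
}

#' Canonical hg19 long-range LD regions
#'
#' The four high-LD regions conventionally excluded before PCA/ADMIXTURE
#' style analyses (extended MHC on chr6, chr5, chr8 inversion, chr11),
#' as 0-based half-open intervals.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
longRangeLDRegions <- function() {
  data.frame(chrom = c("5", "6", "8", "11"),
             start = c(43964242, 24892020, 7962589, 45043423),
             end = c(51464244, 33392022, 11962591, 57243424),
             stringsAsFactors = FALSE)
}

#' Allele frequency and missingness helpers
#'
#' @param vt a [VariantTable-class].
#' @return `altFreq`: per-variant alt-allele frequency over non-missing
#'   calls; `maf`: folded minor allele frequency.
#' @keywords internal
altFreqs <- function(vt) {
  g <- vt@calls
  nn <- colSums(!is.na(g))
  af <- colSums(g, na.rm = TRUE) / (2 * nn)
  af[nn == 0] <- NA
  af
}

mafOf <- function(af) pmin(af, 1 - af)

#' Apply call-rate, MAF and HWE filters
#'
#' Order of operations is fixed: samples below the call-rate threshold are
#' removed first, then variants by call rate, then MAF, then HWE exact
#' test, with the later thresholds evaluated on the retained samples.
#' Thresholds are exclusive ("below X removed"), so a variant exactly at a
#' threshold is kept.
#'
#' @param vt a [VariantTable-class].
#' @param cfg a [qcConfig()].
#' @param hweByGroup apply the HWE filter within each sample group and
#'   remove a variant that fails in any group (the convention for
#'   reference panels); default FALSE, i.e. one global test on the
#'   cohort.
#' @return list with `table` (filtered [VariantTable-class]) and `report`,
#'   a data.frame of removal counts by reason.
#' @export
filterGenotypes <- function(vt, cfg = qcConfig(), hweByGroup = FALSE) {
  nS0 <- nSamples(vt)
  sampleRate <- rowMeans(!is.na(vt@calls))
  keepS <- sampleRate >= cfg$sampleCallRateMin
  vt <- vt[keepS, ]

  varRate <- colMeans(!is.na(vt@calls))
  keepRate <- varRate >= cfg$variantCallRateMin
  vt1 <- vt[, keepRate]

  maf <- mafOf(altFreqs(vt1))
  keepMaf <- !is.na(maf) & maf >= cfg$mafMin
  vt2 <- vt1[, keepMaf]

  hweOne <- function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(1)
    hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  hweP <- if (hweByGroup) {
    grp <- vt2@samples$group
    apply(vt2@calls, 2, function(g)
      min(vapply(unique(grp), function(gr) hweOne(g[grp == gr]), 0)))
  } else {
    apply(vt2@calls, 2, hweOne)
  }
  keepHwe <- hweP >= cfg$hwePMin
  out <- vt2[, keepHwe]

  report <- data.frame(
    reason = c("sample_call_rate", "variant_call_rate", "maf", "hwe",
               "retained_samples", "retained_variants"),
    count = c(nS0 - sum(keepS), sum(!keepRate), sum(!keepMaf),
              sum(!keepHwe), nSamples(out), nVariants(out)))
  if (nVariants(out) == 0) warning("no variants survive QC")
  list(table = out, report = report)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the observed allele counts, the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' The conditional distribution is evaluated by the standard stable
#' recurrence over heterozygote counts. Monomorphic sites return 1.
#'
#' @param nAA,nAa,naa genotype counts (AA, Aa, aa).
#' @return The exact two-sided probability.
#' @examples
#' hweExactTest(5, 0, 0)   # monomorphic: 1
#' hweExactTest(0, 50, 0)  # extreme heterozygote excess: tiny
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("total genotype count must be positive")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  nRare <- min(nA, na)
  ## heterozygote count has the parity of the rare allele count
  hetVals <- seq(nRare %% 2, nRare, by = 2)
  probs <- numeric(length(hetVals))
  ## start from the mid value and apply the recurrence both ways:
  ## P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1))
  ## with nAA(h) = (nA - h)/2, naa(h) = (na - h)/2
  mid <- which.min(abs(hetVals - nRare * (nA + na - nRare) / (nA + na)))
  probs[mid] <- 1
  if (mid < length(hetVals)) {
    for (i in mid:(length(hetVals) - 1)) {
      h <- hetVals[i]
      probs[i + 1] <- probs[i] * 4 * ((nA - h) / 2) * ((na - h) / 2) /
        ((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (i in mid:2) {
      h <- hetVals[i]
      probs[i - 1] <- probs[i] * h * (h - 1) /
        (4 * ((nA - h) / 2 + 1) * ((na - h) / 2 + 1))
    }
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(nAa, hetVals)]
  if (is.na(pObs)) stop("impossible heterozygote count given allele totals")
  ## tolerance guards equal-probability ties against FP noise
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

#' Greedy windowed LD pruning
#'
#' PLINK-style `--indep-pairwise`: variants falling in `excludedRegions`
#' are removed first; then, within each window of `pruneWindow` SNPs
#' (sliding by `pruneStep`), while any remaining pair has genotype
#' correlation r^2 above `pruneR2Max`, the member with the lower MAF is
#' dropped (ties: the later variant). r^2 uses 0/1/2 dosages with
#' pairwise-complete observations.
#'
#' @param vt a [VariantTable-class] (position-sorted).
#' @param cfg a [qcConfig()].
#' @return list with `table` (pruned [VariantTable-class]) and `removed`,
#'   a data.frame of removal counts by reason.
#' @export
ldPrune <- function(vt, cfg = qcConfig()) {
  nExcl <- 0
  if (!is.null(cfg$excludedRegions) && nrow(cfg$excludedRegions) > 0) {
    ex <- cfg$excludedRegions
    drop <- rep(FALSE, nVariants(vt))
    for (r in seq_len(nrow(ex))) {
      drop <- drop | (vt@chrom == normChrom(ex$chrom[r]) &
                        vt@pos > ex$start[r] & vt@pos <= ex$end[r])
    }
    nExcl <- sum(drop)
    vt <- vt[, !drop]
  }
  maf <- mafOf(altFreqs(vt))
  keep <- rep(TRUE, nVariants(vt))
  for (ch in unique(vt@chrom)) {
    idxCh <- which(vt@chrom == ch)
    mCh <- length(idxCh)
    st <- 1
    repeat {
      win <- idxCh[st:min(st + cfg$pruneWindow - 1, mCh)]
      win <- win[keep[win]]
      if (length(win) > 1) {
        g <- vt@calls[, win, drop = FALSE]
        r2 <- suppressWarnings(
          cor(g, use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        repeat {
          w <- which(r2 > cfg$pruneR2Max, arr.ind = TRUE)
          if (nrow(w) == 0) break
          w <- w[w[, 1] < w[, 2], , drop = FALSE]
          i <- w[1, 1]; j <- w[1, 2]
          drop <- if (isTRUE(maf[win[i]] < maf[win[j]])) i else j
          keep[win[drop]] <- FALSE
          r2[drop, ] <- 0; r2[, drop] <- 0
        }
      }
      if (st + cfg$pruneWindow - 1 >= mCh) break
      st <- st + cfg$pruneStep
    }
  }
  list(table = vt[, keep],
       removed = data.frame(reason = c("excluded_region", "ld_pruned"),
                            count = c(nExcl, sum(!keep))))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 21)  # 7 groups pairwise -> 0.0024
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) alpha / m
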