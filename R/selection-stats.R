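## selection_stats: windowed Tajima's D, Hudson FST and the population
## branch statistic (PBS), with empirical significance from a coalescent
## null ensemble.

tajimaConstants <- function(n) {
  ## n = number of sequences (haplotypes)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

#' Tajima's D from pi and S
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1)); undefined (NA) when S = 0.
#'
#' @param pi mean pairwise differences.
#' @param S segregating-site count.
#' @param n number of sequences.
#' @return Tajima's D, or NA when S is 0.
#' @export
tajimasD <- function(pi, S, n) {
  if (S == 0) return(NA_real_)
  k <- tajimaConstants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Summary statistics of a haplotype sample
#'
#' The classical per-locus summaries of a 0/1 haplotype matrix:
#' segregating sites S, mean pairwise differences pi (computed as
#' sum over sites of 2 p q n/(n-1), equal to the mean pairwise Hamming
#' distance), and Tajima's D.
#'
#' @param haps haplotypes x sites 0/1 matrix.
#' @return list with `S`, `pi`, `D` (NA when S = 0).
#' @examples
#' sampleStats(rbind(c(0, 0, 1, 1), c(1, 1, 0, 0),
#'                   c(0, 0, 0, 0), c(1, 1, 1, 1)))
#' @export
sampleStats <- function(haps) {
  stopifnot(nrow(haps) >= 2)
  n <- nrow(haps)
  if (ncol(haps) == 0) return(list(S = 0L, pi = 0, D = NA_real_))
  p <- colMeans(haps)
  seg <- p > 0 & p < 1
  S <- sum(seg)
  pi <- sum(2 * p[seg] * (1 - p[seg])) * n / (n - 1)
  list(S = as.integer(S), pi = pi, D = tajimasD(pi, S, n))
}

#' Windowed diversity statistics from diploid genotypes
#'
#' Non-overlapping windows of `windowBp`, anchored at the region start.
#' Per window: S (polymorphic genotyped sites), pi computed from genotype
#' allele frequencies assuming random union of gametes
#' (sum over sites of 2 p (1-p) 2n/(2n-1)), and Tajima's D with
#' n = 2 x samples. Windows with no polymorphic site have S = 0 and D
#' missing.
#'
#' @param vt a [VariantTable-class].
#' @param chrom chromosome of the scanned region.
#' @param start,end region bounds, 0-based half-open; windows tile
#'   `[start, end)`.
#' @param windowBp window size in bp (default 10,000).
#' @param nHap number of chromosomes entering pi and D (default
#'   `2 * nSamples(vt)`; set to `nSamples(vt)` when each row is a
#'   haplotype recoded as a homozygous diploid).
#' @return data.frame: `chrom`, `start`, `end`, `nSnps`, `S`, `pi`, `D`,
#'   with the local minimum of D across windows in attribute `"minD"`.
#' @export
windowStats <- function(vt, chrom, start, end, windowBp = 10000,
                        nHap = 2 * nSamples(vt)) {
  chrom <- normChrom(chrom)
  jj <- which(vt@chrom == chrom & vt@pos > start & vt@pos <= end)
  starts <- seq(start, end - 1, by = windowBp)
  out <- data.frame(chrom = chrom, start = starts,
                    end = pmin(starts + windowBp, end),
                    nSnps = 0L, S = 0L, pi = 0, D = NA_real_)
  if (length(jj) > 0) {
    win <- findInterval(vt@pos[jj] - 1, starts)
    for (w in unique(win)) {
      sel <- jj[win == w]
      g <- vt@calls[, sel, drop = FALSE]
      nn <- colSums(!is.na(g))
      ok <- nn > 0
      p <- colSums(g, na.rm = TRUE)[ok] / (2 * nn[ok])
      seg <- p > 0 & p < 1
      S <- sum(seg)
      pi <- sum(2 * p[seg] * (1 - p[seg])) * nHap / (nHap - 1)
      out$nSnps[w] <- length(sel)
      out$S[w] <- as.integer(S)
      out$pi[w] <- pi
      out$D[w] <- tajimasD(pi, S, nHap)
    }
  }
  attr(out, "minD") <- if (any(!is.na(out$D))) min(out$D, na.rm = TRUE)
    else NA_real_
  out
}

#' Hudson's FST estimator (ratio of averages)
#'
#' Per site: numerator (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' denominator p1(1-p2) + p2(1-p1); FST is the ratio of the site sums.
#' Robust to rare variants; the standard choice for PBS. Undefined when
#' every site is monomorphic in both samples.
#'
#' @param counts1,counts2 data.frames (or lists) with per-site `alt`
#'   (alt-allele count) and `n` (allele total, i.e. 2 x genotyped
#'   individuals).
#' @return FST (possibly slightly negative), or NA when undefined.
#' @export
hudsonFst <- function(counts1, counts2) {
  p1 <- counts1$alt / counts1$n
  p2 <- counts2$alt / counts2$n
  ok <- counts1$n > 1 & counts2$n > 1 & !is.na(p1) & !is.na(p2)
  if (!any(ok)) return(NA_real_)
  num <- (p1[ok] - p2[ok])^2 -
    p1[ok] * (1 - p1[ok]) / (counts1$n[ok] - 1) -
    p2[ok] * (1 - p2[ok]) / (counts2$n[ok] - 1)
  den <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
  if (sum(den) == 0) return(NA_real_)   # monomorphic everywhere in both
  sum(num) / sum(den)
}

#' Allele counts of a VariantTable (for FST/PBS)
#' @param vt a [VariantTable-class].
#' @param j optional variant index.
#' @return data.frame with `alt` and `n` per site.
#' @export
alleleCounts <- function(vt, j = seq_len(nVariants(vt))) {
  g <- vt@calls[, j, drop = FALSE]
  data.frame(alt = colSums(g, na.rm = TRUE),
             n = 2 * colSums(!is.na(g)))
}

#' Population branch statistic
#'
#' PBS for focal population A against B and C:
#' T_xy = -log(1 - FST_xy), PBS_A = (T_AB + T_AC - T_BC) / 2.
#' Negative FST estimates are treated as 0 branch length contribution via
#' the log transform's argument being clamped to (0, 1]; FST >= 1 is
#' clamped just below 1.
#'
#' @param fstAB,fstAC,fstBC pairwise FST values.
#' @return PBS for population A (NA if any input is NA).
#' @examples
#' pbs(0.2, 0.2, 0)  # -log(0.8) = 0.2231
#' @export
pbs <- function(fstAB, fstAC, fstBC) {
  if (anyNA(c(fstAB, fstAC, fstBC))) return(NA_real_)
  tt <- function(f) -log(1 - min(max(f, 0), 1 - 1e-9))
  (tt(fstAB) + tt(fstAC) - tt(fstBC)) / 2
}

#' Windowed PBS from three cohorts
#'
#' @param vtA,vtB,vtC [VariantTable-class] objects on shared loci (A is
#'   the focal population).
#' @param chrom,start,end,windowBp window layout as in [windowStats()].
#' @return data.frame: `chrom`, `start`, `end`, `fstAB`, `fstAC`,
#'   `fstBC`, `PBS`.
#' @export
windowPbs <- function(vtA, vtB, vtC, chrom, start, end, windowBp = 10000) {
  chrom <- normChrom(chrom)
  starts <- seq(start, end - 1, by = windowBp)
  out <- data.frame(chrom = chrom, start = starts,
                    end = pmin(starts + windowBp, end),
                    fstAB = NA_real_, fstAC = NA_real_, fstBC = NA_real_,
                    PBS = NA_real_)
  jj <- which(vtA@chrom == chrom & vtA@pos > start & vtA@pos <= end)
  if (length(jj) == 0) return(out)
  win <- findInterval(vtA@pos[jj] - 1, starts)
  for (w in unique(win)) {
    sel <- jj[win == w]
    cA <- alleleCounts(vtA, sel)
    cB <- alleleCounts(vtB, sel)
    cC <- alleleCounts(vtC, sel)
    out$fstAB[w] <- hudsonFst(cA, cB)
    out$fstAC[w] <- hudsonFst(cA, cC)
    out$fstBC[w] <- hudsonFst(cB, cC)
    out$PBS[w] <- pbs(out$fstAB[w], out$fstAC[w], out$fstBC[w])
  }
  out
}

#' Attach empirical p-values and Bonferroni flags to windowed statistics
#'
#' Tajima's D is tested in the lower tail (sweep-like deficits), PBS in
#' the upper tail, each against its simulated neutral null. Zero-count
#' p-values are floored at 1/N and flagged, matching the "P < 1/N"
#' reporting convention.
#'
#' @param windows data.frame with columns `D` and/or `PBS`.
#' @param nullD,nullPBS `NullEnsemble` objects (see [buildNullEnsemble()]);
#'   either may be NULL.
#' @param mD,mPBS numbers of tests for the per-family Bonferroni
#'   thresholds.
#' @param alpha family-wise error rate.
#' @return `windows` with `pD`, `pDFloored`, `sigD` and/or `pPBS`,
#'   `pPBSFloored`, `sigPBS` columns; thresholds in attributes
#'   `"thresholdD"`, `"thresholdPBS"`.
#' @export
selectionScan <- function(windows, nullD = NULL, nullPBS = NULL,
                          mD = sum(!is.na(windows$D)),
                          mPBS = sum(!is.na(windows$PBS)),
                          alpha = 0.05) {
  if (!is.null(nullD) && !is.null(windows$D)) {
    thrD <- bonferroniThreshold(alpha, max(mD, 1))
    pe <- vapply(windows$D, function(d)
      if (is.na(d)) NA_real_ else empiricalP(d, nullD, tail = "lower"), 0)
    windows$pD <- pmax(pe, 1 / nullD$N)
    windows$pDFloored <- !is.na(pe) & pe == 0
    windows$sigD <- !is.na(windows$pD) & windows$pD < thrD
    attr(windows, "thresholdD") <- thrD
  }
  if (!is.null(nullPBS) && !is.null(windows$PBS)) {
    thrP <- bonferroniThreshold(alpha, max(mPBS, 1))
    pe <- vapply(windows$PBS, function(s)
      if (is.na(s)) NA_real_
      else empiricalP(s, nullPBS, tail = "upper", stat = "PBS"), 0)
    windows$pPBS <- pmax(pe, 1 / nullPBS$N)
    windows$pPBSFloored <- !is.na(pe) & pe == 0
    windows$sigPBS <- !is.na(windows$pPBS) & windows$pPBS < thrP
    attr(windows, "thresholdPBS") <- thrP
  }
  windows
}
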