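## ancestry_scan: genome-wide Z-score scan for local-ancestry deviations,
## region calling, and the diversity follow-up inside called regions.

#' Z-score scan of local-ancestry deviations
#'
#' For each ancestry k, the per-locus mean ancestry fraction (mean
#' dosage / 2 across individuals, unphased averaging unit) is standardized
#' against its own genome-wide mean and empirical SD across loci:
#' Z_jk = (abar_jk - mu_k) / sigma_k. The empirical SD absorbs inference
#' noise and autocorrelation, so the two-sided normal tail at |Z| = 3
#' corresponds to P = 2.7e-3.
#'
#' @param dt a [DosageTensor-class] (>= 2 loci, >= 2 individuals).
#' @return list of class `ZScanResult`: `meanFraction` (loci x K),
#'   `mu`, `sigma` (per ancestry), `z` (loci x K), `chrom`, `pos`,
#'   `ancestries`.
#' @export
zscoreScan <- function(dt) {
  d <- dim(dt@dose)
  stopifnot(d[1] >= 2, d[2] >= 2)
  abar <- colMeans(dt@dose, na.rm = TRUE) / 2    # loci x K
  mu <- colMeans(abar)
  sigma <- apply(abar, 2, sd)
  z <- sweep(sweep(abar, 2, mu), 2, sigma, "/")
  flat <- sigma == 0 | !is.finite(sigma)
  if (any(flat)) {
    warning("constant ancestry fraction for: ",
            paste(dt@ancestries[flat], collapse = ", "), "; Z set to 0")
    z[, flat] <- 0
  }
  structure(list(meanFraction = abar, mu = mu, sigma = sigma, z = z,
                 chrom = dt@chrom, pos = dt@pos,
                 ancestries = dt@ancestries),
            class = "ZScanResult")
}

#' Call deviant-ancestry regions from a Z scan
#'
#' Maximal runs of consecutive loci with |Z| above the threshold, per
#' ancestry and chromosome, tolerating up to `maxGapSnps` sub-threshold
#' loci inside a run. The lead SNP is the locus with the largest |Z|
#' (ties: lowest position). Region bounds are the outermost qualifying
#' SNPs, reported 0-based half-open.
#'
#' @param zs a `ZScanResult` from [zscoreScan()].
#' @param threshold |Z| threshold (default 3, i.e. two-sided P 2.7e-3).
#' @param maxGapSnps sub-threshold loci tolerated within a run (default 0).
#' @return data.frame: `ancestry`, `chrom`, `start`, `end`, `nSnps`,
#'   `leadPos`, `leadZ`, `leadMeanPct` (mean ancestry percent at the lead
#'   SNP).
#' @export
callRegions <- function(zs, threshold = 3, maxGapSnps = 0) {
  out <- vector("list", 0)
  for (k in seq_along(zs$ancestries)) {
    for (ch in unique(zs$chrom)) {
      jj <- which(zs$chrom == ch)
      hot <- abs(zs$z[jj, k]) > threshold
      if (!any(hot)) next
      hotIdx <- which(hot)
      brk <- diff(hotIdx) > maxGapSnps + 1L
      runId <- cumsum(c(TRUE, brk))
      for (rid in unique(runId)) {
        sel <- jj[hotIdx[runId == rid]]
        zv <- zs$z[sel, k]
        lead <- sel[order(-abs(zv), zs$pos[sel])[1]]
        out[[length(out) + 1L]] <- data.frame(
          ancestry = zs$ancestries[k], chrom = ch,
          start = zs$pos[sel[1]] - 1L, end = zs$pos[sel[length(sel)]],
          nSnps = length(sel), leadPos = zs$pos[lead],
          leadZ = zs$z[lead, k],
          leadMeanPct = 100 * zs$meanFraction[lead, k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(ancestry = character(), chrom = character(),
                      start = integer(), end = integer(),
                      nSnps = integer(), leadPos = integer(),
                      leadZ = numeric(), leadMeanPct = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Diversity follow-up inside called regions
#'
#' For every SNP: observed heterozygosity (het calls over non-missing
#' calls) and the number of individuals whose ROH covers the SNP. Each
#' region's per-SNP values are compared against the genome-wide per-SNP
#' distribution with two-sided rank-sum tests; significance is Bonferroni
#' corrected for `mTests` regions.
#'
#' @param vt a [VariantTable-class].
#' @param roh ROH segments from [callRoh()] (same coordinate system).
#' @param regions region calls from [callRegions()].
#' @param mTests number of tests for the Bonferroni threshold (default:
#'   number of regions).
#' @param alpha family-wise error rate.
#' @return list with `perRegion` (meanHet, meanRohCarriers, pHet, pRoh,
#'   significance flags), `genome` (genome-wide means) and
#'   `bonferroniThreshold`.
#' @export
regionDiversity <- function(vt, roh, regions, mTests = nrow(regions),
                            alpha = 0.05) {
  g <- vt@calls
  nn <- colSums(!is.na(g))
  het <- colSums(g == 1L, na.rm = TRUE) / nn
  carriers <- numeric(nVariants(vt))
  if (nrow(roh) > 0) {
    for (r in seq_len(nrow(roh))) {
      sel <- vt@chrom == roh$chrom[r] & vt@pos > roh$start[r] &
        vt@pos <= roh$end[r]
      carriers[sel] <- carriers[sel] + 1
    }
  }
  thr <- bonferroniThreshold(alpha, max(mTests, 1))
  perRegion <- regions
  perRegion$meanHet <- NA_real_
  perRegion$meanRohCarriers <- NA_real_
  perRegion$pHet <- NA_real_
  perRegion$pRoh <- NA_real_
  for (r in seq_len(nrow(regions))) {
    sel <- vt@chrom == regions$chrom[r] & vt@pos > regions$start[r] &
      vt@pos <= regions$end[r]
    if (!any(sel)) next
    perRegion$meanHet[r] <- mean(het[sel], na.rm = TRUE)
    perRegion$meanRohCarriers[r] <- mean(carriers[sel])
    perRegion$pHet[r] <- wilcoxonRankSum(het[sel], het[!sel])$p
    perRegion$pRoh[r] <- wilcoxonRankSum(carriers[sel], carriers[!sel])$p
  }
  perRegion$sigHet <- !is.na(perRegion$pHet) & perRegion$pHet < thr
  perRegion$sigRoh <- !is.na(perRegion$pRoh) & perRegion$pRoh < thr
  list(perRegion = perRegion,
       genome = c(meanHet = mean(het, na.rm = TRUE),
                  meanRohCarriers = mean(carriers)),
       bonferroniThreshold = thr)
}

#' Export Z tracks as TSV
#' @param zs a `ZScanResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeZTracks <- function(zs, path) {
  tb <- data.frame(chrom = zs$chrom, pos = zs$pos)
  for (k in seq_along(zs$ancestries))
    tb[[paste0("Z_", zs$ancestries[k])]] <- zs$z[, k]
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
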