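## roh_caller: PLINK-style sliding-window detection of runs of
## homozygosity, per-group summaries, and rank-sum comparisons.

#' ROH caller configuration
#'
#' The five printed parameters of the standard array ROH screen (5,000-kb
#' window cap, at most 1 heterozygote and 5 missing calls per window,
#' minimum run length 500 kb, minimum density 50 kb/SNP) plus the PLINK
#' defaults the screen leaves implicit: the 50-SNP scanning window, the
#' window hit-rate threshold (0.05) and the maximum internal gap
#' (1,000 kb). The implicit ones affect reproduction on external data and
#' are therefore explicit here. The scanning window is `windowSnp`
#' consecutive SNPs, truncated so it never spans more than `windowKb`.
#'
#' @param windowKb maximum window span in kb.
#' @param windowSnp scanning window size in SNPs (PLINK default 50).
#' @param maxHetPerWindow,maxMissingPerWindow per-window tolerance.
#' @param minRohKb minimum reported run length (kb).
#' @param minDensityKbPerSnp maximum kb per SNP within a run.
#' @param hitFraction minimum fraction of passing windows covering a SNP.
#' @param maxGapKb maximum inter-SNP gap within a run (kb).
#' @return list of class `ROHConfig`.
#' @export
rohConfig <- function(windowKb = 5000, windowSnp = 50,
                      maxHetPerWindow = 1,
                      maxMissingPerWindow = 5, minRohKb = 500,
                      minDensityKbPerSnp = 50, hitFraction = 0.05,
                      maxGapKb = 1000) {
  stopifnot(windowKb > 0, windowSnp > 1, minRohKb > 0,
            minDensityKbPerSnp > 0, hitFraction > 0, maxGapKb > 0)
  structure(list(windowKb = windowKb, windowSnp = windowSnp,
                 maxHetPerWindow = maxHetPerWindow,
                 maxMissingPerWindow = maxMissingPerWindow,
                 minRohKb = minRohKb,
                 minDensityKbPerSnp = minDensityKbPerSnp,
                 hitFraction = hitFraction, maxGapKb = maxGapKb),
            class = "ROHConfig")
}

rohCategories <- function(lengthMb) {
  cut(lengthMb, breaks = c(0.5, 1, 2, 4, 8, 16, Inf), right = FALSE,
      labels = c("0.5-1", "1-2", "2-4", "4-8", "8-16", ">16"))
}

#' Call runs of homozygosity
#'
#' Sliding-window algorithm: the window anchored at each SNP covers the
#' next `windowSnp` SNPs (truncated so its span never exceeds
#' `windowKb`); only anchors whose full window fits on the chromosome are
#' scanned. A window passes for an individual when it contains at most
#' `maxHetPerWindow` heterozygous and `maxMissingPerWindow` missing
#' calls. Each SNP's hit rate is the fraction of passing windows among
#' the scanned windows that contain it; SNPs with hit rate >=
#' `hitFraction` are ROH-eligible. Maximal runs of eligible SNPs - split
#' where the inter-SNP gap exceeds `maxGapKb` - are reported when they
#' meet the length and density constraints. Boundaries are the outermost
#' eligible SNPs (0-based half-open).
#'
#' @param vt a [VariantTable-class] (sorted biallelic genotypes).
#' @param cfg a [rohConfig()].
#' @return data.frame of segments: `individual` (sample id), `chrom`,
#'   `start`, `end`, `lengthKb`, `nSnps`, `category` (six length classes),
#'   `over1.6Mb`.
#' @export
callRoh <- function(vt, cfg = rohConfig()) {
  W <- cfg$windowKb * 1000
  ws <- cfg$windowSnp
  segs <- vector("list", 0)
  ids <- vt@samples$id
  for (ch in unique(vt@chrom)) {
    jj <- which(vt@chrom == ch)
    pos <- as.numeric(vt@pos[jj])
    m <- length(pos)
    nAnchor <- m - ws + 1L
    if (nAnchor < 1) next
    anchors <- seq_len(nAnchor)
    ## window at anchor a covers SNPs a .. ub[a]
    ubKb <- findInterval(pos[anchors] + W - 0.5, pos)
    ub <- pmin(anchors + ws - 1L, ubKb)
    ## anchors covering SNP s: loAnch[s] .. min(s, nAnchor); ub is
    ## nondecreasing, so loAnch[s] = #\{a: ub[a] < s\} + 1
    loAnch <- findInterval(seq_len(m) - 0.5, ub) + 1L
    hiAnch <- pmin(seq_len(m), nAnchor)
    denom <- hiAnch - loAnch + 1L
    for (i in seq_len(nSamples(vt))) {
      g <- vt@calls[i, jj]
      cumHet <- cumsum(!is.na(g) & g == 1L)
      cumMis <- cumsum(is.na(g))
      het <- cumHet[ub] - c(0, cumHet)[anchors]
      mis <- cumMis[ub] - c(0, cumMis)[anchors]
      pass <- het <= cfg$maxHetPerWindow & mis <= cfg$maxMissingPerWindow
      cumPass <- c(0, cumsum(pass))
      hitRate <- ifelse(denom > 0,
                        (cumPass[hiAnch + 1L] - cumPass[loAnch]) / denom,
                        0)
      eligible <- denom > 0 & hitRate >= cfg$hitFraction
      if (!any(eligible)) next
      ## runs of eligible SNPs, split at large gaps
      brk <- diff(eligible) != 0 | diff(pos) > cfg$maxGapKb * 1000
      runId <- cumsum(c(TRUE, brk))
      for (rid in unique(runId[eligible])) {
        sel <- which(runId == rid & eligible)
        if (length(sel) == 0) next
        ## segments start and end on homozygous calls
        gSel <- g[sel]
        okEnd <- !is.na(gSel) & gSel != 1L
        if (!any(okEnd)) next
        sel <- sel[min(which(okEnd)):max(which(okEnd))]
        start <- pos[sel[1]] - 1
        end <- pos[sel[length(sel)]]
        lengthKb <- (end - start) / 1000
        if (lengthKb < cfg$minRohKb) next
        if (lengthKb / length(sel) > cfg$minDensityKbPerSnp) next
        segs[[length(segs) + 1L]] <- data.frame(
          individual = ids[i], chrom = ch, start = start, end = end,
          lengthKb = lengthKb, nSnps = length(sel),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      lengthKb = numeric(), nSnps = integer(),
                      category = factor(character(),
                                        levels = levels(rohCategories(1))),
                      over1.6Mb = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  out$category <- rohCategories(out$lengthKb / 1000)
  out$over1.6Mb <- out$lengthKb > 1600
  rownames(out) <- NULL
  out
}

#' Summarize ROH segments per group
#'
#' @param segments data.frame from [callRoh()].
#' @param samples sample sheet (`id`, `group`).
#' @return list with `perIndividual` (total Mb, count, per-category and
#'   over/under-1.6-Mb totals; individuals with no segments count as 0)
#'   and `perGroup` (group means; empty groups reported with NA).
#' @export
summarizeRoh <- function(segments, samples) {
  catLev <- levels(rohCategories(1))
  perInd <- data.frame(id = samples$id, group = samples$group,
                       totalMb = 0, count = 0L,
                       le1.6Mb = 0, gt1.6Mb = 0, stringsAsFactors = FALSE)
  for (cl in catLev) perInd[[paste0("cat", cl)]] <- 0
  if (nrow(segments) > 0) {
    for (r in seq_len(nrow(segments))) {
      i <- match(segments$individual[r], perInd$id)
      mb <- segments$lengthKb[r] / 1000
      perInd$totalMb[i] <- perInd$totalMb[i] + mb
      perInd$count[i] <- perInd$count[i] + 1L
      cl <- paste0("cat", segments$category[r])
      perInd[[cl]][i] <- perInd[[cl]][i] + mb
      if (segments$over1.6Mb[r]) perInd$gt1.6Mb[i] <- perInd$gt1.6Mb[i] + mb
      else perInd$le1.6Mb[i] <- perInd$le1.6Mb[i] + mb
    }
  }
  num <- setdiff(names(perInd), c("id", "group"))
  perGroup <- aggregate(perInd[num], by = list(group = perInd$group), mean)
  list(perIndividual = perInd, perGroup = perGroup)
}

#' @importFrom stats aggregate
NULL

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties: exact enumeration for
#' small samples without ties, normal approximation with tie correction
#' otherwise (no continuity correction, so identical samples give p = 1
#' exactly). Degenerate input with every value tied across both samples
#' returns p = 1.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (W) and `p` (two-sided).
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p  # exact: 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  wt <- suppressWarnings(wilcox.test(x, y, correct = FALSE))
  list(statistic = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Export ROH segments as PLINK .hom-style TSV
#' @param segments data.frame from [callRoh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRohTsv <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
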