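## ancestry_blocks: integer ancestry calls from dosages, block
## segmentation (excluding centromeres), and block-length statistics with
## expected per-haploid-genome counts.

#' hg19 centromere intervals
#'
#' Bundled defaults for centromere exclusion during block segmentation
#' (0-based half-open, autosomes only). Arrays give essentially no
#' coverage there, so a run crossing a centromere is split rather than
#' bridged.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
hg19Centromeres <- function() {
  data.frame(
    chrom = as.character(1:22),
    start = c(121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
              58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
              16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
              24681782, 26369569, 11288129, 13000000),
    end = c(124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
            61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
            19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
            27681782, 29369569, 14288129, 16000000),
    stringsAsFactors = FALSE)
}

#' Round ancestry dosages to integer calls
#'
#' Dosage below 0.6 rounds to 0, between 0.6 and 1.4 (inclusive) to 1, and
#' above 1.4 to 2. Individual-locus entries whose rounded values do not
#' sum to 2 across ancestries are flagged ambiguous and must be excluded
#' from segmentation.
#'
#' @param dt a [DosageTensor-class].
#' @return list with `calls` (integer array, same dimensions) and
#'   `ambiguous` (individuals x loci logical matrix).
#' @examples
#' d <- array(c(1.45, 0.5, 0.05), c(1, 1, 3))
#' roundDosages(DosageTensor(d, "1", 100L, c("EUR", "NAF", "SSA")))$calls
#' @export
roundDosages <- function(dt) {
  x <- dt@dose
  callsA <- array(1L, dim = dim(x))
  callsA[x < 0.6] <- 0L
  callsA[x > 1.4] <- 2L
  s <- rowSums(callsA, dims = 2)   # per individual x locus, over ancestries
  list(calls = callsA, ambiguous = s != 2L)
}

#' Segment integer ancestry calls into blocks
#'
#' Maximal runs of constant call level (1 or 2) per individual and
#' ancestry. Runs are broken at chromosome ends and centromere intervals;
#' ambiguous loci are dropped before segmentation. Block bounds are the
#' outermost SNP positions of the run, reported 0-based half-open.
#'
#' @param calls integer array from [roundDosages()].
#' @param ambiguous logical matrix from [roundDosages()].
#' @param chrom,pos locus coordinates (1-based positions).
#' @param ancestryLabels ancestry labels (dim 3 of `calls`).
#' @param centromeres data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or NULL.
#' @return data.frame of blocks: `individual`, `ancestry`, `level`,
#'   `chrom`, `start`, `end`, `nSnps`, `lengthMb`.
#' @export
segmentBlocks <- function(calls, ambiguous, chrom, pos, ancestryLabels,
                          centromeres = hg19Centromeres()) {
  chrom <- normChrom(chrom)
  n <- dim(calls)[1]; K <- dim(calls)[3]
  ## locus partition: chromosome x centromere side
  part <- chrom
  if (!is.null(centromeres) && nrow(centromeres) > 0) {
    for (r in seq_len(nrow(centromeres))) {
      sel <- chrom == normChrom(centromeres$chrom[r])
      if (!any(sel)) next
      after <- sel & pos > centromeres$end[r]
      inside <- sel & pos > centromeres$start[r] & pos <= centromeres$end[r]
      part[after] <- paste0(part[after], "_q")
      part[inside] <- NA   # loci inside the centromere gap are dropped
    }
  }
  res <- vector("list", 0)
  segIds <- unique(part[!is.na(part)])
  for (sg in segIds) {
    jj <- which(!is.na(part) & part == sg)
    for (i in seq_len(n)) {
      ok <- jj[!ambiguous[i, jj]]
      if (length(ok) == 0) next
      for (k in seq_len(K)) {
        v <- calls[i, ok, k]
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values >= 1L)
        if (length(hit) == 0) next
        res[[length(res) + 1L]] <- data.frame(
          individual = i, ancestry = ancestryLabels[k],
          level = r$values[hit], chrom = chrom[ok[1]],
          start = pos[ok[starts[hit]]] - 1L,
          end = pos[ok[ends[hit]]],
          nSnps = r$lengths[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(individual = integer(), ancestry = character(),
                      level = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      nSnps = integer(), lengthMb = numeric()))
  out <- do.call(rbind, res)
  out$lengthMb <- (out$end - out$start) / 1e6
  rownames(out) <- NULL
  out
}

#' Block-length statistics and expected counts
#'
#' Lengths are analyzed per ancestry on the haploid scale: a level-2
#' (homozygous-ancestry) block counts as two haploid blocks of its length.
#' Reports the mean length, the maximum-likelihood lognormal fit on log
#' lengths, the expected number of blocks per haploid genome
#' `N_k = round(p_k * L / meanLength_k)`, and pairwise rank-sum tests of
#' the length distributions.
#'
#' @param blocks data.frame from [segmentBlocks()] (or any table with
#'   `ancestry`, `lengthMb` and optionally `level`).
#' @param proportions named admixture proportions per ancestry.
#' @param genomeLengthMb haploid genome length L in Mb (default 3150, the
#'   autosomal span typically covered by array data).
#' @return list with `stats` (per-ancestry data.frame: count, meanMb,
#'   muLog, sigmaLog, expectedCount) and `pairwiseP` (rank-sum p-values).
#' @export
blockStats <- function(blocks, proportions, genomeLengthMb = 3150) {
  labs <- names(proportions)
  if (is.null(labs)) stop("proportions must be named by ancestry")
  lev <- if ("level" %in% names(blocks)) blocks$level else 1L
  idx <- rep(seq_len(nrow(blocks)), lev)   # haploid scale
  lenH <- blocks$lengthMb[idx]
  ancH <- blocks$ancestry[idx]
  stats <- do.call(rbind, lapply(labs, function(k) {
    x <- lenH[ancH == k]
    if (length(x) == 0)
      return(data.frame(ancestry = k, count = 0L, meanMb = NA_real_,
                        muLog = NA_real_, sigmaLog = NA_real_,
                        expectedCount = 0L))
    lx <- log(x)
    sigma <- if (length(x) > 1)
      sqrt(mean((lx - mean(lx))^2)) else 0   # MLE (n denominator)
    data.frame(ancestry = k, count = length(x), meanMb = mean(x),
               muLog = mean(lx), sigmaLog = sigma,
               expectedCount = as.integer(round(
                 proportions[[k]] * genomeLengthMb / mean(x))))
  }))
  rownames(stats) <- NULL
  pw <- list()
  if (length(labs) > 1) {
    for (a in seq_len(length(labs) - 1)) {
      for (b in (a + 1):length(labs)) {
        xa <- lenH[ancH == labs[a]]; xb <- lenH[ancH == labs[b]]
        p <- if (length(xa) && length(xb))
          suppressWarnings(wilcox.test(xa, xb)$p.value) else NA
        pw[[paste(labs[a], labs[b], sep = "_vs_")]] <- p
      }
    }
  }
  list(stats = stats, pairwiseP = unlist(pw),
       totalExpected = sum(stats$expectedCount))
}

#' Expected ancestry-block counts per haploid genome
#'
#' `N_k = round(p_k * L / meanLength_k)`: the genome share of ancestry k
#' divided by its mean block length.
#'
#' @param proportions admixture proportions.
#' @param meanLengthsMb per-ancestry mean block lengths (Mb).
#' @param genomeLengthMb haploid genome length (Mb), default 3150.
#' @return Integer vector of expected counts (same names as
#'   `proportions`).
#' @examples
#' expectedBlockCounts(c(EUR = 0.75, NAF = 0.22, SSA = 0.03),
#'                     c(13.05, 8.46, 7.48))  # 181, 82, 13
#' @export
expectedBlockCounts <- function(proportions, meanLengthsMb,
                                genomeLengthMb = 3150) {
  cnt <- as.integer(round(proportions * genomeLengthMb / meanLengthsMb))
  names(cnt) <- names(proportions)
  cnt
}

#' Export ancestry blocks as BED
#'
#' Name column is `individual|ancestry`, score is the dosage level.
#' @param blocks data.frame from [segmentBlocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlocksBed <- function(blocks, path) {
  writeBedRegions(data.frame(chrom = blocks$chrom, start = blocks$start,
                             end = blocks$end,
                             name = paste0("ind", blocks$individual, "|",
                                           blocks$ancestry),
                             score = blocks$level), path)
}
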