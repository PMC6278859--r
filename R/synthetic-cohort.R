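## synthetic_cohort: seeded generator of three-way admixed cohorts with
## known truth. Haplotypes are Markov ancestry mosaics (switch rate g per
## Morgan, ancestry redrawn from the admixture proportions at each switch),
## alleles are drawn from Balding-Nichols ancestry-specific frequencies,
## and deviant-ancestry regions / autozygous tracts can be injected with
## recorded truth.

#' Three-way ancestry model
#'
#' @param labels ancestry labels, distal pair last/first by convention
#'   (default EUR/NAF/SSA).
#' @param proportions admixture proportions summing to 1
#'   (default 0.75/0.22/0.03).
#' @param generations generations since the single admixture pulse
#'   (default 15).
#' @param F per-ancestry Balding-Nichols divergence from the shared
#'   ancestral frequency. Defaults (0.02, 0.03, 0.12) keep the EUR-NAF
#'   differentiation small and both far smaller than the differentiation
#'   against SSA.
#' @return list of class `AncestryModel`.
#' @export
ancestryModel <- function(labels = c("EUR", "NAF", "SSA"),
                          proportions = c(0.75, 0.22, 0.03),
                          generations = 15,
                          F = c(0.02, 0.03, 0.12)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9, generations >= 1,
            all(F > 0), all(F < 1),
            length(labels) == length(proportions),
            length(F) == length(proportions))
  structure(list(labels = labels, proportions = proportions,
                 generations = generations, F = unname(F)),
            class = "AncestryModel")
}

#' Default simulated genome
#'
#' 22 autosomes with lengths proportional to the human autosomes, scaled
#' to a configurable total (default 3,000 Mb).
#'
#' @param totalMb total genome length in Mb.
#' @param nChrom number of chromosomes (prefix of the 22 autosomes).
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
defaultGenome <- function(totalMb = 3000, nChrom = 22) {
  rel <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
           115, 107, 103, 90, 81, 78, 59, 63, 48, 51)[seq_len(nChrom)]
  len <- rel / sum(rel) * totalMb * 1e6
  setNames(round(len), as.character(seq_len(nChrom)))
}

#' Draw ancestry-specific allele frequencies (Balding-Nichols)
#'
#' For each locus an ancestral frequency p is drawn uniformly on
#' `baseRange`; each ancestry's frequency is then
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so its mean is p and its variance
#' F p (1-p).
#'
#' @param m number of loci.
#' @param model an [ancestryModel()].
#' @param baseRange range of the ancestral frequency distribution.
#' @param seed integer seed.
#' @return m x K matrix of frequencies with the ancestral frequencies in
#'   attribute `"ancestral"`.
#' @export
drawAncestralFreqs <- function(m, model = ancestryModel(),
                               baseRange = c(0.05, 0.95), seed = 1) {
  stopifnot(m > 0)
  set.seed(seed)
  p <- runif(m, baseRange[1], baseRange[2])
  K <- length(model$labels)
  fr <- matrix(NA_real_, m, K, dimnames = list(NULL, model$labels))
  for (k in seq_len(K)) {
    Fk <- model$F[k]
    if (Fk == 0) {
      fr[, k] <- p
    } else {
      fr[, k] <- rbeta(m, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
    }
  }
  attr(fr, "ancestral") <- p
  fr
}

#' Simulate haplotype ancestry mosaics
#'
#' Each haplotype is a Markov path along each chromosome: the ancestry at
#' the chromosome start is drawn from the admixture proportions; switch
#' events arrive as a Poisson process at rate `generations` per Morgan,
#' and at each switch the ancestry is redrawn from the proportions
#' (possibly unchanged, so observed constant-ancestry tracts of ancestry k
#' are exponential with mean 100 / (g (1 - p_k)) cM).
#'
#' @param n number of diploid individuals (2n haplotypes).
#' @param model an [ancestryModel()].
#' @param map a [GeneticMap-class] covering the simulated chromosomes.
#' @param seed integer seed.
#' @return list with `paths` (data.frame: hap, chrom, startBp, endBp
#'   0-based half-open, ancestry index) and `truth` (achieved genome-wide
#'   proportions, seed).
#' @export
simulateMosaic <- function(n, model = ancestryModel(), map, seed = 1) {
  set.seed(seed)
  g <- model$generations
  p <- model$proportions
  K <- length(p)
  H <- 2L * n
  tb <- map@table
  chroms <- unique(tb$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    sub <- tb[tb$chrom == ch, ]
    lenM <- (max(sub$cM) - min(sub$cM)) / 100   # Morgans
    lenBp <- max(sub$bp)
    ## switch positions per haplotype (Poisson process, rate g / Morgan)
    nSw <- rpois(H, g * lenM)
    hapIdx <- rep(seq_len(H), nSw + 1L)
    cuts <- lapply(seq_len(H), function(h) {
      s <- sort(runif(nSw[h], 0, lenM))
      c(0, s)
    })
    startM <- unlist(cuts)
    endM <- unlist(lapply(cuts, function(s) c(s[-1], lenM)))
    anc <- sample.int(K, length(startM), replace = TRUE, prob = p)
    ## cM -> bp via inverse interpolation of the map
    cm0 <- min(sub$cM)
    toBp <- function(m) approx(sub$cM, sub$bp, xout = cm0 + m * 100,
                               rule = 2)$y
    out[[ci]] <- data.frame(hap = hapIdx, chrom = ch,
                            startBp = floor(toBp(startM)),
                            endBp = ceiling(toBp(endM)),
                            ancestry = anc, stringsAsFactors = FALSE)
    out[[ci]]$endBp[out[[ci]]$endBp > lenBp] <- lenBp
  }
  paths <- do.call(rbind, out)
  lenW <- paths$endBp - paths$startBp
  achieved <- vapply(seq_len(K), function(k)
    sum(lenW[paths$ancestry == k]) / sum(lenW), 0)
  list(paths = paths,
       truth = list(achievedProportions = setNames(achieved, model$labels),
                    seed = seed))
}

ancestryAtLoci <- function(paths, chrom, pos, H) {
  ## per-haplotype ancestry index at each locus position (matrix H x m)
  m <- length(pos)
  anc <- matrix(NA_integer_, H, m)
  for (ch in unique(chrom)) {
    jj <- which(chrom == ch)
    sub <- paths[paths$chrom == ch, ]
    for (h in seq_len(H)) {
      ph <- sub[sub$hap == h, ]
      ph <- ph[order(ph$startBp), ]
      k <- findInterval(pos[jj] - 1L, ph$startBp)  # pos 1-based, blocks 0-based
      k[k < 1] <- 1
      anc[h, jj] <- ph$ancestry[k]
    }
  }
  anc
}

#' Emit genotypes and truth dosages from ancestry mosaics
#'
#' Each haplotype's allele at a locus is Bernoulli with the frequency of
#' its local ancestry; genotypes are the haplotype sums; the truth dosage
#' is the integer count of haplotypes of each ancestry (summing to 2).
#'
#' @param mosaic result of [simulateMosaic()].
#' @param freqs m x K frequency matrix from [drawAncestralFreqs()].
#' @param loci data.frame with `chrom`, `pos` (1-based), ordered.
#' @param model the [ancestryModel()].
#' @param seed integer seed.
#' @param withDosage also build the truth [DosageTensor-class] (skip for
#'   large cohorts where only genotypes are needed).
#' @param rohIntervals optional data.frame (`individual`, `chrom`,
#'   `start`, `end`; 0-based half-open): within each interval the second
#'   haplotype of the individual is overwritten by the first, producing a
#'   fully homozygous (autozygous) tract.
#' @return list with `variants` ([VariantTable-class]), `dosage`
#'   (truth [DosageTensor-class] or NULL), and `ancestryMatrix` attribute
#'   hooks used by tests.
#' @export
emitCohort <- function(mosaic, freqs, loci, model = ancestryModel(),
                       seed = 1, withDosage = TRUE, rohIntervals = NULL) {
  set.seed(seed + 1L)
  paths <- mosaic$paths
  H <- max(paths$hap)
  n <- H %/% 2L
  K <- length(model$labels)
  m <- nrow(loci)
  loci$chrom <- normChrom(loci$chrom)
  callsM <- matrix(NA_integer_, n, m)
  dose <- if (withDosage) array(0, c(n, m, K)) else NULL
  for (ch in unique(loci$chrom)) {
    jj <- which(loci$chrom == ch)
    anc <- ancestryAtLoci(paths[paths$chrom == ch, ], rep(ch, length(jj)),
                          loci$pos[jj], H)
    f <- freqs[jj, , drop = FALSE]
    ## per-haplotype allele draws
    fh <- matrix(f[cbind(rep(seq_along(jj), each = H), as.vector(anc))],
                 H, length(jj))
    al <- matrix(as.integer(runif(H * length(jj)) < fh), H, length(jj))
    if (!is.null(rohIntervals)) {
      ri <- rohIntervals[normChrom(rohIntervals$chrom) == ch, , drop = FALSE]
      if (nrow(ri) > 0) {
        for (r in seq_len(nrow(ri))) {
          sel <- loci$pos[jj] > ri$start[r] & loci$pos[jj] <= ri$end[r]
          h1 <- 2L * ri$individual[r] - 1L
          al[h1 + 1L, sel] <- al[h1, sel]
          anc[h1 + 1L, sel] <- anc[h1, sel]
        }
      }
    }
    odd <- seq(1, H, by = 2)
    callsM[, jj] <- al[odd, , drop = FALSE] + al[odd + 1L, , drop = FALSE]
    if (withDosage) {
      for (k in seq_len(K)) {
        dose[, jj, k] <- (anc[odd, , drop = FALSE] == k) +
          (anc[odd + 1L, , drop = FALSE] == k)
      }
    }
  }
  samples <- data.frame(id = sprintf("ind%03d", seq_len(n)),
                        group = "cohort", stringsAsFactors = FALSE)
  vt <- VariantTable(chrom = loci$chrom, pos = loci$pos,
                     ref = rep("A", m), alt = rep("G", m),
                     samples = samples, calls = callsM)
  dt <- if (withDosage)
    DosageTensor(dose, loci$chrom, loci$pos, model$labels) else NULL
  list(variants = vt, dosage = dt)
}

#' Inject ancestry-deviant regions into mosaic paths
#'
#' Within each deviant interval, every haplotype's ancestry is redrawn as
#' a single whole-interval block: exactly `round(targetMean * 2n)`
#' haplotypes receive the focal ancestry and the rest draw from the
#' renormalized background proportions, so the cohort-mean dosage/2 of the
#' focal ancestry inside the interval equals the target up to 1/(4n).
#' Block contiguity is preserved (the interval becomes one block per
#' haplotype).
#'
#' @param mosaic result of [simulateMosaic()].
#' @param deviant data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `ancestry` (label or index), `target` (mean
#'   ancestry fraction in [0,1]).
#' @param model the [ancestryModel()].
#' @param map the [GeneticMap-class] used for the mosaic (bounds check).
#' @param seed integer seed.
#' @return The modified mosaic, with `truth$deviant` recording the
#'   achieved per-interval focal fraction.
#' @export
injectSignals <- function(mosaic, deviant, model = ancestryModel(), map,
                          seed = 1) {
  set.seed(seed + 2L)
  paths <- mosaic$paths
  H <- max(paths$hap)
  K <- length(model$labels)
  achieved <- numeric(nrow(deviant))
  for (r in seq_len(nrow(deviant))) {
    ch <- normChrom(deviant$chrom[r])
    s <- deviant$start[r]; e <- deviant$end[r]
    sub <- map@table[map@table$chrom == ch, ]
    if (nrow(sub) == 0 || e > max(sub$bp) || s < 0)
      stop("deviant interval outside map: ", ch, ":", s, "-", e)
    k <- deviant$ancestry[r]
    if (is.character(k)) k <- match(k, model$labels)
    stopifnot(deviant$target[r] >= 0, deviant$target[r] <= 1)
    nFocal <- round(deviant$target[r] * H)
    focalHaps <- sample.int(H, nFocal)
    pBg <- model$proportions
    pBg[k] <- 0
    pBg <- pBg / sum(pBg)
    newAnc <- integer(H)
    newAnc[focalHaps] <- k
    others <- setdiff(seq_len(H), focalHaps)
    newAnc[others] <- sample.int(K, length(others), replace = TRUE,
                                 prob = pBg)
    ## carve the interval out of existing blocks, then add one block per hap
    onCh <- paths$chrom == ch
    keep <- !(onCh & paths$startBp >= s & paths$endBp <= e)
    paths <- paths[keep, ]
    ## split blocks spanning the whole interval, then truncate partial
    ## overlaps on either side
    both <- paths$chrom == ch & paths$startBp < s & paths$endBp > e
    if (any(both)) {
      right <- paths[both, ]
      right$startBp <- e
      paths$endBp[both] <- s
      paths <- rbind(paths, right)
    }
    lo <- paths$chrom == ch & paths$startBp < s & paths$endBp > s &
      paths$endBp <= e
    hi <- paths$chrom == ch & paths$startBp >= s & paths$startBp < e &
      paths$endBp > e
    paths$endBp[lo] <- s
    paths$startBp[hi] <- e
    paths <- rbind(paths,
                   data.frame(hap = seq_len(H), chrom = ch, startBp = s,
                              endBp = e, ancestry = newAnc,
                              stringsAsFactors = FALSE))
    achieved[r] <- nFocal / H
  }
  paths <- paths[order(paths$chrom, paths$hap, paths$startBp), ]
  mosaic$paths <- paths
  dv <- deviant
  dv$achieved <- achieved
  mosaic$truth$deviant <- dv
  mosaic
}

#' Simulate a complete admixed cohort with known truth
#'
#' Convenience wrapper: genome + map, Balding-Nichols frequencies, Markov
#' mosaics, optional deviant-region and autozygous-tract injection, and
#' genotype/dosage emission. Also emits reference-panel genotype tables
#' drawn directly from each ancestry's frequencies when
#' `refPanelSize > 0`.
#'
#' @param nIndividuals cohort size (diploid individuals).
#' @param model an [ancestryModel()].
#' @param totalMb,nChrom,cMperMb genome scale (see [defaultGenome()]).
#' @param snpSpacingBp inter-SNP spacing (default 20 kb).
#' @param deviant optional deviant-region data.frame (see
#'   [injectSignals()]).
#' @param rohIntervals optional autozygous-tract data.frame (see
#'   [emitCohort()]).
#' @param refPanelSize individuals per ancestry reference panel (0 = none).
#' @param withDosage build the truth dosage tensor.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list: `variants`, `dosage`, `refPanels` (named list of
#'   [VariantTable-class]), `map`, `freqs`, `model`, `truth`.
#' @export
simulateCohort <- function(nIndividuals = 200, model = ancestryModel(),
                           totalMb = 3000, nChrom = 22, cMperMb = 1,
                           snpSpacingBp = 20000, deviant = NULL,
                           rohIntervals = NULL, refPanelSize = 0,
                           withDosage = TRUE, seed = 1) {
  genome <- defaultGenome(totalMb, nChrom)
  map <- uniformMap(genome, cMperMb)
  loci <- do.call(rbind, lapply(names(genome), function(ch) {
    pos <- seq(snpSpacingBp, genome[[ch]], by = snpSpacingBp)
    data.frame(chrom = ch, pos = as.integer(pos), stringsAsFactors = FALSE)
  }))
  freqs <- drawAncestralFreqs(nrow(loci), model, seed = seed)
  mosaic <- simulateMosaic(nIndividuals, model, map, seed = seed)
  if (!is.null(deviant))
    mosaic <- injectSignals(mosaic, deviant, model, map, seed = seed)
  emitted <- emitCohort(mosaic, freqs, loci, model, seed = seed,
                        withDosage = withDosage,
                        rohIntervals = rohIntervals)
  refPanels <- NULL
  if (refPanelSize > 0) {
    set.seed(seed + 3L)
    refPanels <- lapply(seq_along(model$labels), function(k) {
      f <- freqs[, k]
      g <- matrix(rbinom(refPanelSize * nrow(loci), 2,
                         rep(f, each = refPanelSize)),
                  refPanelSize, nrow(loci))
      VariantTable(chrom = loci$chrom, pos = loci$pos,
                   ref = rep("A", nrow(loci)), alt = rep("G", nrow(loci)),
                   samples = data.frame(
                     id = sprintf("%s%03d", model$labels[k],
                                  seq_len(refPanelSize)),
                     group = model$labels[k], stringsAsFactors = FALSE),
                   calls = g)
    })
    names(refPanels) <- model$labels
  }
  truth <- mosaic$truth
  truth$rohIntervals <- rohIntervals
  list(variants = emitted$variants, dosage = emitted$dosage,
       refPanels = refPanels, map = map, freqs = freqs, model = model,
       truth = truth, paths = mosaic$paths)
}

#' Draw block lengths from per-ancestry lognormal distributions
#'
#' Companion generator for block-statistics tests: detected ancestry-block
#' lengths in real admixed data are well described by lognormals; this
#' draws lengths with specified arithmetic means (Mb) and log-scale SD.
#'
#' @param counts per-ancestry block counts.
#' @param meansMb per-ancestry arithmetic mean lengths in Mb
#'   (default 13.05 / 8.46 / 7.48).
#' @param sdlog log-scale standard deviation (shared).
#' @param labels ancestry labels.
#' @param seed integer seed.
#' @return data.frame with `ancestry` and `lengthMb`.
#' @export
simulateLognormalBlocks <- function(counts,
                                    meansMb = c(13.05, 8.46, 7.48),
                                    sdlog = 0.8,
                                    labels = c("EUR", "NAF", "SSA"),
                                    seed = 1) {
  set.seed(seed)
  out <- lapply(seq_along(counts), function(k) {
    mu <- log(meansMb[k]) - sdlog^2 / 2   # arithmetic mean = exp(mu+s^2/2)
    data.frame(ancestry = labels[k],
               lengthMb = exp(rnorm(counts[k], mu, sdlog)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
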