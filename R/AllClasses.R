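#' @import methods
#' @importFrom stats cor cov median na.omit pnorm poisson.test qnorm quantile
#'   rbeta rbinom rexp rnorm rpois runif sd setNames var wilcox.test ks.test
#'   complete.cases coef predict
#' @importFrom utils read.table write.table head tail
NULL

## Central containers. These are deliberately thin S4 wrappers around plain
## matrices/vectors: scans over 1e5+ variants need contiguous numeric storage,
## and all range-based interop goes through the GRanges coercions in
## genotype-io.R.

#' VariantTable: diploid genotype calls for a cohort
#'
#' A sample-by-variant matrix of alt-allele counts (0, 1, 2, `NA` for a
#' missing call) together with the variant annotation (chromosome, 1-based
#' position, id, ref/alt alleles) and a sample sheet (id, group). Only
#' biallelic SNVs are stored; positions are strictly increasing within each
#' chromosome. Chromosome labels are stored without a `"chr"` prefix.
#'
#' @slot chrom character, per-variant chromosome label (no "chr" prefix).
#' @slot pos integer, per-variant 1-based base-pair position.
#' @slot id character, variant identifiers.
#' @slot ref,alt character, reference and alternate alleles.
#' @slot samples data.frame with columns `id` and `group`.
#' @slot calls integer matrix, samples x variants, values in {0,1,2,NA}.
#'
#' @seealso [VariantTable()] for the constructor, [readVcfTable()],
#'   [variantRanges()]
#' @export
setClass("VariantTable",
  representation(
    chrom = "character",
    pos = "integer",
    id = "character",
    ref = "character",
    alt = "character",
    samples = "data.frame",
    calls = "matrix"
  )
)

setValidity("VariantTable", function(object) {
  m <- length(object@pos)
  n <- nrow(object@samples)
  msg <- character()
  if (length(object@chrom) != m || length(object@id) != m ||
      length(object@ref) != m || length(object@alt) != m)
    msg <- c(msg, "variant annotation vectors must have equal length")
  if (!identical(dim(object@calls), c(n, m)))
    msg <- c(msg, sprintf("calls must be %d x %d", n, m))
  if (!all(c("id", "group") %in% names(object@samples)))
    msg <- c(msg, "samples must have columns 'id' and 'group'")
  ok <- object@calls %in% c(0L, 1L, 2L) | is.na(object@calls)
  if (!all(ok))
    msg <- c(msg, "calls must be 0, 1, 2 or NA")
  if (m > 1) {
    for (ch in unique(object@chrom)) {
      p <- object@pos[object@chrom == ch]
      if (is.unsorted(p, strictly = TRUE)) {
        msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantTable
#'
#' @param chrom character vector of chromosome labels; a leading `"chr"`
#'   prefix is stripped to the internal canonical form.
#' @param pos integer vector of 1-based positions.
#' @param id,ref,alt variant ids and alleles; `id` defaults to
#'   `chrom:pos`.
#' @param samples data.frame with columns `id` and `group`, or a character
#'   vector of sample ids (group then defaults to `"cohort"`).
#' @param calls samples x variants matrix of alt-allele counts (0/1/2/NA).
#' @return A [VariantTable-class] object.
#' @examples
#' vt <- VariantTable(chrom = c("1", "1"), pos = c(100L, 200L),
#'                    ref = c("A", "C"), alt = c("G", "T"),
#'                    samples = c("s1", "s2"),
#'                    calls = matrix(c(0L, 1L, 2L, NA), 2, 2))
#' nVariants(vt)
#' @export
VariantTable <- function(chrom, pos, ref, alt, samples, calls,
                         id = NULL) {
  chrom <- normChrom(chrom)
  pos <- as.integer(pos)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  if (is.character(samples))
    samples <- data.frame(id = samples, group = "cohort",
                          stringsAsFactors = FALSE)
  calls <- matrix(as.integer(calls), nrow = nrow(samples))
  rownames(calls) <- samples$id
  new("VariantTable", chrom = as.character(chrom), pos = pos,
      id = as.character(id), ref = as.character(ref),
      alt = as.character(alt), samples = samples, calls = calls)
}

#' DosageTensor: per-individual local-ancestry dosages
#'
#' Individuals x loci x K array of ancestry dosages in [0, 2] (ELAI-style:
#' the expected number of chromosome copies derived from each ancestral
#' population at each locus). For every individual and locus the dosages sum
#' to 2 within a tolerance of 0.05.
#'
#' @slot dose numeric array, individuals x loci x K.
#' @slot chrom,pos per-locus chromosome and 1-based position.
#' @slot ancestries character, ancestry labels in fixed order (e.g.
#'   EUR/NAF/SSA).
#' @seealso [DosageTensor()], [readDosage()], [roundDosages()]
#' @export
setClass("DosageTensor",
  representation(
    dose = "array",
    chrom = "character",
    pos = "integer",
    ancestries = "character"
  )
)

DOSAGE_SUM_TOL <- 0.05

setValidity("DosageTensor", function(object) {
  d <- dim(object@dose)
  msg <- character()
  if (length(d) != 3)
    return("dose must be a 3-d array (individuals x loci x K)")
  if (d[2] != length(object@pos) || d[2] != length(object@chrom))
    msg <- c(msg, "locus annotation must match dim 2 of dose")
  if (d[3] != length(object@ancestries))
    msg <- c(msg, "ancestry labels must match dim 3 of dose")
  rng <- range(object@dose)
  if (rng[1] < 0 || rng[2] > 2)
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (d[1] > 0 && d[2] > 0) {
    s <- rowSums(object@dose, dims = 2)   # sum over ancestries
    if (any(abs(s - 2) > DOSAGE_SUM_TOL))
      msg <- c(msg, sprintf("dosage sums outside 2 +/- %.2f", DOSAGE_SUM_TOL))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DosageTensor
#'
#' @param dose individuals x loci x K numeric array of dosages in [0,2].
#' @param chrom,pos locus coordinates (1-based positions).
#' @param ancestries ancestry labels, length K.
#' @return A [DosageTensor-class] object.
#' @export
DosageTensor <- function(dose, chrom, pos, ancestries) {
  new("DosageTensor", dose = dose, chrom = normChrom(as.character(chrom)),
      pos = as.integer(pos), ancestries = as.character(ancestries))
}

#' GeneticMap: base-pair to centimorgan interpolation
#'
#' Per chromosome, a monotone table of (bp, cM) anchor points. Genetic
#' positions at arbitrary base pairs are obtained by linear interpolation
#' (constant extrapolation beyond the anchors).
#'
#' @slot table data.frame with columns `chrom`, `bp`, `cM`.
#' @seealso [GeneticMap()], [uniformMap()], [interpolateCM()]
#' @export
setClass("GeneticMap", representation(table = "data.frame"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  if (!all(c("chrom", "bp", "cM") %in% names(tb)))
    return("map table needs columns chrom, bp, cM")
  for (ch in unique(tb$chrom)) {
    sub <- tb[tb$chrom == ch, ]
    if (is.unsorted(sub$bp, strictly = TRUE))
      return(sprintf("bp positions not strictly increasing on %s", ch))
    if (is.unsorted(sub$cM))
      return(sprintf("cM not non-decreasing on %s", ch))
  }
  TRUE
})

#' Construct a GeneticMap from anchor points
#'
#' @param chrom,bp,cM parallel vectors of anchors; `cM` must be
#'   non-decreasing in `bp` within each chromosome.
#' @return A [GeneticMap-class] object.
#' @export
GeneticMap <- function(chrom, bp, cM) {
  tb <- data.frame(chrom = normChrom(as.character(chrom)),
                   bp = as.numeric(bp), cM = as.numeric(cM),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$chrom, tb$bp), ]
  rownames(tb) <- NULL
  new("GeneticMap", table = tb)
}

## ---- generics ----

#' @rdname VariantTable-class
#' @param x,object a VariantTable (or DosageTensor where documented).
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname VariantTable-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname VariantTable-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname VariantTable-class
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))
#' @rdname VariantTable-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' Variant loci as a GRanges
#' @param x a VariantTable or DosageTensor.
#' @return A `GenomicRanges::GRanges` with one range per variant/locus.
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))
#' @rdname DosageTensor-class
#' @export
setGeneric("ancestries", function(x) standardGeneric("ancestries"))
#' @rdname DosageTensor-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname VariantTable-class
#' @export
setMethod("nSamples", "VariantTable", function(x) nrow(x@samples))
#' @rdname VariantTable-class
#' @export
setMethod("nVariants", "VariantTable", function(x) length(x@pos))
#' @rdname VariantTable-class
#' @export
setMethod("calls", "VariantTable", function(x) x@calls)
#' @rdname VariantTable-class
#' @export
setMethod("sampleSheet", "VariantTable", function(x) x@samples)
#' @rdname VariantTable-class
#' @export
setMethod("variantInfo", "VariantTable", function(x)
  data.frame(chrom = x@chrom, pos = x@pos, id = x@id, ref = x@ref,
             alt = x@alt, stringsAsFactors = FALSE))

#' @rdname DosageTensor-class
#' @param x a DosageTensor.
#' @export
setMethod("ancestries", "DosageTensor", function(x) x@ancestries)
#' @rdname DosageTensor-class
#' @export
setMethod("dosages", "DosageTensor", function(x) x@dose)
#' @rdname DosageTensor-class
#' @export
setMethod("nSamples", "DosageTensor", function(x) dim(x@dose)[1])
#' @rdname DosageTensor-class
#' @export
setMethod("nVariants", "DosageTensor", function(x) dim(x@dose)[2])
#' @rdname DosageTensor-class
#' @export
setMethod("variantInfo", "DosageTensor", function(x)
  data.frame(chrom = x@chrom, pos = x@pos, stringsAsFactors = FALSE))

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d samples x %d biallelic variants\n",
              nSamples(object), nVariants(object)))
  if (nVariants(object) > 0)
    cat("  chromosomes:",
        paste(unique(object@chrom), collapse = ", "), "\n")
  gr <- unique(object@samples$group)
  cat("  sample groups:", paste(head(gr, 8), collapse = ", "),
      if (length(gr) > 8) "..." else "", "\n")
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
})

setMethod("show", "DosageTensor", function(object) {
  cat(sprintf("DosageTensor: %d individuals x %d loci x %d ancestries (%s)\n",
              dim(object@dose)[1], dim(object@dose)[2], dim(object@dose)[3],
              paste(object@ancestries, collapse = "/")))
})

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  cat(sprintf("GeneticMap: %d anchors on %d chromosome(s), %.1f cM total\n",
              nrow(tb), length(unique(tb$chrom)),
              sum(tapply(tb$cM, tb$chrom, function(z) diff(range(z))))))
})

## ---- small shared helpers ----

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix; the internal canonical form is bare
#' ("1", ..., "22", "X").
#' @param x character vector of chromosome labels.
#' @return Character vector without the prefix.
#' @export
normChrom <- function(x) sub("^chr", "", as.character(x))

#' Subset a VariantTable
#'
#' @param x a VariantTable.
#' @param i sample index (logical/integer).
#' @param j variant index (logical/integer).
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "VariantTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nVariants(x))
  new("VariantTable",
      chrom = x@chrom[j], pos = x@pos[j], id = x@id[j],
      ref = x@ref[j], alt = x@alt[j],
      samples = x@samples[i, , drop = FALSE],
      calls = x@calls[i, j, drop = FALSE])
})

#' @rdname DosageTensor-class
#' @param i individual index.
#' @param j locus index.
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "DosageTensor", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(dim(x@dose)[1])
  if (missing(j)) j <- seq_len(dim(x@dose)[2])
  new("DosageTensor", dose = x@dose[i, j, , drop = FALSE],
      chrom = x@chrom[j], pos = x@pos[j], ancestries = x@ancestries)
})
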