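## genotype_io: readers/writers for the standard formats the pipeline
## touches. Coordinate policy: VCF and all user-facing positions are 1-based
## inclusive; internal interval records (BED, blocks, ROH) are 0-based
## half-open.

#' Read a VCF into a VariantTable
#'
#' Parses a VCF 4.x file (plain or gzipped) and keeps only biallelic SNV
#' records; multiallelic records are dropped, not split. Genotypes are
#' mapped 0/0 -> 0, 0/1 -> 1, 1/1 -> 2 and missing ("./.") to `NA`.
#'
#' @param path path to a VCF file.
#' @param region optional `"chrom:start-end"` string (1-based inclusive);
#'   records outside it are dropped. A region with no records yields an
#'   empty table.
#' @param group group label assigned to all samples (or a named vector
#'   mapping sample id to group).
#' @return A [VariantTable-class].
#' @examples
#' vt <- simulateCohort(nIndividuals = 4, totalMb = 10, nChrom = 1,
#'                      snpSpacingBp = 1e6, seed = 1)$variants
#' f <- tempfile(fileext = ".vcf")
#' writeVcfTable(vt, f)
#' identical(calls(readVcfTable(f)), calls(vt))
#' @export
readVcfTable <- function(path, region = NULL, group = "cohort") {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- normChrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  id <- fix[, "ID"]
  ## biallelic SNVs only
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!is.null(region)) {
    rg <- parseRegion(region)
    keep <- keep & chrom == rg$chrom & pos >= rg$start & pos <= rg$end
  }
  gtRaw <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                    error = function(e) NULL)
  sampleIds <- colnames(v@gt)[-1]
  n <- length(sampleIds)
  idx <- which(keep)
  m <- length(idx)
  callsM <- matrix(NA_integer_, n, m)
  if (m > 0 && !is.null(gtRaw)) {
    g <- gtRaw[idx, , drop = FALSE]
    g <- gsub("|", "/", g, fixed = TRUE)
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    callsM <- matrix(unname(map[t(g)]), nrow = n, ncol = m)
  }
  grp <- if (length(group) == 1) rep(group, n) else unname(group[sampleIds])
  id2 <- id[idx]
  miss <- is.na(id2) | id2 == "."
  id2[miss] <- paste0(chrom[idx][miss], ":", pos[idx][miss])
  VariantTable(chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
               alt = alt[idx],
               samples = data.frame(id = sampleIds, group = grp,
                                    stringsAsFactors = FALSE),
               calls = callsM, id = id2)
}

parseRegion <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("region must be 'chrom:start-end'")
  list(chrom = normChrom(m[2]), start = as.integer(m[3]),
       end = as.integer(m[4]))
}

#' Write a VariantTable as VCF 4.2 text
#'
#' Minimal single-purpose writer (CHROM..FORMAT plus unphased GT calls);
#' output round-trips through [readVcfTable()].
#'
#' @param vt a [VariantTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVcfTable <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=islescan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vt@samples$id), collapse = "\t"), con)
  if (nVariants(vt) > 0) {
    gtChar <- matrix(c("0/0", "0/1", "1/1")[vt@calls + 1L],
                     nrow = nSamples(vt))
    gtChar[is.na(gtChar)] <- "./."
    lines <- paste(vt@chrom, vt@pos, vt@id, vt@ref, vt@alt, ".", "PASS",
                   ".", "GT",
                   apply(gtChar, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an ancestry-dosage table and its locus sidecar
#'
#' The wide dialect: one row per individual, `K` columns per locus in locus
#' order (locus-major, ancestry-minor), first column the individual id. The
#' sidecar is a TSV with columns `chrom` and `pos` (and optionally
#' `ancestries` in a header comment). Rows whose per-locus dosages do not
#' sum to 2 within the tolerance 0.05 are rejected and counted.
#'
#' @param path dosage TSV path.
#' @param lociPath locus sidecar TSV path.
#' @param K number of ancestries.
#' @param ancestries optional ancestry labels (defaults `A1..AK`).
#' @return A list with `tensor` (a [DosageTensor-class]) and `nRejected`,
#'   the number of individual-locus rows that violated the sum-to-2
#'   tolerance (their entries are renormalized out by rejection of the
#'   whole individual row when any locus fails).
#' @export
readDosage <- function(path, lociPath, K, ancestries = NULL) {
  loci <- read.table(lociPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  raw <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  ids <- raw[[1]]
  num <- as.matrix(raw[, -1, drop = FALSE])
  m <- nrow(loci)
  if (ncol(num) != m * K)
    stop(sprintf("dimension error: %d dosage columns but %d loci x K=%d",
                 ncol(num), m, K))
  if (is.null(ancestries)) ancestries <- paste0("A", seq_len(K))
  dose <- array(NA_real_, dim = c(nrow(num), m, K))
  for (k in seq_len(K)) dose[, , k] <- num[, seq(k, m * K, by = K),
                                           drop = FALSE]
  sums <- rowSums(dose, dims = 2)
  bad <- abs(sums - 2) > DOSAGE_SUM_TOL
  nRejected <- sum(bad)
  keep <- rowSums(bad) == 0
  if (nRejected > 0)
    warning(sprintf("%d individual x locus rows violate the sum-to-2 tolerance; %d individuals dropped",
                    nRejected, sum(!keep)))
  tensor <- DosageTensor(dose[keep, , , drop = FALSE], loci$chrom, loci$pos,
                         ancestries)
  attr(tensor, "individuals") <- ids[keep]
  list(tensor = tensor, nRejected = nRejected)
}

#' Write a DosageTensor in the wide dialect
#'
#' @param dt a [DosageTensor-class].
#' @param path dosage TSV path.
#' @param lociPath locus sidecar path.
#' @param ids individual ids (default `ind1..indN`).
#' @return `path`, invisibly.
#' @export
writeDosage <- function(dt, path, lociPath, ids = NULL) {
  d <- dim(dt@dose)
  if (is.null(ids)) ids <- paste0("ind", seq_len(d[1]))
  wide <- matrix(aperm(dt@dose, c(1, 3, 2)), nrow = d[1])
  write.table(data.frame(id = ids, wide), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(chrom = dt@chrom, pos = dt@pos), lociPath,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a long-format dosage table to the wide dialect
#'
#' Long dialect: one row per individual x locus with columns
#' `id`, `chrom`, `pos`, then K dosage columns.
#'
#' @param long data.frame in the long dialect.
#' @param ancestries ancestry labels (default: the K dosage column names).
#' @return A [DosageTensor-class] with an `individuals` attribute.
#' @export
longToDosage <- function(long, ancestries = NULL) {
  ids <- unique(long$id)
  key <- paste(long$chrom, long$pos)
  lociKey <- unique(key)
  doseCols <- setdiff(names(long), c("id", "chrom", "pos"))
  if (is.null(ancestries)) ancestries <- doseCols
  K <- length(doseCols)
  dose <- array(NA_real_, c(length(ids), length(lociKey), K))
  ii <- match(long$id, ids)
  jj <- match(key, lociKey)
  for (k in seq_len(K))
    dose[cbind(ii, jj, k)] <- long[[doseCols[k]]]
  first <- !duplicated(key)
  dt <- DosageTensor(dose, long$chrom[first], long$pos[first], ancestries)
  attr(dt, "individuals") <- ids
  dt
}

#' Write intervals as a BED file
#'
#' Input coordinates are 0-based half-open (BED native). A 1-based
#' inclusive interval `start..end` converts to BED as `(start-1, end)`.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedRegions <- function(regions, path) {
  if (nrow(regions) > 0 && any(regions$end <= regions$start))
    stop("validation error: BED intervals need end > start")
  cols <- data.frame(chrom = regions$chrom,
                     start = format(regions$start, scientific = FALSE,
                                    trim = TRUE),
                     end = format(regions$end, scientific = FALSE,
                                  trim = TRUE))
  if (!is.null(regions$name)) cols$name <- regions$name
  if (!is.null(regions$score)) cols$score <- regions$score
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name` and `score`.
#' @export
readBedRegions <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  tb <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(tb)[seq_len(min(5, ncol(tb)))] <-
    c("chrom", "start", "end", "name", "score")[seq_len(min(5, ncol(tb)))]
  tb$chrom <- as.character(tb$chrom)
  tb
}

#' Look up target sites and their alt-allele frequencies
#'
#' Absent targets are reported as not detected, mirroring a candidate-SNP
#' lookup in sequence data; absence is a result, not an error.
#'
#' @param vt a [VariantTable-class].
#' @param targets data.frame with columns `chrom` and `pos`, or a character
#'   vector of variant ids.
#' @return data.frame with one row per target: `id`, `chrom`, `pos`,
#'   `detected`, `altFreq` (alt alleles / 2 x non-missing genotypes) and a
#'   `genotypes` list-column of per-sample calls.
#' @export
extractSites <- function(vt, targets) {
  if (is.character(targets)) {
    j <- match(targets, vt@id)
    lab <- targets
  } else {
    key <- paste(normChrom(targets$chrom), targets$pos)
    j <- match(key, paste(vt@chrom, vt@pos))
    lab <- key
  }
  out <- data.frame(id = lab,
                    chrom = ifelse(is.na(j), NA, vt@chrom[j]),
                    pos = ifelse(is.na(j), NA, vt@pos[j]),
                    detected = !is.na(j),
                    altFreq = NA_real_, stringsAsFactors = FALSE)
  gl <- vector("list", length(j))
  for (t in seq_along(j)) {
    if (!is.na(j[t])) {
      g <- vt@calls[, j[t]]
      gl[[t]] <- g
      nn <- sum(!is.na(g))
      out$altFreq[t] <- if (nn > 0) sum(g, na.rm = TRUE) / (2 * nn) else NA
    }
  }
  out$genotypes <- gl
  out
}

#' Read a genetic map from TSV (chrom, bp, cM)
#' @param path TSV path with header columns `chrom`, `bp`, `cM`.
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  GeneticMap(tb$chrom, tb$bp, tb$cM)
}

#' Uniform-rate genetic map over given chromosome lengths
#'
#' @param chromLengthsBp named numeric vector of chromosome lengths (bp).
#' @param cMperMb constant recombination rate (default 1 cM/Mb).
#' @return A [GeneticMap-class].
#' @export
uniformMap <- function(chromLengthsBp, cMperMb = 1) {
  chrom <- rep(names(chromLengthsBp), each = 2)
  bp <- as.numeric(rbind(0, chromLengthsBp))
  cM <- as.numeric(rbind(0, chromLengthsBp * cMperMb / 1e6))
  GeneticMap(chrom, bp, cM)
}

#' Interpolate genetic positions
#'
#' Linear interpolation between anchors; constant beyond the range.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome label (scalar or vector parallel to `bp`).
#' @param bp base-pair positions.
#' @return Numeric vector of cM positions.
#' @export
interpolateCM <- function(map, chrom, bp) {
  chrom <- normChrom(chrom)
  if (length(chrom) == 1) chrom <- rep(chrom, length(bp))
  out <- numeric(length(bp))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- map@table[map@table$chrom == ch, ]
    if (nrow(sub) == 0) stop("map does not cover chromosome ", ch)
    out[sel] <- approx(sub$bp, sub$cM, xout = bp[sel], rule = 2)$y
  }
  out
}

#' @importFrom stats approx
NULL

#' Read PLINK-style .ped/.map text files
#'
#' @param pedPath .ped path (FID IID PAT MAT SEX PHENO then two allele
#'   columns per variant; "0" = missing allele).
#' @param mapPath .map path (chrom, id, cM, bp).
#' @return A [VariantTable-class]; the alt allele at each variant is the
#'   minor allele among the observed calls.
#' @export
readPedMap <- function(pedPath, mapPath) {
  mp <- read.table(mapPath, stringsAsFactors = FALSE)
  names(mp) <- c("chrom", "id", "cM", "bp")[seq_len(ncol(mp))]
  ped <- read.table(pedPath, stringsAsFactors = FALSE,
                    colClasses = "character")
  ids <- ped[[2]]
  fam <- ped[[1]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  m <- nrow(mp)
  stopifnot(ncol(al) == 2 * m)
  n <- nrow(al)
  callsM <- matrix(NA_integer_, n, m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    a1 <- al[, 2 * j - 1]; a2 <- al[, 2 * j]
    obs <- c(a1, a2); obs <- obs[obs != "0"]
    alle <- names(sort(table(obs), decreasing = TRUE))
    if (length(alle) == 0) alle <- c("A", "A")
    if (length(alle) == 1) alle <- c(alle, alle)
    ref[j] <- alle[1]; alt[j] <- alle[2]
    g <- (a1 == alt[j]) + (a2 == alt[j])
    g[a1 == "0" | a2 == "0"] <- NA
    callsM[, j] <- as.integer(g)
  }
  ord <- order(normChrom(mp$chrom), mp$bp)
  VariantTable(chrom = mp$chrom[ord], pos = mp$bp[ord], ref = ref[ord],
               alt = alt[ord],
               samples = data.frame(id = ids, group = fam,
                                    stringsAsFactors = FALSE),
               calls = callsM[, ord, drop = FALSE], id = mp$id[ord])
}

#' Read a plain sample x variant genotype TSV
#'
#' Header row `id`, `group`, then one column per variant named
#' `chrom:pos`; entries 0/1/2/NA.
#' @param path TSV path.
#' @return A [VariantTable-class] with placeholder alleles A/G.
#' @export
readGenotypeTsv <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  vcols <- setdiff(names(tb), c("id", "group"))
  parts <- strsplit(vcols, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  pos <- as.integer(vapply(parts, `[`, "", 2))
  ord <- order(normChrom(chrom), pos)
  VariantTable(chrom = chrom[ord], pos = pos[ord],
               ref = rep("A", length(ord)), alt = rep("G", length(ord)),
               samples = data.frame(id = tb$id, group = tb$group,
                                    stringsAsFactors = FALSE),
               calls = as.matrix(tb[, vcols[ord], drop = FALSE]))
}

## ---- GRanges interop ----

#' @describeIn variantRanges variant loci of a VariantTable
#' @export
setMethod("variantRanges", "VariantTable", function(x) {
  GenomicRanges::GRanges(x@chrom, IRanges::IRanges(x@pos, width = 1),
                         id = x@id)
})

#' @describeIn variantRanges loci of a DosageTensor
#' @export
setMethod("variantRanges", "DosageTensor", function(x) {
  GenomicRanges::GRanges(x@chrom, IRanges::IRanges(x@pos, width = 1))
})

#' Convert 0-based half-open interval records to GRanges
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return A `GRanges` (1-based closed, as GRanges requires).
#' @export
intervalsToGRanges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}
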