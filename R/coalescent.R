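## coalescent_engine: ms-dialect command parsing and a structured
## coalescent simulator with recombination (ancestral recombination
## graph), used to build neutral null ensembles for the selection
## statistics. Time is measured in units of 4*N0 generations, sizes
## relative to N0, migration in 4*N0*m units, following the ms
## conventions.

#' Parse an ms-dialect command line
#'
#' Supported flags: `-t`, `-r`, `-I`, `-n`, `-g`, `-ma`, `-es`, `-ej`,
#' `-en`, `-eM`. The literal `tbs` marks theta/rho as deferred
#' per-replicate parameters. Demographic events are kept time-ordered
#' (stable for ties, preserving command order); `-es` increments the
#' population count by one.
#'
#' @param cmdline the command string (a leading program token such as
#'   `ms` or `./msHOT` is ignored).
#' @return A list of class `DemographicModel`: `nsam`, `nreps`, `theta`,
#'   `rho`, `nsites` (NA when `tbs`), `npop`, `sampleConfig`, `sizes`,
#'   `growth`, `migration` (npop x npop, zero diagonal), `events`
#'   (data.frame-ish list of time-ordered events), `tbs` flags.
#' @examples
#' m <- parseMsCommand("ms 2 1 -t 1")
#' m$nsam
#' @export
parseMsCommand <- function(cmdline) {
  tok <- strsplit(trimws(cmdline), "\\s+")[[1]]
  ## drop shell redirections and the program token
  redir <- which(tok %in% c("<", ">"))
  if (length(redir)) tok <- tok[seq_len(min(redir) - 1)]
  if (!grepl("^[0-9]+$", tok[1])) tok <- tok[-1]
  if (length(tok) < 2) stop("parse error: need nsam and nreps")
  nsam <- as.integer(tok[1]); nreps <- as.integer(tok[2])
  i <- 3
  theta <- rho <- NA_real_; nsites <- NA_integer_
  thetaTbs <- rhoTbs <- FALSE
  npop <- 1L
  sampleConfig <- nsam
  sizes <- 1; growth <- 0
  mig <- matrix(0, 1, 1)
  migInit <- NA_real_
  events <- list()
  num <- function(x, flag) {
    if (identical(x, "tbs")) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("parse error near flag ", flag, ": '", x, "'")
    v
  }
  while (i <= length(tok)) {
    flag <- tok[i]
    switch(flag,
      "-t" = { thetaTbs <- tok[i + 1] == "tbs"
               theta <- num(tok[i + 1], flag); i <- i + 2 },
      "-r" = { rhoTbs <- tok[i + 1] == "tbs"
               rho <- num(tok[i + 1], flag)
               nsites <- as.integer(num(tok[i + 2], flag)); i <- i + 3 },
      "-I" = { npop <- as.integer(num(tok[i + 1], flag))
               sampleConfig <- as.integer(
                 vapply(tok[i + 1 + seq_len(npop)], num, 0, flag = flag))
               i <- i + 2 + npop
               ## optional symmetric migration rate
               if (i <= length(tok) && !startsWith(tok[i], "-")) {
                 migInit <- num(tok[i], flag); i <- i + 1
               }
               mig <- matrix(if (is.na(migInit)) 0
                             else migInit / (npop - 1), npop, npop)
               diag(mig) <- 0
               sizes <- rep(1, npop); growth <- rep(0, npop) },
      "-n" = { j <- as.integer(num(tok[i + 1], flag))
               sizes[j] <- num(tok[i + 2], flag); i <- i + 3 },
      "-g" = { j <- as.integer(num(tok[i + 1], flag))
               growth[j] <- num(tok[i + 2], flag); i <- i + 3 },
      "-ma" = { vals <- tok[i + seq_len(npop * npop)]
                vals[vals == "x"] <- "0"
                mig <- matrix(as.numeric(vals), npop, npop, byrow = TRUE)
                diag(mig) <- 0
                i <- i + 1 + npop * npop },
      "-es" = { events[[length(events) + 1]] <-
                  list(t = num(tok[i + 1], flag), kind = "es",
                       pop = as.integer(num(tok[i + 2], flag)),
                       p = num(tok[i + 3], flag))
                i <- i + 4 },
      "-ej" = { events[[length(events) + 1]] <-
                  list(t = num(tok[i + 1], flag), kind = "ej",
                       src = as.integer(num(tok[i + 2], flag)),
                       dst = as.integer(num(tok[i + 3], flag)))
                i <- i + 4 },
      "-en" = { events[[length(events) + 1]] <-
                  list(t = num(tok[i + 1], flag), kind = "en",
                       pop = as.integer(num(tok[i + 2], flag)),
                       x = num(tok[i + 3], flag))
                i <- i + 4 },
      "-eM" = { events[[length(events) + 1]] <-
                  list(t = num(tok[i + 1], flag), kind = "eM",
                       x = num(tok[i + 2], flag))
                i <- i + 3 },
      stop("parse error: unknown flag ", flag)
    )
  }
  if (sum(sampleConfig) != nsam)
    stop("sample sizes (", sum(sampleConfig), ") must sum to nsam (",
         nsam, ")")
  ord <- order(vapply(events, `[[`, 0, "t"))   # stable for ties
  structure(list(nsam = nsam, nreps = nreps, theta = theta, rho = rho,
                 nsites = nsites, thetaTbs = thetaTbs, rhoTbs = rhoTbs,
                 npop = npop, sampleConfig = sampleConfig, sizes = sizes,
                 growth = growth, migration = mig, migInit = migInit,
                 events = events[ord]),
            class = "DemographicModel")
}

#' Serialize a DemographicModel back to a normalized ms command
#'
#' @param model a `DemographicModel`.
#' @return A single normalized command string (flags in canonical order,
#'   `tbs` preserved); `parseMsCommand(serializeMsCommand(m))` is
#'   equivalent to `m`.
#' @export
serializeMsCommand <- function(model) {
  fmt <- function(x) formatC(x, format = "fg", digits = 15, flag = "")
  parts <- c("ms", model$nsam, model$nreps,
             "-t", if (model$thetaTbs) "tbs" else fmt(model$theta))
  if (!is.na(model$rho) || model$rhoTbs)
    parts <- c(parts, "-r", if (model$rhoTbs) "tbs" else fmt(model$rho),
               model$nsites)
  if (model$npop > 1) {
    parts <- c(parts, "-I", model$npop, model$sampleConfig,
               if (!is.na(model$migInit)) fmt(model$migInit))
    for (j in seq_len(model$npop))
      if (model$sizes[j] != 1) parts <- c(parts, "-n", j, fmt(model$sizes[j]))
    for (j in seq_len(model$npop))
      if (model$growth[j] != 0) parts <- c(parts, "-g", j,
                                           fmt(model$growth[j]))
    if (any(model$migration != 0) &&
        !(length(unique(model$migration[row(model$migration) !=
                                          col(model$migration)])) == 1 &&
          !is.na(model$migInit))) {
      mm <- matrix(fmt(model$migration), model$npop, model$npop)
      diag(mm) <- "x"
      parts <- c(parts, "-ma", as.vector(t(mm)))
    }
  } else {
    if (model$sizes[1] != 1) parts <- c(parts, "-n", 1, fmt(model$sizes[1]))
    if (model$growth[1] != 0) parts <- c(parts, "-g", 1,
                                         fmt(model$growth[1]))
  }
  for (e in model$events) {
    parts <- c(parts, switch(e$kind,
      es = c("-es", fmt(e$t), e$pop, fmt(e$p)),
      ej = c("-ej", fmt(e$t), e$src, e$dst),
      en = c("-en", fmt(e$t), e$pop, fmt(e$x)),
      eM = c("-eM", fmt(e$t), fmt(e$x))))
  }
  paste(parts, collapse = " ")
}

#' Draw per-replicate locus parameters
#'
#' theta and rho are drawn from normal distributions with mean equal to
#' the point estimate and variance equal to the mean, truncated to
#' positive values by resampling.
#'
#' @param thetaHat,rhoHat point estimates (thetaHat must be positive;
#'   rhoHat may be 0, which is returned as exactly 0).
#' @return list with `theta` and `rho`.
#' @export
drawLocusParams <- function(thetaHat, rhoHat = 0) {
  stopifnot(thetaHat > 0, rhoHat >= 0)
  drawPos <- function(mu) {
    repeat {
      v <- rnorm(1, mu, sqrt(mu))
      if (v > 0) return(v)
    }
  }
  list(theta = drawPos(thetaHat),
       rho = if (rhoHat == 0) 0 else drawPos(rhoHat))
}

## ---- the simulator ----

## lineage representation: list(pop, segs = 2-col matrix (left, right),
## sets = list of integer sample-id vectors, one per row of segs)

newPopState <- function(model) {
  list(x = model$sizes, alpha = model$growth, tRef = rep(0, model$npop),
       M = model$migration, npop = model$npop)
}

popSizeAt <- function(ps, i, t) ps$x[i] * exp(-ps$alpha[i] * (t - ps$tRef[i]))

## candidate waiting time for coalescence in pop i with k lineages
coalWait <- function(ps, i, k, t) {
  if (k < 2) return(Inf)
  rate0 <- k * (k - 1)   # total pair rate numerator (pair rate 2/x)
  xNow <- popSizeAt(ps, i, t)
  E <- rexp(1)
  a <- ps$alpha[i]
  if (a == 0) return(E * xNow / rate0)
  arg <- 1 + a * xNow * E / rate0
  if (arg <= 0) return(Inf)
  log(arg) / a
}

mergeLineages <- function(l1, l2, nsamTotal) {
  bp <- sort(unique(c(as.vector(l1$segs), as.vector(l2$segs))))
  segs <- NULL; sets <- list()
  findSet <- function(l, a, b) {
    ## set of the segment of l covering (a,b), or NULL
    if (nrow(l$segs) == 0) return(NULL)
    hit <- which(l$segs[, 1] <= a & l$segs[, 2] >= b)
    if (length(hit) == 0) NULL else l$sets[[hit[1]]]
  }
  for (q in seq_len(length(bp) - 1)) {
    a <- bp[q]; b <- bp[q + 1]
    s1 <- findSet(l1, a, b); s2 <- findSet(l2, a, b)
    if (is.null(s1) && is.null(s2)) next
    u <- if (is.null(s1)) s2 else if (is.null(s2)) s1 else
      sort(unique(c(s1, s2)))
    if (length(u) >= nsamTotal) next   # reached the MRCA: drop segment
    ## compact with previous interval when contiguous and identical set
    nseg <- if (is.null(segs)) 0 else nrow(segs)
    if (nseg > 0 && segs[nseg, 2] == a && identical(sets[[nseg]], u)) {
      segs[nseg, 2] <- b
    } else {
      segs <- rbind(segs, c(a, b))
      sets[[nseg + 1]] <- u
    }
  }
  if (is.null(segs)) return(NULL)
  list(pop = l1$pop, segs = segs, sets = sets)
}

splitLineage <- function(l, u) {
  leftRows <- l$segs[, 2] <= u
  rightRows <- l$segs[, 1] >= u
  mid <- which(!leftRows & !rightRows)
  segsL <- l$segs[leftRows, , drop = FALSE]
  setsL <- l$sets[leftRows]
  segsR <- l$segs[rightRows, , drop = FALSE]
  setsR <- l$sets[rightRows]
  if (length(mid) == 1) {
    segsL <- rbind(segsL, c(l$segs[mid, 1], u))
    setsL <- c(setsL, l$sets[mid])
    segsR <- rbind(c(u, l$segs[mid, 2]), segsR)
    setsR <- c(l$sets[mid], setsR)
  }
  out <- list()
  if (nrow(segsL) > 0)
    out <- c(out, list(list(pop = l$pop, segs = segsL, sets = setsL)))
  if (nrow(segsR) > 0)
    out <- c(out, list(list(pop = l$pop, segs = segsR, sets = setsR)))
  out
}

lineageSpan <- function(l) max(l$segs[, 2]) - min(l$segs[, 1])
lineageActiveLen <- function(l) sum(l$segs[, 2] - l$segs[, 1])

#' Simulate one locus under a demographic model
#'
#' Backward-time structured coalescent with recombination (ancestral
#' recombination graph): within-population coalescence at pair rate
#' 2/x_i(t), migration per the (possibly time-varying) matrix,
#' recombination at rate rho times the ancestral span of each lineage,
#' demographic events applied at their scheduled times, and
#' infinite-sites mutations placed as a Poisson process of rate theta per
#' unit (4 N0 generations) of active ancestral branch length.
#'
#' @param model a `DemographicModel` from [parseMsCommand()].
#' @param theta,rho locus parameters; required when the model carries
#'   `tbs` placeholders.
#' @param sampleConfig optional per-population sample sizes overriding
#'   the model's (e.g. to add reference-population haplotypes for PBS
#'   nulls).
#' @return list with `haps` (samples x S 0/1 matrix, rows ordered by
#'   population then sample), `positions` (in (0,1)), `popIndex`
#'   (population of origin per row).
#' @export
simulateLocus <- function(model, theta = NULL, rho = NULL,
                          sampleConfig = NULL) {
  if (is.null(theta)) theta <- model$theta
  if (is.null(rho)) rho <- if (is.na(model$rho)) 0 else model$rho
  if (is.na(theta)) stop("unresolved tbs theta: supply theta")
  if (is.na(rho)) stop("unresolved tbs rho: supply rho")
  sc <- if (is.null(sampleConfig)) model$sampleConfig else sampleConfig
  stopifnot(length(sc) == model$npop)
  nsamTotal <- sum(sc)
  popIndex <- rep(seq_len(model$npop), sc)
  ## initial lineages: one per sample
  lineages <- lapply(seq_len(nsamTotal), function(s)
    list(pop = popIndex[s], segs = matrix(c(0, 1), 1, 2), sets = list(s)))
  ps <- newPopState(model)
  events <- model$events
  evIdx <- 1
  t <- 0
  posList <- numeric(0)
  setList <- list()
  addMutations <- function(dt) {
    if (dt <= 0 || length(lineages) == 0) return()
    lens <- vapply(lineages, lineageActiveLen, 0)
    A <- sum(lens)
    if (A <= 0) return()
    nMut <- rpois(1, theta * dt * A)
    if (nMut == 0) return()
    li <- sample.int(length(lineages), nMut, replace = TRUE, prob = lens)
    for (mm in seq_len(nMut)) {
      l <- lineages[[li[mm]]]
      w <- l$segs[, 2] - l$segs[, 1]
      si <- if (nrow(l$segs) == 1) 1 else
        sample.int(nrow(l$segs), 1, prob = w)
      pos <- runif(1, l$segs[si, 1], l$segs[si, 2])
      posList[[length(posList) + 1]] <<- pos
      setList[[length(setList) + 1]] <<- l$sets[[si]]
    }
  }
  maxIter <- 1e6
  iter <- 0
  while (length(lineages) > 0) {
    iter <- iter + 1
    if (iter > maxIter) stop("simulation did not terminate")
    pops <- vapply(lineages, `[[`, 0L, "pop")
    kPer <- tabulate(pops, nbins = ps$npop)
    ## candidate waiting times
    uCoal <- vapply(seq_len(ps$npop), function(i)
      coalWait(ps, i, kPer[i], t), 0)
    migRates <- vapply(seq_along(lineages), function(li)
      sum(ps$M[pops[li], ]), 0)
    Rmig <- sum(migRates)
    uMig <- if (Rmig > 0) rexp(1, Rmig) else Inf
    spans <- vapply(lineages, lineageSpan, 0)
    Rrec <- rho * sum(spans)
    uRec <- if (Rrec > 0) rexp(1, Rrec) else Inf
    uMin <- min(c(uCoal, uMig, uRec))
    tNextEv <- if (evIdx <= length(events)) events[[evIdx]]$t else Inf
    if (t + uMin > tNextEv) {
      addMutations(tNextEv - t)
      t <- tNextEv
      e <- events[[evIdx]]
      evIdx <- evIdx + 1
      if (e$kind == "en") {
        ps$x[e$pop] <- e$x; ps$alpha[e$pop] <- 0; ps$tRef[e$pop] <- t
      } else if (e$kind == "ej") {
        for (li in seq_along(lineages))
          if (lineages[[li]]$pop == e$src) lineages[[li]]$pop <- e$dst
        ps$M[e$src, ] <- 0; ps$M[, e$src] <- 0
      } else if (e$kind == "es") {
        ps$npop <- ps$npop + 1L
        ps$x <- c(ps$x, 1); ps$alpha <- c(ps$alpha, 0)
        ps$tRef <- c(ps$tRef, t)
        M2 <- matrix(0, ps$npop, ps$npop)
        M2[seq_len(ps$npop - 1), seq_len(ps$npop - 1)] <- ps$M
        ps$M <- M2
        for (li in seq_along(lineages)) {
          if (lineages[[li]]$pop == e$pop && runif(1) > e$p)
            lineages[[li]]$pop <- ps$npop
        }
      } else if (e$kind == "eM") {
        ps$M <- matrix(e$x / (ps$npop - 1), ps$npop, ps$npop)
        diag(ps$M) <- 0
      }
      next
    }
    addMutations(uMin)
    t <- t + uMin
    which1 <- which.min(c(uCoal, uMig, uRec))
    if (which1 <= ps$npop) {
      ## coalescence in population which1
      inPop <- which(pops == which1)
      pair <- sample(inPop, 2)
      merged <- mergeLineages(lineages[[pair[1]]], lineages[[pair[2]]],
                              nsamTotal)
      lineages[pair] <- NULL
      if (!is.null(merged)) lineages[[length(lineages) + 1]] <- merged
    } else if (which1 == ps$npop + 1) {
      ## migration
      li <- sample.int(length(lineages), 1, prob = migRates)
      from <- lineages[[li]]$pop
      lineages[[li]]$pop <- sample.int(ps$npop, 1, prob = ps$M[from, ])
    } else {
      ## recombination
      li <- if (length(lineages) == 1) 1 else
        sample.int(length(lineages), 1, prob = spans)
      l <- lineages[[li]]
      u <- runif(1, min(l$segs[, 1]), max(l$segs[, 2]))
      pieces <- splitLineage(l, u)
      lineages[[li]] <- pieces[[1]]
      if (length(pieces) == 2)
        lineages[[length(lineages) + 1]] <- pieces[[2]]
    }
  }
  S <- length(posList)
  haps <- matrix(0L, nsamTotal, S)
  if (S > 0) {
    ord <- order(unlist(posList))
    positions <- unlist(posList)[ord]
    for (j in seq_len(S)) haps[setList[[ord[j]]], j] <- 1L
  } else positions <- numeric(0)
  list(haps = haps, positions = positions, popIndex = popIndex)
}

#' Build a neutral null ensemble of selection statistics
#'
#' Runs `nreps` independent locus simulations under the model, drawing
#' per-replicate (theta, rho) when point estimates are supplied, and
#' collects Tajima's D for the focal population and optionally PBS
#' (focal vs two reference populations, Hudson FST on the simulated
#' haplotypes).
#'
#' @param model a `DemographicModel`.
#' @param nreps number of replicates (the model's `nreps` by default).
#' @param thetaHat,rhoHat point estimates for [drawLocusParams()]; when
#'   NULL the model's fixed theta/rho are used as-is.
#' @param focalPop population index whose haplotypes enter Tajima's D.
#' @param pbsPops optional integer triple (A, B, C) requesting PBS for A;
#'   requires positive PBS sample sizes via `pbsSamples`.
#' @param pbsSamples haplotypes to sample from each `pbsPops` population
#'   that has no samples in the model (default 28).
#' @param seed integer seed.
#' @return list of class `NullEnsemble`: sorted `D` (NAs dropped), sorted
#'   `PBS` (if requested), `N` replicate count, `seed`, `modelHash`.
#' @export
buildNullEnsemble <- function(model, nreps = model$nreps,
                              thetaHat = NULL, rhoHat = NULL,
                              focalPop = which.max(model$sampleConfig),
                              pbsPops = NULL, pbsSamples = 28,
                              seed = 1) {
  set.seed(seed)
  sc <- model$sampleConfig
  if (!is.null(pbsPops)) {
    for (p in pbsPops) if (sc[p] == 0) sc[p] <- pbsSamples
  }
  Dv <- rep(NA_real_, nreps)
  Pv <- if (!is.null(pbsPops)) rep(NA_real_, nreps) else NULL
  for (r in seq_len(nreps)) {
    lp <- if (!is.null(thetaHat))
      drawLocusParams(thetaHat, if (is.null(rhoHat)) 0 else rhoHat)
    else list(theta = model$theta, rho = model$rho)
    sim <- simulateLocus(model, theta = lp$theta, rho = lp$rho,
                         sampleConfig = sc)
    focal <- sim$haps[sim$popIndex == focalPop, , drop = FALSE]
    st <- sampleStats(focal)
    Dv[r] <- st$D
    if (!is.null(pbsPops)) {
      cnt <- lapply(pbsPops, function(p) {
        h <- sim$haps[sim$popIndex == p, , drop = FALSE]
        data.frame(alt = colSums(h), n = rep(nrow(h), ncol(h)))
      })
      Pv[r] <- pbs(hudsonFst(cnt[[1]], cnt[[2]]),
                   hudsonFst(cnt[[1]], cnt[[3]]),
                   hudsonFst(cnt[[2]], cnt[[3]]))
    }
  }
  tf <- tempfile(); writeLines(serializeMsCommand(model), tf)
  h <- unname(tools::md5sum(tf)); unlink(tf)
  structure(list(D = sort(Dv[!is.na(Dv)]),
                 PBS = if (!is.null(Pv)) sort(Pv[!is.na(Pv)]),
                 N = nreps, seed = seed, modelHash = h),
            class = "NullEnsemble")
}

#' Empirical tail probability against a null ensemble
#'
#' Lower tail: `#\{null <= obs\} / N`; upper tail: `#\{null >= obs\} / N`.
#' A zero count is reported as 0 here; consumers floor it at `1/N` and
#' print it as `"< 1/N"` (see [formatEmpiricalP()]).
#'
#' @param observed observed statistic.
#' @param ens a `NullEnsemble` (or a list with a sorted numeric vector
#'   under `stat`).
#' @param tail `"lower"` or `"upper"`.
#' @param stat which ensemble statistic to use (default `"D"`).
#' @return The empirical p-value (0 when the observation is beyond every
#'   null draw).
#' @export
empiricalP <- function(observed, ens, tail = c("lower", "upper"),
                       stat = "D") {
  tail <- match.arg(tail)
  v <- if (is.numeric(ens)) ens else ens[[stat]]
  if (length(v) == 0) stop("empty null ensemble")
  N <- if (is.numeric(ens)) length(v) else ens$N
  if (tail == "lower") sum(v <= observed) / N else sum(v >= observed) / N
}

#' Format an empirical p-value with flooring
#'
#' @param p empirical p from [empiricalP()].
#' @param N ensemble size.
#' @return `"< 2.0e-04"`-style string when `p` is 0, otherwise the value.
#' @export
formatEmpiricalP <- function(p, N) {
  if (is.na(p)) return(NA_character_)
  if (p == 0) sprintf("< %.1e", 1 / N) else sprintf("%.3g", p)
}

#' Write replicates in ms text format
#'
#' @param sims list of [simulateLocus()] results.
#' @param path output path.
#' @param cmdline command-line header string.
#' @return `path`, invisibly.
#' @export
writeMsOutput <- function(sims, path, cmdline = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(cmdline, paste(sample.int(2^15, 3), collapse = " ")), con)
  for (s in sims) {
    writeLines("", con)
    writeLines("//", con)
    writeLines(paste0("segsites: ", ncol(s$haps)), con)
    if (ncol(s$haps) > 0) {
      writeLines(paste0("positions: ",
                        paste(sprintf("%.5f", s$positions),
                              collapse = " ")), con)
      writeLines(apply(s$haps, 1, paste, collapse = ""), con)
    }
  }
  invisible(path)
}
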