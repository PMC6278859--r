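## The verbatim demographic command used for the neutral null model
canarianMsCommand <- paste(
  "./msHOT 28 5000 -t tbs -r tbs 10000 -I 4 0 0 0 28",
  "-n 1 1.68202 -n 2 3.73683 -n 3 7.29205 -n 4 3.73683",
  "-g 2 116.010723 -g 3 160.246047",
  "-ma x 0.881098 0.561966 0 0.881098 x 2.79746 10",
  "0.561966 2.79746 x 0 0 1 0 x",
  "-es 0.0005 4 0.1 -ej 0.0005 5 2 -en 0.0005 4 0.068",
  "-ej 0.0135 4 1 -ej 0.028985 3 2 -en 0.028985 2 0.287184",
  "-eM 0.028985 28 -ej 0.197963 2 1 -en 0.303501 1 1")

test_that("the four-population command parses with all events", {
  m <- parseMsCommand(canarianMsCommand)
  expect_equal(m$nsam, 28)
  expect_equal(m$nreps, 5000)
  expect_equal(m$npop, 4)
  expect_equal(m$sampleConfig, c(0L, 0L, 0L, 28L))
  expect_true(m$thetaTbs && m$rhoTbs)
  expect_equal(m$nsites, 10000)
  expect_equal(m$growth[2:3], c(116.010723, 160.246047))
  expect_equal(m$migration[2, 4], 10)
  times <- vapply(m$events, `[[`, 0, "t")
  expect_equal(sort(unique(times)),
               c(0.0005, 0.0135, 0.028985, 0.197963, 0.303501))
  kinds <- vapply(m$events, `[[`, "", "kind")
  expect_equal(sum(kinds == "ej"), 4)
  es <- m$events[[which(kinds == "es")]]
  expect_equal(es$pop, 4)
  expect_equal(es$p, 0.1)
  ## the recent size drop implies an isolate of about 500 individuals at
  ## N0 = 7310, inside the 470-560 interval estimated for the aboriginal
  ## population
  en <- m$events[[which(kinds == "en" &
                          vapply(m$events, `[[`, 0, "t") == 0.0005)]]
  expect_true(en$x * 7310 >= 470 && en$x * 7310 <= 560)
})

test_that("minimal and malformed commands behave as documented", {
  m <- parseMsCommand("ms 2 1 -t 1")
  expect_equal(m$nsam, 2)
  expect_equal(m$npop, 1)
  expect_equal(m$theta, 1)
  expect_error(parseMsCommand("ms 2 1 -t 1 -q 3"), "unknown flag")
  expect_error(parseMsCommand("ms 4 1 -t 1 -I 2 1 1"), "sum to nsam")
})

test_that("parse/serialize round-trips random dialect commands", {
  set.seed(14)
  for (r in 1:20) {
    npop <- sample(2:4, 1)
    sizes <- sample(1:5, npop, replace = TRUE)
    cmd <- paste("ms", sum(sizes), sample(1:100, 1),
                 "-t", signif(runif(1, 0.5, 20), 6),
                 "-r", signif(runif(1, 0, 10), 6), 10000,
                 "-I", npop, paste(sizes, collapse = " "),
                 signif(runif(1, 0.1, 5), 6))
    for (e in seq_len(sample(0:3, 1))) {
      t <- signif(runif(1, 0.001, 1), 6)
      cmd <- paste(cmd, sample(c(
        paste("-en", t, sample(npop, 1), signif(runif(1, 0.05, 3), 6)),
        paste("-eM", t, signif(runif(1, 0, 10), 6)),
        paste("-ej", t, sample(npop, 1), sample(npop, 1))), 1))
    }
    m1 <- parseMsCommand(cmd)
    m2 <- parseMsCommand(serializeMsCommand(m1))
    expect_equal(m1, m2, info = cmd)
  }
})

test_that("E[S] matches Watterson's expectation for constant size", {
  set.seed(100)
  ## n = 2, theta = 1: E[S] = 1
  m2 <- parseMsCommand("ms 2 1 -t 1")
  S2 <- replicate(3000, sampleStats(simulateLocus(m2)$haps)$S)
  se2 <- sd(S2) / sqrt(length(S2))
  expect_lt(abs(mean(S2) - 1), 3 * se2)
  ## n = 10, theta = 5: E[S] = 5 * a1(10) ~ 14.14; neutral D near 0
  m10 <- parseMsCommand("ms 10 1 -t 5")
  st <- replicate(2500, {
    s <- sampleStats(simulateLocus(m10)$haps); c(s$S, s$D)
  })
  a1 <- sum(1 / (1:9))
  seS <- sd(st[1, ]) / sqrt(ncol(st))
  expect_lt(abs(mean(st[1, ]) - 5 * a1), 3 * seS)
  expect_gt(mean(st[2, ], na.rm = TRUE), -0.1)
  expect_lt(mean(st[2, ], na.rm = TRUE), 0.1)
})

test_that("recombination preserves E[S] and yields sorted positions", {
  set.seed(101)
  m <- parseMsCommand("ms 6 1 -t 4 -r 6 10000")
  S <- numeric(800)
  for (r in seq_len(800)) {
    sim <- simulateLocus(m)
    S[r] <- ncol(sim$haps)
    expect_false(is.unsorted(sim$positions))
    expect_true(all(sim$positions > 0 & sim$positions < 1))
  }
  a1 <- sum(1 / (1:5))
  expect_lt(abs(mean(S) - 4 * a1), 3 * sd(S) / sqrt(800))
})

test_that("strong migration removes differentiation between demes", {
  set.seed(102)
  m <- parseMsCommand("ms 20 1 -t 2 -I 2 10 10 100")
  num <- 0; den <- 0
  for (r in 1:200) {
    sim <- simulateLocus(m)
    if (ncol(sim$haps) == 0) next
    h1 <- sim$haps[sim$popIndex == 1, , drop = FALSE]
    h2 <- sim$haps[sim$popIndex == 2, , drop = FALSE]
    p1 <- colMeans(h1); p2 <- colMeans(h2)
    num <- num + sum((p1 - p2)^2 - p1 * (1 - p1) / 9 - p2 * (1 - p2) / 9)
    den <- den + sum(p1 * (1 - p2) + p2 * (1 - p1))
  }
  expect_lt(abs(num / den), 0.01)
})

test_that("sample statistics match brute-force pairwise differences", {
  haps <- rbind(c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 0, 0, 0),
                c(1, 1, 1, 1))
  st <- sampleStats(haps)
  expect_equal(st$S, 4L)
  expect_equal(st$pi, brutePi(haps))
  ## monomorphic sample: D undefined
  st0 <- sampleStats(matrix(0L, 2, 2))
  expect_equal(st0$S, 0L)
  expect_equal(st0$pi, 0)
  expect_true(is.na(st0$D))
  ## random matrices against the brute-force oracle
  set.seed(15)
  for (r in 1:10) {
    h <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12)
    expect_equal(sampleStats(h)$pi, brutePi(h), tolerance = 1e-12)
  }
})

test_that("Tajima constants at n = 28 match an independent evaluation", {
  ## direct textbook evaluation, no shared code
  n <- 28
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  S <- 17; pi <- 4.2
  expect_equal(tajimasD(pi, S, n),
               (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)),
               tolerance = 1e-12)
})

test_that("locus parameter draws have the stated mean and variance", {
  set.seed(33)
  th <- replicate(10000, drawLocusParams(10, 4)$theta)
  expect_equal(mean(th), 10, tolerance = 0.3 / 10)
  expect_equal(var(th), 10, tolerance = 0.12)
  expect_error(drawLocusParams(0), "thetaHat")
  set.seed(55); d1 <- drawLocusParams(5, 2)
  set.seed(55); d2 <- drawLocusParams(5, 2)
  expect_identical(d1, d2)
})

test_that("empirical p-values behave at the median, tails and under the null", {
  ens <- structure(list(D = sort(rnorm(5000)), N = 5000),
                   class = "NullEnsemble")
  expect_equal(empiricalP(median(ens$D), ens, "lower"), 0.5,
               tolerance = 1.5 / 5000)
  expect_equal(empiricalP(-100, ens, "lower"), 0)
  expect_equal(formatEmpiricalP(0, 5000), "< 2.0e-04")
  ## uniform observations against a uniform ensemble give uniform p
  set.seed(16)
  ensU <- sort(runif(2000))
  p <- vapply(runif(2000), function(o) empiricalP(o, ensU, "lower"), 0)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the demographic command simulates and gives negative mean D", {
  set.seed(103)
  m <- parseMsCommand(canarianMsCommand)
  D <- replicate(150, {
    lp <- drawLocusParams(7.3, 3.8)
    sampleStats(simulateLocus(m, theta = lp$theta, rho = lp$rho)$haps)$D
  })
  expect_true(all(is.finite(D) | is.na(D)))
  ## recent bottleneck + growth model: site frequency spectrum skewed to
  ## rare variants
  expect_lt(mean(D, na.rm = TRUE), 0)
  expect_error(simulateLocus(m), "tbs")
})
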