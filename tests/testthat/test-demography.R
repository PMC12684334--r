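test_that("the scenario registry enumerates the four model families", {
  reg <- modelRegistry()
  expect_length(reg, 22)
  expect_identical(anyDuplicated(names(reg)), 0L)
  base <- vapply(reg, function(m) m@base, character(1))
  expect_identical(as.integer(table(base)[c("SI", "IM", "AM", "SC")]),
                   c(4L, 6L, 6L, 6L))
  expect_false(any(vapply(reg, function(m) m@twoM && m@base == "SI",
                          logical(1))))
  # 2m variants carry the reduced-migration parameters, 2N the size class
  expect_true(all(c("mef", "P") %in% reg$SC2m@params))
  expect_true(all(c("hrf", "Q") %in% reg$IM2N@params))
  expect_true(all(c("b1", "b2") %in% reg$SIG@params))
})

test_that("the joint SFS is a faithful tally of allele counts", {
  # one diploid per pop, one SNP with alt counts (1, 0)
  g <- rbind(i1 = 1L, i2 = 0L)
  m <- SNPMatrix(g, site = c("p1", "p2"))
  s <- buildJointSFS(m, "p1", "p2")
  expect_equal(sfsCounts(s)[2, 1], 1) # cell (1, 0)
  expect_equal(sfsTotal(s), 1)

  # conservation and brute-force tally on a random matrix
  mr <- random_snp(20, 300, miss = 0.02, seed = 111,
                   sites = rep(c("p1", "p2"), each = 10))
  suppressMessages(sr <- buildJointSFS(mr, "p1", "p2"))
  d <- dosages(mr)
  keep <- colSums(is.na(d)) == 0
  expect_equal(sfsTotal(sr), sum(keep))
  want <- matrix(0, 21, 21)
  for (l in which(keep)) {
    i <- sum(d[1:10, l]); j <- sum(d[11:20, l])
    want[i + 1, j + 1] <- want[i + 1, j + 1] + 1
  }
  expect_equal(sfsCounts(sr), want)

  expect_error(buildJointSFS(mr, "p1", c("p1", "p2")), "overlap")
})

test_that("folding pools complements on the minor allele and is idempotent", {
  # hand case 2n1 = 2n2 = 2: cell (2, 1) has pooled count 3 > 2 and
  # folds onto (0, 1)
  counts <- matrix(0, 3, 3)
  counts[3, 2] <- 1
  s <- new("JointSFS", counts = counts, folded = FALSE, n1 = 2L, n2 = 2L,
           pops = c("a", "b"))
  f <- foldJointSFS(s)
  expect_equal(sfsCounts(f)[1, 2], 1)
  expect_equal(sfsCounts(f)[3, 2], 0)

  set.seed(7)
  counts2 <- matrix(rpois(9 * 11, 5), 9, 11)
  s2 <- new("JointSFS", counts = counts2, folded = FALSE, n1 = 8L,
            n2 = 10L, pops = c("a", "b"))
  f2 <- foldJointSFS(s2)
  expect_equal(sfsTotal(f2), sfsTotal(s2))
  expect_true(isFolded(f2))
  expect_identical(sfsCounts(foldJointSFS(f2)), sfsCounts(f2))

  # folding commutes with spectrum accumulation (same engine stream)
  pars <- c(N1 = 1, N2 = 1.5, Ts = 1, m12 = 1, m21 = 0.5)
  a <- expectedJointSFS("IM", pars, 4, 4, n_loci = 2000, seed = 5,
                        fold = TRUE)
  b <- foldJointSFS(expectedJointSFS("IM", pars, 4, 4, n_loci = 2000,
                                     seed = 5, fold = FALSE))
  expect_equal(sfsCounts(a), sfsCounts(b), tolerance = 1e-12)
})

test_that("expected spectra follow neutral theory in known regimes", {
  # deep-split SI: pop1-private singleton/doubleton ratio ~ theta/i law
  e <- expectedJointSFS("SI", c(N1 = 1, N2 = 1, Ts = 8), 4, 4,
                        n_loci = 30000, seed = 13, fold = FALSE)
  r <- sfsCounts(e)[2, 1] / sfsCounts(e)[3, 1]
  expect_lt(abs(r - 2), 0.15)

  # fully symmetric IM: spectrum symmetric to population swap
  es <- expectedJointSFS("IM", c(N1 = 1, N2 = 1, Ts = 1, m12 = 1,
                                 m21 = 1), 5, 5, n_loci = 30000,
                         seed = 17, fold = FALSE)
  S <- sfsCounts(es)
  expect_lt(sum(abs(S - t(S))) / sum(S), 0.06)

  # determinism: identical seed, identical spectrum
  e2 <- expectedJointSFS("SI", c(N1 = 1, N2 = 1, Ts = 8), 4, 4,
                         n_loci = 30000, seed = 13, fold = FALSE)
  expect_identical(sfsCounts(e), sfsCounts(e2))
})

test_that("the composite likelihood scales the model spectrum exactly", {
  sim <- simDivergence("SI", c(N1 = 1, N2 = 1, Ts = 2), 4, 4, 3000,
                       seed = 19, theta_locus = 0.3, fold = TRUE)
  e <- expectedJointSFS("SI", c(N1 = 1, N2 = 1, Ts = 2), 4, 4,
                        n_loci = 5000, seed = 3, fold = TRUE)
  res <- CloneScape:::.sfsLoglik(sim$sfs, e)
  keep <- CloneScape:::.sfsMask(sim$sfs)
  expect_equal(res$theta * sum(pmax(sfsCounts(e)[keep], 0)),
               sum(sfsCounts(sim$sfs)[keep]), tolerance = 1e-6)
  expect_true(is.finite(res$loglik))
})

test_that("likelihood of the generating model dominates a nested restriction", {
  pars <- c(N1 = 1, N2 = 1, Ts = 1.5, m12 = 1, m21 = 1)
  sim <- simDivergence("IM", pars, 5, 5, 30000, seed = 23,
                       theta_locus = 0.2, fold = TRUE)
  ll <- function(model, p) CloneScape:::.sfsLoglik(
    sim$sfs, expectedJointSFS(model, p, 5, 5, n_loci = 20000, seed = 31,
                              fold = TRUE))$loglik
  # SI is IM restricted to m = 0; at the same remaining parameters the
  # generating model fits no worse (up to MC tolerance)
  expect_gt(ll("IM", pars) + 5,
            ll("SI", c(N1 = 1, N2 = 1, Ts = 1.5)))
})

test_that("fit results carry coherent AIC and model comparison flags", {
  sim <- simDivergence("SI", c(N1 = 1, N2 = 1, Ts = 3), 3, 3, 20000,
                       seed = 37, theta_locus = 0.2, fold = TRUE)
  fit <- fitDemography(sim$sfs, "SI", n_fits = 1, seed = 3,
                       n_loci_mc = 4000, n_random = 15,
                       maxit = c(60, 30), n_perturb = 1)
  expect_equal(fit@AIC, 2 * fit@k - 2 * fit@loglik)
  expect_identical(fit@k, length(fit@model@params) + 1L)
  expect_lt(abs(fit@par["Ts"] - 3) / 3, 1)

  mk <- function(name, aic) {
    mdl <- modelRegistry()[[name]]
    k <- length(mdl@params) + 1L
    new("FitResult", model = mdl, par = setNames(rep(1, length(mdl@params)),
                                                 mdl@params),
        theta = 1, loglik = (2 * k - aic) / 2, AIC = aic, k = k,
        nFits = 1L, bio = list())
  }
  r1 <- compareModels(list(mk("SI", 100), mk("IM", 95)))
  expect_false(any(r1$stronger))
  r2 <- compareModels(list(mk("SI", 100), mk("IM", 85)))
  expect_true(r2$stronger[r2$model == "IM"])
  expect_false(r2$stronger[r2$model == "SI"])
})

test_that("biological-unit conversion round-trips with the stated constants", {
  mdl <- modelRegistry()[["SC"]]
  fit <- new("FitResult", model = mdl,
             par = c(N1 = 0.8, N2 = 1.6, Ts = 1.2, m12 = 2, m21 = 0.5,
                     Tfrac = 0.25),
             theta = 1200, loglik = -10, AIC = 36, k = 8L, nFits = 1L,
             bio = list())
  fit <- toBiologicalUnits(fit, L = 1e6, mu = 1e-8, gen_time = 4)
  expect_equal(fit@bio$Nref, 1200 / (4 * 1e-8 * 1e6))
  back <- fromBiologicalUnits(fit@bio)
  expect_equal(back$theta, 1200)
  expect_equal(unname(back$sizes), c(0.8, 1.6))
  expect_equal(unname(back$times[1]), 1.2)
  expect_equal(unname(back$migration), c(2, 0.5))
})

test_that("spectrum text round trip preserves counts and metadata", {
  sim <- simDivergence("SI", c(N1 = 1, N2 = 1, Ts = 1), 3, 4, 500,
                       seed = 41, theta_locus = 0.4, fold = TRUE)
  p <- tempfile(fileext = ".txt")
  writeJointSFS(sim$sfs, p)
  back <- readJointSFS(p)
  expect_equal(sfsCounts(back), sfsCounts(sim$sfs))
  expect_identical(back@n1, sim$sfs@n1)
  expect_identical(isFolded(back), isFolded(sim$sfs))
})
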