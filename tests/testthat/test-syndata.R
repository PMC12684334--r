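test_that("clonal-site generator encodes its truth partition", {
  # all distinct genets -> clonal fraction 0, recovered R = 1
  cs <- simClonalSite(n_genets = 12, ramets_per_genet = 1, n_loci = 60,
                      seed = 3)
  expect_equal(cs$truth$clonal_fraction, 0)
  a <- contractMLGs(pairwiseDistance(cs$snp), 0)
  expect_equal(clonalRichness(a), 1)

  # one genet, 15 ramets -> monoclonal site, R = 0
  mono <- simClonalSite(n_genets = 1, ramets_per_genet = 15, n_loci = 200,
                        seed = 5)
  expect_equal(mono$truth$clonal_fraction, 1)
  a2 <- contractMLGs(pairwiseDistance(mono$snp), 0)
  expect_identical(nGenets(a2), 1L)
  expect_equal(clonalRichness(a2), 0)

  # error-free truth partition is exactly recoverable at threshold 0
  cs3 <- simClonalSite(n_genets = 6, ramets_per_genet = c(1, 2, 3, 4, 5, 6),
                      n_loci = 80, seed = 11)
  a3 <- contractMLGs(pairwiseDistance(cs3$snp), 0)
  expect_identical(
    unname(split(a3@individual, a3@genet)[order(unique(a3@genet))] |>
             vapply(paste, collapse = ",", FUN.VALUE = "") |> sort()),
    unname(split(names(cs3$truth$genet_of_individual),
                 cs3$truth$genet_of_individual) |>
             vapply(paste, collapse = ",", FUN.VALUE = "") |> sort()))

  expect_error(simClonalSite(3, 2, 0, seed = 1), "n_loci")
  expect_error(simClonalSite(3, 2, 10, error_rate = 1, seed = 1), "rates")
})

test_that("ramet discordance matches the per-allele flip expectation", {
  e <- 0.005
  cs <- simClonalSite(n_genets = 1, ramets_per_genet = 12, n_loci = 4000,
                      error_rate = e, seed = 21)
  d <- dosages(cs$snp)
  # majority vote recovers the genet genotype at this error rate
  g <- apply(d, 2, function(x) as.integer(names(which.max(table(x)))))
  # per-dosage-class expectation of |a - b| / 2 for two independent
  # ramets, enumerated over flip outcomes
  flip_dist <- function(g1) {
    pa <- sapply(0:2, function(a) {
      p <- 0
      for (x in 0:g1) for (y in 0:(2 - g1)) {
        if (g1 - x + y == a)
          p <- p + dbinom(x, g1, e) * dbinom(y, 2 - g1, e)
      }
      p
    })
    pa
  }
  exp_term <- function(g1) {
    pa <- flip_dist(g1)
    sum(outer(0:2, 0:2, function(a, b) abs(a - b)) *
          outer(pa, pa)) / 2
  }
  expected <- mean(vapply(g, exp_term, numeric(1)))
  dm <- as.matrix(pairwiseDistance(cs$snp))
  obs <- mean(dm[upper.tri(dm)])
  # 99% band from the binomial-style variance over loci
  se <- sd(vapply(seq_len(ncol(d)), function(l) {
    v <- abs(outer(d[, l], d[, l], "-"))[upper.tri(dm)] / 2
    mean(v)
  }, numeric(1))) / sqrt(ncol(d))
  expect_lt(abs(obs - expected), 2.6 * se + 1e-4)
})

test_that("generators are pure functions of their seed", {
  expect_identical(dosages(simClonalSite(4, 3, 50, 0.01, 0.05, seed = 9)$snp),
                   dosages(simClonalSite(4, 3, 50, 0.01, 0.05, seed = 9)$snp))
  expect_identical(dosages(simMetapopulation(3, 0.1, 10, 100, seed = 2)),
                   dosages(simMetapopulation(3, 0.1, 10, 100, seed = 2)))
  s1 <- simDivergence("SI", c(N1 = 1, N2 = 1, Ts = 1), 3, 3, 200, seed = 4)
  s2 <- simDivergence("SI", c(N1 = 1, N2 = 1, Ts = 1), 3, 3, 200, seed = 4)
  expect_identical(dosages(s1$snp), dosages(s2$snp))
  expect_identical(simMorpho(data.frame(FW = 5, DBD = 10, UX = 1.2),
                             5, c(1, 1, 0.1), seed = 6),
                   simMorpho(data.frame(FW = 5, DBD = 10, UX = 1.2),
                             5, c(1, 1, 0.1), seed = 6),
                   ignore_attr = FALSE)
})

test_that("metapopulation generator hits its F_ST target", {
  # fst 0: all demes share the ancestral frequencies
  m0 <- simMetapopulation(3, 0, 30, 800, seed = 13)
  d0 <- dosages(m0)
  f0 <- oracle_hudson_fst(d0[siteOf(m0) == "deme1", ],
                          d0[siteOf(m0) == "deme2", ])
  expect_lt(abs(f0), 0.02)

  m <- simMetapopulation(3, 0.2, 40, 2000, seed = 17)
  d <- dosages(m)
  s <- siteOf(m)
  fsts <- c(oracle_hudson_fst(d[s == "deme1", ], d[s == "deme2", ]),
            oracle_hudson_fst(d[s == "deme1", ], d[s == "deme3", ]),
            oracle_hudson_fst(d[s == "deme2", ], d[s == "deme3", ]))
  expect_true(all(abs(fsts - 0.2) < 0.03))
  # package estimator agrees with the hand-written oracle
  expect_equal(hudsonFst(m, "deme1", "deme2"), fsts[1], tolerance = 1e-12)
  expect_error(simMetapopulation(3, 1, 10, 100, seed = 1), "fst_target")
})

test_that("divergence generator is self-consistent and orders F_ST by split time", {
  sim <- simDivergence("IM", c(N1 = 1, N2 = 1, Ts = 1, m12 = 1, m21 = 1),
                       4, 4, 2000, seed = 31, theta_locus = 0.3)
  rebuilt <- buildJointSFS(sim$snp, "pop1", "pop2")
  expect_identical(sfsCounts(sim$sfs), sfsCounts(rebuilt))
  expect_equal(sfsTotal(sim$sfs), nLoci(sim$snp))

  fsts <- vapply(c(0.2, 1, 4), function(ts) {
    s <- simDivergence("SI", c(N1 = 1, N2 = 1, Ts = ts), 6, 6, 3000,
                       seed = 37, theta_locus = 0.3)
    d <- dosages(s$snp)
    oracle_hudson_fst(d[siteOf(s$snp) == "pop1", ],
                      d[siteOf(s$snp) == "pop2", ])
  }, numeric(1))
  expect_true(all(diff(fsts) > 0))
  expect_error(simDivergence("XX", c(N1 = 1), 3, 3, 10, seed = 1),
               "unknown model")
})

test_that("dispersal kernel is stochastic, symmetric without advection, and advective with it", {
  P0 <- simDispersal(12, advection = 0, diffusion = 1.5)
  expect_true(all(abs(rowSums(P0@P) - 1) < 1e-12))
  expect_lt(max(abs(P0@P - t(P0@P))), 1e-12)

  down <- vapply(c(0.5, 1, 2), function(adv) {
    P <- simDispersal(12, advection = adv, diffusion = 1.5)
    sum(P@P[upper.tri(P@P)])
  }, numeric(1))
  expect_true(all(diff(down) > 0))

  mask <- rep(TRUE, 10); mask[c(3, 7)] <- FALSE
  Pm <- simDispersal(10, advection = 0.5, diffusion = 1,
                     habitat_mask = mask)
  expect_true(all(Pm@P[!mask, ] == 0))
  expect_true(all(Pm@P[, !mask] == 0))
  expect_true(all(abs(rowSums(Pm@P)[mask] - 1) < 1e-12))
  expect_error(simDispersal(5, habitat_mask = rep(FALSE, 5)), "habitat")
  expect_error(simDispersal(5, diffusion = 0), "diffusion")
})

test_that("morphometric generator respects lineage means and branch structure", {
  lm_ <- data.frame(FW = c(10, 2), DBD = c(30, 8), UX = c(1.1, 1.6))
  t0 <- simMorpho(lm_, 4, noise_sd = c(0, 0, 0), seed = 8)
  expect_equal(t0$FW, rep(c(10, 2), each = 4))
  expect_equal(t0$UX, rep(c(1.1, 1.6), each = 4))
  br <- attr(t0, "branches")
  expect_identical(dim(br), c(8L, 3L, 3L))

  # configured standardized difference d = 2 on FW realised within +-0.5
  sdf <- 1
  lm2 <- data.frame(FW = c(10, 10 + 2 * sdf), DBD = c(30, 30),
                    UX = c(1.2, 1.2))
  tt <- simMorpho(lm2, 50, noise_sd = c(sdf * sqrt(3), 0.1, 0.05), seed = 15)
  g1 <- tt$FW[tt$lineage == "lineage1"]; g2 <- tt$FW[tt$lineage == "lineage2"]
  d_real <- (mean(g2) - mean(g1)) /
    sqrt((var(g1) + var(g2)) / 2)
  expect_lt(abs(d_real - 2), 0.5)
  expect_error(simMorpho(lm_, 3, noise_sd = -1, seed = 1), "noise_sd")
  expect_error(simMorpho(data.frame(FW = 1, DBD = 1, UX = 0.5), 3,
                         c(1, 1, 1), seed = 1), "UX")
})
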