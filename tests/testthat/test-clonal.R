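snp_from <- function(..., site = NULL) {
  rows <- list(...)
  g <- do.call(rbind, lapply(rows, as.integer))
  rownames(g) <- sprintf("i%d", seq_len(nrow(g)))
  SNPMatrix(g, site = if (is.null(site)) rep("s", nrow(g)) else site)
}

test_that("allelic-difference distance follows its defining formula", {
  m <- snp_from(c(0, 1, 2, 1), c(0, 2, 2, 0))
  expect_equal(as.matrix(pairwiseDistance(m))[1, 2], 0.25)

  ident <- snp_from(c(0, 1, 2), c(0, 1, 2))
  expect_equal(as.matrix(pairwiseDistance(ident))[1, 2], 0)

  opp <- snp_from(rep(0, 5), rep(2, 5))
  expect_equal(as.matrix(pairwiseDistance(opp))[1, 2], 1)

  # oracle agreement with missing data, pairwise-complete denominators
  set.seed(3)
  mr <- random_snp(12, 40, miss = 0.15, seed = 3)
  expect_equal(unname(as.matrix(pairwiseDistance(mr))),
               oracle_distance(dosages(mr)), tolerance = 1e-12)

  # invariance to locus and individual permutation
  d0 <- as.matrix(pairwiseDistance(mr))
  perm_l <- sample(nLoci(mr)); perm_i <- sample(nIndividuals(mr))
  mp <- SNPMatrix(dosages(mr)[perm_i, perm_l],
                  site = unname(siteOf(mr))[perm_i])
  dp <- as.matrix(pairwiseDistance(mp))
  expect_equal(dp, d0[perm_i, perm_i], tolerance = 1e-12)

  # a pair sharing no loci errors by default
  g <- rbind(c(0L, NA), c(NA, 1L), c(1L, 1L))
  mz <- SNPMatrix(g, site = rep("s", 3))
  expect_error(pairwiseDistance(mz), "zero genotyped")
  expect_true(is.na(as.matrix(pairwiseDistance(mz, on_empty = "na"))[1, 2]))
})

test_that("cutoff predictor picks the largest low-distance gap", {
  # ultrametric construction with single-linkage merge heights
  # {0.001, 0.002, 0.003, 0.20, 0.22}
  h <- list(c(1, 2, 0.001), c(3, 4, 0.20))
  dm <- matrix(0.22, 6, 6); diag(dm) <- 0
  dm[1, 2] <- dm[2, 1] <- 0.001
  dm[1, 3] <- dm[3, 1] <- dm[2, 3] <- dm[3, 2] <- 0.002
  dm[1, 4] <- dm[4, 1] <- dm[2, 4] <- dm[4, 2] <-
    dm[3, 4] <- dm[4, 3] <- 0.003
  dm[c(1:4), 5] <- dm[5, c(1:4)] <- 0.20
  rownames(dm) <- colnames(dm) <- sprintf("i%d", 1:6)
  expect_equal(sort(hclust(as.dist(dm), method = "single")$height),
               c(0.001, 0.002, 0.003, 0.20, 0.22))
  d <- new("SNPDistance", d = dm, shared = matrix(10L, 6, 6),
           site = rep("s", 6))
  expect_equal(predictCutoff(d), (0.003 + 0.20) / 2)

  # equally spaced heights 0.1..0.4: all candidate gaps tie at 0.1,
  # broken towards the lowest height -> midpoint (0.1 + 0.2) / 2
  dm2 <- matrix(0, 5, 5)
  heights <- c(0.1, 0.2, 0.3, 0.4)
  for (i in 1:4) for (j in (i + 1):5)
    dm2[i, j] <- dm2[j, i] <- heights[j - 1]
  expect_equal(sort(hclust(as.dist(dm2), method = "single")$height),
               heights)
  d2 <- new("SNPDistance", d = dm2, shared = matrix(10L, 5, 5),
            site = rep("s", 5))
  expect_equal(predictCutoff(d2), 0.15)

  expect_error(predictCutoff(new("SNPDistance",
                                 d = matrix(0, 2, 2),
                                 shared = matrix(1L, 2, 2),
                                 site = rep("s", 2))), "distinct")
})

test_that("predicted cutoff separates ramet pairs from genet pairs on noisy clones", {
  cs <- simClonalSite(n_genets = 8, ramets_per_genet = 5, n_loci = 600,
                      error_rate = 0.005, seed = 29)
  d <- pairwiseDistance(cs$snp)
  thr <- predictCutoff(d)
  truth <- cs$truth$genet_of_individual[rownames(as.matrix(d))]
  same <- outer(truth, truth, "==")
  dm <- as.matrix(d)
  within <- dm[same & upper.tri(dm)]
  between <- dm[!same & upper.tri(dm)]
  expect_true(all(within < thr))
  expect_true(all(between > thr))
})

test_that("MLG contraction is single linkage and monotone in the threshold", {
  # hand-checked transitive chain
  dm <- matrix(c(0, 0.01, 0.02,
                 0.01, 0, 0.01,
                 0.02, 0.01, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  d <- new("SNPDistance", d = dm, shared = matrix(10L, 3, 3),
           site = rep("s", 3))
  expect_identical(nGenets(contractMLGs(d, 0.015)), 1L)

  md <- random_snp(15, 60, seed = 43)
  dd <- pairwiseDistance(md)
  expect_identical(nGenets(contractMLGs(dd, 0)), 15L)
  expect_identical(nGenets(contractMLGs(dd, max(as.matrix(dd)))), 1L)

  # refinement: each genet at t1 sits inside one genet at t2 >= t1
  a1 <- contractMLGs(dd, 0.1); a2 <- contractMLGs(dd, 0.25)
  tab <- table(a1@genet, a2@genet)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("clonal richness follows (G-1)/(N-1)", {
  mk <- function(genets) {
    n <- length(genets)
    new("MLGAssignment", individual = sprintf("i%d", 1:n),
        site = rep("s", n), genet = genets,
        representative = !duplicated(genets), threshold = 0)
  }
  expect_equal(clonalRichness(mk(rep("g1", 10))), 0)
  expect_equal(clonalRichness(mk(sprintf("g%d", 1:10))), 1)
  expect_equal(clonalRichness(mk(sprintf("g%d", c(1:8, 1:7)))), 0.5)
  expect_error(clonalRichness(mk("g1")), "single individual")

  # per-site computation stays within localities
  a <- new("MLGAssignment", individual = sprintf("i%d", 1:6),
           site = rep(c("A", "B"), each = 3),
           genet = c("g1", "g1", "g1", "g2", "g3", "g4"),
           representative = rep(TRUE, 6), threshold = 0)
  expect_equal(clonalRichness(a, by_site = TRUE),
               c(A = 0, B = 1))
})
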