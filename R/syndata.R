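# Synthetic-data generators: every downstream stage can be exercised on
# data with known truth (clone partitions, deme labels, divergence
# histories, dispersal asymmetry, trait lineages).

#' Simulate one partially clonal site
#'
#' Draws \code{n_genets} distinct genets from per-locus allele frequencies
#' (Uniform(0.05, 0.95) by default so within-site polymorphism is
#' near-certain) and copies each genet into ramets. Genotyping error is
#' modelled as independent per-allele flips at rate \code{error_rate}, so
#' the expected discordance between two ramets of one genet has a closed
#' form; missingness is completely at random at rate \code{missing_rate}.
#'
#' @param n_genets number of distinct genets (>= 1).
#' @param ramets_per_genet integer vector of copies per genet (recycled).
#' @param n_loci number of biallelic loci (> 0).
#' @param error_rate per-allele flip probability in \[0, 1).
#' @param missing_rate per-cell masking probability in \[0, 1).
#' @param seed integer seed; the generator is a pure function of it.
#' @param site site label attached to all individuals.
#' @param freq_range range of the per-locus ALT frequencies.
#' @return a list with elements \code{snp} (\linkS4class{SNPMatrix}) and
#'   \code{truth} (list: \code{genet_of_individual}, \code{clonal_fraction}
#'   = 1 - (G-1)/(N-1), \code{error_rate}, \code{missing_rate},
#'   \code{seed}).
#' @examples
#' cs <- simClonalSite(n_genets = 3, ramets_per_genet = 5, n_loci = 50,
#'                     error_rate = 0, missing_rate = 0, seed = 1)
#' table(cs$truth$genet_of_individual)
#' @export
simClonalSite <- function(n_genets, ramets_per_genet, n_loci,
                          error_rate = 0, missing_rate = 0, seed,
                          site = "site1", freq_range = c(0.05, 0.95)) {
  if (n_loci < 1) stop("n_loci must be positive")
  if (n_genets < 1) stop("n_genets must be >= 1")
  if (error_rate < 0 || error_rate >= 1 || missing_rate < 0 ||
      missing_rate >= 1)
    stop("rates must lie in [0, 1)")
  set.seed(as.integer(seed))
  reps <- rep_len(as.integer(ramets_per_genet), n_genets)
  if (any(reps < 1)) stop("each genet needs at least one ramet")
  p <- runif(n_loci, freq_range[1], freq_range[2])
  genets <- matrix(rbinom(n_genets * n_loci, 2L, rep(p, each = n_genets)),
                   nrow = n_genets)
  idx <- rep(seq_len(n_genets), reps)
  g <- genets[idx, , drop = FALSE]
  n <- nrow(g)
  if (error_rate > 0) {
    # per-allele flips: dosage g loses X ~ Bin(g, e) ALT alleles and gains
    # Y ~ Bin(2 - g, e) from the REF copies
    X <- matrix(rbinom(length(g), g, error_rate), n)
    Y <- matrix(rbinom(length(g), 2L - g, error_rate), n)
    g <- g - X + Y
  }
  storage.mode(g) <- "integer"
  if (missing_rate > 0)
    g[matrix(runif(length(g)) < missing_rate, n)] <- NA_integer_
  ids <- sprintf("%s_i%03d", site, seq_len(n))
  rownames(g) <- ids
  snp <- SNPMatrix(g, site = rep(site, n))
  genet_ids <- sprintf("g%03d", idx)
  truth <- list(
    genet_of_individual = setNames(genet_ids, ids),
    clonal_fraction = if (n > 1) 1 - (n_genets - 1) / (n - 1) else NA_real_,
    error_rate = error_rate, missing_rate = missing_rate,
    seed = as.integer(seed))
  list(snp = snp, truth = truth)
}

#' Simulate a structured metapopulation (Balding-Nichols)
#'
#' Deme allele frequencies are drawn from the Balding-Nichols Beta
#' construction around ancestral frequencies with dispersion set by the
#' target F_ST; genotypes are Binomial(2, p_deme). With
#' \code{fst_target = 0} all demes share the ancestral frequencies
#' exactly.
#'
#' @param n_demes number of demes.
#' @param fst_target target F_ST in \[0, 1).
#' @param n_per_deme individuals per deme.
#' @param n_loci number of loci.
#' @param seed integer seed.
#' @param freq_range range of ancestral ALT frequencies.
#' @return a \linkS4class{SNPMatrix} with demes as sites
#'   (\code{deme1}, \code{deme2}, ...).
#' @export
simMetapopulation <- function(n_demes, fst_target, n_per_deme, n_loci,
                              seed, freq_range = c(0.05, 0.95)) {
  if (fst_target < 0 || fst_target >= 1) stop("fst_target must be in [0, 1)")
  set.seed(as.integer(seed))
  p0 <- runif(n_loci, freq_range[1], freq_range[2])
  pd <- matrix(rep(p0, each = n_demes), nrow = n_demes)
  if (fst_target > 0) {
    a <- (1 - fst_target) / fst_target
    pd <- matrix(rbeta(n_demes * n_loci, rep(p0, each = n_demes) * a,
                       rep(1 - p0, each = n_demes) * a), nrow = n_demes)
  }
  n <- n_demes * n_per_deme
  deme <- rep(seq_len(n_demes), each = n_per_deme)
  g <- matrix(rbinom(n * n_loci, 2L, pd[deme, ]), nrow = n)
  storage.mode(g) <- "integer"
  rownames(g) <- sprintf("d%02d_i%03d", deme,
                         sequence(rep(n_per_deme, n_demes)))
  SNPMatrix(g, site = sprintf("deme%d", deme))
}

#' Simulate two diverged populations under a demographic scenario
#'
#' Runs the package's structured-coalescent engine under a registered
#' divergence scenario, places infinite-sites mutations on the simulated
#' genealogies (Poisson with per-locus rate \code{theta_locus}), and
#' returns both the diploid genotype matrix and the joint SFS; the
#' returned spectrum equals \code{buildJointSFS} of the returned matrix
#' exactly.
#'
#' @param model a \linkS4class{DemographicModel} (see [modelRegistry()]) or
#'   a model name.
#' @param params named numeric parameters in coalescent units (see
#'   [expectedJointSFS()]).
#' @param n1,n2 diploid sample sizes of the two populations.
#' @param n_loci number of independent loci (genealogies).
#' @param seed integer seed.
#' @param theta_locus per-locus scaled mutation rate (expected segregating
#'   sites per locus grows with it).
#' @param fold fold the returned spectrum?
#' @return list with \code{snp} (\linkS4class{SNPMatrix}, sites
#'   \code{pop1}/\code{pop2}) and \code{sfs} (\linkS4class{JointSFS}).
#' @export
simDivergence <- function(model, params, n1, n2, n_loci, seed,
                          theta_locus = 1, fold = FALSE) {
  model <- .resolveModel(model)
  raw <- .coal_two_pop(2L * n1, 2L * n2, as.integer(n_loci),
                       .fullParVector(model, params), .migMode(model),
                       TRUE, theta_locus, as.double(seed))
  H <- raw$haplotypes                       # haplotypes x sites, 0/1
  nS <- ncol(H)
  n <- n1 + n2
  if (nS > 0) {
    g <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
         H[seq(2, 2 * n, by = 2), , drop = FALSE]
    colnames(g) <- sprintf("L%05d_s%d", raw$locus, seq_len(nS))
  } else {
    g <- matrix(integer(0), nrow = n, ncol = 0)
  }
  storage.mode(g) <- "integer"
  rownames(g) <- c(sprintf("p1_i%03d", seq_len(n1)),
                   sprintf("p2_i%03d", seq_len(n2)))
  snp <- SNPMatrix(g, site = rep(c("pop1", "pop2"), c(n1, n2)))
  sfs <- buildJointSFS(snp, pop1 = "pop1", pop2 = "pop2", fold = fold)
  list(snp = snp, sfs = sfs)
}

#' Simulate a coastline dispersal matrix
#'
#' Sites sit on a 1-D coastline line graph; per-generation dispersal is a
#' discretised Gaussian kernel with standard deviation \code{diffusion}
#' whose mean is shifted downstream by \code{advection} (in units of
#' site spacing). Kernel mass that falls off the coastline is retained at
#' the source site, so with \code{advection = 0} the matrix is symmetric.
#' Non-habitat sites neither emit nor receive; habitat rows are
#' renormalised afterwards.
#'
#' @param n_sites number of sites (>= 2).
#' @param advection downstream drift, in site spacings per generation.
#' @param diffusion kernel standard deviation (> 0), site spacings.
#' @param habitat_mask logical habitat suitability per site.
#' @param seed integer seed (kept for interface symmetry; the kernel is
#'   deterministic).
#' @return a \linkS4class{DispersalMatrix}.
#' @export
simDispersal <- function(n_sites, advection = 0, diffusion = 1,
                         habitat_mask = rep(TRUE, n_sites), seed = 1L) {
  if (n_sites < 2) stop("need at least 2 sites")
  if (diffusion <= 0) stop("diffusion must be positive")
  if (!any(habitat_mask)) stop("habitat mask excludes every site")
  offs <- seq(-4 * ceiling(diffusion + abs(advection) + 1),
              4 * ceiling(diffusion + abs(advection) + 1))
  w <- dnorm(offs, mean = advection, sd = diffusion)
  w <- w / sum(w)
  P <- matrix(0, n_sites, n_sites)
  for (i in seq_len(n_sites)) {
    j <- i + offs
    inside <- j >= 1 & j <= n_sites
    P[i, j[inside]] <- P[i, j[inside]] + w[inside]
    P[i, i] <- P[i, i] + sum(w[!inside])   # boundary mass stays home
  }
  if (!all(habitat_mask)) {
    P[!habitat_mask, ] <- 0
    P[, !habitat_mask] <- 0
    rs <- rowSums(P)
    ok <- habitat_mask & rs > 0
    P[ok, ] <- P[ok, ] / rs[ok]
  }
  dimnames(P) <- list(sprintf("site%02d", seq_len(n_sites)),
                      sprintf("site%02d", seq_len(n_sites)))
  new("DispersalMatrix", P = P, habitat = as.logical(habitat_mask),
      meta = list(advection = advection, diffusion = diffusion))
}

#' Simulate a lineage-structured morphometric table
#'
#' Each individual receives three branch-level measurements per trait
#' (frond width FW, distance between dichotomies DBD, undulation index
#' UX), drawn Normal around its lineage mean; the reported individual
#' trait is the mean of the three branches. UX draws are floored at 1
#' (an undulation index below 1 is geometrically impossible).
#'
#' @param lineage_means matrix or data.frame with columns FW, DBD, UX and
#'   one row per lineage (UX means >= 1).
#' @param n_per_lineage individuals per lineage.
#' @param noise_sd length-3 per-trait branch-level standard deviations.
#' @param seed integer seed.
#' @return a data.frame with columns individual, lineage, FW, DBD, UX and
#'   an attribute \code{"branches"} (individuals x 3 traits x 3 branches
#'   array of the raw measurements).
#' @export
simMorpho <- function(lineage_means, n_per_lineage, noise_sd, seed) {
  lm_ <- as.matrix(lineage_means)
  if (!all(c("FW", "DBD", "UX") %in% colnames(lm_)))
    stop("lineage_means needs columns FW, DBD, UX")
  lm_ <- lm_[, c("FW", "DBD", "UX"), drop = FALSE]
  if (any(lm_[, "UX"] < 1)) stop("UX means must be >= 1")
  noise_sd <- rep_len(noise_sd, 3)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  set.seed(as.integer(seed))
  nl <- nrow(lm_)
  n <- nl * n_per_lineage
  lineage <- rep(seq_len(nl), each = n_per_lineage)
  br <- array(NA_real_, c(n, 3, 3),
              dimnames = list(NULL, c("FW", "DBD", "UX"), NULL))
  for (tr in 1:3) {
    draws <- matrix(rnorm(n * 3, mean = lm_[lineage, tr],
                          sd = noise_sd[tr]), n, 3)
    if (tr == 3) draws <- pmax(draws, 1)
    br[, tr, ] <- draws
  }
  out <- data.frame(
    individual = sprintf("lin%d_i%03d", lineage,
                         sequence(rep(n_per_lineage, nl))),
    lineage = sprintf("lineage%d", lineage),
    FW = rowMeans(br[, 1, , drop = FALSE], dims = 1),
    DBD = rowMeans(br[, 2, , drop = FALSE], dims = 1),
    UX = rowMeans(br[, 3, , drop = FALSE], dims = 1))
  attr(out, "branches") <- br
  out
}

#' Hudson's F_ST estimator
#'
#' Ratio-of-averages Hudson estimator between two groups of individuals,
#' from allele frequencies with the standard small-sample correction.
#' Used throughout the package's simulation checks as the realised
#' differentiation of generated data.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param g1,g2 site labels (or individual index vectors) of the groups.
#' @return numeric(1) F_ST estimate.
#' @export
hudsonFst <- function(m, g1, g2) {
  d <- dosages(m)
  pick <- function(g) if (is.character(g)) which(siteOf(m) %in% g) else g
  d1 <- d[pick(g1), , drop = FALSE]
  d2 <- d[pick(g2), , drop = FALSE]
  f <- function(x) colMeans(x, na.rm = TRUE) / 2
  nn <- function(x) colSums(!is.na(x)) * 2
  p1 <- f(d1); p2 <- f(d2); n1 <- nn(d1); n2 <- nn(d2)
  keep <- n1 > 1 & n2 > 1 & is.finite(p1) & is.finite(p2)
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
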