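# Per-site evolvability indicators: F_IS and multilocus linkage
# disequilibrium (I_A, r_bar_d) with a permutation null. All individuals
# of a site (sexually recruited and clones) enter these statistics.

.siteSubset <- function(m, site) {
  if (is.null(site)) return(m)
  keep <- siteOf(m) %in% site
  if (!any(keep)) stop("no individuals from site ", site)
  m[, keep]
}

#' Inbreeding coefficient F_IS for one site
#'
#' Per locus \eqn{f_l = 1 - H_{o,l}/H_{e,l}} with \eqn{H_{e,l} =
#' 2p(1-p)} from the site allele frequency, and the multilocus summary
#' \eqn{F_{IS} = 1 - \sum_l H_{o,l} / \sum_l H_{e,l}}. Within-site
#' monomorphic loci are excluded. Negative values signal clonality
#' (fixed heterozygotes); a single heterozygous clone gives exactly -1.
#' By default no small-sample correction is applied to \eqn{H_e}, which
#' keeps that pure-clone value exact; set \code{unbiased = TRUE} for the
#' \eqn{2n/(2n-1)} correction.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param site optional site label; \code{NULL} uses all individuals of
#'   \code{m} (assumed one site).
#' @param unbiased apply the small-sample correction to \eqn{H_e}?
#' @return list: \code{fis} (multilocus), \code{perLocus} data.frame
#'   (locus, p, Ho, He, f), \code{Ho}, \code{He} (the sums),
#'   \code{nPolymorphic}. With no polymorphic locus \code{fis} is NA.
#' @export
fis <- function(m, site = NULL, unbiased = FALSE) {
  m <- .siteSubset(m, site)
  if (ncol(m) < 2) stop("need at least 2 individuals")
  d <- dosages(m)
  nobs <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- nobs > 0 & p > 0 & p < 1
  if (!any(poly))
    return(list(fis = NA_real_,
                perLocus = data.frame(locus = character(), p = numeric(),
                                      Ho = numeric(), He = numeric(),
                                      f = numeric()),
                Ho = NA_real_, He = NA_real_, nPolymorphic = 0L))
  dd <- d[, poly, drop = FALSE]
  p <- p[poly]; nobs <- nobs[poly]
  Ho <- colMeans(dd == 1L, na.rm = TRUE)
  He <- 2 * p * (1 - p)
  if (unbiased) He <- He * (2 * nobs) / (2 * nobs - 1)
  f <- 1 - Ho / He
  list(fis = 1 - sum(Ho) / sum(He),
       perLocus = data.frame(locus = colnames(dd), p = p, Ho = Ho,
                             He = He, f = f, row.names = NULL),
       Ho = sum(Ho), He = sum(He), nPolymorphic = sum(poly))
}

# pairwise per-locus dosage differences: n_pairs x L matrix
.pairLocusDiff <- function(d) {
  n <- nrow(d)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  abs(d[idx[, 1], , drop = FALSE] - d[idx[, 2], , drop = FALSE])
}

.rbarFromPairs <- function(M) {
  np <- nrow(M)
  v <- colMeans(M^2) - colMeans(M)^2      # population-variance convention
  D <- rowSums(M)
  VO <- mean(D^2) - mean(D)^2
  VE <- sum(v)
  denom <- (sum(sqrt(v)))^2 - VE          # = 2 * sum_{l<m} sqrt(v_l v_m)
  c(Ia = VO / VE - 1, rbarD = (VO - VE) / denom)
}

#' Standardised index of association for one site
#'
#' Multilocus linkage disequilibrium: with per-pair per-locus dosage
#' differences \eqn{d_l}, and \eqn{D = \sum_l d_l} over pairs,
#' \eqn{I_A = V_O/V_E - 1} and
#' \eqn{\bar r_d = (V_O - V_E) / (2\sum_{l<m}\sqrt{Var(d_l)Var(d_m)})}
#' where \eqn{V_O = Var(D)} and \eqn{V_E = \sum_l Var(d_l)}
#' (population-variance convention, all \eqn{n(n-1)/2} pairs). Values
#' near zero are expected under free recombination; clonality inflates
#' them. The permutation null shuffles each locus column independently
#' across individuals, which destroys inter-locus association while
#' preserving locus-wise genotype frequencies; \eqn{p} uses the add-one
#' rule.
#'
#' Missing dosages are mean-imputed per locus before the computation
#' (sites passing the 5\% missingness filter are barely affected).
#'
#' @param m a \linkS4class{SNPMatrix} (one site).
#' @param n_perm number of permutations (0 = no p-value).
#' @param seed integer seed for the permutations.
#' @param site optional site label to subset \code{m}.
#' @return list: \code{Ia}, \code{rbarD}, \code{p} (NA when
#'   \code{n_perm = 0}), \code{nPerm}, \code{nLoci}, \code{nInd}.
#' @export
indexAssociation <- function(m, n_perm = 999, seed = 1L, site = NULL) {
  m <- .siteSubset(m, site)
  d <- dosages(m)
  if (nrow(d) < 3) stop("need at least 3 individuals")
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  }
  v0 <- apply(d, 2, var)
  d <- d[, !is.na(v0) & v0 > 0, drop = FALSE]
  if (ncol(d) < 2) stop("need at least 2 polymorphic loci")
  M <- .pairLocusDiff(d)
  obs <- .rbarFromPairs(M)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    n <- nrow(d)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      dp <- apply(d, 2, function(col) col[sample.int(n)])
      if (.rbarFromPairs(.pairLocusDiff(dp))["rbarD"] >= obs["rbarD"])
        hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(Ia = unname(obs["Ia"]), rbarD = unname(obs["rbarD"]), p = p,
       nPerm = n_perm, nLoci = ncol(d), nInd = nrow(d))
}

#' Per-site evolvability summary table
#'
#' One row per site: clonal richness R (from single-linkage contraction
#' at \code{threshold}, computed within the site), multilocus F_IS with
#' its H_o/H_e sums, I_A, r_bar_d and the permutation p-value.
#'
#' @param m a \linkS4class{SNPMatrix} covering one or more sites.
#' @param threshold clone-calling distance threshold; \code{NULL}
#'   predicts one per site with [predictCutoff()] (falling back to 0 when
#'   the predictor has too few heights).
#' @param n_perm permutations for the r_bar_d null.
#' @param seed integer seed.
#' @return data.frame with one row per site.
#' @export
siteStats <- function(m, threshold = NULL, n_perm = 99, seed = 1L) {
  sites <- unique(siteOf(m))
  rows <- lapply(sites, function(s) {
    ms <- .siteSubset(m, s)
    dm <- pairwiseDistance(ms, on_empty = "na")
    thr <- threshold
    if (is.null(thr))
      thr <- tryCatch(predictCutoff(dm), error = function(e) 0)
    a <- contractMLGs(dm, thr, m = ms)
    f <- fis(ms)
    ia <- tryCatch(indexAssociation(ms, n_perm = n_perm, seed = seed),
                   error = function(e) list(Ia = NA_real_,
                                            rbarD = NA_real_, p = NA_real_))
    data.frame(site = s, n = ncol(ms), G = nGenets(a),
               R = clonalRichness(a), threshold = thr,
               Fis = f$fis, Ho = f$Ho, He = f$He,
               nPolymorphic = f$nPolymorphic,
               Ia = ia$Ia, rbarD = ia$rbarD, p = ia$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bubble plot of per-site diversity statistics
#'
#' Simple base-graphics bubble map: one panel of site positions with
#' bubble size and colour scaled to a chosen statistic (R, Fis or
#' rbarD), in the style of per-site diversity maps.
#'
#' @param stats output of [siteStats()].
#' @param coords data.frame with columns site, x, y.
#' @param which column of \code{stats} to display.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the merged plotting table.
#' @export
plotSiteStats <- function(stats, coords, which = "R", ...) {
  df <- merge(stats, coords, by = "site")
  val <- df[[which]]
  sc <- (val - min(val, na.rm = TRUE)) /
    max(1e-12, diff(range(val, na.rm = TRUE)))
  graphics::plot(df$x, df$y, cex = 0.8 + 2.5 * sc,
                 pch = 21, bg = grDevices::gray(1 - 0.8 * sc),
                 xlab = "x", ylab = "y", main = which, ...)
  invisible(df)
}
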