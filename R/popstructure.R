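# Individual-level structure: PCA on dosages, NMF ancestry coefficients,
# and neighbour-joining trees with locus bootstrap.

.keepRepresentatives <- function(m, mlg) {
  if (is.null(mlg)) return(m)
  keep <- mlg@individual[mlg@representative]
  m[, colnames(m) %in% keep]
}

#' PCA of a SNP dosage matrix
#'
#' Missing cells are mean-imputed per locus, columns centred at the mean
#' dosage, and optionally scaled by \eqn{\sqrt{p(1-p)}} (the binomial
#' standard deviation at the locus allele frequency). When an
#' \linkS4class{MLGAssignment} is supplied, ramets are removed first and
#' only one individual per genet enters the decomposition. Each
#' component is oriented so its largest-magnitude loading is positive.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param scale scale loci by their binomial standard deviation?
#' @param mlg optional \linkS4class{MLGAssignment}; keeps genet
#'   representatives only.
#' @return list: \code{scores} (individuals x components),
#'   \code{varianceExplained} (proportions), \code{loadings},
#'   \code{individuals}.
#' @export
snpPCA <- function(m, scale = FALSE, mlg = NULL) {
  m <- .keepRepresentatives(m, mlg)
  d <- dosages(m)
  if (nrow(d) < 2 || ncol(d) < 2) stop("need >= 2 individuals and loci")
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  X <- sweep(d, 2, mu)
  if (scale) {
    p <- mu / 2
    s <- sqrt(pmax(p * (1 - p), 1e-12))
    X <- sweep(X, 2, s, "/")
  }
  if (all(abs(X) < 1e-12)) stop("constant matrix: no variance to decompose")
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, varianceExplained = ve, loadings = loadings,
       individuals = rownames(d))
}

# Euclidean projection of each row onto the probability simplex (Duchi)
.projSimplexRows <- function(M) {
  n <- nrow(M); k <- ncol(M)
  if (k == 1) return(matrix(1, n, 1))
  S <- t(apply(M, 1, sort, decreasing = TRUE))
  cs <- t(apply(S, 1, cumsum))
  jj <- matrix(rep(seq_len(k), each = n), n)
  cond <- S - (cs - 1) / jj > 0
  rho <- apply(cond, 1, function(x) max(which(x)))
  theta <- (cs[cbind(seq_len(n), rho)] - 1) / rho
  P <- pmax(M - theta, 0)
  # guard against all-zero rows from numerical ties
  z <- rowSums(P) == 0
  if (any(z)) P[z, ] <- 1 / k
  P
}

.nmfObjective <- function(X, Q, G) 0.5 * sum((X - Q %*% G)^2)

# one projected-gradient block update with backtracking; returns the new
# block and objective (monotone by construction)
.pgStep <- function(X, Q, G, which, f0, project) {
  if (which == "Q") {
    grad <- (Q %*% G - X) %*% t(G)
    lip <- sum(G * G)
  } else {
    grad <- t(Q) %*% (Q %*% G - X)
    lip <- sum(Q * Q)
  }
  step <- 1 / max(lip, 1e-9)
  for (bt in 1:20) {
    cand <- if (which == "Q") project(Q - step * grad) else
      project(G - step * grad)
    f1 <- if (which == "Q") .nmfObjective(X, cand, G) else
      .nmfObjective(X, Q, cand)
    if (f1 <= f0 + 1e-12) return(list(B = cand, f = f1))
    step <- step / 2
  }
  list(B = if (which == "Q") Q else G, f = f0)
}

#' Ancestry coefficients by constrained non-negative matrix factorisation
#'
#' Genotypes are one-hot encoded (three classes per locus) into an
#' individuals x 3L matrix X, and X is approximated by Q G where the K
#' ancestry proportions of each individual (rows of Q) lie on the
#' probability simplex and each cluster's three genotype frequencies per
#' locus (blocks of G) do too. The fit alternates projected-gradient
#' steps with backtracking, so the least-squares objective never
#' increases and the constraints hold after every iteration. The best of
#' \code{reps} random restarts (by objective) is kept; model choice uses
#' the cross-entropy of a 5\% held-out cell mask.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param K number of ancestral clusters (>= 1, <= individuals).
#' @param reps random restarts.
#' @param seed integer seed.
#' @param mlg optional \linkS4class{MLGAssignment}: ramets removed first.
#' @param max_iter,tol convergence controls (relative objective change).
#' @param mask_frac fraction of observed cells held out for the
#'   cross-entropy.
#' @return an \linkS4class{AncestryResult}.
#' @export
ancestryNMF <- function(m, K, reps = 3, seed = 1L, mlg = NULL,
                        max_iter = 200, tol = 1e-6, mask_frac = 0.05) {
  m <- .keepRepresentatives(m, mlg)
  d <- dosages(m)
  n <- nrow(d); L <- ncol(d)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of individuals")
  set.seed(as.integer(seed))
  # one-hot encoding; missing and masked cells get the locus profile
  freq <- vapply(0:2, function(k) colMeans(d == k, na.rm = TRUE),
                 numeric(L))
  freq[!is.finite(freq)] <- 1 / 3
  obs <- which(!is.na(d))
  mask <- sort(sample(obs, max(1, round(mask_frac * length(obs)))))
  X <- matrix(0, n, 3 * L)
  for (k in 0:2) X[, seq(k + 1, 3 * L, by = 3)] <- (d == k) + 0
  X[is.na(X)] <- 0
  fill <- function(cells) {
    ij <- arrayInd(cells, dim(d))
    for (r in seq_len(nrow(ij))) {
      i <- ij[r, 1]; l <- ij[r, 2]
      X[i, 3 * (l - 1) + 1:3] <<- freq[l, ]
    }
  }
  if (anyNA(d)) fill(which(is.na(d)))
  fill(mask)

  projG <- function(G) {
    # project each (cluster, locus) genotype-frequency triple onto the
    # simplex; G columns are ordered (g0, g1, g2) per locus
    A <- array(G, c(K, 3, L))
    B <- .projSimplexRows(matrix(aperm(A, c(1, 3, 2)), K * L, 3))
    matrix(aperm(array(B, c(K, L, 3)), c(1, 3, 2)), K, 3 * L)
  }

  best <- NULL
  for (r in seq_len(reps)) {
    Q <- matrix(rexp(n * K), n); Q <- Q / rowSums(Q)
    G <- do.call(cbind, lapply(seq_len(L), function(l) {
      base <- matrix(rep(freq[l, ], each = K), K) +
        matrix(runif(3 * K, 0, 0.2), K)
      base / rowSums(base)
    }))
    f <- .nmfObjective(X, Q, G)
    trace <- f
    for (it in seq_len(max_iter)) {
      sQ <- .pgStep(X, Q, G, "Q", f, .projSimplexRows)
      Q <- sQ$B; f1 <- sQ$f
      sG <- .pgStep(X, Q, G, "G", f1, projG)
      G <- sG$B; f2 <- sG$f
      trace <- c(trace, f1, f2)
      if (abs(f - f2) <= tol * max(f, 1e-12)) { f <- f2; break }
      f <- f2
    }
    if (is.null(best) || f < best$f)
      best <- list(Q = Q, G = G, f = f, trace = trace)
  }
  # masked cross-entropy of the kept run
  Pfit <- best$Q %*% best$G
  ij <- arrayInd(mask, dim(d))
  ce <- vapply(seq_len(nrow(ij)), function(r) {
    i <- ij[r, 1]; l <- ij[r, 2]
    pr <- Pfit[i, 3 * (l - 1) + 1:3]
    pr <- pmax(pr, 1e-12); pr <- pr / sum(pr)
    -log(pr[d[i, l] + 1])
  }, numeric(1))
  het <- best$G[, seq(2, 3 * L, by = 3), drop = FALSE]
  hom2 <- best$G[, seq(3, 3 * L, by = 3), drop = FALSE]
  Fmat <- pmin(pmax(hom2 + het / 2, 0), 1)
  dimnames(best$Q) <- list(rownames(d), sprintf("K%d", seq_len(K)))
  attr(best$Q, "trace") <- best$trace
  dimnames(Fmat) <- list(sprintf("K%d", seq_len(K)), colnames(d))
  new("AncestryResult", Q = best$Q, Fmat = Fmat, K = as.integer(K),
      crossEntropy = mean(ce), objective = best$f,
      reps = as.integer(reps))
}

#' Cross-entropy profile over a grid of K
#'
#' Runs [ancestryNMF()] for each K and returns the masked cross-entropy,
#' the usual device for choosing the number of clusters.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param Ks integer vector of K values.
#' @param ... passed to [ancestryNMF()] (same seed implies the same
#'   held-out mask for every K).
#' @return data.frame: K, crossEntropy, objective.
#' @export
selectK <- function(m, Ks, ...) {
  res <- lapply(Ks, function(K) {
    a <- ancestryNMF(m, K = K, ...)
    data.frame(K = K, crossEntropy = a@crossEntropy,
               objective = a@objective)
  })
  do.call(rbind, res)
}

#' Neighbour-joining tree with locus bootstrap support
#'
#' Standard NJ (\code{\link[ape]{nj}}) on the pairwise distance matrix.
#' Negative branch lengths are clamped to zero (flagged in the returned
#' attribute). With \code{boot > 0} and the genotype matrix supplied,
#' loci are resampled with replacement, the distance and tree are
#' rebuilt per replicate, and each internal node is labelled with the
#' proportion of replicates containing its split.
#'
#' @param d a \linkS4class{SNPDistance}.
#' @param boot bootstrap replicates (0 = no support values).
#' @param m the \linkS4class{SNPMatrix} the distances came from (needed
#'   when \code{boot > 0}).
#' @param seed integer seed for the bootstrap.
#' @return an \code{ape::phylo}; support proportions in
#'   \code{node.label}, and attribute \code{"clamped"} giving how many
#'   branch lengths were negative before clamping.
#' @export
njTree <- function(d, boot = 0, m = NULL, seed = 1L) {
  dm <- d@d
  if (nrow(dm) < 3) stop("need at least 3 individuals")
  if (any(abs(dm - t(dm)) > 1e-12)) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(dm))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (boot > 0) {
    if (is.null(m)) stop("bootstrapping needs the genotype matrix 'm'")
    x <- dosages(m)[tr$tip.label, , drop = FALSE]
    set.seed(as.integer(seed))
    bp <- ape::boot.phylo(tr, x, function(xx)
      ape::nj(as.dist(.dosageDist(xx, on_empty = "na")$d)),
      B = boot, quiet = TRUE, rooted = FALSE)
    tr$node.label <- bp / boot
  }
  attr(tr, "clamped") <- clamped
  tr
}
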