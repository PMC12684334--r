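# Clone detection: pairwise allelic-difference distances, automatic
# distance-cutoff prediction, single-linkage MLG contraction, and clonal
# richness.

# core distance on a raw dosage matrix (individuals x loci); decomposes
# |g_a - g_b| over the 3x3 dosage table into indicator cross-products so
# the whole computation is a handful of matrix products
.dosageDist <- function(d, on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  W <- !is.na(d)
  I0 <- W & d == 0L; I1 <- W & d == 1L; I2 <- W & d == 2L
  I0[is.na(I0)] <- FALSE; I1[is.na(I1)] <- FALSE; I2[is.na(I2)] <- FALSE
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  Wn <- matrix(as.double(W), nrow(d))
  shared <- Wn %*% t(Wn)
  s01 <- I0 %*% t(I1); s12 <- I1 %*% t(I2); s02 <- I0 %*% t(I2)
  diffs <- s01 + t(s01) + s12 + t(s12) + 2 * (s02 + t(s02))
  if (any(shared[upper.tri(shared)] == 0)) {
    if (on_empty == "error")
      stop("some pairs share zero genotyped loci; distance undefined")
  }
  dm <- diffs / (2 * shared)
  dm[shared == 0] <- NA_real_
  diag(dm) <- 0
  dimnames(dm) <- list(rownames(d), rownames(d))
  list(d = dm, shared = matrix(as.integer(shared), nrow(d),
                               dimnames = dimnames(dm)))
}

#' Pairwise genetic distance (proportion of allelic differences)
#'
#' For diploid dosages the distance between individuals a and b is
#' \deqn{d(a,b) = \sum_l |g_{a,l} - g_{b,l}| / (2 L_{ab})}
#' over loci genotyped in both, with \eqn{L_{ab}} that pairwise-complete
#' count: a heterozygote versus either homozygote differs by one allele,
#' opposite homozygotes by two.
#'
#' @param m a \linkS4class{SNPMatrix} with at least 2 individuals.
#' @param on_empty what to do when a pair shares no genotyped loci:
#'   \code{"error"} (default) or \code{"na"}.
#' @return a \linkS4class{SNPDistance}.
#' @export
pairwiseDistance <- function(m, on_empty = c("error", "na")) {
  if (ncol(m) < 2) stop("need at least 2 individuals")
  res <- .dosageDist(dosages(m), on_empty = match.arg(on_empty))
  new("SNPDistance", d = res$d, shared = res$shared,
      site = unname(siteOf(m)))
}

#' Predict a clone-calling distance cutoff
#'
#' Distributions of pairwise distances in partially clonal samples show
#' distinct peaks towards low distances (ramet pairs) rather than a
#' single mode. The predictor looks at the single-linkage merge heights,
#' restricts attention to heights at most \code{fraction} of the maximum,
#' and returns the midpoint of the largest gap between such a height and
#' the next one (ties broken towards the lowest height).
#'
#' @param d a \linkS4class{SNPDistance} (or square distance matrix).
#' @param fraction upper fraction of the height range searched (default
#'   0.5).
#' @return numeric(1), the predicted distance threshold.
#' @export
predictCutoff <- function(d, fraction = 0.5) {
  dm <- if (is(d, "SNPDistance")) d@d else as.matrix(d)
  if (length(unique(round(dm[upper.tri(dm)], 12))) < 3)
    stop("need at least 3 distinct pairwise distances")
  h <- sort(hclust(as.dist(dm), method = "single")$height)
  cand <- which(h <= fraction * max(h))
  cand <- cand[cand < length(h)]         # need a following height for a gap
  if (length(cand) < 2)
    stop("fewer than 2 candidate merge heights below fraction * max; ",
         "choose a threshold manually")
  gaps <- h[cand + 1] - h[cand]
  i <- cand[which.max(gaps)]             # which.max takes the first (lowest)
  (h[i] + h[i + 1]) / 2
}

#' Contract individuals into multilocus genotypes (genets)
#'
#' Genets are the connected components of the graph joining pairs at
#' distance at most \code{threshold} (single-linkage contraction). The
#' representative of each genet is its lowest-missingness member when the
#' genotype matrix is supplied, otherwise the first member.
#'
#' @param d a \linkS4class{SNPDistance}.
#' @param threshold distance threshold (>= 0).
#' @param m optional \linkS4class{SNPMatrix} used to pick representatives.
#' @return an \linkS4class{MLGAssignment}.
#' @export
contractMLGs <- function(d, threshold, m = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  dm <- d@d
  n <- nrow(dm)
  adj <- !is.na(dm) & dm <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  genet <- sprintf("MLG%04d", comp)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(n))
  rep_flag <- logical(n)
  miss <- if (!is.null(m)) rowMeans(is.na(dosages(m)))[ids] else rep(0, n)
  for (gid in unique(genet)) {
    members <- which(genet == gid)
    rep_flag[members[which.min(miss[members])]] <- TRUE
  }
  new("MLGAssignment", individual = ids,
      site = if (length(d@site)) d@site else rep("site1", n),
      genet = genet, representative = rep_flag,
      threshold = as.numeric(threshold))
}

#' Clonal richness R = (G - 1) / (N - 1)
#'
#' Genotypic diversity relative to sample size: 0 when every individual
#' belongs to one genet, 1 when all are distinct.
#'
#' @param a an \linkS4class{MLGAssignment}.
#' @param by_site compute R within each site instead of overall?
#' @return numeric(1), or a named vector per site.
#' @export
clonalRichness <- function(a, by_site = FALSE) {
  r1 <- function(genet) {
    n <- length(genet)
    if (n < 2) stop("R undefined for a single individual")
    (length(unique(genet)) - 1) / (n - 1)
  }
  if (!by_site) return(r1(a@genet))
  vapply(split(a@genet, a@site), r1, numeric(1))
}

#' Collapse an individual distance matrix to site level
#'
#' Mean pairwise distance between individuals of different sites (and 0
#' on the diagonal), for site-level dendrograms.
#'
#' @param d a \linkS4class{SNPDistance}.
#' @return a site x site symmetric matrix.
#' @export
collapseToSites <- function(d) {
  sites <- sort(unique(d@site))
  k <- length(sites)
  out <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- d@d[d@site == sites[i], d@site == sites[j], drop = FALSE]
    out[i, j] <- out[j, i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Write an MLG assignment as TSV
#'
#' @param a an \linkS4class{MLGAssignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenetTable <- function(a, path) {
  write.table(asGenetTable(a), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
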