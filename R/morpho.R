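# Morphometrics: undulation index from traced branch margins, trait PCA,
# and congruence between morphological and genetic site dendrograms.

#' Undulation index of a traced branch margin
#'
#' Ratio of the arc length of an ordered 2-D polyline (the traced margin
#' of a thallus branch) to the straight-line distance between its
#' endpoints: 1 for a flat margin, larger for undulated ones. Invariant
#' to rigid motions and uniform scaling.
#'
#' @param margin numeric matrix (or data.frame) of ordered x, y points,
#'   at least 2 rows.
#' @return numeric(1) >= 1 in exact arithmetic (>= the chord ratio for
#'   any polyline).
#' @examples
#' undulationIndex(cbind(0:10, 0))           # straight: 1
#' th <- seq(0, pi, length.out = 1000)
#' undulationIndex(cbind(cos(th), sin(th)))  # semicircle: ~ pi / 2
#' @export
undulationIndex <- function(margin) {
  m <- as.matrix(margin)
  if (nrow(m) < 2) stop("need at least 2 points")
  seg <- sqrt(rowSums(diff(m)^2))
  chord <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  if (chord < 1e-12) stop("coincident endpoints: chord length is zero")
  sum(seg) / chord
}

#' Individual undulation index from three branch traces
#'
#' The individual-level UX is the arithmetic mean of the per-branch
#' values (three measurements taken from different branches).
#'
#' @param branches list of point matrices, one per branch.
#' @return numeric(1).
#' @export
individualUX <- function(branches) {
  mean(vapply(branches, undulationIndex, numeric(1)))
}

.zscoreTraits <- function(x) {
  keep <- vapply(seq_len(ncol(x)), function(j) sd(x[, j]) > 1e-12,
                 logical(1))
  if (!all(keep))
    warning("constant trait(s) dropped: ",
            paste(colnames(x)[!keep], collapse = ", "))
  scale(x[, keep, drop = FALSE])
}

#' PCA of morphometric traits
#'
#' Traits are z-scored before the decomposition; constant traits are
#' dropped with a warning. Components are oriented so the
#' largest-magnitude loading is positive.
#'
#' @param t data.frame with trait columns (default FW, DBD, UX).
#' @param traits trait column names.
#' @return list: \code{scores}, \code{varianceExplained},
#'   \code{loadings}.
#' @export
morphoPCA <- function(t, traits = c("FW", "DBD", "UX")) {
  x <- as.matrix(t[, traits, drop = FALSE])
  if (nrow(x) < 2) stop("need at least 2 individuals")
  z <- .zscoreTraits(x)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]; s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  list(scores = sweep(pc$x, 2, flip, "*"),
       varianceExplained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = sweep(pc$rotation, 2, flip, "*"))
}

#' Compare morphological and genetic site dendrograms
#'
#' Builds an average-linkage dendrogram from Euclidean distances of
#' z-scored site trait means, builds the matching dendrogram from a
#' genetic site distance matrix (see [collapseToSites()]), and reports
#' congruence as the cophenetic correlation and the Robinson-Foulds
#' topological distance. Sites present in only one input are dropped
#' with a warning.
#'
#' @param t morphometric data.frame with a site column and trait
#'   columns.
#' @param genetic site x site genetic distance matrix (or dist).
#' @param site_col name of the site column in \code{t}.
#' @param traits trait column names.
#' @param linkage agglomeration method (default \code{"average"}).
#' @return list: \code{morphoTree}, \code{geneticTree} (hclust),
#'   \code{copheneticCorrelation}, \code{rfDistance}, \code{sites}.
#' @export
siteDendrogramCompare <- function(t, genetic, site_col = "site",
                                  traits = c("FW", "DBD", "UX"),
                                  linkage = "average") {
  g <- as.matrix(genetic)
  x <- as.matrix(t[, traits, drop = FALSE])
  sm <- aggregate(x, by = list(site = t[[site_col]]), FUN = mean)
  rownames(sm) <- sm$site
  shared <- intersect(rownames(sm), rownames(g))
  if (length(shared) < 3) stop("need at least 3 shared sites")
  dropped <- setdiff(union(rownames(sm), rownames(g)), shared)
  if (length(dropped))
    warning("site(s) present in only one input dropped: ",
            paste(dropped, collapse = ", "))
  z <- .zscoreTraits(as.matrix(sm[shared, traits, drop = FALSE]))
  hm <- hclust(dist(z), method = linkage)
  hg <- hclust(as.dist(g[shared, shared]), method = linkage)
  cc <- suppressWarnings(
    stats::cor(as.vector(cophenetic(hm)), as.vector(cophenetic(hg))))
  rf <- phangorn::RF.dist(ape::as.phylo(hm), ape::as.phylo(hg))
  list(morphoTree = hm, geneticTree = hg, copheneticCorrelation = cc,
       rfDistance = rf, sites = shared)
}
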