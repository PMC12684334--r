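#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var sd rbinom rbeta runif rnorm rpois rexp setNames
#'   hclust cutree as.dist cophenetic prcomp dist lm coef confint
#'   aggregate optim mad median dnorm quantile
#' @importFrom utils head read.table write.table
#' @useDynLib CloneScape, .registration = TRUE
NULL

.MISSING_OK <- c(0L, 1L, 2L)

# ---------------------------------------------------------------------------
# SNPMatrix: biallelic dosage genotypes backed by a SummarizedExperiment
# (loci as rows, individuals as columns; site membership in colData).
# ---------------------------------------------------------------------------

#' SNPMatrix: a biallelic SNP dosage matrix with site labels
#'
#' An S4 container for diploid biallelic genotypes coded as ALT-allele
#' dosages (0, 1, 2, or \code{NA} for missing), built on
#' \linkS4class{SummarizedExperiment} with loci as rows and individuals as
#' columns. The sampling site of each individual is kept in
#' \code{colData(x)$site}.
#'
#' @slot ploidy integer(1), fixed at 2.
#'
#' @seealso [SNPMatrix()] for construction, [dosages()], [siteOf()],
#'   [filterSNPMatrix()], [pairwiseDistance()]
#' @export
setClass("SNPMatrix",
  contains = "SummarizedExperiment",
  representation(ploidy = "integer"),
  prototype(ploidy = 2L))

setValidity("SNPMatrix", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !(d %in% .MISSING_OK) & !is.na(d)
    if (any(bad)) msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (!"site" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'site' column")
  if (!identical(object@ploidy, 2L))
    msg <- c(msg, "ploidy is fixed at 2")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SNPMatrix
#'
#' @param dosage integer matrix of ALT-allele dosages, individuals in rows
#'   and loci in columns (the common analysis orientation); values 0/1/2/NA.
#' @param site character vector of site labels, one per individual.
#' @param individuals,loci optional id vectors; defaults are taken from
#'   dimnames or generated.
#' @return a \linkS4class{SNPMatrix}
#' @examples
#' m <- SNPMatrix(matrix(c(0L, 1L, 2L, 1L), 2, 2), site = c("A", "A"))
#' dosages(m)
#' @export
SNPMatrix <- function(dosage, site,
                      individuals = rownames(dosage),
                      loci = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (length(site) != nrow(dosage))
    stop("'site' must have one entry per individual (row of 'dosage')")
  if (is.null(individuals))
    individuals <- sprintf("ind%03d", seq_len(nrow(dosage)))
  if (is.null(loci))
    loci <- sprintf("locus%05d", seq_len(ncol(dosage)))
  a <- t(dosage)
  dimnames(a) <- list(loci, individuals)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = a),
    colData = S4Vectors::DataFrame(site = as.character(site),
                                   row.names = individuals))
  new("SNPMatrix", se, ploidy = 2L)
}

#' Accessors for SNPMatrix
#'
#' \code{dosages} returns the dosage matrix in individuals-by-loci
#' orientation; \code{siteOf} the site label of each individual;
#' \code{nIndividuals} and \code{nLoci} the dimensions.
#'
#' @param x a \linkS4class{SNPMatrix}
#' @return see individual descriptions
#' @aliases dosages siteOf nIndividuals nLoci
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "SNPMatrix", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname dosages
#' @export
setGeneric("siteOf", function(x) standardGeneric("siteOf"))

#' @rdname dosages
#' @export
setMethod("siteOf", "SNPMatrix", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$site),
           colnames(x)))

#' @rdname dosages
#' @export
nIndividuals <- function(x) ncol(x)

#' @rdname dosages
#' @export
nLoci <- function(x) nrow(x)

#' Subset a SNPMatrix by individuals or loci
#'
#' @param x a \linkS4class{SNPMatrix}
#' @param idx integer, logical or character index
#' @return a \linkS4class{SNPMatrix}
#' @export
subsetIndividuals <- function(x, idx) x[, idx]

#' @rdname subsetIndividuals
#' @export
subsetLoci <- function(x, idx) x[idx, ]

setMethod("show", "SNPMatrix", function(object) {
  cat("SNPMatrix:", nrow(object), "loci x", ncol(object), "individuals\n")
  s <- table(siteOf(object))
  cat("  sites:", length(s), "(",
      paste(head(names(s), 5), collapse = ", "),
      if (length(s) > 5) "..." else "", ")\n")
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  missingness: %.2f%%\n", 100 * mean(is.na(d))))
})

# ---------------------------------------------------------------------------
# SNPDistance: pairwise allelic-difference proportions
# ---------------------------------------------------------------------------

#' SNPDistance: pairwise genetic distances between individuals
#'
#' Symmetric matrix of pairwise distances (proportion of allelic
#' differences over loci typed in both individuals) together with the
#' pairwise-complete locus counts used in each denominator.
#'
#' @slot d symmetric numeric matrix in \[0, 1\], zero diagonal.
#' @slot shared integer matrix of pairwise-complete locus counts.
#' @slot site character, site label per individual.
#' @seealso [pairwiseDistance()]
#' @export
setClass("SNPDistance",
  representation(d = "matrix", shared = "matrix", site = "character"))

setValidity("SNPDistance", function(object) {
  msg <- NULL
  d <- object@d
  if (nrow(d) != ncol(d)) msg <- c(msg, "distance matrix must be square")
  if (any(abs(d - t(d)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "distance matrix must be symmetric")
  if (any(diag(d) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(d < -1e-12 | d > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "distances must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SNPDistance distance matrix as a base matrix
#' @param x,object a SNPDistance
#' @export
setMethod("as.matrix", "SNPDistance", function(x) x@d)

setMethod("show", "SNPDistance", function(object) {
  cat("SNPDistance over", nrow(object@d), "individuals;",
      sprintf("mean distance %.4f\n", mean(object@d[upper.tri(object@d)])))
})

# ---------------------------------------------------------------------------
# MLGAssignment: individuals contracted into genets
# ---------------------------------------------------------------------------

#' MLGAssignment: multilocus genotype (clone) membership
#'
#' The partition of individuals into genets (multilocus genotypes, MLGs)
#' obtained by single-linkage contraction of the pairwise distance graph at
#' a distance threshold.
#'
#' @slot individual character, individual ids.
#' @slot site character, site per individual.
#' @slot genet character, genet id per individual.
#' @slot representative logical, TRUE for the lowest-missingness member of
#'   each genet.
#' @slot threshold numeric(1), distance threshold used.
#' @seealso [contractMLGs()], [clonalRichness()]
#' @export
setClass("MLGAssignment",
  representation(individual = "character", site = "character",
                 genet = "character", representative = "logical",
                 threshold = "numeric"))

setValidity("MLGAssignment", function(object) {
  n <- length(object@individual)
  if (length(object@genet) != n || length(object@site) != n ||
      length(object@representative) != n)
    return("individual, site, genet and representative must align")
  if (any(is.na(object@genet))) return("every individual needs a genet")
  TRUE
})

#' @describeIn MLGAssignment number of genets (G)
#' @param a an MLGAssignment
#' @export
nGenets <- function(a) length(unique(a@genet))

#' @describeIn MLGAssignment number of individuals (N)
#' @export
nRamets <- function(a) length(a@individual)

#' @describeIn MLGAssignment assignment as a data.frame
#' @export
asGenetTable <- function(a)
  data.frame(individual = a@individual, site = a@site, genet = a@genet,
             representative = a@representative)

setMethod("show", "MLGAssignment", function(object) {
  cat("MLGAssignment:", nGenets(object), "genets among",
      nRamets(object), "individuals",
      sprintf("(threshold %.4g)\n", object@threshold))
})

# ---------------------------------------------------------------------------
# JointSFS
# ---------------------------------------------------------------------------

#' JointSFS: two-population joint site frequency spectrum
#'
#' A (2n1+1) x (2n2+1) array of site counts indexed by the ALT (or, once
#' folded, pooled minor) allele count in each population.
#'
#' @slot counts numeric matrix of per-cell site counts.
#' @slot folded logical(1).
#' @slot n1,n2 integer(1), haploid sample sizes (2 x diploids).
#' @slot pops character(2), population labels.
#' @seealso [buildJointSFS()], [foldJointSFS()], [fitDemography()]
#' @export
setClass("JointSFS",
  representation(counts = "matrix", folded = "logical",
                 n1 = "integer", n2 = "integer", pops = "character"))

setValidity("JointSFS", function(object) {
  msg <- NULL
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(dim(object@counts),
                 c(object@n1 + 1L, object@n2 + 1L)))
    msg <- c(msg, "counts must be (n1+1) x (n2+1)")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn JointSFS total number of sites in the spectrum
#' @param s a JointSFS
#' @export
sfsTotal <- function(s) sum(s@counts)

#' @describeIn JointSFS the count array
#' @export
sfsCounts <- function(s) s@counts

#' @describeIn JointSFS is the spectrum folded?
#' @export
isFolded <- function(s) s@folded

setMethod("show", "JointSFS", function(object) {
  cat(sprintf("JointSFS (%s): %d x %d cells, %.0f sites, pops %s/%s\n",
              if (object@folded) "folded" else "unfolded",
              nrow(object@counts), ncol(object@counts), sum(object@counts),
              object@pops[1], object@pops[2]))
})

# ---------------------------------------------------------------------------
# DemographicModel and FitResult
# ---------------------------------------------------------------------------

#' DemographicModel: a two-population divergence scenario
#'
#' One of the 22 scenarios from the SI / IM / AM / SC families, with
#' optional exponential growth (G), two effective-size classes (2N) and
#' two migration-rate classes (2m).
#'
#' @slot name model id, e.g. \code{"SC2m"}.
#' @slot base one of SI, IM, AM, SC.
#' @slot growth,twoN,twoM logical flags.
#' @slot params names of the free parameters.
#' @slot lower,upper named parameter bounds (coalescent units).
#' @seealso [modelRegistry()], [expectedJointSFS()], [fitDemography()]
#' @export
setClass("DemographicModel",
  representation(name = "character", base = "character",
                 growth = "logical", twoN = "logical", twoM = "logical",
                 params = "character", lower = "numeric", upper = "numeric"))

setValidity("DemographicModel", function(object) {
  msg <- NULL
  if (!object@base %in% c("SI", "IM", "AM", "SC"))
    msg <- c(msg, "base must be SI, IM, AM or SC")
  if (object@twoM && object@base == "SI")
    msg <- c(msg, "2m variants require migration (IM, AM or SC)")
  if (!identical(names(object@lower), object@params) ||
      !identical(names(object@upper), object@params))
    msg <- c(msg, "bounds must be named by params")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel", object@name, "-", length(object@params),
      "free parameters:", paste(object@params, collapse = ", "), "\n")
})

#' FitResult: a fitted demographic model
#'
#' @slot model the \linkS4class{DemographicModel} fitted.
#' @slot par named numeric, best parameters in coalescent units.
#' @slot theta numeric(1), analytic optimal spectrum scaling.
#' @slot loglik composite Poisson log-likelihood at the optimum.
#' @slot AIC 2k - 2 loglik with k free parameters (+1 for theta).
#' @slot k integer, number of free parameters counted in the AIC.
#' @slot nFits integer, number of replicate three-step fits run.
#' @slot bio list of biological-unit parameters (filled by
#'   [toBiologicalUnits()]).
#' @export
setClass("FitResult",
  representation(model = "DemographicModel", par = "numeric",
                 theta = "numeric", loglik = "numeric", AIC = "numeric",
                 k = "integer", nFits = "integer", bio = "list"))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult %s: loglik %.2f, AIC %.2f (k = %d, %d fits)\n",
              object@model@name, object@loglik, object@AIC, object@k,
              object@nFits))
})

# ---------------------------------------------------------------------------
# DispersalMatrix
# ---------------------------------------------------------------------------

#' DispersalMatrix: per-generation dispersal probabilities between sites
#'
#' Row-stochastic site-by-site matrix: entry (i, j) is the probability that
#' propagules released at site i settle at site j within one generation.
#'
#' @slot P numeric row-stochastic matrix (rows = source sites).
#' @slot habitat logical, habitat suitability mask per site.
#' @slot meta list of informational metadata (drift duration, spawning
#'   window, ...), not used in computation.
#' @seealso [simDispersal()], [multigenConnectivity()]
#' @export
setClass("DispersalMatrix",
  representation(P = "matrix", habitat = "logical", meta = "list"))

setValidity("DispersalMatrix", function(object) {
  msg <- NULL
  P <- object@P
  if (nrow(P) != ncol(P)) msg <- c(msg, "P must be square")
  if (length(object@habitat) != nrow(P))
    msg <- c(msg, "habitat mask must have one entry per site")
  if (any(P < -1e-12)) msg <- c(msg, "entries must be non-negative")
  rs <- rowSums(P)[object@habitat]
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "habitat rows must sum to 1 (+- 1e-9)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DispersalMatrix", function(object) {
  cat("DispersalMatrix:", nrow(object@P), "sites,",
      sum(object@habitat), "habitat\n")
})

# ---------------------------------------------------------------------------
# AncestryResult
# ---------------------------------------------------------------------------

#' AncestryResult: NMF-based individual ancestry coefficients
#'
#' @slot Q individuals x K ancestry proportions (rows sum to 1).
#' @slot Fmat K x loci cluster ALT-allele frequencies.
#' @slot K integer(1), number of ancestral clusters.
#' @slot crossEntropy masked-cell cross-entropy of the kept run.
#' @slot objective final least-squares objective of the kept run.
#' @slot reps integer(1), replicate runs performed.
#' @seealso [ancestryNMF()]
#' @export
setClass("AncestryResult",
  representation(Q = "matrix", Fmat = "matrix", K = "integer",
                 crossEntropy = "numeric", objective = "numeric",
                 reps = "integer"))

setValidity("AncestryResult", function(object) {
  msg <- NULL
  if (any(object@Q < -1e-9)) msg <- c(msg, "Q entries must be >= 0")
  if (any(abs(rowSums(object@Q) - 1) > 1e-9))
    msg <- c(msg, "Q rows must sum to 1")
  if (any(object@Fmat < -1e-9 | object@Fmat > 1 + 1e-9))
    msg <- c(msg, "F entries must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "AncestryResult", function(object) {
  cat(sprintf("AncestryResult: K = %d, %d individuals, cross-entropy %.4f\n",
              object@K, nrow(object@Q), object@crossEntropy))
})
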