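# Multi-generation stepping-stone connectivity from a per-generation
# dispersal matrix.

#' Multi-generation stepping-stone connectivity
#'
#' From a per-generation row-stochastic dispersal matrix P, computes the
#' connectivity accumulated over \code{generations} steps of
#' stepping-stone dispersal, restricted to habitat sites (masked and
#' renormalised before stepping, and renormalised after every
#' multiplication so rows stay stochastic to within accumulated
#' round-off). Two accumulation modes are provided because
#' multi-generation connectivity can be read either as the g-step
#' transition probability or as the average visiting probability along
#' the path: \code{"power"} returns \eqn{\tilde P^g},
#' \code{"cumulative"} returns \eqn{(1/g)\sum_{k=1}^g \tilde P^k}.
#'
#' When a site partition is supplied, the asymmetry summary totals the
#' probability mass flowing from the region to the outside against the
#' reverse direction - the signature of advective seascapes where gene
#' flow out of a basin exceeds flow into it.
#'
#' @param P a \linkS4class{DispersalMatrix}, or a row-stochastic matrix.
#' @param generations number of generations g (>= 1; default 32).
#' @param mode \code{"power"} or \code{"cumulative"}.
#' @param region optional site partition for the asymmetry summary:
#'   logical vector, or character vector of site names.
#' @return list: \code{C} (connectivity matrix, rows = source sites),
#'   \code{asymmetry} (NULL, or list with \code{outward}, \code{inward},
#'   \code{ratio}), \code{mode}, \code{generations}.
#' @export
multigenConnectivity <- function(P, generations = 32,
                                 mode = c("power", "cumulative"),
                                 region = NULL) {
  mode <- match.arg(mode)
  if (generations < 1) stop("generations must be >= 1")
  if (is(P, "DispersalMatrix")) {
    habitat <- P@habitat
    M <- P@P
  } else {
    M <- as.matrix(P)
    habitat <- rep(TRUE, nrow(M))
  }
  M <- M[habitat, habitat, drop = FALSE]
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-6))
    stop("rows of the dispersal matrix must sum to 1")
  M <- M / rs
  step <- M
  acc <- M
  if (generations > 1) {
    for (g in 2:generations) {
      step <- step %*% M
      step <- step / rowSums(step)
      if (mode == "cumulative") acc <- acc + step
    }
  }
  C <- if (mode == "power") step else acc / generations
  asym <- NULL
  if (!is.null(region)) {
    r <- if (is.character(region)) rownames(C) %in% region else
      region[habitat]
    if (!any(r) || all(r))
      stop("region must split the habitat sites into two non-empty parts")
    outward <- sum(C[r, !r, drop = FALSE])
    inward <- sum(C[!r, r, drop = FALSE])
    asym <- list(outward = outward, inward = inward,
                 ratio = outward / inward)
  }
  list(C = C, asymmetry = asym, mode = mode, generations = generations)
}

#' Heatmap of a connectivity matrix
#'
#' Displays the matrix with the source-in-columns, destination-in-rows
#' convention used for seascape connectivity figures (the internal
#' representation has rows as sources, so the matrix is transposed for
#' display). Uses \pkg{pheatmap} when available, otherwise
#' \code{\link[stats]{heatmap}}.
#'
#' @param C connectivity matrix from [multigenConnectivity()] (rows =
#'   source).
#' @param ... passed to the heatmap engine.
#' @return invisibly, the displayed (transposed) matrix.
#' @export
connectivityHeatmap <- function(C, ...) {
  D <- t(C) # columns = source, rows = destination
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(D, cluster_rows = FALSE, cluster_cols = FALSE, ...)
  } else {
    stats::heatmap(D, Rowv = NA, Colv = NA, scale = "none", ...)
  }
  invisible(D)
}
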