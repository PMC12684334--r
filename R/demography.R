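# Two-population demographic inference on the folded joint SFS: the
# scenario registry (22 models in the SI / IM / AM / SC families),
# expected spectra from the structured-coalescent engine, composite
# Poisson likelihood fitting with a three-step optimisation, AIC
# comparison, and conversion to biological units.

.PAR_ORDER <- c("N1", "N2", "Na", "Ts", "Tm", "m12", "m21",
                "b1", "b2", "hrf", "Q", "mef", "P")

.PAR_BOUNDS <- list(
  N1 = c(0.05, 20), N2 = c(0.05, 20),
  Ts = c(0.01, 10), Tfrac = c(0.02, 0.98),
  m12 = c(0.01, 20), m21 = c(0.01, 20),
  b1 = c(0.01, 10), b2 = c(0.01, 10),
  hrf = c(0.01, 1), Q = c(0.05, 0.95),
  mef = c(1e-3, 1), P = c(0.05, 0.95))

.makeModel <- function(base, growth = FALSE, twoN = FALSE, twoM = FALSE) {
  name <- paste0(base,
                 if (twoN) "2N" else "", if (twoM) "2m" else "",
                 if (growth) "G" else "")
  params <- c("N1", "N2", "Ts")
  if (base %in% c("IM", "AM", "SC")) params <- c(params, "m12", "m21")
  if (base %in% c("AM", "SC")) params <- c(params, "Tfrac")
  if (twoN) params <- c(params, "hrf", "Q")
  if (twoM) params <- c(params, "mef", "P")
  if (growth) params <- c(params, "b1", "b2")
  lower <- vapply(params, function(p) .PAR_BOUNDS[[p]][1], numeric(1))
  upper <- vapply(params, function(p) .PAR_BOUNDS[[p]][2], numeric(1))
  new("DemographicModel", name = name, base = base, growth = growth,
      twoN = twoN, twoM = twoM, params = params,
      lower = lower, upper = upper)
}

#' Registry of the 22 two-population divergence scenarios
#'
#' Four base histories - strict isolation (SI), isolation with continuous
#' migration (IM), ancestral migration (AM) and secondary contact (SC) -
#' each with variants for asymmetric exponential growth (G), two
#' effective-size classes capturing linked selection (2N, proportion Q at
#' a reduced size factor), and, for the migration histories, two
#' migration-rate classes capturing barrier loci (2m, proportion P at a
#' reduced migration factor). SI has 4 variants (SI, SI2N, SIG, SI2NG);
#' IM, AM and SC have 6 each (base, G, 2N, 2m, 2NG, 2mG).
#'
#' Sizes and times are expressed relative to the ancestral population
#' (the reference for the spectrum scaling theta), following the usual
#' theta-scaled convention: a free ancestral size together with a free
#' scaling is an exact ridge on a joint SFS and cannot be estimated, so
#' the registry anchors the ancestral size at 1. Custom
#' \linkS4class{DemographicModel} objects may still free \code{Na}, the
#' size of the ancestral epoch spanning one split-time before the split
#' (see [expectedJointSFS()]).
#'
#' @return named list of 22 \linkS4class{DemographicModel} objects.
#' @export
modelRegistry <- function() {
  out <- list()
  for (base in c("SI", "IM", "AM", "SC")) {
    combos <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                   c(FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
    if (base != "SI")
      combos <- c(combos, list(c(FALSE, FALSE, TRUE),
                               c(TRUE, FALSE, TRUE)))
    for (cb in combos)
      out <- c(out, .makeModel(base, growth = cb[1], twoN = cb[2],
                               twoM = cb[3]))
  }
  names(out) <- vapply(out, function(m) m@name, character(1))
  out
}

.resolveModel <- function(model) {
  if (is(model, "DemographicModel")) return(model)
  reg <- modelRegistry()
  if (!model %in% names(reg))
    stop("unknown model '", model, "'; see modelRegistry()")
  reg[[model]]
}

.migMode <- function(model)
  switch(model@base, SI = 0L, IM = 1L, AM = 2L, SC = 3L)

# expand a named free-parameter vector into the fixed 13-slot engine
# vector, with neutral defaults for absent parameters
.fullParVector <- function(model, params) {
  params <- unlist(params)
  missing_p <- setdiff(model@params, names(params))
  if (length(missing_p))
    stop("missing parameter(s): ", paste(missing_p, collapse = ", "))
  full <- c(N1 = 1, N2 = 1, Na = 1, Ts = 1, Tm = 0, m12 = 0, m21 = 0,
            b1 = 1, b2 = 1, hrf = 1, Q = 0, mef = 1, P = 0)
  for (p in setdiff(names(params), "Tfrac")) full[p] <- params[[p]]
  if (model@base %in% c("AM", "SC"))
    full["Tm"] <- params[["Tfrac"]] * full["Ts"]
  unname(full[.PAR_ORDER])
}

#' Expected joint SFS under a demographic scenario
#'
#' Simulates \code{n_loci} independent genealogies under the
#' two-population structured coalescent with the model's events (split
#' at Ts, migration epochs, exponential growth since the split,
#' constant ancestral size) and accumulates the branch-length-weighted
#' spectrum: cell (i, j) collects total branch length subtending i
#' haploid samples from population 1 and j from population 2, which is
#' proportional to the expected site count under infinite-sites
#' mutation. The 2N / 2m variants are realised as locus-class mixtures
#' with weights Q and P. Absolute scale is irrelevant for fitting (the
#' optimal spectrum scaling is analytic).
#'
#' Units: time in 2 N_ref generations; sizes relative to N_ref; m12 is
#' the backward per-lineage rate of migration from population 1 into
#' population 2 per unit time.
#'
#' @param model a \linkS4class{DemographicModel} or model name.
#' @param params named numeric free parameters (see
#'   \code{model@params}).
#' @param n1,n2 diploid sample sizes.
#' @param n_loci Monte Carlo genealogies.
#' @param seed integer seed (fixing it gives common random numbers
#'   across parameter evaluations).
#' @param fold fold the spectrum?
#' @return a \linkS4class{JointSFS} (branch-length weights, not integer
#'   counts).
#' @export
expectedJointSFS <- function(model, params, n1, n2, n_loci = 2e4,
                             seed = 1L, fold = TRUE) {
  model <- .resolveModel(model)
  raw <- .coal_two_pop(2L * n1, 2L * n2, as.integer(n_loci),
                       .fullParVector(model, params), .migMode(model),
                       FALSE, 0, as.double(seed))
  s <- new("JointSFS", counts = raw$sfs, folded = FALSE,
           n1 = 2L * as.integer(n1), n2 = 2L * as.integer(n2),
           pops = c("pop1", "pop2"))
  if (fold) foldJointSFS(s) else s
}

#' Build the joint SFS from a genotype matrix
#'
#' Cell (i, j) counts the loci whose ALT allele is carried i times in
#' population 1 and j times in population 2. Loci with any missing
#' genotype in the selected individuals are dropped (reported by
#' message).
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param pop1,pop2 site labels (or individual ids) defining the two
#'   populations; they must not overlap.
#' @param fold return the folded spectrum?
#' @return a \linkS4class{JointSFS}.
#' @export
buildJointSFS <- function(m, pop1, pop2, fold = FALSE) {
  site <- siteOf(m)
  pick <- function(p) {
    hit <- names(site)[site %in% p]
    if (!length(hit)) hit <- intersect(p, colnames(m))
    hit
  }
  i1 <- pick(pop1); i2 <- pick(pop2)
  if (!length(i1) || !length(i2)) stop("both populations must be non-empty")
  if (length(intersect(i1, i2)))
    stop("population definitions overlap")
  d <- dosages(m)[c(i1, i2), , drop = FALSE]
  ok <- colSums(is.na(d)) == 0
  if (any(!ok)) message(sum(!ok), " loci with missing data dropped")
  d <- d[, ok, drop = FALSE]
  n1 <- 2L * length(i1); n2 <- 2L * length(i2)
  counts <- matrix(0, n1 + 1, n2 + 1)
  if (ncol(d) > 0) {
    c1 <- colSums(d[seq_along(i1), , drop = FALSE])
    c2 <- colSums(d[length(i1) + seq_along(i2), , drop = FALSE])
    tab <- table(factor(c1, levels = 0:n1), factor(c2, levels = 0:n2))
    counts <- matrix(as.numeric(tab), n1 + 1, n2 + 1)
  }
  s <- new("JointSFS", counts = counts, folded = FALSE, n1 = n1, n2 = n2,
           pops = c("pop1", "pop2"))
  if (fold) foldJointSFS(s) else s
}

#' Fold a joint SFS on the pooled minor allele
#'
#' Cell (i, j) is merged with its complement (2n1 - i, 2n2 - j), keyed on
#' the pooled minor-allele count; cells at exactly half the pooled total
#' are averaged once. Folding is idempotent and preserves the total
#' count. Folding an already folded spectrum returns it unchanged.
#'
#' @param s a \linkS4class{JointSFS}.
#' @return the folded \linkS4class{JointSFS}.
#' @export
foldJointSFS <- function(s) {
  if (s@folded) return(s)
  A <- s@counts
  n1 <- s@n1; n2 <- s@n2
  Tt <- n1 + n2
  R <- A[rev(seq_len(n1 + 1)), rev(seq_len(n2 + 1)), drop = FALSE]
  pooled <- outer(0:n1, 0:n2, "+")
  Fm <- matrix(0, n1 + 1, n2 + 1)
  lo <- pooled < Tt / 2
  eq <- pooled == Tt / 2
  Fm[lo] <- A[lo] + R[lo]
  Fm[eq] <- (A[eq] + R[eq]) / 2
  new("JointSFS", counts = Fm, folded = TRUE, n1 = n1, n2 = n2,
      pops = s@pops)
}

# cells entering the composite likelihood: drop the fixed-in-both
# corners and, for folded spectra, the structurally empty half
.sfsMask <- function(s) {
  n1 <- s@n1; n2 <- s@n2
  keep <- matrix(TRUE, n1 + 1, n2 + 1)
  keep[1, 1] <- FALSE
  keep[n1 + 1, n2 + 1] <- FALSE
  if (s@folded) {
    pooled <- outer(0:n1, 0:n2, "+")
    keep[pooled > (n1 + n2) / 2] <- FALSE
  }
  keep
}

# composite Poisson log-likelihood with analytic optimal scaling
.sfsLoglik <- function(obs, model_sfs) {
  keep <- .sfsMask(obs)
  o <- obs@counts[keep]
  e <- model_sfs@counts[keep]
  e <- pmax(e, 1e-10 * max(sum(e), 1))   # floor against MC zeros
  theta <- sum(o) / sum(e)
  lam <- theta * e
  list(loglik = sum(o * log(lam) - lam - lgamma(o + 1)), theta = theta)
}

.logitScale <- function(x, lo, hi) log((x - lo) / (hi - x))
.invLogitScale <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

#' Fit a demographic model to an observed joint SFS
#'
#' Composite Poisson likelihood over spectrum cells (fixed-in-both
#' corners masked), with the spectrum scaling profiled out analytically
#' as \eqn{\hat\theta = \sum obs / \sum model}. Each of \code{n_fits}
#' replicate fits runs a three-step search: (1) a broad log-uniform
#' random scan of the parameter box, (2) Nelder-Mead refinement from the
#' best point on a logit-transformed scale, (3) perturbation restarts
#' around the refined optimum. Expected spectra use common random
#' numbers (one engine seed per replicate fit) so the objective is
#' deterministic within a fit. The best replicate is returned.
#'
#' @param obs observed \linkS4class{JointSFS}.
#' @param model a \linkS4class{DemographicModel} or name.
#' @param n_fits replicate three-step fits (default 20).
#' @param seed integer seed.
#' @param n_loci_mc Monte Carlo genealogies per spectrum evaluation.
#' @param n_random random-scan points in step 1.
#' @param maxit Nelder-Mead iteration caps for steps 2 and 3.
#' @param n_perturb perturbation restarts in step 3.
#' @return a \linkS4class{FitResult}; the AIC counts the free model
#'   parameters plus one for the scaling.
#' @export
fitDemography <- function(obs, model, n_fits = 20, seed = 1L,
                          n_loci_mc = 2e4, n_random = 30,
                          maxit = c(120, 60), n_perturb = 2) {
  model <- .resolveModel(model)
  if (obs@folded != TRUE && obs@folded != FALSE)
    stop("invalid folded flag")
  n1 <- obs@n1 / 2; n2 <- obs@n2 / 2
  lo <- model@lower; hi <- model@upper
  np <- length(model@params)
  set.seed(as.integer(seed))
  fit_seeds <- sample.int(2^30, n_fits)

  objective <- function(par_named, engine_seed) {
    e <- expectedJointSFS(model, par_named, n1, n2, n_loci = n_loci_mc,
                          seed = engine_seed, fold = obs@folded)
    .sfsLoglik(obs, e)
  }

  best <- NULL
  for (f in seq_len(n_fits)) {
    es <- fit_seeds[f]
    # step 1: broad log-uniform scan
    set.seed(es)
    cand <- replicate(n_random, {
      x <- exp(runif(np, log(lo), log(hi)))
      pmin(pmax(x, lo * 1.0001), hi * 0.9999)
    })
    if (np == 1) cand <- matrix(cand, nrow = 1)
    rownames(cand) <- model@params
    lls <- apply(cand, 2, function(x)
      objective(setNames(x, model@params), es)$loglik)
    # step 2: Nelder-Mead on the logit-of-box scale from the best points
    fn <- function(z) {
      x <- setNames(.invLogitScale(z, lo, hi), model@params)
      -objective(x, es)$loglik
    }
    starts <- cand[, order(lls, decreasing = TRUE)[seq_len(
      min(3, ncol(cand)))], drop = FALSE]
    o <- NULL
    for (sidx in seq_len(ncol(starts))) {
      z0 <- .logitScale(pmin(pmax(starts[, sidx], lo * 1.001),
                             hi * 0.999), lo, hi)
      oi <- optim(z0, fn, method = "Nelder-Mead",
                  control = list(maxit = maxit[1]))
      if (is.null(o) || oi$value < o$value) o <- oi
    }
    # step 3: perturbation restarts around the refined optimum
    for (r in seq_len(n_perturb)) {
      zr <- o$par + rnorm(np, 0, 0.5)
      or <- optim(zr, fn, method = "Nelder-Mead",
                  control = list(maxit = maxit[2]))
      if (or$value < o$value) o <- or
    }
    par_f <- setNames(.invLogitScale(o$par, lo, hi), model@params)
    res <- objective(par_f, es)
    if (!is.finite(res$loglik)) next
    if (is.null(best) || res$loglik > best$loglik)
      best <- list(par = par_f, loglik = res$loglik, theta = res$theta)
  }
  if (is.null(best)) stop("all replicate fits were non-finite; check the ",
                          "observed spectrum and model bounds")
  k <- np + 1L # + analytic scaling
  new("FitResult", model = model, par = best$par, theta = best$theta,
      loglik = best$loglik, AIC = 2 * k - 2 * best$loglik, k = k,
      nFits = as.integer(n_fits), bio = list())
}

#' Rank fitted models by AIC with a conservative strength flag
#'
#' Models are sorted by AIC; a model is flagged \code{stronger} only when
#' its AIC beats its best competitor by more than 10 (the conservative
#' \eqn{\Delta AIC < -10} rule).
#'
#' @param fits list of \linkS4class{FitResult}.
#' @return data.frame: model, k, loglik, AIC, deltaAIC (against the best
#'   competitor), stronger.
#' @export
compareModels <- function(fits) {
  if (!length(fits)) stop("need at least one fit")
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f@model@name, k = f@k, loglik = f@loglik,
               AIC = f@AIC)))
  df$deltaAIC <- vapply(seq_len(nrow(df)), function(i)
    if (nrow(df) == 1) NA_real_ else df$AIC[i] - min(df$AIC[-i]),
    numeric(1))
  df$stronger <- !is.na(df$deltaAIC) & df$deltaAIC < -10
  df <- df[order(df$AIC), ]
  rownames(df) <- NULL
  df
}

#' Convert fitted parameters to biological units
#'
#' Anchors the reference size from the fitted spectrum scaling,
#' \eqn{N_{ref} = \hat\theta / (4 \mu L)} with per-base mutation rate
#' \eqn{\mu} and effective sequence length L, then converts: sizes to
#' diploid individuals (\eqn{N_i N_{ref}}), times to years
#' (\eqn{t \cdot 2 N_{ref} \cdot} generation time), and migration to
#' per-generation rates (\eqn{m / (2 N_{ref})}). Defaults: 4-year
#' generations and \eqn{\mu = 10^{-8}} per base per generation.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param L effective sequence length (bases) behind the spectrum.
#' @param mu per-base per-generation mutation rate.
#' @param gen_time generation time in years.
#' @return the fit with its \code{bio} slot filled (list: Nref, sizes,
#'   times_years, migration_per_gen, constants).
#' @export
toBiologicalUnits <- function(fit, L, mu = 1e-8, gen_time = 4) {
  Nref <- fit@theta / (4 * mu * L)
  par <- fit@par
  sizes <- par[names(par) %in% c("N1", "N2", "Na")] * Nref
  tm <- par[names(par) == "Ts"] * 2 * Nref * gen_time
  if ("Tfrac" %in% names(par))
    tm <- c(tm, Tm_years = unname(par[["Tfrac"]] * par[["Ts"]]) *
              2 * Nref * gen_time)
  mig <- par[names(par) %in% c("m12", "m21")] / (2 * Nref)
  fit@bio <- list(Nref = Nref, sizes = sizes, times_years = tm,
                  migration_per_gen = mig,
                  constants = list(L = L, mu = mu, gen_time = gen_time))
  fit
}

#' Convert biological parameters back to coalescent units
#'
#' Inverse of [toBiologicalUnits()] given the same constants; useful for
#' checking that the conversion round-trips.
#'
#' @param bio the \code{bio} list produced by [toBiologicalUnits()].
#' @return named list of coalescent-unit values (sizes relative to Nref,
#'   times in 2 Nref generations, migration per 2 Nref generations) plus
#'   theta.
#' @export
fromBiologicalUnits <- function(bio) {
  Nref <- bio$Nref
  cst <- bio$constants
  list(theta = 4 * Nref * cst$mu * cst$L,
       sizes = bio$sizes / Nref,
       times = bio$times_years / (2 * Nref * cst$gen_time),
       migration = bio$migration_per_gen * 2 * Nref)
}

#' Read / write a joint SFS as plain text
#'
#' One header line (\code{n1 n2 folded}) followed by the count matrix.
#'
#' @param s a \linkS4class{JointSFS}; \code{path} a file path.
#' @param path file path.
#' @return \code{readJointSFS} a \linkS4class{JointSFS};
#'   \code{writeJointSFS} the path, invisibly.
#' @export
writeJointSFS <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n1=%d n2=%d folded=%d", s@n1, s@n2,
                     as.integer(s@folded)), con)
  write.table(s@counts, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeJointSFS
#' @export
readJointSFS <- function(path) {
  hdr <- readLines(path, n = 1)
  gv <- function(k) as.integer(sub(sprintf(".*%s=(\\d+).*", k), "\\1", hdr))
  counts <- as.matrix(read.table(path, skip = 1))
  dimnames(counts) <- NULL
  new("JointSFS", counts = counts, folded = gv("folded") == 1L,
      n1 = gv("n1"), n2 = gv("n2"), pops = c("pop1", "pop2"))
}
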