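# Independent oracle implementations used across the suite. These apply
# the defining formulas literally (loops, no shared code with the
# package internals they check).

# proportion-of-allelic-differences distance by double loop
oracle_distance <- function(d) {
  n <- nrow(d)
  out <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ok <- !is.na(d[a, ]) & !is.na(d[b, ])
    out[a, b] <- out[b, a] <- sum(abs(d[a, ok] - d[b, ok])) / (2 * sum(ok))
  }
  out
}

# I_A and r_bar_d by literal enumeration of pairs and loci
oracle_rbar <- function(d) {
  n <- nrow(d); L <- ncol(d)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  dl <- matrix(0, np, L)
  for (p in seq_len(np)) for (l in seq_len(L))
    dl[p, l] <- abs(d[pairs[1, p], l] - d[pairs[2, p], l])
  D <- rowSums(dl)
  popvar <- function(x) mean((x - mean(x))^2)
  VO <- popvar(D)
  vl <- apply(dl, 2, popvar)
  VE <- sum(vl)
  denom <- 0
  for (l in seq_len(L - 1)) for (m in (l + 1):L)
    denom <- denom + sqrt(vl[l] * vl[m])
  c(Ia = VO / VE - 1, rbarD = (VO - VE) / (2 * denom))
}

# Hudson Fst from genotype dosages, written out directly
oracle_hudson_fst <- function(d1, d2) {
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(d1)); n2 <- 2 * colSums(!is.na(d2))
  keep <- n1 > 1 & n2 > 1
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# ordered missingness/monomorphism filter, recounted from scratch
oracle_filter <- function(d, thr_l, thr_i) {
  repeat {
    changed <- FALSE
    if (ncol(d) && nrow(d)) {
      keep <- colMeans(is.na(d)) <= thr_l
      if (!all(keep)) { d <- d[, keep, drop = FALSE]; changed <- TRUE }
    }
    if (nrow(d) && ncol(d)) {
      keep <- rowMeans(is.na(d)) <= thr_i
      if (!all(keep)) { d <- d[keep, , drop = FALSE]; changed <- TRUE }
    }
    if (ncol(d) && nrow(d)) {
      poly <- apply(d, 2, function(x) {
        x <- x[!is.na(x)]
        length(x) > 0 && !(all(x == 0) || all(x == 2))
      })
      if (!all(poly)) { d <- d[, poly, drop = FALSE]; changed <- TRUE }
    }
    if (!changed) return(d)
  }
}

# random SNPMatrix fixture
random_snp <- function(n, L, miss = 0, seed = 1, sites = "site1") {
  set.seed(seed)
  p <- runif(L, 0.1, 0.9)
  g <- matrix(rbinom(n * L, 2L, rep(p, each = n)), n)
  storage.mode(g) <- "integer"
  if (miss > 0) g[matrix(runif(n * L) < miss, n)] <- NA_integer_
  rownames(g) <- sprintf("i%03d", seq_len(n))
  SNPMatrix(g, site = rep_len(sites, n))
}

# best label-matching accuracy between a clustering and truth labels
match_accuracy <- function(cluster, truth) {
  cl <- as.integer(factor(cluster)); tr <- as.integer(factor(truth))
  k <- max(tr)
  perms <- combinat_perms(seq_len(max(cl)))
  best <- 0
  for (p in perms) best <- max(best, mean(p[cl] == tr))
  best
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}
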