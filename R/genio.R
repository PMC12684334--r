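# Genotype ingestion, export and missingness filtering.

#' Read a VCF into a SNPMatrix
#'
#' Parses a VCF (v4.x, GT field) with \pkg{vcfR} and converts genotypes to
#' ALT-allele dosages. Multi-allelic and non-SNP records are skipped with a
#' message reporting the count; \code{./.} becomes missing.
#'
#' @param path path to a VCF file.
#' @param site site label per sample: a character vector recycled over
#'   samples, or \code{NULL} to label every sample \code{"site1"}.
#' @return a \linkS4class{SNPMatrix}.
#' @seealso [writeSnpVcf()]
#' @export
readSnpVcf <- function(path, site = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  stop("VCF parse error in '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  if (any(!snp))
    message(sum(!snp), " multi-allelic or non-SNP record(s) skipped")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt_clean == "0/0"] <- 0L
  dos[gt_clean == "0/1" | gt_clean == "1/0"] <- 1L
  dos[gt_clean == "1/1"] <- 2L
  ids <- fx[snp, "ID"]
  bad_id <- is.na(ids) | ids == "."
  ids[bad_id] <- paste0(fx[snp, "CHROM"], ":", fx[snp, "POS"])[bad_id]
  d <- t(dos)
  rownames(d) <- colnames(gt)
  colnames(d) <- ids
  if (is.null(site)) site <- "site1"
  SNPMatrix(d, site = rep_len(site, nrow(d)))
}

#' Write a SNPMatrix as a minimal VCF
#'
#' Emits a GT-only unphased VCF v4.2 (CHROM \code{"1"}, sequential POS,
#' locus ids in ID, REF/ALT placeholders A/T). Round-trips through
#' [readSnpVcf()] exactly on dosages, ids and missingness.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSnpVcf <- function(m, path) {
  d <- dosages(m)
  gt <- matrix("./.", ncol(d), nrow(d))
  codes <- c("0/0", "0/1", "1/1")
  for (k in 0:2) gt[t(d) == k] <- codes[k + 1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(d)),
                     collapse = "\t")), con)
  body <- cbind("1", seq_len(ncol(d)), colnames(d), "A", "T", ".", ".",
                ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read / write a dosage TSV
#'
#' TSV with header \code{individual_id}, \code{site}, then one column per
#' locus; missing cells are \code{NA}.
#'
#' @param m a \linkS4class{SNPMatrix}; \code{path} a file path.
#' @param path file path.
#' @return \code{readDosageTsv} a \linkS4class{SNPMatrix};
#'   \code{writeDosageTsv} the path, invisibly.
#' @export
writeDosageTsv <- function(m, path) {
  d <- dosages(m)
  df <- data.frame(individual_id = rownames(d), site = unname(siteOf(m)),
                   d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDosageTsv
#' @export
readDosageTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = c("character", "character"))
  d <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- df$individual_id
  SNPMatrix(d, site = df$site)
}

#' Filter a SNPMatrix for missingness and monomorphism
#'
#' Iterates three rules to a fixed point: (1) drop loci with missingness
#' strictly above \code{max_locus_missing}; (2) drop individuals with
#' missingness strictly above \code{max_ind_missing}; (3) drop loci that
#' are no longer polymorphic (only one allele observed). The fixed-point
#' loop makes the operation idempotent.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param max_locus_missing,max_ind_missing missingness thresholds
#'   (default 0.05; strictly-greater-than comparison).
#' @return list with \code{snp} (filtered \linkS4class{SNPMatrix}) and
#'   \code{report} (list: \code{loci_removed}, \code{individuals_removed}
#'   data.frames with reasons, and the thresholds used).
#' @export
filterSNPMatrix <- function(m, max_locus_missing = 0.05,
                            max_ind_missing = 0.05) {
  d <- dosages(m)
  site <- unname(siteOf(m))
  loci_rm <- data.frame(id = character(), reason = character(),
                        pass = integer())
  ind_rm <- data.frame(id = character(), reason = character(),
                       pass = integer())
  pass <- 0L
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    if (ncol(d) > 0 && nrow(d) > 0) {
      lm_ <- colMeans(is.na(d))
      drop <- lm_ > max_locus_missing
      if (any(drop)) {
        loci_rm <- rbind(loci_rm, data.frame(
          id = colnames(d)[drop], reason = "missingness", pass = pass))
        d <- d[, !drop, drop = FALSE]
        changed <- TRUE
      }
    }
    if (nrow(d) > 0 && ncol(d) > 0) {
      im <- rowMeans(is.na(d))
      drop <- im > max_ind_missing
      if (any(drop)) {
        ind_rm <- rbind(ind_rm, data.frame(
          id = rownames(d)[drop], reason = "missingness", pass = pass))
        site <- site[!drop]
        d <- d[!drop, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (ncol(d) > 0 && nrow(d) > 0) {
      mono <- apply(d, 2, function(x) {
        x <- x[!is.na(x)]
        length(x) == 0 || all(x == 0) || all(x == 2)
      })
      if (any(mono)) {
        loci_rm <- rbind(loci_rm, data.frame(
          id = colnames(d)[mono], reason = "monomorphic", pass = pass))
        d <- d[, !mono, drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (nrow(d) == 0 || ncol(d) == 0)
    stop("filtering removed everything (",
         nrow(ind_rm), " individuals, ", nrow(loci_rm), " loci)")
  list(snp = SNPMatrix(d, site = site),
       report = list(loci_removed = loci_rm, individuals_removed = ind_rm,
                     max_locus_missing = max_locus_missing,
                     max_ind_missing = max_ind_missing, passes = pass))
}

#' Write a filter report as JSON
#'
#' @param report the \code{report} element of [filterSNPMatrix()] output.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Heterozygosity-versus-missingness diagnostic
#'
#' Per-individual missingness and heterozygosity (fraction of non-missing
#' genotypes that are heterozygous), used to spot individuals whose
#' heterozygosity is driven by the amount of missing data. Individuals
#' beyond \code{k} median absolute deviations from the median
#' heterozygosity are flagged. An all-missing individual gets
#' missingness 1 and undefined (NA) heterozygosity.
#'
#' @param m a \linkS4class{SNPMatrix}.
#' @param k MAD multiplier for flagging (default 3).
#' @return data.frame: individual, site, missingness, heterozygosity,
#'   flagged.
#' @export
hetMissingDiag <- function(m, k = 3) {
  d <- dosages(m)
  miss <- rowMeans(is.na(d))
  het <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]; x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x == 1L)
  }, numeric(1))
  md <- median(het, na.rm = TRUE)
  s <- mad(het, na.rm = TRUE)
  flagged <- !is.na(het) & s > 0 & abs(het - md) > k * s
  data.frame(individual = rownames(d), site = unname(siteOf(m)),
             missingness = miss, heterozygosity = het, flagged = flagged)
}
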