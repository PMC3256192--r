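#' Read a genotype dataset from a tab-separated file
#'
#' Expected dialect: UTF-8, tab-separated, header
#' `sample_id<TAB>status<TAB><factor...>`, status coded 0/1.  An optional
#' `group` column carries the stratum tag and columns prefixed `cov_` are
#' read back as covariates (the writer uses the same convention).
#'
#' @param path File path.
#' @param factors Optional list of [factor_definition()] objects declaring
#'   the factor columns; if omitted, definitions are inferred from the data
#'   (values within `{0,1,2}` imply a SNP).
#' @param missing_code String marking a missing genotype (default `"NA"`).
#' @param id_col,status_col,group_col Column names for subject id, status
#'   and (optional) group.
#' @return A `genotype_dataset`.
#' @export
read_genotypes_tsv <- function(path, factors = NULL, missing_code = "NA",
                               id_col = "sample_id", status_col = "status",
                               group_col = "group") {
  raw <- tryCatch(
    read.delim(path, colClasses = "character", check.names = FALSE,
               na.strings = NULL, fill = FALSE, blank.lines.skip = FALSE),
    error = function(e) stop(sprintf("parse error in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  need <- c(id_col, status_col)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  status_chr <- raw[[status_col]]
  if (!all(status_chr %in% c("0", "1"))) {
    bad <- setdiff(unique(status_chr), c("0", "1"))
    stop(sprintf("status column must be coded 0/1; found: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  group <- if (group_col %in% names(raw)) raw[[group_col]] else NULL
  cov_cols <- grep("^cov_", names(raw), value = TRUE)
  covariates <- NULL
  if (length(cov_cols)) {
    covariates <- as.data.frame(
      lapply(raw[cov_cols], type.convert, as.is = TRUE),
      optional = TRUE
    )
    names(covariates) <- sub("^cov_", "", cov_cols)
  }
  fac_cols <- setdiff(names(raw), c(id_col, status_col, group_col, cov_cols))
  if (!length(fac_cols)) stop("no factor columns found", call. = FALSE)

  if (!is.null(factors)) {
    fnames <- vapply(factors, `[[`, character(1), "name")
    miss <- setdiff(fnames, fac_cols)
    if (length(miss)) {
      stop(sprintf("declared factor(s) absent from file: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    fac_cols <- fnames
  }

  n <- nrow(raw)
  values <- matrix(NA_integer_, n, length(fac_cols),
                   dimnames = list(NULL, fac_cols))
  defs <- vector("list", length(fac_cols))
  for (j in seq_along(fac_cols)) {
    col <- raw[[fac_cols[j]]]
    def <- if (is.null(factors)) NULL else factors[[j]]
    mc <- if (is.null(def)) missing_code else def$missing_code
    is_miss <- col == mc
    v <- suppressWarnings(as.integer(col))
    if (any(is.na(v) & !is_miss)) {
      stop(sprintf("factor '%s' contains non-integer codes", fac_cols[j]),
           call. = FALSE)
    }
    v[is_miss] <- NA_integer_
    if (is.null(def)) {
      obs <- sort(unique(v[!is.na(v)]))
      def <- if (length(obs) == 0L || all(obs %in% 0:2)) {
        factor_definition(fac_cols[j], "snp", missing_code = mc)
      } else {
        factor_definition(fac_cols[j], "environment", levels = obs,
                          missing_code = mc)
      }
    } else if (any(!is.na(v) & !(v %in% def$levels))) {
      bad <- setdiff(unique(v[!is.na(v)]), def$levels)
      stop(sprintf("factor '%s': undeclared category code(s) %s",
                   fac_cols[j], paste(bad, collapse = ", ")), call. = FALSE)
    }
    values[, j] <- v
    defs[[j]] <- def
  }
  genotype_dataset(values, status = as.integer(status_chr),
                   subjects = raw[[id_col]], group = group,
                   factors = defs, covariates = covariates)
}

#' Write a genotype dataset as a tab-separated file
#'
#' Inverse of [read_genotypes_tsv()]: `write` then `read` is the identity on
#' valid datasets.  Covariate columns are prefixed `cov_`.
#'
#' @param ds A `genotype_dataset`.
#' @param path Output file path.
#' @param missing_code String written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(ds, path, missing_code = "NA") {
  validate_dataset(ds)
  vals <- ds$values
  chr <- matrix(as.character(vals), nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  chr[is.na(vals)] <- missing_code
  out <- data.frame(sample_id = ds$subjects, status = ds$status,
                    group = ds$group, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(ds$covariates)) {
    cv <- ds$covariates
    names(cv) <- paste0("cov_", names(cv))
    out <- cbind(out, cv)
  }
  out <- cbind(out, as.data.frame(chr, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PLINK PED/MAP text files
#'
#' Biallelic genotypes given as allele pairs are recoded to 0/1/2 by counting
#' copies of the minor allele (the less frequent allele in the file; on a tie
#' the lexicographically smaller allele is taken as the variant).  The PLINK
#' missing genotype `0 0` becomes `NA`; phenotype must be coded 1
#' (control) / 2 (case).
#'
#' @param ped Path to the space-delimited PED file.
#' @param map Path to the MAP file (3 or 4 columns; SNP name in column 2).
#' @return A `genotype_dataset`.
#' @export
read_ped_map <- function(ped, map) {
  mp <- read.table(map, colClasses = "character")
  if (!ncol(mp) %in% c(3L, 4L)) {
    stop("MAP file must have 3 or 4 columns", call. = FALSE)
  }
  snps <- mp[[2]]
  pd <- read.table(ped, colClasses = "character")
  if (ncol(pd) != 6L + 2L * length(snps)) {
    stop(sprintf(
      "PED format error: expected %d columns (6 + 2 alleles per locus), found %d",
      6L + 2L * length(snps), ncol(pd)), call. = FALSE)
  }
  pheno <- pd[[6]]
  if (!all(pheno %in% c("1", "2"))) {
    stop("PED phenotype column must be coded 1 (control) / 2 (case)",
         call. = FALSE)
  }
  n <- nrow(pd)
  values <- matrix(NA_integer_, n, length(snps), dimnames = list(NULL, snps))
  for (j in seq_along(snps)) {
    a1 <- pd[[6L + 2L * j - 1L]]
    a2 <- pd[[6L + 2L * j]]
    alleles <- setdiff(unique(c(a1, a2)), "0")
    if (length(alleles) > 2L) {
      stop(sprintf("locus '%s' has %d alleles; biallelic loci required",
                   snps[j], length(alleles)), call. = FALSE)
    }
    counts <- table(factor(c(a1, a2), levels = alleles))
    minor <- if (length(alleles) == 0L) NA_character_
             else if (length(alleles) == 1L) alleles
             else {
               tied <- counts == min(counts)
               if (all(tied)) min(alleles) else names(counts)[which.min(counts)]
             }
    miss <- a1 == "0" | a2 == "0"
    g <- (a1 == minor) + (a2 == minor)
    g[miss] <- NA_integer_
    values[, j] <- as.integer(g)
  }
  genotype_dataset(values, status = as.integer(pheno == "2"),
                   subjects = pd[[2]])
}

#' Exclude subjects with many missing genotypes
#'
#' Removes subjects whose number of missing factor values exceeds
#' `max_missing` (the cohort protocol dropped individuals with more than 5
#' missing values before interaction analysis).  The input dataset is left
#' untouched.
#'
#' @param ds A `genotype_dataset`.
#' @param max_missing Largest tolerated per-subject missing count (default 5;
#'   a subject with exactly `max_missing` missing values is retained).
#' @return A list with components `dataset` (the filtered dataset) and
#'   `report` (a `missingness_report` with per-subject and per-factor missing
#'   counts and the excluded subject ids).
#' @export
exclude_high_missing <- function(ds, max_missing = 5L) {
  validate_dataset(ds)
  stopifnot(max_missing >= 0L)
  per_subject <- rowSums(is.na(ds$values))
  names(per_subject) <- ds$subjects
  per_factor <- colSums(is.na(ds$values))
  drop <- per_subject > max_missing
  report <- structure(
    list(per_subject = per_subject, per_factor = per_factor,
         excluded = ds$subjects[drop], max_missing = as.integer(max_missing)),
    class = "missingness_report"
  )
  list(dataset = ds_rows(ds, !drop), report = report)
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("<missingness_report> %d subject(s) excluded (> %d missing values)\n",
              length(x$excluded), x$max_missing))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
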