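#' Construct a case-control genotype dataset
#'
#' The universal input container: a subjects x factors matrix of categorical
#' level codes (`NA` = missing), a binary disease status, a free-text group
#' tag per subject, and optional covariates such as age and gender.
#'
#' @param values Integer matrix, subjects in rows, factors in columns;
#'   column names are factor names; `NA` marks missing genotypes.
#' @param status Integer vector, 1 = case, 0 = control.
#' @param subjects Optional subject identifiers (default `S1`, `S2`, ...).
#' @param group Optional per-subject stratum tag; defaults to `"case"` /
#'   `"control"` according to status.  See [mpn_groups()].
#' @param factors Optional list of [factor_definition()] objects, one per
#'   column.  If omitted, columns whose values lie in `{0,1,2}` are declared
#'   SNPs; other integer columns become environmental factors with their
#'   observed levels.
#' @param covariates Optional data.frame of per-subject covariates.
#' @return An object of class `genotype_dataset`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), 2, 2, dimnames = list(NULL, c("A", "B")))
#' genotype_dataset(g, status = c(1L, 0L))
#' @export
genotype_dataset <- function(values, status, subjects = NULL, group = NULL,
                             factors = NULL, covariates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  }
  status <- as.integer(status)
  subjects <- as.character(subjects %||% paste0("S", seq_len(n)))
  group <- as.character(group %||% ifelse(status == 1L, "case", "control"))
  if (is.null(factors)) {
    factors <- lapply(colnames(values), function(nm) {
      obs <- unique(values[, nm])
      obs <- sort(obs[!is.na(obs)])
      if (all(obs %in% 0:2)) {
        factor_definition(nm, "snp")
      } else {
        factor_definition(nm, "environment", levels = obs)
      }
    })
  }
  ds <- structure(
    list(subjects = subjects, status = status, group = group,
         factors = factors, values = values, covariates = covariates),
    class = "genotype_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a genotype dataset
#'
#' Checks the structural invariants: matching dimensions, binary status,
#' and that every non-missing value is a declared level of its factor.
#'
#' @param ds A `genotype_dataset`.
#' @return `ds`, invisibly; stops on violation.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$values)
  if (length(ds$subjects) != n || length(ds$status) != n || length(ds$group) != n) {
    stop("subjects, status and group must match the number of value rows",
         call. = FALSE)
  }
  if (length(ds$factors) != ncol(ds$values)) {
    stop("one factor definition required per value column", call. = FALSE)
  }
  if (n > 0 && !all(ds$status %in% c(0L, 1L))) {
    stop("status must be coded 0 (control) / 1 (case)", call. = FALSE)
  }
  fnames <- vapply(ds$factors, `[[`, character(1), "name")
  if (!identical(fnames, colnames(ds$values))) {
    stop("factor definition names must match value column names", call. = FALSE)
  }
  for (j in seq_along(ds$factors)) {
    v <- ds$values[, j]
    bad <- !is.na(v) & !(v %in% ds$factors[[j]]$levels)
    if (any(bad)) {
      stop(sprintf("factor '%s' contains undeclared level(s): %s",
                   fnames[j], paste(unique(v[bad]), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!is.null(ds$covariates) && nrow(ds$covariates) != n) {
    stop("covariates must have one row per subject", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d subjects (%d cases / %d controls), %d factors\n",
              nrow(x$values), sum(x$status == 1L), sum(x$status == 0L),
              ncol(x$values)))
  kinds <- vapply(x$factors, `[[`, character(1), "kind")
  cat(sprintf("  factors: %d snp, %d environment; missing cells: %d\n",
              sum(kinds == "snp"), sum(kinds == "environment"),
              sum(is.na(x$values))))
  if (length(unique(x$group)) > 1L) {
    cat("  groups: ", paste(names(table(x$group)), table(x$group),
                            sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Names of the factors in a dataset
#' @param ds A `genotype_dataset`.
#' @param kind Optionally restrict to `"snp"` or `"environment"` factors.
#' @return Character vector of factor names.
#' @export
factor_names <- function(ds, kind = NULL) {
  nm <- colnames(ds$values)
  if (!is.null(kind)) {
    kinds <- vapply(ds$factors, `[[`, character(1), "kind")
    nm <- nm[kinds == kind]
  }
  nm
}

## Row subset preserving all parallel components.
ds_rows <- function(ds, i) {
  structure(
    list(subjects = ds$subjects[i], status = ds$status[i], group = ds$group[i],
         factors = ds$factors,
         values = ds$values[i, , drop = FALSE],
         covariates = if (is.null(ds$covariates)) NULL
                      else ds$covariates[i, , drop = FALSE]),
    class = "genotype_dataset"
  )
}

ds_factor <- function(ds, name) {
  j <- match(name, colnames(ds$values))
  if (is.na(j)) stop(sprintf("unknown factor '%s'", name), call. = FALSE)
  ds$factors[[j]]
}
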