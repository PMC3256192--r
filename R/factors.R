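#' Define a categorical risk factor
#'
#' A factor is either a biallelic SNP, coded 0 (homozygous wild type),
#' 1 (heterozygous), 2 (homozygous variant), or a categorical environmental
#' exposure such as tobacco habit.  Genotype labels (e.g. `"Arg/His"`) can be
#' attached so that tables are reported in the field's amino-acid notation
#' while all arithmetic uses the ordinal codes.
#'
#' @param name Factor name, e.g. `"SULT1A1_Arg213His"` or `"habit"`.
#' @param kind `"snp"` or `"environment"`.
#' @param levels Integer level codes.  SNPs must have exactly the three
#'   genotype codes; environmental factors may have any number of levels.
#' @param labels Optional character labels, one per level.
#' @param missing_code Sentinel string marking a missing value in text files.
#' @return An object of class `factor_definition`.
#' @examples
#' factor_definition("SULT1A1_Arg213His", "snp",
#'                   labels = c("Arg/Arg", "Arg/His", "His/His"))
#' @export
factor_definition <- function(name, kind = c("snp", "environment"),
                              levels = NULL, labels = NULL,
                              missing_code = "NA") {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a non-empty string", call. = FALSE)
  }
  if (is.null(levels)) {
    if (kind == "snp") levels <- 0:2
    else stop("'levels' must be supplied for environment factors", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (anyNA(levels)) stop("factor levels must be integer codes", call. = FALSE)
  if (anyDuplicated(levels)) stop("factor levels must be distinct", call. = FALSE)
  if (kind == "snp" && length(levels) != 3L) {
    stop("SNP factors have exactly 3 genotype levels (0/1/2)", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(levels)) {
      stop("'labels' must have one entry per level", call. = FALSE)
    }
  }
  if (as.character(missing_code) %in% as.character(levels)) {
    stop("'missing_code' must not coincide with a declared level", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, levels = levels, labels = labels,
         missing_code = as.character(missing_code)),
    class = "factor_definition"
  )
}

#' @export
print.factor_definition <- function(x, ...) {
  lv <- if (is.null(x$labels)) x$levels else paste0(x$levels, "=", x$labels)
  cat(sprintf("<%s factor> %s: %s\n", x$kind, x$name, paste(lv, collapse = ", ")))
  invisible(x)
}

#' Tobacco-habit factor definition
#'
#' The habit exposure as recorded in the cohort: 0 = no habit, 1 = tobacco
#' only (chewing or smoking), 2 = tobacco plus alcohol.  With
#' `binary = TRUE` the exposure is collapsed to 0 = no tobacco,
#' 1 = any tobacco.
#'
#' @param name Column name, default `"habit"`.
#' @param binary Collapse to a two-level any-tobacco indicator.
#' @return A `factor_definition` of kind `"environment"`.
#' @export
habit_factor <- function(name = "habit", binary = FALSE) {
  if (binary) {
    factor_definition(name, "environment", levels = 0:1,
                      labels = c("no tobacco", "any tobacco"))
  } else {
    factor_definition(name, "environment", levels = 0:2,
                      labels = c("no habit", "only T", "T+A"))
  }
}

#' Cohort stratum tags
#'
#' Constants for the three case strata used throughout: cases with at least
#' one tobacco-related cancer inside the upper aerodigestive tract, cases
#' with tobacco-related cancers only outside it, and cancer-free controls.
#'
#' @return Named character vector of group tags.
#' @export
mpn_groups <- function() {
  c(inside = "UADT_inside", outside = "UADT_outside",
    none = "none_TRC", control = "control")
}
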