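#' Packaged genotype count panels
#'
#' The published genotype-by-status counts for the SNPs with significant
#' univariate effects, for the two tobacco-related-cancer case strata
#' (inside / outside the upper aerodigestive tract) against the common
#' control group.  Shipped as a plain TSV under `inst/extdata`.
#'
#' @return A named list (one entry per SNP) of 3x3 count matrices with
#'   columns `control`, `UADT_inside`, `UADT_outside` and genotype labels as
#'   row names.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "published_counts.tsv", package = "availmdr",
                      mustWork = TRUE)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  split_rows <- split(raw, factor(raw$snp, levels = unique(raw$snp)))
  lapply(split_rows, function(d) {
    d <- d[order(d$genotype), ]
    m <- as.matrix(d[, c("control", "UADT_inside", "UADT_outside")])
    rownames(m) <- d$label
    m
  })
}

#' Count panel for one packaged SNP and case stratum
#'
#' @param snp SNP name as listed by [published_counts()].
#' @param group Case stratum: `"UADT_inside"` or `"UADT_outside"`.
#' @return A `genotype_count_table` (control column + the stratum's cases).
#' @export
count_panel <- function(snp, group = c("UADT_inside", "UADT_outside")) {
  group <- match.arg(group)
  panels <- published_counts()
  if (!snp %in% names(panels)) {
    stop(sprintf("unknown panel '%s'; available: %s", snp,
                 paste(names(panels), collapse = ", ")), call. = FALSE)
  }
  m <- panels[[snp]]
  genotype_count_table(m[, "control"], m[, group], labels = rownames(m),
                       snp = snp, group = group)
}

#' Individual-level fixture reconstructed from packaged counts
#'
#' Delegates to [from_marginal_counts()]: the returned dataset's per-SNP
#' genotype-by-status tabulation reproduces the printed counts exactly.
#' With `snp = NULL` all packaged SNPs are combined; their genotyped totals
#' differ, so each SNP column is filled independently and the joint
#' distribution is synthetic (only marginals are published).
#'
#' @param snp SNP name, or `NULL` for all packaged panels.
#' @param group Case stratum tag.
#' @return A `genotype_dataset`.
#' @export
count_fixture <- function(snp = NULL,
                           group = c("UADT_inside", "UADT_outside")) {
  group <- match.arg(group)
  snps <- snp %||% names(published_counts())
  panels <- lapply(snps, count_panel, group = group)
  from_marginal_counts(panels, case_group = group)
}
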