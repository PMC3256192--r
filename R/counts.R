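#' Genotype-by-status count table for one SNP
#'
#' The unit of the published univariate tables: counts of the three genotypes
#' among controls and among cases of one stratum.
#'
#' @param control,case Length-3 non-negative counts for genotypes 0/1/2.
#' @param labels Optional genotype labels (e.g. `c("Arg/Arg","Arg/His","His/His")`).
#' @param snp Optional SNP name.
#' @param group Optional case-stratum tag.
#' @return A 3x2 integer matrix of class `genotype_count_table` with columns
#'   `control`, `case`.
#' @export
genotype_count_table <- function(control, case, labels = NULL, snp = NULL,
                                 group = NULL) {
  control <- as.integer(control); case <- as.integer(case)
  if (length(control) != 3L || length(case) != 3L) {
    stop("genotype counts must have length 3 (genotypes 0/1/2)", call. = FALSE)
  }
  if (anyNA(c(control, case)) || any(c(control, case) < 0L)) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  m <- cbind(control = control, case = case)
  rownames(m) <- labels %||% c("0", "1", "2")
  structure(m, class = c("genotype_count_table", "matrix"),
            snp = snp, group = group)
}

#' Tabulate one SNP by case-control status
#'
#' Counts non-missing genotypes among controls and among cases of the given
#' stratum (available-case: missing genotypes are simply left out).
#'
#' @param ds A `genotype_dataset`.
#' @param factor Name of a 3-level SNP factor.
#' @param case_group Optional group tag restricting the cases; controls are
#'   always all subjects with status 0.
#' @return A `genotype_count_table`.
#' @export
tabulate_genotypes <- function(ds, factor, case_group = NULL) {
  def <- ds_factor(ds, factor)
  if (def$kind != "snp") {
    stop(sprintf("'%s' is not a SNP factor", factor), call. = FALSE)
  }
  v <- ds$values[, factor]
  is_control <- ds$status == 0L
  is_case <- ds$status == 1L
  if (!is.null(case_group)) is_case <- is_case & ds$group %in% case_group
  cnt <- function(keep) {
    vapply(def$levels, function(l) sum(v[keep] == l, na.rm = TRUE), integer(1))
  }
  genotype_count_table(cnt(is_control), cnt(is_case), labels = def$labels,
                       snp = factor, group = case_group)
}

#' Build an individual-level dataset from printed marginal counts
#'
#' Reconstructs a dataset whose per-SNP genotype-by-status tabulation equals
#' the given count tables exactly.  When several SNPs are supplied with
#' unequal genotyped totals, each SNP column is filled independently against
#' its own leading subjects and the remaining cells are missing; the joint
#' genotype distribution across SNPs is deliberately NOT reconstructed (only
#' marginals are published).
#'
#' @param panels A list of `genotype_count_table` objects (or a single one),
#'   each carrying its factor name via the `snp` attribute or the list names.
#' @param case_group Group tag assigned to the case subjects.
#' @return A `genotype_dataset` with `max` control and case totals across
#'   panels as subjects.
#' @export
from_marginal_counts <- function(panels, case_group = "case") {
  if (inherits(panels, "genotype_count_table")) panels <- list(panels)
  nm <- vapply(seq_along(panels), function(i) {
    attr(panels[[i]], "snp") %||% names(panels)[i] %||% paste0("SNP", i)
  }, character(1))
  for (p in panels) {
    if (any(p < 0)) stop("negative counts are not allowed", call. = FALSE)
  }
  n_ctrl <- vapply(panels, function(p) sum(p[, "control"]), numeric(1))
  n_case <- vapply(panels, function(p) sum(p[, "case"]), numeric(1))
  Nc <- as.integer(max(n_ctrl, 0)); Nk <- as.integer(max(n_case, 0))
  n <- Nc + Nk
  values <- matrix(NA_integer_, n, length(panels), dimnames = list(NULL, nm))
  for (j in seq_along(panels)) {
    p <- panels[[j]]
    ctrl <- rep(0:2, p[, "control"])
    cas <- rep(0:2, p[, "case"])
    if (length(ctrl)) values[seq_along(ctrl), j] <- ctrl
    if (length(cas)) values[Nc + seq_along(cas), j] <- cas
  }
  defs <- lapply(seq_along(panels), function(j) {
    factor_definition(nm[j], "snp", labels = rownames(panels[[j]]))
  })
  genotype_dataset(
    values,
    status = rep(c(0L, 1L), c(Nc, Nk)),
    subjects = c(sprintf("C%04d", seq_len(Nc)), sprintf("K%04d", seq_len(Nk))),
    group = rep(c("control", case_group), c(Nc, Nk)),
    factors = defs
  )
}
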